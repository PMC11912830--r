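# Binned IBD histograms and the Poisson composite log-likelihood over all
# within- and cross-sample-set pairs.

#' Number of haplotype pairs between or within sample sets
#'
#' Cross-set: `4 * n1 * n2` (each diploid contributes two haplotypes). Within
#' a set the default counts inter-individual haplotype pairs only,
#' `2 n (n - 1)`, matching empirical IBD callers which do not report segments
#' within an individual; `within_individual = TRUE` gives the literal
#' `choose(2n, 2)`.
#'
#' @param n1 diploid count of the (first) set.
#' @param n2 diploid count of the second set, or `NULL` for a within-set count.
#' @param within_individual include within-individual haplotype pairs in the
#'   within-set count.
#' @return integer number of haplotype pairs.
#' @export
haplotype_pair_count <- function(n1, n2 = NULL, within_individual = FALSE) {
  if (n1 < 1 || (!is.null(n2) && n2 < 1)) stop_domain("counts must be >= 1")
  if (!is.null(n2)) return(4 * n1 * n2)
  if (within_individual) choose(2 * n1, 2) else 2 * n1 * (n1 - 1)
}

#' Bin IBD segments into a chromosome-resolved histogram
#'
#' Assigns each segment to its sample-set pair (via the individual ids in the
#' scheme), left-closed right-open length bin, and chromosome. Segments whose
#' length falls outside `[lmin, lmax)` are excluded and counted in the
#' `n_below` / `n_above` fields.
#'
#' @param segments data.frame with columns `id1`, `id2`, `chrom`, `length_cm`.
#' @param scheme a [sampling_scheme()] carrying individual ids.
#' @param grid a [length_grid()].
#' @param chrom_map a [chromosome_map()]; unknown chromosome labels are an error.
#' @return an object of class `ibd_histogram`: counts array
#'   (set pair x length bin x chromosome) plus bookkeeping.
#' @export
bin_segments <- function(segments, scheme, grid, chrom_map) {
  stopifnot(inherits(scheme, "sampling_scheme"), inherits(grid, "length_grid"))
  if (is.null(scheme$ids)) stop_domain("scheme must carry individual ids to assign segments")
  req <- c("id1", "id2", "chrom", "length_cm")
  if (!all(req %in% names(segments)))
    stop_domain("segments must have columns: ", paste(req, collapse = ", "))
  if (nrow(segments) > 0 && any(segments$length_cm <= 0))
    stop_domain("segment lengths must be > 0")
  chroms <- names(chrom_map)
  unknown <- setdiff(unique(as.character(segments$chrom)), chroms)
  if (length(unknown) > 0)
    stop_domain("unknown chromosome label(s): ", paste(unknown, collapse = ", "))
  set_of <- setNames(rep(seq_len(scheme$n_sets), scheme$sizes), unlist(scheme$ids))
  ids <- unique(c(as.character(segments$id1), as.character(segments$id2)))
  missing_ids <- setdiff(ids, names(set_of))
  if (length(missing_ids) > 0)
    stop_domain("individual id(s) not in the sampling scheme: ",
                paste(head(missing_ids, 5), collapse = ", "))
  pairs <- scheme_pairs(scheme)
  counts <- array(0L, dim = c(nrow(pairs), grid$nbin, length(chroms)),
                  dimnames = list(pairs$label, NULL, chroms))
  n_below <- 0L; n_above <- 0L
  if (nrow(segments) > 0) {
    si <- set_of[as.character(segments$id1)]
    sj <- set_of[as.character(segments$id2)]
    lab <- paste(pmin(si, sj), pmax(si, sj), sep = "|")
    bin <- findInterval(segments$length_cm, grid$breaks_cm)
    below <- bin < 1L
    above <- bin > grid$nbin
    n_below <- sum(below); n_above <- sum(above)
    keep <- !(below | above)
    if (any(keep)) {
      tab <- table(factor(lab[keep], levels = pairs$label),
                   factor(bin[keep], levels = seq_len(grid$nbin)),
                   factor(as.character(segments$chrom)[keep], levels = chroms))
      counts <- counts + array(as.integer(tab), dim = dim(counts),
                               dimnames = dimnames(counts))
    }
  }
  structure(list(counts = counts, grid = grid, pairs = pairs[, c("i", "j", "label")],
                 chroms = chroms, n_below = n_below, n_above = n_above),
            class = "ibd_histogram")
}

#' @export
print.ibd_histogram <- function(x, ...) {
  cat(sprintf("IBD histogram: %d set pair(s) x %d bins x %d chromosome(s), %d segments\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3], sum(x$counts)))
  if (x$n_below + x$n_above > 0)
    cat(sprintf("  excluded: %d below %g cM, %d at/above %g cM\n",
                x$n_below, x$grid$lmin_cm, x$n_above, x$grid$lmax_cm))
  invisible(x)
}

# Assemble an ibd_histogram directly from a counts array (used by the
# model-based sampler and by tests).
new_ibd_histogram <- function(counts, grid, scheme, chroms) {
  pairs <- scheme_pairs(scheme)
  stopifnot(dim(counts)[1] == nrow(pairs), dim(counts)[2] == grid$nbin,
            dim(counts)[3] == length(chroms))
  dimnames(counts) <- list(pairs$label, NULL, chroms)
  structure(list(counts = counts, grid = grid, pairs = pairs[, c("i", "j", "label")],
                 chroms = chroms, n_below = 0L, n_above = 0L),
            class = "ibd_histogram")
}

# Counts per (pair x bin) summed over a chromosome index multiset.
hist_pair_counts <- function(hist, chrom_idx = seq_along(hist$chroms)) {
  apply(hist$counts[, , chrom_idx, drop = FALSE], c(1, 2), sum)
}

#' Poisson log-likelihood of one sample-set pair
#'
#' Sum over length bins of `n_k log(lambda_k) - lambda_k` with
#' `lambda_k = nhap * fN(mid_k) * delta_l` (error-corrected when an error
#' model is supplied). The data-only `log n_k!` term is omitted. A bin with
#' zero expected rate but nonzero count yields `-Inf` with a warning.
#'
#' @param hist an [bin_segments()] histogram (or sampler output).
#' @param i,j sample-set indices (i <= j; i == j for within-set sharing).
#' @param ne Ne trajectory covering `G + max(sampling times)` generations.
#' @param scheme the [sampling_scheme()].
#' @param chrom_map the [chromosome_map()] restricted to `hist$chroms`.
#' @param error_model optional [error_model()] for detection-error correction.
#' @param within_individual see [haplotype_pair_count()].
#' @return log-likelihood (scalar).
#' @export
pair_loglik <- function(hist, i, j, ne, scheme, chrom_map, error_model = NULL,
                        within_individual = FALSE) {
  validate_ne_trajectory(ne)
  lab <- paste(min(i, j), max(i, j), sep = "|")
  if (!lab %in% hist$pairs$label) stop_domain("pair ", lab, " missing from histogram")
  lens <- chrom_map[hist$chroms]
  if (anyNA(lens)) stop_domain("chromosome map does not cover the histogram's chromosomes")
  ctx <- rate_context(hist$grid, lens, error_model)
  counts <- hist_pair_counts(hist)[lab, ]
  nhap <- if (i == j) haplotype_pair_count(scheme$sizes[i],
                                           within_individual = within_individual)
          else haplotype_pair_count(scheme$sizes[i], scheme$sizes[j])
  pair_rates_core(counts, nhap, scheme$times[min(i, j)], scheme$times[max(i, j)],
                  ne, ctx)$loglik
}

#' Composite log-likelihood over all sample-set pairs
#'
#' Sum of [pair_loglik()] over the `n + n(n-1)/2` within- and cross-set pairs.
#'
#' @inheritParams pair_loglik
#' @param per_pair return the vector of per-pair contributions instead of the sum.
#' @return scalar log-likelihood, or a named vector if `per_pair = TRUE`.
#' @export
composite_loglik <- function(hist, ne, scheme, chrom_map, error_model = NULL,
                             within_individual = FALSE, per_pair = FALSE) {
  validate_ne_trajectory(ne)
  pairs <- scheme_pairs(scheme, within_individual)
  if (!all(pairs$label %in% hist$pairs$label))
    stop_domain("histogram is missing sample-set pair(s): ",
                paste(setdiff(pairs$label, hist$pairs$label), collapse = ", "))
  lens <- chrom_map[hist$chroms]
  if (anyNA(lens)) stop_domain("chromosome map does not cover the histogram's chromosomes")
  ctx <- rate_context(hist$grid, lens, error_model)
  cmat <- hist_pair_counts(hist)
  ll <- vapply(seq_len(nrow(pairs)), function(p) {
    pair_rates_core(cmat[pairs$label[p], ], pairs$nhap[p],
                    pairs$ti[p], pairs$tj[p], ne, ctx)$loglik
  }, numeric(1))
  names(ll) <- pairs$label
  if (per_pair) ll else sum(ll)
}

#' Expected bin counts for every sample-set pair
#'
#' The observation model's mean: `nhap * fN(mid_k) * delta_l` per pair and bin
#' (error-corrected when a model is given), summed over the chromosomes of
#' `chrom_map`. Useful for fit diagnostics (observed vs expected counts).
#'
#' @inheritParams pair_loglik
#' @param grid a [length_grid()].
#' @return matrix (set pairs x bins) of expected counts.
#' @export
expected_bin_counts <- function(ne, scheme, grid, chrom_map, error_model = NULL,
                                within_individual = FALSE) {
  validate_ne_trajectory(ne)
  pairs <- scheme_pairs(scheme, within_individual)
  ctx <- rate_context(grid, as.numeric(chrom_map), error_model)
  out <- t(vapply(seq_len(nrow(pairs)), function(p) {
    pair_rates_core(NULL, pairs$nhap[p], pairs$ti[p], pairs$tj[p],
                    ne, ctx)$lambda
  }, numeric(grid$nbin)))
  rownames(out) <- pairs$label
  out
}
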