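# Domain containers: Ne trajectories, chromosome maps, sampling schemes,
# length grids. Deliberately lightweight (validated base-R structures), in the
# style of ape/vegan rather than S4.

#' Validate an Ne trajectory
#'
#' A trajectory is a plain numeric vector of diploid effective sizes, one per
#' discrete generation backward in time. Index 1 corresponds to generation 0,
#' the generation of the most recent sample set.
#'
#' @param ne numeric vector of effective sizes.
#' @return the validated vector, invisibly unchanged.
#' @export
validate_ne_trajectory <- function(ne) {
  if (!is.numeric(ne) || length(ne) < 1L)
    stop_domain("Ne trajectory must be a non-empty numeric vector")
  if (!all(is.finite(ne)) || any(ne <= 1))
    stop_domain("all Ne values must be finite and > 1")
  invisible(ne)
}

#' Construct a chromosome map
#'
#' @param lengths_morgan numeric vector of genetic lengths in Morgans.
#' @param labels chromosome labels; defaults to names of `lengths_morgan`.
#' @return named numeric vector of class `chromosome_map`.
#' @export
chromosome_map <- function(lengths_morgan, labels = names(lengths_morgan)) {
  if (is.null(labels)) labels <- as.character(seq_along(lengths_morgan))
  if (anyDuplicated(labels)) stop_domain("chromosome labels must be unique")
  if (!all(is.finite(lengths_morgan)) || any(lengths_morgan <= 0))
    stop_domain("all chromosome lengths must be positive and finite")
  structure(as.numeric(lengths_morgan), names = as.character(labels),
            class = c("chromosome_map", "numeric"))
}

#' Human autosome genetic map
#'
#' Approximate sex-averaged genetic lengths of the 22 human autosomes
#' (HapMap-scale values, in Morgans; ~35.5 Morgans total). Used as the default
#' map for simulations and as a template for empirical analyses.
#'
#' @return a [chromosome_map()] with entries `chr1` .. `chr22`.
#' @export
human_autosome_map <- function() {
  cm <- c(286.3, 268.6, 223.4, 214.6, 204.1, 192.1, 187.4, 168.0,
          166.4, 181.0, 158.2, 174.7, 125.8, 120.8, 141.9, 134.0,
          128.5, 117.5, 107.8, 108.3, 62.8, 74.1)
  chromosome_map(cm_to_morgan(cm), labels = paste0("chr", 1:22))
}

#' Construct a sampling scheme
#'
#' Describes the time-stratified sample sets: each set has an integer sampling
#' time in generations (0 = most recent set, increasing backward in time) and
#' a diploid sample count. Optionally carries the member individual ids, which
#' [bin_segments()] uses to assign segments to set pairs.
#'
#' @param times integer sampling times, strictly increasing, `times[1] >= 0`.
#' @param sizes diploid counts per set (>= 1).
#' @param ids optional list of character vectors of individual ids per set.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(times, sizes, ids = NULL) {
  times <- as.integer(times); sizes <- as.integer(sizes)
  if (length(times) != length(sizes) || length(times) < 1L)
    stop_domain("times and sizes must have equal positive length")
  if (any(times < 0L)) stop_domain("sampling times must be non-negative")
  if (is.unsorted(times, strictly = TRUE))
    stop_domain("sampling times must be distinct and sorted increasing")
  if (any(sizes < 1L)) stop_domain("sample sizes must be >= 1")
  if (!is.null(ids)) {
    if (length(ids) != length(times) ||
        !all(lengths(ids) == sizes))
      stop_domain("ids must be a list with sizes[i] ids for set i")
    if (anyDuplicated(unlist(ids))) stop_domain("individual ids must be unique")
  }
  structure(list(times = times, sizes = sizes, ids = ids, n_sets = length(times)),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("sampling scheme: %d set(s)\n", x$n_sets))
  cat(sprintf("  t=%d gen: n=%d diploids\n", x$times, x$sizes), sep = "")
  invisible(x)
}

# Enumerate the n + n(n-1)/2 sample-set pairs in canonical order (all within
# pairs first, then cross pairs i<j), with their haplotype-pair counts.
scheme_pairs <- function(scheme, within_individual = FALSE) {
  n <- scheme$n_sets
  within <- data.frame(i = seq_len(n), j = seq_len(n))
  cross <- if (n > 1L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    data.frame(i = idx[, "row"], j = idx[, "col"])
  } else data.frame(i = integer(), j = integer())
  pairs <- rbind(within, cross)
  pairs$ti <- scheme$times[pairs$i]
  pairs$tj <- scheme$times[pairs$j]
  pairs$nhap <- mapply(function(i, j) {
    if (i == j) haplotype_pair_count(scheme$sizes[i],
                                     within_individual = within_individual)
    else haplotype_pair_count(scheme$sizes[i], scheme$sizes[j])
  }, pairs$i, pairs$j)
  pairs$label <- paste(pairs$i, pairs$j, sep = "|")
  pairs
}

#' Construct an IBD length grid
#'
#' Equally spaced, left-closed right-open length bins. Arguments are in cM (the
#' unit of segment tables); internally midpoints and bin width are also carried
#' in Morgans.
#'
#' @param lmin_cm,lmax_cm grid range in cM. Defaults 8 and 20: segments below
#'   8 cM are unreliable in imputed ancient-DNA IBD calls, segments above
#'   20 cM are dominated by close kin.
#' @param bin_cm bin width in cM (default 0.25).
#' @return an object of class `length_grid`.
#' @export
length_grid <- function(lmin_cm = 8, lmax_cm = 20, bin_cm = 0.25) {
  if (!(lmin_cm < lmax_cm)) stop_domain("lmin must be < lmax")
  if (bin_cm <= 0) stop_domain("bin width must be > 0")
  nbin <- round((lmax_cm - lmin_cm) / bin_cm)
  if (abs(nbin * bin_cm - (lmax_cm - lmin_cm)) > 1e-9)
    stop_domain("grid range must be an integer multiple of the bin width")
  breaks_cm <- lmin_cm + bin_cm * (0:nbin)
  mids_cm <- breaks_cm[-1] - bin_cm / 2
  structure(list(
    lmin_cm = lmin_cm, lmax_cm = lmax_cm, bin_cm = bin_cm, nbin = as.integer(nbin),
    breaks_cm = breaks_cm, mids_cm = mids_cm,
    mids_morgan = cm_to_morgan(mids_cm), bin_morgan = cm_to_morgan(bin_cm)),
    class = "length_grid")
}

#' @export
print.length_grid <- function(x, ...) {
  cat(sprintf("length grid: [%g, %g) cM, %d bins of %g cM\n",
              x$lmin_cm, x$lmax_cm, x$nbin, x$bin_cm))
  invisible(x)
}
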