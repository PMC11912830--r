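# Synthetic data: demographic scenario builders, the fast model-based Poisson
# IBD sampler (exact inverse of the observation model), and the R interface to
# the independent pairwise coalescent-with-recombination oracle.

#' Build a demographic scenario trajectory
#'
#' Three benchmark demographies on the integer generation grid:
#' \describe{
#'   \item{constant}{constant size (default 25,000).}
#'   \item{bottleneck}{constant `pre_ne` (50,000) up to the bottleneck
#'     generation (30), an instantaneous drop to `post_ne` (5,000) at that
#'     generation, then exponential regrowth to `regrow_ne` (100,000) at
#'     generation 0.}
#'   \item{growth}{constant `start_ne` (10,000) before `onset` (50 generations
#'     ago), then exponential growth to `end_ne` (250,000) at generation 0.}
#' }
#'
#' @param scenario one of `"constant"`, `"bottleneck"`, `"growth"`.
#' @param Tmax trajectory length in generations (must cover the change points).
#' @param constant_ne,pre_ne,post_ne,bottleneck_time,regrow_ne,start_ne,end_ne,onset
#'   scenario parameters (defaults above).
#' @return numeric Ne trajectory of length `Tmax` (index 1 = generation 0).
#' @export
build_scenario <- function(scenario = c("constant", "bottleneck", "growth"),
                           Tmax, constant_ne = 25000,
                           pre_ne = 50000, post_ne = 5000, bottleneck_time = 30,
                           regrow_ne = 1e5, start_ne = 10000, end_ne = 250000,
                           onset = 50) {
  scenario <- match.arg(scenario)
  Tmax <- as.integer(Tmax)
  t <- 0:(Tmax - 1L)
  ne <- switch(scenario,
    constant = rep(constant_ne, Tmax),
    bottleneck = {
      if (Tmax <= bottleneck_time)
        stop_domain("Tmax must exceed the bottleneck time")
      ifelse(t > bottleneck_time, pre_ne,
             regrow_ne * (post_ne / regrow_ne)^(t / bottleneck_time))
    },
    growth = {
      if (Tmax <= onset) stop_domain("Tmax must exceed the growth onset")
      ifelse(t >= onset, start_ne,
             end_ne * (start_ne / end_ne)^(t / onset))
    })
  validate_ne_trajectory(ne)
  ne
}

# Default individual ids for a scheme lacking them: set1_01, set1_02, ...
scheme_with_ids <- function(scheme) {
  if (!is.null(scheme$ids)) return(scheme)
  scheme$ids <- lapply(seq_len(scheme$n_sets), function(i)
    sprintf("set%d_%02d", i, seq_len(scheme$sizes[i])))
  scheme
}

#' Sample IBD segment counts from the observation model
#'
#' Draws, for every sample-set pair, length bin and chromosome, a Poisson
#' count with mean `nhap * fN_chrom(midpoint) * delta_l` — the exact inverse
#' of the binned Poisson observation model. Optionally expands counts to
#' segment records (lengths at bin midpoints, individual pairs drawn
#' uniformly), e.g. to feed [inject_errors()].
#'
#' @inheritParams expected_ibd_density
#' @param scheme a [sampling_scheme()].
#' @param grid a [length_grid()].
#' @param seed RNG seed.
#' @param as_segments return a segment data.frame instead of a histogram.
#' @param within_individual see [haplotype_pair_count()].
#' @return an `ibd_histogram`, or a data.frame of segments
#'   (`id1`, `id2`, `chrom`, `length_cm`) when `as_segments = TRUE`.
#' @export
sample_ibd_from_model <- function(ne, scheme, grid, chrom_map, G = NULL,
                                  seed = NULL, as_segments = FALSE,
                                  within_individual = FALSE) {
  validate_ne_trajectory(ne)
  if (!is.null(G)) {
    need <- as.integer(G) + max(scheme$times)
    if (length(ne) < need) stop_domain("trajectory too short: need length >= ", need)
    ne <- ne[seq_len(need)]
  }
  scheme <- scheme_with_ids(scheme)
  pairs <- scheme_pairs(scheme, within_individual)
  chroms <- names(chrom_map)
  counts <- array(0L, dim = c(nrow(pairs), grid$nbin, length(chroms)))
  with_seed(seed, {
    for (ci in seq_along(chroms)) {
      ctx <- rate_context(grid, chrom_map[ci])
      for (p in seq_len(nrow(pairs))) {
        lam <- pair_rates_core(NULL, pairs$nhap[p], pairs$ti[p], pairs$tj[p],
                               ne, ctx)$lambda
        counts[p, , ci] <- rpois(grid$nbin, lam)
      }
    }
    hist <- new_ibd_histogram(counts, grid, scheme, chroms)
    if (as_segments) expand_hist_to_segments(hist, scheme) else hist
  })
}

# Expand histogram counts to per-segment records; individual pairs are drawn
# uniformly among the set pair's inter-individual pairs.
expand_hist_to_segments <- function(hist, scheme) {
  scheme <- scheme_with_ids(scheme)
  pairs <- scheme_pairs(scheme)
  recs <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$i[p]; j <- pairs$j[p]
    for (ci in seq_along(hist$chroms)) {
      n_bin <- hist$counts[p, , ci]
      tot <- sum(n_bin)
      if (tot == 0) next
      if (i == j) {
        a <- sample(scheme$ids[[i]], tot, replace = TRUE)
        b <- vapply(a, function(x) sample(setdiff(scheme$ids[[i]], x), 1L), character(1))
      } else {
        a <- sample(scheme$ids[[i]], tot, replace = TRUE)
        b <- sample(scheme$ids[[j]], tot, replace = TRUE)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        id1 = a, id2 = b, chrom = hist$chroms[ci],
        length_cm = rep(hist$grid$mids_cm, n_bin), stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(id1 = character(), id2 = character(),
                      chrom = character(), length_cm = numeric()))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Pairwise coalescent-with-recombination oracle
#'
#' Simulates the ancestry of two haplotypes sampled `dt` generations apart on
#' a single chromosome of length `L` Morgans, backward in discrete
#' generations: ancestral material is tracked as intervals; each meiosis
#' scatters recombination breakpoints as a Poisson process at rate 1 per
#' Morgan, splitting a lineage's material between the two parental
#' haplotypes of a uniformly drawn parent; lineages landing on the same
#' haplotype merge (pairwise coalescence probability `1/(2 Ne[g])`). An IBD
#' segment is a maximal interval over which the two sampled haplotypes share
#' their most recent common ancestor at the same coalescence event. The
#' engine is independent of the model's product factorization and serves as
#' its verification oracle.
#'
#' @param ne Ne trajectory (index 1 = generation 0); also sets the simulation
#'   horizon: coalescences beyond `length(ne) - 1` generations are not
#'   reported (compare against [expected_ibd_density()] with the same
#'   trajectory).
#' @param dt sampling-time difference in generations (>= 0).
#' @param L chromosome length in Morgans.
#' @param reps number of independent replicate pairs.
#' @param seed RNG seed.
#' @return list of length `reps`; each element a numeric vector of IBD
#'   segment lengths in Morgans (possibly empty).
#' @export
simulate_pair_ibd <- function(ne, dt, L, reps, seed = NULL) {
  validate_ne_trajectory(ne)
  stopifnot(dt >= 0, L > 0, reps >= 1)
  if (dt >= length(ne)) stop_domain("dt beyond trajectory horizon")
  with_seed(seed, sim_pair_ibd_cpp(as.numeric(ne), as.integer(dt),
                                   as.numeric(L), as.integer(reps)))
}

#' Bin oracle replicates into mean counts per length bin
#'
#' @param sims output of [simulate_pair_ibd()].
#' @param grid a [length_grid()].
#' @return data.frame with bin midpoints (cM), mean counts per replicate and
#'   the Monte-Carlo standard error of the mean.
#' @export
bin_pair_sim <- function(sims, grid) {
  reps <- length(sims)
  counts <- matrix(0L, reps, grid$nbin)
  for (r in seq_len(reps)) {
    l_cm <- morgan_to_cm(sims[[r]])
    b <- findInterval(l_cm, grid$breaks_cm)
    b <- b[b >= 1L & b <= grid$nbin]
    if (length(b)) counts[r, ] <- tabulate(b, grid$nbin)
  }
  m <- colMeans(counts)
  se <- apply(counts, 2, stats::sd) / sqrt(reps)
  data.frame(mid_cm = grid$mids_cm, mean = m, se = se)
}
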