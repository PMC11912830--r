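# Coalescent expectations for IBD segment length densities between temporally
# offset haplotype pairs, and the TMRCA posterior for an observed segment.
#
# Conventions: a single global integer generation clock g with 0 at the most
# recent sample set; a pair sampled at (ti, tj) coalescing at generation
# g >= max(ti, tj) has total branch length t* = (g - ti) + (g - tj), which is
# 2t - dt when t is measured from the younger sample. All lengths in Morgans.

#' Expected chromosome segment count density after t* meioses
#'
#' Density (per Morgan) of the expected number of segments of length `l` into
#' which a chromosome of genetic length `L` is cut after a total branch length
#' of `tstar` meioses: `2 t* exp(-t* l)` for the two chromosome-end segments
#' plus `(L - l) t*^2 exp(-t* l)` for interior segments. Integrating over
#' `l` in (0, L] gives `1 + t* L` segments; integrating `l` times the density
#' recovers the chromosome length `L`.
#'
#' @param l segment length in Morgans, `0 < l <= L`.
#' @param tstar total branch length in generations (> 0).
#' @param L chromosome genetic length in Morgans.
#' @return expected segments per Morgan (vectorized over `l`).
#' @export
segment_count_density <- function(l, tstar, L) {
  if (any(tstar <= 0)) stop_domain("tstar must be > 0")
  if (any(l <= 0) || any(l > L)) stop_domain("require 0 < l <= L")
  e <- exp(-tstar * l)
  2 * tstar * e + (L - l) * tstar^2 * e
}

# Unvalidated vectorized version used by the rate machinery; tstar = 0 (a pair
# coalescing into the older sample itself at dt = 0) contributes zero density.
fk_density <- function(l, tstar, L) {
  e <- exp(-tstar * l)
  out <- 2 * tstar * e + (L - l) * tstar^2 * e
  out[tstar <= 0 | l > L] <- 0
  out
}

# Survival-product coalescent probabilities phi(g) for g = gmin..gmax on the
# global clock, gmin = max(ti, tj). The g = gmin term has an empty survival
# product (coalescence into the older sample's own generation is included,
# consistent with the summation's lower limit); for g > gmin the survival
# product runs over i = gmin..g-1, so that the pmf sums to one over an
# unbounded horizon (constant Ne gives the geometric (1/2Ne)(1-1/2Ne)^(g-gmin)).
phi_vector <- function(gmin, gmax, ne) {
  idx <- (gmin:gmax) + 1L            # R indices into ne (generation 0 -> 1)
  rate <- 1 / (2 * ne[idx])
  surv <- cumprod(c(1, 1 - rate[-length(rate)]))
  rate * surv
}

#' Single-locus coalescent probability for a temporally offset pair
#'
#' Probability that two lineages sampled at generations `ti` and `tj` coalesce
#' exactly at global generation `g` under the piecewise trajectory `ne`:
#' `1/(2 Ne[g])` times the product of `(1 - 1/(2 Ne[i]))` over
#' `i = max(ti,tj) .. g-1` (empty product at `g = max(ti,tj)`), a proper
#' probability mass over `g` for any bounded trajectory. For constant Ne and
#' `ti = tj = 0` this is the geometric `(1/2Ne) (1 - 1/2Ne)^g`.
#'
#' @param g global generation(s), `g >= max(ti, tj)`, `g < length(ne)`.
#' @param ti,tj sampling times in generations (0 = most recent set).
#' @param ne Ne trajectory (numeric vector, index 1 = generation 0).
#' @return coalescence probability (vectorized over `g`).
#' @export
coalescent_pmf <- function(g, ti, tj, ne) {
  validate_ne_trajectory(ne)
  gmin <- max(ti, tj)
  if (any(g < gmin))
    stop_domain("coalescence impossible before both lineages exist (g < max(ti, tj))")
  if (any(g >= length(ne)))
    stop_domain("g beyond the trajectory horizon")
  phi <- phi_vector(gmin, max(g), ne)
  phi[g - gmin + 1L]
}

#' Expected IBD segment length density for a haplotype pair
#'
#' Sums `fK(l, t*(g)) * phi(g)` over coalescence generations
#' `g = max(ti,tj) .. max(ti,tj) + G - 1` and over all chromosomes in the map
#' (chromosomes shorter than `l` contribute nothing). The result is the
#' expected number of IBD segments per Morgan per haplotype pair, genome-wide.
#'
#' @param l segment length(s) in Morgans.
#' @param ti,tj sampling times in generations.
#' @param ne Ne trajectory; must cover `max(ti,tj) + G` generations.
#' @param chrom_map a [chromosome_map()].
#' @param G number of coalescence generations summed per pair; `NULL` uses the
#'   whole remaining trajectory.
#' @return expected segments per Morgan (vectorized over `l`).
#' @export
expected_ibd_density <- function(l, ti, tj, ne, chrom_map, G = NULL) {
  validate_ne_trajectory(ne)
  if (any(l <= 0)) stop_domain("l must be > 0")
  gmin <- max(ti, tj)
  gmax <- if (is.null(G)) length(ne) - 1L else gmin + as.integer(G) - 1L
  if (!is.null(G) && G < 1L) stop_domain("G must be >= 1")
  if (gmax > length(ne) - 1L)
    stop_domain("trajectory too short for the requested horizon")
  coefs <- chrom_bin_coefs(chrom_map, l)
  pair_density(l, ti, tj, ne, coefs, gmin, gmax)
}

#' Closed-form IBD density for a constant population size
#'
#' Continuous-time closed form of the expected IBD segment length density for
#' a pair of haplotypes sampled `dt` generations apart in a population of
#' constant size `ne_const`, obtained by integrating the segment-count density
#' against an exponential coalescent density from `dt` to infinity:
#' \deqn{e^{-l\Delta t}\frac{8N_e B + 2\Delta t A B + (L-l)\Delta t^2 A^2}{A^3},}
#' with \eqn{A = 1 + 4 N_e l}, \eqn{B = 1 + 4 N_e L}. (The sign of the last
#' term follows from the defining integral; see the methods vignette.)
#'
#' @param l segment length(s) in Morgans, `l <= L`.
#' @param dt sampling-time difference in generations (>= 0).
#' @param ne_const constant diploid effective size (> 0).
#' @param L chromosome length in Morgans.
#' @return expected segments per Morgan for one chromosome (vectorized over `l`).
#' @export
constant_ne_density <- function(l, dt, ne_const, L) {
  if (ne_const <= 0 || dt < 0 || L <= 0) stop_domain("negative or zero inputs")
  if (any(l <= 0) || any(l > L)) stop_domain("require 0 < l <= L")
  A <- 1 + 4 * ne_const * l
  B <- 1 + 4 * ne_const * L
  exp(-l * dt) / A^3 * (8 * ne_const * B + 2 * dt * A * B + (L - l) * dt^2 * A^2)
}

#' Erlang-2 IBD length density given the coalescence generation
#'
#' Edge-free approximation to the segment length density around a focal
#' marker: the distance to the next recombination on each side of the marker
#' is exponential with rate `t*`, giving `(t*)^2 l exp(-t* l)` with
#' `t* = (g - ti) + (g - tj)`.
#'
#' @param l segment length(s) in Morgans.
#' @param g global coalescence generation.
#' @param ti,tj sampling times in generations.
#' @return probability density over `l` (integrates to 1 on (0, Inf)).
#' @export
erlang2_length_density <- function(l, g, ti, tj) {
  tstar <- (g - ti) + (g - tj)
  if (any(tstar <= 0)) stop_domain("total branch length must be > 0")
  if (any(l <= 0)) stop_domain("l must be > 0")
  tstar^2 * l * exp(-tstar * l)
}

#' Posterior distribution of the TMRCA of an IBD segment
#'
#' Given an inferred trajectory, applies Bayes' theorem over the discrete
#' coalescence generations: the posterior mass at generation `g` is
#' proportional to the Erlang-2 length density at `l` times the coalescent
#' probability of `g`. Coalescence at `g = max(ti,tj)` with `ti = tj` has zero
#' branch length and zero likelihood.
#'
#' @inheritParams expected_ibd_density
#' @param l observed segment length in Morgans (scalar).
#' @return a data.frame of class `tmrca_posterior` with columns `g` (global
#'   generation), `pmf` and `cdf`.
#' @export
tmrca_posterior <- function(l, ti, tj, ne, G = NULL) {
  validate_ne_trajectory(ne)
  if (length(l) != 1L || l <= 0) stop_domain("l must be a positive scalar")
  gmin <- max(ti, tj)
  gmax <- if (is.null(G)) length(ne) - 1L else gmin + as.integer(G) - 1L
  if (gmax > length(ne) - 1L)
    stop_domain("trajectory too short for the requested horizon")
  g <- gmin:gmax
  tstar <- (g - ti) + (g - tj)
  lik <- ifelse(tstar > 0, tstar^2 * l * exp(-tstar * l), 0)
  prior <- phi_vector(gmin, gmax, ne)
  w <- lik * prior
  tot <- sum(w)
  if (tot <= 0) stop_domain("degenerate trajectory: posterior mass is zero everywhere")
  out <- data.frame(g = g, pmf = w / tot, cdf = cumsum(w) / tot)
  class(out) <- c("tmrca_posterior", "data.frame")
  out
}

#' Quantiles of a TMRCA posterior
#'
#' @param posterior result of [tmrca_posterior()].
#' @param probs probabilities.
#' @return the smallest generations with cdf >= probs.
#' @export
tmrca_quantile <- function(posterior, probs = c(0.025, 0.5, 0.975)) {
  vapply(probs, function(p) posterior$g[which(posterior$cdf >= p)[1L]],
         numeric(1))
}
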