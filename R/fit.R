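# Penalized maximum-likelihood inference of the Ne trajectory: objective,
# analytic gradient, constant-Ne initialization, L-BFGS-B optimization,
# cross-validated curvature-penalty strength, chromosome bootstrap.

#' Penalized objective for a candidate trajectory
#'
#' `-composite_loglik + alpha * P1(log Ne) + beta * P2(log Ne, w)` where `P1`
#' is the curvature penalty, `P2` the decayed first-difference penalty and `w`
#' the [decay_weights()]. Both penalties act on the natural log of Ne.
#'
#' @inheritParams pair_loglik
#' @param alpha curvature penalty weight (>= 0).
#' @param beta first-difference penalty weight (>= 0, default 250).
#' @return list with `value` and its breakdown (`neg_loglik`, `pen_curvature`,
#'   `pen_diff`), which sum to `value`.
#' @export
ne_objective <- function(ne, hist, scheme, chrom_map, alpha, beta = 250,
                         error_model = NULL, within_individual = FALSE) {
  validate_ne_trajectory(ne)
  if (alpha < 0 || beta < 0) stop_domain("penalty weights must be >= 0")
  x <- log(ne)
  w <- decay_weights(length(ne) - 1L)
  nll <- -composite_loglik(hist, ne, scheme, chrom_map, error_model,
                           within_individual)
  p1 <- alpha * penalty_curvature(x)
  p2 <- beta * penalty_decayed_diff(x, w)
  list(value = nll + p1 + p2, neg_loglik = nll, pen_curvature = p1, pen_diff = p2)
}

# Build objective/gradient closures over x = log Ne for optim(). All data
# structures that do not depend on Ne are precomputed here.
make_objective <- function(hist, scheme, chrom_map, alpha, beta, Tmax,
                           error_model = NULL, within_individual = FALSE,
                           chrom_idx = seq_along(hist$chroms)) {
  pairs <- scheme_pairs(scheme, within_individual)
  lens <- chrom_map[hist$chroms]
  if (anyNA(lens)) stop_domain("chromosome map does not cover the histogram's chromosomes")
  lens <- as.numeric(lens)[chrom_idx]
  ctx <- rate_context(hist$grid, lens, error_model)
  cmat <- hist_pair_counts(hist, chrom_idx)
  w <- decay_weights(Tmax - 1L)
  eval_all <- function(x, want_grad) {
    ne <- exp(x)
    ll <- 0
    grad <- numeric(Tmax)
    for (p in seq_len(nrow(pairs))) {
      res <- pair_rates_core(cmat[pairs$label[p], ], pairs$nhap[p],
                             pairs$ti[p], pairs$tj[p], ne, ctx,
                             want_grad = want_grad)
      ll <- ll + res$loglik
      if (want_grad) grad <- grad + res$grad
    }
    val <- -ll + alpha * penalty_curvature(x) + beta * penalty_decayed_diff(x, w)
    if (!want_grad) return(val)
    g <- -grad + alpha * penalty_curvature_grad(x) +
      beta * penalty_decayed_diff_grad(x, w)
    list(value = val, grad = g)
  }
  list(
    fn = function(x) eval_all(x, FALSE),
    gr = function(x) eval_all(x, TRUE)$grad
  )
}

#' Constant-Ne maximum-likelihood estimate
#'
#' Maximizes the Poisson likelihood of the binned counts under the closed-form
#' constant-size density, over a single scalar Ne (optimized in log space,
#' box-bounded, starting from Ne = 1000). Used to initialize the trajectory
#' optimization and as a simple summary.
#'
#' @inheritParams pair_loglik
#' @param init starting value (default 1000).
#' @param lower,upper box bounds on Ne.
#' @return list with `estimate`, `loglik` and `convergence`.
#' @export
fit_constant_ne <- function(hist, scheme, chrom_map, error_model = NULL,
                            within_individual = FALSE, init = 1000,
                            lower = 10, upper = 1e8) {
  cmat <- hist_pair_counts(hist)
  if (sum(cmat) == 0)
    stop_domain("all-zero histogram: no segments to fit; check the length grid and input data")
  pairs <- scheme_pairs(scheme, within_individual)
  lens <- as.numeric(chrom_map[hist$chroms])
  ctx <- rate_context(hist$grid, lens, error_model)
  grid <- hist$grid
  rates_const <- function(ne_c, dt) {
    fN <- numeric(length(ctx$z_morgan))
    for (L in lens) {
      okl <- ctx$z_morgan <= L
      fN[okl] <- fN[okl] + constant_ne_density(ctx$z_morgan[okl], dt, ne_c, L)
    }
    ctx$fp_counts + as.vector(ctx$M %*% fN)
  }
  negll <- function(logne) {
    ne_c <- exp(logne)
    tot <- 0
    for (p in seq_len(nrow(pairs))) {
      lam <- pairs$nhap[p] * rates_const(ne_c, abs(pairs$ti[p] - pairs$tj[p]))
      n <- cmat[pairs$label[p], ]
      if (any(lam <= 0 & n > 0)) return(1e300)
      pos <- lam > 0
      tot <- tot - (sum(n[pos] * log(lam[pos])) - sum(lam))
    }
    tot
  }
  opt <- optim(log(init), negll, method = "L-BFGS-B",
               lower = log(lower), upper = log(upper))
  list(estimate = exp(opt$par), loglik = -opt$value, convergence = opt$convergence)
}

#' Initialize a trajectory around a constant estimate
#'
#' Adds i.i.d. Gaussian noise with standard deviation `ne_const / 20` to the
#' constant estimate (helping the optimizer explore beyond the flat start),
#' clipping at the lower optimization bound to stay positive.
#'
#' @param ne_const positive scalar.
#' @param Tmax trajectory length (generations).
#' @param seed RNG seed (reproducible draws); `NULL` uses the current stream.
#' @param lower clip bound (default 10).
#' @return numeric trajectory of length `Tmax`.
#' @export
initialize_trajectory <- function(ne_const, Tmax, seed = NULL, lower = 10) {
  if (ne_const <= 0) stop_domain("ne_const must be > 0")
  with_seed(seed, pmax(ne_const + rnorm(Tmax, 0, ne_const / 20), lower))
}

#' Fit an Ne trajectory by penalized maximum likelihood
#'
#' Box-bounded L-BFGS-B minimization of [ne_objective()] over `x = log Ne`
#' (bounds `Ne` in `[10, 1e8]`), using the analytic gradient of the Poisson
#' term and the quadratic penalties. The trajectory has length
#' `Tmax = G + max(sampling times)`; each pair's expected rate sums
#' coalescence generations from `max(ti, tj)` to the end of the trajectory.
#'
#' @inheritParams ne_objective
#' @param G coalescence horizon in generations beyond the oldest sample set
#'   (default 150; segments >= 8 cM carry negligible signal deeper).
#' @param seed seed for the initialization noise.
#' @param init optional explicit initial trajectory (overrides the
#'   constant-Ne + noise initialization).
#' @param lower,upper box bounds on Ne.
#' @param control passed to [stats::optim()] (defaults: `maxit = 3000`).
#' @return object of class `ne_fit`: `ne` (the fitted trajectory), `objective`
#'   and its breakdown, `convergence` (0 = converged), `iterations`, `alpha`,
#'   `beta`, `G`, `seed`, `init_constant`.
#' @export
fit_trajectory <- function(hist, scheme, chrom_map, alpha, beta = 250, G = 150,
                           seed = NULL, error_model = NULL, init = NULL,
                           within_individual = FALSE, lower = 10, upper = 1e8,
                           control = list()) {
  Tmax <- as.integer(G) + max(scheme$times)
  ne_const <- NA_real_
  if (is.null(init)) {
    ne_const <- fit_constant_ne(hist, scheme, chrom_map, error_model,
                                within_individual, lower = lower, upper = upper)$estimate
    init <- initialize_trajectory(ne_const, Tmax, seed, lower = lower)
  }
  if (length(init) != Tmax) stop_domain("init must have length G + max(times) = ", Tmax)
  obj <- make_objective(hist, scheme, chrom_map, alpha, beta, Tmax,
                        error_model, within_individual)
  x0 <- pmin(pmax(log(init), log(lower)), log(upper))
  ctrl <- modifyList(list(maxit = 3000L), control)
  opt <- optim(x0, obj$fn, obj$gr, method = "L-BFGS-B",
               lower = log(lower), upper = log(upper), control = ctrl)
  ne_hat <- exp(opt$par)
  brk <- ne_objective(ne_hat, hist, scheme, chrom_map, alpha, beta,
                      error_model, within_individual)
  structure(list(
    ne = ne_hat, objective = brk$value,
    breakdown = c(neg_loglik = brk$neg_loglik, pen_curvature = brk$pen_curvature,
                  pen_diff = brk$pen_diff),
    convergence = opt$convergence, message = opt$message,
    iterations = opt$counts, alpha = alpha, beta = beta, G = as.integer(G),
    seed = seed, init_constant = ne_const, initial_objective = obj$fn(x0)),
    class = "ne_fit")
}

#' @export
print.ne_fit <- function(x, ...) {
  cat(sprintf("Ne trajectory fit: %d generations, alpha=%g, beta=%g\n",
              length(x$ne), x$alpha, x$beta))
  cat(sprintf("  objective %.4f (neg. loglik %.4f), convergence %d\n",
              x$objective, x$breakdown["neg_loglik"], x$convergence))
  cat(sprintf("  Ne at t=0: %.0f; at t=%d: %.0f\n",
              x$ne[1], length(x$ne) - 1L, x$ne[length(x$ne)]))
  invisible(x)
}

#' Select the curvature penalty weight by chromosome cross-validation
#'
#' Leave-chromosomes-out cross-validation: chromosomes are shuffled into
#' `nfolds` folds; for each candidate `alpha` the trajectory is fit on the
#' training chromosomes and the composite log-likelihood of the held-out
#' chromosomes is evaluated. Summing over folds gives the held-out
#' log-likelihood of the whole genome (each chromosome left out exactly
#' once), a score whose scale does not depend on the number of folds. The
#' selected `alpha` is the LARGEST value whose summed held-out log-likelihood
#' is within `tol` (default 2) units of the best grid point, i.e.
#' regularization is pushed as high as the data tolerate without a
#' significant drop in goodness of fit.
#'
#' @inheritParams fit_trajectory
#' @param alphas candidate grid (default `10^(-2:4)`).
#' @param nfolds number of folds (default `min(11, #chromosomes)`).
#' @param tol tolerance in log-likelihood units (default 2).
#' @return list with `alpha` (selected), `cv` (data.frame of per-alpha summed
#'   held-out log-likelihoods) and `folds`.
#' @export
select_alpha <- function(hist, scheme, chrom_map, alphas = 10^(-2:4),
                         nfolds = NULL, beta = 250, G = 150, seed = NULL,
                         error_model = NULL, within_individual = FALSE,
                         tol = 2, control = list()) {
  nchrom <- length(hist$chroms)
  if (nchrom < 2)
    stop_domain("cross-validation needs >= 2 chromosomes; supply alpha manually")
  nfolds <- nfolds %||% min(11L, nchrom)
  perm <- with_seed(child_seed(seed, 1L), sample.int(nchrom))
  fold_of <- rep(seq_len(nfolds), length.out = nchrom)[order(perm)]
  Tmax <- as.integer(G) + max(scheme$times)
  held <- matrix(NA_real_, length(alphas), nfolds)
  for (f in seq_len(nfolds)) {
    train <- which(fold_of != f)
    test <- which(fold_of == f)
    train_hist <- subset_hist(hist, train)
    test_hist <- subset_hist(hist, test)
    for (a in seq_along(alphas)) {
      fit <- fit_trajectory(train_hist, scheme, chrom_map, alphas[a], beta, G,
                            seed = child_seed(seed, 100L + f),
                            error_model = error_model,
                            within_individual = within_individual,
                            control = control)
      held[a, f] <- composite_loglik(test_hist, fit$ne, scheme, chrom_map,
                                     error_model, within_individual)
    }
  }
  sum_held <- rowSums(held)
  ok <- sum_held >= max(sum_held) - tol
  alpha <- max(alphas[ok])
  list(alpha = alpha,
       cv = data.frame(alpha = alphas, heldout_loglik = sum_held),
       folds = fold_of)
}

# Restrict a histogram to a chromosome index multiset (indices may repeat for
# bootstrap replicates: duplicated chromosomes contribute duplicated counts).
subset_hist <- function(hist, chrom_idx) {
  counts <- hist$counts[, , chrom_idx, drop = FALSE]
  h <- hist
  h$counts <- counts
  h$chroms <- hist$chroms[chrom_idx]
  h
}

#' Chromosome bootstrap confidence envelope
#'
#' Resamples chromosome labels with replacement `reps` times; each replicate
#' rebuilds the counts and the effective chromosome multiset (a chromosome
#' drawn twice contributes its counts and its expected rates twice), refits
#' the trajectory with the same `alpha`, and the per-generation 2.5% / 97.5%
#' empirical percentiles over replicates form the envelope.
#'
#' @inheritParams fit_trajectory
#' @param reps number of bootstrap replicates (default 200).
#' @return object of class `ne_bootstrap`: `replicates` (reps x Tmax matrix),
#'   `ci_low`, `ci_high`, `seed`, `alpha`.
#' @export
bootstrap_ci <- function(hist, scheme, chrom_map, alpha, beta = 250, G = 150,
                         reps = 200, seed = NULL, error_model = NULL,
                         within_individual = FALSE, control = list()) {
  if (reps < 2) stop_domain("need at least 2 bootstrap replicates")
  nchrom <- length(hist$chroms)
  Tmax <- as.integer(G) + max(scheme$times)
  lens_full <- as.numeric(chrom_map[hist$chroms])
  mat <- matrix(NA_real_, reps, Tmax)
  for (r in seq_len(reps)) {
    idx <- with_seed(child_seed(seed, r), sample.int(nchrom, replace = TRUE))
    # duplicated chromosome labels are disambiguated so chromosome_map lookup
    # is by position; rates use the multiset of lengths directly
    bh <- subset_hist(hist, idx)
    bmap <- chromosome_map(lens_full[idx], labels = paste0("bs", seq_along(idx)))
    bh$chroms <- names(bmap)
    dimnames(bh$counts)[[3]] <- names(bmap)
    fit <- fit_trajectory(bh, scheme, bmap, alpha, beta, G,
                          seed = child_seed(seed, 100000L + r),
                          error_model = error_model,
                          within_individual = within_individual,
                          control = control)
    mat[r, ] <- fit$ne
  }
  ci <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(replicates = mat, ci_low = ci[1, ], ci_high = ci[2, ],
                 seed = seed, alpha = alpha, reps = reps),
            class = "ne_bootstrap")
}

#' @export
print.ne_bootstrap <- function(x, ...) {
  cat(sprintf("chromosome bootstrap: %d replicates, alpha=%g\n", x$reps, x$alpha))
  invisible(x)
}
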