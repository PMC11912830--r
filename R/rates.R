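# Internal machinery turning a trajectory into expected bin rates and the
# analytic gradient of the Poisson composite log-likelihood with respect to
# log Ne. Chromosomes enter only through per-length aggregates, so a
# bootstrap-resampled chromosome multiset is handled by recomputing two
# vectors rather than looping over chromosomes.

# Per-length chromosome aggregates. For evaluation lengths l (Morgans) and a
# multiset of chromosome lengths L_c, the genome-wide segment-count density is
#   fK_sum(l, t*) = a(l) t* e^{-t* l} + b(l) t*^2 e^{-t* l}
# with a(l) = 2 * #{c : L_c >= l} and b(l) = sum_c max(L_c - l, 0).
chrom_bin_coefs <- function(lengths_morgan, mids_morgan) {
  L <- as.numeric(lengths_morgan)
  a <- vapply(mids_morgan, function(l) 2 * sum(L >= l), numeric(1))
  b <- vapply(mids_morgan, function(l) sum(pmax(L - l, 0)), numeric(1))
  list(a = a, b = b)
}

# Expected genome-wide IBD density at lengths l for one pair, summing
# coalescence generations gmin..gmax. Returns a vector over l.
pair_density <- function(l, ti, tj, ne, coefs, gmin, gmax) {
  g <- gmin:gmax
  tstar <- (g - ti) + (g - tj)
  phi <- phi_vector(gmin, gmax, ne)
  E <- exp(-outer(tstar, l))                      # (gens x lengths)
  u <- phi * tstar
  v <- phi * tstar^2
  keep <- tstar > 0
  as.vector(crossprod(E[keep, , drop = FALSE], u[keep])) * coefs$a +
    as.vector(crossprod(E[keep, , drop = FALSE], v[keep])) * coefs$b
}

# Pair-independent evaluation context for expected bin counts.
#
# Without an error model the theoretical density is evaluated directly at the
# grid midpoints: lambda_k = nhap * delta_l * fN(mid_k). With an error model
# the density is evaluated on an extended length lattice z (same 0.25 cM step,
# reaching `window` beyond the grid on both sides), passed through the
# detection-error convolution, and read off at the grid midpoints:
# lambda_k = nhap * (fp_counts_k + (M %*% fN_morgan(z))_k).
# `fp_scale` rescales the (genome-wide) false-positive rate when only a subset
# of the chromosome multiset is in play (cross-validation, bootstrap).
rate_context <- function(grid, lengths_morgan, error_model = NULL) {
  if (is.null(error_model)) {
    z_cm <- grid$mids_cm
    M <- diag(grid$bin_morgan, grid$nbin)
    fp_counts <- numeric(grid$nbin)
  } else {
    em <- error_model
    next_bins <- as.integer(round(em$window_cm / grid$bin_cm))
    z_cm <- seq(grid$lmin_cm - (next_bins - 0.5) * grid$bin_cm,
                grid$lmax_cm + (next_bins - 0.5) * grid$bin_cm,
                by = grid$bin_cm)
    pos <- z_cm > 0
    z_cm <- z_cm[pos]
    fp_scale <- if (is.null(em$fp_total_morgan)) 1
                else sum(lengths_morgan) / em$fp_total_morgan
    y <- grid$mids_cm
    if (em$sigma_cm > 0) {
      K <- outer(y, z_cm, function(yy, zz) {
        d <- yy - zz
        ifelse(abs(d) <= em$window_cm + 1e-9, dnorm(d, 0, em$sigma_cm), 0)
      })
      M0 <- K * rep(em$recall(z_cm), each = length(y)) * grid$bin_cm
    } else {
      M0 <- outer(y, z_cm, function(yy, zz) as.numeric(abs(yy - zz) < grid$bin_cm / 2)) *
        rep(em$recall(z_cm), each = length(y))
    }
    M <- grid$bin_cm * M0 / 100   # maps per-Morgan density on z to bin counts
    fp_counts <- grid$bin_cm * em$fp(y) * fp_scale
  }
  list(z_cm = z_cm, z_morgan = cm_to_morgan(z_cm), M = M, fp_counts = fp_counts,
       coefs = chrom_bin_coefs(lengths_morgan, cm_to_morgan(z_cm)))
}

# Expected bin counts and (optionally) the log-likelihood and its gradient
# with respect to x = log Ne for one sample-set pair.
#
# counts: observed bin counts (length nbin); ne: full trajectory; the sum runs
# g = gmin .. length(ne)-1. Returns list(lambda, loglik, grad).
pair_rates_core <- function(counts, nhap, ti, tj, ne, ctx, want_grad = FALSE) {
  gmin <- max(ti, tj)
  gmax <- length(ne) - 1L
  g <- gmin:gmax
  tstar <- (g - ti) + (g - tj)
  phi <- phi_vector(gmin, gmax, ne)
  E <- exp(-outer(tstar, ctx$z_morgan))
  ok <- tstar > 0
  if (!all(ok)) E[!ok, ] <- 0
  u <- phi * tstar
  v <- phi * tstar^2
  fN <- as.vector(crossprod(E, u)) * ctx$coefs$a +
        as.vector(crossprod(E, v)) * ctx$coefs$b
  lambda <- nhap * (ctx$fp_counts + as.vector(ctx$M %*% fN))
  out <- list(lambda = lambda)
  if (is.null(counts)) return(out)
  bad <- lambda <= 0 & counts > 0
  if (any(bad)) {
    warning(sprintf("%d bin(s) with zero expected rate but nonzero counts; log-likelihood is -Inf",
                    sum(bad)), call. = FALSE)
    out$loglik <- -Inf
    if (want_grad) out$grad <- rep(NA_real_, length(ne))
    return(out)
  }
  pos <- lambda > 0
  out$loglik <- sum(counts[pos] * log(lambda[pos])) - sum(lambda)
  if (want_grad) {
    d <- ifelse(pos, counts / pmax(lambda, .Machine$double.xmin), 0) - 1
    w <- nhap * as.vector(crossprod(ctx$M, d))      # dloglik / dfN(z)
    cg <- tstar * as.vector(E %*% (w * ctx$coefs$a)) +
          tstar^2 * as.vector(E %*% (w * ctx$coefs$b))
    cg[!ok] <- 0
    # chain rule through phi: d phi(g)/d x[h] = -phi(g) [h==g]
    #                       + phi(g) / (2 Ne[h] - 1) [gmin < h < g]
    cphi <- cg * phi
    tail_sum <- rev(cumsum(rev(cphi)))              # sum_{g >= h} cphi
    r <- 1 / (2 * ne[g + 1L] - 1)
    grad_local <- -cphi + r * (tail_sum - cphi)
    grad <- numeric(length(ne))
    grad[g + 1L] <- grad_local
    out$grad <- grad
  }
  out
}
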