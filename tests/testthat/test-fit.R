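# Penalized objective, initialization, constant and trajectory fits,
# alpha cross-validation, chromosome bootstrap.

test_that("objective bookkeeping: breakdown, zero-penalty and flat cases", {
  hist <- toy_hist(seed = 21)
  scheme <- toy_scheme()
  ne <- rep(2000, 65)
  o0 <- ne_objective(ne, hist, scheme, toy_map(), alpha = 0, beta = 0)
  expect_equal(o0$value, -composite_loglik(hist, ne, scheme, toy_map()))
  expect_equal(o0$pen_curvature + o0$pen_diff, 0)
  # a constant trajectory contributes nothing through either penalty
  o1 <- ne_objective(ne, hist, scheme, toy_map(), alpha = 13, beta = 250)
  expect_equal(o1$pen_curvature + o1$pen_diff, 0)
  set.seed(8)
  ne2 <- exp(log(2000) + rnorm(65, 0, 0.2))
  o2 <- ne_objective(ne2, hist, scheme, toy_map(), alpha = 13, beta = 250)
  expect_equal(o2$value, o2$neg_loglik + o2$pen_curvature + o2$pen_diff,
               tolerance = 1e-8)
})

test_that("analytic gradient of the full objective matches finite differences", {
  hist <- toy_hist(seed = 22)
  scheme <- toy_scheme()
  obj <- ibdtransect:::make_objective(hist, scheme, toy_map(), alpha = 5,
                                      beta = 250, Tmax = 65)
  set.seed(9)
  for (rep in 1:3) {
    x <- log(2000) + rnorm(65, 0, 0.3)
    g <- obj$gr(x)
    idx <- sample(65, 8)
    g_fd <- fd_grad(obj$fn, x)[idx]
    expect_equal(g[idx], g_fd, tolerance = 1e-4)
  }
  # with an error model the chain rule passes through the convolution
  em <- default_error_model(toy_map())
  obj2 <- ibdtransect:::make_objective(hist, scheme, toy_map(), alpha = 5,
                                       beta = 250, Tmax = 65, error_model = em)
  x <- log(2000) + rnorm(65, 0, 0.3)
  idx <- c(1, 5, 30, 65)
  expect_equal(obj2$gr(x)[idx], fd_grad(obj2$fn, x)[idx], tolerance = 1e-4)
})

test_that("initialization: reproducible, positive, correctly scaled noise", {
  i1 <- initialize_trajectory(25000, 100, seed = 42)
  i2 <- initialize_trajectory(25000, 100, seed = 42)
  expect_identical(i1, i2)
  expect_true(all(i1 > 0))
  eps <- initialize_trajectory(25000, 1e5, seed = 1) - 25000
  se <- (25000 / 20) / sqrt(1e5)
  expect_lt(abs(mean(eps)), 3 * se)
  expect_equal(sd(eps), 25000 / 20, tolerance = 0.02)
})

test_that("constant-Ne MLE recovers the truth and responds to count scaling", {
  scheme <- sampling_scheme(0, 150, ids = list(sprintf("I%03d", 1:150)))
  cmap <- human_autosome_map()
  grid <- toy_grid()
  ne_true <- rep(25000, 150)
  hist <- sample_ibd_from_model(ne_true, scheme, grid, cmap, seed = 31)
  fit <- fit_constant_ne(hist, scheme, cmap)
  expect_equal(fit$estimate, 25000, tolerance = 0.05)
  # doubling every count implies more sharing, hence a smaller estimate
  h2 <- hist
  h2$counts <- hist$counts * 2L
  expect_lt(fit_constant_ne(h2, scheme, cmap)$estimate, fit$estimate)
  h0 <- hist
  h0$counts[] <- 0L
  expect_error(fit_constant_ne(h0, scheme, cmap), "all-zero")
})

test_that("single-bin constant fit matches method-of-moments inversion", {
  # with one bin the Poisson MLE solves lambda(Ne) = n; invert numerically
  scheme <- sampling_scheme(0, 10, ids = list(sprintf("I%02d", 1:10)))
  grid1 <- length_grid(8, 8.25, 0.25)
  cmap <- toy_map()
  counts <- array(7L, dim = c(1, 1, 3))
  h <- ibdtransect:::new_ibd_histogram(counts, grid1, scheme, names(cmap))
  fit <- fit_constant_ne(h, scheme, cmap)
  nhap <- haplotype_pair_count(10)
  lam_fun <- function(Ne) {
    nhap * grid1$bin_morgan * sum(vapply(as.numeric(cmap), function(L)
      constant_ne_density(grid1$mids_morgan, 0, Ne, L), numeric(1)))
  }
  mom <- uniroot(function(Ne) lam_fun(Ne) - sum(counts), c(50, 1e7), tol = 1e-6)$root
  expect_equal(fit$estimate, mom, tolerance = 1e-3)
})

test_that("trajectory fit: descent, convergence flag, regularization dominance", {
  hist <- toy_hist(ne_const = 2000, seed = 23)
  scheme <- toy_scheme()
  fit <- fit_trajectory(hist, scheme, toy_map(), alpha = 10, G = 60, seed = 2)
  expect_s3_class(fit, "ne_fit")
  expect_lte(fit$objective, fit$initial_objective)
  expect_equal(fit$objective, sum(fit$breakdown), tolerance = 1e-8)
  expect_equal(fit$convergence, 0)
  # overwhelming curvature penalty flattens the log-trajectory
  fit_flat <- fit_trajectory(hist, scheme, toy_map(), alpha = 1e9, G = 60, seed = 2)
  expect_lt(diff(range(log(fit_flat$ne))), 0.05)
})

test_that("alpha selection is seeded and prefers heavy smoothing on flat truth", {
  scheme <- sampling_scheme(0, 25, ids = list(sprintf("I%02d", 1:25)))
  cmap <- human_autosome_map()
  hist <- sample_ibd_from_model(rep(25000, 150), scheme, toy_grid(), cmap,
                                seed = 33)
  alphas <- c(1e-2, 1, 1e2, 1e4)
  s1 <- select_alpha(hist, scheme, cmap, alphas = alphas, nfolds = 3, seed = 10)
  s2 <- select_alpha(hist, scheme, cmap, alphas = alphas, nfolds = 3, seed = 10)
  expect_identical(s1$alpha, s2$alpha)
  expect_equal(s1$alpha, max(alphas))   # flat truth tolerates maximal smoothing
  h1 <- ibdtransect:::subset_hist(hist, 1L)
  expect_error(select_alpha(h1, scheme, cmap), ">= 2 chromosomes")
})

test_that("bootstrap: identity multiset reproduces the fit; seeded envelopes", {
  hist <- toy_hist(ne_const = 2000, seed = 24)
  scheme <- toy_scheme()
  fit <- fit_trajectory(hist, scheme, toy_map(), alpha = 10, G = 60, seed = 7)
  # the identity chromosome multiset is the original problem
  idx <- seq_along(hist$chroms)
  bh <- ibdtransect:::subset_hist(hist, idx)
  refit <- fit_trajectory(bh, scheme, toy_map(), alpha = 10, G = 60, seed = 7)
  expect_equal(refit$ne, fit$ne, tolerance = 1e-6)
  b1 <- bootstrap_ci(hist, scheme, toy_map(), alpha = 10, G = 60, reps = 3,
                     seed = 99)
  b2 <- bootstrap_ci(hist, scheme, toy_map(), alpha = 10, G = 60, reps = 3,
                     seed = 99)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_true(all(b1$ci_low <= b1$ci_high))
  expect_error(bootstrap_ci(hist, scheme, toy_map(), alpha = 10, reps = 1), "2 bootstrap")
})
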