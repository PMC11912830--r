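# Coalescent IBD length densities: segment-count density, coalescence pmf,
# genome-wide expectations, the constant-size closed form, TMRCA posteriors.

test_that("segment-count density: edge case, conservation, domain errors", {
  # at l = L only the two chromosome-end terms remain
  expect_equal(segment_count_density(2, 50, 2), 2 * 50 * exp(-50 * 2))
  # quadrature oracle: total segment count 1 + t*L and total length L
  set.seed(1)
  for (k in 1:4) {
    ts <- runif(1, 5, 300)
    L <- runif(1, 0.3, 3)
    n_seg <- integrate(function(l) segment_count_density(l, ts, L), 0, L,
                       rel.tol = 1e-10)$value
    tot_len <- integrate(function(l) l * segment_count_density(l, ts, L), 0, L,
                         rel.tol = 1e-10)$value
    expect_equal(n_seg, 1 + ts * L, tolerance = 1e-6)
    expect_equal(tot_len, L, tolerance = 1e-6)
  }
  expect_error(segment_count_density(2.5, 50, 2), "l <= L")
  expect_error(segment_count_density(0.1, 0, 2), "tstar")
})

test_that("coalescent pmf: empty product, geometric closed form, partial sums", {
  ne <- rep(1000, 400)
  expect_equal(coalescent_pmf(0, 0, 0, ne), 1 / 2000)
  g <- 0:350
  expect_equal(coalescent_pmf(g, 0, 0, ne),
               (1 / 2000) * (1 - 1 / 2000)^g)
  # offset pair: mass starts at gmin with an empty product
  expect_equal(coalescent_pmf(12, 3, 12, ne), 1 / 2000)
  expect_error(coalescent_pmf(5, 3, 12, ne), "impossible")
  # partial sums increase monotonically towards 1
  ps <- cumsum(coalescent_pmf(g, 0, 0, ne))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps <= 1))
  expect_equal(ps[length(ps)], 1 - (1 - 1 / 2000)^351, tolerance = 1e-12)
})

test_that("constant-size closed form matches its defining integral", {
  # adaptive quadrature of fK(l, 2t - dt) against the exponential coalescent
  # density, from dt to infinity
  quad <- function(l, dt, Ne, L) {
    integrate(function(t) segment_count_density(l, pmax(2 * t - dt, 1e-12), L) *
                (1 / (2 * Ne)) * exp(-(t - dt) / (2 * Ne)),
              dt, Inf, rel.tol = 1e-11)$value
  }
  for (cfg in list(c(l = 0.10, dt = 0, Ne = 1000, L = 2),
                   c(l = 0.10, dt = 10, Ne = 1000, L = 2),
                   c(l = 0.10, dt = 45, Ne = 1000, L = 2),
                   c(l = 0.08, dt = 45, Ne = 25000, L = 2.86))) {
    expect_equal(constant_ne_density(cfg["l"], cfg["dt"], cfg["Ne"], cfg["L"]),
                 quad(cfg["l"], cfg["dt"], cfg["Ne"], cfg["L"]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # dt = 0 special case
  Ne <- 1500; L <- 2; l <- 0.12
  expect_equal(constant_ne_density(l, 0, Ne, L),
               8 * Ne * (1 + 4 * Ne * L) / (1 + 4 * Ne * l)^3)
  # strictly decreasing in l at dt = 0
  lgrid <- seq(0.01, 1.99, by = 0.01)
  expect_true(all(diff(constant_ne_density(lgrid, 0, 1000, 2)) < 0))
  expect_error(constant_ne_density(0.1, -1, 1000, 2), "negative")
})

test_that("discrete time-summation vs continuous closed form", {
  cmap <- chromosome_map(2, labels = "c1")
  # contemporaneous pair: the boundary term vanishes (fK(l, 0) = 0) and the
  # discrete sum matches the closed form to ~Ne^-1 accuracy
  for (Ne in c(1000, 25000)) {
    ne <- rep(Ne, 45 * Ne)
    d_sum <- expected_ibd_density(0.10, 0, 0, ne, cmap)
    d_cf <- constant_ne_density(0.10, 0, Ne, 2)
    expect_equal(d_sum, d_cf, tolerance = 1e-3)
  }
  # temporally offset pair: the discrete sum exceeds the integral by the
  # half-boundary term fK(l, dt)/(2 * 2Ne); the trapezoid average of the
  # inclusive and exclusive sums restores the agreement
  Ne <- 1000; dt <- 10; l <- 0.10
  ne <- rep(Ne, 45 * Ne)
  incl <- expected_ibd_density(l, 0, dt, ne, cmap)
  bdry <- segment_count_density(l, dt, 2) / (2 * 2 * Ne)
  d_cf <- constant_ne_density(l, dt, Ne, 2)
  expect_equal(incl - bdry, d_cf, tolerance = 2e-3)
  # any dt > 0 shifts mass at long l downward (exp(-l dt) factor)
  d0 <- expected_ibd_density(0.15, 0, 0, rep(2000, 500), cmap)
  d10 <- expected_ibd_density(0.15, 0, 10, rep(2000, 500), cmap)
  expect_lt(d10, d0)
})

test_that("expected density: chromosome additivity and monotone tail", {
  ne <- rep(2000, 300)
  l <- seq(0.05, 0.5, by = 0.05)
  m3 <- toy_map()
  d_all <- expected_ibd_density(l, 0, 5, ne, m3)
  d_each <- Reduce(`+`, lapply(seq_along(m3), function(i)
    expected_ibd_density(l, 0, 5, ne, m3[i])))
  expect_equal(d_all, d_each, tolerance = 1e-12)
  # non-increasing in l above the 1/t* scale
  lg <- seq(0.02, 0.9, by = 0.005)
  expect_true(all(diff(expected_ibd_density(lg, 0, 0, ne, m3)) < 0))
  expect_error(expected_ibd_density(0.1, 0, 5, rep(2000, 50), m3, G = 100),
               "too short")
})

test_that("Erlang-2 length density: mode, normalization, dt = 0 reduction", {
  # mode over l at 1/t*
  expect_equal(optimize(function(l) erlang2_length_density(l, 25, 0, 0),
                        c(0.001, 0.5), maximum = TRUE)$maximum,
               1 / 50, tolerance = 5e-3)
  expect_equal(integrate(function(l) erlang2_length_density(l, 25, 0, 0),
                         0, Inf)$value, 1, tolerance = 1e-9)
  t <- 18; l <- 0.07
  expect_equal(erlang2_length_density(l, t, 0, 0), (2 * t)^2 * l * exp(-2 * t * l))
  # dt > 0: rate 2t - dt with t measured from the younger sample
  expect_equal(erlang2_length_density(l, 20, 0, 10), 30^2 * l * exp(-30 * l))
  expect_error(erlang2_length_density(0.1, 5, 5, 5), "branch length")
})

test_that("TMRCA posterior: normalization, brute-force oracle, dominance", {
  ne <- rep(1000, 20)
  post <- tmrca_posterior(0.08, 0, 0, ne)
  expect_equal(sum(post$pmf), 1, tolerance = 1e-12)
  # independent product-and-normalize enumeration on the 20-generation grid
  g <- 0:19
  lik <- (2 * g)^2 * 0.08 * exp(-2 * g * 0.08)
  prior <- (1 / 2000) * (1 - 1 / 2000)^g
  expect_equal(post$pmf, lik * prior / sum(lik * prior), tolerance = 1e-12)
  # longer segments shift mass toward the recent past
  ne2 <- rep(5000, 200)
  cdf_prev <- NULL
  for (l in c(0.20, 0.12, 0.08)) {
    cdf <- tmrca_posterior(l, 0, 0, ne2)$cdf
    if (!is.null(cdf_prev)) expect_true(all(cdf <= cdf_prev + 1e-12))
    cdf_prev <- cdf
  }
  q <- tmrca_quantile(tmrca_posterior(0.08, 0, 0, ne2), c(0.025, 0.5, 0.975))
  expect_true(all(diff(q) >= 0))
})

test_that("Erlang-2 approximation is close to the exact edge-aware posterior", {
  # exact route: likelihood = edge-aware segment-count density (per
  # chromosome, since the edge term depends on L); approximate route =
  # tmrca_posterior (Erlang-2, edge-free)
  ne <- rep(10000, 150)
  g <- 0:149
  prior <- coalescent_pmf(g, 0, 0, ne)
  tv_for <- function(l, lik) {
    exact <- lik * prior / sum(lik * prior)
    0.5 * sum(abs(exact - tmrca_posterior(l, 0, 0, ne)$pmf))
  }
  # single chromosome at the largest-autosome scale: sub-1% agreement
  L <- 2.86
  for (l in c(0.08, 0.10)) {
    lik <- c(0, segment_count_density(rep(l, 149), 2 * (1:149), L))
    expect_lt(tv_for(l, lik), 0.01)
  }
  # genome-wide mixture over the 22 autosomes: edge terms of the short
  # chromosomes push the deviation slightly higher but it stays small
  cmap <- human_autosome_map()
  l <- 0.08
  lik_mix <- vapply(g, function(gg) {
    if (gg == 0) return(0)
    sum(vapply(as.numeric(cmap), function(Lc)
      if (l <= Lc) segment_count_density(l, 2 * gg, Lc) else 0, numeric(1)))
  }, numeric(1))
  expect_lt(tv_for(l, lik_mix), 0.025)
})
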