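# Shared fixture builders. Everything is generated in code at test time.

# A small chromosome map (3 chromosomes, lengths in Morgans).
toy_map <- function() chromosome_map(c(2.0, 1.5, 1.0), labels = c("c1", "c2", "c3"))

toy_grid <- function() length_grid(8, 20, 0.25)

# Two sample sets with ids, 4 + 3 diploids, five generations apart.
toy_scheme <- function() {
  sampling_scheme(c(0L, 5L), c(4L, 3L),
                  ids = list(paste0("A", 1:4), paste0("B", 1:3)))
}

# A histogram with counts drawn from the model under a constant trajectory.
toy_hist <- function(ne_const = 2000, seed = 7, scheme = toy_scheme(),
                     grid = toy_grid(), map = toy_map(), G = 60) {
  ne <- rep(ne_const, G + max(scheme$times))
  sample_ibd_from_model(ne, scheme, grid, map, seed = seed)
}

# Central finite difference of f at x.
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
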