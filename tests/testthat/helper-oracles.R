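# Independent oracles used across the suite. These deliberately avoid the
# package's fitting internals: the grid search enumerates candidate x values
# directly from the model formula, and the per-point oracle inverts each
# titration point algebraically.

# Exhaustive grid-search fit of the protected fraction (step 1e-4).
grid_search_x <- function(series, Kq, step = 1e-4) {
  obs <- sv_ratios(series)
  a <- 1 + Kq * obs$quencher_conc
  xs <- seq(0, 1, by = step)
  rss <- vapply(xs, function(x) {
    d <- obs$ratio - a / (a * x + 1 - x)
    sum(d * d)
  }, numeric(1))
  xs[which.min(rss)]
}

# Median of algebraic per-point inversions (ratios clipped to >= 1).
median_inversion_x <- function(series, Kq) {
  obs <- sv_ratios(series)
  stats::median(invert_point(Kq, obs$quencher_conc, pmax(obs$ratio, 1)))
}

# Noise-free series built directly from the model formulas (not via the
# package generators), for generator round-trip checks.
manual_series <- function(Kq, x, Q, I0 = 1000) {
  a <- 1 + Kq * Q
  titration_series(Q, I0 * (a * x + 1 - x) / a)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), rel_tol)
}
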