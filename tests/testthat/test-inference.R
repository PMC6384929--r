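Kq_ref <- 1e7 # calibration value used throughout the published analysis

test_that("fit_sv_constant recovers the generating constant exactly on clean data", {
  for (Kq in c(1e5, 1e6, Kq_ref, 5e7, 1e8)) {
    ts <- generate_calibration_series(
      synthetic_spec(Kq_true = Kq, noise_cv = 0, seed = 1))
    cal <- fit_sv_constant(ts)
    expect_rel_equal(cal$Kq_hat, Kq, 1e-6)
    expect_equal(cal$intercept, 1, tolerance = 1e-8)
    expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("fit_sv_constant rejects degenerate inputs", {
  flat <- titration_series(seq(0, 1e-6, length.out = 5), rep(100, 5))
  expect_error(fit_sv_constant(flat), "no quenching")
  few <- titration_series(c(0, 1e-7, 2e-7), c(100, 50, 33))
  expect_error(fit_sv_constant(few), "at least 3 nonzero")
  rising <- titration_series(seq(0, 1e-6, length.out = 5),
                             c(100, 110, 120, 130, 140))
  expect_error(fit_sv_constant(rising), "no quenching")
})

test_that("fit_sv_constant warns when the intercept drifts from 1", {
  ts <- generate_calibration_series(synthetic_spec(noise_cv = 0, seed = 1))
  drifted <- titration_series(ts$quencher_conc,
                              replace(ts$intensity, ts$quencher_conc == 0,
                                      i0(ts) * 1.10))
  expect_warning(fit_sv_constant(drifted), "intercept")
})

test_that("fit_sv_constant is unbiased at 2% noise (500 seeds)", {
  kqs <- vapply(1:500, function(i) {
    # at 2% noise the free intercept occasionally drifts past the 0.05
    # diagnostic band; that warning is expected here, not under test
    suppressWarnings(fit_sv_constant(generate_calibration_series(
      synthetic_spec(noise_cv = 0.02, seed = i)))$Kq_hat)
  }, numeric(1))
  expect_rel_equal(mean(kqs), Kq_ref, 0.01)
})

test_that("fit_orientation_fraction recovers x exactly on clean data, including bounds", {
  for (x in c(0, 0.1, 0.25, 0.41, 0.5, 0.64, 0.75, 0.9, 1)) {
    ts <- generate_orientation_series(
      synthetic_spec(x_true = x, noise_cv = 0, seed = 1))
    fit <- fit_orientation_fraction(ts, Kq_ref)
    expect_lt(abs(fit$x_hat - x), 1e-6)
    expect_true(fit$converged)
    expect_true(fit$ci_low <= fit$x_hat && fit$x_hat <= fit$ci_high)
    expect_gte(fit$ci_low, 0)
    expect_lte(fit$ci_high, 1)
  }
})

test_that("noise-free two-parameter recovery holds across a 20-point sweep", {
  grid <- expand.grid(Kq = c(1e6, 5e6, 1e7, 5e7),
                      x = c(0.1, 0.3, 0.5, 0.64, 0.9))
  for (k in seq_len(nrow(grid))) {
    ts <- generate_orientation_series(
      synthetic_spec(Kq_true = grid$Kq[k], x_true = grid$x[k],
                     noise_cv = 0, seed = k))
    cal <- fit_sv_constant(generate_calibration_series(
      synthetic_spec(Kq_true = grid$Kq[k], noise_cv = 0, seed = k)))
    expect_rel_equal(cal$Kq_hat, grid$Kq[k], 1e-6)
    fit <- fit_orientation_fraction(ts, cal$Kq_hat)
    expect_rel_equal(fit$x_hat, grid$x[k], 1e-6)
  }
})

test_that("the optimizer agrees with the exhaustive grid-search oracle", {
  set.seed(7)
  for (i in 1:25) {
    x_true <- runif(1)
    cv <- sample(c(0, 0.01, 0.03), 1)
    ts <- generate_orientation_series(
      synthetic_spec(x_true = x_true, noise_cv = cv, seed = 100 + i))
    fit <- fit_orientation_fraction(ts, Kq_ref)
    expect_lt(abs(fit$x_hat - grid_search_x(ts, Kq_ref)), 1e-4)
  }
})

test_that("optimizer and median per-point inversion agree on noisy data", {
  for (i in 1:20) {
    ts <- generate_orientation_series(
      synthetic_spec(x_true = 0.5, noise_cv = 0.02, seed = 200 + i))
    fit <- fit_orientation_fraction(ts, Kq_ref)
    expect_lt(abs(fit$x_hat - median_inversion_x(ts, Kq_ref)), 0.03)
  }
})

test_that("x_hat is unbiased at 2% noise over the published range (1000 sims each)", {
  for (x_true in c(0.1, 0.4, 0.5, 0.64, 0.9)) {
    xh <- vapply(1:1000, function(i) {
      fit_orientation_fraction(generate_orientation_series(
        synthetic_spec(x_true = x_true, noise_cv = 0.02, seed = 3000 + i)),
        Kq_ref)$x_hat
    }, numeric(1))
    expect_lt(abs(mean(xh) - x_true), 0.01)
  }
})

test_that("fit preconditions and the weak-quenching diagnostic fire", {
  few <- titration_series(c(0, 1e-7, 2e-7), c(100, 80, 70))
  expect_error(fit_orientation_fraction(few, Kq_ref), "at least 3 nonzero")
  expect_error(fit_orientation_fraction(
    generate_orientation_series(synthetic_spec(x_true = 0.5, noise_cv = 0, seed = 1)),
    Kq = -1), "Kq")
  weak <- generate_orientation_series(
    synthetic_spec(x_true = 0.5, Q_max = 2e-8, noise_cv = 0, seed = 1))
  expect_warning(fit <- fit_orientation_fraction(weak, Kq_ref),
                 "weak quenching")
  expect_match(fit$warnings, "poorly identifiable", all = FALSE)
})

test_that("clipped flag marks series whose mean inversion leaves [0, 1]", {
  ts <- generate_orientation_series(
    synthetic_spec(x_true = 0.5, noise_cv = 0, seed = 1))
  # inflate all quenched intensities: ratios drop below the x = 1 limit is
  # impossible, so push the other way (stronger quenching than x = 0 allows)
  boosted <- titration_series(ts$quencher_conc,
                              ifelse(ts$quencher_conc > 0,
                                     ts$intensity * 0.2, ts$intensity))
  fit <- fit_orientation_fraction(boosted, Kq_ref)
  expect_true(fit$clipped)
  expect_equal(fit$x_hat, 0) # bounded optimum pinned at the boundary
})

test_that("bootstrap_ci is seeded, order-invariant, and degenerate on clean data", {
  ts <- generate_orientation_series(
    synthetic_spec(x_true = 0.5, noise_cv = 0.02, seed = 5))
  for (method in c("parametric", "case")) {
    ci1 <- bootstrap_ci(ts, Kq_ref, n_boot = 300, seed = 9, method = method)
    ci2 <- bootstrap_ci(ts, Kq_ref, n_boot = 300, seed = 9, method = method)
    expect_identical(ci1, ci2)
    # shuffled input points give the identical interval
    perm <- sample(seq_along(ts$quencher_conc))
    shuffled <- titration_series(ts$quencher_conc[perm], ts$intensity[perm])
    expect_identical(
      bootstrap_ci(shuffled, Kq_ref, n_boot = 300, seed = 9, method = method),
      ci1)
  }
  clean <- generate_orientation_series(
    synthetic_spec(x_true = 0.41, noise_cv = 0, seed = 5))
  ci <- bootstrap_ci(clean, Kq_ref, n_boot = 300, seed = 9)
  expect_equal(unname(ci["ci_low"]), unname(ci["ci_high"]), tolerance = 1e-8)
  expect_equal(unname(ci["ci_low"]), 0.41, tolerance = 1e-6)
  expect_error(bootstrap_ci(ts, Kq_ref, n_boot = 100, seed = 1), "200")
  expect_error(bootstrap_ci(ts, Kq_ref, n_boot = 300), "seed")
})

test_that("joint_fit recovers both parameters on clean, well-leveraged data", {
  ts <- generate_orientation_series(
    synthetic_spec(x_true = 0.41, noise_cv = 0, seed = 5)) # Kq * Qmax = 10
  jf <- joint_fit(ts)
  expect_rel_equal(jf$params$Kq, Kq_ref, 1e-4)
  expect_rel_equal(jf$params$x, 0.41, 1e-4)
  expect_true(jf$identifiable)
  expect_true(jf$converged)
})

test_that("joint_fit flags the flat likelihood at x = 1", {
  ts <- generate_orientation_series(
    synthetic_spec(x_true = 1, noise_cv = 0, seed = 5))
  jf <- joint_fit(ts)
  expect_false(jf$identifiable)
  expect_gt(jf$cond_number, 1e8)
})

test_that("two-stage beats the joint fit when quenching leverage is weak", {
  # Kq * max(Q) = 0.2: Kq and x trade off along a ridge
  se_joint <- se_two_stage <- numeric(20)
  for (i in 1:20) {
    ts <- generate_orientation_series(
      synthetic_spec(x_true = 0.5, Q_max = 2e-8, noise_cv = 0.02,
                     seed = 400 + i))
    jf <- joint_fit(ts)
    se_joint[i] <- sqrt(jf$covariance["x", "x"])
    se_two_stage[i] <-
      suppressWarnings(fit_orientation_fraction(ts, Kq_ref))$x_stderr
  }
  ok <- is.finite(se_joint) & is.finite(se_two_stage)
  expect_gt(sum(ok), 10)
  expect_gt(median(se_joint[ok]), median(se_two_stage[ok]))
})

test_that("aggregate_replicates matches hand arithmetic", {
  s <- aggregate_replicates(c(0.62, 0.63, 0.65))
  expect_equal(s$x_mean, 0.6333333, tolerance = 1e-6)
  expect_equal(s$x_err, sd(c(0.62, 0.63, 0.65)) / sqrt(3))
  expect_equal(s$x_err, 0.0088192, tolerance = 1e-4)
  one <- aggregate_replicates(0.5)
  expect_equal(one$x_mean, 0.5)
  expect_identical(one$x_err, 0)
  five <- aggregate_replicates(rep(0.4, 5))
  expect_equal(five$x_mean, 0.4)
  expect_equal(five$x_err, 0)
  expect_error(aggregate_replicates(list()), "non-empty")
  expect_error(aggregate_replicates(numeric(0)), "at least one")
  # list-of-fits route
  fits <- lapply(c(0.3, 0.35), function(x) {
    fit_orientation_fraction(generate_orientation_series(
      synthetic_spec(x_true = x, noise_cv = 0, seed = 1)), Kq_ref)
  })
  agg <- aggregate_replicates(fits)
  expect_equal(agg$x_mean, 0.325, tolerance = 1e-6)
  expect_equal(agg$n_replicates, 2)
})

test_that("classify_orientation reproduces the published calls and is symmetric", {
  expect_equal(classify_orientation(aggregate_replicates(c(0.63)))$label,
               "N_IN_PREFERRED")
  expect_equal(classify_orientation(0.40)$label, "C_IN_PREFERRED")
  expect_equal(classify_orientation(0.53)$label, "NO_PREFERENCE")
  expect_equal(classify_orientation(0.57)$label, "N_IN_PREFERRED")
  # symmetry: x -> 1 - x swaps N and C and preserves NO_PREFERENCE
  set.seed(11)
  for (x in runif(200)) {
    a <- classify_orientation(x)$label
    b <- classify_orientation(1 - x)$label
    expect_equal(b, switch(a, N_IN_PREFERRED = "C_IN_PREFERRED",
                           C_IN_PREFERRED = "N_IN_PREFERRED",
                           NO_PREFERENCE = "NO_PREFERENCE"))
  }
})
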