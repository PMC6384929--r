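#' Calibrate the Stern-Volmer quenching constant
#'
#' Stage one of the two-stage analysis: ordinary least squares of the
#' observed \eqn{I_0/I} ratios on quencher concentration for a titration of
#' the free (vesicle-free) labeled protein, where the Stern-Volmer law
#' \eqn{I_0/I = 1 + K_q[Q]} holds exactly. The slope is the quenching
#' constant; the intercept is left free as a baseline diagnostic (it should
#' be ~1, and a warning is raised when it deviates by more than 0.05).
#'
#' @param series a [titration_series()] measured without vesicles; at least
#'   3 distinct nonzero quencher concentrations are required.
#' @return An object of class `calibration_result` with fields `Kq_hat`,
#'   `Kq_stderr` (1/M), `intercept`, `r_squared`, `n_points`, and per-point
#'   `residuals` on the ratio scale.
#' @examples
#' ts <- generate_calibration_series(synthetic_spec(seed = 1, noise_cv = 0))
#' fit_sv_constant(ts)
#' @export
fit_sv_constant <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  obs <- sv_ratios(series, drop_zero = FALSE)
  if (sum(obs$quencher_conc > 0) < 3) {
    stop("calibration requires at least 3 nonzero quencher concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(ratio ~ quencher_conc, data = obs)
  slope <- unname(stats::coef(fit)[2])
  # materiality: total fitted ratio change across the titration must exceed
  # rounding noise, otherwise a perfectly flat series can fit an epsilon slope
  if (!is.finite(slope) || slope * max(obs$quencher_conc) < 1e-6) {
    stop("no quenching detected: fitted Stern-Volmer slope is not positive",
         call. = FALSE)
  }
  intercept <- unname(stats::coef(fit)[1])
  if (abs(intercept - 1) > 0.05) {
    warning(sprintf(
      "calibration intercept %.4f deviates from 1 by more than 0.05; check the zero-quencher baseline",
      intercept), call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit)) # noise-free data triggers a perfect-fit note
  structure(
    list(
      Kq_hat = slope,
      Kq_stderr = unname(sm$coefficients[2, 2]),
      intercept = intercept,
      r_squared = sm$r.squared,
      n_points = nrow(obs),
      residuals = unname(stats::residuals(fit))
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> Kq = %.4g +/- %.2g 1/M (intercept %.4f, R2 %.5f, n = %d)\n",
    x$Kq_hat, x$Kq_stderr, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

# Internal single-series x fitter on precomputed quantities.
# a = 1 + Kq*Q at the nonzero-Q points, r = observed I0/I there.
# Bounded minimization of RSS(x) on [0,1]; candidates are the interior
# optimum, both endpoints, and the initializer (ties resolved toward the
# initializer because it is listed first among equal-RSS candidates).
.fit_x <- function(a, r, init) {
  rss <- function(x) {
    d <- r - a / (a * x + 1 - x)
    sum(d * d)
  }
  opt <- stats::optimize(rss, interval = c(0, 1), tol = 1e-10)
  cand <- c(init, opt$minimum, 0, 1)
  vals <- vapply(cand, rss, numeric(1))
  best <- cand[which.min(vals)]
  list(x = best, rss = min(vals))
}

#' Fit the protected fraction with a fixed quenching constant
#'
#' Stage two of the two-stage analysis: least-squares fit of the
#' two-population quenching model (see [orientation_ratio()]) to the
#' observed \eqn{I_0/I} ratios of a vesicle titration, with the quenching
#' constant held fixed at its stage-one calibration value and the protected
#' fraction `x` bounded to \[0, 1\].
#'
#' The optimizer is a bounded scalar minimization initialized at the mean of
#' the per-point inversions ([invert_point()]) clipped to \[0.01, 0.99\];
#' both endpoints are always evaluated so boundary optima (x = 0 or 1) are
#' found exactly. The standard error is derived from the curvature of the
#' residual sum of squares at the optimum; the reported confidence interval
#' is the Wald interval truncated to \[0, 1\] (use [bootstrap_ci()] for a
#' resampling interval).
#'
#' @param series a [titration_series()] of vesicle-reconstituted protein
#'   with at least 3 nonzero quencher concentrations.
#' @param Kq calibrated Stern-Volmer constant, 1/M.
#' @return An object of class `orientation_fit` with fields `x_hat`,
#'   `x_stderr`, `ci_low`, `ci_high`, `Kq_used`, `rss`, `n_points`,
#'   `converged`, `clipped` (TRUE when the mean per-point inversion fell
#'   outside \[0, 1\]), and `warnings`.
#' @examples
#' ts <- generate_orientation_series(
#'   synthetic_spec(x_true = 0.63, seed = 1, noise_cv = 0))
#' fit_orientation_fraction(ts, Kq = 1e7)
#' @export
fit_orientation_fraction <- function(series, Kq) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.numeric(Kq) || length(Kq) != 1 || !is.finite(Kq) || Kq <= 0) {
    stop("Kq must be a single positive finite number", call. = FALSE)
  }
  obs <- sv_ratios(series)
  if (nrow(obs) < 3) {
    stop("orientation fit requires at least 3 nonzero quencher concentrations",
         call. = FALSE)
  }
  warns <- character(0)
  if (Kq * max(obs$quencher_conc) < 0.5) {
    msg <- sprintf(
      "weak quenching: Kq * max(Q) = %.3g < 0.5; x is poorly identifiable",
      Kq * max(obs$quencher_conc))
    warning(msg, call. = FALSE)
    warns <- c(warns, msg)
  }
  a <- 1 + Kq * obs$quencher_conc
  r <- obs$ratio # fitted unweighted on the raw ratio scale
  # the inversion oracle needs ratios >= 1; clip only for the initializer
  inv_mean <- mean(invert_point(Kq, obs$quencher_conc, pmax(r, 1)))
  clipped <- inv_mean < 0 || inv_mean > 1
  init <- min(max(inv_mean, 0.01), 0.99)
  sol <- .fit_x(a, r, init)
  if (!is.finite(sol$rss)) {
    stop("orientation fit failed to converge: non-finite residual sum of squares",
         call. = FALSE)
  }
  se <- .x_stderr(a, r, sol$x, sol$rss)
  ci <- c(max(0, sol$x - 1.96 * se), min(1, sol$x + 1.96 * se))
  structure(
    list(
      x_hat = sol$x,
      x_stderr = se,
      ci_low = ci[1],
      ci_high = ci[2],
      Kq_used = Kq,
      rss = sol$rss,
      n_points = nrow(obs),
      converged = TRUE,
      clipped = clipped,
      warnings = warns
    ),
    class = "orientation_fit"
  )
}

# Curvature-based standard error: var(x) ~= 2 sigma^2 / RSS''(x_hat),
# with sigma^2 the residual variance. Central difference with a step kept
# inside [0,1]; degenerate (flat) curvature yields NA.
.x_stderr <- function(a, r, x_hat, rss_min) {
  n <- length(r)
  if (n <= 1) return(NA_real_)
  sigma2 <- rss_min / max(n - 1, 1)
  h <- 1e-4
  x0 <- min(max(x_hat, h), 1 - h)
  rss <- function(x) {
    d <- r - a / (a * x + 1 - x)
    sum(d * d)
  }
  d2 <- (rss(x0 + h) - 2 * rss(x0) + rss(x0 - h)) / h^2
  if (!is.finite(d2) || d2 <= 0) return(NA_real_)
  sqrt(2 * sigma2 / d2)
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf(
    "<orientation_fit> x = %.4f +/- %.4f [%.4f, %.4f] (Kq fixed at %.4g 1/M, rss %.3g)\n",
    x$x_hat, x$x_stderr, x$ci_low, x$ci_high, x$Kq_used, x$rss))
  if (x$clipped) cat("  note: mean per-point inversion fell outside [0, 1]\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the protected fraction
#'
#' Percentile interval (2.5/97.5) over bootstrap refits of x with Kq held
#' fixed. Two resampling schemes are available:
#'
#' * `"parametric"` (default): the multiplicative log-normal noise level is
#'   estimated from the fit residuals on the log-intensity scale, and each
#'   bootstrap replicate redraws both the per-point noise and a noise factor
#'   for the zero-quencher baseline. Because the observed \eqn{I_0} enters
#'   every ratio, its measurement noise is a variance component shared
#'   across the whole curve; only a scheme that redraws the baseline
#'   propagates it, which is why this is the default (case resampling of
#'   points underestimates the sampling variance of x several-fold and its
#'   nominal 95% interval covers at well under 50%).
#' * `"case"`: classic case resampling of the nonzero-quencher titration
#'   points with replacement (the zero-quencher baseline is retained as the
#'   fixed \eqn{I_0} reference); resamples with fewer than 3 distinct
#'   concentrations are redrawn. Kept for comparison; see the methods
#'   vignette.
#'
#' Both schemes are deterministic given `seed` and invariant to the input
#' point order (series points are stored sorted by concentration). On
#' noise-free data the estimated noise level is 0 and the parametric
#' interval degenerates to the point estimate.
#'
#' @param series a [titration_series()].
#' @param Kq fixed Stern-Volmer constant, 1/M.
#' @param n_boot number of bootstrap draws, at least 200 (default 1000).
#' @param seed integer seed (mandatory: every stochastic operation in this
#'   package takes an explicit seed).
#' @param method `"parametric"` or `"case"`.
#' @return Named numeric vector `c(ci_low = ..., ci_high = ...)`.
#' @export
bootstrap_ci <- function(series, Kq, n_boot = 1000, seed,
                         method = c("parametric", "case")) {
  stopifnot(inherits(series, "titration_series"))
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  obs <- sv_ratios(series)
  n <- nrow(obs)
  if (n < 3) {
    stop("bootstrap requires at least 3 nonzero quencher concentrations",
         call. = FALSE)
  }
  a_all <- 1 + Kq * obs$quencher_conc
  r_all <- obs$ratio
  xs <- if (method == "parametric") {
    fit <- suppressWarnings(fit_orientation_fraction(series, Kq))
    x_hat <- fit$x_hat
    model_r <- a_all / (a_all * x_hat + 1 - x_hat)
    # log-intensity residuals; df loss: x plus the baseline shift the fit absorbs
    lres <- log(model_r / r_all)
    sdlog <- sqrt(sum(lres^2) / max(n - 2, 1))
    init <- min(max(x_hat, 0.01), 0.99)
    withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        n0 <- exp(stats::rnorm(1, 0, sdlog))
        ei <- exp(stats::rnorm(n, 0, sdlog))
        .fit_x(a_all, model_r * n0 / ei, init)$x
      }, numeric(1))
    })
  } else {
    withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(obs$quencher_conc[idx])) >= 3) break
        }
        a <- a_all[idx]
        r <- r_all[idx]
        init <- min(max(mean((a / pmax(r, 1) - 1) / (a - 1)), 0.01), 0.99)
        .fit_x(a, r, init)$x
      }, numeric(1))
    })
  }
  ci <- stats::quantile(xs, c(0.025, 0.975), names = FALSE)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Joint fit of the quenching constant and protected fraction
#'
#' Identifiability diagnostic for the two-stage design: fits Kq and x
#' simultaneously to the two-population model by bounded least squares and
#' reports the parameter covariance and its condition number. When
#' quenching leverage is weak (small Kq * max(Q)) or x is near 1, the two
#' parameters trade off and the covariance becomes ill-conditioned — which
#' is why the calibrate-then-fit two-stage procedure is preferred.
#'
#' @param series a [titration_series()].
#' @param cond_threshold covariance condition number above which the fit is
#'   declared practically unidentifiable (default 1e8).
#' @return A list with `params` (a [quench_params()]), `covariance` (2x2,
#'   Kq and x), `cond_number`, `identifiable`, `rss`, and `converged`.
#' @export
joint_fit <- function(series, cond_threshold = 1e8) {
  stopifnot(inherits(series, "titration_series"))
  obs <- sv_ratios(series)
  if (nrow(obs) < 3) {
    stop("joint fit requires at least 3 nonzero quencher concentrations",
         call. = FALSE)
  }
  Q <- obs$quencher_conc
  r <- obs$ratio
  # starting values from the two-stage logic
  slope <- stats::coef(stats::lm(r ~ Q))[2]
  Kq0 <- if (is.finite(slope) && slope > 0) unname(slope) else 1 / max(Q)
  x0 <- min(max(mean(((1 + Kq0 * Q) / r - 1) / (Kq0 * Q)), 0.01), 0.99)
  rss_fn <- function(p) {
    Kq <- exp(p[1])
    x <- p[2]
    afit <- 1 + Kq * Q
    d <- r - afit / (afit * x + 1 - x)
    sum(d * d)
  }
  ctrl <- list(factr = 1, pgtol = 1e-15, maxit = 1000)
  lo <- c(log(Kq0) - 12, 0)
  hi <- c(log(Kq0) + 12, 1)
  opt <- stats::optim(c(log(Kq0), x0), rss_fn, method = "L-BFGS-B",
                      lower = lo, upper = hi, control = ctrl)
  # polish by profiling over log(Kq) with the exact inner x fit: L-BFGS-B
  # stops early in the flat near-zero-residual valley of clean data
  profile_rss <- function(lk) {
    a <- 1 + exp(lk) * Q
    .fit_x(a, r, min(max(mean((a / pmax(r, 1) - 1) / pmax(a - 1, 1e-12)),
                         0.01), 0.99))$rss
  }
  po <- stats::optimize(profile_rss, opt$par[1] + c(-0.5, 0.5), tol = 1e-12)
  if (po$objective < opt$value) {
    a_po <- 1 + exp(po$minimum) * Q
    x_po <- .fit_x(a_po, r,
                   min(max(mean((a_po / pmax(r, 1) - 1) /
                                  pmax(a_po - 1, 1e-12)), 0.01), 0.99))
    opt$par <- c(po$minimum, x_po$x)
    opt$value <- x_po$rss
  }
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop(sprintf("joint fit did not converge (optim code %d: %s)",
                 opt$convergence, opt$message), call. = FALSE)
  }
  Kq_hat <- exp(opt$par[1])
  x_hat <- opt$par[2]
  n <- length(r)
  sigma2 <- opt$value / max(n - 2, 1)
  # Hessian of RSS on the natural (Kq, x) scale, relative step for Kq.
  # Inversion and conditioning are done on the unit-free (relative-Kq, x)
  # scale: the 1/M units of Kq (~1e7) otherwise make the natural-scale
  # matrix numerically singular / ill-conditioned regardless of the design.
  H <- .rss_hessian(Q, r, Kq_hat, x_hat)
  S <- diag(c(Kq_hat, 1))
  Hs <- S %*% H %*% S
  cov <- tryCatch(2 * sigma2 * (S %*% solve(Hs) %*% S),
                  error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov))) {
    cov <- matrix(Inf, 2, 2)
  }
  cond <- if (any(!is.finite(Hs)) || abs(det(Hs)) < .Machine$double.eps^2 *
                max(abs(Hs))^2) Inf else kappa(Hs, exact = TRUE)
  dimnames(cov) <- list(c("Kq", "x"), c("Kq", "x"))
  list(
    params = quench_params(Kq_hat, min(max(x_hat, 0), 1)),
    covariance = cov,
    cond_number = cond,
    identifiable = is.finite(cond) && cond <= cond_threshold,
    rss = opt$value,
    converged = TRUE
  )
}

.rss_hessian <- function(Q, r, Kq, x) {
  f <- function(Kq, x) {
    a <- 1 + Kq * Q
    d <- r - a / (a * x + 1 - x)
    sum(d * d)
  }
  hK <- Kq * 1e-5
  hx <- 1e-5
  x0 <- min(max(x, hx), 1 - hx)
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (f(Kq + hK, x0) - 2 * f(Kq, x0) + f(Kq - hK, x0)) / hK^2
  H[2, 2] <- (f(Kq, x0 + hx) - 2 * f(Kq, x0) + f(Kq, x0 - hx)) / hx^2
  H[1, 2] <- H[2, 1] <-
    (f(Kq + hK, x0 + hx) - f(Kq + hK, x0 - hx) -
       f(Kq - hK, x0 + hx) + f(Kq - hK, x0 - hx)) / (4 * hK * hx)
  H
}

#' Aggregate replicate orientation fits
#'
#' Replicate titrations of the same condition are summarized by the
#' arithmetic mean of the fitted protected fractions and the standard error
#' of the mean (0 when there is a single replicate).
#'
#' @param fits a list of [fit_orientation_fraction()] results, or a bare
#'   numeric vector of fitted x values.
#' @return An object of class `replicate_summary` with fields `x_mean`,
#'   `x_err`, `n_replicates`, and `member_fits`.
#' @examples
#' aggregate_replicates(c(0.62, 0.63, 0.65))
#' @export
aggregate_replicates <- function(fits) {
  if (is.numeric(fits)) {
    xs <- fits
    member <- lapply(fits, function(v) v)
  } else if (is.list(fits) && length(fits) > 0 &&
             all(vapply(fits, inherits, logical(1), "orientation_fit"))) {
    xs <- vapply(fits, `[[`, numeric(1), "x_hat")
    member <- fits
  } else {
    stop("fits must be a non-empty list of orientation fits or a numeric vector",
         call. = FALSE)
  }
  if (length(xs) == 0) stop("at least one fit is required", call. = FALSE)
  n <- length(xs)
  err <- if (n == 1) 0 else stats::sd(xs) / sqrt(n)
  structure(
    list(x_mean = mean(xs), x_err = err, n_replicates = n,
         member_fits = member),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> x = %.3f +/- %.3f (n = %d)\n",
              x$x_mean, x$x_err, x$n_replicates))
  invisible(x)
}

#' Classify orientation preference
#'
#' Labels a replicate-averaged protected fraction as N-terminus-in preferred
#' (`x > 0.5 + band`), C-terminus-in preferred (`x < 0.5 - band`), or no
#' preference (within the band). The default band of 0.04 reproduces the
#' field's reading that x = 0.53 means no preference while x = 0.57 is a
#' retained (if weakened) preference.
#'
#' @param summary a [aggregate_replicates()] result, or a single numeric
#'   mean protected fraction.
#' @param band half-width of the no-preference zone around 0.5.
#' @return An object of class `orientation_call` with fields `label` (one of
#'   `"N_IN_PREFERRED"`, `"C_IN_PREFERRED"`, `"NO_PREFERENCE"`) and `margin`
#'   (`|x_mean - 0.5|`).
#' @examples
#' classify_orientation(aggregate_replicates(c(0.62, 0.63, 0.65)))
#' @export
classify_orientation <- function(summary, band = 0.04) {
  x_mean <- if (inherits(summary, "replicate_summary")) summary$x_mean
            else if (is.numeric(summary) && length(summary) == 1) summary
            else stop("summary must be a replicate_summary or a single number",
                      call. = FALSE)
  stopifnot(is.numeric(band), band >= 0)
  margin <- abs(x_mean - 0.5)
  label <- if (margin <= band) "NO_PREFERENCE"
           else if (x_mean > 0.5) "N_IN_PREFERRED"
           else "C_IN_PREFERRED"
  structure(list(label = label, margin = margin, band = band),
            class = "orientation_call")
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf("<orientation_call> %s (margin %.3f, band %.2f)\n",
              x$label, x$margin, x$band))
  invisible(x)
}
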