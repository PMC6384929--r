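#' Specification for a synthetic titration
#'
#' Bundles every generating parameter of a simulated fluorescence quenching
#' titration. Defaults describe a realistic fluorometer experiment: 11
#' evenly spaced quencher concentrations from 0 to 1e-6 M (so Kq*Q spans
#' 0-10 at the default Kq of 1e7 1/M, giving strong leverage on the
#' protected fraction while staying within tryptophan solubility), and
#' multiplicative log-normal intensity noise with a 1.5% coefficient of
#' variation, typical of fluorometer repeatability.
#'
#' @param Kq_true true Stern-Volmer constant, 1/M.
#' @param x_true true protected fraction in \[0, 1\], or `NULL` for a
#'   quencher-only calibration titration (no vesicles).
#' @param n_points number of titration points including the zero-quencher
#'   baseline, at least 3.
#' @param Q_max largest quencher concentration, M.
#' @param noise_cv coefficient of variation of the multiplicative intensity
#'   noise, non-negative.
#' @param n_replicates replicate count for study-level simulation.
#' @param seed integer seed.
#' @param I0_true true unquenched intensity, arbitrary units.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(Kq_true = 1e7, x_true = NULL, n_points = 11,
                           Q_max = 1e-6, noise_cv = 0.015, n_replicates = 5,
                           seed, I0_true = 1e6) {
  stopifnot(is.numeric(Kq_true), Kq_true > 0,
            is.numeric(n_points), n_points >= 3,
            is.numeric(Q_max), Q_max > 0,
            is.numeric(noise_cv), noise_cv >= 0,
            is.numeric(n_replicates), n_replicates >= 1,
            is.numeric(I0_true), I0_true > 0)
  if (!is.null(x_true)) {
    stopifnot(is.numeric(x_true), length(x_true) == 1, x_true >= 0, x_true <= 1)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(
    list(Kq_true = Kq_true, x_true = x_true, n_points = as.integer(n_points),
         Q_max = Q_max, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         I0_true = I0_true),
    class = "synthetic_spec"
  )
}

# Log-normal multiplicative noise factors with unit mean and CV = cv.
# sdlog = sqrt(log(1 + cv^2)); meanlog = -sdlog^2/2 keeps E[factor] = 1, and
# positivity holds for every cv, so intensities stay valid.
.noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.design_grid <- function(spec) seq(0, spec$Q_max, length.out = spec$n_points)

#' Simulate a quencher-only calibration titration
#'
#' Forward model of the Stern-Volmer law for the free labeled protein:
#' \eqn{I = I_0 / (1 + K_q Q)} times multiplicative log-normal noise, over
#' an evenly spaced concentration grid from 0 to `Q_max` inclusive.
#' Reproducible given the spec's seed.
#'
#' @param spec a [synthetic_spec()] with `x_true = NULL`.
#' @return A [titration_series()].
#' @examples
#' generate_calibration_series(synthetic_spec(seed = 7))
#' @export
generate_calibration_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$x_true)) {
    stop("calibration series must not carry x_true (no vesicles present)",
         call. = FALSE)
  }
  Q <- .design_grid(spec)
  ideal <- spec$I0_true / (1 + spec$Kq_true * Q)
  noise <- withr::with_seed(spec$seed, .noise_factors(length(Q), spec$noise_cv))
  titration_series(Q, ideal * noise, sample_id = "calibration")
}

#' Simulate a vesicle-reconstituted protein titration
#'
#' Forward model of the two-population quenching law: a fraction `x_true` of
#' labeled termini points inside the vesicles and escapes quenching, so
#' \eqn{I = I_0 ((1 + K_q Q) x + 1 - x) / (1 + K_q Q)}, times multiplicative
#' log-normal noise. Same design rules as
#' [generate_calibration_series()].
#'
#' @param spec a [synthetic_spec()] with `x_true` set.
#' @param condition optional [condition()] attached to the series.
#' @param sample_id label for the series.
#' @return A [titration_series()].
#' @examples
#' generate_orientation_series(synthetic_spec(x_true = 0.63, seed = 1))
#' @export
generate_orientation_series <- function(spec, condition = NULL,
                                        sample_id = "orientation") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$x_true)) {
    stop("orientation series requires x_true", call. = FALSE)
  }
  Q <- .design_grid(spec)
  ideal <- spec$I0_true /
    orientation_ratio(quench_params(spec$Kq_true, spec$x_true), Q)
  noise <- withr::with_seed(spec$seed, .noise_factors(length(Q), spec$noise_cv))
  titration_series(Q, ideal * noise, sample_id = sample_id,
                   condition = condition)
}

#' Simulate a full replicated study
#'
#' Generates `n_replicates` titration series per experimental condition,
#' using each preset's reported mean protected fraction as generating truth.
#' Per-replicate sub-seeds are derived deterministically from the master
#' seed, so the whole study is reproducible and replicates are independent.
#'
#' @param presets data.frame as returned by [paper_presets()] (or any subset
#'   of its rows with non-missing `x_true`).
#' @param noise_cv multiplicative noise CV (default 0.015).
#' @param n_replicates replicates per condition (default 5).
#' @param seed master integer seed.
#' @param Kq_true generating Stern-Volmer constant, 1/M.
#' @param n_points,Q_max,I0_true design parameters, see [synthetic_spec()].
#' @return A list with one element per condition, each a list with `condition`
#'   (a [condition()]), `x_true`, and `replicates` (list of
#'   [titration_series()]).
#' @export
generate_study <- function(presets, noise_cv = 0.015, n_replicates = 5, seed,
                           Kq_true = 1e7, n_points = 11, Q_max = 1e-6,
                           I0_true = 1e6) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.data.frame(presets) || nrow(presets) == 0) {
    stop("presets must be a non-empty data.frame", call. = FALSE)
  }
  presets <- presets[!is.na(presets$x_true), , drop = FALSE]
  if (nrow(presets) == 0) {
    stop("presets contain no rows with a generating x_true", call. = FALSE)
  }
  seed <- as.integer(seed)
  lapply(seq_len(nrow(presets)), function(i) {
    row <- presets[i, ]
    cond <- condition(row$lipid, row$ionic_strength, row$pH,
                      row$vesicle_diameter)
    reps <- lapply(seq_len(n_replicates), function(rep) {
      # sub-seed scheme keeps seeds distinct across (condition, replicate)
      # and below 2^31 for any master seed
      sub_seed <- (seed * 1009L + i * 131L + rep) %% .Machine$integer.max
      spec <- synthetic_spec(Kq_true = Kq_true, x_true = row$x_true,
                             n_points = n_points, Q_max = Q_max,
                             noise_cv = noise_cv, seed = sub_seed,
                             I0_true = I0_true)
      generate_orientation_series(
        spec, condition = cond,
        sample_id = sprintf("%s_rep%d", format(cond), rep))
    })
    list(condition = cond, x_true = row$x_true, label = row$label,
         replicates = reps)
  })
}

#' Simulate a three-state titration (two-state model misspecification)
#'
#' The two-population analysis assumes every labeled terminus is either
#' fully exposed or fully protected. Two real-world deviations break this:
#' protein lying parallel to the membrane with both termini exposed, and
#' the fluorophore transiently buried in the lipid headgroups, partially
#' shielded. This generator adds a third population with a fixed
#' quencher-accessibility factor of 0.5, so the bias it induces in the
#' two-state fit can be quantified by simulation.
#'
#' The per-point intensity is
#' \eqn{I/I_0 = f_p + f_e/(1 + K_q Q) + f_b/(1 + 0.5 K_q Q)}
#' for protected, exposed, and buried fractions.
#'
#' @param Kq Stern-Volmer constant, 1/M.
#' @param f_exposed,f_protected,f_buried population fractions, non-negative,
#'   summing to 1 (tolerance 1e-9).
#' @param spec a [synthetic_spec()] providing design, noise, I0 and seed
#'   (its `Kq_true`/`x_true` are ignored in favor of the arguments here).
#' @return A [titration_series()].
#' @export
generate_three_state_series <- function(Kq, f_exposed, f_protected, f_buried,
                                        spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            is.numeric(Kq), Kq > 0,
            f_exposed >= 0, f_protected >= 0, f_buried >= 0)
  if (abs(f_exposed + f_protected + f_buried - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  buried_access <- 0.5 # declared constant accessibility of the buried state
  Q <- .design_grid(spec)
  rel <- f_protected + f_exposed / (1 + Kq * Q) +
    f_buried / (1 + buried_access * Kq * Q)
  noise <- withr::with_seed(spec$seed, .noise_factors(length(Q), spec$noise_cv))
  titration_series(Q, spec$I0_true * rel * noise, sample_id = "three_state")
}
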