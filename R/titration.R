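#' Construct a titration series
#'
#' A titration series holds one fluorescence quenching titration: ordered
#' (quencher concentration, intensity) pairs for a single sample, with a
#' mandatory zero-quencher measurement that defines the unquenched intensity
#' \eqn{I_0}. Points are stored sorted by quencher concentration so that all
#' downstream computations are invariant to input order.
#'
#' @param quencher_conc numeric vector of quencher concentrations in molar
#'   units (M). Must be non-negative, unique, and contain at least one zero
#'   (the unquenched baseline).
#' @param intensity numeric vector of fluorescence intensities in arbitrary
#'   units. Must be strictly positive and the same length as `quencher_conc`.
#' @param sample_id character label for the sample.
#' @param condition optional [condition()] object describing the experimental
#'   condition (lipid, ionic strength, pH, vesicle diameter).
#'
#' @return An object of class `titration_series`: a list with elements
#'   `sample_id`, `quencher_conc`, `intensity`, and `condition`.
#' @examples
#' ts <- titration_series(
#'   quencher_conc = c(0, 2.5e-7, 5e-7, 7.5e-7, 1e-6),
#'   intensity = c(100, 28.6, 16.7, 11.8, 9.1)
#' )
#' i0(ts)
#' sv_ratios(ts)
#' @export
titration_series <- function(quencher_conc, intensity, sample_id = "sample",
                             condition = NULL) {
  if (!is.numeric(quencher_conc) || !is.numeric(intensity)) {
    stop("quencher_conc and intensity must be numeric vectors", call. = FALSE)
  }
  if (length(quencher_conc) != length(intensity)) {
    stop("quencher_conc and intensity must have equal length", call. = FALSE)
  }
  if (anyNA(quencher_conc) || anyNA(intensity) ||
      any(!is.finite(quencher_conc)) || any(!is.finite(intensity))) {
    stop("non-finite values in titration data", call. = FALSE)
  }
  if (any(quencher_conc < 0)) {
    stop("quencher concentrations must be non-negative", call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(quencher_conc)) {
    stop("quencher concentrations must be unique within a series",
         call. = FALSE)
  }
  if (!any(quencher_conc == 0)) {
    stop("no zero-quencher baseline: a Q = 0 point defining I0 is required",
         call. = FALSE)
  }
  if (!is.null(condition) && !inherits(condition, "fqt_condition")) {
    stop("condition must be created with condition()", call. = FALSE)
  }
  ord <- order(quencher_conc)
  structure(
    list(
      sample_id = as.character(sample_id)[1],
      quencher_conc = quencher_conc[ord],
      intensity = intensity[ord],
      condition = condition
    ),
    class = "titration_series"
  )
}

#' Unquenched baseline intensity of a series
#'
#' @param series a [titration_series()].
#' @return The intensity measured at zero quencher concentration.
#' @export
i0 <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  series$intensity[series$quencher_conc == 0]
}

#' Observed quenching ratios of a series
#'
#' Computes the observed \eqn{I_0/I} ratio at every titration point, using
#' the zero-quencher intensity as \eqn{I_0}.
#'
#' @param series a [titration_series()].
#' @param drop_zero if `TRUE` (default) the zero-quencher point itself
#'   (ratio identically 1) is omitted.
#' @return data.frame with columns `quencher_conc` and `ratio`.
#' @export
sv_ratios <- function(series, drop_zero = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  keep <- if (drop_zero) series$quencher_conc > 0 else rep(TRUE, length(series$quencher_conc))
  data.frame(
    quencher_conc = series$quencher_conc[keep],
    ratio = i0(series) / series$intensity[keep]
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", x$sample_id, ": ", length(x$quencher_conc),
      " points, Q in [", format(min(x$quencher_conc)), ", ",
      format(max(x$quencher_conc)), "] M, I0 = ", format(i0(x)), "\n",
      sep = "")
  if (!is.null(x$condition)) print(x$condition)
  invisible(x)
}

#' @export
length.titration_series <- function(x) length(x$quencher_conc)

#' Experimental condition metadata
#'
#' Describes the vesicle preparation a titration series was measured under:
#' lipid species, buffer ionic strength, pH, and vesicle diameter (the proxy
#' for membrane curvature).
#'
#' @param lipid one of `"POPC"`, `"POPG"`, `"DOPC"`.
#' @param ionic_strength ionic strength in mM.
#' @param pH buffer pH, in (0, 14).
#' @param vesicle_diameter vesicle diameter in nm, positive.
#' @return An object of class `fqt_condition`.
#' @export
condition <- function(lipid, ionic_strength = 10, pH = 7.0,
                      vesicle_diameter = 100) {
  lipid <- match.arg(lipid, c("POPC", "POPG", "DOPC"))
  stopifnot(is.numeric(ionic_strength), ionic_strength >= 0,
            is.numeric(pH), pH > 0, pH < 14,
            is.numeric(vesicle_diameter), vesicle_diameter > 0)
  structure(
    list(lipid = lipid, ionic_strength = ionic_strength, pH = pH,
         vesicle_diameter = vesicle_diameter),
    class = "fqt_condition"
  )
}

#' @export
print.fqt_condition <- function(x, ...) {
  cat(sprintf("<condition> %s, %g mM, pH %g, %g nm\n",
              x$lipid, x$ionic_strength, x$pH, x$vesicle_diameter))
  invisible(x)
}

#' @export
format.fqt_condition <- function(x, ...) {
  sprintf("%s/%gmM/pH%g/%gnm", x$lipid, x$ionic_strength, x$pH,
          x$vesicle_diameter)
}

#' Quenching model parameters
#'
#' Bundles the Stern-Volmer quenching constant Kq (per molar) and the
#' protected fraction x (the fraction of labeled termini facing the vesicle
#' interior, inaccessible to the membrane-impermeant quencher).
#'
#' @param Kq Stern-Volmer quenching constant, 1/M, positive.
#' @param x protected fraction in \[0, 1\].
#' @return An object of class `quench_params`.
#' @export
quench_params <- function(Kq, x) {
  if (!is.numeric(Kq) || length(Kq) != 1 || !is.finite(Kq) || Kq <= 0) {
    stop("Kq must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("x must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(Kq = Kq, x = x), class = "quench_params")
}
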