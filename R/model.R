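#' Stern-Volmer quenching ratio
#'
#' The collisional quenching law for a fully quencher-accessible fluorophore:
#' \deqn{I_0/I = 1 + K_q [Q]}
#' where \eqn{K_q} is the Stern-Volmer quenching constant and \eqn{[Q]} the
#' quencher concentration.
#'
#' @param Kq Stern-Volmer constant, 1/M, positive.
#' @param Q quencher concentration, M, non-negative. Vectorized.
#' @return The dimensionless ratio \eqn{I_0/I \ge 1}.
#' @examples
#' sv_ratio(1e7, 1e-7) # 2
#' @export
sv_ratio <- function(Kq, Q) {
  check_Kq_Q(Kq, Q)
  1 + Kq * Q
}

#' Two-population quenching ratio for vesicle-reconstituted protein
#'
#' In a vesicle suspension, a fraction `x` of the labeled termini points
#' inside the vesicles and is shielded from the membrane-impermeant quencher;
#' the remaining `1 - x` is exposed and quenched per Stern-Volmer. The
#' observed ratio is
#' \deqn{I_0/I = \frac{1 + K_q [Q]}{(1 + K_q [Q])\,x + 1 - x}.}
#' At `x = 0` this reduces to [sv_ratio()]; at `x = 1` no quenching occurs
#' and the ratio is identically 1.
#'
#' @param params a [quench_params()] object (Kq and protected fraction x).
#' @param Q quencher concentration, M, non-negative. Vectorized.
#' @return The ratio \eqn{I_0/I}, in \eqn{[1, 1 + K_q Q]}.
#' @examples
#' orientation_ratio(quench_params(1e7, 0.5), 1e-7) # 4/3
#' @export
orientation_ratio <- function(params, Q) {
  stopifnot(inherits(params, "quench_params"))
  check_Kq_Q(params$Kq, Q)
  a <- 1 + params$Kq * Q
  a / (a * params$x + 1 - params$x)
}

#' Per-point inversion of the two-population model
#'
#' Algebraic rearrangement of the two-population quenching law for the
#' protected fraction at a single titration point:
#' \deqn{x = \frac{(1 + K_q Q)/r - 1}{K_q Q}}
#' with \eqn{r = I_0/I}. Exact on noise-free data; on noisy data the result
#' can fall outside \[0, 1\] and is returned unclipped so it remains an exact
#' inverse (clipping is an inference-stage concern).
#'
#' @param Kq Stern-Volmer constant, 1/M, positive.
#' @param Q quencher concentration, M, strictly positive (x is not
#'   identifiable at Q = 0). Vectorized.
#' @param ratio observed \eqn{I_0/I}, must be \eqn{\ge 1}.
#' @return Point estimate(s) of x, unclipped.
#' @examples
#' invert_point(1e7, 1e-7, 4/3) # 0.5
#' @export
invert_point <- function(Kq, Q, ratio) {
  check_Kq_Q(Kq, Q)
  if (any(Q == 0)) {
    stop("x is not identifiable at zero quencher concentration", call. = FALSE)
  }
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio < 1)) {
    stop("ratio must be finite and >= 1", call. = FALSE)
  }
  ((1 + Kq * Q) / ratio - 1) / (Kq * Q)
}

check_Kq_Q <- function(Kq, Q) {
  if (!is.numeric(Kq) || length(Kq) != 1 || !is.finite(Kq) || Kq <= 0) {
    stop("Kq must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(Q) || length(Q) < 1 || any(!is.finite(Q)) || any(Q < 0)) {
    stop("Q must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}
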