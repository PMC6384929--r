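#' Reported experimental conditions and orientation fractions
#'
#' The published study's conditions with their reported mean protected
#' fractions, used as generating truths for simulation: the three-lipid
#' baseline (replicate means and the single-experiment fits), the
#' ionic-strength series, the pH series, and the vesicle-size series. The
#' announced 250 mM ionic-strength condition was never tabulated; its rows
#' are present with `x_true = NA` and `available = FALSE`.
#'
#' @return data.frame with columns `label`, `factor` (one of `"baseline"`,
#'   `"single_experiment"`, `"ionic_strength"`, `"pH"`, `"size"`), `lipid`,
#'   `ionic_strength` (mM), `pH`, `vesicle_diameter` (nm), `x_true`
#'   (reported mean protected fraction), `x_err` (reported error), and
#'   `available`.
#' @examples
#' subset(paper_presets(), factor == "baseline")
#' @export
paper_presets <- function() {
  p <- function(label, factor, lipid, ionic, pH, diam, x, err, avail = TRUE) {
    data.frame(label = label, factor = factor, lipid = lipid,
               ionic_strength = ionic, pH = pH, vesicle_diameter = diam,
               x_true = x, x_err = err, available = avail,
               stringsAsFactors = FALSE)
  }
  rbind(
    # replicate-averaged baseline values (pH ~7, 100 nm vesicles)
    p("POPC baseline", "baseline", "POPC", 10, 7.0, 100, 0.63, 0.02),
    p("POPG baseline", "baseline", "POPG", 10, 7.0, 100, 0.40, 0.01),
    p("DOPC baseline", "baseline", "DOPC", 10, 7.0, 100, 0.53, 0.01),
    # single-experiment fits preceding replicate averaging
    p("POPC single", "single_experiment", "POPC", 10, 7.0, 100, 0.64, NA),
    p("POPG single", "single_experiment", "POPG", 10, 7.0, 100, 0.41, NA),
    p("DOPC single", "single_experiment", "DOPC", 10, 7.0, 100, 0.52, NA),
    # ionic-strength series
    p("POPC 10 mM", "ionic_strength", "POPC", 10, 7.0, 100, 0.64, 0.01),
    p("POPC 50 mM", "ionic_strength", "POPC", 50, 7.0, 100, 0.66, 0.03),
    p("POPC 250 mM", "ionic_strength", "POPC", 250, 7.0, 100, NA, NA, FALSE),
    p("POPG 10 mM", "ionic_strength", "POPG", 10, 7.0, 100, 0.41, 0.01),
    p("POPG 50 mM", "ionic_strength", "POPG", 50, 7.0, 100, 0.49, 0.01),
    p("POPG 250 mM", "ionic_strength", "POPG", 250, 7.0, 100, NA, NA, FALSE),
    # pH series
    p("POPC pH 6.2", "pH", "POPC", 10, 6.2, 100, 0.64, 0.03),
    p("POPC pH 8.0", "pH", "POPC", 10, 8.0, 100, 0.57, 0.02),
    p("POPG pH 6.2", "pH", "POPG", 10, 6.2, 100, 0.48, 0.01),
    p("POPG pH 8.0", "pH", "POPG", 10, 8.0, 100, 0.44, 0.01),
    # vesicle-size (curvature) series
    p("POPC 50 nm", "size", "POPC", 10, 7.0, 50, 0.64, 0.01),
    p("POPC 100 nm", "size", "POPC", 10, 7.0, 100, 0.64, 0.01),
    p("POPG 50 nm", "size", "POPG", 10, 7.0, 50, 0.43, 0.01),
    p("POPG 100 nm", "size", "POPG", 10, 7.0, 100, 0.40, 0.01),
    p("DOPC 50 nm", "size", "DOPC", 10, 7.0, 50, 0.57, 0.01),
    p("DOPC 100 nm", "size", "DOPC", 10, 7.0, 100, 0.53, 0.01)
  )
}

#' Look up a preset protected fraction
#'
#' Convenience accessor into [paper_presets()]: supply a lipid plus at most
#' one varying factor. With only a lipid, the baseline mean is returned;
#' with `ionic_strength`, `pH`, or `vesicle_diameter`, the matching row of
#' the corresponding series is returned.
#'
#' @param lipid `"POPC"`, `"POPG"`, or `"DOPC"`.
#' @param ionic_strength mM, selects the ionic-strength series.
#' @param pH selects the pH series.
#' @param vesicle_diameter nm, selects the size series.
#' @param single if `TRUE`, return the single-experiment baseline value.
#' @return One row of [paper_presets()].
#' @examples
#' preset("POPG", ionic_strength = 50)$x_true # 0.49
#' preset("POPC", pH = 8.0)$x_true # 0.57
#' @export
preset <- function(lipid, ionic_strength = NULL, pH = NULL,
                   vesicle_diameter = NULL, single = FALSE) {
  given <- c(!is.null(ionic_strength), !is.null(pH), !is.null(vesicle_diameter),
             isTRUE(single))
  if (sum(given) > 1) {
    stop("supply at most one of ionic_strength, pH, vesicle_diameter, single",
         call. = FALSE)
  }
  pp <- paper_presets()
  row <- if (!is.null(ionic_strength)) {
    pp[pp$factor == "ionic_strength" & pp$lipid == lipid &
         pp$ionic_strength == ionic_strength, ]
  } else if (!is.null(pH)) {
    pp[pp$factor == "pH" & pp$lipid == lipid & pp$pH == pH, ]
  } else if (!is.null(vesicle_diameter)) {
    pp[pp$factor == "size" & pp$lipid == lipid &
         pp$vesicle_diameter == vesicle_diameter, ]
  } else if (isTRUE(single)) {
    pp[pp$factor == "single_experiment" & pp$lipid == lipid, ]
  } else {
    pp[pp$factor == "baseline" & pp$lipid == lipid, ]
  }
  if (nrow(row) != 1) stop("no unique preset matches", call. = FALSE)
  row
}

#' Bundle a condition with its replicate summary
#'
#' @param condition a [condition()].
#' @param summary a [aggregate_replicates()] result.
#' @param label display label; defaults to the formatted condition.
#' @param factor which experimental factor this condition belongs to
#'   (`"baseline"`, `"ionic_strength"`, `"pH"`, `"size"`).
#' @param band classification band passed to [classify_orientation()].
#' @return An object of class `condition_result`; the orientation call is
#'   derived from the summary at construction.
#' @export
condition_result <- function(condition, summary, label = NULL,
                             factor = "baseline", band = 0.04) {
  stopifnot(inherits(condition, "fqt_condition"),
            inherits(summary, "replicate_summary"))
  structure(
    list(condition = condition, summary = summary,
         call = classify_orientation(summary, band = band),
         label = if (is.null(label)) format(condition) else label,
         factor = factor),
    class = "condition_result"
  )
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %-14s x = %.3f +/- %.3f  %s\n",
              x$label, x$summary$x_mean, x$summary$x_err, x$call$label))
  invisible(x)
}

#' Compare fitted conditions
#'
#' Produces the condition-comparison report: one row per condition (mean,
#' SEM, orientation call) and all pairwise contrasts within each factor
#' group — the three lipids at baseline, ionic strength within a lipid, pH
#' within a lipid, size within a lipid. Each contrast carries the difference
#' of means and its pooled standard error; a contrast is flagged when
#' |delta_x| exceeds twice the pooled error. No formal hypothesis test is
#' performed: the rule mirrors descriptive comparison against error bars.
#'
#' @param results list of [condition_result()] objects, at least 2.
#' @return An object of class `study_report`: list with data.frames
#'   `conditions` and `contrasts`.
#' @export
compare_conditions <- function(results) {
  if (!is.list(results) || length(results) == 0 ||
      !all(vapply(results, inherits, logical(1), "condition_result"))) {
    stop("results must be a non-empty list of condition_result objects",
         call. = FALSE)
  }
  if (length(results) < 2) {
    stop("at least 2 condition results are required", call. = FALSE)
  }
  conditions <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, factor = r$factor, lipid = r$condition$lipid,
               ionic_strength = r$condition$ionic_strength,
               pH = r$condition$pH,
               vesicle_diameter = r$condition$vesicle_diameter,
               x_mean = r$summary$x_mean, x_err = r$summary$x_err,
               n_replicates = r$summary$n_replicates,
               call = r$call$label, margin = r$call$margin,
               stringsAsFactors = FALSE)
  }))
  # lipid contrasts pool all baseline rows; other factors contrast within lipid
  group_of <- vapply(results, function(r) {
    if (r$factor == "baseline") "lipid" else paste(r$factor, r$condition$lipid)
  }, character(1))
  contrasts <- list()
  for (g in unique(group_of)) {
    idx <- which(group_of == g)
    if (length(idx) < 2) next
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (j <= i) next
        A <- results[[idx[i]]]; B <- results[[idx[j]]]
        dx <- A$summary$x_mean - B$summary$x_mean
        pe <- sqrt(A$summary$x_err^2 + B$summary$x_err^2)
        contrasts[[length(contrasts) + 1]] <- data.frame(
          group = g, condition_a = A$label, condition_b = B$label,
          delta_x = dx, pooled_err = pe,
          flagged = abs(dx) > 2 * pe, stringsAsFactors = FALSE)
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts)
               else data.frame(group = character(0), condition_a = character(0),
                               condition_b = character(0), delta_x = numeric(0),
                               pooled_err = numeric(0), flagged = logical(0))
  structure(list(conditions = conditions, contrasts = contrasts),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\nConditions:\n")
  print(x$conditions[, c("label", "x_mean", "x_err", "call")],
        row.names = FALSE, digits = 3)
  cat("Contrasts (flagged when |delta| > 2 pooled err):\n")
  print(x$contrasts, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full synthetic study pipeline
#'
#' presets -> simulate replicated titrations -> fit each replicate with the
#' quenching constant fixed -> aggregate -> classify -> compare. This is the
#' end-to-end counterpart of the published workflow, driven entirely by the
#' synthetic generator.
#'
#' @param presets rows of [paper_presets()] to simulate (default: every
#'   available row except the single-experiment duplicates).
#' @param Kq fixed Stern-Volmer constant used both to generate and to fit
#'   (two-stage: assumed calibrated beforehand), 1/M.
#' @param noise_cv,n_replicates,seed simulation controls, see
#'   [generate_study()].
#' @param band classification band, see [classify_orientation()].
#' @return A `study_report` (see [compare_conditions()]); the underlying
#'   `condition_result` list is attached as attribute `"results"`.
#' @export
run_study <- function(presets = NULL, Kq = 1e7, noise_cv = 0.015,
                      n_replicates = 5, seed, band = 0.04) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(presets)) {
    presets <- paper_presets()
    presets <- presets[presets$available & presets$factor != "single_experiment", ]
  }
  presets <- presets[!is.na(presets$x_true), , drop = FALSE]
  sim <- generate_study(presets, noise_cv = noise_cv,
                        n_replicates = n_replicates, seed = seed,
                        Kq_true = Kq)
  results <- lapply(seq_along(sim), function(i) {
    fits <- lapply(sim[[i]]$replicates, fit_orientation_fraction, Kq = Kq)
    condition_result(sim[[i]]$condition, aggregate_replicates(fits),
                     label = sim[[i]]$label,
                     factor = presets$factor[i], band = band)
  })
  report <- compare_conditions(results)
  attr(report, "results") <- results
  report
}
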