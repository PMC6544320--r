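#' Normalize a log10-scale AUC to its maximal possible inhibition
#'
#' The raw area under a dose-response curve on `[c1, c2]` (fraction x log10
#' units) is rescaled to the proportion of the maximal attainable area after
#' discounting a minimum inhibition floor `inh_min` treated as experimental
#' noise:
#' `AUC' = (AUC - inh_min (c2 - c1)) / ((1 - inh_min) (c2 - c1))`.
#' A curve sitting entirely at the noise floor scores 0; a curve pinned at
#' 100% inhibition scores 1. Values outside `[0, 1]` (curves below the floor,
#' or fallback areas from out-of-range observations) are clipped with a
#' message.
#'
#' @param auc area from [combination_auc()] or [monotherapy_auc()].
#' @param conc_range the curve's `[c1, c2]` log10 concentration range.
#' @param inh_min noise-floor fraction in `[0, 1)`; default 0.10.
#' @return normalized fraction in `[0, 1]`.
#' @examples
#' normalize_auc(0.55 * 4, c(-2, 2), 0.10)  # constant 55% inhibition -> 0.5
#' @export
normalize_auc <- function(auc, conc_range, inh_min = 0.10) {
  c1 <- conc_range[1]; c2 <- conc_range[2]
  if (!(c2 > c1))
    stop_combosens("conc_range must satisfy c2 > c1",
                   class = "combosens_value_error")
  if (!(inh_min >= 0 && inh_min < 1))
    stop_combosens("inh_min must be in [0, 1)",
                   class = "combosens_value_error")
  w <- c2 - c1
  raw <- (auc - inh_min * w) / ((1 - inh_min) * w)
  if (raw < 0 || raw > 1)
    message(sprintf("normalized AUC %.4f clipped to [0, 1]", raw))
  clip01(raw)
}

#' Combination sensitivity score from a cross-design record
#'
#' Fits the four-parameter log-logistic curve to each arm of the cross (each
#' drug titrated over the partner fixed near its IC50), integrates it over the
#' tested log10 range, normalizes against the noise floor, and scales to a
#' percentage. `css1` comes from the arm with the row drug as background,
#' `css2` from the mirrored arm; `css` is their mean. The absolute
#' `css1`-`css2` difference acts as a replicate-style consistency QC:
#' `qc_pass` is `TRUE` when `|css1 - css2| <= qc_threshold` (differences
#' strictly exceeding the threshold fail).
#'
#' @param rec a [extract_cross()] record.
#' @param inh_min noise-floor fraction; default 0.10.
#' @param qc_threshold consistency threshold in CSS units; default 10.
#' @return a `css_result`: list with `block_id`, `css1`, `css2`, `css`,
#'   `abs_diff`, `qc_pass`, `inh_min`, and the two fitted curves.
#' @export
css_from_cross <- function(rec, inh_min = 0.10, qc_threshold = 10) {
  stopifnot(inherits(rec, "cross_design_record"))
  fit1 <- fit_combination_curve(rec$curve1_points$conc,
                                rec$curve1_points$inhibition)
  fit2 <- fit_combination_curve(rec$curve2_points$conc,
                                rec$curve2_points$inhibition)
  css1 <- 100 * normalize_auc(combination_auc(fit1), fit1$conc_range, inh_min)
  css2 <- 100 * normalize_auc(combination_auc(fit2), fit2$conc_range, inh_min)
  css <- (css1 + css2) / 2
  abs_diff <- abs(css1 - css2)
  structure(
    list(block_id = rec$block_id, css1 = css1, css2 = css2, css = css,
         abs_diff = abs_diff, qc_pass = abs_diff <= qc_threshold,
         inh_min = inh_min, curve1 = fit1, curve2 = fit2),
    class = "css_result"
  )
}

#' @export
print.css_result <- function(x, ...) {
  cat(sprintf("CSS [%s]: css1=%.2f css2=%.2f css=%.2f |diff|=%.2f qc=%s\n",
              x$block_id, x$css1, x$css2, x$css, x$abs_diff,
              if (x$qc_pass) "pass" else "fail"))
  invisible(x)
}

#' Tabulate CSS results
#'
#' @param results list of `css_result` objects.
#' @return data frame with one row per block (scores reported to full
#'   precision; round for display).
#' @export
css_table <- function(results) {
  if (inherits(results, "css_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(block_id = r$block_id, css1 = r$css1, css2 = r$css2,
               css = r$css, abs_diff = r$abs_diff, qc_pass = r$qc_pass,
               inh_min = r$inh_min, stringsAsFactors = FALSE)))
}

#' Partition CSS results by the consistency QC
#'
#' Splits scored blocks on the absolute `css1`-`css2` difference: blocks whose
#' difference strictly exceeds the threshold fail (a difference exactly at the
#' threshold passes).
#'
#' @param results a [css_table()] data frame (needs an `abs_diff` column) or a
#'   list of `css_result` objects.
#' @param threshold QC threshold in CSS units; default 10.
#' @return list with `pass` and `fail` data frames and counts `n_pass`,
#'   `n_fail`.
#' @export
qc_filter <- function(results, threshold = 10) {
  df <- if (is.data.frame(results)) results else css_table(results)
  if (is.null(df) || nrow(df) == 0L)
    stop_combosens("no results to filter", class = "combosens_value_error")
  ok <- df$abs_diff <= threshold
  list(pass = df[ok, , drop = FALSE], fail = df[!ok, , drop = FALSE],
       n_pass = sum(ok), n_fail = sum(!ok))
}
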