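#' Cross-design S synergy scores
#'
#' The S scores quantify synergy as the CSS minus a reference built from the
#' normalized monotherapy AUCs, all on the percent-inhibition scale so that
#' sensitivity and synergy are directly comparable:
#' `S_sum = CSS - (AUC1 + AUC2)`, `S_max = CSS - max(AUC1, AUC2)`,
#' `S_mean = CSS - mean(AUC1, AUC2)`, where
#' `AUC_i = 100 * normalize_auc(monotherapy_auc(mono_i))` with the same
#' `inh_min` noise floor used for the CSS. Since `sum >= max >= mean` for
#' non-negative AUCs, `S_sum <= S_max <= S_mean` always; `S_sum` is the most
#' conservative variant.
#'
#' @param css combination sensitivity score in `[0, 100]`.
#' @param mono1,mono2 fitted [fit_monotherapy_curve()] objects.
#' @param inh_min noise-floor fraction; default 0.10.
#' @return list with `s_sum`, `s_max`, `s_mean`, `auc1_pct`, `auc2_pct`.
#' @export
s_scores <- function(css, mono1, mono2, inh_min = 0.10) {
  stopifnot(css >= 0, css <= 100)
  auc1 <- 100 * normalize_auc(monotherapy_auc(mono1), mono1$conc_range,
                              inh_min)
  auc2 <- 100 * normalize_auc(monotherapy_auc(mono2), mono2$conc_range,
                              inh_min)
  list(s_sum = css - (auc1 + auc2),
       s_max = css - max(auc1, auc2),
       s_mean = css - mean(c(auc1, auc2)),
       auc1_pct = auc1, auc2_pct = auc2)
}

#' Per-cell reference-model synergy scores
#'
#' Deviation of an observed combination effect `y_c` (fraction) from the
#' expected effect `y_e` under a null model of no interaction:
#' * HSA: `y_e = max(y1, y2)`, the highest single-agent effect;
#' * Bliss: `y_e = y1 + y2 - y1 y2`, probabilistic independence;
#' * Loewe (dose-additivity form): `y_e` is the effect of the summed dose on
#'   a drug combined with itself, computed here as the mean of the two fitted
#'   monotherapy curves evaluated at `x1 + x2` (the two evaluations coincide
#'   when the curves are identical, which is the model's premise).
#'
#' @param y_c observed combination fractional inhibition.
#' @param y1,y2 observed single-drug fractional inhibition at the cell's
#'   doses.
#' @return score fraction (positive = more inhibition than expected).
#' @examples
#' hsa_cell(0.6, 0.5, 0.3)     # 0.1
#' bliss_cell(0.75, 0.5, 0.5)  # 0
#' @export
hsa_cell <- function(y_c, y1, y2) y_c - pmax(y1, y2)

#' @rdname hsa_cell
#' @export
bliss_cell <- function(y_c, y1, y2) {
  stopifnot(all(y1 >= 0 & y1 <= 1), all(y2 >= 0 & y2 <= 1))
  y_c - (y1 + y2 - y1 * y2)
}

#' @rdname hsa_cell
#' @param x1,x2 the two doses (raw concentration; `x1 + x2 > 0`).
#' @param mono1,mono2 fitted monotherapy curves.
#' @export
loewe_cell <- function(y_c, x1, x2, mono1, mono2) {
  stopifnot(all(x1 + x2 > 0))
  y_e <- (predict(mono1, x1 + x2) + predict(mono2, x1 + x2)) / 2
  y_c - y_e
}

#' ZIP score at one cell of a full dose-response matrix
#'
#' The zero-interaction-potency score compares curve-smoothed values rather
#' than raw observations: `y'1(x1)` and `y'2(x2)` come from the fitted
#' monotherapy curves, and `y'c` is the mean of two four-parameter
#' log-logistic fits through the full matrix - one along the row (drug 2
#' titrated with drug 1 fixed at `x1`) and one along the column - each
#' evaluated at `(x1, x2)`. The score is `y'c - (y'1 + y'2 - y'1 y'2)`.
#' If one directional fit fails the other is used alone; if both fail the
#' observed cell value is used and flagged with a warning.
#'
#' @param matrix a `dose_response_matrix` with full row and column through
#'   `at`.
#' @param mono1,mono2 fitted monotherapy curves of the row and column drugs.
#' @param at numeric `(x1, x2)`: row-drug and column-drug doses, both tested
#'   and nonzero.
#' @return score fraction.
#' @export
zip_cell <- function(matrix, mono1, mono2, at) {
  stopifnot(inherits(matrix, "dose_response_matrix"), length(at) == 2)
  x1 <- at[1]; x2 <- at[2]
  i <- match(x1, matrix$row_concs)
  j <- match(x2, matrix$col_concs)
  if (is.na(i) || is.na(j) || x1 <= 0 || x2 <= 0)
    stop_combosens("`at` must name tested nonzero doses",
                   class = "combosens_value_error")
  row_fit <- fit_matrix_slice(matrix, "row", i)
  col_fit <- fit_matrix_slice(matrix, "col", j)
  y_obs <- matrix$inhibition[i, j] / 100
  yc <- zip_smoothed_yc(row_fit, col_fit, x1, x2, y_obs)
  y1 <- predict(mono1, x1)
  y2 <- predict(mono2, x2)
  yc - (y1 + y2 - y1 * y2)
}

# 4PL fit through one row (drug 2 varying) or column (drug 1 varying)
fit_matrix_slice <- function(matrix, dir = c("row", "col"), idx) {
  dir <- match.arg(dir)
  if (dir == "row") {
    keep <- matrix$col_concs > 0
    conc <- matrix$col_concs[keep]
    y <- matrix$inhibition[idx, keep]
  } else {
    keep <- matrix$row_concs > 0
    conc <- matrix$row_concs[keep]
    y <- matrix$inhibition[keep, idx]
  }
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(NULL)
  tryCatch(fit_combination_curve(conc[ok], y[ok]), error = function(e) NULL)
}

zip_smoothed_yc <- function(row_fit, col_fit, x1, x2, y_obs) {
  vals <- c(
    if (!is.null(row_fit)) predict(row_fit, x2),
    if (!is.null(col_fit)) predict(col_fit, x1)
  )
  if (length(vals) == 0L) {
    warning("ZIP: both directional fits failed; using observed value")
    return(y_obs)
  }
  mean(vals)
}

#' Matrix-averaged reference synergy scores
#'
#' Computes the HSA, Bliss, Loewe and ZIP scores at every combination cell
#' (both doses strictly positive) of a full dose-response matrix and averages
#' each, on the percent scale. Zero-dose margins are required: they supply the
#' observed single-agent effects (HSA, Bliss) and the monotherapy curve fits
#' (Loewe, ZIP). Margin cells themselves are excluded from the averages. The
#' consensus label calls a combination synergistic when all four averages
#' strictly exceed `consensus_threshold`, antagonistic when all four fall
#' strictly below its negative, and non-interactive otherwise.
#'
#' @param matrix a `dose_response_matrix` including zero-dose row and column.
#' @param consensus_threshold percent-scale threshold; default 5.
#' @return a `matrix_synergy` list: `hsa`, `bliss`, `loewe`, `zip`
#'   (percent-scale averages), `consensus_label`, `n_cells`, the two fitted
#'   monotherapy curves, and a per-cell score data frame `cells`.
#' @export
matrix_synergy <- function(matrix, consensus_threshold = 5) {
  stopifnot(inherits(matrix, "dose_response_matrix"))
  if (!(0 %in% matrix$row_concs && 0 %in% matrix$col_concs))
    stop_combosens("matrix lacks zero-dose margins",
                   class = "combosens_design_error")
  i0 <- match(0, matrix$row_concs)
  j0 <- match(0, matrix$col_concs)
  nz_ri <- which(matrix$row_concs > 0)
  nz_ci <- which(matrix$col_concs > 0)
  Y <- matrix$inhibition / 100

  mono1_y <- Y[nz_ri, j0]            # observed row-drug monotherapy
  mono2_y <- Y[i0, nz_ci]            # observed column-drug monotherapy
  if (all(is.na(mono1_y)) || all(is.na(mono2_y)))
    stop_combosens("matrix lacks usable monotherapy margins",
                   class = "combosens_design_error")
  mono1 <- fit_monotherapy_curve(matrix$row_concs[nz_ri], 100 * mono1_y)
  mono2 <- fit_monotherapy_curve(matrix$col_concs[nz_ci], 100 * mono2_y)

  row_fits <- lapply(nz_ri, function(i) fit_matrix_slice(matrix, "row", i))
  col_fits <- lapply(nz_ci, function(j) fit_matrix_slice(matrix, "col", j))

  cells <- expand.grid(ri = seq_along(nz_ri), ci = seq_along(nz_ci))
  res <- lapply(seq_len(nrow(cells)), function(k) {
    ri <- cells$ri[k]; ci <- cells$ci[k]
    i <- nz_ri[ri]; j <- nz_ci[ci]
    y_c <- Y[i, j]
    if (is.na(y_c)) return(NULL)
    x1 <- matrix$row_concs[i]; x2 <- matrix$col_concs[j]
    y1o <- mono1_y[ri]; y2o <- mono2_y[ci]
    # observed margins for HSA/Bliss (clip into the unit box for Bliss'
    # probabilistic form); fitted curves for Loewe/ZIP
    y1b <- clip01(y1o); y2b <- clip01(y2o)
    y1f <- predict(mono1, x1); y2f <- predict(mono2, x2)
    yc_fit <- zip_smoothed_yc(row_fits[[ri]], col_fits[[ci]], x1, x2, y_c)
    data.frame(
      conc_row = x1, conc_col = x2, y_c = y_c,
      hsa = if (is.na(y1o) || is.na(y2o)) NA_real_ else
        hsa_cell(y_c, y1o, y2o),
      bliss = if (is.na(y1o) || is.na(y2o)) NA_real_ else
        bliss_cell(y_c, y1b, y2b),
      loewe = y_c - (predict(mono1, x1 + x2) + predict(mono2, x1 + x2)) / 2,
      zip = yc_fit - (y1f + y2f - y1f * y2f)
    )
  })
  cells_df <- do.call(rbind, res)
  if (is.null(cells_df) || nrow(cells_df) == 0L)
    stop_combosens("no combination cells with both doses > 0",
                   class = "combosens_design_error")
  avg <- function(v) 100 * mean(v, na.rm = TRUE)
  scores <- c(hsa = avg(cells_df$hsa), bliss = avg(cells_df$bliss),
              loewe = avg(cells_df$loewe), zip = avg(cells_df$zip))
  structure(
    list(block_id = matrix$block_id, hsa = scores[["hsa"]],
         bliss = scores[["bliss"]], loewe = scores[["loewe"]],
         zip = scores[["zip"]],
         consensus_label = consensus_label(scores, consensus_threshold),
         n_cells = nrow(cells_df), mono1 = mono1, mono2 = mono2,
         cells = cells_df),
    class = "matrix_synergy"
  )
}

#' @export
print.matrix_synergy <- function(x, ...) {
  cat(sprintf(
    "matrix synergy [%s]: HSA=%.2f Bliss=%.2f Loewe=%.2f ZIP=%.2f -> %s\n",
    x$block_id, x$hsa, x$bliss, x$loewe, x$zip, x$consensus_label))
  invisible(x)
}

#' Consensus synergy/antagonism call across the four reference models
#'
#' @param scores numeric vector of the four matrix-averaged reference scores
#'   (percent scale).
#' @param threshold percent threshold; default 5.
#' @return `"synergistic"` if all scores are strictly above `threshold`,
#'   `"antagonistic"` if all are strictly below `-threshold`, else
#'   `"non-interactive"`.
#' @examples
#' consensus_label(c(6, 7, 8, 9))
#' consensus_label(c(6, -2, 8, 9))
#' @export
consensus_label <- function(scores, threshold = 5) {
  scores <- unlist(scores)
  if (any(!is.finite(scores)))
    stop_combosens("non-finite reference scores",
                   class = "combosens_value_error")
  if (all(scores > threshold)) "synergistic"
  else if (all(scores < -threshold)) "antagonistic"
  else "non-interactive"
}

#' Evaluate S scores against the consensus ground truth
#'
#' Treats consensus-synergistic blocks as positives and consensus-antagonistic
#' blocks as negatives (non-interactive blocks are excluded) and measures how
#' well each S variant ranks positives above negatives: AUROC by the
#' rank-based (Mann-Whitney) formula with tied scores given their average
#' rank, and AUPRC as precision at each recall step with tied scores processed
#' as one block.
#'
#' @param results data frame with a `consensus_label` column and one column
#'   per S variant.
#' @param variants S-score column names to evaluate.
#' @return data frame with one row per variant: `variant`, `auroc`, `auprc`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_s_scores <- function(results,
                              variants = c("s_sum", "s_max", "s_mean")) {
  stopifnot(is.data.frame(results), "consensus_label" %in% names(results))
  keep <- results$consensus_label %in% c("synergistic", "antagonistic")
  df <- results[keep, , drop = FALSE]
  pos <- df$consensus_label == "synergistic"
  if (sum(pos) == 0L || sum(!pos) == 0L)
    stop_combosens("need at least one synergistic and one antagonistic block",
                   class = "combosens_value_error")
  do.call(rbind, lapply(variants, function(v) {
    data.frame(variant = v,
               auroc = auroc(df[[v]], pos),
               auprc = average_precision(df[[v]], pos),
               n_pos = sum(pos), n_neg = sum(!pos),
               stringsAsFactors = FALSE)
  }))
}

#' Rank-based AUROC and step-function AUPRC
#'
#' `auroc` is the probability that a random positive outscores a random
#' negative, ties counting one half (equivalently the trapezoidal area under
#' the ROC curve with tie-averaged ranks). `average_precision` sums, over
#' descending unique score levels, the precision attained after each level
#' weighted by the positives it adds, divided by the total positives.
#'
#' @param score numeric scores (higher = more synergistic).
#' @param positive logical vector, `TRUE` for positives.
#' @return scalar in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auroc
#' @export
average_precision <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  o <- order(-score)
  s <- score[o]; p <- positive[o]
  grp <- cumsum(!duplicated(s))
  tp_b <- tapply(as.numeric(p), grp, sum)
  n_b <- tapply(rep(1, length(p)), grp, sum)
  tp <- cumsum(tp_b); n <- cumsum(n_b)
  sum(tp_b * (tp / n)) / sum(p)
}

#' S-S (sensitivity-synergy) prioritization
#'
#' Joins CSS and synergy results on `block_id` and flags the combinations in
#' the upper-right corner of the S-S plot: CSS at or above its `quantile`
#' threshold and the chosen S variant at or above its own. Quantiles use
#' linear interpolation (R type 7). With the default 0.75 this selects hits at
#' the 75th percentile and above on both axes.
#'
#' @param css_results [css_table()]-style data frame with `block_id`, `css`.
#' @param synergy_results data frame with `block_id` and the S variant column.
#' @param s_variant which S score to use; default `"s_sum"` (the most
#'   conservative variant).
#' @param quantile probability for both thresholds; default 0.75.
#' @return the joined data frame with logical column `hit`, plus attributes
#'   `css_threshold` and `s_threshold`.
#' @export
ss_prioritize <- function(css_results, synergy_results, s_variant = "s_sum",
                          quantile = 0.75) {
  stopifnot("css" %in% names(css_results),
            s_variant %in% names(synergy_results))
  df <- merge(css_results, synergy_results, by = "block_id")
  if (nrow(df) == 0L)
    stop_combosens("no blocks shared between css and synergy results",
                   class = "combosens_value_error")
  q_css <- stats::quantile(df$css, quantile, type = 7, names = FALSE)
  q_s <- stats::quantile(df[[s_variant]], quantile, type = 7, names = FALSE)
  df$hit <- df$css >= q_css & df[[s_variant]] >= q_s
  attr(df, "css_threshold") <- q_css
  attr(df, "s_threshold") <- q_s
  df
}
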