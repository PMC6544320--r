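flat_mono <- function(level, conc_range = c(-1, 1)) {
  combosens:::new_monotherapy_curve(
    a = level, b = 0, c = 0, conc_range = conc_range, flat = TRUE,
    fit = list(fallback = FALSE), points = NULL)
}

test_that("s_scores arithmetic and ordering", {
  # flat monotherapy curves give exact normalized AUCs:
  # level 0.37 -> (0.37 - 0.1)/0.9 = 0.30; level 0.28 -> 0.20
  s <- s_scores(60, flat_mono(0.37), flat_mono(0.28))
  expect_equal(s$auc1_pct, 30, tolerance = 1e-10)
  expect_equal(s$auc2_pct, 20, tolerance = 1e-10)
  expect_equal(s$s_sum, 10, tolerance = 1e-10)
  expect_equal(s$s_max, 30, tolerance = 1e-10)
  expect_equal(s$s_mean, 35, tolerance = 1e-10)

  # zero monotherapy effect: every variant equals the CSS
  s0 <- suppressMessages(s_scores(42, flat_mono(0), flat_mono(0)))
  expect_equal(s0$s_sum, 42)
  expect_equal(s0$s_max, 42)
  expect_equal(s0$s_mean, 42)

  # additivity boundary for s_sum
  sb <- s_scores(50, flat_mono(0.325), flat_mono(0.325))
  expect_equal(sb$s_sum, 0, tolerance = 1e-10)
  expect_equal(sb$s_max, 25, tolerance = 1e-10)
})

test_that("per-cell reference scores match their formulas", {
  expect_equal(hsa_cell(0.6, 0.5, 0.3), 0.1)
  expect_equal(hsa_cell(0.5, 0.5, 0.2), 0)
  expect_equal(hsa_cell(0.2, 0.5, 0.3), -0.3)

  expect_equal(bliss_cell(0.75, 0.5, 0.5), 0)
  expect_equal(bliss_cell(0.5, 0.2, 0.3), 0.06)
  expect_equal(bliss_cell(0.4, 0, 0), 0.4)

  # Loewe: a drug combined with itself is exactly additive
  m <- fit_monotherapy_curve(make_logistic3_points(0.8, 1, 0)$conc,
                             make_logistic3_points(0.8, 1, 0)$inhibition)
  y_self <- predict(m, 3)  # effect of the summed dose 1 + 2
  expect_equal(loewe_cell(y_self, 1, 2, m, m), 0, tolerance = 1e-6)
  expect_equal(loewe_cell(0.3, 1, 2, flat_mono(0), flat_mono(0)), 0.3)

  # symmetry: swapping drug labels (and doses) leaves the score unchanged
  m2 <- fit_monotherapy_curve(make_logistic3_points(0.6, 2, 0.3)$conc,
                              make_logistic3_points(0.6, 2, 0.3)$inhibition)
  expect_equal(loewe_cell(0.5, 1, 2, m, m2), loewe_cell(0.5, 2, 1, m2, m))
})

test_that("ZIP recovers zero interaction and uniform potentiation", {
  # noiseless Bliss-built matrix: zip ~ 0 at every combination cell
  spec <- sim_spec(model = "bliss", delta = 0, noise_sd = 0, seed = 1)
  mat <- build_matrix(simulate_matrix(spec))
  syn <- matrix_synergy(mat)
  expect_true(all(abs(syn$cells$zip) < 1e-3))

  # +0.1 uniform potentiation above the Bliss surface; low-efficacy
  # monotherapies keep every expectation away from the [0, 1] clip
  spec_up <- sim_spec(mono1 = list(a = 0.6, b = 2, c = 0),
                      mono2 = list(a = 0.5, b = 2, c = log10(2)),
                      model = "bliss", delta = 0.1, noise_sd = 0, seed = 1)
  syn_up <- matrix_synergy(build_matrix(simulate_matrix(spec_up)))
  expect_equal(mean(syn_up$cells$zip), 0.1, tolerance = 1e-3)

  # everything flat at zero
  rec0 <- make_records(conc_row = rep(c(0, 1, 10), each = 3),
                       conc_col = rep(c(0, 1, 10), times = 3),
                       inhibition = 0)
  syn0 <- matrix_synergy(build_matrix(rec0))
  expect_equal(syn0$zip, 0, tolerance = 1e-10)
  expect_equal(syn0$hsa, 0)
  expect_equal(syn0$bliss, 0)
  expect_equal(syn0$loewe, 0)

  # single-cell accessor agrees with the matrix-level computation
  at <- c(mat$row_concs[3], mat$col_concs[3])
  cell <- syn$cells[syn$cells$conc_row == at[1] &
                      syn$cells$conc_col == at[2], ]
  expect_equal(zip_cell(mat, syn$mono1, syn$mono2, at), cell$zip,
               tolerance = 1e-12)
})

test_that("matrix averages hit construction targets and need margins", {
  # Bliss-built noiseless matrix: bliss average identically zero
  spec <- sim_spec(model = "bliss", delta = 0, noise_sd = 0, seed = 2)
  syn <- matrix_synergy(build_matrix(simulate_matrix(spec)))
  expect_lt(abs(syn$bliss), 1e-6)

  # HSA-built matrix, +0.1 everywhere -> hsa average exactly 10 percent
  spec_h <- sim_spec(model = "hsa", delta = 0.1, noise_sd = 0, seed = 2)
  syn_h <- matrix_synergy(build_matrix(simulate_matrix(spec_h)))
  expect_equal(syn_h$hsa, 10, tolerance = 1e-6)

  no_margin <- make_records(conc_row = rep(c(1, 10), each = 2),
                            conc_col = rep(c(1, 10), times = 2),
                            inhibition = 50)
  expect_error(matrix_synergy(build_matrix(no_margin)),
               class = "combosens_design_error")
})

test_that("per-cell scores shift one-for-one with the observed effect", {
  # antisymmetry under y_c perturbation: +delta to y_c adds delta to score
  d <- 0.07
  expect_equal(hsa_cell(0.6 + d, 0.5, 0.3), hsa_cell(0.6, 0.5, 0.3) + d)
  expect_equal(bliss_cell(0.5 + d, 0.2, 0.3), bliss_cell(0.5, 0.2, 0.3) + d)
  m <- flat_mono(0.2)
  expect_equal(loewe_cell(0.5 + d, 1, 1, m, m),
               loewe_cell(0.5, 1, 1, m, m) + d)
})

test_that("matrix-level scores are invariant under drug-label transposition", {
  spec <- sim_spec(model = "bliss", delta = 0.08, seed = 31)
  rec <- simulate_matrix(spec)
  swapped <- rec
  swapped$drug_row <- rec$drug_col; swapped$drug_col <- rec$drug_row
  swapped$conc_row <- rec$conc_col; swapped$conc_col <- rec$conc_row
  a <- matrix_synergy(build_matrix(rec))
  b <- matrix_synergy(build_matrix(swapped))
  for (sc in c("hsa", "bliss", "loewe", "zip"))
    expect_equal(a[[sc]], b[[sc]], tolerance = 1e-6)
  expect_equal(a$consensus_label, b$consensus_label)
})

test_that("consensus_label follows the strict all-four rule", {
  expect_equal(consensus_label(c(6, 7, 8, 9)), "synergistic")
  expect_equal(consensus_label(c(-6, -7, -8, -9)), "antagonistic")
  expect_equal(consensus_label(c(6, -2, 8, 9)), "non-interactive")
  expect_equal(consensus_label(c(5, 6, 7, 8)), "non-interactive")  # strict >
  expect_error(consensus_label(c(NA, 1, 1, 1)),
               class = "combosens_value_error")
})

test_that("AUROC and AUPRC handle separation, ties and the 2/3 case", {
  df <- data.frame(consensus_label = rep(c("synergistic", "antagonistic"),
                                         each = 3),
                   s_sum = c(10, 9, 8, 1, 2, 3),
                   s_max = c(5, 5, 5, 5, 5, 5),
                   s_mean = c(10, 8, 6, 7, 0, 0))
  out <- evaluate_s_scores(df)
  expect_equal(out$auroc[out$variant == "s_sum"], 1)
  expect_equal(out$auprc[out$variant == "s_sum"], 1)
  expect_equal(out$auroc[out$variant == "s_max"], 0.5)  # all tied

  # 3 synergistic {10, 8, 6} vs 1 antagonistic {7}: 2 of 3 pairs correct
  df2 <- data.frame(consensus_label = c(rep("synergistic", 3),
                                        "antagonistic"),
                    s_sum = c(10, 8, 6, 7))
  expect_equal(evaluate_s_scores(df2, "s_sum")$auroc, 2 / 3)

  df_one <- df[df$consensus_label == "synergistic", ]
  expect_error(evaluate_s_scores(df_one), class = "combosens_value_error")
})

test_that("ss_prioritize applies interpolated 75th-percentile thresholds", {
  css_df <- data.frame(block_id = letters[1:4], css = c(10, 20, 30, 40))
  syn_df <- data.frame(block_id = letters[1:4], s_sum = 1:4)
  out <- ss_prioritize(css_df, syn_df)
  expect_equal(attr(out, "css_threshold"), 32.5)
  expect_equal(attr(out, "s_threshold"), 3.25)
  expect_equal(out$block_id[out$hit], "d")

  same <- ss_prioritize(data.frame(block_id = letters[1:3], css = 7),
                        data.frame(block_id = letters[1:3], s_sum = 2))
  expect_true(all(same$hit))

  anti <- ss_prioritize(
    data.frame(block_id = letters[1:4], css = c(40, 30, 20, 10)),
    data.frame(block_id = letters[1:4], s_sum = 1:4))
  expect_equal(sum(anti$hit), 0L)
})
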