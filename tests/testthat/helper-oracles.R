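# independent numerical oracles and fixture builders, used across tests

# adaptive-quadrature area under the 4PL curve (independent of the closed
# form under test)
quad_auc_4pl <- function(y_min, y_max, lambda, m, c1, c2) {
  stats::integrate(function(x) y_min + (y_max - y_min) /
                     (1 + 10^(lambda * (m - x))),
                   c1, c2, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_auc_logistic3 <- function(a, b, c, c1, c2) {
  stats::integrate(function(x) a / (1 + 10^(b * (c - x))),
                   c1, c2, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# noiseless 4PL points on a log-spaced grid
make_4pl_points <- function(y_min, y_max, lambda, m, c1 = m - 2, c2 = m + 2,
                            n = 8) {
  conc <- 10^seq(c1, c2, length.out = n)
  list(conc = conc,
       inhibition = 100 * (y_min + (y_max - y_min) /
                             (1 + 10^(lambda * (m - log10(conc))))))
}

make_logistic3_points <- function(a, b, c, c1 = c - 2, c2 = c + 2, n = 8) {
  conc <- 10^seq(c1, c2, length.out = n)
  list(conc = conc,
       inhibition = 100 * a / (1 + 10^(b * (c - log10(conc)))))
}

# brute-force grid search over the 4PL parameter box: crude RSS floor used as
# an independent check that the optimiser found at least as good a fit
grid_search_rss_4pl <- function(conc, inhibition) {
  x <- log10(conc)
  y <- pmin(1, pmax(0, inhibition / 100))
  best <- Inf
  for (y_min in seq(0, 1, by = 0.1))
    for (y_max in seq(y_min, 1, by = 0.1))
      for (lambda in c(-4, -2, -1, -0.5, 0.5, 1, 2, 4))
        for (m in seq(min(x) - 2, max(x) + 2, length.out = 21)) {
          f <- y_min + (y_max - y_min) / (1 + 10^(lambda * (m - x)))
          rss <- sum((f - y)^2)
          if (rss < best) best <- rss
        }
  best
}

# hand-built cross record with both arms constant at the given percent levels
flat_cross_record <- function(level1, level2, concs = 10^seq(-1, 1, len = 5)) {
  structure(list(
    block_id = "flat", drug_row = "d1", drug_col = "d2", cell_line = "cl",
    background1_conc = 1,
    curve1_points = data.frame(conc = concs, inhibition = level1),
    background2_conc = 1,
    curve2_points = data.frame(conc = concs, inhibition = level2),
    mono1_points = NULL, mono2_points = NULL
  ), class = "cross_design_record")
}

# long-format records for a tiny block, one row per (cr, cc, rep)
make_records <- function(block_id = "b1", conc_row, conc_col, inhibition,
                         replicate = 1L, drug_row = "A", drug_col = "B") {
  out <- data.frame(block_id = block_id, drug_row = drug_row,
                    drug_col = drug_col, conc_row = conc_row,
                    conc_col = conc_col, inhibition = inhibition,
                    cell_line = "cl", replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_records", class(out))
  out
}

# score one simulated block end to end (cross S scores + matrix consensus)
score_sim_block <- function(delta, seed, model = "bliss", noise_sd = 0.066) {
  spec <- sim_spec(model = model, delta = delta, noise_sd = noise_sd,
                   seed = seed)
  mat <- build_matrix(simulate_matrix(spec))
  syn <- matrix_synergy(mat)
  rec <- extract_cross(mat, 10^spec$mono1$c, 10^spec$mono2$c)
  cssr <- css_from_cross(rec)
  s <- s_scores(cssr$css, syn$mono1, syn$mono2)
  data.frame(delta = delta, css = cssr$css, s_sum = s$s_sum,
             s_max = s$s_max, s_mean = s$s_mean,
             hsa = syn$hsa, bliss = syn$bliss, loewe = syn$loewe,
             zip = syn$zip, label = syn$consensus_label,
             stringsAsFactors = FALSE)
}
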