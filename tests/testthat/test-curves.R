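test_that("noiseless 4PL points are recovered within tight tolerance", {
  cases <- list(
    c(y_min = 0, y_max = 1, lambda = 1, m = 0),
    c(y_min = 0.1, y_max = 0.8, lambda = 2, m = 0.5),
    c(y_min = 0.05, y_max = 0.95, lambda = 0.7, m = -1)
  )
  for (p in cases) {
    pts <- make_4pl_points(p["y_min"], p["y_max"], p["lambda"], p["m"])
    fit <- fit_combination_curve(pts$conc, pts$inhibition)
    expect_true(fit$fit$converged)
    expect_equal(fit$y_min, unname(p["y_min"]), tolerance = 1e-4)
    expect_equal(fit$y_max, unname(p["y_max"]), tolerance = 1e-4)
    expect_equal(fit$lambda, unname(p["lambda"]), tolerance = 1e-4)
    expect_equal(fit$m, unname(p["m"]), tolerance = 1e-4)
  }
})

test_that("degenerate and minimal inputs follow the stated rules", {
  conc <- 10^seq(-2, 2, length.out = 6)
  flat <- fit_combination_curve(conc, rep(50, 6))
  expect_equal(flat$y_min, 0.5)
  expect_equal(flat$y_max, 0.5)
  expect_true(flat$fit$converged)

  expect_error(fit_combination_curve(c(1, 1), c(10, 20)),
               "distinct positive")

  # two points: fitted curve must be monotone increasing and at least as good
  # as a brute-force scan of the parameter box
  fit2 <- fit_combination_curve(c(0.1, 10), c(10, 90))
  grid_rss <- grid_search_rss_4pl(c(0.1, 10), c(10, 90))
  expect_lte(fit2$fit$rss, grid_rss + 1e-12)
  xs <- 10^seq(-1, 1, length.out = 20)
  expect_true(all(diff(predict(fit2, xs)) >= -1e-12))
  expect_equal(predict(fit2, 0.1), 0.10, tolerance = 0.02)
  expect_equal(predict(fit2, 10), 0.90, tolerance = 0.02)
})

test_that("monotherapy fits recover, flatten and flag decreasing curves", {
  pts <- make_logistic3_points(0.8, 1, 0)
  fit <- fit_monotherapy_curve(pts$conc, pts$inhibition)
  expect_equal(fit$a, 0.8, tolerance = 1e-4)
  expect_equal(fit$b, 1, tolerance = 1e-4)
  expect_equal(fit$c, 0, tolerance = 1e-4)

  conc <- 10^seq(-2, 2, length.out = 6)
  flat0 <- fit_monotherapy_curve(conc, rep(0, 6))
  expect_equal(flat0$a, 0)
  expect_equal(monotherapy_auc(flat0), 0)

  dec_pts <- make_logistic3_points(0.7, -1.2, 0)
  expect_warning(dec <- fit_monotherapy_curve(dec_pts$conc,
                                              dec_pts$inhibition),
                 "decreases")
  expect_lt(dec$b, 0)
  expect_equal(dec$b, -1.2, tolerance = 1e-3)
})

test_that("closed-form AUCs match quadrature, limits included", {
  # analytic case: area of the unit logistic over [-2, 2] is exactly
  # log10(101 / 1.01) = 2
  curve <- combosens:::new_combination_curve(
    0, 1, lambda = 1, m = 0, conc_range = c(-2, 2),
    fit = list(fallback = FALSE), points = NULL)
  expect_equal(combination_auc(curve), 2, tolerance = 1e-12)

  # constant curve
  flat <- fit_combination_curve(10^seq(-1, 1, len = 4), rep(35, 4))
  expect_equal(combination_auc(flat), 0.35 * 2)

  # slope -> 0 limit against quadrature
  for (lam in c(1e-7, 1e-5, 1e-3)) {
    cv <- combosens:::new_combination_curve(
      0.2, 0.9, lambda = lam, m = 0, conc_range = c(-2, 2),
      fit = list(fallback = FALSE), points = NULL)
    expect_equal(combination_auc(cv), quad_auc_4pl(0.2, 0.9, lam, 0, -2, 2),
                 tolerance = 1e-6)
  }

  # steep-slope (step-function) limit: y_min (c2 - c1) + (y_max - y_min)(c2 - m)
  cv <- combosens:::new_combination_curve(
    0.1, 0.9, lambda = 20, m = 0.5, conc_range = c(-2, 2),
    fit = list(fallback = FALSE), points = NULL)
  expect_equal(combination_auc(cv), quad_auc_4pl(0.1, 0.9, 20, 0.5, -2, 2),
               tolerance = 1e-8)
  expect_equal(combination_auc(cv), 0.1 * 4 + 0.8 * 1.5, tolerance = 1e-3)

  # monotherapy: a = 1, b = 1, c = 0 over [-2, 2] integrates to exactly 2
  mono <- fit_monotherapy_curve(make_logistic3_points(1, 1, 0)$conc,
                                make_logistic3_points(1, 1, 0)$inhibition)
  expect_equal(monotherapy_auc(mono), 2, tolerance = 1e-6)

  # monotherapy slope -> 0 limit
  mc <- combosens:::new_monotherapy_curve(
    a = 0.6, b = 1e-8, c = 0, conc_range = c(-1, 2), flat = FALSE,
    fit = list(fallback = FALSE), points = NULL)
  expect_equal(monotherapy_auc(mc), 0.6 * 3 / 2, tolerance = 1e-8)
})

test_that("monotherapy AUC equals the equivalent combination AUC", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1, 0.2, 4); c <- runif(1, -1, 1)
    c1 <- c - runif(1, 1, 3); c2 <- c + runif(1, 1, 3)
    mono <- combosens:::new_monotherapy_curve(
      a, b, c, conc_range = c(c1, c2), flat = FALSE,
      fit = list(fallback = FALSE), points = NULL)
    comb <- combosens:::new_combination_curve(
      0, a, lambda = b, m = c, conc_range = c(c1, c2),
      fit = list(fallback = FALSE), points = NULL)
    expect_equal(monotherapy_auc(mono), combination_auc(comb),
                 tolerance = 1e-12)
  }
})

test_that("AUC properties: monotone in y_max, bounded, unit invariant", {
  set.seed(7)
  for (i in 1:50) {
    y_min <- runif(1, 0, 0.5); y_max <- runif(1, y_min, 1)
    lam <- runif(1, 0.05, 5) * sample(c(-1, 1), 1)
    m <- runif(1, -1, 1)
    mk <- function(ymx) combosens:::new_combination_curve(
      y_min, ymx, lambda = lam, m = m, conc_range = c(-2, 2),
      fit = list(fallback = FALSE), points = NULL)
    auc <- combination_auc(mk(y_max))
    expect_gte(auc, 0)
    expect_lte(auc, 4 + 1e-12)
    if (y_max < 0.99)
      expect_gt(combination_auc(mk(y_max + 0.01)), auc)
  }

  # rescaling all concentrations leaves the fitted AUC unchanged
  pts <- make_4pl_points(0.1, 0.9, 1.5, 0)
  auc1 <- combination_auc(fit_combination_curve(pts$conc, pts$inhibition))
  auc2 <- combination_auc(fit_combination_curve(pts$conc * 1000,
                                                pts$inhibition))
  expect_equal(auc1, auc2, tolerance = 1e-6)
})

test_that("responses outside [0, 100] are clipped into the box before fit", {
  conc <- 10^seq(-2, 2, length.out = 8)
  noisy <- make_4pl_points(0, 1, 1, 0)$inhibition
  noisy[1] <- -8   # noise below zero
  noisy[8] <- 106  # noise above full kill
  fit <- fit_combination_curve(conc, noisy)
  expect_gte(fit$y_min, 0)
  expect_lte(fit$y_max, 1)
})
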