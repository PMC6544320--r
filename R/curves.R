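#' Dose-response curve models
#'
#' Two curve families are used throughout the package, both parameterised on
#' log10 concentration `x' = log10(x)`:
#'
#' * the four-parameter log-logistic used for combination (foreground over
#'   background) curves,
#'   `y = y_min + (y_max - y_min) / (1 + 10^(lambda * (m - x')))`,
#'   with bottom/top asymptotes `y_min <= y_max` in `[0, 1]` (fractional
#'   inhibition), midpoint `m = log10(IC50)` and slope `lambda`;
#' * the three-parameter logistic used for monotherapy curves,
#'   `y = a / (1 + 10^(b * (c - x')))`, i.e. the same family with the bottom
#'   pinned at 0, top `a` in `[0, 1]`, slope `b` and midpoint `c`.
#'
#' Responses are supplied in percent inhibition; they are rescaled to
#' fractions and clipped to `[0, 1]` before fitting so the optimisation stays
#' inside the parameter box. Fitting is bounded nonlinear least squares
#' (`stats::optim`, L-BFGS-B, analytic gradients) with multiple starting
#' points; the start with the lowest residual sum of squares wins. Slope signs
#' are unconstrained: a decreasing monotherapy curve fits with `b < 0` and a
#' warning.
#'
#' If every optimisation start fails, the returned curve is flagged
#' `fallback = TRUE` and area computations fall back to trapezoidal
#' integration of the observed points in log10 concentration.
#'
#' @name dose-response-curves
#' @keywords internal
NULL

# 4PL evaluated on log10 concentration
loglogistic4 <- function(xlog, y_min, y_max, lambda, m) {
  y_min + (y_max - y_min) / (1 + 10^(lambda * (m - xlog)))
}

# 3-parameter logistic (bottom = 0) on log10 concentration
logistic3 <- function(xlog, a, b, c) {
  a / (1 + 10^(b * (c - xlog)))
}

# Shared bounded least-squares engine. `model` supplies value and gradient.
fit_bounded_ls <- function(x, y, starts, lower, upper, value, gradient) {
  obj <- function(p) {
    r <- value(x, p) - y
    sum(r * r)
  }
  grad <- function(p) {
    r <- value(x, p) - y
    drop(2 * (r %*% gradient(x, p)))
  }
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(upper, pmax(lower, p0))
    fit <- tryCatch(
      stats::optim(p0, obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e2, pgtol = 0, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

validate_points <- function(conc, inhibition) {
  if (length(conc) != length(inhibition))
    stop_combosens("conc and inhibition must have the same length",
                   class = "combosens_fit_error")
  keep <- is.finite(conc) & is.finite(inhibition) & conc > 0
  conc <- conc[keep]
  inhibition <- inhibition[keep]
  if (length(unique(conc)) < 2L)
    stop_combosens("need at least 2 distinct positive concentrations to fit",
                   class = "combosens_fit_error")
  list(x = log10(conc), y = clip01(inhibition / 100))
}

# starting midpoints: quartiles of the tested log-range plus the log-conc of
# the observation closest to the response midpoint
start_midpoints <- function(x, y) {
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  mid <- (min(y) + max(y)) / 2
  m_int <- x[which.min(abs(y - mid))]
  list(q = q, interp = m_int)
}

#' Fit a combination dose-response curve
#'
#' Fits the four-parameter log-logistic model to (concentration, percent
#' inhibition) points of one cross-design arm (foreground drug titrated over a
#' fixed background). Parameter box: `y_min, y_max` in `[0, 1]` with
#' `y_min <= y_max`, midpoint within the tested log10 range extended by 2,
#' slope `|lambda| <= 20` (sign free).
#'
#' @param conc positive concentrations (any consistent unit).
#' @param inhibition percent inhibition (values outside `[0, 100]` are clipped
#'   to the box before fitting).
#' @return An object of class `combination_curve` with elements `y_min`,
#'   `y_max`, `ic50`, `m` (`log10(ic50)`), `lambda`, `conc_range`
#'   (log10 units) and `fit` diagnostics (`rss`, `converged`, `n_points`,
#'   `fallback`).
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 8)
#' y <- 100 / (1 + 10^(0 - log10(conc)))  # ic50 = 1, lambda = 1
#' fit_combination_curve(conc, y)
#' @export
fit_combination_curve <- function(conc, inhibition) {
  pts <- validate_points(conc, inhibition)
  x <- pts$x; y <- pts$y
  c1 <- min(x); c2 <- max(x)
  points <- data.frame(log10_conc = x, fraction = y)

  if (diff(range(y)) < 1e-12) {
    # degenerate flat curve: exact representation, no optimisation needed
    return(new_combination_curve(y[1], y[1], lambda = 1, m = mean(x),
                                 conc_range = c(c1, c2),
                                 fit = list(rss = 0, converged = TRUE,
                                            n_points = length(x),
                                            fallback = FALSE),
                                 points = points))
  }

  dir <- if (stats::cov(x, y) < 0) -1 else 1
  ms <- start_midpoints(x, y)
  base <- c(max(0, min(y)), min(1, max(y)))
  starts <- c(
    lapply(ms$q, function(m) c(base, dir * 1, m)),
    list(c(base, dir * 0.5, ms$interp), c(base, dir * 2, ms$interp))
  )
  lower <- c(0, 0, -20, c1 - 2)
  upper <- c(1, 1, 20, c2 + 2)
  value <- function(x, p) loglogistic4(x, p[1], p[2], p[3], p[4])
  gradient <- function(x, p) {
    g <- 1 / (1 + 10^(p[3] * (p[4] - x)))
    g1g <- g * (1 - g)
    dy <- p[2] - p[1]
    cbind(1 - g, g,
          -dy * log(10) * (p[4] - x) * g1g,
          -dy * log(10) * p[3] * g1g)
  }
  best <- fit_bounded_ls(x, y, starts, lower, upper, value, gradient)

  if (is.null(best)) {
    warning("combination curve fit failed; using trapezoidal fallback")
    return(new_combination_curve(min(y), max(y), lambda = NA_real_,
                                 m = NA_real_, conc_range = c(c1, c2),
                                 fit = list(rss = NA_real_, converged = FALSE,
                                            n_points = length(x),
                                            fallback = TRUE),
                                 points = points))
  }

  p <- best$par
  if (p[1] > p[2]) {  # normalise so y_min <= y_max (equivalent sign flip)
    p[1:2] <- p[2:1]
    p[3] <- -p[3]
  }
  new_combination_curve(p[1], p[2], lambda = p[3], m = p[4],
                        conc_range = c(c1, c2),
                        fit = list(rss = best$value,
                                   converged = best$convergence == 0,
                                   n_points = length(x), fallback = FALSE),
                        points = points)
}

new_combination_curve <- function(y_min, y_max, lambda, m, conc_range, fit,
                                  points) {
  structure(
    list(y_min = y_min, y_max = y_max, ic50 = 10^m, m = m, lambda = lambda,
         conc_range = conc_range, fit = fit, points = points),
    class = "combination_curve"
  )
}

#' Fit a monotherapy dose-response curve
#'
#' Fits the three-parameter logistic (bottom fixed at 0) to single-drug
#' (concentration, percent inhibition) points. Parameter box: top `a` in
#' `[0, 1]`, midpoint `c` within the tested log10 range extended by 2, slope
#' `|b| <= 20`. A fit with `b < 0` (response decreasing with dose) is kept and
#' reported with a warning. If all responses coincide the curve is returned as
#' an exact flat curve at that level.
#'
#' @inheritParams fit_combination_curve
#' @return An object of class `monotherapy_curve` with elements `a`, `b`, `c`,
#'   `conc_range`, `flat` and `fit` diagnostics.
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 8)
#' y <- 80 / (1 + 10^(0 - log10(conc)))
#' fit_monotherapy_curve(conc, y)
#' @export
fit_monotherapy_curve <- function(conc, inhibition) {
  pts <- validate_points(conc, inhibition)
  x <- pts$x; y <- pts$y
  c1 <- min(x); c2 <- max(x)
  points <- data.frame(log10_conc = x, fraction = y)

  if (diff(range(y)) < 1e-12) {
    return(new_monotherapy_curve(a = y[1], b = 0, c = mean(x),
                                 conc_range = c(c1, c2), flat = TRUE,
                                 fit = list(rss = 0, converged = TRUE,
                                            n_points = length(x),
                                            fallback = FALSE),
                                 points = points))
  }

  dir <- if (stats::cov(x, y) < 0) -1 else 1
  ms <- start_midpoints(x, y)
  a0 <- min(1, max(y))
  starts <- c(
    lapply(ms$q, function(m) c(a0, dir * 1, m)),
    list(c(a0, dir * 0.5, ms$interp), c(a0, dir * 2, ms$interp))
  )
  lower <- c(0, -20, c1 - 2)
  upper <- c(1, 20, c2 + 2)
  value <- function(x, p) logistic3(x, p[1], p[2], p[3])
  gradient <- function(x, p) {
    g <- 1 / (1 + 10^(p[2] * (p[3] - x)))
    g1g <- g * (1 - g)
    cbind(g,
          -p[1] * log(10) * (p[3] - x) * g1g,
          -p[1] * log(10) * p[2] * g1g)
  }
  best <- fit_bounded_ls(x, y, starts, lower, upper, value, gradient)

  if (is.null(best)) {
    warning("monotherapy curve fit failed; using trapezoidal fallback")
    return(new_monotherapy_curve(a = max(y), b = NA_real_, c = NA_real_,
                                 conc_range = c(c1, c2), flat = FALSE,
                                 fit = list(rss = NA_real_, converged = FALSE,
                                            n_points = length(x),
                                            fallback = TRUE),
                                 points = points))
  }
  p <- best$par
  if (p[2] < 0)
    warning("monotherapy response decreases with concentration (b < 0)")
  new_monotherapy_curve(a = p[1], b = p[2], c = p[3], conc_range = c(c1, c2),
                        flat = FALSE,
                        fit = list(rss = best$value,
                                   converged = best$convergence == 0,
                                   n_points = length(x), fallback = FALSE),
                        points = points)
}

new_monotherapy_curve <- function(a, b, c, conc_range, flat, fit, points) {
  structure(
    list(a = a, b = b, c = c, conc_range = conc_range, flat = flat,
         fit = fit, points = points),
    class = "monotherapy_curve"
  )
}

#' Evaluate fitted curves
#'
#' Returns the fitted fractional inhibition (in `[0, 1]`) at raw
#' concentrations. The degenerate flat monotherapy curve returns its constant
#' level; a fallback curve interpolates the observed points linearly in log10
#' concentration (constant extrapolation beyond the tested range).
#'
#' @param object a fitted curve.
#' @param conc positive concentrations to evaluate at.
#' @param ... unused.
#' @return numeric vector of fractional inhibition.
#' @export
predict.combination_curve <- function(object, conc, ...) {
  stopifnot(all(conc > 0))
  x <- log10(conc)
  if (isTRUE(object$fit$fallback)) return(interp_points(object$points, x))
  loglogistic4(x, object$y_min, object$y_max, object$lambda, object$m)
}

#' @rdname predict.combination_curve
#' @export
predict.monotherapy_curve <- function(object, conc, ...) {
  stopifnot(all(conc > 0))
  x <- log10(conc)
  if (object$flat) return(rep(object$a, length(x)))
  if (isTRUE(object$fit$fallback)) return(interp_points(object$points, x))
  logistic3(x, object$a, object$b, object$c)
}

interp_points <- function(points, xout) {
  agg <- stats::aggregate(fraction ~ log10_conc, points, mean)
  stats::approx(agg$log10_conc, agg$fraction, xout = xout, rule = 2)$y
}

trapezoid_auc <- function(points) {
  agg <- stats::aggregate(fraction ~ log10_conc, points, mean)
  agg <- agg[order(agg$log10_conc), ]
  x <- agg$log10_conc; y <- agg$fraction
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Closed-form area under a fitted curve on the log10 scale
#'
#' Integrates the fitted curve over its tested log10 concentration range
#' `[c1, c2]`. For the four-parameter log-logistic the antiderivative gives
#' `y_min (c2 - c1) + (y_max - y_min) (1/lambda) log10((1 + 10^(lambda (c2 - m))) / (1 + 10^(lambda (c1 - m))))`;
#' for the monotherapy logistic,
#' `a ((c2 - c1) + (1/b) (log10(1 + 10^(b (c - c2))) - log10(1 + 10^(b (c - c1)))))`.
#' Below `|slope| < 1e-6` the analytic slope->0 limit (half-span rectangle) is
#' used. A fallback curve integrates its observed points trapezoidally.
#' Units: fraction x log10-concentration, so a curve pinned at 100% inhibition
#' has area `c2 - c1`.
#'
#' @param curve a fitted `combination_curve` or `monotherapy_curve`.
#' @return numeric area.
#' @export
combination_auc <- function(curve) {
  stopifnot(inherits(curve, "combination_curve"))
  if (isTRUE(curve$fit$fallback)) return(trapezoid_auc(curve$points))
  c1 <- curve$conc_range[1]; c2 <- curve$conc_range[2]
  dy <- curve$y_max - curve$y_min
  base <- curve$y_min * (c2 - c1)
  if (dy == 0) return(base)
  lam <- curve$lambda
  if (abs(lam) < 1e-6) return(base + dy * (c2 - c1) / 2)
  base + dy / lam *
    (log10_1p_pow10(lam * (c2 - curve$m)) -
       log10_1p_pow10(lam * (c1 - curve$m)))
}

#' @rdname combination_auc
#' @export
monotherapy_auc <- function(curve) {
  stopifnot(inherits(curve, "monotherapy_curve"))
  if (curve$flat) return(curve$a * diff(curve$conc_range))
  if (isTRUE(curve$fit$fallback)) return(trapezoid_auc(curve$points))
  c1 <- curve$conc_range[1]; c2 <- curve$conc_range[2]
  a <- curve$a; b <- curve$b
  if (a == 0) return(0)
  if (abs(b) < 1e-6) return(a * (c2 - c1) / 2)
  # cancellation-free form of a[(c2-c1) + (L(u2) - L(u1))/b] with
  # u_i = b(c - c_i), L(u) = log10(1 + 10^u) = max(u, 0) + Lx(u),
  # Lx(u) = log1p(10^-|u|)/ln 10; avoids losing all precision when the
  # curve is essentially zero over the range
  u1 <- b * (curve$c - c1)
  u2 <- b * (curve$c - c2)
  lx <- function(u) log1p(10^(-abs(u))) / log(10)
  a * ((pmin(u1, 0) - pmin(u2, 0)) + lx(u2) - lx(u1)) / b
}

#' @export
print.combination_curve <- function(x, ...) {
  cat(sprintf(
    "combination curve: y_min=%.4f y_max=%.4f ic50=%.4g lambda=%.3f (%s)\n",
    x$y_min, x$y_max, x$ic50, x$lambda,
    if (isTRUE(x$fit$fallback)) "fallback" else
      if (isTRUE(x$fit$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
print.monotherapy_curve <- function(x, ...) {
  cat(sprintf("monotherapy curve: a=%.4f b=%.3f c=%.4f (%s)\n",
              x$a, x$b, x$c,
              if (x$flat) "flat" else
                if (isTRUE(x$fit$fallback)) "fallback" else
                  if (isTRUE(x$fit$converged)) "converged" else
                    "not converged"))
  invisible(x)
}
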