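# shared nonlinear least-squares backends

# symbolic gradients: a numeric Jacobian breaks down when a log-scale
# parameter converges to ~0 (finite-difference step underflows), so every
# model hands nlsLM an analytic gradient via deriv()
hyperbola_model <- deriv(~ exp(la) * x / (x + exp(lk)),
                         c("la", "lk"),
                         function.arg = c("la", "lk", "x"))
# hand-written gradient: deriv() produces 0 * log(0) = NaN at x = 0,
# where the correct limits (hill > 0) are all finite
fourpl_model <- function(bottom, top, lmid, hill, x) {
  r <- (x / exp(lmid))^hill
  val <- bottom + (top - bottom) / (1 + r)
  dval_dr <- -(top - bottom) / (1 + r)^2
  lr <- ifelse(x > 0, log(x) - lmid, 0)
  grad <- cbind(bottom = 1 - 1 / (1 + r),
                top = 1 / (1 + r),
                lmid = dval_dr * (-hill * r),
                hill = dval_dr * r * lr)
  attr(val, "gradient") <- grad
  val
}
#
# All saturation-hyperbola fits in the package (SPR isotherm, ligand
# saturation, Michaelis-Menten, depletion-branch fitness) share one Langmuir
# backend, and both sigmoid fits (IC50, overexpression-branch fitness) share
# one four-parameter logistic backend. Amplitude and midpoint parameters are
# log-parameterized so the optimizer cannot wander into negative values;
# standard errors are mapped back to the natural scale by the delta method.

fit_hyperbola <- function(x, y, weights = NULL,
                          xname = "x", amax_name = "amax", k_name = "k") {
  check_numeric_vec(x, xname, lower = 0)
  if (!is.numeric(y) || length(y) != length(x) || anyNA(y)) {
    stop("`y` must be numeric, same length as `x`, no missing values",
         call. = FALSE)
  }
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  if (all(y <= 0)) stop("all responses are zero or negative", call. = FALSE)
  a0 <- max(y)
  pos <- x > 0
  k0 <- x[pos][which.min(abs(y[pos] - a0 / 2))]
  if (length(k0) == 0L || k0 <= 0) k0 <- stats::median(x[pos])
  dat <- data.frame(x = x, y = y)
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  fit <- minpack.lm::nlsLM(
    y ~ hyperbola_model(la, lk, x),
    data = dat, weights = w,
    start = list(la = log(a0), lk = log(k0)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  co <- stats::coef(fit)
  est <- exp(co)
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 2L))
  se <- est * se_log
  names(est) <- names(se) <- c(amax_name, k_name)
  list(estimate = est, se = se,
       rss = sum(stats::resid(fit)^2),
       fitted = stats::fitted(fit), data = dat, fit = fit)
}

fit_fourpl_core <- function(x, y, hill_max = 10) {
  check_numeric_vec(x, "x", lower = 0)
  if (length(x) != length(y) || anyNA(y)) {
    stop("`x` and `y` must be equal-length numeric vectors", call. = FALSE)
  }
  if (length(x) < 5L) stop("need at least 5 points for a 4PL fit",
                           call. = FALSE)
  top0 <- max(y)
  bottom0 <- min(y)
  if ((top0 - bottom0) < 0.3 * max(abs(top0), .Machine$double.eps)) {
    warning("signal spans < 30% of its range; 4PL fit may be ill-determined",
            call. = FALSE)
  }
  mid_target <- (top0 + bottom0) / 2
  pos <- x > 0
  mid0 <- x[pos][which.min(abs(y[pos] - mid_target))]
  if (length(mid0) == 0L || mid0 <= 0) mid0 <- stats::median(x[pos])
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ fourpl_model(bottom, top, lmid, hill, x),
    data = dat,
    start = list(bottom = bottom0, top = top0, lmid = log(mid0), hill = 1),
    lower = c(-Inf, -Inf, -Inf, 1e-6),
    upper = c(Inf, Inf, Inf, hill_max),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  co <- stats::coef(fit)
  sum_se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 4L))
  mid <- exp(co[["lmid"]])
  se <- c(bottom = unname(sum_se["bottom"]), top = unname(sum_se["top"]),
          mid = mid * unname(sum_se["lmid"]), hill = unname(sum_se["hill"]))
  list(bottom = co[["bottom"]], top = co[["top"]], mid = mid,
       hill = co[["hill"]], se = se, rss = sum(stats::resid(fit)^2),
       fitted = stats::fitted(fit), data = dat)
}

fourpl_predict <- function(p, x) {
  p$bottom + (p$top - p$bottom) / (1 + (x / p$mid)^p$hill)
}
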