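# Growth-curve and abundance-fitness analysis: modified-Gompertz fits to
# OD600 time series, saturating (depletion) and sigmoidal (overexpression)
# abundance-fitness branches, ortholog significance testing, the rescue
# factor, and exact Spearman rank correlation.

# analytic gradient for the same reason as the shared fitters: numeric
# Jacobians fail when a parameter (here y0 or lag) sits near zero
gompertz_model <- deriv(~ y0 + A * exp(-exp(mumax * exp(1) / A *
                                              (lag - th) + 1)),
                        c("y0", "A", "mumax", "lag"),
                        function.arg = c("y0", "A", "mumax", "lag",
                                         "th"))

#' Fit a modified Gompertz growth model to an OD600 time series
#'
#' Fits \eqn{y(t) = A \exp(-\exp(\mu e / A (\lambda - t) + 1))} on the
#' log-relative scale \eqn{y = \log(OD_t / OD_0)}, where \eqn{\mu} is the
#' maximum specific growth rate (h^-1), \eqn{\lambda} the lag time (h) and
#' \eqn{A} the amplitude (log OD units). The first time point is used as
#' the baseline \eqn{OD_0}; pass `blank` to subtract a plate background
#' first.
#'
#' @param time time points (minutes by default), monotone increasing.
#' @param od600 optical densities, positive after blank subtraction.
#' @param time_unit `"min"` or `"h"`.
#' @param blank background OD subtracted from all readings (default 0;
#'   input is assumed background-corrected).
#' @return a `growth_params` list with `mu_max` (h^-1), `lag` (h),
#'   `amplitude`, `fit_rss` and `flat` (logical). Flat curves return
#'   `mu_max = 0` with a warning.
#' @export
#' @examples
#' t_min <- seq(0, 720, by = 15)
#' od <- gen_growth_curves(mu = 0.6, lag = 1, amplitude = 2,
#'                         noise_cv = 0, seed = 1)
#' fit_growth_curve(od$time, od$od600)
fit_growth_curve <- function(time, od600, time_unit = c("min", "h"),
                             blank = 0) {
  time_unit <- match.arg(time_unit)
  check_numeric_vec(time, "time")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing",
                                 call. = FALSE)
  od <- od600 - blank
  if (length(od) != length(time) || anyNA(od)) {
    stop("`od600` must match `time` in length", call. = FALSE)
  }
  if (any(od <= 0)) stop("OD must be positive after blank subtraction",
                         call. = FALSE)
  th <- if (time_unit == "min") time / 60 else time
  if (length(th) < 10L || (max(th) - min(th)) < 2) {
    warning("fewer than 10 points or span < 2 h; growth fit may be ",
            "unreliable", call. = FALSE)
  }
  y <- log(od / od[1L])
  if (max(y) < 0.05) {
    warning("flat growth curve; returning mu_max = 0", call. = FALSE)
    return(structure(list(mu_max = 0, lag = NA_real_,
                          amplitude = max(max(y), 0), fit_rss = 0,
                          flat = TRUE),
                     class = "growth_params"))
  }
  slopes <- diff(y) / diff(th)
  i <- which.max(slopes)
  mu0 <- max(slopes[i], 1e-3)
  a0 <- max(y)
  lag0 <- th[i] - y[i] / mu0
  # fit on log(OD) with a free baseline: the Gompertz term is not exactly
  # zero at t = 0, so anchoring to the first reading would bias mu
  dat <- data.frame(th = th, ly = log(od))
  fit <- minpack.lm::nlsLM(
    ly ~ gompertz_model(y0, A, mumax, lag, th),
    data = dat,
    start = list(y0 = log(od[1L]), A = a0, mumax = mu0, lag = lag0),
    lower = c(-Inf, 1e-8, 0, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  co <- stats::coef(fit)
  structure(list(mu_max = unname(co[["mumax"]]), lag = unname(co[["lag"]]),
                 amplitude = unname(co[["A"]]),
                 fit_rss = sum(stats::resid(fit)^2), flat = FALSE),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Gompertz growth fit: mu = %.4g h^-1, lag = %.3g h, A = %.3g\n",
              x$mu_max, x$lag, x$amplitude))
  invisible(x)
}

#' Normalize a growth rate to a reference condition
#'
#' @param mu growth rate (h^-1), `>= 0`.
#' @param mu_ref reference growth rate (h^-1), `> 0` (e.g. the no-inducer
#'   culture for an overexpression series, or the empty-plasmid strain).
#'   The reference is always an explicit argument.
#' @return `mu / mu_ref`, dimensionless.
#' @export
relative_growth <- function(mu, mu_ref) {
  check_numeric_vec(mu, "mu", lower = 0)
  check_number(mu_ref, "mu_ref", lower = 0, strict = TRUE)
  mu / mu_ref
}

#' Construct abundance-fitness points
#'
#' @param rel_abundance protein abundance as fold over the wild-type basal
#'   level, `> 0`.
#' @param rel_growth growth rate normalized to the reference condition,
#'   `>= 0`.
#' @param sd per-point standard deviation of `rel_growth` (default 0.03,
#'   the typical replicate scatter of plate-reader growth rates).
#' @return a `fitness_points` data frame.
#' @export
fitness_points <- function(rel_abundance, rel_growth, sd = 0.03) {
  check_numeric_vec(rel_abundance, "rel_abundance", lower = 0,
                    strict = TRUE)
  check_numeric_vec(rel_growth, "rel_growth", lower = 0)
  if (length(rel_abundance) != length(rel_growth)) {
    stop("`rel_abundance` and `rel_growth` must have equal length",
         call. = FALSE)
  }
  structure(data.frame(rel_abundance = rel_abundance,
                       rel_growth = rel_growth, sd = sd),
            class = c("fitness_points", "data.frame"))
}

#' Fit the depletion branch of the abundance-fitness curve
#'
#' In the low-abundance (depletion) regime fitness follows a saturating
#' Michaelis-Menten-type dependence on enzyme abundance,
#' \eqn{f(a) = F_{max} a / (a + K_f)}, as predicted by metabolic flux
#' kinetics.
#'
#' @param points a [fitness_points()] data frame spanning the
#'   low-abundance regime, at least 4 points.
#' @return a `depletion_fit` list with `fmax`, `kf`, `standard_errors` and
#'   `residual_sum_sq`.
#' @export
fit_depletion_branch <- function(points) {
  if (nrow(points) < 4L) stop("need at least 4 depletion points",
                              call. = FALSE)
  h <- fit_hyperbola(points$rel_abundance, points$rel_growth,
                     xname = "rel_abundance",
                     amax_name = "fmax", k_name = "kf")
  structure(list(fmax = unname(h$estimate["fmax"]),
                 kf = unname(h$estimate["kf"]),
                 standard_errors = h$se, residual_sum_sq = h$rss,
                 data = h$data),
            class = "depletion_fit")
}

#' @export
predict.depletion_fit <- function(object, rel_abundance, ...) {
  object$fmax * rel_abundance / (rel_abundance + object$kf)
}

#' Fit the overexpression branch of the abundance-fitness curve
#'
#' Fits a decreasing four-parameter logistic in log10 abundance,
#' equivalently \eqn{f(a) = bottom + (top - bottom)/(1 + (a/a_{50})^{h})},
#' giving a continuous fitness curve across the overexpression range that
#' can be evaluated at arbitrary abundance via `predict()`.
#'
#' @param points a [fitness_points()] data frame on the overexpression
#'   side, at least 5 points.
#' @return a `fitness_sigmoid` list with `bottom`, `top`, `mid` (abundance
#'   at half-maximal fitness loss), `hill`, `standard_errors` and
#'   `residual_sum_sq`. An increasing trend triggers a warning.
#' @export
fit_overexpression_branch <- function(points) {
  if (nrow(points) < 5L) stop("need at least 5 overexpression points",
                              call. = FALSE)
  sp <- stats::cor(points$rel_abundance, points$rel_growth,
                   method = "spearman")
  if (!is.na(sp) && sp > 0) {
    warning("fitness increases with abundance; not an overexpression ",
            "toxicity branch", call. = FALSE)
  }
  p <- fit_fourpl_core(points$rel_abundance, points$rel_growth)
  se <- p$se
  names(se) <- c("bottom", "top", "mid", "hill")
  structure(list(bottom = p$bottom, top = p$top, mid = p$mid,
                 hill = p$hill, standard_errors = se,
                 residual_sum_sq = p$rss, data = p$data),
            class = "fitness_sigmoid")
}

#' @export
predict.fitness_sigmoid <- function(object, rel_abundance, ...) {
  fourpl_predict(list(bottom = object$bottom, top = object$top,
                      mid = object$mid, hill = object$hill), rel_abundance)
}

#' @export
print.fitness_sigmoid <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fitness fit: top = %.3g, bottom = %.3g, midpoint at %.3g-fold, hill = %.3g\n",
    x$top, x$bottom, x$mid, x$hill))
  invisible(x)
}

#' Test whether an ortholog's fitness deviates from the reference curve
#'
#' The expected growth at the ortholog's abundance is read off the fitted
#' overexpression curve and assigned a standard deviation of `sd_frac`
#' (default 3%) of the predicted value, representing the replicate-level
#' uncertainty of plate-reader growth rates. An unpaired two-sample t-test
#' then compares the observed ortholog replicates against this expected
#' distribution. By default the expected side is represented by a
#' deterministic symmetric triple with exactly the assigned mean and SD;
#' pass `expected_reps` to supply draws from the expected distribution
#' instead (e.g. in calibration simulations).
#'
#' @param fit a `fitness_sigmoid` from [fit_overexpression_branch()].
#' @param ortholog_abundance ortholog abundance (fold over basal).
#' @param ortholog_growth_reps observed relative growth replicates, at
#'   least 3.
#' @param expected_reps optional replicate values for the expected side.
#' @param sd_frac fractional SD assigned to the prediction (default 0.03).
#' @param var_equal use the pooled-variance t-test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return list with `p_value` (two-sided), `predicted`, `expected_reps`
#'   and `observed_mean`.
#' @export
ortholog_significance <- function(fit, ortholog_abundance,
                                  ortholog_growth_reps,
                                  expected_reps = NULL, sd_frac = 0.03,
                                  var_equal = TRUE) {
  stopifnot(inherits(fit, "fitness_sigmoid"))
  check_number(ortholog_abundance, "ortholog_abundance", lower = 0,
               strict = TRUE)
  if (length(ortholog_growth_reps) < 3L) {
    stop("need at least 3 ortholog growth replicates", call. = FALSE)
  }
  rng <- range(fit$data$x)
  if (ortholog_abundance < rng[1L] || ortholog_abundance > rng[2L]) {
    warning("ortholog abundance lies outside the fitted range; ",
            "prediction is an extrapolation", call. = FALSE)
  }
  pred <- predict(fit, ortholog_abundance)
  if (is.null(expected_reps)) {
    # symmetric triple: mean = pred, sample SD = sd_frac * pred
    expected_reps <- pred * (1 + c(-1, 0, 1) * sd_frac)
  }
  tt <- tryCatch(
    stats::t.test(ortholog_growth_reps, expected_reps,
                  var.equal = var_equal),
    error = function(e) NULL)
  p <- if (is.null(tt)) {
    # both sides constant: p = 1 when equal, otherwise an exact separation
    if (isTRUE(all.equal(mean(ortholog_growth_reps), mean(expected_reps))))
      1 else 0
  } else {
    tt$p.value
  }
  list(p_value = p, predicted = pred, expected_reps = expected_reps,
       observed_mean = mean(ortholog_growth_reps))
}

#' Rescue factor of a co-expression experiment
#'
#' Interaction-corrected growth-rate gain from co-expressing a candidate
#' partner protein X alongside the toxic hub:
#' \deqn{(\mu_{hub+X} - \mu_{hub+empty}) - (\mu_X - \mu_{empty})}
#' The second bracket removes X's own expression cost, so the factor is
#' invariant under adding a constant to all four rates.
#'
#' @param mu_dhfr_x growth rate with hub + partner co-expressed (h^-1).
#' @param mu_dhfr_empty growth rate with hub + empty vector.
#' @param mu_x growth rate with partner alone.
#' @param mu_empty growth rate with empty vector alone.
#' @return the rescue factor (h^-1); positive values indicate rescue beyond
#'   the partner's own toxicity.
#' @export
#' @examples
#' rescue_factor(0.50, 0.40, 0.95, 1.00)
rescue_factor <- function(mu_dhfr_x, mu_dhfr_empty, mu_x, mu_empty) {
  for (nm in c("mu_dhfr_x", "mu_dhfr_empty", "mu_x", "mu_empty")) {
    check_numeric_vec(get(nm), nm, lower = 0)
  }
  (mu_dhfr_x - mu_dhfr_empty) - (mu_x - mu_empty)
}

# all permutations of 1:n as an n! x n matrix (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Computes Spearman's rho between abundance and growth (ties handled by
#' average ranks). For `n <= exact_max` (default 8) the p-value is exact,
#' obtained by enumerating all n! orderings; for larger n a t-approximation
#' is used. Sidedness is explicit: `"two.sided"` counts orderings with
#' `|rho*| >= |rho|`, `"less"`/`"greater"` count the corresponding tail.
#'
#' @param x,y numeric vectors (e.g. relative abundance and relative
#'   growth), at least 4 points; alternatively `x` may be a
#'   [fitness_points()] data frame.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max largest n for which the exact permutation null is
#'   enumerated.
#' @return list with `rho` and `p_value`. Degenerate (constant) input
#'   yields `rho = NA` with a warning.
#' @export
#' @examples
#' # five strictly decreasing points: rho = -1, exact two-sided p = 2/120
#' rank_correlation(1:5, 5:1)
rank_correlation <- function(x, y = NULL,
                             alternative = c("two.sided", "less",
                                             "greater"),
                             exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) {
    y <- x$rel_growth
    x <- x$rel_abundance
  }
  if (length(x) < 4L || length(x) != length(y)) {
    stop("need >= 4 paired points", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input; Spearman rho is undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  n <- length(x)
  # tie-free ranks admit the exact rational form, which returns hard
  # +/-1 for perfectly monotone data instead of 1 - 2e-16
  no_ties <- length(unique(rx)) == n && length(unique(ry)) == n
  rho <- if (no_ties) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
  eps <- 1e-12
  if (n <= exact_max) {
    pm <- all_perms(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    ryc <- ry - mean(ry)
    rhos <- apply(pm, 1L, function(idx) sum(rxc * ryc[idx])) / denom
    p <- switch(alternative,
                two.sided = mean(abs(rhos) >= abs(rho) - eps),
                less = mean(rhos <= rho + eps),
                greater = mean(rhos >= rho - eps))
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, eps))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tstat), df = n - 2),
                less = stats::pt(tstat, df = n - 2),
                greater = stats::pt(tstat, df = n - 2,
                                    lower.tail = FALSE))
  }
  list(rho = rho, p_value = min(p, 1))
}
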