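# SPR binding analysis: reference subtraction, equilibrium isotherm fitting
# (RU = Rmax * c / (c + KD)) and global single-exponential dissociation fits.

#' Construct a sensorgram
#'
#' A single SPR trace: response units versus time at one analyte
#' concentration.
#'
#' @param time time in seconds, strictly increasing, at least 2 points.
#' @param response response units (RU).
#' @param conc analyte concentration (mol/L).
#' @return a `sensorgram` data frame with columns `time` and `response` and
#'   the analyte concentration stored in attribute `"conc"`.
#' @export
sensorgram <- function(time, response, conc) {
  check_numeric_vec(time, "time")
  if (length(time) < 2L || any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (length(response) != length(time) || anyNA(response)) {
    stop("`response` must match `time` in length", call. = FALSE)
  }
  check_number(conc, "conc", lower = 0)
  structure(data.frame(time = time, response = response),
            conc = conc, class = c("sensorgram", "data.frame"))
}

#' Subtract a reference (negative-control) sensorgram
#'
#' Corrects a sample trace for nonspecific binding by pointwise subtraction
#' of the signal from a negative-control flow cell. If the control was
#' recorded on a different time grid it is linearly interpolated onto the
#' sample grid; the grids must overlap the full sample range.
#'
#' @param sample,control `sensorgram` objects at the same analyte
#'   concentration.
#' @return a corrected `sensorgram` on the sample time grid.
#' @export
subtract_reference <- function(sample, control) {
  stopifnot(inherits(sample, "sensorgram"), inherits(control, "sensorgram"))
  if (!isTRUE(all.equal(attr(sample, "conc"), attr(control, "conc")))) {
    stop("sample and control analyte concentrations differ", call. = FALSE)
  }
  if (min(sample$time) < min(control$time) ||
      max(sample$time) > max(control$time)) {
    stop("control time range does not cover the sample trace",
         call. = FALSE)
  }
  ctrl <- stats::approx(control$time, control$response,
                        xout = sample$time)$y
  sensorgram(sample$time, sample$response - ctrl, attr(sample, "conc"))
}

#' Read out the equilibrium response of sensorgrams
#'
#' Extracts, for each trace, the response at the time point nearest
#' `readout_time` after injection start, and assembles a binding isotherm
#' (concentration vs response).
#'
#' @param sensorgrams list of `sensorgram` objects at distinct analyte
#'   concentrations.
#' @param readout_time readout time in seconds (default 100 s).
#' @return a data frame with columns `conc` (mol/L) and `response` (RU),
#'   ordered by concentration.
#' @export
isotherm_from_sensorgrams <- function(sensorgrams, readout_time = 100) {
  stopifnot(length(sensorgrams) >= 1L,
            all(vapply(sensorgrams, inherits, TRUE, "sensorgram")))
  conc <- vapply(sensorgrams, attr, numeric(1), "conc")
  resp <- vapply(sensorgrams, function(s) {
    s$response[which.min(abs(s$time - readout_time))]
  }, numeric(1))
  o <- order(conc)
  data.frame(conc = conc[o], response = resp[o])
}

#' Fit a 1:1 Langmuir equilibrium isotherm
#'
#' Nonlinear least squares of \eqn{RU = R_{max} c / (c + K_D)} against
#' analyte concentration. Both parameters are constrained positive via log
#' parameterization; starting values are \eqn{R_{max}} = maximum response
#' and \eqn{K_D} = concentration nearest half-maximum. The objective is
#' unweighted by default.
#'
#' @param conc analyte concentrations (mol/L), at least 3 distinct values,
#'   or a data frame with columns `conc` and `response`.
#' @param response responses (RU) when `conc` is a vector.
#' @param weights optional least-squares weights.
#' @return an `isotherm_fit` list with elements `rmax`, `kd`,
#'   `standard_errors`, `residual_sum_sq`, `fitted` and `data`.
#' @export
#' @examples
#' conc <- c(1, 2, 4, 8, 16, 32, 48, 64) * 1e-6
#' ru <- 100 * conc / (conc + 8e-6)
#' fit_isotherm(conc, ru)
fit_isotherm <- function(conc, response = NULL, weights = NULL) {
  if (is.data.frame(conc)) {
    response <- conc$response
    conc <- conc$conc
  }
  h <- fit_hyperbola(conc, response, weights, xname = "conc",
                     amax_name = "rmax", k_name = "kd")
  structure(list(rmax = unname(h$estimate["rmax"]),
                 kd = unname(h$estimate["kd"]),
                 standard_errors = h$se,
                 residual_sum_sq = h$rss,
                 fitted = h$fitted, data = h$data),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Langmuir isotherm fit: Rmax = %.4g RU (SE %.2g), KD = %.4g M (SE %.2g)\n",
              x$rmax, x$standard_errors["rmax"], x$kd,
              x$standard_errors["kd"]))
  invisible(x)
}

#' @export
predict.isotherm_fit <- function(object, conc, ...) {
  object$rmax * conc / (conc + object$kd)
}

#' Global single-exponential dissociation fit
#'
#' Fits \eqn{R(t) = R_0 e^{-k_d t}} jointly to the dissociation tails of one
#' or more sensorgrams, sharing one dissociation rate constant across curves
#' with a separate amplitude \eqn{R_0} per curve. Time is measured from the
#' start of each tail.
#'
#' @param tails a `sensorgram` or list of `sensorgram` objects whose first
#'   time point is the start of dissociation; at least 3 time points each,
#'   responses positive at the start.
#' @return a `dissociation_fit` list with `kd_off` (s^-1, shared), `r0`
#'   (per-curve amplitudes) and `residual_sum_sq`.
#' @export
fit_dissociation <- function(tails) {
  if (inherits(tails, "sensorgram")) tails <- list(tails)
  stopifnot(length(tails) >= 1L,
            all(vapply(tails, inherits, TRUE, "sensorgram")))
  if (any(vapply(tails, nrow, 1L) < 3L)) {
    stop("each dissociation tail needs at least 3 time points",
         call. = FALSE)
  }
  if (any(vapply(tails, function(s) s$response[1L] <= 0, TRUE))) {
    stop("responses must be positive at dissociation start", call. = FALSE)
  }
  curves <- lapply(tails, function(s) {
    list(t = s$time - s$time[1L], y = s$response)
  })
  # for fixed koff the per-curve amplitude is linear least squares:
  # R0 = sum(y e) / sum(e^2), e = exp(-koff t); profile koff in 1-D
  profile_rss <- function(k) {
    sum(vapply(curves, function(cv) {
      e <- exp(-k * cv$t)
      r0 <- sum(cv$y * e) / sum(e^2)
      sum((cv$y - r0 * e)^2)
    }, numeric(1)))
  }
  # log-linear start: common slope, per-curve intercept
  dat <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(t = curves[[i]]$t, y = curves[[i]]$y,
               id = factor(i, levels = seq_along(curves)))
  }))
  pos <- dat$y > 0
  form <- if (length(curves) > 1L) log(y) ~ 0 + id + t else log(y) ~ t
  lmfit <- stats::lm(form, data = dat[pos, ])
  k0 <- max(-unname(stats::coef(lmfit)["t"]), 0)
  hi <- max(10 * k0, 1 / max(dat$t))
  opt <- stats::optimize(profile_rss, c(0, hi), tol = 1e-12)
  koff <- if (profile_rss(0) <= opt$objective) 0 else opt$minimum
  r0 <- vapply(curves, function(cv) {
    e <- exp(-koff * cv$t)
    sum(cv$y * e) / sum(e^2)
  }, numeric(1))
  names(r0) <- vapply(tails, function(s) format(attr(s, "conc")), "")
  structure(list(kd_off = koff, r0 = r0,
                 residual_sum_sq = profile_rss(koff)),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf("Global dissociation fit: kd = %.4g s^-1 over %d curve(s)\n",
              x$kd_off, length(x$r0)))
  invisible(x)
}
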