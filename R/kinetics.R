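# Enzyme kinetics: Michaelis-Menten initial-rate fits, normalized modulation
# profiles, 4PL inhibition (IC50) and ligand-saturation KD fits.

#' Construct an initial-rate dataset
#'
#' @param substrate_conc substrate concentrations (mol/L).
#' @param rate initial rates (signal/s or mol/L/s), same length. Duplicate
#'   substrate concentrations are allowed and treated as replicates.
#' @param enzyme_conc enzyme concentration (mol/L), `> 0`.
#' @param enzyme_name enzyme identifier.
#' @param modulator_name identifier of an added protein, or `NA` for none.
#' @param modulator_conc modulator concentration (mol/L).
#' @return a `rate_dataset` object.
#' @export
rate_dataset <- function(substrate_conc, rate, enzyme_conc,
                         enzyme_name = "enzyme",
                         modulator_name = NA_character_,
                         modulator_conc = 0) {
  check_numeric_vec(substrate_conc, "substrate_conc", lower = 0)
  check_numeric_vec(rate, "rate", lower = -Inf)
  if (length(rate) != length(substrate_conc)) {
    stop("`substrate_conc` and `rate` must have equal length", call. = FALSE)
  }
  check_number(enzyme_conc, "enzyme_conc", lower = 0, strict = TRUE)
  check_number(modulator_conc, "modulator_conc", lower = 0)
  structure(list(substrate_conc = substrate_conc, rate = rate,
                 enzyme_conc = enzyme_conc, enzyme_name = enzyme_name,
                 modulator_name = modulator_name,
                 modulator_conc = modulator_conc),
            class = "rate_dataset")
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)}. The turnover
#' number is derived as \eqn{k_{cat} = V_{max}/[E]} and the catalytic
#' efficiency as \eqn{k_{cat}/K_M}. A warning flag is set when the substrate
#' grid does not bracket the fitted \eqn{K_M} (fewer than 4 distinct
#' concentrations, or all below/above \eqn{K_M}).
#'
#' @param data a [rate_dataset()].
#' @param weights optional least-squares weights.
#' @return an `mm_fit` list with `vmax`, `kcat`, `km`, `efficiency`,
#'   `standard_errors`, `residual_sum_sq`, `span_warning` and the source
#'   dataset metadata.
#' @export
#' @examples
#' s <- c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16) * 1e-6
#' d <- rate_dataset(s, 10 * 1e-8 * s / (1e-6 + s), enzyme_conc = 1e-8)
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, weights = NULL) {
  stopifnot(inherits(data, "rate_dataset"))
  if (all(data$rate == 0)) stop("all rates are zero", call. = FALSE)
  h <- fit_hyperbola(data$substrate_conc, data$rate, weights,
                     xname = "substrate_conc",
                     amax_name = "vmax", k_name = "km")
  vmax <- unname(h$estimate["vmax"])
  km <- unname(h$estimate["km"])
  kcat <- vmax / data$enzyme_conc
  se <- c(vmax = unname(h$se["vmax"]), km = unname(h$se["km"]),
          kcat = unname(h$se["vmax"]) / data$enzyme_conc)
  span_warning <- length(unique(data$substrate_conc)) < 4L ||
    min(data$substrate_conc) > km || max(data$substrate_conc) < km
  if (span_warning) {
    warning("substrate grid does not bracket the fitted KM; ",
            "parameters may be poorly determined", call. = FALSE)
  }
  structure(list(vmax = vmax, kcat = kcat, km = km,
                 efficiency = kcat / km, standard_errors = se,
                 residual_sum_sq = h$rss, span_warning = span_warning,
                 enzyme_name = data$enzyme_name,
                 enzyme_conc = data$enzyme_conc,
                 modulator_name = data$modulator_name,
                 modulator_conc = data$modulator_conc),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit (%s): kcat = %.4g s^-1, KM = %.4g M, kcat/KM = %.4g M^-1 s^-1\n",
    x$enzyme_name, x$kcat, x$km, x$efficiency))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, substrate_conc, ...) {
  object$vmax * substrate_conc / (object$km + substrate_conc)
}

#' Normalized modulation profile of kinetic parameters
#'
#' Divides the kinetic parameters of each fit by those of a reference fit
#' obtained without added modulator, giving the concentration-dependent
#' modulation of kcat, KM and kcat/KM by an added protein. Standard errors
#' are propagated to the ratios.
#'
#' @param fits list of `mm_fit` objects, one per modulator concentration,
#'   all for the same enzyme.
#' @param reference `mm_fit` measured with `modulator_conc = 0`.
#' @return data frame with columns `modulator_name`, `modulator_conc`,
#'   `kcat_ratio`, `km_ratio`, `efficiency_ratio` and their standard errors,
#'   ordered by modulator concentration.
#' @export
modulation_profile <- function(fits, reference) {
  stopifnot(all(vapply(fits, inherits, TRUE, "mm_fit")),
            inherits(reference, "mm_fit"))
  if (reference$modulator_conc != 0) {
    stop("`reference` must be measured without modulator", call. = FALSE)
  }
  enzymes <- vapply(fits, `[[`, "", "enzyme_name")
  if (any(enzymes != reference$enzyme_name)) {
    stop("all fits must be for the same enzyme as the reference",
         call. = FALSE)
  }
  rows <- lapply(fits, function(f) {
    data.frame(
      modulator_name = f$modulator_name,
      modulator_conc = f$modulator_conc,
      kcat_ratio = f$kcat / reference$kcat,
      kcat_ratio_se = ratio_se(f$kcat, f$standard_errors["kcat"],
                               reference$kcat,
                               reference$standard_errors["kcat"]),
      km_ratio = f$km / reference$km,
      km_ratio_se = ratio_se(f$km, f$standard_errors["km"],
                             reference$km, reference$standard_errors["km"]),
      efficiency_ratio = f$efficiency / reference$efficiency,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$modulator_conc), ]
  rownames(out) <- NULL
  out
}

#' Fit a four-parameter logistic inhibition curve (IC50)
#'
#' Least squares of
#' \eqn{y = bottom + (top - bottom) / (1 + (x / IC_{50})^{hill})}
#' on a fold-excess axis, with a free Hill slope bounded in (0, 10]. At
#' \eqn{x = IC_{50}} the fitted curve passes exactly through the midpoint
#' \eqn{(top + bottom)/2}.
#'
#' @param fold_excess modulator:enzyme fold-excess ratios, `>= 0`, at least
#'   5 points.
#' @param normalized_signal signal normalized to the buffer-only control
#'   (roughly in `[0, 1]` for an inhibition assay).
#' @return a `fourpl_fit` list with `bottom`, `top`, `ic50`, `hill`,
#'   `standard_errors` and `residual_sum_sq`. A warning is issued if the fit
#'   comes out increasing (`bottom > top`) or if the signal span is small.
#' @export
fit_ic50 <- function(fold_excess, normalized_signal) {
  p <- fit_fourpl_core(fold_excess, normalized_signal)
  if (p$bottom > p$top) {
    warning("fitted curve is increasing (bottom > top); ",
            "IC50 interpretation may not apply", call. = FALSE)
  }
  se <- p$se
  names(se) <- c("bottom", "top", "ic50", "hill")
  structure(list(bottom = p$bottom, top = p$top, ic50 = p$mid,
                 hill = p$hill, standard_errors = se,
                 residual_sum_sq = p$rss, data = p$data),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: bottom = %.4g, top = %.4g, IC50 = %.4g, hill = %.3g\n",
    x$bottom, x$top, x$ic50, x$hill))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, fold_excess, ...) {
  fourpl_predict(list(bottom = object$bottom, top = object$top,
                      mid = object$ic50, hill = object$hill), fold_excess)
}

#' Fit a ligand-saturation binding curve
#'
#' Least squares of \eqn{A = A_{max} L / (K_D + L)} for an optical signal
#' that saturates with ligand concentration (e.g. ternary-complex formation
#' followed at 500 nm while titrating the folate ligand).
#'
#' @param ligand_conc ligand concentrations (mol/L); should include 0 and
#'   near-saturating values.
#' @param signal absorbance (or other) signal, same length.
#' @param weights optional least-squares weights.
#' @return a `saturation_fit` list with `amax`, `kd_ligand`,
#'   `standard_errors` and `residual_sum_sq`.
#' @export
fit_saturation_kd <- function(ligand_conc, signal, weights = NULL) {
  h <- fit_hyperbola(ligand_conc, signal, weights, xname = "ligand_conc",
                     amax_name = "amax", k_name = "kd_ligand")
  structure(list(amax = unname(h$estimate["amax"]),
                 kd_ligand = unname(h$estimate["kd_ligand"]),
                 standard_errors = h$se, residual_sum_sq = h$rss,
                 fitted = h$fitted, data = h$data),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit: Amax = %.4g, KD = %.4g M\n",
              x$amax, x$kd_ligand))
  invisible(x)
}
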