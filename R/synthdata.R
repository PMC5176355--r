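# Seeded synthetic-data generators. Every generator takes an explicit seed,
# restores the caller's RNG state on exit, and attaches a `ground_truth`
# attribute recording the generating parameters, so each analysis stage can
# be exercised against known truth without external data.
#
# Noise models: multiplicative Gaussian for continuous signals, Poisson for
# spectral counts, log-normal for metabolite peak areas.

ground_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed,
                 params = list(...)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth [%s], seed %s\n", x$generator,
              format(x$seed)))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Retrieve the ground truth attached to a synthetic dataset
#'
#' @param x an object returned by one of the `gen_*()` generators.
#' @return the `ground_truth` record (generator name, seed, parameters).
#' @export
get_ground_truth <- function(x) attr(x, "ground_truth")

#' SPR analyte concentration grids
#'
#' Concentration series (mol/L) used for the PurH (6 concentrations,
#' 1.5-48 uM) and GlyA (8 concentrations, 1-64 uM) binding titrations.
#'
#' @return numeric vector of concentrations in mol/L.
#' @export
purh_conc_grid <- function() c(1.5, 3, 6, 12, 24, 48) * 1e-6

#' @rdname purh_conc_grid
#' @export
glya_conc_grid <- function() c(1, 2, 4, 8, 16, 32, 48, 64) * 1e-6

#' Substrate concentration grids for initial-rate assays
#'
#' `dhf_conc_grid()`: dihydrofolate series spanning 0.1-16 uM (DHFR
#' assay); `thf_conc_grid()`: 10-formyl-THF series spanning 20 uM - 1 mM
#' (AICAR transformylase assay).
#'
#' @return numeric vector of concentrations in mol/L.
#' @export
dhf_conc_grid <- function() c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16) * 1e-6

#' @rdname dhf_conc_grid
#' @export
thf_conc_grid <- function() c(20, 50, 100, 200, 500, 1000) * 1e-6

#' Generate a synthetic Langmuir binding isotherm
#'
#' Responses \eqn{R_{max} c/(c + K_D)} with multiplicative Gaussian noise
#' of coefficient of variation `noise_cv`.
#'
#' @param kd true dissociation constant (mol/L).
#' @param rmax true maximal response (RU).
#' @param conc analyte concentration grid (mol/L); defaults to the PurH
#'   series.
#' @param noise_cv fractional noise SD, `>= 0`.
#' @param seed RNG seed (required; same seed reproduces the table).
#' @return data frame with columns `conc`, `response` and a
#'   `ground_truth` attribute.
#' @export
gen_isotherm <- function(kd = 3e-6, rmax = 100, conc = purh_conc_grid(),
                         noise_cv = 0.02, seed) {
  if (length(conc) == 0L) stop("empty concentration grid", call. = FALSE)
  check_numeric_vec(conc, "conc", lower = 0)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(kd, "kd", lower = 0, strict = TRUE)
  resp <- with_seed(seed, {
    mu <- rmax * conc / (conc + kd)
    mu * (1 + noise_cv * stats::rnorm(length(conc)))
  })
  out <- data.frame(conc = conc, response = resp)
  attr(out, "ground_truth") <- ground_truth("isotherm", seed, kd = kd,
                                            rmax = rmax,
                                            noise_cv = noise_cv)
  out
}

#' Generate a synthetic Michaelis-Menten initial-rate dataset
#'
#' @param kcat true turnover number (s^-1).
#' @param km true Michaelis constant (mol/L).
#' @param enzyme_conc enzyme concentration (mol/L).
#' @param substrate substrate grid (mol/L); defaults to the dihydrofolate
#'   series.
#' @param noise_cv fractional noise SD.
#' @param seed RNG seed.
#' @param enzyme_name,modulator_name,modulator_conc passed through to the
#'   returned [rate_dataset()].
#' @return a `rate_dataset` with a `ground_truth` attribute.
#' @export
gen_mm_dataset <- function(kcat = 10, km = 1e-6, enzyme_conc = 1e-8,
                           substrate = dhf_conc_grid(), noise_cv = 0.03,
                           seed, enzyme_name = "enzyme",
                           modulator_name = NA_character_,
                           modulator_conc = 0) {
  if (length(substrate) == 0L) stop("empty substrate grid", call. = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  v <- with_seed(seed, {
    mu <- kcat * enzyme_conc * substrate / (km + substrate)
    mu * (1 + noise_cv * stats::rnorm(length(substrate)))
  })
  out <- rate_dataset(substrate, v, enzyme_conc,
                      enzyme_name = enzyme_name,
                      modulator_name = modulator_name,
                      modulator_conc = modulator_conc)
  attr(out, "ground_truth") <- ground_truth("mm_dataset", seed,
                                            kcat = kcat, km = km,
                                            enzyme_conc = enzyme_conc,
                                            noise_cv = noise_cv)
  out
}

#' Generate a synthetic OD600 growth curve
#'
#' Modified-Gompertz optical densities sampled at fixed intervals with
#' multiplicative Gaussian noise: growth-rate noise of a few percent is
#' the regime plate readers typically show.
#'
#' @param mu true maximum specific growth rate (h^-1).
#' @param lag true lag time (h).
#' @param amplitude true amplitude on the log(OD/OD0) scale.
#' @param od0 initial OD600.
#' @param duration total duration (h).
#' @param sampling sampling interval (minutes, default 15).
#' @param noise_cv fractional OD noise SD (default 0.02).
#' @param seed RNG seed.
#' @param label strain/condition identifier.
#' @return data frame with columns `time` (minutes), `od600` and `label`,
#'   plus a `ground_truth` attribute.
#' @export
gen_growth_curves <- function(mu = 0.6, lag = 1, amplitude = 2,
                              od0 = 0.05, duration = 12, sampling = 15,
                              noise_cv = 0.02, seed, label = "synthetic") {
  check_number(mu, "mu", lower = 0)
  check_number(amplitude, "amplitude", lower = 0, strict = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  tmin <- seq(0, duration * 60, by = sampling)
  th <- tmin / 60
  y <- amplitude * exp(-exp(mu * exp(1) / amplitude * (lag - th) + 1))
  od <- with_seed(seed, {
    od0 * exp(y) * (1 + noise_cv * stats::rnorm(length(th)))
  })
  out <- data.frame(time = tmin, od600 = od, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- ground_truth("growth_curve", seed, mu = mu,
                                            lag = lag,
                                            amplitude = amplitude,
                                            od0 = od0,
                                            noise_cv = noise_cv)
  out
}

#' Generate a synthetic co-IP spectral-count table
#'
#' Background proteins draw Poisson counts with the same protein-specific
#' rate in sample and control runs; an enriched subset has its sample-run
#' rate multiplied by `enrichment_factor`. Protein-specific rates are
#' log-normal around `background_lambda`, which makes replicate sample
#' runs positively correlated, as real pull-down repeats are.
#'
#' @param n_background number of background proteins.
#' @param n_enriched number of genuinely enriched proteins.
#' @param background_lambda mean background Poisson rate (peptides/run).
#' @param enrichment_factor multiplicative enrichment of sample-run rates
#'   for the enriched subset (1 = null table).
#' @param n_sample_runs,n_control_runs run counts (defaults 3 sample, 5
#'   pooled control).
#' @param seed RNG seed.
#' @return a [peptide_count_table()] with a `ground_truth` attribute whose
#'   `params$enriched` names the truly enriched proteins.
#' @export
gen_peptide_table <- function(n_background = 300, n_enriched = 30,
                              background_lambda = 3,
                              enrichment_factor = 8, n_sample_runs = 3,
                              n_control_runs = 5, seed) {
  check_number(background_lambda, "background_lambda", lower = 0,
               strict = TRUE)
  check_number(enrichment_factor, "enrichment_factor", lower = 0,
               strict = TRUE)
  n <- n_background + n_enriched
  tab <- with_seed(seed, {
    lam <- background_lambda *
      stats::rlnorm(n, meanlog = -0.5, sdlog = 1)
    lam_sample <- lam * c(rep(1, n_background),
                          rep(enrichment_factor, n_enriched))
    counts <- cbind(
      matrix(stats::rpois(n * n_sample_runs, rep(lam_sample,
                                                 n_sample_runs)),
             nrow = n),
      matrix(stats::rpois(n * n_control_runs, rep(lam, n_control_runs)),
             nrow = n))
    rownames(counts) <- c(sprintf("bg_%03d", seq_len(n_background)),
                          sprintf("hit_%03d", seq_len(n_enriched)))
    colnames(counts) <- c(sprintf("sample_%d", seq_len(n_sample_runs)),
                          sprintf("control_%d", seq_len(n_control_runs)))
    counts
  })
  out <- peptide_count_table(tab, c(rep(TRUE, n_sample_runs),
                                    rep(FALSE, n_control_runs)))
  attr(out, "ground_truth") <- ground_truth(
    "peptide_table", seed, background_lambda = background_lambda,
    enrichment_factor = enrichment_factor,
    enriched = sprintf("hit_%03d", seq_len(n_enriched)))
  out
}

#' Generate a synthetic metabolite peak-area table
#'
#' Log-normal replicate areas per metabolite and strain. A control strain
#' always carries fold 1; `effects` gives the true fold change of each
#' metabolite in each treated strain.
#'
#' @param effects named numeric vector of fold changes for a single
#'   treated strain, or a named list of such vectors (one per strain).
#'   Metabolite names are taken from the vector names.
#' @param control_strain name of the control strain (default
#'   `"control"`).
#' @param n_replicates biological replicates per strain (default 3).
#' @param noise_cv fractional biological coefficient of variation of the
#'   areas (default 0.2).
#' @param base_area median peak area scale.
#' @param seed RNG seed.
#' @return a [metabolite_matrix()] with a `ground_truth` attribute.
#' @export
gen_metabolite_matrix <- function(effects, control_strain = "control",
                                  n_replicates = 3, noise_cv = 0.2,
                                  base_area = 1e6, seed) {
  if (!is.list(effects)) effects <- list(treated = effects)
  mets <- names(effects[[1L]])
  if (is.null(mets)) stop("`effects` must be named by metabolite",
                          call. = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  sdlog <- sqrt(log(1 + noise_cv^2))
  strains <- c(control_strain, names(effects))
  folds <- c(list(stats::setNames(rep(1, length(mets)), mets)), effects)
  names(folds) <- strains
  out <- with_seed(seed, {
    # per-metabolite baseline spread over ~2 decades, as ion currents are
    base <- base_area * stats::rlnorm(length(mets), sdlog = 2)
    names(base) <- mets
    rows <- list()
    for (s in strains) {
      for (m in mets) {
        mu <- base[m] * folds[[s]][m]
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, strain = s, replicate = seq_len(n_replicates),
          area = mu * stats::rlnorm(n_replicates, meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  mm <- metabolite_matrix(out)
  attr(mm, "ground_truth") <- ground_truth("metabolite_matrix", seed,
                                           effects = effects,
                                           control = control_strain,
                                           noise_cv = noise_cv)
  mm
}

#' Generate a synthetic abundance-fitness branch
#'
#' Depletion branches follow the saturating form
#' \eqn{F_{max} a/(a + K_f)}; overexpression branches follow a decreasing
#' four-parameter logistic. Relative growth carries multiplicative
#' Gaussian noise with SD `sd` (default 3%, the replicate scatter typical
#' of plate-reader growth rates).
#'
#' @param branch `"depletion"` or `"overexpression"`.
#' @param params named list of true parameters: `fmax`, `kf` for
#'   depletion; `bottom`, `top`, `mid`, `hill` for overexpression.
#' @param n_points number of abundance points (log-spaced over 0.01-1
#'   fold for depletion, 1-850 fold for overexpression).
#' @param sd fractional SD of relative growth.
#' @param seed RNG seed.
#' @return a [fitness_points()] data frame with a `ground_truth`
#'   attribute.
#' @export
gen_fitness_curve <- function(branch = c("depletion", "overexpression"),
                              params = NULL, n_points = 8, sd = 0.03,
                              seed) {
  branch <- match.arg(branch)
  check_number(sd, "sd", lower = 0)
  if (branch == "depletion") {
    if (is.null(params)) params <- list(fmax = 1, kf = 0.05)
    a <- exp(seq(log(0.01), log(1), length.out = n_points))
    f <- params$fmax * a / (a + params$kf)
  } else {
    if (is.null(params)) {
      params <- list(bottom = 0.25, top = 1, mid = 40, hill = 1.5)
    }
    a <- exp(seq(log(1), log(850), length.out = n_points))
    f <- fourpl_predict(params, a)
  }
  g <- with_seed(seed, f * (1 + sd * stats::rnorm(n_points)))
  out <- fitness_points(a, pmax(g, 0), sd = sd)
  attr(out, "ground_truth") <- ground_truth("fitness_curve", seed,
                                            branch = branch,
                                            params = params, sd = sd)
  out
}
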