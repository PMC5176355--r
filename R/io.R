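# Validated tabular IO, YAML system definitions, and the umbrella pipeline
# driver tying the analysis stages together on real or synthetic inputs.

#' Read a delimited table against a column schema
#'
#' Reads a headered CSV/TSV file (UTF-8, '.' decimal separator) and
#' validates it against a schema of expected columns: every schema column
#' must be present, numeric columns must parse, and parse failures are
#' reported with their (1-based, header-excluded) row index.
#'
#' @param path file path.
#' @param schema named character vector mapping column name to type,
#'   `"numeric"` or `"character"` (e.g.
#'   `c(conc = "numeric", response = "numeric")`).
#' @param sep field separator: `","` (default) or `"\t"`.
#' @return a data frame with typed columns, rows in file order.
#' @export
read_tabular <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (file.size(path) == 0L) {
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "",
                           quote = "\"")
  miss <- setdiff(names(schema), names(raw))
  if (length(miss)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- raw[names(schema)]
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(is.na(v) & !is.na(out[[col]]) &
                     nzchar(trimws(out[[col]])))
      if (anyNA(v) && length(bad) == 0L) bad <- which(is.na(v))
      if (length(bad)) {
        stop(sprintf("column '%s' of %s: non-numeric value '%s' at row %d",
                     col, path, out[[col]][bad[1L]], bad[1L]),
             call. = FALSE)
      }
      out[[col]] <- v
    }
  }
  out
}

#' Write a table as delimited text
#'
#' Writes with a mandatory header, no row names, no quoting of numerics,
#' and full double precision (15 significant digits), so that
#' write-then-read round-trips are lossless.
#'
#' @param x data frame.
#' @param path output path.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(x, path, sep = ",") {
  xx <- as.data.frame(x)
  for (col in names(xx)) {
    if (is.numeric(xx[[col]])) {
      xx[[col]] <- formatC(xx[[col]], digits = 15, format = "g")
    }
  }
  utils::write.table(xx, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an equilibrium system definition from YAML
#'
#' Expected layout:
#' ```yaml
#' hub: {name: DHFR, total: 5.0e-8}
#' partners:
#'   - {name: PurH, total: 2.0e-7, kd: 3.0e-6}
#' ```
#'
#' @param path YAML file path.
#' @return an [equilibrium_system()].
#' @export
read_equilibrium_system <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$hub) || is.null(y$hub$name) || is.null(y$hub$total)) {
    stop("system file must define hub name and total", call. = FALSE)
  }
  partners <- y$partners
  if (is.null(partners)) partners <- list()
  equilibrium_system(
    hub = y$hub$name, hub_total = as.numeric(y$hub$total),
    partners = vapply(partners, function(p) as.character(p$name), ""),
    partner_totals = vapply(partners, function(p) as.numeric(p$total),
                            0),
    kds = vapply(partners, function(p) as.numeric(p$kd), 0))
}

pipeline_stages <- c("equilibrium", "binding", "kinetics", "growth",
                     "interactome", "metabolomics")

validate_config <- function(config) {
  known <- c("stages", "seed", "out_dir", "equilibrium", "sep")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$stages) || length(config$stages) == 0L) {
    stop("config selects no stages", call. = FALSE)
  }
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) {
    stop("config must set `out_dir`", call. = FALSE)
  }
  if (is.null(config$sep)) config$sep <- "\t"
  if (is.null(config$equilibrium)) {
    config$equilibrium <- list(hub_total = 5e-8, partner_total = 2e-7,
                               kd = 3e-6,
                               fold_factors = 10^seq(0, 3, by = 0.5))
  }
  config
}

#' Run the end-to-end analysis pipeline on synthetic demonstration data
#'
#' Executes the selected stages in order, writing one TSV per stage into
#' `out_dir` plus a `summary.yaml` recording the seed and stage outputs.
#' Each stage generates its inputs with the packaged seeded generators
#' (derived deterministically from `config$seed`), runs the corresponding
#' analysis, and reports recovered versus true parameters; the
#' `equilibrium` stage computes the mass-action sequestration table for
#' the configured abundances. Logs go to `stderr` via `message()`, never
#' into the result files; reruns with the same config are byte-identical.
#'
#' @param config a named list (or path to a YAML file) with keys `stages`
#'   (subset of equilibrium, binding, kinetics, growth, interactome,
#'   metabolomics), `seed`,
#'   `out_dir`, optional `sep` and optional `equilibrium` parameters
#'   (`hub_total`, `partner_total`, `kd`, `fold_factors`). Unknown keys
#'   are rejected.
#' @return a named list of per-stage summaries, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  results <- list()
  for (stage in config$stages) {
    message(sprintf("[dosetox] running stage '%s'", stage))
    res <- tryCatch(
      run_stage(stage, config, seed),
      error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
      })
    results[[stage]] <- res
  }
  summary_path <- file.path(config$out_dir, "summary.yaml")
  yaml::write_yaml(list(seed = seed, stages = results), summary_path)
  invisible(results)
}

run_stage <- function(stage, config, seed) {
  out <- function(name) file.path(config$out_dir, name)
  sep <- config$sep
  switch(stage,
    equilibrium = {
      eq <- config$equilibrium
      sys <- equilibrium_system("hub", eq$hub_total, "partner",
                                eq$partner_total, eq$kd)
      tab <- titration_scan(sys, as.numeric(eq$fold_factors))
      write_tabular(tab, out("equilibrium_titration.tsv"), sep = sep)
      basal <- solve_pairwise(eq$hub_total, eq$partner_total, eq$kd)
      list(file = "equilibrium_titration.tsv",
           pct_hub_bound_basal = round_half_up(
             100 * unname(basal$fraction_bound[1L]), 1),
           pct_partner_bound_basal = round_half_up(
             100 * unname(basal$fraction_bound[2L]), 1))
    },
    binding = {
      iso <- gen_isotherm(seed = seed + 1L)
      fit <- fit_isotherm(iso)
      write_tabular(iso, out("binding_isotherm.tsv"), sep = sep)
      list(file = "binding_isotherm.tsv",
           kd_true = get_ground_truth(iso)$params$kd, kd_fit = fit$kd)
    },
    kinetics = {
      mm <- gen_mm_dataset(seed = seed + 2L)
      fit <- fit_michaelis_menten(mm)
      write_tabular(data.frame(substrate_conc = mm$substrate_conc,
                               rate = mm$rate),
                    out("kinetics_rates.tsv"), sep = sep)
      list(file = "kinetics_rates.tsv",
           km_true = get_ground_truth(mm)$params$km, km_fit = fit$km,
           kcat_true = get_ground_truth(mm)$params$kcat,
           kcat_fit = fit$kcat)
    },
    growth = {
      gc <- gen_growth_curves(seed = seed + 3L)
      fit <- fit_growth_curve(gc$time, gc$od600)
      write_tabular(gc, out("growth_curve.tsv"), sep = sep)
      list(file = "growth_curve.tsv",
           mu_true = get_ground_truth(gc)$params$mu,
           mu_fit = fit$mu_max)
    },
    interactome = {
      tab <- gen_peptide_table(seed = seed + 4L)
      hits <- call_interactors(tab)
      shift <- dataset_shift_test(tab)
      hit_df <- as.data.frame(hits)
      write_tabular(hit_df, out("interactome_hits.tsv"), sep = sep)
      truth <- get_ground_truth(tab)$params$enriched
      list(file = "interactome_hits.tsv", n_hits = nrow(hits),
           recall = mean(truth %in% hits$protein),
           shift_p = shift$p_value)
    },
    metabolomics = {
      eff <- c(AICAR = 8, dUMP = 4, IMP = 0.3, dTTP = 0.25, AMP = 0.5,
               GMP = 0.6, glycine = 1, serine = 1)
      mm <- gen_metabolite_matrix(eff, seed = seed + 5L)
      fc <- normalize_to_control(mm, "control")
      sig <- annotate_significance(mm, "treated", "control")
      merged <- merge(as.data.frame(fc), sig, by = "metabolite")
      write_tabular(merged, out("metabolomics_foldchange.tsv"),
                    sep = sep)
      list(file = "metabolomics_foldchange.tsv",
           n_significant = sum(sig$star != ""))
    },
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
}

#' Load an abundance-growth source table
#'
#' Reads a deposited two-column abundance/growth table (columns
#' `rel_abundance`, `rel_growth`, optionally `branch`) as
#' [fitness_points()], for re-analysis of published per-strain
#' measurements.
#'
#' @param path CSV path.
#' @param sep field separator.
#' @return a `fitness_points` data frame (with a `branch` column when
#'   present in the file).
#' @export
read_fitness_table <- function(path, sep = ",") {
  first <- utils::read.table(path, header = TRUE, sep = sep, nrows = 1,
                             check.names = FALSE)
  schema <- c(rel_abundance = "numeric", rel_growth = "numeric")
  if ("branch" %in% names(first)) schema <- c(schema,
                                              branch = "character")
  tab <- read_tabular(path, schema, sep = sep)
  fp <- fitness_points(tab$rel_abundance, tab$rel_growth)
  if ("branch" %in% names(tab)) fp$branch <- tab$branch
  fp
}
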