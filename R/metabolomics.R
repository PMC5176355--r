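# Metabolomics stage: replicate peak-area tables to log2 fold-change
# matrices, per-metabolite significance stars, and metabolite-fitness
# correlation.

#' Construct a metabolite peak-area table
#'
#' Long-format replicate table of integrated ion-current peak areas. Zero
#' areas are floored at half the minimum positive area of the metabolite
#' (the usual missing-value convention for peak integration).
#'
#' @param data data frame with columns `metabolite`, `strain`, `replicate`
#'   and `area` (nonnegative).
#' @return a `metabolite_matrix` data frame.
#' @export
metabolite_matrix <- function(data) {
  need <- c("metabolite", "strain", "replicate", "area")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_numeric_vec(data$area, "area", lower = 0)
  for (m in unique(data$metabolite)) {
    sel <- data$metabolite == m
    pos <- data$area[sel][data$area[sel] > 0]
    if (length(pos) && any(data$area[sel] == 0)) {
      data$area[sel][data$area[sel] == 0] <- min(pos) / 2
    }
  }
  structure(as.data.frame(data), class = c("metabolite_matrix",
                                           "data.frame"))
}

strain_means <- function(m, aggregate = c("mean", "geometric")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") {
    function(x) mean(x)
  } else {
    function(x) exp(mean(log(x)))
  }
  stats::aggregate(area ~ metabolite + strain, data = m, FUN = agg)
}

#' Normalize metabolite levels to a control strain
#'
#' Per metabolite, computes log2(mean replicate area of each strain / mean
#' replicate area of the control strain). The control column is
#' identically zero by construction. Metabolites with a zero or missing
#' control mean are dropped with a message.
#'
#' @param m a [metabolite_matrix()].
#' @param control control strain identifier (e.g. the empty-plasmid
#'   strain).
#' @param aggregate replicate aggregation: arithmetic `"mean"` (default)
#'   or `"geometric"`.
#' @return a metabolite x strain data frame of log2 fold changes with a
#'   `replicates` attribute giving replicate counts per (metabolite,
#'   strain).
#' @export
normalize_to_control <- function(m, control,
                                 aggregate = c("mean", "geometric")) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (!control %in% m$strain) {
    stop(sprintf("control strain '%s' not present", control),
         call. = FALSE)
  }
  means <- strain_means(m, aggregate)
  wide <- stats::reshape(means, idvar = "metabolite",
                         timevar = "strain", direction = "wide")
  names(wide) <- sub("^area\\.", "", names(wide))
  rownames(wide) <- wide$metabolite
  ctrl <- wide[[control]]
  bad <- is.na(ctrl) | ctrl <= 0
  if (any(bad)) {
    message("dropping metabolite(s) with zero/missing control mean: ",
            paste(wide$metabolite[bad], collapse = ", "))
    wide <- wide[!bad, , drop = FALSE]
    ctrl <- ctrl[!bad]
  }
  strains <- setdiff(names(wide), "metabolite")
  fc <- wide[, strains, drop = FALSE]
  for (s in strains) fc[[s]] <- log2(wide[[s]] / ctrl)
  reps <- table(m$metabolite, m$strain)
  structure(cbind(data.frame(metabolite = wide$metabolite,
                             stringsAsFactors = FALSE), fc),
            replicates = reps, control = control,
            class = c("fold_change_matrix", "data.frame"),
            row.names = seq_len(nrow(wide)))
}

star_label <- function(p) {
  ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))
}

#' Per-metabolite significance annotation
#'
#' Unpaired t-test of replicate peak areas between a test strain and a
#' reference strain for each metabolite, with the star convention
#' `"*"` for p < 0.05 and `"**"` for p < 0.001. No multiple-testing
#' correction is applied by default, matching common heat-map annotation
#' practice; set `adjust = "BH"` for Benjamini-Hochberg stars.
#'
#' @param m a [metabolite_matrix()] with at least 2 replicates per side.
#' @param test_strain,reference_strain strain identifiers to compare.
#' @param var_equal `FALSE` (default) for Welch's t-test, `TRUE` for
#'   pooled variance.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data frame with columns `metabolite`, `p_value` and `star`.
#'   Identical replicate sets give `p_value = 1`.
#' @export
annotate_significance <- function(m, test_strain, reference_strain,
                                  var_equal = FALSE, adjust = "none") {
  stopifnot(inherits(m, "metabolite_matrix"))
  for (s in c(test_strain, reference_strain)) {
    if (!s %in% m$strain) stop(sprintf("strain '%s' not present", s),
                               call. = FALSE)
  }
  mets <- unique(m$metabolite)
  p <- vapply(mets, function(met) {
    a <- m$area[m$metabolite == met & m$strain == test_strain]
    b <- m$area[m$metabolite == met & m$strain == reference_strain]
    if (length(a) < 2L || length(b) < 2L) {
      stop(sprintf("metabolite '%s' has fewer than 2 replicates", met),
           call. = FALSE)
    }
    tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # zero variance on both sides: equal means -> 1, separated -> 0
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      tt$p.value
    }
  }, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  data.frame(metabolite = mets, p_value = unname(p),
             star = star_label(unname(p)), stringsAsFactors = FALSE)
}

#' Correlate metabolite levels with fitness across strains
#'
#' Pearson correlation (with two-sided t-based p-value) between a
#' per-strain metabolite level and per-strain relative growth rate.
#'
#' @param levels named numeric vector of metabolite levels per strain.
#' @param growth named numeric vector of relative growth rates; names are
#'   matched to `levels` when present.
#' @return list with `r` and `p_value`; constant input yields a missing
#'   `r` with a warning.
#' @export
correlate_with_fitness <- function(levels, growth) {
  if (!is.null(names(levels)) && !is.null(names(growth))) {
    common <- intersect(names(levels), names(growth))
    if (length(common) < length(levels)) {
      warning("strains without both measurements dropped", call. = FALSE)
    }
    levels <- levels[common]
    growth <- growth[common]
  }
  if (length(levels) < 4L || length(levels) != length(growth)) {
    stop("need >= 4 strains with both measurements", call. = FALSE)
  }
  if (stats::sd(levels) == 0 || stats::sd(growth) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(levels, growth)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
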