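# Co-immunoprecipitation spectral-count analysis: background-subtraction
# hit calling, dataset-level paired shift test, replicate agreement and
# interactome set comparison.

#' Construct a peptide spectral-count table
#'
#' @param counts protein x run matrix of nonnegative integer peptide
#'   counts; row names are protein identifiers, column names run labels.
#'   A protein absent from a run is counted as 0 peptides.
#' @param is_sample logical vector, one per run: `TRUE` for pull-down
#'   sample runs, `FALSE` for control runs (e.g. untransformed wild type
#'   or an orthologue-chromosome strain). Controls are pooled.
#' @return a `peptide_count_table` object.
#' @export
peptide_count_table <- function(counts, is_sample) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("protein_", seq_len(nrow(counts)))
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  if (length(is_sample) != ncol(counts) || !is.logical(is_sample)) {
    stop("`is_sample` must be a logical vector with one entry per run",
         call. = FALSE)
  }
  if (!any(is_sample) || all(is_sample)) {
    stop("need at least one sample run and one control run", call. = FALSE)
  }
  structure(list(counts = counts, is_sample = is_sample),
            class = "peptide_count_table")
}

#' @export
print.peptide_count_table <- function(x, ...) {
  cat(sprintf("Peptide count table: %d proteins, %d sample + %d control runs\n",
              nrow(x$counts), sum(x$is_sample), sum(!x$is_sample)))
  invisible(x)
}

protein_means <- function(table) {
  ms <- rowMeans(table$counts[, table$is_sample, drop = FALSE])
  mc <- rowMeans(table$counts[, !table$is_sample, drop = FALSE])
  data.frame(protein = rownames(table$counts), mean_sample = ms,
             mean_control = mc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call interaction partners from a co-IP count table
#'
#' A protein is retained as a putative interactor when its mean peptide
#' count over the sample runs strictly exceeds its mean over the pooled
#' control runs (background subtraction by control comparison; no multiple
#' testing correction is applied, use [stats::p.adjust()] downstream if
#' desired). Means are taken over all runs, counting absence as zero.
#' Proteins observed in no run at all are excluded.
#'
#' @param table a [peptide_count_table()].
#' @return a `hit_list` data frame with columns `protein`, `mean_sample`
#'   and `mean_control`, ordered by decreasing sample enrichment.
#' @export
call_interactors <- function(table) {
  stopifnot(inherits(table, "peptide_count_table"))
  m <- protein_means(table)
  observed <- rowSums(table$counts) > 0
  keep <- observed & (m$mean_sample > m$mean_control)
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$mean_sample - out$mean_control,
                   decreasing = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("hit_list", "data.frame")
  out
}

#' Dataset-level enrichment shift test
#'
#' Paired t-test across proteins of mean sample count versus mean control
#' count, testing whether the pull-down globally enriches over background.
#'
#' @param table a [peptide_count_table()] with at least 2 proteins.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `p_value`, `mean_difference` and `degenerate`
#'   (`TRUE` when the per-protein differences have zero variance; a
#'   constant nonzero shift then yields `p_value = 0`, all-zero
#'   differences `p_value = 1`).
#' @export
dataset_shift_test <- function(table,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  stopifnot(inherits(table, "peptide_count_table"))
  alternative <- match.arg(alternative)
  m <- protein_means(table)
  if (nrow(m) < 2L) stop("need at least 2 proteins", call. = FALSE)
  d <- m$mean_sample - m$mean_control
  if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    return(list(p_value = p, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(d, alternative = alternative)
  list(p_value = tt$p.value, mean_difference = mean(d),
       degenerate = FALSE)
}

#' Replicate agreement among sample runs
#'
#' All pairwise Pearson correlations of per-protein peptide counts between
#' sample runs, with per-pair p-values, summarizing reproducibility of the
#' pull-down.
#'
#' @param table a [peptide_count_table()] with at least 2 sample runs.
#' @return an `enrichment_summary` list with `average_r`, a `pairs` data
#'   frame (`run1`, `run2`, `r`, `p_value`) and `flagged_constant` (runs
#'   with zero variance, whose pairs have `NA` correlation).
#' @export
replicate_agreement <- function(table) {
  stopifnot(inherits(table, "peptide_count_table"))
  s <- table$counts[, table$is_sample, drop = FALSE]
  if (ncol(s) < 2L) stop("need at least 2 sample runs", call. = FALSE)
  runs <- colnames(s)
  if (is.null(runs)) runs <- paste0("sample_", seq_len(ncol(s)))
  const <- apply(s, 2L, stats::sd) == 0
  pairs <- utils::combn(seq_len(ncol(s)), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (const[i] || const[j]) {
      return(data.frame(run1 = runs[i], run2 = runs[j], r = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(s[, i], s[, j])
    data.frame(run1 = runs[i], run2 = runs[j],
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  pairs_df <- do.call(rbind, rows)
  structure(list(average_r = mean(pairs_df$r, na.rm = TRUE),
                 pairs = pairs_df,
                 flagged_constant = runs[const]),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("Replicate agreement: average r = %.3f over %d pair(s)\n",
              x$average_r, nrow(x$pairs)))
  invisible(x)
}

#' Compare two interactomes
#'
#' Set algebra on hit identifiers from two hit lists (or character
#' vectors), with the Jaccard index of overlap.
#'
#' @param a,b `hit_list` objects from [call_interactors()] or character
#'   vectors of protein identifiers.
#' @return list with `shared`, `a_only`, `b_only` (character vectors) and
#'   `jaccard`.
#' @export
compare_interactomes <- function(a, b) {
  ida <- if (is.data.frame(a)) a$protein else as.character(a)
  idb <- if (is.data.frame(b)) b$protein else as.character(b)
  ida <- unique(ida)
  idb <- unique(idb)
  shared <- intersect(ida, idb)
  uni <- union(ida, idb)
  list(shared = shared,
       a_only = setdiff(ida, idb),
       b_only = setdiff(idb, ida),
       jaccard = if (length(uni)) length(shared) / length(uni) else NaN)
}
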