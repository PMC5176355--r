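small_table <- function() {
  counts <- rbind(
    keep = c(10, 12, 11, 2, 0, 1, 3, 0),   # clear sample enrichment
    tie  = c(3, 3, 3, 3, 3, 3, 3, 3),      # equal means -> excluded
    drop = c(0, 1, 0, 4, 5, 3, 2, 6),      # control-enriched
    zero = c(0, 0, 0, 0, 0, 0, 0, 0))      # never observed
  peptide_count_table(counts, c(rep(TRUE, 3), rep(FALSE, 5)))
}

test_that("hit calling keeps proteins whose sample mean strictly exceeds control", {
  hits <- call_interactors(small_table())
  expect_identical(hits$protein, "keep")
  expect_equal(hits$mean_sample, 11)
  expect_equal(hits$mean_control, 1.2)
  # invariant to run order and protein order
  tab <- small_table()
  perm_runs <- sample(ncol(tab$counts))
  tab2 <- peptide_count_table(tab$counts[c(3, 1, 4, 2), perm_runs],
                              tab$is_sample[perm_runs])
  expect_identical(sort(call_interactors(tab2)$protein),
                   sort(hits$protein))
})

test_that("count table constructor validates its inputs", {
  expect_error(peptide_count_table(matrix(-1, 2, 4),
                                   c(TRUE, TRUE, FALSE, FALSE)),
               "nonnegative")
  expect_error(peptide_count_table(matrix(1.5, 2, 4),
                                   c(TRUE, TRUE, FALSE, FALSE)),
               "integers")
  expect_error(peptide_count_table(matrix(1L, 2, 4), rep(TRUE, 4)),
               "control")
})

test_that("the dataset shift test detects global enrichment and its degenerate cases", {
  # identical means -> p = 1
  counts <- cbind(matrix(rep(c(2L, 5L, 9L), 3), ncol = 3),
                  matrix(rep(c(2L, 5L, 9L), 2), ncol = 2))
  eq <- peptide_count_table(counts, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(dataset_shift_test(eq)$p_value, 1)
  # constant +5 shift: zero-variance differences flagged, p -> 0
  shifted <- peptide_count_table(counts + cbind(matrix(5L, 3, 3),
                                                matrix(0L, 3, 2)),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE))
  res <- dataset_shift_test(shifted)
  expect_identical(res$p_value, 0)
  expect_true(res$degenerate)
  # enriched generator table: dataset-level p < 0.001
  tab <- gen_peptide_table(seed = 1)
  expect_lt(dataset_shift_test(tab)$p_value, 0.001)
})

test_that("enrichment recall rises to one with the enrichment factor", {
  recalls <- sapply(c(1, 2, 8), function(f) {
    tab <- gen_peptide_table(n_background = 150, n_enriched = 20,
                             enrichment_factor = f, seed = 42)
    truth <- get_ground_truth(tab)$params$enriched
    mean(truth %in% call_interactors(tab)$protein)
  })
  expect_true(all(diff(recalls) >= 0))
  expect_identical(recalls[3L], 1)
  # at factor 1 the enriched labels behave like background: recall near
  # the chance level for mean(sample) > mean(control)
  expect_lt(recalls[1L], 0.8)
})

test_that("replicate agreement reports pairwise correlations and flags constants", {
  tab <- gen_peptide_table(seed = 3)
  summ <- replicate_agreement(tab)
  expect_identical(nrow(summ$pairs), 3L)
  expect_true(all(summ$pairs$r > 0.5))
  expect_true(all(summ$pairs$p_value < 0.001))
  # duplicated run correlates perfectly
  counts <- tab$counts
  counts[, 2L] <- counts[, 1L]
  dup <- peptide_count_table(counts, tab$is_sample)
  expect_equal(replicate_agreement(dup)$pairs$r[1L], 1)
  # shuffling protein labels in one run destroys the correlation
  set.seed(5)
  counts2 <- tab$counts
  counts2[, 2L] <- sample(counts2[, 2L])
  shuf <- replicate_agreement(peptide_count_table(counts2,
                                                  tab$is_sample))
  expect_lt(abs(shuf$pairs$r[1L]), 0.2)
  # constant run flagged
  counts3 <- tab$counts
  counts3[, 1L] <- 2L
  cst <- replicate_agreement(peptide_count_table(counts3,
                                                 tab$is_sample))
  expect_identical(cst$flagged_constant, colnames(counts3)[1L])
  expect_true(anyNA(cst$pairs$r))
})

test_that("interactome comparison does exact set algebra", {
  a <- paste0("p", 1:29)
  b <- paste0("p", 1:60)
  cmp <- compare_interactomes(a, b)
  expect_identical(length(cmp$shared), 29L)
  expect_identical(length(cmp$a_only), 0L)
  expect_identical(length(cmp$b_only), 31L)
  expect_equal(cmp$jaccard, 29 / 60)
  expect_equal(compare_interactomes(a, a)$jaccard, 1)
  expect_equal(compare_interactomes(a, paste0("q", 1:5))$jaccard, 0)
})
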