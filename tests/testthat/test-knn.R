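# Independent re-statement of the vote ladder, used as the test oracle:
# try a strict majority among the first 5, then 4, then 3 labels.
vote_oracle <- function(labels) {
  for (lv in c(5, 4, 3)) {
    if (lv > length(labels)) next
    counts <- table(labels[seq_len(lv)])
    winner <- names(counts)[counts > lv / 2]
    if (length(winner) == 1) return(list(label = winner, vote_level = lv))
  }
  list(label = "UNASSIGNED", vote_level = NA_integer_)
}

test_that("the 5-4-3 fallback ladder matches the rule oracle exhaustively", {
  labs <- c("A", "B", "C")
  grid <- expand.grid(rep(list(labs), 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ], use.names = FALSE)
    got <- majority_vote(v)
    want <- vote_oracle(v)
    expect_identical(got$label, want$label,
                     label = paste(v, collapse = ""))
    expect_identical(got$vote_level, as.integer(want$vote_level))
  }
})

test_that("vote ladder worked examples and guards", {
  expect_identical(majority_vote(c("A", "A", "A", "B", "C")),
                   list(label = "A", vote_level = 5L))
  # 5: A=2 no majority; first 4: 2-2 tie; first 3: A=2 > 1.5
  expect_identical(majority_vote(c("A", "B", "A", "B", "C")),
                   list(label = "A", vote_level = 3L))
  expect_identical(majority_vote(c("A", "B", "C", "D", "E"))$label,
                   "UNASSIGNED")
  expect_identical(majority_vote(c("A", "A", "A", "C"))$vote_level, 4L)
  expect_error(majority_vote(c("A", "B")), "at least 3")
})

test_that("queries identical to reference samples are assigned at level 5", {
  set.seed(1)
  ref_dos <- rbind(matrix(rep(c(2L, 0L, 2L, 0L), 5), 5, 4, byrow = TRUE),
                   matrix(sample(0:2, 20, TRUE), 5, 4))
  ref <- toy_dataset(ref_dos, populations = rep(c("A", "B"), each = 5))
  q <- toy_dataset(matrix(c(2L, 0L, 2L, 0L), 1, 4))
  rep_ <- knn_assign(ref, q, markers = ref$snps$snp_id, k = 5)
  expect_identical(rep_$assignments$predicted, "A")
  expect_identical(rep_$assignments$vote_level, 5L)
})

test_that("k larger than the reference truncates with a warning", {
  ref <- toy_dataset(matrix(c(0L, 2L, 1L, 1L), 2, 2),
                     populations = c("A", "B"))
  q <- toy_dataset(matrix(c(1L, 1L), 1, 2))
  expect_warning(rep_ <- knn_assign(ref, q, ref$snps$snp_id, k = 5),
                 "truncating")
  expect_identical(rep_$k, 2L)
})

test_that("missing markers raise an error naming the offenders", {
  ref <- toy_dataset(matrix(0:1, 2, 2), populations = c("A", "B"))
  q <- toy_dataset(matrix(0:1, 2, 2))
  expect_error(knn_assign(ref, q, c("m001", "zzz")), "zzz")
})

test_that("assignments are invariant to reference shuffling without ties", {
  set.seed(2)
  sim <- simulate_dataset(toy_config(n_pops = 3, n_per_pop = 40,
                                     n_snps = 120,
                                     fst = c(0.05, 0.05, 0.05), seed = 3))
  ds <- sim$dataset
  ref_idx <- unlist(lapply(c("A", "B", "C"), function(p)
    which(ds$populations == p)[1:30]))
  q_idx <- setdiff(seq_along(ds$sample_ids), ref_idx)
  ref <- subset_genotypes(ds, samples = ref_idx)
  qry <- subset_genotypes(ds, samples = q_idx)
  markers <- ds$snps$snp_id[1:60]
  a <- knn_assign(ref, qry, markers)
  perm <- sample(length(ref$sample_ids))
  b <- knn_assign(subset_genotypes(ref, samples = perm), qry, markers)
  agree <- mean(a$assignments$predicted == b$assignments$predicted)
  expect_gt(agree, 0.9)    # only exact integer-distance ties may differ
})

test_that("scoring honours exact matches and indistinct pairs only", {
  rep_ <- structure(list(assignments = data.frame(
    sample_id = c("q1", "q2", "q3", "q4"),
    predicted = c("DE", "UNASSIGNED", "FR", "IT"),
    vote_level = c(5L, NA, 3L, 5L),
    neighbours = "", stringsAsFactors = FALSE),
    marker_count = 10, k = 5, per_population = NULL),
    class = "assignment_report")
  truth <- c("FR", "FR", "FR", "FR")
  pairs <- data.frame(pop1 = "DE", pop2 = "FR")
  scored <- score_assignments(rep_, truth, pairs)
  expect_identical(scored$assignments$correct, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(scored$overall, 0.5)
  expect_equal(scored$per_population$n_unassigned, 1L)
})

test_that("well-separated populations leave nothing unassigned", {
  cfg <- toy_config(n_pops = 3, n_per_pop = 60, n_snps = 100,
                    fst = rep(0.4, 3), seed = 5)
  ds <- simulate_dataset(cfg)$dataset
  d <- make_study_design(ds, reference_size = 40, min_test = 5, seed = 1)
  rep_ <- knn_assign(d$reference, d$test, ds$snps$snp_id)
  expect_false(any(rep_$assignments$predicted == "UNASSIGNED"))
  scored <- score_assignments(rep_, d$test$populations, NULL)
  expect_gt(scored$overall, 0.95)
})

test_that("accuracy_curve validates counts and closes over reference labels", {
  cfg <- toy_config(n_pops = 3, n_per_pop = 50, n_snps = 150,
                    fst = rep(0.05, 3), seed = 6)
  ds <- simulate_dataset(cfg)$dataset
  d <- make_study_design(ds, reference_size = 30, min_test = 5,
                         held_out_pops = "C", seed = 2)
  rk <- suppressWarnings(rank_aims(d$reference, thin = FALSE))
  expect_error(accuracy_curve(d$reference, d$test, rk, marker_counts = 0),
               "positive")
  expect_error(accuracy_curve(d$reference, d$test, rk,
                              marker_counts = nrow(rk$table) + 1),
               "only")
  # held-out population queries can only receive reference labels
  hrep <- knn_assign(d$reference, d$heldout, top_markers(rk, 20))
  expect_true(all(hrep$assignments$predicted %in%
                    c(unique(d$reference$populations), "UNASSIGNED")))
  curve <- accuracy_curve(d$reference, d$test, rk,
                          marker_counts = c(10, 50),
                          indistinct_pairs = NULL)
  expect_true(all(c("marker_count", "population", "accuracy") %in%
                    names(curve)))
  expect_identical(sort(unique(curve$marker_count)), c(10, 50))
})
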