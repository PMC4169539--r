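test_that("identical configs give bit-identical datasets", {
  cfg <- toy_config(seed = 11, missing_rate = 0.02,
                    ld_block_size = 2L, ld_flip_prob = 0.05)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$dosages, b$dataset$dosages)
  expect_identical(a$freq_model$pop_freq, b$freq_model$pop_freq)
})

test_that("vanishing F gives population frequencies at the ancestral values", {
  cfg <- toy_config(n_pops = 2, n_snps = 1000, fst = c(1e-6, 1e-6), seed = 3)
  fm <- simulate_frequencies(cfg)
  for (i in 1:2) {
    # clipping floors at 0.005/0.995 only; interior values must match
    interior <- fm$ancestral_freq > 0.02 & fm$ancestral_freq < 0.98
    expect_lt(max(abs(fm$pop_freq[i, interior] -
                        fm$ancestral_freq[interior])), 0.01)
  }
})

test_that("Balding-Nichols frequency variance matches the model identity", {
  # oracle: Var(p_i) = F p0 (1-p0), so E[(p1-p2)^2] = 2 F p0 q0
  cfg <- sim_config(2, c(10, 10), 20000, c(0.01, 0.01),
                    geo = toy_geo(2), seed = 5)
  fm <- simulate_frequencies(cfg)
  d2 <- (fm$pop_freq[1, ] - fm$pop_freq[2, ])^2
  expected <- 2 * 0.01 * fm$ancestral_freq * (1 - fm$ancestral_freq)
  expect_lt(abs(mean(d2) / mean(expected) - 1), 0.1)
})

test_that("clines shift frequencies by the stated amount per km", {
  geo <- geo_panel(c("S", "N"), latitude = c(45, 45 + 1000 / 111.19),
                   longitude = c(10, 10))
  cfg <- sim_config(2, c(5, 5), 4000, c(1e-6, 1e-6),
                    cline_strength = c(0.1, 0), geo = geo, seed = 9)
  fm <- simulate_frequencies(cfg)
  interior <- fm$ancestral_freq > 0.12 & fm$ancestral_freq < 0.88
  expect_equal(mean(fm$pop_freq[2, interior] - fm$pop_freq[1, interior]),
               0.1, tolerance = 0.01)
})

test_that("sampled allele frequencies match the frequency model", {
  # binomial-mean oracle at large n
  geo <- toy_geo(2)
  cfg <- sim_config(2, c(5000, 5000), 20, c(1e-6, 1e-6), geo = geo,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  ft <- allele_frequencies(sim$dataset)
  expect_lt(max(abs(ft$freq[1, ] - sim$freq_model$pop_freq[1, ])), 0.02)
})

test_that("LD blocks produce the advertised correlation structure", {
  cfg0 <- toy_config(n_pops = 2, n_per_pop = 300, n_snps = 40,
                     ld_block_size = 4L, ld_flip_prob = 0, seed = 21)
  sim0 <- simulate_dataset(cfg0)
  d <- sim0$dataset$dosages
  expect_identical(d[, 1], d[, 2])           # flip 0 duplicates columns

  cfg <- toy_config(n_pops = 2, n_per_pop = 400, n_snps = 40,
                    ld_block_size = 4L, ld_flip_prob = 0.05, seed = 22)
  sim <- simulate_dataset(cfg)
  d <- sim$dataset$dosages
  r2 <- sapply(seq(1, 37, by = 4), function(lead)
    cor(d[, lead], d[, lead + 1])^2)
  # oracle: r^2 ~ (1 - 2 * flip)^2 = 0.81
  expect_equal(mean(r2), 0.81, tolerance = 0.08)
})

test_that("missing_rate 0 inserts no missing genotypes", {
  sim <- simulate_dataset(toy_config(seed = 4, missing_rate = 0))
  expect_false(anyNA(sim$dataset$dosages))
})

test_that("study design split follows the harmonized-reference rules", {
  set.seed(31)
  sizes <- c(A = 70, B = 75, C = 39, D = 100)
  dos <- matrix(sample(0:2, sum(sizes) * 5, TRUE), sum(sizes), 5)
  ds <- toy_dataset(dos, populations = rep(names(sizes), sizes))
  d <- make_study_design(ds, reference_size = 70, min_test = 10, seed = 2)

  ref_tab <- table(d$reference$populations)
  expect_identical(sort(names(ref_tab)), c("A", "B", "D"))
  expect_true(all(ref_tab == 70))
  # A leaves 0, B leaves 5 (<= 10, dropped); C has 39 (> 10) and enters
  # the test set whole; D leaves 30
  expect_identical(sort(unique(d$test$populations)), c("C", "D"))
  expect_identical(sum(d$test$populations == "D"), 30L)
  expect_identical(sum(d$test$populations == "C"), 39L)
  # disjoint partition
  expect_length(intersect(d$reference$sample_ids, d$test$sample_ids), 0)
})

test_that("held-out populations appear only in the held-out set", {
  set.seed(32)
  dos <- matrix(sample(0:2, 240 * 4, TRUE), 240, 4)
  ds <- toy_dataset(dos, populations = rep(c("A", "B", "H"), each = 80))
  d <- make_study_design(ds, reference_size = 60, held_out_pops = "H",
                         seed = 3)
  expect_false("H" %in% d$reference$populations)
  expect_false("H" %in% d$test$populations)
  expect_identical(sum(d$heldout$populations == "H"), 80L)
  expect_error(make_study_design(ds, reference_size = 100), "no population")
})

test_that("private loci elevate only the owning population", {
  cfg <- toy_config(n_pops = 3, n_snps = 400, seed = 41,
                    private_loci = c(A = 3L, B = 2L),
                    private_delta = c(0.4, 0.5),
                    private_base = c(0.01, 0.03))
  fm <- simulate_frequencies(cfg)
  expect_length(fm$private_idx, 5)
  for (k in seq_along(fm$private_idx)) {
    col <- fm$pop_freq[, fm$private_idx[k]]
    owner <- fm$private_owner[k]
    expect_gt(col[owner], 0.4)
    expect_lt(max(col[setdiff(names(col), owner)]), 0.04)
  }
  expect_error(toy_config(private_loci = c(Z = 2L)), "known populations")
})

test_that("mixture cohorts reflect their source proportions", {
  cfg <- toy_config(n_pops = 2, n_per_pop = 50, n_snps = 300,
                    fst = c(0.05, 0.05), seed = 51)
  fm <- simulate_frequencies(cfg)
  coh <- simulate_mixture_cohort(fm, cfg, pops = c("A", "B"), n = 100,
                                 prop = c(0.75, 0.25), seed = 6)
  truth <- attr(coh, "truth")
  expect_equal(mean(truth == "A"), 0.75, tolerance = 0.01)
  adm <- simulate_mixture_cohort(fm, cfg, pops = c("A", "B"), n = 20,
                                 per_sample_admixture = TRUE, seed = 7)
  expect_true(all(attr(adm, "truth") >= 0 & attr(adm, "truth") <= 1))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(toy_config(n_pops = 1), "at least 2")
  expect_error(sim_config(2, c(5, 5), 101, c(0.01, 0.01),
                          geo = toy_geo(2), ld_block_size = 2),
               "divisible")
  expect_error(sim_config(2, c(5, 5), 100, c(0, 0.01), geo = toy_geo(2)),
               "strictly in")
})
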