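# helper: wrap score vectors into a minimal pca_result for centroid tests
fake_pca <- function(scores) {
  structure(list(scores = as.matrix(scores),
                 loadings = matrix(0, 1, ncol(as.matrix(scores))),
                 eigenvalues = rep(1, ncol(as.matrix(scores))),
                 variance_fraction = rep(0, ncol(as.matrix(scores))),
                 eigenvalues_full = rep(1, ncol(as.matrix(scores))),
                 n_samples = nrow(as.matrix(scores)), n_snps = 1),
            class = "pca_result")
}

test_that("population centroids are per-population score means", {
  sc <- cbind(PC1 = c(1, -1, 2, 2), PC2 = c(0, 0, 1, 3))
  cent <- population_centroids(fake_pca(sc), c("A", "A", "B", "B"),
                               toy_geo(2, c("A", "B")), m = 2)
  expect_equal(unname(cent$pc[cent$population == "A", "PC1"]), 0)
  expect_equal(unname(cent$pc[cent$population == "B", "PC2"]), 2)
})

test_that("equirectangular projection matches the small-angle formula", {
  g <- geo_panel(c("O", "E"), latitude = c(0, 0), longitude = c(0, 1))
  xy <- equirect_xy(g)
  expect_equal(xy["E", "x"] - xy["O", "x"], 6371 * pi / 180,
               tolerance = 1e-6)   # 111.19 km per degree at the equator
})

test_that("populations without coordinates are dropped with a message", {
  sc <- cbind(PC1 = c(1, 2, 3))
  expect_message(
    cent <- population_centroids(fake_pca(sc), c("A", "B", "USA"),
                                 toy_geo(2, c("A", "B"))),
    "USA")
  expect_identical(sort(cent$population), c("A", "B"))
})

test_that("spearman_axis handles monotone, exact and degenerate inputs", {
  geo <- toy_geo(5)
  sc <- cbind(PC1 = geo$latitude * 2 - 3, PC2 = rep(1, 5))
  cent <- population_centroids(fake_pca(sc), geo$population, geo, m = 2)
  res <- spearman_axis(cent, 1, "latitude")
  expect_equal(res$rho, 1)
  expect_error(spearman_axis(cent, 2, "latitude"), "constant")

  # exact two-sided p at n = 4 equals brute-force enumeration over 4! rankings
  geo4 <- toy_geo(4)
  set.seed(77)
  pc <- rnorm(4)
  cent4 <- population_centroids(fake_pca(cbind(PC1 = pc)),
                                geo4$population, geo4, m = 1)
  res4 <- spearman_axis(cent4, 1, "latitude")
  rho_obs <- cor(pc, geo4$latitude, method = "spearman")
  all_rho <- apply(perms_of(4), 1, function(p)
    cor(pc[p], geo4$latitude, method = "spearman"))
  expect_equal(res4$p, mean(abs(all_rho) >= abs(rho_obs) - 1e-12))
})

test_that("best alignment angle recovers pure gradients and planted bearings", {
  geo <- geo_panel(LETTERS[1:8],
                   latitude = c(40, 45, 50, 55, 42, 47, 52, 57),
                   longitude = c(0, 10, 3, 14, 7, 18, 11, 2))
  xy <- equirect_xy(geo)

  cent_lat <- population_centroids(fake_pca(cbind(PC1 = xy[, "y"])),
                                   geo$population, geo, m = 1)
  res <- best_alignment_angle(cent_lat, 1)
  expect_equal(res$angle_deg, 0)
  expect_equal(res$rho, 1)

  cent_lon <- population_centroids(fake_pca(cbind(PC1 = xy[, "x"])),
                                   geo$population, geo, m = 1)
  res <- best_alignment_angle(cent_lon, 1)
  # Spearman ties over a band of bearings near east-west; the boundary is
  # handled and the correlation is perfect
  expect_gt(abs(res$angle_deg), 75)
  expect_equal(abs(res$rho), 1)

  # planted bearing of -15 degrees recovered from the projection itself;
  # needs the 13-population panel for rank sensitivity to the bearing
  geo13 <- study_geo_panel()
  xy13 <- equirect_xy(geo13)
  theta <- -15 * pi / 180
  proj <- xy13[, "y"] * cos(theta) + xy13[, "x"] * sin(theta)
  cent15 <- population_centroids(fake_pca(cbind(PC1 = proj)),
                                 geo13$population, geo13, m = 1)
  res <- best_alignment_angle(cent15, 1)
  expect_lt(abs(res$angle_deg - (-15)), 10)
})

test_that("mantel test: self-comparison, exactness and validation", {
  D <- rand_dist(6, 1)
  res <- mantel_test(D, D, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)

  # exhaustive 4x4 enumeration equals an independent oracle
  D1 <- rand_dist(4, 2); D2 <- rand_dist(4, 3)
  res <- mantel_test(D1, D2, exact = TRUE)
  ut <- upper.tri(D1)
  r_all <- apply(perms_of(4), 1, function(p)
    cor(D1[ut], D2[p, p][ut]))
  expect_equal(res$p, mean(r_all >= res$r - 1e-12))
  expect_equal(res$r, cor(D1[ut], D2[ut]))

  expect_error(mantel_test(D1, matrix(1:16, 4) * 1), "symmetric")
  Dc <- matrix(1, 4, 4); diag(Dc) <- 0
  expect_error(mantel_test(D1, Dc), "constant")
})

test_that("mantel is invariant to joint relabelling of both matrices", {
  D1 <- rand_dist(7, 4); D2 <- rand_dist(7, 5)
  p <- sample(7)
  a <- mantel_test(D1, D2, n_perm = 50, seed = 9)
  b <- mantel_test(D1[p, p], D2[p, p], n_perm = 50, seed = 9)
  expect_equal(a$r, b$r)
})

test_that("procrustes test: congruence, reflection handling, exactness", {
  set.seed(10)
  X <- matrix(rnorm(12), 6, 2)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  Y <- 3 * X %*% R + matrix(c(5, -2), 6, 2, byrow = TRUE)
  res <- procrustes_test(X, Y, n_perm = 99, seed = 2)
  expect_equal(res$t, 1, tolerance = 1e-10)
  expect_equal(res$p, 1 / 100)

  # mirror image: perfect only when reflections are allowed
  Ym <- Y %*% diag(c(1, -1))
  t_no <- procrustes_test(X, Ym, n_perm = 9, seed = 1)$t
  t_yes <- procrustes_test(X, Ym, n_perm = 9, seed = 1,
                           allow_reflection = TRUE)$t
  expect_lt(t_no, 1 - 1e-6)
  expect_equal(t_yes, 1, tolerance = 1e-10)

  # exhaustive p over all 24 row permutations equals an independent oracle
  X4 <- matrix(rnorm(8), 4, 2)
  Y4 <- matrix(rnorm(8), 4, 2)
  res <- procrustes_test(X4, Y4, exact = TRUE)
  norm_cfg <- function(M) {
    M <- scale(M, scale = FALSE); M / sqrt(sum(M^2))
  }
  t_oracle <- function(Xc, Yc) {
    sv <- svd(crossprod(Yc, Xc))
    d <- sv$d
    if (det(sv$u %*% t(sv$v)) < 0) d[length(d)] <- -d[length(d)]
    min(1, max(0, sum(d)))
  }
  Xc <- norm_cfg(X4); Yc <- norm_cfg(Y4)
  t_all <- apply(perms_of(4), 1, function(p) t_oracle(Xc, Yc[p, ]))
  expect_equal(res$p, mean(t_all >= res$t - 1e-12))

  expect_error(procrustes_test(X4, matrix(1, 4, 2)), "degenerate")
})

test_that("procrustes statistic is invariant to similarity transforms", {
  set.seed(11)
  X <- matrix(rnorm(14), 7, 2)
  Y <- matrix(rnorm(14), 7, 2)
  t0 <- procrustes_test(X, Y, n_perm = 9, seed = 3)$t
  ang <- -1.2
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  Y2 <- 0.3 * Y %*% R + 7
  expect_equal(procrustes_test(X, Y2, n_perm = 9, seed = 3)$t, t0,
               tolerance = 1e-10)
})

test_that("procrustes t agrees with vegan's protest statistic", {
  skip_if_not_installed("vegan")
  set.seed(12)
  X <- matrix(rnorm(20), 10, 2)
  Y <- X %*% matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2) +
    matrix(rnorm(20, sd = 0.2), 10, 2)
  ours <- procrustes_test(X, Y, n_perm = 99, seed = 4,
                          allow_reflection = TRUE)
  ref <- vegan::protest(X, Y, permutations = 99)
  expect_equal(ours$t, sqrt(1 - ref$ss), tolerance = 1e-8)
})
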