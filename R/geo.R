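# Concordance between genetic coordinates (population-mean PCs) and
# geography: equirectangular projection, Spearman axis correlations,
# best-alignment bearing, Mantel and Procrustes permutation tests, and
# great-circle distances.

EARTH_RADIUS_KM <- 6371

#' Equirectangular local projection of a geographic panel
#'
#' Projects latitude/longitude onto planar kilometre coordinates around
#' the panel centroid: `x = R dlon cos(mean lat)`, `y = R dlat`
#' (R = 6371 km, angles in radians).  Adequate at continental scale, and
#' gives the planar coordinates Procrustes analysis needs.
#'
#' @param geo a [geo_panel()].
#' @return numeric matrix with columns `x`, `y` (km), rows named by
#'   population.
#' @export
equirect_xy <- function(geo) {
  stopifnot(inherits(geo, "geo_panel"))
  lat0 <- mean(geo$latitude)
  lon0 <- mean(geo$longitude)
  rad <- pi / 180
  cbind(x = EARTH_RADIUS_KM * (geo$longitude - lon0) * rad * cos(lat0 * rad),
        y = EARTH_RADIUS_KM * (geo$latitude - lat0) * rad) |>
    `rownames<-`(geo$population)
}

#' Great-circle distance matrix between population centres
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param geo a [geo_panel()].
#' @return symmetric km distance matrix, dimnames = populations.
#' @export
geo_distance_matrix <- function(geo) {
  stopifnot(inherits(geo, "geo_panel"))
  n <- nrow(geo)
  pts <- cbind(geo$longitude, geo$latitude)
  D <- matrix(0, n, n, dimnames = list(geo$population, geo$population))
  for (i in seq_len(n)) {
    D[i, ] <- geosphere::distHaversine(pts[i, ], pts,
                                       r = EARTH_RADIUS_KM * 1000) / 1000
  }
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Population centroids in PC space and local geographic coordinates
#'
#' Per-population arithmetic means of sample scores over the leading `m`
#' components, paired with the equirectangular km coordinates of the
#' population centres.  Populations missing from either the PCA samples or
#' the geographic panel are dropped with a message (e.g. cohorts without a
#' meaningful geographic centre).
#'
#' @param pca a `pca_result`.
#' @param populations per-sample population labels, aligned with the PCA
#'   score rows.
#' @param geo a [geo_panel()].
#' @param m number of leading components to keep.
#' @return An object of class `pop_centroids`: list with `population`,
#'   `pc` (K x m matrix of mean scores), `geo_xy` (K x 2 km matrix),
#'   `latitude`, `longitude`.
#' @export
population_centroids <- function(pca, populations, geo, m = 2L) {
  stopifnot(inherits(pca, "pca_result"))
  if (length(populations) != nrow(pca$scores))
    stop("populations must align with PCA score rows")
  m <- min(m, ncol(pca$scores))
  shared <- intersect(unique(populations), geo$population)
  dropped <- setdiff(unique(populations), shared)
  if (length(dropped))
    message("dropping populations without geographic coordinates: ",
            paste(dropped, collapse = ", "))
  if (!length(shared)) stop("no population present in both PCA and geo panel")
  pc <- matrix(unlist(lapply(shared, function(p) {
    colMeans(pca$scores[populations == p, seq_len(m), drop = FALSE])
  })), nrow = length(shared), byrow = TRUE,
  dimnames = list(shared, colnames(pca$scores)[seq_len(m)]))
  sub <- geo[match(shared, geo$population), ]
  class(sub) <- "data.frame"
  sub_geo <- geo_panel(sub$population, sub$latitude, sub$longitude)
  structure(list(population = shared, pc = pc,
                 geo_xy = equirect_xy(sub_geo),
                 latitude = sub_geo$latitude,
                 longitude = sub_geo$longitude,
                 geo = sub_geo),
            class = "pop_centroids")
}

#' Spearman correlation of a PC with a geographic axis
#'
#' @param cent a [population_centroids()] result.
#' @param pc_index which component.
#' @param axis `"latitude"` or `"longitude"`.
#' @return list with `rho` and two-sided `p` (exact when the sample is
#'   small and tie-free).
#' @export
spearman_axis <- function(cent, pc_index = 1L,
                          axis = c("latitude", "longitude")) {
  axis <- match.arg(axis)
  stopifnot(inherits(cent, "pop_centroids"))
  if (length(cent$population) < 4L) stop("at least 4 populations required")
  x <- cent$pc[, pc_index]
  y <- cent[[axis]]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bearing of best alignment between a PC and geography
#'
#' Grid search over bearings `theta` in `[-90, 89.5]` degrees (step 0.5):
#' population centres are projected onto the axis at bearing `theta` from
#' north (`proj = y cos(theta) + x sin(theta)`), the Spearman correlation
#' with the PC column is computed, and the bearing with maximal `|rho|`
#' is returned (ties broken toward smaller `|theta|`).
#'
#' @param cent a [population_centroids()] result.
#' @param pc_index which component.
#' @return list with `angle_deg` and the signed `rho` at that bearing.
#' @export
best_alignment_angle <- function(cent, pc_index = 1L) {
  stopifnot(inherits(cent, "pop_centroids"))
  if (length(cent$population) < 4L) stop("at least 4 populations required")
  pc <- cent$pc[, pc_index]
  if (sd(pc) == 0) stop("constant PC column")
  theta <- seq(-90, 89.5, by = 0.5)
  rad <- theta * pi / 180
  x <- cent$geo_xy[, "x"]; y <- cent$geo_xy[, "y"]
  rho <- vapply(rad, function(t) {
    proj <- y * cos(t) + x * sin(t)
    if (sd(proj) == 0) return(NA_real_)
    cor(proj, pc, method = "spearman")
  }, numeric(1))
  best <- which(abs(rho) == max(abs(rho), na.rm = TRUE))
  best <- best[order(abs(theta[best]), theta[best])][1L]
  list(angle_deg = theta[best], rho = rho[best])
}

.check_dist_matrix <- function(D, name) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop(name, " must be square")
  if (max(abs(D - t(D))) > 1e-8) stop(name, " must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop(name, " must have a zero diagonal")
  D
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson (default) correlation over off-diagonal
#' upper-triangle entries.  The empirical one-sided p-value permutes one
#' random relabelling simultaneously over rows and columns of `D2`, using
#' the add-one formula `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)` so p
#' is never 0.  With `exact = TRUE` all `n!` relabelings are enumerated
#' and `p = #(r_perm >= r_obs) / n!` (identity included).
#'
#' @param D1,D2 square symmetric zero-diagonal distance matrices.
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed integer seed for the permutations.
#' @param method correlation type, `"pearson"` (classical) or
#'   `"spearman"`.
#' @param exact enumerate all permutations (feasible for <= 8 rows).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 1000L, seed = NULL,
                        method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  D1 <- .check_dist_matrix(D1, "D1")
  D2 <- .check_dist_matrix(D2, "D2")
  if (!all(dim(D1) == dim(D2))) stop("D1 and D2 must have the same shape")
  n <- nrow(D1)
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (sd(v1) == 0 || sd(D2[ut]) == 0)
    stop("constant off-diagonal entries: correlation undefined")
  r_obs <- cor(v1, D2[ut], method = method)
  if (exact) {
    perms <- .all_permutations(n)
    r_all <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      cor(v1, D2[p, p][ut], method = method)
    }, numeric(1))
    return(list(r = r_obs, p = mean(r_all >= r_obs - 1e-12),
                n_perm = nrow(perms)))
  }
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(v1, D2[p, p][ut], method = method)
  }, numeric(1)))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

# all n! permutations as a matrix (rows); n <= 8
.all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

#' Procrustes permutation test between two point configurations
#'
#' Both configurations are centred and scaled to unit sum of squares; the
#' optimal rotation comes from the SVD of `Y' X`.  The statistic is
#' `t = sqrt(1 - m2)` where `m2` is the minimized residual sum of squares.
#' Reflections are disallowed by default (geographic orientation is
#' meaningful): when the optimal orthogonal map has negative determinant
#' the smallest singular value enters the trace with a minus sign.  The
#' one-sided empirical p permutes the row order of `Y` with the same
#' add-one convention as [mantel_test()]; `exact = TRUE` enumerates all
#' row permutations.
#'
#' @param X,Y numeric matrices with matching dimensions (>= 3 rows),
#'   e.g. population PC centroids and km coordinates.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param allow_reflection permit orientation-reversing alignment.
#' @param exact enumerate all permutations.
#' @return list with `t`, `p`, `n_perm`.
#' @export
procrustes_test <- function(X, Y, n_perm = 1000L, seed = NULL,
                            allow_reflection = FALSE, exact = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y))
    stop("X and Y must have matching dimensions")
  if (nrow(X) < 3L) stop("at least 3 rows are required")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ssx <- sum(Xc^2)
  if (ssx < 1e-24) stop("degenerate configuration: all X points identical")
  Xc <- Xc / sqrt(ssx)
  norm_y <- function(Y) {
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    ssy <- sum(Yc^2)
    if (ssy < 1e-24) stop("degenerate configuration: all Y points identical")
    Yc / sqrt(ssy)
  }
  t_stat <- function(Yc) {
    sv <- svd(crossprod(Yc, Xc))
    d <- sv$d
    if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0)
      d[length(d)] <- -d[length(d)]
    tr <- sum(d)
    # t = sqrt(1 - m2) with m2 = 1 - tr^2 at the optimal scaling tr; a
    # negative trace (possible only when reflections are disallowed) means
    # no positive scaling helps, so congruence is 0
    min(1, max(0, tr))
  }
  Yc <- norm_y(Y)
  t_obs <- t_stat(Yc)
  n <- nrow(Y)
  if (exact) {
    perms <- .all_permutations(n)
    t_all <- vapply(seq_len(nrow(perms)), function(i)
      t_stat(Yc[perms[i, ], , drop = FALSE]), numeric(1))
    return(list(t = t_obs, p = mean(t_all >= t_obs - 1e-12),
                n_perm = nrow(perms)))
  }
  t_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    t_stat(Yc[sample.int(n), , drop = FALSE]), numeric(1)))
  list(t = t_obs, p = (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Full genetic-geographic concordance report
#'
#' Bundles the per-axis Spearman correlations, the best-alignment bearing
#' of PC1, and Mantel and Procrustes permutation tests between PC-space
#' and geographic distances.
#'
#' @param cent a [population_centroids()] result with at least 2 PCs.
#' @param n_perm permutations for Mantel/Procrustes.
#' @param seed integer seed.
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(cent, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(cent, "pop_centroids"))
  sp <- list(pc1_lat = spearman_axis(cent, 1L, "latitude"),
             pc2_lon = spearman_axis(cent, 2L, "longitude"),
             pc1_lon = spearman_axis(cent, 1L, "longitude"),
             pc2_lat = spearman_axis(cent, 2L, "latitude"))
  ang <- best_alignment_angle(cent, 1L)
  Dg <- as.matrix(dist(cent$geo_xy))
  Dp <- as.matrix(dist(cent$pc[, 1:2, drop = FALSE]))
  man <- mantel_test(Dp, Dg, n_perm = n_perm,
                     seed = derive_seed(seed, "mantel"))
  pro <- procrustes_test(cent$pc[, 1:2, drop = FALSE], cent$geo_xy,
                         n_perm = n_perm,
                         seed = derive_seed(seed, "procrustes"))
  structure(list(spearman = sp, best_angle = ang, mantel = man,
                 procrustes = pro, n_permutations = n_perm),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf("  PC1 ~ latitude : rho = %.3f (p = %.3g)\n",
              x$spearman$pc1_lat$rho, x$spearman$pc1_lat$p))
  cat(sprintf("  PC2 ~ longitude: rho = %.3f (p = %.3g)\n",
              x$spearman$pc2_lon$rho, x$spearman$pc2_lon$p))
  cat(sprintf("  best PC1 bearing: %.1f deg (rho = %.3f)\n",
              x$best_angle$angle_deg, x$best_angle$rho))
  cat(sprintf("  Mantel: r = %.3f, p = %.4g; Procrustes: t = %.3f, p = %.4g\n",
              x$mantel$r, x$mantel$p, x$procrustes$t, x$procrustes$p))
  invisible(x)
}
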