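# Within-population structure: per-population PCA, K-means subcluster
# detection via silhouettes, and nearest-reference-population profiles for
# mixed-origin cohorts.

#' PCA restricted to one population
#'
#' Drops SNPs monomorphic within the population, then runs the standard
#' genotype PCA pipeline on that population's samples alone.
#'
#' @param ds a labelled [geno_dataset()].
#' @param population which population.
#' @param n_pcs number of components (population must have at least
#'   `n_pcs + 1` samples).
#' @return A `pca_result`.
#' @export
within_population_pca <- function(ds, population, n_pcs = 5L) {
  stopifnot(inherits(ds, "geno_dataset"))
  idx <- which(ds$populations == population)
  if (!length(idx)) stop("unknown population: ", population)
  if (length(idx) < n_pcs + 1L)
    stop("population ", population, " has ", length(idx),
         " samples; need at least n_pcs + 1 = ", n_pcs + 1L)
  sub <- subset_genotypes(ds, samples = idx)
  v <- apply(sub$dosages, 2L, function(col) {
    col <- col[!is.na(col)]
    length(col) > 0 && var(col) > 0
  })
  if (!any(v)) stop("all SNPs monomorphic within ", population)
  sub <- subset_genotypes(sub, snps = which(v))
  genotype_pca(sub, n_pcs = n_pcs)
}

#' Detect subclusters in PC space by silhouette-selected K-means
#'
#' K-means (20 random restarts, seeded) on the top-2 PC scores for each k
#' in `k_range`; the k with the highest mean silhouette width wins.  When
#' the best silhouette falls below `silhouette_floor` the population is
#' declared unstructured (`chosen_k = 1`).  The default floor of 0.45
#' sits above the mean silhouette an unstructured 2-D Gaussian cloud
#' produces under K-means (about 0.32-0.40), so noise alone does not
#' declare subclusters; genuinely weak continuum-like structure (e.g.
#' admixture gradients) needs an explicitly lower floor.  Degenerate inputs (fewer
#' distinct points than clusters) skip the affected k with a warning.
#'
#' @param pca a `pca_result` for one population.
#' @param k_range candidate cluster counts (default 2:5).
#' @param seed integer seed for the restarts.
#' @param silhouette_floor minimum mean silhouette to accept structure
#'   (default 0.45).
#' @return An object of class `subcluster_report`: `chosen_k`,
#'   `silhouette` (NA when `chosen_k = 1`), `cluster_assignments`,
#'   `cluster_sizes`, `silhouette_by_k`.
#' @export
kmeans_subclusters <- function(pca, k_range = 2:5, seed = 1L,
                               silhouette_floor = 0.45) {
  stopifnot(inherits(pca, "pca_result"))
  X <- pca$scores[, seq_len(min(2L, ncol(pca$scores))), drop = FALSE]
  n <- nrow(X)
  if (n < 10L) stop("at least 10 samples are required")
  n_distinct <- nrow(unique(X))
  D <- dist(X)
  fits <- list(); sil <- setNames(rep(NA_real_, length(k_range)),
                                  paste0("k", k_range))
  with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      if (k >= n_distinct) {
        warning("skipping k = ", k, ": only ", n_distinct,
                " distinct points")
        next
      }
      km <- kmeans(X, centers = k, nstart = 20L)
      fits[[i]] <- km
      sw <- cluster::silhouette(km$cluster, D)
      sil[i] <- mean(sw[, "sil_width"])
    }
  })
  if (all(is.na(sil)) || max(sil, na.rm = TRUE) < silhouette_floor) {
    return(structure(list(chosen_k = 1L, silhouette = NA_real_,
                          cluster_assignments = rep(1L, n),
                          cluster_sizes = n, silhouette_by_k = sil),
                     class = "subcluster_report"))
  }
  best <- which.max(sil)
  km <- fits[[best]]
  structure(list(chosen_k = k_range[best], silhouette = sil[[best]],
                 cluster_assignments = km$cluster,
                 cluster_sizes = as.integer(km$size),
                 silhouette_by_k = sil),
            class = "subcluster_report")
}

#' @export
print.subcluster_report <- function(x, ...) {
  cat("<subcluster_report> chosen_k = ", x$chosen_k, sep = "")
  if (!is.na(x$silhouette))
    cat(sprintf(" (mean silhouette %.3f)", x$silhouette))
  cat("\ncluster sizes: ", paste(x$cluster_sizes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Nearest-reference-population profile of a cohort
#'
#' Assigns every cohort sample to a reference population by K nearest
#' neighbours over all shared markers and reports the distribution of
#' predicted labels (fractions summing to 1, including unassigned).  Used
#' to characterize cohorts of mixed or uncertain origin against a
#' reference panel.
#'
#' @param reference labelled [geno_dataset()].
#' @param cohort [geno_dataset()] to profile (non-empty).
#' @param k neighbours (default 5).
#' @param markers snp ids to use (default: all SNPs shared by both
#'   datasets).
#' @return named numeric vector of fractions over reference populations
#'   (plus `"UNASSIGNED"`), with the full `assignment_report` attached as
#'   attribute `"report"`.
#' @export
nearest_population_profile <- function(reference, cohort, k = 5L,
                                       markers = NULL) {
  stopifnot(inherits(cohort, "geno_dataset"))
  if (!length(cohort$sample_ids)) stop("empty cohort")
  if (is.null(markers))
    markers <- intersect(reference$snps$snp_id, cohort$snps$snp_id)
  rep_ <- knn_assign(reference, cohort, markers, k = k)
  lev <- c(sort(unique(reference$populations)), UNASSIGNED)
  frac <- table(factor(rep_$assignments$predicted, levels = lev))
  frac <- as.numeric(frac) / nrow(rep_$assignments)
  names(frac) <- lev
  attr(frac, "report") <- rep_
  frac
}
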