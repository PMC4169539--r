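# PCA-informative marker (PCAIM) selection: per-component loading weights
# normalized to the maximum, scaled by the component's eigenvalue, summed
# across significant components, then positionally cluster-pruned.

#' Score SNPs by their contribution to the leading components
#'
#' Per component k the absolute SNP loadings are normalized to the
#' component maximum (so the top contributor gets weight 1) and scaled by
#' the component's importance; a SNP's score is the sum of these scaled
#' weights over the first `n_pcs` components.  The per-component scale is
#' the eigenvalue by default; `pc_weight = "variance-fraction"` uses the
#' variance fraction (identical ranking, different scale) and `"none"`
#' weights all components equally.  Rankings are invariant to the sign
#' indeterminacy of the loading columns and to rescaling all eigenvalues.
#'
#' @param pca a `pca_result` with loadings for at least `n_pcs`
#'   components.
#' @param snps SNP map aligned with the loading rows (defaults to the
#'   loading rownames with no positions; supply the dataset's `$snps` to
#'   enable [prune_clusters()]).
#' @param n_pcs number of components to sum over; default is the
#'   Tracy-Widom-significant count when available.
#' @param pc_weight per-component scale (see above).
#' @return A [marker_ranking()] with method `"pcaim"` and per-component
#'   weight columns `w_PC1 ...`.
#' @export
pcaim_scores <- function(pca, snps = NULL, n_pcs = NULL,
                         pc_weight = c("eigenvalue", "variance-fraction",
                                       "none")) {
  stopifnot(inherits(pca, "pca_result"))
  pc_weight <- match.arg(pc_weight)
  if (is.null(n_pcs)) {
    n_pcs <- if (!is.null(pca$tw_pvalues))
      max(1L, n_significant_pcs(pca)) else ncol(pca$loadings)
  }
  if (n_pcs < 1L || n_pcs > ncol(pca$loadings))
    stop("loadings available for only ", ncol(pca$loadings), " components")
  L <- abs(pca$loadings[, seq_len(n_pcs), drop = FALSE])
  mx <- apply(L, 2L, max)
  if (any(mx == 0)) stop("degenerate (all-zero) loading column")
  W <- sweep(L, 2L, mx, `/`)
  scale_k <- switch(pc_weight,
                    "eigenvalue" = pca$eigenvalues[seq_len(n_pcs)],
                    "variance-fraction" = pca$variance_fraction[seq_len(n_pcs)],
                    "none" = rep(1, n_pcs))
  scores <- as.numeric(W %*% scale_k)
  ids <- rownames(pca$loadings) %||% sprintf("snp%05d", seq_along(scores))
  tab <- data.frame(snp_id = ids, score = scores, stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    idx <- match(ids, snps$snp_id)
    if (anyNA(idx)) stop("SNP map does not cover the loading rows")
    tab$chromosome <- snps$chromosome[idx]
    tab$position_bp <- snps$position_bp[idx]
  }
  Wn <- as.data.frame(W)
  names(Wn) <- paste0("w_", colnames(pca$loadings)[seq_len(n_pcs)])
  tab <- cbind(tab, Wn)
  tab <- tab[order(-tab$score, tab$snp_id), ]
  marker_ranking(tab, method = "pcaim")
}

#' Collapse positional clusters of a ranking to their top marker
#'
#' Greedy scan in score order: a SNP is excluded when a higher-scored kept
#' SNP lies on the same chromosome within `window_bp`.  Clusters of
#' co-locating high-scoring markers (e.g. a selection sweep dominating one
#' component) are thereby represented by their single best SNP.
#'
#' @param ranking a [marker_ranking()] whose table carries `chromosome`
#'   and `position_bp`.
#' @param window_bp cluster radius (default 1 Mb).
#' @return The pruned `marker_ranking`.
#' @export
prune_clusters <- function(ranking, window_bp = 1e6) {
  stopifnot(inherits(ranking, "marker_ranking"))
  tab <- ranking$table
  if (is.null(tab$chromosome) || is.null(tab$position_bp))
    stop("ranking lacks positional information")
  keep <- logical(nrow(tab))
  kept_by_chr <- setNames(vector("list", length(unique(tab$chromosome))),
                          unique(tab$chromosome))
  for (i in seq_len(nrow(tab))) {
    prev <- kept_by_chr[[tab$chromosome[i]]]
    if (!length(prev) ||
        all(abs(tab$position_bp[prev] - tab$position_bp[i]) > window_bp)) {
      keep[i] <- TRUE
      kept_by_chr[[tab$chromosome[i]]] <- c(prev, i)
    }
  }
  marker_ranking(tab[keep, , drop = FALSE], method = ranking$method,
                 tie_rule = ranking$tie_rule)
}

#' Full PCAIM pipeline on a reference dataset
#'
#' PCA with Tracy-Widom selection of the component count, eigenvalue-
#' weighted loading scores, then positional cluster pruning.
#'
#' @param reference a [geno_dataset()].
#' @param n_pcs number of components to use; default = Tracy-Widom-
#'   significant count.
#' @param window_bp cluster-pruning window.
#' @param max_pcs components to extract before selection.
#' @return list with `ranking` (pruned), `ranking_unpruned` and `pca`.
#' @export
rank_pcaims <- function(reference, n_pcs = NULL, window_bp = 1e6,
                        max_pcs = 10L) {
  pca <- genotype_pca(reference, n_pcs = max_pcs)
  rk <- pcaim_scores(pca, snps = reference$snps, n_pcs = n_pcs)
  list(ranking = prune_clusters(rk, window_bp = window_bp),
       ranking_unpruned = rk, pca = pca)
}
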