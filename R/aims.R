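# Ancestry-informative marker (AIM) selection: mean-MAF filtering,
# Rosenberg informativeness, LD thinning, ranking, and
# leave-one-population-out stability.

#' Mean minor allele frequency across populations
#'
#' Per SNP: the unweighted mean across populations of the alternate-allele
#' frequency, folded to the minor allele AFTER averaging
#' (`min(m, 1 - m)`).  Folding after averaging matters: a marker at
#' frequency 0.5 in one of 13 populations and absent elsewhere has mean
#' alternate frequency 0.5/13 ~ 3.8%, not 50%.
#'
#' @param ft a `freq_table`.
#' @return named numeric vector, `NA` where any population is masked.
#' @export
mean_maf <- function(ft) {
  stopifnot(inherits(ft, "freq_table"))
  m <- colMeans(ft$freq)
  pmin(m, 1 - m)
}

#' Rosenberg informativeness for assignment
#'
#' For a biallelic SNP with allele frequencies `p_i` in each of K
#' populations and unweighted means `pbar` over populations,
#' `I_n = sum_j [ -pbar_j ln pbar_j + sum_i (p_ij / K) ln p_ij ]`
#' summed over both alleles j, natural log, with `0 ln 0 = 0`.
#' `I_n = 0` iff all populations share the frequency, and
#' `I_n <= ln K` always.
#'
#' @param ft a `freq_table`; SNPs with any masked population frequency are
#'   skipped (returned `NA`) with a warning.
#' @return named numeric vector of scores (nats).
#' @export
informativeness <- function(ft) {
  stopifnot(inherits(ft, "freq_table"))
  p <- ft$freq
  masked <- colSums(is.na(p)) > 0
  if (any(masked))
    warning(sum(masked), " SNP(s) with masked frequencies skipped")
  pbar <- colMeans(p)
  qbar <- 1 - pbar
  In <- -xlogx(pbar) - xlogx(qbar) + colMeans(xlogx(p)) +
    colMeans(xlogx(1 - p))
  In[masked] <- NA_real_
  setNames(In, ft$snp_ids)
}

#' Thin a marker ranking for linkage disequilibrium
#'
#' Greedy scan in score order: a SNP is kept unless its squared Pearson
#' dosage correlation (pairwise-complete) with an already-kept SNP on the
#' same chromosome within `window_bp` exceeds `r2_threshold`.  The output
#' preserves score order over kept SNPs.
#'
#' @param ds the [geno_dataset()] the dosages come from.
#' @param ranking a [marker_ranking()] over (a subset of) `ds`'s SNPs.
#' @param r2_threshold strict r-squared cutoff (default 0.8).
#' @param window_bp positional window for candidate pairs (default 1 Mb).
#' @return The thinned `marker_ranking`.
#' @export
ld_thin <- function(ds, ranking, r2_threshold = 0.8, window_bp = 1e6) {
  stopifnot(inherits(ds, "geno_dataset"), inherits(ranking, "marker_ranking"))
  tab <- ranking$table
  idx <- match(tab$snp_id, ds$snps$snp_id)
  if (anyNA(idx)) stop("ranking refers to SNPs absent from the dataset")
  X <- ds$dosages[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  chr <- tab$chromosome
  pos <- tab$position_bp
  keep <- logical(nrow(tab))
  kept_by_chr <- setNames(vector("list", length(unique(chr))), unique(chr))
  for (i in seq_len(nrow(tab))) {
    prev <- kept_by_chr[[chr[i]]]
    near <- prev[abs(pos[prev] - pos[i]) <= window_bp]
    ok <- TRUE
    if (length(near)) {
      r <- suppressWarnings(
        cor(X[, i], X[, near, drop = FALSE],
            use = "pairwise.complete.obs"))
      if (any(r^2 > r2_threshold, na.rm = TRUE)) ok <- FALSE
    }
    if (ok) {
      keep[i] <- TRUE
      kept_by_chr[[chr[i]]] <- c(prev, i)
    }
  }
  marker_ranking(tab[keep, , drop = FALSE], method = ranking$method,
                 tie_rule = ranking$tie_rule)
}

#' Marker ranking container
#'
#' @param table data.frame with at least `snp_id` and `score`, sorted by
#'   descending score (ties broken lexicographically by `snp_id`);
#'   typically also `chromosome`, `position_bp` and `mean_maf`.
#' @param method `"informativeness"` or `"pcaim"`.
#' @param tie_rule documentation string for the tie-break used.
#' @return object of class `marker_ranking`.
#' @export
marker_ranking <- function(table, method = c("informativeness", "pcaim"),
                           tie_rule = "ties broken by snp_id (lexicographic)") {
  method <- match.arg(method)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "score") %in% names(table)))
  if (anyDuplicated(table$snp_id)) stop("duplicate snp ids in ranking")
  if (is.unsorted(rev(table$score)))
    stop("scores must be non-increasing")
  rownames(table) <- NULL
  structure(list(table = table, method = method, tie_rule = tie_rule),
            class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, n = 10, ...) {
  cat("<marker_ranking> method = ", x$method, ", ", nrow(x$table),
      " SNPs\n", sep = "")
  print(head(x$table, n))
  invisible(x)
}

#' Top marker ids of a ranking
#' @param ranking a [marker_ranking()].
#' @param n how many markers.
#' @return character vector of snp ids.
#' @export
top_markers <- function(ranking, n = 25L) {
  stopifnot(inherits(ranking, "marker_ranking"))
  if (n > nrow(ranking$table)) stop("ranking has fewer than ", n, " markers")
  ranking$table$snp_id[seq_len(n)]
}

#' Rank ancestry-informative markers
#'
#' The AIM pipeline on a harmonized reference set: per-population allele
#' frequencies, mean-MAF filter (strictly greater than `maf_threshold`),
#' Rosenberg informativeness, descending sort with lexicographic snp-id
#' tie-break, then LD thinning.  Warns when population sizes are unequal,
#' since unequal sizes bias the frequency means toward large populations.
#'
#' @param reference a [geno_dataset()] (ideally equal samples per
#'   population).
#' @param maf_threshold mean-MAF filter (default 0.01, strict `>`).
#' @param r2_threshold,window_bp LD thinning parameters ([ld_thin()]);
#'   `thin = FALSE` skips thinning.
#' @param thin apply LD thinning after scoring (default TRUE).
#' @return A [marker_ranking()] with method `"informativeness"`.
#' @export
rank_aims <- function(reference, maf_threshold = 0.01, r2_threshold = 0.8,
                      window_bp = 1e6, thin = TRUE) {
  stopifnot(inherits(reference, "geno_dataset"))
  sizes <- table(reference$populations)
  if (length(unique(sizes)) > 1L)
    warning("unequal population sizes (", paste(range(sizes), collapse = "-"),
            "); informativeness may be biased toward large populations")
  ft <- allele_frequencies(reference)
  mm <- mean_maf(ft)
  In <- suppressWarnings(informativeness(ft))
  keep <- !is.na(mm) & mm > maf_threshold & !is.na(In)
  if (!any(keep)) stop("no SNPs survive the mean-MAF filter")
  tab <- data.frame(snp_id = ft$snp_ids[keep],
                    chromosome = ft$snps$chromosome[keep],
                    position_bp = ft$snps$position_bp[keep],
                    score = In[keep], mean_maf = mm[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$snp_id), ]
  rk <- marker_ranking(tab, method = "informativeness")
  if (thin) rk <- ld_thin(reference, rk, r2_threshold = r2_threshold,
                          window_bp = window_bp)
  rk
}

#' Leave-one-population-out stability of informativeness
#'
#' For each population, informativeness is recomputed over the same SNP
#' universe without that population (no re-thinning), and the Spearman
#' rank correlation with the full-panel scores is reported.  A low
#' correlation flags a population whose removal reshuffles the ranking,
#' i.e. one carrying unique information (genetically outlying
#' populations).
#'
#' @param reference a [geno_dataset()] with >= 3 populations.
#' @param maf_threshold mean-MAF filter defining the SNP universe (applied
#'   once, on the full panel).
#' @return data.frame with `left_out` and `rho` (`NA`, with a warning,
#'   when the reduced scores are degenerate, e.g. K = 2).
#' @export
lopo_stability <- function(reference, maf_threshold = 0.01) {
  stopifnot(inherits(reference, "geno_dataset"))
  ft <- allele_frequencies(reference)
  if (length(ft$populations) < 3L)
    stop("at least 3 populations are required")
  mm <- mean_maf(ft)
  keep <- !is.na(mm) & mm > maf_threshold
  full <- suppressWarnings(informativeness(ft))[keep]
  out <- data.frame(left_out = ft$populations,
                    rho = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ft$populations)) {
    sub <- freq_table(ft$freq[-i, keep, drop = FALSE],
                      ft$n_called[-i, keep, drop = FALSE])
    red <- suppressWarnings(informativeness(sub))
    ok <- !is.na(full) & !is.na(red)
    if (sum(ok) < 3L || sd(red[ok]) == 0 || sd(full[ok]) == 0) {
      warning("degenerate reduced scores leaving out ", ft$populations[i])
      next
    }
    out$rho[i] <- cor(full[ok], red[ok], method = "spearman")
  }
  out
}
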