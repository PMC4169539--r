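# Per-population allele frequencies, pairwise Hudson Fst (ratio of
# averages), the Fst < 0.001 indistinctness structure, and Fst-versus-
# kilometre concordance.

#' Per-population allele frequencies
#'
#' Alternate-allele frequency and called-diploid count per population per
#' SNP; missing genotypes are excluded from both numerator and
#' denominator, and cells with no calls are masked (`NA`).
#'
#' @param ds a [geno_dataset()] with population labels.
#' @return An object of class `freq_table`: list with `populations`,
#'   `snp_ids`, `freq` (K x m), `n_called` (K x m diploid counts) and the
#'   SNP map.
#' @export
allele_frequencies <- function(ds) {
  stopifnot(inherits(ds, "geno_dataset"))
  if (anyNA(ds$populations)) stop("every sample must be labelled")
  pops <- sort(unique(ds$populations))
  m <- nrow(ds$snps)
  freq <- n_called <- matrix(NA_real_, length(pops), m,
                             dimnames = list(pops, ds$snps$snp_id))
  for (i in seq_along(pops)) {
    d <- ds$dosages[ds$populations == pops[i], , drop = FALSE]
    nc <- colSums(!is.na(d))
    s <- colSums(d, na.rm = TRUE)
    n_called[i, ] <- nc
    freq[i, ] <- ifelse(nc > 0, s / (2 * nc), NA_real_)
  }
  structure(list(populations = pops, snp_ids = ds$snps$snp_id,
                 freq = freq, n_called = n_called, snps = ds$snps),
            class = "freq_table")
}

#' Construct a frequency table directly
#'
#' For workflows that start from known frequencies (e.g. textbook
#' examples) rather than genotypes.
#'
#' @param freq K x m matrix of alternate-allele frequencies, rows named by
#'   population.
#' @param n_called K x m called-diploid counts (defaults to `Inf`-like
#'   large counts meaning "population frequencies known exactly").
#' @param snps optional SNP map.
#' @return A `freq_table`.
#' @export
freq_table <- function(freq, n_called = NULL, snps = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("pop", seq_len(nrow(freq)))
  if (is.null(colnames(freq)))
    colnames(freq) <- sprintf("snp%05d", seq_len(ncol(freq)))
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  if (is.null(n_called))
    n_called <- matrix(1e9, nrow(freq), ncol(freq),
                       dimnames = dimnames(freq))
  structure(list(populations = rownames(freq), snp_ids = colnames(freq),
                 freq = freq, n_called = as.matrix(n_called), snps = snps),
            class = "freq_table")
}

#' Pairwise Hudson Fst between populations
#'
#' Ratio-of-averages Hudson estimator: per SNP the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` with `n` the allele
#' count (2 x called diploids) and the denominator is
#' `p1(1-p2) + p2(1-p1)`; the pair's Fst is the ratio of sums over usable
#' SNPs (both populations called).  Estimates may be slightly negative for
#' indistinguishable pairs and are reported unclipped.
#'
#' @param ft a [allele_frequencies()] result.
#' @param indistinct_threshold threshold below which a pair of populations
#'   is considered genetically indistinct (default 0.001, strict `<`).
#' @return An object of class `fst_matrix`: symmetric matrix `fst` with
#'   zero diagonal (masked `NA` for pairs with no usable SNPs), plus the
#'   threshold.
#' @export
pairwise_fst <- function(ft, indistinct_threshold = 0.001) {
  stopifnot(inherits(ft, "freq_table"))
  K <- length(ft$populations)
  if (K < 2L) stop("at least 2 populations are required")
  fst <- matrix(0, K, K, dimnames = list(ft$populations, ft$populations))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      p1 <- ft$freq[i, ]; p2 <- ft$freq[j, ]
      n1 <- 2 * ft$n_called[i, ]; n2 <- 2 * ft$n_called[j, ]
      ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
      if (!any(ok)) {
        warning("no usable SNPs for pair ", ft$populations[i], "-",
                ft$populations[j], "; entry masked")
        fst[i, j] <- fst[j, i] <- NA_real_
        next
      }
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      s_den <- sum(den[ok])
      fst[i, j] <- fst[j, i] <- if (s_den > 0) sum(num[ok]) / s_den
                                else NA_real_
    }
  }
  structure(list(populations = ft$populations, fst = fst,
                 indistinct_threshold = indistinct_threshold),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("<fst_matrix> ", length(x$populations), " populations (threshold ",
      x$indistinct_threshold, ")\n", sep = "")
  print(round(x$fst, digits))
  invisible(x)
}

#' Genetically indistinct population pairs and their closure
#'
#' Returns both the raw set of pairs with `Fst < threshold` (the set used
#' for assignment-correctness scoring) and its transitive closure as
#' connected components (diagnostic only: indistinctness is not
#' transitive).
#'
#' @param fm a [pairwise_fst()] result.
#' @param threshold override for the matrix's stored threshold.
#' @return list with `pairs` (data.frame `pop1`, `pop2`, `fst`, with
#'   `pop1 < pop2`) and `components` (named membership vector of the
#'   transitive closure).
#' @export
indistinct_groups <- function(fm, threshold = fm$indistinct_threshold) {
  stopifnot(inherits(fm, "fst_matrix"))
  pops <- fm$populations
  K <- length(pops)
  pairs <- data.frame(pop1 = character(0), pop2 = character(0),
                      fst = numeric(0), stringsAsFactors = FALSE)
  comp <- seq_len(K)                      # union-find by relabelling
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      f <- fm$fst[i, j]
      if (!is.na(f) && f < threshold) {
        pairs <- rbind(pairs, data.frame(pop1 = min(pops[i], pops[j]),
                                         pop2 = max(pops[i], pops[j]),
                                         fst = f))
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  components <- setNames(match(comp, unique(comp)), pops)
  list(pairs = pairs, components = components)
}

#' Fst versus geographic distance
#'
#' Relates pairwise Fst to great-circle kilometre distances between
#' population centres: ordinary least-squares `r^2` of Fst on km over the
#' off-diagonal pairs, plus a Mantel permutation test.
#'
#' @param fm a [pairwise_fst()] result.
#' @param geo a [geo_panel()] covering (at least) the Fst populations.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `r_squared`, `mantel_r`, `mantel_p` and the pair
#'   table `pairs` (`pop1`, `pop2`, `fst`, `km`).
#' @export
fst_vs_distance <- function(fm, geo, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(fm, "fst_matrix"))
  shared <- intersect(fm$populations, geo$population)
  if (length(shared) < 4L) stop("at least 4 shared populations required")
  gsub <- geo[match(shared, geo$population), ]
  class(gsub) <- "data.frame"
  km <- geo_distance_matrix(geo_panel(gsub$population, gsub$latitude,
                                      gsub$longitude))
  idx <- match(shared, fm$populations)
  fsub <- fm$fst[idx, idx]
  ut <- upper.tri(fsub)
  fit <- lm(fsub[ut] ~ km[ut])
  man <- mantel_test(fsub, km, n_perm = n_perm, seed = seed)
  ij <- which(ut, arr.ind = TRUE)
  list(r_squared = summary(fit)$r.squared,
       mantel_r = man$r, mantel_p = man$p,
       pairs = data.frame(pop1 = shared[ij[, 1]], pop2 = shared[ij[, 2]],
                          fst = fsub[ut], km = km[ut]))
}
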