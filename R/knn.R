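# K-nearest-neighbour ancestry assignment over a marker panel, with the
# 5 -> 4 -> 3 -> unassigned strict-majority fallback ladder and
# Fst-indistinctness-aware correctness scoring.

UNASSIGNED <- "UNASSIGNED"

#' Majority vote with fallback over ordered neighbour labels
#'
#' A strict majority (count > half the labels considered) is sought among
#' the 5 nearest neighbours; failing that, among the 4 nearest, then the
#' 3 nearest; if still none, the sample is unassigned.  Lists shorter than
#' 5 start the ladder at their length.
#'
#' @param labels character vector of neighbour population labels, ordered
#'   nearest first, length >= 3.
#' @return list with `label` (population or `"UNASSIGNED"`) and
#'   `vote_level` (5, 4, 3 or `NA`).
#' @export
majority_vote <- function(labels) {
  if (length(labels) < 3L) stop("at least 3 neighbour labels are required")
  for (lv in c(5L, 4L, 3L)) {
    if (lv > length(labels)) next
    tab <- table(labels[seq_len(lv)])
    if (max(tab) > lv / 2)
      return(list(label = names(tab)[which.max(tab)], vote_level = lv))
  }
  list(label = UNASSIGNED, vote_level = NA_integer_)
}

#' Assign query samples to reference populations by K nearest neighbours
#'
#' Distances are Euclidean over raw dosages restricted to the marker
#' panel (no standardization, so each marker contributes on the genotype
#' scale); missing cells in both reference and query are imputed with the
#' reference per-marker mean, making assignments query-independent and
#' reproducible sample by sample.  Exact distance ties are broken by
#' reference sample order.
#'
#' @param reference labelled [geno_dataset()].
#' @param query [geno_dataset()] to assign.
#' @param markers character vector of snp ids present in both datasets.
#' @param k neighbours to consult (default 5; truncated with a warning
#'   when the reference is smaller).
#' @return An object of class `assignment_report`: data.frame
#'   `assignments` (sample_id, predicted, vote_level, neighbours), plus
#'   `marker_count` and `k`.  [score_assignments()] completes it.
#' @export
knn_assign <- function(reference, query, markers, k = 5L) {
  stopifnot(inherits(reference, "geno_dataset"),
            inherits(query, "geno_dataset"))
  if (anyNA(reference$populations)) stop("reference must be fully labelled")
  miss_r <- setdiff(markers, reference$snps$snp_id)
  miss_q <- setdiff(markers, query$snps$snp_id)
  if (length(miss_r) || length(miss_q))
    stop("markers absent from ", if (length(miss_r)) "reference" else "query",
         ": ", paste(unique(c(miss_r, miss_q)), collapse = ", "))
  if (!length(markers)) stop("empty marker set")
  R <- reference$dosages[, match(markers, reference$snps$snp_id),
                         drop = FALSE]
  Q <- query$dosages[, match(markers, query$snps$snp_id), drop = FALSE]
  storage.mode(R) <- storage.mode(Q) <- "double"
  mu <- colMeans(R, na.rm = TRUE)
  mu[is.nan(mu)] <- 1                     # marker fully missing in reference
  nr <- which(is.na(R), arr.ind = TRUE)
  if (nrow(nr)) R[nr] <- mu[nr[, 2L]]
  nq <- which(is.na(Q), arr.ind = TRUE)
  if (nrow(nq)) Q[nq] <- mu[nq[, 2L]]
  n_ref <- nrow(R)
  if (k > n_ref) {
    warning("k = ", k, " exceeds reference size ", n_ref, "; truncating")
    k <- n_ref
  }
  d2 <- outer(rowSums(Q^2), rep(1, n_ref)) +
    outer(rep(1, nrow(Q)), rowSums(R^2)) - 2 * tcrossprod(Q, R)
  labs <- reference$populations
  res <- lapply(seq_len(nrow(Q)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]     # stable: ties by reference order
    mv <- if (k >= 3L) majority_vote(labs[ord]) else {
      # degenerate tiny reference: strict majority among all k labels
      tab <- table(labs[ord])
      if (max(tab) > k / 2)
        list(label = names(tab)[which.max(tab)], vote_level = k)
      else list(label = UNASSIGNED, vote_level = NA_integer_)
    }
    list(predicted = mv$label, vote_level = mv$vote_level,
         neighbours = paste(labs[ord], collapse = ","))
  })
  assignments <- data.frame(
    sample_id = query$sample_ids,
    predicted = vapply(res, `[[`, character(1), "predicted"),
    vote_level = vapply(res, `[[`, integer(1), "vote_level"),
    neighbours = vapply(res, `[[`, character(1), "neighbours"),
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments, marker_count = length(markers),
                 k = k, per_population = NULL),
            class = "assignment_report")
}

#' Score assignments against known origins
#'
#' A sample is correct when the predicted population equals the true one
#' or forms a genetically indistinct pair with it (pairwise
#' `Fst < 0.001`); unassigned samples are never correct.  Adds per-sample
#' `truth`/`correct` columns and a per-population summary.
#'
#' @param report a [knn_assign()] result.
#' @param truth per-query-sample true population labels.
#' @param indistinct_pairs data.frame with columns `pop1`, `pop2` (e.g.
#'   `indistinct_groups(fm)$pairs`), or NULL for exact matching only.
#' @return The completed `assignment_report` with `per_population`
#'   (population, n, n_correct, n_unassigned, accuracy) and `overall`
#'   accuracy.
#' @export
score_assignments <- function(report, truth, indistinct_pairs = NULL) {
  stopifnot(inherits(report, "assignment_report"))
  a <- report$assignments
  if (length(truth) != nrow(a))
    stop("truth labels must cover all query samples")
  key <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "\r")
  pairs <- if (!is.null(indistinct_pairs) && nrow(indistinct_pairs))
    key(indistinct_pairs$pop1, indistinct_pairs$pop2) else character(0)
  a$truth <- as.character(truth)
  a$correct <- a$predicted != UNASSIGNED &
    (a$predicted == a$truth | key(a$predicted, a$truth) %in% pairs)
  per <- do.call(rbind, lapply(split(a, a$truth), function(g) {
    data.frame(population = g$truth[1], n = nrow(g),
               n_correct = sum(g$correct),
               n_unassigned = sum(g$predicted == UNASSIGNED),
               accuracy = mean(g$correct), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  report$assignments <- a
  report$per_population <- per
  report$overall <- mean(a$correct)
  report
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("<assignment_report> ", nrow(x$assignments), " queries, ",
      x$marker_count, " markers, k = ", x$k, "\n", sep = "")
  if (!is.null(x$per_population)) {
    cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall))
    print(x$per_population)
  }
  invisible(x)
}

#' Assignment accuracy as a function of marker-panel size
#'
#' Runs [knn_assign()] + [score_assignments()] on each prefix of a marker
#' ranking and returns a long-format accuracy table.
#'
#' @param reference,query labelled [geno_dataset()]s.
#' @param ranking a [marker_ranking()].
#' @param marker_counts panel sizes (all > 0,
#'   `max <= nrow(ranking$table)`).
#' @param k neighbours.
#' @param truth per-query true labels (defaults to the query's population
#'   labels).
#' @param indistinct_pairs passed to [score_assignments()].
#' @return data.frame: `marker_count`, `population` (including
#'   `"overall"`), `n`, `accuracy`, `n_unassigned`.
#' @export
accuracy_curve <- function(reference, query, ranking,
                           marker_counts = c(10L, 25L, 50L, 100L, 250L,
                                             500L, 1000L),
                           k = 5L, truth = query$populations,
                           indistinct_pairs = NULL) {
  stopifnot(inherits(ranking, "marker_ranking"))
  if (any(marker_counts < 1L)) stop("marker counts must be positive")
  if (max(marker_counts) > nrow(ranking$table))
    stop("ranking has only ", nrow(ranking$table), " markers")
  out <- lapply(marker_counts, function(nm) {
    rep_ <- knn_assign(reference, query, top_markers(ranking, nm), k = k)
    rep_ <- score_assignments(rep_, truth, indistinct_pairs)
    rbind(data.frame(marker_count = nm, population = "overall",
                     n = nrow(rep_$assignments), accuracy = rep_$overall,
                     n_unassigned =
                       sum(rep_$assignments$predicted == UNASSIGNED),
                     stringsAsFactors = FALSE),
          data.frame(marker_count = nm,
                     population = rep_$per_population$population,
                     n = rep_$per_population$n,
                     accuracy = rep_$per_population$accuracy,
                     n_unassigned = rep_$per_population$n_unassigned,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}
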