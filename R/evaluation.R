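#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half. Computed from mean
#' ranks, exact for any tie structure.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1) aligned with `scores`.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @examples
#' aurocScore(c(.9, .8, .3, .1), c(1, 1, 0, 0))   # 1
#' aurocScore(rep(0.5, 4), c(1, 1, 0, 0))         # 0.5
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Average precision
#'
#' Non-interpolated stepwise sum over the ranked list:
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} where \eqn{P_k, R_k} are precision
#' and recall after the k-th ranked item. Tied scores are averaged over the
#' orderings by treating the tie group as one block (precision evaluated at
#' the block level).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @return AP in `(0, 1]`, or `NA` with no positives.
#' @examples
#' averagePrecision(c(.9, .8, .3), c(1, 1, 0))  # 1
#' averagePrecision(1:10 / 10, c(1, rep(0, 9))) # single positive ranked last
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1)
  if (nPos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # process tie blocks as units
  blocks <- rle(s)$lengths
  ends <- cumsum(blocks)
  tp <- cumsum(y)[ends]
  n <- ends
  prec <- tp / n
  recall <- tp / nPos
  dRecall <- diff(c(0, recall))
  sum(dRecall * prec)
}

#' Per-epitope AUROC/AP table
#'
#' Scores are computed within each epitope's own positives and negatives, so
#' imbalanced pooling cannot mask weak epitopes (pooled AUROC can differ from
#' the unweighted mean of per-epitope AUROCs).
#'
#' @param scores numeric prediction scores, one per record.
#' @param recordsDf canonical record data.frame with `epitope` and `label`.
#' @return data.frame with columns `epitope`, `n_pos`, `n_neg`, `auroc`,
#'   `ap`; `auroc` is `NA` for single-class epitopes (flagged in `two_class`).
#' @export
perEpitopeScores <- function(scores, recordsDf) {
  stopifnot(length(scores) == nrow(recordsDf))
  eps <- split(seq_len(nrow(recordsDf)), recordsDf$epitope)
  out <- lapply(names(eps), function(e) {
    idx <- eps[[e]]
    y <- recordsDf$label[idx]
    data.frame(epitope = e, n_pos = sum(y == 1), n_neg = sum(y == 0),
               auroc = aurocScore(scores[idx], y),
               ap = averagePrecision(scores[idx], y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$two_class <- out$n_pos > 0 & out$n_neg > 0
  rownames(out) <- NULL
  out
}

#' Minimum Levenshtein distance from test epitopes to the training set
#'
#' @param testEpitopes character vector of test epitope sequences.
#' @param trainEpitopes character vector of training epitope sequences
#'   (non-empty).
#' @return named integer vector: for each unique test epitope, the minimum
#'   edit distance to any training epitope.
#' @export
minEditDistanceToTrain <- function(testEpitopes, trainEpitopes) {
  stopifnot(length(trainEpitopes) > 0)
  test <- unique(testEpitopes)
  d <- adist(test, unique(trainEpitopes))
  setNames(as.integer(apply(d, 1, min)), test)
}

#' Bin per-epitope scores by positive-count and summarize
#'
#' @param perEpitope table from [perEpitopeScores()].
#' @param binEdges increasing numeric vector of bin edges over `n_pos`
#'   (right-closed).
#' @param metric which column to summarize (`"auroc"` or `"ap"`).
#' @return data.frame with one row per bin: `bin`, `n_epitopes`, `mean`,
#'   `sem` (0 with `single = TRUE` when the bin holds one epitope; `NA`
#'   mean for empty bins).
#' @export
frequencyBinnedSummary <- function(perEpitope, binEdges, metric = c("auroc", "ap")) {
  metric <- match.arg(metric)
  vals <- perEpitope[[metric]]
  keep <- !is.na(vals)
  bin <- cut(perEpitope$n_pos[keep], breaks = binEdges, include.lowest = TRUE)
  out <- lapply(levels(bin), function(b) {
    v <- vals[keep][bin == b]
    data.frame(bin = b, n_epitopes = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               single = length(v) == 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stratify per-epitope scores by edit distance to the training set
#'
#' @param perEpitope table from [perEpitopeScores()].
#' @param distances named vector from [minEditDistanceToTrain()].
#' @return the per-epitope table with a `min_dist` column, plus a per-stratum
#'   summary (`"summary"` attribute): unweighted mean and SEM of AUROC per
#'   distance value.
#' @export
distanceStrata <- function(perEpitope, distances) {
  perEpitope$min_dist <- as.integer(distances[perEpitope$epitope])
  ok <- perEpitope$two_class & !is.na(perEpitope$min_dist)
  summ <- lapply(sort(unique(perEpitope$min_dist[ok])), function(d) {
    v <- perEpitope$auroc[ok & perEpitope$min_dist == d]
    data.frame(min_dist = d, n_epitopes = length(v), mean_auroc = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0)
  })
  attr(perEpitope, "summary") <- do.call(rbind, summ)
  perEpitope
}

#' Build a full evaluation report
#'
#' Overall AUROC/AP on the pooled test set, the per-epitope table, a
#' frequency-binned summary and (when training epitopes are supplied) edit
#' distance strata.
#'
#' @param scores numeric prediction scores for the test records.
#' @param recordsDf canonical test records (with `epitope`, `label`).
#' @param trainEpitopes optional character vector of training epitopes for
#'   distance stratification.
#' @param binEdges bin edges over per-epitope positive counts.
#' @param meta optional named list of run metadata carried into the report.
#' @return list of class `"EvalReport"` with elements `overall_auroc`,
#'   `overall_ap`, `per_epitope`, `frequency_bins`, `distance_strata`, `meta`.
#' @export
evalReport <- function(scores, recordsDf, trainEpitopes = NULL,
                       binEdges = c(0, 10, 100, 1000, Inf), meta = list()) {
  pe <- perEpitopeScores(scores, recordsDf)
  strat <- NULL
  if (!is.null(trainEpitopes)) {
    d <- minEditDistanceToTrain(unique(recordsDf$epitope), trainEpitopes)
    strat <- distanceStrata(pe, d)
  }
  structure(list(
    overall_auroc = aurocScore(scores, recordsDf$label),
    overall_ap = averagePrecision(scores, recordsDf$label),
    per_epitope = pe,
    frequency_bins = frequencyBinnedSummary(pe, binEdges),
    distance_strata = strat,
    meta = meta), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: overall AUROC %.3f, AP %.3f over %d epitopes (%d two-class)\n",
              x$overall_auroc, x$overall_ap, nrow(x$per_epitope),
              sum(x$per_epitope$two_class)))
  invisible(x)
}

#' Aggregate evaluation reports across repeated cross-validation runs
#'
#' Each run's fold-level overall metrics are averaged into a run-level mean
#' first; the aggregate is the mean and standard error of the mean across
#' runs.
#'
#' @param reports list of lists of `EvalReport` (outer: runs, inner: folds).
#' @return data.frame with `metric`, `mean`, `sem`, `n_runs`.
#' @export
aggregateRuns <- function(reports) {
  runMeans <- function(metric) vapply(reports, function(folds)
    mean(vapply(folds, function(r) r[[metric]], numeric(1)), na.rm = TRUE), numeric(1))
  out <- lapply(c("overall_auroc", "overall_ap"), function(m) {
    v <- runMeans(m)
    data.frame(metric = m, mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n_runs = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
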