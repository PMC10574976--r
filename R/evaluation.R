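## Performance-evaluation machinery: balanced subset construction, LOOCV with
## threshold grid search, per-subset type-A uncertainty, first-order
## propagation through the mean, expanded uncertainty with a coverage factor.

#' Linearly spaced threshold grid
#'
#' The candidate decision thresholds searched during LOOCV training: `n`
#' linearly spaced values inclusive of both endpoints (default 1000 values
#' from 0.005 to 0.500, step about 4.955e-4).
#'
#' @param lo,hi grid endpoints (defaults 0.005 and 0.500).
#' @param n number of grid points (default 1000).
#' @return strictly increasing numeric vector of length `n`.
#' @export
thresholdGrid <- function(lo = 0.005, hi = 0.500, n = 1000) {
  if (!(lo > 0 && hi > lo && n >= 2))
    stop("threshold grid needs 0 < lo < hi and n >= 2")
  seq(lo, hi, length.out = n)
}

#' Build a score-record table
#'
#' A score record holds, per ROI pair, the t-test p-value, whether the thrust
#' region was the warmer one (`direction_ok`, i.e. mean1 > mean2), and the
#' clinical 0/1 adequacy label. Classification predicts 1 exactly when
#' `p_value < th` and `direction_ok`.
#'
#' @param p_value numeric vector of p-values in [0, 1].
#' @param direction_ok logical vector.
#' @param label integer vector of 0/1 labels.
#' @return data.frame with those three columns.
#' @export
scoreRecords <- function(p_value, direction_ok, label) {
  stopifnot(length(p_value) == length(direction_ok),
            length(p_value) == length(label),
            all(label %in% c(0, 1)),
            all(p_value >= 0 & p_value <= 1))
  data.frame(p_value = as.numeric(p_value),
             direction_ok = as.logical(direction_ok),
             label = as.integer(label))
}

#' Read / write score datasets
#'
#' Delimited text with header `p_value,direction_ok,label`.
#'
#' @param path file path.
#' @return `readScores`: the score data.frame.
#' @export
readScores <- function(path) {
  d <- utils::read.csv(path)
  need <- c("p_value", "direction_ok", "label")
  if (!all(need %in% names(d)))
    stop("format error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  scoreRecords(d$p_value, d$direction_ok, d$label)
}

#' @rdname readScores
#' @param records score data.frame as built by [scoreRecords()].
#' @export
writeScores <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Balanced subsets for an imbalanced score dataset
#'
#' Builds `nSubsets` class-balanced index sets of size `2 * perClass`. Each
#' subset takes the label-0 (inadequate) instances — all of them when there
#' are exactly `perClass`, a seeded sample otherwise — plus `perClass`
#' label-1 indices sampled without replacement; subset i uses seed
#' `seed + i - 1`, so the random draw changes across subsets while the whole
#' construction stays reproducible.
#'
#' @param labels integer vector of 0/1 labels.
#' @param nSubsets number of subsets (default 10).
#' @param perClass instances per class in each subset (default 10).
#' @param seed base integer seed.
#' @return list of `nSubsets` sorted integer index vectors.
#' @export
makeBalancedSubsets <- function(labels, nSubsets = 10, perClass = 10,
                                seed = 42) {
  idx0 <- which(labels == 0)
  idx1 <- which(labels == 1)
  if (length(idx0) < perClass || length(idx1) < perClass)
    stop("data error: need at least ", perClass,
         " instances of each class (have ", length(idx0), " of label 0, ",
         length(idx1), " of label 1)")
  lapply(seq_len(nSubsets), function(i) {
    set.seed(seed + i - 1L)
    z <- if (length(idx0) == perClass) idx0 else sort(sample(idx0, perClass))
    o <- sort(sample(sort(idx1), perClass))
    sort(c(z, o))
  })
}

# prediction matrix: records x grid thresholds; predict 1 iff p < th & dir ok
.predictionMatrix <- function(records, grid) {
  outer(records$p_value, grid, "<") & records$direction_ok
}

#' Leave-one-out accuracy with threshold grid search
#'
#' For each held-out record the threshold is trained on the remaining k - 1
#' records: among the grid values maximising training classification accuracy
#' (predict adequate when `p < th` and the thrust region is the warmer one),
#' the *smallest* is taken — a deterministic, conservative tie-break — and
#' applied to the held-out record. The fold outcome is 1 when the prediction
#' matches the label; accuracy is the percentage of correct folds.
#'
#' @param records score data.frame ([scoreRecords()]), k >= 2 rows.
#' @param grid threshold grid from [thresholdGrid()].
#' @return list with `accuracy_pct` (scalar) and `fold_outcomes` (binary
#'   vector of length k).
#' @export
loocvAccuracy <- function(records, grid = thresholdGrid()) {
  k <- nrow(records)
  if (k < 2L) stop("LOOCV needs at least 2 records")
  pred <- .predictionMatrix(records, grid)         # k x n_grid
  correct <- pred == records$label                 # recycled down columns
  colCorrect <- colSums(correct)
  outcomes <- integer(k)
  for (i in seq_len(k)) {
    trainCorrect <- colCorrect - correct[i, ]
    thMax <- which.max(trainCorrect)               # first = smallest grid value
    outcomes[i] <- as.integer(pred[i, thMax] == records$label[i])
  }
  list(accuracy_pct = 100 * sum(outcomes) / k, fold_outcomes = outcomes)
}

#' Type-A standard uncertainty of a LOOCV accuracy
#'
#' The standard uncertainty of the mean of the n binary fold outcomes,
#' estimated statistically: sample standard deviation (n - 1 denominator)
#' divided by sqrt(n), expressed in percent. For a success fraction p-hat
#' this equals `100 * sqrt(p-hat * (1 - p-hat) / (n - 1))`.
#'
#' @param foldOutcomes binary vector (1 = fold classified correctly), n >= 2.
#' @return u in percent.
#' @examples
#' typeAUncertainty(rep(c(1, 0), c(14, 6)))   # 10.51 -> Table-style 10.5
#' @export
typeAUncertainty <- function(foldOutcomes) {
  n <- length(foldOutcomes)
  if (n < 2L) stop("type-A uncertainty needs at least 2 fold outcomes")
  100 * stats::sd(foldOutcomes) / sqrt(n)
}

#' First-order propagation of subset uncertainties through the mean
#'
#' The overall accuracy is the arithmetic mean of the n subset accuracies;
#' treating their uncertainties as uncorrelated, first-order propagation
#' gives `u_mean = sqrt(sum(u_i^2)) / n`.
#'
#' @param us numeric vector of per-subset standard uncertainties (percent).
#' @return the propagated standard uncertainty of the mean (percent).
#' @export
propagateMeanUncertainty <- function(us) {
  if (!length(us)) stop("need at least one uncertainty")
  sqrt(sum(us^2)) / length(us)
}

#' Expanded uncertainty
#'
#' Multiplies a standard uncertainty by the coverage factor k (k = 2 for a
#' confidence level of about 95 percent under normality).
#'
#' @param uMean standard uncertainty (non-negative).
#' @param coverageK coverage factor (default 2).
#' @return the expanded uncertainty `coverageK * uMean`.
#' @export
expandedUncertainty <- function(uMean, coverageK = 2) {
  if (uMean < 0) stop("standard uncertainty must be non-negative")
  coverageK * uMean
}

#' Aggregate per-subset accuracies and uncertainties into a report
#'
#' The final stage of the evaluation: mean accuracy across subsets,
#' first-order propagated uncertainty of that mean, and the expanded
#' uncertainty.
#'
#' @param accuracies numeric vector of per-subset accuracies (percent).
#' @param us numeric vector of per-subset type-A uncertainties (percent).
#' @param foldOutcomes optional list of per-subset binary outcome vectors.
#' @param coverageK coverage factor (default 2).
#' @return an [EvalReport-class].
#' @export
aggregateSubsets <- function(accuracies, us, foldOutcomes = list(),
                             coverageK = 2) {
  stopifnot(length(accuracies) == length(us))
  uMean <- propagateMeanUncertainty(us)
  new("EvalReport",
      perSubset = data.frame(subset = seq_along(accuracies),
                             accuracy_pct = accuracies, u_pct = us),
      foldOutcomes = foldOutcomes,
      meanAccuracyPct = mean(accuracies),
      uMeanPct = uMean,
      coverageK = coverageK,
      expandedUPct = expandedUncertainty(uMean, coverageK))
}

#' Full performance evaluation of a score dataset
#'
#' Composes [makeBalancedSubsets()], [loocvAccuracy()] per subset,
#' [typeAUncertainty()] per subset, and [aggregateSubsets()]. Fully
#' reproducible given `seed`.
#'
#' @param records score data.frame ([scoreRecords()]).
#' @param grid threshold grid (default [thresholdGrid()]).
#' @param nSubsets,perClass subset construction parameters (defaults 10, 10).
#' @param seed base integer seed for the subset draws.
#' @param coverageK coverage factor (default 2).
#' @return an [EvalReport-class].
#' @export
evaluateSystem <- function(records, grid = thresholdGrid(), nSubsets = 10,
                           perClass = 10, seed = 42, coverageK = 2) {
  subsets <- makeBalancedSubsets(records$label, nSubsets, perClass, seed)
  res <- lapply(subsets, function(ix) loocvAccuracy(records[ix, ], grid))
  aggregateSubsets(
    accuracies = vapply(res, `[[`, numeric(1), "accuracy_pct"),
    us = vapply(res, function(r) typeAUncertainty(r$fold_outcomes), numeric(1)),
    foldOutcomes = lapply(res, `[[`, "fold_outcomes"),
    coverageK = coverageK)
}

#' Write an evaluation report
#'
#' Writes the full-precision report as JSON and, optionally, a table-style
#' delimited summary (one column per subset plus the mean column, values
#' rounded to one decimal for presentation).
#'
#' @param report an [EvalReport-class].
#' @param path JSON output path.
#' @param summaryPath optional path for the delimited summary table.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path, summaryPath = NULL) {
  jsonlite::write_json(list(
    per_subset = report@perSubset,
    fold_outcomes = report@foldOutcomes,
    mean_accuracy_pct = report@meanAccuracyPct,
    u_mean_pct = report@uMeanPct,
    coverage_k = report@coverageK,
    expanded_u_pct = report@expandedUPct
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(summaryPath)) {
    tab <- rbind(
      c(sprintf("%.1f", report@perSubset$accuracy_pct),
        sprintf("%.1f", report@meanAccuracyPct)),
      c(sprintf("%.1f", report@perSubset$u_pct),
        sprintf("%.1f", report@uMeanPct)))
    tab <- cbind(c("A_pct", "u_pct"), tab)
    colnames(tab) <- c("row", paste0("set_", seq_len(nrow(report@perSubset))),
                       "mean")
    utils::write.csv(tab, summaryPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
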