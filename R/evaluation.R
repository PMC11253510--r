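#' One-vs-all confusion counts for one class
#'
#' Treats \code{classLabel} as the positive class and every other label as
#' negative, the standard conversion of a multiclass cell-typing problem
#' into per-type 2x2 confusion matrices.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classLabel the positive class.
#' @return named list with \code{TP}, \code{TN}, \code{FP}, \code{FN} and
#'   \code{class}.
#' @examples
#' oneVsAllCounts(c("A", "A", "B"), c("A", "B", "B"), "A")
#' @export
oneVsAllCounts <- function(truth, predicted, classLabel) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!classLabel %in% truth)
    warning("class '", classLabel,
            "' absent from truth; sensitivity is undefined")
  tp <- truth == classLabel
  pp <- predicted == classLabel
  list(TP = sum(tp & pp), FN = sum(tp & !pp),
       FP = sum(!tp & pp), TN = sum(!tp & !pp),
       class = classLabel)
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is reported as
#' \code{NA} (flagged undefined), never silently zeroed — averaging in
#' zeros would depress summaries for rare classes.
#'
#' @param counts list with \code{TP}, \code{TN}, \code{FP}, \code{FN} (as
#'   from [oneVsAllCounts()]).
#' @return named numeric vector \code{ACC}, \code{SEN}, \code{SPE},
#'   \code{F1}.
#' @examples
#' metricsFromCounts(list(TP = 50, TN = 40, FP = 5, FN = 5))
#' @export
metricsFromCounts <- function(counts) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(
    ACC = safe(TP + TN, TP + TN + FP + FN),
    SEN = safe(TP, TP + FN),
    SPE = safe(TN, TN + FP),
    F1 = safe(2 * TP, 2 * TP + FP + FN)))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks for ties: the probability that a random positive scores above a
#' random negative (ties count one half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth binary truth labels.
#' @param positive the positive class (default: second sorted level).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, truth, positive = NULL) {
  truth <- as.character(truth)
  lev <- sort(unique(truth))
  if (length(lev) != 2L)
    stop("AUC needs exactly two classes present")
  if (is.null(positive)) positive <- lev[2]
  pos <- truth == positive
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class evaluation report
#'
#' One-vs-all counts and metrics for every class in \code{truth}, plus
#' macro (unweighted) averages over classes with defined values; per-class
#' values are always retained.
#'
#' @param truth,predicted equal-length label vectors.
#' @param scores optional numeric scores for a binary problem, adding AUC.
#' @param positive positive class for the AUC.
#' @return list with \code{perClass} (data.frame: class, TP, TN, FP, FN,
#'   ACC, SEN, SPE, F1), \code{macro} (named numeric) and optional
#'   \code{auc}.
#' @export
evalReport <- function(truth, predicted, scores = NULL, positive = NULL) {
  classes <- sort(unique(as.character(truth)))
  rows <- lapply(classes, function(cl) {
    cnt <- oneVsAllCounts(truth, predicted, cl)
    met <- metricsFromCounts(cnt)
    data.frame(class = cl, TP = cnt$TP, TN = cnt$TN, FP = cnt$FP,
               FN = cnt$FN, ACC = met["ACC"], SEN = met["SEN"],
               SPE = met["SPE"], F1 = met["F1"], row.names = NULL)
  })
  perClass <- do.call(rbind, rows)
  macro <- colMeans(perClass[, c("ACC", "SEN", "SPE", "F1")], na.rm = TRUE)
  out <- list(perClass = perClass, macro = macro)
  if (!is.null(scores) && length(classes) == 2L)
    out$auc <- aucScore(scores, truth, positive = positive)
  out
}

#' Write an evaluation report as JSON
#'
#' @param report list from [evalReport()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  per <- report$perClass
  byClass <- stats::setNames(lapply(seq_len(nrow(per)), function(i)
    as.list(per[i, setdiff(names(per), "class")])), per$class)
  jsonlite::write_json(
    c(byClass, list(macro = as.list(report$macro),
                    auc = report$auc %||% NULL)),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
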