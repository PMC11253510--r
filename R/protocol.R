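#' Self-consistency evaluation of annotation methods
#'
#' Splits an annotated reference into a stratified train/test partition
#' (80/20 by default, 50/50 as a variant), annotates the held-out cells with
#' each requested method — the train part plays the reference role for the
#' landmark ("scaffold") method and the training set for the supervised
#' baselines — and scores each method per cell type with one-vs-all metrics.
#'
#' @param reference a \linkS4class{ReferenceSet}.
#' @param trainFrac fraction of cells used for training (0.8 or 0.5).
#' @param methods character subset of \code{c("scaffold", "knn", "lda")}.
#' @param k neighbours for the KNN baseline (default 3).
#' @param seed integer seed for the stratified split (and SOM training).
#' @param ... further arguments to [annotateCells()] (e.g. grid size).
#' @return named list, one [evalReport()] per method.
#' @export
selfConsistencyProtocol <- function(reference, trainFrac = 0.8,
                                    methods = c("scaffold", "knn", "lda"),
                                    k = 3L, seed = 1L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(trainFrac > 0, trainFrac < 1)
  labels <- cellLabels(reference)
  types <- unique(labels)
  if (length(types) < 2L)
    stop("self-consistency needs at least 2 cell types")
  idx <- withSeed(seed, {
    unlist(lapply(types, function(ty) {
      cand <- which(labels == ty)
      sample(cand, max(1L, round(trainFrac * length(cand))))
    }))
  })
  if (!setequal(unique(labels[idx]), types))
    stop("a cell type is absent from the training split")
  test <- setdiff(seq_len(nCells(reference)), idx)
  if (!length(test))
    stop("empty test split")
  trainExpr <- reference@expression[idx, ]
  testExpr <- reference@expression[test, ]
  truth <- labels[test]
  out <- list()
  for (mth in methods) {
    pred <- switch(mth,
      scaffold = cellLabels(annotateCells(
        testExpr, referenceSet(trainExpr), seed = deriveSeed(seed, 1L),
        pooled = TRUE, ...)),
      knn = knnAnnotate(trainExpr, testExpr, k = k),
      lda = ldaAnnotate(trainExpr, testExpr))
    out[[mth]] <- evalReport(truth, pred)
  }
  out
}
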