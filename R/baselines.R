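#' K-nearest-neighbour baseline classifier
#'
#' Supervised per-cell annotation baseline: Euclidean k-NN majority vote on
#' the backbone markers. Vote ties are broken by the label of the single
#' nearest neighbour. Used with k = 3 and k = 10 when benchmarking against
#' the landmark-based annotation.
#'
#' @param train a labelled \linkS4class{CytoExpression} (or matrix).
#' @param trainLabels labels when \code{train} is a bare matrix.
#' @param test a \linkS4class{CytoExpression} or matrix with the same
#'   markers.
#' @param k number of neighbours (default 3).
#' @return character vector of predicted labels, one per test cell.
#' @export
knnAnnotate <- function(train, test, trainLabels = NULL, k = 3L) {
  tm <- if (is.matrix(train)) train else exprValues(train)
  if (is.null(trainLabels))
    trainLabels <- cellLabels(train)
  if (is.null(trainLabels))
    stop("training labels required")
  xm <- if (is.matrix(test)) test else exprValues(test)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(tm))
    stop("k exceeds the number of training cells")
  # squared distances test x train, in blocks to bound memory
  tn2 <- rowSums(tm^2)
  out <- character(nrow(xm))
  blocks <- split(seq_len(nrow(xm)),
                  ceiling(seq_len(nrow(xm)) / 2048))
  for (b in blocks) {
    d2 <- sweep(-2 * xm[b, , drop = FALSE] %*% t(tm), 2, tn2, `+`)
    out[b] <- apply(d2, 1, function(d) {
      nb <- order(d)[seq_len(k)]
      votes <- table(trainLabels[nb])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1L) top else trainLabels[nb[1]]
    })
  }
  out
}

#' Linear discriminant analysis baseline classifier
#'
#' Gaussian LDA via \code{MASS::lda}; each cell is assigned the class with
#' maximum posterior probability, with no rejection threshold.
#'
#' @param train a labelled \linkS4class{CytoExpression} (or matrix).
#' @param trainLabels labels when \code{train} is a bare matrix.
#' @param test a \linkS4class{CytoExpression} or matrix with the same
#'   markers.
#' @return character vector of predicted labels, one per test cell.
#' @export
ldaAnnotate <- function(train, test, trainLabels = NULL) {
  tm <- if (is.matrix(train)) train else exprValues(train)
  if (is.null(trainLabels))
    trainLabels <- cellLabels(train)
  if (is.null(trainLabels))
    stop("training labels required")
  if (length(unique(trainLabels)) < 2L)
    stop("LDA needs at least 2 classes")
  if (any(table(trainLabels) < 2L))
    stop("LDA needs at least 2 cells per class")
  xm <- if (is.matrix(test)) test else exprValues(test)
  fit <- tryCatch(MASS::lda(tm, grouping = factor(trainLabels)),
                  error = function(e)
                    stop("LDA failed (", conditionMessage(e),
                         "); consider removing collinear markers or ",
                         "regularizing", call. = FALSE))
  as.character(stats::predict(fit, xm)$class)
}
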