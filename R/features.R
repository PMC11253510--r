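#' Ordered signaling marker pairs
#'
#' All directed pairs (X, Y), X != Y, in deterministic lexicographic order
#' of the supplied marker order, so feature columns are stable across runs
#' and cohorts. A panel of p markers yields p*(p-1) pairs — 210 for the
#' 15-marker signaling panel.
#'
#' @param signaling ordered character vector of signaling markers.
#' @return data.frame with columns \code{x}, \code{y} and \code{feature}
#'   (the \code{"X->Y"} feature name).
#' @examples
#' nrow(orderedPairs(paste0("m", 1:15)))  # 210
#' @export
orderedPairs <- function(signaling) {
  if (length(signaling) < 2L)
    stop("at least 2 signaling markers required")
  if (anyDuplicated(signaling))
    stop("signaling markers must be unique")
  grid <- expand.grid(y = seq_along(signaling), x = seq_along(signaling))
  grid <- grid[grid$x != grid$y, c("x", "y")]
  grid <- grid[order(grid$x, grid$y), ]
  data.frame(x = signaling[grid$x], y = signaling[grid$y],
             feature = paste0(signaling[grid$x], "->", signaling[grid$y]),
             stringsAsFactors = FALSE)
}

#' Median-expression features for one cell type
#'
#' For every sample, the per-marker median intensity over that sample's
#' cells of the given cell type — the simple single-value-statistic feature
#' set (one feature per signaling marker). Samples with no cells of the
#' type are masked. Medians use the mean-of-middle convention for even
#' counts.
#'
#' @param cells a \linkS4class{CytoExpression} with \code{cellLabels} and
#'   \code{sampleIds}.
#' @param cellType the cell type whose cells are used.
#' @param signaling ordered signaling marker names.
#' @param sampleOrder optional sample ids fixing row order (default: sorted
#'   unique ids present).
#' @return a \linkS4class{CellTypeFeatures} (mode \code{"median"}).
#' @export
medianFeatures <- function(cells, cellType, signaling, sampleOrder = NULL) {
  prep <- featurePrep(cells, cellType, signaling, sampleOrder)
  vals <- matrix(NA_real_, length(prep$samples), length(signaling),
                 dimnames = list(prep$samples, signaling))
  masked <- logical(length(prep$samples))
  for (i in seq_along(prep$samples)) {
    rows <- prep$index[[i]]
    if (!length(rows)) { masked[i] <- TRUE; next }
    vals[i, ] <- apply(prep$m[rows, , drop = FALSE], 2, stats::median)
  }
  new("CellTypeFeatures", cellType = cellType, values = vals,
      masked = masked, mode = "median")
}

#' All-ordered-pairs DREMI features for one cell type
#'
#' For every sample, the DREMI score of every directed signaling pair
#' (X, Y), X != Y, computed on that sample's cells of the given cell type.
#' Samples with fewer cells than \code{params@minCells} are masked and
#' excluded from downstream modelling rather than imputed — imputation
#' would manufacture mutual-information values.
#'
#' @param cells a \linkS4class{CytoExpression} with \code{cellLabels} and
#'   \code{sampleIds}.
#' @param cellType the cell type whose cells are used.
#' @param signaling ordered signaling marker names (p markers give p*(p-1)
#'   features).
#' @param params a \linkS4class{DremiParams}; its \code{minCells} rule
#'   masks low-abundance samples.
#' @param sampleOrder optional sample ids fixing row order.
#' @return a \linkS4class{CellTypeFeatures} (mode \code{"dremi"}).
#' @export
dremiPairFeatures <- function(cells, cellType, signaling,
                              params = dremiParams(), sampleOrder = NULL) {
  pairs <- orderedPairs(signaling)
  prep <- featurePrep(cells, cellType, signaling, sampleOrder)
  vals <- matrix(NA_real_, length(prep$samples), nrow(pairs),
                 dimnames = list(prep$samples, pairs$feature))
  masked <- logical(length(prep$samples))
  for (i in seq_along(prep$samples)) {
    rows <- prep$index[[i]]
    if (length(rows) < params@minCells) { masked[i] <- TRUE; next }
    sub <- prep$m[rows, , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      vals[i, j] <- dremiScore(sub[, pairs$x[j]], sub[, pairs$y[j]],
                               params = params, markerX = pairs$x[j],
                               markerY = pairs$y[j])@score
    }
  }
  new("CellTypeFeatures", cellType = cellType, values = vals,
      masked = masked, mode = "dremi")
}

# Shared validation/indexing for the feature builders.
featurePrep <- function(cells, cellType, signaling, sampleOrder) {
  labels <- cellLabels(cells)
  samples <- sampleIds(cells)
  if (is.null(labels)) stop("cells must carry cellLabels")
  if (is.null(samples)) stop("cells must carry sampleIds")
  if (!cellType %in% labels)
    stop("unknown cell type: ", cellType)
  missing <- setdiff(signaling, markerNames(cells))
  if (length(missing))
    stop("signaling markers absent: ", paste(missing, collapse = ", "))
  if (is.null(sampleOrder)) sampleOrder <- sort(unique(samples))
  sel <- which(labels == cellType)
  index <- lapply(sampleOrder, function(s) sel[samples[sel] == s])
  list(m = exprValues(cells)[, signaling, drop = FALSE],
       samples = sampleOrder, index = index)
}
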