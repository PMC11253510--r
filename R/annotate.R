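#' Reference-guided cell type annotation
#'
#' The Scaffold-map adaptation for automated annotation: query cells are
#' clustered with a SOM on the shared backbone markers; each occupied
#' cluster's centroid (its landmark) is compared with every reference
#' cell-type landmark by cosine similarity; the cluster — and all its member
#' cells — inherits the label of the most similar reference landmark (the
#' highest-weight edge of the scaffold graph). Ties are broken towards the
#' first reference label in canonical (sorted) order. With a similarity
#' threshold, clusters whose best similarity falls below it are labelled
#' \code{"unassigned"}.
#'
#' By default each query sample (per \code{sampleIds}) is clustered
#' independently, matching per-patient annotation use; \code{pooled = TRUE}
#' clusters all cells together.
#'
#' @param query a \linkS4class{CytoExpression}.
#' @param reference a \linkS4class{ReferenceSet} (filtered, labelled).
#' @param config optional \linkS4class{PanelConfig} for alias mapping and
#'   backbone restriction.
#' @param gridRows,gridCols SOM grid (default 10 x 10).
#' @param threshold optional cosine similarity threshold below which
#'   clusters are left \code{"unassigned"} (default none).
#' @param seed integer seed for SOM training.
#' @param pooled cluster all samples together (default \code{FALSE} when
#'   sample ids are present).
#' @param landmarkStatistic \code{"mean"} or \code{"median"} reference
#'   landmarks.
#' @param ... further arguments passed to [trainSOM()].
#' @return an \linkS4class{AnnotationResult}.
#' @examples
#' set.seed(1)
#' ref <- referenceSet(matrix(c(rnorm(200, 0), rnorm(200, 4)), 200, 2,
#'                            dimnames = list(NULL, c("CD3", "CD34"))),
#'                     cellLabels = rep(c("T", "B"), each = 100))
#' q <- cytoExpression(matrix(c(rnorm(100, 0), rnorm(100, 4)), 100, 2,
#'                            dimnames = list(NULL, c("CD3", "CD34"))),
#'                     transformed = TRUE)
#' table(cellLabels(annotateCells(q, ref, gridRows = 2, gridCols = 2,
#'                                seed = 1)))
#' @export
annotateCells <- function(query, reference, config = NULL, gridRows = 10L,
                          gridCols = 10L, threshold = NULL, seed = 1L,
                          pooled = is.null(sampleIds(query)),
                          landmarkStatistic = c("mean", "median"), ...) {
  landmarkStatistic <- match.arg(landmarkStatistic)
  if (!is.null(config)) {
    query <- canonicalizeMarkers(query, config)
    refExpr <- canonicalizeMarkers(reference@expression, config)
    reference <- referenceSet(refExpr,
                              minCellsFilter = reference@minCellsFilter)
  }
  backbone <- harmonizePanels(query, reference@expression, config)
  refLm <- computeReferenceLandmarks(reference, backbone = backbone,
                                     statistic = landmarkStatistic)
  qm <- exprValues(query)[, backbone, drop = FALSE]
  samples <- sampleIds(query)
  if (pooled || is.null(samples)) {
    groups <- list(seq_len(nrow(qm)))
  } else {
    groups <- split(seq_len(nrow(qm)), samples)
  }
  n <- nrow(qm)
  cellLab <- character(n)
  clusterIds <- integer(n)
  tables <- list()
  sims <- list()
  offset <- 0L
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    som <- trainSOM(qm[idx, , drop = FALSE], gridRows = gridRows,
                    gridCols = gridCols, seed = deriveSeed(seed, g), ...)
    nodes <- assignToNodes(som, qm[idx, , drop = FALSE])
    qLm <- computeQueryLandmarks(qm[idx, , drop = FALSE], nodes)
    sim <- landmarkSimilarity(qLm, refLm)
    # argmax per cluster; reference labels are in canonical sorted order, so
    # ties.method = "first" implements the canonical-order tie-break
    best <- max.col(sim, ties.method = "first")
    bestSim <- sim[cbind(seq_len(nrow(sim)), best)]
    lab <- landmarkLabels(refLm)[best]
    if (!is.null(threshold))
      lab[bestSim < threshold] <- "unassigned"
    clusterKey <- match(as.character(nodes), landmarkLabels(qLm))
    cellLab[idx] <- lab[clusterKey]
    clusterIds[idx] <- offset + clusterKey
    tables[[g]] <- data.frame(
      cluster = offset + seq_len(nrow(sim)),
      sample = if (pooled || is.null(samples)) NA_character_
               else names(groups)[g],
      label = lab,
      similarity = bestSim,
      nCells = qLm@memberCounts,
      stringsAsFactors = FALSE)
    rownames(sim) <- as.character(offset + seq_len(nrow(sim)))
    sims[[g]] <- sim
    offset <- offset + nrow(sim)
  }
  new("AnnotationResult",
      cellLabels = cellLab,
      clusterIds = clusterIds,
      clusterTable = do.call(rbind, tables),
      similarityMatrix = do.call(rbind, sims),
      threshold = if (is.null(threshold)) NA_real_ else threshold)
}
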