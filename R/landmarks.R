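#' Landmarks of SOM clusters
#'
#' For each occupied SOM node, the landmark is the arithmetic mean backbone
#' profile of its member cells (the cluster centroid). Empty nodes produce
#' no landmark.
#'
#' @param object a \linkS4class{CytoExpression} or matrix restricted to the
#'   backbone markers.
#' @param clusterIds integer vector of node assignments from
#'   [assignToNodes()].
#' @return a \linkS4class{LandmarkSet} labelled by cluster id.
#' @export
computeQueryLandmarks <- function(object, clusterIds) {
  m <- if (is.matrix(object)) object else exprValues(object)
  if (length(clusterIds) != nrow(m))
    stop("one cluster id per cell required")
  ids <- sort(unique(clusterIds))
  profiles <- rowsum(m, clusterIds, reorder = TRUE)
  counts <- as.integer(table(factor(clusterIds, levels = ids)))
  profiles <- profiles / counts
  landmarkSet(profiles, labels = as.character(ids), memberCounts = counts)
}

#' Landmarks of an annotated reference
#'
#' One landmark per cell type: the mean backbone profile of that type's
#' cells, labelled by the cell type. The reference should already be
#' filtered ([filterReference()]) and restricted to the shared backbone.
#'
#' @param reference a \linkS4class{ReferenceSet}.
#' @param backbone optional character vector of backbone markers to restrict
#'   to (default: all markers of the reference).
#' @param statistic \code{"mean"} (default, the centroid) or
#'   \code{"median"}.
#' @return a \linkS4class{LandmarkSet} labelled by cell type.
#' @export
computeReferenceLandmarks <- function(reference, backbone = NULL,
                                      statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  m <- exprValues(reference)
  if (!is.null(backbone)) {
    missing <- setdiff(backbone, colnames(m))
    if (length(missing))
      stop("backbone markers absent from reference: ",
           paste(missing, collapse = ", "))
    m <- m[, backbone, drop = FALSE]
  }
  labels <- cellLabels(reference)
  types <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = types)))
  if (any(counts == 0L)) {
    warning("cell types with no cells excluded: ",
            paste(types[counts == 0L], collapse = ", "))
    types <- types[counts > 0L]
    counts <- counts[counts > 0L]
  }
  profiles <- if (statistic == "mean") {
    rowsum(m, labels, reorder = TRUE) / counts
  } else {
    t(vapply(types, function(ty)
      apply(m[labels == ty, , drop = FALSE], 2, stats::median),
      numeric(ncol(m))))
  }
  landmarkSet(profiles, labels = types, memberCounts = counts)
}

#' Cosine similarity of two profiles
#'
#' \code{dot(u, v) / (|u| |v|)}; the matching criterion between query
#' cluster landmarks and reference cell-type landmarks. Undefined for a
#' zero vector.
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in [-1, 1].
#' @examples
#' cosineSimilarity(c(1, 2, 3), c(4, 5, 6))
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for a zero vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Cosine similarity matrix between two landmark sets
#'
#' @param query,reference \linkS4class{LandmarkSet}s over the same backbone.
#' @return numeric matrix (query landmarks x reference landmarks) of
#'   similarities in [-1, 1].
#' @export
landmarkSimilarity <- function(query, reference) {
  qm <- landmarkProfiles(query); rm_ <- landmarkProfiles(reference)
  if (ncol(qm) != ncol(rm_))
    stop("landmark sets live in different backbone dimensions")
  qn <- sqrt(rowSums(qm^2)); rn <- sqrt(rowSums(rm_^2))
  if (any(qn == 0) || any(rn == 0))
    stop("cosine similarity is undefined for a zero landmark profile")
  s <- (qm %*% t(rm_)) / outer(qn, rn)
  s[s > 1] <- 1; s[s < -1] <- -1
  dimnames(s) <- list(landmarkLabels(query), landmarkLabels(reference))
  s
}
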