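#' Harmonize marker panels between query and reference
#'
#' The backbone markers of an analysis are the markers shared between the
#' query dataset and the annotated reference, after applying the panel's
#' alias map to both marker name lists. Matching is exact string match on
#' canonical names — no fuzzy matching, so panel mismatches fail loudly
#' rather than silently. The returned order follows the reference panel.
#'
#' @param query a \linkS4class{CytoExpression} (or character vector of
#'   marker names).
#' @param reference a \linkS4class{CytoExpression}, \linkS4class{ReferenceSet}
#'   or character vector of marker names.
#' @param config optional \linkS4class{PanelConfig}; its alias map is applied
#'   first and, when its \code{backbone} slot is non-empty, the intersection
#'   is restricted to those markers.
#' @return character vector of shared backbone marker names, in reference
#'   order.
#' @examples
#' harmonizePanels(c("CD3", "CD34", "CD99"), c("CD3", "CD34", "CD8"))
#' @export
harmonizePanels <- function(query, reference, config = NULL) {
  q <- if (is.character(query)) query else markerNames(query)
  r <- if (is.character(reference)) reference else markerNames(reference)
  if (!is.null(config)) {
    q <- applyAliasMap(q, config@aliasMap)
    r <- applyAliasMap(r, config@aliasMap)
  }
  shared <- r[r %in% q]
  if (!is.null(config) && length(config@backbone))
    shared <- shared[shared %in% config@backbone]
  if (!length(shared))
    stop("no shared backbone: query and reference panels have no markers ",
         "in common")
  shared
}

#' Apply an alias map to marker names
#'
#' @param markers character vector of raw marker names.
#' @param aliasMap named character vector (raw name -> canonical name).
#' @return character vector of canonical names.
#' @export
applyAliasMap <- function(markers, aliasMap) {
  if (!length(aliasMap)) return(markers)
  hit <- markers %in% names(aliasMap)
  markers[hit] <- unname(aliasMap[markers[hit]])
  markers
}

#' Canonicalize the marker names of an expression object
#'
#' @param object a \linkS4class{CytoExpression}.
#' @param config a \linkS4class{PanelConfig} whose alias map is applied.
#' @return the object with canonical marker names.
#' @export
canonicalizeMarkers <- function(object, config) {
  colnames(object@exprs) <- applyAliasMap(colnames(object@exprs),
                                          config@aliasMap)
  validObject(object)
  object
}

#' Filter a reference by minimum cells per type
#'
#' Cell types represented by fewer than \code{minCells} cells are removed
#' together with all their cells; the applied threshold is recorded on the
#' returned object. The default of 300 cells reflects the smallest
#' population size at which reference landmarks remain stable.
#'
#' @param reference a \linkS4class{ReferenceSet}.
#' @param minCells integer threshold; default 300.
#' @return the filtered \linkS4class{ReferenceSet}.
#' @examples
#' m <- matrix(rnorm(800 * 2), 800, 2, dimnames = list(NULL, c("a", "b")))
#' ref <- referenceSet(m, cellLabels = rep(c("A", "B"), c(500, 300)))
#' cellTypeCounts(filterReference(ref, 300))
#' @export
filterReference <- function(reference, minCells = 300L) {
  stopifnot(is(reference, "ReferenceSet"))
  minCells <- as.integer(minCells)
  if (minCells < 1L)
    stop("minCells must be at least 1")
  counts <- cellTypeCounts(reference)
  keep <- names(counts)[counts >= minCells]
  if (!length(keep))
    stop("all cell types fall below the ", minCells, "-cell threshold")
  sel <- reference@expression@cellLabels %in% keep
  referenceSet(reference@expression[sel, ], minCellsFilter = minCells)
}
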