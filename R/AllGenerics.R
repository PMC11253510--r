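#' Extract the expression matrix
#'
#' Accessor for the cells-by-markers numeric matrix held by a
#' \linkS4class{CytoExpression} object (or an object containing one).
#'
#' @param object a \linkS4class{CytoExpression} or
#'   \linkS4class{ReferenceSet}.
#' @return numeric matrix, cells in rows, markers in columns.
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' Marker names
#'
#' @param object an object with a marker panel.
#' @return character vector of marker names, in column order.
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))

#' Per-cell labels
#'
#' @param object an object carrying per-cell cell-type labels.
#' @return character vector with one label per cell, or \code{NULL}.
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))

#' Per-cell sample identifiers
#'
#' @param object an object carrying per-cell sample ids.
#' @return character vector with one sample id per cell, or \code{NULL}.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' Number of cells
#'
#' @param object an object holding single cells.
#' @return integer cell count.
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' Has the arcsinh transform been applied?
#'
#' @param object a \linkS4class{CytoExpression}.
#' @return logical flag.
#' @export
setGeneric("isTransformed", function(object) standardGeneric("isTransformed"))

#' Cell counts per cell type
#'
#' @param object a \linkS4class{ReferenceSet} or labelled
#'   \linkS4class{CytoExpression}.
#' @return named integer vector, one entry per cell type.
#' @export
setGeneric("cellTypeCounts", function(object) standardGeneric("cellTypeCounts"))

#' Landmark profile matrix
#'
#' @param object a \linkS4class{LandmarkSet}.
#' @return numeric matrix, landmarks in rows, backbone markers in columns.
#' @export
setGeneric("landmarkProfiles",
           function(object) standardGeneric("landmarkProfiles"))

#' Landmark labels
#'
#' @param object a \linkS4class{LandmarkSet}.
#' @return character vector of labels (cell types for a reference landmark
#'   set, cluster ids for a query landmark set).
#' @export
setGeneric("landmarkLabels",
           function(object) standardGeneric("landmarkLabels"))
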