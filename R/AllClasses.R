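#' CytoExpression: single-cell protein expression
#'
#' The universal currency of the package: a cells-by-markers numeric matrix
#' of (typically arcsinh-transformed) mass cytometry intensities, with
#' optional per-cell cell-type labels and per-cell sample identifiers.
#' Orientation follows cytometry convention (events in rows, parameters in
#' columns).
#'
#' @slot exprs numeric matrix, cells in rows, markers in columns; column
#'   names are the marker names and must be unique.
#' @slot cellLabels character vector of per-cell cell-type labels
#'   (length 0 when absent).
#' @slot sampleIds character vector of per-cell sample identifiers
#'   (length 0 when absent).
#' @slot transformed logical; \code{TRUE} once the arcsinh transform has
#'   been applied.
#'
#' @seealso [cytoExpression()] for the user-facing constructor,
#'   [readExpression()] for file input.
#' @export
setClass("CytoExpression",
  representation(
    exprs = "matrix",
    cellLabels = "character",
    sampleIds = "character",
    transformed = "logical"
  ),
  prototype(
    cellLabels = character(0),
    sampleIds = character(0),
    transformed = FALSE
  )
)

setValidity("CytoExpression", function(object) {
  msg <- character(0)
  m <- object@exprs
  if (!is.numeric(m))
    msg <- c(msg, "expression matrix must be numeric")
  if (is.null(colnames(m)))
    msg <- c(msg, "expression matrix must have marker names as column names")
  else {
    if (anyDuplicated(colnames(m))) {
      dup <- unique(colnames(m)[duplicated(colnames(m))])
      msg <- c(msg, paste0("duplicate marker names: ",
                           paste(dup, collapse = ", ")))
    }
    if (any(!nzchar(colnames(m))))
      msg <- c(msg, "empty marker names are not allowed")
  }
  if (anyNA(m))
    msg <- c(msg, "expression matrix contains missing values")
  if (length(object@cellLabels) &&
      length(object@cellLabels) != nrow(m))
    msg <- c(msg, "cellLabels must have one entry per cell")
  if (length(object@sampleIds) &&
      length(object@sampleIds) != nrow(m))
    msg <- c(msg, "sampleIds must have one entry per cell")
  if (length(object@transformed) != 1L)
    msg <- c(msg, "transformed must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct a CytoExpression object
#'
#' @param exprs numeric matrix (cells x markers). Column names are taken as
#'   marker names; supply \code{markerNames} to set or override them.
#' @param markerNames optional character vector of marker names.
#' @param cellLabels optional character vector, one cell-type label per cell.
#' @param sampleIds optional character vector, one sample id per cell.
#' @param transformed logical; whether values are already
#'   arcsinh-transformed. Default \code{FALSE}.
#'
#' @return a \linkS4class{CytoExpression} object.
#' @examples
#' m <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("CD3", "CD34")))
#' cytoExpression(m)
#' @export
cytoExpression <- function(exprs, markerNames = NULL, cellLabels = NULL,
                           sampleIds = NULL, transformed = FALSE) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (!is.null(markerNames)) colnames(exprs) <- markerNames
  new("CytoExpression", exprs = exprs,
      cellLabels = if (is.null(cellLabels)) character(0)
                   else as.character(cellLabels),
      sampleIds = if (is.null(sampleIds)) character(0)
                  else as.character(sampleIds),
      transformed = transformed)
}

#' @describeIn cytoExpression expression matrix accessor
#' @param object a \linkS4class{CytoExpression}.
#' @export
setMethod("exprValues", "CytoExpression", function(object) object@exprs)

#' @describeIn cytoExpression marker names accessor
#' @export
setMethod("markerNames", "CytoExpression",
          function(object) colnames(object@exprs))

#' @describeIn cytoExpression per-cell labels (\code{NULL} when absent)
#' @export
setMethod("cellLabels", "CytoExpression", function(object) {
  if (length(object@cellLabels)) object@cellLabels else NULL
})

#' @describeIn cytoExpression per-cell sample ids (\code{NULL} when absent)
#' @export
setMethod("sampleIds", "CytoExpression", function(object) {
  if (length(object@sampleIds)) object@sampleIds else NULL
})

#' @describeIn cytoExpression number of cells
#' @export
setMethod("nCells", "CytoExpression", function(object) nrow(object@exprs))

#' @describeIn cytoExpression arcsinh-transform flag
#' @export
setMethod("isTransformed", "CytoExpression",
          function(object) object@transformed)

setMethod("show", "CytoExpression", function(object) {
  cat("CytoExpression:", nrow(object@exprs), "cells x",
      ncol(object@exprs), "markers",
      if (object@transformed) "(arcsinh-transformed)" else "(raw)", "\n")
  mk <- colnames(object@exprs)
  cat("  markers:", paste(utils::head(mk, 8), collapse = ", "),
      if (length(mk) > 8) "...", "\n")
  if (length(object@cellLabels))
    cat("  cell types:", length(unique(object@cellLabels)), "\n")
  if (length(object@sampleIds))
    cat("  samples:", length(unique(object@sampleIds)), "\n")
})

#' Subset a CytoExpression
#'
#' Standard two-index subsetting; rows select cells (labels and sample ids
#' follow), columns select markers by index or name.
#'
#' @param x a \linkS4class{CytoExpression}.
#' @param i,j row (cell) and column (marker) indices.
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{CytoExpression}.
#' @return a \linkS4class{CytoExpression}.
#' @export
setMethod("[", "CytoExpression", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@exprs))
  if (missing(j)) j <- seq_len(ncol(x@exprs))
  ii <- seq_len(nrow(x@exprs))[if (is.logical(i)) which(i) else i]
  new("CytoExpression",
      exprs = x@exprs[ii, j, drop = FALSE],
      cellLabels = if (length(x@cellLabels)) x@cellLabels[ii]
                   else character(0),
      sampleIds = if (length(x@sampleIds)) x@sampleIds[ii]
                  else character(0),
      transformed = x@transformed)
})

#' ReferenceSet: an annotated reference dataset
#'
#' A labelled \linkS4class{CytoExpression} together with the minimum
#' cell-count filter that has been applied to its cell types. Used to guide
#' automated annotation of query datasets.
#'
#' @slot expression a \linkS4class{CytoExpression} whose \code{cellLabels}
#'   are mandatory.
#' @slot minCellsFilter integer; cell types with fewer cells than this were
#'   removed by [filterReference()] (0 when no filter has been applied).
#'
#' @export
setClass("ReferenceSet",
  representation(
    expression = "CytoExpression",
    minCellsFilter = "integer"
  ),
  prototype(minCellsFilter = 0L)
)

setValidity("ReferenceSet", function(object) {
  msg <- character(0)
  if (!length(object@expression@cellLabels))
    msg <- c(msg, "reference expression must carry cell labels")
  if (length(object@minCellsFilter) != 1L || object@minCellsFilter < 0L)
    msg <- c(msg, "minCellsFilter must be a single non-negative integer")
  if (object@minCellsFilter > 0L &&
      length(object@expression@cellLabels)) {
    cnt <- table(object@expression@cellLabels)
    if (any(cnt < object@minCellsFilter))
      msg <- c(msg, "retained cell types must all meet minCellsFilter")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param expression a \linkS4class{CytoExpression} with per-cell labels, or
#'   a numeric matrix (then \code{cellLabels} is required).
#' @param cellLabels per-cell labels when \code{expression} is a bare matrix.
#' @param minCellsFilter minimum-cells threshold already applied (0 if none).
#' @return a \linkS4class{ReferenceSet}.
#' @export
referenceSet <- function(expression, cellLabels = NULL, minCellsFilter = 0L) {
  if (is.matrix(expression))
    expression <- cytoExpression(expression, cellLabels = cellLabels,
                                 transformed = TRUE)
  else if (!is.null(cellLabels))
    expression@cellLabels <- as.character(cellLabels)
  new("ReferenceSet", expression = expression,
      minCellsFilter = as.integer(minCellsFilter))
}

#' @describeIn referenceSet underlying expression matrix
#' @param object a \linkS4class{ReferenceSet}.
#' @export
setMethod("exprValues", "ReferenceSet",
          function(object) object@expression@exprs)

#' @describeIn referenceSet marker names
#' @export
setMethod("markerNames", "ReferenceSet",
          function(object) colnames(object@expression@exprs))

#' @describeIn referenceSet per-cell labels
#' @export
setMethod("cellLabels", "ReferenceSet",
          function(object) object@expression@cellLabels)

#' @describeIn referenceSet number of cells
#' @export
setMethod("nCells", "ReferenceSet",
          function(object) nrow(object@expression@exprs))

#' @describeIn referenceSet named per-type cell counts
#' @export
setMethod("cellTypeCounts", "ReferenceSet", function(object) {
  tab <- table(object@expression@cellLabels)
  stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "ReferenceSet", function(object) {
  cnt <- cellTypeCounts(object)
  cat("ReferenceSet:", nCells(object), "cells,", length(cnt),
      "cell types,", ncol(object@expression@exprs), "markers\n")
  if (object@minCellsFilter > 0L)
    cat("  min-cells filter applied:", object@minCellsFilter, "\n")
})

#' PanelConfig: marker panel roles and preprocessing
#'
#' Declares which markers are phenotyping ("backbone") markers shared with a
#' reference, which are signaling markers used for feature engineering, how
#' raw marker names map to canonical ones, and the arcsinh cofactor.
#'
#' @slot backbone character; ordered canonical backbone marker names.
#' @slot signaling character; ordered canonical signaling marker names
#'   (disjoint from backbone).
#' @slot aliasMap named character; \code{names()} are raw marker names,
#'   values the canonical names they map to.
#' @slot arcsinhCofactor positive numeric; default 5, the community
#'   convention for CyTOF.
#'
#' @export
setClass("PanelConfig",
  representation(
    backbone = "character",
    signaling = "character",
    aliasMap = "character",
    arcsinhCofactor = "numeric"
  ),
  prototype(backbone = character(0), signaling = character(0),
            aliasMap = character(0), arcsinhCofactor = 5)
)

setValidity("PanelConfig", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@backbone))
    msg <- c(msg, "backbone markers must be unique")
  if (anyDuplicated(object@signaling))
    msg <- c(msg, "signaling markers must be unique")
  overlap <- intersect(object@backbone, object@signaling)
  if (length(overlap))
    msg <- c(msg, paste0("backbone and signaling sets must be disjoint (",
                         paste(overlap, collapse = ", "), ")"))
  if (length(object@arcsinhCofactor) != 1L ||
      !is.finite(object@arcsinhCofactor) || object@arcsinhCofactor <= 0)
    msg <- c(msg, "arcsinhCofactor must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a PanelConfig
#'
#' @param backbone ordered backbone (phenotyping) marker names.
#' @param signaling ordered signaling marker names.
#' @param aliasMap named character vector mapping raw to canonical names.
#' @param arcsinhCofactor positive arcsinh cofactor (default 5).
#' @return a \linkS4class{PanelConfig}.
#' @export
panelConfig <- function(backbone = character(0), signaling = character(0),
                        aliasMap = character(0), arcsinhCofactor = 5) {
  new("PanelConfig", backbone = as.character(backbone),
      signaling = as.character(signaling),
      aliasMap = if (length(aliasMap)) {
        stats::setNames(as.character(aliasMap), names(aliasMap))
      } else character(0),
      arcsinhCofactor = arcsinhCofactor)
}

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", length(object@backbone), "backbone,",
      length(object@signaling), "signaling markers; cofactor",
      object@arcsinhCofactor, "\n")
})

#' SOMModel: a trained self-organizing map
#'
#' Codebook of a rows-by-cols SOM grid trained on backbone markers, as used
#' for FlowSOM-style clustering of query cells before landmark matching.
#'
#' @slot gridRows,gridCols integer grid dimensions (default 10 x 10).
#' @slot codebook numeric matrix with \code{gridRows * gridCols} rows (one
#'   per node, row-major over the grid) and one column per backbone marker.
#' @slot trainingParams list of training settings (passes, initial learning
#'   rate, initial radius, seed).
#'
#' @export
setClass("SOMModel",
  representation(
    gridRows = "integer",
    gridCols = "integer",
    codebook = "matrix",
    trainingParams = "list"
  )
)

setValidity("SOMModel", function(object) {
  msg <- character(0)
  if (nrow(object@codebook) != object@gridRows * object@gridCols)
    msg <- c(msg, "codebook must have one row per grid node")
  if (!all(is.finite(object@codebook)))
    msg <- c(msg, "codebook entries must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SOMModel", function(object) {
  cat("SOMModel:", object@gridRows, "x", object@gridCols, "grid,",
      ncol(object@codebook), "markers\n")
})

#' LandmarkSet: labelled profile vectors
#'
#' Representative backbone profiles: one per cell type for a reference, one
#' per occupied SOM node for a query.
#'
#' @slot profiles numeric matrix, landmarks in rows, backbone markers in
#'   columns; row names are the labels.
#' @slot labels character; cell-type names (reference) or cluster ids
#'   (query).
#' @slot memberCounts integer; number of cells behind each landmark.
#'
#' @export
setClass("LandmarkSet",
  representation(
    profiles = "matrix",
    labels = "character",
    memberCounts = "integer"
  )
)

setValidity("LandmarkSet", function(object) {
  msg <- character(0)
  if (nrow(object@profiles) != length(object@labels))
    msg <- c(msg, "one label per landmark required")
  if (nrow(object@profiles) != length(object@memberCounts))
    msg <- c(msg, "one member count per landmark required")
  if (length(object@memberCounts) && any(object@memberCounts < 1L))
    msg <- c(msg, "landmarks with no member cells must be dropped")
  if (!all(is.finite(object@profiles)))
    msg <- c(msg, "landmark profiles must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn landmarkSet profile matrix accessor
#' @param object a \linkS4class{LandmarkSet}.
#' @export
setMethod("landmarkProfiles", "LandmarkSet", function(object) object@profiles)

#' @describeIn landmarkSet label accessor
#' @export
setMethod("landmarkLabels", "LandmarkSet", function(object) object@labels)

#' Construct a LandmarkSet
#'
#' @param profiles numeric matrix of landmark profiles (landmarks x markers).
#' @param labels one label per landmark.
#' @param memberCounts cells behind each landmark.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(profiles, labels, memberCounts) {
  profiles <- as.matrix(profiles)
  rownames(profiles) <- labels
  new("LandmarkSet", profiles = profiles, labels = as.character(labels),
      memberCounts = as.integer(memberCounts))
}

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nrow(object@profiles), "landmarks x",
      ncol(object@profiles), "markers\n")
})

#' AnnotationResult: reference-guided cell type assignments
#'
#' Output of [annotateCells()]: per-cell predicted labels plus the
#' cluster-level matching evidence (best reference landmark, best cosine
#' similarity, and the full similarity matrix).
#'
#' @slot cellLabels character; predicted label per query cell
#'   (\code{"unassigned"} when below the similarity threshold).
#' @slot clusterIds integer; SOM cluster id per query cell.
#' @slot clusterTable data.frame with one row per occupied cluster:
#'   \code{cluster}, \code{label}, \code{similarity}, \code{nCells}.
#' @slot similarityMatrix numeric matrix, clusters x reference landmarks, of
#'   cosine similarities in [-1, 1].
#' @slot threshold numeric; similarity threshold used (\code{NA} when none).
#'
#' @export
setClass("AnnotationResult",
  representation(
    cellLabels = "character",
    clusterIds = "integer",
    clusterTable = "data.frame",
    similarityMatrix = "matrix",
    threshold = "numeric"
  ),
  prototype(threshold = NA_real_)
)

setValidity("AnnotationResult", function(object) {
  msg <- character(0)
  if (length(object@cellLabels) != length(object@clusterIds))
    msg <- c(msg, "one cluster id per cell required")
  sims <- object@similarityMatrix
  if (length(sims) && (min(sims) < -1 - 1e-9 || max(sims) > 1 + 1e-9))
    msg <- c(msg, "cosine similarities must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn annotationTable per-cell predicted labels
#' @param object an \linkS4class{AnnotationResult}.
#' @export
setMethod("cellLabels", "AnnotationResult", function(object) object@cellLabels)

setMethod("show", "AnnotationResult", function(object) {
  cat("AnnotationResult:", length(object@cellLabels), "cells,",
      nrow(object@clusterTable), "clusters\n")
  tab <- sort(table(object@cellLabels), decreasing = TRUE)
  cat("  top labels:",
      paste(utils::head(paste0(names(tab), " (", tab, ")"), 5),
            collapse = ", "), "\n")
})

#' Cluster-level annotation table
#'
#' @param object an \linkS4class{AnnotationResult}.
#' @return data.frame with columns \code{cluster}, \code{label},
#'   \code{similarity}, \code{nCells}.
#' @export
annotationTable <- function(object) object@clusterTable

#' DremiParams: settings for the DREMI estimator
#'
#' @slot nFineBins integer; fine KDE grid resolution per axis (default 256).
#' @slot nCoarseBins integer; coarse grid per axis over which conditional
#'   mutual information is computed (default 8); must divide
#'   \code{nFineBins}.
#' @slot bandwidthRule character; \code{"grid"} (one fine-grid cell width
#'   per axis, the default), \code{"silverman"}, or \code{"fixed"}.
#' @slot bandwidthValue numeric; bandwidth (KDE standard deviation) when
#'   \code{bandwidthRule == "fixed"}.
#' @slot minCells integer; minimum number of cells required (default 200).
#' @slot minColumnMass numeric in (0,1); an X-column of the coarse grid is
#'   retained when its mass is at least this fraction of the uniform column
#'   mass (default 0.01).
#'
#' @export
setClass("DremiParams",
  representation(
    nFineBins = "integer",
    nCoarseBins = "integer",
    bandwidthRule = "character",
    bandwidthValue = "numeric",
    minCells = "integer",
    minColumnMass = "numeric"
  ),
  prototype(nFineBins = 256L, nCoarseBins = 8L, bandwidthRule = "grid",
            bandwidthValue = NA_real_, minCells = 200L, minColumnMass = 0.01)
)

setValidity("DremiParams", function(object) {
  msg <- character(0)
  if (object@nFineBins %% object@nCoarseBins != 0L)
    msg <- c(msg, "nCoarseBins must divide nFineBins")
  if (object@minCells < object@nCoarseBins^2)
    msg <- c(msg, "minCells must be at least nCoarseBins^2")
  if (object@minColumnMass <= 0 || object@minColumnMass >= 1)
    msg <- c(msg, "minColumnMass must lie in (0, 1)")
  if (!object@bandwidthRule %in% c("grid", "silverman", "fixed"))
    msg <- c(msg, "bandwidthRule must be 'grid', 'silverman' or 'fixed'")
  if (object@bandwidthRule == "fixed" &&
      (!is.finite(object@bandwidthValue) || object@bandwidthValue <= 0))
    msg <- c(msg, "fixed bandwidth requires a positive bandwidthValue")
  if (length(msg)) msg else TRUE
})

#' Construct DREMI estimator settings
#'
#' @param nFineBins fine KDE grid size per axis (default 256).
#' @param nCoarseBins coarse grid size per axis (default 8; must divide
#'   \code{nFineBins}).
#' @param bandwidthRule \code{"grid"}, \code{"silverman"} or \code{"fixed"}.
#' @param bandwidthValue positive bandwidth for \code{"fixed"}.
#' @param minCells minimum cells required per estimation (default 200).
#' @param minColumnMass column-retention mass fraction (default 0.01).
#' @return a \linkS4class{DremiParams}.
#' @export
dremiParams <- function(nFineBins = 256L, nCoarseBins = 8L,
                        bandwidthRule = c("grid", "silverman", "fixed"),
                        bandwidthValue = NA_real_, minCells = 200L,
                        minColumnMass = 0.01) {
  bandwidthRule <- match.arg(bandwidthRule)
  new("DremiParams", nFineBins = as.integer(nFineBins),
      nCoarseBins = as.integer(nCoarseBins), bandwidthRule = bandwidthRule,
      bandwidthValue = bandwidthValue, minCells = as.integer(minCells),
      minColumnMass = minColumnMass)
}

#' DremiResult: a directed DREMI score
#'
#' @slot pair character of length 2: the (X, Y) marker pair, ordered —
#'   DREMI is directional, X to Y.
#' @slot score numeric; conditional mutual information in bits, in
#'   [0, log2(nCoarseBins)].
#' @slot nCells integer; cells used.
#' @slot params the \linkS4class{DremiParams} used.
#'
#' @export
setClass("DremiResult",
  representation(
    pair = "character",
    score = "numeric",
    nCells = "integer",
    params = "DremiParams"
  )
)

setValidity("DremiResult", function(object) {
  msg <- character(0)
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must name exactly two markers (X, Y)")
  cap <- log2(object@params@nCoarseBins)
  if (object@score < 0 || object@score > cap + 1e-9)
    msg <- c(msg, "score must lie in [0, log2(nCoarseBins)]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DremiResult", function(object) {
  cat(sprintf("DREMI %s -> %s: %.4f bits (n = %d cells)\n",
              object@pair[1], object@pair[2], object@score, object@nCells))
})

#' CellTypeFeatures: per-sample features for one cell type
#'
#' Samples-by-features matrix built from the cells of a single annotated
#' cell type: either per-marker medians or all ordered-pair DREMI scores.
#' Samples failing the minimum-cell rule are masked, never imputed.
#'
#' @slot cellType character; the cell type the features describe.
#' @slot values numeric matrix, samples in rows (row names = sample ids),
#'   features in columns.
#' @slot masked logical; per-sample flag, \code{TRUE} when the sample had
#'   too few cells of this type and its row is all-\code{NA}.
#' @slot mode character; \code{"median"} or \code{"dremi"}.
#'
#' @export
setClass("CellTypeFeatures",
  representation(
    cellType = "character",
    values = "matrix",
    masked = "logical",
    mode = "character"
  )
)

setValidity("CellTypeFeatures", function(object) {
  msg <- character(0)
  if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "feature names must be unique")
  if (length(object@masked) != nrow(object@values))
    msg <- c(msg, "one mask flag per sample required")
  if (length(object@masked)) {
    bad <- object@masked & !apply(is.na(object@values), 1, all)
    if (any(bad))
      msg <- c(msg, "masked samples must not carry values")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CellTypeFeatures", function(object) {
  cat(sprintf("CellTypeFeatures [%s, %s]: %d samples x %d features (%d masked)\n",
              object@cellType, object@mode, nrow(object@values),
              ncol(object@values), sum(object@masked)))
})

#' Feature values for modelling
#'
#' Returns the unmasked rows of a \linkS4class{CellTypeFeatures} matrix.
#'
#' @param object a \linkS4class{CellTypeFeatures}.
#' @param dropMasked drop masked samples (default \code{TRUE}).
#' @return numeric matrix with sample ids as row names.
#' @export
featureValues <- function(object, dropMasked = TRUE) {
  if (dropMasked) object@values[!object@masked, , drop = FALSE]
  else object@values
}
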