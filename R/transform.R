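#' Arcsinh-transform raw intensities
#'
#' Applies the standard CyTOF variance-stabilising transform
#' \code{asinh(x / cofactor)} entrywise. The default cofactor of 5 is the
#' community convention for mass cytometry. Values below zero (residuals of
#' upstream bead normalisation) are transformed as-is, not truncated, so
#' that downstream medians are unbiased.
#'
#' @param object a \linkS4class{CytoExpression} with raw values.
#' @param cofactor positive scale; default 5.
#' @param force re-transform even if \code{isTransformed(object)} is already
#'   \code{TRUE} (default \code{FALSE}: double transformation is an error).
#' @return the transformed \linkS4class{CytoExpression}
#'   (\code{transformed = TRUE}).
#' @seealso [inverseArcsinhTransform()]
#' @examples
#' m <- cytoExpression(matrix(0:5, 3, 2, dimnames = list(NULL, c("a", "b"))))
#' isTransformed(arcsinhTransform(m))
#' @export
arcsinhTransform <- function(object, cofactor = 5, force = FALSE) {
  stopifnot(is(object, "CytoExpression"))
  if (!is.numeric(cofactor) || length(cofactor) != 1L ||
      !is.finite(cofactor) || cofactor <= 0)
    stop("cofactor must be a single positive number")
  if (object@transformed && !force)
    stop("data are already arcsinh-transformed; use force = TRUE to repeat")
  object@exprs <- asinh(object@exprs / cofactor)
  object@transformed <- TRUE
  object
}

#' Invert the arcsinh transform
#'
#' Recovers raw intensities via \code{sinh(x) * cofactor}; exact inverse of
#' [arcsinhTransform()] up to floating point.
#'
#' @param object a transformed \linkS4class{CytoExpression}.
#' @param cofactor the cofactor used in the forward transform.
#' @return a raw-scale \linkS4class{CytoExpression}
#'   (\code{transformed = FALSE}).
#' @export
inverseArcsinhTransform <- function(object, cofactor = 5) {
  stopifnot(is(object, "CytoExpression"))
  if (!object@transformed)
    stop("data are not arcsinh-transformed")
  object@exprs <- sinh(object@exprs) * cofactor
  object@transformed <- FALSE
  object
}
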