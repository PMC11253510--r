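#' Two-dimensional kernel density of a marker pair
#'
#' Gaussian KDE (via \code{MASS::kde2d}) evaluated on an
#' \code{nFineBins x nFineBins} grid spanning the data range of each axis
#' expanded by one bandwidth; the grid is normalised to total mass 1. The
#' default bandwidth is one fine-grid cell width per axis, a mild
#' regularisation of the fine histogram that preserves conditional
#' structure at the coarse-grid scale (see the methods vignette);
#' Silverman's rule and fixed bandwidths are available.
#'
#' @param x,y numeric vectors of equal length (cells), e.g. two signaling
#'   markers on arcsinh scale.
#' @param params a \linkS4class{DremiParams}.
#' @return list with \code{z} (nFine x nFine density matrix, X indexing
#'   rows, summing to 1), \code{xBreaks}, \code{yBreaks} and the bandwidths
#'   used.
#' @export
density2d <- function(x, y, params = dremiParams()) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < params@minCells)
    stop("too few cells for DREMI estimation: ", n, " < ", params@minCells)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance on an axis: density is degenerate")
  nf <- params@nFineBins
  bw <- switch(params@bandwidthRule,
    grid = c(diff(range(x)) / nf, diff(range(y)) / nf),
    silverman = c(stats::bw.nrd0(x), stats::bw.nrd0(y)),
    fixed = rep(params@bandwidthValue, 2))
  lims <- c(min(x) - bw[1], max(x) + bw[1], min(y) - bw[2], max(y) + bw[2])
  # kde2d's h is 4x the Gaussian kernel sd
  kd <- MASS::kde2d(x, y, h = 4 * bw, n = nf, lims = lims)
  z <- kd$z / sum(kd$z)
  list(z = z, xGrid = kd$x, yGrid = kd$y, bandwidth = bw)
}

#' Coarse conditional densities p(y | x)
#'
#' Aggregates a fine joint-density grid to \code{nCoarseBins x nCoarseBins}
#' by block sums, then renormalises each X-column with enough mass into an
#' estimate of the conditional distribution of Y given that X state.
#' Columns whose mass falls below \code{minColumnMass} times the uniform
#' column mass (1/nCoarseBins) are excluded — they carry too few cells to
#' estimate a conditional.
#'
#' @param fine list from [density2d()] or a fine joint-density matrix
#'   (X indexing rows).
#' @param params a \linkS4class{DremiParams}.
#' @return list with \code{conditional} (coarse matrix; column-normalised
#'   over Y for retained X columns, \code{NA} for excluded ones; here rows
#'   index X states, columns Y states is transposed: element [i, j] =
#'   p(Y = j | X = i)), \code{columnMass} and logical \code{retained}.
#' @export
conditionalDensity <- function(fine, params = dremiParams()) {
  z <- if (is.list(fine)) fine$z else fine
  nf <- nrow(z)
  nc <- params@nCoarseBins
  if (nf %% nc != 0L)
    stop("coarse grid must divide the fine grid")
  f <- nf %/% nc
  # block-sum both axes: z rows index X, columns index Y
  grp <- rep(seq_len(nc), each = f)
  coarse <- rowsum(t(rowsum(z, grp)), grp)    # Y x X after double rowsum
  coarse <- t(coarse)                          # X x Y
  colMass <- rowSums(coarse)
  retained <- colMass >= params@minColumnMass * (1 / nc)
  if (!any(retained))
    stop("all X columns excluded: no mass to condition on")
  cond <- matrix(NA_real_, nc, nc)
  cond[retained, ] <- coarse[retained, , drop = FALSE] /
    colMass[retained]
  list(conditional = cond, columnMass = colMass, retained = retained)
}

#' DREMI: conditional-density resampled mutual information
#'
#' Scores the strength of a directed signaling relationship X to Y on
#' single cells. The joint density is estimated on a fine grid, aggregated
#' to a coarse grid, and each retained X state's conditional p(y|x) is
#' given equal weight — the "resampling" that removes the influence of the
#' cell-abundance distribution over X — before computing the mutual
#' information (in bits) between X states and Y under those equalised
#' weights:
#' \deqn{D = \sum_x w(x) \sum_y p(y|x) \log_2 \frac{p(y|x)}{q(y)},\quad
#'   q(y) = \sum_x w(x)\, p(y|x)}
#' The score is directional: DREMI(X to Y) generally differs from
#' DREMI(Y to X). It lies in [0, log2(nCoarseBins)].
#'
#' @param x,y numeric vectors of equal length; X is the conditioning
#'   (upstream) marker.
#' @param params a \linkS4class{DremiParams}.
#' @param markerX,markerY names recorded in the result.
#' @return a \linkS4class{DremiResult}.
#' @examples
#' set.seed(1)
#' x <- runif(500); y <- x + rnorm(500, sd = 0.05)
#' dremiScore(x, y, dremiParams(minCells = 100))
#' @export
dremiScore <- function(x, y, params = dremiParams(), markerX = "X",
                       markerY = "Y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  fine <- density2d(x, y, params)
  cond <- conditionalDensity(fine, params)
  score <- dremiFromConditional(cond$conditional, cond$retained)
  new("DremiResult", pair = c(markerX, markerY), score = score,
      nCells = length(x), params = params)
}

#' DREMI score from a coarse joint distribution
#'
#' Computes the resampled conditional mutual information directly from a
#' coarse joint probability (or count) matrix, bypassing density
#' estimation. This is the exact discrete form of the score and is the path
#' used to validate the full estimator against direct summation.
#'
#' @param joint numeric matrix, X states in rows, Y states in columns;
#'   non-negative, any total mass.
#' @param params a \linkS4class{DremiParams} supplying the column-retention
#'   rule (the matrix must already be \code{nCoarseBins} square).
#' @return score in bits.
#' @export
dremiFromJoint <- function(joint, params = dremiParams()) {
  nc <- nrow(joint)
  if (ncol(joint) != nc)
    stop("joint must be square (X states x Y states)")
  joint <- joint / sum(joint)
  colMass <- rowSums(joint)
  retained <- colMass >= params@minColumnMass * (1 / nc)
  if (!any(retained))
    stop("all X columns excluded: no mass to condition on")
  cond <- matrix(NA_real_, nc, nc)
  cond[retained, ] <- joint[retained, , drop = FALSE] / colMass[retained]
  dremiFromConditional(cond, retained)
}

# Mutual information (bits) between equal-weighted retained X states and Y.
dremiFromConditional <- function(cond, retained) {
  p <- cond[retained, , drop = FALSE]
  w <- 1 / nrow(p)
  q <- colSums(p) * w
  terms <- p * log2(p / rep(q, each = nrow(p)))
  terms[p == 0] <- 0
  score <- w * sum(terms)
  # clip numerical noise; cap is exact for the discrete form
  min(max(score, 0), log2(ncol(cond)))
}
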