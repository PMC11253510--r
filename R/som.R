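#' Train a self-organizing map on backbone markers
#'
#' FlowSOM-style clustering step of the annotation pipeline: an online
#' (stochastic) SOM on a rectangular grid, 10 x 10 by default. The codebook
#' is initialised from a random sample of cells; each presented cell updates
#' its best-matching unit (Euclidean distance) and the unit's grid
#' neighbours under a Gaussian neighbourhood whose radius, together with the
#' learning rate, decays linearly over a fixed number of passes through the
#' data. Training is fully deterministic given \code{seed}.
#'
#' @param object a \linkS4class{CytoExpression} already restricted to the
#'   backbone markers (or a bare numeric matrix).
#' @param gridRows,gridCols grid dimensions; default 10 x 10.
#' @param passes number of passes over the data (default 10).
#' @param alpha initial learning rate (default 0.05, decaying linearly
#'   to 0.01).
#' @param radius initial neighbourhood radius in grid units; default half
#'   the larger grid dimension, decaying linearly to 0.5.
#' @param seed integer seed controlling initialisation and presentation
#'   order.
#' @return a \linkS4class{SOMModel}.
#' @examples
#' m <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' som <- trainSOM(m, gridRows = 3, gridCols = 3, seed = 1)
#' @export
trainSOM <- function(object, gridRows = 10L, gridCols = 10L, passes = 10L,
                     alpha = 0.05, radius = NULL, seed = 1L) {
  m <- if (is.matrix(object)) object else exprValues(object)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n < 1L) stop("no cells to cluster")
  if (!all(is.finite(m))) stop("non-finite values in input")
  gridRows <- as.integer(gridRows); gridCols <- as.integer(gridCols)
  k <- gridRows * gridCols
  if (n < k)
    warning("fewer cells (", n, ") than SOM nodes (", k, ")")
  if (is.null(radius)) radius <- max(gridRows, gridCols) / 2
  withSeed(seed, {
    codebook <- m[sample.int(n, k, replace = n < k), , drop = FALSE]
    # squared grid distances between every pair of nodes (row-major layout)
    gr <- arrayInd(seq_len(k), c(gridRows, gridCols))
    gridDist2 <- outer(gr[, 1], gr[, 1], "-")^2 +
                 outer(gr[, 2], gr[, 2], "-")^2
    alphaEnd <- min(alpha, 0.01)
    # final radius small enough that late updates are effectively BMU-only
    radiusEnd <- 0.3
    total <- passes * n
    step <- 0L
    for (p in seq_len(passes)) {
      ord <- sample.int(n)
      for (i in ord) {
        frac <- step / max(total - 1L, 1L)
        a <- alpha + (alphaEnd - alpha) * frac
        r <- radius + (radiusEnd - radius) * frac
        x <- m[i, ]
        d2 <- rowSums(sweep(codebook, 2, x)^2)
        bmu <- which.min(d2)
        h <- a * exp(-gridDist2[, bmu] / (2 * r * r))
        codebook <- codebook + h * (rep(x, each = k) - codebook)
        step <- step + 1L
      }
    }
    new("SOMModel", gridRows = gridRows, gridCols = gridCols,
        codebook = codebook,
        trainingParams = list(passes = passes, alpha = alpha,
                              radius = radius, seed = seed))
  })
}

#' Assign cells to SOM nodes
#'
#' Each cell is mapped to its best-matching codebook vector by Euclidean
#' distance; ties are broken towards the lowest node index.
#'
#' @param som a \linkS4class{SOMModel}.
#' @param object a \linkS4class{CytoExpression} or matrix with the same
#'   markers (columns) the SOM was trained on.
#' @return integer vector of node ids (1-based) per cell.
#' @export
assignToNodes <- function(som, object) {
  m <- if (is.matrix(object)) object else exprValues(object)
  if (ncol(m) != ncol(som@codebook))
    stop("dimension mismatch: data have ", ncol(m), " markers, codebook ",
         ncol(som@codebook))
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per cell
  cross <- m %*% t(som@codebook)
  d2 <- sweep(-2 * cross, 2, rowSums(som@codebook^2), `+`)
  max.col(-d2, ties.method = "first")
}
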