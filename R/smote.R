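#' SMOTE class rebalancing to an exact target ratio
#'
#' Synthetic minority over-sampling: each synthetic point is
#' \code{a + u * (b - a)} with \code{u ~ Uniform(0,1)}, \code{a} a minority
#' point and \code{b} one of its k nearest minority neighbours (Euclidean),
#' so every synthetic point lies on a segment between two real minority
#' samples. The interface is stated in terms of the final class ratio
#' rather than over/under-sampling percentages: for ratio \code{"1:r"}
#' (minority:majority) the final minority count is
#' \code{m = max(nMin, ceiling(nMaj / r))} (original minority points are
#' always retained; synthetic points are added up to \code{m}) and the
#' final majority count is exactly \code{r * m}, drawn without replacement
#' when possible and topped up by resampling with replacement when the
#' exact ratio requires more majority cases than exist (as the classical
#' implementation does). Deterministic given \code{seed}.
#'
#' Apply only to a training partition, never to validation or test data.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y binary labels (factor or character), one per row of \code{x}.
#' @param ratio target minority:majority ratio, \code{"1:1"}, \code{"1:2"}
#'   or \code{"1:3"} (any \code{"a:b"} string is accepted).
#' @param k minority neighbours used for interpolation (default 5).
#' @param seed integer seed.
#' @return list with \code{x} (resampled matrix), \code{y} (labels),
#'   \code{synthetic} (logical flag per output row) and the final
#'   \code{counts}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(43 * 3), 43, 3)
#' y <- rep(c("LTS", "STS"), c(15, 28))
#' table(smoteResample(x, y, ratio = "1:1", seed = 7)$y)
#' @export
smoteResample <- function(x, y, ratio = "1:1", k = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("one label per row required")
  classes <- names(sort(table(y)))
  if (length(classes) != 2L) stop("exactly two classes required")
  minority <- classes[1]; majority <- classes[2]
  if (!is.character(ratio) || length(ratio) != 1L ||
      !grepl("^[0-9]+:[0-9]+$", ratio))
    stop("ratio must be of the form 'a:b' with positive integers")
  ab <- as.integer(strsplit(ratio, ":", fixed = TRUE)[[1]])
  if (any(ab < 1L))
    stop("ratio must be of the form 'a:b' with positive integers")
  minIdx <- which(y == minority); majIdx <- which(y == majority)
  nMin <- length(minIdx); nMaj <- length(majIdx)
  k <- as.integer(k)
  if (nMin <= 1L) stop("minority class has a single point; cannot SMOTE")
  if (nMin <= k)
    stop("minority class has ", nMin, " points but k = ", k,
         "; choose a smaller k")
  targetMin <- max(nMin, as.integer(ceiling(nMaj * ab[1] / ab[2])))
  targetMaj <- as.integer(round(targetMin * ab[2] / ab[1]))
  nSynth <- targetMin - nMin
  withSeed(seed, {
    synth <- NULL
    if (nSynth > 0L) {
      xm <- x[minIdx, , drop = FALSE]
      d2 <- as.matrix(stats::dist(xm))^2
      diag(d2) <- Inf
      nn <- t(apply(d2, 1, function(d) order(d)[seq_len(k)]))
      base <- rep_len(seq_len(nMin), nSynth)
      mate <- nn[cbind(base, sample.int(k, nSynth, replace = TRUE))]
      u <- stats::runif(nSynth)
      synth <- xm[base, , drop = FALSE] +
        u * (xm[mate, , drop = FALSE] - xm[base, , drop = FALSE])
    }
    majKeep <- if (targetMaj <= nMaj) {
      sample(majIdx, targetMaj)
    } else {
      c(majIdx, sample(majIdx, targetMaj - nMaj, replace = TRUE))
    }
    outX <- rbind(x[minIdx, , drop = FALSE], synth,
                  x[majKeep, , drop = FALSE])
    outY <- c(rep(minority, targetMin), rep(majority, targetMaj))
    list(x = outX, y = outY,
         synthetic = c(rep(FALSE, nMin), rep(TRUE, nSynth),
                       rep(FALSE, targetMaj)),
         counts = stats::setNames(c(targetMin, targetMaj),
                                  c(minority, majority)))
  })
}
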