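# Run code under a local RNG state: seeds reproducibly, restores the
# caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' All randomness in a pipeline run flows from one global seed; each stage
#' (and each repeat within a stage) gets a reproducible derived seed so any
#' stage can be re-run in isolation. Derived seeds stay below 2^31.
#'
#' @param seed integer global seed.
#' @param ... integer offsets identifying the stage (and repeat).
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  parts <- c(as.integer(seed), vapply(list(...), as.integer, integer(1)))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483629
  as.integer(h)
}
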