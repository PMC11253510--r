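#' Specification of a synthetic CyTOF study
#'
#' Defines the ground truth for generated references and patient cohorts:
#' well-separated cell-type clusters in arcsinh space over a backbone
#' panel, per-sample cell-type abundance variation, and planted directed
#' dependencies between signaling markers whose strength differs between
#' the short-term (STS) and long-term (LTS) survivor groups.
#'
#' Defaults mirror the shape of the motivating leukemia study: 7 cell
#' types, a 15-marker backbone, a 15-marker signaling panel, 28 STS and 15
#' LTS samples, and a 60-month survival cutoff. Type profiles are drawn at
#' a pairwise cosine similarity of at most \code{separationCap} (0.7) with
#' within-type standard deviation 0.2 in arcsinh space.
#'
#' @param nCellTypes number of cell types (default 7).
#' @param backboneDim backbone panel size (default 15).
#' @param signalingDim signaling panel size (default 15).
#' @param separationCap maximum pairwise cosine similarity between type
#'   profiles (default 0.7).
#' @param withinTypeSd within-type Gaussian sd on backbone markers
#'   (default 0.2).
#' @param signalingSd within-type sd on signaling markers (default 0.5).
#' @param cellsPerType reference cells per type (default 1000; at least
#'   300).
#' @param nSTS,nLTS cohort samples per survival group (defaults 28 and 15).
#' @param cellsPerSample cells per cohort sample (default 2000).
#' @param plantedPairs list of planted dependencies; each element a list
#'   with \code{cellType}, \code{x}, \code{y}, \code{betaSTS},
#'   \code{betaLTS}, \code{noiseSd} (and optional \code{shape} =
#'   \code{"linear"} or \code{"sigmoid"}). In affected cells, marker
#'   \code{y} is overwritten as a function of marker \code{x} with the
#'   group-specific coefficient plus Gaussian noise.
#' @param abundanceConcentration Dirichlet concentration per type
#'   controlling between-sample abundance variation (default 5).
#' @param monthsCutoff survival cutoff separating STS from LTS (default
#'   60 months).
#' @param seed integer seed; identical spec + seed reproduce outputs
#'   bit-identically.
#' @return an object of class \code{"SyntheticSpec"} (a validated list).
#' @export
syntheticSpec <- function(nCellTypes = 7L, backboneDim = 15L,
                          signalingDim = 15L, separationCap = 0.7,
                          withinTypeSd = 0.2, signalingSd = 0.5,
                          cellsPerType = 1000L, nSTS = 28L, nLTS = 15L,
                          cellsPerSample = 2000L, plantedPairs = list(),
                          abundanceConcentration = 5,
                          monthsCutoff = 60, seed = 1L) {
  stopifnot(nCellTypes >= 2L, backboneDim >= 2L, signalingDim >= 2L,
            separationCap > 0, withinTypeSd >= 0, cellsPerType >= 300L,
            nSTS >= 1L, nLTS >= 1L, cellsPerSample >= 1L)
  spec <- list(nCellTypes = as.integer(nCellTypes),
               backboneDim = as.integer(backboneDim),
               signalingDim = as.integer(signalingDim),
               separationCap = separationCap,
               withinTypeSd = withinTypeSd,
               signalingSd = signalingSd,
               cellsPerType = as.integer(cellsPerType),
               nSTS = as.integer(nSTS), nLTS = as.integer(nLTS),
               cellsPerSample = as.integer(cellsPerSample),
               plantedPairs = plantedPairs,
               abundanceConcentration = abundanceConcentration,
               monthsCutoff = monthsCutoff,
               seed = as.integer(seed))
  spec$cellTypes <- defaultCellTypes(spec$nCellTypes)
  spec$backboneMarkers <- defaultBackboneMarkers(spec$backboneDim)
  spec$signalingMarkers <- defaultSignalingMarkers(spec$signalingDim)
  for (p in plantedPairs) {
    if (!all(c("cellType", "x", "y", "betaSTS", "betaLTS") %in% names(p)))
      stop("each planted pair needs cellType, x, y, betaSTS, betaLTS")
    if (!p$cellType %in% spec$cellTypes)
      stop("planted pair cell type not in the generated types: ", p$cellType)
    if (!all(c(p$x, p$y) %in% spec$signalingMarkers))
      stop("planted pair markers must belong to the signaling panel")
    if (!is.finite(p$betaSTS) || !is.finite(p$betaLTS))
      stop("planted pair coefficients must be finite")
  }
  spec$typeProfiles <- generateTypeProfiles(spec)
  spec$signalingBase <- withSeed(deriveSeed(seed, 2L), {
    matrix(stats::runif(spec$nCellTypes * spec$signalingDim, 0.5, 2.5),
           spec$nCellTypes, spec$signalingDim,
           dimnames = list(spec$cellTypes, spec$signalingMarkers))
  })
  class(spec) <- "SyntheticSpec"
  spec
}

defaultCellTypes <- function(n) {
  canonical <- c("B", "CD4_T", "CD8_T", "HSC_MPP", "Monocytes", "NK", "pDC")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, paste0("Type", seq_len(n - length(canonical))))
}

defaultBackboneMarkers <- function(d) {
  canonical <- c("CD11b", "CD8a", "CD33", "CD34", "CD3", "CD123", "CD56",
                 "CD14", "CD117", "CD38", "CD4", "CD16", "CD20", "CD45",
                 "CD7")
  if (d <= length(canonical)) canonical[seq_len(d)]
  else c(canonical, paste0("BB", seq_len(d - length(canonical))))
}

defaultSignalingMarkers <- function(d) {
  canonical <- c("pAxl", "CyclinB1", "pNFkB", "pErk", "pSTAT1", "pP38",
                 "pSTAT3", "pCREB", "pHist3", "Casp3", "pSTAT5", "p4EBP1",
                 "pAkt", "pRB", "pS6")
  if (d <= length(canonical)) canonical[seq_len(d)]
  else c(canonical, paste0("SIG", seq_len(d - length(canonical))))
}

# Draw per-type backbone mean profiles until all pairwise cosine
# similarities respect the separation cap: each type expresses a random
# subset of markers highly (arcsinh ~3-4) and the rest at baseline.
generateTypeProfiles <- function(spec) {
  withSeed(deriveSeed(spec$seed, 1L), {
    for (attempt in seq_len(500L)) {
      profiles <- t(vapply(seq_len(spec$nCellTypes), function(i) {
        p <- stats::runif(spec$backboneDim, 0.1, 0.6)
        nHigh <- max(2L, round(spec$backboneDim / 3))
        hi <- sample.int(spec$backboneDim, nHigh)
        p[hi] <- stats::runif(nHigh, 2.5, 4)
        p
      }, numeric(spec$backboneDim)))
      norms <- sqrt(rowSums(profiles^2))
      cosines <- (profiles %*% t(profiles)) / outer(norms, norms)
      diag(cosines) <- 0
      if (max(cosines) <= spec$separationCap) {
        dimnames(profiles) <- list(spec$cellTypes, spec$backboneMarkers)
        return(profiles)
      }
    }
    stop("could not draw ", spec$nCellTypes, " type profiles at pairwise ",
         "cosine <= ", spec$separationCap, " in ", spec$backboneDim,
         " dimensions")
  })
}

# Draw cells of one type: backbone Gaussians around the profile plus
# signaling markers around the type's baseline, then planted overwrites.
drawCells <- function(spec, type, n, group = NULL) {
  bb <- matrix(stats::rnorm(n * spec$backboneDim,
                            mean = rep(spec$typeProfiles[type, ], each = n),
                            sd = spec$withinTypeSd),
               n, spec$backboneDim,
               dimnames = list(NULL, spec$backboneMarkers))
  sg <- matrix(stats::rnorm(n * spec$signalingDim,
                            mean = rep(spec$signalingBase[type, ], each = n),
                            sd = spec$signalingSd),
               n, spec$signalingDim,
               dimnames = list(NULL, spec$signalingMarkers))
  if (!is.null(group)) {
    for (p in spec$plantedPairs) {
      if (p$cellType != type) next
      beta <- if (group == "STS") p$betaSTS else p$betaLTS
      noiseSd <- p$noiseSd %||% 0.2
      xv <- sg[, p$x]
      f <- if (!is.null(p$shape) && p$shape == "sigmoid")
        2 / (1 + exp(-2 * (xv - mean(xv)))) else xv
      sg[, p$y] <- beta * f + stats::rnorm(n, sd = noiseSd)
    }
  }
  cbind(bb, sg)
}

#' Generate a synthetic annotated reference
#'
#' Draws \code{cellsPerType} cells per cell type from isotropic Gaussians
#' around the type profiles in arcsinh space (backbone markers; signaling
#' markers at their type baselines, no planted effects) and attaches the
#' generating labels. Every type meets the 300-cell reference filter by
#' construction.
#'
#' @param spec a [syntheticSpec()].
#' @return a \linkS4class{ReferenceSet}.
#' @examples
#' ref <- generateReference(syntheticSpec(cellsPerType = 300L, seed = 1))
#' cellTypeCounts(ref)
#' @export
generateReference <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(deriveSeed(spec$seed, 10L), {
    mats <- lapply(spec$cellTypes, function(ty)
      drawCells(spec, ty, spec$cellsPerType))
    m <- do.call(rbind, mats)
    labels <- rep(spec$cellTypes, each = spec$cellsPerType)
    referenceSet(cytoExpression(m, cellLabels = labels, transformed = TRUE),
                 minCellsFilter = 300L)
  })
}

#' Generate a synthetic patient cohort
#'
#' Per sample, cell-type abundances are drawn from a Dirichlet
#' distribution; cells are drawn as for the reference; for every planted
#' pair, in its cell type, the downstream marker is overwritten as the
#' group-specific function of the upstream marker plus Gaussian noise.
#' Survival months are drawn to respect the survival-cutoff rule for each
#' group (STS below the cutoff, LTS at or above it).
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{expression} (a pooled
#'   \linkS4class{CytoExpression} carrying true cell labels and sample
#'   ids) and \code{survival} (data.frame: sample_id, group,
#'   survival_months).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  minNeeded <- 200L
  if (spec$cellsPerSample / spec$nCellTypes < minNeeded)
    warning("cellsPerSample is low relative to the number of cell types; ",
            "samples may fall below the DREMI minimum-cell rule and be ",
            "masked downstream")
  nSamples <- spec$nSTS + spec$nLTS
  groups <- rep(c("STS", "LTS"), c(spec$nSTS, spec$nLTS))
  ids <- sprintf("S%02d", seq_len(nSamples))
  withSeed(deriveSeed(spec$seed, 20L), {
    months <- ifelse(groups == "STS",
                     stats::runif(nSamples, 1, spec$monthsCutoff - 1),
                     stats::runif(nSamples, spec$monthsCutoff,
                                  spec$monthsCutoff * 2.5))
    mats <- vector("list", nSamples)
    labs <- vector("list", nSamples)
    for (s in seq_len(nSamples)) {
      w <- stats::rgamma(spec$nCellTypes, spec$abundanceConcentration)
      counts <- as.integer(stats::rmultinom(1, spec$cellsPerSample,
                                            w / sum(w)))
      cells <- lapply(which(counts > 0), function(t)
        drawCells(spec, spec$cellTypes[t], counts[t], group = groups[s]))
      mats[[s]] <- do.call(rbind, cells)
      labs[[s]] <- rep(spec$cellTypes[counts > 0], counts[counts > 0])
    }
    expr <- cytoExpression(do.call(rbind, mats),
                           cellLabels = unlist(labs),
                           sampleIds = rep(ids, vapply(labs, length,
                                                       integer(1))),
                           transformed = TRUE)
    list(expression = expr,
         survival = data.frame(sample_id = ids, group = groups,
                               survival_months = months,
                               stringsAsFactors = FALSE))
  })
}

#' Machine-readable ground truth of a synthetic spec
#'
#' @param spec a [syntheticSpec()].
#' @return list (JSON-serialisable) with cell types, marker panels, type
#'   profiles, planted pairs with group effect sizes, and cohort shape.
#' @export
truthTable <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  list(cellTypes = spec$cellTypes,
       backboneMarkers = spec$backboneMarkers,
       signalingMarkers = spec$signalingMarkers,
       typeProfiles = apply(spec$typeProfiles, 1, as.list, simplify = FALSE),
       plantedPairs = lapply(spec$plantedPairs, function(p)
         list(cellType = p$cellType, x = p$x, y = p$y,
              betaSTS = p$betaSTS, betaLTS = p$betaLTS,
              noiseSd = p$noiseSd %||% 0.2,
              effectSize = abs(p$betaSTS - p$betaLTS))),
       nSTS = spec$nSTS, nLTS = spec$nLTS,
       cellsPerSample = spec$cellsPerSample,
       monthsCutoff = spec$monthsCutoff,
       seed = spec$seed)
}
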