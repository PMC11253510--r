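# Fixtures are built in code at test time; nothing binary is stored.

# Two (or more) well-separated Gaussian blobs.
makeBlobs <- function(n = 200, centers = list(c(0, 0), c(5, 5)), sd = 0.3,
                      seed = 1) {
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(centers, function(ce)
      matrix(stats::rnorm(n * length(ce), mean = rep(ce, each = n),
                          sd = sd), n, length(ce))))
    colnames(m) <- paste0("m", seq_along(centers[[1]]))
    list(m = m, labels = rep(paste0("blob", seq_along(centers)), each = n))
  })
}

# Labelled reference matrix with given per-type counts around given means.
makeReference <- function(counts, means, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    types <- names(counts)
    m <- do.call(rbind, lapply(types, function(ty)
      matrix(stats::rnorm(counts[[ty]] * length(means[[ty]]),
                          mean = rep(means[[ty]], each = counts[[ty]]),
                          sd = sd),
             counts[[ty]], length(means[[ty]]))))
    colnames(m) <- paste0("bb", seq_along(means[[1]]))
    referenceSet(m, cellLabels = rep(types, unlist(counts)))
  })
}

# Write a minimal FCS 3.0 file (list mode, 32-bit float, little endian).
# Independent of the package reader: built straight from the standard's
# layout so read-back is a genuine round trip.
writeTinyFCS <- function(path, m) {
  nPar <- ncol(m); nTot <- nrow(m)
  dataLen <- 4L * nPar * nTot
  parText <- paste0(vapply(seq_len(nPar), function(i)
    sprintf("$P%dN/%s/$P%dB/32/$P%dE/0,0/$P%dR/262144/",
            i, colnames(m)[i], i, i, i), character(1)), collapse = "")
  text <- sprintf(paste0("/$BEGINDATA/%8d/$ENDDATA/%8d/$TOT/%d/$PAR/%d/",
                         "$MODE/L/$DATATYPE/F/$BYTEORD/1,2,3,4/",
                         "$NEXTDATA/0/%s"),
                  0L, 0L, nTot, nPar, parText)
  textStart <- 58L
  textEnd <- textStart + nchar(text) - 1L
  dataStart <- textEnd + 1L
  dataEnd <- dataStart + dataLen - 1L
  text <- sprintf(paste0("/$BEGINDATA/%8d/$ENDDATA/%8d/$TOT/%d/$PAR/%d/",
                         "$MODE/L/$DATATYPE/F/$BYTEORD/1,2,3,4/",
                         "$NEXTDATA/0/%s"),
                  dataStart, dataEnd, nTot, nPar, parText)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textStart, textEnd, dataStart, dataEnd, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

# Independent brute-force DREMI on a discrete coarse joint: direct
# summation of sum_x w sum_y p(y|x) log2(p(y|x)/q(y)).
bruteForceConditionalMI <- function(joint, minColumnMass = 0.01) {
  joint <- joint / sum(joint)
  nc <- nrow(joint)
  keep <- which(rowSums(joint) >= minColumnMass / nc)
  w <- 1 / length(keep)
  p <- joint[keep, , drop = FALSE] / rowSums(joint[keep, , drop = FALSE])
  q <- colSums(p) / length(keep)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) total <- total + w * p[i, j] * log2(p[i, j] / q[j])
  total
}
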