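#' Read a cells-by-markers expression matrix
#'
#' Reads single-cell expression data from an FCS 3.0/3.1 file or from
#' delimited text with a header row of marker names. The reserved delimited
#' columns \code{__label__} and \code{__sample__} are split off into
#' per-cell labels and sample ids. Values are returned raw
#' (\code{transformed = FALSE}); apply [arcsinhTransform()] afterwards.
#'
#' @param path path to the input file.
#' @param format \code{"fcs"}, \code{"csv"} or \code{"tsv"}; default guessed
#'   from the file extension.
#' @return a \linkS4class{CytoExpression}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(CD3 = 1:3, CD34 = 4:6), f, row.names = FALSE)
#' readExpression(f)
#' @export
readExpression <- function(path, format = c("auto", "fcs", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fcs = "fcs", tsv = "tsv", txt = "tsv", csv = "csv",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (format == "fcs") return(readFCS(path))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("file contains no cells: ", path)
  labels <- NULL
  samples <- NULL
  if ("__label__" %in% names(df)) {
    labels <- as.character(df[["__label__"]])
    df[["__label__"]] <- NULL
  }
  if ("__sample__" %in% names(df)) {
    samples <- as.character(df[["__sample__"]])
    df[["__sample__"]] <- NULL
  }
  nonnum <- !vapply(df, is.numeric, logical(1))
  if (any(nonnum)) {
    col <- which(nonnum)[1]
    vals <- suppressWarnings(as.numeric(as.character(df[[col]])))
    row <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value in column '%s' (row %s)",
                 names(df)[col], ifelse(is.na(row), "?", row)))
  }
  if (anyDuplicated(names(df)))
    stop("duplicate marker names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  cytoExpression(as.matrix(df), cellLabels = labels, sampleIds = samples)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [readExpression()] for the delimited formats; labels and
#' sample ids, when present, are written to the reserved columns
#' \code{__label__} and \code{__sample__}. Full precision is preserved
#' (round-trip agreement to 1e-9 or better).
#'
#' @param object a \linkS4class{CytoExpression}.
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(object, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(object@exprs, check.names = FALSE)
  if (length(object@cellLabels)) df[["__label__"]] <- object@cellLabels
  if (length(object@sampleIds)) df[["__sample__"]] <- object@sampleIds
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal read-only FCS 3.0/3.1 parser: HEADER offsets, TEXT keyword
# segment, list-mode DATA with $DATATYPE F or D. Compensation, analysis
# segments and integer data types are out of scope.
readFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version or not an FCS file: ",
         substr(header, 1, 6))
  off <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(header, a, b))))
    if (is.na(v)) stop("malformed FCS header in ", path)
    v
  }
  textStart <- off(11, 18); textEnd <- off(19, 26)
  seek(con, textStart)
  textRaw <- readBin(con, "raw", textEnd - textStart + 1)
  delim <- rawToChar(textRaw[1])
  fields <- strsplit(rawToChar(textRaw[-1]), delim, fixed = TRUE)[[1]]
  if (length(fields) %% 2 == 1) fields <- fields[-length(fields)]
  kw <- stats::setNames(fields[seq(2, length(fields), 2)],
                        toupper(trimws(fields[seq(1, length(fields), 2)])))
  need <- function(k) {
    if (!k %in% names(kw)) stop("FCS file missing keyword ", k)
    unname(kw[k])
  }
  nEvents <- as.integer(need("$TOT"))
  nPar <- as.integer(need("$PAR"))
  if (is.na(nEvents) || nEvents == 0L)
    stop("FCS file contains 0 events: ", path)
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "' (only F and D)")
  byteOrd <- need("$BYTEORD")
  endian <- if (byteOrd %in% c("1,2,3,4", "1,2")) "little" else "big"
  if (toupper(need("$MODE")) != "L")
    stop("only list-mode ($MODE L) FCS data is supported")
  # marker names: prefer $PnS (stain) over $PnN (short name)
  markers <- vapply(seq_len(nPar), function(i) {
    s <- unname(kw[paste0("$P", i, "S")])
    n <- unname(kw[paste0("$P", i, "N")])
    v <- if (!is.na(s) && nzchar(trimws(s))) s else n
    if (is.na(v)) paste0("P", i) else trimws(v)
  }, character(1))
  dataStart <- suppressWarnings(as.numeric(trimws(kw["$BEGINDATA"])))
  if (is.na(dataStart) || dataStart == 0) dataStart <- off(27, 34)
  size <- if (dtype == "F") 4L else 8L
  seek(con, dataStart)
  vals <- readBin(con, "double", n = nEvents * nPar, size = size,
                  endian = endian)
  if (length(vals) < nEvents * nPar)
    stop("truncated FCS data segment in ", path)
  m <- matrix(vals, nrow = nEvents, ncol = nPar, byrow = TRUE)
  if (anyDuplicated(markers))
    stop("duplicate marker names in FCS file: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  colnames(m) <- markers
  cytoExpression(m)
}

#' Read a sample-level survival table
#'
#' Delimited text with columns \code{sample_id}, and at least one of
#' \code{group} (\code{"STS"}/\code{"LTS"}) and \code{survival_months}.
#' When only months are given, groups are derived from the 60-month rule
#' (survival of 60 months or more after diagnosis is long-term, LTS); when
#' both are given, consistency with that rule is enforced. Any further
#' columns (e.g. mutation status) are kept as covariates.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; default guessed from the extension.
#' @param monthsCutoff survival cutoff in months separating short- from
#'   long-term survivors (default 60).
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{survival_months} and any covariates.
#' @export
readSurvivalTable <- function(path, sep = NULL, monthsCutoff = 60) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("survival table needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_ids in survival table")
  df$sample_id <- as.character(df$sample_id)
  hasGroup <- "group" %in% names(df)
  hasMonths <- "survival_months" %in% names(df)
  if (!hasGroup && !hasMonths)
    stop("survival table needs 'group' and/or 'survival_months'")
  if (hasMonths && any(df$survival_months < 0, na.rm = TRUE))
    stop("survival_months must be non-negative")
  if (!hasGroup)
    df$group <- ifelse(df$survival_months >= monthsCutoff, "LTS", "STS")
  if (!all(df$group %in% c("STS", "LTS")))
    stop("group must be 'STS' or 'LTS'")
  if (hasGroup && hasMonths) {
    expect <- ifelse(df$survival_months >= monthsCutoff, "LTS", "STS")
    bad <- which(df$group != expect)
    if (length(bad))
      stop("group inconsistent with the ", monthsCutoff,
           "-month rule for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  df
}

#' Read a panel configuration
#'
#' Accepts a YAML or JSON file with keys \code{backbone}, \code{signaling},
#' \code{alias_map} (raw name to canonical name) and
#' \code{arcsinh_cofactor}.
#'
#' @param path path to a YAML (.yaml/.yml) or JSON (.json) file.
#' @return a \linkS4class{PanelConfig}.
#' @export
readPanelConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("panel config must be YAML or JSON")
  alias <- character(0)
  if (!is.null(cfg$alias_map) && length(cfg$alias_map))
    alias <- stats::setNames(unlist(cfg$alias_map), names(cfg$alias_map))
  panelConfig(backbone = unlist(cfg$backbone) %||% character(0),
              signaling = unlist(cfg$signaling) %||% character(0),
              aliasMap = alias,
              arcsinhCofactor = cfg$arcsinh_cofactor %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
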