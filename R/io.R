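#' @importFrom data.table fread fwrite as.data.table
NULL

#' Read and write beta-value matrices
#'
#' Beta matrices travel as delimited text (CSV/TSV autodetected) with a
#' header row: the first column holds probe ids, the remaining columns one
#' sample each. Values must lie in \[0, 1\] or be missing; a write followed
#' by a read reproduces the matrix exactly for text-representable numbers.
#'
#' @param path File to read or write.
#' @param x Probes x samples numeric matrix with dimnames.
#' @return `readBetaMatrix` returns the matrix; `writeBetaMatrix` returns
#'   `path` invisibly.
#' @export
readBetaMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = TRUE, data.table = TRUE)
  if (ncol(dt) < 2L) stop("beta matrix needs a probe id column plus samples")
  probes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  if (anyDuplicated(probes)) stop("duplicate probe ids in ", path)
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(m))
    stop(sprintf("beta values outside [0, 1] in %d cell(s): %s",
                 length(bad),
                 paste(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]],
                       sep = "/", collapse = ", ")))
  }
  m
}

#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(x, path) {
  x <- .betaOf(x)
  dt <- data.table::data.table(probe_id = rownames(x))
  dt <- cbind(dt, as.data.table(x))
  fwrite(dt, path)
  invisible(path)
}

#' Read and write probe manifests
#'
#' Flat CSV/TSV with columns `probe_id`, `base_cpg`, `version`,
#' `replicate_index`; validated on read (see [validateProbeManifest()]).
#'
#' @param path File to read or write.
#' @param manifest Manifest data.frame.
#' @return The manifest data.frame / `path` invisibly.
#' @export
readProbeManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateProbeManifest(fread(path, header = TRUE, data.table = FALSE))
}

#' @rdname readProbeManifest
#' @export
writeProbeManifest <- function(manifest, path) {
  fwrite(as.data.table(validateProbeManifest(manifest)), path)
  invisible(path)
}

#' Read and write sample sheets
#'
#' Flat CSV/TSV with one row per array; validated on read (see
#' [validateSampleSheet()]). Empty `replicate_of` cells are read as NA.
#'
#' @param path File to read or write.
#' @param sheet Sample sheet data.frame.
#' @return The sheet data.frame / `path` invisibly.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- fread(path, header = TRUE, data.table = FALSE,
                 colClasses = list(character = "replicate_of"))
  validateSampleSheet(sheet)
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
  fwrite(as.data.table(validateSampleSheet(sheet)), path)
  invisible(path)
}

#' Read companion QC matrices
#'
#' Detection p-values and bead counts use the same probes x samples layout
#' as the beta matrix and must match its shape when combined into a
#' [MethylationSet-class].
#'
#' @param detectionPPath,beadcountPath Files holding the two matrices
#'   (either may be NULL).
#' @return List with elements `detectionP` and `beadcount` (NULL when not
#'   supplied).
#' @export
readQCMatrices <- function(detectionPPath = NULL, beadcountPath = NULL) {
  readOne <- function(path, lo, hi, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- fread(path, header = TRUE, data.table = TRUE)
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(dt[[1L]])
    if (any(!is.na(m) & (m < lo | m > hi)))
      stop(what, " values out of range in ", path)
    m
  }
  list(detectionP = readOne(detectionPPath, 0, 1, "detection p"),
       beadcount = readOne(beadcountPath, 0, Inf, "beadcount"))
}

#' Read and write coefficient-set files
#'
#' Coefficient files are CSV with metadata header lines of the form
#' `#key=value` (keys `name`, `transform`, `adult_age`), followed by a
#' table with columns `base_cpg`, `weight` and optionally
#' `reference_mean`. The reserved row `(Intercept)` carries the intercept.
#'
#' @param path File to read or write.
#' @param coef A [CoefficientSet-class].
#' @return `readCoefficientSet` returns a [CoefficientSet-class];
#'   `writeCoefficientSet` returns `path` invisibly.
#' @export
readCoefficientSet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list(name = "score", transform = "identity", adult_age = "20")
  for (ln in metaLines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  tab <- fread(text = lines[!startsWith(lines, "#")], header = TRUE,
               data.table = FALSE)
  if (!all(c("base_cpg", "weight") %in% names(tab)))
    stop("coefficient file is missing required column(s): ",
         paste(setdiff(c("base_cpg", "weight"), names(tab)), collapse = ", "))
  ic <- tab$base_cpg == "(Intercept)"
  intercept <- if (any(ic)) tab$weight[ic][1L] else 0
  w <- tab$weight[!ic]
  names(w) <- tab$base_cpg[!ic]
  rm <- numeric()
  if ("reference_mean" %in% names(tab)) {
    rm <- tab$reference_mean[!ic]
    names(rm) <- tab$base_cpg[!ic]
    rm <- rm[!is.na(rm)]
  }
  CoefficientSet(name = meta$name, weights = w, intercept = intercept,
                 transform = meta$transform,
                 adultAge = as.numeric(meta$adult_age), referenceMeans = rm)
}

#' @rdname readCoefficientSet
#' @export
writeCoefficientSet <- function(coef, path) {
  stopifnot(is(coef, "CoefficientSet"))
  hdr <- c(sprintf("#name=%s", coef@name),
           sprintf("#transform=%s", coef@transform),
           sprintf("#adult_age=%s", format(coef@adultAge, digits = 15)))
  tab <- data.frame(base_cpg = c("(Intercept)", names(coef@weights)),
                    weight = c(coef@intercept, unname(coef@weights)))
  if (length(coef@referenceMeans)) {
    tab$reference_mean <- c(NA_real_,
                            unname(coef@referenceMeans[names(coef@weights)]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write cell-type reference libraries
#'
#' CSV with probe ids in the first column and one cell type per remaining
#' column, holding mean beta values of purified populations.
#'
#' @param path File to read or write.
#' @param ref A [CellTypeReference-class].
#' @return A [CellTypeReference-class] / `path` invisibly.
#' @export
readCellTypeReference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = TRUE, data.table = TRUE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1L]])
  CellTypeReference(m)
}

#' @rdname readCellTypeReference
#' @export
writeCellTypeReference <- function(ref, path) {
  m <- referenceMeans(ref)
  dt <- data.table::data.table(probe_id = rownames(m))
  fwrite(cbind(dt, as.data.table(m)), path)
  invisible(path)
}
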