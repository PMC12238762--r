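#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

## Column sets required of the per-array sample sheet and per-probe manifest.
.SHEET_COLS <- c("sample_id", "donor_id", "version", "cohort", "sex", "age",
                 "chip", "row", "facility", "replicate_of")
.MANIFEST_COLS <- c("probe_id", "base_cpg", "version", "replicate_index")
.VERSIONS <- c("v1", "v2")

#' MethylationSet: beta values with probe and sample annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' probes x samples matrix of methylation beta values (assay `"beta"`,
#' fractions in \[0, 1\]), optional QC assays `"detectionP"` and
#' `"beadcount"` of the same shape, per-probe manifest columns in
#' `rowData()` (`probe_id`, `base_cpg`, `version`, `replicate_index`) and
#' the per-array sample sheet in `colData()` (`sample_id`, `donor_id`,
#' `version`, `cohort`, `sex`, `age`, `chip`, `row`, `facility`,
#' `replicate_of`).
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @aliases MethylationSet
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- which(!is.na(b) & (b < 0 | b > 1))
    if (length(bad)) {
      idx <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(b))
      cells <- paste(rownames(b)[idx[, 1L]], colnames(b)[idx[, 2L]],
                     sep = "/", collapse = ", ")
      msg <- c(msg, sprintf(
        "beta values outside [0, 1] in %d cell(s), e.g. %s",
        length(bad), cells))
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param beta Numeric probes x samples matrix of beta values in \[0, 1\]
#'   (NA permitted). Row and column names are the probe and sample ids.
#' @param manifest Optional probe manifest `data.frame` with columns
#'   `probe_id`, `base_cpg`, `version`, `replicate_index`; matched to the
#'   rows of `beta` by `probe_id`.
#' @param sampleSheet Optional sample sheet `data.frame` with columns
#'   `sample_id`, `donor_id`, `version`, `cohort`, `sex`, `age`, `chip`,
#'   `row`, `facility`, `replicate_of`; matched to the columns of `beta` by
#'   `sample_id`.
#' @param detectionP,beadcount Optional QC matrices with the same dimnames
#'   as `beta` (detection p-values in \[0, 1\]; non-negative bead counts).
#' @return A [MethylationSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' MethylationSet(b)
#' @export
MethylationSet <- function(beta, manifest = NULL, sampleSheet = NULL,
                           detectionP = NULL, beadcount = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe row names and sample column names")
  assays <- list(beta = beta)
  for (nm in c("detectionP", "beadcount")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (!identical(dim(m), dim(beta)))
        stop(sprintf("'%s' must have the same shape as beta", nm))
      dimnames(m) <- dimnames(beta)
      assays[[nm]] <- m
    }
  }
  rd <- if (is.null(manifest)) {
    DataFrame(probe_id = rownames(beta), row.names = rownames(beta))
  } else {
    manifest <- validateProbeManifest(manifest)
    if (!all(rownames(beta) %in% manifest$probe_id))
      stop("manifest does not cover all probes of the beta matrix")
    DataFrame(manifest[match(rownames(beta), manifest$probe_id), ,
                       drop = FALSE],
              row.names = rownames(beta))
  }
  cd <- if (is.null(sampleSheet)) {
    DataFrame(sample_id = colnames(beta), row.names = colnames(beta))
  } else {
    sampleSheet <- validateSampleSheet(sampleSheet)
    if (!all(colnames(beta) %in% sampleSheet$sample_id))
      stop("sample sheet does not cover all samples of the beta matrix")
    DataFrame(sampleSheet[match(colnames(beta), sampleSheet$sample_id), ,
                          drop = FALSE],
              row.names = colnames(beta))
  }
  new("MethylationSet",
      SummarizedExperiment(assays = assays, rowData = rd, colData = cd))
}

#' Accessors for MethylationSet components
#'
#' `betaValues()` returns the beta assay; `detectionP()` and `beadCount()`
#' the QC assays (or NULL when absent); `probeManifest()` and
#' `sampleSheet()` the row/column annotation as plain data frames.
#'
#' @param x A [MethylationSet-class].
#' @return See description.
#' @export
betaValues <- function(x) assay(x, "beta")

#' @rdname betaValues
#' @export
detectionP <- function(x) {
  if ("detectionP" %in% assayNames(x)) assay(x, "detectionP") else NULL
}

#' @rdname betaValues
#' @export
beadCount <- function(x) {
  if ("beadcount" %in% assayNames(x)) assay(x, "beadcount") else NULL
}

#' @rdname betaValues
#' @export
probeManifest <- function(x) as.data.frame(rowData(x))

#' @rdname betaValues
#' @export
sampleSheet <- function(x) as.data.frame(colData(x))

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet:", nrow(object), "probes x", ncol(object), "samples\n")
  v <- colData(object)$version
  if (!is.null(v)) {
    tb <- table(v)
    cat("  arrays per version:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' HarmonizedPair: version-aligned beta matrices on shared base CpGs
#'
#' Holds one [MethylationSet-class] per array version with identical probe
#' (base CpG) order, plus the probes unique to either version that were
#' dropped during harmonization.
#'
#' @slot v1,v2 Aligned [MethylationSet-class] objects.
#' @slot v1Only,v2Only Character vectors of base CpGs present on only one
#'   version.
#' @export
setClass("HarmonizedPair",
         representation(v1 = "MethylationSet", v2 = "MethylationSet",
                        v1Only = "character", v2Only = "character"))

setValidity("HarmonizedPair", function(object) {
  if (!identical(rownames(object@v1), rownames(object@v2)))
    return("v1 and v2 probe orders differ")
  TRUE
})

#' @describeIn HarmonizedPair-class The aligned v1 arrays.
#' @param x A `HarmonizedPair`.
#' @export
pairV1 <- function(x) x@v1

#' @describeIn HarmonizedPair-class The aligned v2 arrays.
#' @export
pairV2 <- function(x) x@v2

#' @describeIn HarmonizedPair-class Base CpGs dropped from each version
#'   (list with elements `v1_only`, `v2_only`).
#' @export
versionOnlyProbes <- function(x) list(v1_only = x@v1Only, v2_only = x@v2Only)

setMethod("show", "HarmonizedPair", function(object) {
  cat("HarmonizedPair:", nrow(object@v1), "shared base CpGs;",
      ncol(object@v1), "v1 +", ncol(object@v2), "v2 arrays\n")
  cat("  dropped:", length(object@v1Only), "v1-only,",
      length(object@v2Only), "v2-only probes\n")
})

#' CellTypeReference: mean methylation profiles of purified cell types
#'
#' Reference library for constrained-projection deconvolution: a probes x
#' cell-types matrix of mean beta values for purified cell populations.
#'
#' @slot means Numeric probes x cell-types matrix in \[0, 1\].
#' @export
setClass("CellTypeReference", representation(means = "matrix"))

setValidity("CellTypeReference", function(object) {
  m <- object@means
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "means must carry probe row names and cell-type columns")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "cell-type labels must be unique")
  if (anyNA(m)) msg <- c(msg, "reference means must not be missing")
  if (any(m < 0 | m > 1)) msg <- c(msg, "reference means must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellTypeReference-class Constructor.
#' @param means Probes x cell-types matrix of mean beta values.
#' @export
CellTypeReference <- function(means) new("CellTypeReference",
                                         means = as.matrix(means))

#' @describeIn CellTypeReference-class The probes x cell-types mean matrix.
#' @param x A `CellTypeReference`.
#' @export
referenceMeans <- function(x) x@means

#' @describeIn CellTypeReference-class Cell-type labels.
#' @export
cellTypes <- function(x) colnames(x@means)

setMethod("show", "CellTypeReference", function(object) {
  cat("CellTypeReference:", nrow(object@means), "probes x",
      ncol(object@means), "cell types\n")
  cat("  cell types:", paste(colnames(object@means), collapse = ", "), "\n")
})

#' CoefficientSet: a named linear CpG score
#'
#' A published-style linear predictor over CpG beta values: intercept plus a
#' CpG -> weight map, with an output transform tag. `transform` is one of
#' `"identity"` (biomarker scores, most clocks), `"horvath_antilog"` (the
#' piecewise age anti-transform with knot at `adultAge`), or
#' `"equal_weight_mean"` (mitotic-clock style: plain mean beta over the CpG
#' set, ignoring intercept and weight magnitudes). Optional
#' `referenceMeans` carry training-set mean beta values used to impute
#' missing CpGs.
#'
#' @slot name Score label.
#' @slot intercept Intercept of the linear predictor.
#' @slot weights Named numeric vector, base CpG -> weight.
#' @slot transform Output transform tag.
#' @slot adultAge Knot (years) of the `horvath_antilog` transform.
#' @slot referenceMeans Named numeric vector of training mean beta values
#'   (possibly empty).
#' @export
setClass("CoefficientSet",
         representation(name = "character", intercept = "numeric",
                        weights = "numeric", transform = "character",
                        adultAge = "numeric", referenceMeans = "numeric"))

setValidity("CoefficientSet", function(object) {
  msg <- character()
  if (!length(object@weights) || is.null(names(object@weights)))
    msg <- c(msg, "weights must be a non-empty named vector")
  if (!object@transform %in% c("identity", "horvath_antilog",
                               "equal_weight_mean"))
    msg <- c(msg, "unknown transform")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoefficientSet-class Constructor.
#' @param name,intercept,weights,transform,adultAge,referenceMeans See slots.
#' @export
CoefficientSet <- function(name, weights, intercept = 0,
                           transform = "identity", adultAge = 20,
                           referenceMeans = numeric()) {
  new("CoefficientSet", name = name, intercept = intercept,
      weights = weights, transform = transform, adultAge = adultAge,
      referenceMeans = referenceMeans)
}

#' @describeIn CoefficientSet-class CpG -> weight map.
#' @param x A `CoefficientSet`.
#' @export
scoreWeights <- function(x) x@weights

#' @describeIn CoefficientSet-class Score label.
#' @export
scoreName <- function(x) x@name

setMethod("show", "CoefficientSet", function(object) {
  cat("CoefficientSet '", object@name, "': ", length(object@weights),
      " CpGs, intercept ", signif(object@intercept, 4),
      ", transform ", object@transform, "\n", sep = "")
  if (length(object@referenceMeans))
    cat("  reference means available for imputation\n")
})

## -- shared table validators ------------------------------------------------

#' Validate a probe manifest table
#'
#' Checks the column contract of the per-probe manifest: unique `probe_id`,
#' `version` in {v1, v2}, v1 probes carrying `replicate_index` 1, v2
#' replicate probes of one base CpG carrying distinct indices, and at most
#' 10 replicates per base CpG.
#'
#' @param manifest A data.frame.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validateProbeManifest <- function(manifest) {
  manifest <- as.data.frame(manifest)
  miss <- setdiff(.MANIFEST_COLS, names(manifest))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("manifest probe_id values must be unique")
  if (!all(manifest$version %in% .VERSIONS))
    stop("manifest version must be one of: ", paste(.VERSIONS, collapse = ", "))
  v1 <- manifest$version == "v1"
  if (any(manifest$replicate_index[v1] != 1L))
    stop("v1 probes must all have replicate_index 1")
  v2 <- manifest[!v1, , drop = FALSE]
  if (nrow(v2)) {
    sp <- split(v2$replicate_index, v2$base_cpg)
    if (any(vapply(sp, anyDuplicated, 0L) > 0L))
      stop("v2 replicate probes of one base CpG must have distinct indices")
    if (any(lengths(sp) > 10L))
      stop("more than 10 replicate probes for one base CpG")
  }
  manifest
}

#' Validate a sample sheet table
#'
#' Checks unique `sample_id`, `version` in {v1, v2}, non-negative ages, and
#' that `replicate_of` (when set) names another array of the same donor.
#'
#' @param sheet A data.frame.
#' @return The validated data.frame.
#' @export
validateSampleSheet <- function(sheet) {
  sheet <- as.data.frame(sheet)
  miss <- setdiff(.SHEET_COLS, names(sheet))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet sample_id values must be unique")
  if (!all(sheet$version %in% .VERSIONS))
    stop("sample sheet version must be one of: ",
         paste(.VERSIONS, collapse = ", "))
  if (any(!is.na(sheet$age) & sheet$age < 0))
    stop("age must be non-negative")
  ro <- sheet$replicate_of
  ro[!is.na(ro) & ro == ""] <- NA
  sheet$replicate_of <- ro
  set <- !is.na(ro)
  if (any(set)) {
    src <- match(ro[set], sheet$sample_id)
    if (anyNA(src))
      stop("replicate_of names unknown sample id(s): ",
           paste(ro[set][is.na(src)], collapse = ", "))
    if (any(sheet$donor_id[src] != sheet$donor_id[set]))
      stop("replicate_of must point to an array of the same donor")
  }
  sheet
}
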