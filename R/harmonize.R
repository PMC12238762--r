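#' Flag probes of poor technical quality
#'
#' A probe is flagged when its detection p-value exceeds `pThresh` or its
#' beadcount falls below `beadThresh` in more than `sampleFrac` of the
#' samples (strictly greater; with 100 samples, failing in exactly one is
#' tolerated, failing in two is not). Flagged probes are reported, not
#' removed: downstream analyses retain the full probe set and the flag list
#' travels as an annotation.
#'
#' @param x A [MethylationSet-class] carrying `detectionP`/`beadcount`
#'   assays, or NULL when the matrices are passed directly.
#' @param detectionP,beadcount Optional probes x samples matrices overriding
#'   the assays of `x`; either may be NULL, in which case that criterion is
#'   skipped.
#' @param pThresh Detection p-value ceiling (default 0.01).
#' @param beadThresh Minimum acceptable beadcount (default 3).
#' @param sampleFrac Tolerated fraction of failing samples (default 0.01).
#' @return Character vector of flagged probe ids.
#' @export
flagLowQualityProbes <- function(x = NULL, detectionP = NULL,
                                 beadcount = NULL, pThresh = 0.01,
                                 beadThresh = 3, sampleFrac = 0.01) {
  if (!is.null(x)) {
    if (is.null(detectionP)) detectionP <- methCompare::detectionP(x)
    if (is.null(beadcount)) beadcount <- beadCount(x)
  }
  if (is.null(detectionP) && is.null(beadcount))
    stop("need at least one of detectionP or beadcount")
  n <- ncol(if (!is.null(detectionP)) detectionP else beadcount)
  if (is.null(n) || n == 0L) stop("empty sample set")
  flagged <- character()
  if (!is.null(detectionP)) {
    frac <- rowSums(detectionP > pThresh, na.rm = TRUE) / ncol(detectionP)
    flagged <- c(flagged, rownames(detectionP)[frac > sampleFrac])
  }
  if (!is.null(beadcount)) {
    frac <- rowSums(beadcount < beadThresh, na.rm = TRUE) / ncol(beadcount)
    flagged <- c(flagged, rownames(beadcount)[frac > sampleFrac])
  }
  sort(unique(flagged))
}

#' Collapse v2 replicate probes to one row per base CpG
#'
#' EPICv2 carries a few thousand probes with 2-10 replicates per base CpG.
#' Three collapsing strategies are supported: `"detp"` selects, per base
#' CpG, the replicate row whose mean detection p-value across samples is
#' lowest (the representative-probe rule; ties broken by lowest replicate
#' index); `"mean"` and `"median"` aggregate the replicate rows
#' element-wise. Base CpGs measured by a single probe pass through
#' unchanged. The result is keyed by base CpG.
#'
#' @param x A v2 [MethylationSet-class] whose rowData holds the manifest,
#'   or a plain beta matrix (then `manifest` is required).
#' @param manifest Probe manifest covering all rows of `x` (ignored when
#'   `x` is a MethylationSet).
#' @param detectionP Probes x samples detection p-values; required for
#'   `strategy = "detp"` when `x` carries no `detectionP` assay.
#' @param strategy One of `"detp"`, `"mean"`, `"median"`.
#' @return An object of the same kind as `x`, with one row per base CpG.
#'   QC assays follow the selected row (`detp`) or are averaged
#'   (`mean`/`median`).
#' @export
collapseReplicateProbes <- function(x, manifest = NULL, detectionP = NULL,
                                    strategy = c("detp", "mean", "median")) {
  strategy <- match.arg(strategy)
  isSet <- is(x, "SummarizedExperiment")
  beta <- .betaOf(x)
  if (isSet) {
    manifest <- probeManifest(x)
    if (is.null(detectionP)) detectionP <- methCompare::detectionP(x)
  }
  if (is.null(manifest)) stop("a probe manifest is required")
  manifest <- validateProbeManifest(manifest)
  if (!all(rownames(beta) %in% manifest$probe_id))
    stop("manifest does not cover all probes of the beta matrix")
  if (strategy == "detp" && is.null(detectionP))
    stop("strategy 'detp' requires detection p-values")
  mi <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]

  grp <- factor(mi$base_cpg, levels = unique(mi$base_cpg))
  nPer <- tabulate(grp)
  if (strategy == "detp") {
    meanP <- rowMeans(detectionP[rownames(beta), , drop = FALSE],
                      na.rm = TRUE)
    ord <- order(as.integer(grp), meanP, mi$replicate_index)
    keep <- ord[!duplicated(as.integer(grp)[ord])]
    keep <- sort(keep)   # preserve input probe order
    out <- beta[keep, , drop = FALSE]
    rownames(out) <- as.character(mi$base_cpg[keep])
    keepIdx <- keep
  } else {
    fun <- if (strategy == "mean") {
      function(v) mean(v, na.rm = TRUE)
    } else {
      function(v) stats::median(v, na.rm = TRUE)
    }
    single <- nPer[as.integer(grp)] == 1L
    outList <- vector("list", nlevels(grp))
    multiLevels <- which(nPer > 1L)
    out <- matrix(NA_real_, nlevels(grp), ncol(beta),
                  dimnames = list(levels(grp), colnames(beta)))
    out[as.integer(grp)[single], ] <- beta[single, , drop = FALSE]
    for (g in multiLevels) {
      rows <- which(as.integer(grp) == g)
      out[g, ] <- apply(beta[rows, , drop = FALSE], 2L, fun)
    }
    out[is.nan(out)] <- NA_real_
    keepIdx <- NULL
  }

  if (!isSet) return(out)

  collapseQC <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.null(keepIdx)) {
      q <- m[keepIdx, , drop = FALSE]
    } else {
      q <- rowsum(m, group = grp, na.rm = TRUE) /
        rowsum((!is.na(m)) * 1, group = grp)
      q <- q[levels(grp), , drop = FALSE]
    }
    rownames(q) <- rownames(out)
    q
  }
  newManifest <- data.frame(probe_id = rownames(out),
                            base_cpg = rownames(out),
                            version = "v2", replicate_index = 1L)
  MethylationSet(out, manifest = newManifest, sampleSheet = sampleSheet(x),
                 detectionP = collapseQC(detectionP),
                 beadcount = collapseQC(beadCount(x)))
}

#' Align two beta matrices on their shared base CpGs
#'
#' Both inputs must already be keyed by base CpG (collapse v2 replicate
#' probes first). The output pair shares an identical probe order, the
#' sorted intersection; probes unique to either version are recorded in the
#' side report rather than silently dropped.
#'
#' @param v1,v2 [MethylationSet-class] objects (or beta matrices) keyed by
#'   base CpG.
#' @return A [HarmonizedPair-class]. When both inputs are plain matrices, a
#'   list with elements `v1`, `v2`, `v1_only`, `v2_only` instead.
#' @export
harmonizeSharedProbes <- function(v1, v2) {
  b1 <- .betaOf(v1)
  b2 <- .betaOf(v2)
  shared <- sort(intersect(rownames(b1), rownames(b2)))
  if (!length(shared)) stop("no shared base CpGs between the two versions")
  v1Only <- sort(setdiff(rownames(b1), shared))
  v2Only <- sort(setdiff(rownames(b2), shared))
  if (is(v1, "SummarizedExperiment") && is(v2, "SummarizedExperiment")) {
    p <- new("HarmonizedPair",
             v1 = as(v1[shared, ], "MethylationSet"),
             v2 = as(v2[shared, ], "MethylationSet"),
             v1Only = v1Only, v2Only = v2Only)
    return(p)
  }
  list(v1 = b1[shared, , drop = FALSE], v2 = b2[shared, , drop = FALSE],
       v1_only = v1Only, v2_only = v2Only)
}

#' Enumerate donor-matched and technical-replicate array pairs
#'
#' From a validated sample sheet, builds (i) one matched pair per donor
#' with exactly one non-replicate array on each version (donors lacking
#' either version are excluded with a warning; a donor with two primary
#' arrays on one version is an error), (ii) within-version technical
#' replicate pairs (each replicate array against its source), and (iii)
#' between-version replicate pairs: the matched v1/v2 arrays of donors that
#' carry at least one technical replicate, mirroring how between-version
#' reliability is assessed on replicated aliquots.
#'
#' @param sheet Sample sheet data.frame or a [MethylationSet-class].
#' @return List with data.frames `donor_pairs` (columns `donor_id`, `v1`,
#'   `v2`), `within_version` (`version`, `sample`, `replicate`), and
#'   `between_version` (`donor_id`, `v1`, `v2`).
#' @export
matchSamples <- function(sheet) {
  if (is(sheet, "SummarizedExperiment")) sheet <- sampleSheet(sheet)
  sheet <- validateSampleSheet(sheet)
  primary <- sheet[is.na(sheet$replicate_of), , drop = FALSE]
  pairs <- list()
  dropped <- character()
  for (d in unique(primary$donor_id)) {
    rows <- primary[primary$donor_id == d, , drop = FALSE]
    s1 <- rows$sample_id[rows$version == "v1"]
    s2 <- rows$sample_id[rows$version == "v2"]
    if (length(s1) > 1L || length(s2) > 1L)
      stop("donor ", d, " has more than one primary array on one version")
    if (length(s1) == 1L && length(s2) == 1L) {
      pairs[[d]] <- data.frame(donor_id = d, v1 = s1, v2 = s2)
    } else {
      dropped <- c(dropped, d)
    }
  }
  if (length(dropped))
    warning("excluded donor(s) lacking one version: ",
            paste(dropped, collapse = ", "))
  donorPairs <- if (length(pairs)) {
    do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  } else {
    data.frame(donor_id = character(), v1 = character(), v2 = character())
  }
  reps <- sheet[!is.na(sheet$replicate_of), , drop = FALSE]
  within <- data.frame(version = character(), sample = character(),
                       replicate = character())
  if (nrow(reps)) {
    srcVersion <- sheet$version[match(reps$replicate_of, sheet$sample_id)]
    w <- reps$version == srcVersion
    within <- data.frame(version = reps$version[w],
                         sample = reps$replicate_of[w],
                         replicate = reps$sample_id[w])
  }
  repDonors <- unique(reps$donor_id)
  between <- donorPairs[donorPairs$donor_id %in% repDonors, , drop = FALSE]
  names(between) <- c("donor_id", "v1", "v2")
  rownames(between) <- NULL
  list(donor_pairs = donorPairs, within_version = within,
       between_version = between)
}
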