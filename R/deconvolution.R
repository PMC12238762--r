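#' Automatic selection of cell-discriminating probes
#'
#' Reference-based probe selection in the style of blood deconvolution
#' libraries: per probe, a one-way ANOVA F statistic across cell types is
#' computed from purified reference samples; for each cell type, among
#' probes with F-test p below `pMax` (default 1e-8), the `topN` probes
#' (default 100) with the greatest one-vs-rest mean methylation difference
#' are taken, split evenly between the most hypermethylated and most
#' hypomethylated half (`split = "both"`, the usual convention; when one
#' direction runs out the remainder is filled by absolute difference).
#' `split = "magnitude"` takes a plain top-`topN` by absolute difference.
#' The union over cell types, deduplicated, is returned.
#'
#' @param refBeta Probes x reference-samples beta matrix of purified
#'   populations.
#' @param cellType Cell-type label per reference sample (length =
#'   ncol(refBeta); at least 2 samples per type).
#' @param topN Probes to select per cell type (default 100).
#' @param pMax F-test p-value ceiling (default 1e-8).
#' @param split `"both"` (hyper/hypo halves) or `"magnitude"`.
#' @return Character vector of selected probe ids. Cell types for which no
#'   probe passes `pMax` contribute fewer (possibly zero) probes, with a
#'   warning.
#' @export
selectProbesAuto <- function(refBeta, cellType, topN = 100, pMax = 1e-8,
                             split = c("both", "magnitude")) {
  split <- match.arg(split)
  refBeta <- .betaOf(refBeta)
  cellType <- as.factor(cellType)
  if (length(cellType) != ncol(refBeta))
    stop("cellType must label every reference sample")
  if (any(table(cellType) < 2L))
    stop("need at least 2 reference samples per cell type")
  k <- nlevels(cellType)
  N <- ncol(refBeta)
  ## vectorized one-way ANOVA across cell types, per probe
  groupIdx <- lapply(levels(cellType), function(l) which(cellType == l))
  groupMeans <- vapply(groupIdx, function(idx)
    rowMeans(refBeta[, idx, drop = FALSE]), numeric(nrow(refBeta)))
  colnames(groupMeans) <- levels(cellType)
  grand <- rowMeans(refBeta)
  ng <- lengths(groupIdx)
  ssb <- rowSums(sweep((groupMeans - grand)^2, 2L, ng, `*`))
  ssw <- rowSums((refBeta - groupMeans[, as.integer(cellType)])^2)
  fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  pval <- stats::pf(fstat, k - 1, N - k, lower.tail = FALSE)
  pval[ssw == 0 & ssb > 0] <- 0          # perfect separation
  pval[ssw == 0 & ssb == 0] <- 1         # flat probe

  selected <- character()
  starved <- character()
  for (ct in levels(cellType)) {
    restMean <- rowMeans(
      refBeta[, cellType != ct, drop = FALSE])
    diff <- groupMeans[, ct] - restMean
    pool <- which(pval < pMax)
    if (!length(pool)) {
      starved <- c(starved, ct)
      next
    }
    if (split == "magnitude") {
      take <- pool[order(abs(diff[pool]), decreasing = TRUE)]
      take <- take[seq_len(min(topN, length(take)))]
    } else {
      half <- topN %/% 2L
      hyper <- pool[diff[pool] > 0]
      hypo <- pool[diff[pool] < 0]
      hyper <- hyper[order(diff[hyper], decreasing = TRUE)]
      hypo <- hypo[order(diff[hypo])]
      take <- c(hyper[seq_len(min(half, length(hyper)))],
                hypo[seq_len(min(half, length(hypo)))])
      if (length(take) < min(topN, length(pool))) {
        extra <- setdiff(pool[order(abs(diff[pool]), decreasing = TRUE)],
                         take)
        take <- c(take, extra[seq_len(min(topN - length(take),
                                          length(extra)))])
      }
    }
    selected <- c(selected, rownames(refBeta)[take])
  }
  if (length(starved))
    warning("no probe passed the p-value ceiling for cell type(s): ",
            paste(starved, collapse = ", "))
  unique(selected)
}

#' Build a reference library from purified samples
#'
#' Averages purified reference samples within cell type over a probe set
#' (typically the output of [selectProbesAuto()] or a fixed pre-selected
#' panel), yielding the mean matrix used for constrained projection.
#'
#' @inheritParams selectProbesAuto
#' @param probes Probe ids to include (default: all rows).
#' @return A [CellTypeReference-class].
#' @export
buildReference <- function(refBeta, cellType, probes = NULL) {
  refBeta <- .betaOf(refBeta)
  if (!is.null(probes)) refBeta <- refBeta[probes, , drop = FALSE]
  cellType <- as.factor(cellType)
  m <- vapply(levels(cellType), function(l)
    rowMeans(refBeta[, cellType == l, drop = FALSE]),
    numeric(nrow(refBeta)))
  CellTypeReference(m)
}

#' Restrict a reference library to available probes
#'
#' Fixed panels are pre-selected on one platform; probes absent from the
#' target platform are removed from the reference before projection. When
#' more than half the panel would be dropped the panel is no longer
#' trustworthy and an error is raised.
#'
#' @param ref A [CellTypeReference-class].
#' @param availableProbes Probe ids present on the target platform.
#' @return The restricted [CellTypeReference-class]; the number of dropped
#'   probes is reported in attribute `n_dropped` and via a message.
#' @export
restrictReference <- function(ref, availableProbes) {
  m <- referenceMeans(ref)
  keep <- rownames(m) %in% availableProbes
  nDropped <- sum(!keep)
  if (nDropped > nrow(m) / 2)
    stop(nDropped, " of ", nrow(m), " panel probes absent from the target ",
         "platform; panel no longer trustworthy")
  if (nDropped > 0)
    message(nDropped, " of ", nrow(m), " panel probes dropped ",
            "(absent from target platform)")
  out <- CellTypeReference(m[keep, , drop = FALSE])
  attr(out, "n_dropped") <- nDropped
  out
}

#' Estimate cell-type proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: per sample, the
#' coefficient vector w minimizing ||beta_s - R w||^2 subject to w >= 0 is
#' found by non-negative least squares over the reference probes (active
#' set method of Lawson-Hanson, gradient tolerance at solver precision).
#' Proportions are reported raw (their sum is a diagnostic column, not
#' forced to one); `normalize = TRUE` rescales each sample to sum to one.
#'
#' @param x [MethylationSet-class] or probes x samples beta matrix.
#' @param ref A [CellTypeReference-class].
#' @param normalize Rescale proportions to sum to 1 (default FALSE,
#'   matching the usual raw-projection convention).
#' @return data.frame with `sample_id`, one column per cell type, and
#'   `sum`.
#' @export
projectCellProportions <- function(x, ref, normalize = FALSE) {
  beta <- .betaOf(x)
  R <- referenceMeans(ref)
  shared <- intersect(rownames(R), rownames(beta))
  if (!length(shared)) stop("no shared probes between sample and reference")
  if (length(shared) < 10L)
    warning("only ", length(shared), " shared probes; estimates unreliable")
  R <- R[shared, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    cors <- stats::cor(R)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
    stop("reference rank-deficient on shared probes; collinear cell types ",
         "include: ", paste(colnames(R)[worst], collapse = ", "))
  }
  beta <- beta[shared, , drop = FALSE]
  out <- matrix(NA_real_, ncol(beta), ncol(R),
                dimnames = list(colnames(beta), colnames(R)))
  for (j in seq_len(ncol(beta))) {
    b <- beta[, j]
    ok <- !is.na(b)
    out[j, ] <- pracma::lsqnonneg(R[ok, , drop = FALSE], b[ok])$x
  }
  sums <- rowSums(out)
  if (normalize) out <- out / ifelse(sums == 0, 1, sums)
  data.frame(sample_id = rownames(out), out, sum = rowSums(out),
             row.names = NULL, check.names = FALSE)
}
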