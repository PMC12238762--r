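#' Sample-to-sample correlation matrix
#'
#' Array-level concordance: pairwise Pearson or Spearman correlations
#' between samples over a probe subset, using complete pairs per sample
#' pair. Sample pairs sharing fewer than 3 complete probes are set to NA
#' with a warning.
#'
#' @param x [MethylationSet-class] or probes x samples beta matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param probeSubset Optional probe ids to restrict to (e.g. the SNP
#'   fingerprint probes for identity checks).
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
arrayCorrelationMatrix <- function(x, method = c("pearson", "spearman"),
                                   probeSubset = NULL) {
  method <- match.arg(method)
  beta <- .betaOf(x)
  if (!is.null(probeSubset)) {
    probeSubset <- intersect(probeSubset, rownames(beta))
    beta <- beta[probeSubset, , drop = FALSE]
  }
  if (nrow(beta) < 2L) stop("need at least 2 probes after subsetting")
  cc <- stats::cor(beta, use = "pairwise.complete.obs", method = method)
  nShared <- crossprod(!is.na(beta))
  few <- nShared < 3L
  diag(few) <- FALSE
  if (any(few)) {
    cc[few] <- NA_real_
    warning(sum(few) / 2, " sample pair(s) share fewer than 3 complete ",
            "probes; set to NA")
  }
  diag(cc) <- 1
  cc
}

#' Two-step hierarchical clustering on a correlation matrix
#'
#' Clusters samples by complete-linkage agglomeration on the Euclidean
#' distance between rows of the sample-to-sample correlation matrix (the
#' two-step approach: correlate first, cluster the correlation profiles).
#' `hclust` is deterministic given the input order; merge-height ties
#' resolve to the earliest index.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param k Optional number of clusters to cut the tree into.
#' @return List with elements `hclust` (the tree), `order` (leaf order for
#'   heatmap display), and `labels` (named cluster labels, NULL when `k`
#'   is missing).
#' @export
hierarchicalCluster <- function(corr, k = NULL) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  hc <- stats::hclust(stats::dist(corr, method = "euclidean"),
                      method = "complete")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, order = hc$order, labels = labels)
}

#' Per-probe Spearman correlation between versions
#'
#' Probe-level concordance: for each shared probe, the Spearman rank
#' correlation (mid-ranks for ties) between its v1 beta values and its v2
#' beta values across matched donors. Technical replicates must be excluded
#' beforehand; passing `donorPairs` (from [matchSamples()]) selects and
#' aligns the primary arrays. Probes with zero variance in either vector,
#' or fewer than 4 complete donor pairs, get NA.
#'
#' @param pair A [HarmonizedPair-class], or a list with beta matrices `v1`
#'   and `v2` sharing probe order.
#' @param donorPairs Optional data.frame with columns `v1` and `v2` naming
#'   matched sample columns; defaults to positional matching of columns.
#' @return Named numeric vector of per-probe rho.
#' @export
probeSpearman <- function(pair, donorPairs = NULL) {
  m <- .pairMatrices(pair, donorPairs)
  if (ncol(m$v1) < 4L) stop("need at least 4 matched donors")
  r1 <- .rowRanks(m$v1)
  r2 <- .rowRanks(m$v2)
  ok <- !is.na(m$v1) & !is.na(m$v2)
  if (!all(ok)) {
    ## re-rank within complete pairs where cells are missing
    redo <- which(rowSums(!ok) > 0L)
    for (i in redo) {
      keep <- ok[i, ]
      r1[i, ] <- NA_real_
      r2[i, ] <- NA_real_
      if (sum(keep) >= 4L) {
        r1[i, keep] <- rank(m$v1[i, keep], ties.method = "average")
        r2[i, keep] <- rank(m$v2[i, keep], ties.method = "average")
      }
    }
  }
  rho <- .rowPearson(r1, r2)
  names(rho) <- rownames(m$v1)
  rho
}

## Row-wise Pearson correlation of two matrices over complete pairs.
.rowPearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x[!ok] <- NA_real_
  y[!ok] <- NA_real_
  n <- rowSums(ok)
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  dx <- x - mx
  dy <- y - my
  num <- rowSums(dx * dy, na.rm = TRUE)
  den <- sqrt(rowSums(dx^2, na.rm = TRUE) * rowSums(dy^2, na.rm = TRUE))
  out <- ifelse(den > 0 & n >= 4L, num / den, NA_real_)
  out
}

.pairMatrices <- function(pair, donorPairs = NULL) {
  if (is(pair, "HarmonizedPair")) {
    b1 <- betaValues(pairV1(pair))
    b2 <- betaValues(pairV2(pair))
    if (is.null(donorPairs)) {
      donorPairs <- matchSamples(rbind(sampleSheet(pairV1(pair)),
                                       sampleSheet(pairV2(pair))))$donor_pairs
    }
  } else {
    b1 <- .betaOf(pair$v1)
    b2 <- .betaOf(pair$v2)
  }
  if (!identical(rownames(b1), rownames(b2)))
    stop("pair matrices must share probe order; harmonize first")
  if (!is.null(donorPairs)) {
    b1 <- b1[, donorPairs$v1, drop = FALSE]
    b2 <- b2[, donorPairs$v2, drop = FALSE]
  } else if (ncol(b1) != ncol(b2)) {
    stop("without donorPairs the two matrices need matching column counts")
  }
  list(v1 = b1, v2 = b2)
}

#' Per-probe pooled standard deviation across versions
#'
#' The two-group pooled SD of a probe's beta values: per-version sample
#' variances combined with Bessel weights,
#' sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). Low pooled SD flags
#' probes with little inter-sample variability, for which rank correlations
#' are uninformative.
#'
#' @inheritParams probeSpearman
#' @return Named numeric vector of per-probe pooled SD.
#' @export
pooledSD <- function(pair, donorPairs = NULL) {
  m <- .pairMatrices(pair, donorPairs)
  n1 <- rowSums(!is.na(m$v1))
  n2 <- rowSums(!is.na(m$v2))
  if (any(n1 + n2 < 3L)) stop("need at least 3 observations per probe")
  if (all(n1 < 2L) || all(n2 < 2L))
    stop("need at least 2 samples per version")
  v1 <- .rowVars(m$v1)
  v2 <- .rowVars(m$v2)
  out <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  names(out) <- rownames(m$v1)
  out
}

#' Classify shared probes by concordance and variability
#'
#' Each probe lands in exactly one class: `low_variability` when its pooled
#' SD is at or below the variability threshold (default: the lower quartile
#' of the pooled-SD distribution, which empirically sits near 0.01 on the
#' beta scale); otherwise `poorly_concordant` when its cross-version
#' Spearman rho is at or below `rhoThresh` (default 0.70); otherwise
#' `concordant`. Probes with missing rho are excluded from classification
#' and counted in the `n_unclassified` attribute. Alternative threshold
#' pairs (e.g. SD 0.05 with rho 0.50) can be supplied for threshold grids.
#'
#' @param rho Named per-probe Spearman correlations (see
#'   [probeSpearman()]).
#' @param pooledSd Named per-probe pooled SDs (see [pooledSD()]), aligned
#'   with `rho`.
#' @param rhoThresh Correlation threshold (default 0.70).
#' @param sdThresh Either the string `"lower_quartile"` (default) or a
#'   fixed numeric threshold.
#' @return data.frame with columns `base_cpg`, `rho`, `pooled_sd`, `klass`
#'   (factor with levels concordant, low_variability, poorly_concordant).
#'   Attributes: `sd_threshold` (the value used), `counts` (class counts),
#'   `n_unclassified`.
#' @export
classifyProbes <- function(rho, pooledSd, rhoThresh = 0.70,
                           sdThresh = "lower_quartile") {
  if (length(rho) != length(pooledSd))
    stop("rho and pooledSd must align")
  if (!is.null(names(rho)) && !is.null(names(pooledSd)) &&
      !identical(names(rho), names(pooledSd)))
    pooledSd <- pooledSd[names(rho)]
  thr <- if (identical(sdThresh, "lower_quartile")) {
    unname(stats::quantile(pooledSd, 0.25, na.rm = TRUE, names = FALSE))
  } else {
    as.numeric(sdThresh)
  }
  keep <- !is.na(rho) & !is.na(pooledSd)
  klass <- rep(NA_character_, length(rho))
  klass[keep & pooledSd <= thr] <- "low_variability"
  klass[keep & pooledSd > thr & rho <= rhoThresh] <- "poorly_concordant"
  klass[keep & pooledSd > thr & rho > rhoThresh] <- "concordant"
  out <- data.frame(
    base_cpg = if (is.null(names(rho))) as.character(seq_along(rho))
               else names(rho),
    rho = unname(rho), pooled_sd = unname(pooledSd),
    klass = factor(klass, levels = c("concordant", "low_variability",
                                     "poorly_concordant")))
  attr(out, "sd_threshold") <- thr
  attr(out, "counts") <- table(out$klass)
  attr(out, "n_unclassified") <- sum(!keep)
  out
}

#' Root mean square error between two replicate arrays
#'
#' @param a,b Named beta vectors (one array each); only probes named in
#'   both and non-missing enter the calculation.
#' @return sqrt(mean((a - b)^2)) over complete shared probes.
#' @export
replicateRMSE <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]
    b <- b[shared]
  } else if (length(a) != length(b)) {
    stop("unnamed vectors must have equal length")
  }
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no shared probes")
  sqrt(mean((a[ok] - b[ok])^2))
}

#' Intraclass correlation of replicate arrays, ICC(2,1)
#'
#' Array-level reliability of technical replicates under the two-way
#' random-effects, absolute-agreement, single-measure model: probes are the
#' targets (rows), replicate arrays the raters (columns). From the two-way
#' ANOVA mean squares,
#' ICC = (MS_rows - MS_err) / (MS_rows + (k-1) MS_err +
#' k (MS_cols - MS_err) / n). Probes with any missing value are dropped.
#'
#' @param replicates Probes x k matrix of beta values, k >= 2 replicate
#'   arrays.
#' @return Single numeric ICC; NA when total variance is zero.
#' @export
replicateICC <- function(replicates) {
  replicates <- as.matrix(replicates)
  k <- ncol(replicates)
  if (k < 2L) stop("need at least 2 replicate arrays")
  replicates <- replicates[stats::complete.cases(replicates), , drop = FALSE]
  n <- nrow(replicates)
  if (n < 2L) stop("need at least 2 complete probes")
  grand <- mean(replicates)
  if (all(replicates == grand)) return(NA_real_)
  rowM <- rowMeans(replicates)
  colM <- colMeans(replicates)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sse <- sum((replicates - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Technical-replicate reliability summary
#'
#' Convenience wrapper computing, for each within-version and
#' between-version replicate pair of a cohort, the array-level Spearman
#' correlation, RMSE and the ICC(2,1) of the pair.
#'
#' @param beta Probes x samples beta matrix covering all arrays named in
#'   `pairs` (e.g. shared probes of both versions).
#' @param pairs Output of [matchSamples()].
#' @return data.frame with columns `pair_kind`, `sample_a`, `sample_b`,
#'   `spearman`, `rmse`, `icc`.
#' @export
replicateReliability <- function(beta, pairs) {
  beta <- .betaOf(beta)
  one <- function(a, b, kind) {
    x <- beta[, a]
    y <- beta[, b]
    ok <- !is.na(x) & !is.na(y)
    data.frame(pair_kind = kind, sample_a = a, sample_b = b,
               spearman = stats::cor(x[ok], y[ok], method = "spearman"),
               rmse = replicateRMSE(x[ok], y[ok]),
               icc = replicateICC(cbind(x[ok], y[ok])))
  }
  w <- pairs$within_version
  b <- pairs$between_version
  rows <- c(
    lapply(seq_len(nrow(w)), function(i)
      one(w$sample[i], w$replicate[i], "within_version")),
    lapply(seq_len(nrow(b)), function(i)
      one(b$v1[i], b$v2[i], "between_version")))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
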