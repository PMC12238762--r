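#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment of a beta matrix, per probe: a grand
#' mean plus optional covariate effects are fit by least squares,
#' residuals are standardized by the pooled probe variance, per-batch
#' location (gamma) and scale (delta^2) parameters are estimated and
#' shrunk toward batch-level hyperpriors (normal prior for gamma,
#' inverse-gamma for delta^2, hyperparameters by method of moments, solved
#' by fixed-point iteration), the batch terms are removed, and the grand
#' mean and covariate effects are restored. With `shrink = FALSE` the raw
#' per-batch estimates are used (plain per-batch location/scale
#' equalization). Since the adjustment can push beta values outside the
#' unit interval, the result is clipped to \[1e-6, 1 - 1e-6\] and the
#' number of clipped cells is reported (attribute `n_clipped`).
#'
#' @param x [MethylationSet-class] or probes x samples beta matrix.
#' @param batch Batch label per sample (length = number of samples). A
#'   single level returns the input unchanged; a batch with one sample is
#'   an error.
#' @param covariates Optional per-sample data.frame of covariates to
#'   protect (e.g. age); must not be confounded with batch.
#' @param shrink Apply empirical-Bayes shrinkage (default TRUE).
#' @param conv Relative-change convergence tolerance of the EB fixed-point
#'   iteration (default 1e-4).
#' @return Adjusted matrix (or MethylationSet) of the same shape.
#' @export
combatAdjust <- function(x, batch, covariates = NULL, shrink = TRUE,
                         conv = 1e-4) {
  isSet <- is(x, "SummarizedExperiment")
  dat <- .betaOf(x)
  batch <- factor(batch)
  if (length(batch) != ncol(dat))
    stop("batch must label every sample")
  if (nlevels(batch) < 2L) {
    attr(dat, "n_clipped") <- 0L
    return(if (isSet) x else dat)
  }
  nb <- table(batch)
  if (any(nb < 2L))
    stop("batch level(s) with a single sample: ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  B <- nlevels(batch)
  design <- stats::model.matrix(~ -1 + batch)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    full <- cbind(design, mm)
    if (qr(full)$rank < ncol(full)) {
      stop("covariate(s) confounded with batch: ",
           paste(colnames(mm), collapse = ", "))
    }
    design <- full
  }
  N <- ncol(dat)
  ## per-probe least squares fit of batch + covariate effects
  Bhat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand <- drop(crossprod(Bhat[seq_len(B), , drop = FALSE],
                          as.numeric(nb) / N))
  varPooled <- rowSums((dat - t(design %*% Bhat))^2) / N
  if (any(varPooled == 0))
    varPooled[varPooled == 0] <- .Machine$double.eps
  standMean <- matrix(grand, nrow(dat), N)
  if (ncol(design) > B) {
    tmp <- design
    tmp[, seq_len(B)] <- 0
    standMean <- standMean + t(tmp %*% Bhat)
  }
  sdat <- (dat - standMean) / sqrt(varPooled)

  adj <- sdat
  for (b in levels(batch)) {
    idx <- which(batch == b)
    n <- length(idx)
    gammaHat <- rowMeans(sdat[, idx, drop = FALSE])
    deltaHat <- .rowVars(sdat[, idx, drop = FALSE])
    deltaHat[is.na(deltaHat) | deltaHat == 0] <- .Machine$double.eps
    if (shrink) {
      gbar <- mean(gammaHat)
      t2 <- stats::var(gammaHat)
      m <- mean(deltaHat)
      s2 <- stats::var(deltaHat)
      aPrior <- (2 * s2 + m^2) / s2
      bPrior <- (m * s2 + m^3) / s2
      gNew <- gammaHat
      dNew <- deltaHat
      change <- 1
      while (change > conv) {
        gOld <- gNew
        dOld <- dNew
        gNew <- (n * t2 * gammaHat + dOld * gbar) / (n * t2 + dOld)
        sum2 <- rowSums((sdat[, idx, drop = FALSE] - gNew)^2)
        dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
        change <- max(abs(gNew - gOld) / abs(gOld),
                      abs(dNew - dOld) / abs(dOld))
      }
      gammaStar <- gNew
      deltaStar <- dNew
    } else {
      gammaStar <- gammaHat
      deltaStar <- deltaHat
    }
    adj[, idx] <- (sdat[, idx, drop = FALSE] - gammaStar) / sqrt(deltaStar)
  }
  out <- adj * sqrt(varPooled) + standMean

  lo <- 1e-6
  hi <- 1 - 1e-6
  nClip <- sum(out < lo | out > hi, na.rm = TRUE)
  out[out < lo] <- lo
  out[out > hi] <- hi
  if (nClip > 0)
    message(nClip, " adjusted value(s) clipped to [1e-06, 1 - 1e-06]")
  attr(out, "n_clipped") <- nClip
  if (isSet) {
    y <- x
    SummarizedExperiment::assay(y, "beta") <- out
    return(y)
  }
  out
}

#' Sequential batch correction over version, chip and row
#'
#' Applies [combatAdjust()] once per batch variable, in order (by default
#' array version, then chip, then row position), feeding each adjusted
#' matrix into the next step. Variables with a single level are skipped
#' with a message. Applying the driver to already-corrected data changes
#' nothing beyond numerical tolerance.
#'
#' @param x [MethylationSet-class], or a beta matrix (then `sheet` is
#'   required).
#' @param sheet Sample sheet supplying the batch variables (ignored when
#'   `x` carries one).
#' @param batches Batch variable names, applied in order (default
#'   `c("version", "chip", "row")`).
#' @param covariates Optional covariate data.frame passed to every step.
#' @param shrink Apply empirical-Bayes shrinkage (default TRUE).
#' @return Adjusted object of the same kind as `x`.
#' @export
combatSequential <- function(x, sheet = NULL,
                             batches = c("version", "chip", "row"),
                             covariates = NULL, shrink = TRUE) {
  if (is.null(sheet)) {
    if (!is(x, "SummarizedExperiment"))
      stop("a sample sheet is required for a plain matrix")
    sheet <- sampleSheet(x)
  }
  out <- x
  for (bv in batches) {
    if (!bv %in% names(sheet)) stop("unknown batch variable: ", bv)
    lv <- sheet[[bv]]
    if (length(unique(lv)) < 2L) {
      message("skipping batch variable '", bv, "' (single level)")
      next
    }
    out <- combatAdjust(out, batch = lv, covariates = covariates,
                        shrink = shrink)
  }
  out
}

#' Paired comparison of per-donor estimates between versions
#'
#' For each endpoint, a paired t test on the per-donor differences
#' d = v2 - v1: t = mean(d) / (sd(d) / sqrt(n)), two-sided p from the t
#' distribution with n - 1 df, Bonferroni adjustment over the endpoints
#' passed in the call. Effect size is Cohen's d for paired data,
#' d_z = mean(d) / sd(d) (positive = higher on v2); `dMethod = "av"`
#' instead divides by the mean of the two group SDs. Effect classes follow
#' the conventional benchmarks: negligible below 0.2, small 0.2-0.49,
#' medium 0.5-0.79, large at or above 0.8 (on |d|).
#'
#' @param xV1,xV2 Donor-aligned numeric matrices (donors x endpoints) or
#'   vectors of per-donor estimates from each version.
#' @param endpoints Endpoint labels (default: column names).
#' @param dMethod `"z"` (default) or `"av"`.
#' @return data.frame with columns `endpoint`, `n_pairs`, `t_stat`,
#'   `p_value`, `p_bonferroni`, `cohens_d`, `d_class`, `degenerate`
#'   (TRUE when sd(d) = 0 with a nonzero mean difference).
#' @export
pairedCompare <- function(xV1, xV2, endpoints = NULL, dMethod = c("z", "av")) {
  dMethod <- match.arg(dMethod)
  xV1 <- as.matrix(xV1)
  xV2 <- as.matrix(xV2)
  if (!identical(dim(xV1), dim(xV2)))
    stop("xV1 and xV2 must be donor-aligned with identical shape")
  if (is.null(endpoints))
    endpoints <- colnames(xV1)
  if (is.null(endpoints))
    endpoints <- paste0("endpoint", seq_len(ncol(xV1)))
  d <- xV2 - xV1
  n <- colSums(!is.na(d))
  if (any(n < 3L)) stop("need at least 3 complete pairs per endpoint")
  md <- colMeans(d, na.rm = TRUE)
  sdd <- apply(d, 2L, stats::sd, na.rm = TRUE)
  degenerate <- sdd == 0 & md != 0
  tstat <- ifelse(sdd > 0, md / (sdd / sqrt(n)),
                  ifelse(md == 0, 0, sign(md) * Inf))
  pval <- ifelse(is.finite(tstat),
                 2 * stats::pt(-abs(tstat), df = n - 1), 0)
  pval[sdd == 0 & md == 0] <- 1
  cohensD <- if (dMethod == "z") {
    ifelse(sdd > 0, md / sdd, ifelse(md == 0, 0, sign(md) * Inf))
  } else {
    s1 <- apply(xV1, 2L, stats::sd, na.rm = TRUE)
    s2 <- apply(xV2, 2L, stats::sd, na.rm = TRUE)
    md / ((s1 + s2) / 2)
  }
  dClass <- cut(pmin(abs(cohensD), Inf),
                breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
                labels = c("negligible", "small", "medium", "large"))
  data.frame(endpoint = endpoints, n_pairs = as.integer(n), t_stat = tstat,
             p_value = pval,
             p_bonferroni = pmin(1, pval * length(endpoints)),
             cohens_d = cohensD, d_class = dClass, degenerate = degenerate,
             row.names = NULL)
}
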