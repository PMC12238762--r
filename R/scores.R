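#' Compute a linear CpG-coefficient score
#'
#' Evaluates a [CoefficientSet-class] on a beta matrix: the linear
#' predictor intercept + sum(w_c * beta_c) over the score's CpGs, followed
#' by the set's output transform ([applyAgeTransform()]). The
#' `equal_weight_mean` transform instead returns the plain mean beta over
#' the CpG set (mitotic-clock convention), ignoring intercept and weight
#' magnitudes.
#'
#' Missing CpGs are imputed: `"reference_mean"` uses the training means
#' shipped with the coefficient set; `"cohort_mean"` fills missing cells
#' with the CpG's mean over the available samples (CpGs absent from the
#' matrix altogether fall back to the reference mean when present, since a
#' cohort mean does not exist for them); `"fail"` raises an error listing
#' the missing CpGs. The default, `"auto"`, uses reference means when the
#' set ships them and cohort means otherwise. More than half the CpGs
#' missing is always an error.
#'
#' @param x [MethylationSet-class] or probes x samples beta matrix keyed by
#'   base CpG.
#' @param coef A [CoefficientSet-class].
#' @param impute One of `"auto"`, `"reference_mean"`, `"cohort_mean"`,
#'   `"fail"`.
#' @return data.frame with columns `sample_id`, `score`, `value`,
#'   `n_missing_cpgs` (CpGs absent from the matrix and imputed).
#' @export
computeLinearScore <- function(x, coef,
                               impute = c("auto", "reference_mean",
                                          "cohort_mean", "fail")) {
  impute <- match.arg(impute)
  stopifnot(is(coef, "CoefficientSet"))
  beta <- .betaOf(x)
  cpgs <- names(coef@weights)
  present <- cpgs[cpgs %in% rownames(beta)]
  absent <- setdiff(cpgs, present)
  if (length(present) < length(cpgs) / 2)
    stop("more than 50% of score CpGs missing from the matrix (",
         length(absent), " of ", length(cpgs), ")")
  if (impute == "fail" &&
      (length(absent) || anyNA(beta[present, , drop = FALSE])))
    stop("missing score CpG values with impute = 'fail': ",
         paste(utils::head(absent, 10L), collapse = ", "))
  if (impute == "auto")
    impute <- if (length(coef@referenceMeans)) "reference_mean"
              else "cohort_mean"

  sub <- matrix(NA_real_, length(cpgs), ncol(beta),
                dimnames = list(cpgs, colnames(beta)))
  sub[present, ] <- beta[present, , drop = FALSE]
  if (anyNA(sub)) {
    fillRef <- coef@referenceMeans[cpgs]
    names(fillRef) <- cpgs
    if (impute == "reference_mean") {
      fill <- fillRef
    } else {                      # cohort_mean for cells, reference for rows
      fill <- rowMeans(sub, na.rm = TRUE)
      rowAbsent <- !(cpgs %in% present)
      fill[rowAbsent] <- fillRef[rowAbsent]
    }
    bad <- is.na(fill) & rowSums(is.na(sub)) > 0
    if (any(bad))
      stop("cannot impute CpG(s) without reference means: ",
           paste(utils::head(cpgs[bad], 10L), collapse = ", "))
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- fill[idx[, 1L]]
  }

  value <- if (coef@transform == "equal_weight_mean") {
    colMeans(sub)
  } else {
    lp <- coef@intercept + drop(crossprod(sub, coef@weights))
    applyAgeTransform(lp, coef@transform, coef@adultAge)
  }
  data.frame(sample_id = colnames(beta), score = coef@name,
             value = unname(value), n_missing_cpgs = length(absent))
}

#' Output transform of a linear age predictor
#'
#' `"identity"` passes the linear predictor through. `"horvath_antilog"`
#' inverts the log-linear age calibration used by the pan-tissue style
#' clocks: for x <= 0, age = (1 + adultAge) * exp(x) - 1; for x > 0,
#' age = (1 + adultAge) * x + adultAge, so x = 0 maps to `adultAge`.
#'
#' @param x Linear predictor value(s).
#' @param transform `"identity"`, `"horvath_antilog"` or
#'   `"equal_weight_mean"` (treated as identity here; the mean is taken in
#'   [computeLinearScore()]).
#' @param adultAge Knot of the antilog transform, in years (default 20).
#' @return Age(s) in years (or the untransformed score).
#' @export
applyAgeTransform <- function(x, transform = "identity", adultAge = 20) {
  switch(transform,
         identity = x,
         equal_weight_mean = x,
         horvath_antilog =
           ifelse(x <= 0, (1 + adultAge) * exp(x) - 1,
                  (1 + adultAge) * x + adultAge),
         stop("unknown transform: ", transform))
}

#' Epigenetic age acceleration under version-aware strategies
#'
#' EAA is the residual of epigenetic age regressed on chronological age.
#' Three strategies handle two-version designs: `"separate"` fits one
#' regression per array version (residuals are version-free by
#' construction); `"combined"` fits a single regression over all arrays
#' (a systematic version offset then surfaces in the residuals);
#' `"combined_adjusted"` fits a single regression with a version indicator
#' covariate, absorbing the offset. Technical replicates are excluded from
#' every fit.
#'
#' @param scores Score table (from [computeLinearScore()]) with columns
#'   `sample_id`, `score`, `value`.
#' @param sheet Sample sheet providing `age`, `version` and `replicate_of`
#'   per sample.
#' @param mode `"separate"`, `"combined"` or `"combined_adjusted"`.
#' @return data.frame with columns `sample_id`, `clock`, `mode`, `eaa`
#'   (years). Residuals of each underlying fit sum to zero.
#' @export
computeEAA <- function(scores, sheet,
                       mode = c("separate", "combined",
                                "combined_adjusted")) {
  mode <- match.arg(mode)
  if (is(sheet, "SummarizedExperiment")) sheet <- sampleSheet(sheet)
  sheet <- validateSampleSheet(sheet)
  idx <- match(scores$sample_id, sheet$sample_id)
  if (anyNA(idx)) stop("score table names samples absent from the sheet")
  dat <- cbind(scores, age = sheet$age[idx], version = sheet$version[idx],
               replicate_of = sheet$replicate_of[idx])
  dat <- dat[is.na(dat$replicate_of), , drop = FALSE]
  if (anyNA(dat$age)) stop("age must be present for all samples")
  out <- lapply(split(dat, dat$score), function(d) {
    eaa <- rep(NA_real_, nrow(d))
    if (mode == "separate") {
      for (v in unique(d$version)) {
        sel <- d$version == v
        if (sum(sel) < 3L) stop("fewer than 3 samples in version ", v)
        eaa[sel] <- stats::resid(stats::lm(value ~ age, data = d[sel, ]))
      }
    } else {
      if (nrow(d) < 3L) stop("fewer than 3 samples")
      fml <- if (mode == "combined") value ~ age else
        value ~ age + factor(version)
      eaa <- stats::resid(stats::lm(fml, data = d))
    }
    data.frame(sample_id = d$sample_id, clock = d$score[1L], mode = mode,
               eaa = unname(eaa))
  })
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}

#' Version-adjust a rate-style clock estimate
#'
#' Rate and length estimators (pace-of-aging, telomere-length, mitotic
#' clocks) have no chronological-age regression step; version effects are
#' removed by regressing the estimate on the version indicator and keeping
#' the residuals, re-centered at the grand mean so the adjusted values stay
#' on the original scale.
#'
#' @param scores Score table with `sample_id`, `score`, `value`.
#' @param sheet Sample sheet providing `version` per sample.
#' @return The score table with `value` replaced by the version-adjusted
#'   estimate.
#' @export
adjustRateEstimate <- function(scores, sheet) {
  if (is(sheet, "SummarizedExperiment")) sheet <- sampleSheet(sheet)
  sheet <- validateSampleSheet(sheet)
  version <- sheet$version[match(scores$sample_id, sheet$sample_id)]
  if (anyNA(version)) stop("score table names samples absent from the sheet")
  out <- scores
  for (s in unique(scores$score)) {
    sel <- scores$score == s
    if (length(unique(version[sel])) < 2L)
      stop("need both versions present to adjust score ", s)
    fit <- stats::lm(scores$value[sel] ~ factor(version[sel]))
    out$value[sel] <- stats::resid(fit) + mean(scores$value[sel])
  }
  out
}
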