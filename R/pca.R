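#' Principal component analysis of a beta matrix
#'
#' PCA on the samples: probes are centered across samples (optionally
#' scaled to unit variance; off by default, since beta values share a
#' common scale) and the per-sample scores on the top components are
#' returned with the fraction of total variance each explains.
#'
#' @param x [MethylationSet-class] or probes x samples beta matrix.
#' @param nPcs Number of components to keep.
#' @param scale. Scale probes to unit variance before decomposition
#'   (default FALSE).
#' @return List with `scores` (samples x nPcs matrix), `varianceFraction`
#'   (length-nPcs numeric, non-increasing), and the full `prcomp` fit.
#' @export
runPCA <- function(x, nPcs = 5, scale. = FALSE) {
  beta <- .betaOf(x)
  if (ncol(beta) < nPcs + 1L)
    stop("need at least nPcs + 1 samples")
  keep <- .rowVars(beta) > 0
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("constant matrix: no variance to decompose")
  fit <- stats::prcomp(t(beta[keep, , drop = FALSE]), center = TRUE,
                       scale. = scale.)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(nPcs), drop = FALSE],
       varianceFraction = vf[seq_len(nPcs)], fit = fit)
}

#' Associate principal components with sample variables
#'
#' For every (component, variable) combination, fits the simple linear
#' regression PC ~ variable (categorical variables enter as one-way ANOVA
#' factors) and records the overall-F p-value and R-squared. P-values are
#' Bonferroni-adjusted over all tests actually performed, so with 5
#' components and 18 variables the family size is 90. Variables with a
#' single unique level (e.g. sex in an all-female cohort) are skipped with
#' a warning and do not count toward the family.
#'
#' @param pca Output of [runPCA()], or a samples x PCs score matrix.
#' @param variables data.frame of per-sample variables (rows aligned with
#'   the score rows), e.g. the sample sheet joined with estimated cell-type
#'   proportions.
#' @param nPcs Number of leading components to test (default: all score
#'   columns).
#' @return data.frame with columns `pc_index`, `variable`, `r_squared`,
#'   `p_value`, `p_bonferroni`, `pc_variance_fraction`.
#' @export
associatePCs <- function(pca, variables, nPcs = NULL) {
  scores <- if (is.list(pca) && !is.data.frame(pca)) pca$scores else pca
  vf <- if (is.list(pca) && !is.data.frame(pca)) pca$varianceFraction else NULL
  if (is.null(nPcs)) nPcs <- ncol(scores)
  nPcs <- min(nPcs, ncol(scores))
  variables <- as.data.frame(variables)
  if (nrow(variables) != nrow(scores))
    stop("variables must have one row per sample")
  usable <- names(variables)[vapply(variables, function(v)
    length(unique(v[!is.na(v)])) > 1L, logical(1))]
  skipped <- setdiff(names(variables), usable)
  if (length(skipped))
    warning("skipped single-level variable(s): ",
            paste(skipped, collapse = ", "))
  rows <- list()
  for (i in seq_len(nPcs)) {
    for (v in usable) {
      val <- variables[[v]]
      if (is.character(val) || is.logical(val)) val <- factor(val)
      fit <- stats::lm(scores[, i] ~ val)
      sm <- summary(fit)
      p <- if (is.null(sm$fstatistic)) NA_real_ else
        stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                  lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        pc_index = i, variable = v, r_squared = sm$r.squared,
        p_value = unname(p),
        pc_variance_fraction = if (is.null(vf)) NA_real_ else vf[i])
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out[, c("pc_index", "variable", "r_squared", "p_value", "p_bonferroni",
          "pc_variance_fraction")]
}
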