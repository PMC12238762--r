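#' Logit and inverse-logit transforms
#'
#' The simulator and batch-correction internals work on the logit (M-value
#' like) scale, where technical and batch effects are additive; observed
#' methylation fractions live on the beta scale in (0, 1).
#'
#' @param p Methylation fraction(s) in (0, 1).
#' @param x Real value(s) on the logit scale.
#' @return `logit` returns log(p / (1 - p)); `invlogit` its inverse.
#' @examples
#' invlogit(logit(0.3))
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Extract a beta matrix from a MethylationSet or pass a plain matrix through.
.betaOf <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    return(SummarizedExperiment::assay(x, "beta"))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("expected a matrix or MethylationSet")
  x
}

## Row-wise variance with complete observations per row (Bessel-corrected).
.rowVars <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  out <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
  out[n < 2] <- NA_real_
  out
}

## Row-wise ranks with mid-ranks for ties; NAs stay NA.
.rowRanks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average", na.last = "keep"))
}
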