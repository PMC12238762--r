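# Brute-force oracles, kept independent of the package implementation:
# mid-ranks computed from pairwise comparisons, moments by explicit sums,
# ANOVA mean squares through lm(), paired t through t.test().

midRankOracle <- function(x) {
  vapply(seq_along(x), function(i) {
    (sum(x < x[i]) + 1 + sum(x <= x[i])) / 2
  }, numeric(1))
}

pearsonOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

spearmanOracle <- function(x, y) {
  pearsonOracle(midRankOracle(x), midRankOracle(y))
}

pooledSdOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  va <- sum((a - mean(a))^2) / (n1 - 1)
  vb <- sum((b - mean(b))^2) / (n2 - 1)
  sqrt(((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2))
}

rmseOracle <- function(a, b) sqrt(sum((a - b)^2) / length(a))

icc21Oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   probe = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(lm(y ~ probe + rater, data = df))
  msr <- ms["probe", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

pairedTOracle <- function(a, b) {
  tt <- t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
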