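test_that("array correlations: identity, rank invariance, sparse-overlap NA", {
  b <- tinyBeta(50, 3, seed = 3)
  cc <- arrayCorrelationMatrix(b, method = "spearman")
  expect_equal(diag(cc), setNames(rep(1, 3), colnames(b)))
  expect_equal(cc, t(cc))

  # a monotone transform of a sample leaves Spearman at 1, Pearson below
  b2 <- cbind(b, s99 = logit(b[, 1]) / 20 + 0.5)
  expect_equal(arrayCorrelationMatrix(b2, "spearman")["s01", "s99"], 1)
  expect_lt(arrayCorrelationMatrix(b2, "pearson")["s01", "s99"], 1)

  bNA <- b
  bNA[3:50, 2] <- NA   # only 2 complete probes against every other sample
  expect_warning(ccNA <- arrayCorrelationMatrix(bNA), "fewer than 3")
  expect_true(is.na(ccNA[1, 2]))
  expect_equal(ccNA[2, 2], 1)
})

test_that("SNP-style fingerprint probes make matched donors mutual nearest neighbours", {
  set.seed(42)
  nDonor <- 8
  geno <- matrix(sample(c(0.05, 0.5, 0.95), 57 * nDonor, replace = TRUE),
                 57, nDonor)
  noise1 <- matrix(rnorm(57 * nDonor, 0, 0.01), 57, nDonor)
  noise2 <- matrix(rnorm(57 * nDonor, 0, 0.01), 57, nDonor)
  b <- cbind(geno + noise1, geno + noise2)
  colnames(b) <- c(paste0("d", 1:nDonor, "_v1"), paste0("d", 1:nDonor, "_v2"))
  rownames(b) <- paste0("snp", 1:57)
  cc <- arrayCorrelationMatrix(b, method = "pearson")
  diag(cc) <- -Inf
  for (i in seq_len(nDonor)) {
    expect_equal(names(which.max(cc[paste0("d", i, "_v1"), ])),
                 paste0("d", i, "_v2"))
    expect_equal(names(which.max(cc[paste0("d", i, "_v2"), ])),
                 paste0("d", i, "_v1"))
  }
})

test_that("complete-linkage clustering recovers planted blocks", {
  skip_if_not_installed("mclust")
  # two blocks of near-identical samples
  set.seed(7)
  base <- matrix(runif(200, 0.1, 0.9), 100, 2)
  b <- cbind(base[, 1] + rnorm(100, 0, 0.005),
             base[, 1] + rnorm(100, 0, 0.005),
             base[, 1] + rnorm(100, 0, 0.005),
             base[, 2] + rnorm(100, 0, 0.005),
             base[, 2] + rnorm(100, 0, 0.005),
             base[, 2] + rnorm(100, 0, 0.005))
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(paste0("p", 1:100), paste0("s", 1:6))
  cc <- arrayCorrelationMatrix(b, "pearson")
  cl <- hierarchicalCluster(cc, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, rep(1:2, each = 3)), 1)

  # all-equal correlations cut at k = 1 form a single cluster
  flat <- matrix(0.9, 4, 4)
  diag(flat) <- 1
  dimnames(flat) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_equal(unname(hierarchicalCluster(flat, k = 1)$labels), rep(1L, 4))

  asym <- cc
  asym[1, 2] <- 0
  expect_error(hierarchicalCluster(asym), "symmetric")
})

test_that("probe-level Spearman matches the mid-rank oracle", {
  v1 <- rbind(p1 = c(0.1, 0.2, 0.3, 0.4),
              p2 = c(0.1, 0.2, 0.2, 0.4),
              p3 = c(0.4, 0.3, 0.2, 0.1))
  v2 <- rbind(p1 = c(0.1, 0.2, 0.3, 0.4),
              p2 = c(0.3, 0.1, 0.4, 0.2),
              p3 = c(0.1, 0.2, 0.3, 0.4))
  colnames(v1) <- colnames(v2) <- paste0("s", 1:4)
  rho <- probeSpearman(list(v1 = v1, v2 = v2))
  expect_equal(rho[["p1"]], 1)
  expect_equal(rho[["p3"]], -1)
  expect_equal(rho[["p2"]], -1 / sqrt(10), tolerance = 1e-12)
  expect_equal(rho[["p2"]], spearmanOracle(v1["p2", ], v2["p2", ]),
               tolerance = 1e-12)

  # random instances against the oracle
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(sample(seq(0.1, 0.9, by = 0.1), 16, replace = TRUE), 2, 8)
    y <- matrix(sample(seq(0.1, 0.9, by = 0.1), 16, replace = TRUE), 2, 8)
    dimnames(x) <- dimnames(y) <- list(c("a", "b"), paste0("s", 1:8))
    got <- probeSpearman(list(v1 = x, v2 = y))
    for (p in c("a", "b")) {
      want <- spearmanOracle(x[p, ], y[p, ])
      if (is.nan(want)) expect_true(is.na(got[[p]]))
      else expect_equal(got[[p]], want, tolerance = 1e-10)
    }
  }

  # zero-variance vectors yield NA
  z1 <- rbind(p = rep(0.5, 5)); z2 <- rbind(p = c(0.1, 0.2, 0.3, 0.4, 0.5))
  colnames(z1) <- colnames(z2) <- paste0("s", 1:5)
  expect_true(is.na(probeSpearman(list(v1 = z1, v2 = z2))[["p"]]))
})

test_that("pooled SD pools per-version variances with Bessel weights", {
  v1 <- rbind(p = c(0.1, 0.2, 0.3))
  v2 <- rbind(p = c(0.2, 0.4, NA))
  colnames(v1) <- colnames(v2) <- paste0("s", 1:3)
  got <- pooledSD(list(v1 = v1, v2 = v2))
  expect_equal(got[["p"]], sqrt(0.04 / 3), tolerance = 1e-12)
  expect_equal(got[["p"]],
               pooledSdOracle(c(0.1, 0.2, 0.3), c(0.2, 0.4)),
               tolerance = 1e-12)

  # constant vectors -> 0; doubling deviations doubles the pooled SD
  c1 <- rbind(p = rep(0.3, 4)); c2 <- rbind(p = rep(0.6, 4))
  colnames(c1) <- colnames(c2) <- paste0("s", 1:4)
  expect_equal(pooledSD(list(v1 = c1, v2 = c2))[["p"]], 0)
  a <- c(0.2, 0.3, 0.4); b <- c(0.5, 0.6, 0.7)
  a2 <- mean(a) + 2 * (a - mean(a)); b2 <- mean(b) + 2 * (b - mean(b))
  m1 <- function(v) matrix(v, 1, 3, dimnames = list("p", paste0("s", 1:3)))
  expect_equal(2 * pooledSD(list(v1 = m1(a), v2 = m1(b)))[["p"]],
               pooledSD(list(v1 = m1(a2), v2 = m1(b2)))[["p"]])
})

test_that("probe classification partitions and honours both threshold styles", {
  rho <- c(a = 0.9, b = 0.5, c = 0.5, d = NA)
  sd <- c(a = 0.05, b = 0.05, c = 0.005, d = 0.2)
  out <- classifyProbes(rho, sd, rhoThresh = 0.70, sdThresh = 0.01)
  expect_equal(as.character(out$klass[1:3]),
               c("concordant", "poorly_concordant", "low_variability"))
  expect_true(is.na(out$klass[4]))
  expect_equal(attr(out, "n_unclassified"), 1L)
  expect_equal(sum(attr(out, "counts")), 3L)

  # lower-quartile threshold computed from the pooled-SD distribution
  set.seed(5)
  rho2 <- runif(200, -1, 1)
  sd2 <- runif(200, 0, 0.2)
  names(rho2) <- names(sd2) <- paste0("p", 1:200)
  out2 <- classifyProbes(rho2, sd2)
  expect_equal(attr(out2, "sd_threshold"),
               unname(quantile(sd2, 0.25)), tolerance = 1e-12)
  # partition: every classified probe in exactly one class
  expect_equal(sum(attr(out2, "counts")) + attr(out2, "n_unclassified"),
               200L)
})

test_that("replicate RMSE and ICC match their ANOVA oracles", {
  a <- c(p1 = 0.1, p2 = 0.5)
  b <- c(p1 = 0.3, p2 = 0.5)
  expect_equal(replicateRMSE(a, b), sqrt(0.02), tolerance = 1e-12)
  expect_equal(replicateRMSE(a, a), 0)
  expect_equal(replicateRMSE(a, a + 0.1), 0.1, tolerance = 1e-12)

  m <- rbind(c(0.1, 0.12), c(0.5, 0.49), c(0.8, 0.83), c(0.3, 0.31))
  expect_equal(replicateICC(m), icc21Oracle(m), tolerance = 1e-10)

  # identical replicates with probe-to-probe variance -> ICC 1
  mm <- cbind(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(replicateICC(mm), 1)

  # ICC decreases as independent replicate noise grows
  set.seed(21)
  base <- runif(300, 0.1, 0.9)
  iccs <- vapply(c(0.01, 0.05, 0.15), function(s)
    replicateICC(cbind(base, pmin(pmax(base + rnorm(300, 0, s), 0), 1))),
    numeric(1))
  expect_true(all(diff(iccs) < 0))

  # zero total variance -> undefined
  expect_true(is.na(replicateICC(matrix(0.5, 5, 2))))
})
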