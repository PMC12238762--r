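test_that("batch adjustment: identity, location oracle, sva agreement", {
  set.seed(9)
  d <- matrix(runif(150 * 12, 0.2, 0.8), 150, 12,
              dimnames = list(paste0("p", 1:150), paste0("s", 1:12)))

  # single batch level: nothing to correct
  same <- combatAdjust(d, batch = rep("a", 12))
  expect_equal(unname(same), unname(d), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pure per-probe mean shift, shrinkage off: equals per-batch
  # mean-centering with the weighted grand mean restored, up to the
  # per-batch scale factor; check batch means equalize per probe
  batch <- rep(c("a", "b"), each = 6)
  shift <- matrix(0, 150, 12)
  shift[, batch == "b"] <- rnorm(150) * 0.05
  d2 <- pmin(pmax(d + shift, 0.01), 0.99)
  adj <- combatAdjust(d2, batch, shrink = FALSE)
  mA <- rowMeans(adj[, batch == "a"])
  mB <- rowMeans(adj[, batch == "b"])
  expect_equal(mA, mB, tolerance = 1e-10)
  grand <- 0.5 * rowMeans(d2[, batch == "a"]) +
    0.5 * rowMeans(d2[, batch == "b"])
  expect_equal(mA, grand, tolerance = 1e-10)

  # parametric EB version agrees with the reference implementation
  skip_if_not_installed("sva")
  mine <- combatAdjust(d2, batch)
  theirs <- suppressMessages(sva::ComBat(dat = d2, batch = batch))
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(combatAdjust(d, batch = c(rep("a", 11), "b")),
               "single sample")
})

test_that("covariate effects orthogonal to batch survive correction", {
  set.seed(10)
  n <- 40
  age <- rep(runif(n / 2, 25, 85), 2)   # matched design: age balanced
  batch <- rep(c("v1", "v2"), each = n / 2)
  slope <- runif(100, -0.003, 0.003)
  d <- 0.5 + outer(slope, age - mean(age)) +
    matrix(rnorm(100 * n, 0, 0.01), 100, n)
  d[, batch == "v2"] <- d[, batch == "v2"] + rnorm(100) * 0.05
  d <- pmin(pmax(d, 0.01), 0.99)
  dimnames(d) <- list(paste0("p", 1:100), paste0("s", 1:n))
  adj <- combatAdjust(d, batch)
  # recovered per-probe age slopes stay close to the injected ones
  fitSlope <- function(m) apply(m, 1, function(y) coef(lm(y ~ age))[2])
  got <- fitSlope(adj)
  strong <- abs(slope) > 0.002
  expect_lt(median(abs(got[strong] - slope[strong]) / abs(slope[strong])),
            0.05)

  # confounded covariate is rejected
  expect_error(combatAdjust(d, batch,
                            covariates = data.frame(v = batch)),
               "confounded")
})

test_that("sequential correction runs version, chip, row and is idempotent", {
  cfg <- simConfig(seed = 14, nDonors = 16, nCpgs = 800,
                   nTechReplicates = 0)
  sim <- simulateCohort(cfg)
  hc <- harmonizedCohort(sim)
  comb <- cbind(betaValues(pairV1(hc$pair)), betaValues(pairV2(hc$pair)))
  sheet <- hc$sheet[match(colnames(comb), hc$sheet$sample_id), ]
  # re-running single-variable correction without shrinkage only rescales
  # residuals by the known degrees-of-freedom factor sqrt((N - B) / N)
  # (batch variances use n - 1, the pooled variance uses N), so a second
  # pass is a deterministic ~0.4% contraction toward the grand mean
  v <- sheet$version
  adjV <- suppressMessages(combatAdjust(comb, v, shrink = FALSE))
  adjVV <- suppressMessages(combatAdjust(adjV, v, shrink = FALSE))
  clipped <- rowSums(adjV <= 1e-6 | adjV >= 1 - 1e-6) > 0
  grand <- rowMeans(adjV)
  N <- ncol(adjV)
  want <- grand + (adjV - grand) * sqrt((N - 2) / N)
  expect_lt(max(abs(adjVV[!clipped, ] - want[!clipped, ])), 1e-8)

  # a second pass of the full sequential driver is only a marginal
  # perturbation (scale steps of nested batch variables interact)
  eb1 <- suppressMessages(combatSequential(comb, sheet))
  eb2 <- suppressMessages(combatSequential(eb1, sheet))
  expect_lt(median(abs(eb1 - eb2)), 0.01)

  # a single-level batch variable is skipped, not an error
  sheet$facility <- "one"
  expect_message(combatSequential(comb, sheet, batches = "facility"),
                 "single level")
})

test_that("paired comparisons match the t oracle with effect-size classes", {
  # zero-mean differences
  out <- pairedCompare(matrix(c(0, 0, 0)), matrix(c(0.01, -0.01, 0)),
                       endpoints = "e")
  expect_equal(out$t_stat, 0)
  expect_equal(out$p_value, 1)
  expect_equal(as.character(out$d_class), "negligible")

  # constant-slope differences: d = mean/sd = 2, class large
  v1 <- c(0.10, 0.20, 0.30)
  v2 <- c(0.12, 0.24, 0.36)
  out2 <- pairedCompare(matrix(v1), matrix(v2), endpoints = "e")
  expect_equal(out2$cohens_d, 2, tolerance = 1e-12)
  expect_equal(as.character(out2$d_class), "large")
  orc <- pairedTOracle(v1, v2)
  expect_equal(out2$t_stat, orc$t, tolerance = 1e-10)
  expect_equal(out2$p_value, orc$p, tolerance = 1e-10)

  # random instances against t.test
  set.seed(33)
  for (i in 1:10) {
    a <- runif(8); b <- a + rnorm(8, 0.02, 0.05)
    got <- pairedCompare(matrix(a), matrix(b), endpoints = "x")
    orc <- pairedTOracle(a, b)
    expect_equal(got$t_stat, orc$t, tolerance = 1e-10)
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  }

  # class boundaries follow the conventional benchmarks
  mk <- function(d) {
    diffs <- c(-0.01, 0, 0.01) + d * 0.01   # sd = 0.01, mean = d * 0.01
    pairedCompare(matrix(rep(0, 3)), matrix(diffs), endpoints = "e")
  }
  expect_equal(as.character(mk(0.6)$d_class), "medium")
  expect_equal(as.character(mk(0.3)$d_class), "small")
  expect_equal(as.character(mk(0.85)$d_class), "large")

  # Bonferroni family = endpoints in the call
  set.seed(44)
  m1 <- matrix(runif(30), 10, 3)
  m2 <- m1 + matrix(rnorm(30, 0, 0.05), 10, 3)
  colnames(m1) <- colnames(m2) <- c("a", "b", "c")
  out3 <- pairedCompare(m1, m2)
  expect_equal(out3$p_bonferroni, pmin(1, out3$p_value * 3),
               tolerance = 1e-12)

  # degenerate: identical nonzero shift with zero difference SD
  # (binary-exact values keep the differences exactly constant)
  outD <- pairedCompare(matrix(c(0.125, 0.25, 0.375)),
                        matrix(c(0.125, 0.25, 0.375) + 0.25),
                        endpoints = "e")
  expect_true(outD$degenerate)
  expect_equal(outD$p_value, 0)
})
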