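test_that("beta matrix round-trips through CSV bit-identically", {
  b <- tinyBeta(3, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeBetaMatrix(b, path)
  expect_identical(readBetaMatrix(path), b)
})

test_that("schema and range violations are rejected with informative errors", {
  sheet <- tinySheet("s1", "d1", "v1")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(sheet[, setdiff(names(sheet), "version")], path,
            row.names = FALSE)
  expect_error(readSampleSheet(path), "version")

  b <- tinyBeta(2, 2)
  b[2, 1] <- 1.2
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(probe_id = rownames(b), b), path2, row.names = FALSE)
  expect_error(readBetaMatrix(path2), "cg00002/s01")

  expect_error(MethylationSet(b), "outside")
})

test_that("manifest and sheet validators enforce the replicate contracts", {
  m <- tinyManifest(c("p1", "p2"))
  expect_silent(validateProbeManifest(m))
  m2 <- tinyManifest(c("a_r1", "a_r2"), baseCpgs = "a", version = "v2",
                     replicateIndex = c(1L, 1L))
  expect_error(validateProbeManifest(m2), "distinct")
  m3 <- tinyManifest("p1", replicateIndex = 2L)
  expect_error(validateProbeManifest(m3), "replicate_index 1")

  sh <- tinySheet(c("s1", "s2"), c("d1", "d2"), c("v1", "v1"),
                  replicateOf = c(NA, "s1"))
  expect_error(validateSampleSheet(sh), "same donor")
})

test_that("coefficient sets round-trip with metadata and reference means", {
  coef <- CoefficientSet("clockX", weights = c(cg1 = 0.5, cg2 = -0.2),
                         intercept = 1.25, transform = "horvath_antilog",
                         adultAge = 20,
                         referenceMeans = c(cg1 = 0.4, cg2 = 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCoefficientSet(coef, path)
  back <- readCoefficientSet(path)
  expect_equal(scoreWeights(back), scoreWeights(coef))
  expect_equal(back@intercept, 1.25)
  expect_equal(back@transform, "horvath_antilog")
  expect_equal(back@referenceMeans[names(coef@referenceMeans)],
               coef@referenceMeans)
})

test_that("probe flagging follows the strict >1% rule on both criteria", {
  n <- 100
  detp <- matrix(0.001, 3, n,
                 dimnames = list(c("pA", "pB", "pC"), paste0("s", 1:n)))
  bead <- matrix(10, 3, n, dimnames = dimnames(detp))
  detp["pA", 1:2] <- 0.5     # fails in 2% of samples -> flagged
  detp["pB", 1] <- 0.5       # fails in exactly 1% -> not flagged
  bead["pC", 1:5] <- 2       # beadcount branch -> flagged
  flagged <- flagLowQualityProbes(detectionP = detp, beadcount = bead)
  expect_setequal(flagged, c("pA", "pC"))

  # monotone: lowering the detection-p threshold never unflags a probe
  f1 <- flagLowQualityProbes(detectionP = detp, pThresh = 0.01)
  f2 <- flagLowQualityProbes(detectionP = detp, pThresh = 0.001)
  expect_true(all(f1 %in% f2))

  expect_error(flagLowQualityProbes(detectionP = detp[, 0]), "empty")
})

test_that("replicate collapsing honours all three strategies", {
  beta <- rbind(a_r1 = c(0.50, 0.52), a_r2 = c(0.60, 0.62),
                b_r1 = c(0.30, 0.31))
  colnames(beta) <- c("s1", "s2")
  man <- data.frame(probe_id = rownames(beta),
                    base_cpg = c("a", "a", "b"), version = "v2",
                    replicate_index = c(1L, 2L, 1L))
  detp <- matrix(c(0.2, 0.2, 0.001, 0.001, 0.01, 0.01), 3, 2,
                 byrow = TRUE, dimnames = dimnames(beta))

  out <- collapseReplicateProbes(beta, man, detp, strategy = "detp")
  expect_equal(out["a", ], c(s1 = 0.60, s2 = 0.62))   # lowest mean detp row
  expect_equal(out["b", ], c(s1 = 0.30, s2 = 0.31))   # singleton unchanged

  out <- collapseReplicateProbes(beta, man, strategy = "mean")
  expect_equal(out["a", ], c(s1 = 0.55, s2 = 0.57))

  beta3 <- rbind(beta, a_r3 = c(0.90, 0.92))
  man3 <- rbind(man, data.frame(probe_id = "a_r3", base_cpg = "a",
                                version = "v2", replicate_index = 3L))
  out <- collapseReplicateProbes(beta3, man3, strategy = "median")
  expect_equal(out["a", ], c(s1 = 0.60, s2 = 0.62))

  expect_error(collapseReplicateProbes(beta, man, strategy = "detp"),
               "detection p")

  # identical replicates collapse identically under every strategy
  betaEq <- rbind(a_r1 = c(0.4, 0.5), a_r2 = c(0.4, 0.5))
  colnames(betaEq) <- c("s1", "s2")
  manEq <- data.frame(probe_id = rownames(betaEq), base_cpg = "a",
                      version = "v2", replicate_index = 1:2)
  detpEq <- matrix(0.01, 2, 2, dimnames = dimnames(betaEq))
  res <- lapply(c("detp", "mean", "median"), function(s)
    collapseReplicateProbes(betaEq, manEq, detpEq, strategy = s))
  expect_equal(res[[1]], res[[2]])
  expect_equal(res[[2]], res[[3]])

  # detp ties break by lowest replicate index
  detpTie <- matrix(0.01, 3, 2, dimnames = dimnames(beta))
  out <- collapseReplicateProbes(beta, man, detpTie, strategy = "detp")
  expect_equal(out["a", ], c(s1 = 0.50, s2 = 0.52))
})

test_that("harmonization aligns on the sorted intersection and is idempotent", {
  b1 <- tinyBeta(3, 2)
  rownames(b1) <- c("a", "b", "c")
  b2 <- tinyBeta(3, 2, seed = 2)
  rownames(b2) <- c("b", "c", "d")
  h <- harmonizeSharedProbes(b1, b2)
  expect_identical(rownames(h$v1), c("b", "c"))
  expect_identical(h$v1_only, "a")
  expect_identical(h$v2_only, "d")

  h2 <- harmonizeSharedProbes(h$v1, h$v2)
  expect_identical(h2$v1, h$v1)
  expect_identical(h2$v2, h$v2)

  rownames(b2) <- c("x", "y", "z")
  expect_error(harmonizeSharedProbes(b1, b2), "no shared")
})

test_that("sample matching pairs donors and enumerates replicates", {
  sheet <- rbind(
    tinySheet(c("D_v1", "D_v2"), "D", c("v1", "v2")),
    tinySheet("E_v1", "E", "v1"),
    tinySheet(c("F_v2", "F_v2r"), "F", c("v2", "v2"),
              replicateOf = c(NA, "F_v2")))
  expect_warning(res <- matchSamples(sheet), "E")
  expect_equal(res$donor_pairs$donor_id, "D")
  expect_equal(nrow(res$within_version), 1L)
  expect_equal(res$within_version$replicate, "F_v2r")
  # F lacks a v1 primary, so no between-version pair exists
  expect_equal(nrow(res$between_version), 0L)

  amb <- rbind(tinySheet(c("G1", "G2", "G3"), "G", c("v1", "v1", "v2")))
  expect_error(matchSamples(amb), "more than one primary")
})
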