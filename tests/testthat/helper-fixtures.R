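# Small in-code fixtures shared across test files.

tinyBeta <- function(nProbes = 3, nSamples = 2, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  matrix(round(runif(nProbes * nSamples, 0.05, 0.95), 6), nProbes, nSamples,
         dimnames = list(sprintf("cg%05d", seq_len(nProbes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

tinySheet <- function(sampleIds, donorIds, versions,
                      replicateOf = NA_character_, age = 50, sex = "F") {
  n <- length(sampleIds)
  data.frame(sample_id = sampleIds, donor_id = donorIds,
             version = versions, cohort = "C", sex = rep_len(sex, n),
             age = rep_len(age, n), chip = "chip1", row = "R01",
             facility = "lab", replicate_of = rep_len(replicateOf, n))
}

tinyManifest <- function(probeIds, baseCpgs = probeIds, version = "v1",
                         replicateIndex = 1L) {
  data.frame(probe_id = probeIds, base_cpg = baseCpgs,
             version = rep_len(version, length(probeIds)),
             replicate_index = rep_len(as.integer(replicateIndex),
                                       length(probeIds)))
}

# Scenario configuration used by the version-offset remediation tests:
# 60 matched donors, 5,000 fully shared CpGs, a +3 y clock-output shift on
# v2 plus broad version offsets so the version signature is visible on PC1.
eaaScenarioConfig <- function(seed) {
  simConfig(seed = seed, nDonors = 60, nCpgs = 5000, fracShared = 1,
            clockVersionShiftYears = 3, fracVersionShifted = 0.5,
            versionOffsetSd = 0.8)
}

# Harmonize a simulated cohort (detp collapsing) and return the pieces
# most tests need.
harmonizedCohort <- function(sim) {
  v2c <- collapseReplicateProbes(sim$v2, strategy = "detp")
  pair <- harmonizeSharedProbes(sim$v1, v2c)
  sheet <- rbind(sampleSheet(sim$v1), sampleSheet(sim$v2))
  pairs <- suppressWarnings(matchSamples(sheet))
  list(pair = pair, sheet = sheet, pairs = pairs)
}
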