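#' Simulation configuration for a matched two-version cohort
#'
#' Holds every knob of the synthetic-cohort generator. The signal model
#' lives in logit space, where version offsets, chip/row effects and
#' technical noise are additive and the observed beta values stay strictly
#' inside (0, 1); all `*Sd` parameters are therefore in logit units.
#' Clock CpGs are the exception: their age signal is linear on the beta
#' scale so that a linear CpG score can be calibrated to return
#' chronological age exactly in the noiseless limit.
#'
#' The seed fully determines all outputs: identical configurations produce
#' bit-identical cohorts.
#'
#' @slot seed Integer RNG seed (keep below 2^31 - 16; several fixed small
#'   offsets derive sub-streams).
#' @slot nDonors Donors with one matched array per version.
#' @slot nCpgs Base CpGs in the simulated probe universe.
#' @slot fracShared Fraction of base CpGs present on both versions (the
#'   rest split evenly between v1-only and v2-only).
#' @slot fracV2Replicated Fraction of v2 base CpGs carrying replicate
#'   probes (2 to `maxReplicates` each).
#' @slot maxReplicates Upper bound on replicate probes per base CpG (2-10).
#' @slot nCellTypes Immune cell types in the mixing model (default 12).
#' @slot nMarkerProbesPerType Cell-discriminating probes planted per type.
#' @slot nClockCpgs CpGs carrying the chronological-age signal.
#' @slot ageRange Donor age range in years.
#' @slot versionOffsetSd SD of per-probe version offsets (logit units).
#' @slot fracVersionShifted Fraction of probes receiving a version offset.
#' @slot fracDiscordant Fraction of shared background probes rendered
#'   discordant (independent per-version noise).
#' @slot discordantNoiseSd SD of the independent discordant noise.
#' @slot techNoiseSd SD of per-measurement technical noise.
#' @slot chipEffectSd,rowEffectSd SDs of per-(probe, chip) and
#'   per-(probe, row) batch effects.
#' @slot nTechReplicates Technical replicate arrays per version.
#' @slot fracFemale Fraction of female donors.
#' @slot fracLowVariability Fraction of probes drawn from the
#'   low-biological-variability regime.
#' @slot refNoiseSd Within-cell-type noise of purified reference samples.
#' @slot nRefSamplesPerType Purified reference samples per cell type.
#' @slot clockVersionShiftYears Version offset injected at clock CpGs,
#'   expressed in years of clock output shift on v2 (default 0).
#' @slot fracFailedDetp Fraction of probe-sample cells with uniform
#'   (failed) detection p-values.
#' @slot dirichletAlpha Dirichlet concentration vector of the cell-mixing
#'   proportions; empty means the built-in whole-blood-like default
#'   (neutrophil-dominant).
#' @export
setClass("SimConfig", representation(
  seed = "integer", nDonors = "integer", nCpgs = "integer",
  fracShared = "numeric", fracV2Replicated = "numeric",
  maxReplicates = "integer", nCellTypes = "integer",
  nMarkerProbesPerType = "integer", nClockCpgs = "integer",
  ageRange = "numeric", versionOffsetSd = "numeric",
  fracVersionShifted = "numeric", fracDiscordant = "numeric",
  discordantNoiseSd = "numeric", techNoiseSd = "numeric",
  chipEffectSd = "numeric", rowEffectSd = "numeric",
  nTechReplicates = "integer", fracFemale = "numeric",
  fracLowVariability = "numeric", refNoiseSd = "numeric",
  nRefSamplesPerType = "integer", clockVersionShiftYears = "numeric",
  fracFailedDetp = "numeric", dirichletAlpha = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(fracShared = object@fracShared,
          fracV2Replicated = object@fracV2Replicated,
          fracVersionShifted = object@fracVersionShifted,
          fracDiscordant = object@fracDiscordant,
          fracFemale = object@fracFemale,
          fracLowVariability = object@fracLowVariability,
          fracFailedDetp = object@fracFailedDetp)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, paste("fraction(s) outside [0, 1]:",
                        paste(names(fr)[fr < 0 | fr > 1], collapse = ", ")))
  sds <- c(object@versionOffsetSd, object@discordantNoiseSd,
           object@techNoiseSd, object@chipEffectSd, object@rowEffectSd,
           object@refNoiseSd)
  if (any(sds < 0)) msg <- c(msg, "noise SDs must be non-negative")
  if (object@maxReplicates < 2L || object@maxReplicates > 10L)
    msg <- c(msg, "maxReplicates must lie in 2..10")
  if (object@nCellTypes < 2L) msg <- c(msg, "need at least 2 cell types")
  if (object@nCellTypes * object@nMarkerProbesPerType +
      object@nClockCpgs > object@nCpgs)
    msg <- c(msg, "marker + clock probes exceed nCpgs")
  if (object@seed >= 2^31 - 16)
    msg <- c(msg, "seed too large (must stay below 2^31 - 16)")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0 ||
      any(object@ageRange < 0))
    msg <- c(msg, "ageRange must be an increasing non-negative pair")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class Constructor with study-condition defaults:
#'   50 matched donors, 20,000 base CpGs of which 90% are shared, ~0.5% of
#'   v2 CpGs replicated, 12 cell types with 50 markers each, 100 clock
#'   CpGs, ages 25-85, version offsets of SD 0.4 logit on 20% of probes,
#'   5% discordant probes (independent noise SD 1.5), technical noise SD
#'   0.07, chip/row effects 0.05/0.02, and 2 technical replicate arrays
#'   per version.
#' @param seed,nDonors,nCpgs,fracShared,fracV2Replicated,maxReplicates See
#'   slots.
#' @param nCellTypes,nMarkerProbesPerType,nClockCpgs,ageRange See slots.
#' @param versionOffsetSd,fracVersionShifted,fracDiscordant See slots.
#' @param discordantNoiseSd,techNoiseSd,chipEffectSd,rowEffectSd See slots.
#' @param nTechReplicates,fracFemale,fracLowVariability,refNoiseSd See
#'   slots.
#' @param nRefSamplesPerType,clockVersionShiftYears,fracFailedDetp See
#'   slots.
#' @param dirichletAlpha See slots.
#' @export
simConfig <- function(seed = 1, nDonors = 50, nCpgs = 20000,
                      fracShared = 0.9, fracV2Replicated = 0.005,
                      maxReplicates = 10, nCellTypes = 12,
                      nMarkerProbesPerType = 50, nClockCpgs = 100,
                      ageRange = c(25, 85), versionOffsetSd = 0.4,
                      fracVersionShifted = 0.2, fracDiscordant = 0.05,
                      discordantNoiseSd = 1.5, techNoiseSd = 0.07,
                      chipEffectSd = 0.05, rowEffectSd = 0.02,
                      nTechReplicates = 2, fracFemale = 0.5,
                      fracLowVariability = 0.3, refNoiseSd = 0.1,
                      nRefSamplesPerType = 6,
                      clockVersionShiftYears = 0, fracFailedDetp = 0.002,
                      dirichletAlpha = numeric()) {
  new("SimConfig", seed = as.integer(seed), nDonors = as.integer(nDonors),
      nCpgs = as.integer(nCpgs), fracShared = fracShared,
      fracV2Replicated = fracV2Replicated,
      maxReplicates = as.integer(maxReplicates),
      nCellTypes = as.integer(nCellTypes),
      nMarkerProbesPerType = as.integer(nMarkerProbesPerType),
      nClockCpgs = as.integer(nClockCpgs), ageRange = as.numeric(ageRange),
      versionOffsetSd = versionOffsetSd,
      fracVersionShifted = fracVersionShifted,
      fracDiscordant = fracDiscordant,
      discordantNoiseSd = discordantNoiseSd, techNoiseSd = techNoiseSd,
      chipEffectSd = chipEffectSd, rowEffectSd = rowEffectSd,
      nTechReplicates = as.integer(nTechReplicates),
      fracFemale = fracFemale, fracLowVariability = fracLowVariability,
      refNoiseSd = refNoiseSd,
      nRefSamplesPerType = as.integer(nRefSamplesPerType),
      clockVersionShiftYears = clockVersionShiftYears,
      fracFailedDetp = fracFailedDetp,
      dirichletAlpha = as.numeric(dirichletAlpha))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "-", object@nDonors, "donors x",
      object@nCpgs, "base CpGs,", object@nCellTypes, "cell types\n")
  cat("  version offsets: sd", object@versionOffsetSd, "on",
      object@fracVersionShifted * 100, "% of probes;",
      object@fracDiscordant * 100, "% discordant\n")
})

## Whole-blood-like mixing baseline (neutrophil-dominant), concentration 60.
.bloodAlpha <- function(nCellTypes) {
  if (nCellTypes == 12L) {
    p0 <- c(Bas = 0.005, Bmem = 0.03, Bnv = 0.02, CD4mem = 0.09,
            CD4nv = 0.07, CD8mem = 0.05, CD8nv = 0.04, Eos = 0.025,
            Mono = 0.08, Neu = 0.53, NK = 0.05, Treg = 0.01)
    return(60 * p0)
  }
  stats::setNames(rep(5, nCellTypes), paste0("ct", seq_len(nCellTypes)))
}

## Deterministic per-probe ground-truth layout shared by simulateReference,
## simulateCoefficients and simulateCohort. Sub-stream: seed + 0.
.simLayout <- function(config) {
  c0 <- config
  withSeed(c0@seed, {
    nC <- c0@nCpgs
    probeIds <- sprintf("cg%08d", seq_len(nC))
    role <- rep("background", nC)

    nMark <- c0@nCellTypes * c0@nMarkerProbesPerType
    nSex <- round(0.01 * nC)
    pool <- sample.int(nC)                 # random role placement
    markerIdx <- pool[seq_len(nMark)]
    clockIdx <- pool[nMark + seq_len(c0@nClockCpgs)]
    sexIdx <- pool[nMark + c0@nClockCpgs + seq_len(nSex)]
    role[markerIdx] <- "marker"
    role[clockIdx] <- "clock"
    role[sexIdx] <- "sex"
    markerType <- rep(NA_integer_, nC)
    markerType[markerIdx] <- rep(seq_len(c0@nCellTypes),
                                 each = c0@nMarkerProbesPerType)
    markerDir <- rep(NA_integer_, nC)
    markerDir[markerIdx] <- rep(rep(c(1L, -1L),
                                    length.out = c0@nMarkerProbesPerType),
                                times = c0@nCellTypes)

    ## bimodal background logit means, typical of methylation arrays
    comp <- sample.int(3L, nC, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    baseLogit <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(nC) *
      c(1, 1, 1.2)[comp]

    ## clock CpGs: beta-linear age calibration kept inside (0.1, 0.9)
    aMax <- c0@ageRange[2L]
    sMag <- stats::runif(c0@nClockCpgs, 0.002, 0.005)
    sSign <- sample(c(-1, 1), c0@nClockCpgs, replace = TRUE)
    clockS <- sMag * sSign
    clockM <- ifelse(sSign > 0,
                     stats::runif(c0@nClockCpgs, 0.1, 0.9 - sMag * aMax),
                     stats::runif(c0@nClockCpgs, 0.1 + sMag * aMax, 0.9))

    sexShift <- stats::runif(nSex, 0.8, 1.5) *
      sample(c(-1, 1), nSex, replace = TRUE)

    lowVar <- stats::runif(nC) < c0@fracLowVariability
    bioSd <- ifelse(lowVar, stats::runif(nC, 0.01, 0.1),
                    stats::runif(nC, 0.4, 1.2))
    bioSd[clockIdx] <- 0                    # age is their biological signal

    u <- stats::runif(nC)
    shared <- ifelse(u < c0@fracShared, "both",
                     ifelse(u < c0@fracShared + (1 - c0@fracShared) / 2,
                            "v1", "v2"))

    onV2 <- shared %in% c("both", "v2")
    repCount <- rep(1L, nC)
    candidates <- which(onV2)
    nRep <- round(c0@fracV2Replicated * length(candidates))
    if (nRep > 0) {
      repIdx <- sample(candidates, nRep)
      repCount[repIdx] <- sample(2:c0@maxReplicates, nRep, replace = TRUE)
    }

    ## random version offsets avoid clock CpGs: their version effect is
    ## controlled explicitly through clockVersionShiftYears
    versionOffset <- numeric(nC)
    shiftPool <- setdiff(seq_len(nC), clockIdx)
    nShift <- round(c0@fracVersionShifted * nC)
    nShift <- min(nShift, length(shiftPool))
    if (nShift > 0) {
      shiftIdx <- sample(shiftPool, nShift)
      versionOffset[shiftIdx] <- stats::rnorm(nShift) * c0@versionOffsetSd
    }

    discordant <- rep(FALSE, nC)
    discPool <- which(shared == "both" & role == "background")
    nDisc <- round(c0@fracDiscordant * sum(shared == "both"))
    nDisc <- min(nDisc, length(discPool))
    if (nDisc > 0) discordant[sample(discPool, nDisc)] <- TRUE

    list(probeIds = probeIds, role = role, markerType = markerType,
         markerDir = markerDir, baseLogit = baseLogit,
         clockIdx = clockIdx, clockM = clockM, clockS = clockS,
         sexIdx = sexIdx, sexShift = sexShift, bioSd = bioSd,
         shared = shared, repCount = repCount,
         versionOffset = versionOffset, discordant = discordant)
  })
}

## Beta-scale cell-type mean matrix (probes x cell types) implied by the
## layout; clock CpGs sit at their mid-age value, identical across types.
.refMeansFromLayout <- function(layout, config) {
  nC <- config@nCpgs
  K <- config@nCellTypes
  sep <- 3                                   # logit separation of markers
  alpha <- if (length(config@dirichletAlpha)) config@dirichletAlpha else
    .bloodAlpha(K)
  L <- matrix(layout$baseLogit, nC, K)
  mi <- which(layout$role == "marker")
  for (p in mi) {
    t <- layout$markerType[p]
    L[p, ] <- -layout$markerDir[p] * sep / 2
    L[p, t] <- layout$markerDir[p] * sep / 2
  }
  M <- invlogit(L)
  ci <- layout$clockIdx
  midAge <- mean(config@ageRange)
  M[ci, ] <- layout$clockM + layout$clockS * midAge
  dimnames(M) <- list(layout$probeIds, names(alpha))
  M
}

#' Simulate a purified-cell reference resource
#'
#' Builds the reference library implied by the configuration (marker
#' probes carry cell-specific logit means separated by 3 logit units,
#' background probes share one mean across types) and draws purified
#' reference samples around the cell means with within-type logit noise
#' `refNoiseSd`.
#'
#' @param config A [SimConfig-class].
#' @return List with `reference` (a [CellTypeReference-class] over all
#'   simulated probes) and `samples` (list with beta matrix `beta` and
#'   label vector `cellType`).
#' @export
simulateReference <- function(config) {
  stopifnot(is(config, "SimConfig"))
  layout <- .simLayout(config)
  M <- .refMeansFromLayout(layout, config)
  withSeed(config@seed + 4L, {
    K <- config@nCellTypes
    nPer <- config@nRefSamplesPerType
    beta <- matrix(NA_real_, nrow(M), K * nPer)
    ct <- rep(colnames(M), each = nPer)
    colnames(beta) <- sprintf("ref_%s_%d", ct, rep(seq_len(nPer), K))
    rownames(beta) <- rownames(M)
    for (j in seq_len(ncol(beta))) {
      mu <- M[, ct[j]]
      beta[, j] <- invlogit(logit(mu) +
                              stats::rnorm(nrow(M)) * config@refNoiseSd)
    }
    list(reference = CellTypeReference(M),
         samples = list(beta = beta, cellType = ct))
  })
}

#' Simulate a clock coefficient set calibrated to chronological age
#'
#' The planted clock CpGs carry beta-scale age slopes; weights are chosen
#' to invert that linear map (w_c = 1 / (K s_c), intercept absorbing the
#' CpG baselines), so the noiseless cohort score equals chronological age
#' exactly. Training means at the mid-age are shipped as reference means
#' for missing-CpG imputation.
#'
#' @param config A [SimConfig-class].
#' @return A [CoefficientSet-class] named `"sim_clock"`.
#' @export
simulateCoefficients <- function(config) {
  stopifnot(is(config, "SimConfig"))
  layout <- .simLayout(config)
  cpgs <- layout$probeIds[layout$clockIdx]
  K <- length(cpgs)
  w <- 1 / (K * layout$clockS)
  names(w) <- cpgs
  intercept <- -sum(w * layout$clockM)
  refMeans <- layout$clockM + layout$clockS * mean(config@ageRange)
  names(refMeans) <- cpgs
  CoefficientSet(name = "sim_clock", weights = w, intercept = intercept,
                 transform = "identity", referenceMeans = refMeans)
}

#' Simulate a matched two-version cohort with ground truth
#'
#' Generates matched EPICv1/EPICv2-style arrays for `nDonors` donors plus
#' technical replicates. Donor truth on the logit scale is the logit of
#' the cell-mean mixture under Dirichlet mixing weights, plus a sex shift
#' at a probe subset and a per-probe donor random effect; clock CpGs
#' instead follow their beta-linear age calibration. Observations add the
#' per-probe version offset (v2 only), chip and row effects, and
#' technical noise, all in logit space, so every beta value stays in
#' (0, 1). Discordant probes receive independent per-version noise. The
#' v2 array carries replicate probes (same base signal, independent
#' noise) and each version drops its version-unique base CpGs. Detection
#' p-values are Beta(0.1, 10) for well-behaved cells with a configurable
#' uniform (failed) fraction; beadcounts are Poisson(13) clamped at 1.
#'
#' @param config A [SimConfig-class].
#' @param ref Optional output of [simulateReference()] (regenerated from
#'   `config` when NULL).
#' @param coef Optional [CoefficientSet-class] from
#'   [simulateCoefficients()] (regenerated when NULL).
#' @return List with elements `v1` and `v2` ([MethylationSet-class]
#'   objects including QC assays, manifest and sample sheet) and `truth`,
#'   a ground-truth list: `mixing` (donors x cell types), `versionOffset`
#'   (named per base CpG), `discordant` (base CpG ids), `clock` (cpgs,
#'   intercepts m, slopes s), `age`/`sex` per donor, `bioSd`, `role`, and
#'   the `config`.
#' @export
simulateCohort <- function(config, ref = NULL, coef = NULL) {
  stopifnot(is(config, "SimConfig"))
  layout <- .simLayout(config)
  M <- .refMeansFromLayout(layout, config)
  withSeed(config@seed + 1L, {
    nD <- config@nDonors
    nC <- config@nCpgs
    K <- config@nCellTypes
    alpha <- if (length(config@dirichletAlpha)) config@dirichletAlpha else
      .bloodAlpha(K)
    donors <- sprintf("d%03d", seq_len(nD))
    age <- stats::runif(nD, config@ageRange[1L], config@ageRange[2L])
    sex <- ifelse(stats::runif(nD) < config@fracFemale, "F", "M")
    W <- matrix(stats::rgamma(nD * K, shape = rep(alpha, each = nD)),
                nD, K)
    W <- W / rowSums(W)
    dimnames(W) <- list(donors, names(alpha))

    ## donor truth on the logit scale
    Tb <- M %*% t(W)                        # beta-scale mixture
    ci <- layout$clockIdx
    Tb[ci, ] <- layout$clockM + outer(layout$clockS, age)
    L <- logit(pmin(pmax(Tb, 1e-6), 1 - 1e-6))
    fem <- which(sex == "F")
    if (length(fem))
      L[layout$sexIdx, fem] <- L[layout$sexIdx, fem] + layout$sexShift
    bio <- matrix(stats::rnorm(nC * nD), nC, nD) * layout$bioSd
    L <- L + bio

    ## per-version true signal
    L1 <- L
    L2 <- L + layout$versionOffset
    if (config@clockVersionShiftYears != 0) {
      shifted <- pmin(pmax(Tb[ci, , drop = FALSE] +
                             layout$clockS * config@clockVersionShiftYears,
                           1e-6), 1 - 1e-6)
      L2[ci, ] <- logit(shifted) + bio[ci, ] + layout$versionOffset[ci]
    }
    di <- which(layout$discordant)
    if (length(di)) {
      L1[di, ] <- L1[di, ] +
        matrix(stats::rnorm(length(di) * nD), length(di), nD) *
        config@discordantNoiseSd
      L2[di, ] <- L2[di, ] +
        matrix(stats::rnorm(length(di) * nD), length(di), nD) *
        config@discordantNoiseSd
    }

    ## chip / row layout: chips of 8 arrays per version
    chipOf <- function(i, v) sprintf("chip_%s_%02d", v, (i - 1L) %/% 8L + 1L)
    rowOf <- function(i) sprintf("R%02d", (i - 1L) %% 8L + 1L)
    buildVersion <- function(Lv, v) {
      keep <- which(layout$shared %in% c("both", if (v == "v1") "v1"
                                         else "v2"))
      nChips <- (nD - 1L) %/% 8L + 1L
      chipEff <- matrix(stats::rnorm(length(keep) * nChips), length(keep),
                        nChips) * config@chipEffectSd
      rowEff <- matrix(stats::rnorm(length(keep) * 8L), length(keep),
                       8L) * config@rowEffectSd
      chips <- chipOf(seq_len(nD), v)
      rows <- rowOf(seq_len(nD))
      sig <- Lv[keep, , drop = FALSE] +
        chipEff[, (seq_len(nD) - 1L) %/% 8L + 1L] +
        rowEff[, (seq_len(nD) - 1L) %% 8L + 1L]
      if (v == "v1") {
        rc <- rep(1L, length(keep))
      } else {
        rc <- layout$repCount[keep]
      }
      expand <- rep(seq_along(keep), rc)
      repIdx <- sequence(rc)
      beta <- invlogit(sig[expand, , drop = FALSE] +
                         matrix(stats::rnorm(length(expand) * nD),
                                length(expand), nD) * config@techNoiseSd)
      baseIds <- layout$probeIds[keep]
      probeIds <- if (v == "v1") baseIds else
        sprintf("%s_r%d", baseIds[expand], repIdx)
      rownames(beta) <- probeIds
      sampleIds <- sprintf("%s_%s", donors, v)
      colnames(beta) <- sampleIds
      detp <- matrix(stats::rbeta(length(beta), 0.1, 10), nrow(beta),
                     ncol(beta), dimnames = dimnames(beta))
      nFail <- round(config@fracFailedDetp * length(detp))
      if (nFail > 0) {
        cells <- sample.int(length(detp), nFail)
        detp[cells] <- stats::runif(nFail)
      }
      bead <- matrix(pmax(1, stats::rpois(length(beta), 13)), nrow(beta),
                     ncol(beta), dimnames = dimnames(beta))
      manifest <- data.frame(probe_id = probeIds,
                             base_cpg = baseIds[expand],
                             version = v,
                             replicate_index = as.integer(repIdx))
      sheet <- data.frame(sample_id = sampleIds, donor_id = donors,
                          version = v, cohort = "SIM", sex = sex,
                          age = age, chip = chips, row = rows,
                          facility = "sim_facility",
                          replicate_of = NA_character_)
      MethylationSet(beta, manifest = manifest, sampleSheet = sheet,
                     detectionP = detp, beadcount = bead)
    }
    v1 <- buildVersion(L1, "v1")
    v2 <- buildVersion(L2, "v2")
    if (config@nTechReplicates > 0) {
      v1 <- makeTechnicalReplicates(v1, config, seedOffset = 2L)
      v2 <- makeTechnicalReplicates(v2, config, seedOffset = 3L)
    }
    truth <- list(
      mixing = W,
      versionOffset = stats::setNames(layout$versionOffset,
                                      layout$probeIds),
      discordant = layout$probeIds[layout$discordant],
      clock = list(cpgs = layout$probeIds[layout$clockIdx],
                   m = layout$clockM, s = layout$clockS),
      sexProbes = layout$probeIds[layout$sexIdx],
      age = stats::setNames(age, donors),
      sex = stats::setNames(sex, donors),
      bioSd = stats::setNames(layout$bioSd, layout$probeIds),
      role = stats::setNames(layout$role, layout$probeIds),
      shared = stats::setNames(layout$shared, layout$probeIds),
      config = config)
    list(v1 = v1, v2 = v2, truth = truth)
  })
}

#' Append technical replicate arrays to a simulated version
#'
#' Technical replicates re-measure the same bisulfite-converted aliquot:
#' the replicate array equals the source array's logit signal plus fresh
#' technical noise of SD `techNoiseSd` (with `techNoiseSd = 0` the
#' replicate is identical to its source). Replicates of the first
#' `nTechReplicates` donors are appended with `replicate_of` set; chip and
#' row labels are inherited from the source array. Fresh QC assays are
#' drawn for the new arrays.
#'
#' @param x A [MethylationSet-class] of one version.
#' @param config A [SimConfig-class].
#' @param donors Donor ids to replicate (default: the first
#'   `nTechReplicates` primary donors).
#' @param seedOffset Offset added to the configuration seed for this
#'   sub-stream (distinct offsets per version keep the noise independent).
#' @return The augmented [MethylationSet-class].
#' @export
makeTechnicalReplicates <- function(x, config, donors = NULL,
                                    seedOffset = 2L) {
  stopifnot(is(x, "MethylationSet"), is(config, "SimConfig"))
  sheet <- sampleSheet(x)
  primary <- sheet[is.na(sheet$replicate_of), , drop = FALSE]
  if (is.null(donors))
    donors <- utils::head(unique(primary$donor_id), config@nTechReplicates)
  if (!length(donors)) return(x)
  if (!all(donors %in% primary$donor_id))
    stop("donor(s) to replicate not present: ",
         paste(setdiff(donors, primary$donor_id), collapse = ", "))
  withSeed(config@seed + seedOffset, {
    src <- primary[match(donors, primary$donor_id), , drop = FALSE]
    beta <- betaValues(x)
    b <- beta[, src$sample_id, drop = FALSE]
    eps <- 1e-12
    rep_ <- invlogit(logit(pmin(pmax(b, eps), 1 - eps)) +
                       matrix(stats::rnorm(length(b)), nrow(b), ncol(b)) *
                       config@techNoiseSd)
    if (config@techNoiseSd == 0) rep_ <- b   # exact copy, no logit round-trip
    newIds <- sprintf("%s_rep", src$sample_id)
    colnames(rep_) <- newIds
    detp <- matrix(stats::rbeta(length(rep_), 0.1, 10), nrow(rep_),
                   ncol(rep_), dimnames = dimnames(rep_))
    bead <- matrix(pmax(1, stats::rpois(length(rep_), 13)), nrow(rep_),
                   ncol(rep_), dimnames = dimnames(rep_))
    newSheet <- src
    newSheet$sample_id <- newIds
    newSheet$replicate_of <- src$sample_id
    allBeta <- cbind(beta, rep_)
    oldDetp <- detectionP(x)
    oldBead <- beadCount(x)
    MethylationSet(allBeta, manifest = probeManifest(x),
                   sampleSheet = rbind(sheet, newSheet),
                   detectionP = if (is.null(oldDetp)) NULL else
                     cbind(oldDetp, detp),
                   beadcount = if (is.null(oldBead)) NULL else
                     cbind(oldBead, bead))
  })
}
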