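#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Synthetic LC-MS/MS data generator
## ---------------------------------------------------------------------------

#' Synthetic dataset generator configuration
#'
#' Parameters of the synthetic LC-MS/MS generator, which emulates the
#' statistical structure the pipeline assumes: molecular families of
#' structurally related compounds sharing a fragment backbone with
#' mass-shifted members, ionization of a subset of compounds in both
#' polarities, a three-group design (fungal monoculture, bacterial
#' monoculture, coculture) with replicates, multiplicative log-normal
#' replicate noise, detection dropout, and planted coculture-enriched
#' compounds at a stated fold change.
#'
#' @slot nFamilies number of molecular families.
#' @slot compoundsPerFamily members per family (mass-shifted analogs).
#' @slot modificationDeltas Da mass shifts between successive family
#'   members (recycled cumulatively); defaults are common biochemical
#'   shifts (CH2 = 14.0157, H2 = 2.0157).
#' @slot nBackboneFragments fragment peaks per family backbone.
#' @slot massErrorPpm maximum relative mass error applied to every m/z.
#' @slot rtJitterMin maximum retention-time jitter between observations
#'   of one compound, minutes.
#' @slot nNoisePeaks uniform-random low-intensity noise peaks added per
#'   spectrum.
#' @slot replicateCv coefficient of variation of replicate heights
#'   (log-normal, multiplicative).
#' @slot dropoutProb probability a feature is undetected (height 0) in a
#'   given sample.
#' @slot nPlantedEnriched number of compounds planted as
#'   coculture-enriched.
#' @slot plantedFoldChange true coculture/monoculture ratio of planted
#'   compounds.
#' @slot replicatesPerGroup biological replicates per group.
#' @slot dualModeFraction fraction of compounds ionizing in both modes.
#' @slot nBackgroundFeatures constitutive null features added to the
#'   feature table only (no MS/MS spectra, so they are never networked,
#'   like real features dropped for lacking fragmentation data). They
#'   dominate the total ion current so that per-file row-sum
#'   normalization is not distorted by the planted enriched features —
#'   the regime the enrichment screen assumes.
#' @slot seed mandatory random seed; all generation is deterministic
#'   given the seed.
#'
#' @export
setClass("SimulationConfig",
  representation(nFamilies = "integer", compoundsPerFamily = "integer",
                 modificationDeltas = "numeric",
                 nBackboneFragments = "integer", massErrorPpm = "numeric",
                 rtJitterMin = "numeric", nNoisePeaks = "integer",
                 replicateCv = "numeric", dropoutProb = "numeric",
                 nPlantedEnriched = "integer", plantedFoldChange = "numeric",
                 replicatesPerGroup = "integer", dualModeFraction = "numeric",
                 nBackgroundFeatures = "integer", seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nFamilies < 1L || object@compoundsPerFamily < 1L ||
      object@nBackboneFragments < 1L || object@replicatesPerGroup < 1L)
    msg <- c(msg, "counts must be >= 1")
  if (object@massErrorPpm < 0 || object@rtJitterMin < 0 ||
      object@nNoisePeaks < 0L)
    msg <- c(msg, "noise parameters must be non-negative")
  if (object@replicateCv < 0) msg <- c(msg, "replicateCv must be >= 0")
  if (object@dropoutProb < 0 || object@dropoutProb >= 1)
    msg <- c(msg, "dropoutProb must lie in [0, 1)")
  if (object@dualModeFraction < 0 || object@dualModeFraction > 1)
    msg <- c(msg, "dualModeFraction must lie in [0, 1]")
  if (object@nPlantedEnriched >
      object@nFamilies * object@compoundsPerFamily)
    msg <- c(msg, "nPlantedEnriched exceeds the number of compounds")
  if (object@plantedFoldChange < 1)
    msg <- c(msg, "plantedFoldChange must be >= 1")
  if (object@nBackgroundFeatures < 0L)
    msg <- c(msg, "nBackgroundFeatures must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nFamilies,compoundsPerFamily,modificationDeltas see slots.
#' @param nBackboneFragments,massErrorPpm,rtJitterMin,nNoisePeaks see slots.
#' @param replicateCv,dropoutProb,nPlantedEnriched,plantedFoldChange see
#'   slots.
#' @param replicatesPerGroup,dualModeFraction,nBackgroundFeatures,seed see
#'   slots.
#' @export
SimulationConfig <- function(nFamilies = 5L, compoundsPerFamily = 4L,
                             modificationDeltas = c(14.0157, 2.0157),
                             nBackboneFragments = 8L, massErrorPpm = 3,
                             rtJitterMin = 0.03, nNoisePeaks = 3L,
                             replicateCv = 0.2, dropoutProb = 0.05,
                             nPlantedEnriched = 5L, plantedFoldChange = 8,
                             replicatesPerGroup = 4L,
                             dualModeFraction = 0.4,
                             nBackgroundFeatures = 150L, seed = 17L) {
  new("SimulationConfig", nFamilies = as.integer(nFamilies),
      compoundsPerFamily = as.integer(compoundsPerFamily),
      modificationDeltas = modificationDeltas,
      nBackboneFragments = as.integer(nBackboneFragments),
      massErrorPpm = massErrorPpm, rtJitterMin = rtJitterMin,
      nNoisePeaks = as.integer(nNoisePeaks), replicateCv = replicateCv,
      dropoutProb = dropoutProb,
      nPlantedEnriched = as.integer(nPlantedEnriched),
      plantedFoldChange = plantedFoldChange,
      replicatesPerGroup = as.integer(replicatesPerGroup),
      dualModeFraction = dualModeFraction,
      nBackgroundFeatures = as.integer(nBackgroundFeatures),
      seed = as.integer(seed))
}

## deterministic sub-seed for an integer-indexed random stream; keeps the
## result well below 2^31 so set.seed() always accepts it
.subseed <- function(seed, ...) {
  s <- as.double(seed %% 1000003L)
  for (k in c(...)) s <- (s * 131 + as.double(k)) %% 2147483629
  as.integer(s)
}

## run expr under a temporary RNG state seeded from an indexed stream
.withStream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subseed(seed, ...))
  expr
}

#' Generate synthetic compounds with family structure and ground truth
#'
#' Families have base neutral masses at least 50 Da apart and fragment
#' backbones of well-separated peaks; members within a family carry
#' cumulative mass modifications so that half of their fragments shift
#' with the modification (matching under the precursor-difference shift
#' rule) and half stay put (direct matches). Compounds are spaced at
#' least 0.5 min apart in retention time. A deterministic subset ionizes
#' in both polarities; a deterministic subset is planted as
#' coculture-enriched at `plantedFoldChange`.
#'
#' @param cfg a [SimulationConfig-class].
#' @return data.frame with one row per compound: `compoundId`,
#'   `familyId`, `neutralMass`, `rt`, `modificationDelta`,
#'   `ionizesPositive`, `ionizesNegative`, `meanFungal`, `meanBacterial`,
#'   `meanCoculture`, `plantedFc`, `enriched`, and a list column
#'   `fragments` (two-column matrix `mz`, `intensity` per compound).
#' @export
generateCompounds <- function(cfg = SimulationConfig()) {
  stopifnot(is(cfg, "SimulationConfig"))
  nC <- cfg@nFamilies * cfg@compoundsPerFamily

  famBase <- .withStream(cfg@seed, 1, expr =
    350 + (seq_len(cfg@nFamilies) - 1) * 60 + runif(cfg@nFamilies, 0, 8))
  famRt <- 2 + (seq_len(cfg@nFamilies) - 1) *
    (cfg@compoundsPerFamily * 0.8 + 0.6)

  ## per-family fragment backbone: evenly spread with jitter, so windowed
  ## top-k filtering never discards backbone peaks
  backbones <- lapply(seq_len(cfg@nFamilies), function(f)
    .withStream(cfg@seed, 2, f, expr = {
      nf <- cfg@nBackboneFragments
      mz <- seq(80, famBase[f] - 60, length.out = nf) + runif(nf, -3, 3)
      cbind(mz = sort(mz), intensity = runif(nf, 20, 100))
    }))

  ## cumulative modification delta of member m within its family
  deltas <- vapply(seq_len(cfg@compoundsPerFamily), function(m)
    if (m == 1L) 0 else
      sum(rep_len(cfg@modificationDeltas, m - 1L)), numeric(1))

  dualIdx <- .withStream(cfg@seed, 3, expr =
    sample.int(nC, round(cfg@dualModeFraction * nC)))
  enrichedIdx <- .withStream(cfg@seed, 4, expr =
    sample.int(nC, cfg@nPlantedEnriched))

  rows <- lapply(seq_len(nC), function(i) {
    f <- (i - 1L) %/% cfg@compoundsPerFamily + 1L
    m <- (i - 1L) %% cfg@compoundsPerFamily + 1L
    baseMean <- .withStream(cfg@seed, 5, i, expr = runif(1, 500, 5000))
    fc <- if (i %in% enrichedIdx) cfg@plantedFoldChange else 1
    bb <- backbones[[f]]
    ## even-index fragments carry the modification (neutral-loss side),
    ## odd-index fragments are charge-retained and stay put
    frag <- bb
    shifted <- seq_len(nrow(bb)) %% 2L == 0L
    frag[shifted, "mz"] <- frag[shifted, "mz"] + deltas[m]
    data.frame(
      compoundId = sprintf("C%02d_%02d", f, m), familyId = f,
      neutralMass = famBase[f] + deltas[m],
      rt = famRt[f] + (m - 1L) * 0.8,
      modificationDelta = deltas[m],
      ionizesPositive = TRUE, ionizesNegative = i %in% dualIdx,
      meanFungal = baseMean, meanBacterial = baseMean,
      meanCoculture = fc * baseMean,
      plantedFc = fc, enriched = i %in% enrichedIdx,
      fragments = I(list(frag)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$compoundId
  out
}

#' Generate MS/MS spectra for synthetic compounds
#'
#' One spectrum per compound ionizing in the requested polarity:
#' precursor m/z is the neutral mass plus or minus one proton mass, every
#' m/z is perturbed by a uniform relative error within
#' `massErrorPpm`, retention time is jittered within `rtJitterMin`, and
#' `nNoisePeaks` low-intensity uniform noise peaks are added. Spectra are
#' raw (unfiltered) and deterministic given the config seed.
#'
#' @param compounds output of [generateCompounds()].
#' @param polarity `"positive"` or `"negative"`.
#' @param cfg the [SimulationConfig-class] used to generate `compounds`.
#' @return List of [Ms2Spectrum-class]; feature ids are
#'   `<compoundId>_pos` / `<compoundId>_neg`.
#' @export
generateSpectra <- function(compounds, polarity, cfg = SimulationConfig()) {
  stopifnot(polarity %in% .POLARITIES)
  sign <- if (polarity == "positive") 1 else -1
  ion <- if (polarity == "positive") compounds$ionizesPositive
         else compounds$ionizesNegative
  polK <- if (polarity == "positive") 10L else 20L
  idx <- which(ion)
  lapply(idx, function(i) {
    .withStream(cfg@seed, polK, i, expr = {
      prec <- compounds$neutralMass[i] + sign * PROTON_MASS
      prec <- prec * (1 + runif(1, -1, 1) * cfg@massErrorPpm * 1e-6)
      frag <- compounds$fragments[[i]]
      mz <- frag[, "mz"] *
        (1 + runif(nrow(frag), -1, 1) * cfg@massErrorPpm * 1e-6)
      int <- frag[, "intensity"]
      if (cfg@nNoisePeaks > 0L) {
        nmz <- runif(cfg@nNoisePeaks, 50, prec - 25)
        mz <- c(mz, nmz)
        int <- c(int, runif(cfg@nNoisePeaks, 0.5, 2))
      }
      rt <- compounds$rt[i] + runif(1, -1, 1) * cfg@rtJitterMin
      Ms2Spectrum(paste0(compounds$compoundId[i], "_",
                         substr(polarity, 1, 3)),
                  prec, polarity, rt, mz = mz, intensity = int)
    })
  })
}

#' Generate a replicate feature table with ground truth
#'
#' One feature per (compound, ionized polarity), plus
#' `nBackgroundFeatures` constitutive null features (equal true means in
#' all groups, no associated spectra) emulating the bulk of an
#' untargeted feature table. Each replicate height is
#' the compound's true group mean times a log-normal multiplier with
#' median 1 and coefficient of variation `replicateCv`, zeroed with
#' probability `dropoutProb` (dropout applied before any normalization,
#' emulating non-detection). The design has `replicatesPerGroup` samples
#' in each of the groups `fungal_mono`, `bacterial_mono` and `coculture`,
#' all under one condition `"avicel"`.
#'
#' Ground truth (feature to compound/family map, planted fold changes,
#' enrichment labels, dual-mode pairing) is stored in
#' `S4Vectors::metadata(table)$groundTruth`.
#'
#' @param compounds output of [generateCompounds()].
#' @param cfg the [SimulationConfig-class] used to generate `compounds`.
#' @return A [FeatureTable-class] with ground-truth metadata.
#' @export
generateFeatureTable <- function(compounds, cfg = SimulationConfig()) {
  feats <- do.call(rbind, lapply(seq_len(nrow(compounds)), function(i) {
    pols <- c("positive", "negative")[c(compounds$ionizesPositive[i],
                                        compounds$ionizesNegative[i])]
    do.call(rbind, lapply(pols, function(p) data.frame(
      featureId = paste0(compounds$compoundId[i], "_", substr(p, 1, 3)),
      compound = i,
      mz = compounds$neutralMass[i] +
        if (p == "positive") PROTON_MASS else -PROTON_MASS,
      rt = compounds$rt[i], polarity = p, stringsAsFactors = FALSE)))
  }))

  nBg <- cfg@nBackgroundFeatures
  if (nBg > 0L) {
    bg <- .withStream(cfg@seed, 50, expr = data.frame(
      featureId = sprintf("BG_%04d", seq_len(nBg)),
      compound = NA_integer_,
      mz = runif(nBg, 100, 1000),
      rt = runif(nBg, 1, 20), polarity = "positive",
      stringsAsFactors = FALSE))
    feats <- rbind(feats, bg)
  }

  groups <- c("fungal_mono", "bacterial_mono", "coculture")
  nr <- cfg@replicatesPerGroup
  design <- data.frame(
    sampleId = paste(rep(groups, each = nr), seq_len(nr), sep = "_"),
    group = rep(groups, each = nr), condition = "avicel",
    stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + cfg@replicateCv^2))
  h <- matrix(0, nrow = nrow(feats), ncol = nrow(design))
  for (r in seq_len(nrow(feats))) {
    i <- feats$compound[r]
    mu <- if (is.na(i)) {
      rep(.withStream(cfg@seed, 51, r, expr = runif(1, 500, 5000)), 3L * nr)
    } else {
      rep(c(compounds$meanFungal[i], compounds$meanBacterial[i],
            compounds$meanCoculture[i]), each = nr)
    }
    polK <- if (is.na(i)) 60L
            else if (feats$polarity[r] == "positive") 30L else 40L
    h[r, ] <- .withStream(cfg@seed, polK, r, expr = {
      v <- mu * rlnorm(length(mu), 0, sdlog)
      if (cfg@dropoutProb > 0)
        v[runif(length(mu)) < cfg@dropoutProb] <- 0
      v
    })
  }

  tab <- FeatureTable(h, feats[, c("featureId", "mz", "rt", "polarity")],
                      design)
  cmpIdx <- feats$compound
  truth <- data.frame(
    featureId = feats$featureId,
    compoundId = ifelse(is.na(cmpIdx), NA_character_,
                        compounds$compoundId[cmpIdx]),
    familyId = ifelse(is.na(cmpIdx), NA_integer_,
                      compounds$familyId[cmpIdx]),
    polarity = feats$polarity,
    plantedFc = ifelse(is.na(cmpIdx), 1, compounds$plantedFc[cmpIdx]),
    enriched = ifelse(is.na(cmpIdx), FALSE, compounds$enriched[cmpIdx]),
    dualMode = ifelse(is.na(cmpIdx), FALSE,
                      compounds$ionizesNegative[cmpIdx] &
                        compounds$ionizesPositive[cmpIdx]),
    stringsAsFactors = FALSE)
  S4Vectors::metadata(tab)$groundTruth <- truth
  S4Vectors::metadata(tab)$simulationSeed <- cfg@seed
  tab
}

#' Write a complete synthetic dataset to disk
#'
#' Generates compounds, spectra for both polarities and the replicate
#' feature table, and writes them as the pipeline's input files: one MGF
#' per polarity, a feature CSV and a design CSV.
#'
#' @param dir output directory (created if missing).
#' @param cfg a [SimulationConfig-class].
#' @return Invisibly, a list with the file `paths`, the `compounds`
#'   table, the `featureTable` and its ground truth.
#' @export
writeSyntheticDataset <- function(dir, cfg = SimulationConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- generateCompounds(cfg)
  pos <- generateSpectra(compounds, "positive", cfg)
  neg <- generateSpectra(compounds, "negative", cfg)
  tab <- generateFeatureTable(compounds, cfg)
  paths <- list(posMgf = file.path(dir, "spectra_pos.mgf"),
                negMgf = file.path(dir, "spectra_neg.mgf"),
                featureCsv = file.path(dir, "features.csv"),
                designCsv = file.path(dir, "design.csv"))
  writeMgf(pos, paths$posMgf)
  writeMgf(neg, paths$negMgf)
  writeFeatureCsv(tab, paths$featureCsv, paths$designCsv)
  invisible(list(paths = paths, compounds = compounds, featureTable = tab,
                 groundTruth = S4Vectors::metadata(tab)$groundTruth))
}
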