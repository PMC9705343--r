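# End-to-end two-arm synthetic study: per-animal phantoms at two CMR
# timepoints, one optical movie, histology tables; analysis through the
# imaging modules; medians/IQR and exact Mann-Whitney tests per endpoint.
# Analysis stages never see arm labels; labels are joined only at the
# statistics stage.

#' Two-arm study configuration
#'
#' Arm-specific remodeling rules follow the scar-evolution scheme the
#' pipeline emulates: in the control arm a fraction of the epicardial
#' heterogeneous tissue converts to dense scar between timepoints (with
#' stable HT extent, replenished from healthy myocardium); in the treated
#' arm HT grows while dense scar is stable. Endocardial remodeling is
#' identical in both arms. Optical effect sizes are the target HT-vs-HM
#' relative differences in conduction velocity and APD (%); per-animal
#' values are jittered around each target.
#'
#' @slot nTreated,nControl animals per arm (>= 3).
#' @slot conversionControl,conversionTreated epicardial HT-to-DS
#'   conversion fraction per arm, in `[0, 1]`.
#' @slot htGrowthTreated,htGrowthControl epicardial HT growth fraction
#'   per arm, in `[0, 1]`.
#' @slot endoGrowth endocardial HT and DS growth fraction (both arms).
#' @slot opticalTreated,opticalControl named numeric `c(cv =, apd =)`
#'   target percentages.
#' @slot histoTreated,histoControl per-arm ordinal level probabilities
#'   (format of [syntheticHistoSpec()]'s `levelProbs`).
#' @slot cmrGrid,cmrVoxel,opticalGrid,opticalFrameInterval,opticalBeats,nSections
#'   problem-size knobs for the per-animal phantoms.
#' @slot seed top-level seed; per-animal/stage seeds are fanned out
#'   deterministically.
#' @exportClass StudyConfig
setClass("StudyConfig",
  slots = c(nTreated = "integer", nControl = "integer",
            conversionControl = "numeric", conversionTreated = "numeric",
            htGrowthTreated = "numeric", htGrowthControl = "numeric",
            endoGrowth = "numeric",
            opticalTreated = "numeric", opticalControl = "numeric",
            histoTreated = "list", histoControl = "list",
            cmrGrid = "integer", cmrVoxel = "numeric",
            opticalGrid = "integer", opticalFrameInterval = "numeric",
            opticalBeats = "integer", nSections = "integer",
            seed = "integer"))

setValidity("StudyConfig", function(object) {
  fr <- c(object@conversionControl, object@conversionTreated,
          object@htGrowthTreated, object@htGrowthControl, object@endoGrowth)
  if (any(fr < 0 | fr > 1)) return("remodeling fractions must lie in [0, 1]")
  if (object@nTreated < 3L || object@nControl < 3L)
    return("need at least 3 animals per arm")
  TRUE
})

# arm-specific histology level distributions emulating lower fibrosis,
# better viability/vascularisation and more/better-polarised connexin 43
# in the treated epicardial HT; endocardial distributions are identical.
armHistoProbs <- function(arm) {
  endo <- c(0.10, 0.25, 0.30, 0.25, 0.10)
  epi <- if (arm == "treated") list(
    fibrosis        = c(0.70, 0.25, 0.05, 0.00, 0.00),
    cx43_quantity   = c(0.00, 0.05, 0.20, 0.50, 0.25),
    cx43_polarity   = c(0.05, 0.30, 0.45, 0.20, 0.00),
    viability       = c(0.00, 0.05, 0.25, 0.50, 0.20),
    vascularization = c(0.00, 0.15, 0.55, 0.25, 0.05))
  else list(
    fibrosis        = c(0.10, 0.30, 0.40, 0.15, 0.05),
    cx43_quantity   = c(0.05, 0.15, 0.35, 0.35, 0.10),
    cx43_polarity   = c(0.35, 0.45, 0.15, 0.05, 0.00),
    viability       = c(0.05, 0.20, 0.40, 0.30, 0.05),
    vascularization = c(0.05, 0.35, 0.45, 0.15, 0.00))
  stats::setNames(lapply(histoVariables, function(v)
    list(endo = endo, epi = epi[[v]])), histoVariables)
}

#' @describeIn StudyConfig constructor with the study's default
#'   conditions: 10 treated vs 9 control animals; control epicardial
#'   HT-to-DS conversion 0.8 with no HT growth; treated HT growth 0.5
#'   with no conversion; optical targets (cv, apd) = (-20, 12)% treated
#'   and (-48.3, 40)% control.
#' @param nTreated,nControl,conversionControl,conversionTreated see slots.
#' @param htGrowthTreated,htGrowthControl,endoGrowth see slots.
#' @param opticalTreated,opticalControl,histoTreated,histoControl see slots.
#' @param cmrGrid,cmrVoxel,opticalGrid,opticalFrameInterval see slots.
#' @param opticalBeats,nSections,seed see slots.
#' @return a `StudyConfig`.
#' @export
studyConfig <- function(nTreated = 10L, nControl = 9L,
                        conversionControl = 0.8, conversionTreated = 0,
                        htGrowthTreated = 0.5, htGrowthControl = 0,
                        endoGrowth = 0.45,
                        opticalTreated = c(cv = -20, apd = 12),
                        opticalControl = c(cv = -48.3, apd = 40),
                        histoTreated = armHistoProbs("treated"),
                        histoControl = armHistoProbs("control"),
                        cmrGrid = c(56L, 56L, 8L),
                        cmrVoxel = c(1.4, 1.4, 5),
                        opticalGrid = c(48L, 48L),
                        opticalFrameInterval = 2,
                        opticalBeats = 3L, nSections = 6L, seed = 1L) {
  new("StudyConfig", nTreated = as.integer(nTreated),
      nControl = as.integer(nControl),
      conversionControl = conversionControl,
      conversionTreated = conversionTreated,
      htGrowthTreated = htGrowthTreated,
      htGrowthControl = htGrowthControl, endoGrowth = endoGrowth,
      opticalTreated = opticalTreated, opticalControl = opticalControl,
      histoTreated = histoTreated, histoControl = histoControl,
      cmrGrid = as.integer(cmrGrid), cmrVoxel = as.numeric(cmrVoxel),
      opticalGrid = as.integer(opticalGrid),
      opticalFrameInterval = opticalFrameInterval,
      opticalBeats = as.integer(opticalBeats),
      nSections = as.integer(nSections), seed = as.integer(seed))
}

#' Identical-arm (null) variant of a study configuration
#'
#' Both arms receive the averaged remodeling, optical and histology
#' parameters of the two original arms, so every endpoint satisfies the
#' null hypothesis; used for type-I-error calibration.
#'
#' @param config a [StudyConfig-class].
#' @return a [StudyConfig-class] with identical arms.
#' @export
nullStudyConfig <- function(config) {
  conv <- mean(c(config@conversionControl, config@conversionTreated))
  gro <- mean(c(config@htGrowthTreated, config@htGrowthControl))
  opt <- (config@opticalTreated + config@opticalControl) / 2
  hp <- config@histoTreated
  methods::initialize(config,
    conversionControl = conv, conversionTreated = conv,
    htGrowthTreated = gro, htGrowthControl = gro,
    opticalTreated = opt, opticalControl = opt,
    histoTreated = hp, histoControl = hp)
}

#' Study report
#'
#' @slot perAnimal one row per animal: arm, per-endpoint values.
#' @slot endpoints one row per endpoint: per-arm median and IQR, exact
#'   Mann-Whitney U and two-sided p.
#' @slot config the [StudyConfig-class] used.
#' @exportClass StudyReport
setClass("StudyReport",
  slots = c(perAnimal = "data.frame", endpoints = "data.frame",
            config = "StudyConfig"))

setMethod("show", "StudyReport", function(object) {
  e <- object@endpoints
  cat(sprintf("StudyReport: %d treated vs %d control, %d endpoints\n",
              sum(object@perAnimal$arm == "treated"),
              sum(object@perAnimal$arm == "control"), nrow(e)))
  for (i in seq_len(nrow(e)))
    cat(sprintf(
      "  %-28s treated %7.1f [%6.1f, %6.1f]  control %7.1f [%6.1f, %6.1f]  p=%.4g\n",
      e$endpoint[i], e$medianTreated[i], e$q1Treated[i], e$q3Treated[i],
      e$medianControl[i], e$q1Control[i], e$q3Control[i], e$p[i]))
})

# square binary erosion of a logical matrix by `r` pixels
erodeMask <- function(mask, r) {
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    sh <- matrix(FALSE, nrow(mask), ncol(mask))
    rs <- max(1, 1 - dr):min(nrow(mask), nrow(mask) - dr)
    cs <- max(1, 1 - dc):min(ncol(mask), ncol(mask) - dc)
    sh[rs, cs] <- mask[rs + dr, cs + dc]
    out <- out & sh
  }
  out
}

# ---- per-animal generation (knows the arm parameters, not the label) ----

# scar layout at the two timepoints for one animal: angular sectors on
# middle slices; control-style conversion extends DS into the adjacent HT
# sector while HT shifts (stable extent); treated-style growth extends HT.
animalScarTimepoints <- function(conv, htGrowth, endoGrowth, seed,
                                 nSlices) {
  withSeed(seed, {
    ht0 <- 40 * stats::runif(1, 0.8, 1.2)
    ds0 <- 40 * stats::runif(1, 0.8, 1.2)
    enHT0 <- 30 * stats::runif(1, 0.8, 1.2)
    enDS0 <- 35 * stats::runif(1, 0.8, 1.2)
    convI <- min(1, conv * stats::runif(1, 0.85, 1.15))
    groI <- htGrowth * stats::runif(1, 0.7, 1.3)
    engI <- endoGrowth * stats::runif(1, 0.7, 1.3)
    sl <- seq.int(1L, max(2L, nSlices - 2L))
    mkEpi <- function(dsSpan, htStart, htSpan) list(
      list(angleStart = 0, angleSpan = dsSpan, slices = sl,
           compartment = "epi-half", offset = 4),
      list(angleStart = htStart, angleSpan = htSpan, slices = sl,
           compartment = "epi-half", offset = 2.5))
    mkEndo <- function(dsSpan, htSpan) list(
      list(angleStart = 180, angleSpan = dsSpan, slices = sl,
           compartment = "endo-half", offset = 4),
      list(angleStart = 180 + dsSpan, angleSpan = htSpan, slices = sl,
           compartment = "endo-half", offset = 2.5))
    convDeg <- convI * ht0
    baseline <- c(mkEpi(ds0, ds0, ht0), mkEndo(enDS0, enHT0))
    followup <- c(
      mkEpi(ds0 + convDeg, ds0 + convDeg, ht0 * (1 + groI)),
      mkEndo(enDS0 * (1 + engI), enHT0 * (1 + engI)))
    list(baseline = baseline, followup = followup)
  })
}

analyzeCMRTimepoint <- function(cmr, cmrVoxel) {
  masks <- splitWallHalves(cmr$contours, cmr$volume)
  zvol <- normalizeToSDUnits(cmr$volume, cmr$remoteROI, masks)
  meshEn <- contourSurfaceMesh(cmr$contours, "endo", cmrVoxel[3L])
  meshEp <- contourSurfaceMesh(cmr$contours, "epi", cmrVoxel[3L])
  mapEn <- projectHalfWallSI(zvol, "endo", meshEn)
  mapEp <- projectHalfWallSI(zvol, "epi", meshEp)
  quantifyScar(mapEn, mapEp, zvol)
}

# one animal through CMR (2 timepoints), optical mapping and histology
analyzeAnimal <- function(animalId, pars, config) {
  stage <- "cmr"
  res <- tryCatch({
    tp <- animalScarTimepoints(pars$conversion, pars$htGrowth,
                               config@endoGrowth, pars$seedScar,
                               config@cmrGrid[3L])
    q <- lapply(c(baseline = "baseline", followup = "followup"),
                function(w) {
      # contour-ring density scaled to the voxel size so each surface node
      # averages a stable number of voxels
      nv <- max(24L, min(96L, round(pi * pars$epiR /
                                      max(config@cmrVoxel[1:2]))))
      spec <- syntheticCMRSpec(gridShape = config@cmrGrid,
                               voxelSize = config@cmrVoxel,
                               endoRadius = pars$endoR, epiRadius = pars$epiR,
                               scarRegions = tp[[w]],
                               nContourVertices = nv,
                               seed = deriveSeed(pars$seedScar,
                                                 if (w == "baseline") 1 else 2))
      analyzeCMRTimepoint(generateCMR(spec), config@cmrVoxel)
    })
    d <- function(b, f) percentChange(b, f)
    cmrOut <- c(dEnHT = d(q$baseline@enHT, q$followup@enHT),
                dEnDS = d(q$baseline@enDS, q$followup@enDS),
                dEpHT = d(q$baseline@epHT, q$followup@epHT),
                dEpDS = d(q$baseline@epDS, q$followup@epDS))

    stage <- "optical"
    g <- config@opticalGrid
    patch <- circularPatchMask(g, c(round(g[1L] * 0.5), round(g[2L] * 0.62)),
                               max(6, round(min(g) / 5)))
    vr <- 1 + pars$cvTarget * stats::runif(1, 0.85, 1.15) / 100
    ar <- 1 + pars$apdTarget * stats::runif(1, 0.85, 1.15) / 100
    ospec <- syntheticOpticalSpec(gridShape = g,
                                  frameInterval = config@opticalFrameInterval,
                                  nBeats = config@opticalBeats,
                                  htPatch = list(mask = patch,
                                                 velocityRatio = vr,
                                                 apdRatio = ar),
                                  noiseSD = 2000 / 20,
                                  seed = pars$seedOptical)
    syn <- generateOptical(ospec)
    maps <- computeOpticalMaps(syn$recording, k = min(2L, config@opticalBeats))
    cv <- estimateCV(maps$activation)
    eroR <- max(2L, round(min(g) / 16))   # keep ROIs clear of the border zone
    htIn <- erodeMask(syn$rois$ht, eroR)
    hmIn <- erodeMask(syn$rois$hm, eroR)
    optOut <- c(
      cvDiff = regionalRelativeDifference(cv, list(hm = hmIn, ht = htIn)),
      apdDiff = regionalRelativeDifference(maps$apd,
                                           list(hm = hmIn, ht = htIn)))

    stage <- "histology"
    hspec <- syntheticHistoSpec(animalId = animalId,
                                nSections = config@nSections,
                                levelProbs = pars$histoProbs,
                                seed = pars$seedHisto)
    tab <- generateHistology(hspec)
    histOut <- unlist(lapply(histoVariables, function(v) {
      m <- weightedAnimalMean(tab, v)
      stats::setNames(m$mean_percent,
                      paste0("histo_", v, "_", m$compartment))
    }))
    c(cmrOut, optOut, histOut)
  }, error = function(e)
    stop(sprintf("[animal %s, stage %s] %s", animalId, stage,
                 conditionMessage(e)), call. = FALSE))
  res
}

#' Run an end-to-end two-arm synthetic study
#'
#' For every animal: two CMR phantoms (baseline and follow-up, applying
#' the arm's remodeling rule) are generated and pushed through wall
#' splitting, remote-SD normalisation, half-wall projection and scar
#' quantification; one optical movie is generated and analysed to the
#' HT-vs-HM relative CV and APD differences; a histology table is scored
#' into area-weighted means. Per-animal endpoint values are then compared
#' between arms with exact Mann-Whitney tests and summarised as median
#' and IQR. Analysis stages never receive the arm label (it is joined at
#' the statistics stage); the full report is reproducible at a fixed
#' seed.
#'
#' @param config a [StudyConfig-class].
#' @return a [StudyReport-class].
#' @export
runStudy <- function(config) {
  methods::validObject(config)
  arms <- c(rep("treated", config@nTreated), rep("control", config@nControl))
  ids <- c(sprintf("T%02d", seq_len(config@nTreated)),
           sprintf("C%02d", seq_len(config@nControl)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    arm <- arms[i]
    pars <- withSeed(deriveSeed(config@seed, i, 99), list(
      conversion = if (arm == "control") config@conversionControl
                   else config@conversionTreated,
      htGrowth = if (arm == "control") config@htGrowthControl
                 else config@htGrowthTreated,
      cvTarget = if (arm == "control") config@opticalControl[["cv"]]
                 else config@opticalTreated[["cv"]],
      apdTarget = if (arm == "control") config@opticalControl[["apd"]]
                  else config@opticalTreated[["apd"]],
      histoProbs = if (arm == "control") config@histoControl
                   else config@histoTreated,
      endoR = 17 + stats::runif(1, -1, 1),
      epiR = 25 + stats::runif(1, -1, 1),
      seedScar = deriveSeed(config@seed, i, 1),
      seedOptical = deriveSeed(config@seed, i, 2),
      seedHisto = deriveSeed(config@seed, i, 3)))
    vals <- withSeed(deriveSeed(config@seed, i, 4),
                     analyzeAnimal(ids[i], pars, config))
    rows[[i]] <- data.frame(animal = ids[i], t(vals))
  }
  perAnimal <- do.call(rbind, rows)
  # statistics stage: arm labels joined here only
  perAnimal$arm <- arms
  endpointNames <- setdiff(names(perAnimal), c("animal", "arm"))
  ep <- lapply(endpointNames, function(nm) {
    xt <- perAnimal[[nm]][perAnimal$arm == "treated"]
    xc <- perAnimal[[nm]][perAnimal$arm == "control"]
    tst <- exactMannWhitney(xt, xc)
    mt <- medianIQR(xt); mc <- medianIQR(xc)
    data.frame(endpoint = nm,
               medianTreated = mt[["median"]], q1Treated = mt[["q1"]],
               q3Treated = mt[["q3"]],
               medianControl = mc[["median"]], q1Control = mc[["q1"]],
               q3Control = mc[["q3"]],
               U = testStatistic(tst), p = pValue(tst))
  })
  new("StudyReport", perAnimal = perAnimal,
      endpoints = do.call(rbind, ep), config = config)
}

#' Type-I error calibration on identical-arm replicate studies
#'
#' Runs `nReplicates` studies under [nullStudyConfig()] (both arms share
#' every generation parameter) and reports the fraction of endpoint
#' p-values below `alpha`.
#'
#' @param config base [StudyConfig-class].
#' @param nReplicates number of replicate studies.
#' @param seed integer seed; replicate seeds are fanned out from it.
#' @param alpha significance level (default 0.05).
#' @return list with `falsePositiveRate`, `nTests` and the per-replicate
#'   p-value matrix.
#' @export
studyNullCalibration <- function(config, nReplicates = 200L, seed = 1L,
                                 alpha = 0.05) {
  nullCfg <- nullStudyConfig(config)
  pv <- NULL
  for (r in seq_len(nReplicates)) {
    cfg <- methods::initialize(nullCfg, seed = deriveSeed(seed, r))
    rep <- runStudy(cfg)
    pv <- rbind(pv, rep@endpoints$p)
  }
  list(falsePositiveRate = mean(pv < alpha), nTests = length(pv),
       pValues = pv)
}
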