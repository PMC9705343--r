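# Synthetic voltage-dye movies: paced wavefronts with region-specific
# conduction velocity and APD80, closed-form action-potential template.

#' Synthetic optical-mapping specification
#'
#' Emulates drive-train pacing recorded by a 128 x 128, 16-bit camera. The
#' wavefront travel time is a slowness-weighted shortest path on the pixel
#' lattice (16-neighbour stencil), so a slow heterogeneous-tissue (HT)
#' patch produces curved isochrones. The action-potential template has a
#' linear upstroke centred on the ground-truth activation instant and a
#' raised-cosine repolarisation scaled so the 20%-amplitude crossing falls
#' exactly `apd80` ms after activation. Dye polarity is inverted by default
#' (fluorescence falls on depolarisation).
#'
#' @slot gridShape integer(2): rows, cols (pixels).
#' @slot pixelSize mm per pixel.
#' @slot frameInterval ms per frame (> 0).
#' @slot nBeats number of paced beats.
#' @slot cycleLength pacing cycle length (ms), must exceed every region's
#'   action-potential duration.
#' @slot apAmplitude,apd80,upstroke template amplitude (a.u.), APD80 (ms)
#'   and upstroke duration (ms).
#' @slot hmVelocity healthy-myocardium conduction velocity (cm/s).
#' @slot htPatch empty list, or list with `mask` (logical rows x cols),
#'   `velocityRatio` (> 0) and `apdRatio` (> 0).
#' @slot waveOrigin `"edge"` (left edge, plane wave) or integer c(row, col)
#'   point source.
#' @slot baselineOffset camera baseline (counts).
#' @slot noiseSD Gaussian sensor noise SD (counts, >= 0).
#' @slot invertPolarity logical.
#' @slot firstStimulus time of the first stimulus (ms).
#' @slot seed integer RNG seed.
#' @exportClass SyntheticOpticalSpec
setClass("SyntheticOpticalSpec",
  slots = c(gridShape = "integer", pixelSize = "numeric",
            frameInterval = "numeric", nBeats = "integer",
            cycleLength = "numeric", apAmplitude = "numeric",
            apd80 = "numeric", upstroke = "numeric", hmVelocity = "numeric",
            htPatch = "list", waveOrigin = "ANY", baselineOffset = "numeric",
            noiseSD = "numeric", invertPolarity = "logical",
            firstStimulus = "numeric", seed = "integer"))

# time from activation to full repolarisation for a given APD80
apFullDuration <- function(apd80, upstroke) {
  sStar <- acos(-0.6) / pi
  upstroke / 2 + (apd80 - upstroke / 2) / sStar
}

setValidity("SyntheticOpticalSpec", function(object) {
  if (length(object@gridShape) != 2L || any(object@gridShape < 4L))
    return("gridShape must be 2 integers >= 4")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (object@hmVelocity <= 0) return("hmVelocity must be > 0")
  apdMax <- object@apd80
  if (length(object@htPatch)) {
    p <- object@htPatch
    if (!all(c("mask", "velocityRatio", "apdRatio") %in% names(p)))
      return("htPatch needs mask/velocityRatio/apdRatio")
    if (!identical(dim(p$mask), as.integer(object@gridShape)))
      return("ht_patch mask outside grid: dimensions must match gridShape")
    if (p$velocityRatio <= 0 || p$apdRatio <= 0)
      return("velocity and APD ratios must be > 0")
    apdMax <- max(apdMax, object@apd80 * p$apdRatio)
  }
  if (object@cycleLength <= apFullDuration(apdMax, object@upstroke))
    return("cycleLength must exceed the action-potential duration of every region")
  if (is.character(object@waveOrigin)) {
    if (object@waveOrigin != "edge") return("waveOrigin must be 'edge' or c(row, col)")
  } else if (length(object@waveOrigin) != 2L) {
    return("waveOrigin must be 'edge' or c(row, col)")
  }
  TRUE
})

#' @describeIn SyntheticOpticalSpec constructor; defaults follow the
#'   acquisition conditions emulated (128 x 128 pixels, 16-bit counts,
#'   600 ms cycle length).
#' @param gridShape,pixelSize,frameInterval,nBeats,cycleLength see slots.
#' @param apAmplitude,apd80,upstroke,hmVelocity,htPatch,waveOrigin see slots.
#' @param baselineOffset,noiseSD,invertPolarity,firstStimulus,seed see slots.
#' @return a `SyntheticOpticalSpec`.
#' @export
syntheticOpticalSpec <- function(gridShape = c(128L, 128L), pixelSize = 0.5,
                                 frameInterval = 1, nBeats = 4L,
                                 cycleLength = 600, apAmplitude = 2000,
                                 apd80 = 250, upstroke = 2, hmVelocity = 50,
                                 htPatch = list(), waveOrigin = "edge",
                                 baselineOffset = 30000, noiseSD = 0,
                                 invertPolarity = TRUE, firstStimulus = 10,
                                 seed = 1L) {
  new("SyntheticOpticalSpec",
      gridShape = as.integer(gridShape), pixelSize = pixelSize,
      frameInterval = frameInterval, nBeats = as.integer(nBeats),
      cycleLength = cycleLength, apAmplitude = apAmplitude, apd80 = apd80,
      upstroke = upstroke, hmVelocity = hmVelocity, htPatch = htPatch,
      waveOrigin = waveOrigin, baselineOffset = baselineOffset,
      noiseSD = noiseSD, invertPolarity = invertPolarity,
      firstStimulus = firstStimulus, seed = as.integer(seed))
}

#' Circular pixel mask helper
#'
#' @param gridShape integer(2) rows, cols.
#' @param center c(row, col) centre (pixels).
#' @param radius radius (pixels).
#' @return logical rows x cols matrix.
#' @export
circularPatchMask <- function(gridShape, center, radius) {
  r <- matrix(seq_len(gridShape[1L]), gridShape[1L], gridShape[2L])
  c <- matrix(seq_len(gridShape[2L]), gridShape[1L], gridShape[2L],
              byrow = TRUE)
  (r - center[1L])^2 + (c - center[2L])^2 <= radius^2
}

# Slowness-weighted travel time (ms) from the wave origin to every pixel.
# 16-neighbour lattice (axis, diagonal and knight moves) keeps the metric
# anisotropy below ~3%.
travelTimeField <- function(velocity, pixelSize, waveOrigin) {
  nr <- nrow(velocity); nc <- ncol(velocity)
  n <- nr * nc
  slow <- 100 / velocity            # cm/s -> ms per mm
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L),
                c(1L, 2L), c(2L, 1L), c(1L, -2L), c(2L, -1L))
  id <- function(r, c) (c - 1L) * nr + r
  el <- vector("list", nrow(offs)); wl <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    rr <- rep(r1, times = length(c1)); cc <- rep(c1, each = length(r1))
    a <- id(rr, cc); b <- id(rr + dr, cc + dc)
    len <- sqrt(sum(c(dr, dc)^2)) * pixelSize
    el[[k]] <- cbind(a, b)
    wl[[k]] <- len * (slow[a] + slow[b]) / 2
  }
  edges <- do.call(rbind, el); w <- do.call(c, wl)
  if (is.character(waveOrigin)) {
    sources <- id(seq_len(nr), rep(1L, nr))
  } else {
    sources <- id(waveOrigin[1L], waveOrigin[2L])
  }
  # virtual source (vertex n + 1) connected at zero cost
  edges <- rbind(edges, cbind(rep(n + 1L, length(sources)), sources))
  w <- c(w, rep(0, length(sources)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g, v = n + 1L, weights = w,
                         algorithm = "dijkstra")[1L, seq_len(n)]
  matrix(d, nr, nc)
}

# Closed-form AP template: linear upstroke centred on tau = 0, raised-cosine
# repolarisation crossing 0.2 * amplitude exactly at tau = apd80.
apTemplate <- function(tau, amplitude, apd80, upstroke) {
  sStar <- acos(-0.6) / pi
  tRep <- (apd80 - upstroke / 2) / sStar
  v <- numeric(length(tau))
  up <- tau >= -upstroke / 2 & tau < upstroke / 2
  v[up] <- amplitude * (tau[up] + upstroke / 2) / upstroke
  rp <- tau >= upstroke / 2
  s <- pmin((tau[rp] - upstroke / 2) / tRep, 1)
  v[rp] <- amplitude * 0.5 * (1 + cos(pi * s))
  v
}

#' Generate a synthetic optical-mapping movie with ground truth
#'
#' Computes per-pixel ground-truth activation times as slowness-weighted
#' shortest-path travel times from the wave origin at the regional
#' conduction velocities, then renders each pixel's fluorescence trace as
#' the AP template shifted by activation, repeated every cycle, polarity
#' inverted when flagged, plus Gaussian sensor noise. Same seed, same
#' movie.
#'
#' @param spec a [SyntheticOpticalSpec-class].
#' @return list with `recording` ([OpticalRecording-class]), `activation`
#'   ([ActivationMap-class], ms from stimulus), `apd` ([APDMap-class]),
#'   `cv` ([CVField-class], regional ground-truth speed), and `rois`
#'   (list of logical `hm`/`ht` masks).
#' @export
generateOptical <- function(spec) {
  methods::validObject(spec)
  nr <- spec@gridShape[1L]; nc <- spec@gridShape[2L]
  vel <- matrix(spec@hmVelocity, nr, nc)
  apd <- matrix(spec@apd80, nr, nc)
  ht <- matrix(FALSE, nr, nc)
  if (length(spec@htPatch)) {
    ht <- spec@htPatch$mask
    vel[ht] <- spec@hmVelocity * spec@htPatch$velocityRatio
    apd[ht] <- spec@apd80 * spec@htPatch$apdRatio
  }
  act <- travelTimeField(vel, spec@pixelSize, spec@waveOrigin)
  stim <- spec@firstStimulus + (seq_len(spec@nBeats) - 1L) * spec@cycleLength
  tEnd <- spec@firstStimulus + spec@nBeats * spec@cycleLength
  nT <- ceiling(tEnd / spec@frameInterval)
  tt <- (seq_len(nT) - 1L) * spec@frameInterval
  npix <- nr * nc
  # phase within the pacing cycle, mapped to [-upstroke/2, CL - upstroke/2)
  rel <- outer(as.vector(act), tt, function(a, t) t - spec@firstStimulus - a)
  tau <- ((rel + spec@upstroke / 2) %% spec@cycleLength) - spec@upstroke / 2
  tau[rel < -spec@upstroke / 2] <- -Inf     # before the first beat
  # APD varies by region: evaluate the template per region
  v <- matrix(0, npix, nT)
  apdVec <- as.vector(apd)
  for (a in unique(apdVec)) {
    rows <- which(apdVec == a)
    v[rows, ] <- apTemplate(as.vector(tau[rows, , drop = FALSE]),
                            spec@apAmplitude, a, spec@upstroke)
  }
  sgn <- if (spec@invertPolarity) -1 else 1
  fr <- withSeed(spec@seed, {
    noise <- matrix(stats::rnorm(npix * nT), npix, nT)
    spec@baselineOffset + sgn * v + spec@noiseSD * noise
  })
  framesArr <- array(fr, dim = c(nr, nc, nT))
  rec <- new("OpticalRecording", frames = framesArr,
             frameInterval = spec@frameInterval, pixelSize = spec@pixelSize,
             stimulusTimes = stim, cycleLength = spec@cycleLength)
  ok <- matrix(TRUE, nr, nc)
  list(recording = rec,
       activation = new("ActivationMap", values = act, valid = ok,
                        pixelSize = spec@pixelSize),
       apd = new("APDMap", values = apd, valid = ok,
                 pixelSize = spec@pixelSize),
       cv = new("CVField", values = vel, valid = ok,
                pixelSize = spec@pixelSize,
                dirX = matrix(NA_real_, nr, nc),
                dirY = matrix(NA_real_, nr, nc)),
       rois = list(hm = !ht, ht = ht))
}
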