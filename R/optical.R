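# Optical-mapping analysis: trace conditioning, beat segmentation,
# activation detection, APD80, isochrones and gradient-based conduction
# velocity.

# npix x T trace matrix in column-major pixel order (row fastest), matching
# as.vector() of an nr x nc matrix.
tracesMatrix <- function(rec) {
  d <- dim(frames(rec))
  matrix(frames(rec), d[1L] * d[2L], d[3L])
}

#' Condition an optical recording
#'
#' Corrects dye polarity so depolarisation is positive-going (the sign is
#' detected from the pooled mean-minus-median statistic: a fluorescence
#' trace spends most of its time at baseline, so brief depolarisations
#' pull the mean above the median only when polarity is upright) and
#' optionally applies a spatial box blur and a temporal moving average.
#'
#' @param rec an [OpticalRecording-class].
#' @param spatialRadius half-width (pixels) of a spatial box filter
#'   (0 = off).
#' @param temporalWindow width (frames) of a temporal moving average
#'   (0/1 = off).
#' @return an [OpticalRecording-class] with conditioned frames.
#' @export
preprocessOptical <- function(rec, spatialRadius = 0L, temporalWindow = 0L) {
  fr <- frames(rec)
  d <- dim(fr)
  tm <- matrix(fr, d[1L] * d[2L], d[3L])
  pol <- mean(rowMeans(tm) - apply(tm, 1L, stats::median))
  if (pol < 0) {
    mid <- (max(tm) + min(tm)) / 2
    tm <- 2 * mid - tm                      # flip around the mid level
  }
  if (temporalWindow > 1L) {
    k <- rep(1 / temporalWindow, temporalWindow)
    tm <- t(apply(tm, 1L, function(x)
      stats::filter(x, k, sides = 2L, circular = FALSE)))
    # fill filter NAs at the ends with the nearest value
    for (j in seq_len(ncol(tm))) if (anyNA(tm[, j]))
      tm[, j] <- ifelse(is.na(tm[, j]), tm[, max(1L, j - 1L)], tm[, j])
  }
  fr2 <- array(tm, d)
  if (spatialRadius > 0L) {
    for (t in seq_len(d[3L])) {
      m <- fr2[, , t]
      acc <- matrix(0, d[1L], d[2L]); nrm <- matrix(0, d[1L], d[2L])
      for (dr in -spatialRadius:spatialRadius)
        for (dc in -spatialRadius:spatialRadius) {
          r1 <- max(1, 1 + dr):min(d[1L], d[1L] + dr)
          c1 <- max(1, 1 + dc):min(d[2L], d[2L] + dc)
          acc[r1 - dr, c1 - dc] <- acc[r1 - dr, c1 - dc] + m[r1, c1]
          nrm[r1 - dr, c1 - dc] <- nrm[r1 - dr, c1 - dc] + 1
        }
      fr2[, , t] <- acc / nrm
    }
  }
  methods::initialize(rec, frames = fr2)
}

#' Segment a recording into per-stimulus beat windows
#'
#' One window per stimulus, `[t_stim, t_stim + cycleLength)`, expressed as
#' frame index ranges. Windows extending past the end of the recording are
#' dropped with a warning.
#'
#' @param stimulusTimes stimulus times (ms).
#' @param cycleLength pacing cycle length (ms).
#' @param frameInterval ms per frame.
#' @param nFrames number of frames in the recording.
#' @return data.frame with `stimulus` (ms), `start`, `end` (frame indices).
#' @export
segmentBeats <- function(stimulusTimes, cycleLength, frameInterval, nFrames) {
  len <- floor(cycleLength / frameInterval)
  start <- ceiling(stimulusTimes / frameInterval) + 1L  # first frame >= stim
  end <- start + len - 1L
  keep <- end <= nFrames
  if (!any(keep)) stop("no complete beat window in the recording")
  if (any(!keep)) warning(sprintf("%d incomplete beat window(s) dropped",
                                  sum(!keep)))
  data.frame(stimulus = stimulusTimes[keep], start = start[keep],
             end = end[keep])
}

# Average the last k complete beats and normalise each pixel to [0, 1].
# Returns list(beat = npix x L matrix, relTime = ms from stimulus,
# valid = non-flat pixels).
averagedBeat <- function(tm, windows, frameInterval, k = 3L,
                         flatTol = 1e-9) {
  use <- utils::tail(seq_len(nrow(windows)), k)
  L <- windows$end[1L] - windows$start[1L] + 1L
  acc <- 0
  for (i in use)
    acc <- acc + tm[, windows$start[i]:windows$end[i], drop = FALSE]
  beat <- acc / length(use)
  i <- use[length(use)]
  relTime <- ((windows$start[i]:windows$end[i]) - 1L) * frameInterval -
    windows$stimulus[i]
  lo <- apply(beat, 1L, min); hi <- apply(beat, 1L, max)
  amp <- hi - lo
  valid <- amp > flatTol * max(1, max(abs(hi)))
  beat <- (beat - lo) / ifelse(valid, amp, 1)
  beat[!valid, ] <- NA_real_
  list(beat = beat, relTime = relTime, valid = valid)
}

#' Detect activation times on normalised beat traces
#'
#' Activation is the instant of maximum positive temporal derivative
#' (dF/dt max), refined below the frame interval by quadratic
#' interpolation around the discrete maximum. A contiguous plateau of
#' maximal derivative (e.g. a linear upstroke) activates at the plateau
#' centre; separated equal maxima take the earliest (documented
#' tie-break). Pixels whose derivative maximum sits at a window edge are
#' invalidated.
#'
#' @param beat npix x L matrix of normalised beat traces.
#' @param relTime frame times (ms) relative to the stimulus.
#' @param valid logical, pixels to process.
#' @return list `time` (ms, NA when invalid) and `valid`.
#' @export
detectActivation <- function(beat, relTime, valid = rep(TRUE, nrow(beat))) {
  L <- ncol(beat)
  dt <- relTime[2L] - relTime[1L]
  d <- beat[, 2:L, drop = FALSE] - beat[, 1:(L - 1L), drop = FALSE]
  nd <- ncol(d)
  tmid <- (relTime[-1L] + relTime[-L]) / 2
  n <- nrow(beat)
  out <- rep(NA_real_, n)
  ok <- valid
  for (p in which(valid)) {
    dp <- d[p, ]
    m <- max(dp)
    tol <- 1e-9 * max(1, abs(m))
    hits <- which(dp >= m - tol)
    # a contiguous plateau activates at its centre; separated equal maxima
    # take the earliest run (documented tie-break)
    gap <- which(diff(hits) > 1L)
    f <- hits[1L]
    l <- if (length(gap)) hits[gap[1L]] else hits[length(hits)]
    # derivative maximum touching a window edge: unreliable, invalidate
    if (f <= 1L || l >= nd) { ok[p] <- FALSE; next }
    if (f == l) {
      a <- dp[f - 1L]; b <- dp[f]; c <- dp[f + 1L]
      den <- a - 2 * b + c
      off <- if (abs(den) > tol) 0.5 * (a - c) / den else 0
      off <- max(-0.5, min(0.5, off))
      out[p] <- tmid[f] + off * dt
    } else {
      out[p] <- tmid[1L] + ((f + l) / 2 - 1) * dt
    }
  }
  list(time = out, valid = ok)
}

#' Compute APD80 from normalised beat traces
#'
#' APD80 is the time from activation to 80% repolarisation: the first
#' instant after the beat peak at which the normalised trace falls to
#' 0.2 of its amplitude (linear interpolation between frames), minus the
#' activation time. Pixels with no crossing before the window end are
#' invalidated.
#'
#' @param beat npix x L normalised beat traces.
#' @param relTime frame times (ms) relative to the stimulus.
#' @param activation activation times from [detectActivation()].
#' @param valid logical pixel mask.
#' @return list `apd` (ms, NA when invalid) and `valid`.
#' @export
computeAPD80 <- function(beat, relTime, activation,
                         valid = rep(TRUE, nrow(beat))) {
  n <- nrow(beat); L <- ncol(beat)
  out <- rep(NA_real_, n); ok <- valid & is.finite(activation)
  thr <- 0.2
  for (p in which(ok)) {
    tr <- beat[p, ]
    pk <- which.max(tr)
    below <- which(tr[(pk + 1L):L] <= thr)
    if (pk >= L || !length(below)) { ok[p] <- FALSE; next }
    j <- pk + below[1L]                 # first frame at/below threshold
    if (tr[j] == thr) {
      tc <- relTime[j]
    } else {
      f <- (tr[j - 1L] - thr) / (tr[j - 1L] - tr[j])
      tc <- relTime[j - 1L] + f * (relTime[j] - relTime[j - 1L])
    }
    out[p] <- tc - activation[p]
  }
  ok[ok & !(out > 0)] <- FALSE
  out[!ok] <- NA_real_
  list(apd = out, valid = ok)
}

#' Activation and APD80 maps from a recording
#'
#' Full per-pixel pipeline: conditioning, beat segmentation, averaging of
#' the last `k` paced beats, activation detection and APD80 measurement.
#'
#' @param rec an [OpticalRecording-class].
#' @param k number of trailing beats to average (default 3).
#' @param spatialRadius,temporalWindow see [preprocessOptical()]; the
#'   defaults (1 px box blur, 3-frame moving average) are conventional
#'   light conditioning for voltage-dye movies.
#' @return list with `activation` ([ActivationMap-class]) and `apd`
#'   ([APDMap-class]).
#' @export
computeOpticalMaps <- function(rec, k = 3L, spatialRadius = 1L,
                               temporalWindow = 3L) {
  rec <- preprocessOptical(rec, spatialRadius, temporalWindow)
  d <- dim(frames(rec))
  tm <- tracesMatrix(rec)
  win <- segmentBeats(stimulusTimes(rec), cycleLength(rec),
                      frameInterval(rec), d[3L])
  ab <- averagedBeat(tm, win, frameInterval(rec), k = k)
  actd <- detectActivation(ab$beat, ab$relTime, ab$valid)
  apdd <- computeAPD80(ab$beat, ab$relTime, actd$time, actd$valid)
  nr <- d[1L]; nc <- d[2L]
  list(activation = new("ActivationMap",
                        values = matrix(actd$time, nr, nc),
                        valid = matrix(actd$valid, nr, nc),
                        pixelSize = pixelSize(rec)),
       apd = new("APDMap", values = matrix(apdd$apd, nr, nc),
                 valid = matrix(apdd$valid, nr, nc),
                 pixelSize = pixelSize(rec)))
}

#' Isochronal contours of an activation map
#'
#' Level sets of activation time at a fixed step, for display and for the
#' normal directions underlying the velocity field.
#'
#' @param act an [ActivationMap-class].
#' @param step isochrone spacing (ms).
#' @return list of contours as returned by [grDevices::contourLines()]
#'   (possibly empty).
#' @export
buildIsochrones <- function(act, step) {
  v <- mapValues(act)
  v[!validMask(act)] <- NA
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(list())
  lev <- seq(ceiling(rng[1L] / step) * step, rng[2L], by = step)
  if (!length(lev)) return(list())
  px <- pixelSize(act)
  grDevices::contourLines(x = (seq_len(nrow(v)) - 0.5) * px,
                          y = (seq_len(ncol(v)) - 0.5) * px,
                          z = v, levels = lev)
}

#' Estimate conduction velocity from an activation map
#'
#' Fits a local plane T(x, y) to activation time over a `w x w`
#' neighbourhood of valid pixels (least squares; at least 6 neighbours
#' required). The velocity vector is the isochrone-normal
#' `grad T / |grad T|^2`: speed `1/|grad T|` (converted to cm/s) and unit
#' direction along propagation. Pixels failing the fit or exceeding the
#' physiological speed cap are invalidated.
#'
#' @param act an [ActivationMap-class].
#' @param window odd window size in pixels (default 5).
#' @param speedCap maximum physiological speed (cm/s, default 200).
#' @return a [CVField-class].
#' @export
estimateCV <- function(act, window = 5L, speedCap = 200) {
  stopifnot(window %% 2L == 1L)
  v <- mapValues(act); ok <- validMask(act) & is.finite(v)
  nr <- nrow(v); nc <- ncol(v)
  px <- pixelSize(act)
  h <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  dx <- offs$dr * px; dy <- offs$dc * px
  speed <- matrix(NA_real_, nr, nc)
  dirX <- matrix(NA_real_, nr, nc); dirY <- matrix(NA_real_, nr, nc)
  vfull <- cbind(1, dx, dy)
  AtAfullInv <- solve(crossprod(vfull))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!ok[r, c]) next
    rr <- r + offs$dr; cc <- c + offs$dc
    inb <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    idx <- cbind(rr[inb], cc[inb])
    use <- ok[idx]
    if (sum(use) < 6L) next
    tvals <- v[idx][use]
    if (all(inb) && all(use)) {
      beta <- AtAfullInv %*% crossprod(vfull, tvals)
    } else {
      A <- vfull[inb, , drop = FALSE][use, , drop = FALSE]
      beta <- tryCatch(solve(crossprod(A), crossprod(A, tvals)),
                       error = function(e) NULL)
      if (is.null(beta)) next
    }
    g <- c(beta[2L], beta[3L])             # ms / mm
    gn <- sqrt(sum(g^2))
    if (gn <= 0) next
    sp <- 100 / gn                         # cm/s
    if (sp > speedCap) next
    speed[r, c] <- sp
    dirX[r, c] <- g[1L] / gn
    dirY[r, c] <- g[2L] / gn
  }
  new("CVField", values = speed, valid = is.finite(speed), pixelSize = px,
      dirX = dirX, dirY = dirY)
}

#' Regional HT-vs-HM relative difference
#'
#' `100 * (stat_HT - stat_HM) / stat_HM` for an APD or conduction-velocity
#' map, with the regional statistic taken over valid pixels of each ROI
#' (median by default). Both ROIs must be disjoint and contribute at least
#' 10 valid pixels.
#'
#' @param field an [APDMap-class] or [CVField-class].
#' @param rois list with logical matrices `hm` and `ht`.
#' @param stat `"median"` (default) or `"mean"`.
#' @return percentage difference (scalar).
#' @export
regionalRelativeDifference <- function(field, rois,
                                       stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- switch(stat, median = stats::median, mean = mean)
  if (any(rois$hm & rois$ht)) stop("HM and HT ROIs must be disjoint")
  ok <- validMask(field)
  vHM <- mapValues(field)[rois$hm & ok]
  vHT <- mapValues(field)[rois$ht & ok]
  if (length(vHM) < 10L || length(vHT) < 10L)
    stop("each ROI needs at least 10 valid pixels")
  100 * (f(vHT) - f(vHM)) / f(vHM)
}
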