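# Shared fixtures and independent oracles used across test files.

# small CMR phantom with one epicardial-half scar sector
smallCMRSpec <- function(..., scar = TRUE, offset = 4, span = 60,
                         slices = 1:4, compartment = "epi-half",
                         gridShape = c(48L, 48L, 6L), noiseSD = 0,
                         seed = 7L) {
  regions <- if (scar) list(list(angleStart = 0, angleSpan = span,
                                 slices = slices, compartment = compartment,
                                 offset = offset)) else list()
  syntheticCMRSpec(gridShape = gridShape, scarRegions = regions,
                   noiseSD = noiseSD, seed = seed, ...)
}

# run a phantom through the full CMR chain; returns maps + quantification
runCMRChain <- function(spec, remote = NULL) {
  g <- generateCMR(spec)
  masks <- splitWallHalves(g$contours, g$volume)
  zv <- normalizeToSDUnits(g$volume,
                           if (is.null(remote)) g$nominalRemote else remote,
                           masks)
  dz <- spec@voxelSize[3L]
  mapEn <- projectHalfWallSI(zv, "endo",
                             contourSurfaceMesh(g$contours, "endo", dz))
  mapEp <- projectHalfWallSI(zv, "epi",
                             contourSurfaceMesh(g$contours, "epi", dz))
  list(gen = g, z = zv, mapEn = mapEn, mapEp = mapEp,
       quant = quantifyScar(mapEn, mapEp, zv))
}

# ---- independent brute-force oracles for the exact rank tests ----

# two-sided doubled-tail Mann-Whitney p by direct enumeration of all
# group assignments (written against the definition, not the package DP)
oracleMWp <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(n, n1), 2L, function(ix) sum(r[ix]))
  pl <- mean(sums <= wObs + 1e-9)
  ph <- mean(sums >= wObs - 1e-9)
  min(1, 2 * min(pl, ph))
}

# two-sided doubled-tail signed-rank p by enumerating all sign vectors
oracleWSRp <- function(before, after) {
  d <- before - after
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  sums <- apply(signs, 1L, function(s) sum(r[s]))
  pl <- mean(sums <= wObs + 1e-9)
  ph <- mean(sums >= wObs - 1e-9)
  min(1, 2 * min(pl, ph))
}

# quantile oracle: sorted-vector linear interpolation at h = (n-1)p + 1
oracleQuantile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
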