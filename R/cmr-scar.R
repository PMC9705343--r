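# LGE-CMR scar compartmentalization: remote-SD normalisation, HM/HT/DS
# classification, half-wall surface projection and scar quantification.

#' Classify myocardial tissue from z-scored signal intensity
#'
#' Late-enhancement voxels (or surface nodes) are classified against remote
#' healthy myocardium on the remote-SD scale: below 2 SD is healthy
#' myocardium (HM), at or above 2 but below 3 SD is heterogeneous tissue
#' (HT), and at or above 3 SD is dense scar (DS).
#'
#' @param z numeric vector of signal intensities in remote-SD units.
#' @return factor with levels `HM`, `HT`, `DS`.
#' @examples
#' classifyTissue(c(1.99, 2, 2.5, 3))
#' @export
classifyTissue <- function(z) {
  if (length(z) && any(!is.finite(z)))
    stop("z values must be finite")
  factor(ifelse(z >= 3, "DS", ifelse(z >= 2, "HT", "HM")),
         levels = c("HM", "HT", "DS"))
}

#' Partition the wall into endocardial and epicardial halves
#'
#' Every wall voxel (inside the epicardial contour, outside the endocardial
#' contour of its slice) is assigned to the half whose bounding contour is
#' nearer in-plane; equidistant voxels go to the endocardial half
#' (deterministic tie rule).
#'
#' @param contours a [WallContours-class].
#' @param volume an [LGEVolume-class] providing the voxel grid geometry.
#' @return list with logical arrays `wall`, `endoHalf`, `epiHalf`.
#' @export
splitWallHalves <- function(contours, volume) {
  stopifnot(is(contours, "WallContours"), is(volume, "LGEVolume"))
  methods::validObject(contours)   # rejects non-nested contours
  d <- dim(intensities(volume))
  vs <- voxelSize(volume)
  wall <- array(FALSE, d); endoH <- array(FALSE, d); epiH <- array(FALSE, d)
  cx <- (seq_len(d[1L]) - 0.5) * vs[1L]
  cy <- (seq_len(d[2L]) - 0.5) * vs[2L]
  gx <- rep(cx, times = d[2L])
  gy <- rep(cy, each = d[1L])
  cc <- contourTable(contours)
  for (s in sort(unique(cc$slice))) {
    k <- s + 1L
    if (k < 1L || k > d[3L]) next
    en <- cc[cc$slice == s & cc$surface == "endo", ]
    ep <- cc[cc$slice == s & cc$surface == "epi", ]
    inEp <- pracma::inpolygon(gx, gy, ep$x, ep$y)
    inEn <- pracma::inpolygon(gx, gy, en$x, en$y)
    w <- inEp & !inEn
    if (!any(w)) next
    dEn <- distToPolygon(gx[w], gy[w], en$x, en$y)
    dEp <- distToPolygon(gx[w], gy[w], ep$x, ep$y)
    wallSlice <- matrix(w, d[1L], d[2L])
    endoPick <- rep(FALSE, length(w)); endoPick[w] <- dEn <= dEp
    wall[, , k] <- wallSlice
    endoH[, , k] <- matrix(endoPick, d[1L], d[2L])
    epiH[, , k] <- wallSlice & !endoH[, , k]
  }
  list(wall = wall, endoHalf = endoH, epiHalf = epiH)
}

#' Normalise an LGE volume to remote-SD units
#'
#' z = (I - mu_remote) / sigma_remote per wall voxel, where mu/sigma come
#' either from a remote healthy-myocardium ROI mask (>= 30 voxels, non-zero
#' SD) or are supplied directly as `c(mean, sd)`.
#'
#' @param volume an [LGEVolume-class].
#' @param remote logical array (ROI mask, same dimensions) or numeric
#'   `c(mean, sd)` in a.u.
#' @param masks wall partition as returned by [splitWallHalves()].
#' @return a [ZVolume-class].
#' @export
normalizeToSDUnits <- function(volume, remote, masks) {
  ii <- intensities(volume)
  if (is.array(remote) || is.logical(remote)) {
    roi <- as.logical(remote)
    if (sum(roi) < 30L)
      stop("remote ROI must contain at least 30 voxels")
    mu <- mean(ii[roi]); sd <- stats::sd(ii[roi])
    if (!is.finite(sd) || sd <= 1e-9 * max(1, abs(mu)))
      stop("degenerate normalisation: remote ROI has zero or near-zero SD")
  } else {
    if (length(remote) != 2L || remote[2L] <= 0)
      stop("'remote' must be an ROI mask or c(mean, sd) with sd > 0")
    mu <- remote[1L]; sd <- remote[2L]
    roi <- NULL
  }
  z <- array(NA_real_, dim(ii))
  z[masks$wall] <- (ii[masks$wall] - mu) / sd
  if (!is.null(roi)) {
    zroi <- (ii[roi] - mu) / sd
    # a clean Gaussian ROI has P(z >= 2) ~ 2.3%; flag well above that
    if (mean(zroi >= 2) > 0.05)
      warning("remote ROI appears to overlap enhanced tissue (z >= 2)")
  }
  new("ZVolume", z = z, wall = masks$wall, endoHalf = masks$endoHalf,
      epiHalf = masks$epiHalf, remoteMean = mu, remoteSD = sd,
      voxelSize = voxelSize(volume))
}

#' Project half-wall signal intensity onto a surface
#'
#' Each voxel of the requested wall half is assigned to the nearest surface
#' node of its own slice (the discrete analogue of a transmural ray); the
#' node signal intensity is the mean z over its assigned voxels and the node
#' label follows [classifyTissue()]. Nodes with no assigned voxels are
#' flagged unmapped and excluded from area sums.
#'
#' @param zvol a [ZVolume-class].
#' @param half `"endo"` or `"epi"`.
#' @param mesh the corresponding surface [TriangleMesh-class]
#'   (from [contourSurfaceMesh()]).
#' @return a [SurfaceSIMap-class].
#' @export
projectHalfWallSI <- function(zvol, half = c("endo", "epi"), mesh) {
  half <- match.arg(half)
  mask <- halfMask(zvol, half)
  vs <- voxelSize(zvol)
  nodes <- meshNodes(mesh)
  nodeSlice <- floor(nodes[, 3L] / vs[3L])    # ring z = (slice + 0.5) dz
  idx <- which(mask, arr.ind = TRUE)
  vx <- (idx[, 1L] - 0.5) * vs[1L]
  vy <- (idx[, 2L] - 0.5) * vs[2L]
  vslice <- idx[, 3L] - 1L
  zv <- zValues(zvol)[mask]
  si <- rep(NA_real_, nrow(nodes))
  cnt <- integer(nrow(nodes))
  acc <- numeric(nrow(nodes))
  for (s in unique(vslice)) {
    nid <- which(nodeSlice == s)
    if (!length(nid)) next
    vi <- which(vslice == s)
    # nearest in-plane node on the same slice
    d2 <- outer(vx[vi], nodes[nid, 1L], "-")^2 +
          outer(vy[vi], nodes[nid, 2L], "-")^2
    nearest <- nid[max.col(-d2, ties.method = "first")]
    for (u in unique(nearest)) {
      sel <- vi[nearest == u]
      acc[u] <- acc[u] + sum(zv[sel])
      cnt[u] <- cnt[u] + length(sel)
    }
  }
  mapped <- cnt > 0L
  si[mapped] <- acc[mapped] / cnt[mapped]
  lab <- factor(rep(NA_character_, nrow(nodes)), levels = c("HM", "HT", "DS"))
  lab[mapped] <- classifyTissue(si[mapped])
  areas <- nodeAreasFromMesh(nodes, meshTriangles(mesh)) / 100  # mm^2 -> cm^2
  new("SurfaceSIMap", mesh = mesh, si = si, label = lab, nodeArea = areas,
      mapped = mapped, surface = half)
}

# Slice-summation (Simpson) volume of the endocardial cavity, in ml.
simpsonVolume <- function(contours, sliceThickness) {
  cc <- contourTable(contours)
  cc <- cc[cc$surface == "endo", , drop = FALSE]
  a <- vapply(sort(unique(cc$slice)), function(s) {
    ring <- cc[cc$slice == s, , drop = FALSE]
    polygonArea(ring$x, ring$y)
  }, numeric(1))
  sum(a) * sliceThickness / 1000
}

#' Quantify scar compartments, masses and ventricular volumes
#'
#' Compartment areas are label-wise sums of mapped node areas on the
#' endocardial and epicardial surface maps. Total scar mass (TSM) is the
#' volume of wall voxels at z >= 2 times a myocardial density of
#' 1.05 g/ml; total myocardial mass (TMM) uses the whole wall. Ventricular
#' volumes are slice summations of the endocardial contour areas at the
#' end-diastolic / end-systolic phases when those contours are given;
#' otherwise volumes and ejection fraction are reported `NA` (areas are
#' still computed).
#'
#' @param mapEndo,mapEpi endocardial / epicardial [SurfaceSIMap-class].
#' @param zvol the [ZVolume-class] the maps were built from.
#' @param edContours,esContours optional [WallContours-class] at
#'   end-diastole / end-systole.
#' @return a [ScarQuantification-class].
#' @export
quantifyScar <- function(mapEndo, mapEpi, zvol,
                         edContours = NULL, esContours = NULL) {
  stopifnot(mapEndo@surface == "endo", mapEpi@surface == "epi")
  areaBy <- function(m, lab)
    sum(m@nodeArea[m@mapped & !is.na(m@label) & m@label == lab])
  vs <- voxelSize(zvol)
  voxMl <- prod(vs) / 1000
  scarVox <- sum(zvol@wall & !is.na(zvol@z) & zvol@z >= 2)
  density <- 1.05                         # g/ml, standard CMR convention
  tsm <- scarVox * voxMl * density
  tmm <- sum(zvol@wall) * voxMl * density
  lvedv <- lvesv <- lvef <- NA_real_
  if (!is.null(edContours)) lvedv <- simpsonVolume(edContours, vs[3L])
  if (!is.null(esContours)) lvesv <- simpsonVolume(esContours, vs[3L])
  if (is.finite(lvedv) && is.finite(lvesv) && lvedv > 0)
    lvef <- 100 * (lvedv - lvesv) / lvedv
  new("ScarQuantification",
      enDS = areaBy(mapEndo, "DS"), enHT = areaBy(mapEndo, "HT"),
      epDS = areaBy(mapEpi, "DS"), epHT = areaBy(mapEpi, "HT"),
      tsm = tsm, tmm = tmm, lvedv = lvedv, lvesv = lvesv, lvef = lvef)
}

#' Relative percentage change between two timepoints
#'
#' `100 * (followup - baseline) / baseline`, the longitudinal change
#' definition used for all scalar CMR summaries.
#'
#' @param baseline,followup numeric vectors (baseline non-zero).
#' @return percentage change.
#' @examples
#' percentChange(10, 15)   # +50
#' percentChange(20, 15)   # -25
#' @export
percentChange <- function(baseline, followup) {
  if (any(baseline == 0))
    stop("relative change undefined for zero baseline")
  100 * (followup - baseline) / baseline
}
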