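# Electroanatomic voltage mapping: IDW surface interpolation, amplitude
# classes and class areas; plus the synthetic point-cloud generator.

#' Synthetic electroanatomic study specification
#'
#' Points are placed on an LV-like triangulated cap surface so that every
#' mesh node lies within `pointSpacing` of at least one mapping point
#' (the fill rule); bipolar amplitudes are drawn per ground-truth class:
#' dense scar at or below 0.5 mV, heterogeneous tissue in (0.5, 1.5] mV,
#' healthy above 1.5 mV.
#'
#' @slot mesh a [TriangleMesh-class] (an LV-like cap by default).
#' @slot pointSpacing mm; points are a node subsample satisfying the fill
#'   rule at this spacing.
#' @slot scarPatches list of lists with `center` (c(theta, phi) degrees on
#'   the cap), `radius` (angular degrees) and `class` ("DS" or "HT").
#' @slot dsRange,htRange,healthyRange amplitude ranges (mV) per class.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticEAMSpec
setClass("SyntheticEAMSpec",
  slots = c(mesh = "TriangleMesh", pointSpacing = "numeric",
            scarPatches = "list", dsRange = "numeric", htRange = "numeric",
            healthyRange = "numeric", seed = "integer"))

setValidity("SyntheticEAMSpec", function(object) {
  if (nrow(object@mesh@nodes) == 0L || nrow(object@mesh@triangles) == 0L)
    return("empty mesh rejected")
  if (object@pointSpacing <= 0) return("pointSpacing must be > 0")
  for (p in object@scarPatches) {
    if (!all(c("center", "radius", "class") %in% names(p)))
      return("scar patches need center/radius/class")
    if (!p$class %in% c("DS", "HT")) return("patch class must be DS or HT")
  }
  TRUE
})

#' LV-like cap surface mesh
#'
#' Spherical cap (apex plus latitude rings up to `phiMax`) used as the
#' default electroanatomic surface.
#'
#' @param radius sphere radius (mm).
#' @param nTheta nodes per ring.
#' @param nPhi number of rings.
#' @param phiMax cap opening angle from the apex (degrees).
#' @return a [TriangleMesh-class].
#' @export
lvCapMesh <- function(radius = 25, nTheta = 36L, nPhi = 14L, phiMax = 120) {
  th <- 2 * pi * (seq_len(nTheta) - 1L) / nTheta
  ph <- pi / 180 * phiMax * seq_len(nPhi) / nPhi
  nodes <- rbind(c(0, 0, -radius))             # apex
  for (p in ph)
    nodes <- rbind(nodes, cbind(radius * sin(p) * cos(th),
                                radius * sin(p) * sin(th),
                                -radius * cos(p)))
  tris <- NULL
  ring <- function(i) 1L + (i - 1L) * nTheta + seq_len(nTheta)
  r1 <- ring(1L)
  tris <- cbind(rep(1L, nTheta), r1, c(r1[-1L], r1[1L]))
  for (i in seq_len(nPhi - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    tris <- rbind(tris, cbind(a, a2, b), cbind(a2, b2, b))
  }
  TriangleMesh(nodes, tris)
}

#' @describeIn SyntheticEAMSpec constructor.
#' @param mesh,pointSpacing,scarPatches,dsRange,htRange,healthyRange,seed
#'   see slots.
#' @return a `SyntheticEAMSpec`.
#' @export
syntheticEAMSpec <- function(mesh = lvCapMesh(), pointSpacing = 5,
                             scarPatches = list(),
                             dsRange = c(0.05, 0.45),
                             htRange = c(0.6, 1.4),
                             healthyRange = c(2, 8), seed = 1L) {
  new("SyntheticEAMSpec", mesh = mesh, pointSpacing = pointSpacing,
      scarPatches = scarPatches, dsRange = dsRange, htRange = htRange,
      healthyRange = healthyRange, seed = as.integer(seed))
}

# angular distance (deg) between mesh nodes and a cap direction
capAngle <- function(nodes, center) {
  thc <- center[1L] * pi / 180; phc <- center[2L] * pi / 180
  dirc <- c(sin(phc) * cos(thc), sin(phc) * sin(thc), -cos(phc))
  nn <- nodes / sqrt(rowSums(nodes^2))
  acos(pmin(1, pmax(-1, nn %*% dirc))) * 180 / pi
}

#' Generate a synthetic electroanatomic study with ground truth
#'
#' @param spec a [SyntheticEAMSpec-class].
#' @return list with `study` ([EAMStudy-class]), `truthClass` (per-node
#'   factor DS/HT/healthy) and `truthAreas` (named cm^2, by the triangle
#'   majority rule on the ground-truth classes).
#' @export
generateEAM <- function(spec) {
  methods::validObject(spec)
  nodes <- meshNodes(spec@mesh)
  cls <- factor(rep("healthy", nrow(nodes)),
                levels = c("DS", "HT", "healthy", "unmapped"))
  for (p in spec@scarPatches) {
    sel <- capAngle(nodes, p$center) <= p$radius
    cls[sel] <- p$class
  }
  # systematic node subsample satisfying the fill rule
  pts <- withSeed(spec@seed, {
    keep <- logical(nrow(nodes))
    ordn <- sample.int(nrow(nodes))          # random greedy cover
    for (i in ordn) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d <- sqrt(rowSums((nodes[keep, , drop = FALSE] -
                           matrix(nodes[i, ], sum(keep), 3,
                                  byrow = TRUE))^2))
      if (min(d) > 0.6 * spec@pointSpacing) keep[i] <- TRUE
    }
    # guarantee the declared coverage: add any node still uncovered
    repeat {
      kn <- nodes[keep, , drop = FALSE]
      mind <- vapply(seq_len(nrow(nodes)), function(i)
        min(sqrt(colSums((t(kn) - nodes[i, ])^2))), numeric(1))
      bad <- which(mind > spec@pointSpacing)
      if (!length(bad)) break
      keep[bad[1L]] <- TRUE
    }
    idx <- which(keep)
    rng <- function(cl) switch(cl, DS = spec@dsRange, HT = spec@htRange,
                               healthy = spec@healthyRange)
    amp <- vapply(idx, function(i) {
      r <- rng(as.character(cls[i])); stats::runif(1, r[1L], r[2L])
    }, numeric(1))
    data.frame(x = nodes[idx, 1L], y = nodes[idx, 2L], z = nodes[idx, 3L],
               amplitude = amp)
  })
  truthAreas <- computeClassAreas(spec@mesh, cls)
  list(study = EAMStudy(pts, spec@mesh, fillThreshold = spec@pointSpacing),
       truthClass = cls, truthAreas = truthAreas)
}

# Triangle-based class areas (cm^2): a triangle belongs to a class when at
# least two vertices share it; with three distinct vertex classes each
# receives one third.
computeClassAreas <- function(mesh, nodeClass) {
  tris <- meshTriangles(mesh)
  ta <- triangleAreas(meshNodes(mesh), tris) / 100     # mm^2 -> cm^2
  lv <- c("DS", "HT", "healthy", "unmapped")
  areas <- stats::setNames(numeric(4), lv)
  cl <- matrix(as.character(nodeClass[tris]), ncol = 3L)
  for (t in seq_len(nrow(tris))) {
    cs <- cl[t, ]
    tab <- table(cs)
    if (max(tab) >= 2L) {
      win <- names(tab)[which.max(tab)]
      areas[win] <- areas[win] + ta[t]
    } else {
      areas[cs] <- areas[cs] + ta[t] / 3
    }
  }
  areas
}

#' Interpolate bipolar voltage onto the surface and classify nodes
#'
#' Node amplitude is the inverse-distance-weighted (power 2) mean of the
#' mapping points within the fill threshold; nodes farther than the
#' threshold from every point are unmapped. Classes: dense scar at or
#' below 0.5 mV, heterogeneous tissue in (0.5, 1.5] mV, healthy above
#' 1.5 mV.
#'
#' @param study an [EAMStudy-class].
#' @return a [VoltageClassMap-class].
#' @export
interpolateVoltage <- function(study) {
  pts <- study@points
  if (nrow(pts) == 0L) stop("empty point set")
  nodes <- meshNodes(study@mesh)
  P <- as.matrix(pts[, c("x", "y", "z")])
  amp <- rep(NA_real_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    d <- sqrt(colSums((t(P) - nodes[i, ])^2))
    near <- d <= study@fillThreshold
    if (!any(near)) next
    if (any(d[near] < 1e-9)) {
      amp[i] <- pts$amplitude[near][which.min(d[near])]
    } else {
      w <- 1 / d[near]^2
      amp[i] <- sum(w * pts$amplitude[near]) / sum(w)
    }
  }
  cls <- factor(ifelse(is.na(amp), "unmapped",
                 ifelse(amp <= 0.5, "DS",
                  ifelse(amp <= 1.5, "HT", "healthy"))),
                levels = c("DS", "HT", "healthy", "unmapped"))
  areas <- computeClassAreas(study@mesh, cls)
  new("VoltageClassMap", mesh = study@mesh, amplitude = amp,
      nodeClass = cls, areas = areas)
}

#' Class areas of a voltage map
#'
#' @param map a [VoltageClassMap-class].
#' @return named numeric: DS, HT, healthy and unmapped areas (cm^2).
#' @export
classAreas <- function(map) {
  stopifnot(is(map, "VoltageClassMap"))
  computeClassAreas(map@mesh, map@nodeClass)
}
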