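# S4 classes for the imaging, mapping and statistics containers.

#' Triangulated surface mesh
#'
#' Minimal triangle-mesh container: node coordinates in mm and 1-based
#' triangle vertex indices. Used for epicardial/endocardial shell
#' reconstructions and electroanatomic surfaces.
#'
#' @slot nodes numeric matrix, n x 3, node coordinates (mm).
#' @slot triangles integer matrix, m x 3, 1-based vertex indices.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  slots = c(nodes = "matrix", triangles = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@nodes) != 3L) return("'nodes' must have 3 columns (mm)")
  if (nrow(object@triangles) > 0L) {
    if (ncol(object@triangles) != 3L) return("'triangles' must have 3 columns")
    ix <- as.integer(object@triangles)
    if (any(ix < 1L) || any(ix > nrow(object@nodes)))
      return("triangle indices out of node range")
  }
  TRUE
})

#' @describeIn TriangleMesh constructor.
#' @param nodes,triangles see slots.
#' @return a `TriangleMesh`.
#' @export
TriangleMesh <- function(nodes, triangles) {
  new("TriangleMesh", nodes = as.matrix(nodes),
      triangles = matrix(as.integer(as.matrix(triangles)), ncol = 3L))
}

#' Late gadolinium enhancement volume
#'
#' A 3D short-axis LGE intensity volume. Voxels are indexed 0-based with
#' half-open mm extents; the slice axis is the third array dimension.
#'
#' @slot intensities numeric 3D array (a.u.), finite.
#' @slot voxelSize numeric length-3, voxel edge lengths (mm), all > 0.
#' @exportClass LGEVolume
setClass("LGEVolume",
  slots = c(intensities = "array", voxelSize = "numeric"))

setValidity("LGEVolume", function(object) {
  if (length(dim(object@intensities)) != 3L) return("intensities must be 3D")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive mm values")
  if (!all(is.finite(object@intensities))) return("intensities must be finite")
  TRUE
})

#' @describeIn LGEVolume constructor.
#' @param intensities,voxelSize see slots.
#' @return an `LGEVolume`.
#' @export
LGEVolume <- function(intensities, voxelSize) {
  new("LGEVolume", intensities = intensities, voxelSize = as.numeric(voxelSize))
}

#' Endocardial and epicardial wall contours
#'
#' Per-slice closed polygons (mm, in-plane) for the endocardial and
#' epicardial boundary, 0-based slice index. The endocardial polygon must
#' lie strictly inside the epicardial one on every slice.
#'
#' @slot contours data.frame with columns `slice` (0-based integer),
#'   `surface` ("endo"/"epi"), `x`, `y` (mm), vertices in order.
#' @exportClass WallContours
setClass("WallContours", slots = c(contours = "data.frame"))

setValidity("WallContours", function(object) {
  cc <- object@contours
  need <- c("slice", "surface", "x", "y")
  if (!all(need %in% names(cc))) return("contours need slice/surface/x/y")
  if (!all(cc$surface %in% c("endo", "epi")))
    return("surface must be 'endo' or 'epi'")
  for (s in unique(cc$slice)) {
    en <- cc[cc$slice == s & cc$surface == "endo", ]
    ep <- cc[cc$slice == s & cc$surface == "epi", ]
    if (nrow(en) < 3L || nrow(ep) < 3L)
      return(sprintf("slice %d: both contours need >= 3 vertices", s))
    if (!all(pracma::inpolygon(en$x, en$y, ep$x, ep$y)))
      return(sprintf("slice %d: endocardial contour not inside epicardial", s))
  }
  TRUE
})

#' @describeIn WallContours constructor.
#' @param contours see slot.
#' @return a `WallContours`.
#' @export
WallContours <- function(contours) new("WallContours", contours = contours)

#' Z-scored wall volume
#'
#' Per-voxel signal intensity in remote-SD units together with the wall
#' mask and its exact endocardial-half / epicardial-half partition.
#'
#' @slot z numeric 3D array, z value on wall voxels (NA elsewhere).
#' @slot wall,endoHalf,epiHalf logical 3D arrays; the halves partition the
#'   wall exactly (union = wall, intersection empty).
#' @slot remoteMean,remoteSD the normalisation constants used (a.u.).
#' @slot voxelSize voxel edge lengths (mm).
#' @exportClass ZVolume
setClass("ZVolume",
  slots = c(z = "array", wall = "array", endoHalf = "array",
            epiHalf = "array", remoteMean = "numeric", remoteSD = "numeric",
            voxelSize = "numeric"))

setValidity("ZVolume", function(object) {
  if (!identical(dim(object@z), dim(object@wall)) ||
      !identical(dim(object@wall), dim(object@endoHalf)) ||
      !identical(dim(object@wall), dim(object@epiHalf)))
    return("all arrays must share dimensions")
  if (any(object@endoHalf & object@epiHalf))
    return("endo-half and epi-half masks overlap")
  if (!identical(object@endoHalf | object@epiHalf, object@wall))
    return("halves do not partition the wall mask")
  if (object@remoteSD <= 0) return("remoteSD must be > 0")
  TRUE
})

#' Half-wall surface signal-intensity map
#'
#' Surface reconstruction with per-node mean signal intensity (remote-SD
#' units), tissue label and barycentric node area. Unmapped nodes
#' (no assigned voxels) are excluded from area sums.
#'
#' @slot mesh a [TriangleMesh-class].
#' @slot si per-node mean SI in SD units (NA when unmapped).
#' @slot label factor with levels HM/HT/DS (NA when unmapped).
#' @slot nodeArea per-node area (cm^2).
#' @slot mapped logical, node received >= 1 voxel.
#' @slot surface "endo" or "epi".
#' @exportClass SurfaceSIMap
setClass("SurfaceSIMap",
  slots = c(mesh = "TriangleMesh", si = "numeric", label = "factor",
            nodeArea = "numeric", mapped = "logical", surface = "character"))

setValidity("SurfaceSIMap", function(object) {
  n <- nrow(object@mesh@nodes)
  if (length(object@si) != n || length(object@label) != n ||
      length(object@nodeArea) != n || length(object@mapped) != n)
    return("per-node vectors must match node count")
  if (!identical(levels(object@label), c("HM", "HT", "DS")))
    return("label levels must be HM, HT, DS")
  ok <- object@mapped & is.finite(object@si)
  lab <- classifyTissue(object@si[ok])
  if (!identical(as.character(lab), as.character(object@label[ok])))
    return("labels inconsistent with node SI under the classification rule")
  TRUE
})

#' Scar quantification summary
#'
#' Compartment areas (cm^2), scar and myocardial mass (g), and left
#' ventricular volumes/ejection fraction when phase contours are available
#' (NA otherwise).
#'
#' @slot enDS,enHT,epDS,epHT compartment surface areas (cm^2).
#' @slot tsm,tmm total scar / myocardial mass (g).
#' @slot lvedv,lvesv,lvef volumes (ml) and ejection fraction (%).
#' @exportClass ScarQuantification
setClass("ScarQuantification",
  slots = c(enDS = "numeric", enHT = "numeric", epDS = "numeric",
            epHT = "numeric", tsm = "numeric", tmm = "numeric",
            lvedv = "numeric", lvesv = "numeric", lvef = "numeric"))

setValidity("ScarQuantification", function(object) {
  vals <- c(object@enDS, object@enHT, object@epDS, object@epHT,
            object@tsm, object@tmm)
  if (any(is.finite(vals) & vals < 0)) return("areas and masses must be >= 0")
  if (is.finite(object@lvedv) && is.finite(object@lvesv) &&
      is.finite(object@lvef)) {
    ef <- 100 * (object@lvedv - object@lvesv) / object@lvedv
    if (abs(ef - object@lvef) > 1e-6) return("LVEF inconsistent with volumes")
  }
  TRUE
})

#' Optical-mapping recording
#'
#' A voltage-dye movie: H x W x T frame stack with acquisition metadata.
#'
#' @slot frames numeric array H x W x T (camera counts).
#' @slot frameInterval ms between frames (> 0).
#' @slot pixelSize mm per pixel (> 0).
#' @slot stimulusTimes pacing stimulus times (ms), strictly increasing.
#' @slot cycleLength pacing cycle length (ms).
#' @exportClass OpticalRecording
setClass("OpticalRecording",
  slots = c(frames = "array", frameInterval = "numeric", pixelSize = "numeric",
            stimulusTimes = "numeric", cycleLength = "numeric"))

setValidity("OpticalRecording", function(object) {
  if (length(dim(object@frames)) != 3L) return("frames must be H x W x T")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  st <- object@stimulusTimes
  if (length(st) && any(diff(st) <= 0))
    return("stimulusTimes must be strictly increasing")
  nT <- dim(object@frames)[3L]
  if (nT * object@frameInterval < object@cycleLength)
    return("recording must cover at least one full cycle")
  TRUE
})

#' Per-pixel map classes
#'
#' `PixelMap` holds a per-pixel value matrix and a validity mask;
#' `ActivationMap` (ms from stimulus), `APDMap` (APD80, ms) and `CVField`
#' (speed in cm/s plus unit direction components) specialise it.
#'
#' @slot values numeric matrix.
#' @slot valid logical matrix, same dimensions.
#' @slot pixelSize mm per pixel.
#' @aliases ActivationMap-class APDMap-class CVField-class
#' @exportClass PixelMap
setClass("PixelMap",
  slots = c(values = "matrix", valid = "matrix", pixelSize = "numeric"))

setValidity("PixelMap", function(object) {
  if (!identical(dim(object@values), dim(object@valid)))
    return("values/valid dimensions differ")
  TRUE
})

#' @exportClass ActivationMap
setClass("ActivationMap", contains = "PixelMap")

#' @exportClass APDMap
setClass("APDMap", contains = "PixelMap")

#' @slot dirX,dirY unit propagation direction components (CVField only).
#' @exportClass CVField
#' @rdname PixelMap-class
setClass("CVField", contains = "PixelMap",
  slots = c(dirX = "matrix", dirY = "matrix"))

#' Electroanatomic mapping study
#'
#' Bipolar-voltage point cloud plus the chamber surface mesh it is rendered
#' on. The fill threshold is the maximum point-to-node distance for a node
#' to count as mapped (5 mm default).
#'
#' @slot points data.frame with `x`, `y`, `z` (mm) and `amplitude` (mV >= 0).
#' @slot mesh a [TriangleMesh-class].
#' @slot fillThreshold mm.
#' @exportClass EAMStudy
setClass("EAMStudy",
  slots = c(points = "data.frame", mesh = "TriangleMesh",
            fillThreshold = "numeric"))

setValidity("EAMStudy", function(object) {
  need <- c("x", "y", "z", "amplitude")
  if (!all(need %in% names(object@points)))
    return("points need x/y/z/amplitude columns")
  if (nrow(object@points) && any(object@points$amplitude < 0))
    return("amplitudes must be >= 0")
  if (object@fillThreshold <= 0) return("fillThreshold must be > 0")
  tri <- object@mesh@triangles
  if (nrow(tri)) {
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (any(table(key) > 2L)) return("mesh not manifold (edge shared > 2x)")
  }
  TRUE
})

#' @describeIn EAMStudy constructor.
#' @param points,mesh,fillThreshold see slots.
#' @return an `EAMStudy`.
#' @export
EAMStudy <- function(points, mesh, fillThreshold = 5) {
  new("EAMStudy", points = points, mesh = mesh,
      fillThreshold = fillThreshold)
}

#' Voltage class map
#'
#' Node-interpolated bipolar amplitudes and amplitude classes
#' (DS <= 0.5 mV, HT (0.5, 1.5] mV, healthy > 1.5 mV, unmapped beyond the
#' fill threshold), with class areas in cm^2.
#'
#' @slot mesh a [TriangleMesh-class].
#' @slot amplitude per-node interpolated mV (NA when unmapped).
#' @slot nodeClass factor DS/HT/healthy/unmapped.
#' @slot areas named numeric: DS, HT, healthy, unmapped (cm^2).
#' @exportClass VoltageClassMap
setClass("VoltageClassMap",
  slots = c(mesh = "TriangleMesh", amplitude = "numeric",
            nodeClass = "factor", areas = "numeric"))

#' Exact rank-test result
#'
#' @slot statistic U (rank-sum design) or W+ (signed-rank design), computed
#'   from mid-ranks.
#' @slot pValue exact two-sided p.
#' @slot method "exact-enumeration" or "exact-shift".
#' @slot n1,n2 group sizes (n2 = 0 for paired designs; n1 = non-zero pairs).
#' @slot ties TRUE when tied values were present.
#' @slot test "mann-whitney" or "wilcoxon-signed-rank".
#' @exportClass RankTestResult
setClass("RankTestResult",
  slots = c(statistic = "numeric", pValue = "numeric", method = "character",
            n1 = "integer", n2 = "integer", ties = "logical",
            test = "character"))

setValidity("RankTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  TRUE
})
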