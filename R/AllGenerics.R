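# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for epiScarMap containers
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an epiScarMap S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "LGEVolume", function(object) object@intensities)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "LGEVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ZVolume", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setGeneric("contourTable", function(object) standardGeneric("contourTable"))
#' @rdname accessors
#' @export
setMethod("contourTable", "WallContours", function(object) object@contours)

#' @rdname accessors
#' @export
setGeneric("zValues", function(object) standardGeneric("zValues"))
#' @rdname accessors
#' @export
setMethod("zValues", "ZVolume", function(object) object@z)

#' @rdname accessors
#' @export
setGeneric("wallMask", function(object) standardGeneric("wallMask"))
#' @rdname accessors
#' @export
setMethod("wallMask", "ZVolume", function(object) object@wall)

#' @rdname accessors
#' @param half "endo" or "epi".
#' @export
setGeneric("halfMask", function(object, half) standardGeneric("halfMask"))
#' @rdname accessors
#' @export
setMethod("halfMask", "ZVolume", function(object, half) {
  half <- match.arg(half, c("endo", "epi"))
  if (half == "endo") object@endoHalf else object@epiHalf
})

#' @rdname accessors
#' @export
setGeneric("meshNodes", function(object) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setMethod("meshNodes", "TriangleMesh", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("meshNodes", "SurfaceSIMap", function(object) object@mesh@nodes)

#' @rdname accessors
#' @export
setGeneric("meshTriangles", function(object) standardGeneric("meshTriangles"))
#' @rdname accessors
#' @export
setMethod("meshTriangles", "TriangleMesh", function(object) object@triangles)
#' @rdname accessors
#' @export
setMethod("meshTriangles", "SurfaceSIMap",
          function(object) object@mesh@triangles)

#' @rdname accessors
#' @export
setGeneric("nodeSI", function(object) standardGeneric("nodeSI"))
#' @rdname accessors
#' @export
setMethod("nodeSI", "SurfaceSIMap", function(object) object@si)

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setMethod("tissueLabels", "SurfaceSIMap", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("nodeAreas", function(object) standardGeneric("nodeAreas"))
#' @rdname accessors
#' @export
setMethod("nodeAreas", "SurfaceSIMap", function(object) object@nodeArea)

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "OpticalRecording", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "OpticalRecording",
          function(object) object@frameInterval)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "OpticalRecording", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "PixelMap", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("stimulusTimes", function(object) standardGeneric("stimulusTimes"))
#' @rdname accessors
#' @export
setMethod("stimulusTimes", "OpticalRecording",
          function(object) object@stimulusTimes)

#' @rdname accessors
#' @export
setGeneric("cycleLength", function(object) standardGeneric("cycleLength"))
#' @rdname accessors
#' @export
setMethod("cycleLength", "OpticalRecording",
          function(object) object@cycleLength)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "PixelMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "PixelMap", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("nodeAmplitudes", function(object) standardGeneric("nodeAmplitudes"))
#' @rdname accessors
#' @export
setMethod("nodeAmplitudes", "VoltageClassMap", function(object) object@amplitude)

#' @rdname accessors
#' @export
setGeneric("nodeClasses", function(object) standardGeneric("nodeClasses"))
#' @rdname accessors
#' @export
setMethod("nodeClasses", "VoltageClassMap", function(object) object@nodeClass)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "RankTestResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))
#' @rdname accessors
#' @export
setMethod("testStatistic", "RankTestResult", function(object) object@statistic)

setMethod("show", "LGEVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("LGEVolume: %d x %d x %d voxels, %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
})

setMethod("show", "ZVolume", function(object) {
  cat(sprintf(
    "ZVolume: %d wall voxels (%d endo-half / %d epi-half), remote %.1f +/- %.1f a.u.\n",
    sum(object@wall), sum(object@endoHalf), sum(object@epiHalf),
    object@remoteMean, object@remoteSD))
})

setMethod("show", "SurfaceSIMap", function(object) {
  tab <- table(object@label[object@mapped])
  cat(sprintf("SurfaceSIMap (%s): %d nodes (%d mapped); HM %d, HT %d, DS %d\n",
              object@surface, length(object@si), sum(object@mapped),
              tab[["HM"]], tab[["HT"]], tab[["DS"]]))
})

setMethod("show", "ScarQuantification", function(object) {
  cat("ScarQuantification\n")
  cat(sprintf("  EnDS %.2f  EnHT %.2f  EpDS %.2f  EpHT %.2f  (cm^2)\n",
              object@enDS, object@enHT, object@epDS, object@epHT))
  cat(sprintf("  TSM %.2f g  TMM %.2f g\n", object@tsm, object@tmm))
  cat(sprintf("  LVEDV %.1f ml  LVESV %.1f ml  LVEF %.1f%%\n",
              object@lvedv, object@lvesv, object@lvef))
})

setMethod("show", "OpticalRecording", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "OpticalRecording: %d x %d px, %d frames @ %.2f ms, %.3f mm/px, %d stimuli (CL %.0f ms)\n",
    d[1], d[2], d[3], object@frameInterval, object@pixelSize,
    length(object@stimulusTimes), object@cycleLength))
})

setMethod("show", "PixelMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("%s: %d x %d px, %d valid, median %.2f\n", class(object),
              nrow(object@values), ncol(object@values), sum(object@valid),
              stats::median(v)))
})

setMethod("show", "EAMStudy", function(object) {
  cat(sprintf("EAMStudy: %d points on %d-node mesh, fill threshold %.1f mm\n",
              nrow(object@points), nrow(object@mesh@nodes),
              object@fillThreshold))
})

setMethod("show", "VoltageClassMap", function(object) {
  a <- object@areas
  cat(sprintf(
    "VoltageClassMap: DS %.2f, HT %.2f, healthy %.2f, unmapped %.2f cm^2\n",
    a[["DS"]], a[["HT"]], a[["healthy"]], a[["unmapped"]]))
})

setMethod("show", "RankTestResult", function(object) {
  cat(sprintf("%s (%s%s): statistic = %.2f, exact two-sided p = %.4g\n",
              object@test, object@method,
              if (object@ties) ", ties" else "", object@statistic,
              object@pValue))
})
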