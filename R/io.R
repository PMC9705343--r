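# Readers and writers for the on-disk interchange formats: NIfTI volumes,
# CSV contours, multi-page 16-bit TIFF movies with JSON sidecars, CSV
# point clouds and histology tables, JSON summaries and YAML study
# configuration.

#' Read and write LGE volumes as NIfTI
#'
#' @param volume an [LGEVolume-class].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `readLGEVolume` returns an [LGEVolume-class]; the writer
#'   returns `path` invisibly.
#' @export
writeLGEVolume <- function(volume, path) {
  img <- RNifti::asNifti(intensities(volume),
                         reference = list(pixdim = c(-1, voxelSize(volume),
                                                     rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeLGEVolume
#' @export
readLGEVolume <- function(path) {
  img <- RNifti::readNifti(path)
  LGEVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' Read and write a voxel mask as NIfTI
#'
#' @param mask logical 3D array.
#' @param voxelSize mm per axis.
#' @param path file path.
#' @return `readMaskNifti` returns a logical array.
#' @export
writeMaskNifti <- function(mask, voxelSize, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         reference = list(pixdim = c(-1, voxelSize,
                                                     rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMaskNifti
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img))
}

#' Read and write wall contours as CSV
#'
#' Columns: `slice` (0-based), `surface` ("endo"/"epi"), `x`, `y` (mm),
#' vertices in order.
#'
#' @param contours a [WallContours-class].
#' @param path file path.
#' @return `readContoursCSV` returns a [WallContours-class].
#' @export
writeContoursCSV <- function(contours, path) {
  utils::write.csv(contourTable(contours), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContoursCSV
#' @export
readContoursCSV <- function(path) {
  WallContours(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write and read an optical recording (multi-page TIFF + JSON sidecar)
#'
#' Frames are stored as 16-bit TIFF pages; acquisition metadata
#' (`frame_interval_ms`, `pixel_size_mm`, `stimulus_times_ms`,
#' `cycle_length_ms`) goes to a JSON sidecar.
#'
#' @param rec an [OpticalRecording-class].
#' @param tiffPath,sidecarPath file paths.
#' @return `readOpticalRecording` returns an [OpticalRecording-class]
#'   (counts quantised to the 16-bit scale).
#' @export
writeOpticalRecording <- function(rec, tiffPath, sidecarPath) {
  fr <- frames(rec)
  pages <- lapply(seq_len(dim(fr)[3L]), function(t)
    pmin(pmax(round(fr[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_interval_ms = frameInterval(rec),
                            pixel_size_mm = pixelSize(rec),
                            stimulus_times_ms = stimulusTimes(rec),
                            cycle_length_ms = cycleLength(rec)),
                       sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(tiffPath)
}

#' @rdname writeOpticalRecording
#' @export
readOpticalRecording <- function(tiffPath, sidecarPath) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  side <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  fr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]] * 65535
  new("OpticalRecording", frames = fr,
      frameInterval = side$frame_interval_ms,
      pixelSize = side$pixel_size_mm,
      stimulusTimes = side$stimulus_times_ms,
      cycleLength = side$cycle_length_ms)
}

#' Read and write electroanatomic mapping points as CSV
#'
#' Columns: `x`, `y`, `z` (mm), `bipolar_mV`.
#'
#' @param points data.frame with `x`, `y`, `z`, `amplitude`.
#' @param path file path.
#' @return `readEAMPointsCSV` returns the points data.frame.
#' @export
writeEAMPointsCSV <- function(points, path) {
  out <- data.frame(x = points$x, y = points$y, z = points$z,
                    bipolar_mV = points$amplitude)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEAMPointsCSV
#' @export
readEAMPointsCSV <- function(path) {
  d <- utils::read.csv(path)
  data.frame(x = d$x, y = d$y, z = d$z, amplitude = d$bipolar_mV)
}

#' Read and write histology score tables as CSV
#'
#' Long format: `animal_id`, `section_id`, `compartment`, `ht_extent`
#' (mm^2), `variable`, `ordinal_level` (1-5).
#'
#' @param sections histology data.frame (see [generateHistology()]).
#' @param path file path.
#' @return `readHistologyCSV` returns the data.frame.
#' @export
writeHistologyCSV <- function(sections, path) {
  utils::write.csv(sections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHistologyCSV
#' @export
readHistologyCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-node surface map as CSV
#'
#' Columns: `node_id`, `si_sd`, `label`, `area_cm2`.
#'
#' @param map a [SurfaceSIMap-class].
#' @param path file path.
#' @export
writeSurfaceSIMapCSV <- function(map, path) {
  utils::write.csv(data.frame(node_id = seq_along(map@si),
                              si_sd = map@si,
                              label = as.character(map@label),
                              area_cm2 = map@nodeArea),
                   path, row.names = FALSE)
  invisible(path)
}

#' Scar quantification as a plain list / JSON
#'
#' @param quant a [ScarQuantification-class].
#' @param path optional JSON path; when given the list is also written.
#' @return named list of the quantities.
#' @export
scarQuantAsList <- function(quant, path = NULL) {
  out <- list(EnDS_cm2 = quant@enDS, EnHT_cm2 = quant@enHT,
              EpDS_cm2 = quant@epDS, EpHT_cm2 = quant@epHT,
              TSM_g = quant@tsm, TMM_g = quant@tmm,
              LVEDV_ml = quant@lvedv, LVESV_ml = quant@lvesv,
              LVEF_pct = quant@lvef)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}

#' Read a study configuration from YAML
#'
#' Scalar fields of [studyConfig()] may be overridden from a YAML file;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [StudyConfig-class].
#' @export
readStudyConfigYAML <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(studyConfig))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown study config keys: ",
                        paste(bad, collapse = ", "))
  do.call(studyConfig, cfg)
}
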