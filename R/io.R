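## Readers/writers for the standard on-disk formats: multi-page float TIFF
## for stacks and volumes (with a YAML sidecar carrying scale and
## provenance), single-page float TIFF per parameter map, CSV for tables
## and profiles, JSON for matrices and reports, plain text for single
## Mueller matrices.

#' Write / read a single Mueller matrix as plain text
#'
#' @param M 4 x 4 matrix.
#' @param path file path.
#' @return `readMuellerMatrix` returns the 4 x 4 matrix.
#' @export
writeMuellerMatrix <- function(M, path) {
  stopifnot(all(dim(M) == 4))
  utils::write.table(format(M, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMuellerMatrix
#' @export
readMuellerMatrix <- function(path) {
  matrix(as.matrix(utils::read.table(path, header = FALSE)), 4, 4)
}

## Multi-page float TIFF, affinely mapped into [0,1]; the offset and scale
## go to a YAML sidecar so values (including negatives) round-trip.
writePagedTiff <- function(arr3, path, extra_meta = list()) {
  d <- dim(arr3)
  lo <- min(arr3); hi <- max(arr3)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) (arr3[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(list(offset = lo, scale = scale, pages = d[3], height = d[1],
                 width = d[2]), extra_meta)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

readPagedTiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(meta$height, meta$width, meta$pages))
  for (k in seq_len(meta$pages))
    arr[, , k] <- pages[[k]] * meta$scale + (meta$offset %||% 0)
  list(data = arr, meta = meta)
}

#' Write / read a 48-frame intensity stack (multi-page TIFF + YAML sidecar)
#'
#' Frame order, bit depth, gain, seed and the schedule digest go to the
#' sidecar so a stack can be matched to its instrument.
#'
#' @param stack an [IntensityStack-class].
#' @param path `.tif` path.
#' @return `readIntensityStack` returns the [IntensityStack-class].
#' @export
writeIntensityStack <- function(stack, path) {
  writePagedTiff(stack@frames, path,
                 c(list(bitDepth = stack@bitDepth), stack@meta))
}

#' @rdname writeIntensityStack
#' @export
readIntensityStack <- function(path) {
  r <- readPagedTiff(path)
  keep <- setdiff(names(r$meta),
                  c("scale", "pages", "height", "width", "bitDepth"))
  new("IntensityStack", frames = r$data,
      bitDepth = r$meta$bitDepth %||% "float", meta = r$meta[keep])
}

#' Write parameter maps as single-page float TIFFs
#'
#' One `<name>.tif` per map (e.g. `delta_deg.tif`), scale in a sidecar.
#'
#' @param maps a [PolarimetricMaps-class] or named list of matrices.
#' @param dir output directory (created if needed).
#' @return invisible vector of paths.
#' @export
writeParameterMaps <- function(maps, dir) {
  if (is(maps, "PolarimetricMaps")) maps <- paramMaps(maps)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps), function(nm) {
    m <- maps[[nm]]
    m[!is.finite(m)] <- 0
    writePagedTiff(array(m, c(dim(m), 1)), file.path(dir,
                                                     paste0(nm, ".tif")))
  }, character(1))
  invisible(paths)
}

#' Read one parameter map written by [writeParameterMaps()]
#' @param path `.tif` path.
#' @return numeric matrix.
#' @export
readParameterMap <- function(path) {
  r <- readPagedTiff(path)
  r$data[, , 1]
}

#' Serialize / restore an instrument model (JSON)
#'
#' @param instrument an [InstrumentModel-class] or [CalibrationResult-class].
#' @param path `.json` path.
#' @return `readInstrumentModel` returns an [InstrumentModel-class].
#' @export
writeInstrumentModel <- function(instrument, path) {
  if (is(instrument, "CalibrationResult")) {
    obj <- list(W = instrument@instrument@W, A = instrument@instrument@A,
                residual = instrument@residual,
                refFits = instrument@refFits)
  } else {
    obj <- list(W = instrument@W, A = instrument@A)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeInstrumentModel
#' @export
readInstrumentModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("InstrumentModel", W = matrix(unlist(obj$W), 4, 6),
      A = matrix(unlist(obj$A), 8, 4), schedule = list(),
      meta = list(residual = obj$residual))
}

#' Write / read a sample table (CSV, fixed column schema)
#'
#' @param table data.frame from rows of [roiSummary()].
#' @param path `.csv` path.
#' @return `readSampleTable` returns the data.frame.
#' @export
writeSampleTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleTable
#' @export
readSampleTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a radial line profile (CSV: distance_um, value, n_pixels)
#'
#' @param profile result of [radialProfile()].
#' @param path `.csv` path.
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(profile$profile, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an orientation field (CSV)
#'
#' @param field an [OrientationField-class].
#' @param path `.csv` path.
#' @return `readOrientationField` returns an [OrientationField-class].
#' @export
writeOrientationField <- function(field, path) {
  utils::write.csv(field@axes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOrientationField
#' @export
readOrientationField <- function(path) {
  new("OrientationField", axes = utils::read.csv(path), meta = list())
}

#' Write / read a fiber volume (multi-page TIFF + YAML sidecar)
#'
#' @param vol a [FiberVolume-class].
#' @param path `.tif` path.
#' @return `readFiberVolume` returns a [FiberVolume-class].
#' @export
writeFiberVolume <- function(vol, path) {
  d <- dim(vol@voxels)
  ## store as pages along z: page k = x-y slice
  writePagedTiff(vol@voxels, path, list(voxelSize = vol@voxelSize))
}

#' @rdname writeFiberVolume
#' @export
readFiberVolume <- function(path) {
  r <- readPagedTiff(path)
  fiberVolume(r$data, unlist(r$meta$voxelSize))
}
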