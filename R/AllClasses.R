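#' @import methods
NULL

#' InstrumentModel: PSG/PSA characteristic matrices
#'
#' The polarization state generator is described by `W` (4 x 6, columns are
#' the input Stokes vectors) and the analyzer by `A` (8 x 4, rows are the
#' analyzer projection vectors). `schedule` keeps the optical settings the
#' matrices were built from, `meta` free-form provenance.
#'
#' @slot W 4 x 6 generator matrix.
#' @slot A 8 x 4 analyzer matrix.
#' @slot schedule list as returned by [idealSchedule()].
#' @slot meta list of provenance metadata.
#' @export
setClass("InstrumentModel",
  representation(W = "matrix", A = "matrix", schedule = "list",
                 meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@W) == c(4, 6))) msg <- c(msg, "W must be 4 x 6")
    if (!all(dim(object@A) == c(8, 4))) msg <- c(msg, "A must be 8 x 4")
    if (length(msg) == 0 && qr(object@W)$rank < 4)
      msg <- c(msg, "W is rank-deficient: unmeasurable design")
    if (length(msg) == 0 && qr(object@A)$rank < 4)
      msg <- c(msg, "A is rank-deficient: unmeasurable design")
    if (length(msg)) msg else TRUE
  })

#' IntensityStack: one 48-frame polarimetric acquisition
#'
#' `frames` is H x W x 48, ordered PSG-major / PSA-minor (frame
#' `(j - 1) * 8 + i` holds PSG state j analyzed by PSA configuration i, so a
#' pixel's frames unstack column-wise into its 8 x 6 intensity matrix B).
#'
#' @slot frames numeric H x W x 48 array, values >= 0.
#' @slot bitDepth "8", "16" or "float".
#' @slot meta list (noise parameters, seed, gain, schedule digest).
#' @export
setClass("IntensityStack",
  representation(frames = "array", bitDepth = "character", meta = "list"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3 || d[3] != 48)
      return("frames must be an H x W x 48 array")
    if (!object@bitDepth %in% c("8", "16", "float"))
      return("bitDepth must be one of '8', '16', 'float'")
    if (any(object@frames < 0, na.rm = TRUE))
      return("intensities must be non-negative")
    if (object@bitDepth != "float" &&
        max(object@frames, na.rm = TRUE) > 2^as.integer(object@bitDepth) - 1)
      return("quantized values exceed bit depth")
    TRUE
  })

#' MuellerImage: per-pixel Mueller matrices
#'
#' `field` is H x W x 4 x 4; `valid` marks pixels where reconstruction
#' produced finite values; `normalized` records whether each pixel has been
#' divided by its m11.
#'
#' @slot field numeric H x W x 4 x 4 array.
#' @slot normalized logical scalar.
#' @slot valid logical H x W matrix.
#' @slot meta list of provenance metadata.
#' @export
setClass("MuellerImage",
  representation(field = "array", normalized = "logical", valid = "matrix",
                 meta = "list"),
  validity = function(object) {
    d <- dim(object@field)
    if (length(d) != 4 || d[3] != 4 || d[4] != 4)
      return("field must be H x W x 4 x 4")
    if (!all(dim(object@valid) == d[1:2]))
      return("valid mask dimensions must match the field")
    if (isTRUE(object@normalized)) {
      m11 <- object@field[, , 1, 1][object@valid]
      if (length(m11) && max(abs(m11 - 1)) > 1e-6)
        return("normalized flag set but m11 != 1 at valid pixels")
    }
    TRUE
  })

#' PolarimetricMaps: scalar parameter maps of one acquisition
#'
#' Named list of H x W maps. Lu-Chipman maps: `D`, `R_deg`, `delta_deg`,
#' `psi_deg`, `Delta`, `DeltaL`, `DeltaC`, `axis_deg`; Mueller-matrix-
#' transformation maps: `b`, `t`, `A_mmt`. `clipCount` counts pixels where an
#' arccos/sqrt argument had to be clipped into range (quality metric).
#'
#' @slot maps named list of numeric matrices with identical dimensions.
#' @slot factors optional list of per-pixel factor arrays (MDelta, MR, MD).
#' @slot clipCount integer.
#' @slot meta list.
#' @export
setClass("PolarimetricMaps",
  representation(maps = "list", factors = "list", clipCount = "integer",
                 meta = "list"),
  validity = function(object) {
    if (length(object@maps) == 0) return("no maps")
    d <- dim(object@maps[[1]])
    ok <- vapply(object@maps, function(m) identical(dim(m), d), logical(1))
    if (!all(ok)) return("all maps must share dimensions")
    TRUE
  })

#' CalibrationResult: recovered instrument and fit diagnostics
#'
#' @slot instrument recovered [InstrumentModel-class].
#' @slot refFits list of fitted reference parameters per reference sample.
#' @slot residual smallest-to-next singular/eigen-value ratio of the
#'   calibration kernel (0 for a perfectly consistent data set).
#' @slot meta list.
#' @export
setClass("CalibrationResult",
  representation(instrument = "InstrumentModel", refFits = "list",
                 residual = "numeric", meta = "list"),
  validity = function(object) {
    if (length(object@residual) != 1 || object@residual < 0)
      return("residual must be a non-negative scalar")
    TRUE
  })

#' RingPhantom: synthetic ring-tissue ground truth plus its Mueller field
#'
#' @slot truth named list of H x W ground-truth parameter maps
#'   (`delta_deg`, `DeltaC`, `DeltaL`, `psi_deg`, `D`, `axis_deg`,
#'   `inside` logical ring support, `defect` logical defect support).
#' @slot mueller [MuellerImage-class] composed from the truth.
#' @slot spec the generating specification list.
#' @slot geometry list: `center` (pixels), `innerRadius_um`, `width_um`,
#'   `pitch_um`.
#' @export
setClass("RingPhantom",
  representation(truth = "list", mueller = "MuellerImage", spec = "list",
                 geometry = "list"))

#' FiberVolume: synthetic fiber intensity volume
#'
#' @slot voxels numeric X x Y x Z array of non-negative intensities.
#' @slot voxelSize numeric length-3, micrometres per voxel along x, y, z.
#' @slot meta list (ground-truth axes when synthesized).
#' @export
setClass("FiberVolume",
  representation(voxels = "array", voxelSize = "numeric", meta = "list"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3) return("voxels must be 3D")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive numbers")
    if (max(dim(object@voxels)) < 16)
      return("at least one volume side must be >= 16 voxels")
    TRUE
  })

#' OrientationField: per-subvolume fiber axes
#'
#' One row per subvolume: centre indices, the unit axis (antipodally
#' identified), in-plane angle `theta_deg` in [0, 180), out-of-plane angle
#' `phi_deg` in [-90, 90], spectral energy weight, validity flag.
#'
#' @slot axes data.frame with columns ix, iy, iz, vx, vy, vz, theta_deg,
#'   phi_deg, weight, valid.
#' @slot meta list (subvolume size, step, thresholds).
#' @export
setClass("OrientationField",
  representation(axes = "data.frame", meta = "list"),
  validity = function(object) {
    need <- c("ix", "iy", "iz", "vx", "vy", "vz", "theta_deg", "phi_deg",
              "weight", "valid")
    if (!all(need %in% names(object@axes)))
      return(paste("axes must have columns:", paste(need, collapse = ", ")))
    v <- object@axes[object@axes$valid, c("vx", "vy", "vz"), drop = FALSE]
    if (nrow(v) && max(abs(sqrt(rowSums(as.matrix(v)^2)) - 1)) > 1e-6)
      return("valid axes must be unit vectors")
    TRUE
  })

## ---- accessors ----

#' @describeIn InstrumentModel-class generator matrix W (4 x 6)
#' @param object an object.
#' @export
setGeneric("instrumentW", function(object) standardGeneric("instrumentW"))
#' @describeIn InstrumentModel-class analyzer matrix A (8 x 4)
#' @export
setGeneric("instrumentA", function(object) standardGeneric("instrumentA"))
setMethod("instrumentW", "InstrumentModel", function(object) object@W)
setMethod("instrumentA", "InstrumentModel", function(object) object@A)
setMethod("instrumentW", "CalibrationResult",
          function(object) object@instrument@W)
setMethod("instrumentA", "CalibrationResult",
          function(object) object@instrument@A)

#' Frames of an intensity stack
#' @param object an [IntensityStack-class].
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
setMethod("frames", "IntensityStack", function(object) object@frames)

#' Per-pixel Mueller field array (H x W x 4 x 4)
#' @param object a [MuellerImage-class] or [RingPhantom-class].
#' @export
setGeneric("muellerField", function(object) standardGeneric("muellerField"))
setMethod("muellerField", "MuellerImage", function(object) object@field)
setMethod("muellerField", "RingPhantom",
          function(object) object@mueller@field)

#' Extract one named parameter map
#' @param object a [PolarimetricMaps-class] or [RingPhantom-class].
#' @param name map name, e.g. `"delta_deg"`.
#' @export
setGeneric("paramMap", function(object, name) standardGeneric("paramMap"))
setMethod("paramMap", "PolarimetricMaps", function(object, name) {
  if (!name %in% names(object@maps))
    stop("no map named '", name, "'; available: ",
         paste(names(object@maps), collapse = ", "))
  object@maps[[name]]
})
setMethod("paramMap", "RingPhantom", function(object, name) {
  if (!name %in% names(object@truth))
    stop("no truth map named '", name, "'")
  object@truth[[name]]
})

#' All parameter maps as a named list
#' @param object a [PolarimetricMaps-class].
#' @export
setGeneric("paramMaps", function(object) standardGeneric("paramMaps"))
setMethod("paramMaps", "PolarimetricMaps", function(object) object@maps)

#' Orientation table of an [OrientationField-class]
#' @param object an OrientationField.
#' @export
setGeneric("orientationTable",
           function(object) standardGeneric("orientationTable"))
setMethod("orientationTable", "OrientationField",
          function(object) object@axes)

#' Calibration kernel residual
#' @param object a [CalibrationResult-class].
#' @export
setGeneric("calibrationResidual",
           function(object) standardGeneric("calibrationResidual"))
setMethod("calibrationResidual", "CalibrationResult",
          function(object) object@residual)

## ---- show methods ----

setMethod("show", "InstrumentModel", function(object) {
  cat("InstrumentModel: W 4x6 (rank", qr(object@W)$rank, "), A 8x4 (rank",
      qr(object@A)$rank, ")\n")
  if (!is.null(object@meta$perturbed))
    cat("  perturbed:", object@meta$perturbed, "\n")
})

setMethod("show", "IntensityStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("IntensityStack: %d x %d pixels, %d frames, %s-bit\n",
              d[1], d[2], d[3], object@bitDepth))
})

setMethod("show", "MuellerImage", function(object) {
  d <- dim(object@field)
  cat(sprintf("MuellerImage: %d x %d pixels (%snormalized), %d invalid\n",
              d[1], d[2], if (object@normalized) "" else "not ",
              sum(!object@valid)))
})

setMethod("show", "PolarimetricMaps", function(object) {
  d <- dim(object@maps[[1]])
  cat(sprintf("PolarimetricMaps: %d x %d pixels; maps: %s; clipped px: %d\n",
              d[1], d[2], paste(names(object@maps), collapse = ", "),
              object@clipCount))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: kernel residual %.3g, %d references\n",
              object@residual, length(object@refFits)))
})

setMethod("show", "RingPhantom", function(object) {
  d <- dim(object@truth$delta_deg)
  cat(sprintf("RingPhantom: %d x %d px, inner radius %.0f um, width %.0f um\n",
              d[1], d[2], object@geometry$innerRadius_um,
              object@geometry$width_um))
})

setMethod("show", "FiberVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("FiberVolume: %d x %d x %d voxels, voxel %.2f x %.2f x %.2f um\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
})

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %d subvolumes (%d valid)\n",
              nrow(object@axes), sum(object@axes$valid)))
})
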