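#' Greyscale confocal stack
#'
#' A `grey_stack` holds an 8-bit greyscale z-stack as a 3D integer array with
#' dimensions `(y, x, z)` plus the physical voxel pitch: the in-plane pixel
#' edge (`lateral_pitch`, micrometres) and the slice spacing (`axial_pitch`,
#' micrometres). Confocal stacks are typically anisotropic (e.g. 0.54 um
#' lateral, 1 um axial) and must be made isotropic before any volumetric
#' measurement.
#'
#' @param voxels 3D numeric array of intensities in `[0, 255]`, dims
#'   `(y, x, z)`. A 2D matrix is promoted to a single-slice stack.
#' @param lateral_pitch in-plane pixel edge length, micrometres.
#' @param axial_pitch slice spacing, micrometres.
#' @return An object of class `grey_stack`.
#' @export
grey_stack <- function(voxels, lateral_pitch, axial_pitch = lateral_pitch) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  if (length(voxels) == 0L) stopf("zero-sized stack")
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 255)
    stopf("intensities must lie in [0, 255]")
  if (!is.numeric(lateral_pitch) || lateral_pitch <= 0 ||
      !is.numeric(axial_pitch) || axial_pitch <= 0)
    stopf("voxel pitches must be strictly positive")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels,
                 lateral_pitch = as.numeric(lateral_pitch),
                 axial_pitch = as.numeric(axial_pitch)),
            class = "grey_stack")
}

#' @export
print.grey_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("grey_stack: %d x %d x %d (y, x, z), pitch %.3g um lateral / %.3g um axial\n",
              d[1], d[2], d[3], x$lateral_pitch, x$axial_pitch))
  cat(sprintf("  intensity range [%d, %d]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.grey_stack <- function(x) dim(x$voxels)

#' Read an 8-bit greyscale TIFF stack
#'
#' Reads a single- or multi-page 8-bit greyscale TIFF into a [grey_stack].
#' Slices are stacked along the third dimension in page order. The voxel
#' pitch is not reliably stored in confocal TIFF exports, so it must be
#' supplied by the caller (or a pipeline config).
#'
#' @param path path to the TIFF file.
#' @inheritParams grey_stack
#' @return A [grey_stack].
#' @export
read_stack <- function(path, lateral_pitch, axial_pitch = lateral_pitch) {
  if (!file.exists(path)) stopf("stack not found: %s", path)
  if (missing(lateral_pitch)) stopf("voxel pitch is required to read %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!length(pages)) stopf("empty TIFF: %s", path)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 8L)
    stopf("unsupported format: %s is %d-bit, only 8-bit greyscale is supported",
          path, bits)
  if (length(dim(pages[[1]])) > 2L)
    stopf("unsupported format: %s has multiple channels, only greyscale is supported",
          path)
  vox <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), dim(pages[[1]])))
      stopf("TIFF pages differ in size: %s", path)
    vox[, , k] <- pages[[k]]
  }
  if (max(vox) > 255L)
    stopf("unsupported format: %s holds values above 255", path)
  grey_stack(vox, lateral_pitch, axial_pitch)
}

#' Write a greyscale stack (or binary volume) as an 8-bit TIFF
#'
#' Binary volumes are encoded 0/255. Round-trips voxel-exactly through
#' [read_stack()] / [read_binary_stack()].
#'
#' @param x a [grey_stack] or [binary_volume].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  vox <- if (inherits(x, "binary_volume")) 255L * (x$voxels * 1L) else x$voxels
  pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Resample a stack to isotropic voxels
#'
#' Confocal stacks have coarser axial than lateral sampling; volumetric
#' morphology (cross-sections, dilation, skeletons) requires cubic voxels.
#' The stack is resampled along z by linear interpolation so that the slice
#' spacing equals the lateral pixel edge; the output slice count is
#' `round(n_z * axial_pitch / lateral_pitch)`.
#'
#' @param stack a [grey_stack] with `axial_pitch >= lateral_pitch`.
#' @return A [grey_stack] with equal lateral and axial pitch.
#' @export
make_isotropic <- function(stack) {
  stopifnot(inherits(stack, "grey_stack"))
  if (stack$axial_pitch < stack$lateral_pitch)
    stopf("axial pitch (%g) below lateral pitch (%g): not a confocal geometry",
          stack$axial_pitch, stack$lateral_pitch)
  factor <- stack$axial_pitch / stack$lateral_pitch
  d <- dim(stack$voxels)
  if (factor == 1) return(stack)
  n_out <- max(1L, as.integer(round(d[3] * factor)))
  # input slice coordinate (1-based) of each output slice
  pos <- 1 + (seq_len(n_out) - 1) / factor
  pos <- pmin(pos, d[3])
  k0 <- pmin(floor(pos), d[3] - 1L)
  if (d[3] == 1L) k0 <- rep(1L, n_out)
  w <- pos - k0
  out <- array(0L, dim = c(d[1], d[2], n_out))
  for (j in seq_len(n_out)) {
    lo <- stack$voxels[, , k0[j]]
    hi <- stack$voxels[, , min(k0[j] + 1L, d[3])]
    out[, , j] <- as.integer(pmax(0, pmin(255, round((1 - w[j]) * lo + w[j] * hi))))
  }
  grey_stack(out, stack$lateral_pitch, stack$lateral_pitch)
}

#' Per-slice conditional contrast normalization
#'
#' Linearly rescales each z-slice to the full 8-bit range (min to 0, max to
#' 255, rounded to nearest), but only when the slice's dynamic range
#' (max - min) is strictly greater than `min_dynamic_range` grey levels.
#' Slices with a smaller range -- typically empty or out-of-tissue slices
#' whose "signal" is noise -- are left untouched rather than having their
#' noise amplified.
#'
#' @param stack a [grey_stack].
#' @param min_dynamic_range dynamic-range gate in grey levels (default 30).
#' @return A [grey_stack].
#' @export
enhance_contrast <- function(stack, min_dynamic_range = 30) {
  stopifnot(inherits(stack, "grey_stack"))
  vox <- stack$voxels
  for (k in seq_len(dim(vox)[3])) {
    sl <- vox[, , k]
    lo <- min(sl); hi <- max(sl)
    if ((hi - lo) > min_dynamic_range)
      vox[, , k] <- as.integer(round((sl - lo) / (hi - lo) * 255))
  }
  grey_stack(vox, stack$lateral_pitch, stack$axial_pitch)
}
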