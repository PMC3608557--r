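#' Caliber bin sets
#'
#' Vessel voxels are binned by the minimal Cartesian cross-sectional area of
#' the (filled) vessel they belong to. The default preset (`"set1"`) is the
#' doubling sequence 4-8-16-32-64-128-256 px, which at the reference pitch
#' of 0.54 um reads 1-2, 2-5, 5-9, 9-19, 19-37 and 37-75 um^2. Three further
#' presets (`"set2"`..`"set4"`) interleave that sequence with shifted bin
#' edges (1-3-6-12-23-47, 2-3-7-14-28-56, 2-4-8-16-33-65 um^2), giving a
#' redundant classification that can flag sensitivity of results to bin
#' placement; their pixel bounds are the integers closest to the um^2 edges
#' at the reference pitch. Areas below the lowest edge or at/above the
#' highest edge are excluded (label 0): vessels larger than the top bin are
#' deliberately removed from the analysis.
#'
#' Bins are half-open `[lower, upper)` in pixel area.
#'
#' @param preset one of `"set1"`, `"set2"`, `"set3"`, `"set4"`, or
#'   `"set_all"` (the union of all four, 21 classes, ordered by lower edge).
#' @param pitch isotropic voxel pitch in micrometres used for um^2 labels
#'   (default 0.54).
#' @return A `caliber_bins` object: data frame with `class`, `lower_px`,
#'   `upper_px`, `lower_um2`, `upper_um2`, `label`, plus the pitch.
#' @export
caliber_bins <- function(preset = "set1", pitch = 0.54) {
  presets <- list(
    set1 = c(4L, 8L, 16L, 32L, 64L, 128L, 256L),
    set2 = c(3L, 10L, 21L, 41L, 79L, 161L),
    set3 = c(7L, 10L, 24L, 48L, 96L, 192L),
    set4 = c(7L, 14L, 27L, 55L, 113L, 223L)
  )
  if (identical(preset, "set_all")) {
    parts <- lapply(names(presets), caliber_bins, pitch = pitch)
    df <- do.call(rbind, lapply(seq_along(parts), function(i) {
      b <- parts[[i]]; b$preset <- names(presets)[i]; b
    }))
    df <- df[order(df$lower_px, df$upper_px), ]
    df$class <- seq_len(nrow(df))
    rownames(df) <- NULL
    return(structure(df, pitch = pitch, preset = "set_all",
                     class = c("caliber_bins", "data.frame")))
  }
  edges <- presets[[preset]]
  if (is.null(edges)) stopf("unknown bin preset: %s", preset)
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  df <- data.frame(
    class = seq_along(lower),
    lower_px = lower,
    upper_px = upper,
    lower_um2 = px_to_um2(lower, pitch),
    upper_um2 = px_to_um2(upper, pitch)
  )
  df$label <- sprintf("%d-%d um2", df$lower_um2, df$upper_um2)
  df$preset <- preset
  structure(df, pitch = pitch, preset = preset,
            class = c("caliber_bins", "data.frame"))
}

#' Convert a pixel area to a um^2 label
#'
#' @param area_px pixel area (non-negative).
#' @param pitch pixel edge length in micrometres.
#' @param rounded round to the nearest integer um^2 (the convention used for
#'   bin labels); set `FALSE` for the raw product.
#' @return Numeric area in um^2.
#' @export
px_to_um2 <- function(area_px, pitch = 0.54, rounded = TRUE) {
  if (any(area_px < 0)) stopf("pixel area must be non-negative")
  if (pitch <= 0) stopf("pitch must be strictly positive")
  um2 <- area_px * pitch^2
  if (rounded) round(um2) else um2
}

#' Remove sub-resolution particles
#'
#' Deletes every 26-connected foreground component whose largest 2D
#' cross-sectional area -- taken over all slices in all three Cartesian
#' orientations (2D components 8-connected in-plane) -- is strictly smaller
#' than `min_area_px`. At the reference pitch of 0.54 um the default of 4 px
#' corresponds to 1 um^2: isolated specks below the optical resolution are
#' noise, while genuine thin vessels survive because they present a large
#' longitudinal section in at least one orientation.
#'
#' @param vol a [binary_volume] (isotropic).
#' @param min_area_px minimum maximal cross-section, in pixels (default 4).
#' @return A [binary_volume] with small particles removed.
#' @export
remove_small_particles <- function(vol, min_area_px = 4) {
  stopifnot(inherits(vol, "binary_volume"))
  if (!any(vol$voxels)) return(vol)
  d <- dim(vol$voxels)
  max_area <- pmax(cpp_slice_areas(vol$voxels, d, 1L),
                   cpp_slice_areas(vol$voxels, d, 2L),
                   cpp_slice_areas(vol$voxels, d, 3L))
  labels <- cpp_label3d(vol$voxels, d, 26L)
  fg <- labels > 0L
  comp_max <- tapply(max_area[fg], labels[fg], max)
  drop <- as.integer(names(comp_max))[comp_max < min_area_px]
  out <- vol$voxels
  if (length(drop)) out[labels %in% drop] <- FALSE
  binary_volume(out, vol$pitch)
}

#' Fill hollow vessels
#'
#' Vessel walls are stained, not lumina, so binarized vessels are hollow
#' tubes. Caliber must be measured on the full vessel section, so 2D holes
#' are filled slice-wise in each of the three Cartesian orientations and the
#' three fills are unioned with the input. A tube whose profile is an open
#' "C" in one orientation (e.g. a tilted tube, or one cut by the stack face)
#' is still closed in another, which a single-orientation (or pure 3D) fill
#' would miss.
#'
#' @param vol a particle-filtered [binary_volume].
#' @return A [binary_volume]; always a superset of the input.
#' @export
fill_vessels <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$voxels)
  out <- cpp_fill_slices(vol$voxels, d, 1L) |
    cpp_fill_slices(vol$voxels, d, 2L) |
    cpp_fill_slices(vol$voxels, d, 3L)
  dim(out) <- d
  binary_volume(out, vol$pitch)
}

#' Minimal Cartesian cross-section per voxel
#'
#' For every foreground voxel, the area (pixel count) of the 2D connected
#' component containing it is measured in its xy, xz and yz slice
#' (8-connectivity in-plane) and the minimum of the three is returned. On
#' filled vessels this minimum is a caliber proxy: for a tube the smallest of
#' the three projections is close to its true cross-section, underestimating
#' it by at most sqrt(2) for tubes tilted up to 45 degrees from a Cartesian
#' axis.
#'
#' @param filled a filled [binary_volume].
#' @return Integer 3D array of minimal cross-section areas (0 on
#'   background).
#' @export
min_cartesian_cross_section <- function(filled) {
  stopifnot(inherits(filled, "binary_volume"))
  d <- dim(filled$voxels)
  a <- pmin(cpp_slice_areas(filled$voxels, d, 1L),
            cpp_slice_areas(filled$voxels, d, 2L),
            cpp_slice_areas(filled$voxels, d, 3L))
  dim(a) <- d
  a
}

#' Classify vessel voxels by caliber
#'
#' Bins every filled-vessel voxel by its minimal Cartesian cross-section
#' into the caliber classes of `bins`; areas outside the bin range get label
#' 0 (excluded -- in particular vessels with exceedingly large
#' cross-sections). The per-class maps are then intersected with the input
#' (pre-fill) binary volume, so that the reported wall stacks contain only
#' originally stained voxels, each inheriting the caliber of the whole
#' vessel it belongs to rather than of its own thin wall.
#'
#' @param input_vol the particle-filtered, pre-fill [binary_volume].
#' @param filled `fill_vessels(input_vol)`; computed if missing.
#' @param bins a [caliber_bins] set.
#' @return A list of class `caliber_classification`:
#'   \describe{
#'     \item{map}{integer 3D array of class labels (0 = excluded), defined
#'       on filled voxels}
#'     \item{min_px}{integer 3D array of minimal cross-sections}
#'     \item{volumes}{data frame per class: `filled_count`, `wall_count`,
#'       `lumen_count` (filled minus wall)}
#'     \item{wall_masks}{list of per-class logical arrays (class map
#'       intersected with `input_vol`)}
#'     \item{bins}{the bin set used}
#'   }
#' @export
classify_voxels <- function(input_vol, filled = fill_vessels(input_vol),
                            bins = caliber_bins()) {
  stopifnot(inherits(input_vol, "binary_volume"),
            inherits(filled, "binary_volume"))
  if (!identical(dim(input_vol$voxels), dim(filled$voxels)))
    stopf("input and filled volumes differ in shape")
  if (!all(filled$voxels[input_vol$voxels]))
    stopf("filled volume does not contain the input volume")
  if (nrow(bins) > 1 && any(bins$lower_px[-1] != bins$upper_px[-nrow(bins)]))
    stopf("bins must be contiguous and non-overlapping; classify redundant presets one set at a time")
  min_px <- min_cartesian_cross_section(filled)
  edges <- c(bins$lower_px[1], bins$upper_px)
  lab <- findInterval(min_px, edges)          # 0 below, nrow+1 at/above top
  lab[lab > nrow(bins)] <- 0L
  lab[min_px == 0L] <- 0L
  map <- array(as.integer(lab), dim = dim(min_px))
  wall_masks <- lapply(bins$class, function(k) {
    m <- map == k & input_vol$voxels
    dim(m) <- dim(map)
    m
  })
  names(wall_masks) <- bins$label
  volumes <- data.frame(
    class = bins$class,
    lower_px = bins$lower_px,
    upper_px = bins$upper_px,
    label = bins$label,
    filled_count = vapply(bins$class, function(k) sum(map == k), integer(1)),
    wall_count = vapply(wall_masks, sum, integer(1)),
    row.names = NULL
  )
  volumes$lumen_count <- volumes$filled_count - volumes$wall_count
  structure(list(map = map, min_px = min_px, volumes = volumes,
                 wall_masks = wall_masks, bins = bins),
            class = "caliber_classification")
}

#' @export
print.caliber_classification <- function(x, ...) {
  cat(sprintf("caliber_classification (%s): %d classes\n",
              attr(x$bins, "preset"), nrow(x$bins)))
  print(x$volumes[, c("class", "label", "filled_count", "wall_count", "lumen_count")])
  invisible(x)
}
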