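# 1D binary dilation (window of 3) along one array dimension, clipped at
# the faces
dilate_axis <- function(a, axis) {
  d <- dim(a)
  out <- a
  n <- d[axis]
  if (n == 1L) return(out)
  # OR in the +1 and -1 shifts along `axis`
  if (axis == 1L) {
    out[-1, , ] <- out[-1, , ] | a[-n, , ]
    out[-n, , ] <- out[-n, , ] | a[-1, , ]
  } else if (axis == 2L) {
    out[, -1, ] <- out[, -1, ] | a[, -n, ]
    out[, -n, ] <- out[, -n, ] | a[, -1, ]
  } else {
    out[, , -1] <- out[, , -1] | a[, , -n]
    out[, , -n] <- out[, , -n] | a[, , -1]
  }
  out
}

dilate_cross3d <- function(a) {
  out <- a
  for (axis in 1:3) {
    b <- dilate_axis(a, axis)
    out <- out | b
  }
  out
}

dilate_cube3d <- function(a) {
  for (axis in 1:3) a <- dilate_axis(a, axis)
  a
}

#' One cycle of rhombicuboctahedral dilation
#'
#' Alternating binary dilation that approximates spherical growth on a voxel
#' grid: odd cycles dilate by the 6-neighbor 3D cross structuring element,
#' even cycles by the 3x3x3 cube. Alternation compensates the cross's
#' octahedral and the cube's cubical growth bias; the effective structuring
#' element over two cycles is rhombicuboctahedral. Growth is clipped at the
#' stack faces (no wraparound, no padding).
#'
#' @param vol a [binary_volume].
#' @param cycle_index 1-based cycle number; parity selects the element.
#' @param cross_first if `FALSE`, the parity is swapped (cube on odd
#'   cycles). The Halo index depends on this choice, so it is recorded in
#'   [fill_curve()] output.
#' @return A [binary_volume].
#' @export
rhombicuboctahedral_step <- function(vol, cycle_index, cross_first = TRUE) {
  stopifnot(inherits(vol, "binary_volume"))
  if (cycle_index < 1) stopf("cycle_index must be >= 1")
  odd <- cycle_index %% 2 == 1
  use_cross <- if (cross_first) odd else !odd
  out <- if (use_cross) dilate_cross3d(vol$voxels) else dilate_cube3d(vol$voxels)
  binary_volume(out, vol$pitch)
}

#' Dilation fill curve of a volume
#'
#' Iterates [rhombicuboctahedral_step()] from the initial foreground,
#' recording the foreground fraction after each cycle (cycle 0 is the
#' initial fraction), and stops at the first cycle whose fraction reaches
#' `target_fraction` (or when growth saturates).
#'
#' @param vol a [binary_volume] with at least one foreground voxel.
#' @param target_fraction stop fraction (default 0.90).
#' @param cross_first structuring-element parity, see
#'   [rhombicuboctahedral_step()].
#' @return A `fill_curve` object: data frame with `cycle`, `count`,
#'   `fraction`; attributes `total` (stack voxels), `target_fraction`,
#'   `cross_first`.
#' @export
fill_curve <- function(vol, target_fraction = 0.90, cross_first = TRUE) {
  stopifnot(inherits(vol, "binary_volume"))
  total <- length(vol$voxels)
  count <- sum(vol$voxels)
  if (count == 0L) stopf("no foreground to expand")
  if (target_fraction <= 0 || target_fraction > 1)
    stopf("target_fraction must be in (0, 1]")
  cycles <- 0L
  counts <- count
  cur <- vol
  while (counts[length(counts)] / total < target_fraction) {
    cycles <- cycles + 1L
    cur <- rhombicuboctahedral_step(cur, cycles, cross_first = cross_first)
    nc <- sum(cur$voxels)
    if (nc == counts[length(counts)]) break  # saturated (cannot happen on a connected grid before 100%)
    counts <- c(counts, nc)
  }
  out <- data.frame(cycle = seq_along(counts) - 1L, count = counts,
                    fraction = counts / total)
  structure(out, total = total, target_fraction = target_fraction,
            cross_first = cross_first,
            class = c("fill_curve", "data.frame"))
}

# fractional cycle at which a non-decreasing curve first reaches `target`
# (in the same units as `values`): linear interpolation between the two
# cycles encompassing the target
interp_cycles <- function(cycle, values, target) {
  if (any(diff(values) < 0)) stopf("fill curve is not non-decreasing")
  if (values[1] >= target) return(0)
  i <- which(values >= target)[1]
  if (is.na(i)) stopf("fill curve never reaches the target")
  (cycle[i - 1]) + (target - values[i - 1]) / (values[i] - values[i - 1])
}

#' Volumetric Halo index (Hv)
#'
#' The number of dilation cycles needed to fill exactly `target_fraction`
#' of the stack, obtained by linear interpolation between the two recorded
#' cycles encompassing that fraction. Low Hv means space-filling
#' (homogeneous) foreground; high Hv means clustered foreground that must
#' grow a long way to occupy the stack.
#'
#' @param curve a [fill_curve()].
#' @param target_fraction target fill fraction; defaults to the curve's own.
#' @return Fractional cycle count (>= 0).
#' @export
halo_index <- function(curve, target_fraction = attr(curve, "target_fraction")) {
  stopifnot(inherits(curve, "fill_curve"))
  interp_cycles(curve$cycle, curve$fraction, target_fraction)
}

#' Cohort normalization count
#'
#' The largest initial foreground voxel count among the volumes to be
#' analyzed together. All volumes must share the same stack dimensions:
#' the Halo index is measured against the stack, so dispersions are only
#' comparable across identically sized stacks.
#'
#' @param samples list of [binary_volume]s.
#' @return Integer voxel count.
#' @export
cohort_normalization_count <- function(samples) {
  if (!length(samples)) stopf("empty cohort")
  dims <- lapply(samples, function(s) dim(s$voxels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("samples differ in stack dimensions; nHv would not be comparable")
  max(vapply(samples, function(s) sum(s$voxels), integer(1)))
}

#' Normalized volumetric Halo index (nHv)
#'
#' Samples with more initial foreground fill the stack in fewer cycles
#' regardless of their layout. To compare layouts across samples, every
#' sample is first (conceptually) grown to the cohort's largest initial
#' foreground count; the fractional cycles spent reaching that count
#' (`norm_cycles`, interpolated on absolute counts with the same rule as
#' Hv) are subtracted: `nHv = Hv - norm_cycles`. Higher nHv means a more
#' clustered, less volume-filling layout.
#'
#' @param vol a [binary_volume].
#' @param normalization_count from [cohort_normalization_count()]; must be
#'   at least this sample's count and at most `target_fraction` of the
#'   stack.
#' @param target_fraction fill target (default 0.90).
#' @param cross_first structuring-element parity.
#' @param integer_norm if `TRUE`, `norm_cycles` is rounded up to whole
#'   cycles instead of interpolated.
#' @return A `dispersion_result` list: `Hv`, `norm_cycles`, `nHv`,
#'   `initial_count`, `normalization_count`, `target_fraction`, `curve`.
#' @export
normalized_halo <- function(vol, normalization_count,
                            target_fraction = 0.90, cross_first = TRUE,
                            integer_norm = FALSE) {
  stopifnot(inherits(vol, "binary_volume"))
  count <- sum(vol$voxels)
  if (count == 0L) stopf("no foreground to expand")
  if (normalization_count < count)
    stopf("normalization count (%d) below this sample's initial count (%d)",
          normalization_count, count)
  total <- length(vol$voxels)
  if (normalization_count > target_fraction * total)
    stopf("normalization count exceeds the fill target; nHv undefined")
  curve <- fill_curve(vol, target_fraction = target_fraction,
                      cross_first = cross_first)
  hv <- halo_index(curve)
  nc <- interp_cycles(curve$cycle, curve$count, normalization_count)
  if (integer_norm) nc <- ceiling(nc)
  structure(list(Hv = hv, norm_cycles = nc, nHv = hv - nc,
                 initial_count = count,
                 normalization_count = as.integer(normalization_count),
                 target_fraction = target_fraction, curve = curve),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion_result: Hv = %.3f, norm_cycles = %.3f, nHv = %.3f (initial %d voxels, normalized to %d, target %.0f%%)\n",
              x$Hv, x$norm_cycles, x$nHv, x$initial_count,
              x$normalization_count, 100 * x$target_fraction))
  invisible(x)
}
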