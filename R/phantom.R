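#' Specification for a synthetic vascular phantom
#'
#' Describes a seeded synthetic confocal stack of hollow tubular "vessels"
#' with known ground truth, used to validate every pipeline stage. Tubes
#' are digital cylinders (a voxel belongs to a tube when its center lies
#' within `radius` of the centerline segment); with `wall` smaller than the
#' radius only the annular shell of thickness `wall` is bright, emulating
#' wall-only staining. Layouts: `"homogeneous"` scatters tube anchors
#' uniformly; `"clustered"` draws `cluster_parents` parent points uniformly
#' and scatters anchors around them with isotropic Gaussian spread
#' `cluster_sd` (a Thomas-process layout).
#'
#' @param dims stack dimensions `c(y, x, z)` in voxels.
#' @param pitch isotropic voxel pitch, micrometres (default 0.54).
#' @param n_tubes number of tubes.
#' @param radii tube radii in pixels, sampled with `radius_weights`.
#' @param radius_weights sampling weights (default uniform).
#' @param wall wall thickness in pixels; `Inf` (or `>= radius`) gives solid
#'   tubes.
#' @param orientation `"axis"` (random Cartesian axis per tube), `"random"`
#'   (uniform direction), or a 3-vector used for every tube.
#' @param max_tilt_deg when `orientation = "random"`, maximum tilt from the
#'   nearest Cartesian axis, degrees (default 45).
#' @param layout `"homogeneous"` or `"clustered"`.
#' @param anchors optional n x 3 matrix of fixed tube anchor coordinates
#'   `(y, x, z)` (recycled over tubes); overrides the layout. Anchors are
#'   voxel centers, so axis-aligned tubes have exact digital-disc
#'   cross-sections.
#' @param cluster_parents,cluster_sd Thomas-layout parameters.
#' @param fg_mean,fg_sd foreground (wall) intensity mean and noise sd.
#' @param bg_mean,bg_sd background intensity mean and noise sd.
#' @param overlap allow tubes to overlap (default; real networks touch).
#'   With `FALSE`, anchors are re-drawn (rejection sampling) until the new
#'   tube keeps at least one voxel of clearance from all previous ones.
#' @param n_artifact_blobs number of solid "stained cell body" spheres.
#' @param artifact_radius,artifact_intensity blob radius (px) and mean
#'   intensity; the default intensity sits between background and wall so
#'   that thresholding excludes the blobs.
#' @param seed integer; the same seed reproduces the stack bit-for-bit.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 48L), pitch = 0.54,
                         n_tubes = 6L, radii = c(2L, 3L, 4L),
                         radius_weights = NULL, wall = 1L,
                         orientation = "axis", max_tilt_deg = 45,
                         layout = c("homogeneous", "clustered"),
                         anchors = NULL,
                         cluster_parents = 2L, cluster_sd = 4,
                         overlap = TRUE,
                         fg_mean = 220, fg_sd = 10,
                         bg_mean = 10, bg_sd = 5,
                         n_artifact_blobs = 0L, artifact_radius = 3L,
                         artifact_intensity = 60,
                         seed = 1L) {
  layout <- match.arg(layout)
  if (any(radii < 1)) stopf("tube radii must be >= 1 px")
  if (length(dims) != 3L || any(dims < 8L)) stopf("dims must be 3 values >= 8")
  if (2 * max(radii) + 2 >= min(dims))
    stopf("tubes of radius %d cannot fit a %s stack", max(radii),
          paste(dims, collapse = "x"))
  structure(list(dims = as.integer(dims), pitch = pitch,
                 n_tubes = as.integer(n_tubes), radii = as.integer(radii),
                 radius_weights = radius_weights, wall = wall,
                 orientation = orientation, max_tilt_deg = max_tilt_deg,
                 layout = layout, anchors = anchors,
                 cluster_parents = as.integer(cluster_parents),
                 cluster_sd = cluster_sd, overlap = isTRUE(overlap),
                 fg_mean = fg_mean, fg_sd = fg_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 n_artifact_blobs = as.integer(n_artifact_blobs),
                 artifact_radius = artifact_radius,
                 artifact_intensity = artifact_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance from each voxel center in a grid to a segment a..b (all in voxel
# coordinates); returns the mask of voxels within `radius`
tube_mask <- function(dims, a, b, radius) {
  lo <- pmax(1, floor(pmin(a, b) - radius - 1))
  hi <- pmin(dims, ceiling(pmax(a, b) + radius + 1))
  if (any(lo > hi)) return(NULL)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  p <- cbind(g$i, g$j, g$k)
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) rep(0, nrow(p)) else
    pmin(1, pmax(0, ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
                       (p[, 3] - a[3]) * ab[3]) / len2))
  dx <- p[, 1] - (a[1] + t * ab[1])
  dy <- p[, 2] - (a[2] + t * ab[2])
  dz <- p[, 3] - (a[3] + t * ab[3])
  d2 <- dx * dx + dy * dy + dz * dz
  sel <- d2 <= radius^2
  if (!any(sel)) return(NULL)
  cbind(g$i[sel], g$j[sel], g$k[sel], sqrt(d2[sel]))
}

#' Generate a synthetic vascular phantom
#'
#' Rasterizes the tubes of a [phantom_spec] into an 8-bit greyscale stack
#' with Gaussian intensity noise (clamped to `[0, 255]`) and returns the
#' stack together with its ground truth. The same seed always yields the
#' identical stack.
#'
#' @param spec a [phantom_spec].
#' @return List with:
#'   \describe{
#'     \item{stack}{a [grey_stack] (isotropic, at `spec$pitch`)}
#'     \item{truth}{data frame per tube: anchor, direction, `radius_px`,
#'       `wall_px`, `expected_class` (under set1 bins at `spec$pitch`),
#'       `wall_voxels`, `filled_voxels`}
#'     \item{wall_mask, filled_mask}{noise-free logical ground-truth arrays}
#'     \item{class_mask}{integer array of expected caliber classes (the
#'       last tube wins where tubes overlap)}
#'     \item{blobs}{data frame of artifact blob centers/radii}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dims
    wall_mask <- array(FALSE, d)
    filled_mask <- array(FALSE, d)
    class_mask <- array(0L, d)   # expected caliber class (last tube wins)
    bins <- caliber_bins("set1", pitch = spec$pitch)

    # anchor sampler by layout (clustered = Thomas process around parents)
    parents <- NULL
    if (spec$layout == "clustered") {
      parents <- matrix(0, spec$cluster_parents, 3)
      for (c3 in 1:3)
        parents[, c3] <- runif(spec$cluster_parents, 1 + d[c3] / 4, d[c3] - d[c3] / 4)
    }
    anchor_i <- 0L
    draw_anchor <- function() {
      # anchors snap to voxel centers so axis-aligned tubes carry exact
      # digital-disc cross-sections
      if (!is.null(spec$anchors)) {
        anchor_i <<- anchor_i %% nrow(spec$anchors) + 1L
        return(round(as.numeric(spec$anchors[anchor_i, ])))
      }
      a <- if (spec$layout == "homogeneous") {
        vapply(1:3, function(c3) runif(1, 1, d[c3]), numeric(1))
      } else {
        pa <- sample.int(spec$cluster_parents, 1)
        vapply(1:3, function(c3)
          min(d[c3], max(1, parents[pa, c3] + rnorm(1, 0, spec$cluster_sd))),
          numeric(1))
      }
      round(a)
    }
    draw_direction <- function() {
      if (is.numeric(spec$orientation))
        return(spec$orientation / sqrt(sum(spec$orientation^2)))
      ax <- sample.int(3, 1)
      v <- c(0, 0, 0); v[ax] <- 1
      if (spec$orientation == "axis") return(v)
      # random direction within max_tilt_deg of a random Cartesian axis
      tilt <- runif(1, 0, spec$max_tilt_deg) * pi / 180
      perp <- rnorm(3); perp <- perp - sum(perp * v) * v
      perp <- perp / sqrt(sum(perp^2))
      cos(tilt) * v + sin(tilt) * perp
    }

    radii <- if (length(spec$radii) == 1L) rep(spec$radii, spec$n_tubes)
      else sample(spec$radii, spec$n_tubes, replace = TRUE, prob = spec$radius_weights)

    span <- 2 * sqrt(sum(d^2))
    truth <- vector("list", spec$n_tubes)
    for (t in seq_len(spec$n_tubes)) {
      r <- radii[t]
      for (attempt in 1:100) {
        anchor <- draw_anchor()
        dir <- draw_direction()
        a <- anchor - span / 2 * dir
        b <- anchor + span / 2 * dir
        vox <- tube_mask(d, a, b, r)
        if (is.null(vox)) next
        if (spec$overlap) break
        # require >= 1 voxel clearance from all previous tubes
        clear <- tube_mask(d, a, b, r + 1.5)
        cidx <- clear[, 1] + d[1] * (clear[, 2] - 1 + d[2] * (clear[, 3] - 1))
        if (!any(filled_mask[cidx])) break
        vox <- NULL
      }
      if (is.null(vox))
        stopf("could not place tube %d (radius %d) without overlap", t, r)
      idx <- vox[, 1] + d[1] * (vox[, 2] - 1 + d[2] * (vox[, 3] - 1))
      filled_mask[idx] <- TRUE
      hollow <- is.finite(spec$wall) && spec$wall < r
      widx <- if (hollow) idx[vox[, 4] > r - spec$wall] else idx
      wall_mask[widx] <- TRUE
      disc <- digital_disc_area(r)
      class_mask[idx] <- expected_class(r, bins)
      truth[[t]] <- data.frame(
        anchor_y = anchor[1], anchor_x = anchor[2], anchor_z = anchor[3],
        dir_y = dir[1], dir_x = dir[2], dir_z = dir[3],
        radius_px = r, wall_px = if (hollow) spec$wall else NA,
        disc_area_px = disc,
        expected_class = expected_class(r, bins),
        filled_voxels = length(idx), wall_voxels = length(widx))
    }
    truth <- do.call(rbind, truth)
    truth$tube <- seq_len(nrow(truth))

    # artifact blobs: stained cell bodies, dimmer than vessel walls.
    # Separate RNG streams per stage, so adding blobs to a spec leaves the
    # tubes and the noise field of the same seed untouched.
    blobs <- NULL
    blob_mask <- array(FALSE, d)
    set.seed(spec$seed + 1000003L)
    if (spec$n_artifact_blobs > 0) {
      centers <- matrix(0, spec$n_artifact_blobs, 3)
      for (c3 in 1:3)
        centers[, c3] <- runif(spec$n_artifact_blobs,
                               1 + spec$artifact_radius, d[c3] - spec$artifact_radius)
      for (bi in seq_len(spec$n_artifact_blobs)) {
        vox <- tube_mask(d, centers[bi, ], centers[bi, ], spec$artifact_radius)
        idx <- vox[, 1] + d[1] * (vox[, 2] - 1 + d[2] * (vox[, 3] - 1))
        blob_mask[idx] <- TRUE
      }
      blobs <- data.frame(y = centers[, 1], x = centers[, 2], z = centers[, 3],
                          radius_px = spec$artifact_radius)
    }

    set.seed(spec$seed + 2000003L)
    intens <- array(rnorm(prod(d), spec$bg_mean, spec$bg_sd), d)
    if (any(blob_mask))
      intens[blob_mask] <- rnorm(sum(blob_mask), spec$artifact_intensity, spec$fg_sd)
    intens[wall_mask] <- rnorm(sum(wall_mask), spec$fg_mean, spec$fg_sd)
    intens <- round(pmin(255, pmax(0, intens)))

    list(stack = grey_stack(array(as.integer(intens), d), spec$pitch, spec$pitch),
         truth = truth,
         wall_mask = wall_mask, filled_mask = filled_mask,
         class_mask = class_mask, blobs = blobs)
  })
}

#' Digital disc area
#'
#' Number of integer lattice points `(x, y)` with `x^2 + y^2 <= r^2` -- the
#' cross-sectional area, in pixels, of a digital cylinder of radius `r`
#' voxels.
#'
#' @param radius_px radius in pixels.
#' @return Integer pixel count.
#' @export
digital_disc_area <- function(radius_px) {
  r <- radius_px
  ix <- -floor(r):floor(r)
  sum(outer(ix^2, ix^2, "+") <= r^2)
}

#' Expected caliber class of a tube radius
#'
#' The caliber bin of the digital-disc area of a tube of the given radius:
#' the class a perfectly rasterized axis-aligned tube of that radius should
#' receive. Radii whose disc area falls off the bin range return 0
#' (excluded).
#'
#' @param radius_px tube radius in pixels (>= 1).
#' @param bins a [caliber_bins] set.
#' @return Integer class index (0 = excluded).
#' @export
expected_class <- function(radius_px, bins = caliber_bins()) {
  if (any(radius_px < 1)) stopf("radius must be >= 1 px")
  vapply(radius_px, function(r) {
    area <- digital_disc_area(r)
    edges <- c(bins$lower_px[1], bins$upper_px)
    k <- findInterval(area, edges)
    if (k < 1 || k > nrow(bins)) 0L else as.integer(k)
  }, integer(1))
}
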