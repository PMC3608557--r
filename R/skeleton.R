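#' Skeletonize a filled vessel volume
#'
#' Reduces the filled vessels to 1-voxel-wide centerlines by
#' topology-preserving directional thinning (the decision-tree border
#' thinning family): in each pass, simple border voxels of the six face
#' directions are deleted (endpoints kept), with the simplicity test --
#' exactly one foreground 26-component and one face-adjacent background
#' 6-component in the voxel neighborhood -- re-evaluated at deletion time.
#' The skeleton is a subset of the input, has the same number of
#' 26-connected components and preserves loops, so skeleton voxel counts are
#' a wall-thickness-free proxy for vessel length.
#'
#' @param filled a filled [binary_volume].
#' @return A [binary_volume] containing the skeleton.
#' @export
skeletonize_volume <- function(filled) {
  stopifnot(inherits(filled, "binary_volume"))
  d <- dim(filled$voxels)
  binary_volume(cpp_thin3d(filled$voxels, d), filled$pitch)
}

#' Classify skeleton voxels by the caliber map
#'
#' Every skeleton voxel inherits the caliber class assigned to its
#' coordinate in the vessel map (computed on the filled vessels, the same
#' map used to classify wall voxels). Skeleton voxels falling on excluded
#' (label 0) vessels are counted separately.
#'
#' @param skel a skeleton [binary_volume] (subset of the filled volume).
#' @param classification a `caliber_classification` from [classify_voxels()].
#' @return Data frame per class with `skeleton_count`; attribute
#'   `unclassified` holds the label-0 skeleton count.
#' @export
classify_skeleton <- function(skel, classification) {
  stopifnot(inherits(skel, "binary_volume"),
            inherits(classification, "caliber_classification"))
  map <- classification$map
  if (!identical(dim(skel$voxels), dim(map)))
    stopf("skeleton and caliber map differ in shape")
  labs <- map[skel$voxels]
  bins <- classification$bins
  counts <- vapply(bins$class, function(k) sum(labs == k), integer(1))
  out <- data.frame(class = bins$class, label = bins$label,
                    skeleton_count = counts, row.names = NULL)
  attr(out, "unclassified") <- sum(labs == 0L)
  out
}

#' Artifact-control ratios per caliber class
#'
#' Two ratios that expose staining artifacts independently of vessel
#' amount:
#' \describe{
#'   \item{`staining_per_length`}{wall voxels per skeleton voxel -- the
#'     amount of stained wall per unit of vessel length. Intracellular
#'     staining (stained cell bodies) inflates it.}
#'   \item{`lumen_fraction`}{luminal voxels per wall voxel -- the
#'     patent-lumen content relative to wall staining.}
#' }
#' Classes with a zero denominator are flagged `NA` rather than silently
#' divided.
#'
#' @param class_volumes the `volumes` data frame of a
#'   `caliber_classification` (columns `class`, `wall_count`,
#'   `lumen_count`).
#' @param skeleton_counts data frame from [classify_skeleton()].
#' @return Data frame per class: counts plus `staining_per_length`,
#'   `lumen_fraction`.
#' @export
compute_ratios <- function(class_volumes, skeleton_counts) {
  if (!identical(class_volumes$class, skeleton_counts$class))
    stopf("class volumes and skeleton counts use different bin sets")
  if (any(class_volumes$wall_count < 0) || any(class_volumes$lumen_count < 0) ||
      any(skeleton_counts$skeleton_count < 0))
    stopf("negative counts")
  out <- data.frame(
    class = class_volumes$class,
    label = class_volumes$label,
    wall = class_volumes$wall_count,
    skeleton = skeleton_counts$skeleton_count,
    lumen = class_volumes$lumen_count,
    row.names = NULL
  )
  out$staining_per_length <- ifelse(out$skeleton > 0, out$wall / out$skeleton, NA_real_)
  out$lumen_fraction <- ifelse(out$wall > 0, out$lumen / out$wall, NA_real_)
  out
}
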