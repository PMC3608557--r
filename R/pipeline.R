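#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end analysis. The
#' defaults are the reference operating conditions of the method: 0.54 um
#' lateral pitch, 1 um slice spacing, a 30-grey-level dynamic-range gate,
#' Renyi-entropy thresholding of the pooled stack histogram, a 4 px
#' (1 um^2) particle filter, the set1 caliber bins and a 90% fill target.
#'
#' @param lateral_pitch,axial_pitch voxel pitch of the input stacks, um.
#' @param bin_set caliber bin preset name (see [caliber_bins()]).
#' @param target_fraction Halo fill target (default 0.90).
#' @param min_dynamic_range contrast-normalization gate, grey levels.
#' @param min_particle_px particle-filter threshold, pixel area.
#' @param threshold_method `"renyi"` (pooled-histogram Renyi entropy) or
#'   `"renyi_per_slice"` (per-slice thresholds; exposed for comparison,
#'   flickers across slices).
#' @param cross_first dilation parity (see [rhombicuboctahedral_step()]).
#' @param output_dir where [run_pipeline()] writes CSVs (created if
#'   needed); `NULL` for no file output.
#' @param save_volumes persist intermediate binary volumes as TIFF.
#' @return A `run_config` list.
#' @export
run_config <- function(lateral_pitch = 0.54, axial_pitch = 1,
                       bin_set = "set1", target_fraction = 0.90,
                       min_dynamic_range = 30, min_particle_px = 4,
                       threshold_method = c("renyi", "renyi_per_slice"),
                       cross_first = TRUE,
                       output_dir = NULL, save_volumes = FALSE) {
  threshold_method <- match.arg(threshold_method)
  structure(list(lateral_pitch = lateral_pitch, axial_pitch = axial_pitch,
                 bin_set = bin_set, target_fraction = target_fraction,
                 min_dynamic_range = min_dynamic_range,
                 min_particle_px = min_particle_px,
                 threshold_method = threshold_method,
                 cross_first = cross_first,
                 output_dir = output_dir, save_volumes = save_volumes),
            class = "run_config")
}

#' Preprocess one greyscale stack to a binary volume
#'
#' Isotropic resampling, conditional per-slice contrast normalization, and
#' Renyi-entropy binarization.
#'
#' @param stack a [grey_stack].
#' @param config a [run_config()].
#' @return A [binary_volume].
#' @export
preprocess_stack <- function(stack, config = run_config()) {
  iso <- make_isotropic(stack)
  iso <- enhance_contrast(iso, min_dynamic_range = config$min_dynamic_range)
  if (config$threshold_method == "renyi_per_slice") {
    d <- dim(iso$voxels)
    out <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      sl <- iso$voxels[, , k]
      thr <- tryCatch(
        renyi_threshold_histogram(tabulate(as.vector(sl) + 1L, nbins = 256L)),
        error = function(e) 255L)  # constant slice: nothing above threshold
      out[, , k] <- sl > thr
    }
    binary_volume(out, iso$lateral_pitch)
  } else {
    binarize_stack(iso)
  }
}

#' Analyze one binary sample end to end
#'
#' Particle filter, vessel fill, caliber classification, skeletonization
#' and skeleton classification, artifact-control ratios, and per-class
#' percent volumes. Dispersion (nHv) needs the whole cohort for
#' normalization and is added by [run_pipeline()].
#'
#' @param vol a preprocessed [binary_volume].
#' @param config a [run_config()].
#' @return List with `classification`, `skeleton`, `skeleton_counts`,
#'   `ratios`, `input_vol` (particle-filtered), `class_masks` (per-class
#'   wall [binary_volume]s).
#' @export
analyze_sample <- function(vol, config = run_config()) {
  bins <- caliber_bins(config$bin_set, pitch = vol$pitch)
  clean <- remove_small_particles(vol, min_area_px = config$min_particle_px)
  filled <- fill_vessels(clean)
  cls <- classify_voxels(clean, filled, bins)
  skel <- skeletonize_volume(filled)
  skc <- classify_skeleton(skel, cls)
  ratios <- compute_ratios(cls$volumes, skc)
  class_masks <- lapply(cls$wall_masks, binary_volume, pitch = vol$pitch)
  list(classification = cls, skeleton = skel, skeleton_counts = skc,
       ratios = ratios, input_vol = clean, class_masks = class_masks)
}

#' Run the full cohort pipeline
#'
#' Executes, for every sample: preprocessing (isotropic resampling,
#' conditional contrast normalization, Renyi-entropy binarization),
#' particle filtering, vessel fill-up, minimal-Cartesian-cross-section
#' caliber classification, skeletonization, and per-class dispersion
#' (Hv/nHv, normalized per class to the largest initial per-class volume in
#' the whole analysis set). Finally builds the cohort significance table.
#'
#' @param samples named list; each element is either a [grey_stack], a
#'   [binary_volume] (already preprocessed), or a file path to a TIFF
#'   stack.
#' @param manifest data frame mapping `sample` names to `treatment` labels.
#' @param config a [run_config()].
#' @return List of class `pipeline_result`: `metrics` (long data frame:
#'   sample, treatment, class, counts, `v_pct`, `Hv`, `norm_cycles`,
#'   `nhv`, ratios), `summary` (a `cohort_summary` when >= 2 treatments),
#'   `normalization_count`, `config`.
#' @export
run_pipeline <- function(samples, manifest, config = run_config()) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    stopf("samples must be a named list")
  if (!all(c("sample", "treatment") %in% names(manifest)))
    stopf("manifest needs columns sample, treatment")
  missing_samples <- setdiff(names(samples), manifest$sample)
  if (length(missing_samples))
    stopf("manifest lacks treatment for: %s", paste(missing_samples, collapse = ", "))

  analyzed <- lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    if (is.character(s)) {
      if (!file.exists(s)) stopf("sample %s: file not found: %s", nm, s)
      s <- read_stack(s, config$lateral_pitch, config$axial_pitch)
    }
    vol <- if (inherits(s, "grey_stack")) preprocess_stack(s, config) else s
    if (!inherits(vol, "binary_volume"))
      stopf("sample %s is neither a stack, a binary volume nor a path", nm)
    analyze_sample(vol, config)
  })
  names(analyzed) <- names(samples)

  # normalization: greatest initial per-class volume over the whole
  # analysis set (all samples x classes co-analyzed)
  all_masks <- unlist(lapply(analyzed, function(a) a$class_masks),
                      recursive = FALSE)
  norm_count <- cohort_normalization_count(all_masks)
  total_vox <- length(all_masks[[1]]$voxels)
  if (norm_count > config$target_fraction * total_vox)
    stopf("largest class volume exceeds the fill target; nHv undefined for this cohort")

  metrics <- do.call(rbind, lapply(names(analyzed), function(nm) {
    a <- analyzed[[nm]]
    tr <- manifest$treatment[match(nm, manifest$sample)]
    df <- a$ratios
    df$filled <- a$classification$volumes$filled_count
    df$sample <- nm
    df$treatment <- tr
    df$v_pct <- 100 * df$wall / total_vox
    disp <- lapply(seq_len(nrow(df)), function(i) {
      m <- a$class_masks[[i]]
      if (sum(m$voxels) == 0L)  # absent class: dispersion missing by design
        return(c(Hv = NA_real_, norm_cycles = NA_real_, nhv = NA_real_))
      r <- normalized_halo(m, norm_count,
                           target_fraction = config$target_fraction,
                           cross_first = config$cross_first)
      c(Hv = r$Hv, norm_cycles = r$norm_cycles, nhv = r$nHv)
    })
    disp <- do.call(rbind, disp)
    cbind(df, as.data.frame(disp))
  }))
  rownames(metrics) <- NULL
  metrics <- metrics[, c("sample", "treatment", "class", "label",
                         "filled", "wall", "lumen", "skeleton",
                         "staining_per_length", "lumen_fraction",
                         "v_pct", "Hv", "norm_cycles", "nhv")]

  summary <- NULL
  if (length(unique(manifest$treatment[manifest$sample %in% names(samples)])) >= 2)
    summary <- build_significance_table(metrics)

  res <- structure(list(metrics = metrics, summary = summary,
                        normalization_count = norm_count,
                        config = config, analyzed = analyzed),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d samples, normalization count %d\n",
              length(unique(x$metrics$sample)), x$normalization_count))
  print(utils::head(x$metrics, 12))
  invisible(x)
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$metrics, file.path(dir, "sample_metrics.csv"), row.names = FALSE)
  if (!is.null(res$summary)) {
    write.csv(res$summary$tests, file.path(dir, "significance_table.csv"),
              row.names = FALSE)
    write.csv(res$summary$summaries, file.path(dir, "cohort_summaries.csv"),
              row.names = FALSE)
    write.csv(res$summary$fits, file.path(dir, "quadratic_fits.csv"),
              row.names = FALSE)
  }
  cfg <- res$config
  cfg$output_dir <- NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "run_config.yaml"))
  invisible(dir)
}

#' Color-coded maximum-intensity projection for QC
#'
#' Writes a PNG of the z maximum-intensity projection of a caliber
#' classification, grouping classes into small (cyan), medium (yellow) and
#' large (red) calibers -- a flat stand-in for 3D surface renderings.
#'
#' @param classification a `caliber_classification`.
#' @param path output PNG path.
#' @param groups list of integer class-index vectors for the cyan, yellow
#'   and red groups (defaults to pairs of the six set1 classes: 1-5, 5-19,
#'   19-75 um^2).
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(classification, path,
                                 groups = list(cyan = 1:2, yellow = 3:4, red = 5:6)) {
  map <- classification$map
  d <- dim(map)
  img <- array(0, c(d[1], d[2], 3))
  colors <- list(cyan = c(0, 1, 1), yellow = c(1, 1, 0), red = c(1, 0, 0))
  wall <- Reduce(`|`, classification$wall_masks)
  for (gi in seq_along(groups)) {
    sel <- array(map %in% groups[[gi]], d) & wall
    proj <- apply(sel, c(1, 2), any)
    col <- colors[[names(groups)[gi]]]
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[proj] <- pmax(layer[proj], col[ch])
      img[, , ch] <- layer
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
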