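#' Binary voxel volume
#'
#' A `binary_volume` is a 3D logical array (dims `(y, x, z)`) with a single
#' isotropic voxel pitch; foreground voxels (`TRUE`) are vessel (or filled
#' vessel) voxels.
#'
#' @param voxels 3D logical array. A 2D matrix is promoted to one slice.
#' @param pitch isotropic voxel edge length, micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, pitch) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  if (!is.logical(voxels)) {
    u <- unique(as.vector(voxels))
    if (!all(u %in% c(0, 1, 255))) stopf("voxels must be logical or 0/1/255 coded")
    voxels <- array(voxels > 0, dim = dim(voxels))
  }
  if (anyNA(voxels)) stopf("voxels must not contain NA")
  if (!is.numeric(pitch) || pitch <= 0) stopf("pitch must be strictly positive")
  structure(list(voxels = voxels, pitch = as.numeric(pitch)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_volume: %d x %d x %d (y, x, z), pitch %.3g um, %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], x$pitch, sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' @export
dim.binary_volume <- function(x) dim(x$voxels)

#' Read a binary 8-bit TIFF (0/255 coded) as a binary volume
#'
#' @param path path to the TIFF file.
#' @param pitch isotropic voxel pitch, micrometres.
#' @return A [binary_volume].
#' @export
read_binary_stack <- function(path, pitch) {
  gs <- read_stack(path, lateral_pitch = pitch, axial_pitch = pitch)
  u <- unique(as.vector(gs$voxels))
  if (!all(u %in% c(0L, 255L)))
    stopf("not a binary stack (values other than 0/255): %s", path)
  binary_volume(gs$voxels > 0L, pitch)
}

# pooled 256-bin histogram of an 8-bit stack
stack_histogram <- function(stack) {
  tabulate(as.vector(stack$voxels) + 1L, nbins = 256L)
}

#' Renyi-entropy automatic threshold
#'
#' Computes a global binarization threshold from the pooled 256-bin
#' histogram of the stack by the Renyi-entropy criterion (Sahoo's
#' three-order combination: the maximum-entropy thresholds at Renyi orders
#' 1/2, 1 and 2 are blended according to their mutual agreement). This is the
#' criterion behind the common "RenyiEntropy" auto-threshold implementation
#' and is well suited to bright, sparse structures on a dark background,
#' where it is robust to the large background mode.
#'
#' Voxels strictly greater than the returned threshold are foreground.
#'
#' @param stack a [grey_stack] (or a raw 256-bin histogram via
#'   `renyi_threshold_histogram`).
#' @return Integer threshold in `[0, 254]`.
#' @export
renyi_threshold <- function(stack) {
  stopifnot(inherits(stack, "grey_stack"))
  renyi_threshold_histogram(stack_histogram(stack))
}

#' @rdname renyi_threshold
#' @param counts integer vector of 256 histogram counts (grey levels 0-255).
#' @export
renyi_threshold_histogram <- function(counts) {
  if (length(counts) != 256L) stopf("histogram must have 256 bins")
  if (sum(counts > 0) < 2L) stopf("constant stack: no threshold exists")
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  eps <- .Machine$double.eps
  first_bin <- which(P1 > eps)[1] - 1L                     # grey level, 0-based
  last_bin <- max(which(P2 >= eps)) - 1L
  if (first_bin >= last_bin) stopf("degenerate histogram: no threshold exists")
  it_range <- first_bin:last_bin
  best <- function(score) it_range[which.max(score)]

  # precompute partial sums for the three Renyi orders
  plogp <- ifelse(p > 0, p * log(p), 0)
  H1 <- cumsum(plogp)           # sum p log p up to t
  Hs <- cumsum(sqrt(p))         # sum sqrt(p) up to t
  H2 <- cumsum(p^2)             # sum p^2 up to t
  tot1 <- H1[256]; tots <- Hs[256]; tot2 <- H2[256]

  score1 <- score2 <- score3 <- rep(-Inf, length(it_range))
  for (m in seq_along(it_range)) {
    it <- it_range[m]
    i1 <- it + 1L                      # R index of grey level `it`
    p1 <- P1[i1]; p2 <- P2[i1]
    if (p1 <= 0 || p2 <= 0) next
    # order 1 (Shannon maximum entropy)
    ent_back <- -(H1[i1] / p1) + log(p1)
    ent_obj <- -((tot1 - H1[i1]) / p2) + log(p2)
    score2[m] <- ent_back + ent_obj
    # order 1/2
    eb <- Hs[i1] / sqrt(p1)
    eo <- (tots - Hs[i1]) / sqrt(p2)
    if (eb > 0 && eo > 0) score1[m] <- log(eb * eo) / 0.5
    # order 2
    eb2 <- H2[i1] / p1^2
    eo2 <- (tot2 - H2[i1]) / p2^2
    if (eb2 > 0 && eo2 > 0) score3[m] <- -log(eb2 * eo2)
  }
  t1 <- best(score1); t2 <- best(score2); t3 <- best(score3)
  ts <- sort(c(t1, t2, t3))
  t_star1 <- ts[1]; t_star2 <- ts[2]; t_star3 <- ts[3]

  # blend weights depend on how closely the three orders agree
  if (abs(t_star1 - t_star2) <= 5) {
    if (abs(t_star2 - t_star3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t_star2 - t_star3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  omega <- P1[t_star3 + 1L] - P1[t_star1 + 1L]
  thr <- t_star1 * (P1[t_star1 + 1L] + 0.25 * omega * b[1]) +
    0.25 * t_star2 * omega * b[2] +
    t_star3 * (P2[t_star3 + 1L] + 0.25 * omega * b[3])
  as.integer(thr)
}

#' Binarize a greyscale stack at a threshold
#'
#' Voxels with intensity strictly greater than `threshold` become foreground
#' (bright vessels on dark background). The stack must be isotropic, since
#' all downstream morphology assumes cubic voxels.
#'
#' @param stack an isotropic [grey_stack].
#' @param threshold grey level in `[0, 254]`; defaults to
#'   [renyi_threshold()].
#' @return A [binary_volume].
#' @export
binarize_stack <- function(stack, threshold = renyi_threshold(stack)) {
  stopifnot(inherits(stack, "grey_stack"))
  if (stack$lateral_pitch != stack$axial_pitch)
    stopf("stack is anisotropic; run make_isotropic() first")
  binary_volume(stack$voxels > threshold, stack$lateral_pitch)
}
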