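#' Multi-planar breast-mask fusion
#'
#' Stage 1 combines one breast-probability (or binary) volume per anatomical
#' plane model — axial, sagittal, coronal — into a single mask by a weighted
#' voxelwise mean, binarized at a threshold. Weights default to `(1, 1, 1)`
#' (unweighted majority) and the threshold to 0.5; both are configuration,
#' not fixed by the method.
#'
#' @param masks list of three 3D arrays (probabilities in `[0,1]` or binary),
#'   co-registered to the study grid.
#' @param weights three non-negative reals, not all zero.
#' @return a `plane_mask_set`.
#' @export
plane_mask_set <- function(masks, weights = c(1, 1, 1)) {
  stopifnot(is.list(masks), length(masks) == 3L, length(weights) == 3L)
  shp <- dim(masks[[1L]])
  for (m in masks)
    if (!identical(dim(m), shp))
      stop("all three plane masks must share one spatial shape", call. = FALSE)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero", call. = FALSE)
  structure(list(masks = masks, weights = as.double(weights)),
            class = "plane_mask_set")
}

#' @param plane_set a [plane_mask_set()].
#' @param threshold binarization fraction in `(0, 1)`; the comparison is `>=`.
#' @return binary 3D array.
#' @rdname plane_mask_set
#' @export
fuse_plane_masks <- function(plane_set, threshold = 0.5) {
  stopifnot(inherits(plane_set, "plane_mask_set"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  w <- plane_set$weights / sum(plane_set$weights)
  fused <- w[1] * plane_set$masks[[1L]] + w[2] * plane_set$masks[[2L]] +
    w[3] * plane_set$masks[[3L]]
  array(as.double(fused >= threshold), dim = dim(fused))
}

# Otsu threshold on a numeric vector; errors on degenerate (constant) input.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("Otsu threshold undefined: constant intensity volume", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.double(tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Geometric fallback breast mask
#'
#' Untrained stand-in for the learned per-plane models: Otsu thresholding of
#' the pre-contrast volume, 6-connected component analysis keeping anterior
#' tissue components (centroid in the anterior 60% of the y axis, where low y
#' is anterior), and hole filling. On phantoms this covers every lesion voxel.
#'
#' @param study a [dce_study()].
#' @param min_component_frac discard components smaller than this fraction of
#'   the foreground (speckle guard).
#' @return binary 3D array.
#' @export
geometric_fallback_mask <- function(study, min_component_frac = 0.01) {
  stopifnot(inherits(study, "dce_study"))
  pre <- pre_contrast_indices(study)
  vol <- get_series(study, pre[length(pre)])
  thr <- otsu_threshold(as.vector(vol))
  fg <- array(as.integer(vol > thr), dim = dim(vol))
  if (!any(fg == 1L)) stop("empty foreground after thresholding", call. = FALSE)
  lab <- label_components6(fg)
  n_fg <- sum(fg)
  Y <- dim(vol)[2]
  keep <- integer(0)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) < min_component_frac * n_fg) next
    cy <- mean(arrayInd(idx, dim(vol))[, 2])
    if (cy < 0.6 * Y) keep <- c(keep, l)
  }
  if (!length(keep))
    stop("no anterior tissue component found", call. = FALSE)
  mask <- array(as.integer(lab %in% keep), dim = dim(vol))
  array(as.double(fill_holes3d(mask)), dim = dim(vol))
}

#' Zero a study outside a breast mask
#'
#' Every series is zeroed outside the mask; intensities inside are untouched
#' and the `breast_mask` field is set. Idempotent.
#'
#' @param study a [dce_study()].
#' @param mask binary 3D array matching the study's spatial shape.
#' @return the masked [dce_study()].
#' @export
apply_breast_mask <- function(study, mask) {
  stopifnot(inherits(study, "dce_study"))
  spatial <- dim(study$volumes)[1:3]
  if (!is.array(mask) || !all(dim(mask) == spatial))
    stop("mask shape (", paste(dim(mask), collapse = ","),
         ") does not match study spatial shape (",
         paste(spatial, collapse = ","), ")", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary {0,1}", call. = FALSE)
  keep <- as.vector(mask) == 1
  n_series <- dim(study$volumes)[4L]
  for (s in seq_len(n_series)) {
    v <- study$volumes[, , , s]
    v[!keep] <- 0
    study$volumes[, , , s] <- v
  }
  study$breast_mask <- array(as.double(mask), dim = spatial)
  study
}

#' Per-plane probability masks from a trained 2D model
#'
#' Runs a 1-channel segmentation network over slices along each of the three
#' anatomical plane axes, producing co-registered probability volumes for
#' [fuse_plane_masks()]. Slices are zero-padded up to the model's spatial
#' granularity and cropped back. This is the learned route of stage 1; the
#' untrained default is [geometric_fallback_mask()].
#'
#' @param study a [dce_study()].
#' @param models list of up to three trained 1-channel models (see
#'   [build_model()]), named `z`, `y`, `x`; a model can be shared.
#' @param series which series to feed (default: latest pre-contrast).
#' @return a [plane_mask_set()] of probability volumes.
#' @export
plane_masks_from_models <- function(study, models, series = NULL) {
  stopifnot(inherits(study, "dce_study"))
  if (is.null(series)) {
    pre <- pre_contrast_indices(study)
    series <- pre[length(pre)]
  }
  vol <- get_series(study, series)
  axes <- c("z", "y", "x")
  masks <- vector("list", 3L)
  for (a in 1:3) {
    model <- models[[axes[a]]]
    if (is.null(model)) stop("missing plane model for axis ", axes[a], call. = FALSE)
    gran <- 2L^(model$spec$levels - 1L)
    n_slices <- dim(vol)[a]
    prob <- array(0, dim(vol))
    for (i in seq_len(n_slices)) {
      sl <- switch(a, vol[i, , ], vol[, i, ], vol[, , i])
      padded <- pad_to_multiple(sl, gran)
      x <- array(padded, dim = c(dim(padded), 1L, 1L))
      p <- unet_predict(model, x)[seq_len(nrow(sl)), seq_len(ncol(sl)), 1L, 1L]
      switch(a, prob[i, , ] <- p, prob[, i, ] <- p, prob[, , i] <- p)
    }
    masks[[a]] <- prob
  }
  plane_mask_set(masks)
}

# Zero-pad a 2D matrix so both dims are multiples of `m`.
pad_to_multiple <- function(mat, m) {
  d <- dim(mat)
  d2 <- as.integer(ceiling(d / m) * m)
  if (all(d2 == d)) return(mat)
  out <- matrix(0, d2[1], d2[2])
  out[seq_len(d[1]), seq_len(d[2])] <- mat
  out
}
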