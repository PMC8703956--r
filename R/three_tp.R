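#' Select the three canonical time points
#'
#' The three-time-point (3TP) encoding characterizes contrast kinetics using
#' only the pre-contrast acquisition (t0) and the acquisitions nearest 2 min
#' and 6 min post-injection (t1, t2). `i0` is the latest pre-contrast series;
#' `i1` is the post-contrast series minimizing `|time - targets[2]|` (ties
#' resolve to the earlier series); `i2` minimizes `|time - targets[3]|` over
#' the remaining post-contrast series (same tie rule), so `i1 != i2` always.
#'
#' @param times_post_injection seconds per series, strictly increasing.
#' @param targets seconds triple, default `c(0, 120, 360)`.
#' @return a `time_point_selection` with 1-based `indices` `(i0, i1, i2)`,
#'   `realized_times`, and `target_times`.
#' @export
select_time_points <- function(times_post_injection, targets = c(0, 120, 360)) {
  times <- as.double(times_post_injection)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  pre <- which(times <= 0)
  post <- which(times > 0)
  if (length(pre) < 1L || length(post) < 2L)
    stop("at least three acquisitions are required: one pre-contrast and ",
         "two post-contrast series", call. = FALSE)
  i0 <- pre[length(pre)]
  i1 <- post[which.min(abs(times[post] - targets[2]))]
  rest <- setdiff(post, i1)
  i2 <- rest[which.min(abs(times[rest] - targets[3]))]
  structure(list(target_times = as.double(targets),
                 indices = c(i0 = i0, i1 = i1, i2 = i2),
                 realized_times = times[c(i0, i1, i2)]),
            class = "time_point_selection")
}

#' @export
print.time_point_selection <- function(x, ...) {
  cat(sprintf("<3TP selection> series (%d, %d, %d) at (%s) s for targets (%s) s\n",
              x$indices[1], x$indices[2], x$indices[3],
              paste(x$realized_times, collapse = ", "),
              paste(x$target_times, collapse = ", ")))
  invisible(x)
}

#' Choose the slicing plane
#'
#' DCE-MRI voxels are anisotropic; slices are extracted perpendicular to the
#' axis with the LARGEST spacing so the in-plane resolution is maximal. Ties
#' break by fixed priority z > y > x.
#'
#' @param spacing_mm positive `(z, y, x)` spacing.
#' @return `"z"`, `"y"` or `"x"`.
#' @export
select_slicing_plane <- function(spacing_mm) {
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  c("z", "y", "x")[which.max(spacing_mm)]
}

#' Bilateral split and merge
#'
#' The segmentation network expects square, single-breast inputs, so volumes
#' are cut at the mid plane of the patient left-right axis `x`:
#' left = `x in [1, floor(X/2)]`, right = the rest. `merge_bilateral()` is
#' the exact inverse concatenation.
#'
#' @param volume_or_mask 3D array `(z, y, x)` with x extent >= 2.
#' @return `split_bilateral()`: list with `left` and `right` 3D arrays.
#' @export
split_bilateral <- function(volume_or_mask) {
  d <- dim(volume_or_mask)
  stopifnot(length(d) == 3L, d[3] >= 2L)
  half <- d[3] %/% 2L
  list(left = volume_or_mask[, , seq_len(half), drop = FALSE],
       right = volume_or_mask[, , (half + 1L):d[3], drop = FALSE])
}

#' @param left_pred,right_pred 3D arrays agreeing on the non-x axes.
#' @rdname split_bilateral
#' @export
merge_bilateral <- function(left_pred, right_pred) {
  dl <- dim(left_pred); dr <- dim(right_pred)
  stopifnot(length(dl) == 3L, length(dr) == 3L)
  if (!all(dl[1:2] == dr[1:2]))
    stop("left/right halves disagree on the (z, y) axes", call. = FALSE)
  out <- array(0, dim = c(dl[1], dl[2], dl[3] + dr[3]))
  out[, , seq_len(dl[3])] <- left_pred
  out[, , (dl[3] + 1L):(dl[3] + dr[3])] <- right_pred
  out
}

# One 2D slice of a 3D array along a named axis.
.slice3 <- function(vol, axis, i) {
  switch(axis,
         z = vol[i, , , drop = TRUE],
         y = vol[, i, , drop = TRUE],
         x = vol[, , i, drop = TRUE])
}

#' Extract the labeled 3TP slice dataset of a study
#'
#' For every slice position along the slicing plane and each breast side, a
#' three-channel image is emitted whose channels are the homologous slices of
#' the t0/t1/t2 series — no resampling, channels are bit-equal to the source
#' slices. A slice is labeled `lesion` iff its ground-truth half-slice has at
#' least one lesion voxel; slices without breast voxels are kept (labelled
#' healthy), since inference must scan the whole breast.
#'
#' @param study a breast-masked [dce_study()] (lesion_mask needed for labels).
#' @param selection a [select_time_points()] result; default computed from
#'   the study's times.
#' @param plane slicing axis; default from [select_slicing_plane()].
#' @param labeled emit labels/gt from `lesion_mask` (default: if present).
#' @return list of `three_tp_slice` objects: `pixels` (H x W x 3, channels
#'   t0, t1, t2), `patient_id`, `side`, `slice_index`, `label`, `gt_mask`.
#' @export
extract_3tp_dataset <- function(study, selection = NULL, plane = NULL,
                                labeled = !is.null(study$lesion_mask)) {
  stopifnot(inherits(study, "dce_study"))
  if (is.null(selection))
    selection <- select_time_points(study$times_post_injection)
  if (is.null(plane)) plane <- select_slicing_plane(study$spacing_mm)
  if (labeled && is.null(study$lesion_mask))
    stop("labels requested but the study has no lesion_mask", call. = FALSE)
  idx <- selection$indices
  halves <- lapply(idx, function(s) split_bilateral(get_series(study, s)))
  gt_halves <- if (labeled) split_bilateral(study$lesion_mask)
  sides <- c("left", "right")
  n_slices <- dim(halves[[1L]]$left)[match(plane, c("z", "y", "x"))]
  out <- vector("list", 2L * n_slices)
  k <- 0L
  for (side in sides) {
    for (i in seq_len(n_slices)) {
      ch <- lapply(halves, function(h) .slice3(h[[side]], plane, i))
      px <- array(0, dim = c(dim(ch[[1L]]), 3L))
      for (c in 1:3) px[, , c] <- ch[[c]]
      gt <- if (labeled) .slice3(gt_halves[[side]], plane, i)
      k <- k + 1L
      out[[k]] <- structure(list(
        pixels = px, patient_id = study$study_id, side = side,
        slice_index = i,
        label = if (labeled) { if (any(gt > 0)) "lesion" else "healthy" } else NA_character_,
        gt_mask = gt), class = "three_tp_slice")
    }
  }
  out
}

#' Write a 3TP dataset to disk
#'
#' One NIfTI per slice (H x W x 3 channel stack) plus an index CSV
#' (`patient_id, side, slice_index, label, file`).
#'
#' @param slices list of `three_tp_slice` from [extract_3tp_dataset()].
#' @param dir output directory.
#' @return the index CSV path, invisibly.
#' @export
write_3tp_dataset <- function(slices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    f <- sprintf("slice_%05d.nii.gz", i)
    write_nifti(s$pixels, file.path(dir, f))
    data.frame(patient_id = s$patient_id, side = s$side,
               slice_index = s$slice_index, label = s$label, file = f,
               stringsAsFactors = FALSE)
  })
  path <- file.path(dir, "index.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
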