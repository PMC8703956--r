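#' 4D DCE-MRI study container
#'
#' A `dce_study` bundles one patient's dynamic contrast-enhanced acquisition:
#' the stack of 3D series volumes, their acquisition times relative to
#' contrast-agent injection, voxel spacing, and optional breast / lesion masks.
#'
#' Spatial axes follow the package convention `(z, y, x)`: `z` is the slice
#' axis, `y` runs anterior (low index) to posterior, and `x` is the patient
#' left-right axis used by the bilateral split. Volumes are stored as a 4D
#' array with the series as the *last* dimension, `volumes[z, y, x, series]`,
#' so that each 3D series is memory-contiguous; a series' acquisition time is
#' its acquisition start in seconds relative to injection (pre-contrast series
#' have time <= 0).
#'
#' @param volumes 4D numeric array `(z, y, x, series)` of non-negative
#'   intensities, or a list of identically shaped 3D arrays.
#' @param times_post_injection numeric vector, seconds per series, strictly
#'   increasing, with at least one value <= 0 (the pre-contrast series).
#' @param spacing_mm positive numeric length-3 `(z, y, x)` voxel size in mm.
#' @param study_id opaque identifier string.
#' @param breast_mask,lesion_mask optional binary 3D arrays matching the
#'   spatial shape.
#' @return an object of class `dce_study`.
#' @export
dce_study <- function(volumes, times_post_injection, spacing_mm,
                      study_id = "study", breast_mask = NULL, lesion_mask = NULL) {
  if (is.list(volumes)) {
    shapes <- lapply(volumes, dim)
    for (i in seq_along(shapes)) {
      if (is.null(shapes[[i]]) || length(shapes[[i]]) != 3L)
        stop("series ", i, " is not a 3D volume", call. = FALSE)
      if (!identical(shapes[[i]], shapes[[1L]]))
        stop("series ", i, " has shape (", paste(shapes[[i]], collapse = ","),
             ") but series 1 has (", paste(shapes[[1L]], collapse = ","), ")",
             call. = FALSE)
    }
    volumes <- array(unlist(volumes, use.names = FALSE),
                     dim = c(shapes[[1L]], length(volumes)))
  }
  if (!is.array(volumes) || length(dim(volumes)) != 4L)
    stop("`volumes` must be a (z, y, x, series) 4D array", call. = FALSE)
  n_series <- dim(volumes)[4L]
  if (length(times_post_injection) != n_series)
    stop("length(times_post_injection) must equal the number of series", call. = FALSE)
  if (any(diff(times_post_injection) <= 0))
    stop("times_post_injection must be strictly increasing", call. = FALSE)
  if (!any(times_post_injection <= 0))
    stop("at least one pre-contrast series (time <= 0) is required", call. = FALSE)
  spatial <- dim(volumes)[1:3]
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive values (z, y, x)", call. = FALSE)
  check_mask <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), as.integer(spatial)) && !identical(dim(m), spatial))
      stop(what, " shape does not match the study's spatial shape", call. = FALSE)
    if (!all(m %in% c(0, 1))) stop(what, " must be binary {0,1}", call. = FALSE)
    array(as.double(m), dim = spatial)
  }
  structure(list(
    study_id = as.character(study_id),
    volumes = volumes,
    times_post_injection = as.double(times_post_injection),
    spacing_mm = as.double(spacing_mm),
    breast_mask = check_mask(breast_mask, "breast_mask"),
    lesion_mask = check_mask(lesion_mask, "lesion_mask")
  ), class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dce_study '%s'>: %d series of %dx%dx%d (z,y,x), spacing %s mm\n",
              x$study_id, d[4], d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  cat(sprintf("  times post-injection [s]: %s\n",
              paste(x$times_post_injection, collapse = ", ")))
  cat(sprintf("  breast_mask: %s, lesion_mask: %s\n",
              if (is.null(x$breast_mask)) "absent" else "present",
              if (is.null(x$lesion_mask)) "absent" else "present"))
  invisible(x)
}

#' Extract one series volume
#'
#' @param study a [dce_study()].
#' @param i series index (1-based).
#' @return 3D array `(z, y, x)`.
#' @export
get_series <- function(study, i) {
  stopifnot(inherits(study, "dce_study"))
  study$volumes[, , , i, drop = TRUE]
}

#' Indices of pre-/post-contrast series
#'
#' Pre-contrast means acquisition time <= 0 s relative to injection.
#' @param study a [dce_study()].
#' @return integer vector of series indices.
#' @export
pre_contrast_indices <- function(study) which(study$times_post_injection <= 0)

#' @rdname pre_contrast_indices
#' @export
post_contrast_indices <- function(study) which(study$times_post_injection > 0)

#' Load a DCE-MRI study from per-series NIfTI files
#'
#' Reads one 3D NIfTI volume per series, in acquisition order, and assembles
#' a validated [dce_study()]. Intensities are kept exactly as stored (no
#' rescaling); normalization happens downstream, fold-wise.
#'
#' @param volume_paths character vector of NIfTI paths, one per series, in
#'   temporal order.
#' @param times seconds post-injection per series, strictly increasing.
#' @param spacing mm voxel size `(z, y, x)`; when `NULL`, taken from the first
#'   volume's header.
#' @param study_id identifier for the study.
#' @param breast_mask_path,lesion_mask_path optional NIfTI mask paths.
#' @return a [dce_study()].
#' @export
load_study <- function(volume_paths, times, spacing = NULL, study_id = "study",
                       breast_mask_path = NULL, lesion_mask_path = NULL) {
  if (length(volume_paths) != length(times))
    stop("one time per volume path is required", call. = FALSE)
  vols <- vector("list", length(volume_paths))
  for (i in seq_along(volume_paths)) {
    v <- read_nifti(volume_paths[i])
    if (i == 1L && is.null(spacing)) spacing <- attr(v, "spacing_mm")
    attr(v, "spacing_mm") <- NULL
    if (i > 1L && !identical(dim(v), dim(vols[[1L]])))
      stop("series ", i, " ('", basename(volume_paths[i]), "') has shape (",
           paste(dim(v), collapse = ","), ") but series 1 has (",
           paste(dim(vols[[1L]]), collapse = ","), ")", call. = FALSE)
    vols[[i]] <- v
  }
  bm <- if (!is.null(breast_mask_path)) read_nifti(breast_mask_path)
  lm <- if (!is.null(lesion_mask_path)) read_nifti(lesion_mask_path)
  if (!is.null(bm)) attr(bm, "spacing_mm") <- NULL
  if (!is.null(lm)) attr(lm, "spacing_mm") <- NULL
  dce_study(vols, times, spacing, study_id = study_id,
            breast_mask = bm, lesion_mask = lm)
}

#' Save a binary mask as NIfTI
#'
#' Masks are written as uint8 with values in `{0, 1}` and round-trip
#' bit-identically through [read_nifti()].
#'
#' @param mask binary 3D array.
#' @param spacing mm voxel size `(z, y, x)`.
#' @param path destination (`.nii` or `.nii.gz`).
#' @export
save_mask <- function(mask, spacing, path) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("`mask` must be binary {0,1}", call. = FALSE)
  write_nifti(array(as.double(mask), dim = dim(mask)), path,
              spacing_mm = spacing, datatype = "uint8")
}

#' Write a study to a directory (NIfTI series + JSON sidecar)
#'
#' Emits `series_###.nii.gz` per series, optional `breast_mask.nii.gz` /
#' `lesion_mask.nii.gz`, and a `study.json` sidecar recording the file order,
#' acquisition times and spacing.
#'
#' @param study a [dce_study()].
#' @param dir output directory (created if missing).
#' @return the sidecar path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dce_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(study$volumes)[4L]
  files <- sprintf("series_%03d.nii.gz", seq_len(n))
  for (i in seq_len(n))
    write_nifti(get_series(study, i), file.path(dir, files[i]),
                spacing_mm = study$spacing_mm, datatype = "float64")
  side <- list(study_id = study$study_id, series_files = files,
               times_post_injection = study$times_post_injection,
               spacing_mm = study$spacing_mm)
  if (!is.null(study$breast_mask)) {
    save_mask(study$breast_mask, study$spacing_mm, file.path(dir, "breast_mask.nii.gz"))
    side$breast_mask_file <- "breast_mask.nii.gz"
  }
  if (!is.null(study$lesion_mask)) {
    save_mask(study$lesion_mask, study$spacing_mm, file.path(dir, "lesion_mask.nii.gz"))
    side$lesion_mask_file <- "lesion_mask.nii.gz"
  }
  path <- file.path(dir, "study.json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a study written by [write_study()]
#'
#' @param dir directory containing `study.json`.
#' @return a [dce_study()].
#' @export
load_study_dir <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  load_study(file.path(dir, side$series_files), side$times_post_injection,
             spacing = side$spacing_mm, study_id = side$study_id,
             breast_mask_path = if (!is.null(side$breast_mask_file))
               file.path(dir, side$breast_mask_file),
             lesion_mask_path = if (!is.null(side$lesion_mask_file))
               file.path(dir, side$lesion_mask_file))
}

#' Subtractive series
#'
#' The first post-contrast volume minus the (latest) pre-contrast volume,
#' voxelwise — the subtraction image radiologists use to localize enhancement.
#'
#' @param study a [dce_study()].
#' @return 3D array `(z, y, x)`.
#' @export
subtractive_series <- function(study) {
  stopifnot(inherits(study, "dce_study"))
  pre <- pre_contrast_indices(study)
  post <- post_contrast_indices(study)
  if (!length(post)) stop("no post-contrast series in the study", call. = FALSE)
  get_series(study, post[1L]) - get_series(study, pre[length(pre)])
}

#' Per-voxel time intensity curve
#'
#' @param study a [dce_study()].
#' @param z,y,x voxel coordinates (1-based, `(z, y, x)` convention).
#' @return list with `values` (one intensity per series) and `times` (seconds).
#' @export
voxel_tic <- function(study, z, y, x) {
  stopifnot(inherits(study, "dce_study"))
  structure(list(values = as.double(study$volumes[z, y, x, ]),
                 times = study$times_post_injection),
            class = "voxel_tic")
}
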