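#' Registration configuration
#'
#' Controls the native intensity-based registration used by stage 2. The
#' default is a translation model driven by normalized cross-correlation
#' (NCC) with a coarse-to-fine pyramid: an exhaustive integer-shift search at
#' the coarsest level followed by Nelder-Mead refinement at every level.
#' `rigid` adds three rotation angles; `bspline` refines a coarse
#' control-point displacement grid from the translation solution. All routes
#' are deterministic given the configuration.
#'
#' @param model `"translation"`, `"rigid"`, or `"bspline"`.
#' @param metric `"NCC"` (default) or `"MI"` (32-bin joint-histogram mutual
#'   information).
#' @param pyramid_levels number of resolution levels (>= 1).
#' @param max_iterations optimizer iteration cap per level (>= 1).
#' @param grid_spacing_mm B-spline control-point spacing in mm.
#' @param search_radius_vox half-width of the integer search at full
#'   resolution, voxels.
#' @param seed integer recorded for provenance (the native optimizer draws no
#'   random numbers).
#' @return a `registration_config`.
#' @export
registration_config <- function(model = c("translation", "rigid", "bspline"),
                                metric = c("NCC", "MI"),
                                pyramid_levels = 2L, max_iterations = 100L,
                                grid_spacing_mm = 60, search_radius_vox = 5L,
                                seed = 0L) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  stopifnot(pyramid_levels >= 1, max_iterations >= 1, grid_spacing_mm > 0,
            search_radius_vox >= 1)
  structure(list(model = model, metric = metric,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 grid_spacing_mm = as.double(grid_spacing_mm),
                 search_radius_vox = as.integer(search_radius_vox),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Spatial transforms
#'
#' Transforms act by *pull* resampling on the `(z, y, x)` voxel grid:
#' `out[p] = in[p + shift]` for translations (shift in voxels), with rigid
#' transforms additionally rotating about the volume center, and B-spline
#' transforms adding a trilinearly interpolated control-grid displacement.
#' Out-of-field samples are 0. Transforms compose by sequential
#' [apply_transform()] calls; two translations combine exactly by adding
#' their shift vectors, and translation/rigid transforms are invertible via
#' [invert_transform()].
#'
#' @param shift_vox numeric length-3 `(z, y, x)` translation in voxels.
#' @param angles_rad numeric length-3 rotation angles (radians).
#' @param control 4D array `(nz, ny, nx, 3)` of control-point displacements
#'   (voxels), `NULL` for non-deformable models.
#' @param model transform tag.
#' @param spacing_mm optional voxel spacing to express the translation in mm.
#' @return a `spatial_transform`.
#' @export
spatial_transform <- function(shift_vox = c(0, 0, 0), angles_rad = c(0, 0, 0),
                              control = NULL,
                              model = c("translation", "rigid", "bspline"),
                              spacing_mm = NULL) {
  model <- match.arg(model)
  structure(list(model = model, shift_vox = as.double(shift_vox),
                 angles_rad = as.double(angles_rad), control = control,
                 translation_mm = if (!is.null(spacing_mm))
                   as.double(shift_vox) * as.double(spacing_mm)),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform %s> shift (z,y,x) = (%s) vox",
              x$model, paste(signif(x$shift_vox, 4), collapse = ", ")))
  if (x$model != "translation")
    cat(sprintf(", angles = (%s) rad", paste(signif(x$angles_rad, 4), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Invert a translation/rigid transform
#'
#' @param transform a [spatial_transform()] (not `bspline`).
#' @return the inverse [spatial_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "spatial_transform"))
  if (transform$model == "translation")
    return(spatial_transform(-transform$shift_vox, model = "translation"))
  if (transform$model == "rigid") {
    R <- .rot_zyx(transform$angles_rad)
    return(structure(list(model = "rigid_inverse", R = t(R),
                          shift_vox = as.double(-t(R) %*% transform$shift_vox),
                          angles_rad = -transform$angles_rad),
                     class = "spatial_transform"))
  }
  stop("bspline transforms are not invertible in closed form", call. = FALSE)
}

.rot_zyx <- function(a) {
  ca <- cos(a[1]); sa <- sin(a[1]); cb <- cos(a[2]); sb <- sin(a[2])
  cg <- cos(a[3]); sg <- sin(a[3])
  matrix(c(cb * cg, -cb * sg, sb,
           sa * sb * cg + ca * sg, -sa * sb * sg + ca * cg, -sa * cb,
           -ca * sb * cg + sa * sg, ca * sb * sg + sa * cg, ca * cb),
         3, 3, byrow = TRUE)
}

#' Apply a spatial transform to a volume
#'
#' @param volume 3D array `(z, y, x)`.
#' @param transform a [spatial_transform()].
#' @return resampled 3D array (linear interpolation; out-of-field 0).
#' @export
apply_transform <- function(volume, transform) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            inherits(transform, "spatial_transform"))
  switch(transform$model,
    translation = resample_translate3d(volume, transform$shift_vox),
    rigid = ,
    rigid_inverse = resample_rigid3d(volume, transform$angles_rad, transform$shift_vox),
    bspline = {
      disp <- .dense_dispfield(transform$control, dim(volume))
      resample_dispfield3d(volume, disp)
    },
    stop("unknown transform model ", transform$model, call. = FALSE))
}

# Trilinear upsampling of a (nz, ny, nx, 3) control grid to a dense
# (Z, Y, X, 3) displacement field.
.dense_dispfield <- function(control, shape) {
  nc <- dim(control)[1:3]
  axis_weights <- function(n_out, n_in) {
    if (n_in == 1L) return(matrix(1, n_out, 1))
    pos <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2)
    f <- pos - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - f
    W[cbind(seq_len(n_out), lo + 2)] <- f
    W
  }
  Wz <- axis_weights(shape[1], nc[1])
  Wy <- axis_weights(shape[2], nc[2])
  Wx <- axis_weights(shape[3], nc[3])
  out <- array(0, dim = c(shape, 3))
  for (c in 1:3) {
    g <- control[, , , c, drop = TRUE]
    g <- array(g, dim = nc)
    a <- Wz %*% matrix(g, nc[1], nc[2] * nc[3])             # (Z, ncy*ncx)
    a <- array(a, dim = c(shape[1], nc[2], nc[3]))
    a <- aperm(a, c(2, 1, 3))
    a <- Wy %*% matrix(a, nc[2], shape[1] * nc[3])          # (Y, Z*ncx)
    a <- array(a, dim = c(shape[2], shape[1], nc[3]))
    a <- aperm(a, c(3, 2, 1))
    a <- Wx %*% matrix(a, nc[3], shape[1] * shape[2])       # (X, Z*Y)
    a <- array(a, dim = c(shape[3], shape[1], shape[2]))
    out[, , , c] <- aperm(a, c(2, 3, 1))
  }
  out
}

.metric_value <- function(fixed, moved, metric, mask = NULL) {
  if (metric == "NCC") return(ncc3d(fixed, moved, mask))
  # 32-bin joint-histogram mutual information
  sel <- if (!is.null(mask)) as.vector(mask) > 0 else TRUE
  a <- as.vector(fixed)[sel]; b <- as.vector(moved)[sel]
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(NA_real_)
  ia <- pmin(1L + as.integer(31.999 * (a - ra[1]) / diff(ra)), 32L)
  ib <- pmin(1L + as.integer(31.999 * (b - rb[1]) / diff(rb)), 32L)
  h <- tabulate(ia + 32L * (ib - 1L), nbins = 1024L)
  p <- h / sum(h)
  pa <- rowSums(matrix(p, 32)); pb <- colSums(matrix(p, 32))
  nz <- p > 0
  sum(p[nz] * log(p[nz])) - sum(pa[pa > 0] * log(pa[pa > 0])) -
    sum(pb[pb > 0] * log(pb[pb > 0]))
}

#' Register a moving volume onto a fixed reference
#'
#' Maximizes the configured similarity metric between the fixed volume and
#' the pull-resampled moving volume over the transform family. The returned
#' transform, applied via [apply_transform()] to `moving`, aligns it with
#' `fixed`.
#'
#' @param moving,fixed 3D arrays of identical shape.
#' @param config a [registration_config()].
#' @param mask optional binary 3D array restricting the metric support (e.g.
#'   the breast mask, to decouple registration from contrast enhancement).
#' @return a [spatial_transform()] with attribute `metric` (achieved value).
#' @export
register_volume <- function(moving, fixed, config = registration_config(),
                            mask = NULL) {
  stopifnot(identical(dim(moving), dim(fixed)))
  rng_m <- range(moving); rng_f <- range(fixed)
  if (rng_m[1] == rng_m[2] || rng_f[1] == rng_f[2])
    stop("registration error: degenerate similarity metric ",
         "(zero-variance image)", call. = FALSE)
  # NA (zero-variance support at this shift) scores -Inf; a search whose
  # best score is -Inf is degenerate and errors.
  score <- function(fx, mv, t, mk) {
    v <- .metric_value(fx, resample_translate3d(mv, t), config$metric, mk)
    if (is.na(v)) -Inf else v
  }
  # pyramid, full resolution first
  pyr <- list(list(f = fixed, m = moving, k = mask))
  for (l in seq_len(config$pyramid_levels - 1L)) {
    prev <- pyr[[l]]
    if (any(dim(prev$f) < 8L)) break
    pyr[[l + 1L]] <- list(f = downsample2(prev$f), m = downsample2(prev$m),
                          k = if (!is.null(prev$k))
                            array(as.double(downsample2(prev$k) > 0.25),
                                  dim = dim(downsample2(prev$f))))
  }
  n_lev <- length(pyr)
  # shrinking-step coordinate descent (deterministic, ripple-robust)
  refine <- function(lev, t0, steps, budget) {
    best_t <- t0
    best_v <- score(lev$f, lev$m, best_t, lev$k)
    for (st in steps) {
      for (it in seq_len(budget)) {
        moved <- FALSE
        for (ax in 1:3) for (dir in c(-1, 1)) {
          cand <- best_t
          cand[ax] <- cand[ax] + dir * st
          v <- score(lev$f, lev$m, cand, lev$k)
          if (v > best_v + 1e-12) { best_v <- v; best_t <- cand; moved <- TRUE }
        }
        if (!moved) break
      }
    }
    best_t
  }
  # exhaustive integer search at the coarsest level
  r <- max(2L, ceiling(config$search_radius_vox / 2^(n_lev - 1L)))
  grid <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  cz <- pyr[[n_lev]]
  grid_scores <- apply(grid, 1L, function(t) score(cz$f, cz$m, t, cz$k))
  if (!any(is.finite(grid_scores)))
    stop("registration error: degenerate similarity metric ",
         "(zero-variance image?)", call. = FALSE)
  t_cur <- as.double(grid[which.max(grid_scores), ])
  for (l in rev(seq_len(n_lev))) {
    lev <- pyr[[l]]
    if (l < n_lev) t_cur <- t_cur * 2
    steps <- if (l == 1L) c(1, 0.5, 0.25, 0.125, 0.0625) else c(1, 0.5)
    t_cur <- refine(lev, t_cur, steps, config$max_iterations)
  }
  tr <- spatial_transform(t_cur, model = "translation")
  if (config$model == "rigid") {
    f6 <- function(p) {
      moved <- resample_rigid3d(moving, p[1:3], p[4:6])
      v <- .metric_value(fixed, moved, config$metric, mask)
      if (is.na(v)) return(1e9)
      -v
    }
    opt <- stats::optim(c(0, 0, 0, t_cur), f6, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = 1e-6))
    tr <- spatial_transform(opt$par[4:6], angles_rad = opt$par[1:3],
                            model = "rigid")
  } else if (config$model == "bspline") {
    shp <- dim(fixed)
    spacing <- attr(fixed, "spacing_mm")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    nc <- pmax(2L, as.integer(ceiling(shp * spacing / config$grid_spacing_mm)) + 1L)
    ctrl0 <- array(rep(t_cur, each = prod(nc)), dim = c(nc, 3))
    fgrid <- function(p) {
      ctrl <- array(p, dim = c(nc, 3))
      moved <- resample_dispfield3d(moving, .dense_dispfield(ctrl, shp))
      v <- .metric_value(fixed, moved, config$metric, mask)
      if (is.na(v)) return(1e9)
      -v
    }
    opt <- stats::optim(as.vector(ctrl0), fgrid, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = 1e-6))
    tr <- spatial_transform(t_cur, control = array(opt$par, dim = c(nc, 3)),
                            model = "bspline")
  }
  attr(tr, "metric") <- .metric_value(fixed, apply_transform(moving, tr),
                                      config$metric, mask)
  tr
}

#' Motion-correct a DCE study
#'
#' Registers every post-contrast series to the (latest) pre-contrast
#' reference and replaces it by its registered resampling; pre-contrast
#' series are never altered. When a breast mask is present the metric is
#' evaluated inside it only, which decouples the alignment from
#' contrast-driven intensity change.
#'
#' @param study a [dce_study()].
#' @param config a [registration_config()].
#' @return the corrected [dce_study()]; per-series transforms are attached as
#'   attribute `mc_transforms` (a list, `NULL` entries for pre-contrast).
#' @export
motion_correct_study <- function(study, config = registration_config()) {
  stopifnot(inherits(study, "dce_study"))
  pre <- pre_contrast_indices(study)
  fixed <- get_series(study, pre[length(pre)])
  attr(fixed, "spacing_mm") <- study$spacing_mm
  mask <- study$breast_mask
  transforms <- vector("list", dim(study$volumes)[4L])
  for (s in post_contrast_indices(study)) {
    tr <- tryCatch(register_volume(get_series(study, s), fixed, config, mask),
                   error = function(e)
                     stop("series ", s, ": ", conditionMessage(e), call. = FALSE))
    study$volumes[, , , s] <- apply_transform(get_series(study, s), tr)
    transforms[[s]] <- tr
  }
  attr(study, "mc_transforms") <- transforms
  study
}

#' External registration adapter
#'
#' Contract for plugging an external motion-correction tool (e.g. Elastix)
#' into [motion_correct_study()]'s slot: the adapter writes fixed/moving
#' volumes as NIfTI to a temp directory, runs a user command template, and
#' reads back the registered volume. The template may reference `{fixed}`,
#' `{moving}`, `{out}`.
#'
#' @param study a [dce_study()].
#' @param command executable path.
#' @param args_template character vector of arguments with placeholders.
#' @return the corrected [dce_study()].
#' @export
motion_correct_external <- function(study, command, args_template) {
  stopifnot(inherits(study, "dce_study"))
  pre <- pre_contrast_indices(study)
  td <- tempfile("extreg"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fixed_path <- file.path(td, "fixed.nii.gz")
  write_nifti(get_series(study, pre[length(pre)]), fixed_path,
              spacing_mm = study$spacing_mm)
  for (s in post_contrast_indices(study)) {
    moving_path <- file.path(td, sprintf("moving_%03d.nii.gz", s))
    out_path <- file.path(td, sprintf("out_%03d.nii.gz", s))
    write_nifti(get_series(study, s), moving_path, spacing_mm = study$spacing_mm)
    args <- gsub("{fixed}", fixed_path,
                 gsub("{moving}", moving_path,
                      gsub("{out}", out_path, args_template, fixed = TRUE),
                      fixed = TRUE), fixed = TRUE)
    status <- system2(command, args)
    if (status != 0 || !file.exists(out_path))
      stop("external registrar failed on series ", s, call. = FALSE)
    v <- read_nifti(out_path)
    attr(v, "spacing_mm") <- NULL
    study$volumes[, , , s] <- v
  }
  study
}
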