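#' Seeded synthetic bilateral DCE-MRI cohorts
#'
#' The phantom emulates the acquisition geometry this pipeline targets:
#' bilateral coronal breast volumes (default 80 slices of 128 x 256 in-plane,
#' 2 x 1.45 x 1.45 mm voxels), one pre-contrast series and nine post-contrast
#' series spaced 56 s apart, spherical lesions with washout kinetics embedded
#' in persistently enhancing parenchyma, a posterior chest/muscle band, and
#' exact-zero air. The whole cohort is a deterministic function of `seed`.
#'
#' @param n_patients number of studies in the cohort.
#' @param shape integer `(z, y, x)` voxel counts.
#' @param spacing_mm voxel size `(z, y, x)` in mm.
#' @param series_times seconds post-injection, one per series, strictly
#'   increasing, first value <= 0.
#' @param lesions_per_patient integer range `c(min, max)` of lesions.
#' @param lesion_radius_mm numeric range `c(min, max)` of lesion radii in mm.
#' @param noise_sigma additive Gaussian noise s.d. in intensity units,
#'   applied to tissue voxels in every series (air stays exactly 0).
#' @param texture_amplitude relative amplitude of the smooth multiplicative
#'   intensity field emulating parenchymal heterogeneity; the field is fixed
#'   per patient (it is anatomy, shared by all series, and what
#'   intensity-based registration locks onto). 0 gives piecewise-constant
#'   tissue classes.
#' @param motion_amplitude_vox half-width of the uniform per-axis random
#'   translation injected into each post-contrast series, in voxels; 0
#'   disables motion.
#' @param seed integer fixing the full cohort.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 1L,
                           shape = c(80L, 128L, 256L),
                           spacing_mm = c(2.0, 1.45, 1.45),
                           series_times = c(-56, 56 * (1:9)),
                           lesions_per_patient = c(1L, 3L),
                           lesion_radius_mm = c(5, 10),
                           noise_sigma = 5,
                           texture_amplitude = 0.15,
                           motion_amplitude_vox = 0,
                           seed = 1234L) {
  stopifnot(n_patients >= 0, length(shape) == 3L, all(shape >= 1),
            all(spacing_mm > 0), length(series_times) >= 1,
            all(diff(series_times) > 0), series_times[1L] <= 0,
            length(lesions_per_patient) == 2L, lesions_per_patient[1L] >= 0,
            lesion_radius_mm[1L] > 0, noise_sigma >= 0,
            texture_amplitude >= 0, motion_amplitude_vox >= 0)
  structure(list(n_patients = as.integer(n_patients), shape = as.integer(shape),
                 spacing_mm = as.double(spacing_mm),
                 series_times = as.double(series_times),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 lesion_radius_mm = as.double(lesion_radius_mm),
                 noise_sigma = as.double(noise_sigma),
                 texture_amplitude = as.double(texture_amplitude),
                 motion_amplitude_vox = as.double(motion_amplitude_vox),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Time-intensity-curve parameters
#'
#' The enhancement model is bi-exponential:
#' `e(t) = plateau_gain * (1 - exp(-wash_in_rate * t)) * exp(-washout_rate * t)`
#' for `t > 0` and 0 otherwise, with the voxel intensity
#' `baseline * (1 + e(t))`. Lesion-class parameters use `washout_rate > 0`
#' (wash-in then washout); parenchyma uses `washout_rate = 0` (rise to a
#' plateau).
#'
#' @param baseline pre-contrast intensity, > 0.
#' @param wash_in_rate uptake rate constant, 1/s, >= 0.
#' @param washout_rate release rate constant, 1/s, >= 0.
#' @param plateau_gain dimensionless maximal relative enhancement.
#' @return a `tic_params` list; `peak_time` (s) is derived from the rates
#'   (`Inf` for pure-plateau curves).
#' @export
tic_params <- function(baseline, wash_in_rate, washout_rate = 0, plateau_gain = 1) {
  stopifnot(baseline > 0, wash_in_rate >= 0, washout_rate >= 0)
  peak <- if (washout_rate > 0 && wash_in_rate > 0)
    log(1 + wash_in_rate / washout_rate) / wash_in_rate else Inf
  structure(list(baseline = baseline, wash_in_rate = wash_in_rate,
                 washout_rate = washout_rate, plateau_gain = plateau_gain,
                 peak_time = peak),
            class = "tic_params")
}

#' Evaluate a TIC at given times
#'
#' @param params a [tic_params()].
#' @param t seconds post-injection (vectorized).
#' @return intensities; exactly `baseline` for `t <= 0`.
#' @export
tic_value <- function(params, t) {
  e <- ifelse(t <= 0, 0,
              params$plateau_gain * (1 - exp(-params$wash_in_rate * pmax(t, 0))) *
                exp(-params$washout_rate * pmax(t, 0)))
  params$baseline * (1 + e)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derived per-patient seeds; recomputable so generate_study() is standalone.
.patient_seeds <- function(config) {
  with_seed(config$seed,
            sample.int(.Machine$integer.max - 1L, max(config$n_patients, 1L)))
}

# Smooth random field in [1 - amp, 1 + amp]: coarse uniform grid noise
# upsampled trilinearly to the full volume shape.
.smooth_field <- function(shape, amp, ctrl_every = 8L) {
  nc <- pmax(2L, as.integer(ceiling(shape / ctrl_every)) + 1L)
  ctrl <- array(runif(prod(nc), -1, 1), dim = nc)
  axis_weights <- function(n_out, n_in) {
    pos <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2)
    f <- pos - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - f
    W[cbind(seq_len(n_out), lo + 2)] <- f
    W
  }
  a <- axis_weights(shape[1], nc[1]) %*% matrix(ctrl, nc[1], nc[2] * nc[3])
  a <- aperm(array(a, c(shape[1], nc[2], nc[3])), c(2, 1, 3))
  a <- axis_weights(shape[2], nc[2]) %*% matrix(a, nc[2], shape[1] * nc[3])
  a <- aperm(array(a, c(shape[2], shape[1], nc[3])), c(3, 2, 1))
  a <- axis_weights(shape[3], nc[3]) %*% matrix(a, nc[3], shape[1] * shape[2])
  1 + amp * aperm(array(a, c(shape[3], shape[1], shape[2])), c(2, 3, 1))
}

# Ellipsoid mask in index space: center/semi in (z, y, x) voxels.
.ellipsoid <- function(shape, center, semi) {
  z <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  x <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
}

#' Generate one phantom study
#'
#' @param config a [phantom_config()].
#' @param patient_index 1-based index, `<= n_patients`.
#' @return a [dce_study()] with `breast_mask` and `lesion_mask` set and a
#'   `provenance` attribute recording the patient seed, the injected
#'   per-series translations (voxels), and lesion centers/radii. Masks are
#'   defined in the motion-free reference frame.
#' @export
generate_study <- function(config, patient_index = 1L) {
  stopifnot(inherits(config, "phantom_config"),
            patient_index >= 1, patient_index <= max(config$n_patients, 1L))
  pseed <- .patient_seeds(config)[patient_index]
  with_seed(pseed, .generate_study_impl(config, patient_index, pseed))
}

.generate_study_impl <- function(config, patient_index, pseed) {
  shp <- config$shape
  Z <- shp[1]; Y <- shp[2]; X <- shp[3]
  jit <- function(x, f = 0.1) x * runif(length(x), 1 - f, 1 + f)

  # two breast compartments, anterior half, split about x = X/2
  semi_l <- jit(c(0.40 * Z, 0.28 * Y, 0.19 * X))
  semi_r <- jit(c(0.40 * Z, 0.28 * Y, 0.19 * X))
  cen_l <- c(Z / 2 + runif(1, -0.03, 0.03) * Z, 0.38 * Y + runif(1, -0.02, 0.02) * Y,
             0.25 * X + runif(1, -0.01, 0.01) * X)
  cen_r <- c(Z / 2 + runif(1, -0.03, 0.03) * Z, 0.38 * Y + runif(1, -0.02, 0.02) * Y,
             0.75 * X + runif(1, -0.01, 0.01) * X)
  breast <- .ellipsoid(shp, cen_l, semi_l) | .ellipsoid(shp, cen_r, semi_r)

  # posterior chest/muscle band, separated from the breasts (pectoral gap)
  chest <- array(FALSE, shp)
  chest[, seq.int(ceiling(0.85 * Y), Y), ] <- TRUE
  chest <- chest & !breast

  # lesions: spheres (in mm) fully inside breast tissue
  n_les <- if (config$lesions_per_patient[2] >= config$lesions_per_patient[1])
    sample(config$lesions_per_patient[1]:config$lesions_per_patient[2], 1L)
  else config$lesions_per_patient[1]
  lesion <- array(FALSE, shp)
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  breast_idx <- which(breast)
  for (l in seq_len(n_les)) {
    r_mm <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    semi <- pmax(r_mm / config$spacing_mm, 1.0)
    placed <- FALSE
    for (try in 1:200) {
      cand <- arrayInd(sample(breast_idx, 1L), shp)
      sph <- .ellipsoid(shp, as.double(cand), semi)
      if (all(breast[sph])) {
        lesion <- lesion | sph
        centers <- rbind(centers, as.double(cand))
        radii <- c(radii, r_mm)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a lesion of radius ", signif(r_mm, 3),
           " mm inside breast tissue after bounded retries", call. = FALSE)
  }

  # per-patient kinetic variability around the class archetypes
  p_les <- tic_params(100, jit(1 / 40), jit(1 / 600), jit(1.8))
  p_par <- tic_params(100, jit(1 / 180), 0, jit(0.8))
  p_mus <- tic_params(80, jit(1 / 200), 0, jit(0.3))

  par_mask <- breast & !lesion
  tissue_idx <- which(breast | chest)
  les_idx <- which(lesion)
  par_idx <- which(par_mask)
  chest_idx <- which(chest)

  # anatomy: smooth per-patient intensity heterogeneity, shared by all series
  tex <- if (config$texture_amplitude > 0)
    .smooth_field(shp, config$texture_amplitude) else NULL

  n_series <- length(config$series_times)
  vols <- array(0, dim = c(shp, n_series))
  translations <- matrix(0, nrow = n_series, ncol = 3,
                         dimnames = list(NULL, c("z", "y", "x")))
  for (s in seq_len(n_series)) {
    t <- config$series_times[s]
    v <- array(0, shp)
    v[les_idx] <- tic_value(p_les, t)
    v[par_idx] <- tic_value(p_par, t)
    v[chest_idx] <- tic_value(p_mus, t)
    if (!is.null(tex)) v[tissue_idx] <- v[tissue_idx] * tex[tissue_idx]
    if (config$noise_sigma > 0)
      v[tissue_idx] <- pmax(v[tissue_idx] +
                              rnorm(length(tissue_idx), 0, config$noise_sigma), 0)
    if (config$motion_amplitude_vox > 0 && t > 0) {
      tr <- runif(3, -config$motion_amplitude_vox, config$motion_amplitude_vox)
      translations[s, ] <- tr
      v <- resample_translate3d(v, tr)
    }
    vols[, , , s] <- v
  }

  study <- dce_study(vols, config$series_times, config$spacing_mm,
                     study_id = sprintf("phantom_%03d", patient_index),
                     breast_mask = array(as.double(breast), shp),
                     lesion_mask = array(as.double(lesion), shp))
  attr(study, "provenance") <- list(patient_seed = pseed,
                                    translations = translations,
                                    lesion_centers = centers,
                                    lesion_radii_mm = radii)
  study
}

#' Generate a phantom cohort
#'
#' @param config a [phantom_config()].
#' @return list of [dce_study()] of length `n_patients`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  lapply(seq_len(config$n_patients), function(i) generate_study(config, i))
}

#' Write a phantom cohort to disk
#'
#' One sub-directory per patient in the [write_study()] layout, plus a
#' cohort-level `provenance.json` with the seeds, injected translations and
#' lesion geometry.
#'
#' @param config a [phantom_config()].
#' @param dir output directory.
#' @return character vector of per-study directories, invisibly.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(config$n_patients)
  prov <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    st <- generate_study(config, i)
    dirs[i] <- file.path(dir, st$study_id)
    write_study(st, dirs[i])
    p <- attr(st, "provenance")
    prov[[i]] <- list(study_id = st$study_id, patient_seed = p$patient_seed,
                      translations = p$translations,
                      lesion_centers = p$lesion_centers,
                      lesion_radii_mm = p$lesion_radii_mm)
  }
  jsonlite::write_json(list(config = unclass(config), studies = prov),
                       file.path(dir, "provenance.json"), digits = NA)
  invisible(dirs)
}
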