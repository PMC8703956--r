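test_that("self-registration returns (near-)identity", {
  st <- generate_study(tiny_config(noise_sigma = 0), 1)
  v <- get_series(st, 1)
  tr <- register_volume(v, v, registration_config())
  expect_lt(max(abs(tr$shift_vox)), 0.1)
})

test_that("a known shift is recovered (pull-resampling convention)", {
  st <- generate_study(tiny_config(noise_sigma = 0), 1)
  fixed <- get_series(st, 1)
  moving <- tracerseg:::resample_translate3d(fixed, c(0, 3, -2))
  tr <- register_volume(moving, fixed, registration_config())
  # moving[p] = fixed[p + (0,3,-2)], so aligning needs the opposite shift
  expect_lt(sqrt(sum((tr$shift_vox - c(0, -3, 2))^2)), 0.5)
})

test_that("degenerate metrics error", {
  v <- array(runif(12 * 16 * 16), dim = c(12, 16, 16))
  flat <- array(1, dim = dim(v))
  expect_error(register_volume(flat, v, registration_config()), "degenerate")
})

test_that("apply_transform semantics: identity, delta bookkeeping, inverse", {
  set.seed(4)
  v <- array(runif(10 * 12 * 14), dim = c(10, 12, 14))
  id <- spatial_transform(c(0, 0, 0))
  expect_identical(apply_transform(v, id), v)       # bitwise at zero shift

  delta <- array(0, dim = c(8, 8, 8)); delta[4, 5, 6] <- 1
  moved <- apply_transform(delta, spatial_transform(c(1, 2, -1)))
  expect_identical(moved[3, 3, 7], 1)               # out[p] = in[p + t]
  expect_identical(sum(moved), 1)

  # round-trip residual on an analytically smooth volume is interpolation-bounded
  g <- expand.grid(z = 1:16, y = 1:24, x = 1:32)
  smooth <- array(sin(g$z / 3) + cos(g$y / 4) + sin(g$x / 5), dim = c(16, 24, 32))
  t <- spatial_transform(c(0.4, -1.3, 0.8))
  round_trip <- apply_transform(apply_transform(smooth, t), invert_transform(t))
  interior <- 3:14
  expect_lt(max(abs((round_trip - smooth)[interior, 3:22, 3:30])), 0.05)
})

test_that("motion correction recovers injected translations", {
  cfg <- tiny_config(shape = c(24L, 64L, 128L), motion_amplitude_vox = 2.5,
                     noise_sigma = 2,
                     series_times = c(-56, 56, 112, 168, 224))
  st <- generate_study(cfg, 1)
  prov <- attr(st, "provenance")
  corrected <- motion_correct_study(st, registration_config())
  mct <- attr(corrected, "mc_transforms")
  # pre-contrast untouched, transforms reported per post series
  expect_null(mct[[1]])
  expect_identical(get_series(corrected, 1), get_series(st, 1))
  posts <- 2:5
  res <- vapply(posts, function(s)
    sqrt(sum((mct[[s]]$shift_vox + prov$translations[s, ])^2)), 0)
  expect_lt(mean(res), 0.5)
  # registered series correlate strictly better with the reference
  fixed <- get_series(st, 1)
  for (s in posts) {
    before <- tracerseg:::ncc3d(fixed, get_series(st, s), st$breast_mask)
    after <- tracerseg:::ncc3d(fixed, get_series(corrected, s), st$breast_mask)
    expect_gt(after, before)
  }
})

test_that("motion-free studies pass through almost unchanged", {
  cfg <- tiny_config(shape = c(24L, 64L, 128L), noise_sigma = 0,
                     series_times = c(-56, 56, 112))
  st <- generate_study(cfg, 1)
  corrected <- motion_correct_study(st, registration_config())
  mct <- attr(corrected, "mc_transforms")
  for (s in 2:3)   # nothing to correct: recovered shifts are sub-voxel noise
    expect_lt(max(abs(mct[[s]]$shift_vox)), 0.25)
  expect_lt(mean(abs(corrected$volumes - st$volumes)), 1.5)
  # single-series studies are returned unchanged
  single <- dce_study(list(get_series(st, 1)), 0, st$spacing_mm)
  expect_identical(motion_correct_study(single)$volumes, single$volumes)
})

test_that("rigid and bspline models run and do not worsen alignment", {
  cfg <- tiny_config(motion_amplitude_vox = 1.5, noise_sigma = 2)
  st <- generate_study(cfg, 1)
  fixed <- get_series(st, 1)
  moving <- get_series(st, 2)
  base <- tracerseg:::ncc3d(fixed, moving, st$breast_mask)
  for (model in c("rigid", "bspline")) {
    tr <- register_volume(moving, fixed,
                          registration_config(model = model, max_iterations = 30),
                          mask = st$breast_mask)
    expect_s3_class(tr, "spatial_transform")
    expect_gte(attr(tr, "metric"), base - 1e-6)
  }
})

test_that("MI metric also recovers a shift", {
  st <- generate_study(tiny_config(noise_sigma = 0), 1)
  fixed <- get_series(st, 1)
  moving <- tracerseg:::resample_translate3d(fixed, c(0, 2, -1))
  tr <- register_volume(moving, fixed, registration_config(metric = "MI"))
  expect_lt(sqrt(sum((tr$shift_vox - c(0, -2, 1))^2)), 1)
})

test_that("external registrar adapter honours its file contract", {
  st <- generate_study(net_config(), 1)
  # a "registrar" that just copies moving to out: the adapter must accept it
  script <- tempfile(fileext = ".R")
  writeLines("a <- commandArgs(TRUE); file.copy(a[1], a[2])", script)
  out <- motion_correct_external(st, file.path(R.home("bin"), "Rscript"),
                                 c(script, "{moving}", "{out}"))
  expect_equal(out$volumes, st$volumes, tolerance = 1e-6)
  expect_error(motion_correct_external(st, file.path(R.home("bin"), "Rscript"),
                                       c("--version")), "failed")
  unlink(script)
})
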