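test_that("time-point selection matches the 56 s protocol and exact grids", {
  # 1 pre + 9 post series, 56 s apart: t1 -> 2nd post (112 s), t2 -> 6th post (336 s)
  sel <- select_time_points(c(-56, 56 * (1:9)))
  expect_identical(unname(sel$indices), c(1L, 3L, 7L))
  expect_identical(sel$realized_times, c(-56, 112, 336))
  # exact hits
  sel2 <- select_time_points(c(0, 120, 360))
  expect_identical(unname(sel2$indices), c(1L, 2L, 3L))
  expect_identical(sel2$realized_times, c(0, 120, 360))
  # equidistant ties resolve to the earlier series
  sel3 <- select_time_points(c(-10, 90, 150, 330, 390))
  expect_identical(sel3$realized_times[2], 90)
  expect_identical(sel3$realized_times[3], 330)
  # fewer than three usable acquisitions
  expect_error(select_time_points(c(-10, 50)), "at least three")
  expect_error(select_time_points(c(-10, -5)), "at least three")
})

test_that("selection equals exhaustive argmin search on random grids", {
  oracle <- function(times, targets = c(0, 120, 360)) {
    pre <- which(times <= 0); post <- which(times > 0)
    i0 <- max(pre)
    best <- function(cands, target) {
      d <- abs(times[cands] - target)
      cands[which(d == min(d))][1]         # earlier tie, exhaustive
    }
    i1 <- best(post, targets[2])
    i2 <- best(setdiff(post, i1), targets[3])
    c(i0, i1, i2)
  }
  set.seed(99)
  for (rep in 1:1000) {
    n_pre <- sample(1:2, 1); n_post <- sample(2:10, 1)
    times <- sort(c(-runif(n_pre, 0, 120), runif(n_post, 1, 700)))
    times[times == 0] <- -1
    sel <- select_time_points(times)
    expect_identical(unname(sel$indices), as.integer(oracle(times)))
  }
})

test_that("slicing plane follows the largest spacing with z>y>x ties", {
  expect_identical(select_slicing_plane(c(2, 1.45, 1.45)), "z")
  expect_identical(select_slicing_plane(c(1, 1, 1)), "z")
  expect_identical(select_slicing_plane(c(0.5, 3, 0.5)), "y")
  expect_identical(select_slicing_plane(c(0.5, 1, 1)), "y")
})

test_that("bilateral split/merge is an exact inverse pair", {
  set.seed(5)
  v <- array(runif(4 * 6 * 10), dim = c(4, 6, 10))
  halves <- split_bilateral(v)
  expect_identical(dim(halves$left)[3], 5L)
  expect_identical(merge_bilateral(halves$left, halves$right), v)
  # odd extents use the floor convention
  v5 <- array(runif(2 * 2 * 5), dim = c(2, 2, 5))
  h5 <- split_bilateral(v5)
  expect_identical(dim(h5$left)[3], 2L)
  expect_identical(dim(h5$right)[3], 3L)
  expect_identical(merge_bilateral(h5$left, h5$right), v5)
  # index bookkeeping
  m <- merge_bilateral(array(1, dim = c(2, 2, 3)), array(0, dim = c(2, 2, 3)))
  expect_true(all(m[, , 1:3] == 1) && all(m[, , 4:6] == 0))
  expect_error(merge_bilateral(array(0, dim = c(2, 2, 3)),
                               array(0, dim = c(3, 2, 3))), "disagree")
})

test_that("3TP extraction emits 2 x extent bit-faithful labeled slices", {
  st <- generate_study(tiny_config(), 1)
  st <- apply_breast_mask(st, st$breast_mask)
  sel <- select_time_points(st$times_post_injection)
  slices <- extract_3tp_dataset(st, sel)
  n_z <- dim(st$volumes)[1]
  expect_length(slices, 2L * n_z)
  labels <- slice_labels(slices)
  expect_identical(sum(labels == "lesion") + sum(labels == "healthy"),
                   length(slices))

  halves <- lapply(sel$indices, function(s) split_bilateral(get_series(st, s)))
  gt_halves <- split_bilateral(st$lesion_mask)
  for (sl in slices[sample(length(slices), 8)]) {
    side <- sl$side; i <- sl$slice_index
    for (c in 1:3)   # channels are bit-equal to the source slices
      expect_identical(sl$pixels[, , c], halves[[c]][[side]][i, , ])
    # label equals the brute-force any-lesion-voxel scan of the half slice
    expect_identical(sl$label,
                     if (any(gt_halves[[side]][i, , ] > 0)) "lesion" else "healthy")
    expect_identical(sl$gt_mask, gt_halves[[side]][i, , ])
  }
})

test_that("labeling edge cases behave", {
  st <- generate_study(tiny_config(), 1)
  st$lesion_mask <- array(0, dim(st$volumes)[1:3])      # empty ground truth
  slices <- extract_3tp_dataset(st)
  expect_true(all(slice_labels(slices) == "healthy"))
  st$lesion_mask <- NULL
  expect_error(extract_3tp_dataset(st, labeled = TRUE), "lesion_mask")
  unlabeled <- extract_3tp_dataset(st)
  expect_true(all(is.na(slice_labels(unlabeled))))
})

test_that("3TP datasets round-trip through the on-disk index layout", {
  st <- apply_breast_mask(generate_study(net_config(), 1),
                          generate_study(net_config(), 1)$breast_mask)
  slices <- extract_3tp_dataset(st)
  dir <- tempfile("3tp")
  idx_path <- write_3tp_dataset(slices, dir)
  idx <- utils::read.csv(idx_path)
  expect_identical(nrow(idx), length(slices))
  back <- read_nifti(file.path(dir, idx$file[1]))
  expect_equal(as.vector(back), as.vector(slices[[1]]$pixels), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
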