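test_that("patient-wise folds partition the cohort with near-equal sizes", {
  ids <- sprintf("p%02d", 1:33)
  folds <- make_folds(ids, k = 10, seed = 1)
  expect_length(folds, 10)
  tested <- unlist(lapply(folds, function(f) f$test_patients))
  expect_setequal(tested, ids)                       # each patient tested once
  expect_length(tested, 33)
  for (f in folds) {
    expect_length(intersect(f$train_patients, f$test_patients), 0)
    expect_length(intersect(f$train_patients, f$val_patients), 0)
    expect_length(intersect(f$val_patients, f$test_patients), 0)
    expect_setequal(c(f$train_patients, f$val_patients, f$test_patients), ids)
    expect_true(length(f$train_patients) %in% 26:27)
  }
  # at 160 slices/patient a 27-train-patient repetition holds 4320 slices
  sizes27 <- vapply(folds, function(f) length(f$train_patients), 0L)
  expect_true(any(sizes27 == 27))
  expect_identical(27L * 160L, 4320L)
  # exactly k patients: the 8/1/1 geometry
  f10 <- make_folds(sprintf("q%d", 1:10), k = 10, seed = 2)
  expect_true(all(vapply(f10, function(f) length(f$train_patients), 0L) == 8L))
  expect_error(make_folds(sprintf("q%d", 1:9), k = 10), "at least")
})

# a minimal labeled slice: in-breast where channel sums are nonzero
fake_slice <- function(pid, side, idx, vals, gt = NULL, h = 2, w = 2) {
  px <- array(0, dim = c(h, w, 3))
  for (c in 1:3) px[, , c][seq_along(vals)] <- vals
  if (is.null(gt)) gt <- matrix(0, h, w)
  structure(list(pixels = px, patient_id = pid, side = side, slice_index = idx,
                 label = if (any(gt > 0)) "lesion" else "healthy", gt_mask = gt),
            class = "three_tp_slice")
}

test_that("z-score statistics use in-breast training pixels only", {
  s <- fake_slice("a", "left", 1, c(1, 2, 3))
  stats <- fit_normalization(list(s))
  expect_equal(stats$mean, 2)
  expect_equal(stats$std, sqrt(2 / 3))               # population estimator
  # leakage audit: only the slices passed as training contribute
  other <- fake_slice("b", "left", 1, c(100, 200, 300))
  expect_equal(fit_normalization(list(s))$mean, 2)
  expect_false(fit_normalization(list(s, other))$mean == 2)
  expect_identical(stats$fit_scope, "a")
  expect_error(fit_normalization(list()), "no training slices")
  expect_error(fit_normalization(list(fake_slice("a", "left", 1, c(5, 5, 5)))),
               "variance")
})

test_that("normalization standardizes in-breast pixels and keeps background 0", {
  slices <- cohort_slices(net_config())
  stats <- fit_normalization(slices)
  norm <- apply_normalization(slices, stats)
  vals <- c(); zeros_ok <- TRUE
  for (i in seq_along(slices)) {
    px0 <- slices[[i]]$pixels; px1 <- norm[[i]]$pixels
    inb <- (px0[, , 1] != 0) | (px0[, , 2] != 0) | (px0[, , 3] != 0)
    for (c in 1:3) {
      vals <- c(vals, px1[, , c][inb])
      zeros_ok <- zeros_ok && all(px1[, , c][!inb] == 0)
    }
  }
  expect_true(zeros_ok)
  expect_lt(abs(mean(vals)), 1e-8)
  expect_equal(stats::sd(vals), 1, tolerance = 1e-3)
})

test_that("evaluation scores oracle and degenerate predictors correctly", {
  # slices whose ground truth is recoverable from channel 2 (values > 900)
  set.seed(20)
  slices <- list()
  for (p in c("pa", "pb")) for (i in 1:3) {
    gt <- matrix(rbinom(16, 1, ifelse(i == 1, 0.4, 0)), 4, 4)
    px <- array(runif(48, 1, 10), dim = c(4, 4, 3))
    px[, , 2] <- px[, , 2] + 1000 * gt
    slices[[length(slices) + 1]] <- structure(
      list(pixels = px, patient_id = p, side = "left", slice_index = i,
           label = if (any(gt > 0)) "lesion" else "healthy", gt_mask = gt),
      class = "three_tp_slice")
  }
  oracle <- function(x) {
    p <- (x[, , 2, , drop = FALSE] > 900) * 1
    dim(p) <- c(dim(x)[1:2], 1L, dim(x)[4])
    p
  }
  rep <- evaluate(oracle, slices)
  expect_true(all(rep$per_patient_dsc == 1))
  expect_identical(rep$median_dsc, 1)

  background <- function(x) array(0, dim = c(dim(x)[1:2], 1L, dim(x)[4]))
  rep0 <- evaluate(background, slices)
  has_lesion <- vapply(unique(slice_patients(slices)), function(p)
    any(vapply(slices[slice_patients(slices) == p],
               function(s) any(s$gt_mask > 0), TRUE)), TRUE)
  expect_true(all(rep0$per_patient_dsc[has_lesion] == 0))

  # false positives on healthy slices: lesion-only mode scores higher
  fp <- function(x) {
    p <- oracle(x)
    p[1, 1, 1, ] <- 1
    p
  }
  all_m <- evaluate(fp, slices, mode = "all_slices")
  les_m <- evaluate(fp, slices, mode = "lesion_slices_only")
  expect_gt(les_m$median_dsc, all_m$median_dsc)
})

test_that("ranking tables use competition ranking and sum to 100%", {
  pats <- c("p1", "p2", "p3", "p4")
  mk <- function(v) stats::setNames(v, pats)
  scores <- list(A = mk(rep(0.9, 4)), B = mk(rep(0.8, 4)), C = mk(rep(0.7, 4)))
  tab <- ranking_table(scores)
  expect_identical(unname(tab["A", ]), c(100, 0, 0))
  expect_identical(unname(tab["B", ]), c(0, 100, 0))
  expect_identical(unname(tab["C", ]), c(0, 0, 100))
  expect_true(all(abs(rowSums(tab) - 100) < 1e-9))
  # ties share the better rank; the next rank is skipped ("1224")
  scores2 <- list(A = mk(c(0.9, 0.9, 0.9, 0.9)), B = mk(rep(0.9, 4)),
                  C = mk(rep(0.1, 4)))
  tab2 <- ranking_table(scores2)
  expect_identical(unname(tab2["A", ]), c(100, 0, 0))
  expect_identical(unname(tab2["B", ]), c(100, 0, 0))
  expect_identical(unname(tab2["C", ]), c(0, 0, 100))
  expect_error(ranking_table(scores[1]), "two methods")
  bad <- scores; names(bad$B) <- c("p1", "p2", "p3", "zz")
  expect_error(ranking_table(bad), "different patient set")
})

test_that("run_training learns, is seed-deterministic, and validates input", {
  slices <- cohort_slices(net_config())
  pid <- slice_patients(slices)
  pats <- unique(pid)
  tr <- slices[pid %in% pats[1:3]]
  va <- slices[pid == pats[4]]
  stats <- fit_normalization(tr)
  tr <- apply_normalization(tr, stats); va <- apply_normalization(va, stats)
  cfg <- training_config(eras = 3, batch_size = 4, seed = 17)
  spec <- model_spec(c(16, 16), 3, 2, 4)
  res <- run_training(tr, va, spec, cfg)
  expect_identical(nrow(res$history), 3L)
  expect_lt(res$history$train_loss[3], res$history$train_loss[1])
  res2 <- run_training(tr, va, spec, cfg)
  expect_identical(res$history, res2$history)         # full determinism

  healthy_only <- tr[slice_labels(tr) == "healthy"]
  expect_error(run_training(healthy_only, va, spec, cfg), "no lesion slices")
  expect_error(training_config(eras = 0), "eras")
})

test_that("training history is invariant to val/test intensity perturbation", {
  slices <- cohort_slices(net_config())
  pid <- slice_patients(slices)
  pats <- unique(pid)
  tr <- apply_normalization(slices[pid == pats[1]],
                            fit_normalization(slices[pid == pats[1]]))
  va <- slices[pid == pats[2]]
  va_perturbed <- lapply(va, function(s) { s$pixels <- s$pixels * 3 + 7; s })
  cfg <- training_config(eras = 2, batch_size = 4, seed = 9)
  spec <- model_spec(c(16, 16), 3, 2, 2)
  h1 <- run_training(tr, list(), spec, cfg)$history
  h2 <- run_training(tr, list(), spec, cfg)$history
  expect_identical(h1$train_loss, h2$train_loss)
  # the validation fold only monitors: losses match with either val set
  h3 <- run_training(tr, va, spec, cfg)$history
  h4 <- run_training(tr, va_perturbed, spec, cfg)$history
  expect_identical(h3$train_loss, h4$train_loss)
})

test_that("predict_study assembles a full-grid mask", {
  st <- generate_study(net_config(), 1)
  st <- apply_breast_mask(st, st$breast_mask)
  oracle <- function(x) array(0.9, dim = c(dim(x)[1:2], 1L, dim(x)[4]))
  mask <- predict_study(oracle, st)
  expect_identical(dim(mask), dim(st$volumes)[1:3])
  expect_true(all(mask == 1))
})

test_that("evaluation reports serialize to JSON + per-patient CSV", {
  rep <- structure(list(per_patient_dsc = c(pa = 0.8, pb = 0.6),
                        median_dsc = 0.7, mode = "all_slices"),
                   class = "eval_report")
  path <- tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$median_dsc, 0.7)
  expect_equal(back$per_patient_dsc$pa, 0.8)
  csv <- utils::read.csv(paste0(path, ".per_patient.csv"))
  expect_identical(csv$patient_id, c("pa", "pb"))
  unlink(c(path, paste0(path, ".per_patient.csv")))
})

test_that("3TP channels beat a pre-contrast-only (1TP) input", {
  # pre-contrast intensity carries no kinetic signal, so a 1-channel t0
  # network has nothing to discriminate lesions with; the 3TP encoding does.
  # (property test: lr 1e-3 exposes the direction within a small step budget)
  slices <- list()
  cfg <- phantom_config(n_patients = 6L, shape = c(16L, 64L, 128L),
                        spacing_mm = c(2, 1.45, 1.45),
                        lesions_per_patient = c(1L, 2L),
                        lesion_radius_mm = c(5, 9), noise_sigma = 3,
                        seed = 31L)
  for (st in generate_cohort(cfg))
    slices <- c(slices, extract_3tp_dataset(apply_breast_mask(st, st$breast_mask)))
  pid <- slice_patients(slices)
  pats <- unique(pid)
  tr <- slices[pid %in% pats[1:4]]
  te <- slices[pid %in% pats[5:6]]
  stats <- fit_normalization(tr)
  tr <- apply_normalization(tr, stats)
  te <- apply_normalization(te, stats)
  dsc <- vapply(list(1:3, 1L), function(ch) {
    tc <- training_config(eras = 5L, batch_size = 2L, seed = 17L,
                          learning_rate = 1e-3)
    res <- run_training(tr, list(), model_spec(c(64L, 64L), length(ch), 5L, 8L),
                        tc, channels = ch)
    evaluate(res$model, te, channels = ch)$median_dsc
  }, 0)
  expect_gt(dsc[1], dsc[2])      # 3TP strictly better
  expect_gt(dsc[1], 0.5)         # and genuinely learns at this budget
})
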