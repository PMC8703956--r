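#' Patient-wise k-fold cross-validation
#'
#' Folds are drawn over *patients*, never over slices, so no patient
#' contributes to two roles within a repetition. Patients are shuffled with
#' `seed` and split into `k` near-equal folds (e.g. 33 patients over 10
#' folds gives sizes 4 and 3); repetition `r` uses fold `r` as test, fold
#' `r %% k + 1` as validation, and the remaining `k - 2` folds as training.
#'
#' @param patient_ids character vector of distinct patient identifiers.
#' @param k number of folds (default 10).
#' @param seed integer.
#' @return list of `k` `fold_spec`s with `repetition_index`,
#'   `train_patients`, `val_patients`, `test_patients`.
#' @export
make_folds <- function(patient_ids, k = 10L, seed = 0L) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient_ids must be distinct", call. = FALSE)
  if (n < k) stop("need at least k = ", k, " patients, got ", n, call. = FALSE)
  shuffled <- with_seed(seed, patient_ids[sample.int(n)])
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) {
    # spread the larger folds so no test+validation pair grabs two of them
    at <- unique(round(seq(1, k, length.out = extra + 1L))[seq_len(extra)])
    sizes[at] <- sizes[at] + 1L
    sizes[seq_len(extra - length(at))] <- sizes[seq_len(extra - length(at))] + 1L
  }
  folds <- split(shuffled, rep(seq_len(k), times = sizes))
  lapply(seq_len(k), function(r) {
    val <- (r %% k) + 1L
    structure(list(repetition_index = r,
                   train_patients = unlist(folds[-c(r, val)], use.names = FALSE),
                   val_patients = folds[[val]],
                   test_patients = folds[[r]]),
              class = "fold_spec")
  })
}

#' Fold-wise z-score normalization
#'
#' Statistics are fitted on the *training* slices only — specifically on
#' their in-breast pixels (any nonzero channel), because the masked
#' background is a synthetic 0 that would bias the mean — and then applied
#' unchanged to validation and test slices. Background pixels stay exactly 0
#' after application. The population (n) estimator is used for the s.d.
#'
#' @param training_slices non-empty list of `three_tp_slice`.
#' @return a `normalization_stats` with `mean`, `std`, `fit_scope`.
#' @export
fit_normalization <- function(training_slices) {
  if (!length(training_slices)) stop("no training slices", call. = FALSE)
  s <- 0; s2 <- 0; n <- 0
  for (sl in training_slices) {
    px <- sl$pixels
    inb <- (px[, , 1] != 0) | (px[, , 2] != 0) | (px[, , 3] != 0)
    if (!any(inb)) next
    for (c in 1:3) {
      v <- px[, , c][inb]
      s <- s + sum(v); s2 <- s2 + sum(v * v); n <- n + length(v)
    }
  }
  if (n == 0) stop("no in-breast pixels in the training slices", call. = FALSE)
  mean <- s / n
  var <- s2 / n - mean^2
  if (var <= 0) stop("zero variance: z-score undefined", call. = FALSE)
  structure(list(mean = mean, std = sqrt(var),
                 fit_scope = unique(vapply(training_slices,
                                           function(x) x$patient_id, ""))),
            class = "normalization_stats")
}

#' @param slices list of `three_tp_slice` to transform.
#' @param stats a [fit_normalization()] result.
#' @rdname fit_normalization
#' @export
apply_normalization <- function(slices, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  lapply(slices, function(sl) {
    px <- sl$pixels
    inb <- (px[, , 1] != 0) | (px[, , 2] != 0) | (px[, , 3] != 0)
    for (c in 1:3) {
      v <- px[, , c]
      v[inb] <- (v[inb] - stats$mean) / stats$std
      px[, , c] <- v
    }
    sl$pixels <- px
    sl
  })
}

# Stack a slice list into (H, W, C, N) input and (H, W, 1, N) target tensors.
slices_to_tensors <- function(slices, with_gt = TRUE, channels = 1:3) {
  d <- dim(slices[[1L]]$pixels)
  n <- length(slices)
  x <- array(0, dim = c(d[1], d[2], length(channels), n))
  for (i in seq_len(n)) x[, , , i] <- slices[[i]]$pixels[, , channels]
  out <- list(x = x)
  if (with_gt) {
    g <- array(0, dim = c(d[1], d[2], 1L, n))
    for (i in seq_len(n)) g[, , 1L, i] <- slices[[i]]$gt_mask
    out$gt <- g
  }
  out
}

# batched inference over a slice list; returns list of 2D probability maps.
# `model` may be a unet_model or any function(x) -> (H, W, 1, N) probability
# tensor (oracle predictors, external models).
.predict_slices <- function(model, slices, channels = 1:3, batch = 16L) {
  predict_fn <- if (is.function(model)) model else function(x) unet_predict(model, x)
  out <- vector("list", length(slices))
  i <- 1L
  while (i <= length(slices)) {
    j <- min(i + batch - 1L, length(slices))
    x <- slices_to_tensors(slices[i:j], with_gt = FALSE, channels = channels)$x
    p <- predict_fn(x)
    for (k in i:j) out[[k]] <- p[, , 1L, k - i + 1L]
    i <- j + 1L
  }
  out
}

#' Train the segmentation network on one fold
#'
#' Runs the eras/epochs scheduler over the training slices for
#' `config$eras` eras: each era re-partitions the majority class into
#' chunks, each epoch processes one chunk plus the full minority class in
#' seeded balanced batches, and each batch takes one ADAM step on the soft
#' Dice loss. After every era the validation fold is scored (median
#' per-patient DSC) and the best-era weights are kept.
#'
#' @param train_slices,val_slices labeled `three_tp_slice` lists (already
#'   normalized with the fold's [fit_normalization()] statistics).
#' @param spec a [model_spec()]; `NULL` derives one from the slice size.
#' @param config a [training_config()].
#' @param channels input channels to feed (default all three; `1` gives the
#'   pre-contrast-only ablation).
#' @param verbose print per-era progress.
#' @return list `model` (best-era weights), `history` (data.frame of era,
#'   train_loss, val_dsc), `best_era`, `config`.
#' @export
run_training <- function(train_slices, val_slices, spec = NULL,
                         config = training_config(), channels = 1:3,
                         verbose = FALSE) {
  labels <- vapply(train_slices, function(s) s$label, "")
  if (anyNA(labels)) stop("training slices must be labeled", call. = FALSE)
  lesion_ids <- which(labels == "lesion")
  healthy_ids <- which(labels == "healthy")
  if (!length(lesion_ids))
    stop("training fold has no lesion slices: the scheduler needs a ",
         "non-empty minority class", call. = FALSE)
  if (!length(healthy_ids))
    stop("training fold has no healthy slices", call. = FALSE)
  minority <- if (length(lesion_ids) <= length(healthy_ids)) lesion_ids else healthy_ids
  majority <- if (length(lesion_ids) <= length(healthy_ids)) healthy_ids else lesion_ids

  d <- dim(train_slices[[1L]]$pixels)
  if (is.null(spec))
    spec <- model_spec(input_size = d[1:2], in_channels = length(channels))
  tens <- slices_to_tensors(train_slices, channels = channels)
  model <- initialize_weights(build_model(spec), config)
  opt <- NULL
  history <- data.frame(era = integer(), train_loss = double(), val_dsc = double())
  best <- list(dsc = -Inf, era = 0L, params = model$params, bn = model$bn_state)
  for (era in seq_len(config$eras)) {
    plan <- plan_era(majority, minority, era, config$seed)
    losses <- c()
    for (ep in seq_along(plan$chunks)) {
      stream <- epoch_batches(plan, ep, config$batch_size, config$seed)
      for (b in stream$batches) {
        st <- unet_train_step(model, opt,
                              tens$x[, , , b, drop = FALSE],
                              tens$gt[, , , b, drop = FALSE], config)
        model <- st$model; opt <- st$opt_state
        losses <- c(losses, st$loss)
      }
    }
    val_dsc <- if (length(val_slices)) {
      rep_eval <- evaluate(model, val_slices, mode = "all_slices",
                           threshold = config$threshold, channels = channels)
      rep_eval$median_dsc
    } else NA_real_
    history <- rbind(history, data.frame(era = era, train_loss = mean(losses),
                                         val_dsc = val_dsc))
    if (verbose)
      message(sprintf(
        "era %2d: %d chunks x %d samples (coverage: all %d majority, %d x %d minority)  loss %.4f  val DSC %s",
        era, length(plan$chunks), 2L * length(minority), length(majority),
        length(plan$chunks), length(minority), mean(losses),
        ifelse(is.na(val_dsc), "-", sprintf("%.3f", val_dsc))))
    if (!is.na(val_dsc) && val_dsc > best$dsc)
      best <- list(dsc = val_dsc, era = era, params = model$params,
                   bn = model$bn_state)
  }
  if (best$era > 0L) {
    model$params <- best$params
    model$bn_state <- best$bn
  } else best$era <- config$eras
  list(model = model, history = history, best_era = best$era, config = config)
}

#' Evaluate a model patient-wise
#'
#' Every slice of every patient is predicted, binarized at `threshold`, and
#' the Dice similarity is computed per patient over the stacked (bilaterally
#' merged) masks against the full ground truth. `lesion_slices_only`
#' restricts both prediction and ground truth to slices whose ground truth
#' contains at least one lesion pixel before computing DSC — the evaluation
#' convention that hides false positives on healthy slices.
#'
#' @param model a trained `unet_model`, or any `function(x)` mapping an input
#'   tensor to a probability tensor (e.g. an oracle predictor).
#' @param slices labeled `three_tp_slice` list (normalized like training).
#' @param mode `"all_slices"` or `"lesion_slices_only"`.
#' @param threshold binarization fraction.
#' @param channels input channels fed to the model.
#' @return an `eval_report`: `per_patient_dsc` (named), `median_dsc`, `mode`.
#' @export
evaluate <- function(model, slices, mode = c("all_slices", "lesion_slices_only"),
                     threshold = 0.5, channels = 1:3) {
  mode <- match.arg(mode)
  if (any(vapply(slices, function(s) is.null(s$gt_mask), TRUE)))
    stop("evaluation requires ground-truth masks on every slice", call. = FALSE)
  patients <- vapply(slices, function(s) s$patient_id, "")
  per_patient <- c()
  for (pid in unique(patients)) {
    ps <- slices[patients == pid]
    if (mode == "lesion_slices_only")
      ps <- ps[vapply(ps, function(s) any(s$gt_mask > 0), TRUE)]
    if (!length(ps)) { per_patient[pid] <- NA_real_; next }
    probs <- .predict_slices(model, ps, channels = channels)
    inter <- 0; p_sum <- 0; g_sum <- 0
    for (i in seq_along(ps)) {
      pred <- binarize(probs[[i]], threshold)
      inter <- inter + sum(pred * ps[[i]]$gt_mask)
      p_sum <- p_sum + sum(pred)
      g_sum <- g_sum + sum(ps[[i]]$gt_mask)
    }
    per_patient[pid] <- if (p_sum + g_sum == 0) 1 else 2 * inter / (p_sum + g_sum)
  }
  structure(list(per_patient_dsc = per_patient,
                 median_dsc = stats::median(per_patient, na.rm = TRUE),
                 mode = mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s> median DSC %.4f over %d patients\n",
              x$mode, x$median_dsc, length(x$per_patient_dsc)))
  invisible(x)
}

#' Predict the lesion mask of a whole study
#'
#' Full inference route: 3TP extraction, optional normalization, per-breast
#' slice prediction, binarization, bilateral merge and restacking into a 3D
#' mask on the study grid.
#'
#' @param model a trained `unet_model`.
#' @param study a breast-masked [dce_study()].
#' @param stats optional [fit_normalization()] statistics.
#' @param threshold binarization fraction.
#' @param channels input channels fed to the model.
#' @return binary 3D array `(z, y, x)`.
#' @export
predict_study <- function(model, study, stats = NULL, threshold = 0.5,
                          channels = 1:3) {
  plane <- select_slicing_plane(study$spacing_mm)
  slices <- extract_3tp_dataset(study, labeled = FALSE)
  if (!is.null(stats)) slices <- apply_normalization(slices, stats)
  probs <- .predict_slices(model, slices, channels = channels)
  shp <- dim(study$volumes)[1:3]
  ax <- match(plane, c("z", "y", "x"))
  n_slices <- length(slices) / 2L
  half_shapes <- lapply(split_bilateral(array(0, shp)), dim)
  halves <- list(left = array(0, half_shapes$left),
                 right = array(0, half_shapes$right))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    pred <- binarize(probs[[i]], threshold)
    h <- halves[[s$side]]
    switch(plane,
           z = { h[s$slice_index, , ] <- pred },
           y = { h[, s$slice_index, ] <- pred },
           x = { h[, , s$slice_index] <- pred })
    halves[[s$side]] <- h
  }
  merge_bilateral(halves$left, halves$right)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON plus a per-patient CSV
#' (`<path>.per_patient.csv`, columns `patient_id, dsc`) suitable for
#' violin-style plotting.
#'
#' @param report an [evaluate()] result.
#' @param path JSON destination.
#' @return the JSON path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(list(mode = report$mode, median_dsc = report$median_dsc,
                            per_patient_dsc = as.list(report$per_patient_dsc)),
                       path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(patient_id = names(report$per_patient_dsc),
                              dsc = unname(report$per_patient_dsc)),
                   paste0(path, ".per_patient.csv"), row.names = FALSE)
  invisible(path)
}

#' DSC ranking table across methods
#'
#' For each patient the methods are ranked by DSC (descending, competition
#' ranking: ties share the better position and the next position is
#' skipped); the table reports, per method, the percentage of patients at
#' each position.
#'
#' @param per_patient_scores named list: method -> named numeric vector of
#'   per-patient DSC; all methods must cover the same patients.
#' @return matrix (methods x positions) of percentages; rows sum to 100.
#' @export
ranking_table <- function(per_patient_scores) {
  if (length(per_patient_scores) < 2L)
    stop("at least two methods are required", call. = FALSE)
  methods <- names(per_patient_scores)
  pats <- sort(names(per_patient_scores[[1L]]))
  for (m in methods)
    if (!identical(sort(names(per_patient_scores[[m]])), pats))
      stop("method '", m, "' covers a different patient set", call. = FALSE)
  n_m <- length(methods)
  counts <- matrix(0L, n_m, n_m, dimnames = list(methods, paste0("rank", seq_len(n_m))))
  for (p in pats) {
    scores <- vapply(per_patient_scores, function(v) v[[p]], 0)
    r <- rank(-scores, ties.method = "min")
    for (i in seq_len(n_m)) counts[i, r[i]] <- counts[i, r[i]] + 1L
  }
  100 * counts / length(pats)
}
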