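#' Modified U-Net architecture specification
#'
#' The segmentation network is a U-shaped encoder/decoder with, per level and
#' side, two 3x3 stride-1 convolutions each followed by ReLU and then batch
#' normalization (BN deliberately *after* the activation), 2x2 stride-2
#' max-pooling between encoder levels, 2x2 up-convolutions whose outputs are
#' concatenated with the same-level encoder feature map, and a final 1x1
#' convolution to a single channel with sigmoid output. All convolutions use
#' size-preserving zero padding, so the output mask has the input's spatial
#' shape. Filters double per level from `base_filters`.
#'
#' @param input_size `(H, W)` pixels; both divisible by `2^(levels - 1)`.
#' @param in_channels input channels (3 for 3TP slices).
#' @param levels depth of the U (default 5, L1..L5).
#' @param base_filters filters at the top level; 32 reproduces the ~7.7 M
#'   parameter budget of the reference architecture (64 would give ~31 M).
#' @return a `model_spec`.
#' @export
model_spec <- function(input_size = c(128L, 128L), in_channels = 3L,
                       levels = 5L, base_filters = 32L) {
  stopifnot(length(input_size) == 2L, levels >= 1L, base_filters >= 1L,
            in_channels >= 1L)
  gran <- 2L^(levels - 1L)
  if (any(input_size %% gran != 0L))
    stop("input_size must be divisible by 2^(levels-1) = ", gran, call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 out_channels = 1L),
            class = "model_spec")
}

#' Training configuration
#'
#' Optimization follows the reference protocol: ADAM with `beta1 = 0.9`,
#' `beta2 = 0.999`, learning rate `1e-4`, 20 training eras; convolution
#' weights drawn from `N(0, 2 / (fan_in + fan_out))` and all convolution
#' biases set to the constant 0.1.
#'
#' @param learning_rate ADAM step size.
#' @param beta1,beta2 ADAM moment decays.
#' @param eras number of training eras (>= 1).
#' @param batch_size samples per gradient step.
#' @param threshold probability binarization threshold.
#' @param seed integer seed for initialization and scheduling.
#' @param bn_momentum running-statistics update rate.
#' @return a `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            eras = 20L, batch_size = 8L, threshold = 0.5,
                            seed = 0L, bn_momentum = 0.1) {
  stopifnot(learning_rate > 0, eras >= 1, batch_size >= 1,
            threshold > 0, threshold < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eras = as.integer(eras), batch_size = as.integer(batch_size),
                 threshold = threshold, seed = as.integer(seed),
                 bn_momentum = bn_momentum, adam_eps = 1e-8, bn_eps = 1e-5),
            class = "training_config")
}

# Enumerate every trainable tensor of a spec: name -> dim vector.
unet_layer_dims <- function(spec) {
  f <- spec$base_filters * 2L^(seq_len(spec$levels) - 1L)
  dims <- list()
  add_block <- function(dims, prefix, cin, cout) {
    dims[[paste0(prefix, "_conv1_w")]] <- c(3L, 3L, cin, cout)
    dims[[paste0(prefix, "_conv1_b")]] <- cout
    dims[[paste0(prefix, "_bn1_gamma")]] <- cout
    dims[[paste0(prefix, "_bn1_beta")]] <- cout
    dims[[paste0(prefix, "_conv2_w")]] <- c(3L, 3L, cout, cout)
    dims[[paste0(prefix, "_conv2_b")]] <- cout
    dims[[paste0(prefix, "_bn2_gamma")]] <- cout
    dims[[paste0(prefix, "_bn2_beta")]] <- cout
    dims
  }
  cin <- spec$in_channels
  for (l in seq_len(spec$levels)) {
    dims <- add_block(dims, sprintf("enc%d", l), cin, f[l])
    cin <- f[l]
  }
  for (l in rev(seq_len(spec$levels - 1L))) {
    dims[[sprintf("dec%d_up_w", l)]] <- c(2L, 2L, f[l + 1L], f[l])
    dims[[sprintf("dec%d_up_b", l)]] <- f[l]
    dims <- add_block(dims, sprintf("dec%d", l), 2L * f[l], f[l])
  }
  dims[["out_w"]] <- c(1L, 1L, f[1L], 1L)
  dims[["out_b"]] <- 1L
  dims
}

#' Build an executable model
#'
#' Allocates all parameter tensors (convolution weights zero until
#' [initialize_weights()] is called; BN scale 1, shift 0) and the BN running
#' statistics.
#'
#' @param spec a [model_spec()].
#' @return a `unet_model` list with `spec`, `params`, `bn_state`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  dims <- unet_layer_dims(spec)
  params <- lapply(names(dims), function(nm) {
    d <- dims[[nm]]
    v <- if (grepl("_gamma$", nm)) rep(1, d) else
      if (length(d) == 1L) rep(0, d) else array(0, dim = d)
    v
  })
  names(params) <- names(dims)
  bn_names <- grep("_gamma$", names(dims), value = TRUE)
  bn_state <- list()
  for (nm in bn_names) {
    base <- sub("_gamma$", "", nm)
    bn_state[[paste0(base, "_rmean")]] <- rep(0, dims[[nm]])
    bn_state[[paste0(base, "_rvar")]] <- rep(1, dims[[nm]])
  }
  structure(list(spec = spec, params = params, bn_state = bn_state),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d levels, base %d, input %dx%dx%d -> 1 channel, %s parameters\n",
              x$spec$levels, x$spec$base_filters, x$spec$input_size[1],
              x$spec$input_size[2], x$spec$in_channels,
              format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count
#'
#' Sums every trainable tensor (convolution and up-convolution weights and
#' biases, BN scale and shift; running statistics are not trainable). The
#' default spec lands at ~7.77 M parameters.
#'
#' @param spec a [model_spec()] (or a built `unet_model`).
#' @return integer count.
#' @export
count_parameters <- function(spec) {
  if (inherits(spec, "unet_model"))
    return(sum(vapply(spec$params, length, 1L)))
  sum(vapply(unet_layer_dims(spec), prod, 1))
}

#' Initialize network weights
#'
#' Convolution and up-convolution weights are drawn from
#' `N(0, 2 / (fan_in + fan_out))` with `fan = k * k * channels`; every
#' convolution bias is set to the constant 0.1; BN scale/shift reset to 1/0.
#' Deterministic given `config$seed`.
#'
#' @param model a [build_model()] result.
#' @param config a [training_config()] (its `seed` is used).
#' @return the initialized model.
#' @export
initialize_weights <- function(model, config = training_config()) {
  stopifnot(inherits(model, "unet_model"))
  with_seed(config$seed, {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      if (grepl("_w$", nm)) {
        d <- dim(p)
        fan_in <- d[1] * d[2] * d[3]
        fan_out <- d[1] * d[2] * d[4]
        model$params[[nm]] <- array(rnorm(length(p), 0, sqrt(2 / (fan_in + fan_out))),
                                    dim = d)
      } else if (grepl("_b$", nm)) {
        model$params[[nm]] <- rep(0.1, length(p))
      } else if (grepl("_gamma$", nm)) {
        model$params[[nm]] <- rep(1, length(p))
      } else if (grepl("_beta$", nm)) {
        model$params[[nm]] <- rep(0, length(p))
      }
    }
  })
  for (nm in names(model$bn_state))
    model$bn_state[[nm]] <- if (grepl("_rvar$", nm))
      rep(1, length(model$bn_state[[nm]])) else rep(0, length(model$bn_state[[nm]]))
  model
}

# channel concatenation / split on (H, W, C, N) tensors
.concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# conv -> ReLU -> BN block forward; returns y + cache + updated model
.crb_fwd <- function(model, prefix, j, x, training, cfg) {
  p <- model$params
  ck <- sprintf("%s_conv%d", prefix, j)
  bk <- sprintf("%s_bn%d", prefix, j)
  a <- nn_conv2d_fwd(x, p[[paste0(ck, "_w")]], p[[paste0(ck, "_b")]])
  r <- nn_relu(a)
  cache <- list(x = x, a = a, r = r)
  if (training) {
    res <- nn_bn_fwd(r, p[[paste0(bk, "_gamma")]], p[[paste0(bk, "_beta")]], cfg$bn_eps)
    cache$mean <- res$mean
    cache$var <- res$var
    mom <- cfg$bn_momentum
    model$bn_state[[paste0(bk, "_rmean")]] <-
      (1 - mom) * model$bn_state[[paste0(bk, "_rmean")]] + mom * res$mean
    model$bn_state[[paste0(bk, "_rvar")]] <-
      (1 - mom) * model$bn_state[[paste0(bk, "_rvar")]] + mom * res$var
    y <- res$y
  } else {
    y <- nn_bn_infer(r, p[[paste0(bk, "_gamma")]], p[[paste0(bk, "_beta")]],
                     model$bn_state[[paste0(bk, "_rmean")]],
                     model$bn_state[[paste0(bk, "_rvar")]], cfg$bn_eps)
  }
  list(y = y, cache = cache, model = model)
}

# reverse of .crb_fwd; accumulates parameter grads into `grads`
.crb_bwd <- function(model, prefix, j, cache, gy, grads, cfg) {
  p <- model$params
  ck <- sprintf("%s_conv%d", prefix, j)
  bk <- sprintf("%s_bn%d", prefix, j)
  bn <- nn_bn_bwd(cache$r, p[[paste0(bk, "_gamma")]], cache$mean, cache$var,
                  gy, cfg$bn_eps)
  grads[[paste0(bk, "_gamma")]] <- bn$ggamma
  grads[[paste0(bk, "_beta")]] <- bn$gbeta
  ga <- nn_relu_bwd(bn$gx, cache$a)
  cv <- nn_conv2d_bwd(cache$x, p[[paste0(ck, "_w")]], ga)
  grads[[paste0(ck, "_w")]] <- cv$gw
  grads[[paste0(ck, "_b")]] <- cv$gb
  list(gx = cv$gx, grads = grads)
}

#' Forward pass
#'
#' @param model a `unet_model`.
#' @param x input tensor `(H, W, in_channels, N)` with `H`, `W` divisible by
#'   `2^(levels-1)`.
#' @param training use batch statistics and build a backward cache.
#' @param config a [training_config()] (BN constants).
#' @return list with `prob` `(H, W, 1, N)`, `cache` (when training), and the
#'   (possibly BN-updated) `model`.
#' @export
unet_forward <- function(model, x, training = FALSE, config = training_config()) {
  stopifnot(inherits(model, "unet_model"), length(dim(x)) == 4L)
  gran <- 2L^(model$spec$levels - 1L)
  if (any(dim(x)[1:2] %% gran != 0L))
    stop("input spatial dims must be divisible by ", gran, call. = FALSE)
  L <- model$spec$levels
  cache <- list()
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    for (j in 1:2) {
      r <- .crb_fwd(model, sprintf("enc%d", l), j, h, training, config)
      model <- r$model
      cache[[sprintf("enc%d_%d", l, j)]] <- r$cache
      h <- r$y
    }
    if (l < L) {
      skips[[l]] <- h
      pl <- nn_maxpool_fwd(h)
      cache[[sprintf("pool%d", l)]] <- list(idx = pl$idx, xdim = dim(h))
      h <- pl$y
    }
  }
  for (l in rev(seq_len(L - 1L))) {
    up <- nn_upconv_fwd(h, model$params[[sprintf("dec%d_up_w", l)]],
                        model$params[[sprintf("dec%d_up_b", l)]])
    cache[[sprintf("dec%d_up", l)]] <- list(x = h, ca = dim(skips[[l]])[3])
    h <- .concat_c(skips[[l]], up)
    for (j in 1:2) {
      r <- .crb_fwd(model, sprintf("dec%d", l), j, h, training, config)
      model <- r$model
      cache[[sprintf("dec%d_%d", l, j)]] <- r$cache
      h <- r$y
    }
  }
  cache$out <- list(x = h)
  logits <- nn_conv2d_fwd(h, model$params$out_w, model$params$out_b)
  prob <- 1 / (1 + exp(-logits))
  cache$prob <- prob
  list(prob = prob, cache = if (training) cache, model = model)
}

#' Backward pass
#'
#' @param model a `unet_model`.
#' @param cache forward cache from `unet_forward(training = TRUE)`.
#' @param gprob gradient of the loss w.r.t. the probability output.
#' @param config a [training_config()].
#' @return named list of parameter gradients.
#' @export
unet_backward <- function(model, cache, gprob, config = training_config()) {
  L <- model$spec$levels
  grads <- list()
  glogits <- gprob * cache$prob * (1 - cache$prob)
  cv <- nn_conv2d_bwd(cache$out$x, model$params$out_w, glogits)
  grads$out_w <- cv$gw
  grads$out_b <- cv$gb
  gh <- cv$gx
  gskips <- vector("list", L)
  for (l in seq_len(L - 1L)) {          # reverse of decoder order
    for (j in 2:1) {
      r <- .crb_bwd(model, sprintf("dec%d", l), j, cache[[sprintf("dec%d_%d", l, j)]],
                    gh, grads, config)
      grads <- r$grads
      gh <- r$gx
    }
    upc <- cache[[sprintf("dec%d_up", l)]]
    ca <- upc$ca
    gskips[[l]] <- gh[, , seq_len(ca), , drop = FALSE]
    gup <- gh[, , (ca + 1L):dim(gh)[3], , drop = FALSE]
    uv <- nn_upconv_bwd(upc$x, model$params[[sprintf("dec%d_up_w", l)]], gup)
    grads[[sprintf("dec%d_up_w", l)]] <- uv$gw
    grads[[sprintf("dec%d_up_b", l)]] <- uv$gb
    gh <- uv$gx
  }
  for (l in rev(seq_len(L))) {
    for (j in 2:1) {
      r <- .crb_bwd(model, sprintf("enc%d", l), j, cache[[sprintf("enc%d_%d", l, j)]],
                    gh, grads, config)
      grads <- r$grads
      gh <- r$gx
    }
    if (l > 1L) {
      pl <- cache[[sprintf("pool%d", l - 1L)]]
      gh <- nn_maxpool_bwd(gh, pl$idx, pl$xdim) + gskips[[l - 1L]]
    }
  }
  grads
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` over voxel counts; two empty masks score 1
#' (a healthy slice predicted healthy is a perfect outcome).
#'
#' @param pred_mask,gt_mask binary arrays of identical shape.
#' @return fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)) &&
      length(pred_mask) != length(gt_mask))
    stop("mask shapes differ", call. = FALSE)
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1)))
    stop("masks must be binary {0,1}", call. = FALSE)
  s <- sum(pred_mask) + sum(gt_mask)
  if (s == 0) return(1)
  2 * sum(pred_mask * gt_mask) / s
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + smooth) / (sum(p) + sum(g) + smooth)`, computed over
#' the whole batch (summed counts, not per-image averages). With binary
#' probabilities and `smooth = 0` this equals `1 - dice_coefficient()`,
#' including the both-empty case, which is defined as its `smooth -> 0`
#' limit (loss 0).
#'
#' @param probabilities array of values in `[0, 1]`.
#' @param gt_mask binary array of the same shape.
#' @param smooth smoothing constant (default 1) keeping the loss defined on
#'   empty masks and its gradient bounded.
#' @return scalar loss.
#' @export
dice_loss <- function(probabilities, gt_mask, smooth = 1) {
  if (length(probabilities) != length(gt_mask))
    stop("shape mismatch", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  num <- 2 * sum(probabilities * gt_mask) + smooth
  den <- sum(probabilities) + sum(gt_mask) + smooth
  if (den == 0) return(0)      # smooth = 0 and both empty: the limit is 0
  1 - num / den
}

# loss and its gradient w.r.t. probabilities (batch-level soft Dice)
.dice_loss_grad <- function(prob, gt, smooth = 1) {
  num <- 2 * sum(prob * gt) + smooth
  den <- sum(prob) + sum(gt) + smooth
  list(loss = 1 - num / den, grad = -(2 * gt * den - num) / den^2)
}

#' Binarize a probability map
#'
#' @param probability_map array of values in `[0, 1]`.
#' @param threshold cut point; the comparison is `>=`.
#' @return binary array of the same shape.
#' @export
binarize <- function(probability_map, threshold = 0.5) {
  if (any(probability_map < 0 | probability_map > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  out <- (probability_map >= threshold) * 1
  if (!is.null(dim(probability_map))) dim(out) <- dim(probability_map)
  out
}

# ---- ADAM -------------------------------------------------------------

adam_state <- function(model) {
  zeros <- lapply(model$params, function(p)
    if (is.null(dim(p))) rep(0, length(p)) else array(0, dim = dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(model, grads, state, cfg) {
  state$t <- state$t + 1L
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    upd <- nn_adam(model$params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]],
                   cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$adam_eps, c1, c2)
    state$m[[nm]] <- upd$m
    state$v[[nm]] <- upd$v
    model$params[[nm]] <- upd$p
  }
  list(model = model, state = state)
}

#' One training step
#'
#' Forward (training mode), batch-level soft Dice loss, backward, ADAM
#' update; BN running statistics are refreshed as a side effect.
#'
#' @param model a `unet_model`.
#' @param opt_state an optimizer state from `adam_state()` internals (pass
#'   `NULL` on the first call).
#' @param x input tensor `(H, W, C, N)`.
#' @param gt binary target tensor `(H, W, 1, N)`.
#' @param config a [training_config()].
#' @return list `model`, `opt_state`, `loss`.
#' @export
unet_train_step <- function(model, opt_state, x, gt, config = training_config()) {
  if (is.null(opt_state)) opt_state <- adam_state(model)
  fw <- unet_forward(model, x, training = TRUE, config = config)
  lg <- .dice_loss_grad(fw$prob, gt)
  grads <- unet_backward(fw$model, fw$cache, lg$grad, config)
  upd <- adam_step(fw$model, grads, opt_state, config)
  list(model = upd$model, opt_state = upd$state, loss = lg$loss)
}

#' Predict probability maps
#'
#' Inference-mode forward pass (BN running statistics).
#'
#' @param model a `unet_model`.
#' @param x input tensor `(H, W, C, N)`.
#' @return probability tensor `(H, W, 1, N)`.
#' @export
unet_predict <- function(model, x) {
  unet_forward(model, x, training = FALSE)$prob
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialization of the parameters and BN
#' statistics plus a human-readable JSON sidecar describing the
#' architecture (`<path>.spec.json`).
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(params = model$params, bn_state = model$bn_state,
               spec = unclass(model$spec)), path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- readRDS(path)
  spec <- do.call(model_spec, raw$spec[c("input_size", "in_channels",
                                         "levels", "base_filters")])
  model <- build_model(spec)
  stopifnot(identical(sort(names(model$params)), sort(names(raw$params))))
  model$params <- raw$params
  model$bn_state <- raw$bn_state
  model
}

#' Segment a probability map into a result object
#'
#' @param probability_map array in `[0, 1]`.
#' @param threshold binarization fraction.
#' @return a `segmentation_result` with `probability_map`, `binary_mask`,
#'   `threshold`.
#' @export
segmentation_result <- function(probability_map, threshold = 0.5) {
  structure(list(probability_map = probability_map,
                 binary_mask = binarize(probability_map, threshold),
                 threshold = threshold),
            class = "segmentation_result")
}
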