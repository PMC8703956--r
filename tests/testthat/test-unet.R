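test_that("the default architecture lands at ~7.7 M parameters", {
  n <- count_parameters(model_spec())
  expect_gte(n, 7.6e6)
  expect_lte(n, 7.9e6)
  expect_identical(n, closed_form_params(3, 5, 32))
})

test_that("count_parameters equals the closed form and the built model", {
  set.seed(6)
  for (rep in 1:5) {
    levels <- sample(1:4, 1)
    base <- sample(c(2, 4, 8), 1)
    in_ch <- sample(1:3, 1)
    gran <- 2^(levels - 1)
    spec <- model_spec(c(8 * gran, 8 * gran), in_ch, levels, base)
    expect_identical(count_parameters(spec),
                     closed_form_params(in_ch, levels, base))
    model <- build_model(spec)
    expect_identical(count_parameters(model), as.integer(count_parameters(spec)))
  }
  # degenerate single-level net: two 3x3 convs + BNs + 1x1 output, by hand
  s1 <- model_spec(c(4, 4), 2, 1, 3)
  expect_identical(count_parameters(s1),
                   (9 * 2 * 3 + 3) + 6 + (9 * 3 * 3 + 3) + 6 + (3 + 1))
  # conv-dominated scaling: doubling base multiplies the count by ~4
  r <- count_parameters(model_spec(c(32, 32), 3, 3, 32)) /
    count_parameters(model_spec(c(32, 32), 3, 3, 16))
  expect_gt(r, 3.5); expect_lt(r, 4.3)
})

test_that("outputs preserve the input spatial shape", {
  spec <- model_spec(c(32, 16), 3, 3, 4)
  model <- initialize_weights(build_model(spec), training_config(seed = 1))
  x <- array(rnorm(32 * 16 * 3 * 2), dim = c(32, 16, 3, 2))
  p <- unet_predict(model, x)
  expect_identical(dim(p), c(32L, 16L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))
  expect_error(model_spec(c(30, 32), 3, 3, 4), "divisible")
  expect_error(unet_forward(model, array(0, dim = c(10, 10, 3, 1))), "divisible")
})

test_that("initialization follows the stated distribution", {
  spec <- model_spec(c(16, 16), 3, 2, 16)
  cfg <- training_config(seed = 123)
  model <- initialize_weights(build_model(spec), cfg)
  for (nm in grep("_b$", names(model$params), value = TRUE))
    expect_true(all(model$params[[nm]] == 0.1))       # every bias exactly 0.1
  # empirical variance of a large conv within 10% of 2/(fan_in + fan_out)
  w <- model$params$enc2_conv2_w                       # 3x3x32x32: 9216 draws
  d <- dim(w)
  expect_equal(var(as.vector(w)), 2 / (9 * d[3] + 9 * d[4]), tolerance = 0.1)
  expect_lt(abs(mean(w)), 0.01)
  # determinism
  model2 <- initialize_weights(build_model(spec), cfg)
  expect_identical(model$params, model2$params)
})

test_that("backprop matches finite differences through every layer type", {
  set.seed(8)
  spec <- model_spec(c(8, 8), 2, 2, 3)
  cfg <- training_config(seed = 7)
  model <- initialize_weights(build_model(spec), cfg)
  x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  gt <- array(rbinom(8 * 8 * 2, 1, 0.3), dim = c(8, 8, 1, 2))
  fw <- unet_forward(model, x, training = TRUE, config = cfg)
  lg <- tracerseg:::.dice_loss_grad(fw$prob, gt)
  grads <- unet_backward(fw$model, fw$cache, lg$grad, cfg)
  loss_at <- function(m) dice_loss(unet_forward(m, x, TRUE, cfg)$prob, gt)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (i in sample(length(grads[[nm]]), min(2, length(grads[[nm]])))) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mn <- model; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) /
                  max(1e-6, abs(num) + abs(grads[[nm]][i])), 1e-4)
    }
  }
})

test_that("Dice coefficient matches a brute-force voxel loop", {
  # voxel-loop oracle
  oracle <- function(a, b) {
    inter <- 0; na <- 0; nb <- 0
    for (i in seq_along(a)) {
      if (a[i] == 1 && b[i] == 1) inter <- inter + 1
      na <- na + a[i]; nb <- nb + b[i]
    }
    if (na + nb == 0) 1 else 2 * inter / (na + nb)
  }
  expect_identical(dice_coefficient(array(0, c(2, 2)), array(0, c(2, 2))), 1)
  a <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)
  expect_identical(dice_coefficient(a, b), 0.6)        # 2*3 / (4+6)
  expect_identical(dice_coefficient(c(1, 0), c(0, 1)), 0)
  set.seed(9)
  for (rep in 1:1000) {
    n <- sample(4:40, 1)
    x <- rbinom(n, 1, runif(1)); y <- rbinom(n, 1, runif(1))
    d <- dice_coefficient(x, y)
    expect_identical(d, oracle(x, y))
    expect_identical(d, dice_coefficient(y, x))        # symmetry
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(dice_coefficient(c(1, 0), c(0.5, 1)), "binary")
})

test_that("soft Dice loss agrees with 1 - DSC on binary inputs", {
  set.seed(12)
  for (rep in 1:50) {
    p <- array(rbinom(64, 1, 0.4), dim = c(8, 8))
    g <- array(rbinom(64, 1, 0.4), dim = c(8, 8))
    expect_equal(dice_loss(p, g, smooth = 0) + dice_coefficient(p, g), 1,
                 tolerance = 1e-12)
  }
  # plug-in arithmetic: p = 0, |gt| = 5, smooth 1 -> 1 - 1/6
  g <- c(rep(1, 5), rep(0, 5))
  expect_equal(dice_loss(rep(0, 10), g, smooth = 1), 1 - 1 / 6)
  # moving uniform mass from background onto gt pixels decreases the loss
  losses <- vapply(seq(0, 1, by = 0.1), function(a)
    dice_loss(ifelse(g == 1, a, 1 - a), g), 0)
  expect_true(all(diff(losses) < 0))
  expect_error(dice_loss(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("binarize uses the >= 0.5 convention", {
  expect_identical(binarize(c(0.49, 0.51)), c(0, 1))
  expect_identical(binarize(array(0.5, c(2, 2))), array(1, c(2, 2)))
  set.seed(13)
  p <- runif(200)
  expect_identical(binarize(p, 0.3), vapply(p, function(v) (v >= 0.3) * 1, 0))
  res <- segmentation_result(array(p[1:4], c(2, 2)), 0.5)
  expect_identical(res$binary_mask, binarize(res$probability_map, 0.5))
})

test_that("training steps are deterministic and reduce the loss", {
  set.seed(14)
  spec <- model_spec(c(16, 16), 3, 2, 4)
  cfg <- training_config(seed = 3, learning_rate = 1e-3)
  x <- array(rnorm(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  gt <- array(0, dim = c(16, 16, 1, 4))
  gt[5:10, 5:10, 1, ] <- rbinom(36 * 4, 1, 0.8)
  run <- function() {
    m <- initialize_weights(build_model(spec), cfg)
    st <- list(model = m, opt_state = NULL)
    losses <- c()
    for (i in 1:30) {
      st <- unet_train_step(st$model, st$opt_state, x, gt, cfg)
      losses <- c(losses, st$loss)
    }
    losses
  }
  l1 <- run(); l2 <- run()
  expect_identical(l1, l2)                            # same-seed determinism
  expect_lt(mean(tail(l1, 5)), mean(head(l1, 5)))     # optimization works
})

test_that("model checkpoints round-trip with a JSON spec sidecar", {
  spec <- model_spec(c(16, 16), 3, 2, 4)
  model <- initialize_weights(build_model(spec), training_config(seed = 21))
  x <- array(rnorm(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  p1 <- unet_predict(model, x)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  side <- jsonlite::read_json(paste0(path, ".spec.json"), simplifyVector = TRUE)
  expect_identical(side$base_filters, 4L)
  back <- load_model(path)
  expect_identical(unet_predict(back, x), p1)
  unlink(c(path, paste0(path, ".spec.json")))
})
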