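# Shared miniature phantoms and tensors used across test files.

# Small but realistic bilateral phantom: 12 slices of 32 x 64, one lesion.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 2L, shape = c(12L, 32L, 64L),
         spacing_mm = c(2, 1.45, 1.45), lesions_per_patient = c(1L, 1L),
         lesion_radius_mm = c(4, 6), noise_sigma = 2, seed = 101L),
    list(...))
  do.call(phantom_config, args)
}

# Study whose slices are 16 x 16 after the bilateral split (fast U-Net I/O).
net_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 4L, shape = c(8L, 16L, 32L),
         spacing_mm = c(2, 1.45, 1.45), lesions_per_patient = c(1L, 1L),
         lesion_radius_mm = c(3, 4.5), noise_sigma = 2, seed = 202L),
    list(...))
  do.call(phantom_config, args)
}

# Labeled, masked, per-study 3TP slices of a cohort, concatenated.
cohort_slices <- function(config) {
  out <- list()
  for (st in generate_cohort(config))
    out <- c(out, extract_3tp_dataset(apply_breast_mask(st, st$breast_mask)))
  out
}

slice_patients <- function(slices) vapply(slices, function(s) s$patient_id, "")
slice_labels <- function(slices) vapply(slices, function(s) s$label, "")

random_binary <- function(dims, p = 0.3) {
  array(rbinom(prod(dims), 1, p), dim = dims)
}

# closed-form parameter count, written independently of unet_layer_dims():
# per level l with f_l = base * 2^(l-1) filters, two 3x3 convs + BN pairs per
# side, 2x2 up-convs, and a final 1x1 conv to one channel.
closed_form_params <- function(in_ch, levels, base) {
  f <- base * 2^(seq_len(levels) - 1)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  bn <- function(c) 2 * c
  total <- 0
  cin <- in_ch
  for (l in seq_len(levels)) {
    total <- total + conv(3, cin, f[l]) + bn(f[l]) + conv(3, f[l], f[l]) + bn(f[l])
    cin <- f[l]
  }
  for (l in seq_len(levels - 1)) {
    total <- total + (2 * 2 * f[l + 1] * f[l] + f[l]) +      # up-conv
      conv(3, 2 * f[l], f[l]) + bn(f[l]) + conv(3, f[l], f[l]) + bn(f[l])
  }
  total + conv(1, f[1], 1)
}
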