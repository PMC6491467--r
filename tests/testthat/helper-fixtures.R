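# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; the heavy objects (fine PSF stacks,
# trained networks) are reused across test files.

.fix <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

fx_grid <- function() fx("grid", function() grid_config())

fx_optics <- function(lambda, matched = FALSE) {
  optical_config(sample_index = if (matched) 1.51 else 1.33,
                 emission_wavelength = lambda)
}

# Fine-resolution stacks at the reference configuration (61 slices).
fx_stack <- function(lambda) {
  fx(paste0("stack", lambda), function() {
    prepare_stack_slices(generate_psf_stack(fx_optics(lambda), fx_grid()))
  })
}

fx_model <- function(lambda) {
  fx(paste0("model", lambda), function() {
    build_spline_model(downsample_to_detector(fx_stack(lambda), fx_grid()))
  })
}

# Matched-index stack on a coarser z grid (clean symmetric optics for the
# degeneracy and width-monotonicity properties).
fx_matched_stack <- function() {
  fx("matched_stack", function() {
    gr <- grid_config(z_range = 600, z_step = 100)
    prepare_stack_slices(generate_psf_stack(fx_optics(700, matched = TRUE),
                                            gr))
  })
}

fx_matched_model <- function() {
  fx("matched_model", function() {
    gr <- grid_config(z_range = 600, z_step = 100)
    build_spline_model(downsample_to_detector(fx_matched_stack(), gr))
  })
}

fx_two_optics <- function() list(fx_optics(600), fx_optics(700))
fx_two_stacks <- function() list(fx_stack(600), fx_stack(700))
fx_two_models <- function() list(fx_model(600), fx_model(700))

# Benchmark datasets at the study sizes (classifier 10000/class in the
# 4500-5500 photon band over z +/- 400 nm; matched test sets at 5000 and
# 2000 photons sharing z and sub-pixel offsets).
fx_class_train <- function() {
  fx("class_train", function() {
    generate_benchmark_dataset(
      fx_two_optics(), fx_grid(), 10000,
      photon_distribution = function(n) runif(n, 4500, 5500),
      z_distribution = function(n) runif(n, -400, 400),
      rng_seed = 101, stacks = fx_two_stacks())
  })
}

fx_class_val <- function() {
  fx("class_val", function() {
    generate_benchmark_dataset(
      fx_two_optics(), fx_grid(), 1000,
      photon_distribution = function(n) runif(n, 4500, 5500),
      z_distribution = function(n) runif(n, -400, 400),
      rng_seed = 102, stacks = fx_two_stacks())
  })
}

fx_class_test <- function(photons) {
  fx(paste0("class_test", photons), function() {
    generate_benchmark_dataset(
      fx_two_optics(), fx_grid(), 400,
      photon_distribution = photons,
      z_distribution = function(n) runif(n, -400, 400),
      rng_seed = 103, stacks = fx_two_stacks())
  })
}

fx_color_net <- function() {
  fx("color_net", function() {
    ptr <- dataset_patches(fx_class_train())
    pva <- dataset_patches(fx_class_val())
    net <- build_network(
      network_spec(hidden_layers = c(1024, 1024, 512, 256),
                   task = "classifier", n_classes = 2), seed = 107)
    train_color_network(net, ptr$patches, ptr$truth$color_label,
                        pva$patches, pva$truth$color_label,
                        config = training_config(seed = 113))
  })
}

# Axial regressor for the 700 nm dye, trained over the +/- 580 nm label
# range at the consistent 4500-5500 photon level (6000 molecules).
fx_axial_net <- function() {
  fx("axial_net", function() {
    tr <- generate_benchmark_dataset(
      list(fx_optics(700)), fx_grid(), 6000,
      photon_distribution = function(n) runif(n, 4500, 5500),
      z_distribution = function(n) runif(n, -580, 580),
      rng_seed = 121, stacks = list(fx_stack(700)))
    va <- generate_benchmark_dataset(
      list(fx_optics(700)), fx_grid(), 600,
      photon_distribution = function(n) runif(n, 4500, 5500),
      z_distribution = function(n) runif(n, -580, 580),
      rng_seed = 122, stacks = list(fx_stack(700)))
    ptr <- dataset_patches(tr)
    pva <- dataset_patches(va)
    net <- build_network(network_spec(hidden_layers = c(256, 256, 128, 64),
                                      task = "regressor"), seed = 108)
    train_axial_network(net, ptr$patches, ptr$truth$z_nm, pva$patches,
                        pva$truth$z_nm)
  })
}

# z-grid evaluation set for the axial network (5000 photons).
fx_axial_test <- function() {
  fx("axial_test", function() {
    zrep <- rep(seq(-400, 400, by = 50), each = 40)
    ds <- generate_benchmark_dataset(
      list(fx_optics(700)), fx_grid(), length(zrep),
      photon_distribution = 5000, z_distribution = zrep,
      rng_seed = 123, stacks = list(fx_stack(700)))
    dataset_patches(ds)
  })
}

# Small classifier on synthetic separable inputs (cheap network tests).
fx_patch_matrix <- function(ds) dataset_patches(ds)

# Construct a frame holding rendered molecules plus Poisson background.
fx_frame_with_molecules <- function(centers_px, stack, grid, photons = 5000,
                                    background = 10, z = 0, seed = 1,
                                    size = 64) {
  set.seed(seed)
  frame <- matrix(rpois(size * size, background), size, size)
  roi <- grid$roi_size
  for (i in seq_len(nrow(centers_px))) {
    tr <- emitter_truth(z = z, photons = photons, background = 0)
    img <- render_molecule_image(stack, tr, grid,
                                 rng_seed = seed + i)$image
    r0 <- centers_px[i, 2] - roi / 2 + 1 # y
    c0 <- centers_px[i, 1] - roi / 2 + 1 # x
    frame[r0:(r0 + roi - 1), c0:(c0 + roi - 1)] <-
      frame[r0:(r0 + roi - 1), c0:(c0 + roi - 1)] + img
  }
  frame
}

# Synthetic isotropic Gaussian spot on a constant offset (pixel units).
fx_gauss_frame <- function(size, x0, y0, A, sigma_px, offset = 5) {
  xs <- 0:(size - 1)
  d2 <- outer(xs - y0, xs - x0, function(a, b) a^2 + b^2)
  offset + A * exp(-d2 / (2 * sigma_px^2))
}
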