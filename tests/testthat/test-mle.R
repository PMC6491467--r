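# Maximum-likelihood fitting, dual-initialization z, MLE color calls.

test_that("a noiseless model image is a fixed point of the fit", {
  model <- fx_model(700)
  th <- c(x = 10, y = -20, z = 180, photons = 5000, background = 10)
  mu <- evaluate_psf(model, as.list(th))$mu
  f <- fit_mle(mu, model, init = th)
  expect_true(f$converged)
  expect_lte(f$iterations, 2)
  expect_equal(f$theta_hat, th, tolerance = 1e-6)
})

test_that("perturbed initialization recovers the generating parameters", {
  model <- fx_model(700)
  th <- c(x = -25, y = 15, z = -220, photons = 6000, background = 12)
  mu <- evaluate_psf(model, as.list(th))$mu
  init <- th + c(100, -100, 150, -1200, 3)
  f <- fit_mle(mu, model, init = init)
  expect_true(f$converged)
  expect_lt(abs(f$theta_hat[["x"]] - th[["x"]]), 1)
  expect_lt(abs(f$theta_hat[["y"]] - th[["y"]]), 1)
  expect_lt(abs(f$theta_hat[["z"]] - th[["z"]]), 1)
  expect_lt(abs(f$theta_hat[["photons"]] / th[["photons"]] - 1), 0.01)
})

test_that("the fit never increases the likelihood error", {
  model <- fx_model(600)
  gr <- fx_grid()
  st <- fx_stack(600)
  for (s in 1:8) {
    tr <- emitter_truth(z = runif(1, -350, 350), photons = 5000,
                        background = 10)
    img <- render_molecule_image(st, tr, gr, rng_seed = 200 + s)$image[7:19, 7:19]
    init <- smlmpsf:::mle_init_theta(img, model, init_z = 300)
    L0 <- smlmpsf:::neg_loglik(img, evaluate_psf(model,
      as.list(smlmpsf:::mle_clamp(init, model, 13L)))$mu)
    f <- fit_mle(img, model, init_z = 300)
    expect_lte(f$likelihood_error, L0 + 1e-9)
  }
})

test_that("invalid images are rejected before fitting", {
  model <- fx_model(600)
  expect_error(fit_mle(matrix(-1, 13, 13), model), "nonnegative")
  expect_error(fit_mle(matrix(NA_real_, 13, 13), model), "nonnegative")
})

test_that("dual initialization selects the branch-minimum likelihood", {
  model <- fx_model(700)
  gr <- fx_grid()
  st <- fx_stack(700)
  # deep noiseless emitter
  tr <- emitter_truth(z = 250, photons = 10000, background = 10)
  img <- round(render_molecule_image(st, tr, gr, 1)$expected[7:19, 7:19])
  f <- fit_z_dual_init(img, model)
  br <- attr(f, "branches")
  l_min <- min(vapply(br, function(b) b$likelihood_error, numeric(1)))
  expect_lte(f$likelihood_error - l_min, 1e-9 * (1 + abs(l_min)))
  expect_lt(abs(f$theta_hat[["z"]] - 250), 5)
  expect_identical(attr(f, "n_mle_runs"), 2L)
  # noisy batch: selection invariant holds for every fit
  for (s in 1:10) {
    tr <- emitter_truth(z = runif(1, -300, 300), photons = 5000,
                        background = 10)
    img <- render_molecule_image(st, tr, gr, 300 + s)$image[7:19, 7:19]
    f <- fit_z_dual_init(img, model)
    br <- attr(f, "branches")
    l_min <- min(vapply(br, function(b) b$likelihood_error, numeric(1)))
    expect_lte(f$likelihood_error - l_min, 1e-9 * (1 + abs(l_min)))
  }
})

test_that("symmetric ties break deterministically toward the +z branch", {
  # exactly z-symmetric toy model: Gaussian widening evenly in |z|
  zs <- seq(-300, 300, 100)
  xs <- (-8:8) * 100
  V <- array(0, dim = c(7, 17, 17))
  for (i in 1:7) {
    s <- 130 * (1 + 0.3 * (zs[i] / 300)^2)
    g <- exp(-outer(xs^2, xs^2, "+") / (2 * s^2))
    V[i, , ] <- g / sum(g)
  }
  model <- build_spline_model(
    structure(list(values = V, z_positions = zs, pixel_size = 100,
                   wavelength = 700, resolution = "detector"),
              class = "psf_stack"), normalize = "none")
  th <- list(x = 0, y = 0, z = 0, photons = 8000, background = 10)
  mu <- evaluate_psf(model, th)$mu
  f <- fit_z_dual_init(round(mu), model)
  br <- attr(f, "branches")
  expect_lt(abs(br[["+300"]]$likelihood_error -
                br[["-300"]]$likelihood_error), 1e-3)
  expect_equal(f$init_z, 300)
})

test_that("a zero iteration budget flags non-convergence without error", {
  model <- fx_model(600)
  img <- matrix(10L, 13, 13)
  f <- fit_z_dual_init(img, model, max_iter = 0L)
  expect_false(f$converged)
})

test_that("color classification needs two models and counts four MLE runs", {
  models <- fx_two_models()
  gr <- fx_grid()
  img <- round(render_molecule_image(fx_stack(600),
    emitter_truth(z = 200, photons = 8000, background = 10), gr,
    1)$expected[7:19, 7:19])
  expect_error(classify_color_mle(img, models[1]), "at least two")
  cl <- classify_color_mle(img, models)
  expect_identical(cl$color, 1L)
  expect_identical(cl$n_mle_runs, 4L)
  expect_length(cl$scores, 2)
  img7 <- round(render_molecule_image(fx_stack(700),
    emitter_truth(z = -150, photons = 8000, background = 10), gr,
    1)$expected[7:19, 7:19])
  expect_identical(classify_color_mle(img7, models)$color, 2L)
})

test_that("the z estimator tracks truth with near-unit slope", {
  model <- fx_model(700)
  st <- fx_stack(700)
  gr <- fx_grid()
  zs <- seq(-400, 400, 100)
  mean_hat <- vapply(zs, function(z) {
    zh <- vapply(1:20, function(s) {
      img <- render_molecule_image(st, emitter_truth(z = z, photons = 5000,
                                                     background = 10), gr,
                                   7000 + 100 * z + s)$image[7:19, 7:19]
      fit_z_dual_init(img, model)$theta_hat[["z"]]
    }, numeric(1))
    mean(zh)
  }, numeric(1))
  slope <- stats::coef(stats::lm(mean_hat ~ zs))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("batch fitting returns one localization row per molecule", {
  models <- fx_two_models()
  gr <- fx_grid()
  ds <- generate_benchmark_dataset(fx_two_optics(), gr, 3,
                                   photon_distribution = 8000,
                                   z_distribution = c(-200, 200),
                                   rng_seed = 17, stacks = fx_two_stacks())
  p <- dataset_patches(ds)
  tab <- batch_fit_mle(p$patches, models)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("frame", "x_nm", "y_nm", "z_nm", "photons",
                      "background", "likelihood_error", "color_mle",
                      "converged"))
  expect_type(tab$converged, "logical")
  single <- batch_fit_mle(p$patches[1:2], models[[1]])
  expect_equal(single$color_mle, c(1L, 1L))
})
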