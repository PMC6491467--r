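# Simulator: configs, Gibson-Lanni stacks, binning, rendering, datasets.

test_that("configuration invariants are enforced", {
  expect_error(optical_config(numerical_aperture = 1.6,
                              immersion_index = 1.51))
  expect_error(optical_config(emission_wavelength = 1200))
  expect_error(grid_config(fine_resolution = 7), "integer multiple")
  expect_error(grid_config(patch_size = 12))
  expect_error(grid_config(z_range = 610, z_step = 20))
})

test_that("stack geometry matches the reference grid", {
  st <- fx_stack(700)
  expect_equal(dim(st$values)[1], 61) # 2*600/20 + 1
  expect_equal(st$z_positions, seq(-600, 600, 20))
  expect_true(all(is.finite(st$values)) && all(st$values >= 0))
})

test_that("matched-index stack peaks at the in-focus centre sample", {
  st <- fx_matched_stack()
  n <- dim(st$values)[2]
  ctr <- c(n / 2, n / 2 + 1)
  i0 <- which(st$z_positions == 0)
  expect_equal(max(st$values), max(st$values[i0, ctr, ctr]))
})

test_that("on-axis PSF slices are reflection-symmetric", {
  st <- fx_stack(700)
  det <- downsample_to_detector(st, fx_grid())
  for (i in c(1, 31, 61)) {
    m <- det$values[i, , ]
    expect_lt(max(abs(m - m[nrow(m):1, ])) / max(m), 1e-6)
    expect_lt(max(abs(m - m[, ncol(m):1])) / max(m), 1e-6)
  }
})

test_that("in-focus width grows with emission wavelength", {
  gr <- fx_grid()
  widths <- vapply(c(600, 700), function(l) {
    det <- downsample_to_detector(fx_stack(l), gr)
    m <- det$values[31, , ] / sum(det$values[31, , ])
    xs <- seq_len(ncol(m)) - (ncol(m) + 1) / 2
    sqrt(sum(colSums(m) * xs^2))
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})

test_that("area binning is linear and flux-conserving with floor dims", {
  gr <- fx_grid()
  st <- fx_stack(600)
  det <- downsample_to_detector(st, gr)
  b <- gr$bin_factor
  expect_equal(dim(det$values)[2:3], dim(st$values)[2:3] %/% b)
  covered <- b * (dim(st$values)[2] %/% b)
  for (i in c(1, 31)) {
    expect_lt(abs(sum(det$values[i, , ]) -
                  sum(st$values[i, 1:covered, 1:covered])) /
                sum(det$values[i, , ]), 1e-10)
  }
  # constant field scales by the bin area
  stc <- st
  stc$values <- array(2, dim = c(2, 60, 60))
  stc$slices <- NULL
  detc <- downsample_to_detector(stc, gr)
  expect_equal(as.vector(detc$values), rep(2 * b^2, 2 * 3 * 3))
  # non-integer binning factor is a configuration error
  std <- st
  std$pixel_size <- 7
  expect_error(downsample_to_detector(std, gr), "integer multiple")
})

test_that("rendering matches the photon accounting contract", {
  gr <- fx_grid()
  st <- fx_stack(700)
  r <- render_molecule_image(st, emitter_truth(z = 150, photons = 5000,
                                               background = 10), gr, 1)
  expect_equal(sum(r$expected), 5000 + 10 * gr$roi_size^2, tolerance = 1e-12)
  expect_true(all(r$image >= 0))
  # photons 0, background 0 -> all-zero image for any seed
  for (s in c(1, 99)) {
    r0 <- render_molecule_image(st, emitter_truth(photons = 0,
                                                  background = 0), gr, s)
    expect_true(all(r0$image == 0))
  }
  # same seed identical, different seed different
  a <- render_molecule_image(st, emitter_truth(z = 50), gr, 7)$image
  b <- render_molecule_image(st, emitter_truth(z = 50), gr, 7)$image
  d <- render_molecule_image(st, emitter_truth(z = 50), gr, 8)$image
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(render_molecule_image(st, emitter_truth(z = 900), gr, 1),
               "outside stack range")
})

test_that("rendered counts obey the Poisson mean-variance identity", {
  gr <- fx_grid()
  st <- fx_stack(700)
  tr <- emitter_truth(z = 0, photons = 5000, background = 10)
  n <- 3000
  px <- rbind(c(12, 12), c(12, 13), c(6, 6)) # bright centre and background
  draws <- matrix(0, n, nrow(px))
  for (i in seq_len(n)) {
    img <- render_molecule_image(st, tr, gr, rng_seed = 5000 + i)$image
    draws[i, ] <- img[px]
  }
  mu <- render_molecule_image(st, tr, gr, 1)$expected[px]
  for (j in seq_len(nrow(px))) {
    expect_lt(abs(var(draws[, j]) / mu[j] - 1), 0.08)
    expect_lt(abs(mean(draws[, j]) / mu[j] - 1), 0.05)
  }
})

test_that("benchmark datasets are labeled, counted and reproducible", {
  gr <- fx_grid()
  stacks <- fx_two_stacks()
  opts <- fx_two_optics()
  ds <- generate_benchmark_dataset(opts, gr, 5, rng_seed = 3,
                                   stacks = stacks)
  expect_length(ds$images, 10)
  expect_equal(as.integer(table(ds$truth$color_label)), c(5, 5))
  ds2 <- generate_benchmark_dataset(opts, gr, 5, rng_seed = 3,
                                    stacks = stacks)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$truth, ds2$truth)
  expect_error(generate_benchmark_dataset(list(), gr, 5), "at least one")
  # discrete z distribution reproduces the reference-stack coverage
  zgrid <- seq(-600, 600, 20)
  dsz <- generate_benchmark_dataset(opts[1], gr, 40, z_distribution = zgrid,
                                    rng_seed = 4, stacks = stacks[1])
  expect_true(all(dsz$truth$z_nm %in% zgrid))
})

test_that("defocus broadens the fitted width monotonically", {
  st <- fx_matched_stack()
  gr <- grid_config(z_range = 600, z_step = 100)
  det <- downsample_to_detector(st, gr)
  zs <- c(0, 100, 200, 300, 400)
  w <- vapply(zs, function(z) {
    i <- which(det$z_positions == z)
    m <- det$values[i, 8:20, 8:20]
    f <- smlmpsf:::fit_gauss2d(m * 1e4)
    2 * f$sigma_px * gr$pixel_size
  }, numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("non-convergent quadrature reports an integration error", {
  expect_error(
    smlmpsf:::gl_radial_profile(fx_optics(600), 0, c(0, 100), tol = 1e-14,
                                n_start = 4L, n_max = 8L),
    "did not converge")
})

test_that("stack and dataset round-trip through TIFF/CSV/JSON", {
  gr <- fx_grid()
  ds <- generate_benchmark_dataset(fx_two_optics(), gr, 3, rng_seed = 9,
                                   stacks = fx_two_stacks())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, seed = 9)
  back <- read_dataset(dir)
  expect_equal(back$images, ds$images)
  expect_equal(back$truth$z_nm, ds$truth$z_nm, tolerance = 1e-12)
  st <- downsample_to_detector(fx_stack(600), gr)
  f <- file.path(dir, "stack.tif")
  write_psf_stack_tiff(st, f)
  expect_true(file.exists(f))
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_length(pages, 61)
})
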