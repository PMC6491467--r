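# Rendering noisy single-molecule images from a fine-resolution PSF stack.
#
# Sub-pixel lateral offsets are applied by shifting the fine-resolution
# field (5 nm default granularity) before area-binning to detector pixels,
# so the pixelated image carries genuine sampling jitter rather than
# interpolation of the coarse grid. Axial positions between stack slices
# are linearly interpolated on the fine stack.

#' Attach a per-slice matrix cache to a fine PSF stack
#'
#' Rendering interpolates between two z-slices per image; extracting those
#' slices from the 3D array dominates the cost. This helper precomputes a
#' list of slice matrices so batch rendering reuses them.
#'
#' @param stack A fine-resolution `psf_stack`.
#' @return The same stack with a `slices` element.
#' @export
prepare_stack_slices <- function(stack) {
  if (is.null(stack$slices)) {
    stack$slices <- lapply(seq_len(dim(stack$values)[1]),
                           function(i) stack$values[i, , ])
  }
  stack
}

# n x (n/b) block-indicator matrix for area binning, memoized per size.
.bin_cache <- new.env(parent = emptyenv())
block_indicator <- function(n, b) {
  key <- paste(n, b, sep = "x")
  if (!is.null(.bin_cache[[key]])) return(.bin_cache[[key]])
  m <- matrix(0, n, n %/% b)
  m[cbind(seq_len(n), rep(seq_len(n %/% b), each = b))] <- 1
  .bin_cache[[key]] <- m
  m
}

interp_fine_slice <- function(stack, z) {
  zp <- stack$z_positions
  if (z < zp[1] - 1e-9 || z > zp[length(zp)] + 1e-9) {
    stop(sprintf("z = %g nm outside stack range [%g, %g]", z, zp[1],
                 zp[length(zp)]), call. = FALSE)
  }
  z <- min(max(z, zp[1]), zp[length(zp)])
  i <- findInterval(z, zp, rightmost.closed = TRUE)
  i <- min(i, length(zp) - 1L)
  w <- (z - zp[i]) / (zp[i + 1] - zp[i])
  (1 - w) * stack$values[i, , ] + w * stack$values[i + 1, , ]
}

#' Render one noisy single-molecule image with known ground truth
#'
#' Builds the expected (noiseless) detector image of an emitter described by
#' `truth`: the fine PSF slice at `truth$z` (linear interpolation between
#' stack slices) is shifted laterally by the sub-pixel offset, area-binned
#' to detector pixels, scaled so its sum over the `roi_size^2` window equals
#' `truth$photons`, and offset by the uniform background. The returned image
#' is one Poisson draw per pixel with that expectation.
#'
#' @param stack A fine-resolution `psf_stack`.
#' @param truth An [emitter_truth()]; `x`/`y` are quantized to the fine grid
#'   and must lie within +/- 1.5 pixels.
#' @param grid The [grid_config()] used to build the stack.
#' @param rng_seed Integer seed; the same seed reproduces the image exactly.
#' @return A list with `image` (integer counts, `roi_size` square),
#'   `expected` (the Poisson rate per pixel) and `truth`.
#' @export
render_molecule_image <- function(stack, truth, grid, rng_seed = 1L) {
  stopifnot(inherits(stack, "psf_stack"), identical(stack$resolution, "fine"),
            inherits(truth, "emitter_truth"), inherits(grid, "grid_config"))
  b <- grid$bin_factor
  fr <- grid$fine_resolution
  roi <- grid$roi_size
  n <- dim(stack$values)[2]
  base <- (n - roi * b) / 2
  stopifnot(abs(base - round(base)) < 1e-9)
  base <- as.integer(round(base))
  sx <- as.integer(round(truth$x / fr))
  sy <- as.integer(round(truth$y / fr))
  if (abs(sx) > base || abs(sy) > base) {
    stop("lateral offset exceeds the guard band of the fine stack",
         call. = FALSE)
  }
  rows <- (base - sy + 1L):(base - sy + roi * b)
  cols <- (base - sx + 1L):(base - sx + roi * b)
  # interpolate in z only over the cropped region, then area-bin by a
  # block-indicator matrix product (much faster than per-pixel summation)
  zp <- stack$z_positions
  z <- truth$z
  if (z < zp[1] - 1e-9 || z > zp[length(zp)] + 1e-9) {
    stop(sprintf("z = %g nm outside stack range [%g, %g]", z, zp[1],
                 zp[length(zp)]), call. = FALSE)
  }
  z <- min(max(z, zp[1]), zp[length(zp)])
  i <- min(findInterval(z, zp, rightmost.closed = TRUE), length(zp) - 1L)
  w <- (z - zp[i]) / (zp[i + 1] - zp[i])
  sl <- if (!is.null(stack$slices)) {
    (1 - w) * stack$slices[[i]][rows, cols] +
      w * stack$slices[[i + 1]][rows, cols]
  } else {
    (1 - w) * stack$values[i, rows, cols] +
      w * stack$values[i + 1, rows, cols]
  }
  Bt <- block_indicator(roi * b, b)
  binned <- crossprod(Bt, sl %*% Bt)
  tot <- sum(binned)
  expected <- if (truth$photons > 0 && tot > 0) {
    truth$photons * binned / tot + truth$background
  } else {
    matrix(truth$background, roi, roi)
  }
  set.seed(rng_seed)
  img <- matrix(stats::rpois(length(expected), lambda = expected), roi, roi)
  list(image = img, expected = expected, truth = truth)
}

#' Generate a labeled benchmark dataset of noisy molecule images
#'
#' Renders `n_per_color` images per color class with randomized axial
#' positions, photon counts and (optionally) sub-pixel lateral offsets,
#' recording the full ground truth for every image. All randomness derives
#' from `rng_seed`: truth parameters use the seed itself and image `i` uses
#' an independent substream seeded by `rng_seed + i`, so regeneration is
#' byte-identical.
#'
#' @param optics_per_color List of [optical_config()], one per color class.
#' @param grid A [grid_config()].
#' @param n_per_color Images per class.
#' @param photon_distribution Either a numeric vector of photon operating
#'   points (sampled uniformly with replacement) or a `function(n)` drawing
#'   `n` photon counts. Default mirrors the simulator's operating points
#'   `c(2000, 5000, 10000, 15000)`.
#' @param background Uniform background, photons/pixel.
#' @param z_distribution Either a numeric vector of z values (used in
#'   order if it has one entry per molecule, otherwise sampled with
#'   replacement) or a `function(n)`; default uniform on +/- 400 nm.
#' @param rng_seed Integer master seed.
#' @param subpixel_offsets If `TRUE` (default), lateral offsets are drawn
#'   uniformly within +/- half a pixel; if `FALSE`, emitters sit exactly
#'   between the two central pixel columns/rows of the ROI.
#' @param stacks Optional list of precomputed fine `psf_stack`s matching
#'   `optics_per_color`, to avoid regenerating them.
#' @return A list with `images` (list of count matrices), `truth`
#'   (data.frame: frame, x_nm, y_nm, z_nm, photons, background,
#'   color_label), and `grid`.
#' @export
generate_benchmark_dataset <- function(optics_per_color, grid,
                                       n_per_color,
                                       photon_distribution = c(2000, 5000, 10000, 15000),
                                       background = 10,
                                       z_distribution = function(n) stats::runif(n, -400, 400),
                                       rng_seed = 1L,
                                       subpixel_offsets = TRUE,
                                       stacks = NULL) {
  if (length(optics_per_color) < 1) {
    stop("at least one color class is required", call. = FALSE)
  }
  stopifnot(n_per_color >= 1)
  if (is.null(stacks)) {
    stacks <- lapply(optics_per_color, generate_psf_stack, grid = grid)
  }
  stopifnot(length(stacks) == length(optics_per_color))
  stacks <- lapply(stacks, prepare_stack_slices)
  ncol_cls <- length(optics_per_color)
  ntot <- ncol_cls * n_per_color

  draw <- function(spec, n) {
    if (is.function(spec)) {
      spec(n)
    } else if (length(spec) == 1) {
      rep(spec, n)
    } else if (length(spec) == n) {
      spec # one value per molecule, used in order
    } else {
      spec[sample.int(length(spec), n, replace = TRUE)]
    }
  }
  set.seed(rng_seed)
  labels <- rep(seq_len(ncol_cls), each = n_per_color)
  zs <- draw(z_distribution, ntot)
  ph <- draw(photon_distribution, ntot)
  if (subpixel_offsets) {
    half <- grid$pixel_size / 2
    xs <- stats::runif(ntot, -half, half)
    ys <- stats::runif(ntot, -half, half)
  } else {
    xs <- ys <- rep(0, ntot)
  }
  fr <- grid$fine_resolution
  xs <- round(xs / fr) * fr
  ys <- round(ys / fr) * fr

  images <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    tr <- emitter_truth(x = xs[i], y = ys[i], z = zs[i], photons = ph[i],
                        background = background, color_label = labels[i])
    images[[i]] <- render_molecule_image(stacks[[labels[i]]], tr, grid,
                                         rng_seed = rng_seed + i)$image
  }
  truth <- data.frame(
    frame = seq_len(ntot), x_nm = xs, y_nm = ys, z_nm = zs,
    photons = ph, background = background, color_label = labels
  )
  list(images = images, truth = truth, grid = grid)
}

#' Extract network-ready patches from a benchmark dataset
#'
#' Crops the `patch_size` (default 13x13) window centred on the rounded
#' emitter pixel of each rendered ROI, mirroring how experimental crops are
#' centred on the rounded 2D localization. Residual sub-pixel offsets of the
#' emitter relative to the patch centre are returned for lateral-regression
#' labels.
#'
#' @param dataset Output of [generate_benchmark_dataset()].
#' @return A list with `patches` (list of matrices), `dx_nm`, `dy_nm`
#'   (residual offsets) and the dataset `truth`.
#' @export
dataset_patches <- function(dataset) {
  grid <- dataset$grid
  half <- (grid$patch_size - 1L) / 2L
  roi <- grid$roi_size
  ctr0 <- (roi - 1) / 2 # 0-based emitter reference column for x = 0
  px <- grid$pixel_size
  n <- nrow(dataset$truth)
  patches <- vector("list", n)
  dx <- dy <- numeric(n)
  for (i in seq_len(n)) {
    cx <- ctr0 + dataset$truth$x_nm[i] / px
    cy <- ctr0 + dataset$truth$y_nm[i] / px
    icx <- as.integer(round(cx))
    icy <- as.integer(round(cy))
    patches[[i]] <- dataset$images[[i]][(icy - half + 1L):(icy + half + 1L),
                                        (icx - half + 1L):(icx + half + 1L)]
    dx[i] <- (cx - icx) * px
    dy[i] <- (cy - icy) * px
  }
  list(patches = patches, dx_nm = dx, dy_nm = dy, truth = dataset$truth)
}

#' Write a PSF stack as a multi-page float TIFF
#'
#' Values are rescaled by the stack maximum into `[0, 1]` for storage (the
#' absolute scale of a noiseless stack is a normalization convention, not
#' information).
#'
#' @param stack A `psf_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psf_stack_tiff <- function(stack, path) {
  peak <- max(stack$values)
  pages <- lapply(seq_len(dim(stack$values)[1]),
                  function(i) stack$values[i, , ] / peak)
  tiff::writeTIFF(pages, path, bits.per.sample = 32,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Write a benchmark dataset to disk
#'
#' Writes noisy images as a multi-page 16-bit TIFF, the ground truth as a
#' sidecar CSV (frame, x_nm, y_nm, z_nm, photons, background, color_label)
#' and a JSON file capturing the grid configuration and seed.
#'
#' @param dataset Output of [generate_benchmark_dataset()].
#' @param dir Output directory (created if needed).
#' @param seed The master seed used to create the dataset (echoed to JSON).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(dataset$images, function(m) pmin(m, 65535) / 65535)
  tiff::writeTIFF(pages, file.path(dir, "images.tif"), bits.per.sample = 16,
                  reduce = FALSE, compression = "none")
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$grid)
  cfg$seed <- seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a benchmark dataset written by [write_dataset()]
#'
#' @param dir Directory containing `images.tif`, `truth.csv`, `config.json`.
#' @return A dataset list as produced by [generate_benchmark_dataset()].
#' @export
read_dataset <- function(dir) {
  pages <- tiff::readTIFF(file.path(dir, "images.tif"), all = TRUE)
  images <- lapply(pages, function(m) {
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  grid <- grid_config(z_range = cfg$z_range, z_step = cfg$z_step,
                      fine_resolution = cfg$fine_resolution,
                      pixel_size = cfg$pixel_size, roi_size = cfg$roi_size,
                      patch_size = cfg$patch_size)
  list(images = images, truth = truth, grid = grid)
}
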