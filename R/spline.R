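# Tricubic-spline PSF model.
#
# A reference z-stack is converted to a per-cell tricubic polynomial grid by
# three separable natural-cubic-spline passes (x, then y, then z). Each cell
# holds 64 coefficients C[a,b,c]; the model value at local coordinates
# (tx, ty, tz) in [0,1)^3 is sum C * tx^a ty^b tz^c, which interpolates the
# stack exactly at every knot and is C2 across cell boundaries. Analytic
# first derivatives come from differentiating the polynomial, which is what
# the Poisson MLE and Fisher-information machinery consume.

# Linear operator mapping n knot values (unit spacing) to the (n-1) x 4
# per-interval coefficients of the natural cubic interpolating spline.
# Returned as a ((n-1)*4) x n matrix with polynomial order varying fastest.
nat_spline_op <- function(n) {
  stopifnot(n >= 4)
  # second derivatives M (natural: M_1 = M_n = 0), M = K f
  m <- n - 2L
  A <- diag(4, m)
  if (m > 1) {
    A[cbind(seq_len(m - 1), seq_len(m - 1) + 1)] <- 1
    A[cbind(seq_len(m - 1) + 1, seq_len(m - 1))] <- 1
  }
  B <- matrix(0, m, n)
  for (i in seq_len(m)) {
    B[i, i:(i + 2)] <- c(6, -12, 6)
  }
  K <- rbind(0, solve(A, B), 0) # n x n
  E <- diag(n)
  L <- matrix(0, (n - 1L) * 4L, n)
  for (i in seq_len(n - 1L)) {
    r <- (i - 1L) * 4L
    L[r + 1L, ] <- E[i, ]
    L[r + 2L, ] <- (E[i + 1L, ] - E[i, ]) - (2 * K[i, ] + K[i + 1L, ]) / 6
    L[r + 3L, ] <- K[i, ] / 2
    L[r + 4L, ] <- (K[i + 1L, ] - K[i, ]) / 6
  }
  L
}

#' Build a tricubic-spline PSF model from a reference stack
#'
#' Converts a detector-resolution PSF z-stack into a grid of per-cell
#' tricubic coefficients via separable natural-cubic-spline passes. By
#' default each slice is first normalized to unit sum, so the `photons`
#' fit parameter corresponds to the photon count inside the stack window
#' regardless of z (the same convention the simulator uses when matching
#' the ROI sum to a photon count).
#'
#' @param stack A `psf_stack` (detector resolution) with at least 4 slices
#'   and 4 pixels per lateral axis. The emitter is assumed at the lateral
#'   centre of the stack.
#' @param normalize `"slice_sum"` (default) to normalize each slice to unit
#'   sum, or `"none"` to spline the raw values.
#' @return An object of class `spline_psf`.
#' @export
build_spline_model <- function(stack, normalize = c("slice_sum", "none")) {
  stopifnot(inherits(stack, "psf_stack"))
  normalize <- match.arg(normalize)
  V <- stack$values
  nz <- dim(V)[1]; ny <- dim(V)[2]; nx <- dim(V)[3]
  if (nz < 4 || ny < 4 || nx < 4) {
    stop("stack too small for a tricubic model (need >= 4 knots per axis)",
         call. = FALSE)
  }
  if (normalize == "slice_sum") {
    for (i in seq_len(nz)) {
      s <- sum(V[i, , ])
      if (s <= 0) stop("slice with nonpositive total intensity", call. = FALSE)
      V[i, , ] <- V[i, , ] / s
    }
  }
  Lx <- nat_spline_op(nx); Ly <- nat_spline_op(ny); Lz <- nat_spline_op(nz)

  # pass along x: [z,y,x] -> [xord, xcell, z, y]
  Vx <- matrix(aperm(V, c(3, 1, 2)), nrow = nx)
  A1 <- array(Lx %*% Vx, dim = c(4, nx - 1, nz, ny))
  # pass along y: -> [yord, ycell, xord, xcell, z]
  A1 <- aperm(A1, c(4, 1, 2, 3)) # [y, xord, xcell, z]
  A2 <- array(Ly %*% matrix(A1, nrow = ny), dim = c(4, ny - 1, 4, nx - 1, nz))
  # pass along z: -> [zord, zcell, yord, ycell, xord, xcell]
  A2 <- aperm(A2, c(5, 1, 2, 3, 4)) # [z, yord, ycell, xord, xcell]
  A3 <- array(Lz %*% matrix(A2, nrow = nz),
              dim = c(4, nz - 1, 4, ny - 1, 4, nx - 1))
  # -> [xcell, ycell, zcell, xord, yord, zord], cells with x fastest
  A3 <- aperm(A3, c(6, 4, 2, 5, 3, 1))
  coef <- matrix(A3, nrow = (nx - 1) * (ny - 1) * (nz - 1), ncol = 64)

  structure(
    list(
      coef = coef, nx = nx, ny = ny, nz = nz,
      x0 = -(nx - 1) / 2, y0 = -(ny - 1) / 2,
      z_positions = stack$z_positions,
      z_step = diff(stack$z_positions[1:2]),
      pixel_size = stack$pixel_size,
      wavelength = stack$wavelength,
      normalization = normalize,
      value_floor = 1e-6,
      schema_version = 1L,
      source_stack_id = sprintf("stack-lambda%g-%dz", stack$wavelength,
                                length(stack$z_positions))
    ),
    class = "spline_psf"
  )
}

#' @export
print.spline_psf <- function(x, ...) {
  cat(sprintf(
    "<spline_psf> %d x %d x %d knots, z in [%g, %g] nm (step %g), pixel %g nm, lambda %g nm, norm '%s'\n",
    x$nz, x$ny, x$nx, x$z_positions[1], x$z_positions[x$nz], x$z_step,
    x$pixel_size, x$wavelength, x$normalization
  ))
  invisible(x)
}

# Axis domain (in knot coordinates 1..n) excluding the outer knot shell.
spline_domain <- function(model) {
  list(
    x_px = c(model$x0 + 1, model$x0 + model$nx - 2),
    y_px = c(model$y0 + 1, model$y0 + model$ny - 2),
    z_nm = c(model$z_positions[2], model$z_positions[model$nz - 1])
  )
}

# Evaluate the spline (and optionally the gradient) at arbitrary points
# given in pixel units (x, y, relative to the emitter) and nm (z).
# Vectorized over points. Used by tests and generic prediction; the MLE
# hot path uses eval_psf_patch() below.
spline_eval <- function(model, x_px, y_px, z_nm, deriv = FALSE) {
  n <- max(length(x_px), length(y_px), length(z_nm))
  x_px <- rep_len(x_px, n); y_px <- rep_len(y_px, n); z_nm <- rep_len(z_nm, n)
  gx <- x_px - model$x0 + 1
  gy <- y_px - model$y0 + 1
  gz <- (z_nm - model$z_positions[1]) / model$z_step + 1
  loc <- function(g, nk) {
    i <- pmin(pmax(floor(g), 1), nk - 1)
    list(i = i, t = g - i)
  }
  lx <- loc(gx, model$nx); ly <- loc(gy, model$ny); lz <- loc(gz, model$nz)
  lin <- ((lz$i - 1) * (model$ny - 1) + (ly$i - 1)) * (model$nx - 1) + lx$i
  pw <- function(t) cbind(1, t, t^2, t^3)
  dpw <- function(t) cbind(0, 1, 2 * t, 3 * t^2)
  Bx <- pw(lx$t); By <- pw(ly$t); Bz <- pw(lz$t)
  val <- numeric(n)
  dx <- dy <- dz <- numeric(n)
  for (k in seq_len(n)) {
    b <- as.vector(Bx[k, ] %o% By[k, ] %o% Bz[k, ])
    cf <- model$coef[lin[k], ]
    val[k] <- sum(cf * b)
    if (deriv) {
      dx[k] <- sum(cf * as.vector(dpw(lx$t)[k, ] %o% By[k, ] %o% Bz[k, ]))
      dy[k] <- sum(cf * as.vector(Bx[k, ] %o% dpw(ly$t)[k, ] %o% Bz[k, ]))
      dz[k] <- sum(cf * as.vector(Bx[k, ] %o% By[k, ] %o% dpw(lz$t)[k, ])) /
        model$z_step
    }
  }
  if (deriv) list(value = val, dx = dx, dy = dy, dz = dz) else val
}

#' Predict PSF values from a spline model
#'
#' @param object A `spline_psf` model.
#' @param x_px,y_px Lateral coordinates in pixel units relative to the
#'   emitter.
#' @param z_nm Axial position in nm.
#' @param ... Unused.
#' @return Numeric vector of spline values.
#' @export
predict.spline_psf <- function(object, x_px = 0, y_px = 0, z_nm = 0, ...) {
  spline_eval(object, x_px, y_px, z_nm)
}

#' Expected molecule image and parameter gradients under a spline model
#'
#' Computes the expected pixel values `mu_k = photons * S_k + background`
#' over a square patch centred on a chosen pixel, together with the analytic
#' partial derivatives of every pixel with respect to the five fit
#' parameters (x, y, z, photons, background). `S_k` is the unit-amplitude
#' spline value at pixel `k` for an emitter at `(x, y)` nm from the patch
#' centre and axial position `z` nm. Spline values below the model's value
#' floor are clamped (with zero spatial gradient) so the Poisson likelihood
#' stays finite.
#'
#' @param model A `spline_psf`.
#' @param theta Named list or vector with `x`, `y`, `z` (nm), `photons`,
#'   `background`.
#' @param patch_size Side of the square patch in pixels (odd).
#' @return A list with `mu` (patch_size x patch_size matrix), `S` (unit
#'   spline values), and `grad` (npix x 5 matrix, columns x, y, z, photons,
#'   background, pixel order column-major like `as.vector(mu)`).
#' @export
evaluate_psf <- function(model, theta, patch_size = 13L) {
  theta <- as.list(theta)
  h <- (patch_size - 1L) / 2L
  px <- model$pixel_size
  dom <- spline_domain(model)
  if (theta$z < dom$z_nm[1] || theta$z > dom$z_nm[2]) {
    stop("z outside the spline fit domain", call. = FALSE)
  }
  # knot coordinate of the first patch pixel (all pixels share fractions)
  gx0 <- (-h - theta$x / px) - model$x0 + 1
  gy0 <- (-h - theta$y / px) - model$y0 + 1
  gz <- (theta$z - model$z_positions[1]) / model$z_step + 1
  ix0 <- floor(gx0); tx <- gx0 - ix0
  iy0 <- floor(gy0); ty <- gy0 - iy0
  iz <- min(max(floor(gz), 1L), model$nz - 1L); tz <- gz - iz
  cells_x <- ix0 + 0:(patch_size - 1L)
  cells_y <- iy0 + 0:(patch_size - 1L)
  if (min(cells_x) < 1 || max(cells_x) > model$nx - 1 ||
      min(cells_y) < 1 || max(cells_y) > model$ny - 1) {
    stop("patch extends outside the spline fit domain", call. = FALSE)
  }
  lin <- outer(cells_y, cells_x,
               function(iy, ix) ((iz - 1) * (model$ny - 1) + (iy - 1)) *
                 (model$nx - 1) + ix)
  Cg <- model$coef[as.vector(lin), , drop = FALSE] # npix x 64, y fastest

  bx <- c(1, tx, tx^2, tx^3); dbx <- c(0, 1, 2 * tx, 3 * tx^2)
  by <- c(1, ty, ty^2, ty^3); dby <- c(0, 1, 2 * ty, 3 * ty^2)
  bz <- c(1, tz, tz^2, tz^3); dbz <- c(0, 1, 2 * tz, 3 * tz^2)
  B <- cbind(
    as.vector(bx %o% by %o% bz),
    as.vector(dbx %o% by %o% bz),
    as.vector(bx %o% dby %o% bz),
    as.vector(bx %o% by %o% dbz)
  )
  SV <- Cg %*% B # npix x 4: S, dS/dtx, dS/dty, dS/dtz
  S <- SV[, 1]
  low <- S < model$value_floor
  S[low] <- model$value_floor
  dSx <- SV[, 2] * (-1 / px); dSx[low] <- 0
  dSy <- SV[, 3] * (-1 / px); dSy[low] <- 0
  dSz <- SV[, 4] / model$z_step; dSz[low] <- 0

  mu <- theta$photons * S + theta$background
  grad <- cbind(
    x = theta$photons * dSx,
    y = theta$photons * dSy,
    z = theta$photons * dSz,
    photons = S,
    background = rep(1, length(S))
  )
  list(mu = matrix(mu, patch_size, patch_size),
       S = matrix(S, patch_size, patch_size), grad = grad)
}

#' Fisher information of the Poisson imaging model
#'
#' For expected pixel values `mu_k(theta)` under independent Poisson noise,
#' `I_ij = sum_k (dmu_k/dtheta_i)(dmu_k/dtheta_j) / mu_k`. The matrix is
#' symmetric positive semidefinite by construction.
#'
#' @inheritParams evaluate_psf
#' @return A 5x5 symmetric matrix (parameter order x, y, z, photons,
#'   background).
#' @export
fisher_information <- function(model, theta, patch_size = 13L) {
  ev <- evaluate_psf(model, theta, patch_size)
  mu <- as.vector(ev$mu)
  if (any(mu <= 0)) {
    stop("expected image has nonpositive pixels; model invalid here",
         call. = FALSE)
  }
  G <- ev$grad
  I <- crossprod(G / sqrt(mu))
  (I + t(I)) / 2
}

#' Cramer-Rao lower bounds for the spline PSF model
#'
#' Inverts the Fisher information of the Poisson imaging model and returns
#' the per-parameter lower-bound standard deviations
#' `sqrt(diag(I(theta)^-1))` for (x, y, z, photons, background).
#'
#' @inheritParams evaluate_psf
#' @return Named numeric vector of class `crlb_result` with entries `x`,
#'   `y`, `z` (nm), `photons`, `background`.
#' @export
crlb <- function(model, theta, patch_size = 13L) {
  I <- fisher_information(model, theta, patch_size)
  kappa <- kappa(I, exact = FALSE)
  inv <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(inv) || any(diag(inv) <= 0)) {
    stop(sprintf(
      "Fisher information singular or indefinite (condition number %.3g)",
      kappa), call. = FALSE)
  }
  out <- sqrt(diag(inv))
  names(out) <- c("x", "y", "z", "photons", "background")
  class(out) <- "crlb_result"
  out
}

#' @export
print.crlb_result <- function(x, ...) {
  cat("CRLB standard deviations:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Serialize a spline PSF model
#'
#' Writes a JSON metadata file plus a sibling binary blob of tricubic
#' coefficients (little-endian doubles).
#'
#' @param model A `spline_psf`.
#' @param path Path of the JSON file; the blob is written next to it with
#'   extension `.bin`.
#' @return `path`, invisibly.
#' @export
save_spline_model <- function(model, path) {
  blob <- sub("\\.json$", ".bin", path)
  if (identical(blob, path)) blob <- paste0(path, ".bin")
  meta <- model[setdiff(names(model), "coef")]
  meta$coef_blob <- basename(blob)
  meta$coef_dim <- dim(model$coef)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  con <- file(blob, "wb")
  on.exit(close(con))
  writeBin(as.vector(model$coef), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a spline PSF model written by [save_spline_model()]
#'
#' @param path Path of the JSON metadata file.
#' @return A `spline_psf`.
#' @export
load_spline_model <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  blob <- file.path(dirname(path), meta$coef_blob)
  dims <- meta$coef_dim
  con <- file(blob, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  model <- meta[setdiff(names(meta), c("coef_blob", "coef_dim"))]
  model$coef <- matrix(v, dims[1], dims[2])
  class(model) <- "spline_psf"
  model
}
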