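# Gibson-Lanni stratified-medium scalar diffraction model, particle-scan
# geometry: the focal plane is fixed (focused paraxially on the nominal
# particle depth d0 = `particle_depth`) and the axial coordinate z moves
# the EMITTER, whose depth is d0 + z. This is the situation in SMLM of
# cells, where molecules sit at different heights while the objective stays
# put; the index mismatch then couples axial position and aberration, which
# is exactly the PSF asymmetry the color and z decoders exploit.
#
# Pupil field over the normalized pupil radius rho:
#
#   U(r, z) = int_0^rho_max J0(k r NA rho) exp(i k OPD(rho, z)) rho drho
#   OPD(rho, z) = (d0 + z) * sqrt(n_s^2 - NA^2 rho^2)
#               - d0 * (n_i/n_s) * sqrt(n_i^2 - NA^2 rho^2)
#
# The second term is the immersion-path change from paraxially refocusing
# the stage onto depth d0, so z = 0 is the paraxial focus of the nominal
# depth. rho_max = min(1, n_s/NA): beyond the sample-medium critical angle
# the axial wavevector in the sample is imaginary (supercritical-angle
# fluorescence, out of scope). Matched indices give rho_max = 1,
# OPD = z*sqrt(n^2 - NA^2 rho^2) (+ constant piston), and at z = 0 exactly
# the Airy integral.

# Radial intensity profile by adaptive Gauss-Legendre quadrature over the
# pupil.  Node count doubles until two successive evaluations agree to
# `tol` relative to the profile maximum.
gl_radial_profile <- function(optics, z_emitter, r, tol = 1e-6,
                              n_start = 64L, n_max = 1024L) {
  na <- optics$numerical_aperture
  ni <- optics$immersion_index
  ns <- optics$sample_index
  d <- optics$particle_depth * 1000 # um -> nm
  k <- 2 * pi / optics$emission_wavelength
  rho_max <- min(1, ns / na)

  eval_profile <- function(n_nodes) {
    gq <- pracma::gaussLegendre(n_nodes, 0, rho_max)
    rho <- gq$x
    w <- gq$w
    arg_i <- sqrt(pmax(ni^2 - na^2 * rho^2, 0))
    arg_s <- sqrt(pmax(ns^2 - na^2 * rho^2, 0))
    opd <- (d + z_emitter) * arg_s - d * (ni / ns) * arg_i
    phase <- k * opd
    cw <- w * rho * cos(phase)
    sw <- w * rho * sin(phase)
    bes <- besselJ(outer(r, k * na * rho), 0) # length(r) x n_nodes
    re <- bes %*% cw
    im <- bes %*% sw
    as.numeric(re^2 + im^2)
  }

  n <- n_start
  prof <- eval_profile(n)
  repeat {
    if (n * 2L > n_max) {
      stop(sprintf(
        "pupil quadrature did not converge to %.1e at %d nodes (z=%g nm, lambda=%g nm)",
        tol, n, z_emitter, optics$emission_wavelength
      ), call. = FALSE)
    }
    n <- n * 2L
    prof2 <- eval_profile(n)
    if (max(abs(prof2 - prof)) < tol * max(prof2)) {
      prof <- prof2
      break
    }
    prof <- prof2
  }
  # scale so the matched-index in-focus on-axis intensity is 1
  prof / (rho_max^2 / 2)^2
}

# Physical axial offset (nm, relative to the paraxial focus of the nominal
# depth) at which the on-axis intensity peaks. With index mismatch the
# spherical aberration shifts the plane of best focus away from the
# paraxial one; experimentally z = 0 is where the microscope is focused,
# i.e. best focus, so the stack generator re-labels its axis accordingly.
find_best_focus <- function(optics, search = c(-1500, 500), step = 10,
                            n_nodes = 256L) {
  na <- optics$numerical_aperture
  ni <- optics$immersion_index
  ns <- optics$sample_index
  d <- optics$particle_depth * 1000
  k <- 2 * pi / optics$emission_wavelength
  rho_max <- min(1, ns / na)
  gq <- pracma::gaussLegendre(n_nodes, 0, rho_max)
  arg_i <- sqrt(pmax(ni^2 - na^2 * gq$x^2, 0))
  arg_s <- sqrt(pmax(ns^2 - na^2 * gq$x^2, 0))
  zs <- seq(search[1], search[2], by = step)
  wr <- gq$w * gq$x
  inten <- vapply(zs, function(z) {
    ph <- k * ((d + z) * arg_s - d * (ni / ns) * arg_i)
    sum(wr * cos(ph))^2 + sum(wr * sin(ph))^2
  }, numeric(1))
  i <- which.max(inten)
  if (i == 1 || i == length(zs)) return(zs[i])
  # parabolic refinement
  y1 <- inten[i - 1]; y2 <- inten[i]; y3 <- inten[i + 1]
  zs[i] + step * 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
}

# Number of fine lateral samples used for a stack: the ROI plus a 1.5-pixel
# guard band on each side so sub-pixel shifts can be applied before binning.
fine_grid_size <- function(grid) {
  (grid$roi_size + 3L) * grid$bin_factor
}

# Fine sample-centre coordinates (nm), symmetric about the emitter.
fine_coords <- function(grid) {
  n <- fine_grid_size(grid)
  (seq_len(n) - (n + 1) / 2) * grid$fine_resolution
}

#' Evaluate one fine-resolution PSF slice
#'
#' Computes the expected intensity field of an emitter at axial position
#' `z_emitter`, sampled on the fine lateral grid defined by `grid`, from the
#' scalar-diffraction integral of the stratified-medium (Gibson--Lanni)
#' optical-path-difference model. The field is radially symmetric about the
#' emitter, which sits at the grid centre.
#'
#' @param optics An [optical_config()].
#' @param z_emitter Axial emitter position in nm relative to the focal plane.
#' @param grid A [grid_config()].
#' @param tol Relative convergence tolerance of the adaptive pupil quadrature.
#' @param best_focus_offset Physical offset (nm) of the focal plane from the
#'   paraxial focus; `z_emitter` is measured from the focal plane.
#'   [generate_psf_stack()] sets this to the plane of maximal on-axis
#'   intensity, matching how a microscope is focused in practice.
#' @return A square numeric matrix of nonnegative intensities at
#'   `fine_resolution` sampling, normalized so that the matched-index
#'   in-focus on-axis value is 1.
#' @export
gibson_lanni_slice <- function(optics, z_emitter, grid, tol = 1e-6,
                               best_focus_offset = 0) {
  stopifnot(inherits(optics, "optical_config"), inherits(grid, "grid_config"))
  if (abs(z_emitter) > grid$z_range) {
    stop("z_emitter outside the configured axial range", call. = FALSE)
  }
  xc <- fine_coords(grid)
  rmax <- sqrt(2) * max(abs(xc)) + grid$fine_resolution
  r_tab <- seq(0, rmax, by = grid$fine_resolution / 2)
  prof <- gl_radial_profile(optics, z_emitter + best_focus_offset, r_tab,
                            tol = tol)
  r2 <- outer(xc^2, xc^2, "+")
  field <- matrix(
    stats::approx(r_tab, prof, xout = sqrt(r2), rule = 2)$y,
    nrow = length(xc)
  )
  field[field < 0] <- 0
  field
}

#' Generate a fine-resolution PSF z-stack
#'
#' Evaluates [gibson_lanni_slice()] on a symmetric axial grid
#' (`-z_range .. +z_range` in steps of `z_step`) and normalizes the stack so
#' that the largest on-axis (emitter-centre) value across slices is 1.
#'
#' @inheritParams gibson_lanni_slice
#' @return A `psf_stack` object at fine resolution: a list with `values`
#'   (array indexed `[z, y, x]`), `z_positions` (nm), `pixel_size` (nm,
#'   here the fine resolution), `wavelength` (nm), `resolution = "fine"`,
#'   and the originating configs.
#' @examples
#' \donttest{
#' st <- generate_psf_stack(optical_config(), grid_config(z_range = 100))
#' st
#' }
#' @export
generate_psf_stack <- function(optics, grid, tol = 1e-6) {
  stopifnot(inherits(optics, "optical_config"), inherits(grid, "grid_config"))
  zs <- seq(-grid$z_range, grid$z_range, by = grid$z_step)
  bf <- find_best_focus(optics)
  n <- fine_grid_size(grid)
  vals <- array(0, dim = c(length(zs), n, n))
  for (i in seq_along(zs)) {
    vals[i, , ] <- gibson_lanni_slice(optics, zs[i], grid, tol = tol,
                                      best_focus_offset = bf)
  }
  ctr <- (n + 1) / 2 # emitter centre falls between samples; use the 4 nearest
  c_idx <- c(floor(ctr), ceiling(ctr))
  peak <- max(vals[, c_idx, c_idx])
  vals <- vals / peak
  structure(
    list(values = vals, z_positions = zs,
         pixel_size = grid$fine_resolution,
         wavelength = optics$emission_wavelength,
         resolution = "fine", best_focus_offset = bf,
         optics = optics, grid = grid),
    class = "psf_stack"
  )
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<psf_stack %s> %d slices of %d x %d, z in [%g, %g] nm, sampling %g nm, lambda %g nm\n",
    x$resolution, d[1], d[2], d[3],
    min(x$z_positions), max(x$z_positions), x$pixel_size, x$wavelength
  ))
  invisible(x)
}

# Sum-bin a fine matrix by integer factor b (area integration).
bin_matrix <- function(m, b) {
  nr <- nrow(m) %/% b
  nc <- ncol(m) %/% b
  m <- m[seq_len(nr * b), seq_len(nc * b), drop = FALSE]
  # fold rows then columns
  m <- rowsum(m, group = rep(seq_len(nr), each = b))
  t(rowsum(t(m), group = rep(seq_len(nc), each = b)))
}

#' Down-sample a fine PSF stack to the detector pixel grid
#'
#' Each detector pixel is the sum of the `bin x bin` fine samples it covers
#' (area integration), so per-slice flux over the covered region is
#' conserved exactly. Output slice dimensions are `floor(input / bin)` per
#' axis; for stacks from [generate_psf_stack()] the fine grid is an exact
#' multiple of the bin factor and the emitter falls on the centre pixel of
#' an odd-sized detector grid.
#'
#' @param stack A fine-resolution `psf_stack` from [generate_psf_stack()].
#' @param grid The [grid_config()] used to build the stack.
#' @return A detector-resolution `psf_stack`.
#' @export
downsample_to_detector <- function(stack, grid) {
  stopifnot(inherits(stack, "psf_stack"), identical(stack$resolution, "fine"))
  b <- grid$pixel_size / stack$pixel_size
  if (abs(b - round(b)) > 1e-9) {
    stop("pixel_size is not an integer multiple of the stack sampling",
         call. = FALSE)
  }
  b <- as.integer(round(b))
  n <- dim(stack$values)[2:3]
  npx <- n %/% b
  nz <- dim(stack$values)[1]
  out <- array(0, dim = c(nz, npx[1], npx[2]))
  for (i in seq_len(nz)) {
    out[i, , ] <- bin_matrix(stack$values[i, , ], b)
  }
  structure(
    list(values = out, z_positions = stack$z_positions,
         pixel_size = grid$pixel_size, wavelength = stack$wavelength,
         resolution = "detector", optics = stack$optics, grid = grid),
    class = "psf_stack"
  )
}
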