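#' Optical configuration for PSF simulation
#'
#' Collects the parameters of the imaging system and sample geometry used by
#' the stratified-medium (Gibson--Lanni) PSF model: a high-NA oil-immersion
#' objective imaging an emitter embedded at some depth in an aqueous medium
#' whose refractive index differs from the immersion oil.
#'
#' @param numerical_aperture Objective numerical aperture (dimensionless).
#' @param immersion_index Refractive index of the immersion medium.
#' @param sample_index Refractive index of the sample medium.
#' @param working_distance Objective working distance in micrometres.
#' @param particle_depth Emitter distance from the coverslip in micrometres.
#' @param emission_wavelength Emission wavelength in nanometres.
#'
#' @return An object of class `optical_config`.
#' @examples
#' optical_config(emission_wavelength = 700)
#' @export
optical_config <- function(numerical_aperture = 1.45,
                           immersion_index = 1.51,
                           sample_index = 1.33,
                           working_distance = 130,
                           particle_depth = 1,
                           emission_wavelength = 600) {
  stopifnot(
    numerical_aperture > 0,
    numerical_aperture <= immersion_index,
    immersion_index >= 1, sample_index >= 1,
    emission_wavelength > 300, emission_wavelength < 1000,
    working_distance > 0, particle_depth >= 0
  )
  structure(
    list(
      numerical_aperture = numerical_aperture,
      immersion_index = immersion_index,
      sample_index = sample_index,
      working_distance = working_distance,
      particle_depth = particle_depth,
      emission_wavelength = emission_wavelength
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> NA=%.2f  n_i=%.3f  n_s=%.3f  WD=%g um  depth=%g um  lambda=%g nm\n",
    x$numerical_aperture, x$immersion_index, x$sample_index,
    x$working_distance, x$particle_depth, x$emission_wavelength
  ))
  invisible(x)
}

#' Sampling-grid configuration
#'
#' Describes how the continuous PSF model is sampled: the axial range and
#' step of the reference stack, the fine lateral resolution of the physical
#' model, the detector pixel size, the region of interest used for photon
#' normalization, and the patch size cropped for the neural networks.
#'
#' @param z_range Axial half-range in nm (stack covers `-z_range .. +z_range`).
#' @param z_step Axial step in nm; `z_range` must be divisible by `z_step`.
#' @param fine_resolution Lateral sampling of the physical model in nm.
#'   Must divide `pixel_size` evenly.
#' @param pixel_size Detector pixel size in nm.
#' @param roi_size Side of the square region-of-interest (pixels) over which
#'   the photon count is normalized.
#' @param patch_size Side of the square crop fed to the networks (odd).
#'
#' @return An object of class `grid_config`.
#' @examples
#' grid_config()
#' @export
grid_config <- function(z_range = 600, z_step = 20, fine_resolution = 5,
                        pixel_size = 100, roi_size = 24, patch_size = 13) {
  stopifnot(
    z_range > 0, z_step > 0,
    abs(z_range / z_step - round(z_range / z_step)) < 1e-9,
    fine_resolution > 0, pixel_size > 0
  )
  bin <- pixel_size / fine_resolution
  if (abs(bin - round(bin)) > 1e-9) {
    stop("pixel_size must be an integer multiple of fine_resolution",
         call. = FALSE)
  }
  stopifnot(patch_size %% 2 == 1, roi_size >= patch_size)
  structure(
    list(
      z_range = z_range, z_step = z_step,
      fine_resolution = fine_resolution, pixel_size = pixel_size,
      roi_size = roi_size, patch_size = patch_size,
      bin_factor = as.integer(round(bin))
    ),
    class = "grid_config"
  )
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf(
    "<grid_config> z: +/-%g nm step %g nm | fine %g nm -> pixel %g nm (bin %d) | ROI %d px, patch %d px\n",
    x$z_range, x$z_step, x$fine_resolution, x$pixel_size, x$bin_factor,
    x$roi_size, x$patch_size
  ))
  invisible(x)
}

#' Ground-truth descriptor for one simulated emitter
#'
#' @param x,y Lateral offsets in nm relative to the patch centre.
#' @param z Axial position in nm relative to the focal plane; positive z
#'   means the emitter is farther from the coverslip than the focal plane.
#' @param photons Expected signal photons within the normalization ROI.
#' @param background Uniform background in photons/pixel.
#' @param color_label Integer dye-class index (1-based).
#'
#' @return An object of class `emitter_truth`.
#' @export
emitter_truth <- function(x = 0, y = 0, z = 0, photons = 5000,
                          background = 10, color_label = 1L) {
  stopifnot(photons >= 0, background >= 0, color_label >= 1)
  structure(
    list(x = x, y = y, z = z, photons = photons,
         background = background, color_label = as.integer(color_label)),
    class = "emitter_truth"
  )
}
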