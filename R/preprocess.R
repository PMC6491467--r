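# Preprocessing: from raw frames to filtered, normalized 13x13 patches.
#
# Coordinate convention (applied consistently with the simulator): pixel
# indices are 0-based, x runs along columns and y along rows, the frame
# origin is the centre of the top-left pixel, and a localization exactly at
# a pixel centre has fractional part .0.

gauss2d_model <- function(par, xs, ys) {
  # par: x0, y0, A, sigma, offset (pixel units)
  dx2 <- outer(ys - par[2], xs - par[1], function(a, b) a^2 + b^2)
  par[5] + par[3] * exp(-dx2 / (2 * par[4]^2))
}

fit_gauss2d <- function(window, x_off = 0, y_off = 0, init = NULL) {
  ny <- nrow(window); nx <- ncol(window)
  xs <- (seq_len(nx) - 1) + x_off
  ys <- (seq_len(ny) - 1) + y_off
  # normalize so the sigma-bound penalty always dominates the data term
  scale <- max(abs(window), 1e-12)
  wn <- window / scale
  if (is.null(init)) {
    off <- stats::median(wn)
    peak <- which(wn == max(wn), arr.ind = TRUE)[1, ]
    init <- c(xs[peak[2]], ys[peak[1]], max(wn) - off, 1.3, off)
  } else {
    init[c(3, 5)] <- init[c(3, 5)] / scale
  }
  sse <- function(p) {
    if (p[4] <= 0.2 || p[4] > 10) return(1e12)
    sum((wn - gauss2d_model(p, xs, ys))^2)
  }
  fit <- stats::optim(init, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- fit$par
  list(x0 = p[1], y0 = p[2], amplitude = p[3] * scale,
       sigma_px = abs(p[4]), offset = p[5] * scale, sse = fit$value)
}

#' Detect and localize single molecules in 2D
#'
#' Local-maximum detection above a threshold over the estimated uniform
#' background, followed by isotropic 2D Gaussian least-squares refinement of
#' each candidate (centre, amplitude, single sigma, constant offset).
#' Photons are estimated as `2*pi*A*sigma^2` in pixel units.
#'
#' @param frame 2D matrix of pixel counts.
#' @param intensity_threshold Absolute detection threshold; default is
#'   `median(frame) + 5*sqrt(median(frame))`, conservative for the photon
#'   regimes simulated here.
#' @param pixel_size Pixel size in nm (for the width statistic `2*sigma`).
#' @param fit_halfwidth Half-size of the refinement window in pixels.
#' @return data.frame with columns `x_px`, `y_px` (0-based sub-pixel
#'   coordinates), `amplitude`, `sigma_px`, `sigma2_nm` (the `2*sigma`
#'   width in nm), `offset`, `photons`. Zero rows if nothing is detected.
#' @export
detect_and_localize_2d <- function(frame, intensity_threshold = NULL,
                                   pixel_size = 100, fit_halfwidth = 5L) {
  stopifnot(is.matrix(frame))
  bg <- stats::median(frame)
  if (is.null(intensity_threshold)) {
    intensity_threshold <- bg + 5 * sqrt(max(bg, 1))
  }
  ny <- nrow(frame); nx <- ncol(frame)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      amplitude = numeric(0), sigma_px = numeric(0),
                      sigma2_nm = numeric(0), offset = numeric(0),
                      photons = numeric(0))
  if (ny < 3 || nx < 3) return(empty)
  # strict local maxima over the 8-neighbourhood, above threshold
  cand <- which(frame > intensity_threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r == 1 || r == ny || c == 1 || c == nx) next
    nb <- frame[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- frame[r, c] >= max(nb) &&
      sum(nb == max(nb)) <= 2 # tolerate one tied neighbour
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # suppress maxima within 2 px of a brighter one
  vals <- frame[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(cand))
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    sel[i] <- TRUE
    d2 <- (cand[, 1] - cand[i, 1])^2 + (cand[, 2] - cand[i, 2])^2
    taken[d2 <= 4 & seq_len(nrow(cand)) > i] <- TRUE
  }
  cand <- cand[sel, , drop = FALSE]

  h <- fit_halfwidth
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r1 <- max(1, r - h); r2 <- min(ny, r + h)
    c1 <- max(1, c - h); c2 <- min(nx, c + h)
    w <- frame[r1:r2, c1:c2]
    f <- fit_gauss2d(w, x_off = c1 - 1, y_off = r1 - 1)
    data.frame(x_px = f$x0, y_px = f$y0, amplitude = f$amplitude,
               sigma_px = f$sigma_px,
               sigma2_nm = 2 * f$sigma_px * pixel_size, offset = f$offset,
               photons = max(0, 2 * pi * f$amplitude * f$sigma_px^2))
  })
  do.call(rbind, rows)
}

#' Filtering rules for molecule cropping
#'
#' @param pixel_size Pixel size in nm.
#' @param min_separation_nm Pairs of candidates closer than this are both
#'   removed (default 1000 nm = 1 um).
#' @param max_width_nm Candidates with fitted width `2*sigma` above this are
#'   removed (default 400 nm).
#' @param photon_range Optional `c(low, high)` photon filter.
#' @return A list of class `crop_rules`.
#' @export
crop_rules <- function(pixel_size = 100, min_separation_nm = 1000,
                       max_width_nm = 400, photon_range = NULL) {
  structure(list(pixel_size = pixel_size,
                 min_separation_nm = min_separation_nm,
                 max_width_nm = max_width_nm, photon_range = photon_range),
            class = "crop_rules")
}

#' Crop candidate molecules and apply quality filters
#'
#' Crops a `patch_size` window centred on the rounded localization pixel of
#' each candidate and applies, independently on the full candidate set (so
#' the rules commute): the neighbour rule (pairs closer than
#' `min_separation_nm` are both removed), the width rule (`2*sigma`
#' above `max_width_nm` removed), the frame-edge rule (clipped crops
#' removed) and, when configured, the photon-range rule.
#'
#' @param frame 2D count matrix.
#' @param candidates data.frame from [detect_and_localize_2d()].
#' @param rules A [crop_rules()].
#' @param patch_size Crop side in pixels (odd).
#' @param frame_index Frame provenance index stored in each molecule.
#' @return List with `molecules` (each a `molecule_image`: `patch`,
#'   `frame_index`, `x0`, `y0` 0-based centre pixel, `x_px`, `y_px`
#'   sub-pixel localization, `photons`, `sigma2_nm`) and `rejects`
#'   (data.frame of candidate index and reason code:
#'   `too_close` / `too_wide` / `edge_clip` / `photon_range`).
#' @export
crop_and_filter <- function(frame, candidates, rules = crop_rules(),
                            patch_size = 13L, frame_index = 1L) {
  n <- nrow(candidates)
  if (n == 0) return(list(molecules = list(), rejects = data.frame(
    candidate = integer(0), reason = character(0))))
  h <- (patch_size - 1L) / 2L
  px <- rules$pixel_size
  reasons <- vector("list", n)
  # neighbour rule on the full set
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(candidates$x_px, candidates$y_px))) * px
    diag(d) <- Inf
    close_pair <- apply(d < rules$min_separation_nm, 1, any)
  } else {
    close_pair <- FALSE
  }
  ny <- nrow(frame); nx <- ncol(frame)
  molecules <- list()
  rej <- list()
  for (i in seq_len(n)) {
    why <- character(0)
    if (isTRUE(close_pair[i])) why <- c(why, "too_close")
    if (candidates$sigma2_nm[i] > rules$max_width_nm) {
      why <- c(why, "too_wide")
    }
    cx <- as.integer(round(candidates$x_px[i]))
    cy <- as.integer(round(candidates$y_px[i]))
    if (cy - h < 0 || cy + h > ny - 1 || cx - h < 0 || cx + h > nx - 1) {
      why <- c(why, "edge_clip")
    }
    if (!is.null(rules$photon_range)) {
      p <- candidates$photons[i]
      if (p < rules$photon_range[1] || p > rules$photon_range[2]) {
        why <- c(why, "photon_range")
      }
    }
    if (length(why) > 0) {
      rej[[length(rej) + 1L]] <- data.frame(candidate = i,
                                            reason = why[1])
      next
    }
    patch <- frame[(cy - h + 1L):(cy + h + 1L), (cx - h + 1L):(cx + h + 1L)]
    molecules[[length(molecules) + 1L]] <- structure(
      list(patch = patch, frame_index = frame_index, x0 = cx, y0 = cy,
           x_px = candidates$x_px[i], y_px = candidates$y_px[i],
           photons = candidates$photons[i],
           sigma2_nm = candidates$sigma2_nm[i]),
      class = "molecule_image"
    )
  }
  list(molecules = molecules,
       rejects = if (length(rej)) do.call(rbind, rej) else
         data.frame(candidate = integer(0), reason = character(0)))
}

#' Zero-centre and unit-norm normalize a patch
#'
#' Subtracts the patch mean and divides by the Euclidean norm of the
#' centred patch, the canonical input normalization of both networks. The
#' result has mean 0 and L2 norm 1 and is invariant to affine rescaling of
#' the input; normalizing twice is a no-op.
#'
#' @param patch Numeric matrix (nonconstant).
#' @return Matrix of the same shape with mean 0 and unit Euclidean norm.
#' @export
normalize_patch <- function(patch) {
  centred <- patch - mean(patch)
  nrm <- sqrt(sum(centred^2))
  if (nrm < 1e-12) {
    stop("constant patch cannot be normalized", call. = FALSE)
  }
  centred / nrm
}

#' Read a multi-page TIFF frame stack
#'
#' @param path TIFF file with one frame per page.
#' @param scale Factor applied to the stored values (the package's own
#'   16-bit writer stores counts / 65535; cameras differ).
#' @return List of numeric matrices.
#' @export
read_frames <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) m * scale)
}

#' Partition molecules by a photon band
#'
#' Splits molecules into those inside `[low, high]` (used for training, to
#' keep a consistent noise level) and those above `high` (used for
#' validation); molecules below the band are dropped.
#'
#' @param molecules List of `molecule_image` objects, or a numeric vector
#'   of photon counts.
#' @param low,high Band limits (inclusive), `low <= high`.
#' @return List with `in_band`, `above_band` and `n_below`.
#' @export
photon_band_filter <- function(molecules, low = 4500, high = 5500) {
  if (low > high) stop("low must not exceed high", call. = FALSE)
  ph <- if (is.numeric(molecules)) molecules else
    vapply(molecules, function(m) m$photons, numeric(1))
  in_idx <- which(ph >= low & ph <= high)
  up_idx <- which(ph > high)
  pick <- function(idx) if (is.numeric(molecules)) molecules[idx] else
    molecules[idx]
  list(in_band = pick(in_idx), above_band = pick(up_idx),
       n_below = sum(ph < low))
}
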