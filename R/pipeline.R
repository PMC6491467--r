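# End-to-end workflow: preprocess -> color call -> per-color z call ->
# merged localization table, plus the evaluation summaries used to
# benchmark both the network and spline-MLE arms.

#' Bundle a color classifier with per-color axial regressors
#'
#' @param classifier Trained classifier `smlm_mlp` over `length(classes)`
#'   classes.
#' @param regressors List of trained axial regressors, one per class, in
#'   class order.
#' @param classes Character or integer labels of the color classes.
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(classifier, regressors, classes = seq_along(regressors)) {
  stopifnot(inherits(classifier, "smlm_mlp"),
            classifier$spec$task == "classifier")
  if (length(regressors) != classifier$spec$n_classes ||
      length(classes) != length(regressors)) {
    stop("need exactly one axial regressor per classifier class",
         call. = FALSE)
  }
  for (r in regressors) {
    stopifnot(inherits(r, "smlm_mlp"), r$spec$task == "regressor")
  }
  structure(list(classifier = classifier, regressors = regressors,
                 classes = classes),
            class = "model_bundle")
}

#' Wrap patches as a molecule container
#'
#' @param patches List of square count matrices.
#' @param photons Optional photon estimates (defaults to the
#'   background-subtracted patch sum).
#' @param frame Optional frame indices.
#' @param x_nm,y_nm Optional 2D localizations in nm.
#' @return List of `molecule_image` objects.
#' @export
as_molecules <- function(patches, photons = NULL, frame = NULL,
                         x_nm = NULL, y_nm = NULL) {
  n <- length(patches)
  if (is.null(photons)) {
    photons <- vapply(patches, function(p) {
      max(0, sum(p) - length(p) * stats::median(p))
    }, numeric(1))
  }
  if (is.null(frame)) frame <- seq_len(n)
  lapply(seq_len(n), function(i) {
    structure(list(patch = patches[[i]], frame_index = frame[i],
                   x0 = NA_integer_, y0 = NA_integer_,
                   x_px = if (is.null(x_nm)) NA_real_ else x_nm[i],
                   y_px = if (is.null(y_nm)) NA_real_ else y_nm[i],
                   photons = photons[i], sigma2_nm = NA_real_),
              class = "molecule_image")
  })
}

#' Run the end-to-end inference pipeline
#'
#' Applies the photon threshold, runs the color classifier at confidence
#' threshold `delta`, routes each accepted molecule to the axial network
#' trained for its called color, and merges everything into one
#' localization table. Molecules removed at any stage are logged with a
#' reason code; accepted + rejected always equals the input count.
#'
#' @param molecules List of `molecule_image` (see [as_molecules()]).
#' @param bundle A [model_bundle()].
#' @param delta Confidence threshold for color acceptance.
#' @param photon_threshold Minimum photon estimate (applied before
#'   classification, mirroring the brightness gating of the analysis).
#' @return List with `records` (data.frame: frame, x_nm, y_nm, z_nm, color,
#'   photons, confidence, method) and `log` (data.frame: frame, reason).
#' @export
run_inference_pipeline <- function(molecules, bundle, delta = 0,
                                   photon_threshold = 0) {
  stopifnot(inherits(bundle, "model_bundle"))
  n <- length(molecules)
  empty_rec <- data.frame(frame = integer(0), x_nm = numeric(0),
                          y_nm = numeric(0), z_nm = numeric(0),
                          color = character(0), photons = numeric(0),
                          confidence = numeric(0), method = character(0))
  empty_log <- data.frame(frame = integer(0), reason = character(0))
  if (n == 0) return(list(records = empty_rec, log = empty_log))
  frames <- vapply(molecules, function(m) as.integer(m$frame_index),
                   integer(1))
  photons <- vapply(molecules, function(m) as.numeric(m$photons), numeric(1))
  bright <- photons >= photon_threshold
  log <- data.frame(frame = frames[!bright],
                    reason = rep("low_photons", sum(!bright)))
  keep <- which(bright)
  if (length(keep) == 0) return(list(records = empty_rec, log = log))

  patches <- lapply(molecules[keep], function(m) m$patch)
  calls <- infer_color(bundle$classifier, patches, delta_threshold = delta)
  rej <- !calls$accepted
  log <- rbind(log, data.frame(frame = frames[keep][rej],
                               reason = rep("low_confidence", sum(rej))))
  acc <- which(!rej)
  if (length(acc) == 0) return(list(records = empty_rec, log = log))

  z <- rep(NA_real_, length(acc))
  cls <- calls$map_class[acc]
  for (k in seq_along(bundle$regressors)) {
    sel <- which(cls == k)
    if (length(sel) > 0) {
      z[sel] <- infer_axial(bundle$regressors[[k]], patches[acc][sel])
    }
  }
  idx <- keep[acc]
  records <- data.frame(
    frame = frames[idx],
    x_nm = vapply(molecules[idx], function(m) as.numeric(m$x_px), numeric(1)),
    y_nm = vapply(molecules[idx], function(m) as.numeric(m$y_px), numeric(1)),
    z_nm = z,
    color = as.character(bundle$classes[cls]),
    photons = photons[idx],
    confidence = abs(calls$delta[acc]),
    method = "ann",
    stringsAsFactors = FALSE
  )
  list(records = records, log = log)
}

#' Classification accuracy and rejection summaries
#'
#' Computes, for each confidence threshold, the accuracy among accepted
#' molecules and the rejection rate, overall and stratified by photon bins
#' and/or true-z bins. Empty strata report `NA` accuracy (undefined, not
#' zero).
#'
#' @param calls A `color_calls` data.frame from [infer_color()] (thresholds
#'   are re-applied per row of the summary, so the `accepted` column of
#'   `calls` is ignored).
#' @param truth True class labels (1-based integers).
#' @param photons,z Optional per-molecule photon counts and true z for
#'   stratification.
#' @param photon_bins,z_bins Optional numeric break vectors.
#' @param thresholds Confidence thresholds to evaluate.
#' @return data.frame of class `evaluation_summary` with columns
#'   `threshold`, `stratum_type`, `stratum`, `n`, `n_accepted`,
#'   `accuracy`, `rejection_rate`.
#' @export
evaluate_classification <- function(calls, truth, photons = NULL, z = NULL,
                                    photon_bins = NULL, z_bins = NULL,
                                    thresholds = c(0, 0.4, 0.8)) {
  stopifnot(nrow(calls) == length(truth))
  strata <- list(data.frame(type = "all", stratum = "all",
                            idx = I(list(seq_len(nrow(calls))))))
  add_bins <- function(vals, breaks, type) {
    b <- cut(vals, breaks, include.lowest = TRUE)
    lapply(levels(b), function(lv) {
      data.frame(type = type, stratum = lv, idx = I(list(which(b == lv))))
    })
  }
  if (!is.null(photons) && !is.null(photon_bins)) {
    strata <- c(strata, add_bins(photons, photon_bins, "photons"))
  }
  if (!is.null(z) && !is.null(z_bins)) {
    strata <- c(strata, add_bins(z, z_bins, "z"))
  }
  strata <- do.call(rbind, strata)
  rows <- list()
  for (d in thresholds) {
    acc_mask <- abs(calls$delta) >= d
    correct <- calls$map_class == truth
    for (i in seq_len(nrow(strata))) {
      idx <- strata$idx[[i]]
      nacc <- sum(acc_mask[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = d, stratum_type = strata$type[i],
        stratum = strata$stratum[i], n = length(idx), n_accepted = nacc,
        accuracy = if (nacc > 0) mean(correct[idx][acc_mask[idx]]) else
          NA_real_,
        rejection_rate = if (length(idx) > 0) 1 - nacc / length(idx) else
          NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_summary", class(out))
  out
}

#' Axial bias and precision per true z
#'
#' @param z_est Estimated z (nm).
#' @param z_true Paired true z (nm); must match `z_est` in length.
#' @param z_bins Optional break vector; by default each distinct true z is
#'   its own stratum.
#' @param model Optional `spline_psf` plus `theta0` photometry to overlay
#'   the CRLB at each stratum centre.
#' @param theta0 Named list with `photons` and `background` for the CRLB
#'   overlay (default 5000 photons, 10 background).
#' @return data.frame of class `evaluation_summary` with columns `z`, `n`,
#'   `bias`, `std`, and `crlb` when a model is supplied.
#' @export
evaluate_axial <- function(z_est, z_true, z_bins = NULL, model = NULL,
                           theta0 = list(photons = 5000, background = 10)) {
  if (length(z_est) != length(z_true)) {
    stop("z_est and z_true must be paired", call. = FALSE)
  }
  grp <- if (is.null(z_bins)) {
    factor(z_true)
  } else {
    cut(z_true, z_bins, include.lowest = TRUE)
  }
  centre <- if (is.null(z_bins)) {
    as.numeric(levels(grp))
  } else {
    vapply(split(z_true, grp), function(v) mean(range(v)), numeric(1))
  }
  out <- data.frame(
    z = centre,
    n = as.integer(table(grp)),
    bias = vapply(split(z_est - z_true, grp), mean, numeric(1)),
    std = vapply(split(z_est, grp), function(v) {
      if (length(v) > 1) stats::sd(v) else 0
    }, numeric(1))
  )
  if (!is.null(model)) {
    out$crlb <- vapply(out$z, function(zz) {
      crlb(model, list(x = 0, y = 0, z = zz, photons = theta0$photons,
                       background = theta0$background))[["z"]]
    }, numeric(1))
  }
  rownames(out) <- NULL
  class(out) <- c("evaluation_summary", class(out))
  out
}

#' Study-size configuration for the simulated benchmark
#'
#' Defaults are the package's desk-scale rendition of the reference study
#' conditions: two colors at 600/700 nm, background 10 photons/pixel,
#' classification over z uniform on +/- 400 nm, axial training over the
#' +/- 600 nm reference range, classifier training 10000 molecules per
#' color in the 4500-5500 photon band, axial training 6000 molecules.
#'
#' @param n_train_per_color,n_val_per_color Classifier set sizes per color.
#' @param n_axial_train,n_axial_val Axial regressor set sizes.
#' @param n_test_per_color Test molecules per color and photon level.
#' @param photon_levels Photon counts at which test sets are rendered.
#' @param background Background photons/pixel.
#' @param hidden_layers Hidden-layer sizes of the color classifier.
#' @param hidden_layers_axial Hidden-layer sizes of the axial regressor
#'   (a narrower net suffices for the scalar task).
#' @param wavelengths Emission wavelengths (nm) of the color classes.
#' @param z_class_range Half-range (nm) of the classification z prior.
#' @param z_axial_range Half-range (nm) of axial training labels.
#' @param max_epochs Epoch cap for both trainings.
#' @param n_mle_test Molecules for the spline-MLE classification arm.
#' @param axial_test_z z grid for the axial evaluation.
#' @param n_axial_test_per_z Replicates per axial test z.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_train_per_color = 10000L,
                             n_val_per_color = 1000L,
                             n_axial_train = 6000L, n_axial_val = 600L,
                             n_test_per_color = 400L,
                             photon_levels = c(5000, 2000),
                             background = 10,
                             hidden_layers = c(1024L, 1024L, 512L, 256L),
                             hidden_layers_axial = c(256L, 256L, 128L, 64L),
                             wavelengths = c(600, 700),
                             z_class_range = 400, z_axial_range = 580,
                             max_epochs = 10L,
                             n_mle_test = 200L,
                             axial_test_z = seq(-400, 400, by = 50),
                             n_axial_test_per_z = 40L) {
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the full simulated two-color benchmark
#'
#' Single-command reproduction of the simulated study: generates both PSF
#' stacks, builds spline models, trains the color classifier and the
#' per-color axial networks, runs both the ANN and spline-MLE arms, and
#' returns evaluation summaries plus a machine-readable report. All
#' randomness derives from `seed`.
#'
#' @param config A [benchmark_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `report.json` and diagnostic
#'   plots (`benchmark.pdf`) there.
#' @param stacks Optional precomputed fine stacks (list per color).
#' @param verbose Print stage progress.
#' @return List of class `benchmark_report`.
#' @export
run_full_benchmark <- function(config = benchmark_config(), seed = 1L,
                               out_dir = NULL, stacks = NULL,
                               verbose = interactive()) {
  stopifnot(inherits(config, "benchmark_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- grid_config()
  optics <- lapply(config$wavelengths,
                   function(w) optical_config(emission_wavelength = w))
  say("stage 1/6: PSF stacks")
  if (is.null(stacks)) {
    stacks <- lapply(optics, generate_psf_stack, grid = grid)
  }
  stacks <- lapply(stacks, prepare_stack_slices)
  say("stage 2/6: spline models")
  models <- lapply(stacks, function(s) {
    build_spline_model(downsample_to_detector(s, grid))
  })

  say("stage 3/6: datasets")
  band <- function(n) stats::runif(n, 4500, 5500)
  zcls <- function(n) stats::runif(n, -config$z_class_range,
                                   config$z_class_range)
  zax <- function(n) stats::runif(n, -config$z_axial_range,
                                  config$z_axial_range)
  tr <- generate_benchmark_dataset(optics, grid, config$n_train_per_color,
                                   photon_distribution = band,
                                   background = config$background,
                                   z_distribution = zcls,
                                   rng_seed = seed, stacks = stacks)
  va <- generate_benchmark_dataset(optics, grid, config$n_val_per_color,
                                   photon_distribution = band,
                                   background = config$background,
                                   z_distribution = zcls,
                                   rng_seed = seed + 1L, stacks = stacks)
  tests <- lapply(seq_along(config$photon_levels), function(i) {
    generate_benchmark_dataset(optics, grid, config$n_test_per_color,
                               photon_distribution = config$photon_levels[i],
                               background = config$background,
                               z_distribution = zcls,
                               rng_seed = seed + 2L, # matched sets across levels
                               stacks = stacks)
  })
  names(tests) <- paste0("p", config$photon_levels)

  say("stage 4/6: color networks (ANN arm)")
  ptr <- dataset_patches(tr); pva <- dataset_patches(va)
  cls_spec <- network_spec(hidden_layers = config$hidden_layers,
                           task = "classifier",
                           n_classes = length(optics))
  cnet <- build_network(cls_spec, seed = seed + 10L)
  cnet <- train_color_network(
    cnet, ptr$patches, ptr$truth$color_label, pva$patches,
    pva$truth$color_label,
    config = training_config(seed = seed + 11L,
                             max_epochs = config$max_epochs))
  color_eval <- lapply(tests, function(ds) {
    p <- dataset_patches(ds)
    calls <- infer_color(cnet, p$patches, 0)
    list(calls = calls, truth = p$truth,
         summary = evaluate_classification(
           calls, p$truth$color_label, photons = p$truth$photons,
           z = p$truth$z_nm,
           z_bins = seq(-config$z_class_range, config$z_class_range,
                        length.out = 5)))
  })

  say("stage 5/6: axial networks and MLE arm")
  atrain <- generate_benchmark_dataset(
    list(optics[[length(optics)]]), grid, config$n_axial_train,
    photon_distribution = band, background = config$background,
    z_distribution = zax, rng_seed = seed + 20L,
    stacks = stacks[length(stacks)])
  aval <- generate_benchmark_dataset(
    list(optics[[length(optics)]]), grid, config$n_axial_val,
    photon_distribution = band, background = config$background,
    z_distribution = zax, rng_seed = seed + 21L,
    stacks = stacks[length(stacks)])
  pat <- dataset_patches(atrain); pav <- dataset_patches(aval)
  anet_main <- build_network(network_spec(
    hidden_layers = config$hidden_layers_axial, task = "regressor"),
    seed = seed + 22L)
  anet_main <- train_axial_network(anet_main, pat$patches, pat$truth$z_nm,
                                   pav$patches, pav$truth$z_nm,
                                   config = training_config(
                                     initial_learning_rate = 1e-3,
                                     batch_size = 32L, seed = seed + 23L,
                                     max_epochs = config$max_epochs))
  zrep <- rep(config$axial_test_z, each = config$n_axial_test_per_z)
  atest <- generate_benchmark_dataset(
    list(optics[[length(optics)]]), grid, length(zrep),
    photon_distribution = config$photon_levels[1],
    background = config$background, z_distribution = zrep,
    rng_seed = seed + 24L, stacks = stacks[length(stacks)])
  pat_test <- dataset_patches(atest)
  zhat <- infer_axial(anet_main, pat_test$patches)
  axial_summary <- evaluate_axial(zhat, pat_test$truth$z_nm,
                                  model = models[[length(models)]],
                                  theta0 = list(
                                    photons = config$photon_levels[1],
                                    background = config$background))
  cal <- stats::lm(est ~ z, data = data.frame(z = axial_summary$z,
                                              est = axial_summary$z +
                                                axial_summary$bias))
  # spline-MLE classification arm on a subset of the main test set
  mle_ds <- tests[[1]]
  pmle <- dataset_patches(mle_ds)
  nmle <- min(config$n_mle_test, length(pmle$patches))
  mle_idx <- seq_len(nmle)
  mle_pred <- vapply(mle_idx, function(i) {
    cl <- classify_color_mle(pmle$patches[[i]], models)
    if (is.na(cl$color)) -1L else cl$color
  }, integer(1))
  mle_acc <- mean(mle_pred == pmle$truth$color_label[mle_idx])

  say("stage 6/6: report")
  acc_at <- function(ev, d) {
    s <- ev$summary
    s$accuracy[s$threshold == d & s$stratum_type == "all"]
  }
  report <- list(
    config = unclass(config), seed = seed,
    grid = unclass(grid),
    color = list(
      ann_accuracy = stats::setNames(
        vapply(color_eval, function(e) acc_at(e, 0), numeric(1)),
        names(tests)),
      ann_accuracy_by_threshold = lapply(color_eval, function(e) {
        s <- e$summary
        s[s$stratum_type == "all", c("threshold", "accuracy",
                                     "rejection_rate")]
      }),
      mle_accuracy = mle_acc, n_mle = nmle
    ),
    axial = list(summary = axial_summary,
                 calibration_slope = unname(stats::coef(cal)[2])),
    networks = list(classifier_log = cnet$log, axial_log = anet_main$log)
  )
  class(report) <- "benchmark_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rep_json <- report
    rep_json$axial$summary <- as.data.frame(rep_json$axial$summary)
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    grDevices::pdf(file.path(out_dir, "benchmark.pdf"), width = 9,
                   height = 4.5)
    graphics::par(mfrow = c(1, 2))
    plot(report, which = "axial")
    plot(report, which = "color")
    grDevices::dev.off()
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  cat("  ANN color accuracy: ",
      paste(sprintf("%s=%.3f", names(x$color$ann_accuracy),
                    x$color$ann_accuracy), collapse = ", "), "\n")
  cat(sprintf("  MLE color accuracy: %.3f (n=%d)\n", x$color$mle_accuracy,
              x$color$n_mle))
  cat(sprintf("  Axial calibration slope: %.3f\n",
              x$axial$calibration_slope))
  cat(sprintf("  Axial std range: %.1f-%.1f nm (CRLB %.1f-%.1f nm)\n",
              min(x$axial$summary$std), max(x$axial$summary$std),
              min(x$axial$summary$crlb), max(x$axial$summary$crlb)))
  invisible(x)
}

#' @export
plot.benchmark_report <- function(x, which = c("axial", "color"), ...) {
  which <- match.arg(which)
  if (which == "axial") {
    s <- x$axial$summary
    graphics::plot(s$z, s$std, type = "b", pch = 16, col = "firebrick",
                   xlab = "true z (nm)", ylab = "z precision (nm)",
                   main = "axial precision vs CRLB",
                   ylim = c(0, max(s$std, na.rm = TRUE) * 1.2))
    if (!is.null(s$crlb)) {
      graphics::lines(s$z, s$crlb, lty = 2)
      graphics::legend("topright", c("ANN std", "CRLB"), lty = c(1, 2),
                       pch = c(16, NA), col = c("firebrick", "black"),
                       bty = "n")
    }
  } else {
    tab <- x$color$ann_accuracy_by_threshold[[1]]
    tab <- tab[is.finite(tab$accuracy), , drop = FALSE]
    if (nrow(tab) == 0) {
      return(invisible(x)) # every molecule rejected at every threshold
    }
    graphics::plot(tab$threshold, tab$accuracy, type = "b", pch = 16,
                   ylim = c(min(tab$accuracy) - 0.02, 1),
                   xlab = "confidence threshold", ylab = "accuracy",
                   main = "accuracy vs confidence threshold")
    graphics::lines(tab$threshold, tab$rejection_rate, type = "b", pch = 1,
                    lty = 3)
    graphics::legend("bottomright", c("accuracy", "rejection"),
                     lty = c(1, 3), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Write a localization table as CSV
#'
#' @param records data.frame from [run_inference_pipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
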