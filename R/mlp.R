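# Fully-connected networks for color classification and axial/lateral
# regression, written in base R matrix operations.
#
# Both tasks share one architecture: four fully-connected hidden layers of
# rectified-linear units on the flattened, normalized patch. The classifier
# ends in a Softmax head trained with cross-entropy and dropout before the
# final layer (no weight penalty); the regressors end in a scalar head
# trained with squared-error loss plus an L2 weight penalty (no dropout).

#' Network architecture specification
#'
#' @param input_size Flattened patch length (169 for 13x13).
#' @param hidden_layers Neuron counts of the four hidden layers.
#' @param task `"classifier"` (Softmax head over `n_classes`) or
#'   `"regressor"` (scalar head).
#' @param n_classes Number of color classes (classifier only).
#' @param dropout_rate Dropout fraction applied before the final layer
#'   during classifier training.
#' @param weight_decay L2 weight-penalty factor (regressor only).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(input_size = 169L,
                         hidden_layers = c(4096L, 4096L, 2048L, 1024L),
                         task = c("classifier", "regressor"),
                         n_classes = 2L, dropout_rate = 0.5,
                         weight_decay = 0.01) {
  task <- match.arg(task)
  if (length(hidden_layers) != 4L) {
    stop("the architecture uses exactly four hidden layers", call. = FALSE)
  }
  stopifnot(input_size >= 1, all(hidden_layers >= 1))
  if (task == "classifier") {
    stopifnot(n_classes >= 2, dropout_rate >= 0, dropout_rate < 1)
    weight_decay <- 0
  } else {
    stopifnot(weight_decay >= 0)
    dropout_rate <- 0
    n_classes <- 1L
  }
  structure(list(input_size = as.integer(input_size),
                 hidden_layers = as.integer(hidden_layers), task = task,
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, weight_decay = weight_decay),
            class = "network_spec")
}

#' Training configuration
#'
#' Defaults follow the two standard operating points: classifier — Adam at
#' initial rate 1e-4 with batch 64; regressor — 1e-3 with batch 32. The
#' learning rate decays by `decay_factor` every `decay_interval` optimizer
#' iterations; training runs at most `max_epochs` epochs with early stop
#' after `patience` epochs without validation improvement.
#'
#' @param initial_learning_rate Adam step size at iteration 0.
#' @param decay_factor Multiplicative decay (default 0.2, i.e. ~5x down).
#' @param decay_interval Iterations between decays.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stop patience in epochs.
#' @param seed RNG seed governing shuffling and dropout.
#' @return A list of class `training_config`.
#' @export
training_config <- function(initial_learning_rate = 1e-4, decay_factor = 0.2,
                            decay_interval = 1000L, batch_size = 64L,
                            max_epochs = 10L, patience = 3L, seed = 1L) {
  stopifnot(initial_learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(initial_learning_rate = initial_learning_rate,
                 decay_factor = decay_factor,
                 decay_interval = as.integer(decay_interval),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

#' Build (initialize) a network
#'
#' Weights are Xavier-initialized, uniform on
#' `+/- sqrt(6 / (fan_in + fan_out))`; biases start at zero. The same seed
#' reproduces identical parameters.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `smlm_mlp`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- c(spec$input_size, spec$hidden_layers, spec$n_classes)
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(spec = spec, W = W, b = b, trained = FALSE,
                 label_center = 0, label_scale = 1, init_seed = seed,
                 log = NULL),
            class = "smlm_mlp")
}

#' @export
print.smlm_mlp <- function(x, ...) {
  npar <- sum(vapply(x$W, length, numeric(1))) +
    sum(vapply(x$b, length, numeric(1)))
  cat(sprintf("<smlm_mlp %s> %s -> %d | %s params, %s\n",
              x$spec$task,
              paste(c(x$spec$input_size, x$spec$hidden_layers), collapse = "-"),
              x$spec$n_classes, format(npar, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

mlp_forward <- function(net, X, dropout_mask = NULL) {
  A <- list(X)
  nl <- length(net$W)
  H <- X
  for (l in seq_len(nl - 1L)) {
    Z <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    H <- pmax(Z, 0)
    A[[l + 1L]] <- H
  }
  if (!is.null(dropout_mask)) {
    H <- H * dropout_mask
    A[[nl]] <- H
  }
  out <- sweep(H %*% net$W[[nl]], 2, net$b[[nl]], "+")
  list(activations = A, out = out)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# One backward pass; dout is dLoss/dout (n x out). Returns gradients.
mlp_backward <- function(net, fw, dout) {
  nl <- length(net$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- dout
  for (l in nl:1) {
    A <- fw$activations[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (A > 0)
    }
  }
  list(W = gW, b = gb)
}

# Adam training loop shared by both heads.
mlp_train_core <- function(net, X, Y, Xval, Yval, config, metric) {
  spec <- net$spec
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  it <- 0L
  n <- nrow(X)
  set.seed(config$seed)
  best <- list(metric = Inf, W = net$W, b = net$b, epoch = 0L)
  log <- data.frame()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      nbatch <- length(idx)
      mask <- NULL
      if (spec$dropout_rate > 0) {
        keep <- 1 - spec$dropout_rate
        mask <- matrix(stats::rbinom(nbatch * spec$hidden_layers[4], 1, keep),
                       nbatch, spec$hidden_layers[4]) / keep
      }
      fw <- mlp_forward(net, Xb, dropout_mask = mask)
      if (spec$task == "classifier") {
        P <- softmax_rows(fw$out)
        yb <- Y[idx]
        loss <- -mean(log(pmax(P[cbind(seq_len(nbatch), yb)], 1e-12)))
        dout <- P
        dout[cbind(seq_len(nbatch), yb)] <-
          dout[cbind(seq_len(nbatch), yb)] - 1
        dout <- dout / nbatch
      } else {
        # batch loss is the L2 norm of the residual vector
        yb <- Y[idx]
        r <- fw$out[, 1] - yb
        loss <- sqrt(sum(r^2))
        dout <- matrix(r / max(loss, 1e-12), ncol = 1)
      }
      gr <- mlp_backward(net, fw, dout)
      it <- it + 1L
      lr <- config$initial_learning_rate *
        config$decay_factor^(it %/% config$decay_interval)
      for (l in seq_len(nl)) {
        g <- gr$W[[l]]
        if (spec$weight_decay > 0) {
          # penalty is the per-layer L2 (Frobenius) norm of the weights,
          # weight_decay * sum_l ||W_l||; gradient wd * W / ||W||
          g <- g + spec$weight_decay * net$W[[l]] /
            max(sqrt(sum(net$W[[l]]^2)), 1e-12)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g^2
        mhat <- mW[[l]] / (1 - beta1^it)
        vhat <- vW[[l]] / (1 - beta2^it)
        net$W[[l]] <- net$W[[l]] - lr * mhat / (sqrt(vhat) + eps)
        g <- gr$b[[l]]
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g^2
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / (1 - beta1^it)) /
          (sqrt(vb[[l]] / (1 - beta2^it)) + eps)
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    val <- metric(net, Xval, Yval)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                 val_metric = val, iterations = it))
    if (val < best$metric - 1e-9) {
      best <- list(metric = val, W = net$W, b = net$b, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  net$W <- best$W
  net$b <- best$b
  net$trained <- TRUE
  net$log <- log
  net
}

patches_to_matrix <- function(patches, normalize = TRUE) {
  do.call(rbind, lapply(patches, function(p) {
    if (inherits(p, "molecule_image")) p <- p$patch
    if (normalize) p <- normalize_patch(p)
    as.vector(p)
  }))
}

#' Train the color-separating network
#'
#' Minimizes Softmax cross-entropy with dropout before the final layer and
#' no weight penalty, using Adam under the classifier schedule (initial
#' rate 1e-4, batch 64, rate x0.2 every 1000 iterations by default).
#' Classes are balanced by stratified subsampling to the smallest class.
#'
#' @param net An untrained classifier `smlm_mlp`.
#' @param train_patches,train_labels Training patches (list of matrices,
#'   raw counts; normalized internally) and 1-based integer class labels.
#' @param val_patches,val_labels Validation set for the early-stop metric.
#' @param config A [training_config()].
#' @return The trained network; `net$log` holds per-epoch train loss and
#'   validation error rate.
#' @export
train_color_network <- function(net, train_patches, train_labels,
                                val_patches, val_labels,
                                config = training_config()) {
  stopifnot(inherits(net, "smlm_mlp"), net$spec$task == "classifier")
  train_labels <- as.integer(train_labels)
  if (length(unique(train_labels)) < 2) {
    stop("training set must contain at least two classes", call. = FALSE)
  }
  # stratified balance: equal per-class counts
  set.seed(config$seed)
  split <- split(seq_along(train_labels), train_labels)
  nmin <- min(lengths(split))
  idx <- unlist(lapply(split, function(s) sample(s, nmin)))
  X <- patches_to_matrix(train_patches[idx])
  Y <- train_labels[idx]
  Xv <- patches_to_matrix(val_patches)
  Yv <- as.integer(val_labels)
  metric <- function(nt, Xv, Yv) {
    P <- softmax_rows(mlp_forward(nt, Xv)$out)
    mean(max.col(P) != Yv) # error rate
  }
  mlp_train_core(net, X, Y, Xv, Yv, config, metric)
}

train_regressor <- function(net, train_patches, train_labels, val_patches,
                            val_labels, config) {
  stopifnot(inherits(net, "smlm_mlp"), net$spec$task == "regressor")
  X <- patches_to_matrix(train_patches)
  ctr <- mean(train_labels)
  scl <- stats::sd(train_labels)
  if (!is.finite(scl) || scl < 1e-9) scl <- 1
  net$label_center <- ctr
  net$label_scale <- scl
  Y <- (train_labels - ctr) / scl
  Xv <- patches_to_matrix(val_patches)
  Yv <- (val_labels - ctr) / scl
  metric <- function(nt, Xv, Yv) {
    sqrt(mean((mlp_forward(nt, Xv)$out[, 1] - Yv)^2)) # scaled RMSE
  }
  mlp_train_core(net, X, Y, Xv, Yv, config, metric)
}

#' Train an axial-localization network for one fluorophore
#'
#' Minimizes squared-error loss on the axial position plus an L2 weight
#' penalty (factor `weight_decay` of the [network_spec()], default 0.01),
#' using Adam under the regressor schedule (initial rate 1e-3, batch 32,
#' rate x0.2 every 1000 iterations by default). One network is trained per
#' dye; pass `color_labels` to assert the set is single-fluorophore.
#'
#' @param net An untrained regressor `smlm_mlp`.
#' @param train_patches List of raw count patches.
#' @param train_z Axial labels in nm.
#' @param val_patches,val_z Validation set.
#' @param config A [training_config()]; default uses the regressor schedule.
#' @param color_labels Optional per-molecule dye labels; mixed labels are an
#'   error.
#' @return The trained network (predictions are returned in nm).
#' @export
train_axial_network <- function(net, train_patches, train_z, val_patches,
                                val_z,
                                config = training_config(
                                  initial_learning_rate = 1e-3,
                                  batch_size = 32L),
                                color_labels = NULL) {
  if (!is.null(color_labels) && length(unique(color_labels)) > 1) {
    stop("axial networks are trained per fluorophore; mixed color labels",
         call. = FALSE)
  }
  train_regressor(net, train_patches, train_z, val_patches, val_z, config)
}

#' Train a lateral-localization network
#'
#' Same machinery as [train_axial_network()] with sub-pixel lateral offsets
#' (nm) as labels; train one network for x and one for y.
#'
#' @inheritParams train_axial_network
#' @param train_offsets,val_offsets Sub-pixel offsets in nm.
#' @export
train_lateral_network <- function(net, train_patches, train_offsets,
                                  val_patches, val_offsets,
                                  config = training_config(
                                    initial_learning_rate = 1e-3,
                                    batch_size = 32L),
                                  color_labels = NULL) {
  if (!is.null(color_labels) && length(unique(color_labels)) > 1) {
    stop("lateral networks are trained per fluorophore; mixed color labels",
         call. = FALSE)
  }
  train_regressor(net, train_patches, train_offsets, val_patches,
                  val_offsets, config)
}

#' Predict from a trained network
#'
#' @param object A `smlm_mlp`.
#' @param patches List of patches (raw counts) or an already-normalized
#'   input matrix with one flattened patch per row.
#' @param type `"response"` (default): class posteriors for classifiers,
#'   nm predictions for regressors.
#' @param ... Unused.
#' @return Classifier: matrix of class posteriors (rows sum to 1).
#'   Regressor: numeric vector in label units (nm).
#' @export
predict.smlm_mlp <- function(object, patches, type = "response", ...) {
  X <- if (is.matrix(patches) && !inherits(patches, "molecule_image")) {
    patches
  } else {
    patches_to_matrix(patches)
  }
  if (ncol(X) != object$spec$input_size) {
    stop("input dimension does not match the network input size",
         call. = FALSE)
  }
  out <- mlp_forward(object, X)$out
  if (object$spec$task == "classifier") {
    softmax_rows(out)
  } else {
    out[, 1] * object$label_scale + object$label_center
  }
}

#' Color inference with confidence-based rejection
#'
#' Runs the classifier (dropout disabled), takes the maximum-a-posteriori
#' class, and computes the confidence `Delta`: for two classes the signed
#' difference `P(class 1) - P(class 2)`, in general the top posterior minus
#' the runner-up. Molecules with `|Delta|` below `delta_threshold` are
#' rejected rather than assigned.
#'
#' @param net Trained classifier.
#' @param molecules Patches (list) or normalized input matrix.
#' @param delta_threshold Confidence threshold `delta` in `[0, 1]`.
#' @return data.frame of class `color_calls`: columns `map_class`, `delta`
#'   (signed for the binary case), `accepted`, and posterior columns
#'   `p1..pM`.
#' @export
infer_color <- function(net, molecules, delta_threshold = 0) {
  P <- predict(net, molecules)
  M <- ncol(P)
  map_class <- max.col(P, ties.method = "first")
  if (M == 2) {
    delta <- P[, 1] - P[, 2]
  } else {
    srt <- t(apply(P, 1, sort, decreasing = TRUE))
    delta <- srt[, 1] - srt[, 2]
  }
  out <- data.frame(map_class = map_class, delta = delta,
                    accepted = abs(delta) >= delta_threshold)
  post <- as.data.frame(P)
  names(post) <- paste0("p", seq_len(M))
  out <- cbind(out, post)
  attr(out, "delta_threshold") <- delta_threshold
  class(out) <- c("color_calls", class(out))
  out
}

#' Axial inference
#'
#' @param net Trained axial regressor for the molecules' dye.
#' @param molecules Patches (list) or normalized input matrix.
#' @return Numeric vector of z estimates in nm (deterministic).
#' @export
infer_axial <- function(net, molecules) {
  predict(net, molecules)
}

#' Serialize a trained network bundle
#'
#' Writes a JSON file with the architecture, label scaling, training log
#' and a reference to a sibling binary weight blob (little-endian doubles).
#'
#' @param net A `smlm_mlp`.
#' @param path Path of the JSON file.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  blob <- sub("\\.json$", ".bin", path)
  if (identical(blob, path)) blob <- paste0(path, ".bin")
  sizes <- lapply(net$W, dim)
  meta <- list(schema_version = 1L, spec = unclass(net$spec),
               trained = net$trained, label_center = net$label_center,
               label_scale = net$label_scale, init_seed = net$init_seed,
               weight_dims = sizes, log = net$log,
               weights_blob = basename(blob),
               normalization = "zero-centred, unit Euclidean norm per patch")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  con <- file(blob, "wb")
  on.exit(close(con))
  for (l in seq_along(net$W)) {
    writeBin(as.vector(net$W[[l]]), con, size = 8, endian = "little")
    writeBin(net$b[[l]], con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Load a network bundle written by [save_network()]
#'
#' @param path Path of the JSON file.
#' @return A `smlm_mlp`.
#' @export
load_network <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, meta$spec[c("input_size", "hidden_layers",
                                            "task", "n_classes",
                                            "dropout_rate", "weight_decay")])
  net <- build_network(spec, seed = meta$init_seed)
  con <- file(file.path(dirname(path), meta$weights_blob), "rb")
  on.exit(close(con))
  for (l in seq_along(net$W)) {
    d <- dim(net$W[[l]])
    net$W[[l]] <- matrix(readBin(con, "double", prod(d), size = 8,
                                 endian = "little"), d[1], d[2])
    net$b[[l]] <- readBin(con, "double", d[2], size = 8, endian = "little")
  }
  net$trained <- meta$trained
  net$label_center <- meta$label_center
  net$label_scale <- meta$label_scale
  net$log <- meta$log
  net
}
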