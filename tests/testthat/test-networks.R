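# Network construction, training behaviour, inference contracts.

synth_two_class <- function(n_per_class, seed = 1, shift = 4) {
  set.seed(seed)
  base1 <- fx_gauss_frame(13, 3, 3, 50, 1.5, 0)
  base2 <- fx_gauss_frame(13, 3 + shift, 3 + shift, 50, 1.5, 0)
  patches <- c(
    lapply(seq_len(n_per_class), function(i) base1 + matrix(rnorm(169, 0, 4), 13, 13)),
    lapply(seq_len(n_per_class), function(i) base2 + matrix(rnorm(169, 0, 4), 13, 13))
  )
  list(patches = patches, labels = rep(1:2, each = n_per_class))
}

test_that("the architecture contract is enforced at construction", {
  expect_error(network_spec(hidden_layers = c(64, 64)), "four hidden")
  sc <- network_spec(hidden_layers = c(32, 32, 16, 8), task = "classifier",
                     dropout_rate = 0.5)
  expect_equal(sc$weight_decay, 0) # dropout and weight decay are exclusive
  sr <- network_spec(hidden_layers = c(32, 32, 16, 8), task = "regressor",
                     weight_decay = 0.01)
  expect_equal(sr$dropout_rate, 0)
  expect_equal(sr$n_classes, 1L)
})

test_that("initialization is Xavier-bounded and seed-deterministic", {
  sp <- network_spec(hidden_layers = c(32, 32, 16, 8), task = "classifier")
  a <- build_network(sp, seed = 42)
  b <- build_network(sp, seed = 42)
  d <- build_network(sp, seed = 43)
  expect_identical(a$W, b$W)
  expect_false(identical(a$W, d$W))
  lim1 <- sqrt(6 / (169 + 32))
  expect_lte(max(abs(a$W[[1]])), lim1)
  expect_true(all(a$b[[1]] == 0))
})

test_that("classifier head returns normalized posteriors, regressor a scalar", {
  sp <- network_spec(hidden_layers = c(32, 32, 16, 8), task = "classifier")
  net <- build_network(sp, seed = 1)
  X <- matrix(rnorm(5 * 169), 5, 169)
  P <- predict(net, X)
  expect_equal(dim(P), c(5, 2))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
  rnet <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                     task = "regressor"), seed = 1)
  expect_length(predict(rnet, X), 5)
  expect_error(predict(net, matrix(0, 2, 100)), "dimension")
})

test_that("linearly separable classes are learned within a few epochs", {
  d <- synth_two_class(600, seed = 5)
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "classifier"), seed = 2)
  net <- train_color_network(net, d$patches, d$labels,
                             d$patches[c(1:50, 601:650)],
                             d$labels[c(1:50, 601:650)],
                             config = training_config(seed = 4,
                                                      max_epochs = 10))
  acc <- mean(infer_color(net, d$patches, 0)$map_class == d$labels)
  expect_gte(acc, 0.99)
})

test_that("single-class training sets are rejected", {
  d <- synth_two_class(10, seed = 6)
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "classifier"), seed = 2)
  expect_error(train_color_network(net, d$patches[1:10], rep(1L, 10),
                                   d$patches[1:10], rep(1L, 10)),
               "two classes")
})

test_that("constant-z training collapses the regressor onto that constant", {
  set.seed(7)
  patches <- lapply(1:120, function(i) matrix(rpois(169, 20), 13, 13))
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "regressor"), seed = 3)
  net <- train_axial_network(net, patches[1:100], rep(137, 100),
                             patches[101:120], rep(137, 20))
  expect_lt(max(abs(infer_axial(net, patches[101:120]) - 137)), 5)
})

test_that("mixed-fluorophore axial training is a configuration error", {
  patches <- lapply(1:10, function(i) matrix(rpois(169, 20), 13, 13))
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "regressor"), seed = 3)
  expect_error(train_axial_network(net, patches, rnorm(10), patches,
                                   rnorm(10),
                                   color_labels = c(rep(1, 5), rep(2, 5))),
               "per fluorophore")
})

test_that("confidence thresholds reject monotonically from the posteriors", {
  d <- synth_two_class(60, seed = 8, shift = 2)
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "classifier"), seed = 2)
  net <- train_color_network(net, d$patches, d$labels, d$patches, d$labels,
                             config = training_config(seed = 4,
                                                      max_epochs = 3))
  calls0 <- infer_color(net, d$patches, 0)
  expect_true(all(calls0$accepted)) # delta = 0 accepts everything
  expect_true(all(abs(calls0$delta) <= 1))
  expect_equal(rowSums(as.matrix(calls0[, c("p1", "p2")])), rep(1, 120),
               tolerance = 1e-6)
  expect_equal(calls0$delta, calls0$p1 - calls0$p2, tolerance = 1e-12)
  rej <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9), function(d0) {
    mean(!infer_color(net, d$patches, d0)$accepted)
  }, numeric(1))
  expect_true(all(diff(rej) >= 0))
  expect_equal(rej[6], mean(abs(calls0$delta) < 1 + 1e-9))
})

test_that("inference is deterministic and survives serialization", {
  d <- synth_two_class(30, seed = 9)
  net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                    task = "classifier"), seed = 2)
  net <- train_color_network(net, d$patches, d$labels, d$patches, d$labels,
                             config = training_config(seed = 4,
                                                      max_epochs = 2))
  p1 <- predict(net, d$patches)
  p2 <- predict(net, d$patches)
  expect_identical(p1, p2)
  dir <- withr::local_tempdir()
  save_network(net, file.path(dir, "net.json"))
  back <- load_network(file.path(dir, "net.json"))
  expect_equal(predict(back, d$patches), p1, tolerance = 1e-12)
})

test_that("seeded training is reproducible end to end", {
  d <- synth_two_class(50, seed = 10)
  go <- function() {
    net <- build_network(network_spec(hidden_layers = c(32, 32, 16, 8),
                                      task = "classifier"), seed = 2)
    train_color_network(net, d$patches, d$labels, d$patches, d$labels,
                        config = training_config(seed = 4, max_epochs = 2))
  }
  n1 <- go(); n2 <- go()
  expect_identical(n1$W, n2$W)
  expect_identical(n1$log, n2$log)
})

test_that("lateral regressors behave symmetrically under transposition", {
  gr <- fx_grid()
  ds <- generate_benchmark_dataset(list(fx_optics(700)), gr, 800,
    photon_distribution = function(n) runif(n, 4500, 5500),
    z_distribution = function(n) runif(n, -200, 200),
    rng_seed = 31, stacks = list(fx_stack(700)))
  p <- dataset_patches(ds)
  idx_tr <- 1:600; idx_te <- 601:800
  cfg <- training_config(initial_learning_rate = 1e-3, batch_size = 32,
                         seed = 5, max_epochs = 5)
  netx <- train_lateral_network(
    build_network(network_spec(hidden_layers = c(64, 64, 32, 16),
                               task = "regressor"), seed = 6),
    p$patches[idx_tr], p$dx_nm[idx_tr], p$patches[idx_te],
    p$dx_nm[idx_te], config = cfg)
  tpatch <- lapply(p$patches, t)
  nety <- train_lateral_network(
    build_network(network_spec(hidden_layers = c(64, 64, 32, 16),
                               task = "regressor"), seed = 6),
    tpatch[idx_tr], p$dx_nm[idx_tr], tpatch[idx_te], p$dx_nm[idx_te],
    config = cfg)
  # the transposed patch swaps x and y, so nety estimates the same offsets
  # from the y axis; error distributions should match closely
  ex <- infer_axial(netx, p$patches[idx_te]) - p$dx_nm[idx_te]
  ey <- infer_axial(nety, tpatch[idx_te]) - p$dx_nm[idx_te]
  expect_lt(abs(mean(ex)), 15)
  expect_lt(abs(mean(ey)), 15)
  expect_lt(abs(sd(ex) / sd(ey) - 1), 0.4)
  # trained on symmetric offsets: predictions centred near zero
  expect_lt(abs(mean(infer_axial(netx, p$patches[idx_te]))), 15)
})
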