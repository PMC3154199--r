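test_that("weight initialization has the right shape, bound and determinism", {
  arch <- network_architecture()
  expect_equal(n_parameters(arch), 31)  # (4+1)*3 + (3+1)*3 + (3+1)*1

  w1 <- init_weights(arch, seed = 3, scale = 0.5)
  w2 <- init_weights(arch, seed = 3, scale = 0.5)
  expect_identical(w1, w2)
  expect_true(all(vapply(w1, function(w) max(abs(w)) <= 0.5, TRUE)))
  expect_equal(vapply(w1, dim, c(0L, 0L)), cbind(c(5L, 3L), c(4L, 3L), c(4L, 1L)),
               ignore_attr = TRUE)
})

test_that("forward pass realizes the bipolar sigmoid with affine output range", {
  arch <- network_architecture()
  w0 <- lapply(init_weights(arch, 1), function(w) w * 0)
  expect_equal(mlp_forward(w0, c(1, 2, 0.5, 1), arch)$output, 1.5)

  w <- init_weights(arch, 2, scale = 2)
  set.seed(4)
  X <- matrix(rnorm(400, 1, 0.5), 100, 4)
  out <- mlp_forward(w, X, arch)$output
  expect_true(all(out > 0 & out < 3))

  # hand-composed two-hidden-unit chain, all weights and biases 0.5, input 1
  toy <- network_architecture(hidden1 = 1, hidden2 = 1, inputs = 1)
  wt <- list(matrix(0.5, 2, 1), matrix(0.5, 2, 1), matrix(0.5, 2, 1))
  a1 <- tanh(0.5 * 1 + 0.5)
  a2 <- tanh(0.5 * a1 + 0.5)
  expected <- 1.5 * (tanh(0.5 * a2 + 0.5) + 1)
  expect_equal(mlp_forward(wt, 1, toy)$output, expected, tolerance = 1e-12)

  expect_error(mlp_forward(w, c(1, NA, 1, 1), arch), "non-finite")
})

test_that("backprop gradient matches central finite differences", {
  arch <- network_architecture()
  set.seed(8)
  X <- matrix(runif(40, 0.2, 2), 10, 4)
  y <- runif(10, 0.3, 2.7)
  w <- init_weights(arch, 17, 0.5)
  g <- mlp_gradient(w, X, y, arch)$grad
  h <- 1e-6
  for (l in seq_along(w)) {
    fd <- w[[l]] * 0
    for (i in seq_along(fd)) {
      wp <- w; wm <- w
      wp[[l]][i] <- wp[[l]][i] + h
      wm[[l]][i] <- wm[[l]][i] - h
      fd[i] <- (mlp_gradient(wp, X, y, arch)$mse -
                  mlp_gradient(wm, X, y, arch)$mse) / (2 * h)
    }
    expect_lt(max(abs(g[[l]] - fd) / pmax(abs(fd), 1e-8)), 1e-5)
  }
})

test_that("batch updates behave like batch updates", {
  arch <- network_architecture()
  set.seed(9)
  X <- matrix(runif(32, 0.2, 2), 8, 4); y <- runif(8, 0.3, 2.7)
  w <- init_weights(arch, 5)

  frozen <- batch_epoch(w, X, y, training_config(learning_rate = 1e-12), arch)
  expect_equal(frozen$weights, w, tolerance = 1e-9)
  expect_gt(frozen$mse, 0)

  # duplicating every sample leaves the mean-based update unchanged
  cfg <- training_config(learning_rate = 0.1)
  a <- batch_epoch(w, X, y, cfg, arch)
  b <- batch_epoch(w, rbind(X, X), c(y, y), cfg, arch)
  expect_equal(a$update, b$update, tolerance = 1e-12)
  expect_equal(a$mse, b$mse)
})

test_that("training descends, converges on trivial targets, and is deterministic", {
  arch <- network_architecture()
  set.seed(10)
  X <- matrix(runif(200, 0.2, 2), 50, 4)

  # constant target at the output midpoint: near-zero weights are optimal
  y15 <- rep(1.5, 50)
  net <- train_network(X, y15, arch,
                       training_config(learning_rate = 0.5, mse_threshold = 1e-4,
                                       max_epochs = 2000, init_scale = 0.1),
                       trace_ccf = FALSE)
  expect_true(net$converged)
  expect_lte(tail(net$trace$mse, 1), 1e-4)

  # separable two-class targets: error decreases
  y2 <- ifelse(X[, 1] > 1.1, 2.5, 0.5)
  net2 <- suppressWarnings(
    train_network(X, y2, arch, training_config(max_epochs = 200), trace_ccf = FALSE))
  expect_lt(tail(net2$trace$mse, 1), net2$trace$mse[1])

  cfg <- training_config(max_epochs = 50)
  t1 <- suppressWarnings(train_network(X, y2, arch, cfg))$trace
  t2 <- suppressWarnings(train_network(X, y2, arch, cfg))$trace
  expect_identical(t1, t2)
})

test_that("epoch MSE is non-increasing at a small learning rate", {
  arch <- network_architecture()
  set.seed(12)
  X <- matrix(runif(80, 0.2, 2), 20, 4)
  y <- runif(20, 0.3, 2.7)
  net <- suppressWarnings(
    train_network(X, y, arch,
                  training_config(learning_rate = 1e-4, momentum = 0,
                                  max_epochs = 50),
                  trace_ccf = FALSE))
  expect_true(all(diff(net$trace$mse) <= 1e-12))
})

test_that("predicted maps agree with per-voxel forward passes and stay in range", {
  st <- small_normalized_study()
  arch <- network_architecture()
  model <- structure(list(weights = init_weights(arch, 6), arch = arch,
                          trace = data.frame(epoch = 1, mse = 1),
                          config = training_config(), converged = TRUE),
                     class = "trained_network")
  map <- predict_map(model, st)
  mask <- st$brain_mask
  expect_true(all(map[!mask] == 0))
  expect_true(all(map[mask] > 0 & map[mask] < 3))

  idx <- which(mask, arr.ind = TRUE)[c(1, 50, 200), , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    feats <- c(st$channels$dwi[v[1], v[2], v[3]], st$channels$t1[v[1], v[2], v[3]],
               st$channels$t2[v[1], v[2], v[3]], st$channels$pd[v[1], v[2], v[3]])
    expect_equal(map[v[1], v[2], v[3]], mlp_forward(model$weights, feats, arch)$output)
  }

  # a spatially constant (already normalized) study maps to a constant value
  flat <- st
  for (ch in names(flat$channels)) {
    a <- array(0, dim(mask)); a[mask] <- 1
    flat$channels[[ch]] <- a
  }
  mf <- predict_map(model, flat)
  expect_equal(length(unique(mf[mask])), 1)

  raw <- generate_study(5, list(nrow = 24, ncol = 24, nslices = 3))
  expect_error(predict_map(model, raw), "normalized")
})

test_that("models survive a JSON round trip", {
  arch <- network_architecture()
  net <- structure(list(weights = init_weights(arch, 42), arch = arch,
                        trace = data.frame(epoch = 1, mse = 0.1),
                        config = training_config(), converged = TRUE),
                   class = "trained_network")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(net, path)
  back <- read_model_json(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12, ignore_attr = TRUE)
  x <- c(1.2, 0.8, 1.1, 0.9)
  expect_equal(mlp_forward(back$weights, x, back$arch)$output,
               mlp_forward(net$weights, x, arch)$output)
})
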