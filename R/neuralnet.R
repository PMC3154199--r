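#' Feed-forward network architecture
#'
#' The prediction model is a small fully connected multilayer perceptron:
#' 4 inputs (the normalized acute DWI, T1WI, T2WI, PDWI intensities of one
#' voxel), two hidden layers with bipolar-sigmoid (tanh) units and a bias on
#' every non-output layer, and one output unit affinely rescaled to the
#' normalized chronic-T2WI range. The reference configuration is
#' [4+1 bias] : [3+1 bias] : [3+1 bias] : 1.
#'
#' @param hidden1,hidden2 hidden layer sizes (>= 1).
#' @param inputs number of input features (4 acute channels).
#' @param output_range numeric length-2; the affine range of the output unit,
#'   default \code{c(0, 3)} so the output is a continuous value with the
#'   brain-mean (= 1) inside its span.
#' @return an object of class \code{network_architecture}.
#' @export
network_architecture <- function(hidden1 = 3, hidden2 = 3, inputs = 4,
                                 output_range = c(0, 3)) {
  if (any(c(hidden1, hidden2, inputs) < 1))
    stop2("network_architecture: all layer sizes must be >= 1")
  structure(list(sizes = c(inputs = inputs, hidden1 = hidden1,
                           hidden2 = hidden2, outputs = 1L),
                 output_range = output_range),
            class = "network_architecture")
}

#' Number of free parameters of an architecture
#'
#' Every unit of a non-input layer has one weight per upstream unit plus a
#' bias, so the count is the sum over layers of (fan_in + 1) * fan_out.
#'
#' @param arch a \code{network_architecture}.
#' @return integer parameter count (31 for the 4:3:3:1 reference network).
#' @export
n_parameters <- function(arch) {
  s <- arch$sizes
  sum((s[-length(s)] + 1) * s[-1])
}

#' Initialize network weights
#'
#' Weights (including bias weights) are drawn independently and uniformly
#' from [-scale, scale].
#'
#' @param arch a \code{network_architecture}.
#' @param seed integer seed.
#' @param scale half-width of the uniform initialization interval (> 0).
#' @return list of weight matrices, one per layer, each of shape
#'   \code{(fan_in + 1) x fan_out} with the bias in the last row.
#' @export
init_weights <- function(arch, seed = 1, scale = 0.5) {
  if (scale <= 0) stop2("init_weights: scale must be positive")
  s <- arch$sizes
  with_seed(seed, {
    lapply(seq_len(length(s) - 1L), function(l) {
      matrix(stats::runif((s[l] + 1L) * s[l + 1L], -scale, scale),
             s[l] + 1L, s[l + 1L])
    })
  })
}

#' Training configuration
#'
#' @param learning_rate batch gradient-descent step (default 0.01).
#' @param momentum momentum factor in [0, 1) (default 0).
#' @param mse_threshold termination (stopping) error; training stops once the
#'   pre-update epoch MSE falls to or below it (default 0.06, on the
#'   normalized chronic-T2 0-3 scale).
#' @param max_epochs hard cap on epochs (default 1000).
#' @param init_scale weight-initialization half-width.
#' @param seed seed for weight initialization.
#' @param ccf_window discretization window for CCF evaluation (default 0.05).
#' @return a list of class \code{training_config}.
#' @export
training_config <- function(learning_rate = 0.01, momentum = 0,
                            mse_threshold = 0.06, max_epochs = 1000,
                            init_scale = 0.5, seed = 1, ccf_window = 0.05) {
  if (learning_rate <= 0) stop2("training_config: learning rate must be positive")
  if (momentum < 0 || momentum >= 1) stop2("training_config: momentum must be in [0, 1)")
  if (mse_threshold <= 0) stop2("training_config: termination MSE must be positive")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 mse_threshold = mse_threshold, max_epochs = max_epochs,
                 init_scale = init_scale, seed = seed,
                 ccf_window = ccf_window),
            class = "training_config")
}

#' Forward pass through the network
#'
#' Hidden activations are tanh (the bipolar sigmoid, polar between -1 and 1);
#' the output unit is tanh followed by an affine map onto the configured
#' range, so predictions are strictly inside (lo, hi) — (0, 3) by default.
#'
#' @param weights weight list from \code{\link{init_weights}}.
#' @param x feature matrix (n x inputs) or a single feature vector.
#' @param arch the \code{network_architecture}.
#' @return list with \code{output} (length-n vector) and \code{activations}
#'   (per-layer activation matrices, inputs first).
#' @export
mlp_forward <- function(weights, x, arch) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop2("mlp_forward: non-finite input")
  if (ncol(x) != arch$sizes[1]) stop2("mlp_forward: feature count mismatch")
  acts <- list(x)
  a <- x
  nl <- length(weights)
  for (l in seq_len(nl)) {
    z <- cbind(a, 1) %*% weights[[l]]
    a <- tanh(z)
    acts[[l + 1L]] <- a
  }
  lo <- arch$output_range[1]; hi <- arch$output_range[2]
  list(output = as.vector((hi - lo) / 2 * (a + 1) + lo), activations = acts)
}

#' Gradient of the mean-squared error by back-propagation
#'
#' The cost is the per-epoch mean (not sum) of squared residuals between the
#' network output and the continuous target, so the learning rate keeps the
#' same meaning whatever the sample count.
#'
#' @param weights weight list.
#' @param x feature matrix (n x inputs).
#' @param y numeric targets (length n).
#' @param arch the \code{network_architecture}.
#' @return list with \code{grad} (weight-shaped list), \code{mse}, and
#'   \code{output}.
#' @export
mlp_gradient <- function(weights, x, y, arch) {
  fw <- mlp_forward(weights, x, arch)
  out <- fw$output
  acts <- fw$activations
  n <- length(y)
  resid <- out - y
  mse <- mean(resid^2)
  lo <- arch$output_range[1]; hi <- arch$output_range[2]
  nl <- length(weights)
  grad <- vector("list", nl)
  # output layer: d out / d z = (hi-lo)/2 * (1 - tanh(z)^2); tanh(z) = a
  a_out <- acts[[nl + 1L]]
  delta <- (2 / n) * resid * (hi - lo) / 2 * (1 - a_out^2)
  delta <- matrix(delta, ncol = 1)
  for (l in nl:1) {
    grad[[l]] <- crossprod(cbind(acts[[l]], 1), delta)
    if (l > 1) {
      back <- delta %*% t(weights[[l]][seq_len(ncol(acts[[l]])), , drop = FALSE])
      delta <- back * (1 - acts[[l]]^2)
    }
  }
  list(grad = grad, mse = mse, output = out)
}

#' One batch training epoch
#'
#' Weight changes are accumulated over the entire sample set and applied in a
#' single update (batch mode): update = -lr * gradient + momentum * previous
#' update. The reported MSE is the pre-update error of the epoch, the
#' quantity the termination rule watches.
#'
#' @param weights current weight list.
#' @param x,y features and targets.
#' @param config a \code{\link{training_config}}.
#' @param arch the \code{network_architecture}.
#' @param prev_update previous update (weight-shaped list) for the momentum
#'   term; \code{NULL} for the first epoch.
#' @return list with \code{weights} (post-update), \code{mse} (pre-update),
#'   and \code{update}.
#' @export
batch_epoch <- function(weights, x, y, config, arch, prev_update = NULL) {
  if (length(y) == 0) stop2("batch_epoch: empty sample set")
  g <- mlp_gradient(weights, x, y, arch)
  update <- lapply(seq_along(weights), function(l) {
    u <- -config$learning_rate * g$grad[[l]]
    if (!is.null(prev_update)) u <- u + config$momentum * prev_update[[l]]
    u
  })
  list(weights = Map(`+`, weights, update), mse = g$mse, update = update,
       output = g$output)
}

#' Train the network by batch back-propagation
#'
#' Iterates \code{\link{batch_epoch}} until the pre-update MSE reaches the
#' termination error, a fixed epoch count is hit, or \code{max_epochs}
#' elapse. The trace records per-epoch MSE and, when the CCF window is
#' evaluated, the per-epoch correct-classification fraction on the training
#' set and on an optional held-out validation set.
#'
#' @param x,y training features (n x 4) and continuous targets.
#' @param arch the \code{network_architecture}.
#' @param config a \code{\link{training_config}}.
#' @param stopping either \code{list(mse_threshold = e)} (default: the
#'   config's threshold) or \code{list(fixed_epoch = k)} to train exactly k
#'   epochs.
#' @param validation optional list with \code{x} and \code{y} of held-out
#'   samples whose CCF is traced per epoch.
#' @param keep_history keep the weight list of every epoch (tiny for this
#'   network); needed to read the model back at an earlier stopping epoch.
#' @param trace_ccf evaluate per-epoch CCF traces (default TRUE).
#' @return object of class \code{trained_network}: final \code{weights}, the
#'   \code{trace} data.frame (epoch, mse, ccf_train, ccf_validation), the
#'   architecture/config, a \code{converged} flag, and (optionally)
#'   \code{history}.
#' @export
train_network <- function(x, y, arch = network_architecture(),
                          config = training_config(), stopping = NULL,
                          validation = NULL, keep_history = FALSE,
                          trace_ccf = TRUE) {
  if (length(y) < 2) stop2("train_network: need at least 2 samples")
  if (is.null(stopping)) stopping <- list(mse_threshold = config$mse_threshold)
  fixed <- !is.null(stopping$fixed_epoch)
  max_ep <- if (fixed) stopping$fixed_epoch else config$max_epochs
  thr <- if (fixed) -Inf else stopping$mse_threshold

  x <- as.matrix(x)
  weights <- init_weights(arch, config$seed, config$init_scale)
  upd <- NULL
  mse <- numeric(0); ccf_tr <- numeric(0); ccf_va <- numeric(0)
  history <- if (keep_history) vector("list", max_ep) else NULL
  converged <- FALSE
  epoch <- 0L
  while (epoch < max_ep) {
    epoch <- epoch + 1L
    # history/trace entries describe the pre-update state of each epoch
    if (keep_history) history[[epoch]] <- weights
    st <- batch_epoch(weights, x, y, config, arch, upd)
    mse[epoch] <- st$mse
    if (trace_ccf) {
      # the batch gradient already evaluated the pre-update outputs
      ccf_tr[epoch] <- ccf(st$output, y, evaluation_config(window = config$ccf_window,
                                                        range = arch$output_range))
      if (!is.null(validation)) {
        out_va <- mlp_forward(weights, as.matrix(validation$x), arch)$output
        ccf_va[epoch] <- ccf(out_va, validation$y,
                             evaluation_config(window = config$ccf_window,
                                               range = arch$output_range))
      }
    }
    if (!fixed && st$mse <= thr) {
      # threshold met by the pre-update error: keep the pre-update weights
      converged <- TRUE
      break
    }
    weights <- st$weights
    upd <- st$update
  }
  if (fixed) converged <- TRUE
  if (!converged)
    warning(sprintf("train_network: MSE %.4f still above threshold %.4f after %d epochs",
                    mse[epoch], thr, epoch))
  trace <- data.frame(epoch = seq_len(epoch), mse = mse[seq_len(epoch)])
  if (trace_ccf) {
    trace$ccf_train <- ccf_tr[seq_len(epoch)]
    if (!is.null(validation)) trace$ccf_validation <- ccf_va[seq_len(epoch)]
  }
  structure(list(weights = weights, trace = trace, arch = arch,
                 config = config, converged = converged,
                 history = if (keep_history) history[seq_len(epoch)] else NULL),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  s <- x$arch$sizes
  cat(sprintf("Trained MLP %s, %d epochs, final MSE %.4f%s\n",
              paste(s, collapse = ":"), nrow(x$trace),
              x$trace$mse[nrow(x$trace)],
              if (x$converged) "" else " (termination error not reached)"))
  invisible(x)
}

#' Predict the chronic-T2WI map of a study
#'
#' Maps every brain-mask voxel of a normalized study through the trained
#' network; voxels outside the mask are set to 0. Predictions inherit the
#' network's output range, (0, 3) by default.
#'
#' @param model a \code{trained_network} (or a bare weight list plus
#'   \code{arch}).
#' @param study a normalized \code{subject_study} with a brain mask.
#' @param arch architecture, taken from \code{model} when absent.
#' @return numeric array of the study's dimensions.
#' @export
predict_map <- function(model, study, arch = NULL) {
  if (inherits(model, "trained_network")) {
    arch <- model$arch
    weights <- model$weights
  } else weights <- model
  if (!isTRUE(study$normalized) || is.null(study$brain_mask))
    stop2("predict_map: study must be normalized (with a brain mask) first")
  mask <- study$brain_mask
  # guard against a study that was rescaled after normalization
  mu <- mean(study$channels$t2[mask])
  if (abs(mu - 1) > 1e-6)
    stop2("predict_map: study does not look normalized (in-mask T2 mean != 1)")
  X <- cbind(study$channels$dwi[mask], study$channels$t1[mask],
             study$channels$t2[mask], study$channels$pd[mask])
  out <- array(0, dim(mask))
  out[mask] <- mlp_forward(weights, X, arch)$output
  out
}

#' Serialize a trained network to JSON
#'
#' @param model a \code{trained_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    sizes = as.list(model$arch$sizes),
    output_range = model$arch$output_range,
    weights = lapply(model$weights, function(w) as.vector(w)),
    config = unclass(model$config),
    converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized network back
#'
#' @param path JSON path written by \code{\link{write_model_json}}.
#' @return list with \code{weights} and \code{arch}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- network_architecture(hidden1 = obj$sizes$hidden1,
                               hidden2 = obj$sizes$hidden2,
                               inputs = obj$sizes$inputs,
                               output_range = obj$output_range)
  s <- arch$sizes
  weights <- lapply(seq_len(length(s) - 1L), function(l)
    matrix(obj$weights[[l]], s[l] + 1L, s[l + 1L]))
  list(weights = weights, arch = arch)
}
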