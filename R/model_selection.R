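#' Leave-one-out folds at the patient level
#'
#' One fold per subject: the network is trained on K-1 subjects and tested on
#' the left-out one, so no voxel of a test subject ever enters its fold's
#' training set.
#'
#' @param cohort list of \code{subject_study} objects, or a character vector
#'   of subject ids.
#' @return list of folds, each \code{list(train = ids, test = id)}.
#' @export
loocv_folds <- function(cohort) {
  ids <- if (is.character(cohort)) cohort
         else vapply(cohort, function(s) s$subject, "")
  if (length(ids) < 2) stop2("loocv_folds: need at least 2 subjects")
  if (anyDuplicated(ids)) stop2("loocv_folds: duplicate subject ids")
  lapply(seq_along(ids), function(i) list(train = ids[-i], test = ids[i]))
}

#' Stopping epoch from the plateau of a CCF curve
#'
#' The held-out CCF curve saturates as training proceeds; its plateau is
#' estimated as the mean CCF over the final fraction of epochs, and the
#' stopping epoch is the first epoch whose CCF comes within the tolerance
#' fraction (default 10 percent) of that plateau.
#'
#' @param ccf_by_epoch numeric CCF series (>= 5 epochs, finite).
#' @param plateau_window_fraction final fraction of epochs averaged into the
#'   plateau estimate (default 0.1).
#' @param tolerance_fraction relative shortfall from the plateau that still
#'   counts as arrived (default 0.10).
#' @return integer epoch index.
#' @export
stopping_epoch <- function(ccf_by_epoch, plateau_window_fraction = 0.1,
                           tolerance_fraction = 0.10) {
  n <- length(ccf_by_epoch)
  if (n < 5) stop2("stopping_epoch: need at least 5 epochs")
  if (!all(is.finite(ccf_by_epoch))) stop2("stopping_epoch: non-finite CCF values")
  k <- max(1L, ceiling(plateau_window_fraction * n))
  plateau <- mean(ccf_by_epoch[(n - k + 1L):n])
  hit <- which(ccf_by_epoch >= (1 - tolerance_fraction) * plateau)
  if (length(hit) == 0) return(n)
  hit[1]
}

#' Termination (stopping) error across folds
#'
#' The mean over folds of each fold's training MSE at its stopping epoch —
#' the single termination error subsequently used to train the final network.
#'
#' @param folds list of fold results, each with \code{stopping_mse}; or a
#'   numeric vector of per-fold stopping MSEs.
#' @return arithmetic mean.
#' @export
termination_error <- function(folds) {
  v <- if (is.numeric(folds)) folds
       else vapply(folds, function(f) f$stopping_mse, 0)
  if (length(v) < 1) stop2("termination_error: need at least one fold")
  mean(v)
}

#' Patient-level leave-one-out cross-validation of the network
#'
#' For each fold the network is trained on the pooled voxels of the K-1
#' training subjects and evaluated on the held-out subject. Two stopping
#' modes are available:
#' \describe{
#'   \item{\code{"mse"}}{train each fold until the termination error
#'     (\code{config$mse_threshold}) is reached; evaluate at the final
#'     weights. This is the production mode once the termination error is
#'     known.}
#'   \item{\code{"plateau"}}{train each fold for \code{config$max_epochs}
#'     epochs, average the held-out CCF curves across folds (aligned by
#'     truncation to the shortest trace), locate the stopping epoch on the
#'     averaged curve, and evaluate every fold at that common epoch. The mean
#'     per-fold MSE at the stopping epoch is reported as the termination
#'     error.}
#' }
#' Per-fold seeds are derived deterministically from the config seed, so the
#' whole procedure is reproducible from one number.
#'
#' @param samples pooled sample data.frame (from
#'   \code{\link{extract_samples}}) with a \code{subject} column.
#' @param arch a \code{network_architecture}.
#' @param config a \code{training_config}.
#' @param stopping \code{"mse"} or \code{"plateau"}.
#' @param plateau_window_fraction,tolerance_fraction plateau-rule knobs (see
#'   \code{\link{stopping_epoch}}).
#' @return object of class \code{crossval_result}: per-fold results (trace,
#'   stopping epoch, stopping MSE, held-out CCF and AUROC, held-out
#'   predictions), the pooled held-out predictions with labels/targets, the
#'   averaged held-out CCF curve, the stopping epoch, and the termination
#'   error.
#' @export
run_crossval <- function(samples, arch = network_architecture(),
                         config = training_config(), stopping = c("mse", "plateau"),
                         plateau_window_fraction = 0.1, tolerance_fraction = 0.10) {
  stopping <- match.arg(stopping)
  ids <- unique(samples$subject)
  folds <- loocv_folds(ids)
  seeds <- split_seed(config$seed, length(folds))
  feat <- c("dwi", "t1", "t2", "pd")
  eval_cfg <- evaluation_config(window = config$ccf_window,
                                range = arch$output_range)

  fits <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    tr <- samples[samples$subject %in% f$train, ]
    te <- samples[samples$subject == f$test, ]
    cfg <- config; cfg$seed <- seeds[i]
    fits[[i]] <- list(
      fold = f,
      test = te,
      net = train_network(as.matrix(tr[feat]), tr$target, arch, cfg,
                          stopping = if (stopping == "mse")
                            list(mse_threshold = config$mse_threshold)
                          else list(fixed_epoch = config$max_epochs),
                          validation = list(x = as.matrix(te[feat]), y = te$target),
                          keep_history = (stopping == "plateau")))
  }

  if (stopping == "plateau") {
    len <- min(vapply(fits, function(z) nrow(z$net$trace), 0L))
    ccf_mat <- vapply(fits, function(z) z$net$trace$ccf_validation[seq_len(len)],
                      numeric(len))
    avg_ccf <- rowMeans(ccf_mat)
    stop_ep <- stopping_epoch(avg_ccf, plateau_window_fraction, tolerance_fraction)
  } else {
    avg_ccf <- NULL
    stop_ep <- NA_integer_
  }

  fold_results <- lapply(seq_along(fits), function(i) {
    z <- fits[[i]]
    net <- z$net
    ep <- if (stopping == "plateau") stop_ep else nrow(net$trace)
    w <- if (stopping == "plateau") net$history[[ep]] else net$weights
    pred <- mlp_forward(w, as.matrix(z$test[feat]), arch)$output
    list(subject = z$fold$test,
         trace = net$trace,
         stopping_epoch = ep,
         stopping_mse = net$trace$mse[ep],
         converged = net$converged,
         heldout_ccf = ccf(pred, z$test$target, eval_cfg),
         heldout_auroc = roc_curve(pred, z$test$label)$auroc,
         predictions = data.frame(subject = z$test$subject,
                                  slice = z$test$slice, row = z$test$row,
                                  col = z$test$col, predicted = pred,
                                  target = z$test$target,
                                  label = z$test$label))
  })

  pooled <- do.call(rbind, lapply(fold_results, `[[`, "predictions"))
  structure(list(folds = fold_results, pooled = pooled,
                 avg_heldout_ccf = avg_ccf, stopping_epoch = stop_ep,
                 termination_error = termination_error(fold_results),
                 arch = arch, config = config, stopping = stopping),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation: %d folds (%s stopping)\n",
              length(x$folds), x$stopping))
  cat(sprintf("  termination error (mean stopping MSE): %.4f\n", x$termination_error))
  cat(sprintf("  pooled held-out AUROC: %.4f\n",
              roc_curve(x$pooled$predicted, x$pooled$label)$auroc))
  invisible(x)
}

#' Select the second-hidden-layer size by maximizing AUCCF
#'
#' For each candidate size the full leave-one-out loop is run (first hidden
#' layer fixed at 3 units, the smallest trainable size) and the CCF of the
#' concatenated held-out predictions is computed at each epoch index (traces
#' aligned by truncation to the shortest fold). The normalized area under
#' that pooled CCF curve (AUCCF) scores the candidate; the maximum wins and
#' ties break toward the smaller network.
#'
#' @param samples pooled sample data.frame.
#' @param candidates integer vector of second-hidden-layer sizes (>= 1).
#' @param config a \code{training_config}; \code{max_epochs} bounds each
#'   fold's training.
#' @param hidden1 first hidden layer size (default 3).
#' @param output_range network output range.
#' @return object of class \code{architecture_search}: \code{candidates},
#'   \code{auccf} per candidate, and the \code{selected} size.
#' @export
architecture_search <- function(samples, candidates, config = training_config(),
                                hidden1 = 3, output_range = c(0, 3)) {
  if (length(candidates) == 0) stop2("architecture_search: no candidates")
  if (any(candidates < 1)) stop2("architecture_search: candidate sizes must be >= 1")
  ids <- unique(samples$subject)
  folds <- loocv_folds(ids)
  seeds <- split_seed(config$seed, length(folds))
  feat <- c("dwi", "t1", "t2", "pd")

  scores <- vapply(candidates, function(n2) {
    arch <- network_architecture(hidden1 = hidden1, hidden2 = n2,
                                 output_range = output_range)
    eval_cfg <- evaluation_config(window = config$ccf_window, range = output_range)
    preds <- vector("list", length(folds))
    for (i in seq_along(folds)) {
      f <- folds[[i]]
      tr <- samples[samples$subject %in% f$train, ]
      te <- samples[samples$subject == f$test, ]
      cfg <- config; cfg$seed <- seeds[i]
      net <- train_network(as.matrix(tr[feat]), tr$target, arch, cfg,
                           stopping = list(fixed_epoch = config$max_epochs),
                           keep_history = TRUE, trace_ccf = FALSE)
      outs <- vapply(net$history,
                     function(w) mlp_forward(w, as.matrix(te[feat]), arch)$output,
                     numeric(nrow(te)))
      preds[[i]] <- list(outs = outs, gold = te$target)
    }
    len <- min(vapply(preds, function(p) ncol(p$outs), 0L))
    gold <- unlist(lapply(preds, `[[`, "gold"))
    pooled_ccf <- vapply(seq_len(len), function(ep) {
      ccf(unlist(lapply(preds, function(p) p$outs[, ep])), gold, eval_cfg)
    }, 0)
    auccf(pooled_ccf)
  }, 0)

  best <- max(scores)
  sel <- min(candidates[scores >= best - 1e-12])
  structure(list(candidates = candidates, auccf = scores, selected = sel),
            class = "architecture_search")
}

#' @export
print.architecture_search <- function(x, ...) {
  cat("Second-hidden-layer search (AUCCF):\n")
  print(data.frame(size = x$candidates, auccf = round(x$auccf, 4)))
  cat("Selected size:", x$selected, "\n")
  invisible(x)
}
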