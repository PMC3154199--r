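#' Evaluation configuration
#'
#' @param window discretization window for the correct-classification
#'   fraction, on the normalized-intensity scale (default 0.05, the minimum
#'   acceptable interval of T2WI signal change).
#' @param range value range used for binning (default \code{c(0, 3)}).
#' @param match either \code{"bin"} (same discrete bin index, default) or
#'   \code{"band"} (absolute difference at most one window).
#' @return list of class \code{evaluation_config}.
#' @export
evaluation_config <- function(window = 0.05, range = c(0, 3), match = "bin") {
  if (window <= 0) stop2("evaluation_config: window must be positive")
  match <- match.arg(match, c("bin", "band"))
  structure(list(window = window, range = range, match = match),
            class = "evaluation_config")
}

#' Discretize intensities into fixed-width bins
#'
#' Values are broken into fragments of width \code{window} over the
#' configured range: bin = floor((value - lo) / window), 0-based, with the
#' exact upper range edge assigned to the last bin. Out-of-range values are
#' clipped to the range bounds.
#'
#' @param value numeric vector.
#' @param config an \code{\link{evaluation_config}}.
#' @return integer vector of bin indices.
#' @export
discretize <- function(value, config = evaluation_config()) {
  lo <- config$range[1]; hi <- config$range[2]
  v <- pmin(pmax(value, lo), hi)
  nbins <- ceiling((hi - lo) / config$window)
  b <- floor((v - lo) / config$window)
  as.integer(pmin(b, nbins - 1L))
}

#' Correct classification fraction (CCF)
#'
#' The fraction of voxels whose predicted value falls in the same
#' discretization bin as the gold-standard value — the ratio of voxels
#' successfully classified to all voxels shown to the network. With
#' \code{match = "band"} a prediction instead counts as correct when it is
#' within one window of the gold value.
#'
#' @param predicted,gold numeric vectors of equal length.
#' @param config an \code{\link{evaluation_config}}.
#' @return fraction in [0, 1].
#' @export
ccf <- function(predicted, gold, config = evaluation_config()) {
  if (length(predicted) != length(gold))
    stop2("ccf: predicted and gold lengths differ")
  if (length(gold) == 0) stop2("ccf: empty input")
  if (config$match == "bin") {
    mean(discretize(predicted, config) == discretize(gold, config))
  } else {
    mean(abs(predicted - gold) <= config$window)
  }
}

#' Normalized area under a CCF curve (AUCCF)
#'
#' Trapezoidal area under a CCF series (against epochs or against a neuron
#' count), normalized by the index span so that a constant curve of height c
#' scores c. Used as the model-selection index: it rises with the ROC area.
#'
#' @param ccf_values numeric CCF series (>= 2 points).
#' @return unitless area in [0, 1] for CCF-valued input.
#' @export
auccf <- function(ccf_values) {
  n <- length(ccf_values)
  if (n < 2) stop2("auccf: need at least 2 points")
  sum((ccf_values[-n] + ccf_values[-1]) / 2) / (n - 1)
}

#' Empirical ROC curve
#'
#' Sweeps thresholds over all midpoints between consecutive distinct scores,
#' plus sentinels beyond the extremes, classifying a voxel as lesion when its
#' score exceeds the threshold. The true-positive fraction (sensitivity) and
#' false-positive fraction (1 - specificity) at each threshold form a
#' monotone curve from (0,0) to (1,1); its trapezoidal area (AUROC) equals
#' the tie-corrected probability that a random lesion voxel outscores a
#' random normal voxel.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = lesion, 0 = normal); both classes must be
#'   present.
#' @return object of class \code{roc_curve} with \code{points} (threshold,
#'   fpf, tpf) and \code{auroc}.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop2("roc_curve: length mismatch")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop2("roc_curve: labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop2("roc_curve: both classes must be present")
  u <- sort(unique(scores))
  thr <- if (length(u) > 1) c(Inf, rev(u[-length(u)] + diff(u) / 2), -Inf)
         else c(Inf, -Inf)
  pts <- t(vapply(thr, function(t) {
    pos <- scores > t
    c(fpf = sum(pos & labels == 0L) / n0, tpf = sum(pos & labels == 1L) / n1)
  }, c(fpf = 0, tpf = 0)))
  curve <- data.frame(threshold = thr, fpf = pts[, "fpf"], tpf = pts[, "tpf"])
  au <- sum(diff(curve$fpf) * (curve$tpf[-nrow(curve)] + curve$tpf[-1]) / 2)
  structure(list(points = curve, auroc = au, n_lesion = n1, n_normal = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUROC = %.4f (%d lesion / %d normal voxels)\n",
              nrow(x$points), x$auroc, x$n_lesion, x$n_normal))
  invisible(x)
}

# roc_curve-shaped object from bare (fpf, tpf) vertices, e.g. an analytic curve
as_roc_curve <- function(fpf, tpf) {
  o <- order(fpf, tpf)
  curve <- data.frame(threshold = NA_real_, fpf = fpf[o], tpf = tpf[o])
  au <- sum(diff(curve$fpf) * (curve$tpf[-nrow(curve)] + curve$tpf[-1]) / 2)
  structure(list(points = curve, auroc = au, n_lesion = NA_integer_,
                 n_normal = NA_integer_), class = "roc_curve")
}

#' Half-angle optimal operating point of a ROC curve
#'
#' The operating point is read off where the piecewise-linear ROC intersects
#' the descending 45-degree line TPF = 1 - FPF (the sensitivity = specificity
#' locus), linearly interpolating between curve vertices. On the intersection
#' point sensitivity and specificity are equal by construction.
#'
#' @param roc a \code{roc_curve}.
#' @return object of class \code{operating_point}: \code{sensitivity},
#'   \code{specificity}, \code{fpf}, and the interpolated \code{threshold}
#'   (NA for analytic curves).
#' @export
optimal_point <- function(roc) {
  p <- roc$points
  # g changes sign exactly where the curve crosses tpf = 1 - fpf
  g <- p$tpf + p$fpf - 1
  i <- which(g >= 0)[1]
  if (is.na(i)) stop2("optimal_point: curve never reaches the anti-diagonal")
  if (i == 1L || g[i] == 0) {
    fpf <- p$fpf[i]; tpf <- p$tpf[i]; thr <- p$threshold[i]
  } else {
    w <- g[i - 1] / (g[i - 1] - g[i])
    fpf <- p$fpf[i - 1] + w * (p$fpf[i] - p$fpf[i - 1])
    tpf <- p$tpf[i - 1] + w * (p$tpf[i] - p$tpf[i - 1])
    thr <- if (all(is.finite(p$threshold[c(i - 1, i)])))
      p$threshold[i - 1] + w * (p$threshold[i] - p$threshold[i - 1])
    else p$threshold[i]
  }
  structure(list(sensitivity = tpf, specificity = 1 - fpf, fpf = fpf,
                 threshold = thr),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Optimal operating point: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Confusion fractions at a threshold
#'
#' A voxel is called lesion when its score exceeds the threshold. Returns the
#' true-positive fraction (sensitivity), true-negative fraction
#' (specificity), and false-positive fraction (1 - specificity).
#'
#' @param scores numeric scores; @param labels binary labels (both classes
#'   required); @param threshold decision threshold.
#' @return named list with \code{tpf}, \code{tnf}, \code{fpf}.
#' @export
confusion_fractions <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop2("confusion_fractions: both classes must be present")
  pos <- scores > threshold
  tpf <- sum(pos & labels == 1L) / n1
  fpf <- sum(pos & labels == 0L) / n0
  list(tpf = tpf, tnf = 1 - fpf, fpf = fpf)
}

#' Correlation of predicted and observed maps, adjusted for patient clusters
#'
#' Ordinary least squares of the observed (gold) values on the predicted
#' values over all voxels, with the slope's variance estimated by the
#' cluster-robust sandwich: voxels of one patient are correlated, so the meat
#' is the sum of within-cluster score outer products and the two-sided
#' p-value uses a t reference with (number of clusters - 1) degrees of
#' freedom. The Pearson correlation r is reported alongside.
#'
#' @param predicted,gold numeric vectors over all voxels.
#' @param cluster cluster (patient) id per voxel; at least 2 clusters.
#' @return object of class \code{cluster_correlation}: \code{r},
#'   \code{slope}, \code{intercept}, \code{se} (cluster-robust),
#'   \code{t}, \code{p}, \code{n_clusters}, \code{n}.
#' @export
cluster_adjusted_correlation <- function(predicted, gold, cluster) {
  n <- length(predicted)
  if (length(gold) != n || length(cluster) != n)
    stop2("cluster_adjusted_correlation: length mismatch")
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < 2) stop2("cluster_adjusted_correlation: need at least 2 clusters")
  X <- cbind(1, predicted)
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, gold)
  e <- gold - X %*% beta
  meat <- matrix(0, 2, 2)
  for (g in unique(cluster)) {
    sel <- cluster == g
    sg <- crossprod(X[sel, , drop = FALSE], e[sel])
    meat <- meat + tcrossprod(sg)
  }
  V <- XtX_inv %*% meat %*% XtX_inv
  se <- sqrt(V[2, 2])
  tval <- beta[2] / se
  p <- 2 * stats::pt(-abs(tval), df = G - 1)
  structure(list(r = stats::cor(predicted, gold), slope = beta[2],
                 intercept = beta[1], se = se, t = tval, p = p,
                 n_clusters = G, n = n),
            class = "cluster_correlation")
}

#' @export
print.cluster_correlation <- function(x, ...) {
  cat(sprintf("Cluster-adjusted correlation: r = %.3f, slope = %.3f (robust SE %.4f), p = %.3g (n = %d voxels, %d clusters)\n",
              x$r, x$slope, x$se, x$p, x$n, x$n_clusters))
  invisible(x)
}
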