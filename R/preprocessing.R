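#' Smooth a 2D image with a 3x3 unity (box) filter
#'
#' Each output voxel is the unweighted mean of its 3x3 neighbourhood, the
#' smoothing applied to reduce residual mis-registration effects before
#' normalization. Borders use symmetric (edge-replicating) padding so
#' brain-edge voxels are not darkened the way zero padding would.
#'
#' @param image numeric matrix, at least 3x3.
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_image <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop2("smooth_image: image must be a matrix of at least 3x3")
  .box_smooth(image, 1L)
}

#' Smooth every slice of every channel of a study
#'
#' @param study a \code{subject_study}.
#' @param channels channel names to smooth; default all (including the
#'   chronic outcome channel).
#' @return the study with smoothed channels.
#' @export
smooth_study <- function(study, channels = names(study$channels)) {
  for (ch in channels) {
    vol <- study$channels[[ch]]
    for (s in seq_len(dim(vol)[3])) vol[, , s] <- smooth_image(vol[, , s])
    study$channels[[ch]] <- vol
  }
  study
}

#' Brain mask from the acute T2WI
#'
#' Thresholds the smoothed acute T2WI at a fraction of the whole-stack
#' maximum, giving the support over which channel means (the normalization
#' denominators) are computed.
#'
#' @param study a \code{subject_study} with a \code{t2} channel.
#' @param fraction threshold as a fraction of the stack maximum (default
#'   0.10).
#' @return logical array of the study's dimensions.
#' @export
brain_mask <- function(study, fraction = 0.10) {
  if (is.null(study$channels$t2)) stop2("brain_mask: study has no t2 channel")
  vol <- study$channels$t2
  sm <- vol
  for (s in seq_len(dim(vol)[3])) sm[, , s] <- smooth_image(vol[, , s])
  mask <- sm >= fraction * max(sm)
  if (!any(mask)) stop2("brain_mask: mask is empty")
  mask
}

#' Normalize a study to its brain-mean intensities
#'
#' Divides every channel by the mean of that channel inside the brain mask,
#' computed once over the whole study (all slices). This makes the feature
#' set insensitive to the MR system gain: multiplying any channel by a
#' positive constant leaves the normalized channel unchanged. The chronic
#' outcome channel is normalized the same way, putting the regression target
#' on a brain-mean = 1 scale (nominal range 0-3).
#'
#' @param study a \code{subject_study}.
#' @param mask logical array from \code{\link{brain_mask}}; computed if
#'   missing.
#' @return the study with normalized channels, the mask attached as
#'   \code{$brain_mask}, and \code{$normalized = TRUE}.
#' @export
normalize_study <- function(study, mask = NULL) {
  if (is.null(mask)) mask <- brain_mask(study)
  if (!any(mask)) stop2("normalize_study: mask is empty")
  for (ch in names(study$channels)) {
    m <- mean(study$channels[[ch]][mask])
    if (!is.finite(m) || m == 0)
      stop2(sprintf("normalize_study: zero in-mask mean for channel '%s'", ch))
    study$channels[[ch]] <- study$channels[[ch]] / m
  }
  study$brain_mask <- mask
  study$normalized <- TRUE
  study
}

#' Define lesion and contralateral-normal ROIs
#'
#' The lesion ROI is obtained by thresholding the normalized chronic T2WI;
#' the normal ROI is the lesion ROI reflected about the midline column, the
#' device used to balance lesion and normal samples. Mirrored voxels that
#' fall back inside the lesion ROI (midline-crossing lesions, bright midline
#' CSF) are removed from the normal mask with a warning. Prevalence is the
#' lesion fraction of all selected voxels.
#'
#' @param chronic normalized chronic T2WI array (\code{nrow x ncol x
#'   nslices}) or a normalized \code{subject_study}.
#' @param threshold intensity threshold (> 0) on the normalized scale.
#' @param midline column position (1-based, may be half-integer) of the
#'   reflection axis; default the image centre \code{(ncol + 1) / 2}.
#' @param target_prevalence optional requested lesion prevalence; when given,
#'   the normal mask is eroded (voxels dropped) or dilated (in-brain
#'   neighbours added) to land within 2 percentage points of it. Default
#'   off: prevalence is an outcome of the ROI construction, not a constraint.
#' @param brain optional logical array restricting dilation to brain voxels.
#' @return an object of class \code{roi_set}: \code{lesion} and
#'   \code{normal} logical arrays plus the achieved \code{prevalence}.
#' @export
define_rois <- function(chronic, threshold, midline = NULL,
                        target_prevalence = NULL, brain = NULL) {
  if (inherits(chronic, "subject_study")) {
    if (!isTRUE(chronic$normalized))
      stop2("define_rois: study must be normalized first")
    if (is.null(brain)) brain <- chronic$brain_mask
    chronic <- chronic$channels$chronic_t2
  }
  if (threshold <= 0) stop2("define_rois: threshold must be positive")
  dims <- dim(chronic)
  lesion <- chronic > threshold
  if (!any(lesion))
    stop2(sprintf("define_rois: no voxels exceed threshold %.3f", threshold))
  if (is.null(midline)) midline <- (dims[2] + 1) / 2

  normal <- array(FALSE, dims)
  idx <- which(lesion, arr.ind = TRUE)
  mcol <- as.integer(round(2 * midline - idx[, 2]))
  ok <- mcol >= 1L & mcol <= dims[2]
  if (any(!ok))
    warning("define_rois: some mirrored voxels fall outside the grid and were dropped")
  midx <- cbind(idx[ok, 1], mcol[ok], idx[ok, 3])
  normal[midx] <- TRUE
  overlap <- normal & lesion
  if (any(overlap)) {
    warning(sprintf(
      "define_rois: %d mirrored voxel(s) overlap the lesion ROI and were removed from the normal mask",
      sum(overlap)))
    normal[overlap] <- FALSE
  }
  if (!any(normal)) stop2("define_rois: contralateral normal mask is empty")

  if (!is.null(target_prevalence)) {
    normal <- .adjust_normal_mask(lesion, normal, target_prevalence, brain)
  }
  prevalence <- sum(lesion) / (sum(lesion) + sum(normal))
  structure(list(lesion = lesion, normal = normal, prevalence = prevalence,
                 threshold = threshold, midline = midline),
            class = "roi_set")
}

# deterministically erode (drop trailing voxels) or dilate (grow into
# in-brain 4-neighbours) the normal mask until prevalence is within 2
# percentage points of the request
.adjust_normal_mask <- function(lesion, normal, target, brain) {
  L <- sum(lesion)
  want_n <- function() round(L / target - L)
  n_target <- max(1L, want_n())
  cur <- sum(normal)
  if (cur > n_target) {
    drop <- which(normal)[seq.int(n_target + 1L, cur)]
    normal[drop] <- FALSE
  } else if (cur < n_target) {
    dims <- dim(normal)
    allowed <- if (is.null(brain)) !lesion else (brain & !lesion)
    repeat {
      if (sum(normal) >= n_target) break
      idx <- which(normal, arr.ind = TRUE)
      cand <- rbind(
        cbind(idx[, 1] - 1L, idx[, 2], idx[, 3]),
        cbind(idx[, 1] + 1L, idx[, 2], idx[, 3]),
        cbind(idx[, 1], idx[, 2] - 1L, idx[, 3]),
        cbind(idx[, 1], idx[, 2] + 1L, idx[, 3]))
      cand <- cand[cand[, 1] >= 1 & cand[, 1] <= dims[1] &
                     cand[, 2] >= 1 & cand[, 2] <= dims[2], , drop = FALSE]
      new <- cand[allowed[cand] & !normal[cand], , drop = FALSE]
      if (nrow(new) == 0) {
        warning("define_rois: could not dilate normal mask to the requested prevalence")
        break
      }
      need <- n_target - sum(normal)
      new <- unique(new)
      if (nrow(new) > need) new <- new[seq_len(need), , drop = FALSE]
      normal[new] <- TRUE
    }
  }
  normal
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d lesion voxel(s), %d normal voxel(s), prevalence %.3f\n",
              sum(x$lesion), sum(x$normal), x$prevalence))
  invisible(x)
}

#' Assemble per-voxel training samples from a normalized study
#'
#' One sample per ROI voxel: the 4 normalized acute intensities as features,
#' the normalized chronic T2WI intensity as the continuous regression target,
#' and a binary label (1 = lesion ROI, 0 = contralateral normal ROI) kept for
#' the classification-style evaluation statistics.
#'
#' @param study a normalized \code{subject_study}.
#' @param rois a \code{\link{define_rois}} result.
#' @return a \code{data.frame} with columns \code{subject}, \code{slice},
#'   \code{row}, \code{col}, \code{dwi}, \code{t1}, \code{t2}, \code{pd},
#'   \code{target}, \code{label}.
#' @export
extract_samples <- function(study, rois) {
  if (!isTRUE(study$normalized))
    stop2("extract_samples: study must be normalized first")
  need <- c("dwi", "t1", "t2", "pd", "chronic_t2")
  missing_ch <- setdiff(need, names(study$channels))
  if (length(missing_ch))
    stop2("extract_samples: missing channel(s): ", paste(missing_ch, collapse = ", "))
  if (!any(rois$normal)) stop2("extract_samples: normal mask is empty")
  if (!any(rois$lesion)) stop2("extract_samples: lesion mask is empty")
  dims <- dim(study$channels$dwi)
  if (!all(dim(rois$lesion) == dims))
    stop2("extract_samples: ROI masks do not match the study grid")

  one <- function(mask, label) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(subject = study$subject,
               slice = idx[, 3], row = idx[, 1], col = idx[, 2],
               dwi = study$channels$dwi[mask],
               t1 = study$channels$t1[mask],
               t2 = study$channels$t2[mask],
               pd = study$channels$pd[mask],
               target = study$channels$chronic_t2[mask],
               label = label,
               stringsAsFactors = FALSE)
  }
  rbind(one(rois$lesion, 1L), one(rois$normal, 0L))
}

#' Preprocess one study end to end
#'
#' Convenience wrapper: smooth all channels, compute the brain mask,
#' normalize to brain means, threshold the chronic T2WI into ROIs, and
#' extract per-voxel samples.
#'
#' @param study a raw \code{subject_study}.
#' @param roi_threshold chronic-T2WI threshold on the normalized scale.
#' @param midline reflection axis (default image centre).
#' @param mask_fraction brain-mask threshold fraction.
#' @param target_prevalence optional prevalence request (see
#'   \code{\link{define_rois}}).
#' @return list with the normalized \code{study}, the \code{rois}, and the
#'   \code{samples} data.frame.
#' @export
preprocess_study <- function(study, roi_threshold = 1.35, midline = NULL,
                             mask_fraction = 0.10, target_prevalence = NULL) {
  study <- smooth_study(study)
  mask <- brain_mask(study, mask_fraction)
  study <- normalize_study(study, mask)
  rois <- define_rois(study, roi_threshold, midline,
                      target_prevalence = target_prevalence, brain = mask)
  samples <- extract_samples(study, rois)
  list(study = study, rois = rois, samples = samples)
}
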