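#' Tissue intensity model for multi-parametric MRI phantoms
#'
#' Describes three tissue populations (normal parenchyma, ischemic lesion,
#' CSF) by class-conditional Gaussian intensities in five channels: the four
#' acute contrasts (DWI, T1WI, T2WI, PDWI) and the chronic (3-month) T2WI
#' outcome. Intensities are unitless, expressed relative to a whole-brain
#' mean of about 1, the scale the analysis works on after normalization.
#' The defaults encode the qualitative contrast the method relies on: the
#' ischemic lesion is bright and CSF dark on DWI, while both are bright on
#' the chronic T2WI, so the lesion/CSF DWI contrast inverts between input
#' and outcome.
#'
#' @param means named matrix (rows \code{normal}, \code{lesion}, \code{csf};
#'   columns \code{dwi}, \code{t1}, \code{t2}, \code{pd},
#'   \code{chronic_t2}) of class-conditional mean intensities.
#' @param sds matrix of the same shape giving per-class, per-channel
#'   intensity standard deviations (all >= 0).
#' @param smoothness half-width, in voxels, of the box kernel applied to the
#'   noise field (not to class boundaries); 0 disables spatial coherence.
#' @param jitter integer (row, column) shift applied to the chronic channel
#'   only, emulating residual mis-registration; default none.
#' @param lesion acute lesion geometry: list with \code{center} (row, col)
#'   and \code{radius}, a per-slice vector of radii in voxels (0 = no lesion
#'   on that slice).
#' @param chronic_scale multiplier applied to the acute lesion radii to give
#'   the chronic lesion geometry (>1 growth, <1 recovery, 1 = same extent).
#' @param csf CSF geometry: list with \code{centers} (matrix of (row, col)
#'   disk centers, mirrored placement keeps the phantom bilaterally
#'   symmetric) and \code{radius} (scalar, voxels).
#'
#' @return an object of class \code{tissue_model}.
#' @export
tissue_model <- function(means = NULL, sds = NULL, smoothness = 1,
                         jitter = c(0L, 0L),
                         lesion = list(center = c(0.45, 0.28),
                                       radius = c(2, 3, 3.5, 4, 3.5, 3, 2)),
                         chronic_scale = 1,
                         csf = list(centers = rbind(c(0.5, 0.42),
                                                    c(0.5, 0.58)),
                                    radius = 1.2)) {
  channels <- c("dwi", "t1", "t2", "pd", "chronic_t2")
  classes <- c("normal", "lesion", "csf")
  if (is.null(means)) {
    means <- rbind(
      normal = c(dwi = 1.0, t1 = 1.0, t2 = 1.0, pd = 1.0, chronic_t2 = 0.9),
      lesion = c(dwi = 1.6, t1 = 0.9, t2 = 1.3, pd = 1.2, chronic_t2 = 1.8),
      csf    = c(dwi = 0.4, t1 = 0.6, t2 = 1.6, pd = 1.3, chronic_t2 = 1.9))
  }
  if (is.null(sds)) {
    sds <- matrix(0.1, 3, 5, dimnames = list(classes, channels))
  }
  means <- as.matrix(means)[classes, channels]
  sds <- as.matrix(sds)[classes, channels]
  if (any(sds < 0)) stop2("tissue_model: all intensity SDs must be >= 0")
  if (means["lesion", "chronic_t2"] <= means["normal", "chronic_t2"])
    stop2("tissue_model: lesion must be brighter than normal tissue on the chronic T2WI")
  if (means["csf", "dwi"] >= means["normal", "dwi"])
    stop2("tissue_model: CSF must be darker than normal tissue on DWI")
  if (means["csf", "chronic_t2"] <= means["normal", "chronic_t2"])
    stop2("tissue_model: CSF must be brighter than normal tissue on the chronic T2WI")
  structure(list(means = means, sds = sds, smoothness = smoothness,
                 jitter = as.integer(jitter), lesion = lesion,
                 chronic_scale = chronic_scale, csf = csf,
                 channels = channels, classes = classes),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue intensity model (brain-mean units)\n")
  cat("Class means:\n"); print(round(x$means, 3))
  cat("Noise-field smoothing half-width:", x$smoothness, "voxel(s)\n")
  invisible(x)
}

# fractional coordinates (all <= 1) are placed relative to the grid centre so
# that a pair of fractions symmetric about 0.5 stays mirror-symmetric about
# the central column for any grid width
.to_grid <- function(coord, nr, nc) {
  if (all(coord <= 1))
    c((nr + 1) / 2 + (coord[1] - 0.5) * nr, (nc + 1) / 2 + (coord[2] - 0.5) * nc)
  else coord
}

# disk membership on an (nr x nc) grid; center in voxel units, radius in voxels
.disk <- function(nr, nc, center, radius) {
  if (radius <= 0) return(matrix(FALSE, nr, nc))
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# elliptical "brain" support leaving a background rim
.brain_support <- function(nr, nc, margin = 2) {
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ay <- nr / 2 - margin; ax <- nc / 2 - margin
  ((r - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
}

# box smoothing of a noise field, symmetric (edge-replicating) padding
.box_smooth <- function(m, hw) {
  if (hw <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, hw), seq_len(nr), rep(nr, hw))
  ci <- c(rep(1L, hw), seq_len(nc), rep(nc, hw))
  p <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  k <- 2L * hw + 1L
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L))
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  out / k^2
}

#' Generate one synthetic multi-parametric stroke study
#'
#' Builds a stack of 2D phantom slices with an elliptical brain, a one-sided
#' ischemic lesion whose radius varies across slices, and a symmetric pair of
#' CSF (ventricle) disks. Voxel intensities are drawn class-wise from the
#' model's Gaussian intensity distributions (truncated at 0); the noise field
#' is spatially smoothed so neighbouring voxels are correlated, while class
#' boundaries stay crisp. The chronic T2WI channel uses the chronic lesion
#' geometry (acute radii times \code{chronic_scale}) and may be shifted by an
#' integer mis-registration jitter.
#'
#' @param seed integer seed; identical (seed, parameters) gives bit-identical
#'   studies.
#' @param geometry list with \code{nrow}, \code{ncol}, \code{nslices}.
#' @param model a \code{\link{tissue_model}}.
#' @param subject_id subject identifier string.
#' @return an object of class \code{subject_study}: named channel arrays
#'   (\code{nrow x ncol x nslices}), the true tissue-class map (0 background,
#'   1 normal, 2 lesion, 3 CSF, coded on the acute geometry), and a
#'   provenance record.
#' @export
generate_study <- function(seed, geometry = list(nrow = 32, ncol = 32, nslices = 7),
                           model = tissue_model(), subject_id = "S01") {
  nr <- geometry$nrow; nc <- geometry$ncol; ns <- geometry$nslices
  if (any(c(nr, nc, ns) <= 0)) stop2("generate_study: geometry must be positive")
  radii <- rep_len(model$lesion$radius, ns)
  lc <- .to_grid(model$lesion$center, nr, nc)
  csf_centers <- t(apply(model$csf$centers, 1, .to_grid, nr = nr, nc = nc))

  brain <- .brain_support(nr, nc)
  class_map <- array(0L, c(nr, nc, ns))
  chronic_lesion <- array(FALSE, c(nr, nc, ns))
  for (s in seq_len(ns)) {
    rad <- radii[s]
    if (rad > 0) {
      les <- .disk(nr, nc, lc, rad)
      if (any(les & !brain))
        stop2(sprintf("generate_study: lesion geometry leaves the brain on slice %d", s))
      chr <- .disk(nr, nc, lc, rad * model$chronic_scale)
      if (any(chr & !brain))
        stop2(sprintf("generate_study: chronic lesion geometry leaves the brain on slice %d", s))
    } else {
      les <- chr <- matrix(FALSE, nr, nc)
    }
    cls <- matrix(0L, nr, nc)
    cls[brain] <- 1L
    cls[les] <- 2L
    for (k in seq_len(nrow(csf_centers))) {
      d <- .disk(nr, nc, csf_centers[k, ], model$csf$radius)
      cls[d & brain & !les] <- 3L
    }
    class_map[, , s] <- cls
    chronic_lesion[, , s] <- chr
  }

  channels <- with_seed(seed, {
    out <- list()
    for (ch in model$channels) {
      vol <- array(0, c(nr, nc, ns))
      for (s in seq_len(ns)) {
        cls <- class_map[, , s]
        # chronic channel follows the chronic lesion geometry
        if (ch == "chronic_t2") {
          cls2 <- cls
          cls2[cls2 == 2L] <- 1L
          cls2[chronic_lesion[, , s] & cls2 == 1L] <- 2L
          cls <- cls2
        }
        mu <- matrix(0, nr, nc)
        sd <- matrix(0, nr, nc)
        for (ci in 1:3) {
          sel <- cls == ci
          mu[sel] <- model$means[ci, ch]
          sd[sel] <- model$sds[ci, ch]
        }
        noise <- matrix(stats::rnorm(nr * nc), nr, nc) * sd
        noise <- .box_smooth(noise, model$smoothness)
        img <- mu + noise
        img[cls == 0L] <- 0
        img[img < 0] <- 0
        vol[, , s] <- img
      }
      if (ch == "chronic_t2" && any(model$jitter != 0L)) {
        vol <- .shift_volume(vol, model$jitter)
      }
      out[[ch]] <- vol
    }
    out
  })

  structure(list(subject = subject_id, channels = channels,
                 class_map = class_map,
                 geometry = c(nrow = nr, ncol = nc, nslices = ns),
                 normalized = FALSE,
                 provenance = list(seed = seed,
                                   smoothness = model$smoothness,
                                   jitter = model$jitter,
                                   chronic_scale = model$chronic_scale)),
            class = "subject_study")
}

# integer (row, col) shift with zero fill, applied slice-wise
.shift_volume <- function(vol, shift) {
  nr <- dim(vol)[1]; nc <- dim(vol)[2]
  out <- array(0, dim(vol))
  sr <- shift[1]; sc <- shift[2]
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + sr; cdst <- cs + sc
  ok_r <- rdst >= 1 & rdst <= nr; ok_c <- cdst >= 1 & cdst <= nc
  out[rdst[ok_r], cdst[ok_c], ] <- vol[rs[ok_r], cs[ok_c], , drop = FALSE]
  out
}

#' @export
print.subject_study <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("Subject study '%s': %d x %d voxels, %d slice(s), channels: %s%s\n",
              x$subject, g["nrow"], g["ncol"], g["nslices"],
              paste(names(x$channels), collapse = ", "),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Generate a synthetic cohort of stroke studies
#'
#' Produces \code{n_subjects} phantom studies with unique subject ids and
#' independent noise draws. Each subject receives a sub-seed derived from the
#' master seed. With \code{variation = TRUE} the lesion centre is displaced
#' and the radii rescaled per subject, emulating anatomical variability;
#' with \code{variation = FALSE} all subjects share the exact geometry and
#' differ only in noise.
#'
#' @param n_subjects number of subjects (>= 2, cross-validation needs folds).
#' @param seed master seed.
#' @param model a \code{\link{tissue_model}} (per-subject geometry is derived
#'   from it).
#' @param geometry grid spec passed to \code{\link{generate_study}}.
#' @param variation logical; randomize lesion centre (+/- 1.5 voxels) and
#'   radius scale (0.85-1.15) per subject.
#' @return list of \code{subject_study} objects.
#' @export
generate_cohort <- function(n_subjects = 12, seed = 1, model = tissue_model(),
                            geometry = list(nrow = 32, ncol = 32, nslices = 7),
                            variation = TRUE) {
  if (n_subjects < 2) stop2("generate_cohort: need at least 2 subjects for cross-validation")
  seeds <- split_seed(seed, n_subjects)
  jit <- if (variation) {
    with_seed(seed + 1L, list(
      dr = stats::runif(n_subjects, -1.5, 1.5),
      dc = stats::runif(n_subjects, -1.5, 1.5),
      sc = stats::runif(n_subjects, 0.85, 1.15)))
  } else NULL
  lapply(seq_len(n_subjects), function(i) {
    m <- model
    if (variation) {
      m$lesion$center <- .to_grid(m$lesion$center, geometry$nrow, geometry$ncol) +
        c(jit$dr[i], jit$dc[i])
      m$lesion$radius <- m$lesion$radius * jit$sc[i]
    }
    generate_study(seeds[i], geometry, m,
                   subject_id = sprintf("S%02d", i))
  })
}

#' Patient demographics of the 12-subject stroke cohort
#'
#' Returns the packaged demographic table of the twelve-patient cohort the
#' method was developed on: age, gender, stroke location, ischemic stroke
#' subtype, and the intervals from symptom onset to the acute MRI (hours)
#' and to the outcome MRI (days).
#'
#' @return a \code{data.frame} with columns \code{pt}, \code{age},
#'   \code{gender}, \code{location}, \code{subtype}, \code{onset_acute_h},
#'   \code{onset_outcome_d}.
#' @export
demographic_table <- function() {
  path <- system.file("extdata", "table1_demographics.csv",
                      package = "strokenet", mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ag <- strsplit(raw[["Age/Gender"]], "/", fixed = TRUE)
  out <- data.frame(
    pt = raw[["Pt"]],
    age = as.numeric(vapply(ag, `[`, "", 1L)),
    gender = vapply(ag, `[`, "", 2L),
    location = raw[["Stroke Location"]],
    subtype = raw[["Ischemic Stroke Subtype"]],
    onset_acute_h = raw[["Onset-Acute MRI (hours)"]],
    onset_outcome_d = raw[["Onset-Outcome MRI (days)"]],
    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 12L, all(out$age > 0),
            all(out$onset_acute_h > 0), all(out$onset_outcome_d > 0))
  out
}

#' Write a demographic table with its original column headers
#'
#' Round-trips the cohort table to CSV using the exact published column
#' headers (age and gender recombined as \code{Age/Gender}).
#'
#' @param table a data.frame as returned by \code{\link{demographic_table}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  out <- data.frame(
    Pt = table$pt,
    `Age/Gender` = paste0(table$age, "/", table$gender),
    `Stroke Location` = table$location,
    `Ischemic Stroke Subtype` = table$subtype,
    `Onset-Acute MRI (hours)` = table$onset_acute_h,
    `Onset-Outcome MRI (days)` = table$onset_outcome_d,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
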