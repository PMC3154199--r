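#' Pipeline configuration
#'
#' Exactly one of \code{paths} (a list of per-subject NIfTI channel files) or
#' \code{simulation} (a phantom-cohort spec) must be supplied.
#'
#' @param simulation list with \code{n_subjects}, \code{geometry},
#'   \code{model} (a \code{\link{tissue_model}}), \code{variation}.
#' @param paths named list: one entry per subject, each a named vector of
#'   channel file paths (\code{dwi}, \code{t1}, \code{t2}, \code{pd},
#'   \code{chronic_t2}).
#' @param roi_threshold chronic-T2WI lesion threshold (normalized scale).
#' @param midline reflection axis; NULL = image centre.
#' @param target_prevalence optional prevalence request.
#' @param arch a \code{\link{network_architecture}}.
#' @param training a \code{\link{training_config}}; the pipeline default
#'   raises \code{max_epochs} to 5000 so every fold can descend to the
#'   termination error before the cap intervenes.
#' @param evaluation an \code{\link{evaluation_config}}.
#' @param search_candidates optional integer vector; when given, the
#'   second-hidden-layer size is selected by AUCCF before the final
#'   cross-validated run.
#' @param seed global seed; every downstream seed derives from it.
#' @param out_dir optional output directory; when given, the report, sample
#'   CSVs, ROC/CCF tables and figures, and predicted-map NIfTIs are written.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = list(n_subjects = 12,
                                              geometry = list(nrow = 32, ncol = 32, nslices = 7),
                                              model = tissue_model(),
                                              variation = TRUE),
                            paths = NULL,
                            roi_threshold = 1.35, midline = NULL,
                            target_prevalence = NULL,
                            arch = network_architecture(),
                            training = training_config(max_epochs = 5000),
                            evaluation = evaluation_config(),
                            search_candidates = NULL,
                            seed = 1, out_dir = NULL) {
  if (is.null(simulation) == is.null(paths))
    stop2("pipeline_config: provide exactly one of simulation or paths")
  structure(list(simulation = simulation, paths = paths,
                 roi_threshold = roi_threshold, midline = midline,
                 target_prevalence = target_prevalence, arch = arch,
                 training = training, evaluation = evaluation,
                 search_candidates = search_candidates, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full prediction pipeline
#'
#' Stages: simulate (or load) the cohort; preprocess every study (smooth,
#' brain-mask, normalize, define ROIs, extract samples); optionally select
#' the second-hidden-layer size by AUCCF; run patient-level leave-one-out
#' cross-validation; evaluate the pooled held-out predictions (ROC/AUROC,
#' half-angle operating point, cluster-adjusted correlation, prevalence); and
#' write the report and figure data when an output directory is configured.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{run_report}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  cohort <- stage("simulate/load", {
    if (!is.null(config$simulation)) {
      s <- config$simulation
      generate_cohort(s$n_subjects, seed = config$seed,
                      model = if (is.null(s$model)) tissue_model() else s$model,
                      geometry = s$geometry,
                      variation = isTRUE(s$variation))
    } else {
      lapply(names(config$paths), function(id)
        read_study(config$paths[[id]], subject_id = id))
    }
  })

  prep <- stage("preprocess", lapply(cohort, preprocess_study,
                                     roi_threshold = config$roi_threshold,
                                     midline = config$midline,
                                     target_prevalence = config$target_prevalence))
  samples <- do.call(rbind, lapply(prep, `[[`, "samples"))
  prevalence <- mean(samples$label)
  message(sprintf("pipeline: %d subjects, %d samples, prevalence %.3f",
                  length(cohort), nrow(samples), prevalence))

  arch <- config$arch
  search <- NULL
  if (!is.null(config$search_candidates)) {
    search <- stage("architecture search",
                    architecture_search(samples, config$search_candidates,
                                        config$training,
                                        hidden1 = arch$sizes["hidden1"],
                                        output_range = arch$output_range))
    arch <- network_architecture(hidden1 = arch$sizes["hidden1"],
                                 hidden2 = search$selected,
                                 output_range = arch$output_range)
  }

  cv <- stage("crossval", run_crossval(samples, arch, config$training,
                                       stopping = "mse"))

  report <- stage("evaluate", {
    roc <- roc_curve(cv$pooled$predicted, cv$pooled$label)
    opt <- optimal_point(roc)
    corr <- cluster_adjusted_correlation(cv$pooled$predicted, cv$pooled$target,
                                         cv$pooled$subject)
    structure(list(
      n_subjects = length(cohort),
      n_samples = nrow(samples),
      prevalence = prevalence,
      architecture = unname(arch$sizes),
      search = search,
      folds = lapply(cv$folds, function(f)
        f[c("subject", "stopping_epoch", "stopping_mse", "converged",
            "heldout_ccf", "heldout_auroc")]),
      termination_error = cv$termination_error,
      pooled_auroc = roc$auroc,
      roc = roc,
      optimal = opt,
      correlation = corr,
      pooled = cv$pooled,
      crossval = cv,
      config = config,
      version = as.character(utils::packageVersion("strokenet"))),
      class = "run_report")
  })

  if (!is.null(config$out_dir))
    stage("write outputs", write_maps(report, config$out_dir,
                                      studies = lapply(prep, `[[`, "study")))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Chronic-T2WI prediction report\n")
  cat(sprintf("  subjects: %d, voxel samples: %d, prevalence: %.3f\n",
              x$n_subjects, x$n_samples, x$prevalence))
  cat(sprintf("  network: %s (%d free parameters)\n",
              paste(x$architecture, collapse = ":"),
              n_parameters(network_architecture(x$architecture[2], x$architecture[3],
                                                inputs = x$architecture[1]))))
  cat(sprintf("  termination error (mean stopping MSE): %.4f\n", x$termination_error))
  cat(sprintf("  pooled held-out AUROC: %.4f\n", x$pooled_auroc))
  cat(sprintf("  optimal operating point: sensitivity %.3f / specificity %.3f\n",
              x$optimal$sensitivity, x$optimal$specificity))
  cat(sprintf("  predicted vs observed chronic T2WI: r = %.3f, cluster-robust p = %.3g\n",
              x$correlation$r, x$correlation$p))
  invisible(x)
}

#' Column-wise demographic summary
#'
#' Mean and sample (n-1) standard deviation of every numeric column, rounded
#' to 2 decimals — the form in which cohort demographics are reported.
#'
#' @param table a data.frame, e.g. from \code{\link{demographic_table}}.
#' @return data.frame with \code{column}, \code{mean}, \code{sd}.
#' @export
demographic_summary <- function(table) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  num <- setdiff(num, "pt")
  if (length(num) == 0) stop2("demographic_summary: no numeric columns")
  if (nrow(table) < 2) stop2("demographic_summary: sample SD undefined for fewer than 2 rows")
  data.frame(column = num,
             mean = round(vapply(table[num], mean, 0), 2),
             sd = round(vapply(table[num], stats::sd, 0), 2),
             row.names = NULL)
}

#' Read a subject study from NIfTI channel volumes
#'
#' @param paths named character vector of file paths; names must include
#'   \code{dwi}, \code{t1}, \code{t2}, \code{pd} and (for training data)
#'   \code{chronic_t2}.
#' @param subject_id subject identifier.
#' @return a \code{subject_study}.
#' @export
read_study <- function(paths, subject_id = "S01") {
  need <- c("dwi", "t1", "t2", "pd")
  missing_ch <- setdiff(need, names(paths))
  if (length(missing_ch))
    stop2("read_study: missing channel file(s): ", paste(missing_ch, collapse = ", "))
  channels <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    arr <- array(as.numeric(v), dim(v))
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    arr
  })
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop2("read_study: channel grids differ: ",
          paste(names(dims), vapply(dims, paste, "", collapse = "x"),
                sep = "=", collapse = ", "))
  structure(list(subject = subject_id, channels = channels,
                 class_map = NULL,
                 geometry = c(nrow = dims[[1]][1], ncol = dims[[1]][2],
                              nslices = dims[[1]][3]),
                 normalized = FALSE,
                 provenance = list(paths = paths)),
            class = "subject_study")
}

#' Write a subject study as NIfTI volumes plus a JSON sidecar
#'
#' One float32 volume per channel, named \code{<subject>_<channel>.nii.gz},
#' with the generator's seed and parameters recorded alongside.
#'
#' @param study a \code{subject_study}.
#' @param dir output directory (created if needed).
#' @return named vector of written channel paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(study$channels), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", study$subject, ch))
    RNifti::writeNifti(study$channels[[ch]], p, datatype = "float")
    p
  }, "")
  jsonlite::write_json(study$provenance,
                       file.path(dir, sprintf("%s_provenance.json", study$subject)),
                       auto_unbox = TRUE, digits = NA)
  paths
}

#' Write the pipeline report, tables, figures and predicted maps
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @param studies optional list of normalized studies; when given, each
#'   subject's predicted chronic map (from a network retrained on all other
#'   subjects' voxels during cross-validation) is reconstructed from the
#'   pooled held-out predictions and written as NIfTI.
#' @return \code{dir}, invisibly.
#' @export
write_maps <- function(report, dir, studies = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$pooled, file.path(dir, "heldout_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc$points, file.path(dir, "roc_curve.csv"),
                   row.names = FALSE)
  for (f in report$crossval$folds)
    utils::write.csv(f$trace, file.path(dir, sprintf("trace_%s.csv", f$subject)),
                     row.names = FALSE)

  json <- list(
    version = report$version,
    n_subjects = report$n_subjects, n_samples = report$n_samples,
    prevalence = report$prevalence,
    architecture = report$architecture,
    termination_error = report$termination_error,
    pooled_auroc = report$pooled_auroc,
    optimal_sensitivity = report$optimal$sensitivity,
    optimal_specificity = report$optimal$specificity,
    pearson_r = report$correlation$r,
    cluster_robust_p = report$correlation$p,
    folds = lapply(report$folds, function(f) f[c("subject", "stopping_epoch",
                                                 "stopping_mse", "heldout_ccf",
                                                 "heldout_auroc")]),
    seed = report$config$seed)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  grDevices::png(file.path(dir, "roc_curve.png"), width = 600, height = 600)
  plot(report$roc$points$fpf, report$roc$points$tpf, type = "l",
       xlab = "False-positive fraction (1 - specificity)",
       ylab = "True-positive fraction (sensitivity)",
       main = sprintf("ROC of pooled held-out predictions (AUROC = %.3f)",
                      report$pooled_auroc))
  graphics::abline(1, -1, lty = 3)
  graphics::points(report$optimal$fpf, report$optimal$sensitivity, pch = 19)
  grDevices::dev.off()

  tr1 <- report$crossval$folds[[1]]$trace
  if (!is.null(tr1$ccf_validation)) {
    grDevices::png(file.path(dir, "ccf_curve.png"), width = 600, height = 450)
    plot(tr1$epoch, tr1$ccf_validation, type = "l", xlab = "Epoch",
         ylab = "Held-out CCF", main = "CCF versus epochs (first fold)")
    grDevices::dev.off()
  }

  grDevices::png(file.path(dir, "scatter_predicted_vs_observed.png"),
                 width = 600, height = 600)
  sel <- report$pooled
  plot(sel$predicted, sel$target, pch = ".", col = ifelse(sel$label == 1, 2, 4),
       xlab = "Predicted chronic T2WI (normalized)",
       ylab = "Observed chronic T2WI (normalized)",
       main = sprintf("r = %.3f (n = %d voxels)", report$correlation$r, report$correlation$n))
  grDevices::dev.off()

  if (!is.null(studies)) {
    for (st in studies) {
      pr <- report$pooled[report$pooled$subject == st$subject, ]
      vol <- array(0, dim(st$channels$chronic_t2))
      vol[cbind(pr$row, pr$col, pr$slice)] <- pr$predicted
      RNifti::writeNifti(vol, file.path(dir, sprintf("%s_predicted_chronic_t2.nii.gz",
                                                     st$subject)),
                         datatype = "float")
    }
  }
  invisible(dir)
}
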