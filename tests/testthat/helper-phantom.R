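# Shared fixtures, all generated in code.

# small cohort + pooled samples for cross-validation tests
small_cohort_samples <- function(n_subjects = 3, seed = 99,
                                 geometry = list(nrow = 24, ncol = 24, nslices = 3)) {
  model <- tissue_model(lesion = list(center = c(0.45, 0.3),
                                      radius = c(2.5, 3, 2.5)))
  cohort <- generate_cohort(n_subjects, seed = seed, model = model,
                            geometry = geometry, variation = FALSE)
  prep <- suppressWarnings(lapply(cohort, preprocess_study))
  do.call(rbind, lapply(prep, `[[`, "samples"))
}

# a normalized single study for prediction tests
small_normalized_study <- function(seed = 5) {
  st <- generate_study(seed, geometry = list(nrow = 24, ncol = 24, nslices = 3),
                       model = tissue_model(lesion = list(center = c(0.45, 0.3),
                                                          radius = c(2.5, 3, 2.5))))
  normalize_study(smooth_study(st))
}

# brute-force 3x3 mean with symmetric (edge-replicating) padding — the
# independent smoothing oracle
brute_smooth <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + img[ii, jj]
    }
    out[i, j] <- acc / 9
  }
  out
}

# brute-force tie-corrected AUROC by exhaustive pair counting
brute_auroc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
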