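test_that("3x3 unity filter matches its definition and the brute-force oracle", {
  expect_equal(smooth_image(matrix(4.2, 5, 5)), matrix(4.2, 5, 5))

  imp <- matrix(0, 7, 7); imp[4, 4] <- 9
  sm <- smooth_image(imp)
  expect_equal(sm[3:5, 3:5], matrix(1, 3, 3))
  expect_equal(sum(sm), 9)

  set.seed(1)
  img <- matrix(runif(25), 5, 5)
  expect_equal(smooth_image(img), brute_smooth(img), tolerance = 1e-12)

  expect_error(smooth_image(matrix(1, 2, 5)), "3x3")
})

test_that("smoothing preserves the ordering of a two-level image", {
  set.seed(2)
  for (rep in 1:5) {
    img <- matrix(sample(c(0.5, 2), 64, replace = TRUE), 8, 8)
    sm <- smooth_image(img)
    expect_gte(min(sm), 0.5)
    expect_lte(max(sm), 2)
    # level means keep their order
    expect_lt(mean(sm[img == 0.5]), mean(sm[img == 2]))
  }
})

test_that("brain mask covers the support it should", {
  st <- generate_study(4, list(nrow = 24, ncol = 24, nslices = 2))
  mask <- brain_mask(st)
  # clean zero background: mask must stay inside (the smoothing-dilated)
  # support and cover the undilated brain
  expect_true(all(mask[st$class_map > 0L]))

  flat <- st
  flat$channels$t2 <- array(2, dim(st$channels$t2))
  expect_true(all(brain_mask(flat)))

  one <- st
  one$channels$t2 <- array(1, c(24, 24, 2))
  one$channels$t2[10, 10, 1] <- 5
  m <- brain_mask(one, fraction = 1.0)
  sm <- smooth_image(one$channels$t2[, , 1])
  expect_identical(which(m[, , 1]), which(sm == max(sm)))
})

test_that("normalization is exact, gain-invariant and mean-one", {
  st <- generate_study(9, list(nrow = 24, ncol = 24, nslices = 2))
  mask <- brain_mask(st)

  cst <- st
  cst$channels$dwi <- array(0, dim(mask)); cst$channels$dwi[mask] <- 5
  n1 <- normalize_study(cst, mask)
  expect_equal(unique(n1$channels$dwi[mask]), 1)

  for (k in c(0.5, 3, 100)) {
    scaled <- st
    for (ch in names(scaled$channels))
      scaled$channels[[ch]] <- scaled$channels[[ch]] * k
    a <- normalize_study(st, mask)
    b <- normalize_study(scaled, mask)
    expect_equal(a$channels, b$channels, tolerance = 1e-12)
  }

  n <- normalize_study(st, mask)
  for (ch in names(n$channels))
    expect_equal(mean(n$channels[[ch]][mask]), 1, tolerance = 1e-9)

  # two-voxel mask: values 1 and 3 normalize to 0.5 and 1.5
  toy <- st
  m2 <- array(FALSE, dim(mask)); m2[1, 1, 1] <- TRUE; m2[1, 2, 1] <- TRUE
  for (ch in names(toy$channels)) toy$channels[[ch]][m2] <- 1
  toy$channels$dwi[1, 1, 1] <- 1; toy$channels$dwi[1, 2, 1] <- 3
  n2 <- normalize_study(toy, m2)
  expect_equal(n2$channels$dwi[1, 1, 1], 0.5)
  expect_equal(n2$channels$dwi[1, 2, 1], 1.5)
})

test_that("ROI definition mirrors the lesion about the midline", {
  # one-sided supra-threshold blob: the mirror has the lesion's size, so
  # prevalence is exactly 0.5
  vol <- array(0.5, c(6, 8, 1))
  vol[3:4, 2:3, 1] <- 2
  rois <- define_rois(vol, threshold = 1.5)
  expect_equal(rois$prevalence, 0.5)
  expect_equal(sum(rois$normal), sum(rois$lesion))

  # hand-enumerated mirror: 6x6 slice, 4-voxel patch in columns 1-2,
  # reflection axis at column 3.5 maps columns (1,2) to (6,5)
  toy <- array(0, c(6, 6, 1))
  toy[2:3, 1:2, 1] <- 2
  r2 <- define_rois(toy, threshold = 1, midline = 3.5)
  expect_equal(sum(r2$normal), 4)
  expect_true(all(which(r2$normal[, , 1], arr.ind = TRUE)[, 2] %in% c(5, 6)))
  expect_equal(which(r2$normal[, , 1], arr.ind = TRUE)[, 1], c(2, 3, 2, 3),
               ignore_attr = TRUE)

  expect_error(define_rois(toy, threshold = 99), "99")

  # midline-crossing lesion: the overlapping mirror voxels are removed with
  # a warning, the rest survive
  cross <- array(0, c(6, 6, 1))
  cross[3, 2:4, 1] <- 2
  expect_warning(r3 <- define_rois(cross, threshold = 1, midline = 3.5),
                 "overlap")
  expect_equal(sum(r3$normal & r3$lesion), 0)
  expect_equal(which(r3$normal[, , 1], arr.ind = TRUE), cbind(row = 3L, col = 5L),
               ignore_attr = TRUE)
})

test_that("requested prevalence is honoured within 2 points", {
  st <- small_normalized_study()
  rois <- suppressWarnings(define_rois(st, 1.35, target_prevalence = 0.57,
                                       brain = st$brain_mask))
  expect_lt(abs(rois$prevalence - 0.57), 0.02)
})

test_that("sample extraction is a faithful per-voxel lookup", {
  st <- small_normalized_study()
  dims <- dim(st$channels$dwi)
  lesion <- array(FALSE, dims); normal <- array(FALSE, dims)
  lesion[5:6, 5:9, 1] <- TRUE           # 10 voxels
  normal[10:11, 5:8, 2] <- TRUE         # 8 voxels
  rois <- structure(list(lesion = lesion, normal = normal,
                         prevalence = 10 / 18), class = "roi_set")
  sam <- extract_samples(st, rois)
  expect_equal(nrow(sam), 18)
  expect_equal(sum(sam$label), 10)

  # index-by-index feature lookup
  for (i in c(1, 7, 12, 18)) {
    v <- sam[i, ]
    expect_equal(v$dwi, st$channels$dwi[v$row, v$col, v$slice])
    expect_equal(v$target, st$channels$chronic_t2[v$row, v$col, v$slice])
  }

  none <- rois; none$normal <- array(FALSE, dims)
  expect_error(extract_samples(st, none), "normal mask")
  broke <- st; broke$channels$pd <- NULL
  expect_error(extract_samples(broke, rois), "pd")
})

test_that("prevalence equals the label mean of the extracted samples", {
  st <- small_normalized_study()
  rois <- suppressWarnings(define_rois(st, 1.35, brain = st$brain_mask))
  sam <- extract_samples(st, rois)
  expect_equal(rois$prevalence, mean(sam$label))
})
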