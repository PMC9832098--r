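cfg <- workflow_config()

test_that("nuclear segmentation handles blank and sub-area inputs", {
  blank <- matrix(100, 64, 64)
  expect_message(m <- segment_nuclei(blank, cfg), "empty mask")
  expect_equal(n_labels(m), 0L)

  img <- matrix(100, 64, 64)
  img[30:40, 30:40] <- 3000       # 121 px nucleus
  img[10, 10] <- 3000             # 1 px speck < min_nucleus_area
  m <- segment_nuclei(img, cfg)
  expect_equal(n_labels(m), 1L)
  expect_equal(m$label_image[10, 10], 0L)
})

test_that("noiseless nuclei are found with centroids within 1 px", {
  f <- generate_cell_field(field_spec(n_cells = 15, width = 384,
                                      height = 384, seed = 4))
  m <- segment_nuclei(f$dapi, cfg)
  expect_equal(n_labels(m), 15L)
  map <- match_to_truth(m, f$truth$nuclei)
  for (k in mask_labels(m)) {
    px <- which(m$label_image == k)
    cy <- mean((px - 1) %% 384 + 1)
    cx <- mean((px - 1) %/% 384 + 1)
    tr <- f$truth$cells[f$truth$cells$cell_id == map[[as.character(k)]], ]
    expect_lt(sqrt((cx - tr$x)^2 + (cy - tr$y)^2), 1)
  }
})

test_that("cell segmentation covers reporter-positive area", {
  blank <- matrix(100, 64, 64)
  expect_false(any(segment_cells(blank, cfg)))

  f1 <- generate_cell_field(field_spec(n_cells = 1, infected_fraction = 1,
                                       width = 96, height = 96, seed = 2))
  cm <- segment_cells(f1$venus, cfg)
  area_true <- sum(f1$truth$cell_mask$label_image > 0)
  expect_lt(abs(sum(cm) - area_true) / area_true, 0.05)

  f0 <- generate_cell_field(field_spec(n_cells = 10, infected_fraction = 0,
                                       width = 256, height = 256, seed = 6))
  expect_equal(sum(segment_cells(f0$venus, cfg)), 0L)
})

test_that("uninfected nuclei are discarded exactly on noiseless fields", {
  f <- generate_cell_field(field_spec(n_cells = 30, infected_fraction = 0.7,
                                      width = 448, height = 448, seed = 12))
  nuc <- segment_nuclei(f$dapi, cfg)
  cm <- segment_cells(f$venus, cfg)

  none <- filter_uninfected(nuc, matrix(FALSE, 448, 448), cfg)
  expect_equal(n_labels(none), 0L)
  all_kept <- filter_uninfected(nuc, matrix(TRUE, 448, 448), cfg)
  expect_equal(n_labels(all_kept), n_labels(nuc))

  kept <- filter_uninfected(nuc, cm, cfg)
  map <- match_to_truth(kept, f$truth$nuclei)
  expect_setequal(unname(map),
                  f$truth$cells$cell_id[f$truth$cells$infected])
  # labels of survivors preserved
  expect_true(all(mask_labels(kept) %in% mask_labels(nuc)))
})

test_that("single-nucleus Voronoi region is the whole foreground", {
  lab <- matrix(0L, 64, 64); lab[30:34, 30:34] <- 1L
  nuc <- labeled_mask(lab, "nucleus")
  cm <- matrix(TRUE, 64, 64)
  vp <- voronoi_partition(nuc, cm)
  expect_true(all(vp$label_image == 1L))
})

test_that("symmetric pair splits at the perpendicular bisector", {
  lab <- matrix(0L, 64, 64)
  yy <- outer(1:64, rep(1, 64)); xx <- outer(rep(1, 64), 1:64)
  lab[(yy - 32)^2 + (xx - 20)^2 <= 36] <- 1L
  lab[(yy - 32)^2 + (xx - 45)^2 <= 36] <- 2L
  nuc <- labeled_mask(lab, "nucleus")
  cm <- (xx - 20)^2 + (yy - 32)^2 <= 169 | (xx - 45)^2 + (yy - 32)^2 <= 169
  vp <- voronoi_partition(nuc, cm)$label_image
  # bisector at x = 32.5: columns <= 32 are label 1, >= 33 label 2
  expect_true(all(vp[, 1:32][cm[, 1:32]] == 1L))
  expect_true(all(vp[, 33:64][cm[, 33:64]] == 2L))
})

test_that("Voronoi assignment equals exhaustive nearest-seed search", {
  for (seed in c(31, 32)) {
    f <- clumped_test_field(seed)
    nuc <- segment_nuclei(f$dapi, cfg)
    cm <- segment_cells(f$venus, cfg)
    vp <- voronoi_partition(nuc, cm)
    expect_identical(vp$label_image, brute_force_voronoi(nuc, cm))
  }
})

test_that("cytoplasm masks obey set algebra for every label", {
  f <- clumped_test_field(seed = 41)
  nuc <- segment_nuclei(f$dapi, cfg)
  cm <- segment_cells(f$venus, cfg)
  cells <- voronoi_partition(nuc, cm)
  cyt <- cytoplasm_masks(cells, nuc)
  nl <- nuc$label_image; cl <- cells$label_image; yl <- cyt$label_image
  # disjoint, union = cell region, per label
  expect_true(all((nl > 0) + (yl > 0) <= 1))
  for (k in mask_labels(nuc)) {
    expect_identical(which(cl == k),
                     sort(c(which(nl == k), which(yl == k))))
  }
  # cell-equal-to-nucleus degenerate: empty cytoplasm
  cy2 <- cytoplasm_masks(labeled_mask(nl, "cell"), nuc)
  expect_equal(n_labels(cy2), 0L)
})

test_that("measurement returns exact means on constructed input", {
  uni <- matrix(7, 32, 32)
  lab <- matrix(0L, 32, 32); lab[10:14, 10:14] <- 1L
  cyl <- matrix(0L, 32, 32); cyl[20:24, 20:24] <- 1L
  m <- measure_cells(labeled_mask(lab, "nucleus"),
                     labeled_mask(cyl, "cytoplasm"), uni)
  expect_equal(m$nuclear_mean, 7)
  expect_equal(m$cn_ratio, 1)
  expect_equal(m$cytoplasmic_integrated_density, 7 * 25)

  img <- matrix(0, 32, 32); img[lab == 1L] <- 100; img[cyl == 1L] <- 50
  m2 <- measure_cells(labeled_mask(lab, "nucleus"),
                      labeled_mask(cyl, "cytoplasm"), img)
  expect_equal(m2$cn_ratio, 0.5)

  # absent cytoplasm -> NA ratio
  m3 <- measure_cells(labeled_mask(lab, "nucleus"),
                      labeled_mask(matrix(0L, 32, 32), "cytoplasm"), img)
  expect_true(is.na(m3$cn_ratio))
})

test_that("G0/G1 classification is strict at the 0.65 boundary", {
  m <- data.frame(cell_id = 1:4, nuclear_mean = 1, cytoplasmic_mean = 1,
                  cn_ratio = c(0.64, 0.65, 2.0, NA),
                  cytoplasmic_integrated_density = 1)
  cl <- classify_cycle_state(m, cfg)
  expect_equal(cl$cycle_class, c("G0G1", "cycling", "cycling", "G0G1"))
})

test_that("C/N ratios are invariant to reporter gain; IntDens scales", {
  f <- clumped_test_field(seed = 51, n_cells = 10)
  nuc <- segment_nuclei(f$dapi, cfg)
  cm <- segment_cells(f$venus, cfg)
  cells <- voronoi_partition(nuc, cm)
  cyt <- cytoplasm_masks(cells, nuc)
  m1 <- measure_cells(nuc, cyt, f$venus)
  m3 <- measure_cells(nuc, cyt, f$venus * 3)
  expect_equal(m3$cn_ratio, m1$cn_ratio)
  expect_equal(m3$cytoplasmic_integrated_density,
               3 * m1$cytoplasmic_integrated_density)
})

test_that("residual activity fold change recovers a constructed doubling", {
  mk <- function(cyto, seed, sd = 0) {
    f <- generate_cell_field(field_spec(
      n_cells = 40, width = 512, height = 512, infected_fraction = 1,
      clumped_fraction = 0.2, nuclear_intensity_range = 2000,
      cytoplasmic_intensity_range = cyto, gaussian_noise_sd = sd,
      seed = seed))
    wf <- run_cdk2_workflow(f$dapi, f$venus)
    wf$measurements
  }
  ref <- mk(500, seed = 61)
  dbl <- mk(1000, seed = 61)  # same seed: identical geometry
  sc <- score_residual_activity(list(ref = ref, dbl = dbl), "ref")
  expect_equal(sc$fold_change[sc$condition == "ref"], 1.0)
  expect_equal(sc$fold_change[sc$condition == "dbl"], 2.0,
               tolerance = 0.05)
})

test_that("degenerate residual-activity references are flagged", {
  ok <- data.frame(cell_id = 1, nuclear_mean = 10, cytoplasmic_mean = 5,
                   cn_ratio = 0.5, cytoplasmic_integrated_density = 50,
                   cycle_class = "G0G1")
  none <- ok[0, ]
  expect_warning(sc <- score_residual_activity(list(a = ok, b = none), "b"),
                 "reference")
  expect_true(all(is.na(sc$fold_change)))
  expect_true(sc$degenerate[sc$condition == "b"])
})

test_that("minimum-cell QC is a strict count boundary", {
  m <- function(n) data.frame(cell_id = seq_len(n))
  expect_true(qc_min_cells(m(250), cfg)$pass)
  expect_false(qc_min_cells(m(249), cfg)$pass)
  r <- qc_min_cells(m(0), cfg)
  expect_false(r$pass)
  expect_equal(r$n_cells, 0L)
})

test_that("workflow output is deterministic for fixed input and config", {
  f <- clumped_test_field(seed = 71, n_cells = 12)
  w1 <- run_cdk2_workflow(f$dapi, f$venus, cfg)
  w2 <- run_cdk2_workflow(f$dapi, f$venus, cfg)
  expect_identical(w1$measurements, w2$measurements)
  expect_identical(w1$cells$label_image, w2$cells$label_image)
})
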