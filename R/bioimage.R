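#' Configuration of the CDK2 reporter workflow
#'
#' @param nuclear_threshold_method `"otsu"` (global Otsu on the DAPI
#'   channel) or `"fixed"` (use `nuclear_threshold`).
#' @param nuclear_threshold gray level used when the method is `"fixed"`.
#' @param cell_threshold_method `"otsu2"` (lower threshold of a
#'   three-class Otsu; robust when background, cytoplasm and nucleus form
#'   three modes in the reporter channel), `"otsu"` or `"fixed"`.
#' @param cell_threshold gray level used when the method is `"fixed"`.
#' @param min_nucleus_area smallest nuclear particle kept, in pixels.
#' @param min_overlap_for_infected fraction of a nucleus' pixels that must
#'   lie inside the reporter-positive cell mask for the cell to count as
#'   infected (reporter-negative nuclei are discarded).
#' @param cn_g0g1_threshold C/N ratio below which (strictly) a cell is
#'   classified G0/G1; default 0.65.
#' @param min_cells_per_culture minimum number of scored cells for a
#'   culture to pass QC; default 250.
#' @param background_subtract constant background subtracted from the
#'   reporter image before measurement (default 0: none).
#' @return object of class `workflow_config`.
#' @export
workflow_config <- function(nuclear_threshold_method = c("otsu", "fixed"),
                            nuclear_threshold = NULL,
                            cell_threshold_method = c("otsu2", "otsu",
                                                      "fixed"),
                            cell_threshold = NULL,
                            min_nucleus_area = 50,
                            min_overlap_for_infected = 0.5,
                            cn_g0g1_threshold = 0.65,
                            min_cells_per_culture = 250,
                            background_subtract = 0) {
  cfg <- list(nuclear_threshold_method = match.arg(nuclear_threshold_method),
              nuclear_threshold = nuclear_threshold,
              cell_threshold_method = match.arg(cell_threshold_method),
              cell_threshold = cell_threshold,
              min_nucleus_area = min_nucleus_area,
              min_overlap_for_infected = min_overlap_for_infected,
              cn_g0g1_threshold = cn_g0g1_threshold,
              min_cells_per_culture = min_cells_per_culture,
              background_subtract = background_subtract)
  stopifnot(cfg$min_nucleus_area > 0, cfg$cn_g0g1_threshold > 0,
            cfg$min_overlap_for_infected >= 0,
            cfg$min_overlap_for_infected <= 1)
  if (cfg$nuclear_threshold_method == "fixed" &&
      is.null(cfg$nuclear_threshold))
    stop("`nuclear_threshold` required for method \"fixed\"")
  if (cfg$cell_threshold_method == "fixed" && is.null(cfg$cell_threshold))
    stop("`cell_threshold` required for method \"fixed\"")
  structure(cfg, class = "workflow_config")
}

#' Segment nuclei in a DAPI image
#'
#' Global threshold (Otsu by default), hole filling, connected-component
#' labelling, and removal of particles below `min_nucleus_area`. Labels are
#' renumbered contiguously from 1. A blank or all-background image yields
#' an empty mask, with a message.
#'
#' @param dapi_image 2-D numeric matrix of gray values.
#' @param config a [workflow_config()].
#' @return [labeled_mask] of kind `"nucleus"`.
#' @export
segment_nuclei <- function(dapi_image, config = workflow_config()) {
  stopifnot(is.matrix(dapi_image))
  thr <- switch(config$nuclear_threshold_method,
                otsu = otsu_threshold(as.vector(dapi_image)),
                fixed = config$nuclear_threshold)
  bin <- dapi_image > thr
  if (!any(bin)) {
    message("segment_nuclei: no pixels above threshold; empty mask")
    return(labeled_mask(matrix(0L, nrow(dapi_image), ncol(dapi_image)),
                        "nucleus"))
  }
  img <- EBImage::Image(bin * 1)
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  m <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(dapi_image))
  areas <- label_areas(as.vector(m))
  keep <- as.integer(names(areas)[areas >= config$min_nucleus_area])
  remap <- integer(max(m))
  remap[keep] <- seq_along(keep)
  pos <- m > 0L
  m[pos] <- remap[m[pos]]
  labeled_mask(m, "nucleus")
}

#' Segment the reporter-positive cell area in an mVenus image
#'
#' Returns the binary foreground covering nucleus + cytoplasm of infected
#' (reporter-expressing) cells. The default threshold is the lower split of
#' a three-class Otsu, which separates background from any reporter signal
#' even when nuclear and cytoplasmic levels form two distinct modes.
#'
#' @param venus_image 2-D numeric matrix of reporter gray values.
#' @param config a [workflow_config()].
#' @return logical matrix (TRUE = reporter-positive area).
#' @export
segment_cells <- function(venus_image, config = workflow_config()) {
  stopifnot(is.matrix(venus_image))
  thr <- switch(config$cell_threshold_method,
                otsu2 = otsu_two_level(as.vector(venus_image)),
                otsu = otsu_threshold(as.vector(venus_image)),
                fixed = config$cell_threshold)
  # no hole filling here: background pockets enclosed between touching
  # cells are not reporter-positive area and must not enter the cytoplasm
  venus_image > thr
}

#' Discard nuclei of reporter-negative (uninfected) cells
#'
#' A nucleus is retained iff the fraction of its pixels falling inside the
#' reporter-positive cell mask is at least `min_overlap_for_infected`.
#' Labels of the survivors are preserved (not renumbered), so downstream
#' masks stay comparable with the original segmentation.
#'
#' @param nuclei [labeled_mask] of kind `"nucleus"`.
#' @param cell_mask logical matrix from [segment_cells()].
#' @param config a [workflow_config()].
#' @return [labeled_mask] of kind `"nucleus"` containing only retained
#'   nuclei.
#' @export
filter_uninfected <- function(nuclei, cell_mask,
                              config = workflow_config()) {
  stopifnot(inherits(nuclei, "labeled_mask"), nuclei$kind == "nucleus")
  check_same_frame(nuclei, cell_mask)
  lab <- nuclei$label_image
  areas <- label_areas(as.vector(lab))
  inside <- label_sums(as.vector(lab), as.numeric(cell_mask))
  frac <- inside / areas
  keep <- as.integer(names(frac)[frac >= config$min_overlap_for_infected])
  out <- lab
  out[!(out %in% keep)] <- 0L
  labeled_mask(out, "nucleus")
}

#' Separate touching cells by seeded Voronoi partition
#'
#' Partitions the reporter-positive foreground among the retained nuclei:
#' each foreground pixel is assigned to the nucleus region whose nearest
#' pixel is closest (Euclidean distance to the seed region; ties broken
#' toward the lowest label). Nucleus pixels always belong to their own
#' region. A nucleus with no foreground pixel reachable keeps only its own
#' pixels, with a warning.
#'
#' @param nuclei retained-nucleus [labeled_mask] (seeds).
#' @param cell_mask logical matrix of reporter-positive area.
#' @return [labeled_mask] of kind `"cell"`; the regions cover
#'   `cell_mask | nuclei` and are pairwise disjoint.
#' @export
voronoi_partition <- function(nuclei, cell_mask) {
  stopifnot(inherits(nuclei, "labeled_mask"))
  check_same_frame(nuclei, cell_mask)
  lab <- nuclei$label_image
  ids <- mask_labels(nuclei)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(ids) == 0L) return(labeled_mask(out, "cell"))
  fg <- cell_mask | lab > 0L
  best <- matrix(Inf, nrow(lab), ncol(lab))
  for (k in ids) {  # ascending: strict '<' leaves ties with the lowest label
    seed <- lab == k
    d <- EBImage::distmap(EBImage::Image((!seed) * 1), metric = "euclidean")
    d <- matrix(as.numeric(EBImage::imageData(d)), nrow = nrow(lab))
    upd <- fg & d < best
    out[upd] <- k
    best[upd] <- d[upd]
  }
  orphan <- ids[!(ids %in% unique(out[cell_mask]))]
  if (length(orphan))
    warning(sprintf("nuclei with no reachable foreground: %s",
                    paste(orphan, collapse = ", ")))
  labeled_mask(out, "cell")
}

#' Derive cytoplasm masks by subtracting nuclei from cell regions
#'
#' For every label, cytoplasm = cell region minus that label's nucleus
#' pixels (the XOR of the whole-cell and nuclear masks). Nucleus pixels
#' found outside their own cell region are clipped, with a warning.
#'
#' @param cells [labeled_mask] of kind `"cell"` (e.g. from
#'   [voronoi_partition()]).
#' @param nuclei [labeled_mask] of kind `"nucleus"`.
#' @return [labeled_mask] of kind `"cytoplasm"` with the same labels.
#' @export
cytoplasm_masks <- function(cells, nuclei) {
  stopifnot(inherits(cells, "labeled_mask"), inherits(nuclei, "labeled_mask"))
  check_same_frame(cells, nuclei)
  cl <- cells$label_image
  nl <- nuclei$label_image
  stray <- nl > 0L & cl != nl
  if (any(stray))
    warning(sprintf("%d nucleus pixels outside their cell region; clipped",
                    sum(stray)))
  out <- cl
  out[nl > 0L] <- 0L
  labeled_mask(out, "cytoplasm")
}

#' Measure per-cell reporter signal
#'
#' Redirects the nuclear and cytoplasmic masks to the reporter gray image:
#' per cell, N = mean gray over nucleus pixels, C = mean gray over
#' cytoplasm pixels (`NA` when the cytoplasm mask is empty), C/N ratio, and
#' the cytoplasmic integrated density (sum of gray values over cytoplasm
#' pixels, i.e. area x mean).
#'
#' @param nuclei [labeled_mask] of retained nuclei.
#' @param cytoplasms [labeled_mask] from [cytoplasm_masks()].
#' @param venus_image reporter gray matrix.
#' @param config a [workflow_config()]; `background_subtract` is applied
#'   to the image before measuring.
#' @return data frame with columns cell_id, nuclear_mean, cytoplasmic_mean,
#'   cn_ratio, cytoplasmic_integrated_density.
#' @export
measure_cells <- function(nuclei, cytoplasms, venus_image,
                          config = workflow_config()) {
  check_same_frame(nuclei, cytoplasms)
  check_same_frame(nuclei, venus_image)
  img <- venus_image - config$background_subtract
  nl <- as.vector(nuclei$label_image)
  cl <- as.vector(cytoplasms$label_image)
  v <- as.vector(img)
  nmean <- label_means(nl, v)
  cmean <- label_means(cl, v)
  csum <- label_sums(cl, v)
  ids <- sort(as.integer(names(nmean)))
  key <- as.character(ids)
  cm <- unname(cmean[key])
  data.frame(cell_id = ids,
             nuclear_mean = unname(nmean[key]),
             cytoplasmic_mean = cm,
             cn_ratio = cm / unname(nmean[key]),
             cytoplasmic_integrated_density = ifelse(is.na(cm), NA_real_,
                                                     unname(csum[key])))
}

#' Classify cells as G0/G1 or cycling from the C/N ratio
#'
#' A cell is G0/G1 when it has no cytoplasmic reporter mask (C/N absent) or
#' its C/N ratio is strictly below the threshold; otherwise it is cycling.
#'
#' @param measurements data frame from [measure_cells()].
#' @param config a [workflow_config()] supplying `cn_g0g1_threshold`.
#' @return the measurements with an added `cycle_class` column
#'   (`"G0G1"`/`"cycling"`).
#' @export
classify_cycle_state <- function(measurements,
                                 config = workflow_config()) {
  stopifnot(is.data.frame(measurements), "cn_ratio" %in% names(measurements))
  measurements$cycle_class <- ifelse(
    is.na(measurements$cn_ratio) |
      measurements$cn_ratio < config$cn_g0g1_threshold, "G0G1", "cycling")
  measurements
}

#' Score residual CDK2 activity across conditions
#'
#' Residual activity of a condition is the mean cytoplasmic integrated
#' density of its G0/G1 cells; each condition is expressed as fold change
#' relative to the reference condition. Conditions without G0/G1 cells, or
#' a reference with zero/undefined summary, are flagged and yield no fold
#' change.
#'
#' @param measurements_by_condition named list of classified measurement
#'   data frames (see [classify_cycle_state()]).
#' @param reference_condition name of the reference entry.
#' @return data frame with condition, n_g0g1, mean_intdens, fold_change,
#'   degenerate (logical).
#' @export
score_residual_activity <- function(measurements_by_condition,
                                    reference_condition) {
  stopifnot(is.list(measurements_by_condition),
            reference_condition %in% names(measurements_by_condition))
  summ <- lapply(measurements_by_condition, function(m) {
    g <- m[m$cycle_class == "G0G1" &
             !is.na(m$cytoplasmic_integrated_density), , drop = FALSE]
    if (nrow(g) == 0L)
      list(n = 0L, mean = NA_real_)
    else
      list(n = nrow(g), mean = mean(g$cytoplasmic_integrated_density))
  })
  ref <- summ[[reference_condition]]
  ref_ok <- !is.na(ref$mean) && ref$mean > 0
  if (!ref_ok)
    warning("reference condition has no usable G0/G1 signal; ",
            "fold changes not emitted")
  data.frame(condition = names(summ),
             n_g0g1 = vapply(summ, function(s) s$n, integer(1)),
             mean_intdens = vapply(summ, function(s) s$mean, numeric(1)),
             fold_change = if (ref_ok)
               vapply(summ, function(s) s$mean / ref$mean, numeric(1))
             else NA_real_,
             degenerate = vapply(summ, function(s) s$n == 0L, logical(1)) |
               !ref_ok,
             row.names = NULL)
}

#' Check the minimum scored-cell count per culture
#'
#' @param measurements data frame of scored cells.
#' @param config a [workflow_config()] supplying `min_cells_per_culture`.
#' @return list with `n_cells`, `min_required` and `pass`.
#' @export
qc_min_cells <- function(measurements, config = workflow_config()) {
  n <- if (is.data.frame(measurements)) nrow(measurements)
       else length(measurements)
  list(n_cells = n, min_required = config$min_cells_per_culture,
       pass = n >= config$min_cells_per_culture)
}

#' Run the full CDK2 reporter workflow on one two-channel field
#'
#' Segments nuclei (DAPI) and reporter-positive area (mVenus), discards
#' uninfected cells, separates touching cells by seeded Voronoi partition,
#' derives cytoplasms by mask subtraction, measures per-cell N, C, C/N and
#' cytoplasmic integrated density, classifies G0/G1 vs cycling and reports
#' QC.
#'
#' @param dapi_image,venus_image gray matrices sharing one pixel frame.
#' @param config a [workflow_config()].
#' @return list with `nuclei`, `cell_mask`, `cells`, `cytoplasms`,
#'   `measurements` (classified) and `qc`.
#' @export
run_cdk2_workflow <- function(dapi_image, venus_image,
                              config = workflow_config()) {
  check_same_frame(dapi_image, venus_image)
  nuclei_all <- segment_nuclei(dapi_image, config)
  cell_mask <- segment_cells(venus_image, config)
  nuclei <- filter_uninfected(nuclei_all, cell_mask, config)
  cells <- voronoi_partition(nuclei, cell_mask)
  cytos <- cytoplasm_masks(cells, nuclei)
  meas <- measure_cells(nuclei, cytos, venus_image, config)
  meas <- classify_cycle_state(meas, config)
  list(nuclei = nuclei, cell_mask = cell_mask, cells = cells,
       cytoplasms = cytos, measurements = meas,
       qc = qc_min_cells(meas, config))
}
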