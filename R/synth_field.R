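#' Specification of a synthetic two-channel cell field
#'
#' Describes a field of cultured cells imaged in a DAPI (nuclear) channel
#' and a DHB-mVenus (CDK2 reporter) channel. Cells are modelled as disk
#' nuclei with concentric annular cytoplasms — the simplest geometry that
#' still exercises clump splitting. A stated fraction of cells is
#' reporter-negative (uninfected: no mVenus signal in either compartment),
#' and a stated fraction is placed touching a neighbour so that cytoplasms
#' overlap and must be separated downstream.
#'
#' Intensities are drawn per cell, rounded to integer gray levels so that
#' noiseless images reproduce them exactly, and clipped to the 16-bit range.
#'
#' @param width,height field size in pixels.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_range length-2 numeric, pixels.
#' @param cytoplasm_thickness_range length-2 numeric, pixels (annulus width).
#' @param infected_fraction probability a cell carries the reporter.
#' @param clumped_fraction probability a cell is placed touching an already
#'   placed neighbour (cytoplasm overlap, nuclei still disjoint).
#' @param nuclear_intensity_range,cytoplasmic_intensity_range per-cell
#'   reporter gray-level ranges (a.u.) for nucleus and cytoplasm.
#' @param dapi_intensity_range per-cell DAPI nuclear gray-level range.
#' @param background_level constant background gray level in both channels.
#' @param gaussian_noise_sd additive Gaussian read-noise SD (gray levels);
#'   0 disables.
#' @param poisson_noise logical; apply Poisson (shot) noise to each pixel.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width = 512, height = 512, n_cells = 50,
                       nucleus_radius_range = c(8, 12),
                       cytoplasm_thickness_range = c(4, 8),
                       infected_fraction = 0.8,
                       clumped_fraction = 0.2,
                       nuclear_intensity_range = c(800, 1200),
                       cytoplasmic_intensity_range = c(400, 900),
                       dapi_intensity_range = c(2500, 3500),
                       background_level = 100,
                       gaussian_noise_sd = 0,
                       poisson_noise = FALSE,
                       seed = 1L) {
  rng2 <- function(x) if (length(x) == 1L) c(x, x) else sort(x[1:2])
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               nucleus_radius_range = rng2(nucleus_radius_range),
               cytoplasm_thickness_range = rng2(cytoplasm_thickness_range),
               infected_fraction = infected_fraction,
               clumped_fraction = clumped_fraction,
               nuclear_intensity_range = rng2(nuclear_intensity_range),
               cytoplasmic_intensity_range = rng2(cytoplasmic_intensity_range),
               dapi_intensity_range = rng2(dapi_intensity_range),
               background_level = background_level,
               gaussian_noise_sd = gaussian_noise_sd,
               poisson_noise = isTRUE(poisson_noise),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(width > 0, height > 0, n_cells >= 0,
              infected_fraction >= 0, infected_fraction <= 1,
              clumped_fraction >= 0, clumped_fraction <= 1,
              nucleus_radius_range[1] > 0,
              cytoplasm_thickness_range[1] >= 0,
              all(nuclear_intensity_range >= 0),
              all(cytoplasmic_intensity_range >= 0),
              all(dapi_intensity_range >= 0),
              background_level >= 0, gaussian_noise_sd >= 0)
  })
  structure(spec, class = "field_spec")
}

# Place n cells sequentially. Nuclei are kept >= 2 px apart (edge to edge)
# so DAPI components stay disjoint; clumped cells are dropped at a centre
# distance below the sum of outer radii so cytoplasms overlap. Consumes RNG
# draws from the current stream; the caller controls seeding.
place_cells <- function(spec, clumped, max_attempts = 500L) {
  n <- spec$n_cells
  r <- round(runif(n, spec$nucleus_radius_range[1],
                   spec$nucleus_radius_range[2]), 1)
  th <- round(runif(n, spec$cytoplasm_thickness_range[1],
                    spec$cytoplasm_thickness_range[2]), 1)
  R <- r + th
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      if (clumped[i] && i > 1L) {
        j <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
        lo <- r[i] + r[j] + 3
        hi <- max(R[i] + R[j] - 1, lo)
        d <- runif(1, lo, hi)
        a <- runif(1, 0, 2 * pi)
        x <- cx[j] + d * cos(a); y <- cy[j] + d * sin(a)
        if (x < R[i] + 2 || x > spec$width - R[i] - 1 ||
            y < R[i] + 2 || y > spec$height - R[i] - 1) next
        others <- setdiff(seq_len(i - 1L), j)
        if (length(others)) {
          dd <- sqrt((cx[others] - x)^2 + (cy[others] - y)^2)
          if (any(dd < r[i] + r[others] + 3)) next
        }
      } else {
        x <- runif(1, R[i] + 2, spec$width - R[i] - 1)
        y <- runif(1, R[i] + 2, spec$height - R[i] - 1)
        if (i > 1L) {
          k <- seq_len(i - 1L)
          dd <- sqrt((cx[k] - x)^2 + (cy[k] - y)^2)
          if (any(dd < R[i] + R[k] + 2)) next
        }
      }
      cx[i] <- x; cy[i] <- y; placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("could not place cell %d after %d attempts: ",
                          "field too dense for n_cells = %d at %dx%d px"),
                   i, max_attempts, n, spec$width, spec$height))
  }
  data.frame(cell_id = seq_len(n), x = cx, y = cy,
             nucleus_radius = r, cytoplasm_outer_radius = R)
}

# Rasterize disk nuclei and annular cytoplasms. Overlapping annuli are
# resolved to the cell whose nucleus disk is nearest (continuous
# distance-to-disk |p-c| - r; ties to the lowest label); nucleus pixels
# always belong to their own cell. Returns integer matrices (height rows x
# width cols; x = column, y = row, 1-based internally).
rasterize_cells <- function(geom, width, height) {
  nuc <- matrix(0L, nrow = height, ncol = width)
  cyto <- matrix(0L, nrow = height, ncol = width)
  cyto_dist <- matrix(Inf, nrow = height, ncol = width)
  for (i in seq_len(nrow(geom))) {
    x0 <- geom$x[i]; y0 <- geom$y[i]
    r <- geom$nucleus_radius[i]; R <- geom$cytoplasm_outer_radius[i]
    cols <- max(1L, floor(x0 - R)):min(width, ceiling(x0 + R))
    rows <- max(1L, floor(y0 - R)):min(height, ceiling(y0 + R))
    d2 <- outer((rows - y0)^2, (cols - x0)^2, `+`)
    in_nuc <- d2 <= r^2
    in_ann <- !in_nuc & d2 <= R^2
    sub_n <- nuc[rows, cols, drop = FALSE]
    sub_n[in_nuc] <- geom$cell_id[i]
    nuc[rows, cols] <- sub_n
    di <- sqrt(d2) - r
    sub_c <- cyto[rows, cols, drop = FALSE]
    sub_d <- cyto_dist[rows, cols, drop = FALSE]
    upd <- in_ann & di < sub_d
    sub_c[upd] <- geom$cell_id[i]
    sub_d[upd] <- di[upd]
    cyto[rows, cols] <- sub_c
    cyto_dist[rows, cols] <- sub_d
  }
  cyto[nuc > 0L] <- 0L  # nucleus wins where an annulus overlaps a nucleus
  list(nuclei = nuc, cytoplasms = cyto)
}

apply_noise <- function(img, spec) {
  v <- as.vector(img)
  if (spec$poisson_noise) v <- rpois(length(v), v)
  if (spec$gaussian_noise_sd > 0)
    v <- v + rnorm(length(v), 0, spec$gaussian_noise_sd)
  matrix(pmin(65535, pmax(0, round(v))), nrow = nrow(img))
}

#' Generate a ground-truthed synthetic DHB-mVenus field
#'
#' Produces a DAPI image (all nuclei visible), an mVenus reporter image
#' (nucleus + cytoplasm signal only for infected cells; background
#' elsewhere) and the full ground truth: per-cell geometry, true
#' compartment intensities, true C/N ratio and true cell-cycle class, plus
#' reference label masks for nuclei, whole cells and cytoplasms.
#'
#' RNG draw order is fixed and documented so that individual draws can be
#' replayed independently: (1) infected flags `runif(n) < infected_fraction`,
#' (2) clumped flags `runif(n) < clumped_fraction`, (3) geometry and
#' intensities, (4) noise. The true cell-cycle class is `"G0G1"` when the
#' true C/N ratio is below `class_threshold` or the cell is uninfected
#' (no cytoplasmic reporter), else `"cycling"`.
#'
#' @param spec a [field_spec()].
#' @param class_threshold C/N cutoff used to record the true class
#'   (default 0.65, the workflow's G0/G1 rule).
#' @return A list of class `synthetic_field` with elements `dapi`, `venus`
#'   (integer gray matrices), and `truth`: a list with `cells` (data frame:
#'   cell_id, x, y, nucleus_radius, cytoplasm_outer_radius, infected,
#'   true_nuclear_mean, true_cytoplasmic_mean, true_cn_ratio, true_class)
#'   and reference [labeled_mask]s `nuclei`, `cell_mask`, `cytoplasms`.
#' @examples
#' f <- generate_cell_field(field_spec(n_cells = 5, seed = 42))
#' f$truth$cells
#' @export
generate_cell_field <- function(spec, class_threshold = 0.65) {
  stopifnot(inherits(spec, "field_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    infected <- runif(n) < spec$infected_fraction
    clumped <- runif(n) < spec$clumped_fraction
    if (n == 0L) {
      bg <- matrix(spec$background_level, spec$height, spec$width)
      empty <- matrix(0L, spec$height, spec$width)
      structure(list(
        dapi = apply_noise(bg, spec), venus = apply_noise(bg, spec),
        truth = list(
          cells = data.frame(cell_id = integer(0), x = numeric(0),
                             y = numeric(0), nucleus_radius = numeric(0),
                             cytoplasm_outer_radius = numeric(0),
                             infected = logical(0),
                             true_nuclear_mean = numeric(0),
                             true_cytoplasmic_mean = numeric(0),
                             true_cn_ratio = numeric(0),
                             true_class = character(0)),
          nuclei = labeled_mask(empty, "nucleus"),
          cell_mask = labeled_mask(empty, "cell"),
          cytoplasms = labeled_mask(empty, "cytoplasm")),
        spec = spec), class = "synthetic_field")
    } else {
    geom <- place_cells(spec, clumped)
    nuc_int <- round(runif(n, spec$nuclear_intensity_range[1],
                           spec$nuclear_intensity_range[2]))
    cyt_int <- round(runif(n, spec$cytoplasmic_intensity_range[1],
                           spec$cytoplasmic_intensity_range[2]))
    dapi_int <- round(runif(n, spec$dapi_intensity_range[1],
                            spec$dapi_intensity_range[2]))
    masks <- rasterize_cells(geom, spec$width, spec$height)
    nuc <- masks$nuclei; cyto <- masks$cytoplasms

    dapi <- matrix(spec$background_level, spec$height, spec$width)
    venus <- matrix(spec$background_level, spec$height, spec$width)
    nz <- which(nuc > 0L)
    dapi[nz] <- dapi_int[nuc[nz]]
    inf_nuc <- nz[infected[nuc[nz]]]
    venus[inf_nuc] <- nuc_int[nuc[inf_nuc]]
    cz <- which(cyto > 0L)
    inf_cyto <- cz[infected[cyto[cz]]]
    venus[inf_cyto] <- cyt_int[cyto[inf_cyto]]

    truth <- geom
    truth$infected <- infected
    truth$true_nuclear_mean <- ifelse(infected, nuc_int,
                                      spec$background_level)
    truth$true_cytoplasmic_mean <- ifelse(infected, cyt_int,
                                          spec$background_level)
    truth$true_cn_ratio <- ifelse(infected, cyt_int / nuc_int, NA_real_)
    truth$true_class <- ifelse(!infected | truth$true_cn_ratio <
                                 class_threshold, "G0G1", "cycling")
    cell_lab <- nuc
    cell_lab[cz] <- cyto[cz]
    structure(list(
      dapi = apply_noise(dapi, spec),
      venus = apply_noise(venus, spec),
      truth = list(cells = truth,
                   nuclei = labeled_mask(nuc, "nucleus"),
                   cell_mask = labeled_mask(cell_lab, "cell"),
                   cytoplasms = labeled_mask(cyto, "cytoplasm")),
      spec = spec), class = "synthetic_field")
    }
  })
}

#' Generate a synthetic nuclear-marker field
#'
#' Produces a DAPI channel plus one image per nuclear marker (e.g. SOX2,
#' OLIG2, ASCL1) over the same disk-nucleus geometry as
#' [generate_cell_field()]. Per-cell marker intensities are drawn
#' log-normally per population, which emulates genotype- or dosage-driven
#' shifts of an intensity distribution (two populations suffice to emulate
#' a wild-type vs knockout comparison).
#'
#' RNG draw order: (1) population assignment, (2) clumped flags,
#' (3) geometry, (4) per-marker log-normal intensities, (5) noise.
#'
#' @param spec a [field_spec()] (reporter intensity fields are ignored).
#' @param marker_params named list, one element per marker, each a list
#'   with numeric vectors `meanlog` and `sdlog` of length = number of
#'   populations.
#' @param population_fractions numeric vector of population weights
#'   (summing to 1); ignored when `population_assignments` is given.
#' @param population_assignments optional integer vector (length
#'   `n_cells`) fixing each cell's population.
#' @return list of class `synthetic_marker_field`: `dapi`, `markers`
#'   (named list of gray matrices), `nuclei` ([labeled_mask]) and `truth`
#'   (data frame: cell_id, x, y, population, one `true_<marker>` column per
#'   marker).
#' @export
generate_marker_field <- function(spec, marker_params,
                                  population_fractions = 1,
                                  population_assignments = NULL) {
  stopifnot(inherits(spec, "field_spec"), length(marker_params) >= 1,
            !is.null(names(marker_params)))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    pop <- if (is.null(population_assignments)) {
      sample.int(length(population_fractions), n, replace = TRUE,
                 prob = population_fractions)
    } else {
      stopifnot(length(population_assignments) == n)
      as.integer(population_assignments)
    }
    clumped <- runif(n) < spec$clumped_fraction
    geom <- place_cells(spec, clumped)
    masks <- rasterize_cells(geom, spec$width, spec$height)
    nuc <- masks$nuclei
    nz <- which(nuc > 0L)
    dapi_int <- round(runif(n, spec$dapi_intensity_range[1],
                            spec$dapi_intensity_range[2]))
    dapi <- matrix(spec$background_level, spec$height, spec$width)
    if (n > 0L) dapi[nz] <- dapi_int[nuc[nz]]
    truth <- data.frame(cell_id = geom$cell_id, x = geom$x, y = geom$y,
                        population = pop)
    markers <- list()
    for (m in names(marker_params)) {
      p <- marker_params[[m]]
      stopifnot(length(p$meanlog) >= max(c(pop, 1L)),
                length(p$sdlog) == length(p$meanlog))
      val <- round(exp(rnorm(n, p$meanlog[pop], p$sdlog[pop])))
      img <- matrix(spec$background_level, spec$height, spec$width)
      if (n > 0L) img[nz] <- val[nuc[nz]]
      markers[[m]] <- apply_noise(img, spec)
      truth[[paste0("true_", m)]] <- val
    }
    structure(list(dapi = apply_noise(dapi, spec), markers = markers,
                   nuclei = labeled_mask(nuc, "nucleus"),
                   truth = truth, spec = spec),
              class = "synthetic_marker_field")
  })
}

#' Match segmented labels to ground-truth labels by majority overlap
#'
#' Segmentation renumbers objects, so validating against a synthetic field
#' requires a correspondence: each segmented label is mapped to the truth
#' label covering the majority of its pixels (0 when a segmented object
#' overlaps no truth object).
#'
#' @param segmented a [labeled_mask] produced by the pipeline.
#' @param truth_mask the reference [labeled_mask] of the same kind and
#'   frame.
#' @return named integer vector: names are segmented labels, values the
#'   matched truth labels.
#' @export
match_to_truth <- function(segmented, truth_mask) {
  check_same_frame(segmented, truth_mask)
  seg <- segmented$label_image
  tru <- truth_mask$label_image
  ids <- mask_labels(segmented)
  vapply(stats::setNames(ids, ids), function(k) {
    tv <- tru[seg == k]
    tv <- tv[tv > 0L]
    if (!length(tv)) return(0L)
    tab <- tabulate(tv)
    which.max(tab)
  }, integer(1))
}
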