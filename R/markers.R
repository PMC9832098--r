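#' Maximum-intensity projection of an image stack
#'
#' @param stack a 3-D numeric array (`x`, `y`, `plane`) or a list of
#'   equally sized matrices.
#' @return matrix of per-pixel maxima across planes.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack")
    out <- stack[[1L]]
    for (p in stack[-1L]) {
      check_same_frame(out, p)
      out <- pmax(out, p)
    }
    return(out)
  }
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (dim(stack)[3L] == 0L) stop("empty stack")
  apply(stack, c(1, 2), max)
}

#' Measure per-cell nuclear marker intensities
#'
#' For every nucleus label and marker image, the mean gray value over the
#' nucleus pixels.
#'
#' @param nuclei [labeled_mask] of kind `"nucleus"`.
#' @param marker_images named list of gray matrices (one per marker), or a
#'   single matrix.
#' @return data frame with columns cell_id, marker,
#'   nuclear_mean_intensity; one row per (cell, marker).
#' @export
measure_nuclear_markers <- function(nuclei, marker_images) {
  stopifnot(inherits(nuclei, "labeled_mask"))
  if (is.matrix(marker_images))
    marker_images <- list(marker = marker_images)
  stopifnot(is.list(marker_images), length(marker_images) >= 1,
            !is.null(names(marker_images)))
  nl <- as.vector(nuclei$label_image)
  out <- lapply(names(marker_images), function(m) {
    img <- marker_images[[m]]
    check_same_frame(nuclei, img)
    mu <- label_means(nl, as.vector(img))
    if (length(mu) == 0L)
      return(data.frame(cell_id = integer(0), marker = character(0),
                        nuclear_mean_intensity = numeric(0)))
    ids <- sort(as.integer(names(mu)))
    data.frame(cell_id = ids, marker = m,
               nuclear_mean_intensity = unname(mu[as.character(ids)]))
  })
  do.call(rbind, out)
}

#' Percentage of marker-positive cells
#'
#' @param intensities numeric vector of per-cell intensities.
#' @param positivity_threshold cells with intensity strictly above it are
#'   positive; defaults to an Otsu split of the supplied intensities (a
#'   reproducible stand-in for visual threshold setting).
#' @param denominator `"subpopulation"` (the supplied cells) or a count
#'   (e.g. total DAPI-labelled cells) relative to which the percentage is
#'   computed.
#' @return percentage in `[0, 100]`.
#' @export
percent_positive <- function(intensities,
                             positivity_threshold = NULL,
                             denominator = "subpopulation") {
  stopifnot(is.numeric(intensities))
  if (is.null(positivity_threshold)) {
    positivity_threshold <- otsu_threshold(intensities)
    message(sprintf("percent_positive: Otsu positivity threshold %.4g",
                    positivity_threshold))
  }
  den <- if (identical(denominator, "subpopulation")) length(intensities)
         else as.numeric(denominator)
  if (is.na(den) || den <= 0) stop("denominator count must be positive")
  100 * sum(intensities > positivity_threshold) / den
}

#' Max-normalized frequency histogram of one or more populations
#'
#' Computes raw counts over bins shared across all compared populations
#' (default: 50 equal bins over the pooled range) and divides every count
#' by the single maximum bin count across the comparison, so that the
#' modal bin of the comparison equals 1. Reports each population's median.
#'
#' @param intensities numeric vector, or named list of numeric vectors
#'   (one per population in a comparison).
#' @param bins number of bins, or a numeric vector of strictly increasing
#'   bin edges spanning the pooled range.
#' @return object of class `histogram_summary`: `bin_edges`, `counts`
#'   (matrix: bin x population), `normalized_counts` (same shape,
#'   max = 1), `median_intensity` (per population), `n_cells`.
#' @export
frequency_histogram <- function(intensities, bins = 50) {
  if (!is.list(intensities)) intensities <- list(all = intensities)
  n <- vapply(intensities, length, integer(1))
  if (all(n == 0L)) {
    out <- list(bin_edges = numeric(0), counts = NULL,
                normalized_counts = NULL, median_intensity = NULL,
                n_cells = n, empty = TRUE)
    class(out) <- "histogram_summary"
    return(out)
  }
  pooled <- unlist(intensities, use.names = FALSE)
  if (length(bins) == 1L) {
    rng <- range(pooled)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- bins
    stopifnot(all(diff(edges) > 0), min(pooled) >= edges[1],
              max(pooled) <= edges[length(edges)])
  }
  nb <- length(edges) - 1L
  counts <- vapply(intensities, function(x) {
    tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                          all.inside = TRUE), nb)
  }, integer(nb))
  counts <- matrix(counts, nrow = nb,
                   dimnames = list(NULL, names(intensities)))
  mx <- max(counts)
  out <- list(bin_edges = edges, counts = counts,
              normalized_counts = counts / mx,
              median_intensity = vapply(intensities, function(x)
                if (length(x)) median(x) else NA_real_, numeric(1)),
              n_cells = n, empty = FALSE)
  class(out) <- "histogram_summary"
  out
}

#' @export
print.histogram_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<histogram_summary: empty>\n")
    return(invisible(x))
  }
  cat(sprintf("<histogram_summary: %d bins, populations: %s>\n",
              length(x$bin_edges) - 1L,
              paste(sprintf("%s (n=%d, median=%.4g)", names(x$n_cells),
                            x$n_cells, x$median_intensity),
                    collapse = ", ")))
  invisible(x)
}

#' Label the brightest fraction of cells as "high"
#'
#' The `ceiling(fraction * n)` brightest cells are labelled high; the
#' threshold is the intensity of the dimmest high cell, and all cells tied
#' at the threshold are included (so the high set can exceed the nominal
#' count, which is reported with a message).
#'
#' @param intensities numeric vector (n >= 1).
#' @param fraction fraction labelled high, in (0, 1]; default 0.30 (the
#'   "30% brightest" convention for SOX2-high calls).
#' @return list with `threshold`, `high` (logical vector aligned with the
#'   input) and `n_high`.
#' @export
top_fraction_high <- function(intensities, fraction = 0.30) {
  stopifnot(length(intensities) >= 1, fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(intensities))
  thr <- sort(intensities, decreasing = TRUE)[k]
  high <- intensities >= thr
  if (sum(high) > k)
    message(sprintf(paste0("top_fraction_high: ties at the threshold; ",
                           "high set has %d cells (nominal %d)"),
                    sum(high), k))
  list(threshold = thr, high = high, n_high = sum(high))
}

#' Fold change of population medians
#'
#' @param profiles_condition,profiles_reference numeric intensity vectors
#'   (both nonempty).
#' @return `median(condition) / median(reference)`; `NA` with a warning
#'   when the reference median is zero.
#' @export
median_fold_change <- function(profiles_condition, profiles_reference) {
  stopifnot(length(profiles_condition) >= 1,
            length(profiles_reference) >= 1)
  mref <- median(profiles_reference)
  if (mref == 0) {
    warning("reference median is zero; fold change undefined")
    return(NA_real_)
  }
  median(profiles_condition) / mref
}
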