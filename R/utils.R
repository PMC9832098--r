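#' Labeled compartment mask
#'
#' A thin container around an integer label image: 0 is background, positive
#' integers identify cells/nuclei/cytoplasms. All masks derived from one
#' field share the same pixel frame (matrix dimensions), so masks of
#' different kinds can be combined pixel-wise.
#'
#' @param label_image integer matrix, values >= 0; 0 is background.
#' @param kind one of `"nucleus"`, `"cell"`, `"cytoplasm"`.
#' @return An object of class `labeled_mask` with elements `label_image`
#'   and `kind`.
#' @export
labeled_mask <- function(label_image, kind = c("nucleus", "cell", "cytoplasm")) {
  kind <- match.arg(kind)
  if (!is.matrix(label_image))
    stop("`label_image` must be a matrix")
  storage.mode(label_image) <- "integer"
  if (any(label_image < 0, na.rm = TRUE))
    stop("labels must be nonnegative integers")
  structure(list(label_image = label_image, kind = kind),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask kind=%s  %d x %d px  %d labels>\n",
              x$kind, nrow(x$label_image), ncol(x$label_image),
              n_labels(x)))
  invisible(x)
}

#' Number of distinct positive labels in a mask
#' @param mask a [labeled_mask].
#' @return integer count of distinct nonzero labels.
#' @export
n_labels <- function(mask) {
  length(mask_labels(mask))
}

#' Distinct positive labels in a mask
#' @param mask a [labeled_mask].
#' @return sorted integer vector of nonzero labels.
#' @export
mask_labels <- function(mask) {
  u <- unique(as.vector(mask$label_image))
  sort(u[u > 0L])
}

# shared-frame check used before any pixel-wise mask combination
check_same_frame <- function(a, b) {
  da <- if (inherits(a, "labeled_mask")) dim(a$label_image) else dim(a)
  db <- if (inherits(b, "labeled_mask")) dim(b$label_image) else dim(b)
  if (!identical(da, db))
    stop(sprintf("pixel frames differ: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

# Otsu threshold on a numeric vector (histogram formulation, 256 bins).
# Returns a value t; foreground is x > t. Constant input returns that value,
# so thresholding a blank image yields an empty mask.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  p <- h / sum(h)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[n_bins]
  w2 <- 1 - w1
  num <- (muT * w1 - mu1)^2
  den <- w1 * w2
  sigma <- ifelse(den > 0, num / den, -Inf)
  k <- which.max(sigma[-n_bins])
  br[k + 1L]
}

# Two-threshold (three-class) Otsu; returns the LOWER threshold. Suited to
# reporter images where background, cytoplasm and nucleus form three modes:
# the lower split separates background from any reporter signal even when
# the two signal modes dominate the variance.
otsu_two_level <- function(x, n_bins = 128L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  p <- h / sum(h)
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  best <- -Inf; best_t1 <- 1L
  for (t1 in 1:(n_bins - 2L)) {
    w1 <- W[t1 + 1L]; m1 <- M[t1 + 1L]
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- W[t2 + 1L] - w1
    m2 <- M[t2 + 1L] - m1
    w3 <- 1 - W[t2 + 1L]
    m3 <- M[n_bins + 1L] - M[t2 + 1L]
    s <- ifelse(w1 > 0, m1^2 / w1, 0) +
      ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    i <- which.max(s)
    if (s[i] > best) { best <- s[i]; best_t1 <- t1 }
  }
  br[best_t1 + 1L]
}

# per-label mean of image values; labels: integer vector (0 dropped),
# values: numeric vector of same length. Returns named numeric vector.
label_means <- function(labels, values) {
  keep <- labels > 0L
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  s <- rowsum(values[keep], labels[keep])
  n <- rowsum(rep(1, sum(keep)), labels[keep])
  stats::setNames(as.vector(s / n), rownames(s))
}

label_sums <- function(labels, values) {
  keep <- labels > 0L
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  s <- rowsum(values[keep], labels[keep])
  stats::setNames(as.vector(s), rownames(s))
}

label_areas <- function(labels) {
  keep <- labels > 0L
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tab <- table(labels[keep])
  stats::setNames(as.integer(tab), names(tab))
}
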