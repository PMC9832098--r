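#' Read a single-plane gray TIFF as an integer matrix
#'
#' @param path file path.
#' @return numeric matrix of gray levels (native integer scale).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L)
      stop("expected a single-channel image: ", path)
    img <- img[, , 1L]
  }
  storage.mode(img) <- "double"
  img
}

#' Write a gray matrix (or label mask) as a 16-bit TIFF
#'
#' Values are clipped to `[0, 65535]` and stored at 16-bit depth, so label
#' images round-trip exactly for up to 65535 labels.
#'
#' @param img numeric/integer matrix, or a [labeled_mask].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  if (inherits(img, "labeled_mask")) img <- img$label_image
  m <- pmin(pmax(round(img), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a labeled mask from a 16-bit TIFF
#'
#' @param path file path.
#' @param kind compartment kind of the stored mask.
#' @return a [labeled_mask].
#' @export
read_mask_tiff <- function(path, kind = c("nucleus", "cell", "cytoplasm")) {
  labeled_mask(round(read_image_tiff(path)), match.arg(kind))
}

#' Read a ChIP-qPCR Ct table
#'
#' Expects columns region, condition, antibody, fraction, dilution, ct
#' (optional replicate).
#'
#' @param path CSV file path.
#' @return data frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "condition", "antibody", "fraction", "dilution", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$ct <= 0) || any(tab$dilution <= 0))
    stop("Ct values and dilutions must be positive")
  tab
}

#' Read a peak table from a BED6+ file
#'
#' BED columns chrom, start, end, name, score, strand followed by `fdr`
#' and `direction`. Coordinates are kept 0-based half-open (native BED);
#' set `one_based = TRUE` for tables exported with 1-based starts.
#'
#' @param path BED-like file path (tab-separated, no header).
#' @param one_based convert 1-based inclusive starts on ingest.
#' @return data frame peak_id, chrom, start, end, stat, strand, fdr,
#'   direction.
#' @export
read_peaks_bed <- function(path, one_based = FALSE) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 8L)
    stop("expected BED6 + fdr + direction (8 columns), got ", ncol(tab))
  names(tab)[1:8] <- c("chrom", "start", "end", "peak_id", "stat",
                       "strand", "fdr", "direction")
  if (one_based) tab$start <- tab$start - 1L
  tab[c("peak_id", "chrom", "start", "end", "stat", "strand", "fdr",
        "direction")]
}

#' Write a peak table as BED6+2
#' @param peaks data frame as returned by [generate_gene_tables()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- peaks[c("chrom", "start", "end", "peak_id", "stat", "strand",
                 "fdr", "direction")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table (TSV: gene_id, log2fc, fdr)
#' @param path file path.
#' @return data frame.
#' @export
read_de_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Read a gene annotation table (TSV: gene_id, chrom, tss, strand, start,
#' end)
#' @param path file path.
#' @return data frame.
#' @export
read_annotation_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tab)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Write a data frame as CSV (deterministic byte layout)
#' @param x data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a QC / summary report as JSON
#' @param x a list of scalar summaries.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
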