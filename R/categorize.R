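#' Assign accessibility peaks to gene promoters
#'
#' A peak is promoter-associated with a gene iff it overlaps the window
#' `[TSS - promoter_window, TSS + promoter_window)` on the same chromosome
#' (0-based half-open coordinates; the window is symmetric around the TSS
#' for either strand). `flank` is the maximum assignment distance for
#' 5'-associated peaks; since the symmetric window already lies within it
#' under the defaults (3 kb window, 5 kb flank), it acts as a cap, not an
#' extension. Peaks on chromosomes absent from the annotation are left
#' unassigned with a warning.
#'
#' @param peaks data frame with columns peak_id, chrom, start, end
#'   (0-based half-open), plus fdr and direction for downstream labelling.
#' @param genes data frame with columns gene_id, chrom, tss, strand.
#' @param promoter_window half-width of the promoter window, bp.
#' @param flank maximum assignment distance, bp.
#' @return data frame with columns gene_id, peak_id (one row per
#'   overlapping pair; zero rows when nothing is assigned).
#' @export
assign_peaks_to_promoters <- function(peaks, genes, promoter_window = 3000,
                                      flank = 5000) {
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss") %in% names(genes)),
            promoter_window > 0, flank >= promoter_window)
  if (nrow(peaks) && any(peaks$start >= peaks$end))
    stop("peaks must satisfy start < end (0-based half-open)")
  bad <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(bad))
    warning("peak chromosome(s) absent from annotation: ",
            paste(bad, collapse = ", "))
  half <- min(promoter_window, flank)
  out <- list()
  for (ch in intersect(unique(genes$chrom), unique(peaks$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(g) || !nrow(p)) next
    # half-open [a, b) -> closed 1-based [a + 1, b] for IRanges
    win <- IRanges::IRanges(start = g$tss - half + 1L, end = g$tss + half)
    pk <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    ov <- IRanges::findOverlaps(pk, win)
    if (length(ov))
      out[[ch]] <- data.frame(
        gene_id = g$gene_id[S4Vectors::subjectHits(ov)],
        peak_id = p$peak_id[S4Vectors::queryHits(ov)])
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), peak_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve genes with multiple promoter peaks to a single peak
#'
#' When more than one peak maps to a gene's promoter window, the peak whose
#' midpoint is nearest the TSS is kept; ties are broken by the largest
#' overlap with the promoter window, then by the lowest start coordinate.
#'
#' @param assignment data frame from [assign_peaks_to_promoters()].
#' @param peaks,genes the tables used for the assignment.
#' @param promoter_window half-width used for the overlap tie-break.
#' @return data frame gene_id, peak_id with at most one row per gene.
#' @export
resolve_multi_peaks <- function(assignment, peaks, genes,
                                promoter_window = 3000) {
  if (nrow(assignment) == 0L) return(assignment)
  m <- merge(assignment, peaks[c("peak_id", "start", "end")],
             by = "peak_id")
  m <- merge(m, genes[c("gene_id", "tss")], by = "gene_id")
  m$mid_dist <- abs((m$start + m$end) / 2 - m$tss)
  lo <- pmax(m$start, m$tss - promoter_window)
  hi <- pmin(m$end, m$tss + promoter_window)
  m$overlap <- pmax(0, hi - lo)
  m <- m[order(m$gene_id, m$mid_dist, -m$overlap, m$start), ]
  keep <- m[!duplicated(m$gene_id), c("gene_id", "peak_id")]
  rownames(keep) <- NULL
  keep
}

#' Differential-accessibility call per gene
#'
#' `Closed`/`Open` when the assigned promoter peak has FDR strictly below
#' the threshold with the corresponding direction; `Unchanged` otherwise;
#' `NoPromoterPeak` for genes without an assigned peak.
#'
#' @param genes data frame with gene_id (defines the gene universe).
#' @param resolved data frame gene_id, peak_id from
#'   [resolve_multi_peaks()].
#' @param peaks peak table with fdr and direction
#'   (`more_open`/`more_closed`/`unchanged`).
#' @param fdr_threshold significance cutoff (strict `<`), default 0.05.
#' @return data frame gene_id, peak_id (NA when none), da_call.
#' @export
label_da <- function(genes, resolved, peaks, fdr_threshold = 0.05) {
  out <- data.frame(gene_id = genes$gene_id, peak_id = NA_character_,
                    da_call = "NoPromoterPeak")
  if (nrow(resolved)) {
    m <- merge(resolved, peaks[c("peak_id", "fdr", "direction")],
               by = "peak_id")
    call <- ifelse(m$fdr < fdr_threshold & m$direction == "more_closed",
                   "Closed",
            ifelse(m$fdr < fdr_threshold & m$direction == "more_open",
                   "Open", "Unchanged"))
    i <- match(m$gene_id, out$gene_id)
    out$peak_id[i] <- m$peak_id
    out$da_call[i] <- call
  }
  out
}

#' Differential-expression call per gene
#'
#' `UP`/`DOWN` when the gene's FDR is strictly below the threshold with a
#' positive/negative log fold change; `Unchanged` otherwise. Genes missing
#' from the DE table, or significant genes with a zero fold change, are
#' `Unchanged` with a warning.
#'
#' @param genes data frame with gene_id.
#' @param de data frame gene_id, log2fc, fdr.
#' @param fdr_threshold significance cutoff (strict `<`), default 0.05.
#' @return data frame gene_id, de_call.
#' @export
label_de <- function(genes, de, fdr_threshold = 0.05) {
  i <- match(genes$gene_id, de$gene_id)
  if (anyNA(i))
    warning(sprintf("%d gene(s) missing from the DE table; set Unchanged",
                    sum(is.na(i))))
  fdr <- de$fdr[i]; lfc <- de$log2fc[i]
  zero_sig <- !is.na(fdr) & fdr < fdr_threshold & !is.na(lfc) & lfc == 0
  if (any(zero_sig))
    warning(sprintf("%d significant gene(s) with zero fold change; %s",
                    sum(zero_sig), "set Unchanged"))
  call <- ifelse(!is.na(fdr) & fdr < fdr_threshold & !is.na(lfc) & lfc > 0,
                 "UP",
          ifelse(!is.na(fdr) & fdr < fdr_threshold & !is.na(lfc) & lfc < 0,
                 "DOWN", "Unchanged"))
  data.frame(gene_id = genes$gene_id, de_call = call)
}

#' Combine DA and DE calls into joint regulation categories
#'
#' A gene receives a category only when both modalities are significant:
#' `Closed_UP`, `Closed_DOWN`, `Open_UP` or `Open_DOWN`; all other genes
#' are `"none"`.
#'
#' @param da data frame from [label_da()].
#' @param de data frame from [label_de()].
#' @return data frame gene_id, peak_id, da_call, de_call, category; the
#'   per-category counts are attached as attribute `"category_counts"`.
#' @export
combine_categories <- function(da, de) {
  rec <- merge(da, de, by = "gene_id", sort = TRUE)
  both <- rec$da_call %in% c("Closed", "Open") &
    rec$de_call %in% c("UP", "DOWN")
  rec$category <- ifelse(both, paste(rec$da_call, rec$de_call, sep = "_"),
                         "none")
  lev <- c("Closed_UP", "Closed_DOWN", "Open_UP", "Open_DOWN")
  counts <- vapply(lev, function(l) sum(rec$category == l), integer(1))
  attr(rec, "category_counts") <- counts
  rec
}

#' Full peak-to-category pipeline
#'
#' Runs [assign_peaks_to_promoters()], [resolve_multi_peaks()],
#' [label_da()], [label_de()] and [combine_categories()] in sequence.
#'
#' @param peaks,de,genes input tables (see the individual steps).
#' @param promoter_window,flank assignment geometry, bp.
#' @param fdr_threshold significance cutoff for both modalities.
#' @return the per-gene record data frame from [combine_categories()].
#' @export
categorize_genes <- function(peaks, de, genes, promoter_window = 3000,
                             flank = 5000, fdr_threshold = 0.05) {
  asg <- assign_peaks_to_promoters(peaks, genes, promoter_window, flank)
  res <- resolve_multi_peaks(asg, peaks, genes, promoter_window)
  da <- label_da(genes, res, peaks, fdr_threshold)
  dl <- label_de(genes, de, fdr_threshold)
  combine_categories(da, dl)
}

#' Cross-condition overlap of categorized genes
#'
#' Compares the categorized gene sets of two conditions (e.g. genotypes):
#' per-category Venn counts and the fraction of condition A's categorized
#' genes absent from condition B ("lost fraction").
#'
#' @param records_a,records_b data frames from [combine_categories()]
#'   over the same gene universe.
#' @param categories categories included in the lost-fraction summary;
#'   default all four.
#' @return list with `per_category` (data frame: category, n_a, n_b,
#'   n_both, n_a_only, n_b_only), `lost_fraction` (|A \ B| / |A| over the
#'   selected categories, NA when A is empty) and `n_a`, `n_b`.
#' @export
intersect_conditions <- function(records_a, records_b,
                                 categories = c("Closed_UP", "Closed_DOWN",
                                                "Open_UP", "Open_DOWN")) {
  if (!length(intersect(records_a$gene_id, records_b$gene_id)))
    stop("records share no genes: different gene universes")
  per <- lapply(categories, function(cat) {
    a <- records_a$gene_id[records_a$category == cat]
    b <- records_b$gene_id[records_b$category == cat]
    data.frame(category = cat, n_a = length(a), n_b = length(b),
               n_both = length(intersect(a, b)),
               n_a_only = length(setdiff(a, b)),
               n_b_only = length(setdiff(b, a)))
  })
  a_all <- records_a$gene_id[records_a$category %in% categories]
  b_all <- records_b$gene_id[records_b$category %in% categories]
  list(per_category = do.call(rbind, per),
       lost_fraction = if (length(a_all))
         length(setdiff(a_all, b_all)) / length(a_all) else NA_real_,
       n_a = length(a_all), n_b = length(b_all))
}
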