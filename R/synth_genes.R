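#' Generate synthetic peak / expression / annotation tables with known
#' regulation categories
#'
#' Emulates the tabular outputs of differential-accessibility (ATAC) and
#' differential-expression (RNA) analyses for a set of genes laid out on
#' one synthetic chromosome, with a recorded ground-truth regulation
#' category per gene. Genes are placed in non-overlapping slots wide enough
#' that each promoter window (TSS +/- `promoter_window`) can hold its own
#' peaks and distal peaks stay farther than `flank` from every gene, so the
#' true peak-to-gene assignment is unambiguous.
#'
#' A `fraction_promoter_peaks` share of genes receives a promoter peak;
#' among those, the ground-truth category is drawn from
#' `da_de_category_probs` (remainder: no joint category). Genes without a
#' promoter peak are `NoPromoterPeak` by construction. A share of
#' promoter-peak genes additionally receives a second, non-significant
#' promoter peak strictly farther from the TSS, exercising the
#' closest-to-TSS resolution rule without perturbing the truth.
#'
#' All coordinates are 0-based half-open.
#'
#' @param n_genes number of genes.
#' @param genome_length optional chromosome length (bp); an error is
#'   raised when the gene slots do not fit. `NULL` sizes the chromosome
#'   automatically.
#' @param peak_width_range length-2 numeric, bp.
#' @param fraction_promoter_peaks fraction of genes given a promoter peak.
#' @param da_de_category_probs named numeric vector with (a subset of)
#'   names `Closed_UP`, `Closed_DOWN`, `Open_UP`, `Open_DOWN`; must sum to
#'   <= 1, remainder is uncategorized.
#' @param n_distal_peaks peaks placed farther than `flank` from any gene.
#' @param multi_peak_fraction fraction of promoter-peak genes that get a
#'   second (decoy) promoter peak.
#' @param promoter_window,flank assignment geometry (bp), matching the
#'   categorizer defaults.
#' @param fdr_threshold significance boundary used to draw FDR values on
#'   either side of it.
#' @param seed integer seed.
#' @return list with data frames `peaks` (peak_id, chrom, start, end, stat,
#'   strand, fdr, direction), `de` (gene_id, log2fc, fdr), `annotation`
#'   (gene_id, chrom, tss, strand, start, end) and `truth` (gene_id,
#'   has_promoter_peak, primary_peak_id, da_truth, de_truth,
#'   category_truth).
#' @export
generate_gene_tables <- function(n_genes = 1000, genome_length = NULL,
                                 peak_width_range = c(200, 600),
                                 fraction_promoter_peaks = 0.8,
                                 da_de_category_probs = c(Closed_UP = 0.10,
                                                          Closed_DOWN = 0.25,
                                                          Open_UP = 0.10,
                                                          Open_DOWN = 0.05),
                                 n_distal_peaks = 500,
                                 multi_peak_fraction = 0.1,
                                 promoter_window = 3000, flank = 5000,
                                 fdr_threshold = 0.05, seed = 7L) {
  categories <- c("Closed_UP", "Closed_DOWN", "Open_UP", "Open_DOWN")
  stopifnot(n_genes >= 1, all(names(da_de_category_probs) %in% categories),
            all(da_de_category_probs >= 0),
            fraction_promoter_peaks >= 0, fraction_promoter_peaks <= 1,
            multi_peak_fraction >= 0, multi_peak_fraction <= 1)
  if (sum(da_de_category_probs) > 1 + 1e-12)
    stop("`da_de_category_probs` must sum to at most 1")
  wmax <- max(peak_width_range)
  slot <- 2 * (promoter_window + flank) + 8000 + wmax + 2000
  needed <- n_genes * slot + slot
  if (is.null(genome_length)) genome_length <- needed
  if (genome_length < needed)
    stop(sprintf(paste0("genome_length %d too small: %d genes with ",
                        "non-overlapping bodies and promoter windows ",
                        "need >= %d bp"), genome_length, n_genes, needed))

  withr::with_seed(seed, {
    slot0 <- (seq_len(n_genes) - 1L) * slot
    tss <- slot0 + flank + promoter_window + 4000
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    body_len <- round(runif(n_genes, 2000, 8000))
    gstart <- ifelse(strand == "+", tss, tss - body_len)
    gend <- ifelse(strand == "+", tss + body_len, tss)
    annotation <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                             chrom = "chrS", tss = tss, strand = strand,
                             start = gstart, end = gend)

    has_peak <- runif(n_genes) < fraction_promoter_peaks
    category <- rep("none", n_genes)
    if (any(has_peak) && sum(da_de_category_probs) > 0) {
      pool <- c(names(da_de_category_probs), "none")
      pr <- c(unname(da_de_category_probs),
              max(0, 1 - sum(da_de_category_probs)))
      category[has_peak] <- sample(pool, sum(has_peak), replace = TRUE,
                                   prob = pr)
    }

    sig <- function(k) runif(k, 0.0005, fdr_threshold - 0.001)
    nonsig <- function(k) runif(k, fdr_threshold + 0.01, 0.95)

    # DA truth for the primary promoter peak of each peak-bearing gene
    da_dir <- rep(NA_character_, n_genes)
    da_fdr <- rep(NA_real_, n_genes)
    closed <- grepl("^Closed", category)
    open <- grepl("^Open", category)
    da_dir[closed] <- "more_closed"; da_fdr[closed] <- sig(sum(closed))
    da_dir[open] <- "more_open"; da_fdr[open] <- sig(sum(open))
    none_peak <- has_peak & category == "none"
    # uncategorized peak-bearing genes: DA significant xor DE significant
    # (or neither), so no joint category can arise
    case <- sample(c("da_only", "de_only", "neither"), sum(none_peak),
                   replace = TRUE)
    idx <- which(none_peak)
    da_only <- idx[case == "da_only"]
    de_only <- idx[case == "de_only"]
    neither <- idx[case == "neither"]
    da_dir[da_only] <- sample(c("more_open", "more_closed"),
                              length(da_only), replace = TRUE)
    da_fdr[da_only] <- sig(length(da_only))
    da_dir[c(de_only, neither)] <- "unchanged"
    da_fdr[c(de_only, neither)] <- nonsig(length(de_only) + length(neither))

    # DE truth per gene
    de_lfc <- runif(n_genes, -0.4, 0.4)
    de_fdr <- nonsig(n_genes)
    up <- grepl("UP$", category); down <- grepl("DOWN$", category)
    de_lfc[up] <- runif(sum(up), 0.5, 3)
    de_lfc[down] <- -runif(sum(down), 0.5, 3)
    de_fdr[up | down] <- sig(sum(up | down))
    de_lfc[de_only] <- sample(c(-1, 1), length(de_only), replace = TRUE) *
      runif(length(de_only), 0.5, 3)
    de_fdr[de_only] <- sig(length(de_only))
    de <- data.frame(gene_id = annotation$gene_id, log2fc = de_lfc,
                     fdr = de_fdr)

    # promoter peaks: primary within 1 kb of the TSS; decoys 1.6-2.5 kb out
    peaks <- list()
    primary_id <- rep(NA_character_, n_genes)
    k <- 0L
    for (i in which(has_peak)) {
      w <- round(runif(1, peak_width_range[1], peak_width_range[2]))
      off <- round(runif(1, -1000, 1000))
      s <- tss[i] + off - w %/% 2L
      k <- k + 1L
      primary_id[i] <- sprintf("peak%05d", k)
      peaks[[k]] <- data.frame(peak_id = primary_id[i], chrom = "chrS",
                               start = s, end = s + w,
                               stat = round(runif(1, 5, 200), 2),
                               strand = ".", fdr = da_fdr[i],
                               direction = da_dir[i])
      if (runif(1) < multi_peak_fraction) {
        w2 <- round(runif(1, peak_width_range[1], peak_width_range[2]))
        off2 <- sample(c(-1, 1), 1) * round(runif(1, 1600, 2500))
        s2 <- tss[i] + off2 - w2 %/% 2L
        k <- k + 1L
        peaks[[k]] <- data.frame(peak_id = sprintf("peak%05d", k),
                                 chrom = "chrS", start = s2, end = s2 + w2,
                                 stat = round(runif(1, 5, 200), 2),
                                 strand = ".", fdr = nonsig(1L),
                                 direction = "unchanged")
      }
    }
    # distal peaks: in the inter-gene gap, > flank from any gene
    if (n_distal_peaks > 0) {
      sl <- sample.int(n_genes, n_distal_peaks, replace = TRUE)
      w <- round(runif(n_distal_peaks, peak_width_range[1],
                       peak_width_range[2]))
      s <- slot0[sl] + slot - 2500 - w
      k2 <- k + seq_len(n_distal_peaks)
      peaks[[length(peaks) + 1L]] <- data.frame(
        peak_id = sprintf("peak%05d", k2), chrom = "chrS",
        start = s, end = s + w,
        stat = round(runif(n_distal_peaks, 5, 200), 2), strand = ".",
        fdr = runif(n_distal_peaks, 0.0005, 0.95),
        direction = sample(c("more_open", "more_closed", "unchanged"),
                           n_distal_peaks, replace = TRUE))
    }
    peaks <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(peak_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), stat = numeric(0),
                 strand = character(0), fdr = numeric(0),
                 direction = character(0))
    rownames(peaks) <- NULL

    da_truth <- ifelse(!has_peak, "NoPromoterPeak",
                ifelse(da_dir == "more_closed" & da_fdr < fdr_threshold,
                       "Closed",
                ifelse(da_dir == "more_open" & da_fdr < fdr_threshold,
                       "Open", "Unchanged")))
    de_truth <- ifelse(de_fdr < fdr_threshold & de_lfc > 0, "UP",
                ifelse(de_fdr < fdr_threshold & de_lfc < 0, "DOWN",
                       "Unchanged"))
    truth <- data.frame(gene_id = annotation$gene_id,
                        has_promoter_peak = has_peak,
                        primary_peak_id = primary_id,
                        da_truth = da_truth, de_truth = de_truth,
                        category_truth = category)
    list(peaks = peaks, de = de, annotation = annotation, truth = truth,
         genome_length = genome_length)
  })
}
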