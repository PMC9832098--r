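genes1 <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                     strand = "+")

test_that("promoter assignment respects the half-open window boundary", {
  pk <- function(s, e) data.frame(peak_id = "p1", chrom = "chr1",
                                  start = s, end = e, fdr = 0.01,
                                  direction = "more_open")
  expect_equal(nrow(assign_peaks_to_promoters(pk(9000, 9500), genes1)), 1L)
  # window is [7000, 13000): a peak starting at 13000 does not overlap
  expect_equal(nrow(assign_peaks_to_promoters(pk(13000, 13500), genes1)), 0L)
  expect_equal(nrow(assign_peaks_to_promoters(pk(13001, 13500), genes1)), 0L)
  expect_equal(nrow(assign_peaks_to_promoters(pk(12999, 13500), genes1)), 1L)
  # unknown chromosome: warn, unassigned
  bad <- pk(9000, 9500); bad$chrom <- "chrUn"
  expect_warning(a <- assign_peaks_to_promoters(bad, genes1), "chrUn")
  expect_equal(nrow(a), 0L)
})

test_that("assignment equals a brute-force all-pairs scan", {
  set.seed(23)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      tss = sample.int(2e5, 60), strand = "+")
  peaks <- data.frame(peak_id = sprintf("p%03d", 1:300),
                      chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      start = sample.int(2e5, 300))
  peaks$end <- peaks$start + sample(50:800, 300, TRUE)
  peaks$fdr <- runif(300); peaks$direction <- "more_open"
  got <- assign_peaks_to_promoters(peaks, genes)
  want <- brute_force_assignment(peaks, genes)
  key <- function(d) sort(paste(d$gene_id, d$peak_id))
  expect_identical(key(got), key(want))
})

test_that("multi-peak resolution follows the tie cascade", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                      strand = "+")
  # midpoints 100 bp and 900 bp from the TSS: nearer kept
  peaks <- data.frame(peak_id = c("near", "far"), chrom = "chr1",
                      start = c(10000, 10800), end = c(10200, 11000),
                      fdr = 0.5, direction = "unchanged")
  asg <- assign_peaks_to_promoters(peaks, genes)
  expect_equal(resolve_multi_peaks(asg, peaks, genes)$peak_id, "near")

  # equal midpoint distance: larger window overlap wins
  peaks2 <- data.frame(peak_id = c("small", "big"), chrom = "chr1",
                       start = c(9950, 9900), end = c(10050, 10100),
                       fdr = 0.5, direction = "unchanged")
  asg2 <- assign_peaks_to_promoters(peaks2, genes)
  expect_equal(resolve_multi_peaks(asg2, peaks2, genes)$peak_id, "big")

  # full tie: lowest start coordinate
  peaks3 <- data.frame(peak_id = c("b", "a"), chrom = "chr1",
                       start = c(9990, 9910), end = c(10090, 10010),
                       fdr = 0.5, direction = "unchanged")
  asg3 <- assign_peaks_to_promoters(peaks3, genes)
  expect_equal(resolve_multi_peaks(asg3, peaks3, genes)$peak_id, "a")

  # randomized genes: choice equals brute-force argmin with the cascade
  set.seed(31)
  genes4 <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                       tss = (1:20) * 50000L, strand = "+")
  peaks4 <- do.call(rbind, lapply(1:20, function(i) {
    n <- sample(1:4, 1)
    s <- genes4$tss[i] + sample(-2800:2400, n)
    data.frame(peak_id = sprintf("g%02dp%d", i, seq_len(n)),
               chrom = "chr1", start = s, end = s + sample(100:400, n, TRUE),
               fdr = 0.5, direction = "unchanged")
  }))
  asg4 <- assign_peaks_to_promoters(peaks4, genes4)
  got <- resolve_multi_peaks(asg4, peaks4, genes4)
  for (g in unique(asg4$gene_id)) {
    cand <- merge(asg4[asg4$gene_id == g, ], peaks4, by = "peak_id")
    tss <- genes4$tss[genes4$gene_id == g]
    md <- abs((cand$start + cand$end) / 2 - tss)
    ov <- pmin(cand$end, tss + 3000) - pmax(cand$start, tss - 3000)
    ord <- order(md, -ov, cand$start)
    expect_equal(got$peak_id[got$gene_id == g], cand$peak_id[ord[1]])
  }
})

test_that("DA and DE labels are strict at the FDR threshold", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(1e4, 5e4, 9e4), strand = "+")
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                      start = c(9900, 49900), end = c(10100, 50100),
                      fdr = c(0.01, 0.05),
                      direction = c("more_closed", "more_open"))
  res <- data.frame(gene_id = c("g1", "g2"), peak_id = c("p1", "p2"))
  da <- label_da(genes, res, peaks)
  expect_equal(da$da_call, c("Closed", "Unchanged", "NoPromoterPeak"))

  de <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.2, 0),
                   fdr = c(0.001, 0.01))
  w <- testthat::capture_warnings(dl <- label_de(genes, de))
  expect_match(w, "missing", all = FALSE)
  expect_match(w, "zero fold", all = FALSE)
  expect_equal(dl$de_call, c("UP", "Unchanged", "Unchanged"))
  de2 <- data.frame(gene_id = "g1", log2fc = -2, fdr = 0.2)
  expect_equal(label_de(genes[1, ], de2)$de_call, "Unchanged")
})

test_that("categories combine only doubly-significant genes", {
  da <- data.frame(gene_id = c("g1", "g2", "g3"),
                   peak_id = c("p1", "p2", NA),
                   da_call = c("Closed", "Closed", "NoPromoterPeak"))
  de <- data.frame(gene_id = c("g1", "g2", "g3"),
                   de_call = c("UP", "Unchanged", "DOWN"))
  rec <- combine_categories(da, de)
  expect_equal(rec$category, c("Closed_UP", "none", "none"))
  expect_equal(unname(attr(rec, "category_counts")["Closed_UP"]), 1L)
})

test_that("full pipeline recovers generated truth and stays monotone", {
  g <- generate_gene_tables(n_genes = 400, seed = 7)
  rec <- categorize_genes(g$peaks, g$de, g$annotation)
  i <- match(g$truth$gene_id, rec$gene_id)
  expect_identical(rec$category[i], g$truth$category_truth)
  expect_identical(rec$da_call[i], g$truth$da_truth)
  expect_identical(rec$de_call[i], g$truth$de_truth)
  # assigned primary peak matches the constructed one
  has <- g$truth$has_promoter_peak
  expect_identical(rec$peak_id[i][has], g$truth$primary_peak_id[has])

  # category counts partition the doubly-significant set
  lev <- c("Closed_UP", "Closed_DOWN", "Open_UP", "Open_DOWN")
  expect_equal(sum(attr(rec, "category_counts")),
               sum(rec$category %in% lev))

  # lowering the threshold never adds categorized genes
  rec2 <- categorize_genes(g$peaks, g$de, g$annotation,
                           fdr_threshold = 0.01)
  expect_lte(sum(rec2$category != "none"), sum(rec$category != "none"))

  # fraction_promoter_peaks = 0: nothing assigned
  g0 <- generate_gene_tables(n_genes = 50, fraction_promoter_peaks = 0,
                             n_distal_peaks = 40, seed = 7)
  rec0 <- categorize_genes(g0$peaks, g0$de, g0$annotation)
  expect_true(all(rec0$da_call == "NoPromoterPeak"))

  # single-category fixed point
  g1 <- generate_gene_tables(n_genes = 50, fraction_promoter_peaks = 1,
                             da_de_category_probs = c(Closed_DOWN = 1),
                             n_distal_peaks = 0, seed = 9)
  rec1 <- categorize_genes(g1$peaks, g1$de, g1$annotation)
  expect_true(all(rec1$category == "Closed_DOWN"))
})

test_that("condition intersection reports Venn counts and lost fraction", {
  rec <- function(cats) data.frame(gene_id = sprintf("g%02d",
                                                     seq_along(cats)),
                                   category = cats)
  a <- rec(c("Closed_UP", "Closed_DOWN", "Open_UP", "none"))
  expect_equal(intersect_conditions(a, a)$lost_fraction, 0)
  b_empty <- rec(rep("none", 4))
  expect_equal(intersect_conditions(a, b_empty)$lost_fraction, 1)
  expect_error(intersect_conditions(a, rec("Closed_UP")[0, ]),
               "universe")

  # random labelings vs brute-force set operations
  set.seed(13)
  lev <- c("Closed_UP", "Closed_DOWN", "Open_UP", "Open_DOWN", "none")
  ca <- sample(lev, 200, TRUE); cb <- sample(lev, 200, TRUE)
  a <- rec(ca); b <- rec(cb)
  r <- intersect_conditions(a, b)
  for (j in seq_len(nrow(r$per_category))) {
    cat <- r$per_category$category[j]
    sa <- a$gene_id[ca == cat]; sb <- b$gene_id[cb == cat]
    expect_equal(r$per_category$n_both[j], length(intersect(sa, sb)))
    expect_equal(r$per_category$n_a_only[j], length(setdiff(sa, sb)))
    expect_equal(r$per_category$n_b_only[j], length(setdiff(sb, sa)))
  }
  aa <- a$gene_id[ca != "none"]; bb <- b$gene_id[cb != "none"]
  expect_equal(r$lost_fraction, length(setdiff(aa, bb)) / length(aa))
})
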