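# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Exhaustive nearest-seed search: for every foreground pixel, the label of
# the seed region whose nearest pixel is closest (Euclidean; ties to the
# lowest label). Seed-interior pixels have distance 0 to their own region.
# For integer pixel grids the nearest pixel of a region to an external
# pixel is always on the region's 4-connectivity boundary, so the search
# is restricted to boundary pixels without changing the result.
brute_force_voronoi <- function(nuclei, cell_mask) {
  lab <- nuclei$label_image
  H <- nrow(lab); W <- ncol(lab)
  fg <- which(cell_mask | lab > 0L)
  rows <- (fg - 1L) %% H + 1L
  cols <- (fg - 1L) %/% H + 1L
  ids <- mask_labels(nuclei)
  best_d <- rep(Inf, length(fg))
  best_l <- rep(0L, length(fg))
  for (k in ids) {
    sp <- which(lab == k)
    sr <- (sp - 1L) %% H + 1L
    sc <- (sp - 1L) %/% H + 1L
    inb <- matrix(FALSE, H, W); inb[sp] <- TRUE
    bnd <- vapply(seq_along(sp), function(i) {
      r <- sr[i]; c <- sc[i]
      r == 1L || r == H || c == 1L || c == W ||
        !inb[r - 1L, c] || !inb[r + 1L, c] ||
        !inb[r, c - 1L] || !inb[r, c + 1L]
    }, logical(1))
    d2 <- outer(rows, sr[bnd], `-`)^2 + outer(cols, sc[bnd], `-`)^2
    d <- sqrt(do.call(pmin, as.data.frame(d2)))
    d[lab[fg] == k] <- 0
    upd <- d < best_d
    best_l[upd] <- k
    best_d[upd] <- d[upd]
  }
  out <- matrix(0L, H, W)
  out[fg] <- best_l
  out
}

# All-pairs interval overlap scan for promoter assignment (0-based
# half-open peaks vs [tss - w, tss + w) windows).
brute_force_assignment <- function(peaks, genes, promoter_window = 3000) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != genes$chrom[i]) next
      w0 <- genes$tss[i] - promoter_window
      w1 <- genes$tss[i] + promoter_window
      if (peaks$start[j] < w1 && peaks$end[j] > w0)
        out[[length(out) + 1L]] <- data.frame(gene_id = genes$gene_id[i],
                                              peak_id = peaks$peak_id[j])
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), peak_id = character(0)))
  do.call(rbind, out)
}

# canonical small field used by several mask-algebra tests
clumped_test_field <- function(seed, n_cells = 20, width = 256,
                               height = 256) {
  generate_cell_field(field_spec(width = width, height = height,
                                 n_cells = n_cells, infected_fraction = 1,
                                 clumped_fraction = 0.5, seed = seed))
}

# truth-matched measurement table for a synthetic field
matched_measurements <- function(field, wf) {
  map <- match_to_truth(wf$nuclei, field$truth$nuclei)
  m <- wf$measurements
  m$truth_id <- map[as.character(m$cell_id)]
  merge(m, field$truth$cells, by.x = "truth_id", by.y = "cell_id")
}
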