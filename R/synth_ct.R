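#' Generate a synthetic ChIP-qPCR Ct table with known true enrichment
#'
#' Inverse model of comparative-Ct quantification. A specific
#' immunoprecipitation (IP) pulls down `true_fold` times more template at
#' the assayed region than the non-related antibody (NRA) control; both are
#' compared against the reserved input fraction. Template abundance is
#' converted to a threshold cycle via `Ct = offset - log2(abundance)` with a
#' fixed offset of 40 cycles (arbitrary, cancels in the double difference),
#' and diluting the template 1:d adds `log2(d)` cycles.
#'
#' At `ct_noise_sd = 0` the downstream comparative-Ct pipeline
#' ([chip_enrichment()]) recovers `true_fold` exactly.
#'
#' @param true_fold true IP/NRA enrichment (> 0).
#' @param input_fraction fraction of chromatin reserved as input
#'   (default 0.05, i.e. 5%).
#' @param dilutions dilution factors at which each template is amplified.
#' @param ct_noise_sd SD of Gaussian noise added to every Ct, in cycles.
#' @param n_replicates technical replicates per well.
#' @param region,condition labels copied into the records.
#' @param nra_pulldown fraction of input chromatin recovered by the NRA
#'   control pull-down (sets the absolute Ct scale only).
#' @param seed integer seed.
#' @return data frame with columns region, condition, antibody
#'   (`"IP"`/`"NRA"`), fraction (`"bound"`/`"input"`), dilution, replicate,
#'   ct.
#' @export
generate_ct_table <- function(true_fold, input_fraction = 0.05,
                              dilutions = c(1, 10, 50), ct_noise_sd = 0,
                              n_replicates = 1, region = "amplicon",
                              condition = "PRO", nra_pulldown = 0.001,
                              seed = 1L) {
  if (!is.numeric(true_fold) || length(true_fold) != 1L || true_fold <= 0)
    stop("`true_fold` must be a single positive number")
  stopifnot(input_fraction > 0, input_fraction <= 1, all(dilutions > 0),
            ct_noise_sd >= 0, n_replicates >= 1)
  offset <- 40
  abundance <- c(IP_bound = nra_pulldown * true_fold,
                 NRA_bound = nra_pulldown,
                 IP_input = input_fraction,
                 NRA_input = input_fraction)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dilution = dilutions,
                      key = names(abundance),
                      stringsAsFactors = FALSE)
  ab_frac <- strsplit(grid$key, "_", fixed = TRUE)
  tab <- data.frame(region = region, condition = condition,
                    antibody = vapply(ab_frac, `[`, "", 1L),
                    fraction = vapply(ab_frac, `[`, "", 2L),
                    dilution = grid$dilution,
                    replicate = grid$replicate)
  ct <- offset - log2(abundance[grid$key] / grid$dilution)
  withr::with_seed(seed, {
    if (ct_noise_sd > 0) ct <- ct + rnorm(length(ct), 0, ct_noise_sd)
  })
  tab$ct <- as.numeric(ct)
  tab
}
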