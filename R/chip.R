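#' Delta Ct between bound and input fractions
#'
#' @param ct_bound,ct_input threshold cycles of the immunoprecipitated
#'   (bound) and reserved input fractions for the same antibody, region and
#'   condition. Vectorized.
#' @return `ct_bound - ct_input`, in cycles.
#' @export
delta_ct <- function(ct_bound, ct_input) {
  if (any(is.na(ct_bound)))
    stop("missing bound-fraction Ct at position(s): ",
         paste(which(is.na(ct_bound)), collapse = ", "))
  if (any(is.na(ct_input)))
    stop("missing input-fraction Ct at position(s): ",
         paste(which(is.na(ct_input)), collapse = ", "))
  ct_bound - ct_input
}

#' Comparative-Ct fold enrichment of an IP relative to the NRA control
#'
#' Both the specific IP and the non-related antibody (NRA) are first
#' normalized to their input (delta Ct); the fold enrichment is
#' `efficiency^(dCt_NRA - dCt_IP)`, i.e. 2^(ddCt) under perfect
#' amplification.
#'
#' @param delta_ct_ip,delta_ct_nra input-normalized delta Ct values.
#' @param efficiency per-cycle amplification factor (default 2: perfect
#'   doubling).
#' @return dimensionless fold enrichment (> 0).
#' @export
fold_enrichment <- function(delta_ct_ip, delta_ct_nra, efficiency = 2) {
  stopifnot(efficiency > 1)
  efficiency^(delta_ct_nra - delta_ct_ip)
}

#' Dilution-series positivity rule for a ChIP region
#'
#' A region/condition is called positive only when the bound-fraction Ct
#' of the IP is strictly below that of the NRA control in at least two
#' distinct dilutions. With fewer than two dilutions carrying both Cts the
#' call is `"insufficient"` (not negative).
#'
#' @param ct_table data frame with columns antibody (`IP`/`NRA`), fraction,
#'   dilution, ct (one region/condition; replicate Cts are averaged per
#'   dilution).
#' @return `"positive"`, `"not_positive"` or `"insufficient"`.
#' @export
positivity_call <- function(ct_table) {
  b <- ct_table[ct_table$fraction == "bound", , drop = FALSE]
  agg <- stats::aggregate(ct ~ antibody + dilution, data = b, FUN = mean)
  wide <- merge(agg[agg$antibody == "IP", c("dilution", "ct")],
                agg[agg$antibody == "NRA", c("dilution", "ct")],
                by = "dilution", suffixes = c("_ip", "_nra"))
  if (nrow(wide) < 2L) return("insufficient")
  if (sum(wide$ct_ip < wide$ct_nra) >= 2L) "positive" else "not_positive"
}

#' Comparative-Ct quantification of a ChIP-qPCR table
#'
#' For every (region, condition): replicate Cts are averaged per
#' (antibody, fraction, dilution); delta Ct (bound - input) is formed per
#' antibody and dilution; the per-dilution fold enrichment
#' `efficiency^(dCt_NRA - dCt_IP)` is combined across dilutions as a
#' geometric mean (equivalently, the mean ddCt) — under ideal efficiency
#' the dilution offset cancels exactly. The dilution-series positivity
#' rule ([positivity_call()]) and the raw bound-fraction IP/NRA ratio are
#' reported alongside.
#'
#' @param ct_table data frame with columns region, condition, antibody,
#'   fraction, dilution, ct (optional replicate).
#' @param efficiency per-cycle amplification factor.
#' @return data frame with one row per (region, condition): region,
#'   condition, fold_enrichment, ip_over_nra_ratio (bound fractions only,
#'   not input-normalized), positive_call, n_dilutions.
#' @export
chip_enrichment <- function(ct_table, efficiency = 2) {
  need <- c("region", "condition", "antibody", "fraction", "dilution", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  groups <- unique(ct_table[c("region", "condition")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- ct_table[ct_table$region == groups$region[i] &
                    ct_table$condition == groups$condition[i], ,
                  drop = FALSE]
    agg <- stats::aggregate(ct ~ antibody + fraction + dilution, data = g,
                            FUN = mean)
    get <- function(ab, fr) {
      x <- agg[agg$antibody == ab & agg$fraction == fr,
               c("dilution", "ct")]
      stats::setNames(x$ct, x$dilution)
    }
    ipb <- get("IP", "bound"); ipi <- get("IP", "input")
    nrb <- get("NRA", "bound"); nri <- get("NRA", "input")
    dil <- Reduce(intersect, list(names(ipb), names(ipi), names(nrb),
                                  names(nri)))
    if (length(dil) == 0L)
      stop(sprintf("no dilution with complete IP/NRA bound+input Cts for %s/%s",
                   groups$region[i], groups$condition[i]))
    dct_ip <- delta_ct(ipb[dil], ipi[dil])
    dct_nra <- delta_ct(nrb[dil], nri[dil])
    folds <- fold_enrichment(dct_ip, dct_nra, efficiency)
    data.frame(region = groups$region[i], condition = groups$condition[i],
               fold_enrichment = exp(mean(log(folds))),
               ip_over_nra_ratio =
                 exp(mean(log(efficiency^(nrb[dil] - ipb[dil])))),
               positive_call = positivity_call(g),
               n_dilutions = length(dil))
  })
  do.call(rbind, out)
}

#' Enrichment ratio between differentiative and proliferative conditions
#'
#' @param result_diff,result_pro fold enrichments (e.g. from
#'   [chip_enrichment()]) for the DIFF and PRO conditions of one region.
#' @return `result_diff / result_pro`; `NA` with a warning when the PRO
#'   fold is undefined or zero.
#' @export
differential_enrichment <- function(result_diff, result_pro) {
  if (is.na(result_pro) || result_pro == 0) {
    warning("reference (PRO) fold enrichment undefined or zero")
    return(NA_real_)
  }
  result_diff / result_pro
}

#' Firefly/Renilla luciferase ratio
#'
#' Transfection-normalized reporter activity: firefly luminescence divided
#' by the co-transfected Renilla luminescence, optionally expressed
#' relative to a reference ratio (e.g. the wild-type proliferative
#' condition).
#'
#' @param firefly,renilla luminescence readings (a.u.); vectorized.
#' @param reference_ratio optional reference activity for relative output.
#' @return numeric vector of activities (or relative activities when a
#'   reference is given).
#' @export
luciferase_ratio <- function(firefly, renilla, reference_ratio = NULL) {
  if (any(renilla <= 0))
    stop("Renilla luminescence must be positive (rows: ",
         paste(which(renilla <= 0), collapse = ", "), ")")
  act <- firefly / renilla
  if (!is.null(reference_ratio)) {
    stopifnot(reference_ratio > 0)
    act <- act / reference_ratio
  }
  act
}
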