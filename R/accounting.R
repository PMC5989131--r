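#' Read-accounting summary for a sequencing campaign
#'
#' Recomputes the standard bookkeeping ratios from run totals: the quality
#' trimming retention percentage, the protein-database mapping rate
#' (mapped / trimmed), and the mean mapped reads per sample.
#'
#' @param raw_total total raw sequences.
#' @param trimmed_total sequences surviving quality trimming.
#' @param mapped_total sequences mapped against the reference database.
#' @param n_samples number of samples.
#' @return list `retention_pct`, `mapping_pct`, `mean_mapped_per_sample`.
#' @export
read_accounting <- function(raw_total, trimmed_total, mapped_total,
                            n_samples) {
  stopifnot(raw_total > 0, trimmed_total <= raw_total,
            mapped_total <= trimmed_total, n_samples >= 1)
  list(retention_pct = 100 * trimmed_total / raw_total,
       mapping_pct = 100 * mapped_total / trimmed_total,
       mean_mapped_per_sample = mapped_total / n_samples)
}

#' Mean rainfall per rainy day
#'
#' @param annual_mm total annual rainfall (mm).
#' @param rainy_days number of rainy days in the year.
#' @return mm of rain per rainy day.
#' @export
rain_per_rainy_day <- function(annual_mm, rainy_days) {
  stopifnot(annual_mm >= 0, rainy_days >= 1)
  annual_mm / rainy_days
}
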