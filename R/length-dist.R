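#' Normalized footprint length distribution
#'
#' Aggregates per-unit length histograms into the frequency f(l) of footprint
#' lengths for one footprint class. Each unit (an SD site, or a gene for the
#' NoSD class) contributes its raw counts weighted by 1/N, where N is the
#' number of SD sites in the unit's parent gene (`mode = "per_sd"`) or 1
#' (`mode = "per_gene"`); the sum is then renormalized to total 1. With
#' `unit_normalize = TRUE` each unit's histogram is first normalized to sum 1
#' before weighting (the alternative reading of the per-unit statistic), which
#' makes f(l) invariant to scaling any single unit's counts.
#'
#' @param units long-format unit histograms from [sd_unit_histograms()].
#' @param mode `"per_sd"` or `"per_gene"`.
#' @param unit_normalize normalize each unit's histogram before averaging.
#' @return data.frame with columns `length`, `freq` (summing to 1), with
#'   attribute `n_units`.
#' @export
length_distribution <- function(units, mode = c("per_sd", "per_gene"),
                                unit_normalize = FALSE) {
  mode <- match.arg(mode)
  if (!nrow(units)) stop("no units to aggregate")
  totals <- tapply(units$count, units$unit_id, sum)
  nonzero <- names(totals)[totals > 0]
  if (length(nonzero) < length(totals))
    message(length(totals) - length(nonzero), " empty unit(s) skipped")
  units <- units[units$unit_id %in% nonzero, , drop = FALSE]
  w <- if (mode == "per_sd") 1 / units$n_sd_in_gene else rep(1, nrow(units))
  if (unit_normalize) w <- w / as.numeric(totals[units$unit_id])
  contrib <- units$count * w
  f <- tapply(contrib, units$length, sum)
  out <- data.frame(length = as.integer(names(f)),
                    freq = as.numeric(f) / sum(f))
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_units") <- length(nonzero)
  out
}

#' Mean of a length distribution
#' @param ld data.frame from [length_distribution()].
#' @return expected footprint length, nt.
#' @export
length_distribution_mean <- function(ld) sum(ld$length * ld$freq)

#' Compare two footprint length samples (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test on raw per-footprint lengths,
#' using the normal approximation with the tie-corrected variance. When every
#' value in both samples is identical the test is degenerate and p = 1 by
#' convention.
#'
#' @param a,b numeric vectors of footprint lengths.
#' @return list with `statistic` (W, as in [stats::wilcox.test()]) and
#'   `p.value`.
#' @export
compare_length_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p.value = 1))
  }
  ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
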