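# Metagene end-density machinery: per-site end counts in a fixed window
# around each SD site (s = 1 at the site's first nucleotide, s in
# [-flank+1, flank], width 2*flank), and their per-site-normalized average
#   d(s) = (1/N) * sum_i x_{s,i} / X_i
# where x_{s,i} counts footprint 5' (or 3') ends at offset s for site i and
# X_i is the site's average footprint coverage per nucleotide in the window.

# counts/coverage for one anchor given end coordinates on the same axis
.end_counts_one <- function(anchor, fp5, fp3, flank) {
  lo <- anchor - flank
  hi <- anchor + flank - 1L
  x5 <- tabulate(fp5 - lo + 1L, nbins = 2L * flank)
  x3 <- tabulate(fp3 - lo + 1L, nbins = 2L * flank)
  ov <- pmin(fp3, hi) - pmax(fp5, lo) + 1L
  ov <- ov[ov > 0L]
  list(x5 = x5, x3 = x3,
       coverage = sum(ov) / (2L * flank),
       n_touching = length(ov))
}

#' Footprint end counts around SD sites
#'
#' For every SD site, counts footprint 5' and 3' ends at each offset
#' s in `[-flank + 1, flank]` relative to the site's first nucleotide (s = 1),
#' along with the site's average footprint coverage per nucleotide (X). Sites
#' are excluded when the window is not wholly inside the trimmed ORF interior
#' (truncation bias), when footprint density in the window is at or below
#' `cfg$min_density_profiles` per codon, or when X = 0.
#'
#' @param fp interior-filtered footprint table with `gene_id`, `cds5`, `cds3`.
#' @param sites SD-site table (coding-strand `start` per gene).
#' @param genes gene table.
#' @param cfg a [filter_config()].
#' @param flank half-window, nt (default 50).
#' @param length_stratum restrict footprints (counts and X alike) to this
#'   length, or `NULL` for all lengths. The density floor is always assessed
#'   on all-length footprints; a site additionally needs at least two stratum
#'   footprints in the window (a single clipped footprint makes x/X
#'   numerically unstable).
#' @return object of class `site_end_counts`: list with `s` (offsets),
#'   matrices `x5`, `x3` (sites x offsets), `X`, `site_id`, `n_excluded`.
#' @export
site_end_counts <- function(fp, sites, genes, cfg = filter_config(),
                            flank = 50L, length_stratum = NULL) {
  fp_str <- if (is.null(length_stratum)) fp else
    fp[fp$length == length_stratum, , drop = FALSE]
  s <- seq.int(-flank + 1L, flank)
  x5 <- x3 <- matrix(0L, 0L, 2L * flank)
  X <- numeric(0)
  ids <- character(0)
  n_excl <- 0L
  for (k in seq_len(nrow(sites))) {
    st <- sites[k, ]
    g <- genes[genes$gene_id == st$gene_id, ]
    lo <- st$start - flank
    hi <- st$start + flank - 1L
    if (lo < cfg$head_trim + 1L || hi > g$length - cfg$tail_trim) {
      n_excl <- n_excl + 1L
      next
    }
    all_sub <- fp[fp$gene_id == st$gene_id, , drop = FALSE]
    dens_all <- .end_counts_one(st$start, all_sub$cds5, all_sub$cds3, flank)
    sub <- fp_str[fp_str$gene_id == st$gene_id, , drop = FALSE]
    ec <- .end_counts_one(st$start, sub$cds5, sub$cds3, flank)
    if (ec$coverage <= 0 ||
        dens_all$n_touching / (2L * flank / 3) <= cfg$min_density_profiles ||
        (!is.null(length_stratum) && ec$n_touching < 2L)) {
      n_excl <- n_excl + 1L
      next
    }
    x5 <- rbind(x5, ec$x5)
    x3 <- rbind(x3, ec$x3)
    X <- c(X, ec$coverage)
    ids <- c(ids, paste0(st$gene_id, ":", st$start))
  }
  structure(list(s = s, x5 = x5, x3 = x3, X = X, site_id = ids,
                 n_excluded = n_excl,
                 stratum = if (is.null(length_stratum)) "all" else length_stratum),
            class = "site_end_counts")
}

#' Build end counts from bare coordinates (simulation path)
#'
#' Same statistic as [site_end_counts()] but for footprints on naked
#' sequences: end coordinates and anchor positions live on one per-sequence
#' axis and no gene/interior bookkeeping applies beyond the sequence bounds.
#'
#' @param fp simulated footprint table with `seq_id`, `five_prime`,
#'   `three_prime`.
#' @param anchors data.frame with `seq_id` and `pos` (anchor = SD first
#'   nucleotide).
#' @param seq_length sequence length (anchors closer than `flank` to either
#'   bound are excluded).
#' @param flank half-window, nt.
#' @param length_stratum restrict to footprints of this emitted length (the
#'   density floor stays on all lengths; a stratum site needs >= 2 footprints).
#' @param min_density_per_codon exclusion threshold as in [site_end_counts()].
#' @return a `site_end_counts` object.
#' @export
end_counts_at_anchors <- function(fp, anchors, seq_length, flank = 50L,
                                  length_stratum = NULL,
                                  min_density_per_codon = 0) {
  fp_str <- if (is.null(length_stratum)) fp else
    fp[fp$length == length_stratum, , drop = FALSE]
  fp_by_seq <- split(fp, fp$seq_id)
  fp_str_by_seq <- split(fp_str, fp_str$seq_id)
  x5 <- x3 <- matrix(0L, 0L, 2L * flank)
  X <- numeric(0)
  ids <- character(0)
  n_excl <- 0L
  for (k in seq_len(nrow(anchors))) {
    a <- anchors[k, ]
    if (a$pos - flank < 1L || a$pos + flank - 1L > seq_length) {
      n_excl <- n_excl + 1L
      next
    }
    all_sub <- fp_by_seq[[as.character(a$seq_id)]]
    sub <- fp_str_by_seq[[as.character(a$seq_id)]]
    if (is.null(sub) || is.null(all_sub)) {
      n_excl <- n_excl + 1L
      next
    }
    dens_all <- .end_counts_one(a$pos, all_sub$five_prime, all_sub$three_prime,
                                flank)
    ec <- .end_counts_one(a$pos, sub$five_prime, sub$three_prime, flank)
    if (ec$coverage <= 0 ||
        dens_all$n_touching / (2L * flank / 3) <= min_density_per_codon ||
        (!is.null(length_stratum) && ec$n_touching < 2L)) {
      n_excl <- n_excl + 1L
      next
    }
    x5 <- rbind(x5, ec$x5)
    x3 <- rbind(x3, ec$x3)
    X <- c(X, ec$coverage)
    ids <- c(ids, paste0(a$seq_id, ":", a$pos))
  }
  structure(list(s = seq.int(-flank + 1L, flank), x5 = x5, x3 = x3, X = X,
                 site_id = ids, n_excluded = n_excl,
                 stratum = if (is.null(length_stratum)) "all" else length_stratum),
            class = "site_end_counts")
}

#' Aggregate end counts into a normalized end-density profile
#'
#' @param sec a `site_end_counts` object.
#' @return data.frame with columns `s`, `d5`, `d3`, `stratum`, `n_sites`;
#'   d(s) = mean over sites of x(s)/X.
#' @export
end_density_profile <- function(sec) {
  stopifnot(inherits(sec, "site_end_counts"))
  keep <- sec$X > 0
  if (any(!keep)) message(sum(!keep), " site(s) with X = 0 excluded")
  if (!any(keep)) stop("no sites with positive coverage")
  d5 <- colMeans(sec$x5[keep, , drop = FALSE] / sec$X[keep])
  d3 <- colMeans(sec$x3[keep, , drop = FALSE] / sec$X[keep])
  data.frame(s = sec$s, d5 = d5, d3 = d3,
             stratum = sec$stratum, n_sites = sum(keep))
}

#' Peak summary of an end-density profile column
#'
#' Baseline (median over an SD-distal flank), peak position (argmax), full
#' width at half maximum above baseline, and the excess-density-weighted
#' centroid and variance of the peak.
#'
#' @param s offset vector.
#' @param d density vector.
#' @param baseline_s logical or indices selecting the baseline flank (default:
#'   offsets at or below -15, upstream of any footprint-end peak for SD-driven
#'   pauses at +11).
#' @param peak_window half-width of the window around the argmax over which
#'   the centroid and variance are accumulated (keeps baseline noise far from
#'   the peak out of the moments).
#' @return list with `baseline`, `peak_pos`, `peak_height`, `fwhm`,
#'   `centroid`, `variance`.
#' @export
profile_peak_stats <- function(s, d, baseline_s = s <= -15, peak_window = 16L) {
  baseline <- median(d[baseline_s])
  peak <- which.max(d)
  in_win <- abs(s - s[peak]) <= peak_window
  excess <- pmax(d - baseline, 0) * in_win
  half <- baseline + (d[peak] - baseline) / 2
  centroid <- sum(s * excess) / sum(excess)
  list(baseline = baseline,
       peak_pos = s[peak],
       peak_height = d[peak],
       fwhm = sum(d >= half & in_win),
       centroid = centroid,
       variance = sum(excess * (s - centroid)^2) / sum(excess))
}
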