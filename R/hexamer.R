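#' Hexamer-level correlation of duplex strength, footprint length and density
#'
#' For every hexamer occurrence in the trimmed interiors of sufficiently
#' expressed genes, collects the footprints whose 5' end lies 8 to 2 nt
#' upstream of the hexamer's first nucleotide. Per hexamer it reports the mean
#' footprint length (over contributing footprints), the mean per-gene
#' normalized 5'-end density (per occurrence: window 5'-end count per nt
#' divided by the gene's mean interior 5'-end rate), and the hexamer:aSD
#' duplex energy. Hexamers with fewer than `min_values` contributing
#' footprints are dropped. Pearson correlations are computed on the
#' hexamer-level averages, with binding strength taken as -delta_g so that
#' stronger pairing is a larger value.
#'
#' @param fp interior-filtered footprint table with `gene_id`, `cds5`,
#'   `length`.
#' @param genes gene table.
#' @param genome named character vector of contig sequences.
#' @param model a [duplex_model()].
#' @param cfg a [filter_config()]; genes must exceed
#'   `cfg$min_density_distributions` footprints per codon to enter.
#' @param min_values minimum contributing footprints per hexamer (default 10).
#' @param upstream_window 5'-end offsets upstream of the hexamer start,
#'   `c(far, near)` (default `c(8, 2)`).
#' @return list with `table` (hexamer, delta_g, n_values, n_occurrences,
#'   mean_length, mean_norm_density), `r_strength_length` and
#'   `r_density_length`.
#' @export
correlate_hexamer <- function(fp, genes, genome, model = duplex_model(),
                              cfg = filter_config(), min_values = 10,
                              upstream_window = c(8, 2)) {
  dens <- gene_density(fp, genes, cfg)
  keep_genes <- names(dens)[!is.na(dens) & dens > cfg$min_density_distributions]
  if (!length(keep_genes)) stop("no gene passes the density filter")
  hex_dg <- kmer_energy_table(6L, model)
  n_hex <- length(hex_dg)
  n_values <- n_occ <- numeric(n_hex)
  sum_len <- sum_norm <- numeric(n_hex)
  far <- upstream_window[1]
  near <- upstream_window[2]
  for (gid in keep_genes) {
    g <- genes[genes$gene_id == gid, ]
    L <- g$length
    codes <- kmer_codes(cds_sequence(genome, g), 6L)
    h <- seq.int(cfg$head_trim + 1L, L - cfg$tail_trim - 5L)
    h <- h[!is.na(codes[h])]
    if (!length(h)) next
    sub <- fp[fp$gene_id == gid, , drop = FALSE]
    cnt5 <- tabulate(sub$cds5, nbins = L)
    slen5 <- numeric(L)
    agg <- rowsum(sub$length, sub$cds5)
    slen5[as.integer(rownames(agg))] <- agg[, 1]
    ccnt <- cumsum(c(0, cnt5))
    clen <- cumsum(c(0, slen5))
    # footprint 5' ends in [h - far, h - near]
    win_n <- ccnt[pmax(h - near, 0) + 1L] - ccnt[pmax(h - far - 1L, 0) + 1L]
    win_len <- clen[pmax(h - near, 0) + 1L] - clen[pmax(h - far - 1L, 0) + 1L]
    interior <- seq.int(cfg$head_trim + 1L, L - cfg$tail_trim)
    rate <- mean(cnt5[interior])
    norm_dens <- if (rate > 0) (win_n / (far - near + 1)) / rate else rep(0, length(h))
    code1 <- codes[h] + 1L
    n_values <- n_values + unname(tapply_add(win_n, code1, n_hex))
    sum_len <- sum_len + unname(tapply_add(win_len, code1, n_hex))
    sum_norm <- sum_norm + unname(tapply_add(norm_dens, code1, n_hex))
    n_occ <- n_occ + unname(tapply_add(rep(1, length(h)), code1, n_hex))
  }
  keep <- n_values >= min_values & n_occ > 0
  tab <- data.frame(
    hexamer = names(hex_dg)[keep],
    delta_g = unname(hex_dg[keep]),
    n_values = n_values[keep],
    n_occurrences = n_occ[keep],
    mean_length = sum_len[keep] / n_values[keep],
    mean_norm_density = sum_norm[keep] / n_occ[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(tab) < 2L)
    stop("fewer than 2 hexamers survive the min_values filter; ",
         "correlation undefined")
  list(table = tab,
       r_strength_length = cor(-tab$delta_g, tab$mean_length),
       r_density_length = cor(tab$mean_norm_density, tab$mean_length))
}

# sum `x` into `n` bins indexed by `idx` (1-based)
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
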