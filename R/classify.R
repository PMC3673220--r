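# Footprint classification against internal SD sites.
#
# A footprint is "SD" when some octamer starting within footprint positions
# 3..17 (1-based from the 5' end, coding strand) hybridizes to the aSD at or
# below sd_threshold; "NoSD" when no octamer starting in that window reaches
# nosd_threshold; "Ambiguous" otherwise. For footprints shorter than 24 nt the
# octamer start window is clipped so the octamer stays inside the footprint;
# footprints shorter than 10 nt admit no octamer and are Ambiguous.

CLASS_WINDOW_FIRST <- 3L
CLASS_WINDOW_LAST <- 17L

# per-gene octamer energies along the coding strand (position = octamer start)
gene_octamer_energies <- function(genome, gene, model) {
  tab <- kmer_energy_table(8L, model)
  codes <- kmer_codes(cds_sequence(genome, gene), 8L)
  e <- rep(0, length(codes))
  ok <- !is.na(codes)
  e[ok] <- tab[codes[ok] + 1L]
  e
}

#' Classify footprints as SD / NoSD / Ambiguous
#'
#' @param fp interior-filtered footprint table with `gene_id`, `cds5`,
#'   `length` (see [filter_interior()]).
#' @param genes gene table.
#' @param genome named character vector of contig sequences.
#' @param model a [duplex_model()].
#' @param sd_threshold SD detection threshold, kcal/mol (default -8).
#' @param nosd_threshold exclusion threshold for the NoSD class, kcal/mol
#'   (default -2): NoSD footprints have no octamer at or below this value in
#'   the classification window.
#' @return `fp` with columns `class` (factor SD/NoSD/Ambiguous), `min_dg`
#'   (strongest octamer in the window), `win_from`/`win_to` (coding-strand
#'   octamer start window actually used).
#' @export
classify_footprints <- function(fp, genes, genome, model = duplex_model(),
                                sd_threshold = -8, nosd_threshold = -2) {
  stopifnot(all(c("gene_id", "cds5", "length") %in% names(fp)))
  fp$min_dg <- NA_real_
  fp$win_from <- NA_integer_
  fp$win_to <- NA_integer_
  n_short <- 0L
  for (gid in unique(fp$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    e <- gene_octamer_energies(genome, g, model)
    rows <- which(fp$gene_id == gid)
    len <- fp$length[rows]
    # octamer start window, footprint-relative then coding-strand
    rel_last <- pmin(CLASS_WINDOW_LAST, len - 7L)
    from <- fp$cds5[rows] + CLASS_WINDOW_FIRST - 1L
    to <- fp$cds5[rows] + rel_last - 1L
    n_short <- n_short + sum(rel_last < CLASS_WINDOW_FIRST)
    for (w in unique(to - from + 1L)) {
      if (w < 1L) next
      sl <- .cpp_sliding_min(e, w)
      sel <- which((to - from + 1L) == w)
      idx <- from[sel]
      valid <- idx >= 1L & idx <= length(sl)
      fp$min_dg[rows[sel[valid]]] <- sl[idx[valid]]
    }
    fp$win_from[rows] <- from
    fp$win_to[rows] <- pmax(to, from - 1L)
  }
  if (n_short > 0L)
    message(n_short, " footprint(s) shorter than 10 nt: classified Ambiguous")
  cls <- ifelse(is.na(fp$min_dg), "Ambiguous",
                ifelse(fp$min_dg <= sd_threshold, "SD",
                       ifelse(fp$min_dg > nosd_threshold, "NoSD", "Ambiguous")))
  fp$class <- factor(cls, levels = c("SD", "NoSD", "Ambiguous"))
  fp
}

#' Assign SD-classified footprints to SD sites
#'
#' An SD footprint is attributed to the SD site whose octamer overlaps its
#' classification window (footprints can classify SD through a shifted
#' register of a site's octamer, so the site start itself may sit up to 7 nt
#' outside the window); when several sites qualify the strongest (most
#' negative `delta_g`) wins.
#'
#' @param fp classified footprint table (see [classify_footprints()]).
#' @param sites SD-site table from [scan_sd_sites_genome()] (coding-strand
#'   `start` per gene).
#' @return `fp` with an `sd_site` column (`"<gene_id>:<start>"`, `NA` for
#'   non-SD footprints or SD footprints with no scanned site in the window).
#' @export
assign_sd_sites <- function(fp, sites) {
  fp$sd_site <- NA_character_
  if (!nrow(sites)) return(fp)
  best_dg <- rep(Inf, nrow(fp))
  is_sd <- !is.na(fp$class) & fp$class == "SD"
  for (k in seq_len(nrow(sites))) {
    st <- sites[k, ]
    hit <- is_sd & fp$gene_id == st$gene_id &
      (fp$win_from - 7L) <= st$start & st$start <= (fp$win_to + 7L)
    upd <- hit & st$delta_g < best_dg
    fp$sd_site[upd] <- paste0(st$gene_id, ":", st$start)
    best_dg[upd] <- st$delta_g
  }
  fp
}

#' Per-unit footprint length histograms
#'
#' Builds the normalization units behind the length-frequency statistic: one
#' unit per SD site for the SD class (each carrying N, the number of SD sites
#' in its parent gene) or one unit per gene for the NoSD class.
#'
#' @param fp classified (and for `"SD"` site-assigned) footprint table.
#' @param sites SD-site table (used to count SD sites per gene).
#' @param class `"SD"` or `"NoSD"`.
#' @return data.frame with columns `unit_id`, `gene_id`, `n_sd_in_gene`,
#'   `length`, `count` (long-format histograms).
#' @export
sd_unit_histograms <- function(fp, sites, class = c("SD", "NoSD")) {
  class <- match.arg(class)
  n_sd <- table(sites$gene_id)
  if (class == "SD") {
    sub <- fp[!is.na(fp$sd_site) & fp$class == "SD", , drop = FALSE]
    if (!nrow(sub)) return(data.frame(unit_id = character(), gene_id = character(),
                                      n_sd_in_gene = integer(), length = integer(),
                                      count = integer()))
    agg <- as.data.frame(table(unit_id = sub$sd_site, length = sub$length),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    agg$gene_id <- sub("(:[0-9]+)$", "", agg$unit_id)
    agg$n_sd_in_gene <- as.integer(n_sd[agg$gene_id])
  } else {
    sub <- fp[fp$class == "NoSD", , drop = FALSE]
    if (!nrow(sub)) return(data.frame(unit_id = character(), gene_id = character(),
                                      n_sd_in_gene = integer(), length = integer(),
                                      count = integer()))
    agg <- as.data.frame(table(unit_id = sub$gene_id, length = sub$length),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    agg$gene_id <- agg$unit_id
    agg$n_sd_in_gene <- 1L
  }
  data.frame(unit_id = agg$unit_id, gene_id = agg$gene_id,
             n_sd_in_gene = agg$n_sd_in_gene,
             length = as.integer(agg$length), count = as.integer(agg$Freq),
             stringsAsFactors = FALSE)
}
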