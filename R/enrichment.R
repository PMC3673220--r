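#' SD read enrichment over the uniform-placement expectation
#'
#' Compares the observed number of SD-classified footprints with the number
#' expected if footprints of the same lengths were placed uniformly over the
#' trimmed ORF interiors. For each gene and footprint length l, the expected
#' SD probability is the fraction of admissible interior 5'-end positions
#' whose classification window contains an octamer at or below
#' `sd_threshold`; the expectation sums this probability over the observed
#' footprints.
#'
#' @param fp classified footprint table (interior-filtered, with `class` and
#'   `length`); typically restricted to genes containing strong SD sites.
#' @param genes gene table (the genes underlying `fp`).
#' @param genome named character vector of contig sequences.
#' @param model a [duplex_model()].
#' @param cfg a [filter_config()].
#' @param sd_threshold detection threshold, kcal/mol.
#' @return list with `enrichment` (observed / expected), `observed`,
#'   `expected` and `n` (total classified footprints).
#' @export
sd_read_enrichment <- function(fp, genes, genome, model = duplex_model(),
                               cfg = filter_config(), sd_threshold = -8) {
  stopifnot("class" %in% names(fp))
  observed <- sum(fp$class == "SD", na.rm = TRUE)
  expected <- 0
  for (gid in unique(fp$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    e <- gene_octamer_energies(genome, g, model)
    lens <- fp$length[fp$gene_id == gid]
    for (l in unique(lens)) {
      n_l <- sum(lens == l)
      if (l < 10L) next  # no admissible octamer start: never SD
      w <- min(CLASS_WINDOW_LAST, l - 7L) - CLASS_WINDOW_FIRST + 1L
      q <- seq.int(cfg$head_trim + 1L, g$length - cfg$tail_trim - l + 1L)
      if (!length(q)) next
      sl <- .cpp_sliding_min(e, w)
      idx <- q + CLASS_WINDOW_FIRST - 1L
      valid <- idx <= length(sl)
      p_sd <- sum(sl[idx[valid]] <= sd_threshold) / length(q)
      expected <- expected + n_l * p_sd
    }
  }
  if (expected <= 0) stop("expected SD count is zero; cannot form enrichment")
  list(enrichment = observed / expected, observed = observed,
       expected = expected, n = nrow(fp))
}
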