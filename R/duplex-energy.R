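#' Minimum free energy of an intermolecular RNA:RNA duplex
#'
#' Computes the minimum free energy over all antiparallel duplex structures of
#' `probe` against `target` that contain at least `model$min_helix_pairs`
#' contiguously stacked base pairs, with bulges and internal loops up to
#' `model$max_loop_len` unpaired nucleotides. Returns the 0.0 "no binding"
#' sentinel when no qualifying structure exists; never returns a positive
#' value, so thresholds of the form `dg <= t` compare cleanly.
#'
#' @param probe nucleotide string, 1-20 nt (T accepted, treated as U).
#' @param target nucleotide string, 1-20 nt; defaults to the model's aSD.
#' @param model a [duplex_model()].
#' @param method `"dp"` (dynamic programming, default) or `"enumerate"`
#'   (exhaustive structure enumeration; an independent, much slower kernel
#'   retained as a cross-check oracle).
#' @return duplex free energy in kcal/mol (<= 0).
#' @export
duplex_free_energy <- function(probe, target = model$asd, model = duplex_model(),
                               method = c("dp", "enumerate")) {
  method <- match.arg(method)
  a <- seq_to_int(probe)
  b <- seq_to_int(target)
  if (length(a) > 20L || length(b) > 20L)
    stop("duplex_free_energy is intended for short (<= 20 nt) sequences")
  par <- duplex_par_list(model)
  if (method == "dp") .cpp_duplex_mfe(a, b, par) else .cpp_duplex_enum(a, b, par)
}

#' SD:aSD duplex strength of a hexamer
#'
#' @param hexamer nucleotide string of length exactly 6.
#' @inheritParams duplex_free_energy
#' @return free energy in kcal/mol of the hexamer vs. the model's aSD.
#' @export
hexamer_strength <- function(hexamer, model = duplex_model()) {
  if (nchar(hexamer) != 6L) stop("hexamer must be exactly 6 nt")
  duplex_free_energy(hexamer, model$asd, model)
}

#' Duplex energies of all k-mers against the aSD
#'
#' Returns the free energies of all `4^k` k-mers against `model$asd`, in
#' base-4 lexicographic order (A < C < G < U), named by k-mer. Cached per
#' (k, model) within a session; the octamer table (k = 8) underlies SD-site
#' scanning and footprint classification.
#'
#' @param k k-mer length (8 for SD octamers, 6 for hexamer analyses).
#' @inheritParams duplex_free_energy
#' @param method `"dp"` or `"enumerate"` (oracle).
#' @return named numeric vector of length `4^k`.
#' @export
kmer_energy_table <- function(k = 8L, model = duplex_model(),
                              method = c("dp", "enumerate")) {
  method <- match.arg(method)
  key <- paste0("kmer", k, "_", method, "_",
                paste0(model$asd, "_", model$duplex_initiation, "_",
                       sum(model$stack), "_", model$min_helix_pairs, "_",
                       model$max_loop_len))
  hit <- .riboSD_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- .cpp_all_kmer_energies(as.integer(k), seq_to_int(model$asd),
                              duplex_par_list(model), method == "enumerate")
  names(e) <- all_kmers(k)
  assign(key, e, envir = .riboSD_cache)
  e
}

all_kmers <- function(k) {
  g <- do.call(expand.grid, c(rep(list(RNA_BASES), k),
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; base-4 order needs the last
  do.call(paste0, g[, k:1, drop = FALSE])
}

#' Scan a coding sequence for internal SD sites
#'
#' Slides an 8-nt window over the coding-strand sequence of one gene and
#' reports octamers whose predicted duplex energy against the aSD passes
#' `threshold`. Overlapping passing octamers are resolved greedily: the
#' strongest (most negative; ties broken leftmost) is kept and all octamers
#' overlapping it are discarded, repeatedly. The first nucleotide of the
#' octamer marks the site whether or not it base-pairs.
#'
#' @param cds_sequence coding-strand nucleotide sequence of one gene.
#' @param contig,gene_id identifiers copied into the result.
#' @param model a [duplex_model()].
#' @param threshold detection threshold in kcal/mol (default -8.0; sites are
#'   octamers with `delta_g <= threshold`).
#' @param strand strand annotation copied into the result.
#' @param resolve_overlaps if `FALSE`, every passing octamer window is
#'   returned.
#' @return data.frame with columns `contig`, `gene_id`, `start` (1-based on
#'   the coding strand), `strand`, `octamer`, `delta_g`.
#' @export
scan_sd_sites <- function(cds_sequence, contig = "seq", gene_id = "gene",
                          model = duplex_model(), threshold = -8.0,
                          strand = "+", resolve_overlaps = TRUE) {
  empty <- data.frame(contig = character(), gene_id = character(),
                      start = integer(), strand = character(),
                      octamer = character(), delta_g = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(cds_sequence) < 8L) return(empty)
  tab <- kmer_energy_table(8L, model)
  codes <- kmer_codes(cds_sequence, 8L)
  dg <- rep(0, length(codes))
  ok <- !is.na(codes)
  dg[ok] <- tab[codes[ok] + 1L]
  hits <- which(dg <= threshold & ok)
  if (resolve_overlaps && length(hits) > 1L) {
    kept <- integer(0)
    cand <- hits
    cand_dg <- dg[hits]
    while (length(cand)) {
      best <- cand[order(cand_dg, cand)[1]]
      kept <- c(kept, best)
      drop <- abs(cand - best) < 8L
      cand <- cand[!drop]
      cand_dg <- cand_dg[!drop]
    }
    hits <- sort(kept)
  }
  if (!length(hits)) return(empty)
  rna <- to_rna(cds_sequence)
  data.frame(contig = contig, gene_id = gene_id, start = as.integer(hits),
             strand = strand,
             octamer = substring(rna, hits, hits + 7L),
             delta_g = dg[hits], stringsAsFactors = FALSE)
}

#' Scan every gene of a genome for internal SD sites
#'
#' @param genome named character vector of contig sequences (see
#'   [read_genome()]).
#' @param genes gene table (see [read_genes()]).
#' @param interior_only if `TRUE`, only octamers whose window lies wholly
#'   inside the 30/75-trimmed ORF interior are reported (the read-filter
#'   region); by default whole CDSs are scanned.
#' @inheritParams scan_sd_sites
#' @return row-bound data.frame of [scan_sd_sites()] results; `start` is a
#'   coding-strand coordinate within each gene.
#' @export
scan_sd_sites_genome <- function(genome, genes, model = duplex_model(),
                                 threshold = -8.0, interior_only = FALSE,
                                 cfg = filter_config()) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- cds_sequence(genome, g)
    out <- scan_sd_sites(s, contig = g$contig, gene_id = g$gene_id,
                         model = model, threshold = threshold,
                         strand = g$strand)
    if (interior_only && nrow(out)) {
      out <- out[out$start > cfg$head_trim &
                   (out$start + 7L) <= (g$length - cfg$tail_trim), , drop = FALSE]
    }
    out
  })
  do.call(rbind, res)
}

#' SD-site census over an annotated genome
#'
#' Scans every annotated CDS and tallies discrete SD sites and the number of
#' genes containing at least one.
#'
#' @inheritParams scan_sd_sites_genome
#' @return list with `n_sites`, `n_genes`, and the `sites` table.
#' @export
sd_site_census <- function(genome, genes, model = duplex_model(),
                           threshold = -8.0, interior_only = FALSE,
                           cfg = filter_config()) {
  sites <- scan_sd_sites_genome(genome, genes, model, threshold,
                                interior_only, cfg)
  list(n_sites = nrow(sites),
       n_genes = length(unique(sites$gene_id)),
       sites = sites)
}
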