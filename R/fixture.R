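SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T"), stringsAsFactors = FALSE),
        1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))
CU_CODONS <- c("TTT", "TTC", "TCT", "TCC", "CTT", "CTC", "CCT", "CCC")

#' Synthetic fixture specification
#'
#' Parameterizes a complete ground-truth-labeled dataset: random ORFs with
#' planted SD octamers of known duplex strength, SD-free control ORFs, and
#' simulated footprints with a pause (and caterpillar-style 3'-ward length
#' extension) at the planted sites. The defaults reproduce the data regime the
#' analyses assume: every gene exceeds 10 footprints per codon in its trimmed
#' interior, and SD sites sit at least `flank` nt inside the interior.
#'
#' @param n_genes total genes (default 200); `round(control_fraction *
#'   n_genes)` of them are SD-free controls.
#' @param gene_length ORF length, nt, divisible by 3 (default 600).
#' @param sd_per_gene planted SD sites per non-control gene (default 1).
#' @param sd_strength_range planted octamer duplex energies, kcal/mol
#'   (default -14 to -8.5; octamers are drawn evenly across this range).
#' @param pause_fold relative P-site weight at each pause codon (default 9).
#' @param length_shift_nt requested mean 3'-ward extension of paused
#'   footprints, nt. Realized on the codon lattice as pause codons at
#'   x, x+3, ..., x+3K with K = round(2 * length_shift_nt / 3); the planted
#'   mean extension 3K/2 is recorded in the ground truth.
#' @param reads_per_gene footprints per gene (default 2000).
#' @param length_probs base drawn-length distribution (default
#'   [triangular_length_probs()]).
#' @param control_fraction fraction of SD-free control genes (default 0.25).
#' @param pause_offset nt from SD first nucleotide to the slow P-site codon.
#' @param flank minimum distance from planted SD sites to the trimmed-interior
#'   boundaries (default 50).
#' @param seed top-level RNG seed; all fixture randomness flows from it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 200L, gene_length = 600L, sd_per_gene = 1L,
                         sd_strength_range = c(-14, -8.5), pause_fold = 9,
                         length_shift_nt = 4, reads_per_gene = 2000L,
                         length_probs = NULL, control_fraction = 0.25,
                         pause_offset = 11L, flank = 50L, seed = 7L) {
  if (is.null(length_probs)) length_probs <- triangular_length_probs()
  stopifnot(gene_length %% 3L == 0L, gene_length >= 150L,
            sd_strength_range[1] <= sd_strength_range[2],
            pause_fold >= 1, length_shift_nt >= 0)
  K <- if (length_shift_nt > 0) max(1L, as.integer(round(2 * length_shift_nt / 3)))
       else 0L
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 sd_per_gene = as.integer(sd_per_gene),
                 sd_strength_range = sd_strength_range,
                 pause_fold = pause_fold,
                 length_shift_nt = length_shift_nt,
                 n_extension_steps = K,
                 planted_mean_extension = 3 * K / 2,
                 reads_per_gene = as.integer(reads_per_gene),
                 length_probs = length_probs,
                 control_fraction = control_fraction,
                 pause_offset = as.integer(pause_offset),
                 flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

random_orf <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

control_orf <- function(n_codons) {
  paste0("ATG", paste(sample(CU_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

has_internal_stop <- function(orf) {
  codons <- substring(orf, seq(1, nchar(orf) - 3L, 3L),
                      seq(3, nchar(orf) - 1L, 3L))
  any(codons[-c(1, length(codons))] %in% c("TAA", "TAG", "TGA"))
}

# octamers spanning the requested strength range, one per requested site,
# chosen evenly across the sorted candidate table. Only "scan-canonical"
# octamers are used: those recovered at their own start by scan_sd_sites when
# embedded in a non-pairing all-C context (octamers whose terminal base does
# not pair tie with the window one step left and would be displaced by the
# leftmost tie-break).
pick_sd_octamers <- function(n, range, model) {
  tab <- kmer_energy_table(8L, model)
  cand <- tab[tab >= range[1] & tab <= range[2]]
  if (!length(cand)) stop("no octamer in the requested strength range")
  pad <- strrep("C", 20)
  canonical <- vapply(names(cand), function(o) {
    hit <- scan_sd_sites(paste0(pad, o, pad), model = model,
                         threshold = range[2])
    nrow(hit) == 1L && hit$start == 21L
  }, logical(1))
  cand <- cand[canonical]
  if (!length(cand)) stop("no scan-canonical octamer in the requested range")
  cand <- sort(cand)
  idx <- unique(round(seq(1, length(cand), length.out = max(n, 2))))
  pool <- cand[idx]
  pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
}

#' Plant SD genes: genome, annotation and ground truth
#'
#' Builds `n_genes` random ORFs on one contig (alternating strands, separated
#' by low-complexity C/T spacers). Non-control genes carry `sd_per_gene`
#' planted SD octamers spanning `sd_strength_range`, placed so that a
#' `flank`-nt window around each site stays inside the trimmed interior; genes
#' are resampled until an SD scan at -8 kcal/mol recovers exactly the planted
#' sites and the reading frame stays stop-free. Control ORFs are built from
#' C/U-only codons (no base of which can pair more than once with the aSD)
#' and verified to contain no octamer at or below -2 kcal/mol.
#'
#' @param spec a [fixture_spec()].
#' @param model a [duplex_model()].
#' @param cfg a [filter_config()].
#' @param max_attempts resampling bound per gene before erroring.
#' @return list with `genome` (named character vector, one contig), `genes`
#'   (annotation table), `sd_sites` (planted sites: `gene_id`, `start`
#'   (coding), `octamer`, `delta_g`), `truth` (per-gene labels and planted
#'   effect sizes), `spec`.
#' @export
plant_sd_genes <- function(spec, model = duplex_model(), cfg = filter_config(),
                           max_attempts = 200L) {
  set.seed(spec$seed)
  n_ctrl <- round(spec$control_fraction * spec$n_genes)
  n_sd <- spec$n_genes - n_ctrl
  is_control <- c(rep(FALSE, n_sd), rep(TRUE, n_ctrl))
  L <- spec$gene_length
  n_codons <- L %/% 3L
  lo <- cfg$head_trim + spec$flank + 1L
  hi <- L - cfg$tail_trim - spec$flank - 7L
  if (hi < lo) stop("gene_length too short to hold an SD site with flanks")
  octs <- if (n_sd > 0)
    pick_sd_octamers(n_sd * spec$sd_per_gene, spec$sd_strength_range, model)
  else numeric(0)

  seqs <- character(spec$n_genes)
  site_rows <- list()
  oct_i <- 0L
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("g%03d", g)
    if (is_control[g]) {
      for (attempt in seq_len(max_attempts)) {
        orf <- control_orf(n_codons)
        if (nrow(scan_sd_sites(orf, model = model, threshold = -2)) == 0L) break
        if (attempt == max_attempts)
          stop("control gene ", gid, " failed the -2 kcal/mol scan; ",
               "relax the fixture spec")
      }
      seqs[g] <- orf
      next
    }
    planted_oct <- octs[oct_i + seq_len(spec$sd_per_gene)]
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      orf <- random_orf(n_codons)
      pos <- sort(sample(seq.int(lo, hi), spec$sd_per_gene))
      if (spec$sd_per_gene > 1L && min(diff(pos)) < 60L) next
      for (k in seq_len(spec$sd_per_gene)) {
        substr(orf, pos[k], pos[k] + 7L) <- to_dna(names(planted_oct)[k])
      }
      if (has_internal_stop(orf)) next
      found <- scan_sd_sites(orf, model = model, threshold = -8)
      if (nrow(found) == spec$sd_per_gene && all(found$start == pos)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not plant SD sites in gene ", gid,
                  " after ", max_attempts, " attempts; relax the fixture spec")
    seqs[g] <- orf
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      gene_id = gid, start = pos, octamer = names(planted_oct),
      delta_g = unname(planted_oct), stringsAsFactors = FALSE)
    oct_i <- oct_i + spec$sd_per_gene
  }

  # assemble one contig: genes on alternating strands, C/T spacers between
  spacer <- paste(rep("CT", 30), collapse = "")
  strands <- rep(c("+", "-"), length.out = spec$n_genes)
  contig_parts <- character(0)
  cursor <- nchar(spacer)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(spec$n_genes)),
                      contig = "synth1", strand = strands,
                      cds_start = NA_integer_, cds_end = NA_integer_,
                      length = L, stringsAsFactors = FALSE)
  contig_parts <- c(contig_parts, spacer)
  for (g in seq_len(spec$n_genes)) {
    genomic <- if (strands[g] == "+") seqs[g] else revcomp_dna(seqs[g])
    genes$cds_start[g] <- cursor + 1L
    genes$cds_end[g] <- cursor + L
    contig_parts <- c(contig_parts, genomic, spacer)
    cursor <- cursor + L + nchar(spacer)
  }
  genome <- setNames(paste(contig_parts, collapse = ""), "synth1")

  sd_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(), start = integer(),
               octamer = character(), delta_g = numeric())
  truth <- list(
    is_control = setNames(is_control, genes$gene_id),
    sd_sites = sd_sites,
    pause_fold = spec$pause_fold,
    n_extension_steps = spec$n_extension_steps,
    planted_mean_extension = spec$planted_mean_extension,
    pause_offset = spec$pause_offset,
    seed = spec$seed
  )
  list(genome = genome, genes = genes, sd_sites = sd_sites, truth = truth,
       spec = spec)
}

#' Simulate footprints over a planted fixture
#'
#' Reuses the footprint sampling engine per gene, in coding-strand
#' coordinates: pause codons at x, x+3, ..., x+3K (x = SD start +
#' `pause_offset`, K = `spec$n_extension_steps`) each carry relative weight
#' `pause_fold`, and footprints with P-sites downstream of x within the pause
#' window are extended 5'-ward caterpillar-style. All footprints are placed
#' wholly inside the trimmed interior so that every gene passes the
#' 10-per-codon density filter deterministically.
#'
#' @param fixture output of [plant_sd_genes()].
#' @param cfg a [filter_config()].
#' @param seed RNG seed; default derives from the fixture seed.
#' @return footprint table (`contig`, `strand`, `five_prime`, `length`,
#'   `gene_id`, plus ground-truth columns `paused`, `extended_by`) in genomic
#'   coordinates, consumable by [assign_genes()] / [filter_interior()].
#' @export
generate_reads <- function(fixture, cfg = filter_config(),
                           seed = fixture$spec$seed + 1L) {
  spec <- fixture$spec
  set.seed(seed)
  genes <- fixture$genes
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    sd_start <- fixture$sd_sites$start[fixture$sd_sites$gene_id == gid]
    slow <- sd_start + spec$pause_offset
    fp <- sample_fp_engine(
      slow, spec$reads_per_gene, spec$length_probs,
      multiplier = spec$pause_fold,
      n_pause_codons = spec$n_extension_steps + 1L,
      extend = spec$n_extension_steps > 0L,
      bound_lo = cfg$head_trim + 1L,
      bound_hi = genes$length[g] - cfg$tail_trim)
    # coding -> genomic coordinates
    if (genes$strand[g] == "+") {
      five <- genes$cds_start[g] + fp$five_prime - 1L
    } else {
      five <- genes$cds_end[g] - fp$five_prime + 1L
    }
    out[[g]] <- data.frame(contig = genes$contig[g], strand = genes$strand[g],
                           five_prime = five, length = fp$length,
                           gene_id = gid, paused = fp$paused,
                           extended_by = fp$extended_by,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build and optionally write a complete fixture
#'
#' @param spec a [fixture_spec()].
#' @param dir if non-`NULL`, writes `genome.fa`, `genes.gff3`, `reads.bed` and
#'   `truth.json` there (plain text; each file records the seed in a header
#'   comment).
#' @param model a [duplex_model()].
#' @param cfg a [filter_config()].
#' @return list with `genome`, `genes`, `sd_sites`, `truth`, `reads`, `spec`.
#' @export
build_fixture <- function(spec = fixture_spec(), dir = NULL,
                          model = duplex_model(), cfg = filter_config()) {
  fx <- plant_sd_genes(spec, model, cfg)
  fx$reads <- generate_reads(fx, cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tag <- paste0("riboSD fixture, seed=", spec$seed)
    write_fasta(fx$genome, file.path(dir, "genome.fa"), header_comment = tag)
    write_gff3(fx$genes, file.path(dir, "genes.gff3"), comment = tag)
    write_bed6(fx$reads, file.path(dir, "reads.bed"), comment = tag)
    truth <- fx$truth
    truth$sd_sites <- as.list(truth$sd_sites)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}
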