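#' Read filter configuration
#'
#' Holds the read-filtering rules applied before any statistic: footprints
#' must lie wholly downstream of the first `head_trim` nt and upstream of the
#' last `tail_trim` nt of a coding ORF (removing initiation/termination
#' signals), genes enter length-distribution analyses at an average density of
#' more than `min_density_distributions` footprints per codon, and SD-site
#' regions enter end-density profiles at more than `min_density_profiles`
#' footprints per codon.
#'
#' @param head_trim nt trimmed from the ORF 5' end (default 30).
#' @param tail_trim nt trimmed from the ORF 3' end (default 75).
#' @param min_density_distributions footprints per codon (default 10).
#' @param min_density_profiles footprints per codon (default 1).
#' @return a `filter_config` list.
#' @export
filter_config <- function(head_trim = 30L, tail_trim = 75L,
                          min_density_distributions = 10,
                          min_density_profiles = 1) {
  stopifnot(head_trim >= 0, tail_trim >= 0,
            min_density_distributions >= 0, min_density_profiles >= 0)
  structure(list(head_trim = as.integer(head_trim),
                 tail_trim = as.integer(tail_trim),
                 min_density_distributions = min_density_distributions,
                 min_density_profiles = min_density_profiles),
            class = "filter_config")
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase contig sequences; names are
#'   FASTA header words up to the first whitespace.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Read protein-coding gene models (GFF3 or BED12)
#'
#' CDS features of a GFF3 file, or BED intervals, become single-interval gene
#' models with 1-based inclusive genomic coordinates. Coordinates are
#' validated against the genome; out-of-bounds records are skipped with a
#' message. A length not divisible by 3 triggers a warning, not an error.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param genome named character vector from [read_genome()].
#' @return data.frame with columns `gene_id`, `contig`, `strand`,
#'   `cds_start`, `cds_end`, `length`.
#' @export
read_genes <- function(path, genome) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    keep <- as.character(gr$type) == "CDS"
    gr <- gr[keep]
    ids <- gr$ID
    if (is.null(ids) || all(is.na(ids))) ids <- gr$Name
    ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  } else {
    ids <- gr$name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  }
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = GenomicRanges::start(gr),
    cds_end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  ok <- genes$contig %in% names(genome)
  ok[ok] <- genes$cds_start[ok] >= 1L &
    genes$cds_end[ok] <= nchar(genome[genes$contig[ok]])
  if (any(!ok)) {
    message(sum(!ok), " gene record(s) out of contig bounds; skipped")
    genes <- genes[ok, , drop = FALSE]
  }
  genes$length <- genes$cds_end - genes$cds_start + 1L
  if (any(genes$length %% 3L != 0L))
    warning(sum(genes$length %% 3L != 0L),
            " gene(s) have length not divisible by 3")
  rownames(genes) <- NULL
  genes
}

#' Coding-strand sequence of one gene
#'
#' @param genome named character vector of contig sequences.
#' @param gene one row of a gene table.
#' @return nucleotide string on the coding strand (reverse complement of the
#'   genomic slice for minus-strand genes).
#' @export
cds_sequence <- function(genome, gene) {
  s <- substring(genome[[gene$contig]], gene$cds_start, gene$cds_end)
  if (gene$strand == "-") s <- revcomp_dna(to_dna(s))
  s
}

# reference span of a SAM alignment from its CIGAR (M/D/N/=/X consume ref)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read aligned ribosome footprints (BED6, SAM or BAM)
#'
#' Each uniquely aligned record becomes one footprint with its 5'-most
#' transcribed nucleotide (`five_prime`, 1-based genomic) and reference
#' length. SAM/BAM records flagged secondary/supplementary/unmapped, and
#' records with mapping quality 0, are dropped as non-unique; BED input is
#' assumed pre-deduplicated. Footprints are assigned to the gene that fully
#' contains them on the same contig and strand (`gene_id` is `NA` otherwise).
#'
#' @param path `.bed` (6 columns), `.sam` or `.bam` file.
#' @param genes gene table from [read_genes()].
#' @return data.frame with columns `contig`, `strand`, `five_prime`,
#'   `length`, `gene_id`.
#' @export
read_footprints <- function(path, genes) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("footprint BED must have 6 columns")
    fp <- data.frame(
      contig = as.character(bed[[1]]),
      strand = as.character(bed[[6]]),
      five_prime = ifelse(bed[[6]] == "+", bed[[2]] + 1L, bed[[3]]),
      length = bed[[3]] - bed[[2]],
      stringsAsFactors = FALSE
    )
  } else if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    bam_path <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam_path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                   indexDestination = FALSE)
    }
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
      flag = flags, what = c("rname", "strand", "pos", "cigar", "mapq"))
    rec <- Rsamtools::scanBam(bam_path, param = param)[[1]]
    total <- length(rec$pos)
    keep <- is.na(rec$mapq) | rec$mapq > 0L
    if (any(!keep)) message(sum(!keep), " record(s) with MAPQ 0 dropped as multi-mapping")
    w <- cigar_ref_width(rec$cigar[keep])
    start <- rec$pos[keep]
    strand <- as.character(rec$strand[keep])
    fp <- data.frame(
      contig = as.character(rec$rname[keep]),
      strand = strand,
      five_prime = ifelse(strand == "+", start, start + w - 1L),
      length = w,
      stringsAsFactors = FALSE
    )
  } else {
    stop("unknown footprint format (expect .bed, .sam or .bam): ", path)
  }
  assign_genes(fp, genes)
}

#' Assign footprints to fully containing genes
#'
#' @param fp footprint table (`contig`, `strand`, `five_prime`, `length`).
#' @param genes gene table.
#' @return `fp` with a `gene_id` column (`NA` when no same-strand gene fully
#'   contains the footprint).
#' @export
assign_genes <- function(fp, genes) {
  if (!nrow(fp)) {
    fp$gene_id <- character(0)
    return(fp)
  }
  gstart <- ifelse(fp$strand == "+", fp$five_prime, fp$five_prime - fp$length + 1L)
  fpr <- GenomicRanges::GRanges(fp$contig,
                                IRanges::IRanges(gstart, width = fp$length),
                                strand = fp$strand)
  gr <- GenomicRanges::GRanges(genes$contig,
                               IRanges::IRanges(genes$cds_start, genes$cds_end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(fpr, gr, type = "within")
  gene_id <- rep(NA_character_, nrow(fp))
  # first containing gene wins when genes are nested on the same strand
  hit <- !duplicated(S4Vectors::queryHits(ov))
  gene_id[S4Vectors::queryHits(ov)[hit]] <- genes$gene_id[S4Vectors::subjectHits(ov)[hit]]
  fp$gene_id <- gene_id
  fp
}

#' Footprint coordinates on the coding strand
#'
#' Adds `cds5` and `cds3`: positions of the footprint 5' and 3' ends in
#' 1-based coding-strand coordinates of the assigned gene (`cds3 = cds5 +
#' length - 1`).
#'
#' @param fp gene-assigned footprint table.
#' @param genes gene table.
#' @return `fp` with `cds5` and `cds3` columns (`NA` for unassigned rows).
#' @export
footprint_cds_coords <- function(fp, genes) {
  gi <- match(fp$gene_id, genes$gene_id)
  cds5 <- ifelse(fp$strand == "+",
                 fp$five_prime - genes$cds_start[gi] + 1L,
                 genes$cds_end[gi] - fp$five_prime + 1L)
  fp$cds5 <- as.integer(cds5)
  fp$cds3 <- as.integer(cds5 + fp$length - 1L)
  fp
}

#' Restrict footprints to trimmed ORF interiors
#'
#' Keeps gene-assigned footprints fully contained in the interior window: the
#' 5' end strictly after CDS nucleotide `head_trim` and the 3' end at or
#' before CDS nucleotide `length - tail_trim` (coding-strand coordinates).
#' Idempotent; genes shorter than `head_trim + tail_trim` contribute nothing.
#'
#' @param fp footprint table with `gene_id`.
#' @param genes gene table.
#' @param cfg a [filter_config()].
#' @return filtered footprint table with `cds5`/`cds3` columns.
#' @export
filter_interior <- function(fp, genes, cfg = filter_config()) {
  fp <- fp[!is.na(fp$gene_id), , drop = FALSE]
  fp <- footprint_cds_coords(fp, genes)
  L <- genes$length[match(fp$gene_id, genes$gene_id)]
  keep <- fp$cds5 > cfg$head_trim & fp$cds3 <= (L - cfg$tail_trim)
  out <- fp[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene footprint density (footprints per codon)
#'
#' @param fp interior-filtered footprint table.
#' @param genes gene table.
#' @param cfg a [filter_config()].
#' @param denominator `"interior"` (default; interior codons,
#'   `(length - head_trim - tail_trim) / 3`) or `"full"` (whole-ORF codons).
#' @return named numeric vector of densities, one per gene (0 for genes with
#'   no retained footprints; `NA` for genes with an empty interior).
#' @export
gene_density <- function(fp, genes, cfg = filter_config(),
                         denominator = c("interior", "full")) {
  denominator <- match.arg(denominator)
  nt <- if (denominator == "interior")
    genes$length - cfg$head_trim - cfg$tail_trim else genes$length
  codons <- nt / 3
  counts <- table(factor(fp$gene_id, levels = genes$gene_id))
  d <- as.numeric(counts) / codons
  d[codons <= 0] <- NA_real_
  setNames(d, genes$gene_id)
}

# ---- plain-text writers (fixtures, analysis outputs) -----------------------

#' Write a named set of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param header_comment optional comment line(s) written before the records
#'   (prefixed with `;`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste(";", header_comment), con)
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(nchar(s), seq(70, nchar(s) + 69, 70))), con)
  }
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes gene table.
#' @param path output file.
#' @param comment optional `#`-comment line(s) after the version pragma.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste(genes$contig, "riboSD", "CDS", genes$cds_start,
                   genes$cds_end, ".", genes$strand, "0",
                   paste0("ID=", genes$gene_id), sep = "\t"), con)
  invisible(path)
}

#' Write footprints as 6-column BED
#' @param fp footprint table (`contig`, `strand`, `five_prime`, `length`).
#' @param path output file.
#' @param comment optional `#`-comment line(s) (e.g. the generating seed).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(fp, path, comment = NULL) {
  gstart <- ifelse(fp$strand == "+", fp$five_prime, fp$five_prime - fp$length + 1L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste(fp$contig, gstart - 1L, gstart + fp$length - 1L,
                   paste0("fp", seq_len(nrow(fp))), 0L, fp$strand, sep = "\t"),
             con)
  invisible(path)
}
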