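test_that("genome FASTA round-trips and headers are trimmed at whitespace", {
  seqs <- c(chrA = "ACGTACGTACGTAA", chrB = strrep("ACGT", 40))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrA some description", seqs[1], ">chrB", seqs[2]), fa)
  g <- read_genome(fa)
  expect_identical(g, c(chrA = unname(seqs[1]), chrB = unname(seqs[2])))

  fa2 <- tempfile(fileext = ".fa")
  write_fasta(g, fa2, header_comment = "round trip")
  expect_identical(read_genome(fa2), g)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_warning(e <- read_genome(empty), "empty")
  expect_length(e, 0)
})

test_that("GFF3 and BED12 encodings of the same gene give identical models", {
  genome <- c(chr1 = strrep("ACGT", 200))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "CDS", 101, 400, ".", "+", "0",
                     "ID=geneA", sep = "\t"),
               paste("chr1", "src", "CDS", 101, 400, ".", "-", "0",
                     "ID=geneB", sep = "\t")), gff)
  g1 <- read_genes(gff, genome)
  expect_equal(g1$length, c(300L, 300L))
  expect_equal(g1$cds_start, c(101L, 101L))

  bed <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 100, 400, "geneA", 0, "+", 100, 400, "0", 1, "300,",
                   "0,", sep = "\t"), bed)
  g2 <- read_genes(bed, genome)
  expect_equal(g2$cds_start, 101L)
  expect_equal(g2$cds_end, 400L)
  expect_equal(g2$length, 300L)

  # minus-strand gene models expose the reverse complement as coding sequence
  expect_identical(cds_sequence(genome, g1[2, ]),
                   unname(riboSD:::revcomp_dna(substring(genome, 101, 400))))

  # out-of-bounds records are skipped with a message
  gff_bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "CDS", 701, 900, ".", "+", "0",
                     "ID=off", sep = "\t")), gff_bad)
  expect_message(gb <- read_genes(gff_bad, genome), "out of contig bounds")
  expect_equal(nrow(gb), 0L)
})

test_that("BED footprints follow the 0-based half-open convention", {
  genome <- c(chr1 = strrep("A", 400))
  genes <- data.frame(gene_id = "g", contig = "chr1", strand = "+",
                      cds_start = 1L, cds_end = 400L, length = 400L)
  bed <- tempfile(fileext = ".bed")
  writeLines(c(paste("chr1", 99, 129, "r1", 0, "+", sep = "\t"),
               paste("chr1", 99, 129, "r2", 0, "-", sep = "\t")), bed)
  fp <- read_footprints(bed, genes)
  expect_equal(fp$five_prime, c(100L, 129L))
  expect_equal(fp$length, c(30L, 30L))
  # write/read round trip
  out <- tempfile(fileext = ".bed")
  write_bed6(fp, out, comment = "seed 1")
  fp2 <- read_footprints(out, genes)
  expect_equal(fp2[c("contig", "strand", "five_prime", "length")],
               fp[c("contig", "strand", "five_prime", "length")])
})

test_that("SAM ingestion drops non-unique alignments and honors the CIGAR span", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:400",
    paste("r1", 0, "chr1", 100, 42, "30M", "*", 0, 0,
          strrep("A", 30), "*", sep = "\t"),
    paste("r2", 256, "chr1", 120, 42, "30M", "*", 0, 0,
          strrep("A", 30), "*", sep = "\t"),      # secondary: dropped
    paste("r3", 16, "chr1", 140, 42, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),      # minus strand
    paste("r4", 0, "chr1", 160, 0, "30M", "*", 0, 0,
          strrep("A", 30), "*", sep = "\t"),      # MAPQ 0: dropped
    paste("r5", 0, "chr1", 180, 42, "10M2D18M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t")       # deletion consumes reference
  ), sam)
  genes <- data.frame(gene_id = "g", contig = "chr1", strand = "+",
                      cds_start = 1L, cds_end = 400L, length = 400L)
  expect_message(fp <- read_footprints(sam, genes), "MAPQ 0")
  expect_equal(nrow(fp), 3L)
  expect_equal(fp$five_prime, c(100L, 167L, 180L))
  expect_equal(fp$length, c(30L, 28L, 30L))
  expect_equal(fp$strand, c("+", "-", "+"))
})

test_that("gene assignment requires same strand and full containment", {
  genes <- data.frame(gene_id = c("plus", "minus"),
                      contig = "chr1", strand = c("+", "-"),
                      cds_start = c(100L, 150L), cds_end = c(300L, 350L),
                      length = c(201L, 201L), stringsAsFactors = FALSE)
  fp <- data.frame(contig = "chr1", strand = c("+", "-", "+", "+"),
                   five_prime = c(200L, 229L, 90L, 200L),
                   length = c(30L, 30L, 30L, 30L))
  out <- assign_genes(fp, genes)
  expect_equal(out$gene_id, c("plus", "minus", NA, "plus"))
})

test_that("interior filter applies both trim bounds and is idempotent", {
  g <- one_gene_genome(gene_length = 300L)
  cfg <- filter_config()
  fp <- rbind(fp_at_cds(g$genes, 10L, 30L),    # inside the first 30 nt
              fp_at_cds(g$genes, 100L, 30L),   # retained: 129 <= 225
              fp_at_cds(g$genes, 200L, 30L),   # 229 > 225: excluded
              fp_at_cds(g$genes, 31L, 30L),    # 5' end exactly at 31: retained
              fp_at_cds(g$genes, 30L, 30L))    # 5' end at 30: excluded
  kept <- filter_interior(fp, g$genes, cfg)
  expect_equal(kept$cds5, c(100L, 31L))
  expect_equal(kept$cds3, kept$cds5 + kept$length - 1L)
  expect_identical(filter_interior(kept, g$genes, cfg)$cds5, kept$cds5)
})

test_that("footprint counts are conserved across assignment and filtering", {
  p <- small_pipeline()
  n_unassigned <- sum(is.na(p$fp$gene_id))
  n_excluded <- nrow(p$fp) - n_unassigned - nrow(p$fpi)
  expect_equal(n_unassigned + n_excluded + nrow(p$fpi), nrow(p$fx$reads))
  expect_gte(n_excluded, 0L)
})

test_that("gene density is footprints per interior codon and scales linearly", {
  g <- one_gene_genome(gene_length = 300L)
  cfg <- filter_config()
  fp <- fp_at_cds(g$genes, rep(100L, 650), 30L)
  fp <- filter_interior(fp, g$genes, cfg)
  expect_equal(unname(gene_density(fp, g$genes, cfg)["g1"]), 10.0)
  expect_equal(unname(gene_density(fp[integer(0), ], g$genes, cfg)["g1"]), 0.0)
  expect_equal(unname(gene_density(rbind(fp, fp), g$genes, cfg)["g1"]), 20.0)
})

test_that("every downstream statistic survives a strand mirror of the data", {
  m <- test_model()
  cfg <- filter_config()
  g <- one_gene_genome(gene_length = 300L, sd_at = 150L, strand = "+")
  fp <- rbind(fp_at_cds(g$genes, c(120L, 135L, 148L, 160L, 200L), 30L),
              fp_at_cds(g$genes, c(90L, 100L), 28L))
  # mirrored encoding: reverse-complement the contig, flip every record
  L <- nchar(g$genome)
  genome2 <- setNames(riboSD:::revcomp_dna(g$genome), "ctg")
  genes2 <- g$genes
  genes2$strand <- "-"
  genes2$cds_start <- L - g$genes$cds_end + 1L
  genes2$cds_end <- L - g$genes$cds_start + 1L
  fp2 <- fp
  fp2$strand <- "-"
  fp2$five_prime <- L - fp$five_prime + 1L

  run <- function(genome, genes, fp) {
    fpi <- filter_interior(fp, genes, cfg)
    sites <- scan_sd_sites_genome(genome, genes, m, -8)
    cl <- classify_footprints(fpi, genes, genome, m)
    list(sites = sites$start, class = as.character(cl$class),
         cds5 = cl$cds5, dens = gene_density(fpi, genes, cfg))
  }
  expect_identical(run(g$genome, g$genes, fp), run(genome2, genes2, fp2))
})
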