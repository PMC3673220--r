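#!/usr/bin/env Rscript
# Scan every annotated CDS for internal SD sites (octamers with SD:aSD duplex
# energy <= -8 kcal/mol) and compare against the planted ground truth.
# To run the same census on a real genome, pass FASTA and GFF3 paths:
#   Rscript analysis/02_scan_sd_sites.R genome.fa genes.gff3
suppressMessages(library(riboSD))

args <- commandArgs(trailingOnly = TRUE)
fa <- if (length(args) >= 1) args[1] else "results/fixture/genome.fa"
gff <- if (length(args) >= 2) args[2] else "results/fixture/genes.gff3"

genome <- read_genome(fa)
genes <- read_genes(gff, genome)
census <- sd_site_census(genome, genes, duplex_model(), threshold = -8)

dir.create("results", showWarnings = FALSE)
write.table(census$sites, "results/sd_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(census$n_sites, " SD sites in ", census$n_genes, " of ", nrow(genes),
        " genes -> results/sd_sites.tsv")

truth_file <- "results/fixture/truth.json"
if (fa == "results/fixture/genome.fa" && file.exists(truth_file)) {
  truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  planted <- paste(truth$sd_sites$gene_id, truth$sd_sites$start)
  found <- paste(census$sites$gene_id, census$sites$start)
  message("planted-site recovery: ", sum(planted %in% found), "/",
          length(planted))
}
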