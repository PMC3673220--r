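#!/usr/bin/env Rscript
# Build the ground-truth synthetic dataset every later step consumes:
# 200 random ORFs (150 carrying one planted SD octamer spanning -14..-8.5
# kcal/mol, 50 SD-free controls) on one contig, plus 2000 footprints per gene
# drawn with a 9-fold pause at the planted SD + 11 nt and caterpillar-style
# 3'-ward extension (planted mean 4.5 nt).
suppressMessages(library(riboSD))

dir.create("results/fixture", showWarnings = FALSE, recursive = TRUE)
spec <- fixture_spec(seed = 7L)
fx <- build_fixture(spec, dir = "results/fixture")

write.table(fx$sd_sites, "results/fixture/planted_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("genome: ", nchar(fx$genome), " nt on ", length(fx$genome), " contig")
message("genes:  ", nrow(fx$genes), " (", sum(fx$truth$is_control), " controls)")
message("reads:  ", nrow(fx$reads), "; planted SD sites: ", nrow(fx$sd_sites),
        "; planted mean extension: ", fx$truth$planted_mean_extension, " nt")
message("written to results/fixture/ (genome.fa, genes.gff3, reads.bed, truth.json)")
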