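#!/usr/bin/env Rscript
# Hexamer-level analysis: for footprints whose 5' end lies 8..2 nt upstream of
# a hexamer, correlate the hexamer's SD:aSD duplex strength and its normalized
# ribosome density with the mean footprint length.
suppressMessages(library(riboSD))

m <- duplex_model()
cfg <- filter_config()
genome <- read_genome("results/fixture/genome.fa")
genes <- read_genes("results/fixture/genes.gff3", genome)
fpi <- filter_interior(read_footprints("results/fixture/reads.bed", genes),
                       genes, cfg)

hx <- correlate_hexamer(fpi, genes, genome, m, cfg, min_values = 10)
write.table(hx$table, "results/hexamer_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(hx$table), " hexamers with >= 10 contributing footprints")
message(sprintf("Pearson r (binding strength vs mean length): %.3f",
                hx$r_strength_length))
message(sprintf("Pearson r (normalized density vs mean length): %.3f",
                hx$r_density_length))
strong <- hx$table[hx$table$delta_g <= -8, ]
message(sprintf("strong hexamers (dG <= -8): mean length %.1f nt vs %.1f nt overall",
                mean(strong$mean_length), mean(hx$table$mean_length)))
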