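#!/usr/bin/env Rscript
# Classify footprints (SD / NoSD / Ambiguous by the 3..17 window rule),
# build the per-SD and per-gene normalized length distributions, test the
# SD-vs-NoSD length difference (Wilcoxon rank-sum), and quantify how many
# reads interact with SD sites relative to uniform placement.
suppressMessages(library(riboSD))

m <- duplex_model()
cfg <- filter_config()
genome <- read_genome("results/fixture/genome.fa")
genes <- read_genes("results/fixture/genes.gff3", genome)
fp <- read_footprints("results/fixture/reads.bed", genes)
fpi <- filter_interior(fp, genes, cfg)
message(nrow(fpi), "/", nrow(fp), " footprints inside the 30/75 interior; ",
        sum(gene_density(fpi, genes, cfg) > cfg$min_density_distributions),
        " genes above 10 footprints/codon")

sites <- read.delim("results/sd_sites.tsv")
cl <- assign_sd_sites(classify_footprints(fpi, genes, genome, m), sites)
print(table(cl$class))

uSD <- sd_unit_histograms(cl, sites, "SD")
uNo <- sd_unit_histograms(cl, sites, "NoSD")
ldSD <- length_distribution(uSD, mode = "per_sd")
ldNo <- length_distribution(uNo, mode = "per_gene")
out <- rbind(cbind(class = "SD", ldSD), cbind(class = "NoSD", ldNo))
write.table(out, "results/length_distributions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

wt <- compare_length_distributions(cl$length[cl$class == "SD"],
                                   cl$length[cl$class == "NoSD"])
message(sprintf("mean length SD %.2f vs NoSD %.2f nt (distribution shift %.2f nt)",
                length_distribution_mean(ldSD), length_distribution_mean(ldNo),
                length_distribution_mean(ldSD) - length_distribution_mean(ldNo)))
message("Wilcoxon rank-sum p = ", format(wt$p.value))

enr <- sd_read_enrichment(cl[cl$gene_id %in% sites$gene_id, ], genes, genome,
                          m, cfg)
message(sprintf("SD-classified reads: %d observed vs %.0f expected (%.1f-fold)",
                enr$observed, enr$expected, enr$enrichment))
write.table(data.frame(observed = enr$observed, expected = enr$expected,
                       enrichment = enr$enrichment),
            "results/sd_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
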