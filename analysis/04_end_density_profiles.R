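#!/usr/bin/env Rscript
# Metagene 5'/3' end-density profiles around SD sites (s = 1 at the SD first
# nucleotide), overall and per footprint length, and recovery of the planted
# pause parameters from the profile alone.
suppressMessages(library(riboSD))

m <- duplex_model()
cfg <- filter_config()
genome <- read_genome("results/fixture/genome.fa")
genes <- read_genes("results/fixture/genes.gff3", genome)
fpi <- filter_interior(read_footprints("results/fixture/reads.bed", genes),
                       genes, cfg)
sites <- read.delim("results/sd_sites.tsv")
cl <- classify_footprints(fpi, genes, genome, m)

prof <- end_density_profile(site_end_counts(cl, sites, genes, cfg, flank = 50L))
strata <- 27:33
prof_l <- do.call(rbind, lapply(strata, function(l) {
  end_density_profile(site_end_counts(cl, sites, genes, cfg, 50L,
                                      length_stratum = l))
}))
write.table(rbind(prof, prof_l), "results/end_density_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

p5 <- profile_peak_stats(prof$s, prof$d5)
p3 <- profile_peak_stats(prof$s, prof$d3)
message(sprintf("5' peak at s = %d, 3' peak at s = %d (N = %d sites)",
                p5$peak_pos, p3$peak_pos, prof$n_sites[1]))
for (l in strata) {
  q <- prof_l[prof_l$stratum == l, ]
  message(sprintf("  length %d: 5' argmax %3d, 3' argmax %3d", l,
                  q$s[which.max(q$d5)], q$s[which.max(q$d3)]))
}

truth <- jsonlite::read_json("results/fixture/truth.json", simplifyVector = TRUE)
rec <- recover_pause_parameters(prof, truth$n_extension_steps + 1,
                                mean(cl$length[cl$class == "NoSD"]))
message(sprintf("recovered pause fold %.2f (planted %g); mean extension %.2f nt (planted %g)",
                rec$pause_fold, truth$pause_fold, rec$extension_nt,
                truth$planted_mean_extension))
write.table(data.frame(pause_fold = rec$pause_fold,
                       extension_nt = rec$extension_nt,
                       planted_fold = truth$pause_fold,
                       planted_extension = truth$planted_mean_extension),
            "results/recovered_parameters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
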