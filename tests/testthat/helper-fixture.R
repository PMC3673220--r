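# Shared, lazily built test data (built once per test run).
.test_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.test_cache$model)) .test_cache$model <- duplex_model()
  .test_cache$model
}

# a moderate fixture: 24 genes x 1300 reads keeps every gene above the
# 10-per-codon filter ((450 - 105)/3 = 115 interior codons)
small_fixture_spec <- function(...) {
  fixture_spec(n_genes = 24L, gene_length = 450L, reads_per_gene = 1300L,
               length_shift_nt = 4, pause_fold = 9, seed = 7L, ...)
}

small_fixture <- function() {
  if (is.null(.test_cache$fx))
    .test_cache$fx <- build_fixture(small_fixture_spec(), model = test_model())
  .test_cache$fx
}

# fixture pushed through assignment/filtering/classification once
small_pipeline <- function() {
  if (is.null(.test_cache$pipe)) {
    fx <- small_fixture()
    cfg <- filter_config()
    m <- test_model()
    fp <- assign_genes(fx$reads[, c("contig", "strand", "five_prime", "length")],
                       fx$genes)
    fpi <- filter_interior(fp, fx$genes, cfg)
    sites <- scan_sd_sites_genome(fx$genome, fx$genes, m, -8)
    cl <- assign_sd_sites(classify_footprints(fpi, fx$genes, fx$genome, m), sites)
    .test_cache$pipe <- list(fx = fx, fp = fp, fpi = fpi, sites = sites,
                             cl = cl, cfg = cfg)
  }
  .test_cache$pipe
}

# one-gene genome with a planted strong SD octamer, for targeted tests
one_gene_genome <- function(gene_length = 300L, sd_at = 150L, strand = "+",
                            background = "C") {
  cds <- strrep(background, gene_length)
  substr(cds, sd_at, sd_at + 7L) <- "AGGAGGTG"
  genomic <- if (strand == "-") riboSD:::revcomp_dna(cds) else cds
  pad <- strrep("T", 20)
  genome <- setNames(paste0(pad, genomic, pad), "ctg")
  genes <- data.frame(gene_id = "g1", contig = "ctg", strand = strand,
                      cds_start = 21L, cds_end = 20L + gene_length,
                      length = gene_length, stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, sd_at = sd_at)
}

# footprint rows in coding coordinates of a one-gene genome
fp_at_cds <- function(genes, cds5, length) {
  g <- genes[1, ]
  five <- if (g$strand == "+") g$cds_start + cds5 - 1L else g$cds_end - cds5 + 1L
  data.frame(contig = g$contig, strand = g$strand, five_prime = five,
             length = as.integer(length), gene_id = g$gene_id,
             stringsAsFactors = FALSE)
}

# default-scale simulations and fixture shared by the acceptance checks
default_sim <- function(model_kind) {
  key <- paste0("sim_", model_kind)
  if (is.null(.test_cache[[key]])) {
    strata <- if (model_kind == "caterpillar") 26:34 else integer(0)
    .test_cache[[key]] <- run_simulation(
      sim_config(model = model_kind, seed = 101L), test_model(),
      strata = strata)
  }
  .test_cache[[key]]
}

default_fixture_pipeline <- function() {
  if (is.null(.test_cache$default_pipe)) {
    m <- test_model()
    cfg <- filter_config()
    fx <- build_fixture(fixture_spec(), model = m, cfg = cfg)
    fp <- assign_genes(fx$reads[, c("contig", "strand", "five_prime", "length")],
                       fx$genes)
    fpi <- filter_interior(fp, fx$genes, cfg)
    sites <- scan_sd_sites_genome(fx$genome, fx$genes, m, -8)
    cl <- assign_sd_sites(classify_footprints(fpi, fx$genes, fx$genome, m), sites)
    .test_cache$default_pipe <- list(fx = fx, fpi = fpi, sites = sites,
                                     cl = cl, cfg = cfg)
  }
  .test_cache$default_pipe
}
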