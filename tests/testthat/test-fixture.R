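test_that("planted SD sites are recovered exactly by the scan, controls are clean", {
  fx <- small_fixture()
  m <- test_model()
  sites <- scan_sd_sites_genome(fx$genome, fx$genes, m, -8)
  expect_equal(paste(sites$gene_id, sites$start),
               paste(fx$sd_sites$gene_id, fx$sd_sites$start))
  expect_true(all(sites$delta_g <= -8))
  # control genes hold nothing even at the loose -2 kcal/mol threshold
  ctrl <- fx$genes[fx$truth$is_control[fx$genes$gene_id], ]
  expect_gt(nrow(ctrl), 0)
  loose <- scan_sd_sites_genome(fx$genome, ctrl, m, -2)
  expect_equal(nrow(loose), 0L)
})

test_that("fixtures are deterministic in their seed and change with it", {
  spec <- fixture_spec(n_genes = 6L, gene_length = 300L, reads_per_gene = 50L,
                       seed = 19L)
  f1 <- build_fixture(spec, model = test_model())
  f2 <- build_fixture(spec, model = test_model())
  expect_identical(f1$genome, f2$genome)
  expect_identical(f1$reads, f2$reads)
  spec2 <- fixture_spec(n_genes = 6L, gene_length = 300L, reads_per_gene = 50L,
                        seed = 20L)
  f3 <- build_fixture(spec2, model = test_model())
  expect_false(identical(f1$genome, f3$genome))
})

test_that("ORFs are well-formed: start, stop, no internal stop, length %% 3 == 0", {
  fx <- small_fixture()
  for (i in seq_len(nrow(fx$genes))) {
    cds <- cds_sequence(fx$genome, fx$genes[i, ])
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substring(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("every emitted footprint is parseable, assignable and interior", {
  fx <- small_fixture()
  cfg <- filter_config()
  fp <- assign_genes(fx$reads[, c("contig", "strand", "five_prime", "length")],
                     fx$genes)
  expect_true(all(!is.na(fp$gene_id)))
  expect_identical(fp$gene_id, fx$reads$gene_id)
  fpi <- filter_interior(fp, fx$genes, cfg)
  expect_equal(nrow(fpi), nrow(fp))   # generator places reads inside the interior
  dens <- gene_density(fpi, fx$genes, cfg)
  expect_true(all(dens > cfg$min_density_distributions))
})

test_that("fixture files round-trip through the standard readers", {
  dir <- tempfile("fx")
  spec <- fixture_spec(n_genes = 6L, gene_length = 300L, reads_per_gene = 40L,
                       seed = 19L)
  fx <- build_fixture(spec, dir = dir, model = test_model())
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(genome, fx$genome)
  genes <- read_genes(file.path(dir, "genes.gff3"), genome)
  expect_equal(genes$gene_id, fx$genes$gene_id)
  expect_equal(genes$cds_start, fx$genes$cds_start)
  expect_equal(genes$strand, fx$genes$strand)
  fp <- read_footprints(file.path(dir, "reads.bed"), genes)
  expect_equal(nrow(fp), nrow(fx$reads))
  expect_equal(fp$five_prime, fx$reads$five_prime)
  expect_equal(fp$gene_id, fx$reads$gene_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, spec$seed)
  expect_equal(sort(truth$sd_sites$start), sort(fx$sd_sites$start))
})

test_that("planted pause and extension are visible in the ground-truth labels", {
  fx <- small_fixture()
  expect_true(any(fx$reads$paused))
  expect_true(all(fx$reads$extended_by[!fx$reads$paused] %in%
                    0:(3 * fx$spec$n_extension_steps)))
  # paused reads at the planted fold: relative weight check per gene
  sd_genes <- unique(fx$sd_sites$gene_id)
  frac <- mean(fx$reads$paused[fx$reads$gene_id %in% sd_genes])
  # K+1 pause codons at weight 9 among ~(interior codons) candidates
  n_cand <- length(seq.int(31L + 22L, 450L - 75L - 24L, by = 3L))
  k1 <- fx$spec$n_extension_steps + 1
  p_exp <- (9 * k1) / (n_cand - k1 + 9 * k1)
  expect_equal(frac, p_exp, tolerance = 0.15)
})

test_that("null fixtures carry no pause or extension signal", {
  spec <- fixture_spec(n_genes = 8L, gene_length = 300L, reads_per_gene = 300L,
                       pause_fold = 1, length_shift_nt = 0, seed = 4L)
  fx <- build_fixture(spec, model = test_model())
  expect_true(all(fx$reads$extended_by == 0L))
  expect_equal(spec$planted_mean_extension, 0)
})
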