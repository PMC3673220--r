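test_that("sequence generation is seeded, uniform and length-exact", {
  cfg <- sim_config(n_sequences = 5L, seq_length = 2000L, seed = 42L)
  s1 <- generate_sequences(cfg)
  s2 <- generate_sequences(cfg)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1) == 2000L))
  s3 <- generate_sequences(sim_config(n_sequences = 5L, seq_length = 2000L,
                                      seed = 43L))
  expect_false(identical(s1, s3))
  # nucleotide frequencies near 0.25 at large n (3 SE of a binomial)
  counts <- table(strsplit(paste(generate_sequences(
    sim_config(n_sequences = 100L, seq_length = 10000L, seed = 1L)),
    collapse = ""), "")[[1]])
  n <- sum(counts)
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(counts / n - 0.25) < 3 * se + 1e-12))
})

test_that("slow codons sit pause_offset nt downstream of each SD site", {
  m <- test_model()
  cfg <- sim_config(seed = 1L)
  seq1 <- paste0(strrep("C", 99), "AGGAGGUG", strrep("C", 400))
  expect_equal(locate_pause_codons(seq1, cfg, m), 111L)
  expect_length(locate_pause_codons(strrep("C", 500), cfg, m), 0L)
  seq2 <- paste0(strrep("C", 99), "AGGAGGUG", strrep("C", 92), "GGGAGGUG",
                 strrep("C", 300))
  expect_equal(locate_pause_codons(seq2, cfg, m), c(111L, 211L))
  # a slow codon that would extend past the sequence end is dropped
  seq3 <- paste0(strrep("C", 489), "AGGAGGUG", strrep("C", 3))
  expect_length(locate_pause_codons(seq3, cfg, m), 0L)
})

test_that("footprints are centered on the P-site with the 5' half longer", {
  cfg <- sim_config(footprints_per_seq = 2000L, model = "single", seed = 5L)
  seqn <- strrep("C", 1000)
  set.seed(5)
  fp <- sample_footprints(seqn, integer(0), cfg)
  expect_equal(nrow(fp), 2000L)
  expect_equal(fp$three_prime - fp$five_prime + 1L, fp$length)
  expect_true(all(fp$five_prime >= 1L & fp$three_prime <= 1000L))
  expect_true(all(fp$p_site >= fp$five_prime & fp$p_site + 2L <= fp$three_prime + 1L))
  up <- fp$p_site - fp$five_prime
  down <- fp$three_prime - (fp$p_site + 2L)
  expect_true(all((up - down) %in% c(0L, 1L)))  # extra nucleotide 5' of the codon
  expect_true(all(up == ceiling((fp$length - 3L) / 2L)))
})

test_that("caterpillar extension anchors the 5' end at the slow codon's footprint", {
  cfg <- sim_config(footprints_per_seq = 30000L, model = "caterpillar", seed = 9L)
  x <- 499L  # slow codon on the global lattice (499 = 3*166 + 1)
  set.seed(9)
  fp <- sample_footprints(strrep("C", 1000), x, cfg)
  ext <- fp[fp$extended_by > 0L, ]
  expect_gt(nrow(ext), 0L)
  expect_true(all(ext$extended_by %in% c(3L, 6L)))
  drawn <- ext$length - ext$extended_by
  # 5' end equals that of a drawn-length footprint whose P-site is x
  expect_true(all(ext$five_prime == x - ceiling((drawn - 3L) / 2L)))
  # example: P-site at x+3, drawn 30 -> emitted 33 sharing the x footprint 5' end
  case <- ext[ext$p_site == x + 3L & drawn == 30L, ]
  expect_gt(nrow(case), 0L)
  expect_true(all(case$length == 33L))
  expect_true(all(case$five_prime == x - 14L))
  # far-from-SD footprints keep their drawn length
  far <- fp[abs(fp$p_site - x) > 10L, ]
  expect_true(all(far$extended_by == 0L))
  expect_true(all(far$length %in% 20:47))
})

test_that("single-model pause weights follow 9/(M-1+9) within 3 binomial SE", {
  n <- 200000L
  cfg <- sim_config(footprints_per_seq = n, model = "single", seed = 3L)
  x <- 499L
  set.seed(3)
  fp <- sample_footprints(strrep("C", 1000), x, cfg)
  # candidate P-sites: the codon lattice 1, 4, ... restricted to 25..976
  # (margins keep a 47-nt footprint inside); x is on the lattice
  M <- length(seq.int(25L, 976L, by = 3L))
  p_expect <- 9 / (M - 1 + 9)
  p_hat <- mean(fp$paused)
  expect_lt(abs(p_hat - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("simulations are reproducible and footprint counts are exact", {
  cfg <- sim_config(n_sequences = 20L, footprints_per_seq = 300L,
                    model = "caterpillar", seed = 77L)
  m <- test_model()
  r1 <- run_simulation(cfg, m)
  r2 <- run_simulation(cfg, m)
  expect_identical(r1$footprints, r2$footprints)
  expect_identical(r1$profile, r2$profile)
  expect_equal(nrow(r1$footprints), 20L * 300L)
})

test_that("a unit pause multiplier yields a flat end-density profile", {
  cfg <- sim_config(n_sequences = 150L, footprints_per_seq = 600L,
                    model = "single", pause_multiplier = 1, seed = 8L)
  r <- run_simulation(cfg, test_model())
  # no position deviates from the mean by more than 4 position-level SD
  for (d in list(r$profile$d5, r$profile$d3)) {
    expect_lt(max(abs(d - mean(d))) / sd(d), 4)
  }
})

test_that("single and caterpillar models leave their distinct end signatures", {
  m <- test_model()
  rs <- run_simulation(sim_config(n_sequences = 150L, model = "single",
                                  seed = 21L), m)
  p5 <- profile_peak_stats(rs$profile$s, rs$profile$d5)
  p3 <- profile_peak_stats(rs$profile$s, rs$profile$d3)
  expect_lte(abs(p5$fwhm - p3$fwhm), 2L)
  expect_lt(abs(p5$variance - p3$variance) / p3$variance, 0.35)
  rc <- run_simulation(sim_config(n_sequences = 150L, model = "caterpillar",
                                  seed = 21L), m)
  c5 <- profile_peak_stats(rc$profile$s, rc$profile$d5)
  c3 <- profile_peak_stats(rc$profile$s, rc$profile$d3)
  expect_gt(c3$variance, c5$variance)
  dip <- rc$profile$s > c5$peak_pos & rc$profile$s <= c5$peak_pos + 8L
  expect_lt(min(rc$profile$d5[dip]), c5$baseline)
})

test_that("caterpillar 5' ends stay put while 3' ends track footprint length", {
  rc <- run_simulation(sim_config(n_sequences = 300L, model = "caterpillar",
                                  seed = 33L), test_model(), strata = 27:33)
  pk5 <- pk3 <- integer(0)
  for (l in 27:33) {
    q <- rc$profiles_by_length[[as.character(l)]]
    pk5 <- c(pk5, q$s[which.max(q$d5)])
    pk3 <- c(pk3, q$s[which.max(q$d3)])
  }
  lens <- 27:33
  # 5' peak is stationary (no trend, narrow band); 3' peak advances with length
  expect_lte(diff(range(pk5)), 3L)
  expect_lt(abs(coef(lm(pk5 ~ lens))[2]), 0.35)
  expect_gt(coef(lm(pk3 ~ lens))[2], 0.6)
  expect_equal(unname(coef(lm(pk3 ~ lens))[2]), 1, tolerance = 0.4)
})
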