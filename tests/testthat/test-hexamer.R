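# A constructed mini-dataset for the hexamer analysis: genes whose single
# strong hexamer context receives 5'-anchored footprints with lengths that are
# a linear function of the hexamer's binding strength. Background reads avoid
# the hexamer's upstream window so the planted support is exact.
hexamer_testbed <- function(slope = 2, noise = 1, n_per_gene = 1300L,
                            n_anchored = 150L, shuffle = FALSE, seed = 31L) {
  m <- test_model()
  cfg <- filter_config()
  set.seed(seed)
  hex <- c("GGAGGU", "GGAGGC", "GGAGCU", "GGACGU", "GCAGGU", "AGGAGA")
  strength <- -vapply(hex, hexamer_strength, numeric(1), model = m)
  L <- 450L
  genes <- data.frame(gene_id = paste0("h", seq_along(hex)), contig = "ctg",
                      strand = "+",
                      cds_start = 21L + (seq_along(hex) - 1L) * (L + 40L),
                      stringsAsFactors = FALSE)
  genes$cds_end <- genes$cds_start + L - 1L
  genes$length <- L
  parts <- strrep("C", 20)
  # background reads avoid the planted window except in the shuffled null,
  # where the planted hexamers must still accumulate (unrelated) support
  bg_pos <- if (shuffle) seq.int(31L, 340L) else
    setdiff(seq.int(31L, 340L), 185:210)
  fp <- list()
  for (i in seq_along(hex)) {
    cds <- strrep("C", L)
    substr(cds, 200L, 205L) <- riboSD:::to_dna(hex[i])
    parts <- c(parts, cds, strrep("C", 40))
    base_len <- round(24 + slope * strength[i])
    q <- sample(bg_pos, n_per_gene, replace = TRUE)
    lens <- rep(30L, n_per_gene)
    if (n_anchored > 0) {
      # anchored reads: 5' end 8..2 nt upstream of the hexamer start (or at
      # random positions when shuffled, which severs the link to the hexamer)
      if (!shuffle)
        q[seq_len(n_anchored)] <- 200L - sample(2:8, n_anchored, replace = TRUE)
      # shuffled null: long-read lengths no longer encode the gene's strength
      lens[seq_len(n_anchored)] <- (if (shuffle) 30L else base_len) +
        sample(seq.int(-noise, noise), n_anchored, replace = TRUE)
    }
    fpi <- fp_at_cds(genes[i, ], q, 1L)
    fpi$length <- as.integer(lens)
    fp[[i]] <- fpi
  }
  genome <- setNames(paste(c(parts, ""), collapse = ""), "ctg")
  fp <- do.call(rbind, fp)
  fp <- filter_interior(fp, genes, cfg)
  list(genome = genome, genes = genes, fp = fp, hex = hex,
       strength = strength, cfg = cfg, model = m)
}

test_that("a planted linear strength-length relation is recovered with r near 1", {
  tb <- hexamer_testbed(slope = 2, noise = 1)
  res <- correlate_hexamer(tb$fp, tb$genes, tb$genome, tb$model, tb$cfg,
                           min_values = 10)
  got <- res$table[match(tb$hex, res$table$hexamer), ]
  expect_false(anyNA(got$hexamer))
  expect_equal(got$n_values, rep(150, length(tb$hex)))
  r <- cor(-got$delta_g, got$mean_length)
  expect_gt(r, 0.95)
  # anchored hexamers show elevated normalized density relative to background
  bg <- res$table[!res$table$hexamer %in% tb$hex, ]
  expect_gt(min(got$mean_norm_density), mean(bg$mean_norm_density))
})

test_that("shuffled footprint positions destroy the correlation", {
  tb <- hexamer_testbed(shuffle = TRUE)
  res <- correlate_hexamer(tb$fp, tb$genes, tb$genome, tb$model, tb$cfg,
                           min_values = 10)
  got <- res$table[res$table$hexamer %in% tb$hex, ]
  if (nrow(got) >= 3)
    expect_lt(abs(cor(-got$delta_g, got$mean_length)), 0.9)
  expect_lt(abs(res$r_strength_length), 0.3)
})

test_that("hexamers with fewer than min_values contributing footprints are dropped", {
  tb <- hexamer_testbed(n_anchored = 9L)
  res <- correlate_hexamer(tb$fp, tb$genes, tb$genome, tb$model, tb$cfg,
                           min_values = 10)
  expect_true(all(res$table$n_values >= 10))
  # the planted hexamers each had exactly 9 contributing footprints
  expect_false(any(tb$hex %in% res$table$hexamer))
  # at 9 they are admitted
  res9 <- correlate_hexamer(tb$fp, tb$genes, tb$genome, tb$model, tb$cfg,
                            min_values = 9)
  expect_true(all(tb$hex %in% res9$table$hexamer))
})

test_that("fewer than two surviving hexamers is an error", {
  tb <- hexamer_testbed()
  expect_error(correlate_hexamer(tb$fp, tb$genes, tb$genome, tb$model, tb$cfg,
                                 min_values = 1e7), "fewer than 2")
})
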