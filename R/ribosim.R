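#' Default simulated footprint length distribution
#'
#' Discretized triangular distribution over `range`, peaking at `peak` nt.
#' Stands in for the empirical footprint-length distribution of a profiling
#' library (which rises steeply to a mode near 28 nt and tails off slowly).
#'
#' @param range inclusive length range, nt (default 20-47).
#' @param peak mode, nt (default 28).
#' @return named numeric vector of probabilities summing to 1.
#' @export
triangular_length_probs <- function(range = c(20L, 47L), peak = 28L) {
  l <- seq.int(range[1], range[2])
  p <- ifelse(l <= peak, (l - range[1] + 1) / (peak - range[1] + 1),
              (range[2] - l + 1) / (range[2] - peak + 1))
  setNames(p / sum(p), l)
}

#' Simulation configuration
#'
#' Parameterizes the in-silico footprint generator. Under the `single` model
#' ribosome P-site codons are chosen with relative weight 1 at ordinary codons
#' and `pause_multiplier` (default 9) at slow codons located `pause_offset` nt
#' downstream of each SD site's first nucleotide. Under the `caterpillar`
#' model the pause is spread over three adjacent codons at x, x+3 and x+6
#' (weight `pause_multiplier`, default 3, replacing the base weight), and
#' footprints whose P-site p lies within x+1..x+6 are extended at their
#' 5' end by p - x, anchoring the 5' end where a footprint with P-site x
#' would start while the 3' end keeps its own position.
#'
#' @param n_sequences number of random sequences (default 1000).
#' @param seq_length sequence length, nt (default 1000).
#' @param footprints_per_seq footprints sampled per sequence (default 600).
#' @param length_range admissible drawn lengths, nt (within 15-60).
#' @param length_probs drawn-length distribution
#'   (default [triangular_length_probs()]).
#' @param pause_offset nt from the SD first nucleotide to the first nucleotide
#'   of the slow P-site codon (default 11).
#' @param model `"single"` or `"caterpillar"`.
#' @param pause_multiplier relative P-site weight at slow codons; defaults to
#'   9 (single) or 3 (caterpillar).
#' @param sd_threshold SD detection threshold used to place slow codons,
#'   kcal/mol.
#' @param seed RNG seed; every random draw of a simulation flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sequences = 1000L, seq_length = 1000L,
                       footprints_per_seq = 600L,
                       length_range = c(20L, 47L),
                       length_probs = NULL,
                       pause_offset = 11L,
                       model = c("single", "caterpillar"),
                       pause_multiplier = NULL,
                       sd_threshold = -8,
                       seed = 1L) {
  model <- match.arg(model)
  if (is.null(length_probs))
    length_probs <- triangular_length_probs(length_range)
  stopifnot(abs(sum(length_probs) - 1) < 1e-8,
            length_range[1] >= 15L, length_range[2] <= 60L)
  if (is.null(pause_multiplier))
    pause_multiplier <- if (model == "single") 9 else 3
  stopifnot(pause_multiplier >= 1)
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 footprints_per_seq = as.integer(footprints_per_seq),
                 length_range = as.integer(length_range),
                 length_probs = length_probs,
                 pause_offset = as.integer(pause_offset),
                 model = model,
                 pause_multiplier = pause_multiplier,
                 sd_threshold = sd_threshold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate random RNA sequences
#'
#' i.i.d. uniform nucleotides; deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`); pass `NA` to use the current RNG
#'   state (as [run_simulation()] does after seeding once).
#' @return character vector of `cfg$n_sequences` RNA strings.
#' @export
generate_sequences <- function(cfg, seed = cfg$seed) {
  if (!is.na(seed)) set.seed(seed)
  vapply(seq_len(cfg$n_sequences), function(i) {
    paste(sample(RNA_BASES, cfg$seq_length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Locate slow codons downstream of SD sites
#'
#' Scans the sequence for SD sites and places one slow coordinate per site at
#' `sd_start + pause_offset` (the first nucleotide of the slow P-site codon).
#' Coordinates whose codon would extend past the sequence end are dropped.
#'
#' @param sequence one RNA string.
#' @param cfg a [sim_config()].
#' @param model a [duplex_model()].
#' @return integer vector of slow-codon first-nucleotide coordinates.
#' @export
locate_pause_codons <- function(sequence, cfg, model = duplex_model()) {
  sites <- scan_sd_sites(sequence, model = model, threshold = cfg$sd_threshold)
  x <- sites$start + cfg$pause_offset
  x[x + 2L <= nchar(sequence)]
}

# Core sampling engine shared by the two pause models and the fixture
# generator. P-site candidates are codon starts (step 3 from `lattice_from`)
# plus the pause codons themselves; pause codons sit at x + 3k,
# k = 0..n_pause_codons-1 for each slow coordinate x, each with relative
# weight `multiplier` (replacing the base weight 1). With `extend = TRUE`,
# footprints whose P-site p satisfies 0 < p - x <= 3*(n_pause_codons - 1)
# are extended at the 5' end by p - x. P-sites are restricted to
# [min_pos, max_pos]; footprints falling outside [bound_lo, bound_hi] are
# resampled.
sample_fp_engine <- function(slow, n, length_probs, multiplier,
                             n_pause_codons, extend,
                             bound_lo, bound_hi, lattice_from = 1L,
                             max_resample = 100L) {
  lens <- as.integer(names(length_probs))
  max_len <- max(lens)
  # keep any drawn length inside the bounds: P-site codon start must leave
  # ceil((max_len - 3) / 2) nt upstream and the rest downstream
  up_max <- ceiling((max_len - 3L) / 2L)
  down_max <- max_len - 3L - up_max
  min_pos <- bound_lo + up_max
  max_pos <- bound_hi - 2L - down_max
  if (max_pos < min_pos) stop("bounds leave no admissible P-site")
  lattice <- seq.int(lattice_from, max_pos, by = 3L)
  lattice <- lattice[lattice >= min_pos]
  pause_pos <- integer(0)
  if (length(slow) && n_pause_codons >= 1L)
    pause_pos <- as.vector(outer(slow, 3L * (seq_len(n_pause_codons) - 1L), `+`))
  pause_pos <- pause_pos[pause_pos >= min_pos & pause_pos <= max_pos]
  cand <- sort(unique(c(lattice, pause_pos)))
  w <- rep(1, length(cand))
  w[cand %in% pause_pos] <- multiplier
  p_site <- cand[sample.int(length(cand), n, replace = TRUE, prob = w)]
  drawn <- lens[sample.int(length(lens), n, replace = TRUE, prob = length_probs)]
  five <- p_site - ceiling((drawn - 3L) / 2L)
  three <- five + drawn - 1L
  len <- drawn
  ext <- integer(n)
  if (extend && length(slow)) {
    win <- 3L * (n_pause_codons - 1L)
    if (win > 0L) {
      # distance to the nearest slow coordinate at or upstream of the P-site
      idx <- findInterval(p_site, sort(slow))
      x_near <- sort(slow)[pmax(idx, 1L)]
      delta <- p_site - x_near
      sel <- idx >= 1L & delta > 0L & delta <= win
      ext[sel] <- delta[sel]
      five[sel] <- five[sel] - delta[sel]
      len[sel] <- len[sel] + delta[sel]
    }
  }
  # resample rare boundary violations (extension can cross bound_lo)
  bad <- which(five < bound_lo | three > bound_hi)
  tries <- 0L
  while (length(bad) && tries < max_resample) {
    tries <- tries + 1L
    nb <- length(bad)
    p2 <- cand[sample.int(length(cand), nb, replace = TRUE, prob = w)]
    d2 <- lens[sample.int(length(lens), nb, replace = TRUE, prob = length_probs)]
    f2 <- p2 - ceiling((d2 - 3L) / 2L)
    t2 <- f2 + d2 - 1L
    l2 <- d2
    e2 <- integer(nb)
    if (extend && length(slow)) {
      win <- 3L * (n_pause_codons - 1L)
      if (win > 0L) {
        idx <- findInterval(p2, sort(slow))
        x_near <- sort(slow)[pmax(idx, 1L)]
        delta <- p2 - x_near
        sel <- idx >= 1L & delta > 0L & delta <= win
        e2[sel] <- delta[sel]
        f2[sel] <- f2[sel] - delta[sel]
        l2[sel] <- l2[sel] + delta[sel]
      }
    }
    p_site[bad] <- p2
    five[bad] <- f2
    three[bad] <- t2
    len[bad] <- l2
    ext[bad] <- e2
    bad <- bad[f2 < bound_lo | t2 > bound_hi]
  }
  if (length(bad)) stop("could not place ", length(bad), " footprints in bounds")
  paused <- p_site %in% pause_pos
  data.frame(p_site = p_site, five_prime = five, three_prime = three,
             length = len, paused = paused, extended_by = ext)
}

#' Sample simulated footprints on one sequence
#'
#' Draws `cfg$footprints_per_seq` footprints with P-site codons chosen by the
#' configured pause model and lengths from `cfg$length_probs`; footprints are
#' centered on the P-site codon (the 5' half carries the extra nucleotide for
#' even lengths). Under the caterpillar model, footprints with P-sites in
#' x+1..x+6 are extended 5'-ward by their distance to the slow coordinate x.
#' Footprints extending beyond the sequence are resampled.
#'
#' @param sequence RNA string (only its length is used).
#' @param slow_codons slow-codon coordinates from [locate_pause_codons()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed; `NA` (default) uses the current RNG state.
#' @return data.frame with `p_site`, `five_prime`, `three_prime`, `length`
#'   (emitted, including any extension), `paused`, `extended_by`.
#' @export
sample_footprints <- function(sequence, slow_codons, cfg, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  n_pause <- if (cfg$model == "caterpillar") 3L else 1L
  sample_fp_engine(slow_codons, cfg$footprints_per_seq, cfg$length_probs,
                   cfg$pause_multiplier, n_pause,
                   extend = cfg$model == "caterpillar",
                   bound_lo = 1L, bound_hi = nchar(sequence))
}

#' Run a full footprint simulation
#'
#' Generates random sequences, locates SD sites and slow codons, samples
#' footprints per the configured pause model, and aggregates 5'/3' end-density
#' profiles around the SD sites (overall and per emitted length stratum).
#' Fully reproducible given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param model a [duplex_model()].
#' @param strata emitted footprint lengths for per-length profiles (default
#'   none).
#' @param flank profile half-window, nt.
#' @return list with `footprints` (all sequences pooled, with `seq_id`),
#'   `sd_positions` (data.frame `seq_id`, `pos`), `profile` (all lengths),
#'   `profiles_by_length` (named list over `strata`), and `config`.
#' @export
run_simulation <- function(cfg, model = duplex_model(), strata = integer(0),
                           flank = 50L) {
  set.seed(cfg$seed)
  seqs <- generate_sequences(cfg, seed = NA)
  fps <- vector("list", cfg$n_sequences)
  anchors <- vector("list", cfg$n_sequences)
  for (i in seq_len(cfg$n_sequences)) {
    slow <- locate_pause_codons(seqs[i], cfg, model)
    fp <- sample_footprints(seqs[i], slow, cfg)
    fp$seq_id <- i
    fps[[i]] <- fp
    if (length(slow))
      anchors[[i]] <- data.frame(seq_id = i, pos = slow - cfg$pause_offset)
  }
  fp_all <- do.call(rbind, fps)
  anchor_all <- do.call(rbind, anchors)
  if (is.null(anchor_all) || !nrow(anchor_all))
    stop("no SD sites found in the simulated sequences")
  prof <- end_density_profile(
    end_counts_at_anchors(fp_all, anchor_all, cfg$seq_length, flank))
  by_len <- lapply(strata, function(l) {
    end_density_profile(
      end_counts_at_anchors(fp_all, anchor_all, cfg$seq_length, flank,
                            length_stratum = l))
  })
  names(by_len) <- as.character(strata)
  list(footprints = fp_all, sd_positions = anchor_all, profile = prof,
       profiles_by_length = by_len, config = cfg)
}
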