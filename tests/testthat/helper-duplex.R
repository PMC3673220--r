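# Pure-R exhaustive duplex enumerator: a third, independent implementation of
# the duplex energy used to validate both compiled kernels on tiny inputs.
# Structures are ordered pair lists (probe ascending, target descending);
# consecutive pairs joined by a stack, a bulge (<= max_loop) or an internal
# loop (total <= max_loop); a qualifying structure contains a run of at least
# min_helix stacked pairs.
r_duplex_enum <- function(probe, target, model) {
  a <- riboSD:::seq_to_int(probe)
  b <- riboSD:::seq_to_int(target)
  pairs <- matrix(c(1, 2, 2, 1, 2, 3, 3, 2, 0, 3, 3, 0), ncol = 2, byrow = TRUE)
  pc <- function(x, y) {
    hit <- which(pairs[, 1] == x & pairs[, 2] == y)
    if (length(hit)) hit else NA_integer_
  }
  pn <- c("CG", "GC", "GU", "UG", "AU", "UA")
  best <- Inf
  recurse <- function(i, j, run, maxrun, energy) {
    if (maxrun >= model$min_helix_pairs && energy < best)
      best <<- energy
    for (i2 in seq_len(length(a))) {
      if (i2 <= i || i2 > i + 1 + model$max_loop_len) next
      for (j2 in seq_len(length(b))) {
        if (j2 >= j || j2 < j - 1 - model$max_loop_len) next
        q <- pc(a[i2], b[j2])
        if (is.na(q)) next
        ga <- i2 - i - 1
        gb <- j - j2 - 1
        if (ga == 0 && gb == 0) {
          p1 <- pc(a[i], b[j])
          te <- model$stack[pn[p1], pn[q]]
          run2 <- run + 1
        } else if (gb == 0) {
          if (ga > model$max_loop_len) next
          te <- model$bulge_penalty[ga]
          run2 <- 1
        } else if (ga == 0) {
          if (gb > model$max_loop_len) next
          te <- model$bulge_penalty[gb]
          run2 <- 1
        } else {
          if (ga + gb > model$max_loop_len) next
          te <- model$internal_loop_penalty[ga + gb - 1]
          run2 <- 1
        }
        recurse(i2, j2, run2, max(maxrun, run2), energy + te)
      }
    }
  }
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (!is.na(pc(a[i], b[j]))) recurse(i, j, 1, 1, 0)
  }
  if (!is.finite(best)) return(0)
  min(model$duplex_initiation + best, 0)
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
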