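PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' Nearest-neighbor RNA:RNA duplex energy model
#'
#' Bundles the thermodynamic parameterization used for SD:aSD hybridization:
#' stack free-energy increments over the Watson-Crick and G:U wobble pairs,
#' length-dependent bulge and internal-loop penalties, the intermolecular
#' duplex initiation penalty, the maximum admissible loop length and the
#' minimum helix length (contiguously stacked pairs) a structure must contain
#' to count as a duplex. Defaults are read from the versioned parameter table
#' shipped with the package (`inst/extdata/duplex_params.tsv`, Turner 2004
#' values).
#'
#' @param param_file path to a TSV parameter table with columns
#'   `param` (one of "init", "stack", "bulge", "iloop"), `key1`, `key2`,
#'   `value` (kcal/mol).
#' @param max_loop_len maximum unpaired length of a bulge / internal loop (nt).
#' @param min_helix_pairs minimum number of contiguously stacked base pairs a
#'   qualifying duplex must contain somewhere.
#' @param asd anti-Shine-Dalgarno probe sequence, written 5'->3'. The default
#'   is the 3'-terminal tail of bacterial 16S rRNA used as pairing target.
#' @return an object of class `duplex_model`.
#' @export
#' @examples
#' m <- duplex_model()
#' duplex_free_energy("AGGAGGUG", m$asd, m)
duplex_model <- function(param_file = system.file("extdata", "duplex_params.tsv",
                                                  package = "riboSD"),
                         max_loop_len = 4L,
                         min_helix_pairs = 2L,
                         asd = "CACCUCCU") {
  tab <- read.delim(param_file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("param", "key1", "key2", "value") %in% names(tab)))

  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  st <- tab[tab$param == "stack", ]
  stack[cbind(match(st$key1, PAIR_NAMES), match(st$key2, PAIR_NAMES))] <- st$value

  bl <- tab[tab$param == "bulge", ]
  bulge <- setNames(bl$value, bl$key1)[as.character(seq_len(max_loop_len))]
  il <- tab[tab$param == "iloop", ]
  iloop_full <- setNames(il$value, il$key1)
  iloop <- iloop_full[as.character(2:max(2L, max_loop_len))]

  model <- structure(list(
    stack = stack,
    bulge_penalty = unname(bulge),
    internal_loop_penalty = unname(iloop),
    duplex_initiation = tab$value[tab$param == "init"][1],
    max_loop_len = as.integer(max_loop_len),
    min_helix_pairs = as.integer(min_helix_pairs),
    asd = to_rna(asd)
  ), class = "duplex_model")
  validate_duplex_model(model)
  model
}

validate_duplex_model <- function(m) {
  if (anyNA(m$stack) || any(!is.finite(m$stack)))
    stop("stack table must be complete and finite")
  # strand-exchange symmetry of the stack table: reading the same helix from
  # the other strand must give the same increment
  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p in PAIR_NAMES) for (q in PAIR_NAMES) {
    if (abs(m$stack[p, q] - m$stack[rev_pair(q), rev_pair(p)]) > 1e-9)
      stop("stack table is not strand-symmetric at ", p, "/", q)
  }
  if (any(m$bulge_penalty < 0) || any(m$internal_loop_penalty < 0))
    stop("loop penalties must be non-negative")
  # Published single-nt bulge terms exceed the 2-nt term (the flanking stack
  # is preserved in the source model), so monotonicity is only required from
  # length 2 on.
  if (length(m$bulge_penalty) > 2 && is.unsorted(m$bulge_penalty[-1]))
    stop("bulge penalties must be non-decreasing beyond length 1")
  if (is.unsorted(m$internal_loop_penalty))
    stop("internal loop penalties must be non-decreasing")
  if (!is.finite(m$duplex_initiation)) stop("duplex initiation must be finite")
  if (m$min_helix_pairs < 1L) stop("min_helix_pairs must be >= 1")
  invisible(m)
}

#' @export
print.duplex_model <- function(x, ...) {
  cat("RNA:RNA duplex nearest-neighbor model\n")
  cat("  aSD probe        :", x$asd, "\n")
  cat("  duplex initiation:", x$duplex_initiation, "kcal/mol\n")
  cat("  max loop length  :", x$max_loop_len, "nt\n")
  cat("  min helix pairs  :", x$min_helix_pairs, "\n")
  invisible(x)
}

# parameter list handed to the C++ kernels
duplex_par_list <- function(model) {
  list(stack = unname(model$stack),
       bulge = model$bulge_penalty,
       iloop = model$internal_loop_penalty,
       init = model$duplex_initiation,
       max_loop = model$max_loop_len,
       min_helix = model$min_helix_pairs)
}
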