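#' @useDynLib riboSD, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median runif setNames var wilcox.test cor pnorm
#' @importFrom utils read.delim head tail
NULL

# package-local cache (k-mer energy tables etc.)
.riboSD_cache <- new.env(parent = emptyenv())

RNA_BASES <- c("A", "C", "G", "U")

#' Convert a nucleotide string to the internal RNA integer encoding
#'
#' A=0, C=1, G=2, U=3; T is accepted and mapped to U.
#'
#' @param x single nucleotide string (DNA or RNA alphabet).
#' @return integer vector, one element per nucleotide.
#' @keywords internal
seq_to_int <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  code <- match(chars, RNA_BASES) - 1L
  if (anyNA(code))
    stop("non-nucleotide character in sequence: ",
         paste(unique(chars[is.na(code)]), collapse = ", "))
  code
}

int_to_seq <- function(code) paste(RNA_BASES[code + 1L], collapse = "")

#' Reverse complement of a DNA string
#' @param x single DNA string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @keywords internal
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# base-4 codes (0..4^k-1) of all k-mers starting at positions 1..(n-k+1);
# positions whose window contains a non-ACGU/T character get NA
kmer_codes <- function(seq, k) {
  code <- suppressWarnings(
    match(strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]], RNA_BASES) - 1L
  )
  n <- length(code)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (i in seq_len(k)) out <- out * 4 + code[i:(m + i - 1L)]
  out
}
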