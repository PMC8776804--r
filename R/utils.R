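#' @useDynLib flavoscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats hclust as.dist rbinom rpois rgeom runif setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so no operation leaks
#' global randomness state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647
}

#' Reverse complement of a nucleotide string
#'
#' @param x character string over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file of nucleotide sequences.
#' @return named character vector of uppercase sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_genomes_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (nucleotide or amino acid).
#' @param path output path.
#' @param aa logical; amino-acid alphabet if `TRUE`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, aa = FALSE) {
  ss <- if (aa) Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
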