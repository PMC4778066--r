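#' @useDynLib srnamir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Convert between DNA and RNA alphabets
#'
#' The package stores sequences internally in the DNA alphabet (T); mature
#' miRNA references and report output use the RNA alphabet (U). These helpers
#' convert character vectors between the two conventions.
#'
#' @param x character vector of sequences.
#' @return character vector with the alphabet swapped.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stop unless all sequences use the given alphabet
assert_alphabet <- function(x, letters, what = "sequence") {
  pat <- paste0("^[", paste(letters, collapse = ""), "]*$")
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}: %s", what,
                 paste(letters, collapse = ","),
                 substr(x[which(bad)[1]], 1, 40)), call. = FALSE)
  }
  invisible(x)
}

# deterministic child seed derived from a master seed and a stream label;
# kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# write a data.frame as a plain TSV
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
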