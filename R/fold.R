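#' Fold an RNA sequence into its minimum-free-energy nested structure
#'
#' Computes the minimum-free-energy (MFE) secondary structure of a single RNA
#' sequence under the package's default simplified stacked-pair energy model:
#' every base pair stacked directly inside an adjacent outer pair contributes
#' its own pair energy (G:C -3.0, A:U -2.0, G:U -1.0 kcal/mol), isolated
#' pairs contribute nothing, hairpin loops shorter than 3 nt are forbidden,
#' and structures are nested (no pseudoknots). Absolute energies are therefore
#' not comparable with thermodynamic (Turner-parameter) folders; all
#' thresholds used elsewhere in the package refer to this model.
#'
#' The engine is pluggable: any function taking an RNA string and returning a
#' list with elements `sequence`, `structure` (dot-bracket) and `mfe` may be
#' used wherever a folding engine is accepted.
#'
#' @param sequence single RNA string (A/C/G/U; T is accepted and read as U).
#' @return object of class `fold_result`: list with `sequence` (RNA string),
#'   `structure` (dot-bracket string of the same length), `mfe` (kcal/mol,
#'   <= 0) and `pairs` (integer vector of 1-based partner indices, 0 when
#'   unpaired).
#' @examples
#' fold("GGGGAAAACCCC")
#' @export
fold <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rna <- dna_to_rna(toupper(sequence))
  assert_alphabet(rna, c("A", "C", "G", "U"), "RNA sequence")
  if (nchar(rna) > 1000L) {
    stop("fold() supports sequences up to 1000 nt", call. = FALSE)
  }
  codes <- match(strsplit(rna, "")[[1]], c("A", "C", "G", "U")) - 1L
  res <- .fold_mfe_cpp(as.integer(codes))
  out <- list(sequence = rna, structure = res$structure,
              mfe = as.numeric(res$mfe), pairs = as.integer(res$pairs))
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$mfe), " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param structure dot-bracket string (only `(`, `)`, `.`).
#' @return integer vector of 1-based partner indices (0 = unpaired).
#' @export
structure_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pairs <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    } else if (chars[i] != ".") {
      stop("dot-bracket string may only contain '(', ')' and '.'", call. = FALSE)
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string", call. = FALSE)
  pairs
}

# energy of one base pair under the default model (0 if not a valid pair)
pair_energy <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  unname(ifelse(key %in% names(e), e[key], 0))
}
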