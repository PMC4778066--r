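#' Clean raw sRNA reads
#'
#' Removes contaminant reads and trims the 3' adapter: reads with mean Phred
#' quality below `min_quality` or containing any `N` are discarded
#' ("low_quality"); the adapter is trimmed at the leftmost occurrence of its
#' first `seed_length` bases (reads without such a hit are kept whole); reads
#' whose insert falls outside `length_bounds` after trimming are discarded
#' ("length").
#'
#' @param fastq path to a FASTQ file (Sanger quality encoding).
#' @param adapter 3' adapter sequence (non-empty DNA string, >= `seed_length`
#'   nt).
#' @param min_quality minimum mean Phred quality (default 20).
#' @param length_bounds inclusive insert length bounds in nt (default
#'   c(18, 30)).
#' @param seed_length adapter prefix length used for matching (default 8).
#' @return list with `sequences` (character vector of clean inserts) and
#'   `stats`: `raw_reads`, `low_quality`, `length_out`, `clean_reads`
#'   (raw = clean + low_quality + length_out).
#' @export
clean_reads <- function(fastq, adapter, min_quality = 20,
                        length_bounds = c(18L, 30L), seed_length = 8L) {
  stopifnot(nchar(adapter) >= seed_length, length_bounds[1] <= length_bounds[2])
  adapter <- toupper(adapter)
  assert_alphabet(adapter, c("A", "C", "G", "T"), "adapter")
  bad <- validate_fastq(fastq)
  if (!is.na(bad)) {
    stop(sprintf("malformed FASTQ '%s' at record %d", fastq, bad),
         call. = FALSE)
  }
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  raw_n <- length(reads)
  if (raw_n == 0) {
    return(list(sequences = character(0),
                stats = list(raw_reads = 0L, low_quality = 0L,
                             length_out = 0L, clean_reads = 0L)))
  }
  seqs <- as.character(reads)
  mean_q <- vapply(as(Biostrings::quality(reads), "IntegerList"), mean, numeric(1))
  has_n <- grepl("N", seqs, fixed = TRUE)
  lowq <- mean_q < min_quality | has_n
  seqs <- seqs[!lowq]

  # trim at the leftmost adapter-prefix hit
  hit <- regexpr(substr(adapter, 1, seed_length), seqs, fixed = TRUE)
  trimmed <- ifelse(hit > 0, substr(seqs, 1, hit - 1), seqs)
  len_ok <- nchar(trimmed) >= length_bounds[1] & nchar(trimmed) <= length_bounds[2]

  list(sequences = trimmed[len_ok],
       stats = list(raw_reads = raw_n,
                    low_quality = sum(lowq),
                    length_out = sum(!len_ok),
                    clean_reads = sum(len_ok)))
}

# index of the first malformed FASTQ record, NA when the file is well-formed
validate_fastq <- function(fastq) {
  lines <- readLines(fastq, warn = FALSE)
  n <- length(lines)
  if (n == 0) return(NA_integer_)
  n4 <- n %/% 4
  if (n4 > 0) {
    hdr <- startsWith(lines[seq(1, by = 4, length.out = n4)], "@")
    sep <- startsWith(lines[seq(3, by = 4, length.out = n4)], "+")
    len_ok <- nchar(lines[seq(2, by = 4, length.out = n4)]) ==
      nchar(lines[seq(4, by = 4, length.out = n4)])
    bad <- which(!(hdr & sep & len_ok))
    if (length(bad) > 0) return(bad[1])
  }
  if (n %% 4 != 0) return(n4 + 1L)
  NA_integer_
}

#' Collapse clean reads to unique tags with per-library counts
#'
#' @param reads_ctl,reads_def character vectors of clean read sequences from
#'   the control and treatment libraries.
#' @return data.frame with `sequence`, `count_ctl`, `count_def`; one row per
#'   distinct sequence, counts summing to the clean read totals.
#' @export
collapse_tags <- function(reads_ctl, reads_def = character(0)) {
  seqs <- union(reads_ctl, reads_def)
  if (length(seqs) == 0) {
    return(data.frame(sequence = character(0), count_ctl = integer(0),
                      count_def = integer(0), stringsAsFactors = FALSE))
  }
  tc <- table(factor(reads_ctl, levels = seqs))
  td <- table(factor(reads_def, levels = seqs))
  out <- data.frame(sequence = seqs, count_ctl = as.integer(tc),
                    count_def = as.integer(td), stringsAsFactors = FALSE)
  out[order(out$sequence), , drop = FALSE]
}

#' Per-length tag and read accounting
#'
#' @param tags a [collapse_tags()] data.frame.
#' @return data.frame with one row per observed length: `length`,
#'   `unique_ctl`, `unique_def` (distinct tags with non-zero count),
#'   `total_ctl`, `total_def` (read counts) and the corresponding fractions
#'   of each library's totals (`NA` for an empty library).
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(0), unique_ctl = integer(0),
                      unique_def = integer(0), total_ctl = integer(0),
                      total_def = integer(0), frac_ctl = numeric(0),
                      frac_def = numeric(0)))
  }
  len <- nchar(tags$sequence)
  lv <- sort(unique(len))
  agg <- function(x) vapply(lv, function(l) sum(x[len == l]), numeric(1))
  total_ctl <- agg(tags$count_ctl)
  total_def <- agg(tags$count_def)
  data.frame(length = lv,
             unique_ctl = agg(as.integer(tags$count_ctl > 0)),
             unique_def = agg(as.integer(tags$count_def > 0)),
             total_ctl = as.integer(total_ctl),
             total_def = as.integer(total_def),
             frac_ctl = if (sum(total_ctl) > 0) total_ctl / sum(total_ctl) else NA_real_,
             frac_def = if (sum(total_def) > 0) total_def / sum(total_def) else NA_real_)
}

#' Write collapsed tags as a counts-in-header FASTA
#'
#' Headers carry per-library counts as `tag<N>_x<count_ctl>_y<count_def>`.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  ids <- sprintf("tag%d_x%d_y%d", seq_len(nrow(tags)), tags$count_ctl,
                 tags$count_def)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(tags$sequence, ids)), path)
  invisible(path)
}
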