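#' Hairpin-acceptance parameter set for novel miRNA prediction
#'
#' The Mireap-style criteria a candidate precursor must satisfy: mature
#' length bounds, star-arm length bounds, a cap on the number of genomic loci
#' a tag may have, the maximum precursor folding energy, the maximum distance
#' between the miRNA and its star partner, and the duplex criteria (minimum
#' paired bases, maximum bulge, maximum asymmetry). `flank` is the genomic
#' flank added around the candidate precursor.
#'
#' @param min_mature,max_mature mature length bounds in nt (18, 25).
#' @param min_star,max_star star/reference arm length bounds in nt (20, 23).
#' @param max_copy maximum genomic loci per tag (20).
#' @param max_mfe maximum precursor folding energy in kcal/mol (-18).
#' @param max_gap maximum distance between miRNA and miRNA* in nt (300).
#' @param min_pair minimum base pairs in the miRNA/miRNA* duplex (16).
#' @param max_bulge maximum bulge size in the duplex in nt (4).
#' @param max_asym maximum duplex asymmetry in nt (4).
#' @param flank precursor flank length in nt (20).
#' @return list of class `mireap_params`.
#' @export
mireap_params <- function(min_mature = 18L, max_mature = 25L,
                          min_star = 20L, max_star = 23L,
                          max_copy = 20L, max_mfe = -18,
                          max_gap = 300L, min_pair = 16L,
                          max_bulge = 4L, max_asym = 4L, flank = 20L) {
  structure(list(min_mature = min_mature, max_mature = max_mature,
                 min_star = min_star, max_star = max_star,
                 max_copy = max_copy, max_mfe = max_mfe, max_gap = max_gap,
                 min_pair = min_pair, max_bulge = max_bulge,
                 max_asym = max_asym, flank = flank),
            class = "mireap_params")
}

#' Fold a candidate precursor and evaluate the hairpin criteria
#'
#' Folds the precursor with the supplied engine, locates the miRNA* arm as
#' the duplex partner of the mature sequence with 2-nt 3' overhangs on both
#' arms (the Dicer signature, read from the fold's pair table), and computes
#' the duplex diagnostics: paired bases between the arms, the largest bulge
#' on either arm, the duplex asymmetry (sum over internal loops of the
#' absolute left/right size difference) and the miRNA-to-star gap.
#'
#' @param precursor DNA or RNA precursor sequence.
#' @param mature_start,mature_end 1-based mature coordinates on the precursor.
#' @param params a [mireap_params()].
#' @param engine folding engine, any function with the [fold()] contract.
#' @return list with `fold`, `star_start`, `star_end`, `star_seq` (DNA),
#'   `arm`, `duplex_paired_bases`, `duplex_bulge_max`, `duplex_asymmetry`,
#'   `mature_star_gap`, `mfe`, `accepted` (logical) and `reasons` (character
#'   vector of failed criteria, empty when accepted).
#' @export
hairpin_diagnostics <- function(precursor, mature_start, mature_end,
                                params = mireap_params(), engine = fold) {
  fr <- engine(precursor)
  pairs <- if (!is.null(fr$pairs)) fr$pairs else structure_pairs(fr$structure)
  n <- nchar(fr$sequence)
  i1 <- mature_start; i2 <- mature_end
  fail <- function(why) {
    list(fold = fr, star_start = NA, star_end = NA, star_seq = NA_character_,
         arm = NA_character_, duplex_paired_bases = 0L,
         duplex_bulge_max = NA_integer_, duplex_asymmetry = NA_integer_,
         mature_star_gap = NA_integer_, mfe = fr$mfe, accepted = FALSE,
         reasons = why)
  }
  mlen <- i2 - i1 + 1L
  reasons <- character(0)
  if (mlen < params$min_mature || mlen > params$max_mature) {
    return(fail("mature_length"))
  }
  # anchor pairs for the 2-nt 3' overhang duplex geometry
  mpos <- i1:i2
  paired_m <- mpos[pairs[mpos] > 0 & (pairs[mpos] < i1 | pairs[mpos] > i2)]
  lead <- paired_m[paired_m >= i1]
  trail <- paired_m[paired_m <= i2 - 2L]
  if (length(lead) == 0 || length(trail) == 0) return(fail("no_duplex"))
  a2 <- min(lead)
  b2 <- max(trail)
  if (b2 < a2) return(fail("no_duplex"))
  star_lo <- pairs[b2]
  star_hi <- min(n, pairs[a2] + 2L + (a2 - i1))
  if (star_lo > star_hi) { tmp <- star_lo; star_lo <- star_hi; star_hi <- tmp }
  star_len <- star_hi - star_lo + 1L
  arm <- if (star_lo > i2) "5p" else "3p"

  dpairs <- mpos[pairs[mpos] >= star_lo & pairs[mpos] <= star_hi]
  npair <- length(dpairs)
  bulge_max <- 0L; asym <- 0L
  if (npair >= 2) {
    p <- dpairs
    q <- pairs[p]
    gapL <- diff(p) - 1L
    gapR <- abs(diff(q)) - 1L
    bulge_max <- max(gapL, gapR)
    asym <- sum(abs(gapL - gapR))
  }
  gap <- if (arm == "5p") star_lo - i2 - 1L else i1 - star_hi - 1L

  if (fr$mfe > params$max_mfe) reasons <- c(reasons, "mfe")
  if (npair < params$min_pair) reasons <- c(reasons, "min_pair")
  if (bulge_max > params$max_bulge) reasons <- c(reasons, "bulge")
  if (asym > params$max_asym) reasons <- c(reasons, "asymmetry")
  if (star_len < params$min_star || star_len > params$max_star) {
    reasons <- c(reasons, "star_length")
  }
  if (gap < 0 || gap > params$max_gap) reasons <- c(reasons, "gap")

  list(fold = fr,
       star_start = star_lo, star_end = star_hi,
       star_seq = rna_to_dna(substr(fr$sequence, star_lo, star_hi)),
       arm = arm,
       duplex_paired_bases = npair,
       duplex_bulge_max = bulge_max,
       duplex_asymmetry = asym,
       mature_star_gap = gap,
       mfe = fr$mfe,
       accepted = length(reasons) == 0L,
       reasons = reasons)
}

#' Retain tags within the mature miRNA length bounds
#'
#' @param tags data.frame with a `sequence` column (or character vector).
#' @param bounds length bounds in nt, inclusive.
#' @return the retained tags.
#' @export
filter_mature_length <- function(tags, bounds = c(18L, 25L)) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  keep <- nchar(seqs) >= bounds[1] & nchar(seqs) <= bounds[2]
  if (is.data.frame(tags)) tags[keep, , drop = FALSE] else tags[keep]
}

#' Predict novel miRNA hairpin candidates from unannotated mapped tags
#'
#' For every genomic locus of every candidate tag (length within the mature
#' bounds, at most `max_copy` loci), windows extending up to the maximum
#' miRNA/miRNA* gap on either side are extracted, folded, and examined for a
#' hairpin in which the tag forms a Dicer-style duplex (2-nt 3' overhangs)
#' with a star arm. The precursor is then re-extracted around the
#' mature/star span with `flank`-nt genomic flanks, re-folded, and accepted
#' only if every criterion of [mireap_params()] holds. Candidates are
#' deduplicated by precursor locus.
#'
#' @param tags data.frame with `sequence`, `count_ctl`, `count_def`.
#' @param hits genomic hits as returned by [map_perfect()].
#' @param genome `DNAStringSet` or path to a genome FASTA.
#' @param params a [mireap_params()].
#' @param engine folding engine with the [fold()] contract.
#' @return data.frame with one row per accepted candidate: `id`, `sequence`
#'   (mature, DNA), `count_ctl`, `count_def`, `chrom`, `precursor_start`,
#'   `precursor_end`, `strand`, `arm`, `mature_start`, `mature_end`, `star`,
#'   `mfe`, `duplex_paired_bases`, `duplex_bulge_max`, `duplex_asymmetry`,
#'   `mature_star_gap`, `structure`.
#' @export
predict_novel <- function(tags, hits, genome, params = mireap_params(),
                          engine = fold) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  tags <- filter_mature_length(tags, c(params$min_mature, params$max_mature))
  hits <- hits[hits$sequence %in% tags$sequence, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_candidates())
  copies <- table(hits$sequence)
  keep <- names(copies)[copies <= params$max_copy]
  hits <- hits[hits$sequence %in% keep, , drop = FALSE]

  out <- list()
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    cand <- evaluate_locus(h, tags, genome, params, engine)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0) return(empty_candidates())
  res <- do.call(rbind, out)
  # deduplicate by locus: candidates with overlapping precursors are the same
  # hairpin (a perfect inverted repeat is recovered from both strands); the
  # lowest-MFE candidate of each cluster is kept
  gr <- GenomicRanges::GRanges(res$chrom,
                               IRanges::IRanges(res$precursor_start,
                                                res$precursor_end))
  cl <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr, ignore.strand = TRUE),
                                ignore.strand = TRUE))
  keep <- vapply(split(seq_len(nrow(res)), cl), function(idx) {
    idx[which.min(res$mfe[idx])]
  }, integer(1))
  res <- res[sort(keep), , drop = FALSE]
  res <- res[order(res$chrom, res$precursor_start), , drop = FALSE]
  rownames(res) <- NULL
  res$id <- sprintf("novel_mir_%d", seq_len(nrow(res)))
  res[c("id", setdiff(names(res), "id"))]
}

empty_candidates <- function() {
  data.frame(id = character(0), sequence = character(0),
             count_ctl = integer(0), count_def = integer(0),
             chrom = character(0), precursor_start = integer(0),
             precursor_end = integer(0), strand = character(0),
             arm = character(0), mature_start = integer(0),
             mature_end = integer(0), star = character(0), mfe = numeric(0),
             duplex_paired_bases = integer(0), duplex_bulge_max = integer(0),
             duplex_asymmetry = integer(0), mature_star_gap = integer(0),
             structure = character(0), stringsAsFactors = FALSE)
}

# examine one genomic hit of one tag; returns a candidate row or NULL
evaluate_locus <- function(h, tags, genome, params, engine) {
  chrom_seq <- genome[[h$chrom]]
  clen <- length(chrom_seq)
  tagrow <- tags[match(h$sequence, tags$sequence), ]
  for (ext in c(60L, 150L, params$max_gap + params$flank)) {
    for (side in c("down", "up")) {
      ws <- max(1L, h$start - if (side == "down") params$flank else ext)
      we <- min(clen, h$end + if (side == "down") ext else params$flank)
      wseq <- as.character(Biostrings::subseq(chrom_seq, ws, we))
      if (h$strand == "+") {
        m1 <- h$start - ws + 1L
      } else {
        wseq <- revcomp(wseq)
        m1 <- we - h$end + 1L
      }
      m2 <- m1 + nchar(h$sequence) - 1L
      d <- hairpin_diagnostics(wseq, m1, m2, params, engine)
      if (!d$accepted) next
      # re-extract precursor = mature/star span plus flanks, re-verify
      lo <- max(1L, min(m1, d$star_start) - params$flank)
      hi <- min(nchar(wseq), max(m2, d$star_end) + params$flank)
      pseq <- substr(wseq, lo, hi)
      d2 <- hairpin_diagnostics(pseq, m1 - lo + 1L, m2 - lo + 1L, params, engine)
      if (!d2$accepted) next
      if (h$strand == "+") {
        ps <- ws + lo - 1L
        pe <- ws + hi - 1L
      } else {
        ps <- we - hi + 1L
        pe <- we - lo + 1L
      }
      return(data.frame(
        sequence = h$sequence,
        count_ctl = tagrow$count_ctl, count_def = tagrow$count_def,
        chrom = h$chrom, precursor_start = ps, precursor_end = pe,
        strand = h$strand, arm = d2$arm,
        mature_start = h$start, mature_end = h$end,
        star = d2$star_seq, mfe = d2$mfe,
        duplex_paired_bases = d2$duplex_paired_bases,
        duplex_bulge_max = d2$duplex_bulge_max,
        duplex_asymmetry = d2$duplex_asymmetry,
        mature_star_gap = d2$mature_star_gap,
        structure = d2$fold$structure,
        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Export hairpin candidates as GFF3
#'
#' Writes precursor, mature and star features (1-based inclusive) for each
#' candidate.
#'
#' @param candidates output of [predict_novel()].
#' @param path output GFF3 path.
#' @return the path, invisibly.
#' @export
candidates_to_gff <- function(candidates, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    lines <- c(lines,
      sprintf("%s\tsrnamir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
              cc$chrom, cc$precursor_start, cc$precursor_end, cc$strand, cc$id),
      sprintf("%s\tsrnamir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
              cc$chrom, cc$mature_start, cc$mature_end, cc$strand, cc$id, cc$id))
  }
  writeLines(lines, path)
  invisible(path)
}
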