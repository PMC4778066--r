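#' Map tags to the genome by perfect match
#'
#' Reports every exact-match locus of every tag on both strands of the
#' genome. Coordinates are 1-based inclusive; minus-strand hits are reported
#' on plus-strand coordinates with `strand = "-"`.
#'
#' @param tags a [collapse_tags()] data.frame or character vector of tag
#'   sequences.
#' @param genome `DNAStringSet` or path to a genome FASTA.
#' @return data.frame with `sequence`, `chrom`, `start`, `end`, `strand`.
#' @export
map_perfect <- function(tags, genome) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (length(seqs) == 0) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (w in sort(unique(nchar(seqs)))) {
    group <- seqs[nchar(seqs) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(group))
    for (chrom in names(genome)) {
      subject <- genome[[chrom]]
      clen <- length(subject)
      mplus <- Biostrings::matchPDict(pd, subject)
      mminus <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subject))
      for (k in seq_along(group)) {
        sp <- IRanges::start(mplus[[k]])
        if (length(sp) > 0) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = group[k], chrom = chrom, start = sp, end = sp + w - 1L,
            strand = "+", stringsAsFactors = FALSE)
        }
        sm <- IRanges::start(mminus[[k]])
        if (length(sm) > 0) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = group[k], chrom = chrom,
            start = clen - (sm + w - 1L) + 1L, end = clen - sm + 1L,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(match(res$sequence, seqs), res$chrom, res$start), , drop = FALSE]
}

#' Assign tags to known mature miRNAs
#'
#' Ungapped same-length comparison of every tag against a mature miRNA
#' reference: a tag is assigned to the reference sequence with the fewest
#' mismatches, provided that number does not exceed `max_mismatches`. Ties
#' are broken by reference order. The reference may be in the RNA alphabet
#' (miRBase convention); tags are compared in the DNA alphabet.
#'
#' @param tags a [collapse_tags()] data.frame or character vector.
#' @param mature `RNAStringSet`/`DNAStringSet`, named character vector, or
#'   path to a mature miRNA FASTA.
#' @param max_mismatches maximum mismatches for an assignment (default 2).
#' @return data.frame with `sequence`, `mirna_id`, `mismatches`, one row per
#'   assigned tag.
#' @export
match_known_mirnas <- function(tags, mature, max_mismatches = 2L) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  if (is.character(mature) && length(mature) == 1 && file.exists(mature)) {
    mature <- Biostrings::readBStringSet(mature)
  }
  ref_ids <- names(mature)
  ref <- rna_to_dna(toupper(unname(as.character(mature))))
  if (is.null(ref_ids)) ref_ids <- sprintf("mirna_%d", seq_along(ref))
  empty <- data.frame(sequence = character(0), mirna_id = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0 || length(ref) == 0) return(empty)
  out <- list()
  for (w in sort(unique(nchar(seqs)))) {
    ridx <- which(nchar(ref) == w)
    if (length(ridx) == 0) next
    tgroup <- seqs[nchar(seqs) == w]
    rmat <- do.call(rbind, strsplit(unname(ref[ridx]), ""))
    tmat <- do.call(rbind, strsplit(tgroup, ""))
    for (k in seq_along(tgroup)) {
      mm <- rowSums(rmat != matrix(tmat[k, ], nrow(rmat), w, byrow = TRUE))
      best <- which.min(mm)
      if (mm[best] <= max_mismatches) {
        out[[length(out) + 1L]] <- data.frame(
          sequence = tgroup[k], mirna_id = ref_ids[ridx[best]],
          mismatches = as.integer(mm[best]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(match(res$sequence, seqs)), , drop = FALSE]
}

#' Sum tag counts per assigned known miRNA
#'
#' @param assignments output of [match_known_mirnas()].
#' @param tags a [collapse_tags()] data.frame.
#' @return data.frame with `id`, `x` (control count), `y` (treatment count).
#' @export
mirna_counts <- function(assignments, tags) {
  m <- merge(assignments, tags, by = "sequence")
  if (nrow(m) == 0) {
    return(data.frame(id = character(0), x = integer(0), y = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(x = m$count_ctl, y = m$count_def),
                          by = list(id = m$mirna_id), FUN = sum)
  agg[order(agg$id), , drop = FALSE]
}

#' Load gene models from GFF3 and derive introns
#'
#' @param gff path to a GFF3 file with `gene` and `exon` features.
#' @return list of `GRanges`: `exons` and `introns`, both carrying gene
#'   strand. A feature without strand raises an error.
#' @export
load_gene_models <- function(gff) {
  gr <- rtracklayer::import(gff)
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    stop("GFF feature without strand", call. = FALSE)
  }
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  introns <- GenomicRanges::GRanges()
  for (i in seq_along(genes)) {
    g <- genes[i]
    ex <- exons[S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(g, exons, type = "any"))]
    intr <- GenomicRanges::setdiff(g, ex, ignore.strand = FALSE)
    introns <- c(introns, intr)
  }
  list(exons = exons, introns = introns)
}

# do any of the tag's hits overlap the given ranges? returns per-sequence
# logical for same/opposite strand
hits_overlap <- function(hits, ranges, same_strand = NULL) {
  if (nrow(hits) == 0 || length(ranges) == 0) return(rep(FALSE, nrow(hits)))
  hgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start, hits$end),
                                strand = hits$strand)
  ov <- GenomicRanges::findOverlaps(hgr, ranges, ignore.strand = TRUE)
  keep <- rep(FALSE, nrow(hits))
  if (length(ov) > 0 && !is.null(same_strand)) {
    hs <- as.character(GenomicRanges::strand(hgr))[S4Vectors::queryHits(ov)]
    rs <- as.character(GenomicRanges::strand(ranges))[S4Vectors::subjectHits(ov)]
    ok <- if (same_strand) hs == rs else hs != rs
    keep[unique(S4Vectors::queryHits(ov)[ok])] <- TRUE
  } else {
    keep[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  keep
}

# is each tag a substring of any reference sequence (either strand)?
contained_in_reference <- function(seqs, refs) {
  if (length(seqs) == 0 || length(refs) == 0) return(rep(FALSE, length(seqs)))
  refs <- as.character(refs)
  hay <- paste(c(refs, revcomp(refs)), collapse = "|")
  vapply(seqs, function(s) grepl(s, hay, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' Annotate tags by the priority cascade
#'
#' Classifies every tag into exactly one category by the first matching stage
#' of the cascade: non-coding RNA classes (rRNA > tRNA > snRNA > snoRNA, by
#' substring containment in the class reference on either strand) > known
#' miRNA (by reference assignment) > repeat (genomic hit in a repeat
#' interval) > exon > intron (split into sense/antisense by strand agreement
#' with the gene model). Tags matching nothing are `unannotated`.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param hits genomic hits from [map_perfect()].
#' @param ncrna named list of references per class (`rRNA`, `tRNA`, `snRNA`,
#'   `snoRNA`), each a `DNAStringSet`, character vector or FASTA path.
#' @param mirna_assignments output of [match_known_mirnas()].
#' @param repeats `GRanges` or path to a BED file (0-based half-open) of
#'   repeat intervals.
#' @param gene_models output of [load_gene_models()] (or a GFF3 path).
#' @param require_genome_hit_for_mirna if `TRUE`, a tag needs a perfect
#'   genomic hit in addition to a reference assignment to be counted as a
#'   known miRNA (default `FALSE`: assignment alone suffices, since the
#'   genome may lack loci for some conserved families).
#' @return data.frame with `sequence`, `count_ctl`, `count_def`, `category`,
#'   `evidence`, `n_hits`.
#' @export
annotate_cascade <- function(tags, hits, ncrna, mirna_assignments,
                             repeats, gene_models,
                             require_genome_hit_for_mirna = FALSE) {
  n <- nrow(tags)
  category <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)
  n_hits <- as.integer(table(factor(hits$sequence, levels = tags$sequence)))
  unassigned <- function() is.na(category)

  load_ref <- function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r)) {
      as.character(Biostrings::readDNAStringSet(r))
    } else as.character(r)
  }
  for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    if (is.null(ncrna[[cls]])) next
    idx <- which(unassigned())
    hit <- contained_in_reference(tags$sequence[idx], load_ref(ncrna[[cls]]))
    category[idx[hit]] <- cls
    evidence[idx[hit]] <- cls
  }

  mir_ok <- tags$sequence %in% mirna_assignments$sequence
  if (require_genome_hit_for_mirna) mir_ok <- mir_ok & n_hits > 0
  sel <- unassigned() & mir_ok
  category[sel] <- "known_miRNA"
  evidence[sel] <- mirna_assignments$mirna_id[
    match(tags$sequence[sel], mirna_assignments$sequence)]

  if (is.character(repeats)) repeats <- rtracklayer::import(repeats)
  if (is.character(gene_models)) gene_models <- load_gene_models(gene_models)

  stage_overlap <- function(ranges, label, same_strand = NULL) {
    idx <- which(unassigned())
    if (length(idx) == 0) return(invisible())
    h <- hits[hits$sequence %in% tags$sequence[idx], , drop = FALSE]
    if (nrow(h) == 0) return(invisible())
    ov <- hits_overlap(h, ranges, same_strand)
    matched <- unique(h$sequence[ov])
    sel <- unassigned() & tags$sequence %in% matched
    category[sel] <<- label
    evidence[sel] <<- label
  }
  stage_overlap(repeats, "repeat")
  stage_overlap(gene_models$exons, "exon_sense", same_strand = TRUE)
  stage_overlap(gene_models$exons, "exon_antisense", same_strand = FALSE)
  stage_overlap(gene_models$introns, "intron_sense", same_strand = TRUE)
  stage_overlap(gene_models$introns, "intron_antisense", same_strand = FALSE)

  category[unassigned()] <- "unannotated"
  data.frame(sequence = tags$sequence, count_ctl = tags$count_ctl,
             count_def = tags$count_def, category = category,
             evidence = evidence, n_hits = n_hits, stringsAsFactors = FALSE)
}

#' Percentage of clean reads, as reported in sequencing summaries
#'
#' @param count category count(s).
#' @param clean clean-read total of the library.
#' @return `count / clean * 100` rounded to 2 decimals; `NA` when `clean` is
#'   zero.
#' @export
category_percentage <- function(count, clean) {
  ifelse(clean > 0, round(count / clean * 100, 2), NA_real_)
}

#' Summarize annotation into a sequencing-statistics table
#'
#' Produces the standard per-category accounting of an sRNA library pair:
#' unique tag and total read counts, with percentages of the clean totals
#' (rounded to two decimals), for mapped-to-genome, every annotation category
#' and unannotated tags.
#'
#' @param records output of [annotate_cascade()].
#' @return data.frame with `row` (category), `unique_ctl`, `unique_pct_ctl`,
#'   `total_ctl`, `total_pct_ctl` and the `_def` equivalents.
#' @export
summarize_table1 <- function(records) {
  cats <- c("exon_antisense", "exon_sense", "intron_antisense", "intron_sense",
            "known_miRNA", "rRNA", "repeat", "snRNA", "snoRNA", "tRNA",
            "unannotated")
  count_for <- function(sel, cnt) {
    c(unique = sum(cnt[sel] > 0), total = sum(cnt[sel]))
  }
  rows <- c("clean", "mapped_to_genome", cats)
  mk <- function(cnt) {
    clean <- count_for(rep(TRUE, nrow(records)), cnt)
    mapped <- count_for(records$n_hits > 0, cnt)
    per_cat <- vapply(cats, function(cc) count_for(records$category == cc, cnt),
                      numeric(2))
    rbind(clean, mapped, t(per_cat))
  }
  m_ctl <- mk(records$count_ctl)
  m_def <- mk(records$count_def)
  data.frame(row = rows,
             unique_ctl = as.integer(m_ctl[, "unique"]),
             unique_pct_ctl = category_percentage(m_ctl[, "unique"], m_ctl[1, "unique"]),
             total_ctl = as.integer(m_ctl[, "total"]),
             total_pct_ctl = category_percentage(m_ctl[, "total"], m_ctl[1, "total"]),
             unique_def = as.integer(m_def[, "unique"]),
             unique_pct_def = category_percentage(m_def[, "unique"], m_def[1, "unique"]),
             total_def = as.integer(m_def[, "total"]),
             total_pct_def = category_percentage(m_def[, "total"], m_def[1, "total"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
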