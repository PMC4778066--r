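#' Specification for a synthetic toy genome
#'
#' Describes the composition of a small artificial genome carrying every
#' feature class the annotation cascade distinguishes: known-miRNA hairpin
#' precursors, novel hairpin precursors, non-coding RNA loci (rRNA, tRNA,
#' snRNA, snoRNA), protein-coding genes with exons and introns, and repeat
#' loci. [build_genome()] materializes the spec into FASTA/GFF3/BED files
#' plus a ground-truth table, so every downstream pipeline stage can be
#' tested without any external download.
#'
#' @param genome_length genome length in nt (single chromosome).
#' @param n_known_mirnas number of hairpin precursors whose mature sequence is
#'   included in the bundled known-miRNA reference.
#' @param n_novel_hairpins number of hairpin precursors absent from the
#'   known-miRNA reference (ground truth for novel-miRNA prediction).
#' @param n_ncrna_fragments named integer vector with elements `rRNA`, `tRNA`,
#'   `snRNA`, `snoRNA`: number of loci per non-coding RNA class.
#' @param n_genes number of genes; each has two exons and one intron.
#' @param n_repeats number of repeat loci (BED annotated).
#' @param n_unmappable number of read sequences absent from the genome
#'   (sequencing background).
#' @param flank_gc GC fraction of the random background sequence.
#' @param seed integer seed; identical spec + seed gives byte-identical output.
#' @return list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_length = 60000,
                                  n_known_mirnas = 12,
                                  n_novel_hairpins = 6,
                                  n_ncrna_fragments = c(rRNA = 3, tRNA = 3,
                                                        snRNA = 2, snoRNA = 2),
                                  n_genes = 6,
                                  n_repeats = 3,
                                  n_unmappable = 5,
                                  flank_gc = 0.5,
                                  seed = 1L) {
  ncl <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  if (!all(ncl %in% names(n_ncrna_fragments))) {
    stop("n_ncrna_fragments must name rRNA, tRNA, snRNA and snoRNA", call. = FALSE)
  }
  counts <- c(n_known_mirnas, n_novel_hairpins, n_ncrna_fragments[ncl],
              n_genes, n_repeats, n_unmappable)
  if (any(counts < 0)) stop("all feature counts must be >= 0", call. = FALSE)
  stopifnot(genome_length > 0, flank_gc >= 0, flank_gc <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 n_known_mirnas = as.integer(n_known_mirnas),
                 n_novel_hairpins = as.integer(n_novel_hairpins),
                 n_ncrna_fragments = vapply(n_ncrna_fragments[ncl], as.integer,
                                            integer(1)),
                 n_genes = as.integer(n_genes),
                 n_repeats = as.integer(n_repeats),
                 n_unmappable = as.integer(n_unmappable),
                 flank_gc = flank_gc, seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# random DNA string(s)
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Build an inverted-repeat precursor: a perfect stem of (ext + mature) base
# pairs closed by a short loop. With >= 22 paired positions and no bulges the
# hairpin satisfies the duplex criteria by construction, and its MFE under
# the default stacked-pair model is far below the -18 kcal/mol cutoff.
build_hairpin <- function(mature, arm = c("5p", "3p"), ext = 5L,
                          loop_len = 10L) {
  arm <- match.arg(arm)
  ext_seq <- random_dna(1, ext)
  loop <- random_dna(1, loop_len, gc = 0.2)  # AT-rich loop folds poorly
  if (arm == "5p") {
    upstream <- paste0(ext_seq, mature)
    precursor <- paste0(upstream, loop, revcomp(upstream))
    mstart <- ext + 1L
  } else {
    upstream <- paste0(ext_seq, revcomp(mature))
    precursor <- paste0(upstream, loop, revcomp(upstream))
    mstart <- nchar(upstream) + loop_len + 1L
  }
  list(precursor = precursor, mature = mature, arm = arm,
       mature_start = mstart, mature_end = mstart + nchar(mature) - 1L)
}

#' Build a synthetic genome bundle
#'
#' Places every feature of a [synthetic_genome_spec()] at a random
#' non-overlapping locus on a random background chromosome and writes the
#' reference files a real analysis would take as input: genome FASTA, mature
#' known-miRNA FASTA (RNA alphabet), one FASTA per non-coding RNA class, gene
#' models as GFF3, repeats as BED (0-based half-open), spliced transcript
#' FASTA for target scanning, a toy gene-to-GO mapping, and a ground-truth
#' TSV recording every feature's class, locus, emitted read tag and (for
#' hairpins) precursor/mature coordinates and arm. Each transcript of the
#' first `min(n_genes, n_known_mirnas)` genes carries a perfect complementary
#' target site for the corresponding known miRNA.
#'
#' Every hairpin is re-folded at build time and checked against the hairpin
#' acceptance criteria; construction failure or feature overflow raises an
#' error naming the feature class.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param dir output directory (created if needed).
#' @return list of class `genome_bundle` with file paths (`genome_fasta`,
#'   `mature_fasta`, `ncrna_fastas`, `gff`, `repeat_bed`, `transcript_fasta`,
#'   `go_tsv`, `truth_tsv`), the genome as a `DNAStringSet`, and the truth
#'   table as a data.frame.
#' @export
build_genome <- function(spec, dir = tempfile("bundle")) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, "build_genome"))

  feats <- list()   # per feature: id, class, seq (plus-strand insert), extras
  add_feat <- function(id, class, seq, tag, strand, extra = list()) {
    feats[[length(feats) + 1L]] <<- c(list(id = id, class = class, seq = seq,
                                           tag = tag, strand = strand), extra)
  }

  used_tags <- character(0)
  new_mature <- function() {
    repeat {
      m <- random_dna(1, 21)
      if (!m %in% used_tags) {
        used_tags <<- c(used_tags, m)
        return(m)
      }
    }
  }

  # hairpin precursors (known + novel)
  n_hp <- spec$n_known_mirnas + spec$n_novel_hairpins
  for (i in seq_len(n_hp)) {
    known <- i <= spec$n_known_mirnas
    id <- if (known) sprintf("csi-miR%04d", i) else sprintf("hairpin-novel-%02d", i - spec$n_known_mirnas)
    repeat {
      hp <- build_hairpin(new_mature(), arm = sample(c("5p", "3p"), 1))
      diag <- hairpin_diagnostics(hp$precursor, hp$mature_start, hp$mature_end)
      if (diag$accepted) break
    }
    strand <- sample(c("+", "-"), 1)
    add_feat(id, if (known) "known_miRNA" else "novel_hairpin",
             hp$precursor, hp$mature, strand,
             list(arm = hp$arm, mature_offset = hp$mature_start,
                  star = diag$star_seq))
  }

  # ncRNA loci; the emitted tag is an internal fragment of the reference
  nc_len <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 80L)
  for (cls in names(spec$n_ncrna_fragments)) {
    for (i in seq_len(spec$n_ncrna_fragments[[cls]])) {
      s <- random_dna(1, nc_len[[cls]], gc = spec$flank_gc)
      off <- sample(10:(nc_len[[cls]] - 35), 1)
      tag <- substr(s, off, off + sample(20:24, 1) - 1L)
      add_feat(sprintf("%s-%02d", cls, i), cls, s, tag, sample(c("+", "-"), 1))
    }
  }

  # genes: exon1 - intron - exon2; transcript = exon1 + exon2
  exon_len <- 200L; intron_len <- 150L
  for (i in seq_len(spec$n_genes)) {
    e1 <- random_dna(1, exon_len, gc = spec$flank_gc)
    e2 <- random_dna(1, exon_len, gc = spec$flank_gc)
    if (i <= spec$n_known_mirnas) {
      # embed a perfect target site for known miRNA i mid-exon2
      site <- revcomp(feats[[i]]$tag)
      substr(e2, 90, 90 + nchar(site) - 1L) <- site
    }
    intr <- random_dna(1, intron_len, gc = spec$flank_gc)
    gseq <- paste0(e1, intr, e2)
    # one exon tag and one intron tag per gene; every third gene antisense
    anti <- i %% 3L == 0L
    toff <- sample(20:(exon_len - 45), 1)
    etag <- substr(e1, toff, toff + 20L)
    ioff <- sample(10:(intron_len - 35), 1)
    itag <- substr(intr, ioff, ioff + 20L)
    if (anti) { etag <- revcomp(etag); itag <- revcomp(itag) }
    strand <- sample(c("+", "-"), 1)
    add_feat(sprintf("gene-%02d", i), if (anti) "exon_antisense" else "exon_sense",
             gseq, etag, strand,
             list(exon_len = exon_len, intron_len = intron_len,
                  transcript = paste0(e1, e2),
                  intron_tag = itag,
                  intron_class = if (anti) "intron_antisense" else "intron_sense",
                  target_of = if (i <= spec$n_known_mirnas) feats[[i]]$id else NA_character_))
  }

  # repeats
  for (i in seq_len(spec$n_repeats)) {
    s <- random_dna(1, 60, gc = spec$flank_gc)
    tag <- substr(s, 15, 36)
    add_feat(sprintf("repeat-%02d", i), "repeat", s, tag, "+")
  }

  # place features on a random background without overlap
  genome <- strsplit(random_dna(1, spec$genome_length, gc = spec$flank_gc), "")[[1]]
  occupied <- matrix(numeric(0), ncol = 2)
  place <- function(len, class) {
    for (try in seq_len(1000)) {
      s <- sample(seq_len(spec$genome_length - len - 1L), 1)
      e <- s + len - 1L
      if (nrow(occupied) == 0 ||
          all(e + 5 < occupied[, 1] | s - 5 > occupied[, 2])) {
        occupied <<- rbind(occupied, c(s, e))
        return(c(s, e))
      }
    }
    stop(sprintf("cannot place feature of class '%s': genome too small", class),
         call. = FALSE)
  }
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    loc <- place(nchar(f$seq), f$class)
    insert <- if (f$strand == "+") f$seq else revcomp(f$seq)
    genome[loc[1]:loc[2]] <- strsplit(insert, "")[[1]]
    feats[[k]]$start <- loc[1]
    feats[[k]]$end <- loc[2]
  }
  genome_str <- paste(genome, collapse = "")
  genome_set <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))

  # unmappable background tags (verified absent from either strand)
  for (i in seq_len(spec$n_unmappable)) {
    repeat {
      tag <- random_dna(1, 21)
      if (!grepl(tag, genome_str, fixed = TRUE) &&
          !grepl(revcomp(tag), genome_str, fixed = TRUE)) break
    }
    add_feat(sprintf("unmapped-%02d", i), "unmapped", NA_character_, tag, "+")
  }

  # ---- write reference files -------------------------------------------------
  paths <- list(genome_fasta = file.path(dir, "genome.fa"),
                mature_fasta = file.path(dir, "mature_mirna.fa"),
                gff = file.path(dir, "genes.gff3"),
                repeat_bed = file.path(dir, "repeats.bed"),
                transcript_fasta = file.path(dir, "transcripts.fa"),
                go_tsv = file.path(dir, "gene2go.tsv"),
                truth_tsv = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(genome_set, paths$genome_fasta)

  is_cls <- function(cl) vapply(feats, function(f) f$class == cl, logical(1))
  known <- feats[is_cls("known_miRNA")]
  mat <- Biostrings::RNAStringSet(stats::setNames(
    dna_to_rna(vapply(known, `[[`, character(1), "tag")),
    vapply(known, `[[`, character(1), "id")))
  Biostrings::writeXStringSet(mat, paths$mature_fasta)

  paths$ncrna_fastas <- list()
  for (cls in names(spec$n_ncrna_fragments)) {
    fs <- feats[is_cls(cls)]
    p <- file.path(dir, paste0(tolower(cls), ".fa"))
    seqs <- Biostrings::DNAStringSet(stats::setNames(
      vapply(fs, `[[`, character(1), "seq"),
      vapply(fs, `[[`, character(1), "id")))
    Biostrings::writeXStringSet(seqs, p)
    paths$ncrna_fastas[[cls]] <- p
  }

  genes <- feats[is_cls("exon_sense") | is_cls("exon_antisense")]
  gff_lines <- c("##gff-version 3")
  tx <- character(0)
  go_rows <- list()
  go_terms <- list(
    `biological process` = c("response to stress", "transport",
                             "regulation of transcription"),
    `molecular function` = c("transcription factor activity",
                             "nucleic acid binding"),
    `cellular component` = c("nucleus", "membrane", "chloroplast"))
  for (g in genes) {
    e1 <- c(g$start, g$start + g$exon_len - 1L)
    intr <- c(e1[2] + 1L, e1[2] + g$intron_len)
    e2 <- c(intr[2] + 1L, g$end)
    if (g$strand == "-") {
      flip <- function(iv) c(g$start + g$end - iv[2], g$start + g$end - iv[1])
      tmp <- flip(e1); e1 <- flip(e2); e2 <- tmp; intr <- flip(intr)
    }
    gff_lines <- c(gff_lines,
      sprintf("chr1\tsrnamir\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$start, g$end,
              g$strand, g$id),
      sprintf("chr1\tsrnamir\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s",
              e1[1], e1[2], g$strand, g$id, g$id),
      sprintf("chr1\tsrnamir\texon\t%d\t%d\t.\t%s\t.\tID=%s.e2;Parent=%s",
              e2[1], e2[2], g$strand, g$id, g$id))
    tx[g$id] <- g$transcript
    for (cat in names(go_terms)) {
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        gene = g$id, term = sample(go_terms[[cat]], 1), category = cat,
        stringsAsFactors = FALSE)
    }
  }
  writeLines(gff_lines, paths$gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx), paths$transcript_fasta)
  write_tsv(do.call(rbind, go_rows), paths$go_tsv)

  reps <- feats[is_cls("repeat")]
  rep_bed <- vapply(reps, function(f) {
    sprintf("chr1\t%d\t%d\t%s\t0\t%s", f$start - 1L, f$end, f$id, f$strand)
  }, character(1))
  writeLines(rep_bed, paths$repeat_bed)

  empty_truth <- data.frame(feature_id = character(0), class = character(0),
                            chrom = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            tag = character(0), arm = character(0),
                            mature_offset = integer(0), star = character(0),
                            target_of = character(0), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(feats, function(f) {
    row <- data.frame(feature_id = f$id, class = f$class,
               chrom = ifelse(f$class == "unmapped", NA, "chr1"),
               start = if (is.null(f$start)) NA_integer_ else f$start,
               end = if (is.null(f$end)) NA_integer_ else f$end,
               strand = f$strand, tag = f$tag,
               arm = if (is.null(f$arm)) NA_character_ else f$arm,
               mature_offset = if (is.null(f$mature_offset)) NA_integer_ else f$mature_offset,
               star = if (is.null(f$star)) NA_character_ else f$star,
               target_of = if (is.null(f$target_of)) NA_character_ else f$target_of,
               stringsAsFactors = FALSE)
    if (!is.null(f$intron_tag)) {
      irow <- row
      irow$feature_id <- paste0(f$id, "-intron")
      irow$class <- f$intron_class
      irow$tag <- f$intron_tag
      irow$target_of <- NA_character_
      row <- rbind(row, irow)
    }
    row
  }))
  if (is.null(truth)) truth <- empty_truth
  write_tsv(truth, paths$truth_tsv)

  structure(c(paths, list(genome = genome_set, truth = truth, spec = spec,
                          dir = dir)),
            class = "genome_bundle")
}

#' Expression profile for simulated sRNA libraries
#'
#' Assigns each profiled feature a baseline abundance (TPM) and a log2 fold
#' change between the control and treatment (deficiency) libraries, together
#' with the sequencing parameters of the simulation. Reads are later drawn
#' multinomially from the TPM-derived proportions (control) and the
#' fold-change-adjusted proportions (treatment), emulating the single pooled
#' library per condition of a two-library design.
#'
#' @param features data.frame with columns `id`, `tpm` (baseline, >= 0) and
#'   `log2fc` (0 for null features).
#' @param depth_ctl,depth_def library depths in reads (>= 0).
#' @param error_rate per-base substitution error probability (0 to 0.05).
#' @param adapter 3' adapter DNA sequence appended to every insert.
#' @param low_quality_fraction fraction of reads emitted with uniformly low
#'   base quality (exercises the quality filter).
#' @param read_length raw read length in nt.
#' @param seed integer seed.
#' @return list of class `expression_profile`.
#' @export
expression_profile <- function(features, depth_ctl = 5e5, depth_def = 5e5,
                               error_rate = 0, adapter = "TGGAATTCTCGGGTGCCAAGG",
                               low_quality_fraction = 0, read_length = 36L,
                               seed = 1L) {
  stopifnot(all(c("id", "tpm", "log2fc") %in% names(features)),
            all(features$tpm >= 0), depth_ctl >= 0, depth_def >= 0,
            error_rate >= 0, error_rate <= 0.05,
            low_quality_fraction >= 0, low_quality_fraction <= 1,
            nchar(adapter) >= 8)
  assert_alphabet(toupper(adapter), c("A", "C", "G", "T"), "adapter")
  if (anyDuplicated(features$id)) stop("feature ids must be unique", call. = FALSE)
  structure(list(features = features, depth_ctl = depth_ctl,
                 depth_def = depth_def, error_rate = error_rate,
                 adapter = toupper(adapter),
                 low_quality_fraction = low_quality_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "expression_profile")
}

# expected per-library sampling proportions of a profile (each sums to 1)
profile_proportions <- function(profile) {
  f <- profile$features
  w_ctl <- f$tpm
  w_def <- f$tpm * 2^f$log2fc
  list(ctl = if (sum(w_ctl) > 0) w_ctl / sum(w_ctl) else w_ctl,
       def = if (sum(w_def) > 0) w_def / sum(w_def) else w_def)
}

#' Draw per-feature read counts for the two libraries
#'
#' Counts are multinomial draws of the library depth over the TPM-derived
#' proportions (control) and fold-change-adjusted proportions (treatment).
#' The returned table also reports the exact sampling means.
#'
#' @param profile an [expression_profile()].
#' @return data.frame with `id`, `expected_ctl`, `expected_def`, `count_ctl`,
#'   `count_def`.
#' @export
sample_counts <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  set.seed(derive_seed(profile$seed, "sample_counts"))
  pr <- profile_proportions(profile)
  n <- nrow(profile$features)
  draw <- function(depth, p) {
    if (depth == 0 || sum(p) == 0) return(integer(n))
    as.integer(stats::rmultinom(1, depth, p))
  }
  data.frame(id = profile$features$id,
             expected_ctl = profile$depth_ctl * pr$ctl,
             expected_def = profile$depth_def * pr$def,
             count_ctl = draw(profile$depth_ctl, pr$ctl),
             count_def = draw(profile$depth_def, pr$def),
             stringsAsFactors = FALSE)
}

#' Simulate two sRNA sequencing libraries from a genome bundle
#'
#' Expands the multinomial per-feature counts of [sample_counts()] into raw
#' FASTQ reads: each read is the feature's tag with the 3' adapter appended,
#' cut to the read length, with substitution errors at the profile's rate and
#' Sanger-encoded qualities (uniformly high, except for the configured
#' fraction of low-quality reads).
#'
#' @param bundle a [build_genome()] bundle.
#' @param profile an [expression_profile()]; every profiled id must be a
#'   feature of the bundle.
#' @param dir output directory for `control.fastq` and `deficient.fastq`.
#' @return list with `fastq_ctl`, `fastq_def`, and the `counts` table of
#'   [sample_counts()].
#' @export
simulate_libraries <- function(bundle, profile, dir = bundle$dir) {
  stopifnot(inherits(bundle, "genome_bundle"),
            inherits(profile, "expression_profile"))
  missing <- setdiff(profile$features$id, bundle$truth$feature_id)
  if (length(missing) > 0) {
    stop("profiled features absent from bundle: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- sample_counts(profile)
  tags <- bundle$truth$tag[match(counts$id, bundle$truth$feature_id)]
  set.seed(derive_seed(profile$seed, "simulate_reads"))

  emit <- function(nreads, path, lib) {
    seqs <- rep(paste0(tags, profile$adapter), nreads)
    if (length(seqs) > 0) {
      seqs <- substr(seqs, 1, profile$read_length)
      if (profile$error_rate > 0) {
        m <- do.call(rbind, strsplit(seqs, ""))
        err <- matrix(stats::runif(length(m)) < profile$error_rate, nrow(m))
        if (any(err)) {
          m[err] <- vapply(m[err], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        seqs <- apply(m, 1, paste, collapse = "")
      }
    }
    lowq <- stats::runif(length(seqs)) < profile$low_quality_fraction
    quals <- ifelse(lowq, strrep("#", nchar(seqs)), strrep("I", nchar(seqs)))
    ids <- sprintf("%s_read%06d", lib, seq_along(seqs))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(seqs) > 0) {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
    }
    invisible(path)
  }
  fq_ctl <- file.path(dir, "control.fastq")
  fq_def <- file.path(dir, "deficient.fastq")
  emit(counts$count_ctl, fq_ctl, "ctl")
  emit(counts$count_def, fq_def, "def")
  list(fastq_ctl = fq_ctl, fastq_def = fq_def, counts = counts)
}

#' Default expression profile for a synthetic bundle
#'
#' Gives every bundle feature a field-realistic baseline abundance (rRNA
#' fragments dominate, miRNAs span roughly 20 to 2000 TPM on a log scale) and
#' assigns a configurable subset of miRNAs a symmetric log2 fold change
#' between conditions; all other features are null.
#'
#' @param bundle a [build_genome()] bundle.
#' @param n_regulated number of miRNA features given a non-zero fold change.
#' @param lfc magnitude of the assigned log2 fold changes (alternating sign).
#' @param seed integer seed.
#' @param ... passed on to [expression_profile()].
#' @return an [expression_profile()].
#' @export
default_profile <- function(bundle, n_regulated = 6, lfc = 3, seed = 1L, ...) {
  set.seed(derive_seed(seed, "default_profile"))
  tr <- bundle$truth
  base <- c(known_miRNA = 200, novel_hairpin = 100, rRNA = 3000, tRNA = 400,
            snRNA = 60, snoRNA = 40, exon_sense = 80, exon_antisense = 80,
            intron_sense = 60, intron_antisense = 60,
            `repeat` = 30, unmapped = 120)
  tpm <- base[tr$class] * exp(stats::rnorm(nrow(tr), 0, 0.6))
  lfc_vec <- numeric(nrow(tr))
  mirna_idx <- which(tr$class %in% c("known_miRNA", "novel_hairpin"))
  reg <- utils::head(mirna_idx, n_regulated)
  lfc_vec[reg] <- lfc * rep_len(c(1, -1), length(reg))
  feats <- data.frame(id = tr$feature_id, tpm = unname(tpm), log2fc = lfc_vec,
                      stringsAsFactors = FALSE)
  expression_profile(feats, seed = derive_seed(seed, "profile_rng"), ...)
}
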