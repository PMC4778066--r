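#' Pipeline configuration
#'
#' Collects every input path, threshold and seed of the full two-library
#' analysis in one list. Defaults equal the study parameter set used
#' throughout the package: adapter-prefix trimming, mean Phred >= 20,
#' 18-30 nt retention, up to 2 mismatches against the known-miRNA reference,
#' Mireap-style hairpin criteria, TPM >= 10 retention, p < 0.01 and
#' |log2 fold change| > 1.5 differential-expression gates.
#'
#' @param genome_fasta,mature_fasta,gff,repeat_bed,transcript_fasta input
#'   reference paths; `ncrna_fastas` is a named list (rRNA/tRNA/snRNA/snoRNA).
#' @param fastq_ctl,fastq_def raw read paths (filled in by the simulate stage
#'   when `simulate = TRUE`).
#' @param go_tsv optional gene-to-GO mapping.
#' @param outdir output directory.
#' @param simulate build a synthetic bundle and simulate the libraries first.
#' @param adapter,min_quality,length_bounds cleaning parameters.
#' @param max_mismatches known-miRNA matching mismatch cap.
#' @param mireap hairpin parameters, a [mireap_params()].
#' @param tpm_threshold low-expression filter threshold.
#' @param p_cutoff,fc_cutoff,fc_scale differential-expression gates.
#' @param seed master seed for all randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta = NULL, mature_fasta = NULL,
                            ncrna_fastas = list(), gff = NULL,
                            repeat_bed = NULL, transcript_fasta = NULL,
                            fastq_ctl = NULL, fastq_def = NULL, go_tsv = NULL,
                            outdir = "srnamir_out", simulate = is.null(genome_fasta),
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_quality = 20, length_bounds = c(18L, 30L),
                            max_mismatches = 2L, mireap = mireap_params(),
                            tpm_threshold = 10, p_cutoff = 0.01,
                            fc_cutoff = 1.5, fc_scale = "log2", seed = 1L) {
  structure(list(genome_fasta = genome_fasta, mature_fasta = mature_fasta,
                 ncrna_fastas = ncrna_fastas, gff = gff,
                 repeat_bed = repeat_bed, transcript_fasta = transcript_fasta,
                 fastq_ctl = fastq_ctl, fastq_def = fastq_def, go_tsv = go_tsv,
                 outdir = outdir, simulate = simulate, adapter = adapter,
                 min_quality = min_quality,
                 length_bounds = as.integer(length_bounds),
                 max_mismatches = as.integer(max_mismatches), mireap = mireap,
                 tpm_threshold = tpm_threshold, p_cutoff = p_cutoff,
                 fc_cutoff = fc_cutoff, fc_scale = fc_scale,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly through the file.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` the path invisibly; `read_pipeline_config`
#'   a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$mireap <- unclass(x$mireap)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$mireap <- do.call(mireap_params, x$mireap)
  x$length_bounds <- as.integer(x$length_bounds)
  do.call(pipeline_config, x)
}

#' Run the full two-library sRNA analysis
#'
#' Executes simulate (optional) -> clean -> collapse -> map -> annotate ->
#' known/novel miRNA -> low-expression filter -> differential expression ->
#' target prediction -> (optional) GO tally, writing one TSV per stage plus a
#' machine-readable JSON summary into `config$outdir`. Rerunning with the
#' same configuration and seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param profile expression profile used when `config$simulate` is `TRUE`
#'   (default [default_profile()] of the simulated bundle).
#' @return invisibly, a list with the stage results (`stats`, `tags`,
#'   `annotation`, `table1`, `known_counts`, `novel`, `de`, `targets`,
#'   `summary`).
#' @export
run_pipeline <- function(config, profile = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  if (isTRUE(config$simulate)) {
    log_stage("stage simulate: building synthetic bundle (seed %d)", config$seed)
    bundle <- build_genome(synthetic_genome_spec(seed = config$seed),
                           dir = file.path(config$outdir, "bundle"))
    if (is.null(profile)) {
      profile <- default_profile(bundle, seed = config$seed,
                                 depth_ctl = 2e4, depth_def = 2e4,
                                 error_rate = 0.005,
                                 low_quality_fraction = 0.02,
                                 adapter = config$adapter)
    }
    sim <- simulate_libraries(bundle, profile, dir = file.path(config$outdir, "bundle"))
    config$genome_fasta <- bundle$genome_fasta
    config$mature_fasta <- bundle$mature_fasta
    config$ncrna_fastas <- bundle$ncrna_fastas
    config$gff <- bundle$gff
    config$repeat_bed <- bundle$repeat_bed
    config$transcript_fasta <- bundle$transcript_fasta
    config$go_tsv <- bundle$go_tsv
    config$fastq_ctl <- sim$fastq_ctl
    config$fastq_def <- sim$fastq_def
  }
  for (field in c("genome_fasta", "mature_fasta", "gff", "repeat_bed",
                  "transcript_fasta", "fastq_ctl", "fastq_def")) {
    if (is.null(config[[field]]) || !file.exists(config[[field]])) {
      stop(sprintf("pipeline config field '%s' missing or not a file", field),
           call. = FALSE)
    }
  }

  log_stage("stage clean: %s / %s", config$fastq_ctl, config$fastq_def)
  cl_ctl <- clean_reads(config$fastq_ctl, config$adapter, config$min_quality,
                        config$length_bounds)
  cl_def <- clean_reads(config$fastq_def, config$adapter, config$min_quality,
                        config$length_bounds)
  stats <- data.frame(library = c("ctl", "def"),
                      raw_reads = c(cl_ctl$stats$raw_reads, cl_def$stats$raw_reads),
                      low_quality = c(cl_ctl$stats$low_quality, cl_def$stats$low_quality),
                      length_out = c(cl_ctl$stats$length_out, cl_def$stats$length_out),
                      clean_reads = c(cl_ctl$stats$clean_reads, cl_def$stats$clean_reads))
  write_tsv(stats, file.path(config$outdir, "clean_stats.tsv"))
  log_stage("stage clean: %d / %d clean reads", stats$clean_reads[1], stats$clean_reads[2])

  tags <- collapse_tags(cl_ctl$sequences, cl_def$sequences)
  write_tag_fasta(tags, file.path(config$outdir, "tags.fa"))
  write_tsv(length_distribution(tags), file.path(config$outdir, "length_distribution.tsv"))
  log_stage("stage collapse: %d unique tags", nrow(tags))

  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  hits <- map_perfect(tags, genome)
  log_stage("stage map: %d perfect hits for %d tags", nrow(hits),
            length(unique(hits$sequence)))

  assignments <- match_known_mirnas(tags, config$mature_fasta,
                                    config$max_mismatches)
  gene_models <- load_gene_models(config$gff)
  annotation <- annotate_cascade(tags, hits, config$ncrna_fastas, assignments,
                                 config$repeat_bed, gene_models)
  write_tsv(annotation, file.path(config$outdir, "annotation.tsv"))
  table1 <- summarize_table1(annotation)
  write_tsv(table1, file.path(config$outdir, "table1_summary.tsv"))
  log_stage("stage annotate: %s",
            paste(sprintf("%s=%d", names(table(annotation$category)),
                          as.integer(table(annotation$category))), collapse = " "))

  known_counts <- mirna_counts(assignments, tags)
  unann <- annotation$sequence[annotation$category == "unannotated"]
  novel <- predict_novel(tags[tags$sequence %in% unann, , drop = FALSE],
                         hits, genome, config$mireap)
  write_tsv(novel, file.path(config$outdir, "novel_candidates.tsv"))
  candidates_to_gff(novel, file.path(config$outdir, "novel_candidates.gff3"))
  log_stage("stage novel: %d accepted hairpin candidates", nrow(novel))

  counts <- rbind(known_counts,
                  if (nrow(novel) > 0) {
                    data.frame(id = novel$id, x = novel$count_ctl,
                               y = novel$count_def, stringsAsFactors = FALSE)
                  })
  N1 <- stats$clean_reads[1]; N2 <- stats$clean_reads[2]
  records <- mirna_expression_records(counts, N1, N2)
  kept <- low_expression_filter(records, config$tpm_threshold)
  de <- call_differential(kept, config$p_cutoff, config$fc_cutoff,
                          config$fc_scale)
  write_tsv(de, file.path(config$outdir, "differential_expression.tsv"))
  log_stage("stage de: %d miRNAs tested, %d significant (%d up / %d down)",
            nrow(kept), sum(de$significant),
            sum(de$direction == "up"), sum(de$direction == "down"))

  sig <- de[de$significant, , drop = FALSE]
  sig_seqs <- character(0)
  if (nrow(sig) > 0) {
    mature_ref <- Biostrings::readBStringSet(config$mature_fasta)
    known_seq <- rna_to_dna(as.character(mature_ref))
    sig_seqs <- c(stats::setNames(known_seq[intersect(sig$id, names(known_seq))],
                                  intersect(sig$id, names(known_seq))),
                  stats::setNames(novel$sequence[match(intersect(sig$id, novel$id),
                                                       novel$id)],
                                  intersect(sig$id, novel$id)))
  }
  targets <- if (length(sig_seqs) > 0) {
    scan_transcripts(sig_seqs, config$transcript_fasta)
  } else {
    scan_transcripts(stats::setNames("A", "none"),
                     config$transcript_fasta)[0, , drop = FALSE]
  }
  write_tsv(targets, file.path(config$outdir, "target_predictions.tsv"))
  log_stage("stage targets: %d predicted sites", nrow(targets))

  go <- NULL
  if (!is.null(config$go_tsv) && file.exists(config$go_tsv) && nrow(targets) > 0) {
    go <- go_tally(unique(targets$transcript_id), config$go_tsv)
    write_tsv(go$tallies, file.path(config$outdir, "go_tally.tsv"))
  }

  summary <- list(
    raw_reads = stats$raw_reads, clean_reads = stats$clean_reads,
    discarded = list(low_quality = stats$low_quality,
                     length = stats$length_out),
    unique_tags = nrow(tags),
    known_mirnas = nrow(known_counts),
    novel_candidates = nrow(novel),
    tested = nrow(kept),
    significant = sum(de$significant),
    up = sum(de$direction == "up"), down = sum(de$direction == "down"),
    target_sites = nrow(targets), seed = config$seed)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(stats = stats, tags = tags, annotation = annotation,
                 table1 = table1, known_counts = known_counts, novel = novel,
                 de = de, targets = targets, go = go, summary = summary))
}
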