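# a deterministic constructed genome: 600 nt with a planted 24-mer at 101-124
make_toy_genome <- function() {
  set.seed(31)
  g <- srnamir:::random_dna(1, 600)
  Biostrings::DNAStringSet(c(chr1 = g))
}

test_that("perfect mapping finds plus, minus and absent tags", {
  genome <- make_toy_genome()
  gseq <- as.character(genome[[1]])
  tag_plus <- substr(gseq, 101, 124)
  h <- map_perfect(tag_plus, genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 101)
  expect_equal(h$end, 124)
  expect_equal(h$strand, "+")

  tag_minus <- revcomp(substr(gseq, 201, 222))
  h2 <- map_perfect(tag_minus, genome)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$start, 201)
  expect_equal(h2$end, 222)
  expect_equal(h2$strand, "-")

  expect_equal(nrow(map_perfect(strrep("ACGT", 6), genome)), 0)
})

test_that("known-miRNA matching allows up to two mismatches", {
  ref <- c(mirA = "UGGAGCUCCCUUCAUUCCAAU", mirB = "UUGACAGAAGAUAGAGAGCAC")
  tag0 <- rna_to_dna(ref[["mirA"]])
  tag2 <- tag0; substr(tag2, 3, 3) <- "A"; substr(tag2, 9, 9) <- "T"
  tag3 <- tag2; substr(tag3, 15, 15) <- "C"
  a <- match_known_mirnas(c(tag0, tag2, tag3), ref)
  expect_equal(a$mirna_id[a$sequence == tag0], "mirA")
  expect_equal(a$mismatches[a$sequence == tag0], 0)
  expect_equal(a$mirna_id[a$sequence == tag2], "mirA")
  expect_equal(a$mismatches[a$sequence == tag2], 2)
  expect_false(tag3 %in% a$sequence)
  # per-miRNA counts sum the assigned tags' counts
  tags <- data.frame(sequence = c(tag0, tag2), count_ctl = c(5, 2),
                     count_def = c(1, 0))
  cnt <- mirna_counts(a, tags)
  expect_equal(cnt$x[cnt$id == "mirA"], 7)
  expect_equal(cnt$y[cnt$id == "mirA"], 1)
})

test_that("the cascade assigns exactly one category in priority order", {
  b <- small_bundle()
  tr <- b$truth
  # one representative tag per class, plus an unannotated random tag
  pick <- function(cls) tr$tag[tr$class == cls][1]
  novel_tag <- pick("novel_hairpin")
  tag_df <- data.frame(
    sequence = c(pick("rRNA"), pick("known_miRNA"), pick("repeat"),
                 pick("exon_sense"), pick("intron_sense"), novel_tag,
                 "ACACACACACACACACACACA"),
    count_ctl = 1L, count_def = 2L, stringsAsFactors = FALSE)
  hits <- map_perfect(tag_df, b$genome)
  assignments <- match_known_mirnas(tag_df, b$mature_fasta)
  ann <- annotate_cascade(tag_df, hits, b$ncrna_fastas, assignments,
                          b$repeat_bed, b$gff)
  got <- setNames(ann$category, ann$sequence)
  expect_equal(unname(got[pick("rRNA")]), "rRNA")
  expect_equal(unname(got[pick("known_miRNA")]), "known_miRNA")
  expect_equal(unname(got[pick("repeat")]), "repeat")
  expect_equal(unname(got[pick("exon_sense")]), "exon_sense")
  expect_equal(unname(got[pick("intron_sense")]), "intron_sense")
  expect_equal(unname(got[novel_tag]), "unannotated")
  expect_equal(unname(got["ACACACACACACACACACACA"]), "unannotated")
})

test_that("earlier cascade stages win over later ones", {
  # a tag that is both contained in an rRNA reference and maps to an exon:
  # plant the rRNA reference inside an exon of a constructed gene
  set.seed(41)
  exon1 <- srnamir:::random_dna(1, 150)
  rrna <- srnamir:::random_dna(1, 80)
  intron <- srnamir:::random_dna(1, 100)
  exon2 <- paste0(srnamir:::random_dna(1, 30), rrna, srnamir:::random_dna(1, 40))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(exon1, intron, exon2)))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\ttoy\tgene\t1\t%d\t.\t+\t.\tID=g1", 400),
               "chr1\ttoy\texon\t1\t150\t.\t+\t.\tID=g1.e1;Parent=g1",
               sprintf("chr1\ttoy\texon\t251\t%d\t.\t+\t.\tID=g1.e2;Parent=g1", 400)),
             gff)
  tag_rrna_exon <- substr(rrna, 20, 41)  # inside rRNA AND inside exon2
  tag_exon_only <- substr(exon1, 10, 31)
  tag_intron <- substr(intron, 10, 31)
  tags <- data.frame(sequence = c(tag_rrna_exon, tag_exon_only, tag_intron),
                     count_ctl = 1L, count_def = 1L)
  hits <- map_perfect(tags, genome)
  empty_assign <- data.frame(sequence = character(0), mirna_id = character(0),
                             mismatches = integer(0))
  empty_rep <- GenomicRanges::GRanges()
  ann <- annotate_cascade(tags, hits, list(rRNA = rrna), empty_assign,
                          empty_rep, gff)
  expect_equal(ann$category, c("rRNA", "exon_sense", "intron_sense"))

  # a tag matching a known miRNA and a repeat is a known miRNA
  rep_bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\trep1\t0\t+", 9, 31), rep_bed)
  assign2 <- data.frame(sequence = tag_exon_only, mirna_id = "mirX",
                        mismatches = 0L)
  ann2 <- annotate_cascade(tags, hits, list(), assign2, rep_bed, gff)
  expect_equal(ann2$category[2], "known_miRNA")  # outranks its repeat overlap
  expect_equal(ann2$category[1], "exon_sense")   # no rRNA reference this time

  # removing later-stage references never changes earlier assignments
  ann3 <- annotate_cascade(tags, hits, list(rRNA = rrna), empty_assign,
                           empty_rep,
                           list(exons = GenomicRanges::GRanges(),
                                introns = GenomicRanges::GRanges()))
  expect_equal(ann3$category[1], "rRNA")
})

test_that("a strandless gene model is rejected", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t100\t.\t.\t.\tID=g1",
               "chr1\ttoy\texon\t1\t100\t.\t.\t.\tID=g1.e1;Parent=g1"), gff)
  expect_error(load_gene_models(gff), "strand")
})

test_that("category totals partition the clean reads", {
  b <- small_bundle()
  pr <- default_profile(b, depth_ctl = 4000, depth_def = 4000,
                        error_rate = 0.005, low_quality_fraction = 0.02,
                        seed = 12)
  sim <- simulate_libraries(b, pr, dir = tempfile())
  cl_ctl <- clean_reads(sim$fastq_ctl, pr$adapter)
  cl_def <- clean_reads(sim$fastq_def, pr$adapter)
  tags <- collapse_tags(cl_ctl$sequences, cl_def$sequences)
  hits <- map_perfect(tags, b$genome)
  assignments <- match_known_mirnas(tags, b$mature_fasta)
  ann <- annotate_cascade(tags, hits, b$ncrna_fastas, assignments,
                          b$repeat_bed, b$gff)
  expect_equal(sum(ann$count_ctl), cl_ctl$stats$clean_reads)
  expect_equal(sum(ann$count_def), cl_def$stats$clean_reads)
  tbl <- summarize_table1(ann)
  cat_rows <- !tbl$row %in% c("clean", "mapped_to_genome")
  expect_equal(sum(tbl$total_ctl[cat_rows]), tbl$total_ctl[tbl$row == "clean"])
  expect_equal(sum(tbl$total_def[cat_rows]), tbl$total_def[tbl$row == "clean"])
})

test_that("summary percentages follow the count/clean formula", {
  expect_equal(category_percentage(2280530, 20328011), 11.22)
  expect_equal(category_percentage(4888886, 22218850), 22.00)
  expect_true(is.na(category_percentage(0, 0)))
  # empty annotation gives an all-zero table with absent percentages
  empty <- annotate_cascade(collapse_tags(character(0)),
                            map_perfect(character(0),
                                        Biostrings::DNAStringSet(c(chr1 = "ACGT"))),
                            list(), data.frame(sequence = character(0),
                                               mirna_id = character(0),
                                               mismatches = integer(0)),
                            GenomicRanges::GRanges(),
                            list(exons = GenomicRanges::GRanges(),
                                 introns = GenomicRanges::GRanges()))
  tbl <- summarize_table1(empty)
  expect_true(all(tbl$total_ctl == 0))
  expect_true(all(is.na(tbl$total_pct_ctl)))
})
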