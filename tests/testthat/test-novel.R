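test_that("mature length bounds are inclusive", {
  tags <- data.frame(sequence = c(strrep("A", 17), strrep("C", 18),
                                  strrep("G", 25), strrep("T", 26)),
                     count_ctl = 1L, count_def = 1L)
  kept <- filter_mature_length(tags)
  expect_setequal(kept$sequence, c(strrep("C", 18), strrep("G", 25)))
  expect_equal(nrow(filter_mature_length(tags[0, ])), 0)
})

test_that("designed hairpin tags are recovered at their designed loci", {
  b <- small_bundle()
  hp <- b$truth[b$truth$class == "novel_hairpin", ]
  tags <- data.frame(sequence = hp$tag, count_ctl = 10L, count_def = 20L)
  hits <- map_perfect(tags, b$genome)
  cand <- predict_novel(tags, hits, b$genome)
  expect_equal(nrow(cand), nrow(hp))
  for (i in seq_len(nrow(hp))) {
    j <- which(cand$sequence == hp$tag[i])
    expect_length(j, 1)
    # candidate precursor covers the designed precursor locus
    expect_lte(cand$precursor_start[j], hp$start[i] + 5)
    expect_gte(cand$precursor_end[j], hp$end[i] - 5)
    expect_lte(cand$mfe[j], -18)
    expect_gte(cand$duplex_paired_bases[j], 16)
    expect_lte(cand$duplex_bulge_max[j], 4)
    expect_lte(cand$duplex_asymmetry[j], 4)
    expect_lte(cand$mature_star_gap[j], 300)
  }
})

test_that("accepted diagnostics re-verify against the reported structure", {
  b <- small_bundle()
  hp <- b$truth[b$truth$class == "novel_hairpin", ]
  tags <- data.frame(sequence = hp$tag, count_ctl = 1L, count_def = 1L)
  cand <- predict_novel(tags, map_perfect(tags, b$genome), b$genome)
  for (j in seq_len(nrow(cand))) {
    pairs <- structure_pairs(cand$structure[j])
    # locate the mature inside the reported precursor
    pre <- as.character(Biostrings::subseq(b$genome[["chr1"]],
                                           cand$precursor_start[j],
                                           cand$precursor_end[j]))
    if (cand$strand[j] == "-") pre <- revcomp(pre)
    m1 <- as.integer(regexpr(cand$sequence[j], pre, fixed = TRUE))
    expect_gt(m1, 0)
    m2 <- m1 + nchar(cand$sequence[j]) - 1L
    s1 <- as.integer(regexpr(cand$star[j], pre, fixed = TRUE))
    s2 <- s1 + nchar(cand$star[j]) - 1L
    mpos <- m1:m2
    recount <- sum(pairs[mpos] >= s1 & pairs[mpos] <= s2)
    expect_equal(recount, cand$duplex_paired_bases[j])
  }
})

test_that("the precursor energy gate rejects weak folds", {
  b <- small_bundle()
  hp <- b$truth[b$truth$class == "novel_hairpin", ][1, ]
  pre <- as.character(Biostrings::subseq(b$genome[["chr1"]], hp$start, hp$end))
  if (hp$strand == "-") pre <- revcomp(pre)
  m1 <- as.integer(regexpr(hp$tag, pre, fixed = TRUE))
  m2 <- m1 + nchar(hp$tag) - 1L
  # an engine reporting the same structure but an MFE of -17 fails the gate
  weak_engine <- function(s) { r <- fold(s); r$mfe <- -17; r }
  d <- hairpin_diagnostics(pre, m1, m2, engine = weak_engine)
  expect_false(d$accepted)
  expect_true("mfe" %in% d$reasons)
  # at -18 exactly the gate still passes (threshold is a maximum)
  at_engine <- function(s) { r <- fold(s); r$mfe <- -18; r }
  expect_true(hairpin_diagnostics(pre, m1, m2, engine = at_engine)$accepted)
})

test_that("stem-disrupted mutants with MFE above -18 yield no candidate", {
  b <- small_bundle()
  hp <- b$truth[b$truth$class == "novel_hairpin", ][1, ]
  pre <- as.character(Biostrings::subseq(b$genome[["chr1"]], hp$start, hp$end))
  if (hp$strand == "-") pre <- revcomp(pre)
  m1 <- as.integer(regexpr(hp$tag, pre, fixed = TRUE))
  m2 <- m1 + nchar(hp$tag) - 1L
  # break stem pairs outside the mature until the engine MFE rises above -18
  set.seed(77)
  mut <- weaken_hairpin(pre, m1, m2)
  expect_gt(fold(mut)$mfe, -18)
  set.seed(78)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    srnamir:::random_dna(1, 400), mut, srnamir:::random_dna(1, 400))))
  tags <- data.frame(sequence = hp$tag, count_ctl = 1L, count_def = 1L)
  hits <- map_perfect(tags, genome)
  expect_gte(nrow(hits), 1)
  expect_equal(nrow(predict_novel(tags, hits, genome)), 0)
})

test_that("tags without hits or with too many loci give no candidates", {
  b <- small_bundle()
  tags <- data.frame(sequence = "ACGTGCATGCATCGTACGATC", count_ctl = 1L,
                     count_def = 1L)
  nohits <- map_perfect(tags, b$genome)
  expect_equal(nrow(predict_novel(tags, nohits, b$genome)), 0)

  # the same hairpin repeated 21 times exceeds the copy-number cap
  hp <- b$truth[b$truth$class == "novel_hairpin", ][1, ]
  pre <- as.character(Biostrings::subseq(b$genome[["chr1"]], hp$start, hp$end))
  if (hp$strand == "-") pre <- revcomp(pre)
  set.seed(5)
  spacers <- srnamir:::random_dna(22, 40)
  multi <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste0(spacers[1:21], pre, collapse = ""), spacers[22])))
  tags2 <- data.frame(sequence = hp$tag, count_ctl = 1L, count_def = 1L)
  hits2 <- map_perfect(tags2, multi)
  expect_gte(nrow(hits2), 21)
  expect_equal(nrow(predict_novel(tags2, hits2, multi)), 0)
  # raising the cap restores the candidates
  relaxed <- predict_novel(tags2, hits2, multi,
                           mireap_params(max_copy = 100L))
  expect_gt(nrow(relaxed), 0)
})

test_that("relaxing a threshold never shrinks the candidate set", {
  b <- small_bundle()
  hp <- b$truth[b$truth$class == "novel_hairpin", ]
  tags <- data.frame(sequence = hp$tag, count_ctl = 1L, count_def = 1L)
  hits <- map_perfect(tags, b$genome)
  strict <- predict_novel(tags, hits, b$genome, mireap_params(max_mfe = -18))
  loose <- predict_novel(tags, hits, b$genome, mireap_params(max_mfe = -15))
  expect_true(all(strict$sequence %in% loose$sequence))
  tighter <- predict_novel(tags, hits, b$genome, mireap_params(min_pair = 20L))
  expect_true(all(tighter$sequence %in% strict$sequence))
})
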