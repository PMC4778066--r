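rc_rna <- c(A = "U", C = "G", G = "C", U = "A")
perfect_site <- function(m) {
  paste(rev(rc_rna[strsplit(m, "")[[1]]]), collapse = "")
}
mutate_site <- function(site, mirna_pos, base) {
  # change the site base facing the given miRNA position
  v <- strsplit(site, "")[[1]]
  v[length(v) - mirna_pos + 1] <- base
  paste(v, collapse = "")
}

test_that("duplex alignment classifies pair states and weights", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  d0 <- align_duplex(m, perfect_site(m))
  expect_true(all(d0$position_states == "WC"))
  expect_equal(d0$mismatch_score, 0)
  expect_equal(d0$mfe_duplex, d0$mfe_perfect)

  # G at miRNA position 5 paired to U: wobble, half a mismatch
  d1 <- align_duplex(m, mutate_site(perfect_site(m), 5, "U"))
  expect_equal(d1$position_states[5], "GU")
  expect_equal(d1$mismatch_score, 0.5)

  # two adjacent mismatches at 14-15 plus one wobble
  s2 <- mutate_site(perfect_site(m), 14, "C")
  s2 <- mutate_site(s2, 15, "U")
  s2 <- mutate_site(s2, 5, "U")
  d2 <- align_duplex(m, s2)
  expect_equal(d2$position_states[14:15], c("MM", "MM"))
  expect_equal(d2$mismatch_score, 2.5)

  expect_error(align_duplex("", "ACGU"), "empty")
  expect_error(align_duplex("ACGUACGU", "ACGUACGUACGU"), "at most 1")
})

test_that("a bulged miRNA base is placed at the score-minimizing position", {
  m <- "UGGAGCUCCCUUCAUUCCAAU"
  site20 <- perfect_site(paste0(substr(m, 1, 10), substr(m, 12, 21)))
  d <- align_duplex(m, site20)   # miRNA one base longer: one BULGE state
  expect_equal(sum(d$position_states == "BULGE"), 1)
  expect_equal(d$mismatch_score, 1)
  # site one base longer: one inserted target base, weight 1
  m20 <- paste0(substr(m, 1, 10), substr(m, 12, 21))
  d2 <- align_duplex(m20, perfect_site(m))
  expect_equal(d2$mismatch_score, 1)
  expect_length(d2$site_bulges, 1)
})

test_that("each rule violation flips exactly its own flag", {
  all_pass <- function(m, s) apply_rules(align_duplex(m, s))
  expect_true(all(all_pass("AGCGGCGCCGGCAUAUAUAUA",
                           perfect_site("AGCGGCGCCGGCAUAUAUAUA"))))

  # (d): one mismatch facing position 10
  m <- "AGCGGCGCCGGCAUAUAUAUA"
  f_d <- all_pass(m, mutate_site(perfect_site(m), 10, "A"))
  expect_identical(unname(f_d), c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))

  # (c): adjacent mismatches at positions 5-6
  s_c <- mutate_site(perfect_site(m), 5, "A")
  s_c <- mutate_site(s_c, 6, "C")
  f_c <- all_pass(m, s_c)
  expect_identical(unname(f_c), c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))

  # (e): six wobbles inside positions 2-7 exceed 2.5 in the 5' half
  m_e <- "AGGGUGGUGCCGCGCGCAUAU"
  s_e <- perfect_site(m_e)
  for (p in 2:7) {
    s_e <- mutate_site(s_e, p, ifelse(substr(m_e, p, p) == "G", "U", "G"))
  }
  f_e <- all_pass(m_e, s_e)
  expect_identical(unname(f_e), c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))

  # (a): ten wobbles at position 1 and 13-21 push the total score past 4
  m_a <- "UGCGGCGCCGGCUUUUUUUUU"
  s_a <- perfect_site(m_a)
  for (p in c(1, 13:21)) s_a <- mutate_site(s_a, p, "G")
  f_a <- all_pass(m_a, s_a)
  expect_identical(unname(f_a), c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))

  # (f): three spread mismatches on an AU-rich duplex drop the energy ratio
  m_f <- "AAUAUAUAUGCAAUAUAUAUA"
  s_f <- perfect_site(m_f)
  for (p in c(14, 16, 18)) s_f <- mutate_site(s_f, p, "C")
  f_f <- all_pass(m_f, s_f)
  expect_identical(unname(f_f), c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))

  # (b): three adjacent mismatches outside the 5' window
  s_b <- perfect_site(m_f)
  for (p in c(15, 16, 17)) s_b <- mutate_site(s_b, p, "C")
  expect_false(all_pass(m_f, s_b)[["b"]])
})

test_that("adding a mismatch never improves the score", {
  set.seed(51)
  for (i in 1:10) {
    m <- random_rna(21)
    s <- perfect_site(m)
    score <- 0
    for (p in sample(21, 4)) {
      s <- mutate_site(s, p, sample(c("A", "C", "G", "U"), 1))
      d <- align_duplex(m, s)
      expect_gte(d$mismatch_score, score)
      score <- d$mismatch_score
    }
  }
})

test_that("scanning finds planted sites in coordinate order", {
  m <- c(mirX = "AGCGGCGCCGGCAUAUAUAUA")
  site <- rna_to_dna(perfect_site(m[[1]]))
  set.seed(61)
  pad <- function(n) srnamir:::random_dna(1, n, gc = 0.1)
  tx <- c(t1 = paste0(pad(40), site, pad(60), site, pad(30)),
          t2 = pad(80))
  hits <- scan_transcripts(m, tx)
  hits1 <- hits[hits$transcript_id == "t1", ]
  expect_equal(nrow(hits1), 2)
  expect_equal(hits1$start, c(41, 122))
  expect_equal(hits1$score, c(0, 0))
  expect_equal(hits1$mfe_ratio, c(1, 1))
  expect_equal(nrow(hits[hits$transcript_id == "t2", ]), 0)
})

test_that("scan equals the exhaustive window oracle on short transcripts", {
  set.seed(71)
  m <- c(mir1 = "AGCGGCGCCGGCAUAUAUAUA", mir2 = random_rna(21))
  for (i in 1:6) {
    # transcripts seeded with degenerate copies of the sites so that some
    # windows pass and some fail each rule
    site <- rna_to_dna(perfect_site(m[[sample(2, 1)]]))
    v <- strsplit(site, "")[[1]]
    nmut <- sample(0:4, 1)
    if (nmut > 0) {
      at <- sample(length(v), nmut)
      v[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    tx <- paste0(srnamir:::random_dna(1, sample(40:80, 1)),
                 paste(v, collapse = ""),
                 srnamir:::random_dna(1, sample(40:80, 1)))
    expect_lte(nchar(tx), 200)
    got <- scan_transcripts(m, c(tx1 = tx), merge = FALSE)
    for (k in seq_along(m)) {
      mine <- got$start[got$mirna_id == names(m)[k]]
      expect_identical(mine, oracle_scan(m[[k]], tx), info = paste("case", i))
    }
  }
})

test_that("overlapping passing windows merge to the best-scoring one", {
  # a transcript where two overlapping windows both pass: site with a
  # leading extra complementary base makes the shifted window borderline
  m <- c(mirX = "AGCGGCGCCGGCAUAUAUAUA")
  site <- rna_to_dna(perfect_site(m[[1]]))
  tx <- c(t = paste0(strrep("T", 30), site, strrep("T", 30)))
  unmerged <- scan_transcripts(m, tx, merge = FALSE)
  merged <- scan_transcripts(m, tx)
  expect_gte(nrow(unmerged), nrow(merged))
  expect_equal(merged$score, min(unmerged$score))
})
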