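RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# pair state of one miRNA base against one target base (both RNA, upper case)
pair_state <- function(m, t) {
  unname(ifelse(RNA_COMPLEMENT[m] == t, "WC",
                ifelse((m == "G" & t == "U") | (m == "U" & t == "G"),
                       "GU", "MM")))
}

state_weight <- function(states) {
  w <- c(WC = 0, GU = 0.5, MM = 1, BULGE = 1)
  unname(w[states])
}

# intermolecular duplex energy under the stacked-pair model: consecutive
# paired miRNA positions with no insertion between them stack, and each
# stacked pair contributes its own pair energy
duplex_energy <- function(states, mpairs, tpairs, bulge_after = integer(0)) {
  e <- 0
  for (i in seq_along(states)[-1]) {
    if (states[i] %in% c("WC", "GU") && states[i - 1] %in% c("WC", "GU") &&
        !((i - 1) %in% bulge_after)) {
      e <- e + pair_energy(mpairs[i], tpairs[i])
    }
  }
  e
}

#' Align a miRNA against a candidate target site
#'
#' Pairs the miRNA with the target subsequence antiparallel, position by
#' position from the miRNA 5' end, classifying each miRNA position as
#' Watson-Crick (`WC`), wobble (`GU`), mismatch (`MM`) or bulged (`BULGE`).
#' When the sequences differ in length by one, a single-nucleotide bulge is
#' placed at the score-minimizing position (leftmost on ties): a longer miRNA
#' bulges a miRNA base (state `BULGE`); a longer site leaves one target base
#' unpaired, which adds 1 to the score (`site_bulges`). G:U wobbles weigh
#' 0.5 mismatches; mismatches and bulges weigh 1.
#'
#' The duplex minimum free energy uses the same stacked-pair energy model as
#' [fold()] restricted to intermolecular pairs, and `mfe_perfect` is the
#' energy of the miRNA bound to its exact complement, so the energy ratio
#' tends to 1 as the site approaches the perfect complement.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param site target subsequence, 5' to 3' as read on the transcript.
#' @return list of class `duplex_alignment`: `mirna`, `site`,
#'   `position_states` (per miRNA position), `site_bulges`,
#'   `mismatch_score`, `mfe_duplex`, `mfe_perfect`.
#' @export
align_duplex <- function(mirna, site) {
  if (nchar(mirna) == 0 || nchar(site) == 0) {
    stop("empty sequence in duplex alignment", call. = FALSE)
  }
  m <- strsplit(dna_to_rna(toupper(mirna)), "")[[1]]
  s <- strsplit(dna_to_rna(toupper(site)), "")[[1]]
  assert_alphabet(paste(m, collapse = ""), c("A", "C", "G", "U"), "miRNA")
  assert_alphabet(paste(s, collapse = ""), c("A", "C", "G", "U"), "site")
  Lm <- length(m); Ls <- length(s)
  if (abs(Lm - Ls) > 1) {
    stop("miRNA and site lengths may differ by at most 1 (single bulge)",
         call. = FALSE)
  }
  srev <- rev(s)  # srev[i] faces miRNA position i when lengths match

  best <- NULL
  if (Lm == Ls) {
    states <- pair_state(m, srev)
    best <- list(states = states, tfacing = srev, site_bulges = integer(0),
                 score = sum(state_weight(states)))
  } else if (Lm > Ls) {
    # one miRNA base bulged: try every position
    for (b in seq_len(Lm)) {
      states <- character(Lm)
      states[b] <- "BULGE"
      rest <- setdiff(seq_len(Lm), b)
      states[rest] <- pair_state(m[rest], srev)
      tfacing <- character(Lm)
      tfacing[rest] <- srev
      score <- sum(state_weight(states))
      if (is.null(best) || score < best$score) {
        best <- list(states = states, tfacing = tfacing,
                     site_bulges = integer(0), score = score)
      }
    }
  } else {
    # one site base bulged after miRNA position b (0 = before position 1)
    for (b in 0:(Lm)) {
      drop <- Ls - b  # index in srev of the unpaired site base
      tfacing <- srev[-drop]
      states <- pair_state(m, tfacing)
      score <- sum(state_weight(states)) + 1
      if (is.null(best) || score < best$score) {
        best <- list(states = states, tfacing = tfacing,
                     site_bulges = b, score = score)
      }
    }
  }

  mfe_duplex <- duplex_energy(best$states, m, best$tfacing,
                              bulge_after = best$site_bulges)
  perfect <- unname(RNA_COMPLEMENT[m])
  mfe_perfect <- duplex_energy(rep("WC", Lm), m, perfect)
  structure(list(mirna = paste(m, collapse = ""),
                 site = paste(s, collapse = ""),
                 position_states = best$states,
                 site_bulges = best$site_bulges,
                 mismatch_score = best$score,
                 mfe_duplex = mfe_duplex,
                 mfe_perfect = mfe_perfect),
            class = "duplex_alignment")
}

#' Apply the six plant miRNA target-site rules to a duplex
#'
#' Rules, each evaluated per miRNA position from the 5' end:
#' (a) total mismatch score at most 4 (G:U = 0.5, mismatch/bulge = 1);
#' (b) no more than two adjacent mismatches anywhere in the duplex;
#' (c) no adjacent mismatches in positions 2-12;
#' (d) no mismatches in positions 10-11 (Watson-Crick required: a wobble is
#'     half a mismatch, hence disallowed there);
#' (e) mismatch score over positions 1-12 at most 2.5;
#' (f) duplex MFE strictly greater than 75% of the MFE of the miRNA bound to
#'     its perfect complement.
#' Wobbles do not count toward the adjacency rules (b) and (c) unless
#' `gu_blocks_adjacency` is set.
#'
#' @param duplex an [align_duplex()] result.
#' @param gu_blocks_adjacency treat G:U as a mismatch in rules (b)/(c).
#' @return named logical vector with elements `a` to `f` (TRUE = rule
#'   satisfied).
#' @export
apply_rules <- function(duplex, gu_blocks_adjacency = FALSE) {
  st <- duplex$position_states
  mm_states <- c("MM", "BULGE", if (gu_blocks_adjacency) "GU")
  is_mm <- st %in% mm_states
  # insert site-bulge events between miRNA positions for adjacency/run checks
  ev_pos <- seq_along(st)
  ev_mm <- is_mm
  for (b in duplex$site_bulges) {
    ev_pos <- c(ev_pos, b + 0.5)
    ev_mm <- c(ev_mm, TRUE)
  }
  o <- order(ev_pos)
  ev_pos <- ev_pos[o]; ev_mm <- ev_mm[o]
  runs <- rle(ev_mm)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  run_in <- function(lo, hi) {
    sel <- ev_pos >= lo & ev_pos <= hi
    r <- rle(ev_mm[sel])
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  w12 <- sum(state_weight(st[seq_len(min(12, length(st)))])) +
    sum(duplex$site_bulges > 0 & duplex$site_bulges < 12.5)
  ratio <- if (duplex$mfe_perfect < 0) duplex$mfe_duplex / duplex$mfe_perfect else 0
  c(a = duplex$mismatch_score <= 4,
    b = max_run <= 2,
    c = run_in(2, 12) <= 1,
    d = all(st[10:11] == "WC"),
    e = w12 <= 2.5,
    f = ratio > 0.75)
}

#' Scan transcripts for miRNA target sites
#'
#' Evaluates every window of miRNA length on every transcript with
#' [align_duplex()] and [apply_rules()]; windows passing all six rules are
#' reported. Overlapping passing windows of one miRNA on one transcript are
#' merged to the best-scoring one (leftmost on ties).
#'
#' @param mirnas named character vector, `DNAStringSet`/`RNAStringSet`, or
#'   FASTA path of mature miRNA sequences.
#' @param transcripts `DNAStringSet`, named character vector or FASTA path.
#' @param gu_blocks_adjacency passed to [apply_rules()].
#' @param merge merge overlapping passing windows of one miRNA to the
#'   best-scoring one (default); set `FALSE` to report every passing window.
#' @return data.frame sorted by (transcript, position): `mirna_id`,
#'   `transcript_id`, `start`, `end` (1-based inclusive), `score`,
#'   `mfe_duplex`, `mfe_perfect`, `mfe_ratio`.
#' @export
scan_transcripts <- function(mirnas, transcripts, gu_blocks_adjacency = FALSE,
                             merge = TRUE) {
  if (is.character(mirnas) && length(mirnas) == 1 && file.exists(mirnas)) {
    mirnas <- Biostrings::readBStringSet(mirnas)
  }
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  if (length(transcripts) == 0) stop("no transcripts to scan", call. = FALSE)
  out <- list()
  for (mi in seq_along(mirnas)) {
    L <- nchar(mirnas[mi])
    for (ti in seq_along(transcripts)) {
      tx <- transcripts[ti]
      if (nchar(tx) < L) next
      hits <- list()
      for (s in seq_len(nchar(tx) - L + 1L)) {
        site <- substr(tx, s, s + L - 1L)
        dup <- align_duplex(mirnas[mi], site)
        if (all(apply_rules(dup, gu_blocks_adjacency))) {
          hits[[length(hits) + 1L]] <- data.frame(
            mirna_id = names(mirnas)[mi], transcript_id = names(transcripts)[ti],
            start = s, end = s + L - 1L, score = dup$mismatch_score,
            mfe_duplex = dup$mfe_duplex, mfe_perfect = dup$mfe_perfect,
            mfe_ratio = dup$mfe_duplex / dup$mfe_perfect,
            stringsAsFactors = FALSE)
        }
      }
      if (length(hits) == 0) next
      h <- do.call(rbind, hits)
      if (merge) {
        # merge overlapping windows: keep the best-scoring of each cluster
        keep <- logical(nrow(h))
        i <- 1L
        while (i <= nrow(h)) {
          j <- i
          while (j < nrow(h) && h$start[j + 1L] <= h$end[i]) j <- j + 1L
          cluster <- i:j
          keep[cluster[which.min(h$score[cluster])]] <- TRUE
          i <- j + 1L
        }
        h <- h[keep, , drop = FALSE]
      }
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      mfe_duplex = numeric(0), mfe_perfect = numeric(0),
                      mfe_ratio = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$start, res$mirna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
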