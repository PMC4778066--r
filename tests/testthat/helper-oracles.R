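# Independent oracles used across the test suite. These deliberately do NOT
# share code with the package implementation: the fold oracle enumerates all
# nested structures explicitly, the count-test oracle sums the printed formula
# term by term, and the target-rule oracle re-codes the rule set with plain
# loops.

# ---- brute-force folding oracle ---------------------------------------------

oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, 0)
}

oracle_can_pair <- function(a, b) oracle_pair_e(a, b) < 0

# score a structure given as a list of pairs (2-col matrix of i<j indices):
# a pair directly stacked inside an adjacent outer pair contributes its own
# pair energy
oracle_score <- function(chars, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  partner <- integer(length(chars))
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i > 1 && j < length(chars) && partner[i - 1] == j + 1) {
      e <- e + oracle_pair_e(chars[i], chars[j])
    }
  }
  e
}

# enumerate every nested structure (min hairpin loop 3) and return the
# minimum score
oracle_fold_mfe <- function(sequence) {
  chars <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  n <- length(chars)
  cache <- new.env(parent = emptyenv())
  structs <- function(i, j) {
    if (j - i < 4) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- structs(i + 1, j)  # i unpaired
    for (k in (i + 4):j) {
      if (!oracle_can_pair(chars[i], chars[k])) next
      left <- structs(i + 1, k - 1)
      right <- if (k + 1 <= j) structs(k + 1, j) else list(NULL)
      for (s1 in left) for (s2 in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    cache[[key]] <- out
    out
  }
  if (n < 5) return(0)
  min(vapply(structs(1, n), function(s) oracle_score(chars, s), numeric(1)))
}

# ---- exact count-test oracle ------------------------------------------------

# p(y|x) by term-by-term recursion of the formula:
#   p(0|x) = (1+r)^-(x+1),  p(y+1)/p(y) = r (x+y+1) / ((y+1)(1+r));
# both tails by direct summation (upper until machine-precision convergence)
oracle_count_test <- function(x, y, N1, N2) {
  r <- N2 / N1
  p <- (1 + r)^-(x + 1)
  lower <- p
  for (yy in seq_len(y)) {
    p <- p * r * (x + yy) / (yy * (1 + r))
    lower <- lower + p
  }
  upper <- 0
  t <- p
  yy <- y
  repeat {
    upper <- upper + t
    yy <- yy + 1
    t <- t * r * (x + yy) / (yy * (1 + r))
    if (t <= upper * 1e-18 && yy > y + 10) break
  }
  list(p_point = p, tail_lower = min(lower, 1), tail_upper = min(upper, 1),
       p_reported = min(min(lower, 1), min(upper, 1)))
}

# ---- target-rule oracle -----------------------------------------------------

oracle_rna_comp <- c(A = "U", C = "G", G = "C", U = "A")

# evaluate one equal-length window independently; returns TRUE if it passes
# all six rules
oracle_window_passes <- function(mirna, site) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1]])
  L <- length(m)
  state <- character(L)
  for (i in seq_len(L)) {
    if (oracle_rna_comp[[m[i]]] == s[i]) state[i] <- "WC"
    else if ((m[i] == "G" && s[i] == "U") || (m[i] == "U" && s[i] == "G")) state[i] <- "GU"
    else state[i] <- "MM"
  }
  w <- ifelse(state == "WC", 0, ifelse(state == "GU", 0.5, 1))
  # rule a
  if (sum(w) > 4) return(FALSE)
  # rules b & c: runs of MM (GU does not block adjacency)
  run <- 0
  for (i in seq_len(L)) {
    run <- if (state[i] == "MM") run + 1 else 0
    if (run > 2) return(FALSE)                           # b
    if (run > 1 && i >= 3 && i <= 12) return(FALSE)      # c (positions 2-12)
    if (run > 1 && i == 2) return(FALSE)
  }
  # rule d
  if (state[10] != "WC" || state[11] != "WC") return(FALSE)
  # rule e
  if (sum(w[1:12]) > 2.5) return(FALSE)
  # rule f: stacked-pair duplex energies
  dup_e <- 0; per_e <- 0
  for (i in 2:L) {
    if (state[i] != "MM" && state[i - 1] != "MM") {
      dup_e <- dup_e + oracle_pair_e(m[i], s[i])
    }
    per_e <- per_e + oracle_pair_e(m[i], oracle_rna_comp[[m[i]]])
  }
  if (per_e >= 0) return(FALSE)
  dup_e / per_e > 0.75
}

# exhaustive scan of equal-length windows with the oracle checker
oracle_scan <- function(mirna, transcript) {
  L <- nchar(mirna)
  hits <- integer(0)
  for (s in seq_len(max(0, nchar(transcript) - L + 1))) {
    if (oracle_window_passes(mirna, substr(transcript, s, s + L - 1))) {
      hits <- c(hits, s)
    }
  }
  hits
}

# ---- shared fixtures --------------------------------------------------------

small_spec <- function(seed = 1L) {
  synthetic_genome_spec(genome_length = 20000, n_known_mirnas = 4,
                        n_novel_hairpins = 3,
                        n_ncrna_fragments = c(rRNA = 1, tRNA = 1, snRNA = 1,
                                              snoRNA = 1),
                        n_genes = 3, n_repeats = 2, n_unmappable = 2,
                        seed = seed)
}

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome(small_spec(), dir = tempfile())
    cache
  }
})

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# substitute bases outside the mature (one arm position at a time, with a
# homopolymer filler) until the engine MFE rises strictly above the
# -18 kcal/mol precursor gate
weaken_hairpin <- function(pre, m1, m2) {
  other <- setdiff(seq_len(nchar(pre)), m1:m2)
  for (filler in c("C", "A", "G", "T")) {
    mut <- pre
    for (pos in other) {
      if (fold(mut)$mfe > -18) return(mut)
      substr(mut, pos, pos) <- filler
    }
    if (fold(mut)$mfe > -18) return(mut)
  }
  stop("could not weaken hairpin below the energy gate")
}
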