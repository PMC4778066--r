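#' Relative expression from qRT-PCR Ct values (ddCt)
#'
#' Technical replicates are averaged first; then per biological replicate
#' dCt = Ct(gene) - Ct(internal standard), ddCt = dCt - mean dCt of the
#' reference condition, and relative expression = 2^-ddCt. The reference
#' condition mean is 1 by construction. Adding a constant to every Ct leaves
#' the result unchanged.
#'
#' @param ct data.frame with columns `condition`, `bio_rep`, `tech_rep`,
#'   `target_ct`, `reference_ct` (Ct of the internal-standard gene in the
#'   same well).
#' @param reference_condition condition used as the reference sample
#'   (default `"control"`).
#' @return data.frame with one row per condition: `condition`, `mean`
#'   (relative expression), `sd` (over biological replicates), `n`.
#' @export
ddct_relative_expression <- function(ct, reference_condition = "control") {
  needed <- c("condition", "bio_rep", "tech_rep", "target_ct", "reference_ct")
  stopifnot(all(needed %in% names(ct)))
  if (any(is.na(ct$reference_ct))) {
    stop("missing internal-standard Ct value", call. = FALSE)
  }
  if (!reference_condition %in% ct$condition) {
    stop(sprintf("reference condition '%s' not present", reference_condition),
         call. = FALSE)
  }
  # average technical replicates within each (condition, bio_rep)
  key <- interaction(ct$condition, ct$bio_rep, drop = TRUE)
  agg <- stats::aggregate(cbind(target_ct = ct$target_ct,
                                reference_ct = ct$reference_ct),
                          by = list(condition = ct$condition,
                                    bio_rep = ct$bio_rep), FUN = mean)
  agg$dct <- agg$target_ct - agg$reference_ct
  ref_mean <- mean(agg$dct[agg$condition == reference_condition])
  agg$rel <- 2^-(agg$dct - ref_mean)
  out <- stats::aggregate(agg$rel, by = list(condition = agg$condition),
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  data.frame(condition = out$condition,
             mean = out$x[, "mean"], sd = out$x[, "sd"],
             n = as.integer(out$x[, "n"]), stringsAsFactors = FALSE)
}

#' Classify miRNA/target direction concordance
#'
#' A target is classified `reverse` when it moves opposite to its miRNA
#' (miRNA down and target relative expression above 1, or miRNA up and
#' target below 1), `same` when it moves with the miRNA (or does not move:
#' relative expression exactly 1 is logged and counted as `same`), and
#' `not_detected` when the target expression is absent (`NA` or `"ND"`).
#'
#' @param mirna_log2fc numeric vector of miRNA log2 fold changes (sign gives
#'   the miRNA direction).
#' @param target_rel numeric vector of target relative expression values
#'   (control = 1), `NA` for not detected.
#' @return character vector of classifications.
#' @export
classify_concordance <- function(mirna_log2fc, target_rel) {
  stopifnot(length(mirna_log2fc) == length(target_rel))
  if (any(!is.na(target_rel) & target_rel == 1)) {
    message("target relative expression exactly 1 counted as 'same'")
  }
  ifelse(is.na(target_rel), "not_detected",
         ifelse((mirna_log2fc < 0 & target_rel > 1) |
                  (mirna_log2fc > 0 & target_rel < 1), "reverse", "same"))
}

#' Count concordance classes
#'
#' @param records data.frame with `mirna_log2fc` and `target_rel` columns (a
#'   `classification` column is computed if absent).
#' @return list with `n_reverse`, `n_same`, `n_not_detected`, `total` and
#'   `pct_reverse` (percentage of all records, rounded to integer).
#' @export
concordance_counts <- function(records) {
  if (!"classification" %in% names(records)) {
    records$classification <- classify_concordance(records$mirna_log2fc,
                                                   records$target_rel)
  }
  n_rev <- sum(records$classification == "reverse")
  n_same <- sum(records$classification == "same")
  n_nd <- sum(records$classification == "not_detected")
  total <- nrow(records)
  list(n_reverse = n_rev, n_same = n_same, n_not_detected = n_nd,
       total = total,
       pct_reverse = if (total > 0) as.integer(round(n_rev / total * 100)) else NA_integer_)
}

#' Read a miRNA/target concordance table
#'
#' Reads a TSV with columns `mirna_id`, `mirna_log2fc`, `target_id`,
#' `target_rel` (`ND` or empty = not detected). The package bundles such a
#' table (`extdata/target_qpcr_concordance.tsv`) with qRT-PCR relative
#' expression for 77 predicted target genes of 23 magnesium-deficiency-
#' responsive citrus miRNAs.
#'
#' @param path TSV path.
#' @return data.frame with `target_rel` numeric (`NA` = not detected).
#' @export
read_concordance_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  stopifnot(all(c("mirna_id", "mirna_log2fc", "target_id", "target_rel") %in%
                  names(df)))
  df$mirna_log2fc <- as.numeric(df$mirna_log2fc)
  df$target_rel <- suppressWarnings(as.numeric(ifelse(df$target_rel %in%
                                                        c("ND", ""), NA, df$target_rel)))
  df
}

#' Tally GO terms for predicted target genes
#'
#' Counts, per ontology category, how many of the given genes map to each GO
#' term; a gene with several terms in one category is counted once under each
#' term, and genes without any mapping are tallied as unannotated.
#'
#' @param genes character vector of gene ids.
#' @param mapping data.frame (or TSV path) with columns `gene`, `term`,
#'   `category`; every category must be one of `biological process`,
#'   `molecular function`, `cellular component`.
#' @return list with `tallies` (data.frame `category`, `term`, `n_genes`) and
#'   `unannotated` (count of genes with no mapping).
#' @export
go_tally <- function(genes, mapping) {
  if (is.character(mapping)) mapping <- read_tsv(mapping)
  valid <- c("biological process", "molecular function", "cellular component")
  if (nrow(mapping) > 0 && !all(mapping$category %in% valid)) {
    stop("unknown GO category label: ",
         paste(setdiff(unique(mapping$category), valid), collapse = ", "),
         call. = FALSE)
  }
  genes <- unique(genes)
  m <- unique(mapping[mapping$gene %in% genes, c("gene", "term", "category")])
  if (nrow(m) == 0) {
    tallies <- data.frame(category = character(0), term = character(0),
                          n_genes = integer(0), stringsAsFactors = FALSE)
  } else {
    tallies <- stats::aggregate(list(n_genes = m$gene),
                                by = list(category = m$category, term = m$term),
                                FUN = function(x) length(unique(x)))
    tallies <- tallies[order(tallies$category, -tallies$n_genes, tallies$term), ,
                       drop = FALSE]
    rownames(tallies) <- NULL
  }
  list(tallies = tallies, unannotated = sum(!genes %in% mapping$gene))
}
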