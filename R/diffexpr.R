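#' Tags-per-million normalization
#'
#' Normalized expression = count / total clean reads x 1,000,000.
#'
#' @param count read count(s) of a miRNA (non-negative).
#' @param total total clean reads of the library (> 0).
#' @return TPM value(s).
#' @examples
#' normalize_tpm(100, 1e6)
#' @export
normalize_tpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / total * 1e6
}

#' Log2 fold change between two TPM values
#'
#' Zeros are replaced by a small pseudo-TPM before forming the ratio so that
#' miRNAs detected in only one library get a finite, large-magnitude fold
#' change (e.g. TPM 2000 vs 0 with the default pseudo-count gives
#' log2(200000) ~ 17.6).
#'
#' @param tpm_def TPM in the treatment (deficiency) library.
#' @param tpm_ctl TPM in the control library.
#' @param pseudo pseudo-TPM substituted for zeros (default 0.01).
#' @return log2(tpm_def / tpm_ctl) after zero replacement.
#' @export
log2_fold_change <- function(tpm_def, tpm_ctl, pseudo = 0.01) {
  stopifnot(all(tpm_def >= 0), all(tpm_ctl >= 0), pseudo > 0)
  log2(ifelse(tpm_def == 0, pseudo, tpm_def) /
         ifelse(tpm_ctl == 0, pseudo, tpm_ctl))
}

# log point probability log p(y | x) for the exact conditional count test:
#   p(y|x) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1)
# computed in log space via lgamma for numerical stability.
log_p_point <- function(x, y, N1, N2) {
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Exact conditional test for a count observed in two libraries
#'
#' Given a miRNA observed `x` times among `N1` clean reads in one library and
#' `y` times among `N2` in the other, the conditional probability of each
#' possible `y` given `x` is
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!} (1 + N_2/N_1)^{-(x+y+1)}}
#' and significance is assessed from the two one-sided tail sums
#' \eqn{D(y \ge y_{obs}|x)} and \eqn{C(y \le y_{obs}|x)}. This is the exact
#' count-based test of Audic & Claverie generalized to unequal library depths.
#'
#' @param x,y observed integer counts in library 1 (control) and 2 (treatment).
#' @param N1,N2 total clean reads of the two libraries (> 0).
#' @param reported how to form the reported p-value from the two one-sided
#'   tails: `"min"` (default) uses min(lower, upper); `"2min"` doubles it,
#'   capped at 1.
#' @return list of class `exact_count_test` with `p_point` = p(y_obs|x),
#'   `tail_lower` = C(y <= y_obs|x), `tail_upper` = D(y >= y_obs|x) and
#'   `p_reported`. The tails overlap in the point mass, so
#'   tail_lower + tail_upper - p_point = 1.
#' @examples
#' exact_count_test(5, 15, 1e6, 1e6)
#' @export
exact_count_test <- function(x, y, N1, N2, reported = c("min", "2min")) {
  reported <- match.arg(reported)
  if (length(x) != 1L || length(y) != 1L) stop("x and y must be scalars", call. = FALSE)
  if (x < 0 || y < 0 || x != round(x) || y != round(y)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (N1 <= 0 || N2 <= 0) stop("library totals must be > 0", call. = FALSE)
  p_point <- exp(log_p_point(x, y, N1, N2))
  # lower tail C(y' <= y | x) by direct summation of the point masses
  tail_lower <- min(sum(exp(log_p_point(x, 0:y, N1, N2))), 1)
  # upper tail D(y' >= y | x) by direct summation to machine-precision
  # convergence (the 1 - lower + point complement loses relative precision
  # for very small tails)
  tail_upper <- 0
  from <- y
  chunk <- 256L
  repeat {
    terms <- exp(log_p_point(x, from:(from + chunk - 1L), N1, N2))
    tail_upper <- tail_upper + sum(terms)
    if (terms[chunk] <= tail_upper * 1e-17) break
    from <- from + chunk
  }
  tail_upper <- min(tail_upper, 1)
  p_reported <- min(tail_lower, tail_upper)
  if (reported == "2min") p_reported <- min(1, 2 * p_reported)
  structure(list(p_point = p_point, tail_lower = tail_lower,
                 tail_upper = tail_upper, p_reported = p_reported),
            class = "exact_count_test")
}

#' Build per-miRNA expression records for two libraries
#'
#' Computes TPMs, the log2 fold change (treatment over control) and the exact
#' conditional count test for every miRNA, producing the table on which the
#' low-expression filter and the differential-expression call operate.
#'
#' @param counts data.frame with columns `id`, `x` (control count) and `y`
#'   (treatment count).
#' @param N1,N2 total clean reads of the control and treatment libraries.
#' @param pseudo pseudo-TPM for zero replacement in the fold change.
#' @param reported tail-combination rule passed to [exact_count_test()].
#' @return data.frame with one row per miRNA: `id`, `x`, `y`, `tpm_ctl`,
#'   `tpm_def`, `log2fc`, `p_point`, `tail_lower`, `tail_upper`, `p_reported`.
#' @export
mirna_expression_records <- function(counts, N1, N2, pseudo = 0.01,
                                     reported = "min") {
  stopifnot(all(c("id", "x", "y") %in% names(counts)))
  tpm_ctl <- normalize_tpm(counts$x, N1)
  tpm_def <- normalize_tpm(counts$y, N2)
  tests <- lapply(seq_len(nrow(counts)), function(i) {
    exact_count_test(counts$x[i], counts$y[i], N1, N2, reported = reported)
  })
  data.frame(
    id = as.character(counts$id),
    x = counts$x, y = counts$y,
    N1 = N1, N2 = N2,
    tpm_ctl = tpm_ctl, tpm_def = tpm_def,
    log2fc = log2_fold_change(tpm_def, tpm_ctl, pseudo = pseudo),
    p_point = vapply(tests, `[[`, numeric(1), "p_point"),
    tail_lower = vapply(tests, `[[`, numeric(1), "tail_lower"),
    tail_upper = vapply(tests, `[[`, numeric(1), "tail_upper"),
    p_reported = vapply(tests, `[[`, numeric(1), "p_reported"),
    stringsAsFactors = FALSE
  )
}

#' Drop miRNAs with low expression in both libraries
#'
#' A miRNA is removed only when its normalized expression is below the
#' threshold in BOTH libraries; expression at or above the threshold in either
#' library retains it.
#'
#' @param records data.frame with `tpm_ctl` and `tpm_def` columns.
#' @param threshold TPM threshold (default 10).
#' @return the retained rows of `records`.
#' @export
low_expression_filter <- function(records, threshold = 10) {
  stopifnot(all(c("tpm_ctl", "tpm_def") %in% names(records)))
  records[records$tpm_ctl >= threshold | records$tpm_def >= threshold, ,
          drop = FALSE]
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is significant when its reported p-value is below `p_cutoff` AND
#' the magnitude of its fold change exceeds `fc_cutoff`. By default the fold
#' change gate is applied on the log2 scale (|log2fc| > 1.5); set
#' `fc_scale = "ratio"` to gate on the raw ratio instead.
#'
#' @param records output of [mirna_expression_records()] (optionally filtered).
#' @param p_cutoff p-value threshold (default 0.01).
#' @param fc_cutoff fold-change threshold (default 1.5).
#' @param fc_scale `"log2"` (default) or `"ratio"`.
#' @return `records` with `significant` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns added, sorted by |log2fc| descending
#'   (ties broken by id).
#' @export
call_differential <- function(records, p_cutoff = 0.01, fc_cutoff = 1.5,
                              fc_scale = c("log2", "ratio")) {
  fc_scale <- match.arg(fc_scale)
  fc_mag <- if (fc_scale == "log2") abs(records$log2fc) else 2^abs(records$log2fc)
  records$significant <- records$p_reported < p_cutoff & fc_mag > fc_cutoff
  records$direction <- ifelse(!records$significant, "none",
                              ifelse(records$log2fc > 0, "up", "down"))
  ord <- order(-abs(records$log2fc), records$id)
  records[ord, , drop = FALSE]
}
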