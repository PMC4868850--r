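# Cross-study directional concordance: map a prior study's directional
# gene list onto the current expression data, score sign agreement
# against chance, run direction-specified one-tailed tests, and compute
# the expected-direction FDR (T * alpha) / n_sig.

#' Match a prior direction set against detected genes
#'
#' Restricts a prior study's directional gene list to genes present in
#' the current data. Symbols are matched case-insensitively, so a human
#' SST matches a rat Sst. T, the number of genes tested in all
#' concordance statistics, is the size of the matched set.
#'
#' @param prior A [direction_set()].
#' @param detected A count matrix, \code{norm_mat}, or character vector
#'   of detected gene ids.
#' @return A \code{direction_set} restricted to matched entries, with an
#'   extra \code{gene_id} column carrying the detected id.
#' @export
match_genes <- function(prior, detected) {
  ids <- if (is.character(detected)) detected else rownames(expr_values(detected))
  key <- tolower(ids)
  hit <- match(prior$key, key)
  matched <- prior[!is.na(hit), , drop = FALSE]
  matched$gene_id <- ids[hit[!is.na(hit)]]
  if (nrow(matched) == 0L) warning("no prior genes matched the detected universe")
  attr(matched, "name") <- attr(prior, "name")
  class(matched) <- c("direction_set", "data.frame")
  matched
}

#' Directional agreement with a prior study
#'
#' For each matched gene, the observed direction is the sign of the
#' level-2 minus level-1 group mean difference on the linear expression
#' scale; agreement counts genes whose observed sign equals the prior
#' direction. Exactly tied means cannot agree with a +/-1 prediction
#' and are counted as disagreeing.
#'
#' @param matched A matched \code{direction_set} (see [match_genes()]).
#' @param expr Expression matrix or \code{norm_mat} containing the
#'   matched genes.
#' @param groups Two-level factor over samples (contrast: level 2 minus
#'   level 1).
#' @return List with \code{T} (genes tested), \code{n_same} and
#'   \code{percent_same} (rounded to the nearest integer percent).
#' @export
direction_agreement <- function(matched, expr, groups) {
  if (nrow(matched) == 0L) stop("empty matched set", call. = FALSE)
  lin <- expr_linear(expr)
  groups <- check_groups(groups, ncol(lin))
  m <- lin[matched$gene_id, , drop = FALSE]
  diff <- rowMeans(m[, groups == levels(groups)[2L], drop = FALSE]) -
    rowMeans(m[, groups == levels(groups)[1L], drop = FALSE])
  n_same <- sum(sign(diff) == matched$direction)
  list(T = nrow(matched), n_same = n_same,
       percent_same = round(100 * n_same / nrow(matched)))
}

#' Chi-square test of directional agreement against chance
#'
#' One-degree-of-freedom goodness-of-fit of the observed
#' (agree, disagree) split against the 50:50 split expected by chance,
#' without continuity correction.
#'
#' @param n_same Number of genes changing in the predicted direction.
#' @param T Total genes tested.
#' @return List with \code{chi2} and \code{p}.
#' @export
chi_square_direction <- function(n_same, T) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (n_same < 0 || n_same > T) stop("n_same must lie in [0, T]", call. = FALSE)
  ct <- suppressWarnings(
    stats::chisq.test(c(n_same, T - n_same), p = c(0.5, 0.5))
  )
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Expected-direction false discovery rate
#'
#' The concordance FDR: the number of genes expected to reach one-tailed
#' significance in the predicted direction by chance, T * alpha, divided
#' by the number observed to do so.
#'
#' @param T Total genes tested.
#' @param alpha Per-gene one-tailed significance level.
#' @param n_sig Genes significant in the predicted direction.
#' @return The FDR (T * alpha) / n_sig, or NA when n_sig is 0.
#' @export
expected_direction_fdr <- function(T, alpha, n_sig) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_sig < 0 || n_sig > T) stop("n_sig must lie in [0, T]", call. = FALSE)
  if (n_sig == 0) return(NA_real_)
  (T * alpha) / n_sig
}

#' Direction-specified one-tailed tests with expected-direction FDR
#'
#' Runs, for every matched gene, a pooled-variance two-sample t-test
#' one-tailed in the direction the prior study predicts, and assembles
#' the full concordance report: directional agreement, the chi-square
#' test against chance, directed significant counts split by predicted
#' direction, and the expected-direction FDR. Genes with zero variance
#' in both groups remain in T (T is the number of genes tested, not a
#' post-hoc filtered count) but cannot reach significance; they are
#' reported untestable.
#'
#' @param matched A matched \code{direction_set}.
#' @param expr Expression (\code{norm_mat} recommended, log2 scale for
#'   the t-tests; fold changes use the linear scale).
#' @param groups Two-level factor (contrast: level 2 minus level 1).
#' @param alpha One-tailed per-gene significance level.
#' @return An object of class \code{concordance_report}: list with
#'   \code{name}, \code{T}, \code{n_same}, \code{percent_same},
#'   \code{chi2}, \code{chi2_p}, \code{alpha}, \code{n_sig},
#'   \code{n_sig_up}, \code{n_sig_down}, \code{expected_sig},
#'   \code{fdr}, \code{n_untestable} and a per-gene data frame
#'   \code{genes} (symbol, predicted direction, one-tailed p, signed
#'   fold, significance).
#' @export
directed_tests <- function(matched, expr, groups, alpha = 0.05) {
  if (nrow(matched) == 0L) stop("empty matched set", call. = FALSE)
  m <- expr_values(expr)
  groups <- check_groups(groups, ncol(m), min_per_group = 2L)
  sub <- m[matched$gene_id, , drop = FALSE]
  ts <- row_pooled_t(sub, groups)
  # one-tailed p in the predicted direction
  p_one <- stats::pt(matched$direction * ts$t, df = ts$df, lower.tail = FALSE)
  untestable <- !is.finite(ts$t)
  sig <- !untestable & !is.na(p_one) & p_one < alpha

  lin <- expr_linear(expr)[matched$gene_id, , drop = FALSE]
  mu1 <- rowMeans(lin[, groups == levels(groups)[1L], drop = FALSE])
  mu2 <- rowMeans(lin[, groups == levels(groups)[2L], drop = FALSE])
  fold <- signed_fold(ifelse(mu1 > 0, mu2 / mu1, NA_real_))

  agree <- direction_agreement(matched, expr, groups)
  chi <- chi_square_direction(agree$n_same, agree$T)
  n_sig <- sum(sig)
  report <- list(
    name = attr(matched, "name"),
    T = agree$T,
    n_same = agree$n_same,
    percent_same = agree$percent_same,
    chi2 = chi$chi2,
    chi2_p = chi$p,
    alpha = alpha,
    n_sig = n_sig,
    n_sig_up = sum(sig & matched$direction == 1),
    n_sig_down = sum(sig & matched$direction == -1),
    expected_sig = agree$T * alpha,
    fdr = if (n_sig > 0) (agree$T * alpha) / n_sig else NA_real_,
    n_untestable = sum(untestable),
    genes = data.frame(
      symbol = matched$symbol,
      gene_id = matched$gene_id,
      predicted_direction = matched$direction,
      t = ts$t,
      p_one_tailed = p_one,
      fold_change = fold,
      significant = sig,
      untestable = untestable,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  )
  class(report) <- "concordance_report"
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance with '%s'\n", x$name))
  cat(sprintf("  genes tested (T):       %d\n", x$T))
  cat(sprintf("  same direction:         %d (%d%%)\n", x$n_same, x$percent_same))
  cat(sprintf("  chi-square (1 df):      %.2f, p = %.3g\n", x$chi2, x$chi2_p))
  cat(sprintf("  one-tailed alpha:       %.3f\n", x$alpha))
  cat(sprintf("  significant, predicted: %d (%d up, %d down)\n",
              x$n_sig, x$n_sig_up, x$n_sig_down))
  cat(sprintf("  expected by chance:     %.1f\n", x$expected_sig))
  cat(sprintf("  expected-direction FDR: %s\n",
              if (is.na(x$fdr)) "n/a (no significant genes)" else
                sprintf("%.2f", round_half_up(x$fdr, 2))))
  invisible(x)
}
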