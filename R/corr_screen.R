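#' Critical Pearson correlation for a two-tailed test
#'
#' The smallest correlation magnitude reaching two-tailed significance
#' level \code{alpha} at sample size \code{n}, obtained by inverting the
#' t transform t = r * sqrt((n - 2) / (1 - r^2)) at the two-tailed
#' critical t with n - 2 degrees of freedom. At alpha = 0.025 and n = 20
#' this reproduces the screening cutoff r = 0.499.
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param n Number of paired observations (>= 3).
#' @return Critical |r|.
#' @export
critical_r <- function(alpha, n) {
  if (n < 3) stop("critical_r requires n >= 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Gene-wise Pearson correlation with a behavioral score
#'
#' Correlates each gene's expression with a per-sample behavioral score,
#' typically restricted to aged animals to remove age as a confound.
#' Samples with missing scores are dropped before computing anything.
#' Two-tailed p-values come from the t transform with n - 2 degrees of
#' freedom, so the significance call is exactly equivalent to
#' |r| >= [critical_r()].
#'
#' @param expr A \code{norm_mat} or matrix, genes x samples.
#' @param scores Numeric score per sample (aligned with columns; may
#'   contain NA).
#' @param alpha Two-tailed significance threshold.
#' @return Data frame: \code{gene_id}, \code{r}, \code{p_value},
#'   \code{n}, \code{significant}. Constant genes get NA r/p and a FALSE
#'   significance flag.
#' @export
correlate_genes <- function(expr, scores, alpha = 0.025) {
  m <- expr_values(expr)
  if (length(scores) != ncol(m)) {
    stop("'scores' must have one value per sample column", call. = FALSE)
  }
  keep <- !is.na(scores)
  if (sum(keep) < 3L) {
    stop("need at least 3 samples with non-missing scores", call. = FALSE)
  }
  m <- m[, keep, drop = FALSE]
  s <- scores[keep]
  n <- length(s)
  if (stats::sd(s) == 0) stop("scores are constant; r undefined", call. = FALSE)

  zs <- (s - mean(s)) / stats::sd(s)
  mu <- rowMeans(m)
  sds <- sqrt(rowSums((m - mu)^2) / (n - 1))
  const <- sds == 0
  r <- as.numeric((m - mu) %*% zs) / ((n - 1) * sds)
  r[const] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  data.frame(
    gene_id = rownames(m),
    r = r,
    p_value = p,
    n = n,
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Partition significant correlations by sign
#'
#' Counts significantly correlated genes by the sign of r and reports
#' the rounded percentage shares. For trials-to-criterion scores a
#' positive r means higher expression in more impaired animals; for the
#' discrimination index the interpretation is mirrored (positive r means
#' higher expression in better learners).
#'
#' @param results A [correlate_genes()] result data frame.
#' @return List with \code{n_positive}, \code{n_negative},
#'   \code{percent_positive}, \code{percent_negative} (rounded to whole
#'   percent; NA when nothing is significant).
#' @export
partition_by_sign <- function(results) {
  sig <- results[results$significant & !is.na(results$r), , drop = FALSE]
  n_pos <- sum(sig$r > 0)
  n_neg <- sum(sig$r < 0)
  tot <- n_pos + n_neg
  list(
    n_positive = n_pos,
    n_negative = n_neg,
    percent_positive = if (tot > 0) round(100 * n_pos / tot) else NA_real_,
    percent_negative = if (tot > 0) round(100 * n_neg / tot) else NA_real_
  )
}

#' Pairwise correlations among behavioral measures
#'
#' Pearson correlations between every pair of behavioral measures over
#' aged animals, with pairwise-complete observations, the layout of a
#' behavioral-correlation table. Cells with fewer than 3 complete pairs
#' are reported missing.
#'
#' @param samples Sample table containing an \code{age_group} column and
#'   the behavioral measures.
#' @param measures Character vector of measure columns to correlate.
#' @param group Which age group to use (default aged).
#' @return List of symmetric matrices \code{r}, \code{p}, \code{n}.
#' @export
behavior_correlation_table <- function(samples,
                                       measures = c("visual_ttc",
                                                    "set_shift_ttc",
                                                    "cue_block5",
                                                    "spatial_block5",
                                                    "crossings",
                                                    "discrimination_index"),
                                       group = "aged") {
  measures <- intersect(measures, names(samples))
  sub <- samples[samples$age_group %in% group, measures, drop = FALSE]
  k <- length(measures)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- sub[[i]]; y <- sub[[j]]
      ok <- !is.na(x) & !is.na(y)
      nm[i, j] <- sum(ok)
      if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        r[i, j] <- stats::cor(x[ok], y[ok])
        if (i == j) {
          p[i, j] <- 0
        } else {
          p[i, j] <- stats::cor.test(x[ok], y[ok])$p.value
        }
      }
    }
  }
  list(r = r, p = p, n = nm)
}
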