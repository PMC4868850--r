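# Per-gene two-group screening. With two groups the one-way ANOVA F is
# exactly the square of the pooled two-sample t, so the screen is
# computed from vectorized group means and variances; the equivalence is
# exercised against stats::aov / stats::t.test in the test suite.

row_group_stats <- function(m, idx) {
  n <- length(idx)
  mu <- rowMeans(m[, idx, drop = FALSE])
  va <- rowSums((m[, idx, drop = FALSE] - mu)^2) / (n - 1)
  list(n = n, mean = mu, var = va)
}

row_pooled_t <- function(m, groups) {
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  s1 <- row_group_stats(m, g1)
  s2 <- row_group_stats(m, g2)
  df <- s1$n + s2$n - 2L
  sp2 <- ((s1$n - 1L) * s1$var + (s2$n - 1L) * s2$var) / df
  se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  t <- (s2$mean - s1$mean) / se
  list(t = t, df = df, mean1 = s1$mean, mean2 = s2$mean)
}

#' Signed fold-change convention
#'
#' Converts a ratio of group means into the signed reporting convention
#' used for gene tables: ratios >= 1 are reported as-is, ratios below 1
#' as the negative reciprocal (a ratio of 0.84 is reported as -1.19).
#'
#' @param ratio Positive ratio of group means (numerator group over
#'   denominator group).
#' @return Signed fold change.
#' @export
signed_fold <- function(ratio) {
  ifelse(is.na(ratio) | ratio <= 0, NA_real_,
         ifelse(ratio >= 1, ratio, -1 / ratio))
}

#' Per-gene age-effect screen
#'
#' Runs a per-gene one-way ANOVA across the two age groups on the stored
#' expression scale (log2-normalized counts are the recommended input)
#' and flags genes at an uncorrected threshold, by default p < 0.025.
#' No multiplicity correction is applied at this stage: the screen feeds
#' set-level analyses (enrichment, concordance) rather than single-gene
#' claims. Direction and fold change are computed from group means on
#' the linear normalized scale.
#'
#' @param expr A \code{norm_mat} (or plain matrix) of expression values,
#'   genes x samples.
#' @param groups Two-level factor over samples; the contrast is level 2
#'   (e.g. aged) versus level 1 (e.g. young).
#' @param alpha Per-gene significance threshold.
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{statistic} (ANOVA F), \code{p_value}, \code{direction} (+1/-1
#'   sign of the level-2 minus level-1 linear mean; 0 for exact ties),
#'   \code{fold_change} (signed convention), \code{significant}.
#' @export
age_screen <- function(expr, groups, alpha = 0.025) {
  m <- expr_values(expr)
  groups <- check_groups(groups, ncol(m), min_per_group = 2L)
  ts <- row_pooled_t(m, groups)
  f <- ts$t^2
  p <- stats::pf(f, 1L, ts$df, lower.tail = FALSE)

  lin <- expr_linear(expr)
  mu1 <- rowMeans(lin[, groups == levels(groups)[1L], drop = FALSE])
  mu2 <- rowMeans(lin[, groups == levels(groups)[2L], drop = FALSE])
  ratio <- ifelse(mu1 > 0, mu2 / mu1, NA_real_)

  data.frame(
    gene_id = rownames(m),
    statistic = f,
    p_value = p,
    direction = sign(mu2 - mu1),
    fold_change = signed_fold(ratio),
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Signed fold change for one gene
#'
#' Ratio of group means on the linear normalized scale, reported in the
#' signed convention of [signed_fold()] (level 2 over level 1).
#'
#' @inheritParams age_screen
#' @param gene Gene id.
#' @return Signed fold change (NA, with a warning, if the denominator
#'   group mean is zero).
#' @export
fold_change <- function(expr, groups, gene) {
  lin <- expr_linear(expr)
  if (!gene %in% rownames(lin)) stop("unknown gene: ", gene, call. = FALSE)
  groups <- check_groups(groups, ncol(lin))
  x <- lin[gene, ]
  mu1 <- mean(x[groups == levels(groups)[1L]])
  mu2 <- mean(x[groups == levels(groups)[2L]])
  if (mu1 <= 0 || mu2 <= 0) {
    warning("zero group mean for gene ", gene, "; fold change undefined")
    return(NA_real_)
  }
  signed_fold(mu2 / mu1)
}

#' Cross-region overlap of significant genes
#'
#' Summarizes, for screens run independently per region, how many genes
#' rise or fall significantly in each region and how the significant
#' sets overlap between region pairs, split by direction. Pairwise
#' counts are computed over the intersection of the two regions' gene
#' universes.
#'
#' @param results Named list (one element per region) of [age_screen()]
#'   result data frames.
#' @return A list with \code{per_region} (region, n_up, n_down) and
#'   \code{pairwise} (region pair with same-direction and
#'   opposite-direction overlap counts) data frames.
#' @export
region_overlap <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L, !is.null(names(results)))
  sig_set <- function(res, dir) {
    res$gene_id[res$significant & res$direction == dir]
  }
  per_region <- data.frame(
    region = names(results),
    n_up = vapply(results, function(r) length(sig_set(r, 1)), integer(1)),
    n_down = vapply(results, function(r) length(sig_set(r, -1)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pairs <- if (length(results) >= 2L) utils::combn(names(results), 2L) else
    matrix(character(0), nrow = 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- results[[pairs[1L, k]]]; b <- results[[pairs[2L, k]]]
    common <- intersect(a$gene_id, b$gene_id)
    in_common <- function(g) intersect(g, common)
    data.frame(
      region_a = pairs[1L, k], region_b = pairs[2L, k],
      up_up = length(intersect(in_common(sig_set(a, 1)), sig_set(b, 1))),
      down_down = length(intersect(in_common(sig_set(a, -1)), sig_set(b, -1))),
      opposite = length(intersect(in_common(sig_set(a, 1)), sig_set(b, -1))) +
        length(intersect(in_common(sig_set(a, -1)), sig_set(b, 1))),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(pairwise)) {
    pairwise <- data.frame(region_a = character(), region_b = character(),
                           up_up = integer(), down_down = integer(),
                           opposite = integer())
  }
  list(per_region = per_region, pairwise = pairwise)
}

#' GO term over-representation
#'
#' One-sided hypergeometric over-representation test per GO term with at
#' least one hit in the gene set, followed by Benjamini-Hochberg
#' adjustment across the tested terms. This is a plain term-level
#' enrichment test; it does not perform fuzzy functional-annotation
#' clustering.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   \code{universe}).
#' @param universe Character vector, the tested gene universe.
#' @param anno Named list mapping gene id to GO terms.
#' @param q_cut Adjusted-p cutoff used for the \code{significant} flag.
#' @return Data frame sorted by adjusted p: \code{term},
#'   \code{term_size} (genes in universe with the term), \code{hits},
#'   \code{set_size}, \code{p_value}, \code{q_value},
#'   \code{significant}.
#' @export
go_enrichment <- function(gene_set, universe, anno, q_cut = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of universe", call. = FALSE)
  }
  empty <- data.frame(term = character(), term_size = integer(),
                      hits = integer(), set_size = integer(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical())
  if (length(gene_set) == 0L) return(empty)
  term_genes <- split(
    rep(universe, lengths(anno[universe])),
    unlist(anno[universe], use.names = FALSE)
  )
  hits <- vapply(term_genes, function(g) sum(g %in% gene_set), integer(1))
  tested <- hits > 0L
  if (!any(tested)) return(empty)
  term_size <- lengths(term_genes)[tested]
  hits <- hits[tested]
  N <- length(universe); n <- length(gene_set)
  p <- stats::phyper(hits - 1L, term_size, N - term_size, n,
                     lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(term_genes)[tested], term_size = term_size,
                    hits = hits, set_size = n, p_value = p, q_value = q,
                    significant = q < q_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
}
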