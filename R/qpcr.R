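#' Delta-delta-Ct relative quantification
#'
#' Standard comparative-CT quantification: per sample and target gene,
#' delta CT = CT(target) - CT(reference); delta-delta CT subtracts the
#' control group's mean delta CT for that gene; relative expression is
#' fold = 2^(-delta-delta CT). Technical replicate wells (repeated
#' sample/gene rows) are averaged arithmetically before the differences
#' are taken. Samples missing the reference gene are excluded with a
#' warning, because the plate-offset cancellation depends on it.
#'
#' @param ct Long CT table with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{ct}.
#' @param reference_gene Housekeeping gene used as the within-sample
#'   reference.
#' @param control_group Group label whose mean delta CT anchors fold = 1.
#' @return Data frame: \code{sample_id}, \code{group}, \code{gene},
#'   \code{delta_ct}, \code{delta_delta_ct}, \code{fold}, for every
#'   target (non-reference) gene.
#' @export
delta_delta_ct <- function(ct, reference_gene, control_group) {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  if (!any(ct$gene == reference_gene)) {
    stop("reference gene '", reference_gene, "' not in CT table", call. = FALSE)
  }
  if (!any(ct$group == control_group)) {
    stop("control group '", control_group, "' not in CT table", call. = FALSE)
  }
  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct, FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2L] <- "ref_ct"
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref) > 0L) {
    warning("excluding sample(s) without reference CT: ",
            paste(no_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% no_ref, , drop = FALSE]
  }
  tgt <- merge(tgt, ref, by = "sample_id")
  tgt$delta_ct <- tgt$ct - tgt$ref_ct
  ctrl_mean <- tapply(tgt$delta_ct[tgt$group == control_group],
                      tgt$gene[tgt$group == control_group], mean)
  tgt$delta_delta_ct <- tgt$delta_ct - as.numeric(ctrl_mean[tgt$gene])
  tgt$fold <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$group, tgt$sample_id),
             c("sample_id", "group", "gene", "delta_ct",
               "delta_delta_ct", "fold")]
  row.names(out) <- NULL
  out
}

#' Group comparison of relative expression
#'
#' Two-sample t-test between two groups of a [delta_delta_ct()] result
#' for one gene. By default the test runs on the delta-delta-CT scale
#' (expression differences are closer to normal on the log scale); the
#' fold scale is available. One- or two-tailed per \code{tails}, with
#' the alternative stated for group A relative to group B.
#'
#' @param rel [delta_delta_ct()] output.
#' @param gene Target gene to compare.
#' @param groups Length-2 character vector (A, B) of group labels.
#' @param tails \code{"two"}, or \code{"greater"}/\code{"less"} for a
#'   one-tailed test of A's expression relative to B's.
#' @param scale Test on \code{"ddct"} (default) or \code{"fold"} values.
#' @param var_equal Pooled-variance t-test (default TRUE, consistent
#'   with the one-way ANOVA screens).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
group_compare <- function(rel, gene, groups, tails = c("two", "greater", "less"),
                          scale = c("ddct", "fold"), var_equal = TRUE) {
  tails <- match.arg(tails)
  scale <- match.arg(scale)
  stopifnot(length(groups) == 2L)
  sub <- rel[rel$gene == gene & rel$group %in% groups, , drop = FALSE]
  a <- sub[sub$group == groups[1L], ]
  b <- sub[sub$group == groups[2L], ]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  # on the expression scale: higher expression means LOWER ddct, so the
  # alternative is flipped when testing ddct values
  va <- if (scale == "fold") a$fold else a$delta_delta_ct
  vb <- if (scale == "fold") b$fold else b$delta_delta_ct
  alt <- switch(tails, two = "two.sided", greater = "greater", less = "less")
  if (scale == "ddct" && alt != "two.sided") {
    alt <- if (alt == "greater") "less" else "greater"
  }
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    stop("degenerate variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(va, vb, alternative = alt, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
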