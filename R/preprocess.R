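#' Remove genes with low counts
#'
#' Reproduces the first filtering step of the screening pipeline: genes
#' whose per-gene summary of raw counts is 5 or less are removed before
#' any statistics are computed. The summary is the per-gene mean by
#' default (library-size comparable), with sum and max variants
#' available.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param threshold Removal threshold; genes with summary <= threshold
#'   are dropped ("counts of 5 or less").
#' @param mode Summary statistic: \code{"mean"}, \code{"sum"} or
#'   \code{"max"}.
#' @return The filtered count matrix (sample set unchanged).
#' @export
filter_low_counts <- function(counts, threshold = 5, mode = c("mean", "sum", "max")) {
  mode <- match.arg(mode)
  if (threshold < 0) stop_param("threshold", "must be >= 0")
  s <- switch(mode,
              mean = rowMeans(counts),
              sum = rowSums(counts),
              max = apply(counts, 1L, max))
  keep <- s > threshold
  if (!any(keep)) warning("all genes removed by low-count filter")
  counts[keep, , drop = FALSE]
}

#' Keep only GO-annotated genes
#'
#' Restricts the gene universe to genes carrying at least one gene
#' ontology term, the precondition for enrichment analysis downstream.
#'
#' @param counts Count matrix, genes x samples.
#' @param anno Named list mapping gene id to a character vector of GO
#'   terms (see [read_go_map()]).
#' @return The filtered count matrix.
#' @export
filter_go_annotated <- function(counts, anno) {
  n_terms <- lengths(anno[rownames(counts)])
  counts[n_terms > 0L, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The canonical median-of-ratios estimator: for each sample, the median
#' over genes (restricted to genes with nonzero counts in every sample,
#' so the geometric mean is well defined) of the ratio of the gene's
#' count to its across-sample geometric mean.
#'
#' @param counts Count matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    stop("no gene has nonzero counts in every sample; size factors undefined",
         call. = FALSE)
  }
  lc <- log(counts[keep, , drop = FALSE])
  lgeo <- rowMeans(lc)
  sf <- apply(lc, 2L, function(col) exp(stats::median(col - lgeo)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a count matrix
#'
#' Divides each sample's counts by its median-of-ratios size factor,
#' optionally followed by a log2(x + 1) transform. The result records
#' its scale so downstream screens can compute test statistics on the
#' log scale and fold changes on the linear scale.
#'
#' @param counts Count matrix, genes x samples.
#' @param log2 If TRUE, store log2(normalized + 1) values.
#' @param factors Optional precomputed size factors (defaults to
#'   [size_factors()] of \code{counts}).
#' @return An object of class \code{norm_mat}: a list with \code{values}
#'   (numeric matrix), \code{size_factors} and \code{log_transformed}.
#' @export
normalize_counts <- function(counts, log2 = FALSE, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) stop("size factors must be > 0", call. = FALSE)
  v <- sweep(counts, 2L, factors, `/`)
  if (log2) v <- base::log2(v + 1)
  structure(list(values = v, size_factors = factors,
                 log_transformed = isTRUE(log2)),
            class = "norm_mat")
}

#' @export
as.matrix.norm_mat <- function(x, ...) x$values

#' @export
dim.norm_mat <- function(x) dim(x$values)

#' @export
dimnames.norm_mat <- function(x) dimnames(x$values)

#' @export
print.norm_mat <- function(x, ...) {
  cat(sprintf("norm_mat: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_transformed) "log2(normalized + 1)" else "linear"))
  invisible(x)
}

#' Standardize expression rows to z-scores
#'
#' Each gene (row) is centered and scaled to unit sample standard
#' deviation (n - 1 denominator) across samples. Rows with zero
#' variance cannot be standardized and are dropped with a warning.
#'
#' @param x Numeric matrix or \code{norm_mat}.
#' @return A numeric matrix of row z-scores.
#' @export
zscore_rows <- function(x) {
  m <- expr_values(x)
  sds <- apply(m, 1L, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance row(s) excluded from z-scoring")
    m <- m[!drop, , drop = FALSE]
  }
  z <- t(scale(t(m)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Spike-in linearity QC
#'
#' Regresses log10(observed count) on log10(expected concentration) over
#' the detected transcripts (observed count > 0) and reports the fit
#' R-squared together with the detected count. The sample passes QC only when
#' R-squared exceeds 0.9 and at least 60 transcripts are detected; both
#' gates are strict as stated ("above 0.9", "at least 60").
#'
#' @param table Spike-in data frame with columns
#'   \code{expected_concentration} and \code{observed_count}.
#' @return An object of class \code{qc_report}: list with
#'   \code{r_squared}, \code{n_detected}, \code{passed}.
#' @export
spikein_qc <- function(table) {
  stopifnot(all(c("expected_concentration", "observed_count") %in% names(table)))
  if (any(table$expected_concentration <= 0)) {
    stop("expected concentrations must be > 0", call. = FALSE)
  }
  n_detected <- sum(table$observed_count > 0)
  r2 <- NA_real_
  if (n_detected >= 2L) {
    sub <- table[table$observed_count > 0, ]
    if (length(unique(sub$expected_concentration)) < 2L) {
      stop("degenerate spike-in design: all expected concentrations equal",
           call. = FALSE)
    }
    # for a simple linear regression, R^2 is the squared Pearson
    # correlation of response and predictor
    r2 <- stats::cor(log10(sub$observed_count),
                     log10(sub$expected_concentration))^2
  }
  structure(list(r_squared = r2, n_detected = n_detected,
                 passed = isTRUE(r2 > 0.9) && n_detected >= 60L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("spike-in QC: R^2 = %s, %d transcripts detected -> %s\n",
              format(x$r_squared, digits = 4), x$n_detected,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}
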