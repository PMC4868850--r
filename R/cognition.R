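#' Water-maze probe discrimination index
#'
#' (G - O) / (G + O), where G and O are the percentages of probe-trial
#' time spent in the goal quadrant and the quadrant opposite the goal.
#' Ranges over [-1, 1]; 0 means no spatial bias. Undefined (returned as
#' NA) when no time was spent in either quadrant.
#'
#' @param G,O Percent time in goal and opposite quadrants (vectorized).
#' @return Discrimination index values.
#' @export
discrimination_index <- function(G, O) {
  if (any(G < 0, na.rm = TRUE) || any(O < 0, na.rm = TRUE)) {
    stop("quadrant times must be nonnegative", call. = FALSE)
  }
  if (any(G + O > 100, na.rm = TRUE)) {
    warning("G + O exceeds 100% for some trials")
  }
  out <- (G - O) / (G + O)
  out[!is.na(G + O) & (G + O) == 0] <- NA_real_
  out
}

#' Mean-split classification of aged animals
#'
#' Splits aged animals at the arithmetic mean of their set-shift
#' trials-to-criterion: animals strictly above the mean delayed shifting
#' and are labelled aged-impaired (AI); the rest are aged-unimpaired
#' (AU). Ties at the mean fall to AU.
#'
#' @param ttc Numeric trials-to-criterion per aged animal.
#' @param animal_id Optional ids (defaults to names of \code{ttc} or an
#'   index).
#' @return Data frame: \code{animal_id}, \code{ttc}, \code{label}
#'   ("AI"/"AU"), \code{split_mean}.
#' @export
mean_split <- function(ttc, animal_id = NULL) {
  if (length(ttc) < 2L) stop("need at least 2 aged animals", call. = FALSE)
  if (anyNA(ttc)) stop("ttc must not contain NA", call. = FALSE)
  if (is.null(animal_id)) {
    animal_id <- if (!is.null(names(ttc))) names(ttc) else
      as.character(seq_along(ttc))
  }
  mu <- mean(ttc)
  data.frame(
    animal_id = animal_id,
    ttc = as.numeric(ttc),
    label = ifelse(ttc > mu, "AI", "AU"),
    split_mean = mu,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Composite gene-set index score
#'
#' Builds a per-animal index summarizing the expression of a gene set
#' (for example, the transcription-regulation genes that rise with
#' delayed set shifting): each gene is standardized to a z-score across
#' the included animals, the z-scores are averaged within each animal,
#' and the averages are correlated with the standardized behavioral
#' score. With a single-gene set the composite correlation equals that
#' gene's Pearson correlation exactly.
#'
#' @param expr \code{norm_mat} or matrix, genes x samples.
#' @param gene_set Character vector of gene ids to combine.
#' @param scores Per-sample behavioral scores (NA scores drop the
#'   sample); standardization and correlation use exactly the retained
#'   samples.
#' @return List with \code{scores} (data frame: \code{sample_id},
#'   \code{mean_z}, \code{behavior_z}), \code{r} (Pearson correlation of
#'   mean_z with behavior_z) and \code{n_genes_used}.
#' @export
index_score <- function(expr, gene_set, scores) {
  m <- expr_values(expr)
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing) > 0L) {
    stop("gene_set contains genes absent from expr: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  if (length(scores) != ncol(m)) {
    stop("'scores' must have one value per sample column", call. = FALSE)
  }
  keep <- !is.na(scores)
  if (sum(keep) < 3L) stop("need at least 3 scored animals", call. = FALSE)
  m <- m[gene_set, keep, drop = FALSE]
  s <- scores[keep]
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from the index")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no usable genes left in gene_set", call. = FALSE)
  z <- t(scale(t(m)))
  mean_z <- colMeans(z)
  behavior_z <- as.numeric(scale(s))
  list(
    scores = data.frame(sample_id = colnames(m), mean_z = mean_z,
                        behavior_z = behavior_z,
                        stringsAsFactors = FALSE, row.names = NULL),
    r = stats::cor(mean_z, behavior_z),
    n_genes_used = nrow(m)
  )
}
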