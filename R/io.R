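#' Read a gene-level count matrix
#'
#' Counts are stored as tab-separated text: a header row of sample ids,
#' then one row per gene with the gene id in the first column. Every cell
#' is validated (nonnegative integer); duplicate gene or sample ids,
#' ragged rows and malformed cells raise errors that name the offending
#' line.
#'
#' @param path Path to a tab-separated counts file.
#' @return An integer matrix (genes x samples) with gene ids as rownames
#'   and sample ids as colnames, in file order.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("counts file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell over the gene-id column
  body <- fields[-1L]
  n_field <- lengths(body)
  sample_ids <- if (length(body) > 0L && all(n_field == length(header) + 1L)) {
    header
  } else {
    header[-1L]
  }
  expected <- length(sample_ids) + 1L
  bad <- which(n_field != expected)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 bad[1L] + 1L, expected, n_field[bad[1L]]), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1L], call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L],
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, ncol = length(body))  # guard the 1-sample case
  for (j in seq_along(body)) {
    v <- vals[, j]
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      k <- which(is.na(v) | v < 0 | v != floor(v))[1L]
      stop(sprintf("line %d: count for gene '%s', sample '%s' is not a nonnegative integer",
                   j + 1L, gene_ids[j], sample_ids[k]), call. = FALSE)
    }
  }
  counts <- t(vals)
  dimnames(counts) <- list(gene_ids, sample_ids)
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix as tab-separated text
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read or write a sample metadata table
#'
#' Sample tables are CSV with one row per sample. Missing behavioral
#' values are empty cells and are read back as \code{NA} (never zero).
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("sample table must have a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         tab$sample_id[duplicated(tab$sample_id)][1L], call. = FALSE)
  }
  if ("discrimination_index" %in% names(tab)) {
    di <- tab$discrimination_index
    if (any(!is.na(di) & (di < -1 | di > 1))) {
      stop("discrimination_index outside [-1, 1]", call. = FALSE)
    }
  }
  tab
}

#' @rdname read_sample_table
#' @param samples Data frame of per-sample metadata.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prior-study direction set
#'
#' A direction set lists gene symbols from a prior study together with
#' the direction of change that study reported; it drives the
#' cross-study concordance tests. Input is two-column CSV (symbol,
#' direction) where direction is one of \code{up}, \code{down},
#' \code{increased}, \code{decreased}, \code{+1}, \code{-1}, \code{1}.
#' Symbols are matched case-insensitively (human SST vs rat Sst), so
#' duplicates after case-folding must agree in direction.
#'
#' @param path CSV path.
#' @param name Optional label for the set (defaults to the file name).
#' @return An object of class \code{direction_set}: a data frame with
#'   columns \code{symbol} (as given), \code{key} (case-folded) and
#'   \code{direction} (+1/-1), plus a \code{name} attribute.
#' @export
read_direction_set <- function(path, name = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("direction set needs two columns (symbol, direction)", call. = FALSE)
  }
  direction_set(tab[[1L]], tab[[2L]],
                name = if (is.null(name)) basename(path) else name)
}

#' Construct a direction set from vectors
#'
#' @param symbols Character vector of gene symbols.
#' @param directions Directions, as \code{up}/\code{down} style tokens or
#'   numeric +1/-1.
#' @param name Label for the set.
#' @return A \code{direction_set}; see [read_direction_set()].
#' @export
direction_set <- function(symbols, directions, name = "prior") {
  tok <- tolower(trimws(as.character(directions)))
  dir <- ifelse(tok %in% c("up", "increased", "increase", "+1", "1"), 1,
         ifelse(tok %in% c("down", "decreased", "decrease", "-1"), -1, NA))
  if (anyNA(dir)) {
    stop("unknown direction token: '", tok[which(is.na(dir))[1L]], "'",
         call. = FALSE)
  }
  key <- tolower(trimws(symbols))
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      if (length(unique(dir[key == k])) > 1L) {
        stop("conflicting directions for symbol '", k, "'", call. = FALSE)
      }
    }
    keep <- !dup
    symbols <- symbols[keep]; key <- key[keep]; dir <- dir[keep]
  }
  out <- data.frame(symbol = as.character(symbols), key = key,
                    direction = as.numeric(dir), stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("direction_set", "data.frame")
  out
}

#' Read a gene-to-GO-term annotation map
#'
#' Accepts either a two-column TSV (gene_id, term; one pair per line) or
#' GMT-style lines (term, description, then member genes). The dialect
#' is auto-detected: files whose every line has exactly two fields are
#' read as gene-term pairs, anything else as GMT.
#'
#' @param path TSV or GMT path.
#' @return A named list mapping gene id to a character vector of term
#'   ids (possibly empty for genes never mentioned).
#' @export
read_go_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_field <- lengths(fields)
  bad <- which(n_field < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected at least 2 tab-separated fields",
                 bad[1L]), call. = FALSE)
  }
  if (all(n_field == 2L)) {
    genes <- vapply(fields, `[[`, character(1), 1L)
    terms <- vapply(fields, `[[`, character(1), 2L)
    split(terms, factor(genes, levels = unique(genes)))
  } else {
    # GMT: term, description, members...
    out <- new.env(parent = emptyenv())
    for (f in fields) {
      term <- f[[1L]]
      for (g in f[-(1:2)]) {
        assign(g, c(if (exists(g, out, inherits = FALSE)) get(g, out), term),
               envir = out)
      }
    }
    genes <- ls(out, sorted = FALSE)
    stats::setNames(lapply(genes, function(g) unique(get(g, out))), genes)
  }
}
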