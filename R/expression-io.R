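#' Construct an expression matrix
#'
#' The package's expression container is a plain genes x samples numeric
#' matrix carrying a `scale` attribute that records whether values are raw
#' counts, log2 counts-per-million, or some other log-scale quantity. Gene
#' identifiers live in `rownames()` and sample identifiers in `colnames()`.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param gene_ids,sample_ids character vectors of row/column identifiers;
#'   defaults to the dimnames of `values`.
#' @param scale one of `"counts"`, `"logcpm"`, `"log_generic"`.
#' @return a numeric matrix of class `expr_mat` with a `scale` attribute.
#' @export
expr_mat <- function(values, gene_ids = rownames(values),
                     sample_ids = colnames(values),
                     scale = c("counts", "logcpm", "log_generic")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene and sample identifiers.")
  }
  gene_ids <- toupper(trimws(as.character(gene_ids)))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort("Identifier lengths do not match matrix dimensions.")
  }
  if (anyDuplicated(sample_ids)) {
    abort("Duplicate sample identifiers are not allowed.")
  }
  ndup <- sum(duplicated(gene_ids))
  if (ndup > 0) {
    # duplicates are legal on input; they are resolved at ranking time
    inform(sprintf("%d duplicated gene identifier(s) retained.", ndup))
  }
  if (scale == "counts" && any(values < 0)) {
    abort("Count-scale values must be non-negative.")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
                    4L))
  invisible(x)
}

expr_scale <- function(m) attr(m, "scale") %||% "log_generic"

assert_log_scale <- function(m) {
  if (identical(expr_scale(m), "counts")) {
    abort("A log-scale expression matrix is required; run log_cpm() first.")
  }
  invisible(m)
}

#' Read a count matrix
#'
#' Supports two plain-text layouts: a TSV with gene identifiers in the first
#' column and one column per sample, or an MTX-style triplet file (row, col,
#' value; a `%%`-comment/header line and a dims line are tolerated)
#' accompanied by one-id-per-line row and column index files.
#'
#' @param path path to the TSV, or to the triplet file for `format = "mtx_triplet"`.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param row_index,col_index paths to the gene/sample index files
#'   (mtx_triplet only).
#' @return an [expr_mat] with `scale = "counts"`.
#' @export
read_counts <- function(path, format = c("tsv", "mtx_triplet"),
                        row_index = NULL, col_index = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    sample_ids <- colnames(df)[-1L]
    if (anyDuplicated(sample_ids)) {
      abort("Duplicate sample identifiers in header.")
    }
    values <- as.matrix(df[, -1L, drop = FALSE])
    rownames(values) <- df[[1L]]
    return(expr_mat(values, scale = "counts"))
  }
  genes <- toupper(trimws(readLines(row_index)))
  samples <- trimws(readLines(col_index))
  lines <- readLines(path)
  lines <- lines[!grepl("^%", lines) & nzchar(trimws(lines))]
  trip <- read.table(text = lines, col.names = c("i", "j", "x"))
  # a MatrixMarket dims line (i = nrow, j = ncol, x = nnz) may lead the file
  if (nrow(trip) > 0 && trip$i[1] == length(genes) &&
      trip$j[1] == length(samples) && trip$x[1] == nrow(trip) - 1L) {
    trip <- trip[-1L, , drop = FALSE]
  }
  values <- matrix(0, length(genes), length(samples),
                   dimnames = list(genes, samples))
  if (any(trip$i < 1 | trip$i > length(genes) |
          trip$j < 1 | trip$j > length(samples))) {
    abort("Triplet indices outside the index files' range.")
  }
  values[cbind(trip$i, trip$j)] <- trip$x
  expr_mat(values, scale = "counts")
}

#' Write a count or expression matrix as TSV
#'
#' @param m an [expr_mat].
#' @param path output path; first column `gene`, then one column per sample.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2 counts-per-million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`, the standard
#' moderated-logCPM transform used as input for trend-moderated differential
#' expression.
#'
#' @param m an [expr_mat] on the counts scale.
#' @param prior_count pseudocount added to each count (default 0.5).
#' @return an [expr_mat] with `scale = "logcpm"`.
#' @export
log_cpm <- function(m, prior_count = 0.5) {
  if (!identical(expr_scale(m), "counts")) {
    abort("log_cpm() expects a counts-scale matrix.")
  }
  lib <- colSums(m)
  if (any(lib <= 0)) abort("Every library size must be positive.")
  out <- log2(sweep(unclass(m) + prior_count, 2L, lib + 2 * prior_count,
                    "/") * 1e6)
  expr_mat(out, scale = "logcpm")
}

#' Read / write a sample design table
#'
#' The design TSV has columns `sample`, `tissue`, `line`, `phenotype` (values
#' `PKH26_plus` / `PKH26_minus`) and optionally `replicate`.
#'
#' @param path file path.
#' @return a tibble with those columns.
#' @export
read_design <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  needed <- c("sample", "tissue", "line", "phenotype")
  if (!all(needed %in% names(df))) {
    abort(paste("Design file must have columns:",
                paste(needed, collapse = ", ")))
  }
  bad <- setdiff(unique(df$phenotype), c("PKH26_plus", "PKH26_minus"))
  if (length(bad)) {
    abort(paste("Unknown phenotype label(s):", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$sample)) abort("Duplicate sample ids in design.")
  df
}

#' @rdname read_design
#' @param design a design tibble.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return a named list of character vectors with a `description` attribute
#'   per set (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn("Empty GMT file; returning an empty collection.")
    return(structure(list(), class = "gene_set_collection"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort("GMT line with fewer than one member.")
  sets <- lapply(parts, function(p) {
    structure(unique(p[-(1:2)]), description = p[2L])
  })
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) abort("Duplicate set names in GMT.")
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a named list of member vectors (descriptions optional).
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection), function(i) {
    s <- collection[[i]]
    desc <- attr(s, "description") %||% "na"
    paste(c(names(collection)[i], desc, as.character(s)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
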