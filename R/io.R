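#' Construct a validated expression matrix
#'
#' An expression matrix is a genes-by-samples numeric matrix carrying a scale
#' flag: `"linear"` for abundances on their natural scale (e.g. FPKM-UQ) or
#' `"log2p1"` for values stored as log2(abundance + 1), the common storage
#' convention for large RNA-seq compendia. All values must be finite and
#' non-negative on either scale; gene and sample identifiers must be unique.
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param scale `"linear"` or `"log2p1"`.
#' @return a matrix of class `expr_matrix` with a `scale` attribute.
#' @seealso [read_expression()], [delog()]
#' @export
expression_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  .check_ids(genes, "gene")
  .check_ids(samples, "sample")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative (scale = ", scale, ")",
         call. = FALSE)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

.check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("missing ", what, " identifiers", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifiers: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  invisible(ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

# subset samples, preserving class and scale
.em_subset_samples <- function(m, ids) {
  expression_matrix(unclass(m)[, ids, drop = FALSE], attr(m, "scale"))
}

#' Read a tab-separated expression matrix
#'
#' Expects one header row and one leading identifier column; the remaining
#' cells are numeric abundances. Either orientation is accepted and the result
#' is always genes-by-samples. Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @param orientation `"genes_in_rows"` (default, the usual TCGA export) or
#'   `"samples_in_rows"`.
#' @param scale scale flag recorded on the result; values are not transformed.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            scale = c("linear", "log2p1")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(nf) < 2)
    stop("parse error: expected a header row and at least one data row in ",
         path, call. = FALSE)
  if (length(unique(nf)) != 1L)
    stop("parse error: ragged rows in ", path, " (field counts ",
         paste(unique(nf), collapse = "/"), ")", call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num))
    stop("parse error: non-numeric values in column(s) ",
         paste(utils::head(names(body)[!num], 5), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(body)
  rownames(vals) <- ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param m an [expression_matrix()].
#' @param path output path (`.gz` suffix writes gzip).
#' @param id_label header label of the identifier column.
#' @export
write_expression <- function(m, path, id_label = "gene_id") {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_label
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Invert the log2(x + 1) storage transform
#'
#' Replaces each value v by 2^v - 1 and flips the scale flag to `"linear"`.
#' Applying it to an already-linear matrix is a warning no-op, so pipelines
#' that may receive either scale stay idempotent.
#'
#' @param m an [expression_matrix()].
#' @return the matrix on the linear scale.
#' @export
delog <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (attr(m, "scale") == "linear") {
    warning("expression matrix is already on the linear scale; returning unchanged")
    return(m)
  }
  expression_matrix(2^unclass(m) - 1, "linear")
}

#' Read a clinical survival table
#'
#' Expects a TSV with header columns `sample_id`, `time_days`, `event`
#' (1 = death observed, 0 = censored). Rows with a missing time or event are
#' dropped with a message; any other malformed value is an error.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @return a `data.frame` of class `clinical_table` with columns
#'   `sample_id`, `time_days`, `event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "time_days", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  clinical_table(df[req])
}

#' Construct a validated clinical table
#'
#' @param df data.frame with columns `sample_id`, `time_days`, `event`.
#' @return a `clinical_table`; rows with missing time/event are dropped with a
#'   message.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$time_days <- .parse_numeric(df$time_days, "time_days")
  df$event <- .parse_numeric(df$event, "event")
  drop <- is.na(df$time_days) | is.na(df$event)
  if (any(drop)) {
    message("clinical table: dropped ", sum(drop),
            " row(s) with missing time or event")
    df <- df[!drop, , drop = FALSE]
  }
  if (!nrow(df)) stop("clinical table has no complete rows", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("validation error: `event` must be 0 or 1", call. = FALSE)
  if (any(df$time_days < 0))
    stop("validation error: `time_days` must be non-negative", call. = FALSE)
  .check_ids(df$sample_id, "sample")
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

# numeric coercion that distinguishes "missing" (NA/empty -> NA) from
# "unparseable" (text -> parse error)
.parse_numeric <- function(x, what) {
  if (is.numeric(x)) return(x)
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x)) | trimws(x) %in% c("NA", "na", ".")
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !blank
  if (any(bad))
    stop("parse error: non-numeric ", what, " value(s): ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "), call. = FALSE)
  out[blank] <- NA_real_
  out
}

#' Write a clinical table as TSV
#' @param clin a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  stopifnot(inherits(clin, "clinical_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(clin, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pathway gene set
#'
#' @param name pathway name.
#' @param genes character vector of gene symbols (matched case-sensitively,
#'   exact string equality; no alias resolution is attempted).
#' @return an object of class `pathway_set`.
#' @export
pathway_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("pathway name must be a non-empty string", call. = FALSE)
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("pathway '", name, "' has no genes", call. = FALSE)
  if (anyDuplicated(genes)) {
    warning("pathway '", name, "': duplicate gene symbols removed")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("Pathway '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description (discarded), then gene symbols, all
#' tab-separated. Duplicate symbols within a set are deduplicated with a
#' warning.
#'
#' @param path path to a GMT file (optionally `.gz`).
#' @return a named list of [pathway_set()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("parse error in ", path, " line ", i,
           ": expected name, description and at least one gene", call. = FALSE)
    ps <- pathway_set(fields[1L], fields[-(1:2)])
    if (ps$name %in% names(sets))
      stop("duplicate pathway name '", ps$name, "' at line ", i, call. = FALSE)
    sets[[ps$name]] <- ps
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets a list of [pathway_set()] objects.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(p) {
    stopifnot(inherits(p, "pathway_set"))
    paste(c(p$name, description, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
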