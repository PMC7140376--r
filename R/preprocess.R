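#' Restrict an expression matrix to one pathway
#'
#' Extracts the pathway's transcripts (original pathway order preserved) and
#' transposes to a samples-by-genes matrix, the orientation used by the
#' normalization and embedding steps. The fraction of pathway genes actually
#' present in the matrix is checked against `min_found_fraction`: real cohorts
#' frequently lack a few symbols, but an analysis run on a small remnant of a
#' pathway would no longer measure that pathway's pattern.
#'
#' @param m an [expression_matrix()] on the linear scale (apply [delog()]
#'   first if stored as log2(x + 1)).
#' @param p a [pathway_set()].
#' @param min_found_fraction minimum fraction of `p$genes` that must be present
#'   (default 0.8).
#' @return a samples-by-genes matrix of class `pathway_matrix` at stage
#'   `"raw"`.
#' @export
subset_pathway <- function(m, p, min_found_fraction = 0.8) {
  stopifnot(inherits(m, "expr_matrix"), inherits(p, "pathway_set"))
  if (!(min_found_fraction > 0 && min_found_fraction <= 1))
    stop("`min_found_fraction` must be in (0, 1]", call. = FALSE)
  if (attr(m, "scale") != "linear")
    stop("expression matrix must be on the linear scale; apply delog() first",
         call. = FALSE)
  found <- p$genes[p$genes %in% rownames(m)]
  missing <- setdiff(p$genes, found)
  frac <- length(found) / length(p$genes)
  if (!length(found))
    stop("coverage error: none of the ", length(p$genes), " genes of pathway '",
         p$name, "' are present in the expression matrix", call. = FALSE)
  if (frac < min_found_fraction)
    stop("coverage error: only ", length(found), "/", length(p$genes),
         " genes of pathway '", p$name, "' found (need ",
         min_found_fraction * 100, "%); missing: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  if (length(missing))
    message("pathway '", p$name, "': ", length(found), "/", length(p$genes),
            " genes found; missing: ", paste(missing, collapse = ", "))
  vec <- t(unclass(m)[found, , drop = FALSE])
  structure(vec, stage = "raw", pathway = p$name, dropped = character(0),
            class = c("pathway_matrix", "matrix", "array"))
}

.pm_stage <- function(pm) attr(pm, "stage")

.pm_rebuild <- function(values, template, stage, dropped = NULL) {
  structure(values, stage = stage, pathway = attr(template, "pathway"),
            dropped = if (is.null(dropped)) attr(template, "dropped") else dropped,
            class = c("pathway_matrix", "matrix", "array"))
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("Pathway matrix '%s': %d samples x %d genes (stage: %s)\n",
              attr(x, "pathway"), nrow(x), ncol(x), attr(x, "stage")))
  nd <- length(attr(x, "dropped"))
  if (nd) cat(sprintf("  %d sample(s) dropped for zero pathway expression\n", nd))
  invisible(x)
}

#' Normalize each sample's pathway vector to sum 1
#'
#' First of the two pattern-normalization steps: each sample row is divided by
#' its total pathway abundance, removing between-sample depth differences.
#' Samples with zero total pathway expression carry no pattern information;
#' they are removed, recorded in the `dropped` attribute, and excluded from
#' all downstream analyses of this pathway.
#'
#' @param pm a `pathway_matrix` at stage `"raw"`.
#' @return the matrix at stage `"sum_normalized"` (rows sum to 1).
#' @export
sum_normalize <- function(pm) {
  stopifnot(inherits(pm, "pathway_matrix"))
  if (.pm_stage(pm) != "raw")
    stop("sum_normalize expects stage 'raw', got '", .pm_stage(pm), "'",
         call. = FALSE)
  rs <- rowSums(pm)
  zero <- rs <= 0
  if (all(zero))
    stop("all samples have zero total pathway expression", call. = FALSE)
  dropped <- rownames(pm)[zero]
  if (length(dropped))
    message("sum_normalize: dropped ", length(dropped),
            " sample(s) with zero pathway expression: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  v <- unclass(pm)[!zero, , drop = FALSE] / rs[!zero]
  .pm_rebuild(v, pm, "sum_normalized", dropped = c(attr(pm, "dropped"), dropped))
}

#' Project sum-normalized pathway vectors onto the unit hypersphere
#'
#' Second normalization step: each row is divided by its Euclidean norm so
#' that only the within-sample expression pattern, not its magnitude, remains.
#' For non-negative vectors the two-step composition equals direct L2
#' normalization of the raw vectors (up to the zero-sample dropping rule); the
#' steps are kept separate because both are part of the published procedure.
#'
#' @param pm a `pathway_matrix` at stage `"sum_normalized"`.
#' @return the matrix at stage `"hypersphere"` (rows have Euclidean norm 1).
#' @export
hypersphere_project <- function(pm) {
  stopifnot(inherits(pm, "pathway_matrix"))
  if (.pm_stage(pm) != "sum_normalized")
    stop("hypersphere_project expects stage 'sum_normalized', got '",
         .pm_stage(pm), "'", call. = FALSE)
  nrm <- sqrt(rowSums(unclass(pm)^2))
  if (any(nrm <= 0))
    stop("internal error: zero-norm row after sum normalization", call. = FALSE)
  .pm_rebuild(unclass(pm) / nrm, pm, "hypersphere")
}

# full preprocessing chain used by stratify()
.pathway_vectors <- function(m, p, min_found_fraction = 0.8) {
  hypersphere_project(sum_normalize(subset_pathway(m, p, min_found_fraction)))
}
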