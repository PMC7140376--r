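#' Sequential stratification: re-analyze selected clusters with a second pathway
#'
#' Re-runs the entire pipeline -- pathway restriction, re-normalization, a
#' fresh t-SNE embedding and a fresh mixture fit -- on only the samples of the
#' selected first-pass cluster(s), using a second pathway's transcripts.
#' First-pass coordinates are never reused: a subcohort has its own pattern
#' geometry. The provenance chain is extended and a cross-tabulation of
#' first-pass versus second-pass labels is attached.
#'
#' @param prev a `strat_fit` from [stratify()] (or a previous sequential pass).
#' @param selected_clusters integer vector of first-pass cluster labels to
#'   re-analyze.
#' @param expression,clinical,params,seed as in [stratify()].
#' @param pathway the second [pathway_set()]. Re-using the previous step's
#'   pathway is allowed but warned about.
#' @return an object of class `c("seq_strat_fit", "strat_fit")` with extra
#'   fields `selected_clusters`, `crosstab` and `combined_groups` (the final
#'   partition: refined labels inside the selection, first-pass labels
#'   outside).
#' @export
sequential_stratify <- function(prev, selected_clusters, expression, clinical,
                                pathway, params = strat_params(), seed = 1L) {
  stopifnot(inherits(prev, "strat_fit"), inherits(pathway, "pathway_set"))
  selected_clusters <- as.integer(selected_clusters)
  valid <- seq_len(prev$assignment$k)
  bad <- setdiff(selected_clusters, valid)
  if (length(bad) || !length(selected_clusters))
    stop("invalid cluster selection {", paste(selected_clusters, collapse = ","),
         "}; valid labels are ", paste(valid, collapse = ", "), call. = FALSE)
  depth <- sum(vapply(prev$provenance, function(s)
    s$type %in% c("stratify", "sequential"), logical(1)))
  if (depth + 1 > params$max_depth)
    stop("provenance chain depth ", depth + 1, " exceeds max_depth = ",
         params$max_depth, call. = FALSE)
  prev_path <- prev$provenance[[length(prev$provenance)]]$pathway
  if (identical(pathway$name, prev_path))
    warning("second pathway '", pathway$name,
            "' is identical to the previous step's pathway")
  sel <- prev$assignment$labels %in% selected_clusters
  sel_ids <- prev$assignment$sample_ids[sel]
  if (length(sel_ids) < params$min_subcohort)
    stop("size error: selection of ", length(sel_ids),
         " samples is below min_subcohort = ", params$min_subcohort,
         call. = FALSE)
  fit <- .stratify_core(expression, clinical, pathway, params, seed,
                        min_n = params$min_subcohort,
                        step = list(type = "sequential", pathway = pathway$name,
                                    selection = selected_clusters),
                        prev_provenance = prev$provenance,
                        sample_subset = sel_ids)
  first <- prev$assignment$labels[match(fit$assignment$sample_ids,
                                        prev$assignment$sample_ids)]
  fit$crosstab <- table(first_pass = first, second_pass = fit$assignment$labels)
  fit$selected_clusters <- selected_clusters
  # final partition over all first-pass samples: refined labels inside the
  # selection, untouched first-pass clusters outside
  comb <- list()
  for (i in setdiff(valid, selected_clusters))
    comb[[as.character(i)]] <-
      prev$assignment$sample_ids[prev$assignment$labels == i]
  for (j in seq_len(fit$assignment$k))
    comb[[paste(paste(selected_clusters, collapse = "+"), j, sep = "/")]] <-
      fit$assignment$sample_ids[fit$assignment$labels == j]
  fit$combined_groups <- comb
  class(fit) <- c("seq_strat_fit", "strat_fit")
  fit
}

#' Cut a whole-transcriptome dendrogram into sample groups
#'
#' Hierarchical clustering of samples on the most variable genes, the
#' conventional first stage of transcriptome heatmap analyses: genes are
#' ranked by variance of their log2(x + 1) values, the top `top_n_genes` are
#' retained, samples are clustered agglomeratively (default: correlation
#' distance, average linkage) and the tree is cut into exactly `g` groups.
#'
#' @param m an [expression_matrix()] (either scale; linear values are
#'   log2(x + 1)-transformed for this step).
#' @param g number of groups to cut (>= 2).
#' @param top_n_genes number of most-variable genes retained (default 1500).
#' @param metric `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param linkage agglomeration rule passed to [stats::hclust()] (default
#'   `"average"`).
#' @return an object of class `dendro_assignment` with fields `sample_ids`,
#'   `groups` (1..g), `g`, `linkage` (parameter record) and `tree`.
#' @export
hclust_dendro <- function(m, g, top_n_genes = 1500L,
                          metric = c("correlation", "euclidean"),
                          linkage = "average") {
  stopifnot(inherits(m, "expr_matrix"))
  metric <- match.arg(metric)
  g <- as.integer(g)
  if (g < 2) stop("`g` must be at least 2", call. = FALSE)
  if (g > ncol(m)) stop("`g` exceeds the sample count", call. = FALSE)
  top_n_genes <- as.integer(top_n_genes)
  if (top_n_genes < 2 || top_n_genes > nrow(m))
    stop("`top_n_genes` must be between 2 and the gene count (",
         nrow(m), ")", call. = FALSE)
  x <- unclass(m)
  if (attr(m, "scale") == "linear") x <- log2(x + 1)
  rv <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  top <- order(rv, decreasing = TRUE)[seq_len(top_n_genes)]
  xs <- x[top, , drop = FALSE]
  d <- if (metric == "correlation") stats::as.dist(1 - stats::cor(xs))
       else stats::dist(t(xs))
  tree <- stats::hclust(d, method = linkage)
  grp <- stats::cutree(tree, k = g)
  structure(list(sample_ids = colnames(m), groups = as.integer(unname(grp)),
                 g = g,
                 linkage = list(metric = metric, linkage = linkage,
                                top_n_genes = top_n_genes),
                 tree = tree),
            class = "dendro_assignment")
}

#' @export
print.dendro_assignment <- function(x, ...) {
  cat(sprintf("Dendrogram groups: %d samples cut into g = %d groups (%s distance, %s linkage, top %d genes)\n",
              length(x$sample_ids), x$g, x$linkage$metric, x$linkage$linkage,
              x$linkage$top_n_genes))
  cat("  group sizes:", paste(tabulate(x$groups, x$g), collapse = ", "), "\n")
  invisible(x)
}

#' Pathway stratification within whole-transcriptome dendrogram groups
#'
#' Runs the full pathway-pattern pipeline on only the samples of the selected
#' dendrogram group(s) -- the second stage of sequential hierarchical
#' clustering / pathway profiling. The provenance chain records the
#' dendrogram step (gene filter, distance, linkage, selection) ahead of the
#' stratification step.
#'
#' @param m,clinical,pathway,params,seed as in [stratify()].
#' @param dendro a `dendro_assignment` from [hclust_dendro()].
#' @param selected_groups integer vector of dendrogram group labels.
#' @return a `strat_fit` whose provenance starts with the dendrogram step.
#' @export
dendro_stratify <- function(m, clinical, dendro, selected_groups, pathway,
                            params = strat_params(), seed = 1L) {
  stopifnot(inherits(dendro, "dendro_assignment"))
  selected_groups <- as.integer(selected_groups)
  valid <- seq_len(dendro$g)
  bad <- setdiff(selected_groups, valid)
  if (length(bad) || !length(selected_groups))
    stop("invalid dendro group selection {",
         paste(selected_groups, collapse = ","), "}; valid groups are ",
         paste(valid, collapse = ", "), call. = FALSE)
  sel_ids <- dendro$sample_ids[dendro$groups %in% selected_groups]
  if (length(sel_ids) < params$min_subcohort)
    stop("size error: selection of ", length(sel_ids),
         " samples is below min_subcohort = ", params$min_subcohort,
         call. = FALSE)
  dstep <- list(type = "dendro", pathway = NA_character_,
                selection = selected_groups, g = dendro$g,
                linkage = dendro$linkage, seed = NA_integer_,
                k = dendro$g)
  .stratify_core(m, clinical, pathway, params, seed,
                 min_n = params$min_subcohort,
                 step = list(type = "stratify", pathway = pathway$name,
                             selection = selected_groups),
                 prev_provenance = list(dstep),
                 sample_subset = sel_ids)
}

#' Association between pathway clusters and dendrogram groups
#'
#' For every (cluster, group) pair, forms the one-vs-rest 2x2 table over the
#' samples common to both assignments -- membership in the cluster crossed
#' with membership in the group -- and applies the exact two-sided
#' [fisher_exact_2x2()] test. Benjamini-Hochberg adjusted p-values across all
#' pairs are reported alongside the raw values.
#'
#' @param clusters a `cluster_assignment` (or `strat_fit`).
#' @param dendro a `dendro_assignment`.
#' @return a data.frame of class `association_table` with one row per
#'   (cluster, group) pair: counts `both`, `cluster_only`, `group_only`,
#'   `neither`, plus `odds_ratio`, `p_value`, `p_bh`. Clusters or groups empty
#'   in the overlap yield `NA` rows with a warning.
#' @export
cluster_dendro_association <- function(clusters, dendro) {
  if (inherits(clusters, "strat_fit")) clusters <- clusters$assignment
  stopifnot(inherits(clusters, "cluster_assignment"),
            inherits(dendro, "dendro_assignment"))
  common <- intersect(clusters$sample_ids, dendro$sample_ids)
  if (!length(common))
    stop("cluster and dendro assignments share no samples", call. = FALSE)
  cl <- clusters$labels[match(common, clusters$sample_ids)]
  gr <- dendro$groups[match(common, dendro$sample_ids)]
  rows <- list()
  warned <- FALSE
  for (i in seq_len(clusters$k)) {
    for (j in seq_len(dendro$g)) {
      inc <- cl == i
      ing <- gr == j
      if (!any(inc) || !any(ing)) {
        if (!warned) {
          warning("cluster or dendro group empty in the overlap; ",
                  "reporting NA for the affected pair(s)")
          warned <- TRUE
        }
        rows[[length(rows) + 1L]] <-
          data.frame(cluster = i, dendro = j, both = sum(inc & ing),
                     cluster_only = sum(inc & !ing),
                     group_only = sum(!inc & ing),
                     neither = sum(!inc & !ing),
                     odds_ratio = NA_real_, p_value = NA_real_)
        next
      }
      ft <- fisher_exact_2x2(sum(inc & ing), sum(inc & !ing),
                             sum(!inc & ing), sum(!inc & !ing))
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = i, dendro = j, both = sum(inc & ing),
                   cluster_only = sum(inc & !ing),
                   group_only = sum(!inc & ing),
                   neither = sum(!inc & !ing),
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_bh[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  class(out) <- c("association_table", "data.frame")
  out
}

#' Between-extreme median-survival gap of a partition
#'
#' The difference between the largest and smallest per-group median survival
#' of a partition, using each group's maximum follow-up as the working value
#' when its median is not reached. Used to compare how far apart the extreme
#' prognostic groups of single-pass and sequential partitions are.
#'
#' @param groups named list of sample-id vectors (a partition).
#' @param clinical a `clinical_table`.
#' @return the gap in days (numeric).
#' @export
median_gap <- function(groups, clinical) {
  stopifnot(is.list(groups), inherits(clinical, "clinical_table"))
  meds <- vapply(groups, function(ids) {
    cl <- clinical[clinical$sample_id %in% ids, , drop = FALSE]
    .median_value(km_median(km_estimate(cl$time_days, cl$event)))
  }, numeric(1))
  max(meds) - min(meds)
}
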