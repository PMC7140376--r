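#' Pipeline hyperparameters
#'
#' Collects the tunable parameters of the stratification pipeline with the
#' package defaults: 3-D exact t-SNE at perplexity 30, full-covariance
#' Gaussian mixtures with 5 EM starts, cluster count chosen by BIC over 1..6
#' unless a fixed `k` is forced, at least 80% of a pathway's genes required
#' present, cohorts of at least 50 samples for a first pass and 20 for a
#' sequential pass (small clusters carry too few events for a meaningful
#' log-rank comparison), and a maximum provenance chain depth of 2.
#'
#' @param perplexity t-SNE perplexity (needs > 3 * perplexity samples).
#' @param dims t-SNE output dimensionality, 2 or 3.
#' @param max_iter t-SNE iterations.
#' When `k` is left free, the component count is chosen by BIC scan and
#' components are then merged into final clusters wherever their posterior
#' overlap exceeds `merge_overlap` (see [merge_components()]); forcing a
#' fixed `k` skips merging so published per-cohort cluster counts can be
#' mirrored exactly.
#'
#' @param k fixed number of clusters, or `NULL` to select by BIC.
#' @param k_range candidate cluster counts for BIC selection.
#' @param n_init EM initializations per GMM fit.
#' @param merge_overlap posterior-overlap cutoff for combining mixture
#'   components into clusters (default 0.005; 0 disables).
#' @param min_found_fraction minimum fraction of pathway genes present.
#' @param min_cohort minimum samples for a first-pass analysis.
#' @param min_subcohort minimum samples for a sequential (second-pass) analysis.
#' @param max_depth maximum number of chained stratification passes.
#' @return a list of class `strat_params`.
#' @export
strat_params <- function(perplexity = 30, dims = 3, max_iter = 500L,
                         k = NULL, k_range = 1:6, n_init = 5L,
                         merge_overlap = 0.005,
                         min_found_fraction = 0.8, min_cohort = 50L,
                         min_subcohort = 20L, max_depth = 2L) {
  p <- list(perplexity = perplexity, dims = as.integer(dims),
            max_iter = as.integer(max_iter),
            k = if (!is.null(k)) as.integer(k), k_range = as.integer(k_range),
            n_init = as.integer(n_init), merge_overlap = merge_overlap,
            min_found_fraction = min_found_fraction,
            min_cohort = as.integer(min_cohort),
            min_subcohort = as.integer(min_subcohort),
            max_depth = as.integer(max_depth))
  if (p$perplexity <= 0 || !p$dims %in% c(2L, 3L) || p$max_iter < 50 ||
      p$merge_overlap < 0 || p$merge_overlap >= 1 ||
      p$min_found_fraction <= 0 || p$min_found_fraction > 1 ||
      p$min_cohort < 1 || p$min_subcohort < 1 || p$max_depth < 1)
    stop("invalid stratification parameters", call. = FALSE)
  structure(p, class = "strat_params")
}

#' Stratify a cohort by one pathway's expression pattern
#'
#' The single-pass pipeline: restrict the expression matrix to the pathway's
#' transcripts, normalize each sample's vector to sum 1 and project it onto
#' the unit hypersphere (so only the within-sample pattern remains), embed
#' with t-SNE, delineate clusters with a Gaussian mixture model, and compare
#' the clusters' survival by Kaplan-Meier estimation with overall and
#' pairwise log-rank tests.
#'
#' Samples lacking clinical follow-up or expressing none of the pathway's
#' transcripts are excluded and listed, with reasons, in the result; every
#' input sample is accounted for. The result records the full provenance
#' (pathway, parameters, seed) needed to reproduce it from the input files.
#'
#' @param expression an [expression_matrix()]; a `log2p1`-scale matrix is
#'   converted to linear automatically.
#' @param clinical a `clinical_table` (see [read_clinical()]).
#' @param pathway a [pathway_set()].
#' @param params a [strat_params()] list.
#' @param seed integer seed driving both the t-SNE initialization and the EM
#'   restarts.
#' @return an object of class `strat_fit`; see [summary.strat_fit()].
#' @export
stratify <- function(expression, clinical, pathway, params = strat_params(),
                     seed = 1L) {
  .stratify_core(expression, clinical, pathway, params, seed,
                 min_n = params$min_cohort,
                 step = list(type = "stratify", pathway = pathway$name),
                 prev_provenance = list())
}

.stratify_core <- function(expression, clinical, pathway, params, seed,
                           min_n, step, prev_provenance,
                           sample_subset = NULL) {
  stopifnot(inherits(expression, "expr_matrix"),
            inherits(clinical, "clinical_table"),
            inherits(pathway, "pathway_set"),
            inherits(params, "strat_params"))
  seed <- as.integer(seed)
  if (attr(expression, "scale") == "log2p1")
    expression <- suppressWarnings(delog(expression))
  input_ids <- colnames(expression)
  if (!is.null(sample_subset)) input_ids <- input_ids[input_ids %in% sample_subset]
  common <- input_ids[input_ids %in% clinical$sample_id]
  excluded <- data.frame(sample_id = setdiff(input_ids, common),
                         reason = if (length(setdiff(input_ids, common)))
                           "missing_clinical" else character(0),
                         stringsAsFactors = FALSE)
  if (length(common) < min_n)
    stop("size error: ", length(common), " samples with clinical data is ",
         "below the minimum of ", min_n, call. = FALSE)
  m <- .em_subset_samples(expression, common)
  pm <- .pathway_vectors(m, pathway, params$min_found_fraction)
  dropped <- attr(pm, "dropped")
  if (length(dropped))
    excluded <- rbind(excluded,
                      data.frame(sample_id = dropped,
                                 reason = "zero_pathway_expression",
                                 stringsAsFactors = FALSE))
  emb <- tsne_embed(pm, dims = params$dims, perplexity = params$perplexity,
                    seed = seed, max_iter = params$max_iter)
  if (!is.null(params$k)) {
    assignment <- gmm_fit(emb, params$k, seed = seed, n_init = params$n_init)
    bic_table <- stats::setNames(assignment$bic, params$k)
  } else {
    scan <- .scan_k(emb, params$k_range, seed = seed, n_init = params$n_init)
    assignment <- merge_components(scan$fit, params$merge_overlap)
    bic_table <- scan$bic_table
  }
  clin <- clinical[match(assignment$sample_ids, clinical$sample_id), , drop = FALSE]
  labs <- as.character(seq_len(assignment$k))
  groups <- lapply(seq_len(assignment$k), function(i) {
    sel <- assignment$labels == i
    list(times = clin$time_days[sel], events = clin$event[sel])
  })
  names(groups) <- labs
  curves <- lapply(groups, function(g) km_estimate(g$times, g$events))
  medians <- lapply(curves, km_median)
  lr <- if (assignment$k >= 2) logrank(groups)
  pw <- if (assignment$k >= 2) pairwise_logrank(groups)
  step$params <- unclass(params)
  step$seed <- seed
  step$n_input <- length(input_ids)
  step$n_analyzed <- length(assignment$sample_ids)
  step$k <- assignment$k
  if (!is.null(assignment$n_components))
    step$n_components <- assignment$n_components
  step$bic <- as.list(bic_table)
  structure(list(pathway = pathway$name,
                 assignment = assignment, embedding = emb,
                 groups = groups, curves = curves, medians = medians,
                 logrank = lr, pairwise = pw,
                 clinical = clin, excluded = excluded,
                 bic_table = bic_table,
                 provenance = c(prev_provenance, list(step)),
                 params = params, seed = seed),
            class = "strat_fit")
}

#' @export
print.strat_fit <- function(x, ...) {
  a <- x$assignment
  cat(sprintf("Pathway survival stratification ('%s'): %d samples, k = %d clusters\n",
              x$pathway, length(a$sample_ids), a$k))
  med <- vapply(x$medians, format, character(1))
  cat(sprintf("  cluster %s: n = %d, median survival %s\n",
              names(x$curves), a$cluster_sizes, med), sep = "")
  if (!is.null(x$logrank))
    cat(sprintf("  overall log-rank: chi-square = %.4g (%d df), p = %.4g\n",
                x$logrank$chi_square, x$logrank$df, x$logrank$p_value))
  if (nrow(x$excluded))
    cat(sprintf("  %d sample(s) excluded (%s)\n", nrow(x$excluded),
                paste(unique(x$excluded$reason), collapse = ", ")))
  invisible(x)
}

#' Summarize a stratification fit
#'
#' @param object a `strat_fit`.
#' @param ... unused.
#' @return the object, invisibly; prints cluster sizes, medians, the BIC
#'   table, overall and pairwise log-rank results, exclusions and the
#'   provenance chain.
#' @export
summary.strat_fit <- function(object, ...) {
  print(object)
  if (length(object$bic_table) > 1) {
    cat("  BIC by k:", paste(sprintf("%s=%.1f", names(object$bic_table),
                                     object$bic_table), collapse = ", "), "\n")
  }
  if (!is.null(object$pairwise)) {
    cat("  pairwise log-rank tests:\n")
    print(as.data.frame(object$pairwise), row.names = FALSE)
  }
  cat("  provenance chain:\n")
  for (s in object$provenance)
    cat(sprintf("    %s pathway '%s'%s (seed %d, k = %d)\n", s$type, s$pathway,
                if (!is.null(s$selection))
                  paste0(" within selection {",
                         paste(s$selection, collapse = ","), "}") else "",
                s$seed, s$k))
  invisible(object)
}

#' Plot a stratification fit
#'
#' `which = "km"` draws the per-cluster Kaplan-Meier step curves annotated
#' with n, median survival and the overall log-rank p; `which = "embedding"`
#' draws the first two embedding coordinates colored by cluster.
#'
#' @param x a `strat_fit`.
#' @param which `"km"` or `"embedding"`.
#' @param ... passed to the underlying plot.
#' @export
plot.strat_fit <- function(x, which = c("km", "embedding"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    nms <- sprintf("Cluster %s (n = %d, M %s)", names(x$curves),
                   x$assignment$cluster_sizes,
                   vapply(x$medians, function(m)
                     if (m$reached) paste0("= ", m$value_days)
                     else paste0("> ", m$lower_bound_days), character(1)))
    main <- sprintf("'%s' t-SNE clusters%s", x$pathway,
                    if (!is.null(x$logrank))
                      sprintf(" (log-rank p = %.3g)", x$logrank$p_value) else "")
    plot_km(stats::setNames(x$curves, nms), main = main, ...)
  } else {
    co <- x$embedding$coords
    graphics::plot(co[, 1], co[, 2], col = x$assignment$labels, pch = 16,
                   cex = 0.6, xlab = colnames(co)[1], ylab = colnames(co)[2],
                   main = sprintf("'%s' embedding", x$pathway), ...)
  }
  invisible(x)
}

#' Cluster labels of a stratification fit
#' @param fit a `strat_fit`.
#' @return data.frame with columns `sample_id` and `cluster`.
#' @export
cluster_labels <- function(fit) {
  stopifnot(inherits(fit, "strat_fit"))
  data.frame(sample_id = fit$assignment$sample_ids,
             cluster = fit$assignment$labels, stringsAsFactors = FALSE)
}
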