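#' t-SNE embedding of hypersphere pathway vectors
#'
#' Runs exact t-distributed stochastic neighbor embedding (theta = 0, no PCA
#' preprocessing) on the unit-norm pathway vectors. The embedding is
#' deterministic for a fixed seed, input and parameter set; all parameters are
#' stored in the result so a run can be reproduced from its provenance alone.
#'
#' @param pm a `pathway_matrix` at stage `"hypersphere"`, or any numeric
#'   samples-by-features matrix with rownames.
#' @param dims embedding dimensionality, 2 or 3 (default 3).
#' @param perplexity t-SNE perplexity (default 30). Requires more than
#'   `3 * perplexity` samples.
#' @param seed integer seed for the embedding initialization.
#' @param max_iter gradient-descent iterations (default 500, ample for the
#'   cohort sizes this package targets).
#' @return an object of class `tsne_embedding` with fields `sample_ids`,
#'   `coords` (samples x dims) and `params`.
#' @export
tsne_embed <- function(pm, dims = 3, perplexity = 30, seed = 1L,
                       max_iter = 500L) {
  if (inherits(pm, "pathway_matrix") && .pm_stage(pm) != "hypersphere")
    stop("tsne_embed expects hypersphere-stage vectors, got stage '",
         .pm_stage(pm), "'", call. = FALSE)
  v <- unclass(pm)
  if (!is.matrix(v) || !is.numeric(v) || is.null(rownames(v)))
    stop("`pm` must be a numeric matrix with sample rownames", call. = FALSE)
  if (!dims %in% c(2L, 3L)) stop("`dims` must be 2 or 3", call. = FALSE)
  n <- nrow(v)
  if (n <= 3 * perplexity)
    stop("parameter error: ", n, " samples is too few for perplexity ",
         perplexity, "; largest valid perplexity is ", floor((n - 1) / 3),
         call. = FALSE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(v, dims = dims, perplexity = perplexity, theta = 0,
                      pca = FALSE, max_iter = as.integer(max_iter),
                      check_duplicates = FALSE, num_threads = 1,
                      verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(v)
  colnames(coords) <- c("x", "y", "z")[seq_len(dims)]
  structure(list(sample_ids = rownames(v), coords = coords,
                 params = list(dims = dims, perplexity = perplexity,
                               max_iter = as.integer(max_iter),
                               seed = as.integer(seed), method = "exact")),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "t-SNE embedding: %d samples in %dD (perplexity %g, %d iterations, seed %d)\n",
    length(x$sample_ids), p$dims, p$perplexity, p$max_iter, p$seed))
  invisible(x)
}

.embed_coords <- function(e) {
  if (inherits(e, "tsne_embedding")) return(e$coords)
  v <- as.matrix(e)
  if (is.null(rownames(v)))
    stop("embedding matrix must have sample rownames", call. = FALSE)
  v
}

#' Gaussian-mixture clustering of an embedding
#'
#' Fits a k-component Gaussian mixture with full (ellipsoidal, unconstrained)
#' covariances to the embedded coordinates and assigns each sample to its
#' maximum-posterior component. Several EM starts are attempted -- the default
#' model-based hierarchical initialization plus `n_init - 1` random-subset
#' initializations -- and the fit with the highest log-likelihood is kept.
#' Cluster labels are renumbered 1..k by decreasing cluster size.
#'
#' @param e a `tsne_embedding` or a samples-by-dims coordinate matrix.
#' @param k number of mixture components (k >= 1).
#' @param seed integer seed for the EM restarts.
#' @param n_init number of EM initializations (default 5).
#' @return an object of class `cluster_assignment` with fields `sample_ids`,
#'   `labels`, `k`, `cluster_sizes`, `posterior`, `loglik`, `bic` (standard
#'   convention, -2 logL + npar log n; smaller is better), `model`, `seed`.
#' @export
gmm_fit <- function(e, k, seed = 1L, n_init = 5L) {
  coords <- .embed_coords(e)
  n <- nrow(coords)
  d <- ncol(coords)
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  if (n < k * (d + 1))
    stop("parameter error: ", n, " samples cannot support k = ", k,
         " full-covariance components in ", d, "D", call. = FALSE)
  model <- if (k == 1L) "XXX" else "VVV"
  set.seed(seed)
  fits <- list(.mclust_try(coords, k, model, init = NULL))
  if (k > 1L && n_init > 1L) {
    for (i in seq_len(n_init - 1L)) {
      sub <- sample.int(n, size = min(n, max(k * (d + 1) * 4L, 150L)))
      fits <- c(fits, list(.mclust_try(coords, k, model,
                                       init = list(subset = sub))))
    }
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    # degenerate EM: retry once with a covariance-regularizing prior
    fit <- .mclust_try(coords, k, model, init = NULL, regularize = TRUE)
    if (is.null(fit))
      stop("EM failed for k = ", k,
           " even with covariance regularization", call. = FALSE)
    fits <- list(fit)
  }
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  fit <- fits[[which.max(ll)]]
  raw <- as.integer(fit$classification)
  # renumber so cluster 1 is the largest (stable tie-break on original label)
  sizes <- tabulate(raw, nbins = k)
  ord <- order(-sizes, seq_len(k))
  labels <- match(raw, ord)
  post <- fit$z[, ord, drop = FALSE]
  colnames(post) <- as.character(seq_len(k))
  npar <- mclust::nMclustParams(model, d = d, G = k) + (k - 1)
  structure(list(sample_ids = rownames(coords), labels = labels, k = as.integer(k),
                 cluster_sizes = tabulate(labels, nbins = k),
                 posterior = post, loglik = fit$loglik,
                 bic = -2 * fit$loglik + npar * log(n),
                 model = model, seed = as.integer(seed),
                 n_init = as.integer(n_init)),
            class = "cluster_assignment")
}

.mclust_try <- function(coords, k, model, init = NULL, regularize = FALSE) {
  prior <- if (regularize) mclust::priorControl(functionName = "defaultPrior")
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(coords, G = k, modelNames = model,
                                    initialization = init, prior = prior,
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$classification) || !is.finite(fit$loglik))
    return(NULL)
  fit
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Gaussian-mixture clustering: k = %d (model %s, seed %d)\n",
              x$k, x$model, x$seed))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.2f, BIC %.2f\n", x$loglik, x$bic))
  invisible(x)
}

#' Select the number of clusters by BIC
#'
#' Fits [gmm_fit()] for every k in `k_range` and returns the k minimizing the
#' Bayesian information criterion (-2 logL + npar log n). All candidate BIC
#' values are attached as the `"bic_table"` attribute. The published analyses
#' report per-cohort cluster counts without a stated selection rule, so a
#' fixed k can always be forced instead (see [strat_params()]).
#'
#' @param e a `tsne_embedding` or coordinate matrix.
#' @param k_range integer vector of candidate k (default 1:6).
#' @param seed integer seed passed to each fit.
#' @param n_init EM initializations per fit.
#' @return the selected k (integer) with attribute `bic_table`.
#' @export
select_k <- function(e, k_range = 1:6, seed = 1L, n_init = 5L) {
  scan <- .scan_k(e, k_range, seed, n_init)
  structure(scan$best_k, bic_table = scan$bic_table)
}

#' Merge mixture components into embedding clusters by posterior overlap
#'
#' A Gaussian mixture fit to a t-SNE layout routinely needs several
#' components to model one visually distinct, non-Gaussian cluster, so the
#' BIC-selected component count overstates the number of clusters. This
#' operation merges components the way the component-combining literature
#' prescribes: for each ordered component pair (i, j) it computes the mean
#' posterior probability of component i among the samples assigned to
#' component j (a directly estimated misclassification rate); while any
#' symmetrized overlap exceeds `cutoff`, the most-overlapping pair is merged
#' and posteriors are summed. Components separated by a genuine embedding
#' gap have overlap orders of magnitude below any reasonable cutoff and are
#' never merged.
#'
#' @param assignment a `cluster_assignment` from [gmm_fit()] (posteriors
#'   required).
#' @param cutoff maximum tolerated overlap between distinct clusters
#'   (default 0.005). Zero disables merging.
#' @return a `cluster_assignment` with `k` less than or equal to the input's;
#'   the component fit's log-likelihood/BIC are retained and the original
#'   component count is recorded as `n_components`.
#' @export
merge_components <- function(assignment, cutoff = 0.005) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  z <- assignment$posterior
  if (is.null(z)) stop("assignment carries no posterior matrix", call. = FALSE)
  if (cutoff > 0) {
    repeat {
      G <- ncol(z)
      if (G == 1L) break
      cl <- max.col(z, ties.method = "first")
      p <- matrix(0, G, G)
      for (j in seq_len(G)) {
        nj <- sum(cl == j)
        if (nj > 0) p[, j] <- colSums(z[cl == j, , drop = FALSE]) / nj
      }
      diag(p) <- 0
      ov <- pmax(p, t(p))
      if (max(ov) <= cutoff) break
      ij <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      z[, ij[1]] <- z[, ij[1]] + z[, ij[2]]
      z <- z[, -ij[2], drop = FALSE]
    }
  }
  raw <- max.col(z, ties.method = "first")
  k <- ncol(z)
  sizes <- tabulate(raw, nbins = k)
  ord <- order(-sizes, seq_len(k))
  labels <- match(raw, ord)
  post <- z[, ord, drop = FALSE]
  colnames(post) <- as.character(seq_len(k))
  out <- assignment
  out$labels <- labels
  out$k <- as.integer(k)
  out$cluster_sizes <- tabulate(labels, nbins = k)
  out$posterior <- post
  out$n_components <- assignment$k
  out$merge_cutoff <- cutoff
  out
}

# shared k-scan: returns best fit plus the BIC table so stratify() can reuse
# the winning fit without recomputation
.scan_k <- function(e, k_range, seed = 1L, n_init = 5L) {
  k_range <- as.integer(k_range)
  if (!length(k_range) || any(k_range < 1))
    stop("parameter error: `k_range` must be a non-empty set of k >= 1",
         call. = FALSE)
  coords <- .embed_coords(e)
  feasible <- k_range[nrow(coords) >= k_range * (ncol(coords) + 1)]
  if (!length(feasible))
    stop("parameter error: no k in k_range is feasible for ", nrow(coords),
         " samples", call. = FALSE)
  fits <- lapply(feasible, function(k) gmm_fit(e, k, seed = seed, n_init = n_init))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  best <- which.min(bic)
  list(best_k = feasible[best], fit = fits[[best]],
       bic_table = stats::setNames(bic, feasible))
}
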