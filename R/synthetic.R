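#' Describe a synthetic pathway with planted cluster structure
#'
#' Defines one synthetic transcript set. Each sample receives a pattern label
#' for this pathway (multinomial over `proportions`); the pathway's genes are
#' then mean-shifted on the log2 scale according to the label. By default the
#' shift follows a block design -- the genes are split into `n_clusters`
#' contiguous blocks and pattern c up-shifts block c by `shift` log2 units --
#' so clusters differ in their relative expression pattern, not in overall
#' magnitude, which the hypersphere normalization would erase anyway.
#'
#' @param name pathway name (also the prefix of its gene identifiers).
#' @param n_genes number of member transcripts (>= 2).
#' @param n_clusters number of planted pattern clusters (1 = no structure).
#' @param proportions cluster proportions (default equal; must sum to 1).
#' @param shift either a scalar log2 mean-shift magnitude for the block
#'   design, or a full `n_clusters` x `n_genes` shift matrix.
#' @param sd within-cluster standard deviation on the log2 scale.
#' @return a list of class `pathway_def`.
#' @export
pathway_def <- function(name, n_genes, n_clusters = 1L,
                        proportions = NULL, shift = 2, sd = 0.5) {
  n_genes <- as.integer(n_genes)
  n_clusters <- as.integer(n_clusters)
  if (n_genes < 2) stop("`n_genes` must be at least 2", call. = FALSE)
  if (n_clusters < 1) stop("`n_clusters` must be at least 1", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / n_clusters, n_clusters)
  if (length(proportions) != n_clusters ||
      abs(sum(proportions) - 1) > 1e-8 || any(proportions <= 0))
    stop("`proportions` must be ", n_clusters,
         " positive values summing to 1", call. = FALSE)
  if (is.matrix(shift)) {
    if (!identical(dim(shift), c(n_clusters, n_genes)))
      stop("shift matrix must be n_clusters x n_genes", call. = FALSE)
    shift_mat <- shift
  } else {
    shift_mat <- .block_shift(n_clusters, n_genes, shift)
  }
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  structure(list(name = name, n_genes = n_genes, n_clusters = n_clusters,
                 proportions = proportions, shift = shift_mat, sd = sd,
                 genes = sprintf("%s_%03d", name, seq_len(n_genes))),
            class = "pathway_def")
}

# contiguous-block mean-shift design: cluster c up-shifts gene block c
.block_shift <- function(k, g, magnitude) {
  block <- rep(seq_len(k), each = ceiling(g / k))[seq_len(g)]
  mat <- matrix(0, k, g)
  for (c in seq_len(k)) mat[c, block == c] <- magnitude
  mat
}

#' Describe a synthetic cohort with planted truth
#'
#' Collects everything the generator needs: cohort size, background genes,
#' the synthetic pathways ([pathway_def()]), which label assignment drives
#' the baseline hazards, an optional nested refinement, optional
#' whole-transcriptome ("dendro") group structure planted in the background
#' genes, and the censoring scheme. Every label assignment is independent
#' across sources; survival is exponential with the cluster's hazard.
#'
#' The nested refinement mirrors the sequential-analysis design: the child
#' pathway's expression pattern exists cohort-wide, but its hazard effect
#' (`sub_hazards`, indexed by the child label) applies only to samples inside
#' the designated parent cluster -- so a second-pass analysis within that
#' cluster reveals a survival split that a whole-cohort analysis with the
#' child pathway dilutes.
#'
#' @param n_samples cohort size.
#' @param n_background_genes unstructured noise genes (default 200).
#' @param background_sd log2-scale SD of background genes (default 0.5).
#' @param pathways list of [pathway_def()] objects (unique names).
#' @param hazards per-cluster exponential hazard rates (1/days) of the
#'   `hazard_source` labels.
#' @param hazard_source name of the pathway (or `"dendro"`) whose labels set
#'   the baseline hazard; default: the first pathway.
#' @param nested optional `list(parent =, parent_cluster =, child =,
#'   sub_hazards =)`; `parent` is a pathway name or `"dendro"`, `child` a
#'   pathway name.
#' @param dendro optional `list(n_groups =, proportions =, shift =,
#'   n_informative =)` planting transcriptome-wide groups: the first
#'   `n_informative` background genes get a block mean-shift by group label.
#' @param censor_horizon administrative censoring horizon in days.
#' @param censor_fraction fraction of samples additionally exposed to an
#'   independent Uniform(0, horizon) censoring time.
#' @param seed mandatory integer seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_background_genes = 200L,
                        background_sd = 0.5, pathways, hazards,
                        hazard_source = NULL, nested = NULL, dendro = NULL,
                        censor_horizon = 4500, censor_fraction = 0.3, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("validation error: `seed` is mandatory", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2) stop("`n_samples` must be at least 2", call. = FALSE)
  if (!is.list(pathways) || !length(pathways) ||
      !all(vapply(pathways, inherits, logical(1), "pathway_def")))
    stop("`pathways` must be a list of pathway_def objects", call. = FALSE)
  names(pathways) <- vapply(pathways, `[[`, character(1), "name")
  .check_ids(names(pathways), "pathway")
  if (!is.null(dendro)) {
    need <- c("n_groups", "proportions", "shift", "n_informative")
    dendro <- dendro[intersect(names(dendro), need)]
    if (is.null(dendro$n_groups) || dendro$n_groups < 2)
      stop("dendro: `n_groups` must be >= 2", call. = FALSE)
    dendro$n_groups <- as.integer(dendro$n_groups)
    if (is.null(dendro$proportions))
      dendro$proportions <- rep(1 / dendro$n_groups, dendro$n_groups)
    if (length(dendro$proportions) != dendro$n_groups ||
        abs(sum(dendro$proportions) - 1) > 1e-8)
      stop("dendro: proportions must sum to 1", call. = FALSE)
    if (is.null(dendro$shift)) dendro$shift <- 1.5
    if (is.null(dendro$n_informative))
      dendro$n_informative <- min(n_background_genes,
                                  200L * dendro$n_groups)
    dendro$n_informative <- as.integer(dendro$n_informative)
    if (dendro$n_informative > n_background_genes)
      stop("dendro: `n_informative` exceeds the background gene count",
           call. = FALSE)
  }
  if (is.null(hazard_source))
    hazard_source <- pathways[[1L]]$name
  src_k <- if (identical(hazard_source, "dendro")) {
    if (is.null(dendro)) stop("hazard_source 'dendro' needs a dendro spec",
                              call. = FALSE)
    dendro$n_groups
  } else {
    if (!hazard_source %in% names(pathways))
      stop("hazard_source '", hazard_source, "' is not a pathway",
           call. = FALSE)
    pathways[[hazard_source]]$n_clusters
  }
  if (length(hazards) != src_k || any(hazards <= 0))
    stop("`hazards` must be ", src_k, " positive rates (1/days)",
         call. = FALSE)
  if (!is.null(nested)) {
    need <- c("parent", "parent_cluster", "child", "sub_hazards")
    if (!all(need %in% names(nested)))
      stop("nested spec needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    parent_k <- if (identical(nested$parent, "dendro")) {
      if (is.null(dendro))
        stop("validation error: nested parent 'dendro' but no dendro spec",
             call. = FALSE)
      dendro$n_groups
    } else {
      if (!nested$parent %in% names(pathways))
        stop("validation error: nested parent '", nested$parent,
             "' is not a pathway", call. = FALSE)
      pathways[[nested$parent]]$n_clusters
    }
    if (!nested$parent_cluster %in% seq_len(parent_k))
      stop("validation error: nested parent cluster ", nested$parent_cluster,
           " does not exist in '", nested$parent, "'", call. = FALSE)
    if (!nested$child %in% names(pathways))
      stop("validation error: nested child '", nested$child,
           "' is not a pathway", call. = FALSE)
    if (length(nested$sub_hazards) != pathways[[nested$child]]$n_clusters ||
        any(nested$sub_hazards <= 0))
      stop("nested: `sub_hazards` must be ",
           pathways[[nested$child]]$n_clusters, " positive rates",
           call. = FALSE)
  }
  if (censor_horizon < 0 || censor_fraction < 0 || censor_fraction > 1)
    stop("invalid censoring scheme", call. = FALSE)
  structure(list(n_samples = n_samples,
                 n_background_genes = as.integer(n_background_genes),
                 background_sd = background_sd, pathways = pathways,
                 hazards = hazards, hazard_source = hazard_source,
                 nested = nested, dendro = dendro,
                 censor_horizon = censor_horizon,
                 censor_fraction = censor_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, %d background genes, %d pathway(s), seed %d\n",
              x$n_samples, x$n_background_genes, length(x$pathways), x$seed))
  for (p in x$pathways)
    cat(sprintf("  pathway '%s': %d genes, %d cluster(s), sd %g\n",
                p$name, p$n_genes, p$n_clusters, p$sd))
  if (!is.null(x$dendro))
    cat(sprintf("  dendro groups: %d (shift %g over %d genes)\n",
                x$dendro$n_groups, x$dendro$shift, x$dendro$n_informative))
  if (!is.null(x$nested))
    cat(sprintf("  nested: '%s' splits cluster %d of '%s'\n",
                x$nested$child, x$nested$parent_cluster, x$nested$parent))
  invisible(x)
}

#' Simulate a cohort with known truth
#'
#' Draws a cohort from a [cohort_spec()]: independent label assignments per
#' pathway (and dendro groups), log2-scale Gaussian expression around
#' gene-level baselines plus the label's mean shift, exponential survival
#' with the label-dependent hazard (nested sub-hazards overriding inside the
#' parent cluster), and right censoring by the administrative horizon plus an
#' independent uniform censoring time for a random fraction of samples.
#' Identical spec (including seed) gives byte-identical output; the caller's
#' RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `synthetic_cohort` with fields `expression`
#'   (an [expression_matrix()] on the log2p1 scale), `clinical`
#'   (a `clinical_table`), `truth` (per-source label vectors plus the
#'   per-sample hazard) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  labels <- lapply(spec$pathways, function(p)
    sample.int(p$n_clusters, n, replace = TRUE, prob = p$proportions))
  dendro_lab <- if (!is.null(spec$dendro))
    sample.int(spec$dendro$n_groups, n, replace = TRUE,
               prob = spec$dendro$proportions)

  nbg <- spec$n_background_genes
  bg <- NULL
  if (nbg > 0) {
    mu_bg <- stats::runif(nbg, 2, 9)
    bg <- matrix(stats::rnorm(nbg * n, sd = spec$background_sd), nbg, n) + mu_bg
    if (!is.null(spec$dendro)) {
      shift <- .block_shift(spec$dendro$n_groups, spec$dendro$n_informative,
                            spec$dendro$shift)
      idx <- seq_len(spec$dendro$n_informative)
      bg[idx, ] <- bg[idx, ] + t(shift)[, dendro_lab, drop = FALSE]
    }
    rownames(bg) <- sprintf("BG%05d", seq_len(nbg))
  }

  pw_blocks <- lapply(names(spec$pathways), function(nm) {
    p <- spec$pathways[[nm]]
    mu <- stats::runif(p$n_genes, 4, 9)
    v <- matrix(stats::rnorm(p$n_genes * n, sd = p$sd), p$n_genes, n) + mu
    v <- v + t(p$shift)[, labels[[nm]], drop = FALSE]
    rownames(v) <- p$genes
    v
  })
  vals <- pmax(do.call(rbind, c(list(bg), pw_blocks)), 0)
  colnames(vals) <- sample_ids

  src_lab <- if (identical(spec$hazard_source, "dendro")) dendro_lab
             else labels[[spec$hazard_source]]
  hz <- spec$hazards[src_lab]
  if (!is.null(spec$nested)) {
    parent_lab <- if (identical(spec$nested$parent, "dendro")) dendro_lab
                  else labels[[spec$nested$parent]]
    inside <- parent_lab == spec$nested$parent_cluster
    hz[inside] <- spec$nested$sub_hazards[labels[[spec$nested$child]][inside]]
  }
  tev <- stats::rexp(n, rate = hz)
  cens <- rep(spec$censor_horizon, n)
  unif <- stats::runif(n) < spec$censor_fraction
  cens[unif] <- stats::runif(sum(unif), 0, spec$censor_horizon)
  time <- pmin(tev, cens)
  event <- as.integer(tev <= cens)

  clinical <- clinical_table(data.frame(sample_id = sample_ids,
                                        time_days = time, event = event,
                                        stringsAsFactors = FALSE))
  truth <- c(stats::setNames(labels, names(spec$pathways)),
             if (!is.null(dendro_lab)) list(dendro = dendro_lab))
  structure(list(expression = expression_matrix(vals, "log2p1"),
                 clinical = clinical,
                 truth = list(labels = truth, hazard = hz), spec = spec),
            class = "synthetic_cohort")
}

#' Pathway gene sets of a synthetic cohort spec
#' @param spec a [cohort_spec()].
#' @return named list of [pathway_set()] objects (writable with
#'   [write_gmt()]).
#' @export
synthetic_pathways <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(spec$pathways, function(p) pathway_set(p$name, p$genes))
}

#' Reference synthetic cohort designs
#'
#' The fixed study conditions used throughout the package's tests:
#' \describe{
#'   \item{`two-cluster-HR3`}{n = 400; one 20-gene pathway with two equal
#'     clusters whose per-gene mean shift is 4 standard deviations; cluster
#'     median survivals 2400 vs 800 days (hazard ratio 3); 30% uniform
#'     censoring under a 4500-day horizon. Single-pass recovery conditions.}
#'   \item{`nested-HR2`}{n = 600; pathway PWA splits the cohort 50/50 with
#'     baseline median survivals 3000 vs 1500 days (hazard ratio 2); a second
#'     pathway PWB carries an independent cohort-wide 50/50 pattern whose
#'     hazard effect applies only inside PWA's favorable cluster, splitting it
#'     into 3600- vs 1800-day medians (hazard ratio 2). Sequential recovery
#'     conditions.}
#'   \item{`null`}{n = 300; one structureless pathway, uniform hazard
#'     (1500-day median), 30% censoring. Type-I error conditions.}
#'   \item{`dendro-nested`}{n = 600; three transcriptome-wide groups planted
#'     in 600 of 2000 background genes with modest survival differences; a
#'     pathway splits group 2 into 3600- vs 1800-day medians. Sequential
#'     hierarchical-clustering conditions.}
#' }
#'
#' @return named list of [cohort_spec()] objects.
#' @export
reference_specs <- function() {
  list(
    "two-cluster-HR3" = cohort_spec(
      n_samples = 400, n_background_genes = 200,
      pathways = list(pathway_def("PWA", 20, 2, shift = 2, sd = 0.5)),
      hazards = log(2) / c(2400, 800),
      censor_horizon = 4500, censor_fraction = 0.3, seed = 101L),
    "nested-HR2" = cohort_spec(
      n_samples = 600, n_background_genes = 200,
      pathways = list(pathway_def("PWA", 20, 2, shift = 2, sd = 0.5),
                      pathway_def("PWB", 20, 2, shift = 2, sd = 0.5)),
      hazards = log(2) / c(3000, 1500),
      nested = list(parent = "PWA", parent_cluster = 1L, child = "PWB",
                    sub_hazards = log(2) / c(3600, 1800)),
      censor_horizon = 4500, censor_fraction = 0.2, seed = 202L),
    "null" = cohort_spec(
      n_samples = 300, n_background_genes = 200,
      pathways = list(pathway_def("PWA", 20, 1, shift = 0, sd = 0.5)),
      hazards = log(2) / 1500,
      censor_horizon = 4500, censor_fraction = 0.3, seed = 303L),
    "dendro-nested" = cohort_spec(
      n_samples = 600, n_background_genes = 2000,
      pathways = list(pathway_def("PWA", 20, 2, shift = 2, sd = 0.5)),
      hazards = log(2) / c(1800, 2200, 2600), hazard_source = "dendro",
      dendro = list(n_groups = 3, proportions = c(0.4, 0.3, 0.3),
                    shift = 1.5, n_informative = 600),
      nested = list(parent = "dendro", parent_cluster = 2L, child = "PWA",
                    sub_hazards = log(2) / c(3600, 1800)),
      censor_horizon = 4500, censor_fraction = 0.2, seed = 404L)
  )
}
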