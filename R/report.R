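#' Read and validate a run configuration
#'
#' A single YAML file drives an end-to-end run. Required fields depend on the
#' mode: `expression`, `clinical`, `gmt`, `pathway`, `seed` and `out_dir`
#' always; `second_pathway` and `select_clusters` for mode `"sequential"`;
#' `dendro_groups` (g), `select_groups` for mode `"dendro"`. Optional fields:
#' `mode` (default `"stratify"`), `orientation`, `scale` (default
#' `"log2p1"`), `top_n_genes`, `metric`, `linkage`, `plots`, and any
#' [strat_params()] entry under `params:`.
#'
#' @param path path to a YAML config.
#' @return a validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  cfg$mode <- if (is.null(cfg$mode)) "stratify" else cfg$mode
  if (!cfg$mode %in% c("stratify", "sequential", "dendro"))
    stop("config error: unknown mode '", cfg$mode, "'", call. = FALSE)
  req <- c("expression", "clinical", "gmt", "pathway", "seed", "out_dir")
  if (cfg$mode == "sequential")
    req <- c(req, "second_pathway", "select_clusters")
  if (cfg$mode == "dendro") req <- c(req, "dendro_groups", "select_groups")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config error: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c("expression", "clinical", "gmt"))
    if (!file.exists(cfg[[f]]))
      stop("config error: ", f, " file not found: ", cfg[[f]], call. = FALSE)
  cfg$scale <- if (is.null(cfg$scale)) "log2p1" else cfg$scale
  if (!cfg$scale %in% c("linear", "log2p1"))
    stop("config error: scale must be 'linear' or 'log2p1'", call. = FALSE)
  cfg$orientation <- if (is.null(cfg$orientation)) "genes_in_rows" else cfg$orientation
  cfg$plots <- isTRUE(cfg$plots)
  cfg$seed <- as.integer(cfg$seed)
  cfg$params <- do.call(strat_params, as.list(cfg$params))
  structure(cfg, class = "run_config")
}

# load the three inputs of a configured run, checking pathway names before
# any heavy computation
.load_config_inputs <- function(cfg) {
  sets <- read_gmt(cfg$gmt)
  want <- c(cfg$pathway, cfg$second_pathway)
  miss <- setdiff(want, names(sets))
  if (length(miss))
    stop("config error: pathway(s) not in GMT: ",
         paste(miss, collapse = ", "), "; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  list(expression = read_expression(cfg$expression, cfg$orientation, cfg$scale),
       clinical = read_clinical(cfg$clinical), sets = sets)
}

# create cfg$out_dir (error if non-empty); returns a cleanup closure that
# removes the directory again if the run fails before any artifact is final
.prepare_out_dir <- function(out_dir) {
  existed <- dir.exists(out_dir)
  if (existed && length(list.files(out_dir, all.files = TRUE, no.. = TRUE)))
    stop("config error: output directory ", out_dir, " exists and is not empty",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  function() if (!existed) unlink(out_dir, recursive = TRUE)
}

#' Write the report directory of a stratification fit
#'
#' Writes the static artifacts of a run: `clusters.tsv` (sample, embedding
#' coordinates, cluster label), one `km_cluster_<label>.tsv` step table per
#' cluster, `medians.tsv`, `logrank.tsv` (overall) and
#' `logrank_pairwise.tsv`, `excluded.tsv`, `provenance.json` (the full
#' reproduction record: pathway chain, parameters, seeds, package version),
#' optionally `crosstab.tsv` for sequential fits and `km.png` /
#' `embedding.png` plots. All tables are plain TSV; reruns with the same
#' inputs and seed produce byte-identical tables and provenance.
#'
#' @param fit a `strat_fit`.
#' @param dir output directory (created if needed).
#' @param plots also write PNG plots (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir, plots = FALSE) {
  stopifnot(inherits(fit, "strat_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  co <- fit$embedding$coords
  tsv(data.frame(sample_id = fit$assignment$sample_ids, co,
                 cluster = fit$assignment$labels, check.names = FALSE),
      "clusters.tsv")
  for (nm in names(fit$curves))
    tsv(km_table(fit$curves[[nm]]), sprintf("km_cluster_%s.tsv", nm))
  tsv(data.frame(cluster = names(fit$curves),
                 n = fit$assignment$cluster_sizes,
                 median = vapply(fit$medians, .median_value, numeric(1)),
                 reached = vapply(fit$medians, `[[`, logical(1), "reached"),
                 rendered = vapply(fit$medians, format, character(1))),
      "medians.tsv")
  if (!is.null(fit$logrank))
    tsv(data.frame(chi_square = fit$logrank$chi_square, df = fit$logrank$df,
                   p_value = fit$logrank$p_value), "logrank.tsv")
  if (!is.null(fit$pairwise)) tsv(as.data.frame(fit$pairwise),
                                  "logrank_pairwise.tsv")
  tsv(fit$excluded, "excluded.tsv")
  if (!is.null(fit$crosstab)) {
    ct <- as.data.frame(fit$crosstab)
    tsv(ct, "crosstab.tsv")
  }
  prov <- list(package = "pathstrat",
               version = as.character(utils::packageVersion("pathstrat")),
               seed = fit$seed, chain = fit$provenance)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(dir, "provenance.json"))
  if (plots) {
    .try_png(file.path(dir, "km.png"), function() plot(fit, "km"))
    .try_png(file.path(dir, "embedding.png"),
             function() plot(fit, "embedding"))
  }
  invisible(dir)
}

.try_png <- function(path, draw) {
  tryCatch({
    grDevices::png(path, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off())
    draw()
  }, error = function(e)
    warning("could not write ", path, ": ", conditionMessage(e)))
}

#' Materialize a synthetic cohort as files
#'
#' Writes the expression matrix (log2p1 TSV), clinical table, pathway GMT,
#' the planted truth labels and the spec itself into a directory, in exactly
#' the formats the readers of this package accept -- so a simulated dataset
#' round-trips through the same entry points as a real one.
#'
#' @param spec a [cohort_spec()] or the path to a YAML spec file.
#' @param out_dir output directory (must not already contain files).
#' @return the output directory, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  cleanup <- .prepare_out_dir(out_dir)
  ok <- FALSE
  on.exit(if (!ok) cleanup())
  cohort <- simulate_cohort(spec)
  write_expression(cohort$expression, file.path(out_dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(out_dir, "clinical.tsv"))
  write_gmt(synthetic_pathways(spec), file.path(out_dir, "pathways.gmt"))
  truth <- data.frame(sample_id = cohort$clinical$sample_id,
                      as.data.frame(cohort$truth$labels),
                      hazard = cohort$truth$hazard, check.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cohort_spec(spec, file.path(out_dir, "spec.yaml"))
  ok <- TRUE
  invisible(out_dir)
}

#' Serialize / read a cohort spec as YAML
#' @param spec a [cohort_spec()].
#' @param path YAML path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  ser <- unclass(spec)
  ser$pathways <- lapply(ser$pathways, function(p)
    list(name = p$name, n_genes = p$n_genes, n_clusters = p$n_clusters,
         proportions = p$proportions, shift = as.vector(t(p$shift)),
         sd = p$sd))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop("spec not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed))
    stop("validation error: spec has no seed", call. = FALSE)
  pws <- lapply(raw$pathways, function(p) {
    shift <- if (!is.null(p$shift) && length(p$shift) > 1)
      matrix(unlist(p$shift), nrow = p$n_clusters, byrow = TRUE)
    else if (!is.null(p$shift)) p$shift else 2
    pathway_def(p$name, p$n_genes, p$n_clusters,
                proportions = unlist(p$proportions), shift = shift,
                sd = if (is.null(p$sd)) 0.5 else p$sd)
  })
  cohort_spec(n_samples = raw$n_samples,
              n_background_genes = .default(raw$n_background_genes, 200L),
              background_sd = .default(raw$background_sd, 0.5),
              pathways = pws, hazards = unlist(raw$hazards),
              hazard_source = raw$hazard_source,
              nested = if (!is.null(raw$nested))
                within(raw$nested, sub_hazards <- unlist(sub_hazards)),
              dendro = if (!is.null(raw$dendro))
                within(raw$dendro, proportions <- unlist(proportions)),
              censor_horizon = .default(raw$censor_horizon, 4500),
              censor_fraction = .default(raw$censor_fraction, 0.3),
              seed = raw$seed)
}

.default <- function(x, d) if (is.null(x)) d else x

#' Run a configured single-pass stratification
#'
#' Validates the configuration, reads the inputs, runs [stratify()] and
#' writes the report directory. Configuration failures are raised before any
#' computation starts, and a newly created output directory is removed again
#' if the run fails.
#'
#' @param config a `run_config`, a config list, or the path to a YAML config.
#' @return the report directory, invisibly.
#' @export
cmd_stratify <- function(config) {
  cfg <- .as_config(config)
  inputs <- .load_config_inputs(cfg)
  cleanup <- .prepare_out_dir(cfg$out_dir)
  ok <- FALSE
  on.exit(if (!ok) cleanup())
  fit <- stratify(inputs$expression, inputs$clinical,
                  inputs$sets[[cfg$pathway]], cfg$params, cfg$seed)
  write_report(fit, cfg$out_dir, plots = cfg$plots)
  .write_config_copy(cfg, cfg$out_dir)
  ok <- TRUE
  invisible(cfg$out_dir)
}

#' Run a configured sequential (or dendro-based) analysis
#'
#' Mode `"sequential"`: first-pass [stratify()] with `pathway`, selection of
#' `select_clusters`, second-pass [sequential_stratify()] with
#' `second_pathway`; artifacts of both passes are written under
#' `first_pass/` and `second_pass/`. Mode `"dendro"`: [hclust_dendro()] into
#' `dendro_groups` groups, a whole-cohort first pass with `pathway`, the
#' cluster-group [cluster_dendro_association()] table, and a
#' [dendro_stratify()] second pass within `select_groups`.
#'
#' @param config a `run_config`, a config list, or a YAML path.
#' @return the report directory, invisibly.
#' @export
cmd_sequential <- function(config) {
  cfg <- .as_config(config)
  if (cfg$mode == "stratify")
    stop("config error: cmd_sequential needs mode 'sequential' or 'dendro'",
         call. = FALSE)
  inputs <- .load_config_inputs(cfg)
  cleanup <- .prepare_out_dir(cfg$out_dir)
  ok <- FALSE
  on.exit(if (!ok) cleanup())
  if (cfg$mode == "sequential") {
    first <- stratify(inputs$expression, inputs$clinical,
                      inputs$sets[[cfg$pathway]], cfg$params, cfg$seed)
    second <- sequential_stratify(first, as.integer(cfg$select_clusters),
                                  inputs$expression, inputs$clinical,
                                  inputs$sets[[cfg$second_pathway]],
                                  cfg$params, cfg$seed)
    write_report(first, file.path(cfg$out_dir, "first_pass"),
                 plots = cfg$plots)
    write_report(second, file.path(cfg$out_dir, "second_pass"),
                 plots = cfg$plots)
  } else {
    dendro <- hclust_dendro(inputs$expression, cfg$dendro_groups,
                            top_n_genes = .default(cfg$top_n_genes, 1500L),
                            metric = .default(cfg$metric, "correlation"),
                            linkage = .default(cfg$linkage, "average"))
    first <- stratify(inputs$expression, inputs$clinical,
                      inputs$sets[[cfg$pathway]], cfg$params, cfg$seed)
    assoc <- cluster_dendro_association(first, dendro)
    within <- dendro_stratify(inputs$expression, inputs$clinical, dendro,
                              as.integer(cfg$select_groups),
                              inputs$sets[[cfg$pathway]], cfg$params,
                              cfg$seed)
    write_report(first, file.path(cfg$out_dir, "first_pass"),
                 plots = cfg$plots)
    write_report(within, file.path(cfg$out_dir, "second_pass"),
                 plots = cfg$plots)
    utils::write.table(data.frame(sample_id = dendro$sample_ids,
                                  dendro = dendro$groups),
                       file.path(cfg$out_dir, "dendro_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(assoc),
                       file.path(cfg$out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_config_copy(cfg, cfg$out_dir)
  ok <- TRUE
  invisible(cfg$out_dir)
}

.as_config <- function(config) {
  if (is.character(config)) read_run_config(config)
  else if (inherits(config, "run_config")) config
  else validate_run_config(config)
}

.write_config_copy <- function(cfg, dir) {
  ser <- unclass(cfg)
  ser$params <- unclass(ser$params)
  yaml::write_yaml(ser, file.path(dir, "config.yaml"))
}
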