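# cohort reused across several tests (cached once per test run)
.seq_cache <- new.env(parent = emptyenv())
nested_cohort <- function() {
  if (is.null(.seq_cache$co)) {
    .seq_cache$co <- simulate_cohort(respec("nested-HR2", 515))
    .seq_cache$pws <- synthetic_pathways(.seq_cache$co$spec)
  }
  .seq_cache
}

test_that("stratify composes the pipeline and accounts for every sample", {
  cc <- nested_cohort()
  fit <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 3)
  expect_s3_class(fit, "strat_fit")
  expect_identical(length(fit$assignment$sample_ids) + nrow(fit$excluded),
                   ncol(cc$co$expression))
  expect_identical(sum(fit$assignment$cluster_sizes),
                   length(fit$assignment$sample_ids))
  expect_identical(names(fit$curves), as.character(seq_len(fit$assignment$k)))
  expect_identical(length(fit$provenance), 1L)
  expect_identical(fit$provenance[[1]]$pathway, "PWA")
  # planted two-cluster structure with a strong survival split
  expect_identical(fit$assignment$k, 2L)
  truth <- aligned_truth(cc$co, fit, "PWA")
  expect_gte(ari(fit$assignment$labels, truth), 0.9)
  expect_lt(fit$logrank$p_value, 0.01)
})

test_that("stratify rejects cohorts below the minimum size", {
  cc <- nested_cohort()
  small <- expression_matrix(unclass(cc$co$expression)[, 1:30], "log2p1")
  expect_error(stratify(small, cc$co$clinical, cc$pws$PWA, seed = 1),
               "size error")
})

test_that("rerunning with identical inputs and seed reproduces the fit exactly", {
  cc <- nested_cohort()
  f1 <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 5)
  f2 <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 5)
  expect_identical(f1$assignment$labels, f2$assignment$labels)
  expect_identical(f1$embedding$coords, f2$embedding$coords)
  expect_identical(f1$provenance, f2$provenance)
  expect_equal(f1$logrank$p_value, f2$logrank$p_value, tolerance = 0)
})

test_that("sequential pass refines the selected cluster and keeps provenance", {
  cc <- nested_cohort()
  first <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 3)
  sel <- best_median_cluster(first)
  second <- sequential_stratify(first, sel, cc$co$expression, cc$co$clinical,
                                cc$pws$PWB, seed = 3)
  expect_s3_class(second, "seq_strat_fit")
  expect_identical(length(second$provenance), 2L)
  expect_identical(second$provenance[[2]]$selection, sel)

  # refinement consistency: second-pass samples + exclusions = selection
  sel_ids <- first$assignment$sample_ids[first$assignment$labels %in% sel]
  expect_setequal(c(second$assignment$sample_ids,
                    second$excluded$sample_id), sel_ids)

  # cross-tabulation covers exactly the re-analyzed samples
  expect_identical(sum(second$crosstab), length(second$assignment$sample_ids))

  # combined partition covers every first-pass sample exactly once
  expect_setequal(unlist(second$combined_groups),
                  setdiff(first$assignment$sample_ids,
                          second$excluded$sample_id))

  # the planted sub-split is recovered within the favorable cluster
  subtruth <- aligned_truth(cc$co, second, "PWB")
  expect_gte(ari(second$assignment$labels, subtruth), 0.8)
  expect_lt(second$logrank$p_value, 0.01)
})

test_that("selection validation mirrors the published small-cluster exclusion", {
  # a 7-sample cluster may not seed a second pass at the default minimum
  prev <- stub_fit(c(rep(1, 100), rep(2, 7)))
  cc <- nested_cohort()
  expect_error(
    sequential_stratify(prev, 2L, cc$co$expression, cc$co$clinical,
                        cc$pws$PWB, seed = 1),
    "min_subcohort")
  expect_error(
    sequential_stratify(prev, 9L, cc$co$expression, cc$co$clinical,
                        cc$pws$PWB, seed = 1),
    "valid labels")
})

test_that("selecting every cluster reproduces the single-pass analysis", {
  cc <- nested_cohort()
  first <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 4)
  all_cl <- seq_len(first$assignment$k)
  seq_fit <- sequential_stratify(first, all_cl, cc$co$expression,
                                 cc$co$clinical, cc$pws$PWB, seed = 4)
  direct <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWB, seed = 4)
  expect_identical(seq_fit$assignment$sample_ids, direct$assignment$sample_ids)
  expect_identical(seq_fit$assignment$labels, direct$assignment$labels)
  expect_identical(seq_fit$embedding$coords, direct$embedding$coords)
})

test_that("chain depth and same-pathway reuse are policed", {
  cc <- nested_cohort()
  first <- stratify(cc$co$expression, cc$co$clinical, cc$pws$PWA, seed = 3)
  second <- sequential_stratify(first, best_median_cluster(first),
                                cc$co$expression, cc$co$clinical, cc$pws$PWB,
                                seed = 3)
  expect_error(
    sequential_stratify(second, 1L, cc$co$expression, cc$co$clinical,
                        cc$pws$PWA, seed = 3),
    "max_depth")
  deep <- strat_params(max_depth = 3L)
  expect_warning(
    third <- sequential_stratify(second, seq_len(second$assignment$k),
                                 cc$co$expression, cc$co$clinical, cc$pws$PWB,
                                 params = deep, seed = 3),
    "identical to the previous")
  expect_identical(length(third$provenance), 3L)
})

test_that("hclust_dendro cuts planted transcriptome groups deterministically", {
  sp <- respec("dendro-nested", 616)
  co <- simulate_cohort(sp)
  d1 <- hclust_dendro(co$expression, g = 3, top_n_genes = 500)
  d2 <- hclust_dendro(co$expression, g = 3, top_n_genes = 500)
  expect_identical(d1$groups, d2$groups)
  expect_identical(d1$g, 3L)
  expect_identical(length(d1$groups), ncol(co$expression))
  expect_gte(ari(d1$groups, co$truth$labels$dendro), 0.99)

  # coarser cut still labels every sample
  d3 <- hclust_dendro(co$expression, g = 2, top_n_genes = 500)
  expect_identical(sort(unique(d3$groups)), 1:2)

  expect_error(hclust_dendro(co$expression, g = 1), "at least 2")
  expect_error(hclust_dendro(co$expression, g = 10000), "sample count")
  expect_error(hclust_dendro(co$expression, g = 3, top_n_genes = 1e6),
               "gene count")
})

test_that("cluster-dendro association flags planted and null relations", {
  sp <- respec("dendro-nested", 616)
  co <- simulate_cohort(sp)
  d <- hclust_dendro(co$expression, g = 3, top_n_genes = 500)

  # perfect association: use the dendro grouping itself as a clustering
  fake <- structure(list(sample_ids = d$sample_ids, labels = d$groups,
                         k = 3L), class = "cluster_assignment")
  tab <- cluster_dendro_association(fake, d)
  expect_s3_class(tab, "association_table")
  expect_identical(nrow(tab), 9L)
  diag_p <- tab$p_value[tab$cluster == tab$dendro]
  expect_true(all(diag_p < 1e-10))

  # independent labels: the raw p of a fixed (cluster, group) pair rejects
  # at ~5%; with 200 replicates the count stays inside a wide binomial band
  set.seed(17)
  ids200 <- sprintf("R%03d", 1:200)
  hits <- 0L
  for (r in 1:200) {
    rnd <- structure(list(sample_ids = ids200,
                          labels = sample(1:2, 200, replace = TRUE),
                          k = 2L), class = "cluster_assignment")
    drnd <- structure(list(sample_ids = ids200,
                           groups = sample(1:2, 200, replace = TRUE),
                           g = 2L, linkage = d$linkage),
                      class = "dendro_assignment")
    tt <- cluster_dendro_association(rnd, drnd)
    if (tt$p_value[tt$cluster == 1 & tt$dendro == 1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 2L)   # qbinom(0.0005, 200, 0.05)
  expect_lte(hits, 22L)  # qbinom(0.9995, 200, 0.05)

  # degenerate: a cluster absent from the overlap is reported as NA
  part <- structure(list(sample_ids = d$sample_ids,
                         labels = rep(1L, length(d$sample_ids)), k = 2L),
                    class = "cluster_assignment")
  expect_warning(tab2 <- cluster_dendro_association(part, d), "empty")
  expect_true(any(is.na(tab2$p_value)))

  disjoint <- structure(list(sample_ids = paste0("X", 1:10),
                             labels = rep(1L, 10), k = 1L),
                        class = "cluster_assignment")
  expect_error(cluster_dendro_association(disjoint, d), "no samples")
})

test_that("dendro_stratify equals stratify when every group is selected", {
  sp <- respec("dendro-nested", 616)
  co <- simulate_cohort(sp)
  pw <- synthetic_pathways(sp)$PWA
  d <- hclust_dendro(co$expression, g = 3, top_n_genes = 500)
  whole <- dendro_stratify(co$expression, co$clinical, d, 1:3, pw, seed = 6)
  direct <- stratify(co$expression, co$clinical, pw, seed = 6)
  expect_identical(whole$assignment$labels, direct$assignment$labels)
  expect_identical(whole$provenance[[1]]$type, "dendro")
  expect_identical(length(whole$provenance), 2L)

  expect_error(dendro_stratify(co$expression, co$clinical, d, 99L, pw,
                               seed = 1),
               "valid groups")

  # a dendro group below the subcohort minimum cannot seed a second pass
  tiny <- structure(list(sample_ids = d$sample_ids,
                         groups = c(rep(1L, length(d$sample_ids) - 7),
                                    rep(2L, 7)),
                         g = 2L, linkage = d$linkage),
                    class = "dendro_assignment")
  expect_error(dendro_stratify(co$expression, co$clinical, tiny, 2L, pw,
                               seed = 1),
               "min_subcohort")
})

test_that("within-group stratification sharpens the pathway survival signal", {
  # the planted pathway split only affects hazards inside dendro group 2, so
  # the within-group log-rank should beat the diluted whole-cohort one
  reps <- 20L
  sharper <- 0L
  detected <- 0L
  for (s in seq_len(reps)) {
    sp <- respec("dendro-nested", 700 + s)
    co <- simulate_cohort(sp)
    pw <- synthetic_pathways(sp)$PWA
    d <- hclust_dendro(co$expression, g = 3, top_n_genes = 500)
    # identify the dendro group matching planted group 2 by overlap
    ov <- vapply(1:3, function(g)
      sum(d$groups == g & co$truth$labels$dendro == 2), integer(1))
    target <- which.max(ov)
    within <- dendro_stratify(co$expression, co$clinical, d, target, pw,
                              seed = s)
    whole <- stratify(co$expression, co$clinical, pw, seed = s)
    p_within <- if (is.null(within$logrank)) 1 else within$logrank$p_value
    p_whole <- if (is.null(whole$logrank)) 1 else whole$logrank$p_value
    if (p_within < 0.01) detected <- detected + 1L
    if (p_within < p_whole) sharper <- sharper + 1L
  }
  expect_gte(detected, round(0.8 * reps))
  expect_gte(sharper, round(0.8 * reps))
})

test_that("median_gap measures the between-extreme spread of a partition", {
  set.seed(404)
  clin <- clinical_table(data.frame(
    sample_id = sprintf("S%02d", 1:40),
    time_days = c(rexp(20, log(2) / 500), rexp(20, log(2) / 3000)),
    event = 1))
  groups <- list(short = sprintf("S%02d", 1:20),
                 long = sprintf("S%02d", 21:40))
  gap <- median_gap(groups, clin)
  expect_gt(gap, 0)
})
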