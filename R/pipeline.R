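## Stage orchestration: simulate -> dereplicate -> features ->
## ordination -> stats, each stage reading and writing plain-text
## artifacts in a run directory, with a single reproducibility manifest.

MAJOR_CLASSES <- c("NRPS", "PKS", "RiPP", "terpene")

#' Default analysis thresholds
#'
#' The thresholds in effect across the pipeline: inclusive network
#' cutoff 0.5, sentinel 0.51 for reference-unconnected BGCs, 5% GCF and
#' 20% taxon prevalence filters, strict 0.70 support retention, 10
#' taxonomy PCs, 999 permutations, k in \[2, 8\].
#'
#' @return Named list of threshold values.
#' @export
default_thresholds <- function() {
  list(cutoff = 0.5, sentinel = 0.51, gcf_prevalence = 0.05,
       taxon_prevalence = 0.20, support = 0.70, n_taxonomy_pcs = 10,
       n_permutations = 999, k_range = c(2, 8))
}

require_artifact <- function(path, producer) {
  check_that(file.exists(path),
             "missing artifact '%s'; run %s() first", basename(path), producer)
  path
}

#' Stage 1: write a synthetic study to a run directory
#'
#' @param config A [sim_config()].
#' @param dir Run directory.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(config, dir) {
  study <- simulate_study(config)
  write_study(study, dir, config)
  gcf_log("run_simulate: study written to ", dir)
  invisible(dir)
}

#' Stage 2: dereplicate BGCs into families and score novelty
#'
#' Builds one similarity network per biosynthetic class from the network
#' files and the inventory, derives families as connected components,
#' classifies family novelty against reference nodes, and computes
#' per-BGC and per-sample minimum novelty.
#'
#' @param dir Run directory holding `network_<class>.tsv` files and
#'   `inventory.tsv`.
#' @param cutoff Inclusive network distance cutoff.
#' @param sentinel Sentinel distance for reference-unconnected BGCs.
#' @return Invisibly, the family table.
#' @export
run_dereplicate <- function(dir, cutoff = 0.5, sentinel = 0.51) {
  inv <- read_inventory(require_artifact(file.path(dir, "inventory.tsv"),
                                         "run_simulate"))
  net_files <- list.files(dir, pattern = "^network_.*\\.tsv$",
                          full.names = TRUE)
  net_files <- net_files[c_order(basename(net_files))]
  check_that(length(net_files) > 0L,
             "missing artifact 'network_<class>.tsv'; run run_simulate() first")
  classes <- sub("^network_(.*)\\.tsv$", "\\1", basename(net_files))
  mem_all <- list(); fam_all <- list(); nov_all <- list(); samp_all <- list()
  for (i in seq_along(net_files)) {
    cl <- classes[i]
    edges <- read_network(net_files[i], dialect = "minimal")
    class_bgcs <- inv$bgc_id[inv$bgc_class == cl]
    nodes <- union(class_bgcs, unique(c(edges$a, edges$b)))
    if (length(nodes) == 0L) next
    net <- build_network(edges, nodes = nodes, cutoff = cutoff,
                         bgc_class = cl)
    mem <- connected_components(net)
    fam <- classify_novelty(mem, net$nodes[net$is_reference])
    fam$bgc_class <- cl
    nov <- min_reference_distance(net, sentinel = sentinel)
    mem$bgc_class <- cl
    mem_all[[cl]] <- mem
    fam_all[[cl]] <- fam
    nov_all[[cl]] <- nov
    sm <- sample_min_novelty(nov, inv, cl)
    if (nrow(sm)) {
      sm$bgc_class <- cl
      samp_all[[cl]] <- sm
    }
  }
  membership <- do.call(rbind, mem_all)
  families <- do.call(rbind, fam_all)
  novelty <- do.call(rbind, nov_all)
  sample_novelty <- do.call(rbind, samp_all)
  rownames(membership) <- rownames(families) <- rownames(novelty) <- NULL
  utils::write.table(membership, file.path(dir, "membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(families, file.path(dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(novelty, file.path(dir, "novelty_bgc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sample_novelty, file.path(dir, "novelty_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gcf_log(sprintf("run_dereplicate: %d families (%.1f%% novel)",
                  nrow(families), 100 * novel_fraction(families)))
  invisible(families)
}

#' Stage 3: build feature matrices
#'
#' GCF presence-absence matrix (all metadata samples as rows), the
#' prevalence-filtered matrix, its Hellinger transform, per-sample class
#' proportions, and the taxonomy pipeline (support filter, genus
#' proportions, prevalence filter, Hellinger, PCA).
#'
#' @param dir Run directory.
#' @param gcf_prevalence GCF prevalence filter fraction.
#' @param support_threshold CAT support retention threshold (strict).
#' @param taxon_prevalence Taxon prevalence filter fraction.
#' @param n_taxonomy_pcs Taxonomy principal components to retain.
#' @return Invisibly, the filtered presence matrix.
#' @export
run_features <- function(dir, gcf_prevalence = 0.05,
                         support_threshold = 0.70,
                         taxon_prevalence = 0.20, n_taxonomy_pcs = 10) {
  inv <- read_inventory(require_artifact(file.path(dir, "inventory.tsv"),
                                         "run_simulate"))
  env <- read_metadata(require_artifact(file.path(dir, "metadata.csv"),
                                        "run_simulate"))
  mem_path <- require_artifact(file.path(dir, "membership.tsv"),
                               "run_dereplicate")
  membership <- utils::read.delim(mem_path, stringsAsFactors = FALSE)
  pm <- presence_matrix(inv, membership, samples = env$sample_id)
  pf <- prevalence_filter(pm, gcf_prevalence)
  hel <- hellinger(pf)
  fam_class <- membership$bgc_class[match(colnames(pm), membership$family_id)]
  cp <- suppressWarnings(class_proportions(pm, fam_class))
  write_matrix(pm, file.path(dir, "presence.tsv"))
  write_matrix(pf, file.path(dir, "presence_filtered.tsv"))
  write_matrix(hel, file.path(dir, "hellinger.tsv"))
  write_matrix(cp, file.path(dir, "class_proportions.tsv"))
  contigs <- read_contigs(require_artifact(file.path(dir, "contigs.tsv"),
                                           "run_simulate"))
  tax <- taxonomy_features(contigs, support_threshold, taxon_prevalence,
                           samples = env$sample_id)
  n_pcs <- min(n_taxonomy_pcs, nrow(tax) - 1L, ncol(tax))
  pcs <- pca_profile(hellinger(tax), n_pcs)
  write_matrix(tax, file.path(dir, "taxonomy_profile.tsv"))
  write_matrix(pcs$scores, file.path(dir, "taxonomy_pcs.tsv"))
  gcf_log(sprintf("run_features: %d/%d GCFs retained; %d taxonomy PCs (%.1f%% variance)",
                  ncol(pf), ncol(pm), n_pcs,
                  100 * sum(pcs$variance_fraction)))
  invisible(pf)
}

#' Stage 4: ordination, clustering and multivariate tests
#'
#' Depth-conditioned partial RDA of the Hellinger GCF profile on
#' environmental and tectonic constraints; k-means of site scores with
#' elbow/silhouette k selection; PERMANOVA (cluster contrast, and
#' marginal environmental terms conditioned on depth), ANOSIM,
#' dispersion homogeneity; variation partitioning of environment vs
#' taxonomy PCs; Spearman depth checks on axes before and after
#' conditioning.
#'
#' @param dir Run directory.
#' @param n_permutations Permutations for every test.
#' @param seed Integer seed.
#' @param k_range,restarts k-means settings.
#' @return Invisibly, the results list.
#' @export
run_ordination <- function(dir, n_permutations = 999, seed = 1,
                           k_range = 2:8, restarts = 20) {
  hel <- read_matrix(require_artifact(file.path(dir, "hellinger.tsv"),
                                      "run_features"))
  env <- read_metadata(require_artifact(file.path(dir, "metadata.csv"),
                                        "run_simulate"))
  pcs <- read_matrix(require_artifact(file.path(dir, "taxonomy_pcs.tsv"),
                                      "run_features"))
  env <- env[match(rownames(hel), env$sample_id), ]
  log_depth <- log1p(env$sequencing_depth)
  constraints <- env[, c("temperature", "pH", "conductivity",
                         "crustal_thickness", "tectonic_setting")]
  cond <- data.frame(log_depth = log_depth)

  pca0 <- pca_profile(hel, min(4L, nrow(hel) - 1L, ncol(hel)))
  depth_before <- axis_depth_check(pca0$scores, log_depth)
  ord <- partial_rda(hel, constraints, cond, n_permutations = n_permutations,
                     seed = seed, by = "margin")
  depth_after <- axis_depth_check(ord$site_scores, log_depth)

  cl <- cluster_sites(ord$site_scores, k_range = k_range,
                      restarts = restarts, seed = child_seed(seed, 11L))
  clusters <- factor(cl$labels)
  cluster_df <- data.frame(cluster = clusters)
  pmv_cluster <- permanova(Y = hel, data = cluster_df, terms = "cluster",
                           by = "overall", n_permutations = n_permutations,
                           seed = child_seed(seed, 21L))
  pmv_env <- permanova(Y = hel, data = cbind(env, log_depth = log_depth),
                       terms = c("temperature", "pH", "crustal_thickness"),
                       condition = "log_depth", by = "margin",
                       n_permutations = n_permutations,
                       seed = child_seed(seed, 22L))
  D <- stats::dist(hel)
  ano <- anosim_test(D, clusters, n_permutations = n_permutations,
                     seed = child_seed(seed, 23L))
  disp <- betadisper_test(D, clusters, n_permutations = n_permutations,
                          seed = child_seed(seed, 24L))
  vp <- variation_partition(
    hel, X1 = env[, c("temperature", "pH", "conductivity",
                      "crustal_thickness")],
    X2 = as.data.frame(pcs), condition = cond,
    n_permutations = n_permutations, seed = child_seed(seed, 25L))

  write_matrix(ord$site_scores, file.path(dir, "ordination_scores.tsv"))
  utils::write.table(data.frame(sample_id = rownames(hel),
                                cluster = as.integer(clusters)),
                     file.path(dir, "cluster_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results <- list(
    rda = list(R2 = ord$R2, F = ord$F, p = ord$p,
               eigenvalues = ord$eigenvalues, terms = ord$terms),
    clustering = list(chosen_k = cl$chosen_k, k_elbow = cl$k_elbow,
                      k_silhouette = cl$k_silhouette, per_k = cl$per_k),
    permanova_clusters = as.data.frame(pmv_cluster),
    permanova_env = as.data.frame(pmv_env),
    anosim = ano[c("statistic", "p", "n_permutations")],
    betadisper = disp[c("statistic", "p", "n_permutations")],
    varpart = vp[c("a", "b", "c", "d", "adj_r2", "p_unique")],
    depth_check = list(before = depth_before, after = depth_after)
  )
  write_results_json(results, file.path(dir, "ordination_results.json"),
                     seed = seed)
  invisible(results)
}

#' Stage 5: diversity, group tests and novelty regressions
#'
#' Shannon diversity of per-sample GCF class counts compared across
#' tectonic settings (Kruskal-Wallis, BH-adjusted over the omnibus
#' family, Dunn post hoc); the volcanic-arc versus others Wilcoxon
#' contrast on NRPS class proportions; Kruskal-Wallis with Holm-Dunn on
#' terpene proportions across settings; and per-class OLS regressions of
#' minimum novelty on crustal thickness.
#'
#' @param dir Run directory.
#' @param seed Integer seed (recorded in provenance; all tests here are
#'   deterministic given the inputs).
#' @return Invisibly, the results list.
#' @export
run_stats <- function(dir, seed = 1) {
  env <- read_metadata(require_artifact(file.path(dir, "metadata.csv"),
                                        "run_simulate"))
  pf <- read_matrix(require_artifact(file.path(dir, "presence_filtered.tsv"),
                                     "run_features"))
  cp <- read_matrix(require_artifact(file.path(dir, "class_proportions.tsv"),
                                     "run_features"))
  membership <- utils::read.delim(
    require_artifact(file.path(dir, "membership.tsv"), "run_dereplicate"),
    stringsAsFactors = FALSE)
  sample_novelty <- utils::read.delim(
    require_artifact(file.path(dir, "novelty_sample.tsv"), "run_dereplicate"),
    stringsAsFactors = FALSE)
  env <- env[match(rownames(pf), env$sample_id), ]
  fam_class <- membership$bgc_class[match(colnames(pf),
                                          membership$family_id)]
  class_counts <- vapply(c_sort(unique(fam_class)), function(cl) {
    rowSums(pf[, fam_class == cl, drop = FALSE])
  }, numeric(nrow(pf)))
  ok <- rowSums(class_counts) > 0
  H <- apply(class_counts[ok, , drop = FALSE], 1, shannon)
  setting <- env$tectonic_setting[ok]

  kw_shannon <- kruskal_wallis(H, setting)
  arc <- factor(ifelse(env$tectonic_setting == "volcanic_arc",
                       "volcanic_arc", "others"))
  cps <- cp[match(rownames(pf), rownames(cp)), , drop = FALSE]
  wx_nrps <- if ("NRPS" %in% colnames(cps)) {
    wilcoxon_rank_sum(cps[arc == "volcanic_arc", "NRPS"],
                      cps[arc == "others", "NRPS"])
  } else NULL
  kw_terpene <- if ("terpene" %in% colnames(cps)) {
    kruskal_wallis(cps[, "terpene"], env$tectonic_setting)
  } else NULL
  omnibus_p <- c(shannon = kw_shannon$p,
                 terpene = if (is.null(kw_terpene)) NA else kw_terpene$p)
  omnibus_adj <- adjust_pvalues(unname(omnibus_p), "BH")
  gcf_log(sprintf("omnibus family size for BH adjustment: %d",
                  sum(!is.na(omnibus_p))))
  dunn_shannon <- dunn_posthoc(H, setting, adjust = "BH")
  dunn_terpene <- if (!is.null(kw_terpene) && !kw_terpene$degenerate) {
    dunn_posthoc(cps[, "terpene"], env$tectonic_setting, adjust = "holm")
  } else NULL

  reg <- list()
  for (cl in intersect(MAJOR_CLASSES, unique(sample_novelty$bgc_class))) {
    sn <- sample_novelty[sample_novelty$bgc_class == cl, ]
    ct <- env$crustal_thickness[match(sn$sample_id, env$sample_id)]
    if (nrow(sn) >= 3 && stats::sd(ct) > 0 &&
        stats::sd(sn$min_novelty) > 0) {
      fit <- novelty_regression(sn$min_novelty, ct)
      reg[[cl]] <- fit[c("slope", "intercept", "r_squared", "p", "n")]
    }
  }
  diversity <- data.frame(sample_id = rownames(pf)[ok], shannon = unname(H))
  utils::write.table(diversity, file.path(dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reg_tab <- do.call(rbind, lapply(names(reg), function(cl) {
    data.frame(bgc_class = cl, covariate = "crustal_thickness",
               slope = reg[[cl]]$slope, r_squared = reg[[cl]]$r_squared,
               p = reg[[cl]]$p, n = reg[[cl]]$n,
               stars = significance_stars(reg[[cl]]$p),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(reg_tab)) {
    utils::write.table(reg_tab, file.path(dir, "novelty_regressions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results <- list(
    shannon = list(mean = mean(H), sd = stats::sd(H),
                   by_setting = tapply(H, setting, mean),
                   kruskal_wallis = kw_shannon,
                   p_adjusted_BH = omnibus_adj[1],
                   dunn = dunn_shannon),
    nrps_wilcoxon = wx_nrps,
    terpene_kruskal = c(kw_terpene,
                        list(p_adjusted_BH = omnibus_adj[2],
                             dunn_holm = dunn_terpene)),
    novelty_regressions = reg
  )
  write_results_json(results, file.path(dir, "stats_results.json"),
                     seed = seed)
  invisible(results)
}

#' Run the full pipeline on a synthetic study
#'
#' simulate -> dereplicate -> features -> ordination -> stats, then a
#' reproducibility manifest (`manifest.json`) recording the config hash,
#' seeds, every threshold in effect, and content hashes of all inputs
#' and outputs. Identical config and seed reproduce every artifact
#' bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param dir Run directory.
#' @param n_permutations Permutations for all multivariate tests.
#' @param seed Analysis seed; defaults to the config seed.
#' @param thresholds Threshold list, defaulting to [default_thresholds()]
#'   with `n_permutations` spliced in.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config = sim_config(), dir,
                    n_permutations = default_thresholds()$n_permutations,
                    seed = config$seed) {
  th <- default_thresholds()
  th$n_permutations <- n_permutations
  run_simulate(config, dir)
  run_dereplicate(dir, cutoff = th$cutoff, sentinel = th$sentinel)
  run_features(dir, gcf_prevalence = th$gcf_prevalence,
               support_threshold = th$support,
               taxon_prevalence = th$taxon_prevalence,
               n_taxonomy_pcs = th$n_taxonomy_pcs)
  run_ordination(dir, n_permutations = n_permutations, seed = seed,
                 k_range = th$k_range[1]:th$k_range[2])
  run_stats(dir, seed = seed)
  files <- setdiff(list.files(dir), "manifest.json")
  files <- files[c_order(files)]
  digests <- vapply(file.path(dir, files), content_hash, "")
  names(digests) <- files
  manifest <- list(config_hash = content_hash(deparse(unclass(config))),
                   seed = as.integer(seed),
                   config_seed = config$seed,
                   package_version = as.character(utils::packageVersion("geoGCF")),
                   thresholds = th,
                   artifacts = as.list(digests))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
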