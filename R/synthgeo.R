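## Seeded synthetic geothermal studies with known ground truth: planted
## gene cluster families, reference contamination, tectonic-setting
## effects on class composition, and a sequencing-depth detection bias.

SETTINGS <- c("volcanic_arc", "backarc", "mid_ocean_ridge")

PROVINCES <- list(
  volcanic_arc = c("CAVA", "SA-CVZ_arc", "AAVP"),
  backarc = c("SA-CVZ_backarc", "Campania"),
  mid_ocean_ridge = c("RVB", "EPR")
)

#' Configuration for a synthetic geothermal study
#'
#' Defaults define the study conditions used throughout validation:
#' 60 samples over three tectonic settings, 40 planted families per
#' biosynthetic class, a 10% chance that a family contains a reference
#' member (so roughly 90% of families are novel), a strong
#' setting-to-composition effect, and a sequencing-depth detection bias of
#' the same order as the biological signal.
#'
#' @param n_samples Number of metagenome samples (>= 1).
#' @param n_families_per_class Planted families per biosynthetic class.
#' @param classes Biosynthetic class labels.
#' @param ref_fraction Probability a family contains one reference member.
#' @param within_family_distance Interval (within \[0, cutoff\]) for
#'   within-family pairwise distances.
#' @param cross_family_distance Interval (within (cutoff, 1\]) for
#'   cross-family distances; such pairs exceed the cutoff and are omitted
#'   from emitted edge lists, mirroring BiG-SCAPE network files.
#' @param cutoff Network distance cutoff the intervals must respect.
#' @param effect_size Magnitude of the tectonic-setting tilt on class
#'   composition (log-odds units on detection).
#' @param depth_bias Slope of detection log-odds on centred log1p
#'   sequencing depth.
#' @param noise_sd SD of per-family detectability noise (log-odds).
#' @param ct_known_bias Extra detection log-odds per SD of crustal
#'   thickness for reference-containing families; plants the negative
#'   crustal-thickness/minimum-novelty association.
#' @param base_detect Baseline per-family detection probability.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of sequencing
#'   depth (reads).
#' @param n_genera Number of genera in the simulated taxonomy.
#' @param taxonomy_coupling Strength of the setting effect on genus
#'   composition; defaults to `effect_size`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 60,
                       n_families_per_class = 40,
                       classes = c("NRPS", "PKS", "RiPP", "terpene", "other"),
                       ref_fraction = 0.1,
                       within_family_distance = c(0.05, 0.45),
                       cross_family_distance = c(0.55, 0.95),
                       cutoff = 0.5,
                       effect_size = 2,
                       depth_bias = 1.5,
                       noise_sd = 0.3,
                       ct_known_bias = 1,
                       base_detect = 0.3,
                       depth_meanlog = 16,
                       depth_sdlog = 0.8,
                       n_genera = 30,
                       taxonomy_coupling = NULL,
                       seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_families_per_class = as.integer(n_families_per_class),
    classes = as.character(classes),
    ref_fraction = ref_fraction,
    within_family_distance = as.numeric(within_family_distance),
    cross_family_distance = as.numeric(cross_family_distance),
    cutoff = cutoff,
    effect_size = effect_size,
    depth_bias = depth_bias,
    noise_sd = noise_sd,
    ct_known_bias = ct_known_bias,
    base_detect = base_detect,
    depth_meanlog = depth_meanlog,
    depth_sdlog = depth_sdlog,
    n_genera = as.integer(n_genera),
    taxonomy_coupling = if (is.null(taxonomy_coupling)) effect_size
                        else taxonomy_coupling,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_that(cfg$n_samples >= 1L, "n_samples must be >= 1")
  check_that(cfg$n_families_per_class >= 1L,
             "n_families_per_class must be >= 1")
  check_that(length(cfg$classes) >= 2L, "need at least 2 classes")
  check_that(cfg$ref_fraction >= 0 && cfg$ref_fraction <= 1,
             "ref_fraction must lie in [0, 1]")
  w <- cfg$within_family_distance
  x <- cfg$cross_family_distance
  check_that(length(w) == 2L && w[1] >= 0 && w[1] <= w[2],
             "within_family_distance must be an ordered interval in [0, cutoff]")
  check_that(w[2] <= cfg$cutoff,
             "within_family_distance upper bound must be <= cutoff")
  check_that(length(x) == 2L && x[1] > cfg$cutoff && x[1] <= x[2] && x[2] <= 1,
             "cross_family_distance must lie in (cutoff, 1]")
  check_that(cfg$effect_size >= 0, "effect_size must be nonnegative")
  check_that(cfg$depth_bias >= 0, "depth_bias must be nonnegative")
  check_that(cfg$noise_sd >= 0, "noise_sd must be nonnegative")
  check_that(cfg$base_detect > 0 && cfg$base_detect < 1,
             "base_detect must lie in (0, 1)")
  invisible(TRUE)
}

# Setting-specific tilt directions in class space: three unit vectors at
# 120 degrees in the plane spanned by (class1 - class4) and
# (class2 - class3), so planted settings are pairwise equidistant.
# With the default classes: volcanic arcs gain NRPS and lose terpenes,
# backarcs the reverse (plus PKS), mid-ocean ridges gain RiPPs.
setting_tilts <- function(classes) {
  k <- length(classes)
  u1 <- numeric(k); u2 <- numeric(k)
  if (k >= 4L) {
    u1[1] <- 1; u1[4] <- -1
    u2[2] <- 1; u2[3] <- -1
  } else if (k == 3L) {
    u1[1] <- 1; u1[3] <- -1
    u2[2] <- 1; u2[c(1, 3)] <- -0.5
  } else {
    u1[1] <- 1; u1[2] <- -1
    u2 <- rev(u1)
  }
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- u2 / sqrt(sum(u2^2))
  theta <- c(0, 2 * pi / 3, 4 * pi / 3)
  d <- t(vapply(theta, function(th) cos(th) * u1 + sin(th) * u2,
                numeric(k)))
  dimnames(d) <- list(SETTINGS, classes)
  d
}

simulate_env <- function(cfg) {
  n <- cfg$n_samples
  setting <- SETTINGS[((seq_len(n) - 1L) %% 3L) + 1L]
  province <- vapply(setting, function(s) sample(PROVINCES[[s]], 1L), "")
  temp_mu <- c(volcanic_arc = 65, backarc = 75, mid_ocean_ridge = 80)
  temp_sd <- c(volcanic_arc = 15, backarc = 10, mid_ocean_ridge = 10)
  ph_mu <- c(volcanic_arc = 4, backarc = 6.5, mid_ocean_ridge = 7)
  ct_mu <- c(volcanic_arc = 55, backarc = 45, mid_ocean_ridge = 8)
  ct_sd <- c(volcanic_arc = 8, backarc = 6, mid_ocean_ridge = 3)
  env <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    temperature = pmin(93.5, pmax(4.7,
      stats::rnorm(n, temp_mu[setting], temp_sd[setting]))),
    pH = pmin(10.3, pmax(0.85, stats::rnorm(n, ph_mu[setting], 1.2))),
    conductivity = stats::rlnorm(n, log(2000), 1),
    crustal_thickness = pmax(3, stats::rnorm(n, ct_mu[setting], ct_sd[setting])),
    sequencing_depth = round(stats::rlnorm(n, cfg$depth_meanlog,
                                           cfg$depth_sdlog)),
    tectonic_setting = setting,
    volcanic_province = unname(province),
    stringsAsFactors = FALSE
  )
  env
}

#' Simulate a full synthetic geothermal study
#'
#' Draws sample metadata, plants gene cluster families per biosynthetic
#' class (a fraction of which contain one reference member), simulates
#' per-sample detection of each family with class composition tilted by
#' tectonic setting and detection probability increasing with log1p
#' sequencing depth, and emits per-class similarity-network edge lists in
#' which within-family distances fall below the cutoff and no
#' cross-family edge at or below the cutoff exists — so connected
#' components recover the planted partition exactly. A coupled taxonomy
#' (genus profile plus CAT-style contig table) is generated for variation
#' partitioning.
#'
#' @param config A [sim_config()].
#' @return List with `env`, `inventory`, `networks` (named per-class edge
#'   `data.frame`s), `contigs`, `taxonomy` (samples-by-genera proportion
#'   matrix) and `truth` (ground truth: membership, reference flags,
#'   planted compositions, cluster labels, depth coefficient).
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  env <- simulate_env(cfg)
  n <- cfg$n_samples
  classes <- cfg$classes
  nf <- cfg$n_families_per_class
  fam <- expand.grid(idx = seq_len(nf), bgc_class = classes,
                     stringsAsFactors = FALSE)
  fam$planted_family <- sprintf("F_%s_%03d", fam$bgc_class, fam$idx)
  nfam <- nrow(fam)
  fam$has_ref <- stats::runif(nfam) < cfg$ref_fraction
  fam$ref_id <- NA_character_
  fam$ref_id[fam$has_ref] <- sprintf("BGC%07d", seq_len(sum(fam$has_ref)))
  fam$eps <- stats::rnorm(nfam, 0, cfg$noise_sd)

  d <- setting_tilts(classes)
  ld <- log1p(env$sequencing_depth)
  ldc <- ld - mean(ld)
  ctz <- as.numeric(scale(env$crustal_thickness))
  set_idx <- match(env$tectonic_setting, SETTINGS)
  cls_idx <- match(fam$bgc_class, classes)

  # detection log-odds: samples x families
  logit <- stats::qlogis(cfg$base_detect) +
    cfg$effect_size * d[set_idx, , drop = FALSE][, cls_idx, drop = FALSE] +
    outer(cfg$depth_bias * ldc, rep(1, nfam)) +
    outer(rep(1, n), fam$eps) +
    outer(cfg$ct_known_bias * ctz, as.numeric(fam$has_ref))
  pres <- matrix(stats::runif(n * nfam) < stats::plogis(logit), n, nfam)

  hit <- which(pres, arr.ind = TRUE)
  hit <- hit[order(hit[, "col"], hit[, "row"]), , drop = FALSE]
  inventory <- data.frame(
    bgc_id = sprintf("GEO%06d", seq_len(nrow(hit))),
    sample_id = env$sample_id[hit[, "row"]],
    bgc_class = fam$bgc_class[hit[, "col"]],
    planted_family = fam$planted_family[hit[, "col"]],
    stringsAsFactors = FALSE
  )

  networks <- simulate_networks(cfg, fam, inventory)

  # ground-truth membership covers environmental BGCs and reference nodes
  membership <- rbind(
    data.frame(bgc_id = inventory$bgc_id,
               planted_family = inventory$planted_family,
               bgc_class = inventory$bgc_class,
               is_reference = FALSE, stringsAsFactors = FALSE),
    data.frame(bgc_id = fam$ref_id[fam$has_ref],
               planted_family = fam$planted_family[fam$has_ref],
               bgc_class = fam$bgc_class[fam$has_ref],
               is_reference = TRUE, stringsAsFactors = FALSE)
  )

  # planted per-setting class composition: expected detections per class
  # at mean depth and zero family noise, normalized to the simplex
  pdet <- stats::plogis(stats::qlogis(cfg$base_detect) + cfg$effect_size * d)
  comp <- pdet / rowSums(pdet)

  taxonomy <- simulate_taxonomy(env, cfg$taxonomy_coupling,
                                seed = child_seed(cfg$seed, 101L),
                                n_genera = cfg$n_genera)
  contigs <- simulate_contigs(env, taxonomy, seed = child_seed(cfg$seed, 202L))

  truth <- list(
    membership = membership,
    families = fam[, c("planted_family", "bgc_class", "has_ref", "ref_id")],
    composition = comp,
    cluster_labels = stats::setNames(env$tectonic_setting, env$sample_id),
    depth_coefficient = cfg$depth_bias
  )
  list(env = env, inventory = inventory[, c("bgc_id", "sample_id",
                                            "bgc_class", "planted_family")],
       networks = networks, contigs = contigs, taxonomy = taxonomy,
       truth = truth)
}

# Per-class edge lists: a random spanning tree within each family keeps
# it one connected component; members of reference-containing families
# get direct edges to the reference with probability 0.7 so per-BGC
# distance-to-reference is informative. Cross-family pairs all exceed the
# cutoff and are therefore omitted, as in BiG-SCAPE network files.
simulate_networks <- function(cfg, fam, inventory) {
  w <- cfg$within_family_distance
  by_fam <- split(inventory$bgc_id, inventory$planted_family)
  out <- vector("list", nrow(fam))
  for (i in seq_len(nrow(fam))) {
    members <- by_fam[[fam$planted_family[i]]]
    ref <- fam$ref_id[i]
    all_m <- c(members, if (!is.na(ref)) ref)
    m <- length(all_m)
    if (m < 2L) next
    ord <- sample(all_m)
    parent <- vapply(2:m, function(j) ord[sample.int(j - 1L, 1L)], "")
    ea <- ord[2:m]; eb <- parent
    if (!is.na(ref) && length(members)) {
      extra <- members[stats::runif(length(members)) < 0.7]
      ea <- c(ea, extra); eb <- c(eb, rep(ref, length(extra)))
    }
    out[[i]] <- data.frame(a = ea, b = eb,
                           distance = stats::runif(length(ea), w[1], w[2]),
                           bgc_class = fam$bgc_class[i],
                           stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(edges)) {
    edges <- data.frame(a = character(), b = character(),
                        distance = numeric(), bgc_class = character())
  }
  lapply(stats::setNames(nm = cfg$classes), function(cl) {
    canonicalize_edges(edges[edges$bgc_class == cl, , drop = FALSE])
  })
}

#' Simulate genus-level taxonomy coupled to tectonic setting
#'
#' Genus proportions per sample on the simplex, with log-abundances
#' shifted by fixed per-setting genus loadings of strength `coupling`.
#' `coupling = 0` makes taxonomy independent of setting.
#'
#' @param env Sample metadata (needs `sample_id`, `tectonic_setting`).
#' @param coupling Nonnegative coupling strength.
#' @param seed Integer seed.
#' @param n_genera Number of genera.
#' @param noise_sd SD of per-sample log-abundance noise.
#' @return Samples-by-genera proportion matrix (rows sum to 1).
#' @export
simulate_taxonomy <- function(env, coupling, seed, n_genera = 30,
                              noise_sd = 0.5) {
  check_that(nrow(env) > 0L, "env must be non-empty")
  check_that(coupling >= 0, "coupling must be nonnegative")
  with_seed(seed, {
    n <- nrow(env)
    genera <- sprintf("Genus_%02d", seq_len(n_genera))
    base <- stats::rnorm(n_genera, 0, 1)
    load <- matrix(stats::rnorm(3 * n_genera), 3, n_genera,
                   dimnames = list(SETTINGS, genera))
    k <- match(env$tectonic_setting, SETTINGS)
    la <- outer(rep(1, n), base) + coupling * load[k, , drop = FALSE] +
      matrix(stats::rnorm(n * n_genera, 0, noise_sd), n, n_genera)
    p <- exp(la)
    p <- p / rowSums(p)
    dimnames(p) <- list(env$sample_id, genera)
    p
  })
}

# CAT-style contig table realising a taxonomy profile: per sample the
# classified base pairs are allocated to genera by their proportions and
# split into contigs with Beta(8, 2) support (so roughly a quarter of
# assignments fall at or below the 0.70 support threshold).
simulate_contigs <- function(env, taxonomy, seed, mean_bp = 3e5) {
  with_seed(seed, {
    rows <- list()
    ld <- log1p(env$sequencing_depth)
    ldc <- ld - mean(ld)
    for (i in seq_len(nrow(env))) {
      total <- max(5e4, round(mean_bp * exp(0.3 * ldc[i])))
      bp <- round(taxonomy[i, ] * total)
      bp <- bp[bp >= 2000]
      cid <- 0L
      for (g in names(bp)) {
        ncon <- max(1L, as.integer(ceiling(bp[[g]] / 8000)))
        len <- rep(bp[[g]] %/% ncon, ncon)
        len[1] <- len[1] + bp[[g]] %% ncon
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = sprintf("%s_c%05d", env$sample_id[i], cid + seq_len(ncon)),
          sample_id = env$sample_id[i],
          contig_length = len,
          genus = g,
          support = round(stats::rbeta(ncon, 8, 2), 3),
          stringsAsFactors = FALSE
        )
        cid <- cid + ncon
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' One network TSV per biosynthetic class, a BGC inventory TSV, sample
#' metadata CSV, a contig classification TSV, the ground-truth membership
#' TSV (labelled synthetic), and the generating config.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param config The generating [sim_config()].
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(study$networks)) {
    write_network(study$networks[[cl]],
                  file.path(dir, sprintf("network_%s.tsv", cl)))
  }
  write_inventory(study$inventory, file.path(dir, "inventory.tsv"))
  write_metadata(study$env, file.path(dir, "metadata.csv"))
  write_contigs(study$contigs, file.path(dir, "contigs.tsv"))
  utils::write.table(study$truth$membership,
                     file.path(dir, "synthetic_truth_membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sim_config(config, file.path(dir, "config.txt"))
  invisible(dir)
}
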