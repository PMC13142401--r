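## Feature tables: GCF presence-absence matrices, prevalence filters,
## per-sample class proportions, the Hellinger transform, and the
## taxonomy feature pipeline (support filter -> genus proportions ->
## prevalence filter -> Hellinger -> PCA).

#' Build a samples-by-GCF presence-absence matrix
#'
#' Entry (s, f) is 1 when at least one member BGC of family f was
#' detected in sample s. Samples with no BGCs keep an all-zero row.
#'
#' @param inventory BGC inventory (`bgc_id`, `sample_id`).
#' @param membership Family membership (`bgc_id`, `family_id`), e.g. from
#'   [connected_components()]; every inventory BGC must have a family.
#' @param samples Optional character vector fixing the row universe (so
#'   BGC-free samples are retained); defaults to the inventory's samples.
#' @return Binary matrix with sample rows and family columns.
#' @export
presence_matrix <- function(inventory, membership, samples = NULL) {
  fam <- membership$family_id[match(inventory$bgc_id, membership$bgc_id)]
  missing <- inventory$bgc_id[is.na(fam)]
  check_that(length(missing) == 0L,
             "inventory BGC without family membership: %s", missing[1])
  if (is.null(samples)) samples <- c_sort(unique(inventory$sample_id))
  samples <- as.character(samples)
  fams <- c_sort(unique(fam))
  m <- matrix(0L, length(samples), length(fams),
              dimnames = list(samples, fams))
  si <- match(inventory$sample_id, samples)
  check_that(!anyNA(si), "inventory sample absent from `samples`: %s",
             inventory$sample_id[which(is.na(si))[1]])
  m[cbind(si, match(fam, fams))] <- 1L
  m
}

#' Drop low-prevalence features
#'
#' A feature is removed when it occurs in fewer than
#' `min_fraction * n_samples` samples (strict inequality, the literal
#' reading of "fewer than"). Samples are never dropped.
#'
#' @param m Samples-by-features matrix (nonzero = present).
#' @param min_fraction Prevalence threshold in \[0, 1\]; default 0.05.
#' @return The matrix restricted to retained features.
#' @export
prevalence_filter <- function(m, min_fraction = 0.05) {
  check_that(min_fraction >= 0 && min_fraction <= 1,
             "min_fraction must lie in [0, 1]")
  prev <- colSums(m != 0)
  keep <- prev >= min_fraction * nrow(m)
  m[, keep, drop = FALSE]
}

#' Per-sample biosynthetic class proportions
#'
#' For each sample and class: 100 x (number of GCFs of that class
#' detected) / (number of GCFs detected). Samples with zero detected
#' GCFs are excluded with a warning. Rows sum to 100.
#'
#' @param m Presence-absence matrix (samples x GCFs).
#' @param feature_class Character vector: class of each GCF column.
#' @return Samples-by-classes percentage matrix.
#' @export
class_proportions <- function(m, feature_class) {
  check_that(length(feature_class) == ncol(m),
             "feature_class must have one entry per matrix column")
  classes <- c_sort(unique(feature_class))
  counts <- vapply(classes, function(cl) {
    rowSums(m[, feature_class == cl, drop = FALSE] != 0)
  }, numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m),
                   dimnames = list(rownames(m), classes))
  tot <- rowSums(counts)
  empty <- tot == 0
  if (any(empty)) {
    warning(sprintf("%d sample(s) with zero detected GCFs excluded", sum(empty)),
            call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
    tot <- tot[!empty]
  }
  100 * counts / tot
}

#' Hellinger transform
#'
#' Row-wise square root of relative composition:
#' y'_ij = sqrt(y_ij / sum_j y_ij). All-zero rows map to all-zero rows.
#'
#' @param m Matrix with nonnegative entries.
#' @return Transformed matrix of the same shape.
#' @export
hellinger <- function(m) {
  m <- as.matrix(m)
  check_that(all(m >= 0), "hellinger requires nonnegative entries")
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    gcf_log(sprintf("%d all-zero row(s) kept as zeros in Hellinger transform",
                    sum(zero)))
    tot[zero] <- 1
  }
  sqrt(m / tot)
}

#' Genus-level taxonomy features from contig classifications
#'
#' Retains genus assignments whose support strictly exceeds
#' `support_threshold`, aggregates contig lengths by genus within each
#' sample, converts to proportions of classified base pairs, then drops
#' genera present in fewer than `prevalence_fraction` of samples.
#'
#' @param contigs Contig table (`contig_id`, `sample_id`, `contig_length`,
#'   `genus`, `support`).
#' @param support_threshold Retention threshold on support (strict `>`);
#'   default 0.70.
#' @param prevalence_fraction Genus prevalence threshold; default 0.20.
#' @param samples Optional row universe; defaults to samples present
#'   after the support filter.
#' @return Samples-by-genera proportion matrix.
#' @export
taxonomy_features <- function(contigs, support_threshold = 0.70,
                              prevalence_fraction = 0.20, samples = NULL) {
  check_that(support_threshold >= 0 && support_threshold <= 1 &&
               prevalence_fraction >= 0 && prevalence_fraction <= 1,
             "thresholds must lie in [0, 1]")
  kept <- contigs[contigs$support > support_threshold, , drop = FALSE]
  if (is.null(samples)) samples <- c_sort(unique(kept$sample_id))
  genera <- c_sort(unique(kept$genus))
  m <- matrix(0, length(samples), length(genera),
              dimnames = list(samples, genera))
  if (nrow(kept)) {
    agg <- stats::aggregate(contig_length ~ sample_id + genus, data = kept,
                            FUN = sum)
    agg <- agg[agg$sample_id %in% samples, , drop = FALSE]
    m[cbind(match(agg$sample_id, samples), match(agg$genus, genera))] <-
      agg$contig_length
  }
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m <- m / tot
  prevalence_filter(m, prevalence_fraction)
}

#' Principal component analysis of a feature matrix
#'
#' Centred (not scaled) eigendecomposition of the covariance matrix.
#' Variance-explained fractions are non-increasing; each component's
#' sign is fixed so its largest-magnitude loading is positive.
#'
#' @param m Samples-by-features matrix (typically Hellinger-transformed).
#' @param n_components Number of components to retain; must not exceed
#'   `min(n_samples - 1, n_features)`.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `variance_fraction`.
#' @export
pca_profile <- function(m, n_components) {
  m <- as.matrix(m)
  n <- nrow(m)
  maxc <- min(n - 1L, ncol(m))
  check_that(n_components >= 1L && n_components <= maxc,
             "n_components must lie in [1, min(n_samples - 1, n_features)] = [1, %d]",
             maxc)
  xc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- xc %*% vecs
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(n_components)))
  dimnames(vecs) <- list(colnames(m), colnames(scores))
  list(scores = scores, loadings = vecs,
       variance_fraction = vals[seq_len(n_components)] / sum(vals))
}
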