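## Depth-conditioned multivariate inference from first principles:
## partial RDA with permutation tests, marginal PERMANOVA
## (McArdle-Anderson partitioning), ANOSIM, multivariate dispersion
## homogeneity, variation partitioning with Ezekiel-adjusted R2, and
## k-means clustering of site scores with elbow/silhouette k selection.
##
## Permutation scheme with conditioning: residuals of the reduced model
## (Freedman-Lane). Permutation p-values are always
## (1 + #{stat* >= stat}) / (1 + n_permutations).

# Expand a data.frame of predictors into a design matrix (no intercept
# column), with the term index of every column.
design_block <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = TRUE)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  mm <- stats::model.matrix(~ ., data = df)
  keep <- attr(mm, "assign") != 0L
  list(x = mm[, keep, drop = FALSE], assign = attr(mm, "assign")[keep],
       labels = attr(stats::terms(~ ., data = df), "term.labels"))
}

# Orthogonal projector onto the column space of X (NULL -> zero map).
hat_matrix <- function(X, n) {
  if (is.null(X) || ncol(X) == 0L) return(matrix(0, n, n))
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

qr_rank <- function(X) if (is.null(X) || ncol(X) == 0L) 0L else qr(X)$rank

# After residualizing a design block on the condition, columns wholly
# contained in the condition space collapse to numerical noise; flag
# them by comparing norms before and after residualization.
null_after_residual <- function(Xr, X0) {
  sqrt(colSums(Xr^2)) <= 1e-8 * pmax(sqrt(colSums(X0^2)), 1e-8)
}

# Condition block: intercept plus any conditioning variables, so
# residualizing on it also centres.
condition_projector <- function(Z, n) {
  ones <- matrix(1, n, 1)
  if (is.null(Z)) return(list(h = hat_matrix(ones, n), rank = 1L))
  zb <- design_block(Z)
  zm <- cbind(ones, zb$x)
  list(h = hat_matrix(zm, n), rank = qr_rank(zm))
}

#' Partial redundancy analysis with permutation inference
#'
#' Residualizes both the response matrix and the constraints on the
#' conditioning variables by least squares, fits the residualized
#' response on the residualized constraints, and derives site scores
#' from the eigendecomposition of the fitted values. Because the
#' response here is Hellinger-transformed, this equals a distance-based
#' RDA (capscale) on Hellinger-Euclidean distances.
#'
#' @param Y Numeric response matrix (samples x features), typically
#'   Hellinger-transformed.
#' @param X `data.frame` of constraints (categoricals expanded to
#'   treatment-coded indicators).
#' @param Z Optional `data.frame` of conditioning variables.
#' @param n_permutations Permutations for the overall and marginal tests.
#' @param seed Integer seed for the permutation stream.
#' @param by `"overall"` (default) or `"margin"` to also test each
#'   constraint term given all others (Freedman-Lane residual
#'   permutation under the reduced model).
#' @return A `partial_rda` object: constrained eigenvalues, R2, overall
#'   pseudo-F and permutation p, `site_scores` (weighted-average style:
#'   residualized response projected on constrained axes),
#'   `site_scores_lc` (fitted-value scores), and a per-term table when
#'   `by = "margin"`.
#' @export
partial_rda <- function(Y, X, Z = NULL, n_permutations = 999, seed = 1,
                        by = c("overall", "margin")) {
  by <- match.arg(by)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  cz <- condition_projector(Z, n)
  Hz <- cz$h
  Yr <- Y - Hz %*% Y
  xb <- design_block(X)
  check_that(nrow(xb$x) == n, "X rows must align with Y rows")
  Xr <- xb$x - Hz %*% xb$x
  nullcol <- null_after_residual(Xr, xb$x)
  dropped <- colnames(Xr)[nullcol]
  Xr <- Xr[, !nullcol, drop = FALSE]
  xb$assign <- xb$assign[!nullcol]
  q <- qr(Xr)
  if (q$rank < ncol(Xr)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- c(dropped, colnames(Xr)[setdiff(seq_len(ncol(Xr)), keep)])
    Xr <- Xr[, keep, drop = FALSE]
    xb$assign <- xb$assign[keep]
  }
  if (length(dropped)) {
    warning(sprintf("dropping collinear constraint column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  df_x <- qr_rank(Xr)
  check_that(df_x >= 1L, "no non-collinear constraint columns remain")
  df_res <- n - cz$rank - df_x
  check_that(df_res >= 1L, "no residual degrees of freedom")
  Hx <- hat_matrix(Xr, n)
  Fit <- Hx %*% Yr
  ss_tot <- sum(Yr^2)
  ss_fit <- sum(Fit^2)
  r2 <- ss_fit / ss_tot
  fstat <- (ss_fit / df_x) / ((ss_tot - ss_fit) / df_res)

  sv <- svd(Fit)
  tol <- max(sv$d) * 1e-8
  npos <- sum(sv$d > tol)
  v <- sv$v[, seq_len(max(npos, 1L)), drop = FALSE]
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  wa <- Yr %*% v
  lc <- Fit %*% v
  axnames <- paste0("RDA", seq_len(ncol(v)))
  dimnames(wa) <- list(rownames(Y), axnames)
  dimnames(lc) <- list(rownames(Y), axnames)
  eig <- (sv$d[seq_len(max(npos, 1L))]^2) / (n - 1)

  stat_fun <- function(Yp) {
    Ypr <- Yp - Hz %*% Yp
    ssf <- sum((Hx %*% Ypr)^2)
    sst <- sum(Ypr^2)
    (ssf / df_x) / ((sst - ssf) / df_res)
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) stat_fun(Yr[sample.int(n), ,
                                                            drop = FALSE]),
           numeric(1))
  })
  pval <- (1 + sum(perm >= fstat)) / (1 + n_permutations)

  term_table <- NULL
  if (by == "margin") {
    labs <- xb$labels
    rows <- lapply(seq_along(labs), function(t) {
      Xred <- Xr[, xb$assign != t, drop = FALSE]
      Hr <- hat_matrix(Xred, n)
      ss_t <- ss_fit - sum((Hr %*% Yr)^2)
      df_t <- df_x - qr_rank(Xred)
      if (df_t == 0L) {
        return(data.frame(term = labs[t], df = 0L, ss = ss_t, F = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      f_t <- (ss_t / df_t) / ((ss_tot - ss_fit) / df_res)
      Fit_red <- Hr %*% Yr
      E <- Yr - Fit_red
      perm_t <- with_seed(child_seed(seed, t), {
        vapply(seq_len(n_permutations), function(b) {
          Yp <- Fit_red + E[sample.int(n), , drop = FALSE]
          Ypr <- Yp - Hz %*% Yp
          ssf <- sum((Hx %*% Ypr)^2)
          sstp <- sum(Ypr^2)
          sst_b <- ssf - sum((Hr %*% Ypr)^2)
          (sst_b / df_t) / ((sstp - ssf) / df_res)
        }, numeric(1))
      })
      data.frame(term = labs[t], df = df_t, ss = ss_t, F = f_t,
                 p = (1 + sum(perm_t >= f_t)) / (1 + n_permutations),
                 stringsAsFactors = FALSE)
    })
    term_table <- do.call(rbind, rows)
  }

  structure(list(eigenvalues = eig, R2 = r2, F = fstat, p = pval,
                 df = c(constrained = df_x, residual = df_res),
                 site_scores = wa, site_scores_lc = lc,
                 terms = term_table, dropped = dropped,
                 condition = if (is.null(Z)) character() else names(as.data.frame(Z)),
                 n_permutations = n_permutations),
            class = "partial_rda")
}

#' @export
print.partial_rda <- function(x, ...) {
  cat(sprintf("Partial RDA: R2 = %.4f, F = %.3f, p = %.4g (%d permutations)\n",
              x$R2, x$F, x$p, x$n_permutations))
  if (length(x$condition)) {
    cat("  conditioned on:", paste(x$condition, collapse = ", "), "\n")
  }
  if (!is.null(x$terms)) {
    cat("  marginal terms:\n")
    print(x$terms, row.names = FALSE)
  }
  invisible(x)
}

# Gower-centred matrix from a distance object/matrix.
gower_center <- function(D) {
  dm <- as.matrix(D)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

#' PERMANOVA with marginal terms and conditioning
#'
#' Permutational multivariate analysis of variance via McArdle-Anderson
#' partitioning of the Gower-centred inner-product matrix. Marginal term
#' sums of squares are each term's contribution given all other terms.
#' With conditioning variables, the reduced-model residual structure is
#' permuted (Freedman-Lane); otherwise rows are permuted freely.
#'
#' @param Y Response matrix whose Euclidean row distances define the
#'   analysis (e.g. Hellinger-transformed profiles); ignored when `D`
#'   is supplied.
#' @param data `data.frame` holding model and conditioning variables.
#' @param terms Character vector of column names in `data` to test.
#' @param D Optional `dist` or square distance matrix.
#' @param condition Optional character vector of conditioning columns.
#' @param by `"margin"` (default) for per-term marginal tests plus the
#'   overall model, `"overall"` for the overall model only.
#' @param n_permutations,seed Permutation settings.
#' @return A `permanova` data.frame: one row per term plus `Model`,
#'   `Residual` and `Total`, with df, SS, R2, pseudo-F and permutation p.
#' @export
permanova <- function(Y = NULL, data, terms, D = NULL, condition = NULL,
                      by = c("margin", "overall"), n_permutations = 999,
                      seed = 1) {
  by <- match.arg(by)
  check_that(!is.null(Y) || !is.null(D), "supply Y or D")
  if (is.null(D)) D <- stats::dist(as.matrix(Y))
  G <- gower_center(D)
  n <- nrow(G)
  check_that(all(terms %in% names(data)),
             "terms absent from data: %s",
             paste(setdiff(terms, names(data)), collapse = ", "))
  cz <- condition_projector(if (is.null(condition)) NULL else
    data[, condition, drop = FALSE], n)
  Hz <- cz$h
  R <- diag(n) - Hz
  Gr <- R %*% G %*% R
  xb <- design_block(data[, terms, drop = FALSE])
  Xr <- xb$x - Hz %*% xb$x
  nullcol <- null_after_residual(Xr, xb$x)
  Xr <- Xr[, !nullcol, drop = FALSE]
  xb$assign <- xb$assign[!nullcol]
  df_x <- qr_rank(Xr)
  check_that(df_x >= 1L, "constraints collinear with the condition")
  df_res <- n - cz$rank - df_x
  check_that(df_res >= 1L, "term with zero residual df")
  Hf <- hat_matrix(Xr, n)
  ss_total <- sum(diag(Gr))
  ss_model <- sum(Hf * Gr)
  ss_res <- ss_total - ss_model
  f_model <- (ss_model / df_x) / (ss_res / df_res)

  term_info <- NULL
  if (by == "margin") {
    term_info <- lapply(seq_along(xb$labels), function(t) {
      Xred <- Xr[, xb$assign != t, drop = FALSE]
      Hr <- hat_matrix(Xred, n)
      list(label = xb$labels[t], h = Hr,
           df = df_x - qr_rank(Xred),
           ss = ss_model - sum(Hr * Gr))
    })
  }

  perm_stats <- with_seed(seed, {
    res <- matrix(NA_real_, n_permutations,
                  1L + if (is.null(term_info)) 0L else length(term_info))
    has_cond <- !is.null(condition)
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      Gp <- Gr[p, p]
      # without conditioning Gr is doubly centred already, so the
      # reduced-model re-projection would be the identity
      if (has_cond) Gp <- R %*% Gp %*% R
      ssm <- sum(Hf * Gp)
      sst <- sum(diag(Gp))
      res[b, 1] <- (ssm / df_x) / ((sst - ssm) / df_res)
      if (!is.null(term_info)) {
        for (t in seq_along(term_info)) {
          ti <- term_info[[t]]
          if (ti$df == 0L) next
          res[b, 1L + t] <- ((ssm - sum(ti$h * Gp)) / ti$df) /
            ((sst - ssm) / df_res)
        }
      }
    }
    res
  })
  p_model <- (1 + sum(perm_stats[, 1] >= f_model)) / (1 + n_permutations)

  rows <- list()
  if (!is.null(term_info)) {
    for (t in seq_along(term_info)) {
      ti <- term_info[[t]]
      if (ti$df == 0L) {
        rows[[t]] <- data.frame(term = ti$label, df = 0L, SS = ti$ss,
                                R2 = ti$ss / ss_total, F = NA_real_,
                                p = NA_real_, stringsAsFactors = FALSE)
      } else {
        f_t <- (ti$ss / ti$df) / (ss_res / df_res)
        rows[[t]] <- data.frame(
          term = ti$label, df = ti$df, SS = ti$ss, R2 = ti$ss / ss_total,
          F = f_t,
          p = (1 + sum(perm_stats[, 1L + t] >= f_t)) / (1 + n_permutations),
          stringsAsFactors = FALSE)
      }
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    term = "Model", df = df_x, SS = ss_model, R2 = ss_model / ss_total,
    F = f_model, p = p_model, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    term = "Residual", df = df_res, SS = ss_res, R2 = ss_res / ss_total,
    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    term = "Total", df = n - cz$rank, SS = ss_total, R2 = 1,
    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("permanova", "data.frame")
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (M/2) with M = n(n-1)/2 and mid-ranked ties; permutation
#' p over group-label shuffles.
#'
#' @param D `dist` or square distance matrix.
#' @param grouping Group labels (>= 2 groups, each with >= 2 members).
#' @param n_permutations,seed Permutation settings.
#' @return List with `statistic` (R), `p`, `n_permutations`.
#' @export
anosim_test <- function(D, grouping, n_permutations = 999, seed = 1) {
  dm <- as.matrix(D)
  n <- nrow(dm)
  grouping <- as.factor(grouping)
  check_that(length(grouping) == n, "grouping length must match distances")
  check_that(nlevels(droplevels(grouping)) >= 2L, "need >= 2 groups")
  check_that(all(table(droplevels(grouping)) >= 2L),
             "every group needs >= 2 members")
  idx <- which(lower.tri(dm), arr.ind = TRUE)
  r <- rank(dm[lower.tri(dm)])
  denom <- (n * (n - 1) / 2) / 2
  r_of <- function(g) {
    within <- g[idx[, 1]] == g[idx[, 2]]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  stat <- r_of(grouping)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) r_of(grouping[sample.int(n)]), numeric(1))
  })
  list(statistic = stat, statistic_name = "ANOSIM R",
       p = (1 + sum(perm >= stat)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates (negative
#' eigenvalues handled by subtracting squared distances on imaginary
#' axes), computes each sample's distance to its group centroid, and
#' tests group differences in those distances with a one-way F whose
#' null distribution comes from permuting the distances across groups.
#'
#' @param D `dist` or square distance matrix.
#' @param grouping Group labels.
#' @param n_permutations,seed Permutation settings.
#' @return List with `statistic` (dispersion F), `p`, per-sample
#'   `distances`, per-group mean dispersions.
#' @export
betadisper_test <- function(D, grouping, n_permutations = 999, seed = 1) {
  dm <- as.matrix(D)
  n <- nrow(dm)
  grouping <- droplevels(as.factor(grouping))
  check_that(nlevels(grouping) >= 2L, "need >= 2 groups")
  G <- gower_center(dm)
  ev <- eigen(G, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-8
  keep <- abs(ev$values) > tol
  V <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(abs(ev$values[keep])), sum(keep))
  pos <- ev$values[keep] > 0
  dists <- numeric(n)
  for (g in levels(grouping)) {
    i <- which(grouping == g)
    cen <- colMeans(V[i, , drop = FALSE])
    dev2 <- sweep(V[i, , drop = FALSE], 2, cen)^2
    d2 <- rowSums(dev2[, pos, drop = FALSE]) -
      rowSums(dev2[, !pos, drop = FALSE])
    dists[i] <- sqrt(pmax(d2, 0))
  }
  f_of <- function(d) {
    gm <- tapply(d, grouping, mean)
    ng <- tabulate(grouping)
    ssb <- sum(ng * (gm - mean(d))^2)
    ssw <- sum((d - gm[as.integer(grouping)])^2)
    dfb <- nlevels(grouping) - 1L
    dfw <- n - nlevels(grouping)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }
  stat <- f_of(dists)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) f_of(dists[sample.int(n)]), numeric(1))
  })
  list(statistic = stat, statistic_name = "dispersion F",
       p = (1 + sum(perm >= stat)) / (1 + n_permutations),
       distances = stats::setNames(dists, rownames(dm)),
       group_means = tapply(dists, grouping, mean),
       embedding = V, positive_axes = pos,
       n_permutations = n_permutations)
}

#' Ezekiel-adjusted R-squared
#'
#' @param r2 Unadjusted R2.
#' @param n Number of samples.
#' @param p Number of predictor degrees of freedom.
#' @return 1 - (1 - R2)(n - 1)/(n - p - 1).
#' @export
adjusted_r2 <- function(r2, n, p) {
  check_that(n - p - 1 > 0, "n - p - 1 must be positive for adjusted R2")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variation partitioning between two explanatory blocks
#'
#' Decomposes the explained variation of `Y` into the unique fraction of
#' `X1` (\[a\]), the unique fraction of `X2` (\[b\]), their shared
#' fraction (\[c\]) and the residual (\[d\]), on the adjusted-R2 scale
#' (Ezekiel correction), optionally after removing conditioning
#' variables from response and predictors. Unique fractions are tested
#' by Freedman-Lane permutation of reduced-model residuals.
#'
#' @param Y Response matrix (e.g. Hellinger-transformed GCF profiles).
#' @param X1,X2 `data.frame`s of the two explanatory blocks
#'   (environment; taxonomy PCs).
#' @param condition Optional conditioning `data.frame` (e.g. log1p
#'   sequencing depth).
#' @param n_permutations,seed Permutation settings.
#' @return List with fractions `a`, `b`, `c`, `d`, the block adjusted
#'   R2s, and permutation p-values for the unique fractions.
#' @export
variation_partition <- function(Y, X1, X2, condition = NULL,
                                n_permutations = 999, seed = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  cz <- condition_projector(condition, n)
  Hz <- cz$h
  Yr <- Y - Hz %*% Y
  b1 <- design_block(X1)$x; b1r <- b1 - Hz %*% b1
  b1 <- b1r[, !null_after_residual(b1r, b1), drop = FALSE]
  b2 <- design_block(X2)$x; b2r <- b2 - Hz %*% b2
  b2 <- b2r[, !null_after_residual(b2r, b2), drop = FALSE]
  ss_tot <- sum(Yr^2)
  r2_of <- function(M) sum((hat_matrix(M, n) %*% Yr)^2) / ss_tot
  p1 <- qr_rank(b1); p2 <- qr_rank(b2); p12 <- qr_rank(cbind(b1, b2))
  r2_1 <- r2_of(b1); r2_2 <- r2_of(b2); r2_12 <- r2_of(cbind(b1, b2))
  adj1 <- adjusted_r2(r2_1, n, p1)
  adj2 <- adjusted_r2(r2_2, n, p2)
  adj12 <- adjusted_r2(r2_12, n, p12)
  a <- adj12 - adj2
  b <- adj12 - adj1
  cc <- adj1 + adj2 - adj12
  dd <- 1 - adj12

  unique_p <- function(target, other, sub_seed) {
    Hfull <- hat_matrix(cbind(target, other), n)
    Hred <- hat_matrix(other, n)
    df_t <- qr_rank(cbind(target, other)) - qr_rank(other)
    df_res <- n - cz$rank - qr_rank(cbind(target, other))
    if (df_t == 0L || df_res < 1L) return(NA_real_)
    ssf <- sum((Hfull %*% Yr)^2)
    ss_t <- ssf - sum((Hred %*% Yr)^2)
    fstat <- (ss_t / df_t) / ((ss_tot - ssf) / df_res)
    Fit_red <- Hred %*% Yr
    E <- Yr - Fit_red
    perm <- with_seed(sub_seed, {
      vapply(seq_len(n_permutations), function(bb) {
        Yp <- Fit_red + E[sample.int(n), , drop = FALSE]
        Ypr <- Yp - Hz %*% Yp
        ssfp <- sum((Hfull %*% Ypr)^2)
        sstp <- sum(Ypr^2)
        sstb <- ssfp - sum((Hred %*% Ypr)^2)
        (sstb / df_t) / ((sstp - ssfp) / df_res)
      }, numeric(1))
    })
    (1 + sum(perm >= fstat)) / (1 + n_permutations)
  }

  list(a = a, b = b, c = cc, d = dd,
       adj_r2 = c(X1 = adj1, X2 = adj2, X1X2 = adj12),
       r2 = c(X1 = r2_1, X2 = r2_2, X1X2 = r2_12),
       p_unique = c(X1 = unique_p(b1, b2, child_seed(seed, 1L)),
                    X2 = unique_p(b2, b1, child_seed(seed, 2L))),
       n_permutations = n_permutations)
}

#' Cluster ordination site scores with k selection
#'
#' Seeded multi-restart k-means over a range of k, reporting per-k
#' within-cluster sum of squares and mean silhouette width. The elbow is
#' operationalized as the k maximizing the second difference of WSS; the
#' silhouette-maximizing k is reported alongside, and the elbow k is the
#' chosen one (both criteria are returned so the judgment is auditable).
#'
#' @param scores Site-score matrix (samples x retained axes).
#' @param k_range Candidate k values within \[2, n-1\].
#' @param restarts Random restarts per k (best WSS kept).
#' @param seed Integer seed.
#' @return List with `chosen_k`, `k_elbow`, `k_silhouette`, `labels`
#'   (for `chosen_k`), `per_k` table, and a `degenerate` flag (all
#'   points identical: WSS 0 everywhere, silhouette undefined).
#' @export
cluster_sites <- function(scores, k_range = 2:8, restarts = 20, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  check_that(min(k_range) >= 2L && max(k_range) <= n - 1L,
             "k_range must lie within [2, n - 1]")
  n_distinct <- nrow(unique(scores))
  if (n_distinct == 1L) {
    return(list(chosen_k = NA_integer_, k_elbow = NA_integer_,
                k_silhouette = NA_integer_,
                labels = rep(1L, n),
                per_k = data.frame(k = k_range, wss = 0,
                                   silhouette = NA_real_),
                degenerate = TRUE))
  }
  k_all <- sort(unique(c(max(1L, min(k_range) - 1L), k_range,
                         min(n - 1L, max(k_range) + 1L, n_distinct))))
  k_all <- k_all[k_all <= n_distinct]
  total_ss <- sum(scale(scores, scale = FALSE)^2)
  fits <- list()
  wss <- stats::setNames(rep(NA_real_, length(k_all)), k_all)
  with_seed(seed, {
    for (k in k_all) {
      if (k == 1L) {
        wss[as.character(k)] <- total_ss
        next
      }
      fit <- NULL
      for (try in 1:5) {
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(scores, centers = k,
                                         nstart = restarts, iter.max = 200)),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      check_that(!is.null(fit), "k-means failed for k = %d after retries", k)
      fits[[as.character(k)]] <- fit
      wss[as.character(k)] <- fit$tot.withinss
    }
  })
  dmat <- stats::dist(scores)
  sil <- vapply(k_range, function(k) {
    f <- fits[[as.character(k)]]
    if (is.null(f)) return(NA_real_)
    mean(cluster::silhouette(f$cluster, dmat)[, "sil_width"])
  }, numeric(1))
  d2 <- vapply(k_range, function(k) {
    km1 <- as.character(k - 1L); kp1 <- as.character(k + 1L)
    if (!(km1 %in% names(wss)) || !(kp1 %in% names(wss)) ||
        is.na(wss[km1]) || is.na(wss[kp1])) return(NA_real_)
    wss[km1] - 2 * wss[as.character(k)] + wss[kp1]
  }, numeric(1))
  k_elbow <- k_range[which.max(d2)]
  k_sil <- k_range[which.max(sil)]
  gcf_log(sprintf("cluster_sites: elbow k = %d, silhouette k = %d; using elbow",
                  k_elbow, k_sil))
  list(chosen_k = k_elbow, k_elbow = k_elbow, k_silhouette = k_sil,
       labels = fits[[as.character(k_elbow)]]$cluster,
       per_k = data.frame(k = k_range,
                          wss = unname(wss[as.character(k_range)]),
                          silhouette = sil, wss_second_diff = d2),
       degenerate = FALSE)
}

#' Spearman correlation of ordination axes with sequencing depth
#'
#' Tie-corrected Spearman rho with t-approximation p per axis; constant
#' axes are reported with `NA` rho.
#'
#' @param scores Site-score matrix.
#' @param depth Per-sample depth covariate (same order as rows).
#' @return `data.frame` with `axis`, `rho`, `p`.
#' @export
axis_depth_check <- function(scores, depth) {
  scores <- as.matrix(scores)
  check_that(nrow(scores) >= 3L, "need >= 3 samples")
  check_that(length(depth) == nrow(scores),
             "depth must have one value per sample")
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    if (stats::sd(x) == 0) {
      return(data.frame(axis = j, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, depth, method = "spearman",
                                           exact = FALSE))
    data.frame(axis = j, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}
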