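make_xy <- function(n = 20, p = 6, seed = 5) {
  set.seed(seed)
  x <- data.frame(temperature = rnorm(n), pH = rnorm(n),
                  setting = factor(rep(c("a", "b"), length.out = n)))
  y <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("f%d", 1:p)))
  y[, 1] <- y[, 1] + 2 * x$temperature
  y[, 2] <- y[, 2] + as.numeric(x$setting == "b")
  list(x = x, y = y)
}

test_that("partial RDA recovers exact fits, kills conditioned constraints, and matches the hat-matrix oracle", {
  set.seed(1)
  x <- data.frame(a = rnorm(10), b = rnorm(10))
  # Y exactly linear in X, no conditioning -> R2 = 1
  y_exact <- cbind(1 + 2 * x$a, x$b - x$a)
  fit <- partial_rda(y_exact, x, n_permutations = 49)
  expect_equal(fit$R2, 1, tolerance = 1e-10)

  # conditioning on a copy of a constraint column nullifies that term
  expect_warning(
    fit0 <- partial_rda(y_exact, x, Z = data.frame(z = x$a),
                        n_permutations = 9, by = "margin"),
    "collinear")
  expect_equal(fit0$terms$ss[fit0$terms$term == "a"], 0, tolerance = 1e-16)
  expect_equal(fit0$terms$df[fit0$terms$term == "a"], 0)

  # brute-force projection-matrix oracle at n = 10
  y <- matrix(rnorm(30), 10, 3)
  z <- data.frame(z = rnorm(10))
  fit2 <- partial_rda(y, x, Z = z, n_permutations = 9)
  Zm <- cbind(1, z$z)
  Hz <- Zm %*% solve(crossprod(Zm)) %*% t(Zm)
  Yr <- y - Hz %*% y
  Xm <- as.matrix(x) - Hz %*% as.matrix(x)
  Hx <- Xm %*% solve(crossprod(Xm)) %*% t(Xm)
  expect_equal(fit2$R2, sum((Hx %*% Yr)^2) / sum(Yr^2), tolerance = 1e-10)
})

test_that("partial RDA agrees with the reference constrained-ordination implementation", {
  skip_if_not_installed("vegan")
  d <- make_xy()
  fit <- partial_rda(d$y, d$x, n_permutations = 99, seed = 1, by = "margin")
  vfit <- vegan::rda(d$y ~ temperature + pH + setting, data = d$x)
  expect_equal(unname(fit$eigenvalues),
               unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$R2, vfit$CCA$tot.chi / vfit$tot.chi, tolerance = 1e-10)
  va <- vegan::anova.cca(vfit, permutations = 19)
  expect_equal(fit$F, va$F[1], tolerance = 1e-8)

  # with conditioning, F still matches the reference engine
  z <- data.frame(depth = log1p(rlnorm(20, 10, 1)))
  fitc <- partial_rda(d$y, d$x, Z = z, n_permutations = 99, seed = 1)
  vfitc <- vegan::rda(d$y ~ temperature + pH + setting +
                        Condition(depth), data = cbind(d$x, z))
  vac <- vegan::anova.cca(vfitc, permutations = 19)
  expect_equal(fitc$F, vac$F[1], tolerance = 1e-8)
  expect_equal(unname(fitc$eigenvalues), unname(vfitc$CCA$eig),
               tolerance = 1e-8)
})

test_that("collinear constraint columns are dropped with a warning", {
  d <- make_xy()
  x2 <- cbind(d$x, temp_copy = d$x$temperature)
  expect_warning(fit <- partial_rda(d$y, x2, n_permutations = 9),
                 "collinear")
  expect_equal(fit$df[["constrained"]], 3)
})

test_that("PERMANOVA matches adonis2 on SS, R2 and F for marginal terms", {
  skip_if_not_installed("vegan")
  d <- make_xy()
  res <- permanova(Y = d$y, data = d$x,
                   terms = c("temperature", "pH", "setting"),
                   by = "margin", n_permutations = 99, seed = 2)
  ref <- vegan::adonis2(dist(d$y) ~ temperature + pH + setting,
                        data = d$x, by = "margin", permutations = 19)
  for (term in c("temperature", "pH", "setting")) {
    i <- which(res$term == term)
    j <- which(rownames(ref) == term)
    expect_equal(res$SS[i], ref$SumOfSqs[j], tolerance = 1e-8)
    expect_equal(res$R2[i], ref$R2[j], tolerance = 1e-8)
    expect_equal(res$F[i], ref$F[j], tolerance = 1e-8)
  }
})

test_that("PERMANOVA pseudo-F on Euclidean distances equals the raw-coordinate trace F", {
  d <- make_xy(n = 16, p = 4, seed = 9)
  g <- factor(rep(c("u", "v"), each = 8))
  res <- permanova(Y = d$y, data = data.frame(g = g), terms = "g",
                   by = "overall", n_permutations = 9, seed = 1)
  # classical MANOVA trace decomposition from raw coordinates
  yc <- scale(d$y, scale = FALSE)
  fitted <- apply(yc, 2, function(col) ave(col, g))
  ssb <- sum(fitted^2)
  ssw <- sum((yc - fitted)^2)
  f_classical <- (ssb / 1) / (ssw / 14)
  expect_equal(res$F[res$term == "Model"], f_classical, tolerance = 1e-8)
  # and equals the within/between distance decomposition oracle
  expect_equal(res$F[res$term == "Model"],
               oracle_permanova_F(as.matrix(dist(d$y)), g),
               tolerance = 1e-8)
})

test_that("PERMANOVA permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(4)
  y <- matrix(rnorm(12), 6, 2)
  y[4:6, ] <- y[4:6, ] + 1.2
  g <- data.frame(g = factor(rep(c("A", "B"), each = 3)))
  p_exact <- oracle_permanova_exact_p(as.matrix(dist(y)))
  res <- permanova(Y = y, data = g, terms = "g", by = "overall",
                   n_permutations = 999, seed = 3)
  p_perm <- res$p[res$term == "Model"]
  expect_lt(abs(p_perm - p_exact), 0.06) # Monte-Carlo error at 999 draws
})

test_that("duplicated terms carry zero marginal SS and conditioning reduces the testable variance", {
  d <- make_xy()
  dd <- cbind(d$x, temp2 = d$x$temperature)
  res <- permanova(Y = d$y, data = dd, terms = c("temperature", "temp2"),
                   by = "margin", n_permutations = 19, seed = 1)
  expect_equal(res$SS[res$term == "temperature"], 0, tolerance = 1e-8)
  expect_equal(res$SS[res$term == "temp2"], 0, tolerance = 1e-8)

  resc <- permanova(Y = d$y, data = d$x, terms = "pH",
                    condition = "temperature", by = "overall",
                    n_permutations = 99, seed = 1)
  expect_true(is.finite(resc$F[resc$term == "Model"]))
  expect_lt(resc$SS[resc$term == "Total"],
            sum(scale(d$y, scale = FALSE)^2) + 1e-8)
})

test_that("permutation p-values are seed-reproducible with floor 1/(1+B)", {
  d <- make_xy()
  r1 <- permanova(Y = d$y, data = d$x, terms = "temperature",
                  by = "overall", n_permutations = 99, seed = 7)
  r2 <- permanova(Y = d$y, data = d$x, terms = "temperature",
                  by = "overall", n_permutations = 99, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_gte(min(r1$p, na.rm = TRUE), 1 / 100)
})

test_that("ANOSIM matches its rank definition, the reference implementation, and boundary cases", {
  # perfectly separated groups -> R = 1
  y <- rbind(matrix(rnorm(8, 0, 0.05), 4), matrix(rnorm(8, 10, 0.05), 4))
  r <- anosim_test(dist(y), rep(c("a", "b"), each = 4),
                   n_permutations = 99, seed = 1)
  expect_equal(r$statistic, 1)
  expect_lte(r$p, 0.05)

  # 5-point worked case against the hand rank computation
  dm <- matrix(0, 5, 5)
  dm[lower.tri(dm)] <- c(1, 2, 7, 8, 3, 6, 9, 5, 10, 4)
  dm <- dm + t(dm)
  g <- c("x", "x", "x", "y", "y")
  rk <- rank(dm[lower.tri(dm)])
  within <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  expected <- (mean(rk[!within]) - mean(rk[within])) / (10 / 2)
  r2 <- anosim_test(dm, g, n_permutations = 9, seed = 1)
  expect_equal(r2$statistic, expected, tolerance = 1e-12)

  skip_if_not_installed("vegan")
  set.seed(8)
  y3 <- matrix(rnorm(30), 10, 3)
  g3 <- rep(c("a", "b"), 5)
  ours <- anosim_test(dist(y3), g3, n_permutations = 49, seed = 1)
  ref <- vegan::anosim(dist(y3), g3, permutations = 9)
  expect_equal(ours$statistic, ref$statistic, tolerance = 1e-10)

  expect_error(anosim_test(dm, c("x", "x", "x", "x", "y")), "2 members")
})

test_that("dispersion test reproduces the reference distances and handles symmetric groups", {
  set.seed(6)
  y <- matrix(rnorm(40), 10, 4)
  g <- rep(c("a", "b"), each = 5)
  ours <- betadisper_test(dist(y), g, n_permutations = 99, seed = 1)

  # PCoA embedding reproduces Euclidean input distances
  emb <- ours$embedding[, ours$positive_axes, drop = FALSE]
  expect_equal(as.numeric(dist(emb)), as.numeric(dist(y)), tolerance = 1e-8)

  skip_if_not_installed("vegan")
  ref <- vegan::betadisper(dist(y), g, type = "centroid")
  expect_equal(unname(ours$distances), unname(ref$distances),
               tolerance = 1e-8)

  # coincident group: zero dispersions
  y2 <- rbind(matrix(1, 4, 2), matrix(rnorm(8), 4, 2))
  g2 <- rep(c("flat", "spread"), each = 4)
  r2 <- betadisper_test(dist(y2), g2, n_permutations = 9, seed = 1)
  expect_equal(unname(r2$distances[1:4]), rep(0, 4), tolerance = 1e-10)

  # mirror-image groups have equal dispersion: tiny F, large p
  base <- matrix(rnorm(10), 5, 2)
  y3 <- rbind(base, -base)
  g3 <- rep(c("m1", "m2"), each = 5)
  r3 <- betadisper_test(dist(y3), g3, n_permutations = 199, seed = 2)
  expect_lt(r3$statistic, 1e-10)
  expect_gt(r3$p, 0.5)
})

test_that("variation partitioning honours its algebraic identities and the adjusted-R2 formula", {
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_error(adjusted_r2(0.5, 4, 3), "positive")

  set.seed(11)
  y <- matrix(rnorm(60), 20, 3)
  x1 <- data.frame(u = rnorm(20), v = rnorm(20))
  y[, 1] <- y[, 1] + 2 * x1$u
  # identical blocks: no unique fractions, shared = adjR2(X1)
  vp_same <- variation_partition(y, x1, x1, n_permutations = 19, seed = 1)
  expect_equal(vp_same$a, 0, tolerance = 1e-10)
  expect_equal(vp_same$b, 0, tolerance = 1e-10)
  expect_equal(vp_same$c, unname(vp_same$adj_r2["X1"]), tolerance = 1e-10)

  x2 <- data.frame(w = rnorm(20))
  vp <- variation_partition(y, x1, x2, n_permutations = 99, seed = 1)
  # [a] + [c] = adjR2(X1) and [b] + [c] = adjR2(X2) by construction
  expect_equal(vp$a + vp$c, unname(vp$adj_r2["X1"]), tolerance = 1e-10)
  expect_equal(vp$b + vp$c, unname(vp$adj_r2["X2"]), tolerance = 1e-10)
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-10)
})

test_that("variation partitioning matches the reference implementation and planted structure", {
  skip_if_not_installed("vegan")
  set.seed(12)
  y <- matrix(rnorm(80), 20, 4)
  x1 <- data.frame(u = rnorm(20))
  x2 <- data.frame(w = rnorm(20))
  y[, 1] <- y[, 1] + 1.5 * x1$u
  vp <- variation_partition(y, x1, x2, n_permutations = 19, seed = 1)
  ref <- vegan::varpart(y, ~ u, ~ w, data = cbind(x1, x2))
  # vegan row order: [a] = X1|X2, [b] = X2|X1, [c] = shared
  frac <- ref$part$indfract$Adj.R.squared
  expect_equal(vp$a, frac[1], tolerance = 1e-8)
  expect_equal(vp$b, frac[2], tolerance = 1e-8)
  expect_equal(vp$c, frac[3], tolerance = 1e-8)

  # Y built from X1 with X2 independent: unique X2 and shared ~ 0 on average
  bs <- replicate(50, {
    yy <- matrix(rnorm(60), 20, 3)
    xx1 <- data.frame(u = rnorm(20))
    xx2 <- data.frame(w = rnorm(20))
    yy[, 1] <- yy[, 1] + 2 * xx1$u
    v <- variation_partition(yy, xx1, xx2, n_permutations = 0, seed = 1)
    c(v$a, v$b, v$c)
  })
  expect_gt(mean(bs[1, ]), 0.1)          # unique X1 recovered
  expect_lt(abs(mean(bs[2, ])), 0.03)    # unique X2 ~ 0
  expect_lt(abs(mean(bs[3, ])), 0.03)    # shared ~ 0
})

test_that("k selection finds three planted blobs and is invariant to axis sign flips", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(6, 0), c(3, 5.2))
  scores <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, 0, 0.4), 45, 2)
  res <- cluster_sites(scores, k_range = 2:6, restarts = 10, seed = 4)
  expect_equal(res$k_elbow, 3)
  expect_gte(label_agreement(rep(1:3, each = 15), res$labels), 0.95)

  flip <- cluster_sites(scores %*% diag(c(-1, 1)), k_range = 2:6,
                        restarts = 10, seed = 4)
  expect_equal(partition_signature(seq_len(45), flip$labels),
               partition_signature(seq_len(45), res$labels))

  degen <- cluster_sites(matrix(1, 10, 2), k_range = 2:4, seed = 1)
  expect_true(degen$degenerate)
  expect_true(all(degen$per_k$wss == 0))
  expect_error(cluster_sites(scores, k_range = 2:50), "k_range")
})

test_that("axis-depth Spearman checks match the exhaustive rank formula", {
  depth <- c(3, 9, 1, 7, 5, 11)
  scores <- cbind(monotone = depth^2, anti = -rank(depth), flat = rep(1, 6))
  res <- axis_depth_check(scores, depth)
  expect_equal(res$rho[1], 1)
  expect_equal(res$rho[2], -1)
  expect_true(is.na(res$rho[3]))

  set.seed(14)
  x <- rnorm(6); dd <- rnorm(6)
  got <- axis_depth_check(cbind(x), dd)
  d2 <- sum((rank(x) - rank(dd))^2)
  expect_equal(got$rho[1], 1 - 6 * d2 / (6 * 35), tolerance = 1e-12)
})
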