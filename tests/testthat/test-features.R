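test_that("presence matrix is binary with zero rows kept and column sums equal prevalence", {
  inv <- data.frame(bgc_id = c("G1", "G2", "G3"),
                    sample_id = c("S1", "S1", "S2"),
                    bgc_class = "NRPS")
  mem <- data.frame(bgc_id = c("G1", "G2", "G3"),
                    family_id = c("F1", "F1", "F2"))
  m <- presence_matrix(inv, mem, samples = c("S1", "S2", "S3"))
  expect_equal(m["S1", "F1"], 1L) # two member BGCs still give 1
  expect_equal(unname(rowSums(m)["S3"]), 0) # BGC-free sample retained
  expect_equal(unname(colSums(m)), c(1, 1))
  expect_error(presence_matrix(inv, mem[-1, ], samples = c("S1", "S2")),
               "without family")
})

test_that("prevalence filter removes features strictly below the fraction and is idempotent", {
  set.seed(1)
  m <- matrix(0L, 100, 20, dimnames = list(sprintf("S%03d", 1:100),
                                           sprintf("F%02d", 1:20)))
  for (j in 1:20) m[seq_len(j), j] <- 1L # feature j in j samples
  kept <- prevalence_filter(m, 0.05)
  expect_false("F04" %in% colnames(kept)) # 4 < 5 removed
  expect_true("F05" %in% colnames(kept))  # 5 >= 5 retained
  expect_equal(min(colSums(kept)), 5)
  expect_identical(prevalence_filter(kept, 0.05), kept)
  expect_identical(prevalence_filter(m, 0), m)

  # brute-force column scan oracle on a random matrix
  r <- matrix(rbinom(600, 1, 0.2), 30, 20,
              dimnames = list(sprintf("s%d", 1:30), sprintf("f%d", 1:20)))
  expect_equal(ncol(prevalence_filter(r, 0.25)),
               sum(sapply(seq_len(20), function(j) sum(r[, j] > 0) >= 0.25 * 30)))
})

test_that("class proportions follow the detected-GCF formula and sum to 100", {
  m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 1, 1, 1, 0, 0), 3, 4,
              dimnames = list(c("S1", "S2", "S3"),
                              c("F1", "F2", "F3", "F4")))
  cls <- c("NRPS", "terpene", "terpene", "PKS")
  cp <- class_proportions(m, cls)
  expect_equal(cp["S1", "NRPS"], 50)       # 1 NRPS of 2 detected GCFs
  expect_equal(cp["S2", "NRPS"], 100 / 3)  # 1 NRPS of 3 detected GCFs
  expect_true(all(abs(rowSums(cp) - 100) < 1e-9))
  # all-terpene sample
  m2 <- matrix(c(1, 1), 1, 2, dimnames = list("S1", c("F1", "F2")))
  cp2 <- class_proportions(m2, c("terpene", "terpene"))
  expect_equal(unname(cp2[1, "terpene"]), 100)
  # zero-GCF sample excluded with a warning
  m3 <- rbind(m, S4 = 0)
  expect_warning(cp3 <- class_proportions(m3, cls), "zero detected")
  expect_false("S4" %in% rownames(cp3))
  # duplicating a BGC inside an already-detected family changes nothing:
  # the matrix entry stays 1, so proportions are invariant by construction
  m4 <- m; m4["S1", "F1"] <- 1
  expect_equal(class_proportions(m4, cls), cp)
})

test_that("Hellinger transform matches the closed form and its invariances", {
  h <- hellinger(matrix(c(1, 1, 2), 1))
  expect_equal(as.numeric(h), c(0.5, 0.5, sqrt(0.5)))
  set.seed(2)
  m <- matrix(rpois(50, 3), 10, 5)
  hm <- hellinger(m)
  nz <- rowSums(m) > 0
  expect_true(all(abs(rowSums(hm[nz, ]^2) - 1) < 1e-12))
  # per-row scale invariance
  expect_equal(hellinger(m * 7), hm)
  # orthonormal corners: distance sqrt(2)
  hc <- hellinger(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(as.numeric(dist(hc)), sqrt(2))
  # zero rows pass through; negatives refuse
  expect_equal(unname(hellinger(rbind(c(0, 0), c(1, 1)))[1, ]), c(0, 0))
  expect_error(hellinger(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("taxonomy features apply the strict support and prevalence rules", {
  contigs <- data.frame(
    contig_id = sprintf("c%d", 1:4),
    sample_id = c("S1", "S1", "S1", "S2"),
    contig_length = c(1000, 3000, 2000, 500),
    genus = c("Aquifex", "Aquifex", "Sulfolobus", "Aquifex"),
    support = c(0.70, 0.71, 0.90, 0.95))
  tp <- taxonomy_features(contigs, 0.70, prevalence_fraction = 0)
  # the support == 0.70 contig is discarded: Aquifex in S1 is 3000 bp of 5000
  expect_equal(tp["S1", "Aquifex"], 3000 / 5000)
  expect_equal(tp["S2", "Aquifex"], 1)

  # prevalence: genus present in 1 of 10 samples removed at 20%
  many <- data.frame(contig_id = sprintf("c%d", 1:11),
                     sample_id = c(sprintf("S%02d", 1:10), "S01"),
                     contig_length = 1000,
                     genus = c(rep("Common", 10), "Rare"),
                     support = 0.9)
  tp2 <- taxonomy_features(many, 0.70, 0.20)
  expect_false("Rare" %in% colnames(tp2))
  expect_true("Common" %in% colnames(tp2))
})

test_that("PCA matches the SVD oracle, orders variance, and fixes signs", {
  set.seed(3)
  m <- matrix(rnorm(80), 16, 5)
  res <- pca_profile(m, 4)
  xc <- scale(m, scale = FALSE)
  sv <- svd(xc)
  for (j in 1:4) {
    expect_equal(abs(res$scores[, j]), abs(sv$u[, j] * sv$d[j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    i <- which.max(abs(res$loadings[, j]))
    expect_gt(res$loadings[i, j], 0)
  }
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  expect_lte(sum(res$variance_fraction), 1 + 1e-12)

  # exact line in 2-D: first component explains everything
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_equal(pca_profile(line, 1)$variance_fraction, 1)
  expect_error(pca_profile(m, 20), "n_components")
})
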