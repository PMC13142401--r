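# Independent oracles used across tests. Each is a deliberately naive
# implementation (brute force, enumeration, closed form) kept separate
# from the package's own code paths.

# Connected components by iterated transitive closure over an adjacency
# matrix (Boolean matrix powers until fixpoint).
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- TRUE
    A[edges$b[i], edges$a[i]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  labels <- apply(A, 1, function(row) min(nodes[row]))
  unname(split(nodes, labels))
}

# One-way PERMANOVA pseudo-F for two equal groups, computed directly
# from the classic within/between sum-of-squares decomposition of the
# distance matrix (no hat matrices).
oracle_permanova_F <- function(dm, groups) {
  n <- nrow(dm)
  sst <- sum(dm[lower.tri(dm)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    sub <- dm[i, i]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(i)
  }
  ssa <- sst - ssw
  a <- length(unique(groups))
  (ssa / (a - 1)) / (ssw / (n - a))
}

# Exhaustive PERMANOVA p for n = 6, two groups of 3: all 20 distinct
# relabelings.
oracle_permanova_exact_p <- function(dm) {
  n <- 6L
  obs <- oracle_permanova_F(dm, rep(c("A", "B"), each = 3))
  combos <- utils::combn(n, 3)
  stats <- apply(combos, 2, function(i) {
    g <- rep("B", n); g[i] <- "A"
    oracle_permanova_F(dm, g)
  })
  mean(stats >= obs - 1e-12)
}

# Newman modularity of a partition (membership vector) of an unweighted
# undirected graph given as an edge data.frame.
oracle_modularity <- function(nodes, edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(m)) {
    deg[edges$a[i]] <- deg[edges$a[i]] + 1
    deg[edges$b[i]] <- deg[edges$b[i]] + 1
  }
  q <- 0
  for (cm in unique(membership)) {
    inside <- names(membership)[membership == cm]
    e_c <- sum(edges$a %in% inside & edges$b %in% inside)
    d_c <- sum(deg[inside])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# All set partitions of a vector (restricted growth strings).
oracle_set_partitions <- function(x) {
  n <- length(x)
  parts <- list()
  rec <- function(i, assign, kmax) {
    if (i > n) {
      parts[[length(parts) + 1L]] <<- split(x, assign)
      return(invisible())
    }
    for (k in seq_len(kmax + 1L)) {
      rec(i + 1L, c(assign, k), max(kmax, k))
    }
  }
  rec(2L, c(1L), 1L)
  parts
}

# Exhaustive maximum-modularity partition for small graphs.
oracle_best_modularity <- function(nodes, edges) {
  best_q <- -Inf
  best <- NULL
  for (p in oracle_set_partitions(nodes)) {
    mem <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
    mem <- mem[nodes]
    q <- oracle_modularity(nodes, edges, mem)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- mem
    }
  }
  list(membership = best, modularity = best_q)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# the pooled values to the two samples (no ties assumed).
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  us <- apply(combos, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Canonical form of a partition for comparison up to label permutation.
partition_signature <- function(ids, labels) {
  groups <- split(ids, labels)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = ";")
}

# Best label agreement between two clusterings over all bijections from
# the (small) label set of `a` onto the label set of `b`.
label_agreement <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  stopifnot(length(ua) == length(ub))
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in permute(ub)) {
    mapped <- p[match(a, ua)]
    best <- max(best, mean(mapped == b))
  }
  best
}

# Small deterministic study used by several module tests.
tiny_study <- function(seed = 42, ...) {
  cfg <- sim_config(n_samples = 24, n_families_per_class = 12,
                    seed = seed, ...)
  list(config = cfg, study = simulate_study(cfg))
}
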