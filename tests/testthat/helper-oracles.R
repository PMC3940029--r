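# Independent brute-force oracles and fixture generators. These deliberately
# re-derive every quantity with plain loops so that the package's vectorised
# and compiled code paths are checked against a second, simpler route.

# Silhouette width on the induced dissimilarity d = s_max - s, element by
# element.
oracle_silhouette <- function(S, membership) {
  S <- unclass(S)
  g <- match(membership, unique(membership))
  n <- nrow(S)
  k <- length(unique(g))
  if (k < 2) return(NA_real_)
  s_max <- max(S[upper.tri(S)])
  si <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(g == g[i]), i)
    if (!length(own)) { si[i] <- 0; next }
    a <- mean(S[i, own])
    b <- max(vapply(setdiff(seq_len(k), g[i]),
                    function(c) mean(S[i, which(g == c)]), numeric(1)))
    denom <- s_max - min(a, b)
    si[i] <- if (denom > 1e-12 * max(1, abs(s_max))) (a - b) / denom else 0
  }
  mean(si)
}

# Rand index by explicit enumeration of all unordered element pairs.
oracle_rand <- function(g1, g2) {
  n <- length(g1)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      agree <- agree + ((g1[i] == g1[j]) == (g2[i] == g2[j]))
    }
  }
  agree / total
}

# Threshold selection without presorting: the tail is pulled out of the pool
# by repeated max-extraction (boundary ties included), then thresholds are
# the tail values nearest to evenly spaced points across the tail's range
# (ties snapped to the lower value).
oracle_tail_thresholds <- function(values, top_fraction, n_thresholds) {
  pool <- values
  len <- ceiling(top_fraction * length(values))
  tail_vals <- numeric(0)
  for (i in seq_len(len)) {
    tail_vals <- c(tail_vals, max(pool))
    pool <- pool[-which.max(pool)]
  }
  while (length(pool) && max(pool) == tail_vals[len]) {
    tail_vals <- c(tail_vals, max(pool))
    pool <- pool[-which.max(pool)]
  }
  targets <- seq(min(tail_vals), max(tail_vals), length.out = n_thresholds)
  sort(vapply(targets, function(t) {
    d <- abs(tail_vals - t)
    min(tail_vals[d == min(d)])
  }, numeric(1)))
}

# All set partitions of 1..n (restricted growth strings), as membership
# vectors. Only usable for small n.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(g, i, k) {
    if (i > n) { out[[length(out) + 1L]] <<- g; return(invisible()) }
    for (c in seq_len(k + 1L)) {
      g[i] <- c
      recurse(g, i + 1L, max(k, c))
    }
  }
  recurse(integer(n), 1L, 0L)
  out
}

random_similarity <- function(n, lo = -1, hi = 1) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, lo, hi)
  v <- v + t(v)
  diag(v) <- hi
  similarity_matrix(v)
}

random_membership <- function(n, k_max = max(2, floor(sqrt(n)))) {
  as_partition(sample.int(sample(2:max(2, k_max), 1), n, replace = TRUE))
}

expect_valid_partition <- function(g, n) {
  expect_length(g, n)
  ids <- as.integer(g)
  expect_false(anyNA(ids))
  expect_identical(sort(unique(ids)), seq_len(max(ids)))
  expect_identical(unique(ids), seq_len(max(ids)))  # first-appearance order
}

# Mean intra-cluster similarity of one member set, by direct pair loop.
oracle_cluster_mean <- function(S, members) {
  S <- unclass(S)
  tot <- 0
  np <- 0L
  for (a in seq_along(members)) {
    for (b in seq_len(a - 1L)) {
      tot <- tot + S[members[a], members[b]]
      np <- np + 1L
    }
  }
  tot / np
}

# Compare cluster memberships ignoring names and diagnostic attributes.
expect_membership <- function(g, expected) {
  expect_identical(as.integer(g), as.integer(expected))
}
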