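test_that("cluster_stats reports mean, population variance and pair count", {
  v <- matrix(0.6, 2, 2); diag(v) <- 1
  st <- cluster_stats(similarity_matrix(v, c("a", "b")), c("a", "b"))
  expect_equal(st$mean, 0.6)
  expect_equal(st$variance, 0)
  expect_identical(st$n_pairs, 1L)

  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.2
  v[1, 3] <- v[3, 1] <- 0.4
  v[2, 3] <- v[3, 2] <- 0.6
  diag(v) <- 1
  st <- cluster_stats(similarity_matrix(v), 1:3)
  expect_equal(st$mean, 0.4)
  expect_equal(st$variance, 8 / 300, tolerance = 1e-12)
  expect_identical(st$n_pairs, 3L)

  st <- cluster_stats(similarity_matrix(v), 2)
  expect_identical(st$n_pairs, 0L)
  expect_true(is.na(st$mean) && is.na(st$variance))

  expect_error(cluster_stats(similarity_matrix(v), "nope"),
               class = "pfclust_argument_error")
})

test_that("seed_and_grow admits members only while the mean stays above T", {
  v <- matrix(0.2, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.9
  diag(v) <- 1
  m <- similarity_matrix(v, c("a", "b", "c"))
  # adding c would give mean (0.9 + 0.2 + 0.2)/3 < 0.5
  expect_identical(seed_and_grow(m, c("a", "b", "c"), 0.5), c("a", "b"))
  expect_identical(seed_and_grow(m, 1:3, 0.5), c(1L, 2L))
  # single remaining element is a singleton
  expect_identical(seed_and_grow(m, "c", 0.5), "c")
  # no admissible seed pair
  expect_identical(seed_and_grow(m, 1:3, 0.95), 1L)
})

test_that("merge_pass joins clusters only when the union stays admissible", {
  v <- matrix(0.7, 4, 4)
  v[1, 2] <- v[2, 1] <- 0.9
  v[3, 4] <- v[4, 3] <- 0.9
  diag(v) <- 1
  m <- similarity_matrix(v, letters[1:4])
  merged <- merge_pass(m, c(1, 1, 2, 2), 0.5)   # union mean (2*0.9+4*0.7)/6
  expect_identical(n_clusters(merged), 1L)
  expect_identical(attr(merged, "n_merges"), 1L)

  blocks <- block_similarity(c(3, 3), within = 0.9, between = 0.1)
  same <- merge_pass(blocks, rep(1:2, each = 3), 0.5)  # union mean 0.42
  expect_membership(same, rep(1:2, each = 3L))
  expect_identical(attr(same, "n_merges"), 0L)

  one <- merge_pass(blocks, rep(1, 6), 0.1)
  expect_identical(n_clusters(one), 1L)  # single cluster: nothing to merge
})

test_that("reassign_pass repatriates a misassigned element and respects ties", {
  blocks <- block_similarity(c(3, 3), within = 0.9, between = 0.1)
  bad <- c(1, 1, 1, 1, 2, 2)  # element 4 sits in the wrong block
  fixed <- reassign_pass(blocks, bad, 0.4)
  expect_membership(fixed, rep(1:2, each = 3L))
  expect_true(attr(fixed, "converged"))

  # already locally optimal: unchanged after one clean pass
  again <- reassign_pass(blocks, fixed, 0.4)
  expect_membership(again, fixed)
  expect_identical(attr(again, "passes"), 1L)

  # exact tie between two clusters: the incumbent keeps the element
  v <- matrix(0.5, 5, 5)
  v[1, 2] <- v[2, 1] <- 0.9
  v[4, 5] <- v[5, 4] <- 0.9
  diag(v) <- 1  # element 3 is equally similar (0.5) to both pair clusters
  m <- similarity_matrix(v)
  g <- c(1, 1, 1, 2, 2)
  out <- reassign_pass(m, g, 0.1)
  expect_membership(out, c(1L, 1L, 1L, 2L, 2L))
})

test_that("two-block matrix at mid threshold is cut exactly at the blocks", {
  m <- block_similarity(c(5, 5), within = 0.9, between = 0.1)
  g <- cluster_at_threshold(m, 0.5)
  expect_membership(g, rep(1:2, each = 5L))

  # brute-force oracle on a 6-element version: among all admissible
  # partitions (every >= 2-member cluster mean >= T) the block partition
  # maximises the pooled within-cluster mean, and the engine returns it
  m6 <- block_similarity(c(3, 3), within = 0.9, between = 0.1)
  v6 <- unclass(m6)
  admissible <- Filter(function(g) {
    all(vapply(unique(g), function(c) {
      mem <- which(g == c)
      length(mem) < 2 || oracle_cluster_mean(v6, mem) >= 0.5
    }, logical(1)))
  }, all_partitions(6))
  pooled <- vapply(admissible, function(g) {
    tot <- 0; np <- 0
    for (c in unique(g)) {
      mem <- which(g == c)
      if (length(mem) >= 2) {
        np1 <- choose(length(mem), 2)
        tot <- tot + oracle_cluster_mean(v6, mem) * np1
        np <- np + np1
      }
    }
    if (np == 0) -Inf else tot / np
  }, numeric(1))
  best <- admissible[[which.max(pooled)]]
  expect_identical(unname(as_partition(best)), rep(1:2, each = 3L))
  expect_membership(cluster_at_threshold(m6, 0.5), rep(1:2, each = 3L))
})

test_that("degenerate thresholds give all-singletons or one cluster", {
  m <- block_similarity(c(4, 4), within = 0.9, between = 0.1)
  expect_membership(cluster_at_threshold(m, 0.95), 1:8)

  const <- similarity_matrix(matrix(0.8, 6, 6) + diag(0.2, 6))
  expect_membership(cluster_at_threshold(const, 0.5), rep(1L, 6))
})

test_that("every multi-member output cluster satisfies the admission mean", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    m <- random_similarity(n, lo = runif(1, -1, 0), hi = runif(1, 0.5, 2))
    off <- unclass(m)[upper.tri(m)]
    T <- quantile(off, runif(1), names = FALSE)
    g <- cluster_at_threshold(m, T)
    expect_valid_partition(g, n)
    for (c in seq_len(max(g))) {
      mem <- which(g == c)
      if (length(mem) >= 2)
        expect_gte(oracle_cluster_mean(m, mem), T - 1e-9)
    }
  }
})

test_that("clustering is deterministic and monotone in T on block matrices", {
  set.seed(61)
  m <- random_similarity(30)
  g1 <- cluster_at_threshold(m, 0.2)
  g2 <- cluster_at_threshold(m, 0.2)
  expect_identical(g1, g2)

  blocks <- block_similarity(c(4, 4, 4), within = 0.9, between = 0.1)
  ks <- vapply(c(0.05, 0.3, 0.6, 0.89, 0.95, 2),
               function(T) n_clusters(cluster_at_threshold(blocks, T)),
               integer(1))
  expect_false(is.unsorted(ks))
  expect_identical(ks[1], 1L)           # below the between-block similarity
  expect_identical(ks[6], 12L)          # above the maximum similarity
})

test_that("similarity lookups scale ~ n^2 at fixed cluster count", {
  lookups <- function(n) {
    m <- block_similarity(c(n / 2, n / 2), within = 0.9, between = 0.1)
    attr(cluster_at_threshold(m, 0.5), "lookups")
  }
  expect_lte(lookups(80) / lookups(40), 5)
  expect_lte(lookups(160) / lookups(80), 5)
})
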