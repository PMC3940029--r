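test_that("silhouette on block-constant matrices matches the closed form", {
  m <- block_similarity(c(5, 5), within = 0.9, between = 0.1)
  # a = 0.9, b = 0.1, s_max = 0.9 -> (0.9 - 0.1) / (0.9 - 0.1) = 1
  expect_equal(as.numeric(silhouette_width(m, rep(1:2, each = 5))), 1)

  # all singletons score 0 by convention
  expect_equal(as.numeric(silhouette_width(m, 1:10)), 0)

  # single cluster: no neighbouring cluster exists, silhouette undefined
  expect_true(is.na(silhouette_width(m, rep(1, 10))))

  # constant matrix: zero denominator convention
  const <- similarity_matrix(matrix(0.4, 6, 6) + diag(0.6, 6))
  expect_equal(as.numeric(silhouette_width(const, rep(1:2, each = 3))), 0)
})

test_that("silhouette matches the per-element brute-force oracle", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    m <- random_similarity(n)
    g <- random_membership(n)
    expect_equal(as.numeric(silhouette_width(m, g)), oracle_silhouette(m, g),
                 tolerance = 1e-12)
  }
})

test_that("rand index agrees with pair enumeration and a reference library", {
  a <- as_partition(c(1, 1, 2, 2), labels = letters[1:4])
  b <- as_partition(c(1, 2, 3, 3), labels = letters[1:4])
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, b), 5 / 6)
  expect_equal(rand_index(c(1, 1), c(1, 2)), 0)

  set.seed(81)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    g1 <- random_membership(n)
    g2 <- random_membership(n)
    ri <- rand_index(g1, g2)
    expect_equal(ri, oracle_rand(g1, g2), tolerance = 1e-12)
    expect_equal(ri, rand_index(g2, g1))
    expect_equal(ri, e1071::classAgreement(table(g1, g2))$rand,
                 tolerance = 1e-12)
  }

  # name-based alignment: same partition in a different element order
  shuffled <- b[c("d", "a", "c", "b")]
  expect_equal(rand_index(b, shuffled), 1)
  expect_error(rand_index(c(x = 1, y = 2), c(x = 1, z = 2)),
               class = "pfclust_argument_error")
})

test_that("select_best maximises silhouette with documented tie-breaks", {
  cand <- function(sil, k, thr) {
    list(partition = as_partition(rep(seq_len(k), length.out = 6)),
         threshold = thr, silhouette = sil)
  }
  picked <- select_best(list(cand(0.3, 2, .1), cand(0.7, 3, .2),
                             cand(0.5, 2, .3)))
  expect_equal(picked$silhouette, 0.7)

  picked <- select_best(list(cand(0.7, 5, .1), cand(0.7, 3, .2)))
  expect_equal(n_clusters(picked$partition), 3L)

  picked <- select_best(list(cand(0.7, 3, .4), cand(0.7, 3, .2)))
  expect_equal(picked$threshold, .2)

  expect_error(select_best(list(cand(NA_real_, 1, .1))),
               class = "pfclust_selection_error")
})

test_that("the outer loop is seed-reproducible and runs at least four rounds", {
  m <- block_similarity(c(6, 6, 6), within = 0.9, between = 0.1)
  r1 <- run_pfclust(m, rounds = 400, seed = 9)
  r2 <- run_pfclust(m, rounds = 400, seed = 9)
  expect_identical(r1, r2)
  expect_gte(r1$n_rounds, 4L)
  expect_lte(r1$n_rounds, 10L)
  expect_length(r1$convergence_trace, r1$n_rounds - 1L)
  expect_identical(unname(r1$best$partition), rep(1:3, each = 6L))
  expect_equal(r1$best$silhouette,
               max(vapply(unlist(lapply(r1$rounds, `[[`, "candidates"),
                                 recursive = FALSE),
                          function(x) x$silhouette, numeric(1)), na.rm = TRUE))
})

test_that("parallel and sequential execution give identical results", {
  m <- block_similarity(c(6, 6), within = 0.8, between = 0.2)
  seq_res <- run_pfclust(m, rounds = 400, seed = 3, workers = 1)
  par_res <- run_pfclust(m, rounds = 400, seed = 3, workers = 2)
  expect_identical(seq_res, par_res)
})

test_that("a structureless matrix falls back to one cluster with a warning", {
  const <- similarity_matrix(matrix(0.8, 6, 6) + diag(0.2, 6))
  expect_warning(res <- run_pfclust(const, rounds = 400, seed = 2),
                 "single-cluster")
  expect_identical(n_clusters(res$best$partition), 1L)
  expect_true(is.na(res$best$silhouette))
  expect_identical(res$n_rounds, 10L)  # never converges, hits the cap
})

test_that("the seed argument leaves the caller's RNG stream untouched", {
  m <- block_similarity(c(4, 4), within = 0.9, between = 0.1)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(run_pfclust(m, rounds = 400, seed = 77))
  expect_identical(runif(1), before)
})
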