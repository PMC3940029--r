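test_that("constructor validates shape, labels, finiteness and symmetry", {
  expect_error(similarity_matrix(matrix(1, 2, 3)), class = "pfclust_format_error")
  expect_error(similarity_matrix(matrix(1, 1, 1)), class = "pfclust_argument_error")
  expect_error(similarity_matrix(diag(2), labels = c("a", "a")),
               class = "pfclust_validation_error")

  v <- diag(3)
  v[1, 2] <- NaN
  v[2, 1] <- NaN
  err <- tryCatch(similarity_matrix(v), condition = identity)
  expect_s3_class(err, "pfclust_validation_error")
  expect_match(conditionMessage(err), "non-finite")

  v <- matrix(c(1, .5, .8, 1), 2, 2)  # asymmetry 0.3, far beyond tolerance
  err <- tryCatch(similarity_matrix(v, labels = c("a", "b")),
                  condition = identity)
  expect_s3_class(err, "pfclust_validation_error")
  expect_match(conditionMessage(err), "a.*b|b.*a")

  # asymmetry within tolerance is averaged away
  v <- matrix(c(1, .5, .5 + 1e-10, 1), 2, 2)
  m <- similarity_matrix(v)
  expect_identical(m[1, 2], m[2, 1])
})

test_that("labelled and bare dialects read as documented", {
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\ta\tb\tc",
               "a\t1\t0.5\t0.5",
               "b\t0.5\t1\t0.5",
               "c\t0.5\t0.5\t1"), lab)
  m <- read_similarity_matrix(lab)
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_identical(m["a", "b"], 0.5)

  bare <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,0.3", "0.3,1"), bare)
  m <- read_similarity_matrix(bare, dialect = "bare")
  expect_identical(rownames(m), c("e1", "e2"))
  expect_identical(m[1, 2], 0.3)

  nonsq <- withr::local_tempfile()
  writeLines(c("1,0.3,0.1", "0.3,1,0.1"), nonsq)
  expect_error(read_similarity_matrix(nonsq, dialect = "bare"),
               class = "pfclust_format_error")

  # labelled file misread as bare has non-numeric cells
  expect_error(read_similarity_matrix(lab, dialect = "bare"),
               class = "pfclust_format_error")
  expect_error(read_similarity_matrix("does/not/exist.tsv"),
               class = "pfclust_io_error")
})

test_that("write/read round trip preserves matrices, including negatives", {
  set.seed(41)
  for (i in 1:5) {
    m <- random_similarity(5, lo = -2, hi = 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_similarity_matrix(m, path)
    back <- read_similarity_matrix(path)
    expect_identical(rownames(back), rownames(m))
    expect_lt(max(abs(unclass(back) - unclass(m))), 1e-12)
  }
})

test_that("kernels reproduce closed-form similarities", {
  two <- data.frame(label = c("p", "q"), x = c(0, 0), y = c(0, 0))
  expect_equal(similarity_from_points(two, "gaussian", sigma = 1)["p", "q"], 1)

  pts <- data.frame(label = c("p", "q"), x = c(0, 3), y = c(0, 4))  # d = 5
  expect_equal(similarity_from_points(pts, "inverse_distance")["p", "q"],
               1 / 6, tolerance = 1e-15)
  expect_equal(similarity_from_points(pts, "gaussian", sigma = 5)["p", "q"],
               exp(-0.5), tolerance = 1e-15)
  expect_equal(similarity_from_points(pts, "negative_distance")["p", "q"],
               -5, tolerance = 1e-15)

  expect_error(similarity_from_points(pts, "mahalanobis"),
               class = "pfclust_config_error")
  expect_error(similarity_from_points(pts, "gaussian", sigma = -1),
               class = "pfclust_argument_error")
})

test_that("gaussian and inverse-distance kernels invert the distance order", {
  set.seed(7)
  coords <- matrix(rnorm(30), ncol = 2)
  d <- as.matrix(dist(coords))
  ud <- upper.tri(d)
  for (kern in c("gaussian", "inverse_distance")) {
    s <- similarity_from_points(coords, kern, sigma = 2)
    expect_s3_class(s, "similarity_matrix")
    ord <- order(d[ud])
    expect_identical(order(unclass(s)[ud], decreasing = TRUE), ord)
  }
})

test_that("point tables round-trip with truth column intact", {
  set.seed(13)
  d <- generate_blobs(c(10, 10), rbind(c(-3, 0), c(3, 0)), c(1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_points(d$points, path)
  back <- read_points(path)
  expect_identical(back$label, d$points$label)
  expect_identical(back$truth, d$points$truth)
  expect_lt(max(abs(back$x - d$points$x)), 1e-12)

  expect_error(read_points("no/such/file.tsv"), class = "pfclust_io_error")
  bad <- withr::local_tempfile()
  writeLines(c("x\ty", "1\t2"), bad)  # no label column
  expect_error(read_points(bad), class = "pfclust_format_error")
})

test_that("median pairwise distance matches dist()", {
  set.seed(5)
  coords <- matrix(rnorm(40), ncol = 2)
  expect_equal(median_pairwise_distance(coords),
               median(as.vector(dist(coords))))
})
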