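#' Construct and validate a similarity matrix
#'
#' The sole data input of the clustering algorithm: a square, symmetric,
#' real-valued matrix of pairwise similarities (higher = more similar), with
#' one label per element. Similarities may lie on any finite real scale; they
#' are only ever compared with thresholds drawn from the same matrix, so no
#' \[0, 1\] normalisation is assumed. Diagonal entries are stored but never
#' enter any intra-cluster statistic: only unordered pairs of distinct
#' elements count.
#'
#' @param values Square numeric matrix of pairwise similarities.
#' @param labels Character vector of unique element labels; defaults to the
#'   matrix dimnames, or `e1..en` when absent.
#' @param tol Absolute tolerance for symmetry. Asymmetries within `tol` are
#'   averaged away; anything larger is an error (it usually means a
#'   transposed or corrupted input file).
#'
#' @return A validated `similarity_matrix`: a numeric matrix with both
#'   dimnames set to `labels` and class `"similarity_matrix"`.
#' @export
#' @examples
#' s <- similarity_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"))
#' s["a", "b"]
similarity_matrix <- function(values, labels = NULL, tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values))
    pf_stop("`values` must be a numeric matrix", "pfclust_argument_error")
  n <- nrow(values)
  if (ncol(values) != n)
    pf_stop(sprintf("similarity matrix must be square, got %d x %d",
                    n, ncol(values)), "pfclust_format_error")
  if (n < 2)
    pf_stop("a similarity matrix needs at least 2 elements",
            "pfclust_argument_error")
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("e", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n)
    pf_stop(sprintf("%d labels for %d elements", length(labels), n),
            "pfclust_argument_error")
  if (anyDuplicated(labels))
    pf_stop(sprintf("duplicate element label: '%s'",
                    labels[anyDuplicated(labels)]),
            "pfclust_validation_error")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    pf_stop(sprintf("non-finite similarity at (%s, %s)",
                    labels[ij[1]], labels[ij[2]]),
            "pfclust_validation_error")
  }
  asym <- abs(values - t(values))
  if (any(asym > tol)) {
    ij <- arrayInd(which.max(asym), dim(asym))
    pf_stop(sprintf(
      "matrix is asymmetric beyond tolerance %g: worst at (%s, %s), |s(i,j) - s(j,i)| = %g",
      tol, labels[ij[1]], labels[ij[2]], max(asym)),
      "pfclust_validation_error")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  class(values) <- "similarity_matrix"
  values
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- x[upper.tri(x)]
  cat(sprintf("similarity_matrix: %d elements\n", n))
  cat(sprintf("  off-diagonal range [%.6g, %.6g], mean %.6g\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

# Strip the class for fast numeric work.
sim_values <- function(m) {
  attr(m, "class") <- NULL
  m
}

as_similarity <- function(m, arg = "matrix") {
  if (inherits(m, "similarity_matrix")) return(m)
  if (is.matrix(m) && is.numeric(m)) return(similarity_matrix(m))
  pf_stop(sprintf("`%s` must be a similarity matrix", arg),
          "pfclust_argument_error")
}

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a similarity matrix from delimited text
#'
#' Two dialects are supported. `labelled`: a header row of labels and a first
#' column of labels, cell (i, j) holding s(i, j). `bare`: a pure numeric
#' square block with labels synthesised as `e1..en`. The delimiter (tab or
#' comma) is auto-detected from the first line.
#'
#' @param path Path to the file.
#' @param dialect `"labelled"` (default) or `"bare"`.
#' @return A validated [similarity_matrix()]. Asymmetries within `1e-9` are
#'   symmetrised by averaging; larger asymmetry, non-square blocks and
#'   non-finite entries are errors.
#' @export
read_similarity_matrix <- function(path, dialect = c("labelled", "bare")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    pf_stop(sprintf("no such file: %s", path), "pfclust_io_error")
  first <- readLines(path, n = 1L)
  if (!length(first))
    pf_stop(sprintf("empty file: %s", path), "pfclust_format_error")
  sep <- detect_sep(first)
  if (dialect == "labelled") {
    df <- tryCatch(
      read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                 row.names = 1L, comment.char = ""),
      error = function(e) pf_stop(
        sprintf("cannot parse labelled matrix %s: %s", path, conditionMessage(e)),
        "pfclust_format_error"))
    values <- as.matrix(df)
    if (!is.numeric(values))
      pf_stop(sprintf("non-numeric cells in %s", path), "pfclust_format_error")
    if (nrow(values) != ncol(values))
      pf_stop(sprintf("labelled matrix in %s is %d x %d, not square",
                      path, nrow(values), ncol(values)),
              "pfclust_format_error")
    if (!identical(rownames(values), colnames(values)))
      pf_stop(sprintf("row and column labels disagree in %s", path),
              "pfclust_format_error")
    similarity_matrix(values, labels = rownames(values))
  } else {
    df <- tryCatch(
      read.table(path, header = FALSE, sep = sep, comment.char = ""),
      error = function(e) pf_stop(
        sprintf("cannot parse bare matrix %s: %s", path, conditionMessage(e)),
        "pfclust_format_error"))
    values <- as.matrix(df)
    if (!is.numeric(values))
      pf_stop(sprintf(
        "non-numeric cells in %s (labelled file read with dialect = \"bare\"?)",
        path), "pfclust_format_error")
    if (nrow(values) != ncol(values))
      pf_stop(sprintf("numeric block in %s is %d x %d, not square",
                      path, nrow(values), ncol(values)),
              "pfclust_format_error")
    dimnames(values) <- NULL
    similarity_matrix(values)
  }
}

#' Write a similarity matrix as labelled delimited text
#'
#' Tab-delimited, header row and first column carrying the labels, values at
#' full double precision so that a read/write round trip reproduces the
#' matrix to 1e-12 (no clamping: negative similarities are preserved).
#'
#' @param matrix A [similarity_matrix()] (or plain symmetric numeric matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(matrix, path) {
  m <- as_similarity(matrix)
  labels <- rownames(m)
  v <- sim_values(m)
  lines <- c(
    paste(c("label", labels), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(labels[i], sprintf("%.17g", v[i, ])), collapse = "\t")
    }, character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pf_stop(sprintf("cannot write %s", path), "pfclust_io_error")
  invisible(path)
}

#' Build a similarity matrix from feature vectors
#'
#' Converts a table of points (any dimension, typically 2) to pairwise
#' similarities through a kernel applied to Euclidean distance:
#' \describe{
#'   \item{gaussian}{`s(i,j) = exp(-d(i,j)^2 / (2 sigma^2))`. When `sigma`
#'     is `NULL` the median of all pairwise distances is used (the median
#'     heuristic), keeping the pipeline free of hand-set scale parameters.}
#'   \item{inverse_distance}{`s(i,j) = 1 / (1 + d(i,j))`.}
#'   \item{negative_distance}{`s(i,j) = -d(i,j)`.}
#' }
#' The diagonal holds the kernel's value at distance zero. Duplicate
#' coordinate rows are allowed and get that same value.
#'
#' @param points A point table as returned by [read_points()] or
#'   [generate_blobs()] (data frame with a `label` column and numeric
#'   coordinate columns; a `truth` column is ignored), or a bare numeric
#'   matrix of coordinates.
#' @param kernel Kernel name.
#' @param sigma Bandwidth for the gaussian kernel (must be positive);
#'   `NULL` means the median pairwise distance.
#' @return A [similarity_matrix()] over the points' labels.
#' @export
#' @examples
#' pts <- data.frame(label = c("p", "q"), x = c(0, 3), y = c(0, 4))
#' similarity_from_points(pts, "inverse_distance")["p", "q"]  # 1/6
similarity_from_points <- function(points,
                                   kernel = c("gaussian", "inverse_distance",
                                              "negative_distance"),
                                   sigma = NULL) {
  if (is.character(kernel) && length(kernel) == 1L &&
      !kernel %in% c("gaussian", "inverse_distance", "negative_distance"))
    pf_stop(sprintf("unknown kernel '%s'", kernel), "pfclust_config_error")
  kernel <- match.arg(kernel)
  pt <- as_point_table(points)
  coords <- pt$coords
  if (nrow(coords) < 2)
    pf_stop("need at least 2 points", "pfclust_argument_error")
  d <- as.matrix(dist(coords))
  values <- switch(kernel,
    gaussian = {
      if (is.null(sigma)) sigma <- median(d[upper.tri(d)])
      if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
          sigma <= 0)
        pf_stop("`sigma` must be a positive number", "pfclust_argument_error")
      exp(-d^2 / (2 * sigma^2))
    },
    inverse_distance = 1 / (1 + d),
    negative_distance = -d)
  similarity_matrix(values, labels = pt$labels)
}

#' Median pairwise Euclidean distance of a point set
#'
#' The default bandwidth of the gaussian kernel in
#' [similarity_from_points()].
#'
#' @inheritParams similarity_from_points
#' @return A single number.
#' @export
median_pairwise_distance <- function(points) {
  pt <- as_point_table(points)
  d <- dist(pt$coords)
  median(as.vector(d))
}
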