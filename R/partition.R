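# Partitions are named integer vectors: one cluster id per element, ids
# contiguous 1..k in order of first appearance (the same convention as
# stats::cutree). as_partition() canonicalises any labelling.

#' Canonicalise a partition
#'
#' Accepts an integer, factor or character vector of cluster memberships and
#' returns an integer vector with cluster ids renumbered 1..k in order of
#' first appearance. Names are preserved, or set from `labels`.
#'
#' @param x Cluster membership vector.
#' @param labels Optional element labels (must match `length(x)`).
#' @return A named (when labels are available) integer vector of contiguous
#'   cluster ids.
#' @export
as_partition <- function(x, labels = NULL) {
  if (is.factor(x)) x <- as.character(x)
  if (!is.atomic(x) || !length(x))
    pf_stop("`x` must be a non-empty membership vector",
            "pfclust_argument_error")
  if (anyNA(x))
    pf_stop("partition contains missing cluster ids",
            "pfclust_validation_error")
  g <- match(x, unique(x))
  if (!is.null(labels)) {
    if (length(labels) != length(g))
      pf_stop("`labels` length does not match the partition",
              "pfclust_argument_error")
    names(g) <- as.character(labels)
  } else if (!is.null(names(x))) {
    names(g) <- names(x)
  }
  g
}

#' Number of clusters in a partition
#' @param partition A membership vector (see [as_partition()]).
#' @return Integer cluster count.
#' @export
n_clusters <- function(partition) max(as_partition(partition))

# Align a partition with the elements of a similarity matrix. Returns a bare
# integer assignment in matrix element order.
align_partition <- function(m, partition, arg = "partition") {
  g <- as_partition(partition)
  labels <- rownames(m)
  n <- nrow(m)
  if (length(g) != n)
    pf_stop(sprintf("`%s` has %d elements but the matrix has %d",
                    arg, length(g), n), "pfclust_argument_error")
  if (!is.null(names(g)) && !is.null(labels)) {
    if (!setequal(names(g), labels))
      pf_stop(sprintf("`%s` element names do not match the matrix labels",
                      arg), "pfclust_argument_error")
    g <- g[labels]
  }
  unname(g)
}

#' Write a partition as two-column TSV
#'
#' One line per element: `element<TAB>cluster_id`, cluster ids 1-based
#' integers in order of first appearance, no header.
#'
#' @param partition A membership vector; names are used as element labels
#'   (falling back to `e1..en`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  g <- as_partition(partition)
  labels <- names(g)
  if (is.null(labels)) labels <- paste0("e", seq_along(g))
  ok <- tryCatch({
    writeLines(paste(labels, g, sep = "\t"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pf_stop(sprintf("cannot write %s", path), "pfclust_io_error")
  invisible(path)
}

#' Read a partition from two-column TSV
#'
#' @param path Path to a file written by [write_partition()] (or any
#'   headerless two-column element/cluster TSV).
#' @return A named integer membership vector with contiguous cluster ids.
#' @export
read_partition <- function(path) {
  if (!file.exists(path))
    pf_stop(sprintf("no such file: %s", path), "pfclust_io_error")
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", col.names = c("element", "cluster"),
               colClasses = c("character", "character"), comment.char = ""),
    error = function(e) pf_stop(
      sprintf("cannot parse partition %s: %s", path, conditionMessage(e)),
      "pfclust_format_error"))
  if (anyDuplicated(df$element))
    pf_stop(sprintf("duplicate element '%s' in %s",
                    df$element[anyDuplicated(df$element)], path),
            "pfclust_format_error")
  as_partition(df$cluster, labels = df$element)
}
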