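#' Run the full pipeline on labelled points and score against ground truth
#'
#' Builds the similarity matrix from the point coordinates (gaussian kernel
#' with the median-distance bandwidth by default), runs [run_pfclust()],
#' and reports the proposed cluster count, silhouette, Rand index against
#' the `truth` column, cluster sizes and singleton count.
#'
#' @param points A point-table data frame with a `truth` column, or a
#'   `pfclust_dataset` from the generators.
#' @param kernel,sigma Passed to [similarity_from_points()].
#' @param ... Passed to [run_pfclust()] (e.g. `rounds`, `workers`).
#' @param seed Optional integer seed for the run.
#' @return A `pfclust_evaluation`: list with `n_clusters`, `silhouette`,
#'   `rand_index`, `cluster_sizes`, `n_singletons`, `n_rounds`, `converged`,
#'   and the full `result`.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_benchmark("blobs2_100", seed = 1)
#' ev <- evaluate_benchmark(d, rounds = 400, seed = 1)
#' ev$rand_index
#' }
evaluate_benchmark <- function(points, kernel = "gaussian", sigma = NULL,
                               ..., seed = NULL) {
  if (inherits(points, "pfclust_dataset")) points <- points$points
  pt <- as_point_table(points)
  if (is.null(pt$truth))
    pf_stop("`points` must carry a `truth` column of ground-truth cluster ids",
            "pfclust_argument_error")
  truth <- as_partition(pt$truth, labels = pt$labels)
  m <- similarity_from_points(points, kernel = kernel, sigma = sigma)
  res <- run_pfclust(m, ..., seed = seed)
  partition <- res$best$partition
  sizes <- as.integer(table(partition))
  structure(list(
    n_clusters = res$best$n_clusters,
    silhouette = res$best$silhouette,
    rand_index = rand_index(partition, truth),
    cluster_sizes = sizes,
    n_singletons = sum(sizes == 1L),
    n_rounds = res$n_rounds,
    converged = res$converged,
    result = res), class = "pfclust_evaluation")
}

#' @export
print.pfclust_evaluation <- function(x, ...) {
  cat(sprintf(
    "evaluation: %d clusters (%d singletons), silhouette %s, Rand index vs truth %.4f\n",
    x$n_clusters, x$n_singletons,
    if (is.na(x$silhouette)) "undefined" else sprintf("%.4f", x$silhouette),
    x$rand_index))
  cat(sprintf("%d rounds, %s\n", x$n_rounds,
              if (isTRUE(x$converged)) "converged" else "round cap reached"))
  invisible(x)
}
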