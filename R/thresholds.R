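#' Randomly partition n elements
#'
#' One draw of the randomisation underlying threshold estimation. A cluster
#' count k is drawn uniformly from `{2, ..., min(k_max, n - 1)}`, cluster
#' sizes are a uniform random composition of n into k non-empty parts
#' (k - 1 distinct cut points), and elements are shuffled into the parts.
#' The composition law deliberately produces clusters of widely varying
#' size, including very small ones: those small random clusters are what
#' gives the recorded intra-cluster similarity distribution the long upper
#' tail from which candidate thresholds are drawn.
#'
#' For n = 2 the only partition with a within-cluster pair is the single
#' pair cluster, which is returned deterministically.
#'
#' @param n Number of elements (at least 2).
#' @param k_max Upper bound of the cluster-count draw; default
#'   `max(2, floor(sqrt(n)))`.
#' @return An unnamed integer membership vector with contiguous cluster ids;
#'   at least one cluster always has two or more members. Uses R's global
#'   random-number stream (seed with [set.seed()]).
#' @export
random_partition <- function(n, k_max = max(2, floor(sqrt(n)))) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    pf_stop("`n` must be an integer >= 2", "pfclust_argument_error")
  n <- as.integer(n)
  if (n == 2L) return(c(1L, 1L))
  hi <- min(as.integer(k_max), n - 1L)
  if (hi < 2L)
    pf_stop("`k_max` leaves no admissible cluster count",
            "pfclust_argument_error")
  k <- if (hi == 2L) 2L else sample(2:hi, 1L)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  sizes <- diff(c(0L, cuts, n))
  as_partition(rep.int(seq_len(k), sizes)[sample.int(n)])
}

#' Pooled mean intra-cluster similarity of a partition
#'
#' The mean of s(i, j) over all unordered pairs of distinct elements that
#' share a cluster, pooled across clusters with every pair weighted equally.
#' Diagonal entries never contribute.
#'
#' @param matrix A [similarity_matrix()].
#' @param partition A membership vector over the matrix's elements.
#' @return A single number. An all-singleton partition has no within-cluster
#'   pairs and raises an undefined-statistic error.
#' @export
mean_intra_cluster_similarity <- function(matrix, partition) {
  m <- as_similarity(matrix)
  g <- align_partition(m, partition)
  means <- cpp_cluster_means(sim_values(m), g)
  sizes <- tabulate(g, max(g))
  np <- sizes * (sizes - 1) / 2
  if (all(np == 0))
    pf_stop("all clusters are singletons: mean intra-cluster similarity is undefined",
            "pfclust_undefined_statistic")
  keep <- np > 0
  sum(means[keep] * np[keep]) / sum(np[keep])
}

#' Estimate candidate clustering thresholds
#'
#' Repeatedly random-partitions the elements ([random_partition()]) and
#' records the mean intra-cluster similarity of every cluster with at least
#' two members. Candidate thresholds are then read from the top tail of that
#' recorded distribution: the values are sorted descending, the tail is the
#' first `ceiling(top_fraction * N)` values (ties at the boundary are kept),
#' and the `n_thresholds` selected thresholds are the observed tail values
#' nearest to evenly spaced points across the tail's value range, the tail
#' minimum and maximum always included. The selection is deterministic given
#' the random seed and spans a representative range from the
#' (1 - top_fraction) quantile up to the largest recorded mean.
#'
#' @param matrix A [similarity_matrix()].
#' @param rounds Number of randomisation rounds (default 1000).
#' @param top_fraction Tail proportion of the recorded distribution to
#'   sample thresholds from (default 0.05).
#' @param n_thresholds Number of thresholds to select (default 20).
#' @param k_max Passed to [random_partition()].
#' @return A `threshold_estimate`: list with `thresholds` (ascending, may
#'   contain repeats), `recorded_means` (all per-cluster means in generation
#'   order), `rounds`, `top_fraction`, `n_thresholds`.
#' @export
estimate_thresholds <- function(matrix, rounds = 1000L, top_fraction = 0.05,
                                n_thresholds = 20L,
                                k_max = NULL) {
  m <- as_similarity(matrix)
  n <- nrow(m)
  rounds <- as.integer(rounds)
  n_thresholds <- as.integer(n_thresholds)
  if (rounds < 1L || n_thresholds < 1L)
    pf_stop("`rounds` and `n_thresholds` must be positive",
            "pfclust_argument_error")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 0.5)
    pf_stop("`top_fraction` must be in (0, 0.5]", "pfclust_argument_error")
  if (rounds < n_thresholds / top_fraction)
    pf_stop(sprintf(
      "need rounds >= n_thresholds / top_fraction (= %g) so the tail can hold %d values",
      n_thresholds / top_fraction, n_thresholds), "pfclust_argument_error")
  if (is.null(k_max)) k_max <- max(2, floor(sqrt(n)))
  v <- sim_values(m)
  rec <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    g <- random_partition(n, k_max)
    means <- cpp_cluster_means(v, g)
    rec[[r]] <- means[!is.na(means)]
  }
  rec <- unlist(rec, use.names = FALSE)
  structure(
    list(thresholds = select_tail_thresholds(rec, top_fraction, n_thresholds),
         recorded_means = rec,
         rounds = rounds,
         top_fraction = top_fraction,
         n_thresholds = n_thresholds),
    class = "threshold_estimate")
}

# Representative thresholds from the top tail of `values`: the tail is the
# top ceiling(top_fraction * N) values after a single descending sort (ties
# at the boundary stay in), and thresholds are the observed tail values
# nearest to n_thresholds evenly spaced points across [min(tail), max(tail)].
# Spacing by value rather than by rank guarantees that thin but decisive
# high-similarity bands of the tail are represented even when most of the
# tail's mass sits lower; the tail minimum and maximum are always selected.
select_tail_thresholds <- function(values, top_fraction, n_thresholds) {
  srt <- sort(values, decreasing = TRUE)
  boundary <- srt[ceiling(top_fraction * length(srt))]
  tail_vals <- srt[srt >= boundary]
  targets <- seq(min(tail_vals), max(tail_vals), length.out = n_thresholds)
  # snapping to observed values may repeat a threshold; repeats are allowed
  sort(vapply(targets, function(t) {
    tail_vals[length(tail_vals) + 1L - which.min(abs(rev(tail_vals) - t))]
  }, numeric(1)))
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold_estimate: %d rounds, %d recorded cluster means\n",
              x$rounds, length(x$recorded_means)))
  cat(sprintf("  top %.1f%% tail -> %d thresholds in [%.6g, %.6g]\n",
              100 * x$top_fraction, length(x$thresholds),
              min(x$thresholds), max(x$thresholds)))
  invisible(x)
}
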