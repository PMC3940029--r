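#' Cluster a similarity matrix at one admission threshold
#'
#' Deterministic agglomerative clustering under a single threshold `T`:
#' every cluster with two or more members is guaranteed a mean intra-cluster
#' similarity of at least `T`. Three phases run in order:
#' \enumerate{
#'   \item \strong{seed and grow} ([seed_and_grow()]), repeated until every
#'     element is assigned;
#'   \item \strong{merge} ([merge_pass()]): greedily join cluster pairs whose
#'     union mean stays at or above `T`;
#'   \item \strong{reassign} ([reassign_pass()]): move elements to the
#'     cluster they are most similar to, while both affected clusters keep
#'     their admission guarantee, iterated to a fixed point.
#' }
#' Elements that qualify for no cluster remain singletons. All tie-breaks go
#' to the lowest element index / lowest cluster id, so the output is
#' identical across platforms and runs. Cost is O(k n^2) similarity lookups
#' for k clusters over n elements.
#'
#' @param matrix A [similarity_matrix()].
#' @param threshold Minimum mean intra-cluster similarity `T`.
#' @param max_passes Hard cap on reassignment sweeps (default 100); hitting
#'   the cap is reported with a warning.
#' @return A named integer membership vector (see [as_partition()]) with
#'   attributes `n_merges`, `passes`, and `lookups` (similarity reads
#'   performed, the engine's cost measure).
#' @export
#' @examples
#' s <- block_similarity(c(3, 3), within = 0.9, between = 0.1)
#' cluster_at_threshold(s, 0.5)
cluster_at_threshold <- function(matrix, threshold, max_passes = 100L) {
  m <- as_similarity(matrix)
  check_threshold(threshold)
  res <- cpp_cluster_at_threshold(sim_values(m), threshold,
                                  as.integer(max_passes))
  if (!res$converged)
    warning(sprintf(
      "reassignment stopped at the %d-pass cap before reaching a fixed point",
      as.integer(max_passes)))
  g <- res$assignment
  names(g) <- rownames(m)
  structure(g, n_merges = res$n_merges, passes = res$passes,
            lookups = res$lookups)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    pf_stop("`threshold` must be a single finite number",
            "pfclust_argument_error")
}

#' Grow one cluster from an unassigned element set
#'
#' The seeding/growth phase of [cluster_at_threshold()], exposed on its own.
#' Seeds with the unassigned pair of maximal similarity when that similarity
#' reaches `threshold` (otherwise the single lowest-index element is
#' returned as a singleton), then repeatedly admits the unassigned element
#' with the highest mean similarity to the current members, as long as the
#' grown cluster's mean stays at or above `threshold`.
#'
#' @inheritParams cluster_at_threshold
#' @param unassigned Element indices (1-based) or labels still available.
#' @return The new cluster's members, as indices or labels matching the
#'   `unassigned` input, in ascending index order.
#' @export
seed_and_grow <- function(matrix, unassigned, threshold) {
  m <- as_similarity(matrix)
  check_threshold(threshold)
  idx <- resolve_elements(m, unassigned)
  mem <- cpp_seed_and_grow(sim_values(m), idx, threshold)
  if (is.character(unassigned)) rownames(m)[mem] else mem
}

resolve_elements <- function(m, elements) {
  if (is.character(elements)) {
    idx <- match(elements, rownames(m))
    if (anyNA(idx))
      pf_stop(sprintf("unknown element '%s'", elements[which(is.na(idx))[1]]),
              "pfclust_argument_error")
  } else {
    idx <- as.integer(elements)
    if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(m)))
      pf_stop("element index out of range", "pfclust_argument_error")
  }
  if (!length(idx))
    pf_stop("empty element set", "pfclust_argument_error")
  if (anyDuplicated(idx))
    pf_stop("duplicate elements", "pfclust_argument_error")
  idx
}

#' Merge phase: join cluster pairs whose union stays admissible
#'
#' Repeatedly merges the cluster pair whose union has the highest mean
#' intra-cluster similarity, while that union mean is at least `threshold`.
#'
#' @inheritParams cluster_at_threshold
#' @param partition A membership vector over the matrix's elements.
#' @return The merged partition (named integer vector, canonical ids) with
#'   attribute `n_merges`.
#' @export
merge_pass <- function(matrix, partition, threshold) {
  m <- as_similarity(matrix)
  check_threshold(threshold)
  g <- align_partition(m, partition)
  res <- cpp_merge_pass(sim_values(m), g, threshold)
  out <- res$assignment
  names(out) <- rownames(m)
  structure(out, n_merges = res$n_merges)
}

#' Reassignment phase: move elements to their most similar cluster
#'
#' Each element, in index order, moves to the cluster (including staying
#' put) with which it has the highest mean similarity, provided both
#' affected clusters still satisfy the admission threshold after the move;
#' the incumbent cluster wins ties. Sweeps repeat until a full pass makes no
#' move, up to `max_passes`.
#'
#' @inheritParams merge_pass
#' @param max_passes Hard cap on sweeps (default 100).
#' @return The refined partition (named integer vector, canonical ids) with
#'   attributes `passes` and `converged`.
#' @export
reassign_pass <- function(matrix, partition, threshold, max_passes = 100L) {
  m <- as_similarity(matrix)
  check_threshold(threshold)
  g <- align_partition(m, partition)
  res <- cpp_reassign_pass(sim_values(m), g, threshold,
                           as.integer(max_passes))
  if (!res$converged)
    warning(sprintf(
      "reassignment stopped at the %d-pass cap before reaching a fixed point",
      as.integer(max_passes)))
  out <- res$assignment
  names(out) <- rownames(m)
  structure(out, passes = res$passes, converged = res$converged)
}

#' Mean, variance and pair count of one cluster's similarities
#'
#' A cluster is summarised by the distribution of the pairwise similarities
#' of its members: the mean (the quantity the admission threshold gates) and
#' the population variance over all unordered member pairs. Singletons have
#' no pairs; their mean and variance are undefined and returned as `NA`.
#'
#' @param matrix A [similarity_matrix()].
#' @param members Element indices (1-based) or labels.
#' @return A list with `mean`, `variance` (population), `n_pairs`, and
#'   `n_members`.
#' @export
cluster_stats <- function(matrix, members) {
  m <- as_similarity(matrix)
  idx <- resolve_elements(m, members)
  n_mem <- length(idx)
  if (n_mem < 2)
    return(list(mean = NA_real_, variance = NA_real_, n_pairs = 0L,
                n_members = n_mem))
  v <- sim_values(m)[idx, idx]
  pairs <- v[upper.tri(v)]
  list(mean = mean(pairs),
       variance = mean((pairs - mean(pairs))^2),
       n_pairs = length(pairs),
       n_members = n_mem)
}

#' Block-constant similarity matrix
#'
#' A similarity matrix of `length(sizes)` blocks with constant within-block
#' and between-block similarity. Used throughout the tests and examples as
#' the simplest structured input.
#'
#' @param sizes Block sizes.
#' @param within Within-block similarity.
#' @param between Between-block similarity.
#' @param diagonal Diagonal value (never used by the statistics).
#' @return A [similarity_matrix()]; labels `b<block>_<i>`.
#' @export
block_similarity <- function(sizes, within = 0.9, between = 0.1,
                             diagonal = 1) {
  blocks <- rep(seq_along(sizes), sizes)
  v <- ifelse(outer(blocks, blocks, "=="), within, between)
  diag(v) <- diagonal
  labels <- paste0("b", blocks, "_", unlist(lapply(sizes, seq_len)))
  similarity_matrix(v, labels = labels)
}
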