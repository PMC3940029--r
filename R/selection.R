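#' Silhouette width of a clustering, in similarity space
#'
#' The silhouette width of Rousseeuw, computed on the dissimilarity induced
#' by the similarity matrix: `d(i, j) = s_max - s(i, j)` with `s_max` the
#' largest off-diagonal similarity. In similarity terms the per-element
#' score is
#' \deqn{s(i) = \frac{a(i) - b(i)}{s_{max} - \min(a(i), b(i))}}
#' where `a(i)` is the mean similarity of element i to its own cluster's
#' other members and `b(i)` the largest mean similarity to any other
#' cluster. The shift by `s_max` makes the score invariant to the additive
#' offset of the similarity scale, which matters for smooth kernels (a
#' Gaussian kernel with a wide bandwidth leaves even unrelated elements with
#' substantial similarity; a ratio of raw similarities would barely separate
#' good and bad clusterings there, while the induced-dissimilarity form
#' keeps its full contrast). Scores lie in \[-1, 1\].
#'
#' Conventions: singletons score 0; when the denominator is 0 (all recorded
#' similarities equal) the element scores 0; a partition with fewer than two
#' clusters has no `b(i)` and the silhouette is undefined (`NA`), which
#' excludes it from model selection.
#'
#' @param matrix A [similarity_matrix()].
#' @param partition A membership vector over the matrix's elements.
#' @return The mean silhouette over all elements, or `NA` for a
#'   single-cluster partition. The per-element scores are attached as
#'   attribute `"elements"`.
#' @export
silhouette_width <- function(matrix, partition) {
  m <- as_similarity(matrix)
  g <- align_partition(m, partition)
  v <- sim_values(m)
  n <- nrow(v)
  k <- max(g)
  if (k < 2) return(NA_real_)
  sizes <- tabulate(g, k)
  # cs[i, c] = sum of similarities from element i to members of cluster c
  cs <- t(rowsum(v, group = g, reorder = TRUE))
  own_sum <- cs[cbind(seq_len(n), g)] - diag(v)
  a <- ifelse(sizes[g] >= 2, own_sum / (sizes[g] - 1), NA_real_)
  other <- cs / rep(sizes, each = n)
  other[cbind(seq_len(n), g)] <- -Inf
  b <- other[cbind(seq_len(n), max.col(other, ties.method = "first"))]
  s_max <- max(v[upper.tri(v)])
  # the zero-denominator convention is applied with a hair of relative
  # slack: on an (effectively) constant matrix both a and b equal s_max up
  # to summation noise, and the 0/0 limit must score 0, not +/-1
  tol <- 1e-12 * max(1, abs(s_max))
  denom <- s_max - pmin(a, b)
  si <- ifelse(denom > tol, (a - b) / denom, 0)
  si[sizes[g] < 2] <- 0
  structure(mean(si), elements = stats::setNames(si, rownames(m)))
}

#' Rand index between two partitions
#'
#' The fraction of unordered element pairs on which the two partitions
#' agree: both co-clustered or both separated. 1 means identical
#' partitions. Computed from the k1 x k2 contingency table in O(n + k1 k2).
#'
#' @param p1,p2 Membership vectors over the same elements. When both carry
#'   element names the vectors are aligned by name.
#' @return The Rand index, in \[0, 1\].
#' @export
rand_index <- function(p1, p2) {
  g1 <- as_partition(p1)
  g2 <- as_partition(p2)
  if (length(g1) != length(g2))
    pf_stop("partitions are over different numbers of elements",
            "pfclust_argument_error")
  if (!is.null(names(g1)) && !is.null(names(g2))) {
    if (!setequal(names(g1), names(g2)))
      pf_stop("partitions are over different element sets",
              "pfclust_argument_error")
    g2 <- g2[names(g1)]
  }
  n <- length(g1)
  if (n < 2)
    pf_stop("need at least 2 elements to compare partitions",
            "pfclust_argument_error")
  tab <- table(g1, g2)
  sum_sq <- sum(tab^2)
  a_rows <- sum(rowSums(tab)^2)
  b_cols <- sum(colSums(tab)^2)
  total <- n * (n - 1) / 2
  agreements <- total + sum_sq - (a_rows + b_cols) / 2
  agreements / total
}

#' Select the best clustering by silhouette width
#'
#' Returns the candidate with the largest defined silhouette; ties are
#' broken by fewer clusters, then by lower threshold.
#'
#' @param candidates A list of clustering candidates, each a list with
#'   `partition`, `threshold` and `silhouette` (as produced inside
#'   [run_pfclust()]).
#' @return The winning candidate (a `pfclust_candidate`).
#' @export
select_best <- function(candidates) {
  if (!length(candidates))
    pf_stop("no candidates", "pfclust_argument_error")
  sil <- vapply(candidates, function(x) as.numeric(x$silhouette)[1],
                numeric(1))
  defined <- which(!is.na(sil))
  if (!length(defined))
    pf_stop("no candidate has a defined silhouette (all single-cluster)",
            "pfclust_selection_error")
  k <- vapply(candidates, function(x) n_clusters(x$partition), numeric(1))
  thr <- vapply(candidates, function(x) as.numeric(x$threshold), numeric(1))
  ord <- order(-sil[defined], k[defined], thr[defined])
  candidates[[defined[ord[1]]]]
}

new_candidate <- function(partition, threshold, silhouette) {
  structure(list(partition = partition, threshold = threshold,
                 silhouette = as.numeric(silhouette),
                 n_clusters = n_clusters(partition)),
            class = "pfclust_candidate")
}

#' @export
print.pfclust_candidate <- function(x, ...) {
  cat(sprintf("clustering: %d clusters at threshold %.6g, silhouette %s\n",
              x$n_clusters, x$threshold,
              if (is.na(x$silhouette)) "undefined"
              else sprintf("%.4f", x$silhouette)))
  invisible(x)
}

#' Run the full parameter-free clustering procedure
#'
#' The outer loop of the algorithm. Each round: (1) estimate candidate
#' thresholds from the random-partition similarity distribution
#' ([estimate_thresholds()]); (2) cluster the matrix once per threshold
#' ([cluster_at_threshold()]) — the clusterings are independent of each
#' other and are run concurrently when `workers > 1`, with results
#' identical to sequential execution; (3) score every candidate by
#' [silhouette_width()] and pick the round winner. Rounds repeat until the
#' Rand index between consecutive round winners reaches `convergence_ri`
#' (checked from round `rounds_min` on, so at least `rounds_min` combined
#' randomisation-plus-clustering rounds always run), or until `rounds_max`.
#' The final answer is the best candidate across all rounds.
#'
#' If no candidate in any round produces a partition with at least two
#' clusters, the single-cluster partition is returned with a warning and an
#' undefined silhouette.
#'
#' @param matrix A [similarity_matrix()].
#' @param rounds Randomisation rounds per threshold estimation (default
#'   1000).
#' @param top_fraction,n_thresholds See [estimate_thresholds()].
#' @param rounds_min,rounds_max Minimum / maximum outer rounds (defaults 4
#'   and 10).
#' @param convergence_ri Rand-index level between consecutive round winners
#'   that counts as converged (default 0.99).
#' @param workers Number of parallel workers for the per-threshold
#'   clusterings (forked processes; ignored on platforms without fork).
#' @param seed Optional integer seed; when given, the run is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param verbose Print per-round progress to standard error.
#' @return A `pfclust_result`: list with `best` (the winning candidate:
#'   `partition`, `threshold`, `silhouette`, `n_clusters`), `rounds` (one
#'   entry per round: the `threshold_estimate`, all candidates, the round
#'   winner index), `n_rounds`, `converged`, and `convergence_trace` (Rand
#'   index between consecutive round winners).
#' @export
#' @examples
#' s <- block_similarity(c(5, 5, 5), within = 0.9, between = 0.1)
#' res <- run_pfclust(s, rounds = 400, seed = 1)
#' res$best$n_clusters
run_pfclust <- function(matrix, rounds = 1000L, top_fraction = 0.05,
                        n_thresholds = 20L, rounds_min = 4L,
                        rounds_max = 10L, convergence_ri = 0.99,
                        workers = 1L, seed = NULL, verbose = FALSE) {
  m <- as_similarity(matrix)
  rounds_min <- as.integer(rounds_min)
  rounds_max <- as.integer(rounds_max)
  if (rounds_min < 1L || rounds_max < rounds_min)
    pf_stop("need 1 <= rounds_min <= rounds_max", "pfclust_argument_error")
  if (!is.numeric(convergence_ri) || convergence_ri < 0 || convergence_ri > 1)
    pf_stop("`convergence_ri` must be in [0, 1]", "pfclust_argument_error")
  workers <- max(1L, as.integer(workers))

  with_local_seed(seed, {
    round_log <- list()
    winners <- list()
    trace <- numeric(0)
    converged <- FALSE
    for (r in seq_len(rounds_max)) {
      est <- estimate_thresholds(m, rounds = rounds, top_fraction = top_fraction,
                                 n_thresholds = n_thresholds)
      cands <- cluster_thresholds(m, est$thresholds, workers)
      winner <- tryCatch(select_best(cands),
                         pfclust_selection_error = function(e) NULL)
      round_log[[r]] <- list(estimate = est, candidates = cands,
                             winner = winner)
      winners[r] <- list(winner)  # may be NULL: keep the slot
      if (verbose)
        message(sprintf(
          "round %d: thresholds [%.4g, %.4g], winner %s", r,
          min(est$thresholds), max(est$thresholds),
          if (is.null(winner)) "none (all single-cluster)"
          else sprintf("k=%d sil=%.4f", winner$n_clusters, winner$silhouette)))
      if (r >= 2) {
        ri <- if (is.null(winners[[r]]) || is.null(winners[[r - 1L]]))
          NA_real_
        else rand_index(winners[[r]]$partition, winners[[r - 1L]]$partition)
        trace <- c(trace, ri)
        if (r >= rounds_min && !is.na(ri) && ri >= convergence_ri) {
          converged <- TRUE
          break
        }
      }
    }
    all_cands <- unlist(lapply(round_log, `[[`, "candidates"),
                        recursive = FALSE)
    best <- tryCatch(select_best(all_cands),
                     pfclust_selection_error = function(e) NULL)
    if (is.null(best)) {
      warning("no multi-cluster candidate found; returning the single-cluster partition")
      g <- as_partition(rep(1L, nrow(m)), labels = rownames(m))
      best <- new_candidate(g, NA_real_, NA_real_)
    }
    structure(list(best = best, rounds = round_log,
                   n_rounds = length(round_log), converged = converged,
                   convergence_trace = trace),
              class = "pfclust_result")
  })
}

# One clustering per distinct threshold (the per-threshold runs are
# deterministic, so duplicates are computed once and the results shared).
cluster_thresholds <- function(m, thresholds, workers) {
  v <- sim_values(m)
  uniq <- unique(thresholds)
  one <- function(th) {
    res <- cpp_cluster_at_threshold(v, th, 100L)
    g <- res$assignment
    names(g) <- rownames(m)
    new_candidate(g, th, silhouette_width(m, g))
  }
  use_fork <- workers > 1L && .Platform$OS.type == "unix"
  uniq_res <- if (use_fork) {
    parallel::mclapply(uniq, one, mc.cores = workers)
  } else {
    lapply(uniq, one)
  }
  uniq_res[match(thresholds, uniq)]
}

#' @export
print.pfclust_result <- function(x, ...) {
  cat(sprintf("pfclust result: %d rounds (%s)\n", x$n_rounds,
              if (isTRUE(x$converged)) "converged" else "round cap reached"))
  cat("best ")
  print(x$best)
  sizes <- table(x$best$partition)
  cat(sprintf("cluster sizes: %s\n", paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}
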