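# Synthetic labelled 2D datasets with known ground truth. The generators
# draw from R's global random-number stream: wrap calls in set.seed() (or
# use the `seed` argument of simulate_benchmark()) for reproducibility.

new_dataset <- function(coords, truth, spec) {
  n <- nrow(coords)
  labels <- paste0("p", seq_len(n))
  points <- data.frame(label = labels,
                       x = coords[, 1], y = coords[, 2],
                       truth = truth,
                       stringsAsFactors = FALSE)
  structure(list(points = points,
                 truth = as_partition(truth, labels = labels),
                 spec = spec),
            class = "pfclust_dataset")
}

#' @export
print.pfclust_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset '%s': %d points, %d true clusters\n",
              if (is.null(x$spec$name)) x$spec$kind else x$spec$name,
              nrow(x$points), n_clusters(x$truth)))
  invisible(x)
}

#' Generate isotropic Gaussian blobs
#'
#' Cluster c contributes `sizes[c]` points drawn from an isotropic normal
#' around `centers[c, ]` with standard deviation `sds[c]`; the ground truth
#' records the generating cluster. Sizes, centres and spreads are free, so
#' the family covers clusters of arbitrary sizes and densities.
#'
#' @param sizes Integer vector of per-cluster point counts.
#' @param centers Numeric k x 2 matrix of cluster centres.
#' @param sds Per-cluster standard deviations (positive).
#' @return A `pfclust_dataset`: list with `points` (a point-table data frame
#'   with columns label, x, y, truth), `truth` (the ground-truth partition)
#'   and `spec` (the generating parameters).
#' @export
#' @examples
#' set.seed(1)
#' d <- generate_blobs(c(50, 50), rbind(c(-5, 0), c(5, 0)), c(1, 1))
#' table(d$truth)
generate_blobs <- function(sizes, centers, sds) {
  centers <- rbind(centers)
  k <- length(sizes)
  if (k < 1 || nrow(centers) != k || length(sds) != k)
    pf_stop("`sizes`, `centers` and `sds` must describe the same number of clusters",
            "pfclust_argument_error")
  if (any(sizes < 1) || any(sds <= 0))
    pf_stop("`sizes` must be positive counts and `sds` positive",
            "pfclust_argument_error")
  coords <- do.call(rbind, lapply(seq_len(k), function(c) {
    cbind(rnorm(sizes[c], centers[c, 1], sds[c]),
          rnorm(sizes[c], centers[c, 2], sds[c]))
  }))
  new_dataset(coords, rep.int(seq_len(k), sizes),
              list(kind = "blobs", sizes = sizes, centers = centers,
                   sds = sds))
}

#' Generate non-convex and density-contrast shapes
#'
#' Shape families beyond isotropic blobs:
#' \describe{
#'   \item{ring}{`n` points at angles uniform on the circle, radius
#'     `radius` plus normal noise `radial_sd`; one truth cluster.}
#'   \item{elongated}{an anisotropic Gaussian with axis standard deviations
#'     `axis_sds` (ratio at least 5 for a clearly elongated shape), rotated
#'     by `rotation` radians about `center`; one truth cluster.}
#'   \item{mixed_density}{two isotropic blobs whose spreads differ by the
#'     ratio `sds[2] / sds[1]` (at least 4); two truth clusters.}
#' }
#'
#' @param kind One of `"ring"`, `"elongated"`, `"mixed_density"`.
#' @param n Point count (total; split evenly for `mixed_density` unless
#'   `sizes` is given).
#' @param center Shape centre (ring, elongated).
#' @param radius Ring radius.
#' @param radial_sd Ring radial noise standard deviation.
#' @param axis_sds Length-2 axis standard deviations (elongated).
#' @param rotation Rotation in radians (elongated).
#' @param centers 2 x 2 matrix of blob centres (mixed_density).
#' @param sds Length-2 blob spreads (mixed_density).
#' @param sizes Optional length-2 blob sizes (mixed_density).
#' @return A `pfclust_dataset` (see [generate_blobs()]).
#' @export
generate_shapes <- function(kind, n = 200L,
                            center = c(0, 0), radius = 10, radial_sd = 0.5,
                            axis_sds = c(5, 0.5), rotation = 0,
                            centers = rbind(c(-8, 0), c(8, 0)),
                            sds = c(0.5, 2), sizes = NULL) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("ring", "elongated", "mixed_density"))
    pf_stop(sprintf("unknown shape kind '%s'", as.character(kind)[1]),
            "pfclust_config_error")
  n <- as.integer(n)
  if (n < 2) pf_stop("`n` must be at least 2", "pfclust_argument_error")
  if (kind == "ring") {
    theta <- runif(n, 0, 2 * pi)
    r <- radius + rnorm(n, 0, radial_sd)
    coords <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
    new_dataset(coords, rep(1L, n),
                list(kind = kind, n = n, center = center, radius = radius,
                     radial_sd = radial_sd))
  } else if (kind == "elongated") {
    raw <- cbind(rnorm(n, 0, axis_sds[1]), rnorm(n, 0, axis_sds[2]))
    rot <- matrix(c(cos(rotation), sin(rotation),
                    -sin(rotation), cos(rotation)), 2, 2)
    coords <- sweep(raw %*% t(rot), 2, center, "+")
    new_dataset(coords, rep(1L, n),
                list(kind = kind, n = n, center = center,
                     axis_sds = axis_sds, rotation = rotation))
  } else {
    if (is.null(sizes)) sizes <- c(ceiling(n / 2), floor(n / 2))
    d <- generate_blobs(sizes, centers, sds)
    d$spec <- list(kind = kind, sizes = sizes, centers = rbind(centers),
                   sds = sds)
    d
  }
}

# The frozen benchmark suite: seven named dataset specifications spanning
# 2-10 clusters and 100-5000 points, plus ring, elongated and
# density-contrast cases, in the spirit of the 2D-vector benchmarks the
# algorithm was originally demonstrated on.
benchmark_suite_specs <- function() {
  circle <- function(k, r) {
    ang <- 2 * pi * (seq_len(k) - 1) / k
    cbind(r * cos(ang), r * sin(ang))
  }
  list(
    blobs2_100 = list(kind = "blobs", sizes = c(50L, 50L),
                      centers = rbind(c(-5, 0), c(5, 0)), sds = c(1, 1)),
    blobs4_400 = list(kind = "blobs", sizes = rep(100L, 4),
                      centers = rbind(c(10, 10), c(10, -10),
                                      c(-10, 10), c(-10, -10)),
                      sds = rep(1, 4)),
    mixed_density_300 = list(kind = "mixed_density", sizes = c(150L, 150L),
                             centers = rbind(c(-8, 0), c(8, 0)),
                             sds = c(0.5, 2)),
    ring_core_400 = list(kind = "ring_core", n_ring = 300L, n_core = 100L,
                         radius = 10, radial_sd = 0.5, core_sd = 1),
    elongated2_500 = list(kind = "elongated2", sizes = c(250L, 250L),
                          centers = rbind(c(0, -8), c(0, 8)),
                          axis_sds = c(5, 0.5), rotation = 0),
    blobs10_1000 = list(kind = "blobs", sizes = rep(100L, 10),
                        centers = circle(10, 20), sds = rep(1, 10)),
    blobs5_5000 = list(kind = "blobs", sizes = rep(1000L, 5),
                       centers = circle(5, 20), sds = rep(1, 5))
  )
}

#' Names of the frozen benchmark suite
#'
#' Seven synthetic dataset specifications with known ground truth, spanning
#' 2 to 10 clusters and 100 to 5000 points: Gaussian blob layouts of
#' increasing size, a density-contrast pair, a ring with a central core,
#' and a pair of elongated clusters.
#'
#' @return Character vector of specification names, usable with
#'   [simulate_benchmark()].
#' @export
benchmark_names <- function() names(benchmark_suite_specs())

#' Simulate a benchmark dataset
#'
#' Instantiates one of the frozen suite specifications ([benchmark_names()])
#' or a custom specification list with the same fields.
#'
#' @param spec A suite name or a specification list (field `kind` plus the
#'   generator parameters; see [generate_blobs()] and [generate_shapes()]).
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @return A `pfclust_dataset`.
#' @export
#' @examples
#' d <- simulate_benchmark("blobs4_400", seed = 1)
#' nrow(d$points)
simulate_benchmark <- function(spec, seed = NULL) {
  if (is.character(spec)) {
    all <- benchmark_suite_specs()
    if (length(spec) != 1L || !spec %in% names(all))
      pf_stop(sprintf("unknown benchmark '%s' (known: %s)",
                      spec[1], paste(names(all), collapse = ", ")),
              "pfclust_config_error")
    name <- spec
    spec <- all[[spec]]
    spec$name <- name
  }
  if (!is.list(spec) || is.null(spec$kind))
    pf_stop("`spec` must be a suite name or a list with a `kind` field",
            "pfclust_config_error")
  with_local_seed(seed, {
    d <- switch(spec$kind,
      blobs = generate_blobs(spec$sizes, spec$centers, spec$sds),
      mixed_density = generate_shapes("mixed_density", sizes = spec$sizes,
                                      centers = spec$centers, sds = spec$sds),
      ring_core = {
        ring <- generate_shapes("ring", n = spec$n_ring, radius = spec$radius,
                                radial_sd = spec$radial_sd)
        core <- generate_blobs(spec$n_core, rbind(c(0, 0)), spec$core_sd)
        combine_datasets(list(ring, core), spec)
      },
      elongated2 = {
        parts <- lapply(1:2, function(i)
          generate_shapes("elongated", n = spec$sizes[i],
                          center = spec$centers[i, ],
                          axis_sds = spec$axis_sds,
                          rotation = spec$rotation))
        combine_datasets(parts, spec)
      },
      pf_stop(sprintf("unknown dataset kind '%s'", spec$kind),
              "pfclust_config_error"))
    d$spec <- spec
    d
  })
}

combine_datasets <- function(parts, spec) {
  coords <- do.call(rbind, lapply(parts, function(d)
    cbind(d$points$x, d$points$y)))
  truth <- unlist(lapply(seq_along(parts), function(i)
    rep(i, nrow(parts[[i]]$points))))
  new_dataset(coords, truth, spec)
}
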