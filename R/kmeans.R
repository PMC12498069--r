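#' Seeded K-means clustering with restarts
#'
#' Lloyd's algorithm on Euclidean distance, run `n_restarts` times from
#' random initial centers (k distinct data rows chosen uniformly, or
#' k-means++ seeding) and keeping the run with the lowest distortion.
#' Distortion is the sum over points of squared Euclidean distance to the
#' assigned center. Iteration stops when assignments stabilise or after
#' `max_iter` iterations (default 10,000). Exact distance ties — possible
#' with binary data — are broken toward the lowest cluster index, and an
#' emptied cluster is repaired by re-seeding it with the point farthest
#' from its current center, so k never shrinks. Results are bit-for-bit
#' reproducible for a given seed.
#'
#' @param x numeric matrix (rows = observations), e.g. an [build_matrix()]
#'   result.
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param max_iter Lloyd iteration cap per restart (default 10000).
#' @param n_restarts independent restarts (default 100).
#' @param seed integer RNG seed (required, for reproducibility).
#' @param init `"random-points"` (default) or `"plusplus"`.
#' @return An object of class `sses_kmeans`: list with `assignments`
#'   (named integer vector), `centers` (k x ncol matrix), `distortion`,
#'   `n_iter`, `converged`, `distortion_trace` (per-iteration distortions
#'   of the winning restart), and `restart_distortions`.
#' @export
sses_kmeans <- function(x, k, max_iter = 10000L, n_restarts = 100L,
                        seed = 1L, init = c("random-points", "plusplus")) {
  init <- match.arg(init)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
  stopifnot(k >= 1L, max_iter >= 1L, n_restarts >= 1L)
  set.seed(seed)
  best <- NULL
  restart_distortions <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    centers <- init_centers(x, k, init)
    run <- lloyd(x, centers, max_iter)
    restart_distortions[r] <- run$distortion
    if (is.null(best) || run$distortion < best$distortion) best <- run
  }
  best$assignments <- stats::setNames(best$assignments, rownames(x))
  best$restart_distortions <- restart_distortions
  best$k <- k
  best$seed <- seed
  class(best) <- "sses_kmeans"
  best
}

#' @export
print.sses_kmeans <- function(x, ...) {
  cat("K-means: k =", x$k, " distortion =", format(x$distortion),
      " iterations =", x$n_iter,
      if (x$converged) "(converged)\n" else "(iteration cap hit)\n")
  invisible(x)
}

init_centers <- function(x, k, init) {
  n <- nrow(x)
  if (init == "random-points") {
    # sample k distinct rows; with duplicated rows this can still give
    # coincident centers, which Lloyd's empty-cluster repair handles
    return(x[sample.int(n, k), , drop = FALSE])
  }
  # k-means++: iteratively sample proportional to squared distance
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[idx[1L], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE]
}

# squared Euclidean distances from every row of x to every center row
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(-2 * cross, 2L, rowSums(centers^2), "+") + rowSums(x^2)
}

lloyd <- function(x, centers, max_iter) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_old <- integer(0)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(x, centers)
    assignments <- max.col(-d2, ties.method = "first")
    # repair any emptied cluster with the globally farthest point
    repeat {
      sizes <- tabulate(assignments, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      cur <- d2[cbind(seq_len(n), assignments)]
      donor <- which.max(cur)
      # fewer distinct rows than k: nothing can seed the empty cluster,
      # leave it empty rather than cycling
      if (cur[donor] <= 0) break
      centers[empty[1L], ] <- x[donor, ]
      d2[, empty[1L]] <- colSums((t(x) - centers[empty[1L], ])^2)
      assignments[donor] <- empty[1L]
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), assignments)]))
    if (identical(assignments, assign_old)) {
      converged <- TRUE
      break
    }
    assign_old <- assignments
    if (iter >= max_iter) break
    sizes <- tabulate(assignments, nbins = k)
    present <- sort(unique(assignments))
    centers[present, ] <- rowsum(x, assignments) / sizes[present]
  }
  distortion <- sum((x - centers[assignments, , drop = FALSE])^2)
  rownames(centers) <- NULL
  list(assignments = assignments, centers = centers,
       distortion = distortion, n_iter = iter, converged = converged,
       distortion_trace = trace)
}

#' Recompute a clustering's distortion from scratch
#'
#' @param x the data matrix.
#' @param result an `sses_kmeans` object.
#' @return Sum of squared Euclidean distances of each point to its
#'   assigned center.
#' @export
distortion_of <- function(x, result) {
  x <- as.matrix(x)
  sum((x - result$centers[result$assignments, , drop = FALSE])^2)
}

#' Elbow scan over candidate cluster counts
#'
#' Runs [sses_kmeans()] for every k in `k_range` (best of restarts) and
#' estimates the elbow as the k with the largest discrete second difference
#' of the distortion curve. The estimate is a diagnostic only: the study
#' design fixes K at 3, 6 and 18 by combining the elbow with prior
#' distribution-type divisions, and callers are expected to do the same.
#'
#' @inheritParams sses_kmeans
#' @param k_range sorted integer vector of candidate k.
#' @return Object of class `sses_elbow`: list with `k_values`,
#'   `distortions`, `knee_estimate` (`NA` when `length(k_range) < 3`).
#' @export
elbow_scan <- function(x, k_range, max_iter = 10000L, n_restarts = 20L,
                       seed = 1L, init = "random-points") {
  stopifnot(!is.unsorted(k_range), all(k_range >= 1L),
            all(k_range <= nrow(x)))
  distortions <- vapply(
    seq_along(k_range),
    function(i) {
      sses_kmeans(x, k_range[i], max_iter = max_iter,
                  n_restarts = n_restarts, seed = seed + i,
                  init = init)$distortion
    },
    numeric(1L)
  )
  out <- list(
    k_values = as.integer(k_range),
    distortions = distortions,
    knee_estimate = knee_from_distortions(k_range, distortions)
  )
  class(out) <- "sses_elbow"
  out
}

#' @rdname elbow_scan
#' @param distortions distortion value per element of `k_range`.
#' @export
knee_from_distortions <- function(k_range, distortions) {
  if (length(k_range) < 3L) return(NA_integer_)
  m <- length(distortions)
  second_diff <- distortions[1:(m - 2)] - 2 * distortions[2:(m - 1)] +
    distortions[3:m]
  as.integer(k_range[which.max(second_diff) + 1L])
}

#' Cluster composition against a reference labelling
#'
#' For every cluster, tallies the fraction of member families carrying each
#' reference label and identifies the majority label — the statistic behind
#' statements like "97.93% of families of Cluster 2 were tropical".
#'
#' @param result an `sses_kmeans` object (or a named assignment vector).
#' @param reference named vector mapping every family to a label.
#' @return List with `fractions` (clusters x labels percentage matrix),
#'   `majority` (data frame `cluster`, `label`, `percent`, `n`).
#' @export
composition_report <- function(result, reference) {
  assignments <- if (inherits(result, "sses_kmeans")) {
    result$assignments
  } else {
    result
  }
  if (!all(names(assignments) %in% names(reference))) {
    stop("reference labelling does not cover all families")
  }
  ref <- reference[names(assignments)]
  tab <- table(cluster = assignments, label = ref)
  frac <- 100 * sweep(unclass(tab), 1L, rowSums(tab), "/")
  maj <- apply(frac, 1L, which.max)
  majority <- data.frame(
    cluster = as.integer(rownames(tab)),
    label = colnames(frac)[maj],
    percent = frac[cbind(seq_len(nrow(frac)), maj)],
    n = as.integer(rowSums(tab)),
    stringsAsFactors = FALSE
  )
  list(fractions = frac, majority = majority)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (matched by name when both are
#'   named).
#' @return The adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Align cluster indices to a reference partition
#'
#' Relabels clusters by a one-to-one maximum-agreement matching with a
#' reference partition (greedy on the contingency table), for reporting
#' planted-structure recovery.
#'
#' @param assignments named integer cluster vector.
#' @param reference named reference labels.
#' @return Named vector of reference labels, one per family, after
#'   matching; attribute `"mapping"` gives cluster -> label.
#' @export
align_partitions <- function(assignments, reference) {
  ref <- reference[names(assignments)]
  tab <- table(assignments, ref)
  clusters <- rownames(tab)
  labels <- colnames(tab)
  mapping <- stats::setNames(rep(NA_character_, length(clusters)), clusters)
  work <- unclass(tab)
  while (any(!is.na(work))) {
    ij <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    mapping[clusters[ij[1L]]] <- labels[ij[2L]]
    work[ij[1L], ] <- NA
    work[, ij[2L]] <- NA
    if (all(is.na(mapping)) || sum(!is.na(mapping)) ==
        min(length(clusters), length(labels))) break
  }
  out <- mapping[as.character(assignments)]
  names(out) <- names(assignments)
  attr(out, "mapping") <- mapping
  out
}
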