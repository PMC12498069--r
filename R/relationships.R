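#' Type-center matrix by the 56 percent rule
#'
#' A region is a center of a distribution type when at least `threshold`
#' (default 56 percent, inclusive) of the type's families have that region
#' flagged as a distribution center in the family-level matrix. The rule is
#' applied uniformly to the three zone columns and the seven continent
#' columns. The resulting binary types x 10 matrix is the input to the
#' linkage and ordination analyses that validate the element/supertype
#' structure.
#'
#' @param classification an `sses_classification`.
#' @param family_matrix the binary families x 10 matrix
#'   ([build_matrix()]).
#' @param threshold center fraction, default `0.56`.
#' @return Binary integer matrix (types present x 10) of class
#'   `sses_type_matrix` with attribute `threshold_used`.
#' @export
type_center_matrix <- function(classification, family_matrix,
                               threshold = 0.56) {
  missing <- setdiff(classification$family, rownames(family_matrix))
  if (length(missing) > 0L) {
    stop("classified family/families without a matrix row: ",
         paste(missing, collapse = ", "))
  }
  types <- intersect(sses_catalog()$types$id, unique(classification$type))
  rows <- lapply(types, function(ty) {
    fams <- classification$family[classification$type == ty]
    if (length(fams) == 0L) stop("type ", ty, " has zero families")
    as.integer(colMeans(family_matrix[fams, , drop = FALSE]) >= threshold)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- types
  colnames(m) <- colnames(family_matrix)
  storage.mode(m) <- "integer"
  attr(m, "threshold_used") <- threshold
  class(m) <- c("sses_type_matrix", class(m))
  m
}

#' Euclidean distances between matrix rows
#'
#' @param m numeric matrix.
#' @return A `dist` object (use `as.matrix()` for the full symmetric
#'   matrix).
#' @export
euclidean_distances <- function(m) {
  stats::dist(unclass(m), method = "euclidean")
}

sses_linkage_methods <- c("UPGMA", "UPGMC", "ward.D2", "single",
                          "complete", "WPGMA", "WPGMC")

hclust_method_of <- c(
  UPGMA = "average", UPGMC = "centroid", ward.D2 = "ward.D2",
  single = "single", complete = "complete", WPGMA = "mcquitty",
  WPGMC = "median"
)

#' Agglomerative clustering under one of seven linkage algorithms
#'
#' Runs standard Lance--Williams agglomeration (via [stats::hclust()]) for
#' the method named: UPGMA (size-weighted average), WPGMA (plain average of
#' the two merged clusters' distances), single, complete, ward.D2, and the
#' two centroid methods UPGMC/WPGMC. The centroid methods follow the usual
#' convention of agglomerating squared Euclidean distances; their merge
#' heights and cophenetic distances are reported back on the original
#' distance scale.
#'
#' @param D a `dist` object or symmetric distance matrix.
#' @param method one of `"UPGMA"`, `"UPGMC"`, `"ward.D2"`, `"single"`,
#'   `"complete"`, `"WPGMA"`, `"WPGMC"`.
#' @return Object of class `sses_dendrogram`: list with the underlying
#'   `hclust` object, `method`, and `cophenetic` (a `dist` of cophenetic
#'   distances on the input scale).
#' @export
agglomerate <- function(D, method = sses_linkage_methods) {
  method <- match.arg(method)
  D <- as_dist_checked(D)
  squared <- method %in% c("UPGMC", "WPGMC")
  hc <- stats::hclust(if (squared) D^2 else D,
                      method = hclust_method_of[[method]])
  coph <- stats::cophenetic(hc)
  if (squared) {
    # centroid methods can produce small negative heights on reversals
    coph <- sqrt(pmax(coph, 0))
    hc$height <- sqrt(pmax(hc$height, 0))
  }
  structure(list(hclust = hc, method = method, cophenetic = coph),
            class = "sses_dendrogram")
}

as_dist_checked <- function(D) {
  if (inherits(D, "dist")) return(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  stats::as.dist(D)
}

#' @export
print.sses_dendrogram <- function(x, ...) {
  cat("Agglomerative dendrogram (", x$method, "), ",
      length(x$hclust$labels %||% x$hclust$order), " leaves\n", sep = "")
  invisible(x)
}

#' Cophenetic correlation between a distance matrix and a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (first-merge heights) of the dendrogram. Values
#' near 1 mean the dendrogram faithfully represents the distances.
#'
#' @param D the original `dist` (or symmetric matrix).
#' @param dendrogram an [agglomerate()] result.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(D, dendrogram) {
  D <- as_dist_checked(D)
  n <- attr(D, "Size")
  if (n < 3L) stop("cophenetic correlation needs at least 3 leaves")
  stats::cor(as.vector(D), as.vector(dendrogram$cophenetic))
}

#' Gower's goodness-of-fit distance of a dendrogram
#'
#' Sum over leaf pairs of the squared difference between original and
#' cophenetic distances; 0 for a dendrogram that reproduces the input
#' exactly, smaller is better.
#'
#' @inheritParams cophenetic_correlation
#' @return Non-negative real.
#' @export
gower_distance <- function(D, dendrogram) {
  D <- as_dist_checked(D)
  if (attr(D, "Size") < 3L) stop("Gower distance needs at least 3 leaves")
  sum((as.vector(D) - as.vector(dendrogram$cophenetic))^2)
}

#' Run all seven linkage algorithms and select the best
#'
#' Each method is scored by cophenetic correlation (higher is better) and
#' Gower's goodness-of-fit distance (lower is better). Selection is by
#' maximum cophenetic correlation; exact ties fall back to minimum Gower
#' distance, then to the fixed method order.
#'
#' @param D a `dist` or symmetric distance matrix.
#' @return Object of class `sses_selection`: list with `table` (data frame
#'   `method`, `cophenetic_correlation`, `gower_distance`), `selected`,
#'   and `dendrograms` (named list of [agglomerate()] results).
#' @export
select_algorithm <- function(D) {
  D <- as_dist_checked(D)
  dendrograms <- lapply(sses_linkage_methods, function(m) agglomerate(D, m))
  names(dendrograms) <- sses_linkage_methods
  r <- vapply(dendrograms, function(dd) cophenetic_correlation(D, dd),
              numeric(1L))
  g <- vapply(dendrograms, function(dd) gower_distance(D, dd), numeric(1L))
  tol <- 1e-12
  best_r <- max(r)
  cand <- which(r >= best_r - tol)
  if (length(cand) > 1L) {
    cand <- cand[g[cand] <= min(g[cand]) + tol]
  }
  selected <- sses_linkage_methods[cand[1L]]
  structure(
    list(
      table = data.frame(method = sses_linkage_methods,
                         cophenetic_correlation = unname(r),
                         gower_distance = unname(g),
                         stringsAsFactors = FALSE),
      selected = selected,
      dendrograms = dendrograms
    ),
    class = "sses_selection"
  )
}

#' @export
print.sses_selection <- function(x, ...) {
  print(x$table)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Cut a dendrogram into a fixed number of groups
#'
#' @param dendrogram an [agglomerate()] result.
#' @param n_groups number of groups (1 to number of leaves).
#' @return Named integer vector leaf -> group.
#' @export
grouping_from_dendrogram <- function(dendrogram, n_groups) {
  stats::cutree(dendrogram$hclust, k = n_groups)
}

#' Non-metric multidimensional scaling with multi-start stress minimisation
#'
#' Minimises Kruskal stress-1 (primary tie treatment) for a `dims`-
#' dimensional configuration, taking the best of `n_starts` fits: one
#' started from the metric (principal-coordinates) configuration and the
#' rest from random Gaussian configurations. The engine is
#' [vegan::monoMDS()] — monotone regression of disparities on the rank
#' order of the input distances — which is also how the reported non-metric
#' fit is defined: `r_squared = 1 - stress^2`. The squared linear
#' correlation between input distances and configuration distances is
#' reported alongside as `linear_r_squared`.
#'
#' @param D a `dist` or symmetric distance matrix.
#' @param dims embedding dimension (default 2).
#' @param n_starts number of starts (default 20).
#' @param seed RNG seed for the random starts.
#' @param tol convergence tolerance passed to the engine (default `1e-7`).
#' @param maxit iteration cap per start (default 500).
#' @return Object of class `sses_nmds`: list with `coordinates`
#'   (n x dims), `stress` (Kruskal stress-1, in \[0, 1\]), `r_squared`,
#'   `linear_r_squared`, `n_starts`, `seed`, `engine` (the winning
#'   `monoMDS` fit).
#' @export
nmds <- function(D, dims = 2L, n_starts = 20L, seed = 1L, tol = 1e-7,
                 maxit = 500L) {
  D <- as_dist_checked(D)
  n <- attr(D, "Size")
  stopifnot(dims >= 1L, n_starts >= 1L)
  if (max(D) == 0) stop("degenerate input: all distances are zero")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    y <- if (s == 1L) {
      suppressWarnings(stats::cmdscale(D, k = dims))
    } else {
      matrix(stats::rnorm(n * dims), n, dims)
    }
    if (ncol(y) < dims) {
      y <- cbind(y, matrix(stats::rnorm(n * (dims - ncol(y))) * 1e-4,
                           n, dims - ncol(y)))
    }
    fit <- vegan::monoMDS(D, y = y, k = dims, model = "global",
                          maxit = maxit, sratmax = 1 - tol,
                          scores = "sites")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- attr(D, "Labels")
  config_d <- stats::dist(coords)
  structure(
    list(
      coordinates = coords,
      stress = best$stress,
      r_squared = 1 - best$stress^2,
      linear_r_squared = stats::cor(as.vector(D), as.vector(config_d))^2,
      n_starts = n_starts,
      seed = seed,
      engine = best
    ),
    class = "sses_nmds"
  )
}

#' @export
print.sses_nmds <- function(x, ...) {
  cat("NMDS:", ncol(x$coordinates), "dims; stress =", format(x$stress),
      "; r^2 = 1 - stress^2 =", format(x$r_squared), "\n")
  invisible(x)
}

#' Recompute Kruskal stress-1 for a fixed configuration
#'
#' Evaluates the stress of a given configuration against a distance matrix
#' by monotone (isotonic) regression of the configuration distances on the
#' rank order of `D`, with the primary approach to ties (tied input
#' distances are free to take any disparity order). Used to verify that a
#' reported stress is reproducible from the stored coordinates.
#'
#' @param D a `dist` or symmetric matrix.
#' @param coordinates configuration matrix (rows in the order of `D`).
#' @return Kruskal stress-1.
#' @export
stress_from_configuration <- function(D, coordinates) {
  D <- as_dist_checked(D)
  d <- as.vector(D)
  dhat <- as.vector(stats::dist(coordinates))
  # primary ties: within tied d, order by increasing dhat so ties never
  # contribute to the monotonicity violation
  ord <- order(d, dhat)
  fit <- stats::isoreg(dhat[ord])$yf
  sqrt(sum((dhat[ord] - fit)^2) / sum(dhat^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
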