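test_that("the 56% type-center rule has an inclusive boundary", {
  fams <- sprintf("F%02d", 1:23)
  m <- matrix(0L, 23, 10, dimnames = list(fams, region_codes()))
  # type A: 14 families, 8 flagged in asia (57.1% >= 56%)
  m[1:8, "asia"] <- 1L
  # type B: 9 families, 5 flagged in africa (55.6% < 56%)
  m[15:19, "africa"] <- 1L
  cl <- data.frame(
    family = fams,
    type = rep(c("I", "II"), c(14, 9)),
    supertype = rep(c(1L, 2L), c(14, 9)),
    element = rep(c("cosmopolitan", "tropical"), c(14, 9))
  )
  tm <- type_center_matrix(cl, m)
  expect_equal(tm["I", "asia"], 1L)
  expect_equal(tm["II", "africa"], 0L)
  expect_equal(attr(tm, "threshold_used"), 0.56)
})

test_that("type-center matrix equals a brute-force per-cell tally", {
  b <- generate_families(synth_config(seed = 31, n_families = 60))
  m <- build_matrix(b$records)
  cl <- classification_from_truth(b$truth)
  tm <- type_center_matrix(cl, m, threshold = 0.56)
  for (ty in rownames(tm)) {
    fams <- cl$family[cl$type == ty]
    for (rc in region_codes()) {
      frac <- sum(m[fams, rc]) / length(fams)
      expect_identical(tm[ty, rc], as.integer(frac >= 0.56))
    }
  }
})

test_that("euclidean distances match the brute-force double loop", {
  x <- rbind(a = c(1, 0, 1, 0, 1), b = c(0, 1, 1, 1, 0))
  expect_equal(as.numeric(euclidean_distances(x)), 2)
  expect_equal(as.numeric(euclidean_distances(rbind(x[1, ], x[1, ]))), 0)
  set.seed(3)
  y <- matrix(rbinom(180, 1, 0.5), 18, 10)
  D <- as.matrix(euclidean_distances(y))
  for (i in 1:18) for (j in 1:18) {
    expect_equal(D[i, j], sqrt(sum((y[i, ] - y[j, ])^2)))
  }
})

test_that("the 3-leaf linkage example matches the hand computation", {
  D <- tiny_dist3()
  wp <- agglomerate(D, "WPGMA")
  cm <- as.matrix(wp$cophenetic)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 7)  # (8 + 6) / 2
  expect_equal(cm["B", "C"], 7)
  expect_equal(cophenetic_correlation(D, wp), 0.945, tolerance = 5e-4)
  expect_equal(gower_distance(D, wp), 2)  # 0 + 1 + 1
  sl <- agglomerate(D, "single")
  expect_equal(as.matrix(sl$cophenetic)["A", "C"], 6)
  expect_equal(grouping_from_dendrogram(wp, 2),
               c(A = 1L, B = 1L, C = 2L))
  expect_equal(unname(grouping_from_dendrogram(wp, 3)), 1:3)
  expect_equal(length(unique(grouping_from_dendrogram(wp, 1))), 1L)
})

test_that("averaging linkages are fixed points on ultrametric input", {
  # build an ultrametric distance matrix from a nested 4-leaf hierarchy
  U <- matrix(8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  U["a", "b"] <- U["b", "a"] <- 2
  U["c", "d"] <- U["d", "c"] <- 4
  diag(U) <- 0
  for (mth in c("UPGMA", "WPGMA", "single", "complete")) {
    dd <- agglomerate(U, mth)
    expect_equal(as.matrix(dd$cophenetic)[letters[1:4], letters[1:4]], U,
                 tolerance = 1e-12)
    expect_equal(cophenetic_correlation(U, dd), 1)
    expect_equal(gower_distance(U, dd), 0)
  }
})

test_that("cophenetic correlation and Gower match pair-loop oracles", {
  set.seed(12)
  x <- matrix(rnorm(80), 10, 8)
  D <- euclidean_distances(x)
  for (mth in c("UPGMA", "WPGMA", "ward.D2", "WPGMC")) {
    dd <- agglomerate(D, mth)
    d0 <- as.matrix(D); dc <- as.matrix(dd$cophenetic)
    pairs <- which(upper.tri(d0), arr.ind = TRUE)
    o <- d0[pairs]; cph <- dc[pairs]
    expect_equal(cophenetic_correlation(D, dd), stats::cor(o, cph))
    expect_equal(gower_distance(D, dd), sum((o - cph)^2))
  }
  expect_error(cophenetic_correlation(tiny_dist3()[1:2, 1:2],
                                      agglomerate(D, "UPGMA")),
               "3 leaves")
})

test_that("UPGMA and WPGMA cophenetic matrices are ultrametric", {
  set.seed(4)
  x <- matrix(rbinom(120, 1, 0.4), 12, 10)
  D <- euclidean_distances(x)
  for (mth in c("UPGMA", "WPGMA")) {
    cm <- as.matrix(agglomerate(D, mth)$cophenetic)
    n <- nrow(cm)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-9)
    }
  }
})

test_that("selection picks max cophenetic correlation, ties by Gower", {
  set.seed(20)
  x <- matrix(rnorm(60), 10, 6)
  D <- euclidean_distances(x)
  sel <- select_algorithm(D)
  r <- sel$table$cophenetic_correlation
  expect_equal(sel$selected,
               sel$table$method[which.max(r)])
  # perfectly ultrametric input: the averaging methods tie at r = 1 and
  # zero Gower; the tie resolves by fixed method order to UPGMA
  U <- matrix(8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  U["a", "b"] <- U["b", "a"] <- 2
  U["c", "d"] <- U["d", "c"] <- 4
  diag(U) <- 0
  selU <- select_algorithm(U)
  tied <- subset(selU$table, method %in% c("UPGMA", "WPGMA", "single",
                                           "complete"))
  expect_true(all(abs(tied$cophenetic_correlation - 1) < 1e-12))
  expect_true(all(tied$gower_distance < 1e-12))
  expect_equal(selU$selected, "UPGMA")
  # construction favouring WPGMA: its own cophenetic output plus tiny noise
  wp <- agglomerate(euclidean_distances(matrix(rbinom(100, 1, .5), 10)),
                    "WPGMA")
  Dw <- as.matrix(wp$cophenetic)
  set.seed(1)
  noise <- matrix(runif(100, 0, 1e-4), 10); noise <- noise + t(noise)
  diag(noise) <- 0
  selW <- select_algorithm(Dw + noise)
  expect_true(selW$table$cophenetic_correlation[
    selW$table$method == "WPGMA"] > 0.9999)
})

test_that("NMDS recovers embeddable configurations at zero stress", {
  pts3 <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  o3 <- nmds(stats::dist(pts3), n_starts = 3, seed = 1)
  expect_lt(o3$stress, 1e-6)
  set.seed(5)
  pts <- matrix(rnorm(24), 12, 2)
  o <- nmds(stats::dist(pts), n_starts = 5, seed = 2)
  expect_lt(o$stress, 1e-6)
  expect_equal(o$r_squared, 1 - o$stress^2, tolerance = 1e-12)
  expect_error(nmds(matrix(0, 3, 3)), "degenerate")
})

test_that("reported stress is recomputable from the coordinates", {
  b <- generate_families(synth_config(seed = 44, n_families = 80))
  m <- build_matrix(b$records)
  tm <- type_center_matrix(classification_from_truth(b$truth), m)
  D <- euclidean_distances(tm)
  o <- nmds(D, seed = 6)
  expect_equal(stress_from_configuration(D, o$coordinates), o$stress,
               tolerance = 1e-6)
  expect_equal(o$r_squared, 1 - o$stress^2, tolerance = 1e-12)
  # stress is invariant under rotation, translation and uniform scaling
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(3 * o$coordinates %*% R, 2, c(5, -2), "+")
  expect_equal(stress_from_configuration(D, moved), o$stress,
               tolerance = 1e-6)
})

test_that("a stress of 0.09 corresponds to a non-metric fit of 0.9919", {
  expect_equal(1 - 0.09^2, 0.9919)
  expect_equal(round(1 - 0.09^2, 2), 0.99)
})
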