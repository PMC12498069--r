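make_result <- function(centers, families = paste0("F", seq_len(nrow(centers)))) {
  structure(
    list(assignments = stats::setNames(seq_len(nrow(centers)), families),
         centers = centers, k = nrow(centers)),
    class = "sses_kmeans"
  )
}

test_that("a center equal to a catalog signature gets that type", {
  cat429 <- sses_catalog()
  res <- make_result(unclass(cat429$signatures)[c("I", "IX", "XVII"), ])
  cl <- label_clusters(res, cat429)
  expect_equal(cl$type, c("I", "IX", "XVII"))
  expect_equal(cl$provenance, rep("clustered", 3))
  expect_equal(cl$element, c("cosmopolitan", "tropical", "temperate"))
  expect_equal(cl$supertype, c(1L, 2L, 4L))
})

test_that("cluster and family overrides take precedence and are logged", {
  cat429 <- sses_catalog()
  res <- make_result(unclass(cat429$signatures)[c("I", "IX"), ],
                     families = c("Famone", "Famtwo"))
  ov <- sses_overrides(
    cluster_rules = data.frame(cluster = 2L, type = "VII"),
    family_rules = data.frame(family = "Famone", type = "II",
                              rationale = "origin evidence")
  )
  cl <- label_clusters(res, cat429, ov)
  expect_equal(cl$type, c("II", "VII"))
  expect_equal(cl$provenance, c("curated", "overridden"))
  # idempotent under re-application of the same overrides
  cl2 <- label_clusters(res, cat429, ov)
  expect_identical(cl, cl2)
  expect_error(sses_overrides(cluster_rules = data.frame(cluster = 1L,
                                                         type = "XXV")),
               "unknown type")
})

test_that("signature ties raise by default and break by catalog order on request", {
  cat429 <- sses_catalog()
  # midpoint of IV and VI (they differ only in oceania) ties exactly
  center <- (unclass(cat429$signatures)["IV", ] +
               unclass(cat429$signatures)["VI", ]) / 2
  res <- make_result(rbind(center))
  expect_error(label_clusters(res, cat429), "tie")
  expect_warning(cl <- label_clusters(res, cat429,
                                      on_tie = "catalog-order"),
                 "tie")
  expect_equal(cl$type, "IV")
})

test_that("noisy signature-built clusters are labelled mostly correctly", {
  cat429 <- sses_catalog()
  correct <- vapply(1:25, function(s) {
    set.seed(s)
    centers <- t(vapply(1:18, function(j) {
      members <- matrix(rep(unclass(cat429$signatures)[j, ], 20), 20, 10,
                        byrow = TRUE)
      flips <- matrix(rbinom(200, 1, 0.05), 20, 10)
      colMeans(abs(members - flips))
    }, numeric(10)))
    cl <- suppressWarnings(
      label_clusters(make_result(centers), cat429,
                     on_tie = "catalog-order")
    )
    sum(cl$type == cat429$types$id)
  }, numeric(1))
  expect_true(all(correct >= 16))
})

test_that("subtype predicates follow endemic and disjunction defaults", {
  cat429 <- sses_catalog()
  flags_x <- stats::setNames(c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),
                             region_codes())
  expect_equal(assign_subtype(flags_x, "X",
                              list(endemic_area = "New Caledonia")),
               "X.I")
  expect_equal(assign_subtype(flags_x, "X", list(endemic_area = "Fiji")),
               "X.II")
  expect_true(is.na(assign_subtype(flags_x, "X", list())))
  flags_sa <- stats::setNames(c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
                              region_codes())
  expect_equal(assign_subtype(flags_sa, "XVII", list()), "XVII.I")
  expect_true(is.na(assign_subtype(flags_x, "I", list())))  # I: no subtypes
  # pantropic split: African center decides the chain
  flags_afr <- stats::setNames(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
                               region_codes())
  expect_equal(assign_subtype(flags_afr, "II", list()), "II.II")
  flags_noafr <- stats::setNames(c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
                                 region_codes())
  expect_equal(assign_subtype(flags_noafr, "II", list()), "II.I")
})

test_that("roll-ups conserve totals and reproduce the catalog fixture", {
  cat429 <- sses_catalog()
  b <- generate_families(synth_config(seed = 17))
  cl <- classification_from_truth(b$truth)
  ru <- rollup_counts(cl, cat429)
  expect_equal(ru$total, 429L)
  expect_equal(unname(ru$element),
               c(66L, 238L, 125L))
  expect_equal(unname(ru$supertype), c(66L, 158L, 80L, 43L, 52L, 30L))
  expect_equal(unname(ru$type),
               cat429$types$n_families)
  expect_true(all(ru$delta_vs_catalog == 0L))
  # conservation and hierarchy closure on an arbitrary classification
  cl2 <- cl[sample(nrow(cl), 100), ]
  ru2 <- rollup_counts(cl2, cat429)
  expect_equal(ru2$total, 100L)
  expect_equal(sum(ru2$element), sum(ru2$supertype))
  expect_identical(cl2$element, catalog_element(cl2$type))
  # empty classification: all zeros
  ru0 <- rollup_counts(cl[0, ], cat429)
  expect_equal(ru0$total, 0L)
  expect_true(all(ru0$type == 0L))
})
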