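three_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

test_that("phylogenetic covariance encodes shared path lengths and lambda", {
  tr <- three_tip_tree()
  C1 <- phylo_covariance(tr, 1)
  expect_equal(C1[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  C0 <- phylo_covariance(tr, 0)
  expect_equal(unname(C0), diag(c(2, 2, 2)))
  C5 <- phylo_covariance(tr, 0.5)
  expect_equal(C5["A", "B"], 0.5)
  expect_equal(C5["A", "A"], 2)
  expect_error(phylo_covariance(tr, 1.5), "lambda")
  # positive definite across lambda on a bigger ultrametric tree
  tr2 <- small_bd_tree(n = 40, seed = 11)
  for (lam in c(0, 0.3, 0.7, 1)) {
    ev <- eigen(phylo_covariance(tr2, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("Blomberg's K matches the reference implementation", {
  skip_if_not_installed("phytools")
  tr <- small_bd_tree(n = 60, seed = 5)
  for (lam in c(0.2, 0.9)) {
    x <- generate_trait_with_signal(tr, lam, seed = 100 + lam * 10)$trait
    ours <- blomberg_k(tr, x, n_perm = 99, seed = 1)
    ref <- as.numeric(phytools::phylosig(tr, x, method = "K"))
    expect_equal(ours$statistic, ref, tolerance = 1e-8)
  }
})

test_that("Pagel's lambda matches the reference implementation", {
  skip_if_not_installed("phytools")
  tr <- small_bd_tree(n = 60, seed = 6)
  x <- generate_trait_with_signal(tr, 0.7, seed = 42)$trait
  ours <- pagel_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$statistic, ref$lambda, tolerance = 1e-4)
  expect_equal(ours$logL, ref$logL, tolerance = 1e-6)
})

test_that("K permutation p-values behave and are seeded-deterministic", {
  tr <- small_bd_tree(n = 50, seed = 8)
  x <- generate_trait_with_signal(tr, 1, seed = 3)$trait
  r1 <- blomberg_k(tr, x, n_perm = 199, seed = 7)
  r2 <- blomberg_k(tr, x, n_perm = 199, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  # p recomputable from the stored permutation statistics
  expect_equal(r1$p_value,
               (1 + sum(r1$perm_stats >= r1$observed_ratio)) / 200)
  # clade-matched traits score higher K than the same values shuffled
  set.seed(2)
  cl <- cutree(hclust(dist(ape::cophenetic.phylo(tr))), k = 2)
  trait_match <- stats::setNames(as.numeric(cl[tr$tip.label]) +
                                   rnorm(50, 0, 0.05), tr$tip.label)
  trait_shuf <- stats::setNames(sample(trait_match), tr$tip.label)
  k_match <- blomberg_k(tr, trait_match, n_perm = 99, seed = 1)$statistic
  k_shuf <- blomberg_k(tr, trait_shuf, n_perm = 99, seed = 1)$statistic
  expect_gt(k_match, k_shuf)
  expect_error(blomberg_k(tr, stats::setNames(rep(1, 50), tr$tip.label),
                          n_perm = 99), "constant")
})

test_that("lambda optimiser respects its contract and flags star trees", {
  tr <- small_bd_tree(n = 50, seed = 9)
  for (s in 1:5) {
    x <- generate_trait_with_signal(tr, runif(1), seed = 400 + s)$trait
    r <- pagel_lambda(tr, x)
    expect_gte(r$statistic, 0)
    expect_lte(r$statistic, 1)
    expect_gte(r$logL, r$logL0 - 1e-8)
    expect_gte(r$logL, r$logL1 - 1e-8)
  }
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_error(pagel_lambda(star, stats::setNames(rnorm(4),
                                                  c("A", "B", "C", "D"))),
               "star")
})

test_that("lambda is recovered at both ends of its range", {
  tr <- small_bd_tree(n = 100, seed = 12)
  lam1 <- vapply(1:30, function(i) {
    pagel_lambda(tr, generate_trait_with_signal(tr, 1,
                                                seed = 500 + i)$trait
    )$statistic
  }, numeric(1))
  expect_gte(stats::median(lam1), 0.9)
  lam0 <- vapply(1:30, function(i) {
    set.seed(600 + i)
    pagel_lambda(tr, stats::setNames(rnorm(100), tr$tip.label))$statistic
  }, numeric(1))
  expect_lte(stats::median(lam0), 0.1)
})

test_that("encode_and_prune drops absent tips and encodes in catalog order", {
  b <- generate_families(synth_config(seed = 33, n_families = 50))
  cl <- classification_from_truth(b$truth)
  cfg <- synth_config(seed = 33, n_families = 50)
  tree <- generate_tree(cfg, n_tips = 50, labels = b$truth$family)
  # drop two families from the tree, as the study tree does
  tree2 <- ape::drop.tip(tree, b$truth$family[1:2])
  enc <- encode_and_prune(cl, tree2, "element")
  expect_equal(length(enc$tree$tip.label), 48L)
  expect_setequal(unique(enc$trait), match(
    unique(cl$element[match(enc$tree$tip.label, cl$family)]),
    c("cosmopolitan", "tropical", "temperate")
  ))
  expect_equal(enc$encoding$label[1:3],
               c("cosmopolitan", "tropical", "temperate"))
  # pruning preserves path lengths among retained tips
  keep <- enc$tree$tip.label
  d_full <- ape::cophenetic.phylo(tree)[keep, keep]
  d_pruned <- ape::cophenetic.phylo(enc$tree)[keep, keep]
  expect_equal(d_pruned, d_full, tolerance = 1e-9)
  enc_t <- encode_and_prune(cl, tree2, "type")
  expect_true(all(enc_t$trait %in% 1:18))
  expect_error(encode_and_prune(cl[1:2, ], tree2, "element"), "3 tips")
})
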