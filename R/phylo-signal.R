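#' Phylogenetic covariance matrix with Pagel's lambda transform
#'
#' Under Brownian motion on a tree, trait covariance between two tips is
#' proportional to their shared root-to-MRCA path length. Pagel's lambda
#' rescales all off-diagonal entries by `lambda` while leaving tip
#' variances unchanged: `lambda = 1` is plain Brownian motion, `lambda = 0`
#' the star-tree (independence) limit.
#'
#' @param tree a `phylo` object (warned about if not ultrametric).
#' @param lambda scalar in \[0, 1\].
#' @return Symmetric positive-definite matrix, tips x tips.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (length(tree$tip.label) < 3L) stop("need at least 3 tips")
  if (!is_ultrametric_tree(tree)) {
    warning("tree is not ultrametric; lambda transform assumes equal ",
            "tip depths")
  }
  C <- ape::vcv.phylo(tree)
  if (lambda != 1) {
    d <- diag(C)
    C <- lambda * C
    diag(C) <- d
  }
  C
}

# MSE0/MSE variance ratios for many trait columns at once (Blomberg's K
# numerator before normalisation). X is an n x B matrix of traits.
variance_ratio_many <- function(Cinv, X) {
  n <- nrow(X)
  w <- colSums(Cinv)               # Cinv %*% 1
  denom <- sum(w)
  ahat <- colSums(w * X) / denom   # GLS phylogenetic mean per column
  dev <- sweep(X, 2L, ahat, "-")
  mse0 <- colSums(dev^2) / (n - 1)
  mse <- colSums(dev * (Cinv %*% dev)) / (n - 1)
  mse0 / mse
}

#' Blomberg's K with a tip-permutation p-value
#'
#' K compares the observed ratio of trait variance among tips to the GLS
#' mean-squared error under the Brownian covariance, against the Brownian
#' expectation of that ratio derived from the trace of the covariance
#' matrix: K = 1 is Brownian-like signal, K < 1 weaker, K > 1 stronger.
#' Significance is assessed by permuting trait values across tips
#' `n_perm` times; the one-sided p-value counts permutations whose
#' variance ratio is at least the observed one, with the observed dataset
#' included in both numerator and denominator:
#' `p = (1 + n_exceed) / (1 + n_perm)`.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector over the tips.
#' @param n_perm number of permutations (default 1000, minimum 99).
#' @param seed RNG seed.
#' @return Object of class `sses_signal`: list with `method = "K"`,
#'   `statistic`, `p_value`, `n_perm`, `perm_stats` (the permuted variance
#'   ratios) and `observed_ratio`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  x <- align_trait(tree, trait)
  if (stats::sd(x) == 0) stop("trait is constant; K is undefined")
  n <- length(x)
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  obs <- variance_ratio_many(Cinv, matrix(x, ncol = 1L))
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  K <- as.numeric(obs / expected)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
  perm_stats <- variance_ratio_many(Cinv, P)
  p <- (1 + sum(perm_stats >= obs)) / (1 + n_perm)
  structure(
    list(method = "K", statistic = K, p_value = p, n_perm = n_perm,
         perm_stats = perm_stats, observed_ratio = as.numeric(obs),
         expected_ratio = expected),
    class = "sses_signal"
  )
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      stop("unnamed trait must have one value per tip")
    }
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L) {
    stop("trait missing for tip(s): ", paste(missing, collapse = ", "))
  }
  as.numeric(trait[tree$tip.label])
}

# profile log-likelihood of lambda given eigen-decomposition pieces.
# For ultrametric trees C(lambda) = lambda*C + (1-lambda)*h*I shares C's
# eigenvectors, so each evaluation is O(n).
loglik_lambda_eigen <- function(lambda, evals, h, y, u) {
  n <- length(y)
  w <- lambda * evals + (1 - lambda) * h
  if (any(w <= 0)) return(-Inf)
  mu <- sum(u * y / w) / sum(u^2 / w)
  res <- y - mu * u
  sigma2 <- sum(res^2 / w) / n
  -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + n)
}

loglik_lambda_direct <- function(lambda, C, x) {
  d <- diag(C)
  Cl <- lambda * C
  diag(Cl) <- d
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  n <- length(x)
  one <- rep(1, n)
  z <- backsolve(ch, forwardsolve(t(ch), x))
  zo <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(one * z) / sum(one * zo)
  r <- x - mu
  q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- q / n
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
}

#' Pagel's lambda by maximum likelihood with a likelihood-ratio test
#'
#' Profiles the Gaussian log-likelihood of the trait with mean `mu * 1`
#' and covariance `sigma2 * C(lambda)` over `lambda` in \[0, 1\] (`mu`,
#' `sigma2` profiled analytically). The bounded 1-D optimisation runs from
#' five grid restarts with tolerance `1e-8`. Significance is a likelihood-
#' ratio test of `lambda = lambda_hat` against `lambda = 0`
#' (chi-squared, 1 df). On ultrametric trees the covariance is
#' diagonalised once, making each likelihood evaluation linear in the
#' number of tips. A star tree (all off-diagonal covariances zero) leaves
#' lambda unidentifiable and is an error.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector over the tips.
#' @param tol optimisation tolerance (default `1e-8`).
#' @return Object of class `sses_signal`: list with `method = "lambda"`,
#'   `statistic` (the ML estimate), `p_value`, `logL`, `logL0`
#'   (at lambda = 0), `logL1` (at lambda = 1).
#' @export
pagel_lambda <- function(tree, trait, tol = 1e-8) {
  x <- align_trait(tree, trait)
  if (stats::sd(x) == 0) stop("trait is constant; lambda is undefined")
  C <- ape::vcv.phylo(tree)
  if (max(abs(C[upper.tri(C)])) == 0) {
    stop("star tree: off-diagonal covariances are all zero, ",
         "lambda is unidentifiable (flat likelihood)")
  }
  dC <- diag(C)
  ultra <- (max(dC) - min(dC)) <= 1e-8 * max(dC)
  if (ultra) {
    h <- mean(dC)
    eig <- eigen(C, symmetric = TRUE)
    y <- drop(crossprod(eig$vectors, x))
    u <- drop(crossprod(eig$vectors, rep(1, length(x))))
    f <- function(l) loglik_lambda_eigen(l, eig$values, h, y, u)
  } else {
    f <- function(l) loglik_lambda_direct(l, C, x)
  }
  grid <- seq(0, 1, length.out = 6L)
  best <- list(maximum = 0, objective = f(0))
  for (i in seq_len(5L)) {
    opt <- stats::optimize(f, lower = grid[i], upper = grid[i + 1L],
                           maximum = TRUE, tol = tol)
    if (opt$objective > best$objective) best <- opt
  }
  # include the exact boundaries, which optimize() never returns
  for (b in c(0, 1)) {
    fb <- f(b)
    if (fb > best$objective) best <- list(maximum = b, objective = fb)
  }
  logL0 <- f(0)
  lr <- 2 * (best$objective - logL0)
  p <- stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
  structure(
    list(method = "lambda", statistic = best$maximum,
         p_value = p, logL = best$objective, logL0 = logL0,
         logL1 = f(1)),
    class = "sses_signal"
  )
}

#' @export
print.sses_signal <- function(x, ...) {
  lab <- if (x$method == "K") "Blomberg's K" else "Pagel's lambda"
  cat(lab, "=", format(x$statistic), ", P =", format(x$p_value), "\n")
  invisible(x)
}

#' Prune a tree to a classification and encode labels as a trait
#'
#' Keeps only the tips present in the classification (families absent
#' from the tree — e.g. the two families without stem ages in the study
#' tree — simply drop out), and encodes the requested hierarchy level as
#' consecutive integer codes in catalog order. The encoding is recorded so
#' results can be interpreted; it is deliberately the same crude
#' categorical-as-continuous coding used by standard `phylosig`-style
#' analyses of membership labels.
#'
#' @param classification an `sses_classification`.
#' @param tree a `phylo` object with family tip labels.
#' @param level `"element"`, `"supertype"` or `"type"`.
#' @param catalog an [sses_catalog()].
#' @return List with `tree` (pruned), `trait` (named integer codes) and
#'   `encoding` (data frame `label`, `code`).
#' @export
encode_and_prune <- function(classification, tree,
                             level = c("element", "supertype", "type"),
                             catalog = sses_catalog()) {
  level <- match.arg(level)
  keep <- intersect(tree$tip.label, classification$family)
  if (length(keep) < 3L) {
    stop("fewer than 3 tips shared between tree and classification")
  }
  pruned <- ape::keep.tip(tree, keep)
  labels <- switch(
    level,
    element = c("cosmopolitan", "tropical", "temperate"),
    supertype = as.character(1:6),
    type = catalog$types$id
  )
  value <- switch(
    level,
    element = classification$element,
    supertype = as.character(classification$supertype),
    type = classification$type
  )
  value <- stats::setNames(value, classification$family)[pruned$tip.label]
  codes <- match(value, labels)
  if (anyNA(codes)) {
    stop("classification label(s) outside the catalog at level ", level)
  }
  list(
    tree = pruned,
    trait = stats::setNames(as.numeric(codes), pruned$tip.label),
    encoding = data.frame(label = labels, code = seq_along(labels),
                          stringsAsFactors = FALSE)
  )
}
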