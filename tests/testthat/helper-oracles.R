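# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and ape's vcv/cophenetic): everything is computed from the raw
# edge matrix by explicit path walks or dense linear algebra.

# node path from a node up to the root, as a vector of node ids
path_to_root <- function(tree, node) {
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  path <- node
  while (node != root) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

# root-to-node depth by summing branch lengths along the path walk
oracle_depth <- function(tree, node) {
  nmax <- max(tree$edge)
  elen <- numeric(nmax)
  elen[tree$edge[, 2]] <- tree$edge.length
  sum(elen[path_to_root(tree, node)])
}

# root-to-MRCA depth for a tip pair: deepest node on both root paths
oracle_mrca_depth <- function(tree, i, j) {
  common <- intersect(path_to_root(tree, i), path_to_root(tree, j))
  max(vapply(common, function(nd) oracle_depth(tree, nd), 0))
}

# full MRCA-depth matrix by double loop (diagonal = tip depths)
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- if (i == j) oracle_depth(tree, i) else oracle_mrca_depth(tree, i, j)
    }
  }
  V
}

# patristic distance between two tips by independent path sums
oracle_patristic <- function(tree, i, j) {
  oracle_depth(tree, i) + oracle_depth(tree, j) - 2 * oracle_mrca_depth(tree, i, j)
}

oracle_patristic_named <- function(tree, a, b) {
  oracle_patristic(tree, match(a, tree$tip.label), match(b, tree$tip.label))
}

# explicit normal-equations GLS by naive dense inversion
oracle_gls <- function(X, y, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX) %*% t(X) %*% Vi %*% y
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (nrow(X) - ncol(X))
  list(beta = as.numeric(beta), sigma2 = sigma2, cov_beta = sigma2 * solve(XtViX))
}

# textbook profiled REML of iid-error linear regression (V = I), written
# directly from the restricted-likelihood definition used for that model
oracle_reml_iid <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  rss <- sum((y - X %*% b)^2)
  s2 <- rss / (n - p)
  -0.5 * (n - p) * (log(2 * pi * s2) + 1)
}

# random symmetric positive-definite matrix
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

# random tree with given tips: mixes the ultrametric pure-birth generator and
# ape's nonultrametric uniform-branch generator
random_test_tree <- function(n, seed) {
  set.seed(seed)
  if (seed %% 2 == 0) {
    ape::rtree(n)
  } else {
    ape::rphylo(n, birth = 1, death = 0)
  }
}

# simulated dataset + tree ready for fitting
sim_fit_data <- function(cfg, tree = NULL) {
  dat <- simulate_allometric_dataset(cfg, tree = tree)
  dat$log_mass <- log10(dat$adult_weight_g)
  dat$log_trait <- log10(dat$trait_value)
  dat
}
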