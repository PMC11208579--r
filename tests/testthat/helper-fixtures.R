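# Shared fixtures and independent oracles, built in code at test time.

# Small three-tip tree used across the IO tests: ((A:1,B:1):1,C:2);
toy_tree_path <- function() {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  path
}

toy_assoc_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("mite_id,host_id,credible", lines), path)
  path
}

# Brute-force patristic distance: sum of branch lengths along the unique
# tip-to-tip path, found by walking edge lists (independent of cophenetic).
brute_patristic <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  parent_of <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) return(NULL)
    list(parent = tree$edge[e, 1], len = tree$edge.length[e])
  }
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    nodes <- node; lens <- numeric()
    repeat {
      p <- parent_of(node)
      if (is.null(p)) break
      nodes <- c(nodes, p$parent); lens <- c(lens, p$len)
      node <- p$parent
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  pa <- path_to_root(a); pb <- path_to_root(b)
  mrca <- intersect(pa$nodes, pb$nodes)[1]
  pa$cum[match(mrca, pa$nodes)] + pb$cum[match(mrca, pb$nodes)]
}

# Truncated-power natural cubic spline basis (Hastie et al. construction):
# spans the same function space as any natural spline basis on these knots.
truncated_power_ns <- function(x, knots) {
  K <- length(knots)
  stopifnot(K >= 3)
  d <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  basis <- cbind(1, x)
  for (k in seq_len(K - 2)) basis <- cbind(basis, d(k) - d(K - 1))
  basis
}

# Brute-force Bernoulli log-likelihood maximiser (independent of IRLS).
brute_force_logistic <- function(X, y, start = NULL) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  if (is.null(start)) start <- rep(0, ncol(X))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}

# Concordant-pair AUC (ties count one half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# A small simulated dataset reused by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(generative_spec(n_hosts = 60, n_mites = 300,
                                                 seed = 11))
    cache
  }
})

small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- small_sim()
      cache <<- suppressMessages(
        build_feature_table(s$assoc_observed, s$mites, s$hosts, s$tree,
                            s$ranges))
    }
    cache
  }
})
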