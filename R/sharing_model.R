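#' Project the bipartite mite-host network onto hosts
#'
#' An edge connects every unordered pair of hosts that share at least one
#' mite species. Hosts that share no mite with any other host are listed as
#' excluded (they carry no information for the sharing model).
#'
#' @param assoc association data.frame (analysis view).
#' @return list: `edges` (data.frame host_a, host_b with host_a < host_b,
#'   unique) and `excluded` (hosts with no sharing partner).
#' @export
project_unipartite <- function(assoc) {
  by_mite <- split(assoc$host_id, assoc$mite_id)
  pair_list <- lapply(by_mite, function(hs) {
    hs <- unique(hs)
    if (length(hs) < 2) return(NULL)
    t(utils::combn(sort(hs), 2))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) {
    edges <- data.frame(host_a = character(), host_b = character(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    edges <- data.frame(host_a = pairs[, 1], host_b = pairs[, 2],
                        stringsAsFactors = FALSE)
  }
  all_hosts <- unique(assoc$host_id)
  connected <- unique(c(edges$host_a, edges$host_b))
  list(edges = edges, excluded = sort(setdiff(all_hosts, connected)))
}

#' Recode extreme phylogenetic distances
#'
#' Pairwise patristic distances above 300 (the deep marsupial-placental
#' divergence) are recoded to 178, the largest distance within placental
#' mammals, so the model does not overfit the empty gap between the two
#' groups. Values in (178, 300], a region expected to be empty, are left
#' unchanged with a warning.
#'
#' @param pd numeric vector of patristic distances (>= 0).
#' @return recoded distances.
#' @export
recode_pd <- function(pd) {
  if (any(pd < 0, na.rm = TRUE)) stop("phylogenetic distances must be >= 0")
  gap <- pd > 178 * (1 + 1e-9) & pd <= 300
  if (any(gap, na.rm = TRUE))
    warning(sum(gap, na.rm = TRUE),
            " distance(s) in (178, 300] left unchanged")
  ifelse(pd > 300, 178, pd)
}

#' Build the host-pair table for the sharing model
#'
#' One row per unordered pair of kept hosts: a binary sharing indicator
#' (1 if the pair appears in the projected edge set), the recoded
#' phylogenetic distance and the geographic overlap. Hosts missing from
#' either matrix are dropped with a warning (intersection rule).
#'
#' @param edges edge data.frame from [project_unipartite()].
#' @param kept_hosts hosts to include (typically the connected hosts).
#' @param pd_matrix patristic `host_matrix`.
#' @param go_matrix geographic-overlap `host_matrix`.
#' @return data.frame of class `sharing_pairs`: host_a, host_b, shares,
#'   pd, go.
#' @export
build_pair_table <- function(edges, kept_hosts, pd_matrix, go_matrix) {
  keep <- intersect(intersect(kept_hosts, rownames(pd_matrix)),
                    rownames(go_matrix))
  dropped <- setdiff(kept_hosts, keep)
  if (length(dropped))
    warning("host(s) missing from a matrix dropped: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2) stop("fewer than two hosts remain")
  keep <- sort(keep)
  cmb <- utils::combn(keep, 2)
  edge_key <- paste(edges$host_a, edges$host_b, sep = "\r")
  pair_key <- paste(cmb[1, ], cmb[2, ], sep = "\r")
  out <- data.frame(
    host_a = cmb[1, ], host_b = cmb[2, ],
    shares = as.integer(pair_key %in% edge_key),
    pd = recode_pd(pd_matrix[cbind(cmb[1, ], cmb[2, ])]),
    go = go_matrix[cbind(cmb[1, ], cmb[2, ])],
    stringsAsFactors = FALSE
  )
  class(out) <- c("sharing_pairs", "data.frame")
  out
}

#' Bin specification for pair subsampling
#'
#' @param pd_edges,go_edges strictly increasing bin edges covering the data
#'   range (defaults: distance bins of width 20 on [0, 180], overlap bins of
#'   width 0.1 on [0, 1]).
#' @param max_per_bin retention cap per (pd-bin x go-bin) cell (default
#'   1000).
#' @param seed integer seed.
#' @return list of class `bin_spec`.
#' @export
bin_spec <- function(pd_edges = seq(0, 180, by = 20),
                     go_edges = seq(0, 1, by = 0.1),
                     max_per_bin = 1000L, seed = 1L) {
  stopifnot(all(diff(pd_edges) > 0), all(diff(go_edges) > 0),
            max_per_bin >= 1)
  structure(list(pd_edges = pd_edges, go_edges = go_edges,
                 max_per_bin = as.integer(max_per_bin),
                 seed = as.integer(seed)),
            class = "bin_spec")
}

#' Stratified subsampling of host pairs
#'
#' The joint distribution of distance and overlap is extremely uneven (the
#' vast majority of host pairs are allopatric and deeply divergent). Within
#' each (pd-bin x go-bin) cell holding more than `max_per_bin` pairs, a
#' seeded uniform random subset of that size is retained; smaller cells are
#' untouched.
#'
#' @param pairs `sharing_pairs` data.frame.
#' @param spec a [bin_spec()].
#' @return subsampled `sharing_pairs` (a subset of the input rows).
#' @export
bin_subsample <- function(pairs, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  set.seed(spec$seed)
  pd_bin <- cut(pairs$pd, spec$pd_edges, include.lowest = TRUE)
  go_bin <- cut(pairs$go, spec$go_edges, include.lowest = TRUE)
  cell <- interaction(pd_bin, go_bin, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), cell), function(idx) {
    if (length(idx) > spec$max_per_bin) sample(idx, spec$max_per_bin)
    else idx
  }), use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sharing_design <- function(pd, go, spec = NULL) {
  if (is.null(spec)) spec <- spline_spec(pd, df = 2, variable = "pd")
  B <- natural_spline_basis(pd, spec)
  X <- cbind("(Intercept)" = 1, "ns(pd,2)1" = B[, 1], "ns(pd,2)2" = B[, 2],
             "go" = go, "pd:go" = pd * go)
  list(X = X, spec = spec)
}

#' Fit the host-pair mite-sharing model
#'
#' Binomial GLM of the sharing indicator on a df = 2 natural spline of the
#' (recoded) phylogenetic distance, a linear geographic-overlap term, and a
#' raw distance-by-overlap interaction:
#' `logit(shares) ~ ns(pd, 2) + go + pd:go`. The interaction multiplies the
#' raw distance (not the spline basis) by overlap.
#'
#' @param pairs `sharing_pairs` data.frame (typically after
#'   [bin_subsample()]).
#' @return `glm_fit` with the distance spline spec and input ranges stored
#'   in `$sharing`.
#' @export
fit_sharing_glm <- function(pairs) {
  check_two_classes(pairs$shares)
  d <- sharing_design(pairs$pd, pairs$go)
  fit <- fit_logistic(d$X, pairs$shares)
  fit$sharing <- list(spec = d$spec, pd_range = range(pairs$pd),
                      go_range = range(pairs$go))
  fit
}

#' Predict mite-sharing probability for host pairs
#'
#' Inverse-logit of the fitted linear predictor at given (recoded) distance
#' and overlap values, with a delta-method standard error
#' (`se_p = p (1 - p) se_eta`).
#'
#' @param fit `glm_fit` from [fit_sharing_glm()].
#' @param pd phylogenetic distances in [0, 178] (after recoding).
#' @param go geographic overlaps in [0, 1].
#' @return data.frame pd, go, prob, se.
#' @export
predict_sharing <- function(fit, pd, go) {
  if (is.null(fit$sharing)) stop("fit is not a sharing-model fit")
  if (length(pd) != length(go)) {
    if (length(pd) == 1) pd <- rep(pd, length(go))
    else if (length(go) == 1) go <- rep(go, length(pd))
    else stop("pd and go lengths differ")
  }
  pd <- recode_pd(pd)
  if (any(pd < 0 | pd > 178 * (1 + 1e-9)))
    stop("pd outside [0, 178] after recoding")
  if (any(go < 0 | go > 1)) stop("go outside [0, 1]")
  X <- sharing_design(pd, go, spec = fit$sharing$spec)$X
  eta <- as.numeric(X %*% fit$coefficients)
  se_eta <- sqrt(rowSums((X %*% fit$vcov) * X))
  p <- stats::plogis(eta)
  data.frame(pd = pd, go = go, prob = p, se = p * (1 - p) * se_eta)
}

#' Prediction surface over a distance-by-overlap lattice
#'
#' @param fit `glm_fit` from [fit_sharing_glm()].
#' @param pd_grid,go_grid lattice values (defaults: distance 0-178 in steps
#'   of 2, overlap 0-1 in steps of 0.05).
#' @return data.frame pd, go, prob, se for every lattice point.
#' @export
sharing_surface <- function(fit, pd_grid = seq(0, 178, by = 2),
                            go_grid = seq(0, 1, by = 0.05)) {
  grid <- expand.grid(pd = pd_grid, go = go_grid)
  predict_sharing(fit, grid$pd, grid$go)
}

#' Simulate host pairs from a known sharing model
#'
#' Draws distance and overlap values with the qualitative shape of real
#' host-pair data (a majority of zero-overlap pairs), computes the true
#' linear predictor under the supplied coefficients (named as the
#' sharing-model design columns), and draws the sharing indicator
#' Bernoulli. Used for parameter-recovery and type-I-error checks.
#'
#' @param n number of pairs.
#' @param coefficients named vector over `(Intercept)`, `ns(pd,2)1`,
#'   `ns(pd,2)2`, `go`, `pd:go`.
#' @param seed integer seed.
#' @param p_zero_go fraction of allopatric (zero-overlap) pairs.
#' @return list: `pairs` (`sharing_pairs` with true-model labels) and
#'   `spec` (the distance spline spec the truth used).
#' @export
simulate_sharing_pairs <- function(n, coefficients, seed = 1L,
                                   p_zero_go = 0.55) {
  needed <- c("(Intercept)", "ns(pd,2)1", "ns(pd,2)2", "go", "pd:go")
  stopifnot(setequal(names(coefficients), needed))
  set.seed(seed)
  pd <- stats::runif(n, 0, 178)
  go <- ifelse(stats::runif(n) < p_zero_go, 0, stats::runif(n))
  d <- sharing_design(pd, go)
  eta <- as.numeric(d$X[, needed] %*% coefficients[needed])
  shares <- as.integer(stats::runif(n) < stats::plogis(eta))
  pairs <- data.frame(host_a = sprintf("HA%06d", seq_len(n)),
                      host_b = sprintf("HB%06d", seq_len(n)),
                      shares = shares, pd = pd, go = go,
                      stringsAsFactors = FALSE)
  class(pairs) <- c("sharing_pairs", "data.frame")
  list(pairs = pairs, spec = d$spec)
}
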