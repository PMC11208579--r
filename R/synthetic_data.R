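#' Generative specification for synthetic mite-host datasets
#'
#' Defaults emulate the structure of a curated mite-mammal database: a
#' moderately imbalanced outcome (multi-host base rate 0.286, i.e. 413/1445),
#' multi-host species whose extra hosts are phylogenetically close and
#' sympatric to the primary host (sampling weight proportional to
#' `exp(-PD/tau) * (1 + GO)`), and detection of non-primary host links that
#' improves with the species' publication count, so unobserved multi-hosts
#' concentrate among poorly studied mites. `true_coefficients` are on the
#' host-range model's linear-predictor scale and must be named after the
#' non-intercept design columns; the intercept is calibrated at generation
#' time so the mean true multi-host probability equals
#' `multihost_base_rate`.
#'
#' @param n_hosts number of host species (>= 4).
#' @param n_mites number of mite species (>= 10).
#' @param grid_dims c(rows, cols) of the geographic grid.
#' @param true_coefficients named vector over the 18 non-intercept design
#'   columns; defaults to the preferred host-range model's point estimates.
#' @param multihost_base_rate target mean probability of the multi-host
#'   label.
#' @param tau phylogenetic decay (distance units) of extra-host sampling.
#' @param k_max maximum number of extra hosts for a multi-host mite.
#' @param mean_range_cells mean range size in grid cells.
#' @param p_cluster probability that a host's range is seeded near its
#'   closest relative's range (induces PD-overlap correlation).
#' @param detection_halfsat publication count at which a non-primary host
#'   link is detected with probability 1/2 (`p = pubs / (pubs + halfsat)`).
#' @param seed integer seed governing every random draw.
#' @return list of class `generative_spec`.
#' @export
generative_spec <- function(n_hosts = 150L, n_mites = 1445L,
                            grid_dims = c(30L, 30L),
                            true_coefficients = default_true_coefficients(),
                            multihost_base_rate = 0.286,
                            tau = 25, k_max = 4L,
                            mean_range_cells = 60L, p_cluster = 0.7,
                            detection_halfsat = 5, seed = 1L) {
  stopifnot(n_hosts >= 4, n_mites >= 10,
            multihost_base_rate > 0, multihost_base_rate < 1,
            tau > 0, k_max >= 1, mean_range_cells >= 1,
            p_cluster >= 0, p_cluster <= 1, detection_halfsat >= 0)
  structure(list(n_hosts = as.integer(n_hosts), n_mites = as.integer(n_mites),
                 grid_dims = as.integer(grid_dims),
                 true_coefficients = true_coefficients,
                 multihost_base_rate = multihost_base_rate,
                 tau = tau, k_max = as.integer(k_max),
                 mean_range_cells = as.integer(mean_range_cells),
                 p_cluster = p_cluster,
                 detection_halfsat = detection_halfsat,
                 seed = as.integer(seed)),
            class = "generative_spec")
}

#' Default generative coefficients
#'
#' Point estimates of the preferred host-range model, used as the default
#' ground truth so synthetic datasets are a qualitative bridge to real data.
#'
#' @return named numeric vector over the 18 non-intercept design columns.
#' @export
default_true_coefficients <- function() {
  c("immunity_contact.secondary" = 2.028,
    "immunity_contact.none" = 0.990,
    "parasitism.ecto" = 1.139,
    "bioregion.multiregion" = 3.996,
    "dispersal_stage.F" = 0.426,
    "dispersal_stage.F_IMM" = 0.458,
    "precop_guarding.N" = 0.432,
    "n_CPH_max" = 0.035,
    "n_PSH10_max" = 0.619,
    "avg_litter_size" = 0.089,
    "domesticated_host.Y" = 0.742,
    "ns(log_body_mass,2)1" = -0.849,
    "ns(log_body_mass,2)2" = -1.761,
    "ns(avg_precip,2)1" = 1.594,
    "ns(avg_precip,2)2" = 0.190,
    "ns(avg_temp,2)1" = 2.849,
    "ns(avg_temp,2)2" = -1.268,
    "log_human_pop_density" = 0.287)
}

#' Generate an ultrametric host phylogeny
#'
#' Ultrametric pure-birth (Yule) tree with tips `H0001...`, rescaled so the
#' maximum patristic distance equals 178 distance units (the within-placental
#' maximum used as the upper end of the distance scale). A birth-death-style
#' tree is used rather than a coalescent one because its longer terminal
#' branches reproduce the sparse close-relative structure of a species-level
#' supertree (most species have only a handful of congeners within short
#' patristic reach).
#'
#' @param n_hosts number of tips (>= 4).
#' @param seed integer seed.
#' @return `phylo` object.
#' @export
generate_phylogeny <- function(n_hosts, seed = 1L) {
  stopifnot(n_hosts >= 4)
  set.seed(seed)
  tree <- ape::rphylo(n_hosts, birth = 1, death = 0)
  tree$tip.label <- sprintf("H%04d", seq_len(n_hosts))
  D <- ape::cophenetic.phylo(tree)
  tree$edge.length <- tree$edge.length * (178 / max(D))
  tree
}

grid_cell_id <- function(r, c, dims) (r - 1L) * dims[2] + c
cell_coords <- function(id, dims) {
  cbind(r = (id - 1L) %/% dims[2] + 1L, c = (id - 1L) %% dims[2] + 1L)
}

## grow a contiguous blob of `size` cells from a seed cell (4-neighbourhood)
grow_blob <- function(seed_cell, size, dims) {
  taken <- seed_cell
  if (size <= 1) return(taken)
  repeat {
    rc <- cell_coords(taken, dims)
    nb <- rbind(cbind(rc[, 1] - 1L, rc[, 2]), cbind(rc[, 1] + 1L, rc[, 2]),
                cbind(rc[, 1], rc[, 2] - 1L), cbind(rc[, 1], rc[, 2] + 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] &
             nb[, 2] >= 1 & nb[, 2] <= dims[2], , drop = FALSE]
    cand <- setdiff(grid_cell_id(nb[, 1], nb[, 2], dims), taken)
    if (!length(cand) || length(taken) >= size) break
    take <- sample(cand, min(length(cand), size - length(taken)))
    taken <- c(taken, take)
  }
  sort(taken)
}

#' Generate contiguous host geographic ranges on a grid
#'
#' Each host's range is a contiguous blob grown from a seed cell. With
#' probability `p_cluster` a host is seeded near the seed cell of its
#' phylogenetically closest already-placed relative, inducing the
#' correlation between phylogenetic proximity and sympatry seen in real
#' host assemblages; otherwise the seed cell is uniform on the grid, so
#' most host pairs do not overlap at all.
#'
#' @param tree host phylogeny (tips define the hosts).
#' @param grid_dims c(rows, cols).
#' @param mean_range_cells mean blob size (Poisson, floor 1).
#' @param p_cluster phylogenetic seeding probability.
#' @param seed integer seed.
#' @param seed_cells optional named integer vector forcing seed cells for
#'   some or all hosts (used in tests).
#' @return named list host_id -> sorted integer cell ids.
#' @export
generate_ranges <- function(tree, grid_dims = c(30L, 30L),
                            mean_range_cells = 60L, p_cluster = 0.7,
                            seed = 1L, seed_cells = NULL) {
  stopifnot(mean_range_cells >= 1)
  set.seed(seed)
  hosts <- tree$tip.label
  D <- ape::cophenetic.phylo(tree)[hosts, hosts]
  n <- length(hosts)
  dims <- as.integer(grid_dims)
  ncell <- prod(dims)
  sizes <- pmax(1L, stats::rpois(n, mean_range_cells))
  sizes <- pmin(sizes, ncell)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    forced <- if (!is.null(seed_cells)) seed_cells[hosts[i]] else NA
    if (!is.na(forced)) {
      seeds[i] <- as.integer(forced)
    } else if (i > 1 && stats::runif(1) < p_cluster) {
      rel <- which.min(D[i, seq_len(i - 1)])
      rc <- cell_coords(seeds[rel], dims)
      r <- min(max(rc[1] + sample(-2:2, 1), 1L), dims[1])
      c <- min(max(rc[2] + sample(-2:2, 1), 1L), dims[2])
      seeds[i] <- grid_cell_id(r, c, dims)
    } else {
      seeds[i] <- sample.int(ncell, 1)
    }
  }
  ranges <- vector("list", n)
  for (i in seq_len(n)) ranges[[i]] <- grow_blob(seeds[i], sizes[i], dims)
  names(ranges) <- hosts
  ranges
}

#' Generate host traits tied to range location
#'
#' Climate and disturbance traits are smooth functions of the range centroid
#' plus noise, so spatially close hosts have similar climates (needed for
#' the spline terms of the host-range model to be estimable). Taxonomic
#' orders are clades cut from the phylogeny.
#'
#' @param tree host phylogeny.
#' @param ranges named list of host ranges.
#' @param grid_dims c(rows, cols).
#' @param seed integer seed.
#' @param n_orders number of order labels (clades).
#' @return host trait data.frame (shape of [read_host_traits()]).
#' @export
generate_host_traits <- function(tree, ranges, grid_dims = c(30L, 30L),
                                 seed = 1L, n_orders = 10L) {
  set.seed(seed)
  hosts <- tree$tip.label
  n <- length(hosts)
  dims <- as.integer(grid_dims)
  D <- ape::cophenetic.phylo(tree)[hosts, hosts]
  k <- min(n_orders, max(2L, n %/% 4L))
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"), k = k)
  centro <- t(vapply(ranges[hosts], function(cells) {
    colMeans(cell_coords(cells, dims))
  }, numeric(2)))
  ## north-south temperature gradient (0.1 degC units), east-west rainfall
  temp <- -100 + 350 * centro[, 1] / dims[1] + stats::rnorm(n, 0, 20)
  precip <- pmax(0, 30 + 180 * centro[, 2] / dims[2] + stats::rnorm(n, 0, 25))
  hpd <- exp(1 + 2 * centro[, 2] / dims[2] + stats::rnorm(n, 0, 0.6))
  dom <- stats::runif(n) < 0.05
  ## every mammal assemblage contains at least a couple of domesticated /
  ## peridomestic species; guarantee them so the dummy is always estimable
  if (sum(dom) < 2) dom[sample.int(n, 2)] <- TRUE
  out <- data.frame(
    host_id = hosts,
    order = sprintf("Ord%02d", cl),
    domesticated = dom,
    litter_size = exp(stats::rnorm(n, log(3), 0.4)),
    body_mass = exp(stats::rnorm(n, log(500), 1.2)),
    mean_precip = precip,
    mean_temp = temp,
    human_pop_density = hpd,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

## generative feature table for single (primary) hosts, vectorised
primary_host_features <- function(mites, primary_host, go, pd, host_traits,
                                  jaccard_cutoff = 0.5, pd_cutoff = 10) {
  counts <- host_availability_counts(go, pd, jaccard_cutoff, pd_cutoff)
  i <- match(primary_host, counts$host_id)
  ht <- host_traits[match(primary_host, host_traits$host_id), ]
  data.frame(
    mite_id = mites$mite_id,
    multihost = 0L,
    immunity_contact = mites$immunity_contact,
    parasitism = mites$parasitism,
    bioregion = mites$bioregion,
    dispersal_stage = mites$dispersal_stage,
    precop_guarding = mites$precop_guarding,
    n_CPH_max = counts$n_CPH[i],
    n_PSH10_max = counts$n_PSH10[i],
    avg_litter_size = ht$litter_size,
    domesticated_host = ht$domesticated,
    log_body_mass = log(ht$body_mass),
    avg_precip = ht$mean_precip,
    avg_temp = ht$mean_temp,
    log_human_pop_density = log(ht$human_pop_density + 1),
    publication_count = mites$publication_count,
    stringsAsFactors = FALSE
  )
}

#' Generate mite species, true host sets and ground-truth labels
#'
#' Each mite receives categorical traits from fixed marginal frequencies and
#' a primary host drawn uniformly. Its 13 predictors are computed exactly as
#' the feature builder computes them (single-host rows pass host values
#' through). The true multi-host label is Bernoulli with probability
#' `plogis(c + x' beta)` where `beta = spec$true_coefficients` and the
#' intercept `c` is calibrated so the population mean equals
#' `spec$multihost_base_rate`. True multi-host mites receive 1 to `k_max`
#' extra hosts sampled with weight `exp(-PD/tau) * (1 + GO)` relative to the
#' primary host, so extra hosts are phylogenetically close and sympatric.
#'
#' @param spec a [generative_spec()].
#' @param hosts host trait data.frame.
#' @param tree host phylogeny.
#' @param ranges named list of host ranges.
#' @return list: `mites` (trait table), `assoc` (true association table),
#'   `truth` (per-mite truth table), `features` (generative feature table),
#'   `intercept` (calibrated value).
#' @export
generate_mites <- function(spec, hosts, tree, ranges) {
  stopifnot(inherits(spec, "generative_spec"))
  set.seed(spec$seed + 1000L)
  n <- spec$n_mites
  host_ids <- tree$tip.label
  mites <- data.frame(
    mite_id = sprintf("M%05d", seq_len(n)),
    immunity_contact = factor(sample(IMMUNITY_LEVELS, n, replace = TRUE,
                                     prob = c(0.45, 0.35, 0.20)),
                              levels = IMMUNITY_LEVELS),
    parasitism = factor(sample(PARASITISM_LEVELS, n, replace = TRUE,
                               prob = c(0.2, 0.8)), levels = PARASITISM_LEVELS),
    bioregion = factor(sample(BIOREGION_LEVELS, n, replace = TRUE,
                              prob = c(0.85, 0.15)), levels = BIOREGION_LEVELS),
    dispersal_stage = factor(sample(DISPERSAL_LEVELS, n, replace = TRUE,
                                    prob = c(0.25, 0.15, 0.60)),
                             levels = DISPERSAL_LEVELS),
    precop_guarding = stats::runif(n) < 0.5,
    publication_count = as.integer(stats::rnbinom(n, size = 1.2, mu = 8)),
    stringsAsFactors = FALSE
  )
  primary <- sample(host_ids, n, replace = TRUE)

  go <- build_overlap_matrix(ranges[host_ids])
  pd <- patristic_matrix(tree)
  feats <- primary_host_features(mites, primary, go, pd, hosts)

  d <- build_hostrange_design(feats)
  beta <- spec$true_coefficients
  cols <- setdiff(colnames(d$X), "(Intercept)")
  if (!setequal(names(beta), cols))
    stop("true_coefficients names do not match the design columns; ",
         "expected: ", paste(cols, collapse = ", "))
  eta <- as.numeric(d$X[, names(beta), drop = FALSE] %*% beta)

  rate <- spec$multihost_base_rate
  intercept <- if (all(beta == 0)) stats::qlogis(rate) else
    stats::uniroot(function(cc) mean(stats::plogis(cc + eta)) - rate,
                   interval = c(-max(eta) - 40, -min(eta) + 40),
                   tol = 1e-10)$root
  p_true <- stats::plogis(intercept + eta)
  true_label <- as.integer(stats::runif(n) < p_true)

  ## extra hosts for true multi-host mites: close relatives and sympatrics
  n_extra_choices <- seq_len(spec$k_max)
  extra_probs <- 0.5 ^ (n_extra_choices - 1)
  true_hosts <- as.list(primary)
  for (i in which(true_label == 1L)) {
    w <- exp(-pd[primary[i], ] / spec$tau) * (1 + go[primary[i], ])
    w[primary[i]] <- 0
    k <- sample(n_extra_choices, 1, prob = extra_probs)
    k <- min(k, sum(w > 0))
    if (k > 0)
      true_hosts[[i]] <- c(primary[i], sample(host_ids, k, prob = w))
  }

  assoc <- data.frame(
    mite_id = rep(mites$mite_id, lengths(true_hosts)),
    host_id = unlist(true_hosts, use.names = FALSE),
    credible = TRUE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    mite_id = mites$mite_id,
    true_label = true_label,
    primary_host = primary,
    true_hosts = vapply(true_hosts, paste, character(1), collapse = ";"),
    n_true_hosts = lengths(true_hosts),
    stringsAsFactors = FALSE
  )
  feats$multihost <- as.integer(lengths(true_hosts) > 1)
  list(mites = mites, assoc = assoc, truth = truth, features = feats,
       intercept = intercept)
}

#' Thin non-primary host links by publication-dependent detection
#'
#' Each non-primary host link is retained with probability
#' `pubs / (pubs + halfsat)`; the primary host is always observed, so every
#' mite keeps at least one host. True multi-host mites whose extra links are
#' all lost become planted unobserved multi-hosts (label noise correlated
#' with low publication counts).
#'
#' @param truth truth table from [generate_mites()].
#' @param mites mite trait table (publication counts).
#' @param detection_halfsat half-saturation publication count; 0 means
#'   perfect detection.
#' @param seed integer seed.
#' @return list: `assoc` (observed association table), `truth` (with
#'   `observed_label`, `observed_hosts` and `planted_noise` columns).
#' @export
inject_unobserved <- function(truth, mites, detection_halfsat = 5, seed = 1L) {
  set.seed(seed + 2000L)
  pubs <- mites$publication_count[match(truth$mite_id, mites$mite_id)]
  p_det <- if (detection_halfsat == 0) rep(1, nrow(truth)) else
    pubs / (pubs + detection_halfsat)
  obs_hosts <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hs <- strsplit(truth$true_hosts[i], ";", fixed = TRUE)[[1]]
    keep <- c(TRUE, stats::runif(length(hs) - 1) < p_det[i])
    obs_hosts[[i]] <- hs[keep]
  }
  assoc <- data.frame(
    mite_id = rep(truth$mite_id, lengths(obs_hosts)),
    host_id = unlist(obs_hosts, use.names = FALSE),
    credible = TRUE,
    stringsAsFactors = FALSE
  )
  truth$observed_hosts <- vapply(obs_hosts, paste, character(1), collapse = ";")
  truth$observed_label <- as.integer(lengths(obs_hosts) > 1)
  truth$planted_noise <- truth$true_label == 1L & truth$observed_label == 0L
  list(assoc = assoc, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generative chain (phylogeny, ranges, host traits, mites,
#' detection thinning) from one spec, bit-reproducibly in its seed.
#'
#' @param spec a [generative_spec()].
#' @return list with `tree`, `ranges`, `hosts`, `mites`, `assoc_true`,
#'   `assoc_observed`, `truth`, `features_generative`, `intercept`, `spec`.
#' @export
simulate_dataset <- function(spec = generative_spec()) {
  tree <- generate_phylogeny(spec$n_hosts, seed = spec$seed)
  ranges <- generate_ranges(tree, grid_dims = spec$grid_dims,
                            mean_range_cells = spec$mean_range_cells,
                            p_cluster = spec$p_cluster, seed = spec$seed + 1L)
  hosts <- generate_host_traits(tree, ranges, grid_dims = spec$grid_dims,
                                seed = spec$seed + 2L)
  gen <- generate_mites(spec, hosts, tree, ranges)
  obs <- inject_unobserved(gen$truth, gen$mites,
                           detection_halfsat = spec$detection_halfsat,
                           seed = spec$seed)
  list(tree = tree, ranges = ranges, hosts = hosts, mites = gen$mites,
       assoc_true = gen$assoc, assoc_observed = obs$assoc, truth = obs$truth,
       features_generative = gen$features, intercept = gen$intercept,
       spec = spec)
}
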