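#' Jaccard similarity of two geographic ranges
#'
#' Intersection-over-union of two sets of grid-cell ids:
#' \eqn{J = |A \cap B| / |A \cup B|}. Returns 0 when both ranges are empty
#' (degenerate convention for captive-only hosts).
#'
#' @param cells_a,cells_b integer vectors of grid-cell ids.
#' @return similarity in [0, 1].
#' @export
jaccard_overlap <- function(cells_a, cells_b) {
  a <- unique(cells_a); b <- unique(cells_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise geographic-overlap matrix
#'
#' Symmetric m-by-m matrix of Jaccard range overlaps across hosts; the
#' diagonal is 1 by convention (a host fully overlaps itself). Hosts with an
#' empty range score 0 against every other host and trigger a warning.
#'
#' @param ranges named list of integer cell-id vectors (one per host).
#' @return matrix of class `host_matrix` with kind `geo_overlap`.
#' @export
build_overlap_matrix <- function(ranges) {
  hosts <- names(ranges)
  if (is.null(hosts) || anyDuplicated(hosts))
    stop("ranges must be a uniquely named list")
  empty <- hosts[lengths(ranges) == 0]
  if (length(empty))
    warning("host(s) with empty range: ", paste(empty, collapse = ", "))
  n <- length(hosts)
  ## incidence-matrix formulation: |A∩B| from a crossproduct, |A∪B| from sizes
  cells <- sort(unique(unlist(ranges, use.names = FALSE)))
  M <- diag(1, n)
  if (length(cells)) {
    inc <- matrix(0L, n, length(cells))
    for (i in seq_len(n)) inc[i, match(ranges[[i]], cells)] <- 1L
    inter <- tcrossprod(inc)
    sizes <- lengths(ranges)
    un <- outer(sizes, sizes, "+") - inter
    M <- ifelse(un > 0, inter / un, 0)
    diag(M) <- 1
  }
  dimnames(M) <- list(hosts, hosts)
  structure(M, kind = "geo_overlap", class = c("host_matrix", "matrix"))
}

matrix_row <- function(M, host) {
  if (!host %in% rownames(M)) stop("host not in matrix: ", host)
  M[host, ]
}

#' Count co-distributed potential hosts
#'
#' Number of *other* mammal species whose Jaccard range overlap with `host`
#' strictly exceeds `cutoff` (a tied value of exactly 0.5 does not count).
#'
#' @param host host id present in `M`.
#' @param M geographic-overlap `host_matrix`.
#' @param cutoff overlap threshold (default 0.5).
#' @return integer count.
#' @export
count_codistributed <- function(host, M, cutoff = 0.5) {
  v <- matrix_row(M, host)
  sum(v[names(v) != host] > cutoff)
}

#' Count phylogenetically similar potential hosts
#'
#' Number of *other* mammal species whose patristic distance to `host` is
#' strictly below `cutoff` (a tied value of exactly 10 does not count).
#'
#' @param host host id present in `D`.
#' @param D phylogenetic-distance `host_matrix`.
#' @param cutoff patristic-distance threshold (default 10).
#' @return integer count.
#' @export
count_phylo_similar <- function(host, D, cutoff = 10) {
  v <- matrix_row(D, host)
  sum(v[names(v) != host] < cutoff)
}

## per-host availability counts for all hosts at once (vectorised)
host_availability_counts <- function(M, D, jaccard_cutoff = 0.5,
                                     pd_cutoff = 10) {
  go <- rowSums(M > jaccard_cutoff) - 1L          # diagonal is 1 > cutoff
  pd <- rowSums(D < pd_cutoff) - 1L               # diagonal is 0 < cutoff
  data.frame(host_id = rownames(M), n_CPH = as.integer(go),
             n_PSH10 = as.integer(pd[rownames(M)]),
             stringsAsFactors = FALSE)
}

#' Feature row for one mite species
#'
#' Aggregates host-level predictors over a mite's observed host set:
#' availability counts (`n_CPH_max`, `n_PSH10_max`) take the maximum over
#' hosts (the best-connected host is the most likely reservoir for a range
#' expansion); continuous host traits are averaged on the raw scale and log
#' transforms applied after averaging; `domesticated_host` is TRUE if any
#' observed host is domesticated. Human population density is logged as
#' `log(x + 1)` to tolerate zero-density ranges.
#'
#' @param mite one-row mite trait data.frame.
#' @param observed_hosts character vector of this mite's observed hosts.
#' @param go_matrix,pd_matrix overlap and patristic `host_matrix` objects.
#' @param host_traits host trait data.frame.
#' @param jaccard_cutoff,pd_cutoff availability-count thresholds.
#' @return one-row data.frame (a feature-table row); `NA` fields mark an
#'   incomplete row that is dropped downstream.
#' @export
mite_feature_row <- function(mite, observed_hosts, go_matrix, pd_matrix,
                             host_traits, jaccard_cutoff = 0.5,
                             pd_cutoff = 10) {
  stopifnot(length(observed_hosts) >= 1)
  ht <- host_traits[match(observed_hosts, host_traits$host_id), , drop = FALSE]
  if (anyNA(ht$host_id)) stop("unresolvable host(s) for mite ", mite$mite_id)
  cph <- vapply(observed_hosts, count_codistributed, integer(1),
                M = go_matrix, cutoff = jaccard_cutoff)
  psh <- vapply(observed_hosts, count_phylo_similar, integer(1),
                D = pd_matrix, cutoff = pd_cutoff)
  data.frame(
    mite_id = mite$mite_id,
    multihost = as.integer(length(observed_hosts) > 1),
    immunity_contact = mite$immunity_contact,
    parasitism = mite$parasitism,
    bioregion = mite$bioregion,
    dispersal_stage = mite$dispersal_stage,
    precop_guarding = mite$precop_guarding,
    n_CPH_max = max(cph),
    n_PSH10_max = max(psh),
    avg_litter_size = mean(ht$litter_size),
    domesticated_host = any(ht$domesticated),
    log_body_mass = log(mean(ht$body_mass)),
    avg_precip = mean(ht$mean_precip),
    avg_temp = mean(ht$mean_temp),
    log_human_pop_density = log(mean(ht$human_pop_density) + 1),
    publication_count = mite$publication_count,
    stringsAsFactors = FALSE
  )
}

#' Build the 13-predictor feature table
#'
#' One row per mite species with the binary multi-host label (1 if the
#' observed host count exceeds one) and the 13 predictors: five mite traits,
#' the two availability counts, four averaged host traits (litter size,
#' log body mass, precipitation, temperature), domestication status, and
#' log human population density. Rows with any missing predictor are dropped
#' (listwise) with a message reporting the count.
#'
#' @param assoc association data.frame (analysis view).
#' @param mites mite trait data.frame.
#' @param hosts host trait data.frame.
#' @param tree host phylogeny (`phylo`).
#' @param ranges named list of host ranges.
#' @param config [pipeline_config()] list (cutoffs read from it).
#' @return feature data.frame, one row per mite, class `feature_table`.
#' @export
build_feature_table <- function(assoc, mites, hosts, tree, ranges,
                                config = pipeline_config()) {
  report <- validate_dataset(assoc, hosts, mites, tree, ranges)
  assoc <- apply_validation(assoc, report)
  if (nrow(assoc) == 0) stop("no usable association records after validation")

  host_ids <- sort(unique(assoc$host_id))
  go <- build_overlap_matrix(ranges[host_ids])
  pd_full <- patristic_matrix(tree)
  pd <- structure(pd_full[host_ids, host_ids, drop = FALSE],
                  kind = "phylo_distance", class = c("host_matrix", "matrix"))
  counts <- host_availability_counts(go, pd, config$jaccard_cutoff,
                                     config$pd_cutoff)

  ht <- hosts[match(host_ids, hosts$host_id), ]
  idx <- match(assoc$host_id, host_ids)
  by_mite <- split(idx, assoc$mite_id)
  mt <- mites[match(names(by_mite), mites$mite_id), ]

  agg <- function(values, f) vapply(by_mite, function(i) f(values[i]), numeric(1))
  out <- data.frame(
    mite_id = names(by_mite),
    multihost = as.integer(lengths(by_mite) > 1),
    immunity_contact = mt$immunity_contact,
    parasitism = mt$parasitism,
    bioregion = mt$bioregion,
    dispersal_stage = mt$dispersal_stage,
    precop_guarding = mt$precop_guarding,
    n_CPH_max = agg(counts$n_CPH, max),
    n_PSH10_max = agg(counts$n_PSH10, max),
    avg_litter_size = agg(ht$litter_size, mean),
    domesticated_host = agg(ht$domesticated, function(x) any(x)) > 0,
    log_body_mass = log(agg(ht$body_mass, mean)),
    avg_precip = agg(ht$mean_precip, mean),
    avg_temp = agg(ht$mean_temp, mean),
    log_human_pop_density = log(agg(ht$human_pop_density, mean) + 1),
    publication_count = mt$publication_count,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  complete <- stats::complete.cases(out)
  if (any(!complete))
    message(sprintf("dropped %d incomplete feature row(s)", sum(!complete)))
  out <- out[complete, , drop = FALSE]
  if (nrow(out) == 0) stop("feature table is empty after listwise deletion")
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
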