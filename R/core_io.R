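#' @keywords internal
"_PACKAGE"

## Enum levels shared across readers, generators and design builders.
IMMUNITY_LEVELS  <- c("primary", "secondary", "none")
PARASITISM_LEVELS <- c("endo", "ecto")
BIOREGION_LEVELS <- c("singleregion", "multiregion")
DISPERSAL_LEVELS <- c("IMM", "F", "F_IMM")

#' Default pipeline configuration
#'
#' Central place for the thresholds and resampling settings used across the
#' pipeline: the Jaccard co-distribution cutoff (overlap must exceed 0.5),
#' the phylogenetic-similarity cutoff (patristic distance below 10), the
#' classification cutoff (0.5), the risk-group probability threshold (0.7),
#' cross-validation design (5 folds, 5 repeats), the train fraction
#' (1024/1445), and the sharing-model bin specification (patristic-distance
#' bins of width 20 on [0, 180], geographic-overlap bins of width 0.1 on
#' [0, 1], at most 1000 pairs retained per bin).
#'
#' @param ... named overrides of any default element (nested lists are
#'   replaced wholesale).
#' @return A named list of class `acarange_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    jaccard_cutoff  = 0.5,
    pd_cutoff       = 10,
    classify_cutoff = 0.5,
    risk_threshold  = 0.7,
    enrich_thresholds = c(0.5, 0.7, 0.8, 0.9),
    folds   = 5L,
    repeats = 5L,
    train_fraction = 1024 / 1445,
    seeds = list(split = 1L, cv = 2L, resample = 3L, pu = 4L, synth = 5L),
    strategy = "down",
    sharing_bins = list(pd_edges = seq(0, 180, by = 20),
                        go_edges = seq(0, 1, by = 0.1),
                        max_per_bin = 1000L)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$folds >= 2, cfg$train_fraction > 0, cfg$train_fraction < 1,
            all(unlist(cfg[c("jaccard_cutoff", "classify_cutoff",
                             "risk_threshold")]) >= 0),
            all(unlist(cfg[c("jaccard_cutoff", "classify_cutoff",
                             "risk_threshold")]) <= 1))
  structure(cfg, class = c("acarange_config", "list"))
}

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(what, " file is empty: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a mite-host association table
#'
#' Expects a CSV with columns `mite_id`, `host_id`, `credible`. Duplicate
#' (mite, host) pairs are collapsed with a warning. Records flagged as
#' low-credibility (possible sample cross-contamination) are excluded from
#' the analysis view by default; pass `credible_only = FALSE` to keep them.
#'
#' @param path CSV file path.
#' @param credible_only drop rows with `credible == FALSE` (default `TRUE`).
#' @return data.frame with columns mite_id, host_id, credible.
#' @export
read_association_table <- function(path, credible_only = TRUE) {
  df <- read_checked_csv(path, c("mite_id", "host_id", "credible"),
                         "association")
  as_association_table(df, credible_only = credible_only)
}

#' Construct/validate an association table from a data.frame
#' @param df data.frame with mite_id, host_id, credible columns.
#' @param credible_only drop low-credibility rows.
#' @return validated association data.frame.
#' @export
as_association_table <- function(df, credible_only = TRUE) {
  stopifnot(all(c("mite_id", "host_id", "credible") %in% names(df)))
  df$mite_id <- as.character(df$mite_id)
  df$host_id <- as.character(df$host_id)
  df$credible <- as.logical(df$credible)
  if (anyNA(df$credible)) stop("credible column must be TRUE/FALSE")
  key <- paste(df$mite_id, df$host_id, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf("collapsed %d duplicate (mite, host) pair(s)", ndup))
    ## a pair is credible unless every record of it was flagged
    cred <- tapply(df$credible, key, any)
    df <- df[!duplicated(key), , drop = FALSE]
    df$credible <- as.logical(cred[paste(df$mite_id, df$host_id, sep = "\r")])
  }
  if (credible_only) df <- df[df$credible, , drop = FALSE]
  if (nrow(df) == 0) stop("association table has no usable records")
  rownames(df) <- NULL
  df[, c("mite_id", "host_id", "credible")]
}

#' Read a mite trait table
#'
#' CSV columns: `mite_id`, `immunity_contact` (primary/secondary/none),
#' `parasitism` (ecto/endo), `bioregion` (singleregion/multiregion),
#' `dispersal_stage` (IMM/F/F_IMM), `precop_guarding` (logical),
#' `publication_count` (non-negative integer). Empty strings are treated as
#' missing and flagged by [validate_dataset()].
#'
#' @param path CSV file path.
#' @return data.frame of mite traits with factor-coded enums.
#' @export
read_mite_traits <- function(path) {
  df <- read_checked_csv(path, c("mite_id", "immunity_contact", "parasitism",
                                 "bioregion", "dispersal_stage",
                                 "precop_guarding", "publication_count"),
                         "mite trait")
  df$mite_id <- as.character(df$mite_id)
  if (anyDuplicated(df$mite_id)) stop("duplicate mite_id in trait table")
  for (col in c("immunity_contact", "parasitism", "bioregion",
                "dispersal_stage")) {
    lv <- switch(col,
                 immunity_contact = IMMUNITY_LEVELS,
                 parasitism = PARASITISM_LEVELS,
                 bioregion = BIOREGION_LEVELS,
                 dispersal_stage = DISPERSAL_LEVELS)
    v <- as.character(df[[col]])
    v[v == ""] <- NA
    bad <- setdiff(unique(v[!is.na(v)]), lv)
    if (length(bad))
      stop("invalid ", col, " level(s): ", paste(bad, collapse = ", "))
    df[[col]] <- factor(v, levels = lv)
  }
  df$precop_guarding <- as.logical(df$precop_guarding)
  df$publication_count <- as.integer(df$publication_count)
  if (any(df$publication_count < 0, na.rm = TRUE))
    stop("publication_count must be non-negative")
  df
}

#' Read a host trait table
#'
#' CSV columns: `host_id`, `order` (taxon label), `domesticated` (logical),
#' `litter_size` (offspring per litter, > 0), `body_mass` (grams, > 0),
#' `mean_precip` (mm/month), `mean_temp` (0.1 degC units; may be negative),
#' `human_pop_density` (persons per km^2).
#'
#' @param path CSV file path.
#' @return data.frame of host traits.
#' @export
read_host_traits <- function(path) {
  df <- read_checked_csv(path, c("host_id", "order", "domesticated",
                                 "litter_size", "body_mass", "mean_precip",
                                 "mean_temp", "human_pop_density"),
                         "host trait")
  df$host_id <- as.character(df$host_id)
  if (anyDuplicated(df$host_id)) stop("duplicate host_id in trait table")
  df$order <- as.character(df$order)
  df$domesticated <- as.logical(df$domesticated)
  for (col in c("litter_size", "body_mass", "mean_precip", "mean_temp",
                "human_pop_density"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$litter_size <= 0, na.rm = TRUE) ||
      any(df$body_mass <= 0, na.rm = TRUE))
    stop("litter_size and body_mass must be strictly positive")
  if (any(df$mean_precip < 0, na.rm = TRUE) ||
      any(df$human_pop_density < 0, na.rm = TRUE))
    stop("mean_precip and human_pop_density must be non-negative")
  df
}

#' Read host geographic ranges (long format)
#'
#' CSV columns `host_id`, `cell_id` (integer grid-cell identifiers). A host
#' absent from the file has an empty range (e.g. captive-only hosts).
#'
#' @param path CSV file path.
#' @return named list mapping host_id to an integer vector of cell ids.
#' @export
read_ranges <- function(path) {
  df <- read_checked_csv(path, c("host_id", "cell_id"), "range")
  df$host_id <- as.character(df$host_id)
  df$cell_id <- as.integer(df$cell_id)
  lapply(split(df$cell_id, df$host_id), function(x) sort(unique(x)))
}

#' Read a host phylogeny in Newick format
#'
#' Wraps [ape::read.tree()] with the checks the pipeline relies on: branch
#' lengths must be present and tip labels (host ids) unique. Polytomies are
#' accepted.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` object.
#' @export
read_newick_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length)) stop("phylogeny lacks branch lengths")
  if (anyNA(tree$edge.length)) stop("phylogeny has missing branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Pairwise patristic distances as a labeled host matrix
#'
#' @param tree `phylo` object from [read_newick_tree()].
#' @return symmetric matrix (class `host_matrix`, kind `phylo_distance`)
#'   of branch-length path distances; diagonal 0.
#' @export
patristic_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  structure(D, kind = "phylo_distance", class = c("host_matrix", "matrix"))
}

## ---- writers (round-trip partners of the readers) ----

#' Write pipeline tables back to CSV
#'
#' Writers paired with the readers so that a write/read round trip is the
#' identity on contents.
#'
#' @param x table to write (see the matching reader for its shape).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  utils::write.csv(x[, c("mite_id", "host_id", "credible")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
write_mite_traits <- function(x, path) {
  out <- x
  for (col in c("immunity_contact", "parasitism", "bioregion",
                "dispersal_stage"))
    out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
write_host_traits <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
write_ranges <- function(x, path) {
  df <- data.frame(
    host_id = rep(names(x), lengths(x)),
    cell_id = unlist(x, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- validation ----

#' Validate a dataset before feature construction
#'
#' Reports hosts referenced by the associations that cannot be resolved
#' against the trait table, the phylogeny or the range file, and mites or
#' hosts with missing trait values. Mite species with a missing value in any
#' predictor-relevant trait are marked for listwise exclusion downstream,
#' mirroring complete-case analysis at the species-row level.
#'
#' @param assoc association data.frame.
#' @param hosts host trait data.frame.
#' @param mites mite trait data.frame.
#' @param tree host phylogeny (`phylo`), or NULL to skip tree checks.
#' @param ranges named list of host ranges, or NULL to skip range checks.
#' @return list of class `acarange_validation` with elements
#'   `unresolvable_hosts`, `unresolvable_mites`, `hosts_missing_from_tree`,
#'   `hosts_missing_from_ranges`, `mites_missing_traits`,
#'   `hosts_missing_traits`, `excluded_mites`.
#' @export
validate_dataset <- function(assoc, hosts, mites, tree = NULL, ranges = NULL) {
  ah <- unique(assoc$host_id)
  am <- unique(assoc$mite_id)
  rep_hosts_tree <- if (!is.null(tree)) setdiff(ah, tree$tip.label) else character()
  rep_hosts_rng  <- if (!is.null(ranges)) setdiff(ah, names(ranges)) else character()
  unresolvable_hosts <- setdiff(ah, hosts$host_id)
  unresolvable_mites <- setdiff(am, mites$mite_id)

  mite_trait_cols <- c("immunity_contact", "parasitism", "bioregion",
                       "dispersal_stage", "precop_guarding",
                       "publication_count")
  mm <- mites$mite_id[rowSums(is.na(mites[mite_trait_cols])) > 0]
  host_trait_cols <- c("order", "domesticated", "litter_size", "body_mass",
                       "mean_precip", "mean_temp", "human_pop_density")
  hm <- hosts$host_id[rowSums(is.na(hosts[host_trait_cols])) > 0]

  ## a mite is excluded if its traits are incomplete, unresolvable, or any
  ## of its hosts is unresolvable / missing traits / absent from tree or ranges
  bad_hosts <- unique(c(unresolvable_hosts, hm, rep_hosts_tree, rep_hosts_rng))
  mites_with_bad_host <- unique(assoc$mite_id[assoc$host_id %in% bad_hosts])
  excluded <- sort(unique(c(mm, unresolvable_mites, mites_with_bad_host)))

  structure(list(
    unresolvable_hosts = sort(unresolvable_hosts),
    unresolvable_mites = sort(unresolvable_mites),
    hosts_missing_from_tree = sort(rep_hosts_tree),
    hosts_missing_from_ranges = sort(rep_hosts_rng),
    mites_missing_traits = sort(mm),
    hosts_missing_traits = sort(hm),
    excluded_mites = excluded
  ), class = "acarange_validation")
}

#' @export
print.acarange_validation <- function(x, ...) {
  if (validation_clean(x)) {
    cat("dataset validation: clean\n")
  } else {
    for (nm in names(x))
      if (length(x[[nm]]))
        cat(nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Is a validation report empty?
#' @param report result of [validate_dataset()].
#' @return `TRUE` when no issues were found.
#' @export
validation_clean <- function(report) {
  all(lengths(report) == 0)
}

#' Drop records flagged by a validation report
#'
#' Applies listwise exclusion: removes excluded mites from the association
#' table, and drops association rows whose host cannot be resolved.
#'
#' @param assoc association data.frame.
#' @param report result of [validate_dataset()].
#' @return filtered association data.frame.
#' @export
apply_validation <- function(assoc, report) {
  bad_hosts <- unique(c(report$unresolvable_hosts,
                        report$hosts_missing_from_tree,
                        report$hosts_missing_from_ranges,
                        report$hosts_missing_traits))
  keep <- !(assoc$mite_id %in% report$excluded_mites) &
    !(assoc$host_id %in% bad_hosts)
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
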