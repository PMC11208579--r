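## Pipeline stage runners: thin, file-oriented wrappers over the package
## functions. The Rscript front-end in inst/cli/acarange.R dispatches to
## these; they are equally usable from an interactive session.

write_manifest <- function(out_dir, stage, seeds, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seeds = seeds,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write feature tables; read them back
#'
#' The feature CSV has a stable, documented column order (identifier,
#' label, five mite traits, two availability counts, five host/environment
#' predictors, publication count); enum columns are serialised as literal
#' level names.
#'
#' @param features feature table.
#' @param path CSV path.
#' @return the path (writer) or the feature table (reader).
#' @export
write_feature_table <- function(features, path) {
  out <- as.data.frame(features)
  for (col in c("immunity_contact", "parasitism", "bioregion",
                "dispersal_stage"))
    out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_checked_csv(path, c("mite_id", "multihost", "immunity_contact",
                                 "parasitism", "bioregion", "dispersal_stage",
                                 "precop_guarding", "n_CPH_max", "n_PSH10_max",
                                 "avg_litter_size", "domesticated_host",
                                 "log_body_mass", "avg_precip", "avg_temp",
                                 "log_human_pop_density",
                                 "publication_count"),
                         "feature")
  df$immunity_contact <- factor(df$immunity_contact, levels = IMMUNITY_LEVELS)
  df$parasitism <- factor(df$parasitism, levels = PARASITISM_LEVELS)
  df$bioregion <- factor(df$bioregion, levels = BIOREGION_LEVELS)
  df$dispersal_stage <- factor(df$dispersal_stage, levels = DISPERSAL_LEVELS)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Simulate a dataset and write it as pipeline input files
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [generative_spec()].
#' @return named vector of file paths, invisibly.
#' @export
run_simulate <- function(out_dir, spec = generative_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(spec)
  paths <- c(
    assoc = file.path(out_dir, "associations.csv"),
    mites = file.path(out_dir, "mite_traits.csv"),
    hosts = file.path(out_dir, "host_traits.csv"),
    ranges = file.path(out_dir, "ranges.csv"),
    tree = file.path(out_dir, "host_tree.nwk"),
    truth = file.path(out_dir, "truth.csv")
  )
  write_association_table(sim$assoc_observed, paths["assoc"])
  write_mite_traits(sim$mites, paths["mites"])
  write_host_traits(sim$hosts, paths["hosts"])
  write_ranges(sim$ranges, paths["ranges"])
  ape::write.tree(sim$tree, paths["tree"])
  utils::write.csv(sim$truth[, c("mite_id", "true_label", "observed_label",
                                 "planted_noise")],
                   paths["truth"], row.names = FALSE)
  write_manifest(out_dir, "simulate", seeds = list(synth = spec$seed),
                 inputs = list(), outputs = as.list(paths))
  invisible(paths)
}

#' Build and write the feature table from input files
#'
#' @param in_dir directory holding the files written by [run_simulate()]
#'   (or equivalently shaped real data).
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @return path of the feature CSV, invisibly.
#' @export
run_features <- function(in_dir, out_dir = in_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- read_association_table(file.path(in_dir, "associations.csv"))
  mites <- read_mite_traits(file.path(in_dir, "mite_traits.csv"))
  hosts <- read_host_traits(file.path(in_dir, "host_traits.csv"))
  ranges <- read_ranges(file.path(in_dir, "ranges.csv"))
  tree <- read_newick_tree(file.path(in_dir, "host_tree.nwk"))
  report <- validate_dataset(assoc, hosts, mites, tree, ranges)
  features <- build_feature_table(assoc, mites, hosts, tree, ranges, config)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(features, fpath)
  vpath <- file.path(out_dir, "validation.json")
  jsonlite::write_json(unclass(report), vpath, auto_unbox = FALSE)
  write_manifest(out_dir, "features", seeds = list(),
                 inputs = lapply(c("associations.csv", "mite_traits.csv",
                                   "host_traits.csv", "ranges.csv",
                                   "host_tree.nwk"),
                                 function(f) file.path(in_dir, f)),
                 outputs = list(fpath, vpath))
  invisible(fpath)
}

#' Compare the five strategies and write the comparison tables
#'
#' @param features_csv feature CSV path.
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @param strategies strategies to compare.
#' @param pu_iterations AdaSampling rounds.
#' @return the [compare_strategies()] result, invisibly; CV and holdout
#'   tables plus the chosen strategy are written as CSV/JSON.
#' @export
run_compare <- function(features_csv, out_dir,
                        config = pipeline_config(),
                        strategies = STRATEGIES, pu_iterations = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- read_feature_table(features_csv)
  split <- train_test_split(features, config$train_fraction,
                            seed = config$seeds$split)
  cmp <- compare_strategies(split$train, split$test, strategies = strategies,
                            config = config, seed = config$seeds$cv,
                            pu_iterations = pu_iterations)
  cv_path <- file.path(out_dir, "strategy_cv.csv")
  utils::write.csv(cmp$ranking$table, cv_path, row.names = FALSE)
  hold_path <- file.path(out_dir, "strategy_holdout.csv")
  utils::write.csv(cmp$holdout, hold_path, row.names = FALSE)
  chosen_path <- file.path(out_dir, "chosen_strategy.json")
  jsonlite::write_json(list(chosen = cmp$chosen), chosen_path,
                       auto_unbox = TRUE)
  write_manifest(out_dir, "compare",
                 seeds = config$seeds[c("split", "cv")],
                 inputs = list(features_csv),
                 outputs = list(cv_path, hold_path, chosen_path))
  invisible(cmp)
}

#' Forecast the multi-host risk group and write enrichment tables
#'
#' Refits the requested strategy on the training partition, scores the
#' combined (train plus holdout) population with unmodified features, and
#' writes the confusion matrix, one risk-group CSV per threshold, and the
#' per-order enrichment table with its observation-count footer.
#'
#' @param features_csv feature CSV path.
#' @param orders named vector mite_id -> host order (see
#'   [mite_host_orders()]).
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @param strategy strategy for the final model (default from config).
#' @return the [forecast_report()] result, invisibly.
#' @export
run_forecast <- function(features_csv, orders, out_dir,
                         config = pipeline_config(),
                         strategy = config$strategy) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- read_feature_table(features_csv)
  split <- train_test_split(features, config$train_fraction,
                            seed = config$seeds$split)
  model <- fit_strategy(split$train, strategy, seed = config$seeds$resample)
  ord <- unname(orders[features$mite_id])
  rep <- forecast_report(model, features, ord, config = config)
  out_paths <- character()
  cpath <- file.path(out_dir, "confusion.csv")
  utils::write.csv(as.data.frame(rep$confusion), cpath, row.names = FALSE)
  out_paths <- c(out_paths, cpath)
  for (nm in names(rep$risk_groups)) {
    p <- file.path(out_dir, paste0("risk_group_", nm, ".csv"))
    utils::write.csv(as.data.frame(rep$risk_groups[[nm]]), p,
                     row.names = FALSE)
    out_paths <- c(out_paths, p)
  }
  epath <- file.path(out_dir, "enrichment.csv")
  etab <- rep$enrichment$table
  footer <- c("Observations (n)", rep$enrichment$n_single,
              as.integer(rep$enrichment$counts))
  utils::write.csv(rbind(etab, stats::setNames(as.list(footer), names(etab))),
                   epath, row.names = FALSE)
  out_paths <- c(out_paths, epath)
  spath <- file.path(out_dir, "scores.csv")
  utils::write.csv(rep$scores, spath, row.names = FALSE)
  out_paths <- c(out_paths, spath)
  write_manifest(out_dir, "forecast",
                 seeds = config$seeds[c("split", "resample")],
                 inputs = list(features_csv), outputs = as.list(out_paths))
  invisible(rep)
}

#' Fit the mite-sharing model from input files and write its outputs
#'
#' @param in_dir directory with association, range and tree files.
#' @param out_dir output directory.
#' @param config [pipeline_config()] (bin spec read from it).
#' @return list with the pair table, fit and surface, invisibly.
#' @export
run_sharing <- function(in_dir, out_dir = in_dir,
                        config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- read_association_table(file.path(in_dir, "associations.csv"))
  ranges <- read_ranges(file.path(in_dir, "ranges.csv"))
  tree <- read_newick_tree(file.path(in_dir, "host_tree.nwk"))
  proj <- project_unipartite(assoc)
  connected <- setdiff(unique(assoc$host_id), proj$excluded)
  pd <- patristic_matrix(tree)
  go <- build_overlap_matrix(ranges[intersect(connected, names(ranges))])
  pairs <- build_pair_table(proj$edges, connected, pd, go)
  bs <- bin_spec(pd_edges = config$sharing_bins$pd_edges,
                 go_edges = config$sharing_bins$go_edges,
                 max_per_bin = config$sharing_bins$max_per_bin,
                 seed = config$seeds$resample)
  sub <- bin_subsample(pairs, bs)
  fit <- fit_sharing_glm(sub)
  ppath <- file.path(out_dir, "sharing_pairs.csv")
  utils::write.csv(as.data.frame(sub), ppath, row.names = FALSE)
  fpath <- file.path(out_dir, "sharing_fit.csv")
  utils::write.csv(summary(fit), fpath, row.names = FALSE)
  surf <- sharing_surface(fit)
  gpath <- file.path(out_dir, "sharing_surface.csv")
  utils::write.csv(surf, gpath, row.names = FALSE)
  write_manifest(out_dir, "sharing",
                 seeds = config$seeds["resample"],
                 inputs = lapply(c("associations.csv", "ranges.csv",
                                   "host_tree.nwk"),
                                 function(f) file.path(in_dir, f)),
                 outputs = list(ppath, fpath, gpath))
  invisible(list(pairs = sub, fit = fit, surface = surf,
                 excluded = proj$excluded))
}
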