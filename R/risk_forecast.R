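#' Confusion matrix at a probability cutoff
#'
#' Counts of (observed, predicted) label pairs; a score strictly above the
#' cutoff predicts multihost.
#'
#' @param scores probability vector in [0, 1].
#' @param labels observed binary labels (1 = multihost).
#' @param cutoff classification cutoff (default 0.5).
#' @return 2x2 integer matrix, rows = observed, columns = predicted.
#' @export
confusion_matrix <- function(scores, labels, cutoff = 0.5) {
  stopifnot(all(scores >= 0), all(scores <= 1))
  pred <- factor(as.integer(scores > cutoff), levels = c(0, 1),
                 labels = c("singlehost", "multihost"))
  obs <- factor(as.integer(labels), levels = c(0, 1),
                labels = c("singlehost", "multihost"))
  table(observed = obs, predicted = pred)
}

#' Extract the multi-host risk group
#'
#' Observed single-host mites whose predicted multi-host probability is
#' strictly above the threshold, sorted by descending score: the candidates
#' for unobserved multi-host status / imminent host-range expansion.
#'
#' @param scores probability vector.
#' @param labels observed labels (1 = multihost).
#' @param mite_ids mite identifiers aligned with `scores`.
#' @param threshold probability threshold in (0, 1) (default 0.7).
#' @param orders optional host-order labels aligned with `scores`.
#' @return data.frame of class `risk_group` (mite_id, score, and order if
#'   given), with the threshold stored as an attribute.
#' @export
extract_risk_group <- function(scores, labels, mite_ids, threshold = 0.7,
                               orders = NULL) {
  stopifnot(threshold > 0, threshold < 1 || threshold == 1)
  member <- labels == 0 & scores > threshold
  out <- data.frame(mite_id = mite_ids[member], score = scores[member],
                    stringsAsFactors = FALSE)
  if (!is.null(orders)) out$order <- orders[member]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("risk_group", "data.frame")
  out
}

#' Per-host-order enrichment of the risk group
#'
#' For each host order o and threshold t,
#' `delta_o(t) = 100 * (risk-group members in o / risk-group size)
#'             - 100 * (observed single-hosts in o / total single-hosts)`.
#' The baseline column is each order's percentage share of observed
#' single-hosts; an order with no risk-group members gets
#' `delta = -baseline`. Each delta column sums to zero up to rounding. A
#' threshold with an empty risk group yields an NA column and a warning.
#'
#' @param scores probability vector over all scored mites.
#' @param labels observed labels (1 = multihost).
#' @param orders host-order label per mite (single-host mites inherit their
#'   one host's order).
#' @param thresholds probability thresholds for the delta columns.
#' @return list of class `enrichment_table`: `table` (order, baseline
#'   percentage, one delta column per threshold) and `counts` (risk-group
#'   size per threshold, the observation-count footer).
#' @export
order_enrichment <- function(scores, labels, orders,
                             thresholds = c(0.5, 0.7, 0.8, 0.9)) {
  single <- labels == 0
  if (!any(single)) stop("no observed single-hosts to analyse")
  base_tab <- table(orders[single])
  ord_names <- names(base_tab)
  baseline <- 100 * as.numeric(base_tab) / sum(base_tab)
  out <- data.frame(order = ord_names, single_host_pct = baseline,
                    stringsAsFactors = FALSE)
  counts <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    member <- single & scores > t
    counts[i] <- sum(member)
    col <- paste0("delta_", format(t, trim = TRUE))
    if (counts[i] == 0) {
      warning("empty risk group at threshold ", t, "; delta undefined")
      out[[col]] <- NA_real_
    } else {
      grp <- table(factor(orders[member], levels = ord_names))
      out[[col]] <- 100 * as.numeric(grp) / counts[i] - baseline
    }
  }
  structure(list(table = out,
                 counts = stats::setNames(counts,
                                          format(thresholds, trim = TRUE)),
                 n_single = sum(single)),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  print(x$table, digits = 3)
  cat("Observations (n):",
      paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Combined forecasting report
#'
#' Scores the full population (training plus holdout rows, unmodified
#' features) with a fitted strategy model, builds the confusion matrix at
#' the classification cutoff, and extracts risk groups with per-order
#' enrichment at each configured threshold.
#'
#' @param model `hostrange_model` from [fit_strategy()].
#' @param features feature table covering all mites to score.
#' @param orders host-order label per feature row.
#' @param config [pipeline_config()] (cutoff and thresholds read from it).
#' @return list of class `forecast_report`: `scores` (data.frame mite_id,
#'   observed, score), `confusion`, `risk_groups` (one per threshold),
#'   `enrichment`.
#' @export
forecast_report <- function(model, features, orders,
                            config = pipeline_config()) {
  scores <- predict_model(model, features)
  labels <- features$multihost
  rg <- lapply(config$enrich_thresholds, function(t)
    extract_risk_group(scores, labels, features$mite_id, threshold = t,
                       orders = orders))
  names(rg) <- format(config$enrich_thresholds, trim = TRUE)
  structure(list(
    scores = data.frame(mite_id = features$mite_id, observed = labels,
                        score = scores, stringsAsFactors = FALSE),
    confusion = confusion_matrix(scores, labels,
                                 cutoff = config$classify_cutoff),
    risk_groups = rg,
    enrichment = order_enrichment(scores, labels, orders,
                                  thresholds = config$enrich_thresholds)
  ), class = "forecast_report")
}

#' Host order per mite species
#'
#' Single-host mites inherit their one host's order; for multi-host mites
#' (excluded from enrichment baselines) the first observed host's order is
#' recorded.
#'
#' @param assoc association data.frame (analysis view).
#' @param hosts host trait data.frame.
#' @return named character vector mite_id -> order.
#' @export
mite_host_orders <- function(assoc, hosts) {
  ord <- hosts$order[match(assoc$host_id, hosts$host_id)]
  vapply(split(ord, assoc$mite_id), function(x) x[1], character(1))
}
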