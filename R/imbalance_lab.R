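STRATEGIES <- c("none", "weighted", "down", "up", "pu_ada")

#' Strategy specification
#'
#' One of the five modelling strategies compared for the host-range model:
#' `none` (baseline GLM), `weighted` (publication-count case weights),
#' `down` (majority class down-sampled to minority size), `up` (minority
#' up-sampled with replacement to majority size), `pu_ada`
#' (positive-unlabeled learning with an AdaSampling loop over an SVM).
#'
#' @param name strategy name.
#' @param pu_iterations AdaSampling iterations (default 10).
#' @param weight_threshold publication count granting full weight.
#' @param seed optional strategy seed.
#' @return list of class `strategy_spec`.
#' @export
strategy_spec <- function(name = STRATEGIES, pu_iterations = 10L,
                          weight_threshold = 10L, seed = NULL) {
  name <- match.arg(name)
  structure(list(name = name, pu_iterations = as.integer(pu_iterations),
                 weight_threshold = as.integer(weight_threshold), seed = seed),
            class = "strategy_spec")
}

#' Random train/test split
#'
#' Simple random split without stratification. The training size is
#' `round(train_fraction * n)`; remaining rows form the test set. The two
#' parts are disjoint and exhaustive.
#'
#' @param features feature table.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
train_test_split <- function(features, train_fraction = 1024 / 1445,
                             seed = 1L) {
  n <- nrow(features)
  if (n < 10) stop("too few rows to split (n < 10)")
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  n_train <- round(train_fraction * n)
  idx <- sample.int(n, n_train)
  list(train = features[sort(idx), , drop = FALSE],
       test = features[-sort(idx), , drop = FALSE])
}

#' Publication-count case weights
#'
#' Weight `0.2 + (pubs >= 10) * 0.8`: full weight for species with at least
#' 10 publications, 0.2 for under-studied species, down-weighting records
#' whose single-host label is least trustworthy.
#'
#' @param pub_counts non-negative integer vector.
#' @param threshold publication count granting full weight (default 10).
#' @return numeric weight vector (0.2 or 1).
#' @export
publication_weights <- function(pub_counts, threshold = 10) {
  if (any(pub_counts < 0, na.rm = TRUE))
    stop("publication counts must be non-negative")
  0.2 + as.numeric(pub_counts >= threshold) * 0.8
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
}

#' Down-sample the majority class
#'
#' Subsamples the majority class without replacement to the minority size;
#' minority rows are untouched. Row identity is preserved (no fabricated
#' feature values).
#'
#' @param train feature table with a `multihost` column.
#' @param seed integer seed.
#' @return balanced feature table (a subset of `train`'s rows).
#' @export
downsample <- function(train, seed = 1L) {
  check_two_classes(train$multihost)
  set.seed(seed)
  tab <- table(train$multihost)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) return(train)
  maj_idx <- which(train$multihost == as.integer(majority))
  keep <- sort(c(which(train$multihost == as.integer(minority)),
                 sample(maj_idx, tab[[minority]])))
  out <- train[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Up-sample the minority class
#'
#' Resamples the minority class with replacement up to the majority size;
#' every output row exists in the input.
#'
#' @param train feature table with a `multihost` column.
#' @param seed integer seed.
#' @return balanced feature table.
#' @export
upsample <- function(train, seed = 1L) {
  check_two_classes(train$multihost)
  set.seed(seed)
  tab <- table(train$multihost)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) return(train)
  min_idx <- which(train$multihost == as.integer(minority))
  extra <- sample(min_idx, tab[[majority]] - tab[[minority]], replace = TRUE)
  out <- train[c(seq_len(nrow(train)), extra), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## numeric SVM input: the host-range design matrix without its intercept
svm_design <- function(features, specs = NULL) {
  d <- build_hostrange_design(features, specs = specs)
  list(X = d$X[, -1, drop = FALSE], specs = d$specs)
}

#' Positive-unlabeled learning with an AdaSampling loop
#'
#' Treats observed multi-hosts as the only reliably labeled (positive)
#' class and observed single-hosts as unlabeled (a mixture of true
#' single-hosts and unobserved multi-hosts). Each unlabeled row starts with
#' positive-class probability 0.5; at every iteration, unlabeled rows enter
#' the training sample as negatives with their current negative-class
#' probability, a radial-kernel SVM with probability calibration is fitted,
#' and the unlabeled rows' probabilities are updated from its predictions.
#' The loop stops after `iterations` rounds or when the maximum absolute
#' probability change drops below 1e-3.
#'
#' @param features feature table.
#' @param labels binary labels (1 = observed multihost/positive).
#' @param iterations maximum AdaSampling rounds (0 returns the
#'   initialization, flagged as not converged).
#' @param seed integer seed.
#' @param specs optional spline specs to reuse for the numeric design.
#' @return object of class `pu_fit`: `scores` (positive-class probability
#'   per row), `model` (final SVM or NULL when `iterations = 0`), `specs`,
#'   `converged`, `iterations_run`.
#' @export
adasampling_pu <- function(features, labels, iterations = 10L, seed = 1L,
                           specs = NULL) {
  labels <- as.integer(labels)
  if (!any(labels == 1)) stop("PU learning requires at least one positive")
  set.seed(seed)
  d <- svm_design(features, specs = specs)
  X <- d$X
  pos <- which(labels == 1)
  unl <- which(labels == 0)
  p_pos <- rep(0.5, length(unl))       # positive-class prob of unlabeled rows
  scores <- rep(0.5, nrow(X))
  scores[pos] <- 1
  model <- NULL
  converged <- FALSE
  t_run <- 0L
  for (t in seq_len(iterations)) {
    as_neg <- unl[stats::runif(length(unl)) >= p_pos]   # prob 1 - p_pos
    if (length(as_neg) < 2) as_neg <- unl[order(p_pos)][1:2]
    tr_idx <- c(pos, as_neg)
    yf <- factor(c(rep(1, length(pos)), rep(0, length(as_neg))),
                 levels = c(0, 1))
    model <- tryCatch(
      e1071::svm(X[tr_idx, , drop = FALSE], yf, kernel = "radial",
                 probability = TRUE, scale = apply(X[tr_idx, , drop = FALSE],
                                                   2, stats::sd) > 0),
      error = function(e) stop("PU base classifier failed: ",
                               conditionMessage(e)))
    pr <- attr(stats::predict(model, X[unl, , drop = FALSE],
                              probability = TRUE), "probabilities")[, "1"]
    delta <- max(abs(pr - p_pos))
    p_pos <- pr
    t_run <- t
    if (delta < 1e-3) { converged <- TRUE; break }
  }
  if (!is.null(model)) {
    pr_all <- attr(stats::predict(model, X, probability = TRUE),
                   "probabilities")[, "1"]
    scores <- as.numeric(pr_all)
  }
  structure(list(scores = scores, model = model, specs = d$specs,
                 converged = converged, iterations_run = t_run),
            class = "pu_fit")
}

#' Fit one strategy's final model on a training set
#'
#' Applies the strategy's resampling or weighting to the training data and
#' fits the corresponding classifier: a spline-logistic GLM for `none`,
#' `weighted`, `down` and `up`, or the AdaSampling SVM for `pu_ada`.
#'
#' @param train training feature table.
#' @param strategy a [strategy_spec()] or strategy name.
#' @param seed integer seed for the strategy's randomness.
#' @return object of class `hostrange_model` with a [predict_model()]
#'   method; carries the strategy name and resampled class counts.
#' @export
fit_strategy <- function(train, strategy = "none", seed = 1L) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  stopifnot(inherits(strategy, "strategy_spec"))
  data <- switch(strategy$name,
    none = train,
    weighted = train,
    down = downsample(train, seed = seed),
    up = upsample(train, seed = seed),
    pu_ada = train
  )
  counts <- table(factor(data$multihost, levels = c(0, 1)))
  fit <- switch(strategy$name,
    weighted = fit_hostrange(data,
      weights = publication_weights(data$publication_count,
                                    strategy$weight_threshold)),
    pu_ada = adasampling_pu(data, data$multihost,
                            iterations = strategy$pu_iterations, seed = seed),
    fit_hostrange(data)
  )
  structure(list(strategy = strategy$name, fit = fit,
                 class_counts = c(singlehost = unname(counts["0"]),
                                  multihost = unname(counts["1"]))),
            class = "hostrange_model")
}

#' Score feature rows with a fitted strategy model
#'
#' @param model a `hostrange_model` from [fit_strategy()].
#' @param features feature table rows to score (unmodified).
#' @return numeric vector of multi-host probabilities.
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "hostrange_model"))
  if (model$strategy == "pu_ada") {
    pu <- model$fit
    if (is.null(pu$model)) return(rep(0.5, nrow(features)))
    X <- svm_design(features, specs = pu$specs)$X
    as.numeric(attr(stats::predict(pu$model, X, probability = TRUE),
                    "probabilities")[, "1"])
  } else {
    predict_hostrange(model$fit, features)
  }
}

#' Classification metric suite
#'
#' Confusion-derived metrics at a probability cutoff (a score strictly above
#' the cutoff predicts multihost, the positive class): accuracy,
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), F1 = 2TP/(2TP+FP+FN),
#' Cohen's kappa; plus ROC AUC with a DeLong asymptotic confidence
#' interval.
#'
#' @param scores probability vector in [0, 1].
#' @param labels binary labels (1 = multihost).
#' @param cutoff classification cutoff (default 0.5).
#' @return list of class `metrics_report`.
#' @export
evaluate_scores <- function(scores, labels, cutoff = 0.5) {
  stopifnot(all(scores >= 0), all(scores <= 1))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC undefined: labels contain a single class")
  pred <- as.integer(scores > cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  n <- length(labels)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  structure(list(
    auc = as.numeric(pROC::auc(roc)),
    auc_ci = c(lower = ci[1], upper = ci[3]),
    accuracy = po,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    kappa = if (pe < 1) (po - pe) / (1 - pe) else 0,
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    cutoff = cutoff
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f (%.4f-%.4f)  Acc %.4f  Sens %.4f  Spec %.4f  F1 %.4f  Kappa %.4f\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$accuracy, x$sensitivity,
    x$specificity, x$f1, x$kappa))
  invisible(x)
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Repeated stratified cross-validation of one strategy
#'
#' Folds are stratified by class. The strategy's resampling or weighting is
#' applied only to each fold's training portion; the untouched assessment
#' fold is scored and the metric suite computed per fold. The pooled
#' summary is the mean over all folds and repeats.
#'
#' @param train training feature table.
#' @param strategy a [strategy_spec()] or name.
#' @param folds,repeats cross-validation design (defaults 5 and 5).
#' @param seed integer seed.
#' @param cutoff classification cutoff.
#' @return list of class `cv_result`: `folds` (per-fold metric data.frame
#'   incl. resampled class counts), `summary` (pooled means), `strategy`.
#' @export
cross_validate <- function(train, strategy = "none", folds = 5L, repeats = 5L,
                           seed = 1L, cutoff = 0.5) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  if (min(table(train$multihost)) < folds)
    stop("a class has fewer rows than folds; use fewer folds")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(train$multihost, folds, seed = seed + r)
    for (k in seq_len(folds)) {
      tr <- train[fold_of != k, , drop = FALSE]
      te <- train[fold_of == k, , drop = FALSE]
      model <- fit_strategy(tr, strategy, seed = seed * 1000L + r * 10L + k)
      m <- evaluate_scores(predict_model(model, te), te$multihost,
                           cutoff = cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = k, auc = m$auc, accuracy = m$accuracy,
        sensitivity = m$sensitivity, specificity = m$specificity,
        f1 = m$f1, kappa = m$kappa,
        train_singlehost = model$class_counts[["singlehost"]],
        train_multihost = model$class_counts[["multihost"]]
      )
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("auc", "accuracy", "sensitivity", "specificity", "f1",
                   "kappa")
  structure(list(folds = per_fold,
                 summary = colMeans(per_fold[metric_cols]),
                 strategy = strategy$name),
            class = "cv_result")
}

#' Rank strategies by cross-validated AUC, tie-broken by F1
#'
#' @param cv_results named list of `cv_result` objects (one per strategy).
#' @return list: `table` (one row per strategy, six pooled metrics, sorted
#'   best first) and `chosen` (the winning strategy name).
#' @export
select_model <- function(cv_results) {
  stopifnot(length(cv_results) >= 2)
  tab <- do.call(rbind, lapply(cv_results, function(cv) {
    data.frame(strategy = cv$strategy, t(cv$summary))
  }))
  tab <- tab[order(-tab$auc, -tab$f1), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, chosen = tab$strategy[1])
}

#' Compare all five strategies with CV and holdout evaluation
#'
#' Runs repeated stratified cross-validation per strategy on the training
#' set, then refits each strategy once on the whole training set with a
#' fresh seed and evaluates on the unmodified holdout set. Strategy choice
#' is by cross-validated AUC, tie-broken by F1.
#'
#' @param train,test feature tables from [train_test_split()].
#' @param strategies strategy names to compare (default all five).
#' @param config [pipeline_config()] (folds, repeats, cutoff read from it).
#' @param seed integer seed.
#' @param pu_iterations AdaSampling rounds for the PU strategy.
#' @return list: `cv` (named cv_result list), `ranking` (from
#'   [select_model()]), `holdout` (per-strategy metric data.frame),
#'   `models` (refit final models), `chosen`.
#' @export
compare_strategies <- function(train, test, strategies = STRATEGIES,
                               config = pipeline_config(), seed = 1L,
                               pu_iterations = 10L) {
  cv <- list()
  models <- list()
  hold_rows <- list()
  for (s in strategies) {
    sp <- strategy_spec(s, pu_iterations = pu_iterations)
    cv[[s]] <- cross_validate(train, sp, folds = config$folds,
                              repeats = config$repeats, seed = seed,
                              cutoff = config$classify_cutoff)
    models[[s]] <- fit_strategy(train, sp, seed = seed + 7777L)
    m <- evaluate_scores(predict_model(models[[s]], test), test$multihost,
                         cutoff = config$classify_cutoff)
    hold_rows[[s]] <- data.frame(
      strategy = s, auc = m$auc, auc_lower = m$auc_ci[["lower"]],
      auc_upper = m$auc_ci[["upper"]], accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity, f1 = m$f1,
      kappa = m$kappa,
      train_singlehost = models[[s]]$class_counts[["singlehost"]],
      train_multihost = models[[s]]$class_counts[["multihost"]]
    )
  }
  ranking <- select_model(cv)
  holdout <- do.call(rbind, hold_rows)
  rownames(holdout) <- NULL
  list(cv = cv, ranking = ranking, holdout = holdout, models = models,
       chosen = ranking$chosen)
}
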