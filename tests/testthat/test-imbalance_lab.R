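test_that("train/test split reproduces the documented sizes and is a partition", {
  f <- data.frame(mite_id = sprintf("m%04d", 1:1445), multihost = 0)
  sp <- train_test_split(f, 1024 / 1445, seed = 3)
  expect_equal(nrow(sp$train), 1024)
  expect_equal(nrow(sp$test), 421)
  expect_equal(sort(c(sp$train$mite_id, sp$test$mite_id)), sort(f$mite_id))
  expect_length(intersect(sp$train$mite_id, sp$test$mite_id), 0)

  sp2 <- train_test_split(f, 1024 / 1445, seed = 3)
  expect_identical(sp$train$mite_id, sp2$train$mite_id)
  expect_error(train_test_split(f[1:5, ], 0.5), "too few")
})

test_that("publication weights follow the 0.2/1.0 step at 10 publications", {
  expect_equal(publication_weights(c(10, 9, 0, 25)), c(1, 0.2, 0.2, 1))
  expect_error(publication_weights(-1), "non-negative")
})

test_that("down- and up-sampling equalise class counts per contract", {
  set.seed(12)
  train <- data.frame(id = 1:1024,
                      multihost = rep(c(0, 1), c(733, 291)),
                      x = rnorm(1024))
  d <- downsample(train, seed = 1)
  expect_equal(unname(table(d$multihost)), array(c(291L, 291L)))
  expect_true(all(d$id %in% train$id))
  expect_equal(anyDuplicated(d$id), 0)           # without replacement

  u <- upsample(train, seed = 1)
  expect_equal(unname(table(u$multihost)), array(c(733L, 733L)))
  expect_true(all(u$id %in% train$id))

  balanced <- data.frame(id = 1:10, multihost = rep(c(0, 1), 5))
  expect_identical(downsample(balanced, 1), balanced)
  expect_identical(upsample(balanced, 1), balanced)
  expect_error(downsample(data.frame(multihost = rep(0, 5)), 1),
               "both outcome classes")
})

test_that("metric suite matches hand counts and a pair-counting AUC oracle", {
  scores <- c(0.9, 0.8, 0.4, 0.3)
  labels <- c(1, 0, 1, 0)
  m <- evaluate_scores(scores, labels, cutoff = 0.5)
  expect_equal(m$auc, 0.75)
  expect_equal(m$auc, pair_count_auc(scores, labels))
  expect_equal(m$sensitivity, 0.5)   # TP=1 (0.9), FN=1 (0.4)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$f1, 2 * 1 / (2 * 1 + 1 + 1))

  perfect <- evaluate_scores(c(0.9, 0.95, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  allneg <- evaluate_scores(c(0.2, 0.3, 0.1, 0.4), c(1, 0, 1, 0))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)

  expect_error(evaluate_scores(c(0.2, 0.3), c(1, 1)), "single class")

  # AUC agrees with the double-loop oracle on random scores, and is
  # invariant under strictly monotone transforms
  set.seed(13)
  s <- runif(40); l <- rbinom(40, 1, 0.4)
  expect_equal(evaluate_scores(s, l)$auc, pair_count_auc(s, l))
  expect_equal(evaluate_scores(plogis(5 * s - 2), l)$auc,
               evaluate_scores(s, l)$auc)
})

test_that("AdaSampling hits its degenerate contracts and separable limit", {
  f <- small_features()
  t0 <- adasampling_pu(f, f$multihost, iterations = 0, seed = 1)
  expect_false(t0$converged)
  expect_true(all(t0$scores[f$multihost == 0] == 0.5))

  # separable toy: unlabeled set is pure true negatives
  set.seed(14)
  n <- 120
  lab <- rep(c(1, 0), each = n / 2)
  toy <- f[rep(1, n), ]
  toy$n_PSH10_max <- ifelse(lab == 1, 8, 0) + rbinom(n, 1, 0.3)
  toy$n_CPH_max <- ifelse(lab == 1, 10, 0) + rbinom(n, 1, 0.3)
  toy$avg_temp <- rnorm(n, 100, 30)        # keep spline knots estimable
  toy$log_body_mass <- rnorm(n, 5, 1)
  toy$avg_precip <- rnorm(n, 100, 30)
  toy$multihost <- lab
  pu <- adasampling_pu(toy, lab, iterations = 10, seed = 2)
  expect_gt(mean(pu$scores[lab == 1]), 0.8)
  expect_lt(mean(pu$scores[lab == 0]), 0.2)
})

test_that("cross-validation is stratified, leak-free and strategy-aware", {
  f <- small_features()
  cv <- cross_validate(f, "down", folds = 3, repeats = 2, seed = 4)
  expect_equal(nrow(cv$folds), 6)
  # down-strategy fold training sets are balanced
  expect_equal(cv$folds$train_singlehost, cv$folds$train_multihost)
  expect_true(all(c("auc", "sensitivity", "f1") %in% names(cv$summary)))

  # every row lands in exactly one assessment fold per repeat
  assign1 <- acarange:::stratified_folds(f$multihost, 3, seed = 99)
  expect_equal(length(assign1), nrow(f))
  expect_true(all(table(assign1) >= floor(nrow(f) / 3)))
  for (k in 1:3) {
    cls <- table(f$multihost[assign1 == k])
    expect_equal(length(cls), 2)       # stratification keeps both classes
  }

  expect_error(cross_validate(f[c(which(f$multihost == 0)[1:20],
                                  which(f$multihost == 1)[1:2]), ],
                              "none", folds = 5, repeats = 1, seed = 1),
               "fewer")
})

test_that("model selection ranks by AUC then F1", {
  mk <- function(name, auc, f1) {
    structure(list(folds = NULL,
                   summary = c(auc = auc, accuracy = 0.5, sensitivity = 0.5,
                               specificity = 0.5, f1 = f1, kappa = 0),
                   strategy = name), class = "cv_result")
  }
  sel <- select_model(list(a = mk("a", 0.80, 0.5), b = mk("b", 0.77, 0.9)))
  expect_equal(sel$chosen, "a")
  sel2 <- select_model(list(a = mk("a", 0.8, 0.5), b = mk("b", 0.8, 0.9),
                            c = mk("c", 0.7, 0.99)))
  expect_equal(sel2$chosen, "b")
  expect_equal(nrow(sel2$table), 3)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity", "f1",
                    "kappa") %in% names(sel2$table)))
})

test_that("strategy comparison evaluates an untouched holdout", {
  f <- small_features()
  sp <- train_test_split(f, 0.7, seed = 5)
  cmp <- compare_strategies(sp$train, sp$test,
                            strategies = c("none", "down"),
                            config = pipeline_config(folds = 3L,
                                                     repeats = 1L),
                            seed = 6)
  expect_equal(nrow(cmp$holdout), 2)
  expect_true(cmp$chosen %in% c("none", "down"))
  # the down model was refit on a balanced training set
  dn <- cmp$holdout[cmp$holdout$strategy == "down", ]
  expect_equal(dn$train_singlehost, dn$train_multihost)
  # holdout rows were never part of training
  expect_length(intersect(sp$train$mite_id, sp$test$mite_id), 0)
})
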