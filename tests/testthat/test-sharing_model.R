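test_that("unipartite projection matches a brute-force pair scan", {
  assoc <- data.frame(
    mite_id = c("m1", "m1", "m1", "m2", "m3", "m4"),
    host_id = c("A", "B", "C", "D", "D", "E"),
    credible = TRUE)
  proj <- project_unipartite(assoc)
  expect_equal(nrow(proj$edges), 3)                       # AB, AC, BC
  key <- paste(proj$edges$host_a, proj$edges$host_b)
  expect_setequal(key, c("A B", "A C", "B C"))
  expect_setequal(proj$excluded, c("D", "E"))             # no sharing partner

  # random instance vs double loop
  set.seed(15)
  r_assoc <- data.frame(
    mite_id = sample(sprintf("m%02d", 1:12), 40, replace = TRUE),
    host_id = sample(LETTERS[1:6], 40, replace = TRUE),
    credible = TRUE)
  r_assoc <- r_assoc[!duplicated(r_assoc[1:2]), ]
  proj2 <- project_unipartite(r_assoc)
  hosts <- sort(unique(r_assoc$host_id))
  brute <- 0
  for (i in seq_along(hosts)) for (j in seq_along(hosts)) if (i < j) {
    mi <- r_assoc$mite_id[r_assoc$host_id == hosts[i]]
    mj <- r_assoc$mite_id[r_assoc$host_id == hosts[j]]
    if (length(intersect(mi, mj))) brute <- brute + 1
  }
  expect_equal(nrow(proj2$edges), brute)
})

test_that("distance recoding maps only the marsupial-placental gap", {
  expect_equal(recode_pd(320), 178)
  expect_equal(recode_pd(178), 178)
  expect_equal(recode_pd(50), 50)
  expect_equal(recode_pd(c(10, 301, 500)), c(10, 178, 178))
  expect_warning(recode_pd(200), "left unchanged")
  expect_error(recode_pd(-1), ">= 0")
})

test_that("pair table covers all kept pairs with matching marginals", {
  hosts <- LETTERS[1:4]
  pd <- matrix(30, 4, 4, dimnames = list(hosts, hosts)); diag(pd) <- 0
  go <- matrix(0.2, 4, 4, dimnames = list(hosts, hosts)); diag(go) <- 1
  edges <- data.frame(host_a = c("A", "B"), host_b = c("B", "C"))
  pt <- build_pair_table(edges, hosts, pd, go)
  expect_equal(nrow(pt), 6)                         # 4 choose 2
  expect_equal(sum(pt$shares), 2)
  expect_warning(build_pair_table(edges, c(hosts, "Z"), pd, go), "dropped")
})

test_that("bin subsampling caps only oversized cells, reproducibly", {
  set.seed(16)
  pairs <- data.frame(host_a = "x", host_b = "y",
                      shares = rbinom(5000, 1, 0.2),
                      pd = runif(5000, 0, 20),       # all in one pd bin
                      go = runif(5000, 0, 0.1))      # all in one go bin
  class(pairs) <- c("sharing_pairs", "data.frame")
  spec <- bin_spec(max_per_bin = 1000, seed = 5)
  sub <- bin_subsample(pairs, spec)
  expect_equal(nrow(sub), 1000)
  expect_true(all(rownames(sub) %in% rownames(pairs)) ||
                all(sub$pd %in% pairs$pd))
  expect_identical(bin_subsample(pairs, spec), sub)   # seeded determinism

  small <- pairs[1:500, ]
  expect_equal(nrow(bin_subsample(small, spec)), 500) # under the cap
})

test_that("sharing GLM recovers known coefficients and is order-stable", {
  truth <- c("(Intercept)" = 1.5, "ns(pd,2)1" = -6, "ns(pd,2)2" = -3,
             "go" = 2, "pd:go" = -0.02)
  sim <- simulate_sharing_pairs(8000, truth, seed = 3)
  fit <- fit_sharing_glm(sim$pairs)
  z <- abs(coef(fit)[names(truth)] - truth) / fit$se[names(truth)]
  expect_gte(mean(z <= 2), 0.8)

  perm <- sample(nrow(sim$pairs))
  fit2 <- fit_sharing_glm(sim$pairs[perm, ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("null sharing data keeps the LRT near its nominal size", {
  reject <- logical(30)
  for (r in seq_len(30)) {
    null_truth <- c("(Intercept)" = -0.5, "ns(pd,2)1" = 0, "ns(pd,2)2" = 0,
                    "go" = 0, "pd:go" = 0)
    sim <- simulate_sharing_pairs(400, null_truth, seed = 300 + r)
    fit <- fit_sharing_glm(sim$pairs)
    null_fit <- fit_logistic(matrix(1, 400, 1), sim$pairs$shares)
    reject[r] <- likelihood_ratio_test(fit, null_fit)$p < 0.05
  }
  expect_lte(sum(reject), 5)    # ~95% non-significant at alpha = 0.05
})

test_that("predictions respect fitted monotonicity and stay in (0,1)", {
  truth <- c("(Intercept)" = 1.5, "ns(pd,2)1" = -6, "ns(pd,2)2" = -3,
             "go" = 2, "pd:go" = -0.02)
  fit <- fit_sharing_glm(simulate_sharing_pairs(6000, truth, seed = 4)$pairs)
  lo <- predict_sharing(fit, 5, 0.3)
  hi <- predict_sharing(fit, 150, 0.3)
  expect_gt(lo$prob, hi$prob)
  surf <- sharing_surface(fit, pd_grid = seq(0, 178, by = 20),
                          go_grid = c(0, 0.5, 1))
  expect_true(all(surf$prob > 0 & surf$prob < 1))
  expect_true(all(surf$se >= 0))
  expect_equal(nrow(surf), 9 * 3)   # pd grid 0,20,...,160
  # direct linear-predictor arithmetic reproduces the surface
  spec <- fit$sharing$spec
  B <- natural_spline_basis(surf$pd, spec)
  eta <- coef(fit)["(Intercept)"] + B[, 1] * coef(fit)["ns(pd,2)1"] +
    B[, 2] * coef(fit)["ns(pd,2)2"] + surf$go * coef(fit)["go"] +
    surf$pd * surf$go * coef(fit)["pd:go"]
  expect_equal(surf$prob, unname(plogis(eta)), tolerance = 1e-12)

  expect_error(suppressWarnings(predict_sharing(fit, 200, 0.5)),
               "after recoding")
  expect_error(predict_sharing(fit, 50, 1.5), "go outside")
})

test_that("fitted signs reproduce the negative-distance positive-overlap pattern", {
  truth <- c("(Intercept)" = 1.2, "ns(pd,2)1" = -5, "ns(pd,2)2" = -2.5,
             "go" = 1.5, "pd:go" = -0.01)
  hits <- 0
  for (r in 1:10) {
    fit <- fit_sharing_glm(simulate_sharing_pairs(3000, truth,
                                                  seed = 400 + r)$pairs)
    dec <- predict_sharing(fit, 150, 0.2)$prob < predict_sharing(fit, 5, 0.2)$prob
    pos <- coef(fit)["go"] > 0
    if (dec && pos) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
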