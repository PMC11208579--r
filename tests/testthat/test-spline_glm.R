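test_that("natural spline basis is linear beyond the boundary knots", {
  x <- sort(runif(30, 0, 10))
  spec <- spline_spec(x, df = 2, variable = "x")
  expect_equal(spec$interior_knots, unname(median(x)))
  expect_equal(ncol(natural_spline_basis(x, spec)), 2)

  far <- seq(10.5, 14.5, by = 0.5)          # beyond the upper boundary
  B <- natural_spline_basis(far, spec)
  second_diffs <- apply(B, 2, function(col) diff(diff(col)))
  expect_lt(max(abs(second_diffs)), 1e-9)

  expect_error(natural_spline_basis(c(1, NA), spec), "non-finite")
})

test_that("ns basis spans the truncated-power natural-spline space", {
  set.seed(2)
  x <- sort(runif(10, 0, 1))
  spec <- spline_spec(x, df = 2, variable = "x")
  knots <- c(spec$boundary_knots[1], spec$interior_knots,
             spec$boundary_knots[2])
  B <- natural_spline_basis(x, spec)
  TP <- truncated_power_ns(x, knots)
  # every ns column is exactly reproducible from the truncated-power basis
  for (j in seq_len(ncol(B))) {
    res <- lm.fit(TP, B[, j])$residuals
    expect_lt(max(abs(res)), 1e-10)
  }
  # and vice versa (same column space, both directions)
  design <- cbind(1, B)
  for (j in seq_len(ncol(TP))) {
    res <- lm.fit(design, TP[, j])$residuals
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("IRLS matches a brute-force likelihood maximiser", {
  set.seed(3)
  n <- 120
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  eta <- -0.3 + 0.8 * X[, 2] - 1.1 * X[, 3]
  y <- as.integer(runif(n) < plogis(eta))
  fit <- fit_logistic(X, y)
  brute <- brute_force_logistic(X, y, start = coef(fit) * 0)
  expect_equal(unname(coef(fit)), unname(brute), tolerance = 1e-6)

  # score equations hold at the optimum
  score <- crossprod(X, y - fit$fitted)
  expect_lt(max(abs(score)), 1e-6)
})

test_that("intercept-only fit on balanced outcome gives logit(0.5) = 0", {
  y <- rep(c(0, 1), 25)
  fit <- fit_logistic(matrix(1, 50, 1), y)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
})

test_that("doubling weights preserves coefficients and doubles deviance", {
  set.seed(5)
  X <- cbind(1, rnorm(60)); colnames(X) <- c("int", "x")
  y <- as.integer(runif(60) < plogis(X[, 2]))
  f1 <- fit_logistic(X, y)
  f2 <- fit_logistic(X, y, weights = rep(2, 60))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(f2$deviance, 2 * f1$deviance, tolerance = 1e-8)
})

test_that("stored fit invariants hold: AIC, z, permutation stability", {
  f <- small_features()
  fit <- fit_hostrange(f)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * length(coef(fit)))
  expect_equal(fit$z, fit$coefficients / fit$se)
  expect_gte(fit$deviance, 0)

  set.seed(9)
  perm <- sample(nrow(f))
  fit2 <- fit_hostrange(f[perm, ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("rank deficiency is reported with the offending column", {
  X <- cbind(1, 1:10, 2 * (1:10))
  colnames(X) <- c("int", "a", "a_copy")
  expect_error(fit_logistic(X, rep(c(0, 1), 5)), "a_copy")
})

test_that("likelihood ratio test follows deviance arithmetic", {
  set.seed(6)
  X <- cbind(1, rnorm(80)); colnames(X) <- c("int", "x")
  y <- as.integer(runif(80) < plogis(1.2 * X[, 2]))
  full <- fit_logistic(X, y)
  null <- fit_logistic(X[, 1, drop = FALSE], y)
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$statistic, null$deviance - full$deviance)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_gte(lrt$statistic, 0)

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p, 1)

  expect_error(likelihood_ratio_test(full, fit_logistic(X[1:40, ], y[1:40])),
               "not nested")
})

test_that("odds ratios exponentiate estimates as reported", {
  expect_equal(round(odds_ratios(2.028), 2), 7.60)
  expect_equal(odds_ratios(0), 1)
  expect_equal(round(odds_ratios(0.619), 3), 1.857)
})

test_that("the host-range design has 19 columns and honours references", {
  f <- small_features()
  d <- build_hostrange_design(f)
  expect_equal(ncol(d$X), 19)
  expect_equal(colnames(d$X)[1], "(Intercept)")

  ref <- f[1, ]
  ref$immunity_contact <- factor("primary", levels = levels(f$immunity_contact))
  ref$parasitism <- factor("endo", levels = levels(f$parasitism))
  ref$bioregion <- factor("singleregion", levels = levels(f$bioregion))
  ref$dispersal_stage <- factor("IMM", levels = levels(f$dispersal_stage))
  ref$precop_guarding <- TRUE
  ref$domesticated_host <- FALSE
  row <- build_hostrange_design(ref, specs = d$specs)$X
  dummy_cols <- c("immunity_contact.secondary", "immunity_contact.none",
                  "parasitism.ecto", "bioregion.multiregion",
                  "dispersal_stage.F", "dispersal_stage.F_IMM",
                  "precop_guarding.N", "domesticated_host.Y")
  expect_true(all(row[1, dummy_cols] == 0))

  # spline columns evaluated with frozen training knots are linear outside
  ext <- f[rep(1, 5), ]
  ext$avg_temp <- max(f$avg_temp) + seq(10, 50, by = 10)
  Xe <- build_hostrange_design(ext, specs = d$specs)$X
  for (cn in c("ns(avg_temp,2)1", "ns(avg_temp,2)2"))
    expect_lt(max(abs(diff(diff(Xe[, cn])))), 1e-9)
})

test_that("profile and Wald odds-ratio intervals agree on easy data", {
  set.seed(11)
  X <- cbind(1, rnorm(400)); colnames(X) <- c("int", "x")
  y <- as.integer(runif(400) < plogis(0.7 * X[, 2]))
  fit <- fit_logistic(X, y)
  w <- odds_ratios(fit, method = "wald")
  p <- odds_ratios(fit, method = "profile")
  expect_equal(p$or, w$or)
  expect_equal(p$ci_lower, w$ci_lower, tolerance = 0.05)
  expect_equal(p$ci_upper, w$ci_upper, tolerance = 0.05)
})
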