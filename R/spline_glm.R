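#' Natural-spline specification frozen from training data
#'
#' For `df` degrees of freedom the basis has `df - 1` interior knots placed
#' at equally spaced quantiles of the training values (for the default
#' `df = 2`, a single knot at the median) and boundary knots at the training
#' minimum and maximum. Freezing the spec lets test/holdout data be
#' transformed with the training knots, preventing leakage.
#'
#' @param x numeric training values.
#' @param df degrees of freedom (basis columns), >= 1.
#' @param variable optional variable name carried in the spec.
#' @return list of class `spline_spec` with `variable`, `df`,
#'   `boundary_knots`, `interior_knots`.
#' @export
spline_spec <- function(x, df = 2, variable = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop("non-finite values in spline variable")
  stopifnot(df >= 1)
  boundary <- range(x)
  interior <- if (df > 1)
    as.numeric(stats::quantile(x, probs = seq_len(df - 1) / df, names = FALSE))
  else numeric(0)
  if (any(diff(c(boundary[1], interior, boundary[2])) <= 0))
    stop("degenerate spline knots (too little variation in ", variable, ")")
  structure(list(variable = variable, df = as.integer(df),
                 boundary_knots = boundary, interior_knots = interior),
            class = "spline_spec")
}

#' Evaluate a natural cubic spline basis
#'
#' Natural cubic spline basis (piecewise cubic, C2-continuous at the knots,
#' linear beyond the boundary knots) evaluated at `x`, which may extend
#' beyond the boundary knots. Deterministic given the spec.
#'
#' @param x numeric vector.
#' @param spec a [spline_spec()].
#' @return numeric matrix, `length(x)` rows by `spec$df` columns.
#' @export
natural_spline_basis <- function(x, spec) {
  if (!all(is.finite(x))) stop("non-finite values passed to spline basis")
  stopifnot(inherits(spec, "spline_spec"))
  B <- splines::ns(x, knots = spec$interior_knots,
                   Boundary.knots = spec$boundary_knots)
  B <- unclass(B)[, seq_len(spec$df), drop = FALSE]
  attributes(B)[setdiff(names(attributes(B)), c("dim", "dimnames"))] <- NULL
  colnames(B) <- paste0("ns", seq_len(spec$df))
  B
}

#' Fit a binomial GLM by iteratively reweighted least squares
#'
#' Logistic regression on an explicit design matrix, with optional
#' non-negative case weights. Convergence follows the usual IRLS criterion
#' (relative deviance change below 1e-8, at most 100 iterations). Wald
#' standard errors come from the inverse Fisher information; two-sided p
#' values from the normal reference. The log-likelihood and AIC are the
#' case-weighted Bernoulli quantities, so doubling all weights doubles the
#' deviance while leaving coefficients unchanged.
#'
#' @param design numeric design matrix (include an intercept column
#'   yourself; [build_hostrange_design()] does).
#' @param y binary response vector (0/1).
#' @param weights optional non-negative case weights.
#' @return object of class `glm_fit`: coefficients, `se`, `z`, `p`, `vcov`,
#'   `loglik`, `deviance`, `null_deviance`, `aic`, `fitted`, `converged`,
#'   `separation` flag, plus the design column names and any spline specs
#'   attached by the design builder.
#' @export
fit_logistic <- function(design, y, weights = NULL) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) != length(y)) stop("design and response dimensions differ")
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y) || any(w < 0) || anyNA(w))
    stop("weights must be non-negative, one per observation")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  eps <- 1e-12
  mu_c <- pmin(pmax(mu, eps), 1 - eps)
  loglik <- sum(w * (y * log(mu_c) + (1 - y) * log(1 - mu_c)))
  deviance <- -2 * loglik

  p0 <- sum(w * y) / sum(w)
  null_loglik <- sum(w * (y * log(p0) + (1 - y) * log(1 - p0)))

  W <- w * mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  z <- beta / se
  separation <- !fit$converged || any(abs(beta) > 15 & se > 1e3)

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    vcov = vc,
    loglik = loglik,
    deviance = deviance,
    null_deviance = -2 * null_loglik,
    aic = -2 * loglik + 2 * ncol(X),
    n = length(y),
    y = y,
    design = X,
    weights = w,
    fitted = mu,
    converged = fit$converged,
    separation = separation,
    spline_specs = NULL
  ), class = "glm_fit")
}

#' @export
coef.glm_fit <- function(object, ...) object$coefficients

#' @export
vcov.glm_fit <- function(object, ...) object$vcov

#' @export
logLik.glm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("binomial GLM fit: %d coefficients, n = %d\n",
              length(x$coefficients), x$n))
  cat(sprintf("  deviance %.2f (null %.2f), AIC %.2f\n",
              x$deviance, x$null_deviance, x$aic))
  if (x$separation) cat("  WARNING: possible separation / non-convergence\n")
  print(summary(x), digits = 4)
  invisible(x)
}

#' Tabular fit summary in odds-ratio form
#'
#' Columns mirror the standard coefficient report: Estimate, Wald CI bounds,
#' SE, exponentiated estimate (odds ratio), z value and two-sided p value.
#'
#' @param object a `glm_fit`.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return data.frame, one row per coefficient.
#' @export
summary.glm_fit <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(object$coefficients),
    Estimate = unname(object$coefficients),
    CI.LL = unname(object$coefficients - zq * object$se),
    CI.UL = unname(object$coefficients + zq * object$se),
    SE = unname(object$se),
    ExpB = exp(unname(object$coefficients)),
    z = unname(object$z),
    p = unname(object$p),
    stringsAsFactors = FALSE
  )
}

#' Likelihood ratio test between nested fits
#'
#' @param fit full-model `glm_fit`.
#' @param null_fit nested `glm_fit` on the same data and weights.
#' @return list with `statistic` (deviance difference), `df` (coefficient
#'   count difference) and `p` (chi-square upper tail; 1 when the models are
#'   identical).
#' @export
likelihood_ratio_test <- function(fit, null_fit) {
  stopifnot(inherits(fit, "glm_fit"), inherits(null_fit, "glm_fit"))
  if (fit$n != null_fit$n)
    stop("fits are not nested: different numbers of observations")
  if (!isTRUE(all.equal(sum(fit$weights), sum(null_fit$weights))))
    stop("fits are not nested: different case weights")
  df <- length(fit$coefficients) - length(null_fit$coefficients)
  if (df < 0) stop("null model has more coefficients than the full model")
  statistic <- null_fit$deviance - fit$deviance
  if (statistic < -1e-6)
    stop("full model fits worse than the null; models are not nested")
  statistic <- max(statistic, 0)
  p <- if (df == 0) {
    if (statistic <= 1e-8) 1 else 0
  } else {
    stats::pchisq(statistic, df = df, lower.tail = FALSE)
  }
  list(statistic = statistic, df = df, p = p)
}

#' Odds ratios with confidence intervals
#'
#' Exponentiated coefficient estimates. For a fitted model, Wald intervals
#' (estimate +/- z * SE, default) or profile-likelihood intervals are
#' exponentiated alongside. The numeric method exponentiates raw
#' coefficient estimates directly.
#'
#' @param fit a `glm_fit`, or a numeric vector of coefficient estimates.
#' @param level confidence level.
#' @param method `"wald"` (default) or `"profile"`.
#' @param ... unused.
#' @return data.frame with columns term, or, ci_lower, ci_upper (fit
#'   method), or a named numeric vector (numeric method).
#' @export
odds_ratios <- function(fit, ...) UseMethod("odds_ratios")

#' @rdname odds_ratios
#' @export
odds_ratios.numeric <- function(fit, ...) exp(fit)

#' @rdname odds_ratios
#' @export
odds_ratios.glm_fit <- function(fit, level = 0.95, method = c("wald", "profile"),
                                ...) {
  method <- match.arg(method)
  if (method == "wald") {
    zq <- stats::qnorm(1 - (1 - level) / 2)
    lo <- fit$coefficients - zq * fit$se
    hi <- fit$coefficients + zq * fit$se
  } else {
    ci <- profile_ci(fit, level = level)
    lo <- ci[, 1]; hi <- ci[, 2]
  }
  data.frame(term = names(fit$coefficients),
             or = exp(unname(fit$coefficients)),
             ci_lower = exp(unname(lo)),
             ci_upper = exp(unname(hi)),
             stringsAsFactors = FALSE)
}

## Profile-likelihood CI: for each coefficient, find the values where the
## profiled deviance rises by qchisq(level, 1) above the minimum, holding
## the coefficient fixed via an offset and refitting the rest.
profile_ci <- function(fit, level = 0.95) {
  X <- fit$design; y <- fit$y; w <- fit$weights
  crit <- stats::qchisq(level, df = 1)
  out <- matrix(NA_real_, length(fit$coefficients), 2,
                dimnames = list(names(fit$coefficients), c("lower", "upper")))
  for (j in seq_along(fit$coefficients)) {
    prof_dev <- function(bj) {
      off <- X[, j] * bj
      sub <- suppressWarnings(stats::glm.fit(
        X[, -j, drop = FALSE], y, weights = w, offset = off,
        family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
      mu <- pmin(pmax(sub$fitted.values, 1e-12), 1 - 1e-12)
      -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    }
    target <- fit$deviance + crit
    bhat <- fit$coefficients[j]
    step <- max(fit$se[j], 1e-3)
    for (side in c(-1, 1)) {
      hi <- bhat + side * step
      k <- 0
      while (prof_dev(hi) < target && k < 50) { hi <- hi + side * step; k <- k + 1 }
      if (k < 50) {
        r <- stats::uniroot(function(b) prof_dev(b) - target,
                            interval = sort(c(bhat, hi)), tol = 1e-6)
        out[j, if (side < 0) 1 else 2] <- r$root
      }
    }
  }
  out
}

#' Build the host-range model design matrix
#'
#' Dummy coding with the reference categories primary (immunity contact),
#' endo (parasitism), singleregion (bioregion), IMM (dispersal stage),
#' guarding present, non-domesticated; linear terms for the availability
#' counts, litter size and log human population density; df = 2 natural
#' splines for log body mass, precipitation and temperature. Spline knots
#' are computed from the supplied data unless `specs` (from a training fit)
#' is given, in which case they are reused, so holdout rows are transformed
#' with the training knots.
#'
#' @param features feature-table data.frame (complete rows).
#' @param specs optional named list of three [spline_spec()]s
#'   (`log_body_mass`, `avg_precip`, `avg_temp`) to reuse.
#' @return list with `X` (n x 19 design matrix including intercept) and
#'   `specs` (the spline specs used).
#' @export
build_hostrange_design <- function(features, specs = NULL) {
  f <- features
  need <- c("immunity_contact", "parasitism", "bioregion", "dispersal_stage",
            "precop_guarding", "n_CPH_max", "n_PSH10_max", "avg_litter_size",
            "domesticated_host", "log_body_mass", "avg_precip", "avg_temp",
            "log_human_pop_density")
  missing <- setdiff(need, names(f))
  if (length(missing)) stop("feature table lacks: ", paste(missing, collapse = ", "))
  if (anyNA(f[need])) stop("feature table contains missing values; drop incomplete rows first")
  chk <- function(col, levels) {
    v <- as.character(f[[col]])
    bad <- setdiff(unique(v), levels)
    if (length(bad)) stop("unseen ", col, " level(s): ", paste(bad, collapse = ", "))
    v
  }
  imm <- chk("immunity_contact", IMMUNITY_LEVELS)
  par <- chk("parasitism", PARASITISM_LEVELS)
  bio <- chk("bioregion", BIOREGION_LEVELS)
  dsp <- chk("dispersal_stage", DISPERSAL_LEVELS)

  if (is.null(specs)) {
    specs <- list(
      log_body_mass = spline_spec(f$log_body_mass, df = 2, variable = "log_body_mass"),
      avg_precip = spline_spec(f$avg_precip, df = 2, variable = "avg_precip"),
      avg_temp = spline_spec(f$avg_temp, df = 2, variable = "avg_temp")
    )
  } else {
    stopifnot(all(c("log_body_mass", "avg_precip", "avg_temp") %in% names(specs)))
  }
  ns_bm <- natural_spline_basis(f$log_body_mass, specs$log_body_mass)
  ns_pr <- natural_spline_basis(f$avg_precip, specs$avg_precip)
  ns_tm <- natural_spline_basis(f$avg_temp, specs$avg_temp)

  X <- cbind(
    "(Intercept)" = 1,
    "immunity_contact.secondary" = as.numeric(imm == "secondary"),
    "immunity_contact.none" = as.numeric(imm == "none"),
    "parasitism.ecto" = as.numeric(par == "ecto"),
    "bioregion.multiregion" = as.numeric(bio == "multiregion"),
    "dispersal_stage.F" = as.numeric(dsp == "F"),
    "dispersal_stage.F_IMM" = as.numeric(dsp == "F_IMM"),
    "precop_guarding.N" = as.numeric(!f$precop_guarding),
    "n_CPH_max" = f$n_CPH_max,
    "n_PSH10_max" = f$n_PSH10_max,
    "avg_litter_size" = f$avg_litter_size,
    "domesticated_host.Y" = as.numeric(f$domesticated_host),
    "ns(log_body_mass,2)1" = ns_bm[, 1],
    "ns(log_body_mass,2)2" = ns_bm[, 2],
    "ns(avg_precip,2)1" = ns_pr[, 1],
    "ns(avg_precip,2)2" = ns_pr[, 2],
    "ns(avg_temp,2)1" = ns_tm[, 1],
    "ns(avg_temp,2)2" = ns_tm[, 2],
    "log_human_pop_density" = f$log_human_pop_density
  )
  list(X = X, specs = specs)
}

#' Fit the host-range spline-logistic model
#'
#' Convenience wrapper: builds the 19-column design from a feature table
#' (computing or reusing spline knots), fits the binomial GLM on the
#' `multihost` label, and stores the spline specs in the fit for later
#' prediction on new rows.
#'
#' @param features feature table with a `multihost` column.
#' @param weights optional case weights (e.g. [publication_weights()]).
#' @param specs optional spline specs to reuse (training knots).
#' @return a `glm_fit` with `spline_specs` attached.
#' @export
fit_hostrange <- function(features, weights = NULL, specs = NULL) {
  d <- build_hostrange_design(features, specs = specs)
  fit <- fit_logistic(d$X, features$multihost, weights = weights)
  fit$spline_specs <- d$specs
  fit
}

#' Predict multi-host probabilities for feature rows
#'
#' @param fit a `glm_fit` from [fit_hostrange()] (spline specs frozen from
#'   training are reused).
#' @param features feature table rows to score.
#' @return numeric vector of probabilities.
#' @export
predict_hostrange <- function(fit, features) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.null(fit$spline_specs))
    stop("fit carries no spline specs; use fit_hostrange()")
  d <- build_hostrange_design(features, specs = fit$spline_specs)
  as.numeric(stats::plogis(d$X %*% fit$coefficients))
}
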