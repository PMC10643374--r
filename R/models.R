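# Association models: covariate-adjusted linear models with interquartile
# effect scaling, median (quantile) regression, effect-scale conversions for
# log outcomes, and the sensitivity stack (GAM, county aggregation, spatial
# error model, group-stratified fits).
#
# Classical (non-robust) standard errors by default, two-sided t intervals,
# listwise deletion of incomplete rows (counts reported), no multiple-testing
# adjustment.

#' Model specification
#'
#' @param outcome outcome column name.
#' @param exposure exposure column name (the key independent variable).
#' @param covariates character vector of adjustment columns (may be empty).
#' @param outcome_transform `"identity"` or `"natural_log"`; the log
#'   transform drops nonpositive outcome rows (counted).
#' @param estimator `"ols"`, `"quantile_median"`, `"gam"` or
#'   `"spatial_error"`.
#' @param effect_scaling `"per_unit"`, `"interquartile"` or
#'   `"percent_change"`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, exposure, covariates = character(0),
                       outcome_transform = c("identity", "natural_log"),
                       estimator = c("ols", "quantile_median", "gam", "spatial_error"),
                       effect_scaling = c("per_unit", "interquartile", "percent_change")) {
  outcome_transform <- match.arg(outcome_transform)
  estimator <- match.arg(estimator)
  effect_scaling <- match.arg(effect_scaling)
  if (exposure %in% covariates)
    stop("exposure must not appear among covariates", call. = FALSE)
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = as.character(covariates),
                 outcome_transform = outcome_transform, estimator = estimator,
                 effect_scaling = effect_scaling), class = "model_spec")
}

# Listwise-deleted response and design pieces for a spec.
model_frame <- function(data, spec) {
  need <- c(spec$outcome, spec$exposure, spec$covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks model column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data[, need, drop = FALSE]
  for (col in need) if (is.logical(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n_nonpos <- 0L
  if (spec$outcome_transform == "natural_log") {
    pos <- df[[spec$outcome]] > 0
    n_nonpos <- sum(!pos)
    df <- df[pos, , drop = FALSE]
    df[[spec$outcome]] <- log(df[[spec$outcome]])
  }
  if (n_dropped + n_nonpos > 0)
    fe_log("model ", spec$outcome, " ~ ", spec$exposure, ": dropped ", n_dropped,
           " incomplete and ", n_nonpos, " nonpositive-outcome row(s)")
  y <- df[[spec$outcome]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, c(spec$exposure, spec$covariates), drop = FALSE]))
  list(y = y, X = X, df = df, n_dropped = n_dropped + n_nonpos)
}

check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

new_model_result <- function(spec, coefs, n_units, n_dropped, diagnostics = list()) {
  structure(list(spec = spec, coefficients = coefs, n_units = n_units,
                 n_dropped = n_dropped, scaled_effect = NULL,
                 diagnostics = diagnostics), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat("foodenv model (", x$spec$estimator, "): ", x$spec$outcome,
      if (x$spec$outcome_transform == "natural_log") " (log)", " ~ ",
      x$spec$exposure,
      if (length(x$spec$covariates)) paste0(" + ", length(x$spec$covariates), " covariates"),
      "\n", sep = "")
  cat("n =", x$n_units, "(", x$n_dropped, "dropped )\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$scaled_effect)) {
    cat("scaled effect (", x$scaled_effect$scale, "): ",
        format(x$scaled_effect$estimate, digits = 4), " [",
        format(x$scaled_effect$ci_low, digits = 4), ", ",
        format(x$scaled_effect$ci_high, digits = 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Ordinary least squares fit with t intervals
#'
#' OLS with intercept, classical standard errors and 95% CIs from the
#' t-distribution on the residual degrees of freedom.
#'
#' @param data data.frame containing all model columns.
#' @param spec a [model_spec()].
#' @return object of class `fe_model` with a coefficient table
#'   (`term`, `estimate`, `se`, `ci_low`, `ci_high`, `t`, `p`).
#' @export
fit_linear_model <- function(data, spec) {
  mf <- model_frame(data, spec)
  p <- ncol(mf$X)
  if (nrow(mf$X) < p + 1)
    stop("too few complete rows (", nrow(mf$X), ") for ", p, " parameters",
         call. = FALSE)
  check_rank(mf$X)
  fit <- stats::lm.fit(mf$X, mf$y)
  n <- length(mf$y); dfres <- n - p
  sigma2 <- sum(fit$residuals^2) / dfres
  XtX_inv <- chol2inv(chol(crossprod(mf$X)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  est <- fit$coefficients
  tcrit <- stats::qt(0.975, dfres)
  tval <- est / se
  coefs <- data.frame(term = colnames(mf$X), estimate = unname(est),
                      se = unname(se), ci_low = unname(est - tcrit * se),
                      ci_high = unname(est + tcrit * se), t = unname(tval),
                      p = unname(2 * stats::pt(-abs(tval), dfres)),
                      stringsAsFactors = FALSE)
  res <- new_model_result(spec, coefs, n, mf$n_dropped,
                          diagnostics = list(sigma = sqrt(sigma2), df_residual = dfres,
                                             r_squared = 1 - sum(fit$residuals^2) /
                                               sum((mf$y - mean(mf$y))^2)))
  apply_effect_scaling(res, mf$df)
}

# --- median (tau = 0.5) quantile regression -------------------------------

check_loss <- function(r, tau = 0.5) sum(r * (tau - (r < 0)))

# LAD fit: iteratively reweighted least squares, then a Nelder-Mead polish of
# the nondifferentiable objective from the IRLS solution.
lad_fit <- function(X, y, polish = TRUE, max_iter = 200, tol = 1e-12) {
  beta <- stats::lm.fit(X, y)$coefficients
  obj <- function(b) check_loss(y - X %*% b)
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% beta)
    w <- 1 / pmax(abs(r), 1e-8)
    fit <- stats::lm.wfit(X, y, w)
    if (max(abs(fit$coefficients - beta)) < tol) { beta <- fit$coefficients; break }
    beta <- fit$coefficients
  }
  if (polish && ncol(X) <= 12) {
    nm <- stats::optim(beta, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (nm$value < obj(beta)) beta <- nm$par
  }
  names(beta) <- colnames(X)
  list(coefficients = beta, objective = obj(beta), iterations = it)
}

#' Median (quantile) regression with bootstrap CIs
#'
#' Minimizes the tau = 0.5 check loss (least absolute deviations). CIs come
#' from a nonparametric case-resampling bootstrap with a fixed seed.
#'
#' @param data data.frame containing all model columns.
#' @param spec a [model_spec()].
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return an `fe_model`; diagnostics carry the objective value and
#'   iteration count.
#' @export
fit_quantile_median <- function(data, spec, n_boot = 500, seed = 1L) {
  mf <- model_frame(data, spec)
  p <- ncol(mf$X)
  if (nrow(mf$X) < p + 1)
    stop("too few complete rows for quantile regression", call. = FALSE)
  check_rank(mf$X)
  fit <- lad_fit(mf$X, mf$y)
  n <- length(mf$y)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      lad_fit(mf$X[ix, , drop = FALSE], mf$y[ix], polish = FALSE)$coefficients
    }, numeric(p))
  })
  boot <- matrix(boot, nrow = p)
  se <- apply(boot, 1, stats::sd)
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975))
  est <- fit$coefficients
  coefs <- data.frame(term = colnames(mf$X), estimate = unname(est),
                      se = se, ci_low = pmin(ci[1, ], unname(est)),
                      ci_high = pmax(ci[2, ], unname(est)),
                      t = unname(est) / se,
                      p = 2 * stats::pnorm(-abs(unname(est) / se)),
                      stringsAsFactors = FALSE)
  res <- new_model_result(spec, coefs, n, mf$n_dropped,
                          diagnostics = list(objective = fit$objective,
                                             iterations = fit$iterations,
                                             n_boot = n_boot))
  apply_effect_scaling(res, mf$df)
}

# --- effect-scale conversions ---------------------------------------------

#' Percent change implied by a coefficient on a log outcome
#'
#' For a natural-log outcome, a coefficient `beta` on a predictor translates
#' to a `100 * (exp(beta) - 1)` percent change in the outcome per unit of the
#' predictor. Applied elementwise (so CI bounds convert directly).
#'
#' @param beta coefficient(s) on the log-outcome scale.
#' @return percent change(s).
#' @export
percent_change_from_log_coef <- function(beta) 100 * (expm1(beta))

#' Percent change in a log outcome when a log predictor doubles
#'
#' For log outcome on log predictor, doubling the predictor multiplies the
#' outcome by `2^beta`; returns `100 * (2^beta - 1)`.
#'
#' @param beta coefficient(s) of the log predictor.
#' @return percent change(s) per doubling.
#' @export
doubling_effect_from_loglog <- function(beta) 100 * (exp(beta * log(2)) - 1)

#' Interquartile range of a sample (linear-interpolation quantiles)
#' @param x numeric vector with at least 4 non-missing values.
#' @return `Q75 - Q25` (quantile type 7).
#' @export
interquartile_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 non-missing exposure values", call. = FALSE)
  unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}

#' Rescale a fitted exposure effect to an interquartile increase
#'
#' Multiplies the exposure coefficient and its CI bounds by the interquartile
#' range of the exposure in the analysis sample, giving the outcome change
#' per 25th-to-75th-percentile increase in the exposure.
#'
#' @param result an `fe_model`.
#' @param exposure_values the analysis-sample exposure values.
#' @param as_percent_change additionally pass the scaled effect through
#'   [percent_change_from_log_coef()] (for log outcomes).
#' @return the `fe_model` with `scaled_effect` filled in.
#' @export
interquartile_effect <- function(result, exposure_values, as_percent_change = FALSE) {
  iqr <- interquartile_range(exposure_values)
  if (iqr == 0) warning("constant exposure: interquartile effect is 0", call. = FALSE)
  row <- result$coefficients[result$coefficients$term == result$spec$exposure, ]
  if (nrow(row) != 1) stop("exposure term not found in fitted model", call. = FALSE)
  vals <- c(row$estimate, row$ci_low, row$ci_high) * iqr
  if (as_percent_change) vals <- percent_change_from_log_coef(vals)
  result$scaled_effect <- list(scale = if (as_percent_change)
    "percent change per interquartile increase" else "per interquartile increase",
    iqr = iqr, estimate = vals[1], ci_low = min(vals[2:3]), ci_high = max(vals[2:3]))
  result
}

apply_effect_scaling <- function(result, df) {
  if (result$spec$effect_scaling == "interquartile")
    result <- interquartile_effect(result, df[[result$spec$exposure]])
  else if (result$spec$effect_scaling == "percent_change") {
    row <- result$coefficients[result$coefficients$term == result$spec$exposure, ]
    result$scaled_effect <- list(scale = "percent change per unit",
                                 iqr = NA_real_,
                                 estimate = percent_change_from_log_coef(row$estimate),
                                 ci_low = percent_change_from_log_coef(row$ci_low),
                                 ci_high = percent_change_from_log_coef(row$ci_high))
  }
  result
}

#' Predominant racial/ethnic group flags
#'
#' A tract is flagged predominant for a group when that group's population
#' share is 50% or more (inclusive threshold).
#'
#' @param covariates covariate data.frame with `share_nh_white`,
#'   `share_nh_black`, `share_hispanic`.
#' @return data.frame `tract_id`, `predominant_nh_white`,
#'   `predominant_nh_black`, `predominant_hispanic`.
#' @export
predominant_flags <- function(covariates) {
  data.frame(tract_id = covariates$tract_id,
             predominant_nh_white = covariates$share_nh_white >= 0.5,
             predominant_nh_black = covariates$share_nh_black >= 0.5,
             predominant_hispanic = covariates$share_hispanic >= 0.5,
             stringsAsFactors = FALSE)
}

# --- sensitivity stack ----------------------------------------------------

#' Generalized additive model with a smooth exposure
#'
#' Fits the outcome on a penalized thin-plate spline of the exposure plus
#' linear covariates (mgcv, REML smoothing by default). Returns the smooth
#' term's effective degrees of freedom and the fitted partial-effect curve on
#' a 100-point exposure grid (covariates held at their sample means).
#'
#' @param data data.frame containing all model columns.
#' @param spec a [model_spec()].
#' @param method smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @return an `fe_model`; `diagnostics$edf` is the smooth's effective df and
#'   `diagnostics$partial_effect` the grid curve.
#' @export
fit_gam <- function(data, spec, method = "REML") {
  mf <- model_frame(data, spec)
  df <- mf$df
  rhs <- paste(c(sprintf("s(%s)", spec$exposure), spec$covariates), collapse = " + ")
  fml <- stats::as.formula(paste(spec$outcome, "~", rhs))
  fit <- mgcv::gam(fml, data = df, method = method)
  if (!fit$converged) stop("GAM did not converge", call. = FALSE)
  sm <- summary(fit)
  edf <- unname(sm$s.table[1, "edf"])
  grid <- data.frame(seq(min(df[[spec$exposure]]), max(df[[spec$exposure]]),
                         length.out = 100))
  names(grid) <- spec$exposure
  for (cv in spec$covariates) grid[[cv]] <- mean(df[[cv]])
  pt <- stats::predict(fit, newdata = grid, type = "terms",
                       terms = sprintf("s(%s)", spec$exposure))
  # parametric part as a coefficient table; the exposure lives in the smooth
  pcoef <- sm$p.table
  coefs <- data.frame(term = rownames(pcoef), estimate = pcoef[, "Estimate"],
                      se = pcoef[, "Std. Error"],
                      ci_low = pcoef[, "Estimate"] - 1.96 * pcoef[, "Std. Error"],
                      ci_high = pcoef[, "Estimate"] + 1.96 * pcoef[, "Std. Error"],
                      t = pcoef[, "t value"], p = pcoef[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE, row.names = NULL)
  new_model_result(spec, coefs, nrow(df), mf$n_dropped,
                   diagnostics = list(edf = edf, method = method,
                                      partial_effect = data.frame(
                                        exposure = grid[[spec$exposure]],
                                        effect = as.numeric(pt)),
                                      fitted = stats::fitted(fit)))
}

#' Aggregate tract tables to the county level
#'
#' Flow-derived index counts are pooled (county RFAI = pooled healthy visits
#' over pooled qualified visits, identically for retailer counts); covariate
#' and prevalence columns become population-weighted means; population,
#' visit and retailer counts are summed.
#'
#' @param tract_table data.frame keyed by `tract_id` holding covariates,
#'   outcomes and index component counts (as produced by
#'   [prepare_model_data()] with `keep_counts = TRUE`).
#' @param county_map data.frame `tract_id`, `county_id` covering every tract.
#' @return county-level data.frame with recomputed `rfai` and `mrfei`.
#' @export
aggregate_to_county <- function(tract_table, county_map) {
  idx <- match(tract_table$tract_id, county_map$tract_id)
  if (anyNA(idx))
    stop("unmapped tract_id: ", tract_table$tract_id[which(is.na(idx))[1]],
         call. = FALSE)
  county <- county_map$county_id[idx]
  sum_cols <- intersect(c("population", "n_food_retailers", "total_visits",
                          "n_healthy_visits", "n_less_healthy_visits",
                          "n_healthy_retailers", "n_less_healthy_retailers"),
                        names(tract_table))
  skip <- c("tract_id", sum_cols, "rfai", "mrfei", "alt_location_index")
  mean_cols <- setdiff(names(tract_table)[vapply(tract_table, is.numeric, logical(1)) |
                                            vapply(tract_table, is.logical, logical(1))],
                       skip)
  groups <- split(seq_len(nrow(tract_table)), county)
  rows <- lapply(names(groups), function(cid) {
    ix <- groups[[cid]]
    pop <- tract_table$population[ix]
    w <- if (sum(pop) > 0) pop / sum(pop) else rep(1 / length(ix), length(ix))
    out <- list(county_id = cid)
    for (col in sum_cols) out[[col]] <- sum(tract_table[[col]][ix])
    for (col in mean_cols) {
      v <- as.numeric(tract_table[[col]][ix])
      ok <- !is.na(v)
      out[[col]] <- if (any(ok)) sum(v[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(c("n_healthy_visits", "n_less_healthy_visits") %in% names(out))) {
    denom <- out$n_healthy_visits + out$n_less_healthy_visits
    out$rfai <- ifelse(denom > 0, 100 * out$n_healthy_visits / denom, NA_real_)
  }
  if (all(c("n_healthy_retailers", "n_less_healthy_retailers") %in% names(out))) {
    denom <- out$n_healthy_retailers + out$n_less_healthy_retailers
    out$mrfei <- ifelse(denom > 0, 100 * out$n_healthy_retailers / denom, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Row-standardized contiguity weights for a regular lattice
#'
#' @param nrow,ncol lattice dimensions.
#' @param type `"rook"` (edge neighbors) or `"queen"` (edge + corner).
#' @return an `nrow*ncol` square row-standardized weight matrix with zero
#'   diagonal; cells are ordered row-major.
#' @export
lattice_weights <- function(nrow, ncol, type = c("rook", "queen")) {
  type <- match.arg(type)
  n <- nrow * ncol
  W <- matrix(0, n, n)
  idx <- function(r, c) (r - 1L) * ncol + c
  offs <- if (type == "rook") list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nrow && cc >= 1 && cc <= ncol)
        W[idx(r, c), idx(rr, cc)] <- 1
    }
  }
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
  W
}

#' Spatial error model by maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + e` with Gaussian errors by
#' concentrated maximum likelihood: for each `lambda` the model is a GLS fit
#' on the filtered data `(I - lambda W) y`, and the log-determinant term uses
#' the eigenvalues of `W`. Coefficient standard errors are conditional on the
#' estimated `lambda`.
#'
#' @param data data.frame of areal units (rows must align with `W`).
#' @param spec a [model_spec()].
#' @param W spatial weights matrix (row-standardized, zero diagonal).
#' @return an `fe_model`; `diagnostics$lambda` is the spatial error
#'   parameter.
#' @export
fit_spatial_error <- function(data, spec, W) {
  mf <- model_frame(data, spec)
  n <- length(mf$y)
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix", call. = FALSE)
  if (nrow(W) != nrow(data))
    stop("W dimension does not match the data", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  if (mf$n_dropped > 0)
    stop("spatial error model requires complete data (rows must align with W)",
         call. = FALSE)
  check_rank(mf$X)
  if (all(W == 0)) {
    res <- fit_linear_model(data, spec)
    res$diagnostics$lambda <- 0
    res$diagnostics$lambda_se <- NA_real_
    return(res)
  }
  ev <- Re(eigen(W, only.values = TRUE)$values)
  lo <- max(-0.999, if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.999)
  hi <- min(0.999, if (max(ev) > 0) 1 / max(ev) - 1e-6 else 0.999)
  X <- mf$X; y <- mf$y
  conc_loglik <- function(lambda) {
    B <- diag(n) - lambda * W
    ys <- B %*% y; Xs <- B %*% X
    fit <- stats::lm.fit(Xs, ys)
    s2 <- sum(fit$residuals^2) / n
    if (s2 <= 0) return(-Inf)
    sum(log(pmax(1 - lambda * ev, 1e-300))) - n / 2 * log(s2)
  }
  opt <- stats::optimize(conc_loglik, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  if (lambda <= lo + 1e-4 || lambda >= hi - 1e-4)
    stop("spatial error fit did not identify lambda (estimate at bound ",
         format(lambda, digits = 4), ")", call. = FALSE)
  B <- diag(n) - lambda * W
  ys <- B %*% y; Xs <- B %*% X
  fit <- stats::lm.fit(Xs, ys)
  p <- ncol(X)
  s2 <- sum(fit$residuals^2) / n
  XtX_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(s2 * diag(XtX_inv))
  est <- fit$coefficients
  z <- est / se
  coefs <- data.frame(term = colnames(X), estimate = unname(est), se = unname(se),
                      ci_low = unname(est - 1.96 * se),
                      ci_high = unname(est + 1.96 * se), t = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))), stringsAsFactors = FALSE)
  # numerical second derivative of the concentrated log-likelihood
  h <- 1e-4
  d2 <- (conc_loglik(lambda + h) - 2 * opt$objective + conc_loglik(lambda - h)) / h^2
  lambda_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  res <- new_model_result(spec, coefs, n, 0,
                          diagnostics = list(lambda = lambda, lambda_se = lambda_se,
                                             sigma = sqrt(s2),
                                             loglik = opt$objective))
  apply_effect_scaling(res, mf$df)
}

#' Fit a model separately within group strata
#'
#' One independent fit per stratum (e.g., predominant racial/ethnic group
#' tracts) plus the complement of all flagged strata. Strata too small for
#' the specification are skipped with a warning.
#'
#' @param data data.frame of analysis rows.
#' @param spec a [model_spec()].
#' @param group_flags named list (or data.frame) of logical vectors aligned
#'   with `data` rows.
#' @param fit_fun fitting function, default [fit_linear_model()].
#' @return named list of `fe_model` objects (skipped strata are `NULL`).
#' @export
stratified_fit <- function(data, spec, group_flags, fit_fun = fit_linear_model) {
  if (is.data.frame(group_flags))
    group_flags <- as.list(group_flags[, setdiff(names(group_flags), "tract_id"),
                                       drop = FALSE])
  flags <- lapply(group_flags, function(f) !is.na(f) & f)
  flags$other <- !Reduce(`|`, flags)
  p_need <- length(spec$covariates) + 3L
  out <- lapply(names(flags), function(g) {
    sub <- data[flags[[g]], , drop = FALSE]
    if (nrow(sub) < p_need) {
      warning("stratum ", g, " skipped: only ", nrow(sub), " rows", call. = FALSE)
      return(NULL)
    }
    tryCatch(fit_fun(sub, spec), error = function(e) {
      warning("stratum ", g, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  stats::setNames(out, names(flags))
}

# --- model assembly -------------------------------------------------------

CMD_DISEASES <- c("obesity", "high_blood_pressure", "high_cholesterol",
                  "diagnosed_diabetes", "coronary_heart_disease")

cmd_covariates <- function(use_predominant = FALSE) {
  theme3 <- if (use_predominant)
    c("predominant_nh_white", "predominant_nh_black", "predominant_hispanic")
  else "svi_theme3"
  c("svi_theme1", "svi_theme2", theme3, "svi_theme4", "food_desert", "urban",
    "log_pop_density", "log_per_capita_visits", "pct_female", "pct_minority",
    "pct_low_income", "pct_less_than_hs", "pct_under5_over64",
    "median_family_income", "log_n_food_retailers")
}

#' Specification for an index-to-disease association model
#'
#' Assembles the fully adjusted specification: the four social-vulnerability
#' theme percentiles (theme 3 optionally replaced by predominant-group
#' indicators), food-desert and urban flags, log population density, log
#' per-capita food retailer visits (mobility-coverage control), the
#' demographic percentage variables, median family income and the log count
#' of food retailers; effects are reported per interquartile increase of the
#' index.
#'
#' @param index `"rfai"`, `"mrfei"` or `"alt_location_index"`.
#' @param disease one of the five cardiometabolic outcomes.
#' @param unadjusted drop all covariates (crude model).
#' @param use_predominant replace the theme-3 percentile with
#'   predominant-group indicators.
#' @param estimator passed through to [model_spec()].
#' @return a [model_spec()].
#' @export
build_cmd_model_spec <- function(index = c("rfai", "mrfei", "alt_location_index"),
                                 disease, unadjusted = FALSE,
                                 use_predominant = FALSE, estimator = "ols") {
  index <- match.arg(index)
  if (!disease %in% CMD_DISEASES)
    stop("unknown disease '", disease, "'; expected one of: ",
         paste(CMD_DISEASES, collapse = ", "), call. = FALSE)
  covs <- if (unadjusted) character(0) else cmd_covariates(use_predominant)
  model_spec(outcome = disease, exposure = index, covariates = covs,
             estimator = estimator, effect_scaling = "interquartile")
}

#' Specification for the travel-distance models
#'
#' Log-linear (or median quantile) regression of the tract's median travel
#' distance on sociodemographics, with log per-capita visits as the
#' mobility-coverage control.
#'
#' @param estimator `"ols"` (log outcome) or `"quantile_median"` (identity
#'   outcome).
#' @param use_predominant replace theme 3 with predominant-group indicators.
#' @return a [model_spec()].
#' @export
build_distance_model_spec <- function(estimator = c("ols", "quantile_median"),
                                      use_predominant = FALSE) {
  estimator <- match.arg(estimator)
  theme3 <- if (use_predominant)
    c("predominant_nh_white", "predominant_nh_black", "predominant_hispanic")
  else "svi_theme3"
  covs <- c("svi_theme2", theme3, "svi_theme4", "food_desert", "urban",
            "log_pop_density", "log_per_capita_visits")
  model_spec(outcome = "median_distance_miles", exposure = "svi_theme1",
             covariates = covs,
             outcome_transform = if (estimator == "ols") "natural_log" else "identity",
             estimator = estimator, effect_scaling = "per_unit")
}

#' Assemble the tract-level analysis table
#'
#' Joins covariates, outcomes, index records and mobility summaries on
#' `tract_id` and derives the log-transformed model columns
#' (`log_pop_density`, `log_per_capita_visits`, `log_n_food_retailers`) and
#' the predominant-group flags. Zero-valued arguments of a log produce `NA`
#' (row later dropped by listwise deletion; counts reported at fit time).
#'
#' @param covariates covariate table.
#' @param outcomes outcome table.
#' @param indices index records from [compute_indices()].
#' @param mobility mobility summaries from [summarize_mobility()].
#' @return one analysis data.frame keyed by `tract_id`.
#' @export
prepare_model_data <- function(covariates, outcomes, indices, mobility) {
  df <- merge(covariates, outcomes, by = "tract_id", sort = TRUE)
  df <- merge(df, indices, by = "tract_id", sort = TRUE)
  df <- merge(df, mobility, by = "tract_id", sort = TRUE)
  safe_log <- function(x) ifelse(!is.na(x) & x > 0, log(x), NA_real_)
  df$log_pop_density <- safe_log(df$pop_density)
  df$log_per_capita_visits <- safe_log(df$per_capita_visits)
  df$log_n_food_retailers <- safe_log(df$n_food_retailers)
  pf <- predominant_flags(df)
  df$predominant_nh_white <- pf$predominant_nh_white
  df$predominant_nh_black <- pf$predominant_nh_black
  df$predominant_hispanic <- pf$predominant_hispanic
  df
}

# run code under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
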