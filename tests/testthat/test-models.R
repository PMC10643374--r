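sim_table <- function(n, seed = 1, slope = 2, noise = 1) {
  set.seed(seed)
  x <- runif(n, 0, 10)
  data.frame(y = 1 + slope * x + rnorm(n, 0, noise), x = x,
             z1 = rnorm(n), z2 = rnorm(n))
}

test_that("OLS recovers exact lines and reduces to the sample mean", {
  d <- data.frame(y = 2 * (1:10), x = 1:10)
  fit <- fit_linear_model(d, model_spec("y", "x"))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 2,
               tolerance = 1e-12)
  expect_equal(fit$diagnostics$sigma, 0, tolerance = 1e-9)
  # intercept-only: regress on a constant-free spec via a zero-variance trick
  d2 <- data.frame(y = rnorm(20), x = rnorm(20))
  fit2 <- fit_linear_model(d2, model_spec("y", "x"))
  expect_equal(sum(fit2$coefficients$term == "(Intercept)"), 1)
})

test_that("OLS matches the normal-equations oracle to 1e-8", {
  set.seed(501)
  for (case in 1:20) {
    n <- 50
    X <- cbind(1, matrix(rnorm(n * 4), n, 4))
    beta <- rnorm(5)
    y <- X %*% beta + rnorm(n)
    d <- data.frame(y = y, x = X[, 2], z1 = X[, 3], z2 = X[, 4], z3 = X[, 5])
    fit <- fit_linear_model(d, model_spec("y", "x", c("z1", "z2", "z3")))
    oracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(fit$coefficients$estimate, as.numeric(oracle), tolerance = 1e-8)
    # classical SEs from the same normal equations
    res <- y - X %*% oracle
    s2 <- sum(res^2) / (n - 5)
    expect_equal(fit$coefficients$se, sqrt(diag(s2 * solve(t(X) %*% X))),
                 tolerance = 1e-8)
  }
})

test_that("singular designs fail naming the collinear column", {
  d <- sim_table(30)
  d$x2 <- 2 * d$x
  expect_error(fit_linear_model(d, model_spec("y", "x", "x2")), "x2")
})

test_that("CI bounds always bracket the estimate", {
  d <- sim_table(40, seed = 7)
  fit <- fit_linear_model(d, model_spec("y", "x", c("z1", "z2")))
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$estimate <= fit$coefficients$ci_high))
  expect_equal(fit$n_units, 40)
})

test_that("median regression is exact on noiseless lines", {
  d <- data.frame(y = 3 + 0.5 * (1:20), x = 1:20)
  fit <- fit_quantile_median(d, model_spec("y", "x", estimator = "quantile_median"),
                             n_boot = 20, seed = 5)
  expect_equal(unname(fit$coefficients$estimate), c(3, 0.5), tolerance = 1e-6)
  expect_lt(fit$diagnostics$objective, 1e-8)
})

test_that("median regression beats a dense grid of candidate lines", {
  set.seed(502)
  for (case in 1:40) {
    x <- runif(5, 0, 10); y <- 1 + 0.7 * x + rt(5, 2)
    d <- data.frame(y = y, x = x)
    fit <- fit_quantile_median(d, model_spec("y", "x", estimator = "quantile_median"),
                               n_boot = 10, seed = case)
    a <- seq(min(y) - 3, max(y) + 3, length.out = 80)
    b <- seq(-3, 3, length.out = 80)
    grid_obj <- outer(a, b, Vectorize(function(ai, bi)
      sum(abs(y - ai - bi * x)) * 0.5))
    expect_lte(fit$diagnostics$objective, min(grid_obj) + 1e-6)
  }
})

test_that("median regression slope tracks OLS under symmetric noise", {
  set.seed(503)
  n <- 2000
  x <- runif(n, 0, 10)
  y <- 2 + 1.5 * x + rt(n, 3)  # symmetric, heavy-tailed
  d <- data.frame(y = y, x = x)
  qfit <- fit_quantile_median(d, model_spec("y", "x", estimator = "quantile_median"),
                              n_boot = 200, seed = 11)
  ols <- fit_linear_model(d, model_spec("y", "x"))
  q_slope <- qfit$coefficients[qfit$coefficients$term == "x", ]
  o_slope <- ols$coefficients$estimate[ols$coefficients$term == "x"]
  expect_lt(abs(q_slope$estimate - o_slope), 3 * q_slope$se)
})

test_that("log-scale effect conversions are exact inverses", {
  expect_equal(percent_change_from_log_coef(0), 0)
  expect_equal(percent_change_from_log_coef(log(2)), 100, tolerance = 1e-12)
  expect_equal(percent_change_from_log_coef(-0.2944), 100 * (exp(-0.2944) - 1),
               tolerance = 1e-12)
  expect_equal(round(percent_change_from_log_coef(-0.2944), 2), -25.5)
  expect_equal(doubling_effect_from_loglog(0), 0)
  expect_equal(doubling_effect_from_loglog(1), 100, tolerance = 1e-12)
  expect_equal(round(doubling_effect_from_loglog(-0.4659), 1), -27.6)
  # round trips
  for (beta in c(-1.3, -0.01, 0.4, 2)) {
    expect_equal(log(1 + percent_change_from_log_coef(beta) / 100), beta,
                 tolerance = 1e-12)
    expect_equal(log2(1 + doubling_effect_from_loglog(beta) / 100), beta,
                 tolerance = 1e-12)
  }
})

test_that("interquartile scaling multiplies by the sample IQR", {
  d <- sim_table(200, seed = 9)
  fit <- fit_linear_model(d, model_spec("y", "x", effect_scaling = "interquartile"))
  iqr <- unname(diff(quantile(d$x, c(0.25, 0.75), type = 7)))
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_equal(fit$scaled_effect$iqr, iqr, tolerance = 1e-12)
  expect_equal(fit$scaled_effect$estimate, row$estimate * iqr, tolerance = 1e-12)
  # stated example: beta 0.02 over quartiles 10 and 35
  fake <- fit; fake$coefficients$estimate[2] <- 0.02
  fake2 <- interquartile_effect(fake, c(rep(10, 2), rep(35, 2)))
  expect_equal(fake2$scaled_effect$estimate, 0.02 * 25, tolerance = 1e-12)
  expect_warning(interquartile_effect(fit, rep(5, 10)), "constant")
})

test_that("interquartile effect negates under exposure sign flip", {
  d <- sim_table(150, seed = 10)
  spec <- model_spec("y", "x", c("z1"), effect_scaling = "interquartile")
  fit <- fit_linear_model(d, spec)
  d2 <- d; d2$x <- -d2$x
  fit2 <- fit_linear_model(d2, spec)
  expect_equal(fit2$scaled_effect$estimate, -fit$scaled_effect$estimate,
               tolerance = 1e-10)
  expect_equal(fit2$scaled_effect$ci_low, -fit$scaled_effect$ci_high,
               tolerance = 1e-10)
  expect_equal(fit2$scaled_effect$ci_high, -fit$scaled_effect$ci_low,
               tolerance = 1e-10)
})

test_that("predominant flags use an inclusive 50% threshold", {
  cov <- data.frame(tract_id = c("A", "B", "C"),
                    share_nh_white = c(0.499, 0.2, 0.3),
                    share_nh_black = c(0.2, 0.5, 0.3),
                    share_hispanic = c(0.2, 0.2, 0.3))
  f <- predominant_flags(cov)
  expect_false(f$predominant_nh_white[1])
  expect_true(f$predominant_nh_black[2])
  expect_false(any(unlist(f[3, -1])))
})

test_that("noise covariates leave the exposure estimate within one SE", {
  set.seed(504)
  d <- sim_table(500, seed = 21)
  spec0 <- model_spec("y", "x")
  spec1 <- model_spec("y", "x", c("z1", "z2"))
  f0 <- fit_linear_model(d, spec0)
  f1 <- fit_linear_model(d, spec1)
  b0 <- f0$coefficients[f0$coefficients$term == "x", ]
  b1 <- f1$coefficients$estimate[f1$coefficients$term == "x"]
  expect_lt(abs(b1 - b0$estimate), b0$se)
})

test_that("GAM effective df separates linear from curved truth", {
  set.seed(505)
  n <- 2000
  x <- runif(n, 0, 10); z <- rnorm(n)
  lin <- data.frame(y = 1 + 0.5 * x + 0.3 * z + rnorm(n, 0, 0.3), x = x, z = z)
  fit_lin <- fit_gam(lin, model_spec("y", "x", "z", estimator = "gam"))
  expect_gte(fit_lin$diagnostics$edf, 0.8)
  expect_lte(fit_lin$diagnostics$edf, 1.5)
  quad <- data.frame(y = 1 + 0.3 * (x - 5)^2 + 0.3 * z + rnorm(n, 0, 0.3),
                     x = x, z = z)
  fit_quad <- fit_gam(quad, model_spec("y", "x", "z", estimator = "gam"))
  expect_gt(fit_quad$diagnostics$edf, 1.5)
  # partial effect tracks the centered true curve
  pe <- fit_quad$diagnostics$partial_effect
  truth <- 0.3 * (pe$exposure - 5)^2
  truth <- truth - mean(truth)
  expect_lt(sqrt(mean((pe$effect - mean(pe$effect) - truth)^2)), 0.5)
  # zero-noise linear data is interpolated
  lin0 <- data.frame(y = 1 + 0.5 * x, x = x, z = 0 * z)
  # zero noise is the interpolation limit; mgcv warns about the degenerate
  # smoothing-parameter step there
  fit0 <- suppressWarnings(fit_gam(lin0, model_spec("y", "x", estimator = "gam")))
  expect_lt(max(abs(fit0$diagnostics$fitted - lin0$y)), 1e-6)
})

test_that("county aggregation pools counts and population-weights means", {
  tab <- data.frame(tract_id = c("T1", "T2", "T3"),
                    population = c(100, 300, 50),
                    svi_theme1 = c(0.2, 0.6, 0.9),
                    obesity = c(30, 40, 35),
                    n_healthy_visits = c(3, 1, 8),
                    n_less_healthy_visits = c(1, 3, 0),
                    n_healthy_retailers = c(1, 0, 2),
                    n_less_healthy_retailers = c(1, 2, 0))
  cmap <- data.frame(tract_id = c("T1", "T2", "T3"),
                     county_id = c("C1", "C1", "C2"))
  out <- aggregate_to_county(tab, cmap)
  c1 <- out[out$county_id == "C1", ]
  expect_equal(c1$rfai, 50)  # pooled (3+1)/(3+1+1+3)
  expect_equal(c1$population, 400)
  expect_equal(c1$svi_theme1, (100 * 0.2 + 300 * 0.6) / 400)
  expect_equal(c1$mrfei, 100 * 1 / 4)
  # single-tract county equals the tract row
  c2 <- out[out$county_id == "C2", ]
  expect_equal(c2$rfai, 100)
  expect_equal(c2$svi_theme1, 0.9)
  expect_error(aggregate_to_county(tab, cmap[1:2, ]), "unmapped")
})

test_that("county aggregation equals brute-force pooled recomputation", {
  set.seed(506)
  n <- 60
  tab <- data.frame(tract_id = sprintf("T%02d", 1:n),
                    population = sample(100:5000, n),
                    svi_theme1 = runif(n), obesity = runif(n, 20, 50),
                    n_healthy_visits = sample(0:50, n, TRUE),
                    n_less_healthy_visits = sample(0:50, n, TRUE))
  cmap <- data.frame(tract_id = tab$tract_id,
                     county_id = sample(sprintf("C%d", 1:7), n, TRUE))
  out <- aggregate_to_county(tab, cmap)
  for (cid in unique(cmap$county_id)) {
    ix <- cmap$county_id == cid
    h <- sum(tab$n_healthy_visits[ix]); l <- sum(tab$n_less_healthy_visits[ix])
    want <- if (h + l > 0) 100 * h / (h + l) else NA_real_
    expect_equal(out$rfai[out$county_id == cid], want, tolerance = 1e-12)
    expect_equal(out$svi_theme1[out$county_id == cid],
                 weighted.mean(tab$svi_theme1[ix], tab$population[ix]),
                 tolerance = 1e-12)
  }
})

test_that("spatial error model reduces to OLS when W is zero", {
  d <- sim_table(25, seed = 31)
  spec <- model_spec("y", "x", estimator = "spatial_error")
  sfit <- fit_spatial_error(d, spec, matrix(0, 25, 25))
  ofit <- fit_linear_model(d, model_spec("y", "x"))
  expect_equal(sfit$diagnostics$lambda, 0)
  expect_equal(sfit$coefficients$estimate, ofit$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("spatial error ML recovers planted lambda on a lattice", {
  W <- lattice_weights(20, 20, "rook")
  n <- 400
  set.seed(507)
  X <- cbind(1, rnorm(n))
  make_y <- function(lambda) {
    e <- rnorm(n, 0, 1)
    u <- solve(diag(n) - lambda * W, e)
    as.numeric(X %*% c(1, 2) + u)
  }
  d5 <- data.frame(y = make_y(0.5), x = X[, 2])
  fit5 <- fit_spatial_error(d5, model_spec("y", "x", estimator = "spatial_error"), W)
  expect_lt(abs(fit5$diagnostics$lambda - 0.5), 0.1)
  expect_lt(abs(fit5$coefficients$estimate[2] - 2), 0.2)
  d0 <- data.frame(y = make_y(0), x = X[, 2])
  fit0 <- fit_spatial_error(d0, model_spec("y", "x", estimator = "spatial_error"), W)
  expect_lt(abs(fit0$diagnostics$lambda), 0.1)
})

test_that("stratified fits run per group and skip undersized strata", {
  d <- sim_table(60, seed = 41)
  spec <- model_spec("y", "x", "z1")
  flags <- list(g1 = rep(c(TRUE, FALSE), each = 30),
                g2 = rep(FALSE, 60))
  expect_warning(fits <- stratified_fit(d, spec, flags), "skipped")
  expect_null(fits$g2)
  expect_s3_class(fits$g1, "fe_model")
  expect_s3_class(fits$other, "fe_model")
  # identical strata give identical coefficients
  flags2 <- list(a = rep(TRUE, 60))
  d2 <- rbind(d, d)
  flags3 <- list(a = rep(c(TRUE, FALSE), each = 60))
  fits3 <- stratified_fit(d2, spec, flags3)
  expect_equal(fits3$a$coefficients$estimate, fits3$other$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("disease model specs assemble the documented covariate set", {
  spec <- build_cmd_model_spec("rfai", "obesity")
  expect_length(spec$covariates, 15)
  expect_equal(spec$exposure, "rfai")
  expect_equal(spec$effect_scaling, "interquartile")
  expect_true(all(c("svi_theme3", "log_per_capita_visits",
                    "log_n_food_retailers") %in% spec$covariates))
  spec_p <- build_cmd_model_spec("mrfei", "obesity", use_predominant = TRUE)
  expect_false("svi_theme3" %in% spec_p$covariates)
  expect_true("predominant_hispanic" %in% spec_p$covariates)
  expect_length(build_cmd_model_spec("rfai", "obesity", unadjusted = TRUE)$covariates,
                0)
  expect_error(build_cmd_model_spec("rfai", "gout"), "unknown disease")
  expect_error(model_spec("y", "x", "x"), "covariates")
})
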