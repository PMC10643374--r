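# Synthetic study generator: a grid of square-mile tracts in planar-mile
# coordinates, log-normal populations, rank-transformed correlated social
# vulnerability themes, NAICS-coded POIs whose category mix tilts toward
# convenience stores and limited-service restaurants in deprived tracts, a
# gravity destination-choice model with exponential distance decay and a
# covariate-linked healthy-food preference, and disease prevalence generated
# from the TRUE (choice-probability) activity index with planted
# coefficients. Every stage is deterministic under the scenario seed.

#' Synthetic study scenario
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: a 30 x 30 grid of 1-square-mile tracts, about 1,500 POIs, 20
#' sampled visits per resident, and a planted obesity coefficient of -0.025
#' prevalence points per index unit.
#'
#' @param seed integer RNG seed.
#' @param grid_dims `c(rows, cols)` of the tract grid.
#' @param tract_side_miles tract cell side length.
#' @param pop_lognormal_params `c(meanlog, sdlog)` of tract population.
#' @param poi_intensity expected POIs per tract (scaled within the region by
#'   the square root of population density).
#' @param category_mix base probabilities over the five NAICS categories.
#' @param category_tilt log-odds shift of the less-healthy categories per
#'   unit of socioeconomic-vulnerability percentile above 0.5.
#' @param svi_correlation correlation of each SVI theme with the latent
#'   deprivation factor.
#' @param gravity_decay_miles distance-decay scale (miles) of the
#'   exponential gravity kernel.
#' @param attractiveness_sdlog log-normal spread of POI attractiveness
#'   around its category mean.
#' @param category_attractiveness relative mean attractiveness per category.
#' @param healthy_pref_coefs named coefficients (an `(Intercept)` plus
#'   covariate columns) of the log multiplier applied to healthy
#'   destinations.
#' @param healthy_pref_sd standard deviation of a tract-level random effect
#'   added to the healthy-preference log multiplier - behavioral
#'   heterogeneity not captured by sociodemographics.
#' @param visits_per_capita expected sampled visits per resident.
#' @param years years over which visits are split uniformly.
#' @param urban_density_threshold persons per square mile above which a
#'   tract is urban.
#' @param outcome_coefs per-disease list of `alpha` (intercept), `gamma`
#'   (coefficient on the true index) and `beta` (named covariate
#'   coefficients).
#' @param noise_sd prevalence noise standard deviation (percentage points).
#' @return object of class `fe_scenario`.
#' @export
scenario <- function(seed = 1L,
                     grid_dims = c(30L, 30L),
                     tract_side_miles = 1,
                     pop_lognormal_params = c(meanlog = 8.2, sdlog = 0.5),
                     poi_intensity = 5 / 3,
                     category_mix = c("445110" = 0.18, "452311" = 0.01,
                                      "445230" = 0.02, "445120" = 0.28,
                                      "722513" = 0.51),
                     category_tilt = 0.8,
                     svi_correlation = 0.7,
                     gravity_decay_miles = 3,
                     attractiveness_sdlog = 0.5,
                     category_attractiveness = c("445110" = 5, "452311" = 6,
                                                 "445230" = 0.7, "445120" = 1,
                                                 "722513" = 1.5),
                     healthy_pref_coefs = c("(Intercept)" = 0.3, svi_theme1 = -1.2),
                     healthy_pref_sd = 0.5,
                     visits_per_capita = 20,
                     years = c(2018L, 2019L),
                     urban_density_threshold = 2500,
                     outcome_coefs = default_outcome_coefs(),
                     noise_sd = 2) {
  stopifnot(length(grid_dims) == 2, all(grid_dims >= 1),
            tract_side_miles > 0, poi_intensity >= 0,
            gravity_decay_miles > 0, visits_per_capita >= 0, noise_sd >= 0)
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "fe_scenario")
}

#' Default planted outcome coefficients
#'
#' Prevalence intercepts near national adult levels, an obesity coefficient
#' of -0.025 prevalence points per index unit (about -0.6 points per
#' 25-unit interquartile increase), and deprivation effects through the
#' socioeconomic vulnerability percentile.
#'
#' @return named list, one entry per disease.
#' @export
default_outcome_coefs <- function() {
  list(
    obesity = list(alpha = 42, gamma = -0.025, beta = c(svi_theme1 = 6, urban = -1)),
    high_blood_pressure = list(alpha = 34, gamma = -0.02, beta = c(svi_theme1 = 8)),
    high_cholesterol = list(alpha = 32, gamma = -0.007,
                            beta = c(svi_theme1 = 3, pct_under5_over64 = 10)),
    diagnosed_diabetes = list(alpha = 9, gamma = -0.008, beta = c(svi_theme1 = 6)),
    coronary_heart_disease = list(alpha = 5.5, gamma = -0.003, beta = c(svi_theme1 = 3))
  )
}

stage_seed <- function(seed, stage)
  as.integer((as.numeric(seed) %% 100000) * 16 + stage)

clip01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

#' Generate the tract region and sociodemographics
#'
#' Builds the square-tract grid in planar-mile coordinates and draws tract
#' populations, SVI theme percentile ranks (rank-transformed Gaussians
#' sharing a latent deprivation factor), racial/ethnic shares, demographic
#' percentages and income. `food_desert` and `n_food_retailers` are filled
#' in later from the generated retailers by [derive_access_covariates()].
#'
#' @param sc an [scenario()].
#' @return list with `tracts` (a [tract_set()]) and `covariates`.
#' @export
generate_region <- function(sc) {
  nr <- sc$grid_dims[1]; nc <- sc$grid_dims[2]; s <- sc$tract_side_miles
  n <- nr * nc
  ids <- sprintf("T%05d", seq_len(n))
  polys <- vector("list", n)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- k + 1L
    x0 <- (c - 1) * s; y0 <- (r - 1) * s
    polys[[k]] <- rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s))
  }
  tracts <- tract_set(ids, polys, planar = TRUE)
  cov <- with_seed(stage_seed(sc$seed, 1L), {
    pop <- round(stats::rlnorm(n, sc$pop_lognormal_params[1], sc$pop_lognormal_params[2]))
    z_dep <- stats::rnorm(n)
    rho <- sc$svi_correlation
    themes <- matrix(vapply(1:4, function(k) {
      raw <- rho * z_dep + sqrt(1 - rho^2) * stats::rnorm(n)
      (rank(raw, ties.method = "first") - 0.5) / n
    }, numeric(n)), nrow = n)
    dens <- pop / (s * s)
    pl <- stats::plogis
    alpha <- cbind(white = 6 * pl(-z_dep) + 0.3, black = 2.5 * pl(z_dep) + 0.2,
                   hispanic = 2.5 * pl(z_dep - 0.2) + 0.2, other = 0.8)
    g <- matrix(stats::rgamma(n * 4, shape = alpha), n, 4)
    shares <- g / rowSums(g)
    svi1 <- themes[, 1]
    data.frame(
      tract_id = ids,
      svi_theme1 = svi1, svi_theme2 = themes[, 2], svi_theme3 = themes[, 3],
      svi_theme4 = themes[, 4],
      food_desert = NA, urban = dens > sc$urban_density_threshold,
      population = pop, pop_density = dens,
      share_nh_white = shares[, 1], share_nh_black = shares[, 2],
      share_hispanic = shares[, 3],
      pct_female = clip01(stats::rnorm(n, 0.51, 0.02), 0.3, 0.7),
      pct_minority = 1 - shares[, 1],
      pct_low_income = clip01(0.08 + 0.45 * svi1 + stats::rnorm(n, 0, 0.05)),
      pct_less_than_hs = clip01(0.03 + 0.30 * svi1 + stats::rnorm(n, 0, 0.04)),
      pct_under5_over64 = clip01(stats::rnorm(n, 0.26, 0.04), 0.05, 0.6),
      median_family_income = round(exp(11.6 - 1.0 * svi1 + stats::rnorm(n, 0, 0.15))),
      n_food_retailers = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  list(tracts = tracts, covariates = cov)
}

#' Generate NAICS-coded food retailer POIs
#'
#' Per-tract Poisson counts with intensity increasing in population density;
#' categories drawn from the scenario mix tilted toward less-healthy
#' categories in socioeconomically vulnerable tracts; locations uniform
#' within the tract cell; employee counts drawn for supermarkets/grocery
#' stores so all three employee-size classes are populated.
#'
#' @param sc an [scenario()].
#' @param tracts tract set from [generate_region()].
#' @param covariates covariate table from [generate_region()].
#' @return POI data.frame (`poi_id`, `lon`, `lat`, `naics_code`,
#'   `employee_count`, plus the generating `tract_id` for bookkeeping).
#' @export
generate_pois <- function(sc, tracts, covariates) {
  n <- length(tracts)
  s <- sc$tract_side_miles
  cats <- names(sc$category_mix)
  less_healthy <- cats %in% c("445120", "722513")
  with_seed(stage_seed(sc$seed, 2L), {
    w <- sqrt(pmax(covariates$pop_density, 0))
    lambda <- if (mean(w) > 0) sc$poi_intensity * w / mean(w) else rep(0, n)
    counts <- stats::rpois(n, lambda)
    total <- sum(counts)
    if (total == 0)
      return(data.frame(poi_id = character(0), lon = numeric(0), lat = numeric(0),
                        naics_code = character(0), employee_count = numeric(0),
                        tract_id = character(0), stringsAsFactors = FALSE))
    tract_idx <- rep.int(seq_len(n), counts)
    # tilt the category mix by deprivation
    tilt <- sc$category_tilt * (covariates$svi_theme1[tract_idx] - 0.5)
    logw <- matrix(log(sc$category_mix), total, length(cats), byrow = TRUE)
    logw[, less_healthy] <- logw[, less_healthy] + tilt
    pw <- exp(logw); pw <- pw / rowSums(pw)
    u <- stats::runif(total)
    cum <- t(apply(pw, 1, cumsum))
    cat_idx <- rowSums(u > cum) + 1L
    naics <- cats[cat_idx]
    # uniform location within the generating tract cell
    cent <- tract_centroids(tracts)[tract_idx, , drop = FALSE]
    lon <- cent[, 1] + stats::runif(total, -s / 2, s / 2)
    lat <- cent[, 2] + stats::runif(total, -s / 2, s / 2)
    emp <- rep(NA_real_, total)
    g <- which(naics == "445110")
    if (length(g)) {
      cls <- sample(1:3, length(g), replace = TRUE, prob = c(0.2, 0.15, 0.65))
      emp[g] <- ifelse(cls == 1, sample(1:3, length(g), replace = TRUE),
                ifelse(cls == 2, sample(4:9, length(g), replace = TRUE),
                       10 + stats::rpois(length(g), 40)))
    }
    data.frame(poi_id = sprintf("P%06d", seq_len(total)), lon = lon, lat = lat,
               naics_code = naics, employee_count = emp,
               tract_id = tracts$info$tract_id[tract_idx], stringsAsFactors = FALSE)
  })
}

#' Fill access-derived covariates from the generated retailers
#'
#' `n_food_retailers` is the POI count in the tract; `food_desert` follows a
#' low-income low-access rule: family income in the bottom 40% of tracts AND
#' centroid distance to the nearest supermarket/grocery store beyond 0.5
#' miles (urban) or 10 miles (non-urban).
#'
#' @param tracts tract set.
#' @param covariates covariate table.
#' @param pois generated POI table.
#' @return the covariate table with `food_desert` and `n_food_retailers`
#'   filled.
#' @export
derive_access_covariates <- function(tracts, covariates, pois) {
  tab <- table(factor(pois$tract_id, levels = covariates$tract_id))
  covariates$n_food_retailers <- as.numeric(tab[covariates$tract_id])
  super <- pois[pois$naics_code == "445110", , drop = FALSE]
  cent <- tract_centroids(tracts)
  if (nrow(super) == 0) {
    dmin <- rep(Inf, nrow(covariates))
  } else {
    dmin <- vapply(seq_len(nrow(covariates)), function(i) {
      min(geodesic_distance_miles(
        matrix(cent[i, ], ncol = 2)[rep(1, nrow(super)), , drop = FALSE],
        cbind(super$lon, super$lat), planar = tracts$planar))
    }, numeric(1))
  }
  low_income <- covariates$median_family_income <=
    stats::quantile(covariates$median_family_income, 0.4, type = 7)
  covariates$food_desert <- low_income &
    (dmin > ifelse(covariates$urban, 0.5, 10))
  covariates
}

# gravity choice probabilities: rows tracts, cols POIs; `taste` is the
# realized tract-level healthy-preference random effect
choice_probabilities <- function(sc, tracts, covariates, pois, attractiveness,
                                 taste = 0) {
  cent <- tract_centroids(tracts)
  dx <- outer(cent[, 1], pois$lon, "-")
  dy <- outer(cent[, 2], pois$lat, "-")
  D <- sqrt(dx * dx + dy * dy)
  healthy <- classify_rfai(pois$naics_code) == "healthy"
  theta <- sc$healthy_pref_coefs
  xb <- rep(0, nrow(covariates))
  for (nm in names(theta)) {
    xb <- xb + theta[[nm]] *
      (if (nm == "(Intercept)") 1 else as.numeric(covariates[[nm]]))
  }
  W <- sweep(exp(-D / sc$gravity_decay_miles), 2, attractiveness, "*")
  W[, healthy] <- W[, healthy] * exp(xb + taste)
  P <- W / rowSums(W)
  list(P = P, healthy = healthy, D = D)
}

#' Generate gravity-model visit flows and the true activity index
#'
#' For each tract, total sampled visits are Poisson(population x
#' visits-per-capita) and destinations are multinomial with probability
#' proportional to POI attractiveness x exp(-distance / decay) x a healthy
#' multiplier exp(theta' x). Returns the flow table, the exact choice-model
#' probability of a healthy destination per tract (the TRUE index, x100),
#' and optionally the full probability matrix for analytic checks.
#'
#' @param sc an [scenario()].
#' @param tracts,covariates,pois stage outputs.
#' @param return_probs also return the tract x POI probability matrix and
#'   distances.
#' @return list with `flows`, `true_rfai` (data.frame `tract_id`,
#'   `true_rfai`), `attractiveness`, and (optionally) `probs`.
#' @export
generate_flows <- function(sc, tracts, covariates, pois, return_probs = FALSE) {
  n <- length(tracts)
  empty <- data.frame(origin_tract_id = character(0), poi_id = character(0),
                      year = integer(0), visit_count = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pois) == 0) {
    warning("no POIs: all tracts get zero visits", call. = FALSE)
    return(list(flows = empty,
                true_rfai = data.frame(tract_id = tracts$info$tract_id,
                                       true_rfai = NA_real_)))
  }
  with_seed(stage_seed(sc$seed, 3L), {
    attr_mult <- sc$category_attractiveness[pois$naics_code]
    attractiveness <- as.numeric(attr_mult) *
      stats::rlnorm(nrow(pois), 0, sc$attractiveness_sdlog)
    taste <- stats::rnorm(n, 0, sc$healthy_pref_sd)
    cp <- choice_probabilities(sc, tracts, covariates, pois, attractiveness, taste)
    qualified <- classify_rfai(pois$naics_code) %in% c("healthy", "less_healthy")
    p_heal <- rowSums(cp$P[, cp$healthy, drop = FALSE])
    p_qual <- rowSums(cp$P[, qualified, drop = FALSE])
    true_rfai <- ifelse(p_qual > 0, 100 * p_heal / p_qual, NA_real_)
    totals <- stats::rpois(n, covariates$population * sc$visits_per_capita)
    o_idx <- p_idx <- cnt_all <- vector("list", n)
    for (i in seq_len(n)) {
      if (totals[i] == 0) next
      cnt <- as.numeric(stats::rmultinom(1, totals[i], cp$P[i, ]))
      nz <- which(cnt > 0)
      if (!length(nz)) next
      o_idx[[i]] <- rep.int(i, length(nz)); p_idx[[i]] <- nz; cnt_all[[i]] <- cnt[nz]
    }
    o_idx <- unlist(o_idx); p_idx <- unlist(p_idx); cnt_all <- unlist(cnt_all)
    if (length(o_idx) == 0) {
      flows <- empty
    } else if (length(sc$years) > 1) {
      y1 <- stats::rbinom(length(cnt_all), cnt_all, 1 / length(sc$years))
      flows <- data.frame(
        origin_tract_id = rep(tracts$info$tract_id[o_idx], 2L),
        poi_id = rep(pois$poi_id[p_idx], 2L),
        year = rep(sc$years[1:2], each = length(o_idx)),
        visit_count = c(y1, cnt_all - y1), stringsAsFactors = FALSE)
    } else {
      flows <- data.frame(origin_tract_id = tracts$info$tract_id[o_idx],
                          poi_id = pois$poi_id[p_idx], year = sc$years[1],
                          visit_count = cnt_all, stringsAsFactors = FALSE)
    }
    flows <- flows[flows$visit_count > 0, , drop = FALSE]
    rownames(flows) <- NULL
    out <- list(flows = flows,
                true_rfai = data.frame(tract_id = tracts$info$tract_id,
                                       true_rfai = true_rfai,
                                       stringsAsFactors = FALSE),
                attractiveness = attractiveness, taste = taste)
    if (return_probs) out$probs <- cp
    out
  })
}

#' Generate disease prevalence from the true index
#'
#' `prevalence = alpha + gamma * true_index + beta' x + Normal(0, noise_sd)`,
#' clipped to `[0, 100]` (clip events are reported).
#'
#' @param sc an [scenario()].
#' @param covariates covariate table.
#' @param true_rfai data.frame from [generate_flows()].
#' @return outcome data.frame, one prevalence column per disease.
#' @export
generate_outcomes <- function(sc, covariates, true_rfai) {
  n <- nrow(covariates)
  tr <- true_rfai$true_rfai[match(covariates$tract_id, true_rfai$tract_id)]
  with_seed(stage_seed(sc$seed, 4L), {
    out <- data.frame(tract_id = covariates$tract_id, stringsAsFactors = FALSE)
    n_clip <- 0L
    for (dis in names(sc$outcome_coefs)) {
      oc <- sc$outcome_coefs[[dis]]
      xb <- rep(oc$alpha, n)
      for (nm in names(oc$beta)) xb <- xb + oc$beta[[nm]] * as.numeric(covariates[[nm]])
      prev <- xb + oc$gamma * tr + stats::rnorm(n, 0, sc$noise_sd)
      n_clip <- n_clip + sum(prev < 0 | prev > 100, na.rm = TRUE)
      out[[dis]] <- clip01(prev, 0, 100)
    }
    if (n_clip > 0) fe_log("outcomes: clipped ", n_clip, " prevalence value(s)")
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs all stages under the scenario seed and returns every table plus the
#' planted truth.
#'
#' @param sc an [scenario()].
#' @return list with `tracts`, `covariates`, `pois`, `flows`, `outcomes`,
#'   `truth` (true index and planted coefficients).
#' @export
generate_study <- function(sc) {
  reg <- generate_region(sc)
  pois <- generate_pois(sc, reg$tracts, reg$covariates)
  cov <- derive_access_covariates(reg$tracts, reg$covariates, pois)
  fl <- generate_flows(sc, reg$tracts, cov, pois)
  outcomes <- generate_outcomes(sc, cov, fl$true_rfai)
  list(tracts = reg$tracts, covariates = cov,
       pois = pois[, c("poi_id", "lon", "lat", "naics_code", "employee_count")],
       flows = fl$flows, outcomes = outcomes,
       truth = list(seed = sc$seed, true_rfai = fl$true_rfai,
                    outcome_coefs = sc$outcome_coefs,
                    healthy_pref_coefs = as.list(sc$healthy_pref_coefs),
                    gravity_decay_miles = sc$gravity_decay_miles,
                    visits_per_capita = sc$visits_per_capita))
}

write_tracts_geojson <- function(tracts, path) {
  feat <- lapply(seq_len(length(tracts)), function(i) {
    rings <- lapply(tracts$geometry[[i]], function(r) {
      closed <- rbind(r, r[1, ])
      lapply(seq_len(nrow(closed)), function(k) c(closed[k, 1], closed[k, 2]))
    })
    list(type = "Feature",
         properties = list(tract_id = tracts$info$tract_id[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  gj <- list(type = "FeatureCollection", planar_miles = tracts$planar,
             features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic study bundle to disk
#'
#' Emits `tracts.geojson`, `pois.csv`, `flows.csv`, `covariates.csv`,
#' `outcomes.csv` and `truth.json` (planted parameters and true index) - a
#' complete, schema-valid input set for the pipeline.
#'
#' @param sc an [scenario()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the study list from [generate_study()].
#' @export
emit_study <- function(sc, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  study <- generate_study(sc)
  write_tracts_geojson(study$tracts, file.path(out_dir, "tracts.geojson"))
  wcsv <- function(df, name) {
    out <- df
    for (col in names(out)) {
      if (is.numeric(out[[col]]) && !all(out[[col]] == floor(out[[col]]), na.rm = TRUE))
        out[[col]] <- fmt_num(out[[col]], 8)
      else if (is.logical(out[[col]]))
        out[[col]] <- ifelse(is.na(out[[col]]), "", tolower(as.character(out[[col]])))
      else out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
    }
    utils::write.csv(out, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  wcsv(study$pois, "pois.csv")
  wcsv(study$flows, "flows.csv")
  wcsv(study$covariates, "covariates.csv")
  wcsv(study$outcomes, "outcomes.csv")
  jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(study)
}
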