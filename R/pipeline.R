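# Pipeline orchestration: simulate -> classify -> mobility -> index ->
# associate -> report. Stage outputs are plain files so each step is
# auditable and independently re-runnable.

#' Pipeline run configuration
#'
#' @param input_dir directory holding `tracts.geojson`, `pois.csv`,
#'   `flows.csv`, `covariates.csv`, `outcomes.csv` (e.g., from
#'   [emit_study()]).
#' @param out_dir output directory.
#' @param buffer_radius_miles boundary buffer for the location index and the
#'   half-mile visit share.
#' @param earth_radius_miles sphere radius for lon/lat distances.
#' @param seed seed recorded in the run metadata and used for any resampling
#'   estimator.
#' @param scheme_overrides optional classification override YAML path.
#' @param indices which indices to model against the disease outcomes.
#' @param use_predominant replace the minority-status theme with
#'   predominant-group indicators in adjusted models.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       buffer_radius_miles = 0.5,
                       earth_radius_miles = EARTH_RADIUS_MILES,
                       seed = 1L, scheme_overrides = NULL,
                       indices = c("rfai", "mrfei"),
                       use_predominant = FALSE) {
  stopifnot(buffer_radius_miles > 0, earth_radius_miles > 0)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 buffer_radius_miles = buffer_radius_miles,
                 earth_radius_miles = earth_radius_miles, seed = as.integer(seed),
                 scheme_overrides = scheme_overrides, indices = indices,
                 use_predominant = use_predominant), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reads a study bundle, classifies retailers under both schemes, computes
#' mobility summaries and the three indices, fits the index-disease
#' association battery (adjusted and unadjusted OLS per index x disease,
#' interquartile-scaled) plus the log-distance sociodemographic model, and
#' writes `mobility.csv`, `index.csv`, `models/*.json`, `effects.csv`, a run
#' log and a metadata sidecar carrying the config echo and hash.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the effects table and fitted models.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    fe_log(line)
  }
  hash <- config_hash(config)
  logit("foodenv pipeline, package version ",
        as.character(utils::packageVersion("foodenv")))
  logit("config hash ", hash, ", seed ", config$seed)

  inp <- function(f) file.path(config$input_dir, f)
  tracts <- stage("read", read_tracts(inp("tracts.geojson")))
  pois <- stage("read", read_table(inp("pois.csv"), "pois"))
  flows <- stage("read", read_table(inp("flows.csv"), "flows"))
  covariates <- stage("read", read_table(inp("covariates.csv"), "covariates"))
  outcomes <- stage("read", read_table(inp("outcomes.csv"), "outcomes"))
  logit("inputs: ", length(tracts), " tracts, ", nrow(pois), " POIs, ",
        nrow(flows), " flow rows")

  mobility <- stage("mobility",
                    summarize_mobility(tracts, flows, pois, covariates,
                                       buffer_radius = config$buffer_radius_miles,
                                       earth_radius = config$earth_radius_miles))
  write_mobility_table(mobility, file.path(out_dir, "mobility.csv"))
  logit("mobility: ", sum(mobility$total_visits > 0), " tracts with visits")

  indices <- stage("index",
                   compute_indices(flows, pois, tracts,
                                   buffer = config$buffer_radius_miles,
                                   overrides = config$scheme_overrides))
  write_index_table(indices, file.path(out_dir, "index.csv"), counts = TRUE)
  logit("index: rfai missing ", sum(is.na(indices$rfai)),
        ", mrfei missing ", sum(is.na(indices$mrfei)))

  analysis <- stage("associate",
                    prepare_model_data(covariates, outcomes, indices, mobility))
  # covariates that are constant in this study carry no information and would
  # make the design singular; drop them from adjusted models, with a log line
  drop_constant <- function(spec) {
    keep <- vapply(spec$covariates, function(cv) {
      v <- analysis[[cv]]
      length(unique(v[!is.na(v)])) > 1
    }, logical(1))
    if (any(!keep)) {
      logit("dropping constant covariate(s): ",
            paste(spec$covariates[!keep], collapse = ", "))
      spec$covariates <- spec$covariates[keep]
    }
    spec
  }
  models <- list()
  effects <- list()
  for (index in config$indices) {
    for (disease in CMD_DISEASES) {
      for (adjusted in c(TRUE, FALSE)) {
        id <- paste0(disease, "_", index, if (adjusted) "_adjusted" else "_unadjusted")
        spec <- drop_constant(
          build_cmd_model_spec(index, disease, unadjusted = !adjusted,
                               use_predominant = config$use_predominant))
        fit <- stage("associate", fit_linear_model(analysis, spec))
        models[[id]] <- fit
        effects[[id]] <- data.frame(
          model = id, index = index, disease = disease, adjusted = adjusted,
          n = fit$n_units,
          estimate = fit$coefficients$estimate[fit$coefficients$term == index],
          se = fit$coefficients$se[fit$coefficients$term == index],
          iqr = fit$scaled_effect$iqr,
          iqr_effect = fit$scaled_effect$estimate,
          iqr_ci_low = fit$scaled_effect$ci_low,
          iqr_ci_high = fit$scaled_effect$ci_high, stringsAsFactors = FALSE)
      }
    }
  }
  dist_fit <- stage("associate",
                    fit_linear_model(analysis,
                                     drop_constant(build_distance_model_spec("ols"))))
  models[["log_distance_ols"]] <- dist_fit
  logit("associate: ", length(models), " models fitted")

  for (id in names(models)) {
    m <- models[[id]]
    jsonlite::write_json(
      list(model = id, config_hash = hash, seed = config$seed,
           spec = unclass(m$spec), n_units = m$n_units, n_dropped = m$n_dropped,
           coefficients = m$coefficients, scaled_effect = m$scaled_effect,
           diagnostics = m$diagnostics[!vapply(m$diagnostics, is.data.frame,
                                               logical(1))]),
      file.path(out_dir, "models", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  eff <- do.call(rbind, effects)
  rownames(eff) <- NULL
  out <- eff
  for (col in c("estimate", "se", "iqr", "iqr_effect", "iqr_ci_low", "iqr_ci_high"))
    out[[col]] <- fmt_num(out[[col]], 8)
  utils::write.csv(out, file.path(out_dir, "effects.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                            n_tracts = length(tracts), n_pois = nrow(pois),
                            n_flow_rows = nrow(flows)),
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(effects = eff, models = models, mobility = mobility,
                 indices = indices, analysis = analysis))
}
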