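# Food environment indices on the 0-100 scale.
#
# RFAI (activity-based): 100 * healthy visits / (healthy + less-healthy
# visits) per home tract, from the origin-destination flow table.
# mRFEI (location-based): 100 * healthy retailers / qualified retailers,
# counting retailers inside the tract polygon or within a half mile of its
# boundary. Tracts with a zero denominator get a missing index rather than 0,
# since 0 is a meaningful "all less healthy" value.

#' Activity-based index (RFAI) per tract
#'
#' @param flows flow data.frame (`origin_tract_id`, `poi_id`, `year`,
#'   `visit_count`).
#' @param classes classification table from
#'   [classification_table()] with `scheme = "rfai_2017"`.
#' @param tracts a [tract_set()] (defines the tract universe), or a character
#'   vector of tract ids.
#' @param years optional year filter; default pools all years.
#' @return data.frame `tract_id`, `rfai`, `n_healthy_visits`,
#'   `n_less_healthy_visits`.
#' @export
compute_rfai <- function(flows, classes, tracts, years = NULL) {
  ids <- if (inherits(tracts, "tract_set")) tracts$info$tract_id else as.character(tracts)
  if (!is.null(years)) flows <- flows[flows$year %in% years, , drop = FALSE]
  cl <- classes$retailer_class[match(flows$poi_id, classes$poi_id)]
  if (anyNA(cl))
    stop("flow references unclassified poi_id: ",
         flows$poi_id[which(is.na(cl))[1]], call. = FALSE)
  org <- factor(flows$origin_tract_id, levels = ids)
  if (anyNA(org))
    stop("flow references unknown origin tract: ",
         flows$origin_tract_id[which(is.na(org))[1]], call. = FALSE)
  h <- vapply(split(flows$visit_count * (cl == "healthy"), org), sum, numeric(1))
  l <- vapply(split(flows$visit_count * (cl == "less_healthy"), org), sum, numeric(1))
  denom <- h + l
  rfai <- ifelse(denom > 0, 100 * h / denom, NA_real_)
  n_missing <- sum(denom == 0)
  if (n_missing > 0)
    fe_log("rfai: ", n_missing, " tract(s) with no qualified visits -> missing index")
  data.frame(tract_id = ids, rfai = as.numeric(rfai),
             n_healthy_visits = as.numeric(h), n_less_healthy_visits = as.numeric(l),
             stringsAsFactors = FALSE)
}

# Retailer counts in scope of each tract (inside polygon or within `buffer`
# miles of its boundary); a retailer may count toward several tracts.
retailers_in_scope <- function(pois, tracts, buffer = 0.5) {
  pts <- cbind(pois$lon, pois$lat)
  n <- length(tracts)
  out <- vector("list", n)
  # bounding-box prefilter with a generous margin
  margin <- if (tracts$planar) buffer * 1.01 else buffer / 50
  for (i in seq_len(n)) {
    rings <- tracts$geometry[[i]]
    bb <- do.call(rbind, rings)
    keep <- which(pts[, 1] >= min(bb[, 1]) - margin & pts[, 1] <= max(bb[, 1]) + margin &
                  pts[, 2] >= min(bb[, 2]) - margin & pts[, 2] <= max(bb[, 2]) + margin)
    if (length(keep) == 0) { out[[i]] <- integer(0); next }
    d <- distance_to_polygon(pts[keep, , drop = FALSE], rings,
                             c(tracts$info$centroid_x[i], tracts$info$centroid_y[i]),
                             planar = tracts$planar)
    out[[i]] <- keep[d <= buffer]
  }
  names(out) <- tracts$info$tract_id
  out
}

location_index <- function(pois, classes, tracts, buffer) {
  cl <- classes$retailer_class[match(pois$poi_id, classes$poi_id)]
  if (anyNA(cl)) stop("unclassified poi_id in POI table", call. = FALSE)
  scope <- retailers_in_scope(pois, tracts, buffer)
  h <- vapply(scope, function(ix) sum(cl[ix] == "healthy"), numeric(1))
  l <- vapply(scope, function(ix) sum(cl[ix] == "less_healthy"), numeric(1))
  denom <- h + l
  idx <- ifelse(denom > 0, 100 * h / denom, NA_real_)
  data.frame(tract_id = tracts$info$tract_id, index = as.numeric(idx),
             n_healthy_retailers = as.numeric(h),
             n_less_healthy_retailers = as.numeric(l), stringsAsFactors = FALSE)
}

#' Location-based index (mRFEI) per tract
#'
#' Counts qualified retailers located inside the tract polygon or within
#' `buffer` miles of its boundary, using the employee-size scheme.
#'
#' @param pois POI data.frame.
#' @param classes classification table with `scheme = "mrfei_2007"`.
#' @param tracts a [tract_set()].
#' @param buffer boundary buffer in miles (default 0.5).
#' @return data.frame `tract_id`, `mrfei`, `n_healthy_retailers`,
#'   `n_less_healthy_retailers`.
#' @export
compute_mrfei <- function(pois, classes, tracts, buffer = 0.5) {
  out <- location_index(pois, classes, tracts, buffer)
  names(out)[names(out) == "index"] <- "mrfei"
  n_missing <- sum(is.na(out$mrfei))
  if (n_missing > 0)
    fe_log("mrfei: ", n_missing, " tract(s) with no qualified retailers in scope")
  out
}

#' Alternative location index from the activity-based retailer set
#'
#' The location-index formula applied with the activity-based classification
#' (all supermarkets and grocery stores healthy, employee size ignored) - the
#' sensitivity variant comparing like retailer sets across index types.
#'
#' @inheritParams compute_mrfei
#' @param classes classification table with `scheme = "rfai_2017"`.
#' @return data.frame `tract_id`, `alt_location_index`.
#' @export
compute_alt_location_index <- function(pois, classes, tracts, buffer = 0.5) {
  out <- location_index(pois, classes, tracts, buffer)
  names(out)[names(out) == "index"] <- "alt_location_index"
  out[, c("tract_id", "alt_location_index")]
}

#' All per-tract index records
#'
#' Convenience wrapper joining [compute_rfai()], [compute_mrfei()] and
#' [compute_alt_location_index()] into one record per tract.
#'
#' @param flows flow table.
#' @param pois POI table.
#' @param tracts a [tract_set()].
#' @param buffer boundary buffer in miles.
#' @param overrides optional classification override (see
#'   [classification_table()]).
#' @return data.frame of index records keyed by `tract_id`.
#' @export
compute_indices <- function(flows, pois, tracts, buffer = 0.5, overrides = NULL) {
  cls_r <- classification_table(pois, "rfai_2017", overrides)
  cls_m <- classification_table(pois, "mrfei_2007", overrides)
  a <- compute_rfai(flows, cls_r, tracts)
  m <- compute_mrfei(pois, cls_m, tracts, buffer)
  alt <- compute_alt_location_index(pois, cls_r, tracts, buffer)
  out <- merge(merge(a, m, by = "tract_id", sort = FALSE), alt,
               by = "tract_id", sort = FALSE)
  out[match(tracts$info$tract_id, out$tract_id), , drop = FALSE]
}

#' Correlation between two indices with a 95% CI
#'
#' Pearson correlation over tracts where both indices are non-missing, with
#' the confidence interval from the Fisher z-transform.
#'
#' @param x,y numeric vectors (e.g., `rfai` and `mrfei` columns).
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
index_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3)
    stop("index_correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("correlation undefined: an index is constant over complete pairs",
         call. = FALSE)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
       n = sum(keep))
}
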