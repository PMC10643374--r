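# Per-tract mobility summaries from origin-destination visit flows:
# visit-weighted median travel distance (tract centroid to POI), shares of
# visits in the distance bands [0,1), [1,5), [5,10), [10,20), [20,Inf) miles,
# share of visits within a half-mile buffer of the home tract, and totals.

DISTANCE_BAND_BREAKS <- c(0, 1, 5, 10, 20, Inf)
DISTANCE_BAND_LABELS <- c("band_0_1", "band_1_5", "band_5_10", "band_10_20", "band_20_plus")

#' Lower weighted median
#'
#' Smallest value `v` such that the cumulative weight of observations `<= v`
#' reaches half the total weight. With unit weights this is the lower sample
#' median.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, at least one positive.
#' @return the weighted median value.
#' @export
weighted_median <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights))
    stop("values and weights lengths differ", call. = FALSE)
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0 || any(weights < 0) || sum(weights) <= 0)
    stop("weighted_median needs at least one positive weight", call. = FALSE)
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1]]
}

#' Visit-weighted distance-band shares
#'
#' Shares of visits falling in the half-open distance bands
#' `[0,1), [1,5), [5,10), [10,20), [20,Inf)` miles (lower-inclusive, so a
#' distance of exactly 1.0 belongs to the 1-5 band).
#'
#' @param distances per-flow distances in miles.
#' @param visit_counts per-flow visit counts (nonnegative).
#' @return named numeric vector of 5 shares summing to 1, or all-`NA` when
#'   there are no visits.
#' @export
distance_band_shares <- function(distances, visit_counts) {
  if (length(distances) != length(visit_counts))
    stop("distances and visit_counts lengths differ", call. = FALSE)
  total <- sum(visit_counts)
  if (is.na(total) || total <= 0)
    return(stats::setNames(rep(NA_real_, 5), DISTANCE_BAND_LABELS))
  band <- cut(distances, DISTANCE_BAND_BREAKS, right = FALSE,
              labels = DISTANCE_BAND_LABELS)
  s <- vapply(split(visit_counts, band), sum, numeric(1)) / total
  stats::setNames(as.numeric(s), DISTANCE_BAND_LABELS)
}

#' Share of a tract's visits within a buffer of its boundary
#'
#' Fraction of visits whose destination POI lies inside the tract polygon or
#' within `radius` miles of its boundary. For lon/lat data the tract and its
#' POIs are re-projected to a local azimuthal-equidistant frame first.
#'
#' @param tracts a [tract_set()].
#' @param tract_id single tract identifier.
#' @param flows flow data.frame for this origin tract.
#' @param pois POI data.frame (`poi_id`, `lon`, `lat`).
#' @param radius buffer radius in miles (default 0.5).
#' @return share in `[0,1]`, or `NA` when the tract has no visits.
#' @export
within_buffer_share <- function(tracts, tract_id, flows, pois, radius = 0.5) {
  fl <- flows[flows$origin_tract_id == tract_id, , drop = FALSE]
  if (sum(fl$visit_count) == 0) return(NA_real_)
  idx <- match(fl$poi_id, pois$poi_id)
  if (anyNA(idx))
    stop("flow references unknown poi_id: ", fl$poi_id[which(is.na(idx))[1]],
         call. = FALSE)
  gi <- match(tract_id, tracts$info$tract_id)
  if (is.na(gi)) stop("unknown tract_id: ", tract_id, call. = FALSE)
  pts <- cbind(pois$lon[idx], pois$lat[idx])
  d <- distance_to_polygon(pts, tracts$geometry[[gi]],
                           c(tracts$info$centroid_x[gi], tracts$info$centroid_y[gi]),
                           planar = tracts$planar)
  sum(fl$visit_count[d <= radius]) / sum(fl$visit_count)
}

#' Mobility summary for one tract
#'
#' @param tracts a [tract_set()].
#' @param tract_id tract to summarize.
#' @param flows full flow table.
#' @param pois POI table.
#' @param covariates optional covariate table (for `per_capita_visits`).
#' @param buffer_radius half-mile buffer radius in miles.
#' @param earth_radius sphere radius in miles for lon/lat distances.
#' @return one-row data.frame with `tract_id`, `total_visits`,
#'   `median_distance_miles`, the 5 band shares, `within_half_mile_share`,
#'   `per_capita_visits`.
#' @export
summarize_tract_mobility <- function(tracts, tract_id, flows, pois,
                                     covariates = NULL, buffer_radius = 0.5,
                                     earth_radius = EARTH_RADIUS_MILES) {
  summarize_mobility(tracts, flows, pois, covariates, buffer_radius,
                     earth_radius, subset_ids = tract_id)
}

#' Mobility summaries for all tracts
#'
#' Computes, per origin tract: total visits, the visit-weighted median
#' centroid-to-POI distance, the distance-band shares, the share of visits
#' within `buffer_radius` miles of the tract boundary, and per-capita visits
#' (total visits / population).
#'
#' @inheritParams summarize_tract_mobility
#' @param subset_ids optional subset of tract ids.
#' @return data.frame, one row per tract (tracts without flows get zero
#'   visits and missing distance statistics).
#' @export
summarize_mobility <- function(tracts, flows, pois, covariates = NULL,
                               buffer_radius = 0.5,
                               earth_radius = EARTH_RADIUS_MILES,
                               subset_ids = NULL) {
  ids <- if (is.null(subset_ids)) tracts$info$tract_id else as.character(subset_ids)
  pidx <- match(flows$poi_id, pois$poi_id)
  if (anyNA(pidx))
    stop("flow references unknown poi_id: ", flows$poi_id[which(is.na(pidx))[1]],
         call. = FALSE)
  tidx <- match(flows$origin_tract_id, tracts$info$tract_id)
  if (anyNA(tidx))
    stop("flow references unknown origin tract: ",
         flows$origin_tract_id[which(is.na(tidx))[1]], call. = FALSE)
  cent <- tract_centroids(tracts)
  dist_all <- geodesic_distance_miles(cent[tidx, , drop = FALSE],
                                      cbind(pois$lon[pidx], pois$lat[pidx]),
                                      planar = tracts$planar,
                                      earth_radius = earth_radius)
  by_origin <- split(seq_len(nrow(flows)),
                     factor(flows$origin_tract_id, levels = ids))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    sel <- by_origin[[k]]
    sel <- sel[flows$visit_count[sel] > 0]
    total <- sum(flows$visit_count[sel])
    if (total > 0) {
      d <- dist_all[sel]; w <- flows$visit_count[sel]
      med <- weighted_median(d, w)
      bands <- distance_band_shares(d, w)
      half <- within_buffer_share(tracts, id, flows[sel, , drop = FALSE], pois,
                                  radius = buffer_radius)
    } else {
      med <- NA_real_
      bands <- stats::setNames(rep(NA_real_, 5), DISTANCE_BAND_LABELS)
      half <- NA_real_
    }
    pcv <- NA_real_
    if (!is.null(covariates)) {
      pop <- covariates$population[match(id, covariates$tract_id)]
      if (!is.na(pop) && pop > 0) pcv <- total / pop
    }
    out[[k]] <- data.frame(tract_id = id, total_visits = total,
                           median_distance_miles = med, t(bands),
                           within_half_mile_share = half,
                           per_capita_visits = pcv, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate distance-band shares across tracts
#'
#' Two aggregations of tract-level mobility: `"tract_mean"` averages the
#' tract-level shares (each tract counts once; SDs describe between-tract
#' spread), `"pooled"` recomputes shares over all visits pooled.
#'
#' @param summaries output of [summarize_mobility()].
#' @param how `"tract_mean"` or `"pooled"`.
#' @return named list with `band_shares` (and `band_sd`, `within_half_mile`,
#'   `median_distance` for `"tract_mean"`).
#' @export
aggregate_band_shares <- function(summaries, how = c("tract_mean", "pooled")) {
  how <- match.arg(how)
  bs <- as.matrix(summaries[, DISTANCE_BAND_LABELS, drop = FALSE])
  if (how == "tract_mean") {
    keep <- stats::complete.cases(bs)
    list(band_shares = colMeans(bs[keep, , drop = FALSE]),
         band_sd = apply(bs[keep, , drop = FALSE], 2, stats::sd),
         within_half_mile = mean(summaries$within_half_mile_share, na.rm = TRUE),
         median_distance = stats::median(summaries$median_distance_miles, na.rm = TRUE))
  } else {
    w <- summaries$total_visits
    keep <- stats::complete.cases(bs) & w > 0
    list(band_shares = colSums(bs[keep, , drop = FALSE] * w[keep]) / sum(w[keep]))
  }
}
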