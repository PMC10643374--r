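# Tract container: polygons plus derived centroids and areas.

#' Build a tract set from polygons
#'
#' @param tract_id character vector of unique tract identifiers.
#' @param polygons list (one element per tract) of lists of ring matrices;
#'   a single ring matrix is also accepted.
#' @param planar `TRUE` when coordinates are planar miles, `FALSE` for WGS84
#'   lon/lat degrees.
#' @param on_invalid what to do with a self-intersecting ring: `"repair"`
#'   splits it at its crossing points into simple loops, `"reject"` raises an
#'   error. Either way the event is reported.
#' @return an object of class `tract_set`: a list with `info` (data.frame of
#'   `tract_id`, `centroid_x`, `centroid_y`, `area_sqmi`), `geometry` (named
#'   list of ring lists) and `planar`.
#' @export
tract_set <- function(tract_id, polygons, planar = FALSE,
                      on_invalid = c("repair", "reject")) {
  on_invalid <- match.arg(on_invalid)
  tract_id <- as.character(tract_id)
  if (anyDuplicated(tract_id))
    stop("duplicate tract_id: ", paste(unique(tract_id[duplicated(tract_id)]), collapse = ", "),
         call. = FALSE)
  if (length(tract_id) != length(polygons))
    stop("tract_id and polygons lengths differ", call. = FALSE)
  geometry <- vector("list", length(tract_id))
  n_repaired <- 0L
  for (i in seq_along(polygons)) {
    rings <- polygons[[i]]
    if (is.matrix(rings) || is.data.frame(rings)) rings <- list(rings)
    rings <- lapply(rings, ring_as_matrix)
    bad <- !vapply(rings, ring_is_simple, logical(1))
    if (any(bad)) {
      if (on_invalid == "reject")
        stop("self-intersecting ring in tract ", tract_id[i], call. = FALSE)
      rings <- do.call(c, lapply(rings, split_self_intersecting_ring))
      n_repaired <- n_repaired + 1L
    }
    geometry[[i]] <- rings
  }
  if (n_repaired > 0L)
    warning(n_repaired, " tract polygon(s) repaired (self-intersection split)",
            call. = FALSE)
  names(geometry) <- tract_id
  cent <- matrix(NA_real_, length(tract_id), 2)
  area <- numeric(length(tract_id))
  for (i in seq_along(geometry)) {
    rings <- geometry[[i]]
    if (planar) {
      cent[i, ] <- polygon_centroid(rings)
      area[i] <- polygon_area(rings)
    } else {
      # project about the ring-vertex mean, compute in miles, unproject centroid
      ref <- colMeans(do.call(rbind, rings))
      pr <- lapply(rings, function(r) {
        m <- aeqd_forward(r[, 1], r[, 2], ref[1], ref[2]); colnames(m) <- NULL; m
      })
      c_loc <- polygon_centroid(pr)
      area[i] <- polygon_area(pr)
      cent[i, ] <- aeqd_inverse(c_loc[1], c_loc[2], ref[1], ref[2])[1, ]
    }
  }
  structure(list(
    info = data.frame(tract_id = tract_id, centroid_x = cent[, 1],
                      centroid_y = cent[, 2], area_sqmi = area,
                      stringsAsFactors = FALSE),
    geometry = geometry,
    planar = isTRUE(planar)
  ), class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat("tract_set:", nrow(x$info), "tracts,",
      if (x$planar) "planar-mile" else "WGS84 lon/lat", "coordinates\n")
  cat("total area:", format(sum(x$info$area_sqmi), digits = 6), "sq mi\n")
  invisible(x)
}

#' @export
length.tract_set <- function(x) nrow(x$info)

tract_centroids <- function(tracts) {
  m <- as.matrix(tracts$info[, c("centroid_x", "centroid_y")])
  rownames(m) <- tracts$info$tract_id
  m
}
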