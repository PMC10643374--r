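# Readers and writers for the pipeline's file formats: GeoJSON / shapefile
# tract polygons, and CSV tables for POIs, visit flows, tract covariates,
# health outcomes and index records.
#
# Missing values in CSVs are empty cells only; literal "NA"/"NaN" strings are
# rejected so schemas stay unambiguous.

fe_log <- function(...) message("[foodenv] ", ...)

#' Read tract polygons
#'
#' Reads census-tract polygons from GeoJSON (RFC 7946) or an ESRI shapefile.
#' Every feature must carry a `tract_id` property (attribute field for
#' shapefiles). A GeoJSON top-level member `"planar_miles": true` marks
#' synthetic planar data whose coordinates are miles rather than lon/lat
#' degrees; shapefiles are always taken as lon/lat.
#'
#' @param path file path (`.geojson`/`.json` or `.shp`).
#' @param format `"geojson"` or `"shapefile"`; inferred from the extension
#'   when omitted.
#' @param on_invalid passed to [tract_set()]: `"repair"` or `"reject"`
#'   self-intersecting rings.
#' @return a [tract_set()].
#' @export
read_tracts <- function(path, format = c("auto", "geojson", "shapefile"),
                        on_invalid = "repair") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "shp") "shapefile" else "geojson"
  }
  if (format == "geojson") read_tracts_geojson(path, on_invalid)
  else read_tracts_shapefile(path, on_invalid)
}

read_tracts_geojson <- function(path, on_invalid) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("GeoJSON parse failure in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  planar <- isTRUE(gj$planar_miles)
  feats <- gj$features
  ids <- character(length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties$tract_id
    if (is.null(id) || !nzchar(as.character(id)))
      stop("feature ", i, " lacks a tract_id property", call. = FALSE)
    ids[i] <- as.character(id)
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("feature ", ids[i], ": geometry must be Polygon or MultiPolygon",
           call. = FALSE)
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(v) c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    rings <- if (g$type == "Polygon") lapply(g$coordinates, ring_mat)
             else do.call(c, lapply(g$coordinates, function(p) lapply(p, ring_mat)))
    polys[[i]] <- rings
  }
  tract_set(ids, polys, planar = planar, on_invalid = on_invalid)
}

# Minimal ESRI shapefile reader (shape type 5, Polygon). Geometry comes from
# the .shp; tract_id comes from a "tract_id" field in the sibling .dbf
# (read with foreign::read.dbf). Sufficient for tract polygons; no other
# shape types are supported.
read_tracts_shapefile <- function(path, on_invalid) {
  dbf_path <- sub("\\.shp$", ".dbf", path, ignore.case = TRUE)
  if (!file.exists(dbf_path)) stop("missing .dbf beside ", path, call. = FALSE)
  attrs <- foreign::read.dbf(dbf_path, as.is = TRUE)
  idcol <- grep("^tract_id$", names(attrs), ignore.case = TRUE, value = TRUE)
  if (length(idcol) != 1L) stop("shapefile .dbf lacks a tract_id field", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  code <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(code, 9994L)) stop("not a shapefile: ", path, call. = FALSE)
  seek(con, 24)
  file_len_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  seek(con, 100)
  polys <- list()
  while (seek(con, where = NA) < 2 * file_len_words) {
    readBin(con, "integer", 1, size = 4, endian = "big")  # record number
    readBin(con, "integer", 1, size = 4, endian = "big")  # content length
    shp_type <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (shp_type == 0) { polys[[length(polys) + 1L]] <- NULL; next }
    if (shp_type != 5)
      stop("unsupported shape type ", shp_type, " in record ", length(polys) + 1L,
           call. = FALSE)
    readBin(con, "double", 4, endian = "little")          # bounding box
    n_parts <- readBin(con, "integer", 1, size = 4, endian = "little")
    n_points <- readBin(con, "integer", 1, size = 4, endian = "little")
    parts <- readBin(con, "integer", n_parts, size = 4, endian = "little")
    xy <- matrix(readBin(con, "double", 2 * n_points, endian = "little"),
                 ncol = 2, byrow = TRUE)
    starts <- parts + 1L
    ends <- c(parts[-1], n_points)
    rings <- Map(function(s, e) xy[s:e, , drop = FALSE], starts, ends)
    # put the largest ring first (outer); remaining rings resolve by even-odd
    if (length(rings) > 1L) {
      a <- vapply(rings, function(r) abs(signed_ring_area(ring_as_matrix(r))), numeric(1))
      rings <- rings[order(-a)]
    }
    polys[[length(polys) + 1L]] <- rings
  }
  if (length(polys) != nrow(attrs))
    stop("shapefile record count (", length(polys), ") does not match .dbf rows (",
         nrow(attrs), ")", call. = FALSE)
  tract_set(as.character(attrs[[idcol]]), polys, planar = FALSE,
            on_invalid = on_invalid)
}

table_schemas <- list(
  pois = list(
    cols = c("poi_id", "lon", "lat", "naics_code", "employee_count"),
    numeric = c("lon", "lat", "employee_count")
  ),
  flows = list(
    cols = c("origin_tract_id", "poi_id", "year", "visit_count"),
    numeric = c("year", "visit_count")
  ),
  covariates = list(
    cols = c("tract_id", "svi_theme1", "svi_theme2", "svi_theme3", "svi_theme4",
             "food_desert", "urban", "population", "pop_density",
             "share_nh_white", "share_nh_black", "share_hispanic",
             "pct_female", "pct_minority", "pct_low_income", "pct_less_than_hs",
             "pct_under5_over64", "median_family_income", "n_food_retailers"),
    numeric = c("svi_theme1", "svi_theme2", "svi_theme3", "svi_theme4",
                "population", "pop_density", "share_nh_white", "share_nh_black",
                "share_hispanic", "pct_female", "pct_minority", "pct_low_income",
                "pct_less_than_hs", "pct_under5_over64", "median_family_income",
                "n_food_retailers")
  ),
  outcomes = list(
    cols = c("tract_id", "obesity", "high_blood_pressure", "high_cholesterol",
             "diagnosed_diabetes", "coronary_heart_disease"),
    numeric = c("obesity", "high_blood_pressure", "high_cholesterol",
                "diagnosed_diabetes", "coronary_heart_disease")
  )
)

unit_interval_cols <- c("svi_theme1", "svi_theme2", "svi_theme3", "svi_theme4",
                        "share_nh_white", "share_nh_black", "share_hispanic",
                        "pct_female", "pct_minority", "pct_low_income",
                        "pct_less_than_hs", "pct_under5_over64")

coerce_numeric <- function(x, col) {
  x <- trimws(x)
  if (any(x %in% c("NA", "NaN"), na.rm = TRUE))
    stop("column ", col, ": literal NA/NaN strings are not allowed; use empty cells",
         call. = FALSE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad))
    stop("column ", col, ": non-numeric value '", x[bad[1]], "' at data row ", bad[1],
         call. = FALSE)
  out
}

coerce_logical <- function(x, col) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad))
    stop("column ", col, ": non-boolean value '", x[bad[1]], "' at data row ", bad[1],
         call. = FALSE)
  out
}

#' Read a typed CSV table
#'
#' Reads one of the pipeline's CSV schemas with validation. Duplicate
#' `(origin_tract_id, poi_id, year)` flow rows are summed (the merge count is
#' reported), negative visit counts and out-of-range percentile ranks or
#' shares are rejected with the offending row number.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema one of `"pois"`, `"flows"`, `"covariates"`, `"outcomes"`.
#' @return a data.frame in the schema's column order.
#' @export
read_table <- function(path, schema = c("pois", "flows", "covariates", "outcomes")) {
  schema <- match.arg(schema)
  sc <- table_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         check.names = FALSE)
  missing_cols <- setdiff(sc$cols, names(raw))
  # employee_count is optional in pois files
  if (schema == "pois") missing_cols <- setdiff(missing_cols, "employee_count")
  if (length(missing_cols))
    stop(schema, " file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (schema == "pois" && !"employee_count" %in% names(raw))
    raw$employee_count <- ""
  df <- raw[, sc$cols, drop = FALSE]
  for (col in sc$numeric) df[[col]] <- coerce_numeric(df[[col]], col)
  for (col in intersect(c("food_desert", "urban"), names(df)))
    df[[col]] <- coerce_logical(df[[col]], col)
  validate_table(df, schema)
}

validate_table <- function(df, schema) {
  row_err <- function(col, idx, what)
    stop("column ", col, " row ", idx[1], ": ", what, call. = FALSE)
  if (schema == "pois") {
    df$poi_id <- as.character(df$poi_id)
    if (anyDuplicated(df$poi_id)) stop("duplicate poi_id", call. = FALSE)
    bad <- which(!grepl("^[0-9]{6}$", df$naics_code))
    if (length(bad)) row_err("naics_code", bad, "not a 6-digit NAICS code")
    bad <- which(!is.na(df$employee_count) &
                   (df$employee_count < 0 | df$employee_count != floor(df$employee_count)))
    if (length(bad)) row_err("employee_count", bad, "must be a nonnegative integer")
  } else if (schema == "flows") {
    bad <- which(is.na(df$visit_count) | df$visit_count < 0)
    if (length(bad)) row_err("visit_count", bad, "negative or missing visit count")
    bad <- which(is.na(df$year))
    if (length(bad)) row_err("year", bad, "missing year")
    key <- paste(df$origin_tract_id, df$poi_id, df$year, sep = "\r")
    if (anyDuplicated(key)) {
      n_dup <- sum(duplicated(key))
      agg <- stats::aggregate(df["visit_count"],
                              by = df[c("origin_tract_id", "poi_id", "year")], FUN = sum)
      fe_log("flows: summed ", n_dup, " duplicate (origin, poi, year) row(s)")
      df <- agg[, c("origin_tract_id", "poi_id", "year", "visit_count")]
    }
    df <- df[order(df$origin_tract_id, df$poi_id, df$year), , drop = FALSE]
    rownames(df) <- NULL
  } else if (schema == "covariates") {
    if (anyDuplicated(df$tract_id)) stop("duplicate tract_id in covariates", call. = FALSE)
    for (col in unit_interval_cols) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
      if (length(bad)) row_err(col, bad, "outside [0,1]")
    }
    bad <- which(!is.na(df$population) & df$population < 0)
    if (length(bad)) row_err("population", bad, "negative population")
  } else if (schema == "outcomes") {
    if (anyDuplicated(df$tract_id)) stop("duplicate tract_id in outcomes", call. = FALSE)
    for (col in table_schemas$outcomes$numeric) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
      if (length(bad)) row_err(col, bad, "prevalence outside [0,100]")
    }
  }
  df
}

fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  out
}

#' Write a per-tract index table
#'
#' Writes `tract_id, rfai, mrfei` (plus the alternative location index and
#' the component counts when `counts = TRUE`) as CSV. Values are fixed at six
#' decimals and missing values are empty cells, so a write-then-read
#' round-trip reproduces the table to 1e-6.
#'
#' @param records data.frame of index records (see [compute_indices()]).
#' @param path output CSV path.
#' @param counts include audit columns (visit/retailer counts, alt index)?
#' @return invisibly, `path`.
#' @export
write_index_table <- function(records, path, counts = FALSE) {
  cols <- c("tract_id", "rfai", "mrfei")
  if (counts) cols <- c(cols, intersect(
    c("alt_location_index", "n_healthy_visits", "n_less_healthy_visits",
      "n_healthy_retailers", "n_less_healthy_retailers"), names(records)))
  out <- records[, cols, drop = FALSE]
  lines <- paste(cols, collapse = ",")
  if (nrow(out)) {
    body <- out$tract_id
    for (col in cols[-1]) {
      digits <- if (grepl("^n_", col)) 0 else 6
      body <- paste(body, fmt_num(out[[col]], digits), sep = ",")
    }
    lines <- c(lines, body)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an index table written by [write_index_table()]
#' @param path CSV path.
#' @return data.frame with numeric columns, empty cells as `NA`.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  for (col in setdiff(names(df), "tract_id")) df[[col]] <- coerce_numeric(df[[col]], col)
  df
}

#' Write per-tract mobility summaries as CSV
#' @param summaries data.frame from [summarize_mobility()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_mobility_table <- function(summaries, path) {
  out <- summaries
  for (col in setdiff(names(out), c("tract_id", "total_visits")))
    out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
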