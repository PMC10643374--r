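# Shared fixtures, built in code at test time.

# Grid of unit-square tracts in planar-mile coordinates.
make_grid_tracts <- function(nrow = 1, ncol = 1, side = 1, ids = NULL) {
  n <- nrow * ncol
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(n))
  polys <- vector("list", n)
  k <- 0L
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    k <- k + 1L
    x0 <- (c - 1) * side; y0 <- (r - 1) * side
    polys[[k]] <- rbind(c(x0, y0), c(x0 + side, y0),
                        c(x0 + side, y0 + side), c(x0, y0 + side))
  }
  tract_set(ids, polys, planar = TRUE)
}

make_pois <- function(ids, x, y, naics, emp = NA_real_) {
  data.frame(poi_id = ids, lon = x, lat = y, naics_code = naics,
             employee_count = rep_len(emp, length(ids)), stringsAsFactors = FALSE)
}

make_flows <- function(origin, poi, count, year = 2018L) {
  data.frame(origin_tract_id = origin, poi_id = poi, year = year,
             visit_count = count, stringsAsFactors = FALSE)
}

# Ten-tract enumerated fixture (2 x 5 grid of unit squares) with POIs placed
# so every buffer-inclusion case is decidable by hand, including retailers
# 0.49 and 0.51 miles outside a tract boundary. Expected index values below
# are hand arithmetic on the class definitions and the 0.5-mile scope rule.
enumerated_fixture <- function() {
  tracts <- make_grid_tracts(2, 5)  # T01..T05 bottom row, T06..T10 top row
  pois <- make_pois(
    sprintf("P%02d", 1:11),
    x = c(0.2, 0.8, 1.3, 2.2, 3.8, 4.8, 4.2, 0.2, 1.8, 3.49, 3.51),
    y = c(0.2, 0.2, 0.7, 0.2, 0.2, 0.2, 0.2, 1.8, 1.8, 1.52, 1.52),
    naics = c("445110", "445120", "722513", "445110", "445110", "452311",
              "452910", "445230", "541110", "445120", "445110"),
    emp = c(60, NA, NA, 3, 7, NA, NA, NA, NA, NA, 60)
  )
  flows <- make_flows(
    origin = c("T01", "T01", "T02", "T03", "T03", "T04", "T05", "T05",
               "T06", "T06", "T08", "T09", "T09", "T10"),
    poi = c("P01", "P02", "P03", "P04", "P09", "P07", "P06", "P02",
            "P08", "P03", "P10", "P05", "P10", "P01"),
    count = c(3, 1, 5, 2, 10, 4, 1, 1, 2, 2, 7, 1, 3, 1)
  )
  expected <- data.frame(
    tract_id = sprintf("T%02d", 1:10),
    rfai = c(75, 0, 100, NA, 50, 50, NA, 0, 25, 100),
    mrfei = c(50, 0, 0, 100, 100, 100, NA, 0, 50, 100),
    alt = c(100 / 3, 100 / 3, 100, 100, 100, 50, 0, 0, 50, 100),
    stringsAsFactors = FALSE
  )
  list(tracts = tracts, pois = pois, flows = flows, expected = expected)
}

# Minimal writer for an ESRI shapefile (type 5) plus its .dbf, used only to
# exercise the shapefile reader; rings are closed automatically.
write_test_shapefile <- function(base_path, ids, polys) {
  shp <- paste0(base_path, ".shp")
  dbf <- paste0(base_path, ".dbf")
  recs <- lapply(polys, function(rings) {
    if (is.matrix(rings)) rings <- list(rings)
    lapply(rings, function(r) rbind(r, r[1, ]))
  })
  contents <- lapply(recs, function(rings) {
    pts <- do.call(rbind, rings)
    nparts <- length(rings)
    npts <- nrow(pts)
    # content length in 16-bit words: type(2) + box(16) + counts(4) +
    # parts(2*nparts) + points(8*npts)
    len <- 2 + 16 + 4 + 2 * nparts + 8 * npts
    starts <- cumsum(c(0, vapply(rings, nrow, numeric(1))))[seq_len(nparts)]
    list(len = len, box = c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2])),
         nparts = nparts, npts = npts, starts = starts, pts = pts)
  })
  total_words <- 50 + sum(vapply(contents, function(ct) 4 + ct$len, numeric(1)))
  all_pts <- do.call(rbind, lapply(contents, `[[`, "pts"))
  con <- file(shp, "wb")
  writeBin(as.integer(c(9994, 0, 0, 0, 0, 0)), con, size = 4, endian = "big")
  writeBin(as.integer(total_words), con, size = 4, endian = "big")
  writeBin(c(1000L, 5L), con, size = 4, endian = "little")
  writeBin(c(min(all_pts[, 1]), min(all_pts[, 2]), max(all_pts[, 1]),
             max(all_pts[, 2]), 0, 0, 0, 0), con, size = 8, endian = "little")
  for (i in seq_along(contents)) {
    ct <- contents[[i]]
    writeBin(as.integer(c(i, ct$len)), con, size = 4, endian = "big")
    writeBin(5L, con, size = 4, endian = "little")
    writeBin(ct$box, con, size = 8, endian = "little")
    writeBin(as.integer(c(ct$nparts, ct$npts, ct$starts)), con, size = 4,
             endian = "little")
    writeBin(as.numeric(t(ct$pts)), con, size = 8, endian = "little")
  }
  close(con)
  foreign::write.dbf(data.frame(tract_id = as.character(ids),
                                stringsAsFactors = FALSE), dbf)
  shp
}

# Small scenario for fast end-to-end tests.
small_scenario <- function(seed = 7L, grid = 6L, ...) {
  scenario(seed = seed, grid_dims = c(grid, grid),
           pop_lognormal_params = c(meanlog = 7, sdlog = 0.5), ...)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
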