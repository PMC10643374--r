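# Planar and spherical geometry primitives for tract polygons and POI points.
#
# Polygons are lists of rings; a ring is an n x 2 numeric matrix of vertices
# without a repeated closing vertex (rings are treated as cyclic). The first
# ring is the outer boundary; subsequent rings may be holes or, after repair
# of a self-intersecting ring, additional outer pieces. Point-in-polygon uses
# the even-odd rule throughout, which handles both cases uniformly.

#' Mean Earth radius used throughout, in miles
#' @export
EARTH_RADIUS_MILES <- 3958.8

ring_as_matrix <- function(ring) {
  m <- as.matrix(ring)
  storage.mode(m) <- "double"
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) stop("polygon ring needs at least 3 distinct vertices", call. = FALSE)
  m
}

signed_ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(ring))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

point_in_ring <- function(px, py, ring) {
  # even-odd ray crossing, vectorized over points
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- xor(inside, point_in_ring(px, py, r))
  inside
}

dist_point_segments <- function(px, py, x1, y1, x2, y2) {
  # min over segments, vectorized over points (outer over segments)
  res <- rep(Inf, length(px))
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1[k]) * dx + (py - y1[k]) * dy) / l2))
    d <- sqrt((px - (x1[k] + t * dx))^2 + (py - (y1[k] + t * dy))^2)
    res <- pmin(res, d)
  }
  res
}

dist_to_boundary <- function(px, py, rings) {
  res <- rep(Inf, length(px))
  for (r in rings) {
    n <- nrow(r)
    nxt <- c(seq_len(n)[-1], 1L)
    res <- pmin(res, dist_point_segments(px, py, r[, 1], r[, 2], r[nxt, 1], r[nxt, 2]))
  }
  res
}

polygon_signs <- function(rings) {
  # +1 for outer pieces, -1 for rings lying inside the first ring (holes)
  if (length(rings) == 1L) return(1)
  s <- c(1, vapply(rings[-1], function(r) {
    v <- colMeans(r[1:2, , drop = FALSE])
    if (point_in_ring(v[1], v[2], rings[[1]])) -1 else 1
  }, numeric(1)))
  s
}

polygon_area <- function(rings) {
  s <- polygon_signs(rings)
  sum(s * vapply(rings, function(r) abs(signed_ring_area(r)), numeric(1)))
}

polygon_centroid <- function(rings) {
  s <- polygon_signs(rings)
  w <- s * vapply(rings, function(r) abs(signed_ring_area(r)), numeric(1))
  cs <- t(vapply(rings, ring_centroid, numeric(2)))
  if (sum(w) <= 0) return(colMeans(cs))
  colSums(cs * w) / sum(w)
}

seg_proper_intersection <- function(p1, p2, p3, p4) {
  # returns c(t, u, x, y) for a proper crossing of open segments, else NULL
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  c(t, u, p1[1] + t * d1[1], p1[2] + t * d1[2])
}

ring_self_intersections <- function(ring) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent segments share a vertex
      hit <- seg_proper_intersection(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ])
      if (!is.null(hit)) out[[length(out) + 1L]] <- c(i = i, j = j, hit)
    }
  }
  out
}

ring_is_simple <- function(ring) length(ring_self_intersections(ring)) == 0L

split_self_intersecting_ring <- function(ring) {
  # Node-insertion repair: add every proper self-intersection point as a
  # vertex, then peel off simple loops each time a node is revisited.
  hits <- ring_self_intersections(ring)
  if (length(hits) == 0L) return(list(ring))
  n <- nrow(ring)
  ins <- vector("list", n)  # per-segment list of (t, x, y)
  for (h in hits) {
    i <- h[[1]]; j <- h[[2]]; t <- h[[3]]; u <- h[[4]]; x <- h[[5]]; y <- h[[6]]
    ins[[i]] <- rbind(ins[[i]], c(t, x, y))
    ins[[j]] <- rbind(ins[[j]], c(u, x, y))
  }
  verts <- NULL
  for (i in seq_len(n)) {
    verts <- rbind(verts, ring[i, ])
    if (!is.null(ins[[i]])) {
      ord <- order(ins[[i]][, 1])
      verts <- rbind(verts, ins[[i]][ord, 2:3, drop = FALSE])
    }
  }
  key <- function(v) paste(signif(v[1], 12), signif(v[2], 12))
  loops <- list()
  path <- matrix(numeric(0), ncol = 2)
  keys <- character(0)
  for (i in seq_len(nrow(verts))) {
    k <- key(verts[i, ])
    pos <- match(k, keys)
    if (!is.na(pos)) {
      loop <- path[seq(pos, nrow(path)), , drop = FALSE]
      if (nrow(loop) >= 3) loops[[length(loops) + 1L]] <- loop
      keep <- seq_len(pos - 1L)
      path <- path[keep, , drop = FALSE]
      keys <- keys[keep]
    }
    path <- rbind(path, verts[i, ])
    keys <- c(keys, k)
  }
  if (nrow(path) >= 3) loops[[length(loops) + 1L]] <- path
  loops <- Filter(function(l) abs(signed_ring_area(l)) > 1e-12, loops)
  if (length(loops) == 0L) stop("ring repair produced no valid loops", call. = FALSE)
  loops
}

#' Great-circle (haversine) or planar distance in miles
#'
#' In lon/lat mode, computes the haversine great-circle distance on a sphere
#' of radius `earth_radius` miles. In planar mode, coordinates are assumed to
#' be in miles already and the Euclidean distance is returned. Vectorized over
#' point pairs.
#'
#' @param p,q two-column matrices (or length-2 vectors) of coordinates;
#'   columns are lon, lat in degrees (lon/lat mode) or x, y in miles (planar).
#' @param planar logical; `TRUE` for planar-mile coordinates.
#' @param earth_radius sphere radius in miles.
#' @return numeric vector of distances in miles.
#' @examples
#' geodesic_distance_miles(c(0, 0), c(0, 1))  # about 69.1 miles
#' @export
geodesic_distance_miles <- function(p, q, planar = FALSE,
                                    earth_radius = EARTH_RADIUS_MILES) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  if (planar) return(sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2))
  if (any(abs(p[, 1]) > 180 | abs(q[, 1]) > 180 | abs(p[, 2]) > 90 | abs(q[, 2]) > 90))
    stop("lon/lat coordinates out of range: lon in [-180,180], lat in [-90,90]",
         call. = FALSE)
  to_rad <- pi / 180
  lam1 <- p[, 1] * to_rad; phi1 <- p[, 2] * to_rad
  lam2 <- q[, 1] * to_rad; phi2 <- q[, 2] * to_rad
  a <- sin((phi2 - phi1) / 2)^2 + cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2
  2 * earth_radius * asin(pmin(1, sqrt(a)))
}

# Azimuthal-equidistant projection about (lon0, lat0); x, y in miles.
aeqd_forward <- function(lon, lat, lon0, lat0, earth_radius = EARTH_RADIUS_MILES) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  dlam <- lam - lam0
  cos_c <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cos_c <- pmin(1, pmax(-1, cos_c))
  c_ang <- acos(cos_c)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  cbind(x = earth_radius * k * cos(phi) * sin(dlam),
        y = earth_radius * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam)))
}

aeqd_inverse <- function(x, y, lon0, lat0, earth_radius = EARTH_RADIUS_MILES) {
  to_rad <- pi / 180
  phi0 <- lat0 * to_rad
  r <- sqrt(x^2 + y^2)
  c_ang <- r / earth_radius
  phi <- ifelse(r < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + (y / pmax(r, 1e-300)) * sin(c_ang) * cos(phi0)))
  lam <- ifelse(r < 1e-12, 0,
                atan2(x * sin(c_ang),
                      r * cos(c_ang) * cos(phi0) - y * sin(c_ang) * sin(phi0)))
  cbind(lon = lon0 + lam / to_rad, lat = phi / to_rad)
}

# Project a tract's rings and a set of points into a local planar frame
# (identity for planar data, azimuthal-equidistant about the tract centroid
# for lon/lat data). Returns list(rings=, pts=) in miles.
local_frame <- function(rings, centroid, pts, planar) {
  if (planar) return(list(rings = rings, pts = pts))
  pr <- lapply(rings, function(r) {
    m <- aeqd_forward(r[, 1], r[, 2], centroid[1], centroid[2])
    colnames(m) <- NULL
    m
  })
  pp <- aeqd_forward(pts[, 1], pts[, 2], centroid[1], centroid[2])
  colnames(pp) <- NULL
  list(rings = pr, pts = pp)
}

#' Distance from points to a polygon, zero inside
#'
#' Distance in miles from each point to the polygon: 0 for points inside
#' (even-odd rule), otherwise the distance to the nearest boundary segment.
#' For lon/lat data both polygon and points are first re-projected to a local
#' azimuthal-equidistant frame centered on `centroid`.
#'
#' @param pts two-column matrix of point coordinates.
#' @param rings list of ring matrices.
#' @param centroid polygon centroid (projection center in lon/lat mode).
#' @param planar logical flag for planar-mile coordinates.
#' @return numeric vector of distances (miles).
#' @export
distance_to_polygon <- function(pts, rings, centroid, planar = TRUE) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  lf <- local_frame(rings, centroid, pts, planar)
  d <- dist_to_boundary(lf$pts[, 1], lf$pts[, 2], lf$rings)
  d[point_in_rings(lf$pts[, 1], lf$pts[, 2], lf$rings)] <- 0
  d
}
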