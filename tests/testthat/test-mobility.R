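test_that("weighted median follows the lower-median convention", {
  expect_equal(weighted_median(c(1, 3, 10), c(1, 1, 1)), 3)
  # expansion to unit weights: (1,1,1,1,1,10) -> lower median 1
  expect_equal(weighted_median(c(1, 10), c(5, 1)), 1)
  expect_equal(weighted_median(c(2, 4), c(1, 1)), 2)
  expect_error(weighted_median(c(1, 2), c(0, 0)), "positive weight")
})

test_that("weighted median equals the unit-weight expansion on random cases", {
  set.seed(301)
  for (case in 1:200) {
    n <- sample(1:8, 1)
    v <- round(runif(n, 0, 50), 2)
    w <- sample(0:6, n, replace = TRUE)
    if (sum(w) == 0) w[1] <- 1
    expanded <- rep(v, w)
    oracle <- sort(expanded)[ceiling(length(expanded) / 2)]
    expect_equal(weighted_median(v, w), oracle, label = paste("case", case))
  }
})

test_that("distance-band shares use half-open lower-inclusive bands", {
  s <- distance_band_shares(c(0.5, 3, 30), c(10, 10, 10))
  expect_equal(unname(s), c(1, 1, 0, 0, 1) / 3)
  # exactly 1.0 mile belongs to the 1-5 band
  s <- distance_band_shares(1.0, 5)
  expect_equal(unname(s), c(0, 1, 0, 0, 0))
  expect_true(all(is.na(distance_band_shares(numeric(0), numeric(0)))))
})

test_that("band shares match a per-visit expansion on random instances", {
  set.seed(302)
  for (case in 1:50) {
    n <- 1000
    d <- rexp(n, 1 / 8)
    w <- sample(0:20, n, replace = TRUE)
    if (sum(w) == 0) w[1] <- 1
    s <- distance_band_shares(d, w)
    per_visit <- rep(d, w)
    breaks <- c(0, 1, 5, 10, 20, Inf)
    oracle <- as.numeric(table(cut(per_visit, breaks, right = FALSE))) / length(per_visit)
    expect_equal(unname(s), oracle, tolerance = 1e-12)
    expect_equal(sum(s), 1, tolerance = 1e-9)
  }
})

test_that("buffer share counts interior and near-boundary POIs correctly", {
  tracts <- make_grid_tracts(1, 1)  # unit square [0,1]^2
  pois <- make_pois(c("PC", "PNEAR", "PFAR"),
                    x = c(0.5, 1.49, 1.51), y = c(0.5, 0.5, 0.5), naics = "445110")
  fl <- make_flows(rep("T01", 3), c("PC", "PNEAR", "PFAR"), c(2, 1, 1))
  expect_equal(within_buffer_share(tracts, "T01", fl[1, ], pois), 1.0)
  expect_equal(within_buffer_share(tracts, "T01", fl, pois), 0.75)  # PFAR out
  # zero visits -> missing; unknown POI -> referential error
  fl0 <- make_flows("T01", "PC", 0)
  expect_true(is.na(within_buffer_share(tracts, "T01", fl0, pois)))
  expect_error(within_buffer_share(tracts, "T01", make_flows("T01", "PX", 1), pois),
               "unknown poi_id")
})

test_that("buffer share is monotone in the radius", {
  tracts <- make_grid_tracts(1, 1)
  set.seed(303)
  pois <- make_pois(sprintf("P%d", 1:30), runif(30, -2, 3), runif(30, -2, 3),
                    "445120")
  fl <- make_flows("T01", pois$poi_id, sample(1:9, 30, replace = TRUE))
  radii <- c(0, 0.5, 1, 5)
  shares <- vapply(radii, function(r)
    within_buffer_share(tracts, "T01", fl, pois, radius = r), numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
  expect_equal(shares[4], 1)
})

test_that("tract mobility summary composes its parts", {
  tracts <- make_grid_tracts(1, 2)  # T01 [0,1], T02 [1,2]
  pois <- make_pois(c("PA", "PB"), x = c(3.5, 0.7), y = c(0.5, 0.5),
                    naics = "445110")
  # single flow: 7 visits to a POI 3 miles from T01's centroid (0.5, 0.5)
  fl <- make_flows("T01", "PA", 7)
  s <- summarize_tract_mobility(tracts, "T01", fl, pois)
  expect_equal(s$total_visits, 7)
  expect_equal(s$median_distance_miles, 3)
  expect_equal(as.numeric(s[, foodenv:::DISTANCE_BAND_LABELS]), c(0, 1, 0, 0, 0))
  # equal visits inside (0.2 mi) and far away -> half-mile share 0.5
  fl2 <- make_flows(c("T01", "T01"), c("PB", "PA"), c(5, 5))
  s2 <- summarize_tract_mobility(tracts, "T01", fl2, pois)
  expect_equal(s2$within_half_mile_share, 0.5)
  # per-capita visits uses the covariate population
  cov <- data.frame(tract_id = "T01", population = 100)
  s3 <- summarize_tract_mobility(tracts, "T01", fl2, pois, cov)
  expect_equal(s3$per_capita_visits, 0.1)
})

test_that("summaries are invariant to count scaling and record splitting", {
  tracts <- make_grid_tracts(2, 2)
  set.seed(304)
  pois <- make_pois(sprintf("P%d", 1:40), runif(40, -3, 5), runif(40, -3, 5),
                    "445120")
  fl <- make_flows(sample(tracts$info$tract_id, 60, replace = TRUE),
                   sample(pois$poi_id, 60, replace = TRUE),
                   sample(1:9, 60, replace = TRUE))
  fl <- suppressMessages(foodenv:::validate_table(fl, "flows"))
  base <- summarize_mobility(tracts, fl, pois)
  scaled <- fl; scaled$visit_count <- scaled$visit_count * 5
  s_scaled <- summarize_mobility(tracts, scaled, pois)
  stat_cols <- c("median_distance_miles", foodenv:::DISTANCE_BAND_LABELS,
                 "within_half_mile_share")
  expect_equal(s_scaled[, stat_cols], base[, stat_cols], tolerance = 1e-12)
  # split every record into two halves (possibly 0 + n)
  k <- floor(fl$visit_count / 2)
  split_fl <- rbind(transform(fl, visit_count = k),
                    transform(fl, visit_count = visit_count - k, year = 2019))
  s_split <- summarize_mobility(tracts, split_fl, pois)
  expect_equal(s_split[, stat_cols], base[, stat_cols], tolerance = 1e-12)
})

test_that("full summary equals brute-force per-visit recomputation", {
  tracts <- make_grid_tracts(2, 2)
  set.seed(305)
  pois <- make_pois(sprintf("P%d", 1:100), runif(100, -10, 12), runif(100, -10, 12),
                    "445120")
  fl <- make_flows(sample(tracts$info$tract_id, 500, replace = TRUE),
                   sample(pois$poi_id, 500, replace = TRUE),
                   sample(0:9, 500, replace = TRUE))
  fl <- suppressMessages(foodenv:::validate_table(fl, "flows"))
  res <- summarize_mobility(tracts, fl, pois)
  for (id in tracts$info$tract_id) {
    sub <- fl[fl$origin_tract_id == id & fl$visit_count > 0, ]
    row <- res[res$tract_id == id, ]
    expect_equal(row$total_visits, sum(sub$visit_count))
    if (nrow(sub) == 0 || sum(sub$visit_count) == 0) {
      expect_true(is.na(row$median_distance_miles))
      next
    }
    cent <- foodenv:::tract_centroids(tracts)[id, ]
    d <- sqrt((pois$lon[match(sub$poi_id, pois$poi_id)] - cent[1])^2 +
              (pois$lat[match(sub$poi_id, pois$poi_id)] - cent[2])^2)
    per_visit <- rep(d, sub$visit_count)
    expect_equal(row$median_distance_miles,
                 sort(per_visit)[ceiling(length(per_visit) / 2)])
    oracle_bands <- as.numeric(table(cut(per_visit, c(0, 1, 5, 10, 20, Inf),
                                         right = FALSE))) / length(per_visit)
    expect_equal(as.numeric(row[, foodenv:::DISTANCE_BAND_LABELS]), oracle_bands,
                 tolerance = 1e-12)
  }
})

test_that("band aggregation offers per-tract means and pooled shares", {
  s <- data.frame(tract_id = c("A", "B"), total_visits = c(10, 30),
                  median_distance_miles = c(1, 3),
                  band_0_1 = c(1, 0), band_1_5 = c(0, 1), band_5_10 = 0,
                  band_10_20 = 0, band_20_plus = 0,
                  within_half_mile_share = c(0.5, 0.1), per_capita_visits = NA)
  tm <- aggregate_band_shares(s, "tract_mean")
  expect_equal(unname(tm$band_shares[1:2]), c(0.5, 0.5))
  po <- aggregate_band_shares(s, "pooled")
  expect_equal(unname(po$band_shares[1:2]), c(0.25, 0.75))
})
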