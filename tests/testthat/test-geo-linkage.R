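test_that("haversine distance matches the closed form and is symmetric", {
  expect_identical(great_circle_distance(12, 34, 12, 34), 0)
  # one degree of longitude along the equator: R * pi/180
  expect_equal(great_circle_distance(0, 0, 1, 0), 3958.8 * pi / 180,
               tolerance = 1e-10)
  expect_equal(great_circle_distance(0, 0, 1, 0), 69.09, tolerance = 1e-4)
  expect_identical(great_circle_distance(-70, 40, -71, 41),
                   great_circle_distance(-71, 41, -70, 40))
  expect_error(great_circle_distance(200, 0, 0, 0), "out of range")
  expect_error(great_circle_distance(0, 95, 0, 0), "out of range")
})

test_that("haversine agrees with an independent implementation", {
  set.seed(1)
  lon <- stats::runif(50, -120, 60); lat <- stats::runif(50, -60, 60)
  ours <- great_circle_distance(lon[1:25], lat[1:25], lon[26:50], lat[26:50])
  ref <- geosphere::distHaversine(cbind(lon[1:25], lat[1:25]),
                                  cbind(lon[26:50], lat[26:50]),
                                  r = 3958.8)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("distance satisfies the triangle inequality on random triples", {
  set.seed(7)
  for (k in 1:100) {
    lon <- stats::runif(3, -180, 180); lat <- stats::runif(3, -90, 90)
    d12 <- great_circle_distance(lon[1], lat[1], lon[2], lat[2])
    d23 <- great_circle_distance(lon[2], lat[2], lon[3], lat[3])
    d13 <- great_circle_distance(lon[1], lat[1], lon[3], lat[3])
    expect_lte(d13, d12 + d23 + 1e-8)
  }
})

test_that("nearest-within-radius linkage: basics, ties, and edge cases", {
  t1 <- data.frame(id = "t1", lon = -75, lat = 40)
  s <- data.frame(id = c("s1", "s2"), lon = c(-75, -75.5), lat = c(40, 40.5))
  res <- link_nearest_within(t1, s, radius = 6)
  expect_equal(res$source_id, "s1")
  expect_equal(res$distance_miles, 0)

  # strictly-within rule: a source exactly at the radius is not linked
  tp <- planar_locs(cbind(0, 0), "t")
  sp <- planar_locs(cbind(6, 0), "s")
  expect_true(is.na(link_nearest_within(tp, sp, 6, method = "euclidean")$source_id))

  # equidistant sources break ties to the lexicographically smaller id
  sp2 <- planar_locs(rbind(c(3, 0), c(-3, 0)), c("zzz", "aaa"))
  res2 <- link_nearest_within(tp, sp2, 6, method = "euclidean")
  expect_equal(res2$source_id, "aaa")

  # empty inputs
  expect_equal(nrow(link_nearest_within(tp[0, ], sp, 6)), 0)
  res3 <- link_nearest_within(tp, sp[0, ], 6, method = "euclidean")
  expect_true(is.na(res3$source_id))
  expect_error(link_nearest_within(tp, sp, radius = 0))
})

test_that("linkage matches a brute-force all-pairs scan and ignores source order", {
  set.seed(11)
  targets <- data.frame(id = sprintf("t%03d", 1:40),
                        lon = stats::runif(40, -80, -79),
                        lat = stats::runif(40, 39, 40))
  sources <- data.frame(id = sprintf("s%03d", 1:15),
                        lon = stats::runif(15, -80, -79),
                        lat = stats::runif(15, 39, 40))
  res <- link_nearest_within(targets, sources, radius = 6)
  for (i in seq_len(nrow(targets))) {
    d <- great_circle_distance(targets$lon[i], targets$lat[i],
                               sources$lon, sources$lat)
    if (min(d) < 6) {
      expect_equal(res$source_id[i], sources$id[which.min(d)])
      expect_equal(res$distance_miles[i], min(d))
    } else {
      expect_true(is.na(res$source_id[i]))
    }
  }
  perm <- sample(nrow(sources))
  expect_equal(link_nearest_within(targets, sources[perm, ], radius = 6), res)
})

test_that("buffer aggregation: mean, sum, empty buffers, additivity", {
  mon <- list(lon = 0, lat = 0)
  one <- data.frame(lon = 0, lat = 0, value = 4.2)
  expect_equal(aggregate_buffer(mon, one, 6, "mean")$value, 4.2)

  three <- planar_locs(rbind(c(1, 0), c(0, 2), c(-1, -1)))
  three$value <- c(1, 2, 3)
  agg <- aggregate_buffer(list(lon = 0, lat = 0), three, 6, "sum",
                          method = "euclidean")
  expect_equal(agg$value, 6)
  expect_equal(agg$n_points, 3L)

  far <- data.frame(lon = 10, lat = 10, value = 1)
  empty <- aggregate_buffer(mon, far, 6, "mean")
  expect_true(empty$empty)
  expect_true(is.na(empty$value))

  # sums are additive over disjoint partitions of the point set
  set.seed(3)
  pts <- data.frame(lon = stats::runif(30, -0.1, 0.1),
                    lat = stats::runif(30, -0.1, 0.1),
                    value = stats::rpois(30, 5))
  split <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  whole <- aggregate_buffer(mon, pts, 6, "sum")$value
  part <- sum(aggregate_buffer(mon, pts[split, ], 6, "sum")$value %||% 0,
              aggregate_buffer(mon, pts[!split, ], 6, "sum")$value %||% 0,
              na.rm = TRUE)
  expect_equal(whole, part)
})

test_that("network-wide aggregation supports count-in-both vs assign-to-nearest", {
  mons <- planar_locs(rbind(c(0, 0), c(8, 0)), c("m1", "m2"))
  pts <- planar_locs(rbind(c(5, 0), c(1, 0)))   # first point inside both buffers
  pts$value <- c(10, 1)
  both <- aggregate_buffer_all(mons, pts, 6, "sum", assign = "all",
                               method = "euclidean")
  expect_equal(both$value, c(11, 10))
  nearest <- aggregate_buffer_all(mons, pts, 6, "sum", assign = "nearest",
                                  method = "euclidean")
  expect_equal(nearest$value[2], 10)  # shared point is nearer to m2
  expect_equal(nearest$value[1], 1)
})
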