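test_that("degree-minute parsing handles the common glyphs and rejects bad minutes", {
  expect_equal(parse_dms("25°19′"), 25 + 19 / 60, tolerance = 1e-12)
  expect_equal(parse_dms("0°0′"), 0)
  expect_equal(parse_dms("108° 6′"), 108.1, tolerance = 1e-12)
  expect_equal(parse_dms("30°15′30″"), 30 + 15 / 60 + 30 / 3600)
  expect_equal(parse_dms("25°30′S"), -25.5)
  expect_equal(parse_dms("12.75"), 12.75)
  expect_error(parse_dms("25°61′"), "minutes")
  expect_error(parse_dms("25°x′"), "malformed")
})

test_that("chord distance reproduces its exact geometric cases", {
  p0 <- list(latitude = 12, longitude = 34, elevation = 0)
  expect_equal(chord_distance(p0, p0), 0)
  ## radial case: same direction, elevations differing by 1000 m
  p1 <- list(latitude = 12, longitude = 34, elevation = 1000)
  expect_equal(chord_distance(p0, p1), 1000, tolerance = 1e-9)
  ## right angle at the center: chord R * sqrt(2)
  e1 <- list(latitude = 0, longitude = 0, elevation = 0)
  e2 <- list(latitude = 0, longitude = 90, elevation = 0)
  expect_equal(chord_distance(e1, e2, R = 6371000), 6371000 * sqrt(2),
               tolerance = 1e-9)
  expect_error(chord_distance(e1, e2, R = 0), "R must be")
})

test_that("chord distance is bounded by the great-circle arc and converges to it", {
  R <- 6371000
  arc <- function(lat1, lon1, lat2, lon2) {
    to_r <- pi / 180
    ## haversine form: numerically stable for small separations
    a <- sin((lat2 - lat1) * to_r / 2)^2 +
      cos(lat1 * to_r) * cos(lat2 * to_r) * sin((lon2 - lon1) * to_r / 2)^2
    R * 2 * asin(sqrt(a))
  }
  p <- list(latitude = 20, longitude = 100, elevation = 0)
  for (dlon in c(30, 5, 0.1, 0.001)) {
    q <- list(latitude = 20, longitude = 100 + dlon, elevation = 0)
    ch <- chord_distance(p, q, R)
    a <- arc(20, 100, 20, 100 + dlon)
    expect_lte(ch, a + 1e-9)
    if (dlon <= 0.1) expect_equal(ch / a, 1, tolerance = 1e-6)
  }
})

test_that("the distance matrix matches a hand evaluation on two published sites", {
  meta <- read_population_meta(
    system.file("extdata", "population_sites.csv", package = "qstfst"))
  expect_equal(nrow(meta), 31)
  gm <- geographic_distance_matrix(meta)
  ## independent scalar evaluation for sites 1767 and 1768
  R <- 6371000
  emb <- function(lat, lon, h) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c((h + R) * cos(la) * cos(lo), (h + R) * cos(la) * sin(lo), (h + R) * sin(la))
  }
  a <- emb(36 + 39 / 60, 117 + 7 / 60, 122)
  b <- emb(36 + 13 / 60, 117 + 6 / 60, 641)
  expect_equal(gm$distance["1767", "1768"], sqrt(sum((a - b)^2)), tolerance = 1e-9)
  ## metric properties
  d <- gm$distance
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  ii <- sample(31, 3)
  expect_lte(d[ii[1], ii[3]], d[ii[1], ii[2]] + d[ii[2], ii[3]] + 1e-9)
})

test_that("coincident populations yield zero distance and flagged log cells", {
  meta <- data.frame(population = c("a", "b"), latitude = c(10, 10),
                     longitude = c(20, 20), elevation = c(5, 5))
  expect_warning(gm <- geographic_distance_matrix(meta), "coincident")
  expect_equal(gm$distance["a", "b"], 0)
  expect_true(is.na(gm$log_distance["a", "b"]))
})

test_that("climate distance matrices are absolute differences per variable", {
  ct <- data.frame(population = c("a", "b", "c"), v1 = c(1, 4, 9), v2 = c(2, 2, 2))
  cm <- climate_distance_matrices(ct)
  expect_equal(cm$v1["a", "b"], 3)
  expect_equal(cm$v1["b", "c"], 5)
  expect_equal(cm$v1["a", "c"], 8)
  expect_equal(unname(cm$v2), matrix(0, 3, 3))
  ct$v1[2] <- NA
  expect_error(climate_distance_matrices(ct), "population b, variable v1")
})
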