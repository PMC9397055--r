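wss_of <- function(area, tau) {
  structure(data.frame(area = area, tau = tau),
            class = c("wall_stress_field", "data.frame"))
}

test_that("plate wall shear matches 6 mu U / h within 5%", {
  wss <- cached("plate_wss", compute_wss(plate_solution(), plate_fixture(), blood))
  aw <- sum(wss$tau * wss$area) / sum(wss$area)
  expect_equal(aw, 6 * 0.0045 * 0.001 / 0.0003, tolerance = 0.05)
  # flat walls: element areas are exact voxel faces summing to 2 x L x W
  expect_equal(attr(wss, "total_area"),
               2 * (3 * 0.015) * scaffold_length_mm(plate_fixture()),
               tolerance = 1e-9)
})

test_that("tube wall shear matches 4 mu U / R within 5%", {
  wss <- cached("tube_wss", compute_wss(tube_solution(), tube_fixture(), blood))
  aw <- sum(wss$tau * wss$area) / sum(wss$area)
  expect_equal(aw, 4 * 0.0045 * 0.001 / 0.0005, tolerance = 0.05)
  # projected staircase areas recover the smooth lateral area
  expect_equal(attr(wss, "total_area"),
               2 * pi * 0.5 * scaffold_length_mm(tube_fixture()),
               tolerance = 0.05)
  expect_true(all(wss$tau >= 0))
})

test_that("a quiescent field carries zero wall shear", {
  dom <- plate_fixture()
  sol <- plate_solution()
  still <- sol
  still$ux[] <- 0; still$uy[] <- 0; still$uz[] <- 0
  wss <- compute_wss(still, dom, blood)
  expect_true(all(wss$tau == 0))
})

test_that("viability fraction is the strict area-weighted sub-threshold share", {
  expect_equal(viability_fraction(wss_of(c(1, 1), c(0.010, 0.010)))$viable_fraction, 100)
  expect_equal(viability_fraction(wss_of(c(1, 1), c(0.010, 0.050)))$viable_fraction, 50)
  # strictly "lower than": elements exactly at the threshold do not count
  expect_equal(viability_fraction(wss_of(c(1, 1), c(0.030, 0.030)))$viable_fraction, 0)
  # area weighting, not element counting
  expect_equal(viability_fraction(wss_of(c(3, 1), c(0.010, 0.050)))$viable_fraction, 75)
  # duplicating every element at half area changes nothing
  f1 <- wss_of(c(2, 2), c(0.01, 0.05))
  f2 <- wss_of(c(1, 1, 1, 1), c(0.01, 0.05, 0.01, 0.05))
  expect_equal(viability_fraction(f2)$viable_fraction,
               viability_fraction(f1)$viable_fraction)
  # limits
  f <- wss_of(c(1, 1, 1), c(0.01, 0.2, 5))
  expect_equal(viability_fraction(f, threshold = Inf)$viable_fraction, 100)
  expect_equal(viability_fraction(f, threshold = 1e-12)$viable_fraction, 0)
  expect_error(viability_fraction(f, threshold = 0), "threshold")
  expect_error(viability_fraction(f, threshold = -1), "threshold")
})

test_that("histograms are area-weighted with half-open bins and a closed tail", {
  f <- wss_of(c(1, 1), c(0.010, 0.050))
  h1 <- wss_histogram(f, c(0, 0.060))
  expect_equal(h1$pct, 100)
  h2 <- wss_histogram(f, c(0, 0.030, 0.060))
  expect_equal(h2$pct, c(50, 50))
  # the final bin is closed: a value exactly at the top edge is counted
  h3 <- wss_histogram(wss_of(1, 0.060), c(0, 0.030, 0.060))
  expect_equal(h3$pct, c(0, 100))
  # a value exactly at an interior edge belongs to the upper bin
  h4 <- wss_histogram(wss_of(1, 0.030), c(0, 0.030, 0.060))
  expect_equal(h4$pct, c(0, 100))
  expect_error(wss_histogram(f, c(0.06, 0.03)), "increasing")
  # with an edge at the threshold, the sub-threshold bins rebuild the
  # viability fraction
  f5 <- wss_of(c(2, 1, 1, 4), c(0.005, 0.020, 0.045, 0.090))
  h5 <- wss_histogram(f5, c(0, 0.015, 0.030, 0.060, 0.100))
  expect_equal(sum(h5$pct[h5$hi <= 0.030]),
               viability_fraction(f5)$viable_fraction)
  expect_equal(sum(h5$pct), 100)
})

test_that("viability summaries carry a consistent histogram and stats", {
  f <- wss_of(c(1, 2, 1), c(0.005, 0.025, 0.080))
  v <- viability_fraction(f)
  expect_equal(sum(v$histogram$pct), 100, tolerance = 1e-6)
  expect_equal(v$mean_tau, sum(f$tau * f$area) / sum(f$area))
  expect_equal(v$max_tau, 0.080)
  expect_equal(v$viable_fraction, 75)
})
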