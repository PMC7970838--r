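# Release scheduling, advection, vertical migration and density output.

test_that("per-ground counts follow largest-remainder rounding and sum exactly", {
  p <- releaseParticles(ReleaseConfig(totalParticles = 198580))
  counts <- table(p$ground)
  expect_equal(sum(counts), 198580)
  expect_equal(unname(counts[c("More", "Haltenbanken", "Sklinna", "Rost")]),
               c(99290, 39716, 19858, 39716), ignore_attr = TRUE)
  # ragged fractions still sum exactly
  g <- data.frame(name = c("a", "b", "c"), lon = 1:3, lat = 1:3,
                  fraction = rep(1 / 3, 3))
  p2 <- releaseParticles(ReleaseConfig(totalParticles = 100, grounds = g))
  expect_equal(sum(table(p2$ground)), 100)
  expect_equal(sort(as.integer(table(p2$ground))), c(33, 33, 34))
})

test_that("zero particles give an empty release; bad configs error", {
  expect_equal(nrow(releaseParticles(ReleaseConfig(totalParticles = 0))), 0)
  g <- defaultSpawningGrounds(); g$fraction <- g$fraction * 0.9
  expect_error(releaseParticles(ReleaseConfig(grounds = g)), "sum to 1")
  expect_error(ReleaseConfig(hatchStart = "2017-04-20",
                             hatchEnd = "2017-03-15"), "precede")
})

test_that("hatch times follow the truncated Gaussian and stay in the window", {
  cfg <- ReleaseConfig(totalParticles = 10000, seed = 11)
  p <- releaseParticles(cfg)
  t0 <- utc("2017-03-15"); t1 <- utc("2017-04-20")
  expect_true(all(p$hatch_time >= t0 & p$hatch_time <= t1))
  days <- as.numeric(difftime(p$hatch_time, t0, units = "days"))
  len <- 36; m <- len / 2; s <- len / 6
  ptrunc <- function(x) {
    (pnorm(x, m, s) - pnorm(0, m, s)) /
      (pnorm(len, m, s) - pnorm(0, m, s))
  }
  ks <- suppressWarnings(ks.test(days, ptrunc))
  expect_lt(unname(ks$statistic), 0.02)
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds reproduce the release bit for bit", {
  p1 <- releaseParticles(ReleaseConfig(totalParticles = 500, seed = 3))
  p2 <- releaseParticles(ReleaseConfig(totalParticles = 500, seed = 3))
  expect_identical(p1, p2)
  p3 <- releaseParticles(ReleaseConfig(totalParticles = 500, seed = 4))
  expect_false(identical(p1$hatch_time, p3$hatch_time))
})

test_that("a zero-velocity field leaves position unchanged but grows the larva", {
  ff <- makeUniformField(u0 = 0, v0 = 0)
  p <- advectStep(makeParticle(), ff, utc("2017-06-01 12:00"), 3600,
                  dvm = NULL)
  expect_equal(p$lon, 0)
  expect_equal(p$lat, 0)
  expect_equal(p$length, 9 + 0.4 * 3600 / 86400)
})

test_that("uniform eastward flow gives the closed-form displacement", {
  ff <- makeUniformField(u0 = 0.5, v0 = 0)
  p <- makeParticle()
  t0 <- utc("2017-06-01")
  for (k in 1:24) p <- advectStep(p, ff, t0 + (k - 1) * 3600, 3600,
                                  dvm = NULL)
  disp <- p$lon * pi / 180 * EARTH_R
  expect_lt(abs(disp - 43200) / 43200, 0.001)
})

test_that("solid-body rotation closes its orbit within 1% of the radius", {
  period <- 628319
  ff <- makeRotationField(period = period)
  r <- 50000
  p <- makeParticle(lon = r / EARTH_R * 180 / pi, lat = 0)
  start <- c(p$lon, p$lat)
  t0 <- utc("2017-06-01")
  nsteps <- floor(period / 3600)
  for (k in 1:nsteps) p <- advectStep(p, ff, t0 + (k - 1) * 3600, 3600,
                                      dvm = NULL)
  p <- advectStep(p, ff, t0 + nsteps * 3600, period - nsteps * 3600,
                  dvm = NULL)
  err <- sqrt(sum(((c(p$lon, p$lat) - start) * pi / 180 * EARTH_R)^2))
  expect_lt(err / r, 0.01)
})

test_that("advectStep rejects non-positive dt and skips inactive particles", {
  ff <- makeUniformField()
  expect_error(advectStep(makeParticle(), ff, utc("2017-06-01"), 0),
               "positive")
  p <- makeParticle(status = "beached")
  expect_identical(advectStep(p, ff, utc("2017-06-01"), 3600), p)
})

test_that("particles beach on land and exit at the domain edge", {
  mask <- matrix(FALSE, 9, 9); mask[8:9, ] <- TRUE  # land at lon >= 1.5
  lon <- seq(-2, 2, 0.5)
  dates <- seq(as.Date("2017-06-01"), by = "day", length.out = 3)
  ff <- FlowField(lon, lon, c(0, 50), dates,
                  u = array(0.9, c(9, 9, 2, 3)),
                  v = array(0, c(9, 9, 2, 3)), mask = mask)
  p <- makeParticle(lon = 1.15, lat = 0)
  p <- advectStep(p, ff, utc("2017-06-01"), 12 * 3600, dvm = NULL)
  expect_equal(p$status, "beached")
  expect_equal(p$lon, 1.15)  # reverted to last wet position
  # driving a particle past the eastern edge marks it exited
  ff2 <- makeUniformField(u0 = 0.9)
  q <- makeParticle(lon = 1.95, lat = 0)
  q <- advectStep(q, ff2, utc("2017-06-01"), 12 * 3600, dvm = NULL)
  expect_equal(q$status, "exited")
})

test_that("active particles stay in the migration band and grow at 0.4 mm/day", {
  cfg <- scenarioConfig(seed = 5)
  field <- genFlowField(cfg, dates = seq(as.Date("2017-03-15"), by = "day",
                                         length.out = 22))
  rc <- ReleaseConfig(totalParticles = 300, seed = 5)
  res <- runSimulation(rc, field, dt = 3600,
                       endDate = as.Date("2017-03-15") + 20)
  fs <- res@finalState
  act <- fs[fs$status == "active", ]
  expect_true(all(act$depth >= 5 & act$depth <= 40))
  expect_equal(act$length, 9 + 0.4 * act$age)
})

test_that("particle count is conserved at every snapshot", {
  cfg <- scenarioConfig(seed = 8)
  field <- genFlowField(cfg, dates = seq(as.Date("2017-03-15"), by = "day",
                                         length.out = 42))
  rc <- ReleaseConfig(totalParticles = 200, seed = 8)
  res <- runSimulation(rc, field, dt = 7200,
                       endDate = as.Date("2017-03-15") + 40)
  for (d in as.character(snapshotDates(res))) {
    snap <- snapshotAt(res, d)
    expect_true(nrow(snap) <= rc@totalParticles)
    expect_equal(nrow(snap),
                 sum(snap$status %in% c("active", "beached", "exited")))
  }
  expect_equal(nrow(res@finalState), 200)  # all hatched by day 40
})

test_that("a northward jet carries the cohort north", {
  cfg <- scenarioConfig(seed = 9)
  field <- genFlowField(cfg, dates = seq(as.Date("2017-03-15"), by = "day",
                                         length.out = 22))
  g <- data.frame(name = "core", lon = 10, lat = 64, fraction = 1)
  rc <- ReleaseConfig(totalParticles = 100, seed = 9, grounds = g,
                      hatchEnd = as.Date("2017-03-18"))
  res <- runSimulation(rc, field, dt = 3600,
                       endDate = as.Date("2017-03-15") + 20)
  ml <- vapply(as.character(snapshotDates(res)), function(d) {
    s <- snapshotAt(res, d)
    mean(s$lat[s$status == "active"])
  }, numeric(1))
  ml <- ml[seq(5, length(ml))]  # after the short hatch window
  expect_true(all(res@finalState$status == "active"))
  expect_true(all(diff(ml) > 0))
})

test_that("runSimulation with endDate at the window start does not move anyone", {
  cfg <- scenarioConfig(seed = 2)
  field <- genFlowField(cfg, dates = seq(as.Date("2017-03-15"), by = "day",
                                         length.out = 3))
  rc <- ReleaseConfig(totalParticles = 50, seed = 2)
  res <- runSimulation(rc, field, endDate = as.Date("2017-03-15"))
  expect_equal(length(res@snapshots), 1)
  snap <- snapshotAt(res, "2017-03-15")
  expect_true(all(snap$age == 0))
  # field too short for a longer run -> configuration error
  expect_error(runSimulation(rc, field, endDate = as.Date("2017-06-01")),
               "does not span")
})

test_that("density grids bin half-open, conserve counts and transform", {
  # still water, short hatch window: every particle sits on its ground
  grounds <- data.frame(name = "g", lon = 0.25, lat = 0.1, fraction = 1)
  field <- makeUniformField(u0 = 0, v0 = 0, days = 8)
  mkres <- function(n) runSimulation(
    ReleaseConfig(totalParticles = n, seed = 1, grounds = grounds,
                  hatchStart = as.Date("2017-06-01"),
                  hatchEnd = as.Date("2017-06-03")),
    field, dt = 7200, endDate = as.Date("2017-06-05"))
  res <- mkres(1)
  dg <- densityGrid(res, "2017-06-05", seq(-2, 2, 0.5), seq(-2, 2, 0.5))
  expect_equal(sum(gridCounts(dg)), 1)
  expect_equal(sum(gridCounts(dg) > 0), 1)
  expect_error(densityGrid(res, "2017-06-05", -2:2, -2:2,
                           transform = "cube"), "unknown transform")
  # sqrt transform: 49 particles in one cell -> 7
  res49 <- mkres(49)
  dg49 <- densityGrid(res49, "2017-06-05", seq(-2, 2, 0.5),
                      seq(-2, 2, 0.5), transform = "sqrt_n")
  expect_equal(max(gridValues(dg49)), 7)
  expect_equal(sum(gridCounts(dg49)), 49)
  # log_n transform uses log(n + 1)
  dgl <- densityGrid(res49, "2017-06-05", seq(-2, 2, 0.5),
                     seq(-2, 2, 0.5), transform = "log_n")
  expect_equal(max(gridValues(dgl)), log(50))
  # a particle exactly on the upper edge is outside the half-open grid
  dgE <- densityGrid(res, "2017-06-05", seq(-2, 0.25, 0.25),
                     seq(-2, 2, 0.5))
  expect_equal(sum(gridCounts(dgE)), 0)
})
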