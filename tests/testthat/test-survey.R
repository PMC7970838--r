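# Densities, station ANOVA, correlations, leverage and overlap.

test_that("larval density is individuals per 10 m^3", {
  expect_equal(larvalDensity(50, 100), 5)
  expect_equal(larvalDensity(0, 250), 0)
  expect_error(larvalDensity(5, 0), "positive")
})

test_that("swept-area density is catch over towed area", {
  expect_equal(sweptAreaDensity(100, 1, 0.01), 10000)
  expect_equal(sweptAreaDensity(0, 2, 0.01), 0)
  expect_error(sweptAreaDensity(10, 0, 0.01), "positive")
})

test_that("station ANOVA reports F, df and Tukey HSD on log10(copies + 1)", {
  withr::with_seed(21, {
    copies <- 10^rnorm(84, 7, 0.5)
    station <- rep(LETTERS[1:11], length.out = 84)
  })
  res <- stationAnova(copies, station, year = 2017)
  expect_s4_class(res, "StationTestResult")
  expect_equal(res@dfBetween, 10)
  expect_equal(res@dfWithin, 73)
  expect_equal(nrow(res@tukey), choose(11, 2))
  # F is invariant under shifting or scaling the log response: scaling
  # copies by a constant shifts log10(copies) -> F unchanged (up to the
  # +1 offset, negligible at these magnitudes)
  res2 <- stationAnova(copies * 10, station, year = 2017)
  expect_equal(res2@F, res@F, tolerance = 1e-6)
})

test_that("identical station means give F near 0", {
  copies <- rep(c(1e6, 4e6, 8e6), 4)     # same triple at each station
  station <- rep(c("A", "B", "C", "D"), each = 3)
  res <- stationAnova(copies, station)
  expect_lt(res@F, 1e-20)
  expect_gt(res@p, 0.999)
})

test_that("with two groups the Tukey p equals the ANOVA p", {
  withr::with_seed(33, {
    copies <- 10^c(rnorm(10, 6.5, 0.4), rnorm(10, 7.2, 0.4))
  })
  station <- rep(c("A", "B"), each = 10)
  res <- stationAnova(copies, station)
  expect_equal(res@tukey$p_adj, res@p, tolerance = 1e-6)
})

test_that("underfilled stations are excluded and degenerate data error", {
  copies <- c(1e6, 2e6, 3e6, 4e6, 9e9)
  station <- c("A", "A", "B", "B", "C")
  expect_warning(res <- stationAnova(copies, station), "excluding.*C")
  expect_equal(res@dfBetween + res@dfWithin + 1, 4)
  expect_error(suppressWarnings(stationAnova(rep(1e6, 6),
                                             rep(c("A", "B"), 3))),
               "identical")
  expect_error(stationAnova(c(1, 2), c("A", "A")), "at least 2 stations")
})

test_that("Pearson correlation bookkeeping: r, t, df = n - 2", {
  withr::with_seed(5, {
    x <- rnorm(90); y <- 0.4 * x + rnorm(90)
  })
  res <- pearsonPredictorCor(y, x, "fish_weight")
  expect_equal(res@df, 88)
  expect_equal(res@t, res@r * sqrt(res@df) / sqrt(1 - res@r^2),
               tolerance = 1e-10)
  # exactly collinear data
  resc <- pearsonPredictorCor(2 * x + 1, x)
  expect_equal(resc@r, 1, tolerance = 1e-12)
  expect_error(pearsonPredictorCor(y, rep(1, 90)), "constant")
})

test_that("the Pearson p-value agrees with a permutation null", {
  withr::with_seed(17, {
    x <- rnorm(40); y <- 0.45 * x + rnorm(40)
    robs <- abs(cor(x, y))
    rperm <- replicate(10000, abs(cor(x, sample(y))))
  })
  pPerm <- (sum(rperm >= robs) + 1) / (10000 + 1)
  res <- pearsonPredictorCor(y, x)
  expect_lt(abs(res@p - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / 10000) + 2e-4)
})

test_that("leverages match the hat matrix and sum to 2", {
  withr::with_seed(9, x <- c(rnorm(20), 8))  # one extreme point
  h <- simpleLeverage(x)
  expect_equal(sum(h), 2, tolerance = 1e-12)
  fit <- lm(rnorm(21) ~ x)
  expect_equal(h, unname(hatvalues(fit)), tolerance = 1e-10)
  expect_error(simpleLeverage(rep(3, 5)), "constant")
})

test_that("visual vs molecular flags high-leverage stations", {
  withr::with_seed(41, {
    n <- 30
    vis <- data.frame(stomach_id = sprintf("s%02d", 1:n),
                      larvae_seen = rpois(n, 1),
                      otoliths_seen = rpois(n, 0.5))
    vis$larvae_seen[1] <- 19; vis$otoliths_seen[1] <- 12  # aggregated outlier
    cp <- data.frame(stomach_id = vis$stomach_id,
                     copies_per_g = 1e6 * (vis$larvae_seen +
                                             vis$otoliths_seen) +
                       rlnorm(n, 13, 1))
  })
  res <- visualVsMolecular(vis, cp)
  expect_named(res$correlations, c("larvae", "otoliths", "pooled"))
  expect_equal(sum(res$leverage$leverage), 2, tolerance = 1e-12)
  expect_true(res$leverage$high_leverage[1])
  expect_gt(res$leverage$leverage[1], 0.5)
  # disjoint tables cannot be joined
  cp2 <- cp; cp2$stomach_id <- paste0("x", cp2$stomach_id)
  expect_error(visualVsMolecular(vis, cp2), "no common")
})

test_that("Schoener's D spans disjoint to identical distributions", {
  expect_equal(schoenersD(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(schoenersD(c(2, 1, 1), c(4, 2, 2)), 1)
  # hand-computed 3-cell case: 1 - 0.5*(0.3 + 0 + 0.3) = 0.7
  expect_equal(schoenersD(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)), 0.7)
  expect_error(schoenersD(c(0, 0), c(1, 0)), "positive mass")
})

test_that("overlap summary joins the three survey layers by station", {
  pl <- data.frame(station_id = c("A", "B"), larval_count = c(50, 10),
                   filtered_volume = c(100, 100))
  tr <- data.frame(station_id = c("A", "B"), catch_weight = c(100, 10),
                   tow_distance = 1, effective_width = 0.01)
  cp <- data.frame(station_id = rep(c("A", "B"), each = 2),
                   copies_per_g = c(1e6, 3e6, 1e5, 1e5))
  out <- overlapSummary(pl, tr, cp)
  expect_equal(out$larval_density, c(5, 1))
  expect_equal(out$predator_density, c(10000, 1000))
  expect_equal(out$mean_copies_per_g, c(2e6, 1e5))
  expect_equal(out$n_stomachs, c(2, 2))
  cpBad <- cp; cpBad$station_id <- c("X", "X", "Y", "Y")
  expect_error(overlapSummary(pl, tr, cpBad), "no stations common")
})
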