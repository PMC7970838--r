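# Droplet-count QC, Poisson partition statistics and the normalization
# chain to copies per gram.

test_that("droplet-count QC boundaries are inclusive", {
  expect_equal(qcReaction(c(12999, 13000, 21000, 21001)),
               c("qc_droplet_count", "pass", "pass", "qc_droplet_count"))
})

test_that("Poisson concentration matches hand arithmetic and flags edge cases", {
  # p = 0.5, v = 0.85 nL: -ln(0.5) / 0.00085 = 815.467 copies/ul
  r <- poissonConcentration(10000, 20000)
  expect_equal(r$conc, -log(0.5) / 0.00085, tolerance = 1e-12)
  expect_equal(r$conc, 815.4673, tolerance = 1e-4)
  expect_equal(r$flag, "")
  # no positives -> 0 with below_detection
  r0 <- poissonConcentration(0, 20000)
  expect_equal(r0$conc, 0)
  expect_equal(r0$flag, "below_detection")
  # all positive -> saturated, value evaluated at the threshold
  rs <- poissonConcentration(20000, 20000)
  expect_equal(rs$flag, "saturated")
  expect_equal(rs$conc, -log(30 / 20000) / 0.00085)
  expect_error(poissonConcentration(5, 0), "zero accepted droplets")
})

test_that("the Poisson estimate agrees with the multinomial brute-force oracle", {
  # estimate concentration from brute-force wells across a lambda grid;
  # the median relative error must sit within Monte-Carlo error of zero
  lambdas <- c(0.1, 0.5, 1, 2)
  for (lam in lambdas) {
    conc <- lam / 0.00085  # copies/ul at 0.85 nL droplets
    wells <- do.call(rbind, lapply(1:40, function(i)
      genDropletData(conc, 20000, mode = "multinomial", seed = 1000 + i)))
    est <- poissonConcentration(wells$n_positive, wells$n_total)$conc
    relerr <- (est - conc) / conc
    expect_lt(abs(median(relerr)), 0.02)
  }
})

test_that("copies per gram is monotone in positives and scales with dilution", {
  base <- makeWell(p = 0.3)
  sub <- makeSubsample(); stom <- makeStomach()
  cpg <- function(w) copiesPerGram(w, sub, stom)$copies_per_g
  vals <- vapply(c(0.1, 0.3, 0.6, 0.9), function(p)
    cpg(makeWell(p = p)), numeric(1))
  expect_true(all(diff(vals) > 0))
  # doubling dilution with identical counts exactly doubles copies/g
  w10 <- makeWell(p = 0.3, dilution = 10)
  w20 <- makeWell(p = 0.3, dilution = 20)
  expect_equal(cpg(w20), 2 * cpg(w10), tolerance = 1e-15)
})

test_that("the worked normalization chain is exact to machine precision", {
  # 100 copies/ul reaction, dilution 10, 150 ul elution, 0.2 g wet at
  # 1:3 PBS -> 100 * 4 * 10 * 150 / 0.05 = 1.2e7 copies/g
  w <- makeWell(p = 1 - exp(-100 * 0.00085), dilution = 10)
  res <- copiesPerGram(w, makeSubsample(), makeStomach())
  expect_equal(res$copies_per_g, 1.2e7, tolerance = 1e-12)
  expect_equal(res$copies_per_ul_reaction, 100, tolerance = 1e-12)
})

test_that("replicates average on the copies-per-gram scale", {
  w <- rbind(makeWell(rep = 1, p = 1 - exp(-100 * 0.00085), dilution = 10),
             makeWell(rep = 2, p = 1 - exp(-200 * 0.00085), dilution = 10))
  s <- rbind(makeSubsample(rep = 1), makeSubsample(rep = 2))
  res <- copiesPerGram(w, s, makeStomach())
  expect_equal(res$n_replicates, 2)
  expect_equal(res$copies_per_g, (1.2e7 + 2.4e7) / 2, tolerance = 1e-12)
})

test_that("all-zero replicates yield zero copies with below_detection", {
  w <- rbind(makeWell(rep = 1, p = 0), makeWell(rep = 2, p = 0))
  s <- rbind(makeSubsample(rep = 1), makeSubsample(rep = 2))
  res <- copiesPerGram(w, s, makeStomach())
  expect_equal(res$copies_per_g, 0)
  expect_match(res$flags, "below_detection")
})

test_that("empty stomachs are normalized by the 0.01 g convention", {
  w <- makeWell(p = 1 - exp(-100 * 0.00085), dilution = 10)
  res <- copiesPerGram(w, makeSubsample(), makeStomach(empty = TRUE))
  # denominator 0.01 g instead of 0.05 g -> 5x the worked example
  expect_equal(res$copies_per_g, 1.2e7 * 5, tolerance = 1e-12)
})

test_that("QC-failed replicates are dropped; all failing is an error", {
  wBad <- makeWell(rep = 1, p = 0.3, nTotal = 9000)
  wGood <- makeWell(rep = 2, p = 1 - exp(-100 * 0.00085), nTotal = 20000)
  wGood$dilution <- 10
  s <- rbind(makeSubsample(rep = 1), makeSubsample(rep = 2))
  res <- copiesPerGram(rbind(wBad, wGood), s, makeStomach())
  expect_equal(res$n_replicates, 1)
  expect_equal(res$copies_per_g, 1.2e7, tolerance = 1e-12)
  expect_match(res$flags, "qc_droplet_count")
  expect_error(copiesPerGram(wBad, makeSubsample(), makeStomach()),
               "all replicates failed.*s1-r1")
})

test_that("plate controls gate the run", {
  wells <- data.frame(
    well_id = c("w1", "w2", "w3"),
    role = c("ntc", "positive", "sample"),
    n_total = 20000, n_positive = c(0, 500, 100))
  ok <- checkControls(wells)
  expect_true(ok$valid)
  expect_false(ok$contamination_suspect)
  # contaminated blank
  wells2 <- rbind(wells, data.frame(well_id = "w4", role = "blank",
                                    n_total = 20000, n_positive = 50))
  expect_true(checkControls(wells2)$contamination_suspect)
  # dead positive control invalidates the run
  wells3 <- wells; wells3$n_positive[2] <- 0
  expect_false(checkControls(wells3)$valid)
  # missing controls are configuration errors
  expect_error(checkControls(wells[wells$role != "ntc", ]), "NTC")
  expect_error(checkControls(wells[wells$role != "positive", ]),
               "positive control")
})

test_that("primer-mix arithmetic: 2.2 pmol in 22 ul is 100 nM", {
  expect_equal(primerFinalConcentration(2.2, 22), 100)
})
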