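test_that("hit calling credits the SEM under the default rule", {
  meas <- data.frame(
    compound_id = c("a", "b", "c"),
    concentration_uM = 10,
    inhibition_pct = c(50, 0, 18),
    sem_pct = c(5, 0, 3), n = 3L)
  flags <- callHits(meas)
  expect_equal(flags$hit_10, c(TRUE, FALSE, TRUE))  # 18 + 3 = 21 >= 20
  flags_mean <- callHits(meas, rule = "mean")
  expect_equal(flags_mean$hit_10, c(TRUE, FALSE, FALSE))
  flags_cons <- callHits(meas, rule = "mean_minus_sem")
  expect_equal(flags_cons$hit_10, c(TRUE, FALSE, FALSE))
  # duplicate (compound, concentration) rows are an input error
  expect_error(callHits(rbind(meas, meas[1, ])), "duplicate")
})

test_that("overall hit spans concentrations", {
  meas <- data.frame(
    compound_id = rep(c("a", "b", "c"), each = 2),
    concentration_uM = rep(c(10, 50), 3),
    inhibition_pct = c(5, 60, 30, 80, 2, 3),
    sem_pct = 0, n = 3L)
  flags <- callHits(meas)
  expect_equal(flags$hit_10, c(FALSE, TRUE, FALSE))
  expect_equal(flags$hit_50, c(TRUE, TRUE, FALSE))
  expect_equal(flags$hit_any, c(TRUE, TRUE, FALSE))
})

test_that("hit rates reproduce the screening arithmetic at one decimal", {
  n <- 66
  flags <- data.frame(
    compound_id = sprintf("c%02d", seq_len(n)),
    hit_10 = seq_len(n) %in% c(1:39, 62, 63),  # 41 hits
    hit_50 = seq_len(n) <= 61)                 # 61 hits
  flags$hit_any <- flags$hit_10 | flags$hit_50  # 63 hits
  rates <- hitRate(flags)
  expect_equal(unname(rates["hit_10"]), 62.1)   # 41/66
  expect_equal(unname(rates["hit_50"]), 92.4)   # 61/66
  expect_equal(unname(rates["overall"]), 95.5)  # 63/66
  # zero hits
  none <- data.frame(compound_id = letters[1:5], hit_10 = FALSE,
                     hit_any = FALSE)
  expect_equal(unname(hitRate(none)["hit_10"]), 0.0)
})

test_that("raising the hit threshold never raises a rate", {
  set.seed(31)
  meas <- data.frame(
    compound_id = rep(sprintf("c%02d", 1:40), each = 2),
    concentration_uM = rep(c(10, 50), 40),
    inhibition_pct = stats::runif(80, -5, 95),
    sem_pct = stats::runif(80, 0, 8), n = 3L)
  prev <- NULL
  for (th in c(10, 20, 30, 50)) {
    r <- hitRate(callHits(meas, thresholdPct = th))
    if (!is.null(prev)) expect_true(all(r <= prev))
    prev <- r
  }
})

test_that("closed-form two-point inversion hits forced anchor cases", {
  # y = 50 at x forces IC50 = x; the second point then forces h = 1
  est <- estimateIC50TwoPoint(50, 250 / 3, 10, 50)
  expect_equal(est$ic50, 10, tolerance = 1e-12)
  expect_equal(est$hill, 1, tolerance = 1e-12)
  expect_equal(est$flag, "ok")
  # forward-simulated (IC50 = 25, h = 2), inverted
  est2 <- estimateIC50TwoPoint(logistic3pl(10, 25, 2), logistic3pl(50, 25, 2))
  expect_equal(est2$ic50, 25, tolerance = 1e-9)
  expect_equal(est2$hill, 2, tolerance = 1e-9)
})

test_that("degenerate response pairs are flagged, not estimated", {
  expect_equal(estimateIC50TwoPoint(0, 0)$flag, "no_inhibition")
  expect_equal(estimateIC50TwoPoint(-3, -1)$flag, "no_inhibition")
  expect_equal(estimateIC50TwoPoint(0, 40)$flag, "out_of_range")
  expect_equal(estimateIC50TwoPoint(40, 100)$flag, "out_of_range")
  expect_equal(estimateIC50TwoPoint(60, 40)$flag, "out_of_range")  # non-monotone
  expect_true(is.na(estimateIC50TwoPoint(60, 40)$ic50))
  expect_error(estimateIC50TwoPoint(10, 50, xLow = 50, xHigh = 10), "xLow")
})

test_that("closed form agrees with an iterative 3PL fit on the same points", {
  skip_if_not_installed("minpack.lm")
  grid <- expand.grid(ic50 = c(2, 10, 40, 120, 400), hill = c(0.5, 1, 2, 3.5))
  for (i in seq_len(nrow(grid))) {
    y1 <- logistic3pl(10, grid$ic50[i], grid$hill[i])
    y2 <- logistic3pl(50, grid$ic50[i], grid$hill[i])
    closed <- estimateIC50TwoPoint(y1, y2)
    df <- data.frame(x = c(10, 50), y = c(y1, y2))
    fit <- minpack.lm::nlsLM(y ~ 100 / (1 + (ic50 / x)^h), data = df,
                             start = list(ic50 = 30, h = 1),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    expect_equal(closed$ic50, unname(co["ic50"]), tolerance = 1e-6)
    expect_equal(closed$hill, unname(co["h"]), tolerance = 1e-6)
  }
})

test_that("potency fractions use a strict cutoff over active compounds", {
  est <- data.frame(ic50 = c(10, 60), flag = c("ok", "ok"))
  expect_equal(potencySummary(est), 50.0)
  est2 <- data.frame(ic50 = c(80, 120, NA), flag = c("ok", "ok", "no_inhibition"))
  expect_equal(potencySummary(est2), 0.0)
  # exactly-at-cutoff does not count as potent; flagged rows leave the denominator
  est3 <- data.frame(ic50 = c(50, 49.9, NA), flag = c("ok", "ok", "no_inhibition"))
  expect_equal(potencySummary(est3), 50.0)
  expect_error(potencySummary(data.frame(ic50 = NA, flag = "no_inhibition")),
               "no successfully")
})

test_that("assay table reading validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(compound_id = "a", concentration_uM = 10,
                              inhibition_pct = 50, sem_pct = 2, n = 3),
                   path, row.names = FALSE)
  expect_silent(readAssayTable(path))
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(compound_id = "a", concentration_uM = -10,
                              inhibition_pct = 50, sem_pct = 2, n = 3),
                   path2, row.names = FALSE)
  expect_error(readAssayTable(path2), "positive")
})
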