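test_that("inter-seizure intervals are successive onset gaps in hours", {
  d <- SeizureDiary("a", onset_s = c(0, 3, 7.5) * 3600, duration_s = 60,
                    recordingEnd = dayS)
  expect_equal(interSeizureIntervals(d), c(3, 4.5))
  expect_error(interSeizureIntervals(makeDiary(onsetDays = 1)), "2 events")

  # pooled histogram: two animals with disjoint single-bin ISIs get equal mass
  a <- SeizureDiary("a", onset_s = seq(0, 10, by = 1) * 3600,
                    duration_s = 60, recordingEnd = dayS)
  b <- SeizureDiary("b", onset_s = seq(0, 20, by = 4)[1:4] * 3600,
                    duration_s = 60, recordingEnd = dayS)
  h <- isiHistogram(SeizureCohort(list(a, b)), breaks = c(0, 1.5, 3, 4.5))
  expect_equal(h$mass[h$binStart == 0], 0.5)
  expect_equal(h$mass[h$binStart == 3], 0.5)
})

test_that("exponentiality test calibrates, rejects degenerate data, reproduces", {
  # degenerate: identical intervals are maximally non-exponential
  r <- lillieforsExponential(rep(2.5, 40), nMC = 2000, seed = 3)
  expect_lt(r$pValue, 0.001)
  # D for a point mass at the (estimated) mean: |exp(-1) - 0| bound
  expect_gt(r$D, 0.5)

  expect_error(lillieforsExponential(c(1, -1, 2, 3, 4)), "positive")
  expect_error(lillieforsExponential(c(1, 2, 3, 4)), "at least 5")
  expect_error(lillieforsExponential(1:10, nMC = 10), "1000")

  ra <- lillieforsExponential(c(1, 3, 2, 8, 5, 4, 9, 2, 1, 7), nMC = 1000, seed = 7)
  rb <- lillieforsExponential(c(1, 3, 2, 8, 5, 4, 9, 2, 1, 7), nMC = 1000, seed = 7)
  expect_identical(ra, rb)
})

test_that("Monte-Carlo p-values are uniform under the exponential null", {
  set.seed(123)
  pv <- vapply(1:400, function(i)
    lillieforsExponential(rexp(30), nMC = 1000, seed = 5000 + i)$pValue,
    numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("clustered (self-exciting) diaries are detected as non-Poisson", {
  # clusters must be tight relative to the mean interval for per-animal
  # interval tests to see them: 2 h excitation kernel vs ~6 h mean ISI
  cfg <- simulatorConfig(nAnimals = 100, excitationGain = 0.5,
                         excitationTimescaleH = 2,
                         suppressionGain = 0, circadianAmplitude = 0,
                         weeklyShape = c(1, 1, 1, 1), inductionSuccessP = 1,
                         logRateMean = log(5), logRateSd = 0.3, seed = 77)
  co <- simulateCohort(cfg)
  isis <- interSeizureIntervals(co)
  isis <- isis[vapply(isis, length, integer(1)) >= 100]
  expect_gt(length(isis), 30)
  rej <- vapply(seq_along(isis), function(i)
    lillieforsExponential(isis[[i]], nMC = 1000, seed = 600 + i)$pValue < 0.01,
    logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("peri-seizure histogram applies the stated edge correction", {
  # two events half a day apart
  d <- makeDiary("a", onsetDays = c(0, 0.5), epoch = "first_seizure",
                 recEndDays = 29)
  r <- periSeizureHistogram(SeizureCohort(list(d, d2 = makeDiary("b", c(0, 0.5),
                                               epoch = "first_seizure",
                                               recEndDays = 29))))
  expect_equal(r$rawCounts[1, 1], 1)
  # corrected 1/29.5, then normalised by the animal's 2 events
  expect_equal(unname(r$perAnimal[1, 1]), (1 / 29.5) / 2, tolerance = 1e-12)

  # three events at 0, 10, 20 days: bins centred 10.5 and 20.5
  d3 <- makeDiary("c", onsetDays = c(0, 10, 20), epoch = "first_seizure",
                  recEndDays = 29)
  r3 <- periSeizureHistogram(SeizureCohort(list(d3, d3b = makeDiary("d",
                               c(0, 10, 20), epoch = "first_seizure",
                               recEndDays = 29))),
                             maxLagDays = 21)
  expect_equal(r3$rawCounts[1, 11], 2)  # lags 10, 10
  expect_equal(r3$rawCounts[1, 21], 1)  # lag 20
  expect_equal(unname(r3$perAnimal[1, 11]), (2 / (30 - 10.5)) / 3)
  expect_equal(unname(r3$perAnimal[1, 21]), (1 / (30 - 20.5)) / 3)
})

test_that("closed-form uniform baseline matches brute-force resampling", {
  set.seed(88)
  n <- 10; T <- 30; B <- 10000
  vals <- matrix(0, B, 7)
  for (b in seq_len(B)) {
    t <- sort(runif(n, 0, T))
    p <- outer(t, t, "-"); lag <- p[p > 0]
    raw <- vapply(0:6, function(k) sum(lag >= k & lag < k + 1), numeric(1))
    vals[b, ] <- raw / (T - (0:6 + 0.5)) / n
  }
  expected <- uniformExpectation(n, 1, T)
  for (k in 1:7) {
    se <- sd(vals[, k]) / sqrt(B)
    expect_lt(abs(mean(vals[, k]) - expected), 2 * se + 1e-12)
  }
  # the correction exactly flattens the triangular pair-lag density:
  # same closed-form value for every bin, and it vanishes as T grows
  expect_equal(uniformExpectation(2, 1, 30), uniformExpectation(2, 1, 30))
  expect_lt(uniformExpectation(10, 1, 1e9), 1e-8)
})

test_that("per-bin t-tests do not reject on homogeneous Poisson cohorts", {
  set.seed(52)
  rej <- t(vapply(1:60, function(i) {
    co <- makePoissonCohort(30)
    r <- suppressMessages(periSeizureHistogram(co))
    r$bins$pValue < 0.01
  }, logical(7)))
  # per-bin type-I error near its nominal 1% level ...
  expect_lt(mean(rej), 0.025)
  # ... so the clean-run fraction is near its implied ~0.95
  expect_gte(mean(rowSums(rej) == 0), 0.9)
})

test_that("daily counts bin events into half-open days", {
  d <- SeizureDiary("a", onset_s = c(100, 2000, 30000), duration_s = 60,
                    epoch = "first_seizure", recordingEnd = 31 * dayS)
  dc <- dailyCounts(d)
  expect_equal(dc[1], 3)
  expect_equal(sum(dc), 3)
  expect_length(dc, 30)

  co <- simulateCohort(simulatorConfig(nAnimals = 5, seed = 13))
  for (dd in diaries(co)) {
    if (nSeizures(dd) < 1) next
    t <- diaryEvents(rebaseEpoch(dd, "first_seizure"))$onset_s / dayS
    expect_equal(sum(dailyCounts(dd)), sum(t >= 0 & t < 30))
  }

  # shifting the origin by whole days shifts bins, not counts in them
  d2 <- SeizureDiary("b", onset_s = c(2, 2.6, 5.1) * dayS, duration_s = 60,
                     epoch = "first_seizure", recordingEnd = 31 * dayS)
  d2r <- rebaseEpoch(SeizureDiary("b", onset_s = c(0, 0.6, 3.1) * dayS,
                                  duration_s = 60, epoch = "first_seizure",
                                  recordingEnd = 31 * dayS), "first_seizure")
  expect_equal(dailyCounts(d2)[3:8], dailyCounts(d2r)[1:6])
})

test_that("Durbin-Levinson pacf matches direct normal-equation solves", {
  set.seed(31)
  for (i in 1:50) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.5)), sample(40:120, 1)))
    expect_equal(partialAutocorrelation(x, 5), pacfBySolve(x, 5),
                 tolerance = 1e-6)
  }
  # and the installed reference implementation
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 500))
  expect_equal(partialAutocorrelation(x, 7),
               as.numeric(stats::pacf(x, lag.max = 7, plot = FALSE)$acf),
               tolerance = 1e-8)
})

test_that("pacf recovers autoregressive structure", {
  set.seed(61)
  x <- as.numeric(arima.sim(list(ar = 0.6), 1e5))
  p <- partialAutocorrelation(x, 3)
  ols <- pacfByOLS(x, 3)
  expect_lt(abs(p[1] - 0.6), 0.01)
  expect_lt(abs(p[2]), 0.01)
  expect_lt(max(abs(p - ols)), 0.01)

  w <- rnorm(1e5)
  expect_lt(max(abs(partialAutocorrelation(w, 5))), 0.01)

  x2 <- as.numeric(arima.sim(list(ar = c(0.5, -0.35)), 1e5))
  p2 <- partialAutocorrelation(x2, 2)
  expect_gt(p2[1], 0)
  expect_lt(p2[2], 0)
  expect_lt(max(abs(p2 - pacfByOLS(x2, 2))), 0.01)

  expect_error(partialAutocorrelation(rep(2, 100), 5), "constant")
  expect_error(partialAutocorrelation(rnorm(20), 7), "length")
})

test_that("cohort pacf aggregates per-animal coefficients with t-tests", {
  co <- simulateCohort(simulatorConfig(nAnimals = 20, seed = 19))
  r <- suppressMessages(cohortPacf(co))
  expect_true(all(abs(r$perAnimal) <= 1 + 1e-9))
  expect_equal(nrow(r$lags), 7)
  expect_equal(r$lags$meanCoef, unname(colMeans(r$perAnimal)))
})
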