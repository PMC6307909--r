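test_that("splitCounts uses the half-open [0,7)/[7,30) convention", {
  d <- makeDiary("a", onsetDays = seq(0.5, 29.5, by = 1),
                 epoch = "first_seizure")
  expect_equal(unname(splitCounts(d)), c(7, 23))

  d2 <- makeDiary("b", onsetDays = c(0, 1, 2), epoch = "first_seizure")
  expect_equal(unname(splitCounts(d2)), c(3, 0))

  d3 <- makeDiary("c", onsetDays = c(0, 7), epoch = "first_seizure")
  expect_equal(unname(splitCounts(d3)), c(1, 1))  # day 7.0 is "remaining"

  d4 <- makeDiary("d", onsetDays = c(0, 3), epoch = "first_seizure",
                  recEndDays = 20)
  expect_equal(attr(splitCounts(d4), "truncated"), 20)
})

test_that("linear-kernel GP posterior equals Bayesian linear regression", {
  set.seed(3)
  x <- rnorm(8, 2, 1); y <- 1 + 2 * x + rnorm(8, 0, 0.3)
  xs <- seq(0, 4, length.out = 9)
  for (h in list(c(1, 1, 0.1), c(10, 0.5, 0.01), c(0.2, 3, 1),
                 c(5, 0.05, 0.25))) {
    m <- fitGPLinear(x, y, hyper = h)
    got <- gpPosterior(m, xs)
    want <- blrPosterior(x, y, xs, h[1], h[2], h[3])
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sd, want$sd, tolerance = 1e-9)
    latent <- gpPosterior(m, xs, predictive = FALSE)
    wantL <- blrPosterior(x, y, xs, h[1], h[2], h[3], predictive = FALSE)
    expect_equal(latent$sd, wantL$sd, tolerance = 1e-9)
  }
})

test_that("linear data are interpolated and training targets approached", {
  x <- 1:5; y <- 2 * x + 1
  m <- fitGPLinear(x, y, hyper = c(100, 100, 1e-8))
  post <- gpPosterior(m, c(1.5, 3.7), predictive = FALSE)
  expect_equal(post$mean, 2 * c(1.5, 3.7) + 1, tolerance = 1e-3)
  # posterior reproduces training targets as noise -> 0
  expect_equal(gpPosterior(m, x, predictive = FALSE)$mean, y,
               tolerance = 1e-4)
})

test_that("marginal-likelihood fitting recovers simulated log-log structure", {
  co <- simulateCohort(simulatorConfig(nAnimals = 50, seed = 7))
  m <- suppressWarnings(suppressMessages(fitGPLinear(co)))
  expect_gt(m@pearson, 0.5)
  slope <- diff(gpPosterior(m, c(1, 3))$mean) / 2
  expect_lt(abs(slope - 1), 0.2)  # counts scale together with the rate
  # zero-first-week animals are excluded with a warning, not an error
  ds <- c(diaries(suppressMessages(rebaseEpoch(co, "first_seizure")))[1:5],
          list(z = SeizureDiary("z", onset_s = 10 * dayS, duration_s = 60,
                                epoch = "first_seizure",
                                recordingEnd = 31 * dayS)))
  expect_warning(fitGPLinear(SeizureCohort(ds)), "zero first-week")
})

test_that("interval probabilities behave as a coherent lognormal predictive", {
  set.seed(5)
  x <- log(rpois(12, 20) + 1); y <- x + rnorm(12, 1, 0.3)
  m <- fitGPLinear(x, y, hyper = c(1, 1, 0.09))
  xs <- c(2, 5, 10, 20)
  expect_equal(intervalProbability(m, xs, c(1e-9, 1e12)), rep(1, 4),
               tolerance = 1e-6)
  pN <- intervalProbability(m, xs, c(20, 100))
  pW <- intervalProbability(m, xs, c(20, 200))
  expect_true(all(pW >= pN))
  expect_true(all(pN >= 0 & pN <= 1))

  # vanishing predictive sd concentrates all mass at the posterior mean
  mm <- suppressWarnings(fitGPLinear(1:5, (1:5) * 0 + log(50), hyper = c(10, 10, 1e-8)))
  expect_gt(intervalProbability(mm, 3, c(45, 55)), 0.999)
  expect_error(intervalProbability(m, 3, c(100, 20)))
})

test_that("threshold interval is the >50% region of the probability curve", {
  co <- simulateCohort(simulatorConfig(nAnimals = 40, seed = 15))
  m <- suppressWarnings(suppressMessages(fitGPLinear(co)))
  th <- thresholdInterval(m, c(20, 100))
  manual <- th$curve$firstWeekCount[th$curve$probability > 0.5]
  expect_equal(th$counts, manual)
  if (length(manual)) expect_equal(th$range, range(manual))
  expect_true(th$contiguous)

  # widening the target interval never shrinks the enrollment set
  thW <- thresholdInterval(m, c(20, 200))
  expect_true(all(th$counts %in% thW$counts))

  # an unattainable target gives a legal empty result
  thE <- thresholdInterval(m, c(100000, 100001))
  expect_length(thE$counts, 0)
  expect_null(thE$range)
})

test_that("translation consistency: doubled counts shift the model with them", {
  set.seed(21)
  x <- log(rpois(30, 15) + 1); y <- x + rnorm(30, 0.8, 0.25)
  m1 <- fitGPLinear(x, y)
  m2 <- fitGPLinear(x + log(2), y + log(2))
  xs <- c(5, 10, 20)
  p1 <- intervalProbability(m1, xs, c(20, 100))
  p2 <- intervalProbability(m2, 2 * xs, c(40, 200))
  expect_equal(p1, p2, tolerance = 0.05)
})

test_that("enrollment report predicts per animal and balances arms", {
  co <- simulateCohort(simulatorConfig(nAnimals = 40, seed = 25))
  m <- suppressWarnings(suppressMessages(fitGPLinear(co)))
  tab <- suppressMessages(enrollmentReport(co, list(c(20, 100)), model = m))
  # identical first-week counts give identical predictions
  dupes <- split(seq_len(nrow(tab)), tab$firstWeek)
  for (idx in dupes)
    if (length(idx) > 1)
      expect_equal(var(tab$predictedMedian[idx]), 0)
  # interval widths ordered and positive
  expect_true(all(tab$lo95 < tab$lo50 & tab$lo50 < tab$predictedMedian &
                    tab$predictedMedian < tab$hi50 & tab$hi50 < tab$hi95))
  # ranked alternation: the two largest predictions are in different arms
  o <- order(-tab$predictedMedian)
  expect_true(tab$arm[o[1]] != tab$arm[o[2]])
  # arm balance of expected burden
  armMeans <- tapply(tab$predictedMedian, tab$arm, mean)
  expect_lt(abs(diff(armMeans)) / mean(armMeans), 0.1)
})
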