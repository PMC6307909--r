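# Fixtures are built in code: small hand-constructed diaries plus
# homogeneous-Poisson cohorts for null calibration.

dayS <- 86400

makeDiary <- function(id = "a1", onsetDays = c(3.5, 4), duration = 60,
                      semiology = NULL, epoch = "injection",
                      recEndDays = 40, clockOffset = 7) {
  SeizureDiary(id, onset_s = onsetDays * dayS, duration_s = duration,
               semiology = semiology, epoch = epoch,
               recordingStart = 0, recordingEnd = recEndDays * dayS,
               clockOffset = clockOffset)
}

# homogeneous Poisson diary on [0, TDays]: conditional on its count the
# event times are iid uniform, the null of the uniform-baseline tests
makePoissonDiary <- function(id, rate, TDays = 30) {
  n <- max(2, rpois(1, rate * TDays))
  t <- sort(runif(n, 0, TDays))
  SeizureDiary(id, onset_s = t * dayS, duration_s = 100,
               epoch = "first_seizure", recordingStart = 0,
               recordingEnd = (TDays + 1) * dayS, clockOffset = 7)
}

makePoissonCohort <- function(nAnimals = 30, rates = NULL, TDays = 30) {
  if (is.null(rates)) rates <- exp(rnorm(nAnimals, log(3), 0.5))
  SeizureCohort(lapply(seq_len(nAnimals), function(i)
    makePoissonDiary(sprintf("p%02d", i), rates[i], TDays)))
}

# Bayesian-linear-regression closed form: the independent oracle for the
# linear-kernel GP posterior (prior b ~ N(0, diag(sB2, sV2)), noise sN2).
blrPosterior <- function(x, y, xstar, sB2, sV2, sN2, predictive = TRUE) {
  X <- cbind(1, x)
  S0inv <- diag(1 / c(sB2, sV2))
  SN <- solve(S0inv + crossprod(X) / sN2)
  mN <- SN %*% crossprod(X, y) / sN2
  Xs <- cbind(1, xstar)
  mean <- as.numeric(Xs %*% mN)
  var <- rowSums((Xs %*% SN) * Xs) + if (predictive) sN2 else 0
  data.frame(x = xstar, mean = mean, sd = sqrt(var))
}

# Yule-Walker normal equations solved directly per order: the independent
# check of the Durbin-Levinson recursion.
pacfBySolve <- function(x, maxLag) {
  n <- length(x)
  xc <- x - mean(x)
  rho <- vapply(0:maxLag, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / n, numeric(1))
  rho <- rho / rho[1]
  vapply(seq_len(maxLag), function(k) {
    R <- stats::toeplitz(rho[1:k])
    as.numeric(solve(R, rho[2:(k + 1)]))[k]
  }, numeric(1))
}

# sequential OLS regression pacf: coefficient of the lag-k term when x_t is
# regressed on its k lagged values
pacfByOLS <- function(x, maxLag) {
  n <- length(x)
  vapply(seq_len(maxLag), function(k) {
    Y <- x[(k + 1):n]
    X <- vapply(seq_len(k), function(j) x[(k + 1 - j):(n - j)], numeric(n - k))
    unname(stats::coef(stats::lm(Y ~ X))[k + 1])
  }, numeric(1))
}

# literal 2^n sign-assignment enumeration of the signed-rank test
wilcoxonByEnumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.numeric(signs %*% r)
  pLow <- mean(Wall <= W + 1e-9)
  pHigh <- mean(Wall >= W - 1e-9)
  list(statistic = W, pValue = min(1, 2 * min(pLow, pHigh)))
}
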