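## Clustering/periodicity statistics: inter-seizure intervals, the
## Monte-Carlo Lilliefors test of exponentiality (Poisson-ness of the event
## process), the edge-corrected peri-seizure histogram with its uniform
## baseline, daily counts, and partial autocorrelation.

#' @export
setGeneric("interSeizureIntervals",
           function(x) standardGeneric("interSeizureIntervals"))

#' Inter-seizure intervals
#'
#' @param x a \code{SeizureDiary} with at least 2 events, or a
#'   \code{SeizureCohort} (diaries with fewer than 2 events are excluded
#'   with a note).
#' @return for a diary, the successive onset differences in hours; for a
#'   cohort, a named list of such vectors.
#' @export
setMethod("interSeizureIntervals", "SeizureDiary", function(x) {
  if (nSeizures(x) < 2) stop("at least 2 events are needed for ISIs")
  diff(x@events$onset_s) / 3600
})

#' @rdname interSeizureIntervals
#' @export
setMethod("interSeizureIntervals", "SeizureCohort", function(x) {
  lapply(.eventDiaries(x, minEvents = 2L), interSeizureIntervals)
})

#' Pooled per-animal-normalised ISI histogram
#'
#' Each animal's intervals are weighted by the reciprocal of its interval
#' count before pooling, so the histogram is an average of per-animal
#' distributions rather than being dominated by high-frequency animals.
#'
#' @param cohort a \code{SeizureCohort}.
#' @param breaks histogram breaks in hours (default 1.5 h bins up to the
#'   observed maximum).
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{mass}
#'   (sums to 1), \code{rawCount}.
#' @export
isiHistogram <- function(cohort, breaks = NULL) {
  isis <- interSeizureIntervals(cohort)
  v <- unlist(isis, use.names = FALSE)
  w <- unlist(lapply(isis, function(x) rep(1 / length(x), length(x))),
              use.names = FALSE)
  if (is.null(breaks)) breaks <- seq(0, ceiling(max(v) / 1.5) * 1.5, by = 1.5)
  bin <- findInterval(v, breaks, rightmost.closed = FALSE)
  bin[bin == 0 | bin >= length(breaks)] <- NA
  mass <- vapply(seq_len(length(breaks) - 1),
                 function(b) sum(w[which(bin == b)]), numeric(1))
  raw <- vapply(seq_len(length(breaks) - 1),
                function(b) sum(bin == b, na.rm = TRUE), numeric(1))
  data.frame(binStart = breaks[-length(breaks)], binEnd = breaks[-1],
             mass = mass / sum(mass), rawCount = raw)
}

## KS distance of a sample to Exp(mean = sample mean); columns of a matrix
## are handled together (vectorised over replicates).
.expKSDistance <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  n <- nrow(X); m <- ncol(X)
  Xs <- matrix(X[order(col(X), X)], n, m)  # column-wise sort
  mu <- colMeans(Xs)
  FF <- 1 - exp(-sweep(Xs, 2, mu, "/"))
  i <- seq_len(n)
  Dplus <- apply(i / n - FF, 2, max)
  Dminus <- apply(FF - (i - 1) / n, 2, max)
  pmax(Dplus, Dminus)
}

#' Lilliefors-type test of exponentiality with Monte-Carlo p-value
#'
#' Tests whether positive intervals are consistent with an exponential
#' distribution whose mean is estimated from the sample (the
#' Kolmogorov-Smirnov statistic is therefore not distribution-free in the
#' classical sense, and the null distribution is obtained by Monte Carlo:
#' exponential samples of the same size with the mean re-estimated in every
#' replicate). Under the null the statistic is scale-pivotal, so unit-rate
#' null draws suffice. A small p-value means the event process is not a
#' homogeneous Poisson process on the scale of these intervals.
#'
#' @param intervals positive numeric vector, length >= 5.
#' @param nMC Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @return list with \code{D} (the KS distance), \code{pValue} (with the
#'   \code{(1 + #exceedances)/(nMC + 1)} continuity adjustment), \code{n},
#'   \code{nMC}.
#' @export
lillieforsExponential <- function(intervals, nMC = 10000, seed = 1) {
  if (any(intervals <= 0)) stop("intervals must be positive")
  n <- length(intervals)
  if (n < 5) stop("at least 5 intervals are required")
  if (nMC < 1000) stop("nMC must be at least 1000")
  D <- .expKSDistance(intervals)
  set.seed(seed)
  nullD <- .expKSDistance(matrix(rexp(n * nMC), n, nMC))
  p <- (1 + sum(nullD >= D)) / (nMC + 1)
  list(D = D, pValue = p, n = n, nMC = as.integer(nMC))
}

#' Closed-form uniform baseline of the edge-corrected peri-seizure histogram
#'
#' For \code{n} events i.i.d. uniform on \code{[0, T]}, the expected number
#' of event pairs with lag in a bin of width \code{binDays} centred at
#' \code{c} is \code{n(n-1)/2 * ((T-c+b/2)^2 - (T-c-b/2)^2)/T^2 =
#' n(n-1) * b * (T-c)/T^2}; dividing by the edge-correction factor
#' \code{(T - c)} makes the expectation lag-independent:
#' \code{n(n-1) * binDays / T^2} per bin, or \code{(n-1) * binDays / T^2}
#' after normalising by the animal's event count. The 1/(T-c) correction is
#' thus exactly unbiasing for uniform (memoryless) event times.
#'
#' @param n number of events, or a \code{SeizureDiary} (its event count is
#'   used).
#' @param binDays bin width in days.
#' @param TDays recording span in days.
#' @param normalized divide by the event count (the per-animal
#'   normalisation)?
#' @return the per-bin expected corrected count (scalar; identical for all
#'   bins with centre < TDays).
#' @export
uniformExpectation <- function(n, binDays = 1, TDays = 30, normalized = TRUE) {
  if (is(n, "SeizureDiary")) n <- nSeizures(n)
  stopifnot(n >= 0, binDays > 0, TDays > 0)
  e <- n * (n - 1) * binDays / TDays^2
  if (normalized && n > 0) e / n else e
}

#' Edge-corrected peri-seizure histogram
#'
#' Counts the lags between seizure pairs (all ordered pairs by default, so
#' multi-day lags between non-consecutive seizures contribute) in half-open
#' day bins, and corrects each bin for the finite recording span: a lag near
#' the recording length can hardly ever be observed, so the count in the bin
#' centred at \code{c} days is divided by \code{TDays - c}. Per animal, the
#' corrected counts are normalised by the animal's total seizure count;
#' across animals each bin is compared with the closed-form uniform
#' (memoryless) baseline by a two-tailed one-sample t-test. Bins
#' significantly above baseline at short lags indicate clustering; bins
#' below baseline at longer lags indicate a post-cluster refractory period.
#'
#' @param cohort a \code{SeizureCohort} (diaries rebased internally to the
#'   first-seizure epoch).
#' @param binDays bin width (days).
#' @param TDays analysis window (days); lags beyond the last full bin are
#'   excluded, with a warning if the recording extends further.
#' @param maxLagDays largest lag bin analysed.
#' @param allPairs use all ordered pairs (default) or consecutive intervals
#'   only.
#' @return list with \code{perAnimal} (animal x bin matrix of normalised
#'   corrected counts), \code{bins} (data.frame: binStart, binCentre,
#'   meanCorrected, sem, baseline (cohort mean of per-animal baselines),
#'   tStat, pValue, pHolm), and \code{rawCounts}.
#' @export
periSeizureHistogram <- function(cohort, binDays = 1, TDays = 30,
                                 maxLagDays = 7, allPairs = TRUE) {
  stopifnot(is(cohort, "SeizureCohort"))
  ds <- .eventDiaries(cohort, minEvents = 2L)
  ds <- lapply(ds, rebaseEpochIfNeeded)
  starts <- seq(0, maxLagDays - binDays, by = binDays)
  centres <- starts + binDays / 2
  if (any(centres >= TDays)) stop("lag bins must lie inside the window")
  res <- lapply(ds, function(d) {
    t <- .days(d@events$onset_s)
    if (max(t) >= TDays) {
      warning(sprintf("diary %s extends beyond the %g-day window; later events excluded",
                      d@animalId, TDays))
      t <- t[t < TDays]
    }
    lags <- if (allPairs) {
      p <- outer(t, t, "-"); p[p > 0]
    } else diff(t)
    raw <- vapply(starts, function(s)
      sum(lags >= s & lags < s + binDays), numeric(1))
    corrected <- raw / (TDays - centres)
    n <- length(t)
    list(raw = raw, normCorrected = corrected / n,
         baseline = uniformExpectation(n, binDays, TDays, normalized = TRUE))
  })
  perAnimal <- t(vapply(res, `[[`, numeric(length(starts)), "normCorrected"))
  rawCounts <- t(vapply(res, `[[`, numeric(length(starts)), "raw"))
  baselines <- vapply(res, `[[`, numeric(1), "baseline")
  colnames(perAnimal) <- colnames(rawCounts) <-
    sprintf("lag%g_%g", starts, starts + binDays)
  tp <- vapply(seq_along(starts), function(b) {
    diffs <- perAnimal[, b] - baselines
    if (length(diffs) < 2 || sd(diffs) == 0)
      return(c(NA_real_, NA_real_))  # degenerate across animals
    tt <- t.test(diffs, mu = 0)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  bins <- data.frame(binStart = starts, binCentre = centres,
                     meanCorrected = colMeans(perAnimal),
                     sem = apply(perAnimal, 2, sd) / sqrt(nrow(perAnimal)),
                     baseline = mean(baselines),
                     tStat = tp[1, ], pValue = tp[2, ],
                     pHolm = p.adjust(tp[2, ], "holm"))
  list(perAnimal = perAnimal, bins = bins, rawCounts = rawCounts,
       baselinePerAnimal = baselines)
}

#' @export
setGeneric("dailyCounts", function(x, TDays = 30) standardGeneric("dailyCounts"))

#' Daily seizure counts
#'
#' Events per half-open day bin \code{[k, k+1)} since the first seizure.
#'
#' @param x a \code{SeizureDiary}.
#' @param TDays window length in days.
#' @return integer vector of length \code{TDays}; sums to the number of
#'   in-window events.
#' @export
setMethod("dailyCounts", "SeizureDiary", function(x, TDays = 30) {
  d <- .days(rebaseEpochIfNeeded(x)@events$onset_s)
  d <- d[d >= 0 & d < TDays]
  tabulate(floor(d) + 1, nbins = TDays)
})

#' Partial autocorrelation by Durbin-Levinson recursion
#'
#' Computes the partial autocorrelation function of a series from its sample
#' autocovariances via the Durbin-Levinson recursion. The lag-k coefficient
#' is the correlation between the series and its lag-k past after the
#' intermediate lags are regressed out; a positive lag-1 plus negative
#' lag-2 pattern in daily seizure counts indicates quasi-periodic
#' cluster/refractory alternation.
#'
#' @param x numeric series, length > 3 * maxLag.
#' @param maxLag largest lag.
#' @return numeric vector of coefficients for lags 1..maxLag.
#' @export
partialAutocorrelation <- function(x, maxLag = 7) {
  n <- length(x)
  if (n <= 3 * maxLag)
    stop("series length must exceed 3 x maxLag")
  if (sd(x) == 0) stop("constant series: partial autocorrelation undefined")
  xc <- x - mean(x)
  rho <- vapply(0:maxLag, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / n, numeric(1))
  rho <- rho / rho[1]  # autocorrelations, rho[k+1] = acf at lag k
  phi <- matrix(0, maxLag, maxLag)
  pacf <- numeric(maxLag)
  pacf[1] <- phi[1, 1] <- rho[2]
  if (maxLag > 1) {
    for (k in 2:maxLag) {
      num <- rho[k + 1] - sum(phi[k - 1, 1:(k - 1)] * rho[k:2])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[2:k])
      phi[k, k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] -
        phi[k, k] * phi[k - 1, (k - 1):1]
      pacf[k] <- phi[k, k]
    }
  }
  pacf
}

#' Cohort partial autocorrelation of daily seizure counts
#'
#' Per-animal \code{\link{partialAutocorrelation}} of the daily count
#' series, aggregated across animals with per-lag two-tailed one-sample
#' t-tests against zero.
#'
#' @param cohort a \code{SeizureCohort}.
#' @param maxLag largest lag in days.
#' @param TDays window for the daily count series.
#' @return list with \code{perAnimal} (animal x lag matrix) and \code{lags}
#'   (data.frame: lag, meanCoef, sem, tStat, pValue, pHolm). Animals with a
#'   constant count series are excluded with a message.
#' @export
cohortPacf <- function(cohort, maxLag = 7, TDays = 30) {
  ds <- .eventDiaries(cohort)
  series <- lapply(ds, dailyCounts, TDays = TDays)
  ok <- vapply(series, sd, numeric(1)) > 0
  if (!all(ok))
    message(sprintf("cohortPacf: excluding %d animal(s) with constant daily counts",
                    sum(!ok)))
  perAnimal <- t(vapply(series[ok], partialAutocorrelation, numeric(maxLag),
                        maxLag = maxLag))
  colnames(perAnimal) <- paste0("lag", seq_len(maxLag))
  tp <- vapply(seq_len(maxLag), function(k) {
    if (nrow(perAnimal) < 2 || sd(perAnimal[, k]) == 0)
      return(c(NA_real_, NA_real_))
    tt <- t.test(perAnimal[, k], mu = 0)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  list(perAnimal = perAnimal,
       lags = data.frame(lag = seq_len(maxLag), meanCoef = colMeans(perAnimal),
                         sem = apply(perAnimal, 2, sd) / sqrt(nrow(perAnimal)),
                         tStat = tp[1, ], pValue = tp[2, ],
                         pHolm = p.adjust(tp[2, ], "holm")))
}
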