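## Natural-history descriptives: latent period, induction rate, weekly
## frequency profile, cumulative distribution, and duration trajectory.
## Occurrence analyses run on the first_seizure epoch over a 30-day window;
## latency alone uses the injection epoch.

.days <- function(onset_s) onset_s / 86400

#' Latent period of one animal
#'
#' Time from the epileptogenic insult to the first spontaneous seizure.
#'
#' @param diary a \code{SeizureDiary} on the \code{"injection"} epoch.
#' @return latency in days, or \code{NA} (with a \code{"noSeizures"}
#'   attribute) for a seizure-free diary, which counts only in the induction
#'   denominator.
#' @export
latencyDays <- function(diary) {
  stopifnot(is(diary, "SeizureDiary"))
  if (diary@epoch != "injection")
    stop("latency is defined on the injection epoch")
  if (nSeizures(diary) == 0) {
    return(structure(NA_real_, noSeizures = TRUE))
  }
  .days(diary@events$onset_s[1])
}

#' Epilepsy induction rate of a cohort
#'
#' @param cohort a \code{SeizureCohort} of injected animals (seizure-free
#'   diaries included).
#' @return list with \code{percent} (100 x animals with seizures / injected),
#'   \code{nInjected}, \code{nWithSeizures}.
#' @export
inductionRate <- function(cohort) {
  stopifnot(is(cohort, "SeizureCohort"))
  if (length(cohort) == 0) stop("induction rate of an empty cohort is undefined")
  counts <- nSeizures(cohort)
  list(percent = 100 * sum(counts > 0) / length(counts),
       nInjected = length(counts), nWithSeizures = sum(counts > 0))
}

#' @export
setGeneric("weeklyPercentages",
           function(x, nWeeks = 4) standardGeneric("weeklyPercentages"))

#' Weekly percentage profile of seizure frequency
#'
#' Events are binned into half-open weeks \code{[7(k-1), 7k)} days since the
#' first seizure and expressed as a percentage of the animal's own total, so
#' animals with very different seizure burdens can be compared. Only complete
#' weeks inside the analysis window are used; events beyond \code{7*nWeeks}
#' days are dropped (with a message) and the percentages renormalised.
#'
#' @param x a \code{SeizureDiary} (non-empty) or \code{SeizureCohort}.
#' @param nWeeks number of weeks.
#' @return For a diary, a numeric vector of length \code{nWeeks} summing to
#'   100. For a cohort, a list with the per-animal \code{matrix} and a
#'   \code{summary} data.frame (mean, median, quartiles, Tukey 1.5 IQR
#'   whiskers per week).
#' @export
setMethod("weeklyPercentages", "SeizureDiary", function(x, nWeeks = 4) {
  if (nSeizures(x) == 0) stop("weekly percentages of a seizure-free diary")
  d <- .days(rebaseEpochIfNeeded(x)@events$onset_s)
  drop <- d >= 7 * nWeeks
  if (any(drop))
    message(sprintf("weeklyPercentages: %d event(s) beyond day %d dropped and percentages renormalised",
                    sum(drop), 7 * nWeeks))
  d <- d[!drop]
  if (length(d) == 0) stop("no events inside the weekly analysis window")
  counts <- vapply(seq_len(nWeeks),
                   function(k) sum(d >= 7 * (k - 1) & d < 7 * k), numeric(1))
  100 * counts / sum(counts)
})

rebaseEpochIfNeeded <- function(diary) {
  if (diary@epoch == "first_seizure") diary
  else rebaseEpoch(diary, "first_seizure")
}

#' @rdname weeklyPercentages
#' @export
setMethod("weeklyPercentages", "SeizureCohort", function(x, nWeeks = 4) {
  ds <- .eventDiaries(x)
  m <- t(vapply(ds, weeklyPercentages, numeric(nWeeks), nWeeks = nWeeks))
  colnames(m) <- paste0("week", seq_len(nWeeks))
  summ <- do.call(rbind, lapply(seq_len(nWeeks), function(k) {
    v <- m[, k]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    inlo <- v[v >= q[1] - 1.5 * iqr]
    inhi <- v[v <= q[3] + 1.5 * iqr]
    data.frame(week = k, mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
               whiskerLow = min(inlo), whiskerHigh = max(inhi),
               sem = sd(v) / sqrt(length(v)))
  }))
  list(matrix = m, summary = summ)
})

#' @export
setGeneric("cumulativeCurve",
           function(x, TDays = 30) standardGeneric("cumulativeCurve"))

#' Cumulative percentage distribution of seizures
#'
#' @param x a non-empty \code{SeizureDiary} or a \code{SeizureCohort}.
#' @param TDays analysis window (days since first seizure).
#' @return data.frame with \code{day} (0..TDays) and \code{cumPct}: the
#'   percentage of the animal's in-window seizures occurring before the end
#'   of each day; nondecreasing and ending at 100. For a cohort, columns
#'   \code{day}, \code{meanCumPct}, \code{sem} plus the per-animal matrix as
#'   attribute \code{"perAnimal"}.
#' @export
setMethod("cumulativeCurve", "SeizureDiary", function(x, TDays = 30) {
  if (nSeizures(x) == 0) stop("cumulative curve of a seizure-free diary")
  d <- .days(rebaseEpochIfNeeded(x)@events$onset_s)
  d <- d[d < TDays]
  grid <- 0:TDays
  cum <- vapply(grid, function(g) 100 * sum(d < g) / length(d), numeric(1))
  data.frame(day = grid, cumPct = cum)
})

#' @rdname cumulativeCurve
#' @export
setMethod("cumulativeCurve", "SeizureCohort", function(x, TDays = 30) {
  ds <- .eventDiaries(x)
  m <- vapply(ds, function(d) cumulativeCurve(d, TDays)$cumPct,
              numeric(TDays + 1))
  out <- data.frame(day = 0:TDays, meanCumPct = rowMeans(m),
                    sem = apply(m, 1, sd) / sqrt(ncol(m)))
  attr(out, "perAnimal") <- m
  out
})

#' @export
setGeneric("durationTrajectory",
           function(x, TDays = 30, windowDays = 1)
             standardGeneric("durationTrajectory"))

#' Daily median seizure duration since the first seizure
#'
#' @param x a non-empty \code{SeizureDiary} or a \code{SeizureCohort}.
#' @param TDays analysis window in days.
#' @param windowDays width of the (non-overlapping) day bins.
#' @return data.frame with \code{day} (bin start) and \code{medianDuration}
#'   in seconds; bins with no events carry \code{NA} (a gap, not zero). For
#'   a cohort, the across-animal mean of per-animal medians
#'   (\code{meanMedianDuration}, \code{sem}, \code{nAnimals} contributing).
#' @export
setMethod("durationTrajectory", "SeizureDiary",
          function(x, TDays = 30, windowDays = 1) {
  if (nSeizures(x) == 0) stop("duration trajectory of a seizure-free diary")
  d <- rebaseEpochIfNeeded(x)
  t <- .days(d@events$onset_s)
  starts <- seq(0, TDays - windowDays, by = windowDays)
  med <- vapply(starts, function(s) {
    v <- d@events$duration_s[t >= s & t < s + windowDays]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  data.frame(day = starts, medianDuration = med)
})

#' @rdname durationTrajectory
#' @export
setMethod("durationTrajectory", "SeizureCohort",
          function(x, TDays = 30, windowDays = 1) {
  ds <- .eventDiaries(x)
  m <- vapply(ds, function(d)
    durationTrajectory(d, TDays, windowDays)$medianDuration,
    numeric(length(seq(0, TDays - windowDays, by = windowDays))))
  data.frame(day = seq(0, TDays - windowDays, by = windowDays),
             meanMedianDuration = rowMeans(m, na.rm = TRUE),
             sem = apply(m, 1, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
             }),
             nAnimals = rowSums(!is.na(m)))
})

#' Natural-history summary of a cohort
#'
#' Bundles the descriptive panels: per-animal latency, induction rate,
#' daily count matrix, weekly percentage profile, cumulative curves and the
#' duration trajectory.
#'
#' @param cohort a \code{SeizureCohort} on the injection epoch.
#' @param TDays analysis window after the first seizure (days).
#' @return list with components \code{latency} (named vector, days;
#'   \code{NA} = seizure-free), \code{induction}, \code{dailyCounts}
#'   (animal x day matrix), \code{weekly}, \code{cumulative},
#'   \code{durationTrajectory}.
#' @export
naturalHistory <- function(cohort, TDays = 30) {
  stopifnot(is(cohort, "SeizureCohort"))
  lat <- vapply(cohort@diaries, function(d)
    if (nSeizures(d) == 0) NA_real_ else latencyDays(d), numeric(1))
  ind <- inductionRate(cohort)
  withEv <- rebaseEpoch(cohort, "first_seizure")
  dc <- t(vapply(withEv@diaries, function(d) dailyCounts(d, TDays),
                 numeric(TDays)))
  list(latency = lat, induction = ind, dailyCounts = dc,
       weekly = weeklyPercentages(withEv),
       cumulative = cumulativeCurve(withEv, TDays),
       durationTrajectory = durationTrajectory(withEv, TDays))
}
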