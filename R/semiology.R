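## Semiology tabulation and duration distributions.

## Half-up rounding to `digits` decimals (tabulated percentages convention;
## base round() is round-half-even).
roundHalfUp <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Semiology summary table
#'
#' Counts and percentages of the five behavioural seizure classes, plus the
#' per-class duration vectors. Every event must carry a label; behaviour not
#' visible on video is labelled \code{"unknown"}, not \code{NA}.
#'
#' @param x a \code{SeizureCohort}, \code{SeizureDiary}, or a named integer
#'   vector of per-class counts (order of \code{semiologyLevels()}) when only
#'   the tabulated counts are available.
#' @return list with \code{counts}, \code{percent} (1 decimal, half-up),
#'   \code{total}, and (when events are available) \code{durations}: a list
#'   of per-class duration vectors in seconds.
#' @export
semiologySummary <- function(x) {
  durations <- NULL
  if (is(x, "SeizureCohort")) {
    ev <- do.call(rbind, lapply(x@diaries, diaryEvents))
  } else if (is(x, "SeizureDiary")) {
    ev <- diaryEvents(x)
  } else if (is.numeric(x) && length(x) == 5) {
    counts <- as.integer(x)
    names(counts) <- .semiologyLevels
    pct <- roundHalfUp(100 * counts / sum(counts), 1)
    names(pct) <- .semiologyLevels
    return(list(counts = counts, percent = pct, total = sum(counts),
                durations = NULL))
  } else stop("x must be a cohort, a diary, or a 5-vector of class counts")
  if (nrow(ev) == 0) stop("no events to tabulate")
  if (anyNA(ev$semiology))
    stop("unlabelled event(s) present; label unobservable behaviour as 'unknown'")
  counts <- vapply(.semiologyLevels, function(l) sum(ev$semiology == l),
                   integer(1))
  durations <- lapply(.semiologyLevels,
                      function(l) ev$duration_s[ev$semiology == l])
  names(durations) <- .semiologyLevels
  pct <- roundHalfUp(100 * counts / sum(counts), 1)
  list(counts = counts, percent = pct, total = sum(counts),
       durations = durations)
}

## default histogram breaks: 5 s bins up to 150 s, then 25 s bins
.defaultDurationBreaks <- function(maxDur) {
  upper <- max(175, ceiling(maxDur / 25) * 25)
  c(seq(0, 150, by = 5), seq(175, upper, by = 25))
}

#' Seizure-duration histogram, optionally per-animal normalised
#'
#' In unnormalised mode all events are pooled. In normalised mode each event
#' is weighted by the reciprocal of its animal's total event count, so
#' high-frequency animals cannot dominate the shape of the distribution; the
#' weighted histogram is then scaled to total mass 1.
#'
#' @param cohort a \code{SeizureCohort}.
#' @param breaks histogram breaks in seconds; the default uses 5 s bins up
#'   to 150 s and 25 s bins beyond.
#' @param perAnimalNormalized logical.
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{mass}
#'   (summing to 1) and \code{rawCount}.
#' @export
durationHistogram <- function(cohort, breaks = NULL,
                              perAnimalNormalized = FALSE) {
  stopifnot(is(cohort, "SeizureCohort"))
  ds <- .eventDiaries(cohort)
  dur <- unlist(lapply(ds, function(d) d@events$duration_s), use.names = FALSE)
  wts <- unlist(lapply(ds, function(d) rep(1 / nSeizures(d), nSeizures(d))),
                use.names = FALSE)
  if (is.null(breaks)) breaks <- .defaultDurationBreaks(max(dur))
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  bin <- findInterval(dur, breaks, rightmost.closed = FALSE)
  bin[bin == 0 | bin >= length(breaks)] <- NA  # outside the break range
  w <- if (perAnimalNormalized) wts else rep(1, length(dur))
  mass <- vapply(seq_len(length(breaks) - 1),
                 function(b) sum(w[which(bin == b)]), numeric(1))
  raw <- vapply(seq_len(length(breaks) - 1),
                function(b) sum(bin == b, na.rm = TRUE), numeric(1))
  data.frame(binStart = breaks[-length(breaks)], binEnd = breaks[-1],
             mass = mass / sum(mass), rawCount = raw)
}

#' Seizure duration versus preceding inter-seizure interval
#'
#' Pairs each event (from the second event of a diary on) with the interval
#' since the previous seizure and tests for monotone association with a
#' Spearman rank correlation whose p-value comes from a seeded permutation
#' null (durations permuted within animals).
#'
#' @param cohort a \code{SeizureCohort}.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{pairs} (data.frame: animal, isi_h, duration_s),
#'   \code{rho}, \code{pValue}. With fewer than 2 pairs, \code{rho} is
#'   \code{NA} and flagged \code{undefined}.
#' @export
durationVsISI <- function(cohort, nPerm = 2000, seed = 1) {
  stopifnot(is(cohort, "SeizureCohort"))
  ds <- .eventDiaries(cohort, minEvents = 2L)
  pairs <- do.call(rbind, lapply(ds, function(d) {
    t <- d@events$onset_s
    data.frame(animal = d@animalId, isi_h = diff(t) / 3600,
               duration_s = d@events$duration_s[-1])
  }))
  if (is.null(pairs) || nrow(pairs) < 2)
    return(list(pairs = pairs, rho = NA_real_, pValue = NA_real_,
                undefined = TRUE))
  rho <- cor(pairs$isi_h, pairs$duration_s, method = "spearman")
  set.seed(seed)
  groups <- split(seq_len(nrow(pairs)), pairs$animal)
  permRho <- vapply(seq_len(nPerm), function(i) {
    perm <- seq_len(nrow(pairs))
    for (idx in groups) perm[idx] <- idx[sample.int(length(idx))]
    cor(pairs$isi_h, pairs$duration_s[perm], method = "spearman")
  }, numeric(1))
  p <- (1 + sum(abs(permRho) >= abs(rho))) / (nPerm + 1)
  list(pairs = pairs, rho = rho, pValue = p, undefined = FALSE)
}
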