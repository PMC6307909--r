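#' @import methods
#' @importFrom stats rexp runif rnorm rlnorm rbinom rpois sd quantile median
#'   pexp pnorm qnorm optim cor t.test ks.test complete.cases p.adjust
#' @importFrom utils read.csv write.csv head tail
NULL

## Semiology vocabulary used throughout: five behavioural classes following
## the ILAE-style focal/generalised split used for rodent video scoring.
.semiologyLevels <- c("non_motor", "unilateral_motor", "bilateral_motor",
                      "gtcs", "unknown")

#' Semiology class labels
#'
#' The five behavioural seizure classes recognised by the package:
#' non-motor focal, unilateral motor, bilateral motor, secondarily
#' generalized tonic-clonic, and unknown (behaviour not visible on video).
#'
#' @return Character vector of the five labels, in canonical order.
#' @export
semiologyLevels <- function() .semiologyLevels

.epochLevels <- c("injection", "first_seizure")

#' SeizureDiary: the event record of one animal
#'
#' An ordered list of electrographic seizure events (onset and duration in
#' seconds) for a single animal, together with the recording window, the
#' light-cycle metadata needed to map onsets to wall-clock hours, and the
#' time origin ("epoch") the onsets are measured from: either the
#' epileptogenic insult (\code{"injection"}) or the first spontaneous
#' seizure (\code{"first_seizure"}).
#'
#' @slot animalId single animal identifier.
#' @slot strain rat strain label.
#' @slot events data.frame with columns \code{onset_s} (seconds since the
#'   epoch, ascending), \code{duration_s} (seconds) and \code{semiology}
#'   (one of \code{semiologyLevels()} or \code{NA}).
#' @slot epoch \code{"injection"} or \code{"first_seizure"}.
#' @slot recordingStart,recordingEnd recording window, seconds since epoch.
#' @slot lightsOn,lightsOff hour-of-day the lights switch (defaults 7, 19).
#' @slot clockOffset wall-clock hour-of-day at the epoch (t = 0), needed to
#'   place events on the 24-h clock.
#' @name SeizureDiary-class
#' @aliases SeizureDiary-class
#' @exportClass SeizureDiary
setClass("SeizureDiary",
  representation(
    animalId = "character",
    strain = "character",
    events = "data.frame",
    epoch = "character",
    recordingStart = "numeric",
    recordingEnd = "numeric",
    lightsOn = "numeric",
    lightsOff = "numeric",
    clockOffset = "numeric"
  )
)

setValidity("SeizureDiary", function(object) {
  msg <- character()
  ev <- object@events
  if (length(object@animalId) != 1L || !nzchar(object@animalId))
    msg <- c(msg, "animalId must be a single non-empty string")
  if (!(object@epoch %in% .epochLevels))
    msg <- c(msg, sprintf("epoch must be one of %s",
                          paste(.epochLevels, collapse = ", ")))
  if (!all(c("onset_s", "duration_s", "semiology") %in% names(ev)))
    msg <- c(msg, "events must have columns onset_s, duration_s, semiology")
  else {
    if (nrow(ev) > 0) {
      if (is.unsorted(ev$onset_s, strictly = TRUE))
        msg <- c(msg, "event onsets must be strictly increasing")
      if (any(ev$duration_s <= 0))
        msg <- c(msg, "event durations must be positive")
      if (any(ev$onset_s < object@recordingStart - 1e-9) ||
          any(ev$onset_s > object@recordingEnd + 1e-9))
        msg <- c(msg, "all onsets must fall inside the recording window")
      bad <- !is.na(ev$semiology) & !(ev$semiology %in% .semiologyLevels)
      if (any(bad))
        msg <- c(msg, sprintf("unknown semiology label(s): %s",
                              paste(unique(ev$semiology[bad]), collapse = ", ")))
    }
  }
  if (object@recordingEnd - object@recordingStart <= 0)
    msg <- c(msg, "recording window must have positive length")
  if (object@clockOffset < 0 || object@clockOffset >= 24)
    msg <- c(msg, "clockOffset must lie in [0, 24)")
  if (length(msg)) msg else TRUE
})

#' Construct a SeizureDiary
#'
#' @param animalId animal identifier.
#' @param onset_s numeric vector of event onsets, seconds since the epoch.
#' @param duration_s numeric vector of event durations in seconds.
#' @param semiology optional character vector of class labels
#'   (see \code{\link{semiologyLevels}}); \code{NA} allowed.
#' @param epoch time origin the onsets refer to: \code{"injection"} or
#'   \code{"first_seizure"}.
#' @param recordingStart,recordingEnd recording window in seconds since the
#'   epoch.
#' @param lightsOn,lightsOff light-cycle switch hours (12/12 h cycle by
#'   default: lights on 07:00, off 19:00).
#' @param clockOffset wall-clock hour-of-day at t = 0.
#' @param strain strain label.
#' @return A validated \code{SeizureDiary}; events are sorted by onset.
#' @export
SeizureDiary <- function(animalId, onset_s = numeric(), duration_s = numeric(),
                         semiology = NULL, epoch = "injection",
                         recordingStart = 0,
                         recordingEnd = max(30 * 86400, onset_s, 1),
                         lightsOn = 7, lightsOff = 19, clockOffset = lightsOn,
                         strain = "SD") {
  n <- length(onset_s)
  if (length(duration_s) == 1L) duration_s <- rep(duration_s, n)
  if (is.null(semiology)) semiology <- rep(NA_character_, n)
  stopifnot(length(duration_s) == n, length(semiology) == n)
  o <- order(onset_s)
  ev <- data.frame(onset_s = as.numeric(onset_s)[o],
                   duration_s = as.numeric(duration_s)[o],
                   semiology = as.character(semiology)[o],
                   stringsAsFactors = FALSE)
  new("SeizureDiary", animalId = as.character(animalId),
      strain = as.character(strain), events = ev, epoch = epoch,
      recordingStart = as.numeric(recordingStart),
      recordingEnd = as.numeric(recordingEnd),
      lightsOn = as.numeric(lightsOn), lightsOff = as.numeric(lightsOff),
      clockOffset = as.numeric(clockOffset))
}

#' SeizureCohort: a labelled collection of diaries
#'
#' @slot diaries list of \code{SeizureDiary}, unique \code{animalId}s.
#' @slot label cohort label.
#' @name SeizureCohort-class
#' @aliases SeizureCohort-class
#' @exportClass SeizureCohort
setClass("SeizureCohort",
  representation(diaries = "list", label = "character"))

setValidity("SeizureCohort", function(object) {
  msg <- character()
  ok <- vapply(object@diaries, is, logical(1), class2 = "SeizureDiary")
  if (!all(ok)) msg <- c(msg, "all elements of diaries must be SeizureDiary")
  else {
    ids <- vapply(object@diaries, function(d) d@animalId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate animalId: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeizureCohort
#'
#' @param diaries list of \code{SeizureDiary} objects.
#' @param label cohort label.
#' @return A validated \code{SeizureCohort}; diaries are named by animal id.
#' @export
SeizureCohort <- function(diaries = list(), label = "cohort") {
  obj <- new("SeizureCohort", diaries = unname(diaries),
             label = as.character(label))
  names(obj@diaries) <- vapply(obj@diaries, function(d) d@animalId,
                               character(1))
  obj
}

## ---- generics -------------------------------------------------------------

#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @export
setGeneric("diaryEvents", function(x) standardGeneric("diaryEvents"))
#' @export
setGeneric("diaries", function(x) standardGeneric("diaries"))
#' @export
setGeneric("nSeizures", function(x) standardGeneric("nSeizures"))
#' @export
setGeneric("diaryEpoch", function(x) standardGeneric("diaryEpoch"))
#' @export
setGeneric("recordingWindow", function(x) standardGeneric("recordingWindow"))
#' @export
setGeneric("rebaseEpoch", function(x, epoch) standardGeneric("rebaseEpoch"))
#' @export
setGeneric("clockHour", function(x, onset_s) standardGeneric("clockHour"))

#' @describeIn SeizureDiary-class animal identifier.
#' @param x a \code{SeizureDiary} or \code{SeizureCohort}.
#' @export
setMethod("animalId", "SeizureDiary", function(x) x@animalId)

#' @describeIn SeizureCohort-class animal identifiers of all diaries.
#' @param x a \code{SeizureCohort}.
#' @export
setMethod("animalId", "SeizureCohort",
          function(x) vapply(x@diaries, animalId, character(1)))

#' @describeIn SeizureDiary-class event table (onset_s, duration_s, semiology).
#' @export
setMethod("diaryEvents", "SeizureDiary", function(x) x@events)

#' @describeIn SeizureCohort-class list of member diaries.
#' @export
setMethod("diaries", "SeizureCohort", function(x) x@diaries)

#' @describeIn SeizureDiary-class number of recorded events.
#' @export
setMethod("nSeizures", "SeizureDiary", function(x) nrow(x@events))

#' @describeIn SeizureCohort-class per-animal event counts.
#' @export
setMethod("nSeizures", "SeizureCohort",
          function(x) vapply(x@diaries, nSeizures, integer(1)))

#' @describeIn SeizureDiary-class time origin, "injection" or "first_seizure".
#' @export
setMethod("diaryEpoch", "SeizureDiary", function(x) x@epoch)

#' @describeIn SeizureDiary-class recording window c(start, end) in seconds.
#' @export
setMethod("recordingWindow", "SeizureDiary",
          function(x) c(start = x@recordingStart, end = x@recordingEnd))

setMethod("show", "SeizureDiary", function(object) {
  cat(sprintf("SeizureDiary '%s' (%s): %d events, epoch=%s\n",
              object@animalId, object@strain, nrow(object@events),
              object@epoch))
  cat(sprintf("  recording window [%.2f, %.2f] days; lights %g-%g h; clock offset %.2f h\n",
              object@recordingStart / 86400, object@recordingEnd / 86400,
              object@lightsOn, object@lightsOff, object@clockOffset))
  if (nrow(object@events)) {
    cat(sprintf("  first/last onset: %.2f / %.2f days; median duration %.0f s\n",
                object@events$onset_s[1] / 86400,
                tail(object@events$onset_s, 1) / 86400,
                median(object@events$duration_s)))
  }
})

setMethod("show", "SeizureCohort", function(object) {
  n <- length(object@diaries)
  counts <- if (n) nSeizures(object) else integer()
  cat(sprintf("SeizureCohort '%s': %d animals, %d events (%d seizure-free)\n",
              object@label, n, sum(counts), sum(counts == 0)))
})

#' Length of a cohort
#' @param x a \code{SeizureCohort}.
#' @return number of diaries.
#' @export
setMethod("length", "SeizureCohort", function(x) length(x@diaries))

#' Extract one diary
#' @param x a \code{SeizureCohort}.
#' @param i index or animal id.
#' @return the \code{SeizureDiary}.
#' @export
setMethod("[[", "SeizureCohort", function(x, i) x@diaries[[i]])

## Diaries with >= minEvents events; seizure-free (or too-sparse) animals are
## excluded from event-based analyses with a note, but stay in the cohort for
## induction-rate arithmetic.
.eventDiaries <- function(cohort, minEvents = 1L, quiet = FALSE) {
  keep <- vapply(cohort@diaries, nSeizures, integer(1)) >= minEvents
  if (!all(keep) && !quiet)
    message(sprintf("excluding %d diar%s with < %d events: %s",
                    sum(!keep), if (sum(!keep) == 1) "y" else "ies", minEvents,
                    paste(names(cohort@diaries)[!keep], collapse = ", ")))
  cohort@diaries[keep]
}
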