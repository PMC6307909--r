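## Reading, writing and time-coordinate operations on seizure diaries.
##
## On-disk format: an events CSV (animal_id, onset_s [or onset_iso],
## duration_s, semiology) plus a metadata CSV (animal_id, strain, epoch,
## recording_start_s, recording_end_s, clock_offset_h, lights_on_clock_h,
## lights_off_clock_h). Internally all times are seconds since the diary's
## epoch; occurrence analyses convert to days or clock hours as needed.

.MIN_DURATION_S <- 10  # inclusion criterion: ictal discharges >= 10 s

#' Read a seizure cohort from events + metadata CSVs
#'
#' @param eventsFile CSV with columns \code{animal_id}, \code{onset_s} (or
#'   \code{onset_iso}, ISO-8601 datetimes), \code{duration_s}, and optionally
#'   \code{semiology}.
#' @param metaFile CSV with columns \code{animal_id}, \code{strain},
#'   \code{epoch}, \code{recording_start_s}, \code{recording_end_s},
#'   \code{clock_offset_h}, \code{lights_on_clock_h},
#'   \code{lights_off_clock_h}. When the events file uses \code{onset_iso},
#'   the metadata must instead carry \code{recording_start_iso} and
#'   \code{recording_end_iso}; onsets are converted to seconds from the
#'   recording start and \code{clock_offset_h} is derived from its
#'   time of day.
#' @param strict if \code{TRUE} (default) events shorter than 10 s are
#'   dropped (the electrographic inclusion criterion); if \code{FALSE} they
#'   are kept and flagged in the load report.
#' @param label cohort label.
#' @return A \code{SeizureCohort} with attribute \code{"loadReport"}: a list
#'   with \code{nDropped}, \code{dropped} (the offending rows) and
#'   \code{nKeptShort}.
#' @export
readCohort <- function(eventsFile, metaFile, strict = TRUE, label = "cohort") {
  meta <- read.csv(metaFile, stringsAsFactors = FALSE)
  need <- c("animal_id", "strain", "epoch")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$animal_id))
    stop("duplicate animal_id in metadata: ",
         paste(unique(meta$animal_id[duplicated(meta$animal_id)]),
               collapse = ", "))
  ev <- read.csv(eventsFile, stringsAsFactors = FALSE)
  if (nrow(ev) == 0 && !("animal_id" %in% names(ev)))
    ev <- data.frame(animal_id = character(), onset_s = numeric(),
                     duration_s = numeric())
  isoMode <- "onset_iso" %in% names(ev)
  if (isoMode) {
    if (!all(c("recording_start_iso", "recording_end_iso") %in% names(meta)))
      stop("onset_iso events require recording_start_iso/recording_end_iso metadata")
    startT <- as.POSIXct(meta$recording_start_iso, tz = "UTC")
    endT <- as.POSIXct(meta$recording_end_iso, tz = "UTC")
    meta$recording_start_s <- 0
    meta$recording_end_s <- as.numeric(difftime(endT, startT, units = "secs"))
    lt <- as.POSIXlt(startT)
    meta$clock_offset_h <- lt$hour + lt$min / 60 + lt$sec / 3600
    if (nrow(ev)) {
      idx <- match(ev$animal_id, meta$animal_id)
      if (anyNA(idx))
        stop("events reference unknown animal_id: ",
             paste(unique(ev$animal_id[is.na(idx)]), collapse = ", "))
      t0 <- as.POSIXct(ev$onset_iso, tz = "UTC")
      if (anyNA(t0)) {
        bad <- which(is.na(t0))
        stop("unparseable onset_iso at events row ", bad[1])
      }
      ev$onset_s <- as.numeric(difftime(t0, startT[idx], units = "secs"))
    } else ev$onset_s <- numeric()
  }
  for (col in c("onset_s", "duration_s")) {
    if (!(col %in% names(ev)))
      stop("events file missing column: ", col)
    v <- suppressWarnings(as.numeric(ev[[col]]))
    if (nrow(ev) && anyNA(v))
      stop("malformed ", col, " at events row ", which(is.na(v))[1])
    ev[[col]] <- v
  }
  if (!("semiology" %in% names(ev))) ev$semiology <- NA_character_
  ev$semiology[!is.na(ev$semiology) & ev$semiology == ""] <- NA_character_
  bad <- !is.na(ev$semiology) & !(ev$semiology %in% .semiologyLevels)
  if (any(bad))
    stop("unknown semiology label at events row ", which(bad)[1],
         ": '", ev$semiology[which(bad)[1]], "'")

  short <- !is.na(ev$duration_s) & ev$duration_s < .MIN_DURATION_S
  report <- list(nDropped = 0L, dropped = ev[short, , drop = FALSE],
                 nKeptShort = 0L)
  if (strict && any(short)) {
    report$nDropped <- sum(short)
    message(sprintf("readCohort: %d event(s) below the %g s minimum duration dropped",
                    sum(short), .MIN_DURATION_S))
    ev <- ev[!short, , drop = FALSE]
  } else if (!strict && any(short)) {
    report$nKeptShort <- sum(short)
    warning(sprintf("readCohort: %d event(s) below the %g s minimum duration kept (strict = FALSE)",
                    sum(short), .MIN_DURATION_S))
  }

  ds <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    e <- ev[ev$animal_id == m$animal_id, , drop = FALSE]
    SeizureDiary(animalId = m$animal_id,
                 onset_s = e$onset_s, duration_s = e$duration_s,
                 semiology = e$semiology, epoch = m$epoch,
                 recordingStart = m$recording_start_s,
                 recordingEnd = m$recording_end_s,
                 lightsOn = m$lights_on_clock_h %||% 7,
                 lightsOff = m$lights_off_clock_h %||% 19,
                 clockOffset = m$clock_offset_h,
                 strain = m$strain)
  })
  unknownAnimals <- setdiff(unique(ev$animal_id), meta$animal_id)
  if (length(unknownAnimals))
    stop("events reference animal_id absent from metadata: ",
         paste(unknownAnimals, collapse = ", "))
  out <- SeizureCohort(ds, label = label)
  attr(out, "loadReport") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write a cohort to events + metadata CSVs
#'
#' Inverse of \code{\link{readCohort}}: for a valid cohort,
#' \code{readCohort(writeCohort(...))} reproduces every event field exactly.
#'
#' @param cohort a \code{SeizureCohort}.
#' @param eventsFile,metaFile output paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, eventsFile, metaFile) {
  evs <- do.call(rbind, lapply(cohort@diaries, function(d) {
    e <- d@events
    if (nrow(e) == 0)
      return(data.frame(animal_id = character(), onset_s = numeric(),
                        duration_s = numeric(), semiology = character()))
    data.frame(animal_id = d@animalId, onset_s = e$onset_s,
               duration_s = e$duration_s, semiology = e$semiology)
  }))
  meta <- do.call(rbind, lapply(cohort@diaries, function(d) {
    data.frame(animal_id = d@animalId, strain = d@strain, epoch = d@epoch,
               recording_start_s = d@recordingStart,
               recording_end_s = d@recordingEnd,
               clock_offset_h = d@clockOffset,
               lights_on_clock_h = d@lightsOn,
               lights_off_clock_h = d@lightsOff)
  }))
  ## full-precision numerics so the round trip is bit-exact
  fmt <- function(df) {
    for (cl in names(df))
      if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
    df
  }
  write.csv(fmt(evs), eventsFile, row.names = FALSE, quote = FALSE, na = "")
  write.csv(fmt(meta), metaFile, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(events = eventsFile, meta = metaFile))
}

#' @describeIn SeizureDiary-class shift the time origin of a diary.
#'
#' All onsets, the recording window and the clock offset are shifted
#' consistently so the chosen epoch sits at t = 0; the wall-clock hour of
#' every event is unchanged. Rebasing a seizure-free diary to
#' \code{"first_seizure"} is an error.
#'
#' @param epoch target epoch, \code{"injection"} or \code{"first_seizure"}.
#' @export
setMethod("rebaseEpoch", "SeizureDiary", function(x, epoch) {
  epoch <- match.arg(epoch, .epochLevels)
  if (x@epoch == epoch) return(x)
  if (epoch == "first_seizure") {
    if (nrow(x@events) == 0)
      stop("cannot rebase a seizure-free diary to the first_seizure epoch (",
           x@animalId, ")")
    shift <- x@events$onset_s[1]
  } else {
    stop("rebasing from first_seizure back to injection requires the ",
         "injection time, which the diary no longer carries")
  }
  x@events$onset_s <- x@events$onset_s - shift
  x@recordingStart <- x@recordingStart - shift
  x@recordingEnd <- x@recordingEnd - shift
  x@clockOffset <- (x@clockOffset + shift / 3600) %% 24
  x@epoch <- epoch
  validObject(x)
  x
})

#' @describeIn SeizureCohort-class rebase every (non-empty) diary; seizure-free
#'   diaries are dropped with a message when the target is first_seizure.
#' @export
setMethod("rebaseEpoch", "SeizureCohort", function(x, epoch) {
  epoch <- match.arg(epoch, .epochLevels)
  ds <- x@diaries
  if (epoch == "first_seizure") ds <- .eventDiaries(x, 1L)
  SeizureCohort(lapply(ds, rebaseEpoch, epoch = epoch), label = x@label)
})

#' @describeIn SeizureDiary-class wall-clock hour-of-day of an onset:
#'   \code{(clockOffset + onset_s/3600) mod 24}. \code{onset_s} defaults to
#'   all event onsets of the diary.
#' @param onset_s onset time(s) in seconds since the diary's epoch.
#' @export
setMethod("clockHour", "SeizureDiary", function(x, onset_s) {
  if (missing(onset_s)) onset_s <- x@events$onset_s
  (x@clockOffset + onset_s / 3600) %% 24
})

#' Is a clock hour inside the lights-on (sleep) phase?
#'
#' @param diary a \code{SeizureDiary} (supplies the lights-on/off hours).
#' @param hour clock hour(s) in [0, 24).
#' @return logical vector; \code{TRUE} for hours in the half-open lights-on
#'   interval. Handles light phases that wrap midnight.
#' @export
isLightPhase <- function(diary, hour) {
  on <- diary@lightsOn; off <- diary@lightsOff
  if (on <= off) hour >= on & hour < off else hour >= on | hour < off
}
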