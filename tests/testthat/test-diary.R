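test_that("loader applies the 10 s duration criterion and reports drops", {
  evf <- withr::local_tempfile(fileext = ".csv")
  mtf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,onset_s,duration_s,semiology",
               "r1,1000,60,non_motor",
               "r1,2000,8,unknown",
               "r1,3000,120,gtcs"), evf)
  writeLines(c(paste("animal_id,strain,epoch,recording_start_s,recording_end_s,",
                     "clock_offset_h,lights_on_clock_h,lights_off_clock_h", sep = ""),
               "r1,SD,injection,0,86400,7,7,19"), mtf)
  co <- suppressMessages(readCohort(evf, mtf, strict = TRUE))
  expect_equal(nSeizures(co[["r1"]]), 2L)
  expect_equal(attr(co, "loadReport")$nDropped, 1L)
  expect_equal(attr(co, "loadReport")$dropped$duration_s, 8)

  expect_warning(co2 <- readCohort(evf, mtf, strict = FALSE), "kept")
  expect_equal(nSeizures(co2[["r1"]]), 3L)
})

test_that("seizure-free diaries load and unsorted input equals sorted input", {
  evf <- withr::local_tempfile(fileext = ".csv")
  mtf <- withr::local_tempfile(fileext = ".csv")
  writeLines("animal_id,onset_s,duration_s,semiology", evf)
  writeLines(c("animal_id,strain,epoch,recording_start_s,recording_end_s,clock_offset_h,lights_on_clock_h,lights_off_clock_h",
               "r1,SD,injection,0,86400,7,7,19"), mtf)
  co <- readCohort(evf, mtf)
  expect_equal(nSeizures(co[["r1"]]), 0L)

  evf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,onset_s,duration_s,semiology",
               "r1,3000,120,gtcs", "r1,1000,60,non_motor"), evf2)
  co2 <- readCohort(evf2, mtf)
  expect_equal(diaryEvents(co2[["r1"]])$onset_s, c(1000, 3000))
})

test_that("loader rejects malformed rows, bad labels and duplicate ids", {
  evf <- withr::local_tempfile(fileext = ".csv")
  mtf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,onset_s,duration_s",
               "r1,1000,60", "r1,oops,70"), evf)
  writeLines(c("animal_id,strain,epoch,recording_start_s,recording_end_s,clock_offset_h,lights_on_clock_h,lights_off_clock_h",
               "r1,SD,injection,0,86400,7,7,19"), mtf)
  expect_error(readCohort(evf, mtf), "row 2")

  writeLines(c("animal_id,onset_s,duration_s,semiology",
               "r1,1000,60,blinking"), evf)
  expect_error(readCohort(evf, mtf), "semiology")

  writeLines(c("animal_id,strain,epoch,recording_start_s,recording_end_s,clock_offset_h,lights_on_clock_h,lights_off_clock_h",
               "r1,SD,injection,0,86400,7,7,19",
               "r1,SD,injection,0,86400,7,7,19"), mtf)
  writeLines("animal_id,onset_s,duration_s,semiology", evf)
  expect_error(readCohort(evf, mtf), "duplicate")

  expect_error(SeizureCohort(list(makeDiary("x"), makeDiary("x"))),
               "duplicate")
})

test_that("write/read round trip preserves event fields exactly", {
  set.seed(11)
  co <- simulateCohort(simulatorConfig(nAnimals = 4, seed = 5))
  evf <- withr::local_tempfile(fileext = ".csv")
  mtf <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, evf, mtf)
  co2 <- readCohort(evf, mtf)
  for (id in animalId(co)) {
    expect_identical(diaryEvents(co2[[id]])$onset_s,
                     diaryEvents(co[[id]])$onset_s)
    expect_identical(diaryEvents(co2[[id]])$duration_s,
                     diaryEvents(co[[id]])$duration_s)
    expect_identical(diaryEvents(co2[[id]])$semiology,
                     diaryEvents(co[[id]])$semiology)
  }
})

test_that("ISO-8601 events are converted to seconds and clock offsets", {
  evf <- withr::local_tempfile(fileext = ".csv")
  mtf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,onset_iso,duration_s,semiology",
               "r1,2020-01-01 10:30:00,60,non_motor"), evf)
  writeLines(c("animal_id,strain,epoch,recording_start_iso,recording_end_iso",
               "r1,SD,injection,2020-01-01 08:00:00,2020-01-10 08:00:00"), mtf)
  co <- readCohort(evf, mtf)
  d <- co[["r1"]]
  expect_equal(diaryEvents(d)$onset_s, 2.5 * 3600)
  expect_equal(clockHour(d), 10.5)
})

test_that("rebaseEpoch shifts onsets, window and clock offset consistently", {
  d <- makeDiary(onsetDays = c(3.5, 4), clockOffset = 10)
  r <- rebaseEpoch(d, "first_seizure")
  expect_equal(diaryEvents(r)$onset_s / dayS, c(0, 0.5))
  expect_equal(recordingWindow(r)[["start"]], -3.5 * dayS)
  # clock offset advances by the shift (3.5 d = 84 h): 10 + 84 mod 24 = 22
  expect_equal(r@clockOffset, 22)
  # idempotent
  expect_identical(rebaseEpoch(r, "first_seizure"), r)
  # 5.25 h first event: offset 10 -> 15.25
  d2 <- SeizureDiary("a2", onset_s = 5.25 * 3600, duration_s = 30,
                     recordingEnd = dayS, clockOffset = 10)
  expect_equal(rebaseEpoch(d2, "first_seizure")@clockOffset, 15.25)
  # seizure-free diary cannot be rebased
  empty <- SeizureDiary("a3", recordingEnd = dayS)
  expect_error(rebaseEpoch(empty, "first_seizure"), "seizure-free")
})

test_that("clockHour follows modular 24 h arithmetic and survives rebase", {
  d <- makeDiary(onsetDays = 0, clockOffset = 7, recEndDays = 2)
  expect_equal(clockHour(d, 0), 7)
  expect_equal(clockHour(d, 24 * 3600), 7)
  d2 <- makeDiary(onsetDays = 0, clockOffset = 23, recEndDays = 2)
  expect_equal(clockHour(d2, 2 * 3600), 1)

  d3 <- makeDiary(onsetDays = c(3.27, 9.113), clockOffset = 11)
  expect_equal(clockHour(rebaseEpoch(d3, "first_seizure")), clockHour(d3))
})

test_that("diary validity rejects inconsistent objects", {
  expect_error(SeizureDiary("a", onset_s = c(5, 5), duration_s = 30,
                            recordingEnd = 10),
               "strictly increasing")
  expect_error(SeizureDiary("a", onset_s = 20, duration_s = 30,
                            recordingEnd = 10), "recording window")
  expect_error(SeizureDiary("a", onset_s = 5, duration_s = -1,
                            recordingEnd = 10), "positive")
})
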