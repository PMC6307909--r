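## End-to-end orchestration: simulate (or load) a cohort, then run every
## analysis stage and write tidy per-stage CSVs plus a machine-readable
## summary with full provenance (config echo, seeds, package version).
## Identical config + seed => byte-identical summary.

#' Pipeline configuration
#'
#' @param eventsFile,metaFile input CSVs (see \code{\link{readCohort}});
#'   omit both to run on a simulated cohort.
#' @param simulator a \code{\link{simulatorConfig}} used when no input files
#'   are given.
#' @param TDays analysis window (days after first seizure).
#' @param seed master seed for every stochastic stage.
#' @param nMC Monte-Carlo replicates for the exponentiality test.
#' @param targetIntervals list of remaining-count target intervals for the
#'   prediction stage.
#' @param outDir output directory.
#' @return a named list (class \code{"pipelineConfig"}).
#' @export
pipelineConfig <- function(eventsFile = NULL, metaFile = NULL,
                           simulator = simulatorConfig(),
                           TDays = 30, seed = 1, nMC = 2000,
                           targetIntervals = list(c(20, 100), c(20, 200)),
                           outDir = tempfile("epidiary-run")) {
  structure(list(eventsFile = eventsFile, metaFile = metaFile,
                 simulator = simulator, TDays = TDays, seed = seed,
                 nMC = nMC, targetIntervals = targetIntervals,
                 outDir = outDir),
            class = "pipelineConfig")
}

.writeStage <- function(df, outDir, name) {
  path <- file.path(outDir, paste0(name, ".csv"))
  write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full diary-analysis pipeline
#'
#' Stages, in order: input (simulate or load), natural-history descriptives,
#' semiology, circadian profile with the day/night duration test, temporal
#' structure (ISI + exponentiality tests, edge-corrected peri-seizure
#' histogram, partial autocorrelation of daily counts), and GP count
#' prediction. Each stage writes a tidy CSV under \code{outDir}; a
#' \code{summary.json} collects the headline statistics and the provenance
#' block. Any stage failure aborts with the stage name; outputs of completed
#' stages are left in place.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the summary list (also written as JSON).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  summary <- list(provenance = list(
    package = "epidiary",
    version = as.character(utils::packageVersion("epidiary")),
    seed = config$seed, TDays = config$TDays, nMC = config$nMC,
    simulated = is.null(config$eventsFile)))
  res <- tryCatch({
    if (is.null(config$eventsFile)) {
      sim <- config$simulator
      sim@seed <- config$seed
      cohort <- simulateCohort(sim)
      summary$provenance$simulator <- list(
        nAnimals = sim@nAnimals, durationDays = sim@durationDays,
        excitationGain = sim@excitationGain,
        suppressionGain = sim@suppressionGain,
        circadianAmplitude = sim@circadianAmplitude)
    } else {
      if (is.null(config$metaFile) || !file.exists(config$metaFile))
        stop("metadata file missing: ", config$metaFile %||% "<NULL>")
      cohort <- readCohort(config$eventsFile, config$metaFile)
    }
    writeCohort(cohort, file.path(config$outDir, "events.csv"),
                file.path(config$outDir, "meta.csv"))

    stage <- "descriptives"
    nh <- naturalHistory(cohort, config$TDays)
    .writeStage(data.frame(animal = names(nh$latency),
                           latency_days = unname(nh$latency)),
                config$outDir, "latency")
    .writeStage(nh$weekly$summary, config$outDir, "weekly")
    .writeStage(nh$cumulative, config$outDir, "cumulative")
    .writeStage(nh$durationTrajectory, config$outDir, "duration_trajectory")
    summary$induction <- nh$induction
    summary$weeklyMeanPct <- unname(nh$weekly$summary$mean)

    stage <- "semiology"
    haveLabels <- all(vapply(.eventDiaries(cohort, quiet = TRUE), function(d)
      !anyNA(d@events$semiology), logical(1)))
    if (haveLabels) {
      sem <- semiologySummary(cohort)
      .writeStage(data.frame(class = names(sem$counts),
                             count = unname(sem$counts),
                             percent = unname(sem$percent)),
                  config$outDir, "semiology")
      summary$semiologyPercent <- as.list(sem$percent)
      dvi <- durationVsISI(cohort, seed = config$seed)
      summary$durationVsISI <- list(rho = dvi$rho, pValue = dvi$pValue)
    } else summary$semiologyPercent <- NULL

    stage <- "circadian"
    circ <- circadianProfile(cohort)
    .writeStage(circ$profile, config$outDir, "circadian_profile")
    wt <- dayNightDurationTest(cohort)
    summary$circadian <- list(peakHour = circ$peakHour,
                              meanLightPhaseFraction =
                                mean(circ$lightPhaseFraction),
                              dayNightWilcoxonP = wt$pValue)

    stage <- "temporal_structure"
    isis <- interSeizureIntervals(cohort)
    lill <- lapply(names(isis), function(a) {
      if (length(isis[[a]]) < 5) return(NULL)
      r <- lillieforsExponential(isis[[a]], nMC = config$nMC,
                                 seed = config$seed)
      data.frame(animal = a, n = r$n, D = r$D, pValue = r$pValue)
    })
    lill <- do.call(rbind, lill)
    .writeStage(lill, config$outDir, "isi_lilliefors")
    psh <- periSeizureHistogram(cohort, TDays = config$TDays)
    .writeStage(psh$bins, config$outDir, "periseizure")
    pac <- cohortPacf(cohort, TDays = config$TDays)
    .writeStage(pac$lags, config$outDir, "pacf")
    summary$temporal <- list(
      nLillieforsSignificant = sum(lill$pValue < 0.05),
      nLillieforsTested = nrow(lill),
      day1PeriSeizureP = psh$bins$pValue[1],
      pacf1 = pac$lags$meanCoef[1], pacf1P = pac$lags$pValue[1],
      pacf2 = pac$lags$meanCoef[2], pacf2P = pac$lags$pValue[2])

    stage <- "prediction"
    model <- suppressWarnings(fitGPLinear(cohort, TDays = config$TDays))
    enr <- enrollmentReport(cohort, config$targetIntervals, model = model,
                            TDays = config$TDays)
    .writeStage(enr, config$outDir, "enrollment")
    thr <- lapply(config$targetIntervals, function(iv) {
      th <- thresholdInterval(model, iv)
      list(interval = iv, range = th$range, contiguous = th$contiguous)
    })
    summary$prediction <- list(
      pearson = model@pearson,
      hyper = c(sigmaB2 = model@sigmaB2, sigmaV2 = model@sigmaV2,
                sigmaN2 = model@sigmaN2),
      thresholds = thr)
    summary
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(res, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(res)
}
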