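## Synthetic seizure-diary generator.
##
## Event times follow a multiplicatively modulated self-exciting (Hawkes-type)
## process with conditional intensity, in events/day,
##
##   lambda(t) = r_i * w(t) * c(clock(t)) *
##               (1 + sum_j gE exp(-(t-t_j)/tauE)
##                  - sum_j gS exp(-(t-t_j)/tauS))_+
##
## where r_i is an animal-level lognormal baseline rate, w a week-wise step
## profile of the epilepsy's rise and fall, c a raised-cosine circadian gate,
## the gE term produces within-24-h clustering and the slower gS term the
## post-cluster refractory dip. Kernel heights are normalised by r_i so that
## excitationGain is the branching ratio (expected extra events triggered
## per event) for every animal. Sampling is exact Ogata thinning with an
## adaptive bound (the excitation sum only decays between events, so
## r * max(w) * max(c) * (1 + E(now)) dominates the intensity until the next
## accepted event).

#' SimulatorConfig: parameters of the synthetic seizure-diary generator
#'
#' Defaults emulate a chronic occipital-cortex epilepsy cohort: a 3-7 day
#' latent period, week-wise frequency profile proportional to 26:24:36:12,
#' light-phase-dominant circadian modulation peaking mid light phase,
#' within-day self-excitation followed by a multi-day suppression,
#' bimodal (~20 s / ~110 s) lognormal durations that ramp up over the first
#' week, and an 84\% induction success rate.
#'
#' @slot nAnimals number of injected animals.
#' @slot durationDays analysis window after the first seizure (days).
#' @slot latencyDaysRange integer range of the latent period (days).
#' @slot logRateMean,logRateSd mean/sd of log baseline daily rate across
#'   animals (lognormal heterogeneity).
#' @slot weeklyShape relative multipliers for weeks 1-4 after seizure onset;
#'   normalised internally to mean 1.
#' @slot circadianAmplitude raised-cosine modulation depth in [0, 1].
#' @slot circadianPeakClockH clock hour of peak seizure rate.
#' @slot excitationGain,excitationTimescaleH branching ratio (expected extra
#'   events triggered per event) and e-folding time (hours) of the
#'   self-excitation kernel; \code{excitationGain < 1} for stability.
#' @slot suppressionGain,suppressionTimescaleD expected events suppressed
#'   per event and e-folding time (days) of the post-cluster suppression
#'   kernel.
#' @slot durationMix \code{c(weightShort, modeShort_s, modeLong_s, logSd)} of
#'   the two-component lognormal duration mixture.
#' @slot durationRampupDays days over which durations rise from ~40\% of
#'   plateau to plateau.
#' @slot semiologyProbs multinomial probabilities of the five semiology
#'   classes (order of \code{semiologyLevels()}).
#' @slot inductionSuccessP probability an injected animal develops seizures.
#' @slot seed integer master seed; per-animal substreams are derived from it.
#' @name SimulatorConfig-class
#' @aliases SimulatorConfig-class
#' @exportClass SimulatorConfig
setClass("SimulatorConfig",
  representation(
    nAnimals = "numeric", durationDays = "numeric",
    latencyDaysRange = "numeric",
    logRateMean = "numeric", logRateSd = "numeric",
    weeklyShape = "numeric",
    circadianAmplitude = "numeric", circadianPeakClockH = "numeric",
    excitationGain = "numeric", excitationTimescaleH = "numeric",
    suppressionGain = "numeric", suppressionTimescaleD = "numeric",
    durationMix = "numeric", durationRampupDays = "numeric",
    semiologyProbs = "numeric", inductionSuccessP = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulatorConfig", function(object) {
  msg <- character()
  if (object@nAnimals < 1) msg <- c(msg, "nAnimals must be >= 1")
  if (object@durationDays <= 0) msg <- c(msg, "durationDays must be positive")
  if (length(object@latencyDaysRange) != 2 ||
      object@latencyDaysRange[1] > object@latencyDaysRange[2] ||
      object@latencyDaysRange[1] < 0)
    msg <- c(msg, "latencyDaysRange must be a nondecreasing nonnegative pair")
  if (length(object@weeklyShape) != 4 || any(object@weeklyShape < 0))
    msg <- c(msg, "weeklyShape must be 4 nonnegative multipliers")
  if (object@circadianAmplitude < 0 || object@circadianAmplitude > 1)
    msg <- c(msg, "circadianAmplitude must lie in [0, 1]")
  if (object@excitationGain < 0 || object@excitationGain >= 1)
    msg <- c(msg, "excitationGain must lie in [0, 1) (stability)")
  if (object@suppressionGain < 0)
    msg <- c(msg, "suppressionGain must be nonnegative")
  if (object@excitationTimescaleH <= 0 || object@suppressionTimescaleD <= 0)
    msg <- c(msg, "kernel timescales must be positive")
  if (length(object@durationMix) != 4 || object@durationMix[1] < 0 ||
      object@durationMix[1] > 1 || any(object@durationMix[2:4] <= 0))
    msg <- c(msg, "durationMix must be (weight in [0,1], two positive modes, positive logSd)")
  if (length(object@semiologyProbs) != 5 || any(object@semiologyProbs < 0) ||
      abs(sum(object@semiologyProbs) - 1) > 1e-9)
    msg <- c(msg, "semiologyProbs must be 5 nonnegative values summing to 1")
  if (object@inductionSuccessP < 0 || object@inductionSuccessP > 1)
    msg <- c(msg, "inductionSuccessP must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulatorConfig
#'
#' See \code{\linkS4class{SimulatorConfig}} for slot meanings. Arguments
#' default to the study conditions the package emulates.
#'
#' @param nAnimals,durationDays,latencyDaysRange,logRateMean,logRateSd
#'   see class documentation.
#' @param weeklyShape,circadianAmplitude,circadianPeakClockH see class docs.
#' @param excitationGain,excitationTimescaleH,suppressionGain see class docs.
#' @param suppressionTimescaleD,durationMix,durationRampupDays see class docs.
#' @param semiologyProbs,inductionSuccessP,seed see class documentation.
#' @return a validated \code{SimulatorConfig}.
#' @export
simulatorConfig <- function(nAnimals = 10, durationDays = 30,
                            latencyDaysRange = c(3L, 7L),
                            logRateMean = log(2.5), logRateSd = 0.8,
                            weeklyShape = c(26, 24, 36, 12),
                            circadianAmplitude = 0.6,
                            circadianPeakClockH = 14.5,
                            excitationGain = 0.6, excitationTimescaleH = 10,
                            suppressionGain = 1.2, suppressionTimescaleD = 3,
                            durationMix = c(0.25, 20, 110, 0.25),
                            durationRampupDays = 7,
                            semiologyProbs = c(0.441, 0.186, 0.059, 0.206, 0.108),
                            inductionSuccessP = 0.84, seed = 1L) {
  new("SimulatorConfig", nAnimals = nAnimals, durationDays = durationDays,
      latencyDaysRange = as.numeric(latencyDaysRange),
      logRateMean = logRateMean, logRateSd = logRateSd,
      weeklyShape = as.numeric(weeklyShape),
      circadianAmplitude = circadianAmplitude,
      circadianPeakClockH = circadianPeakClockH,
      excitationGain = excitationGain,
      excitationTimescaleH = excitationTimescaleH,
      suppressionGain = suppressionGain,
      suppressionTimescaleD = suppressionTimescaleD,
      durationMix = as.numeric(durationMix),
      durationRampupDays = durationRampupDays,
      semiologyProbs = as.numeric(semiologyProbs),
      inductionSuccessP = inductionSuccessP, seed = as.numeric(seed))
}

setMethod("show", "SimulatorConfig", function(object) {
  cat(sprintf("SimulatorConfig: %d animals, %g-day window, latency %g-%g d\n",
              as.integer(object@nAnimals), object@durationDays,
              object@latencyDaysRange[1], object@latencyDaysRange[2]))
  cat(sprintf("  rate lognormal(%.2f, %.2f)/day; weekly shape %s\n",
              object@logRateMean, object@logRateSd,
              paste(object@weeklyShape, collapse = ":")))
  cat(sprintf("  circadian A=%.2f peak %.1f h; excitation g=%.2f tau=%g h; suppression g=%.2f tau=%g d\n",
              object@circadianAmplitude, object@circadianPeakClockH,
              object@excitationGain, object@excitationTimescaleH,
              object@suppressionGain, object@suppressionTimescaleD))
})

## step profile of weeks since seizure onset, normalised to mean 1
.weeklyMult <- function(tSinceOnsetDays, shape) {
  shape <- shape / mean(shape)
  idx <- pmin(floor(tSinceOnsetDays / 7) + 1, 4L)
  shape[pmax(idx, 1L)]
}

## raised-cosine circadian gate, mean 1 over the day
.circadianGate <- function(clockH, amplitude, peakH) {
  1 + amplitude * cos(2 * pi * (clockH - peakH) / 24)
}

#' Sample an inhomogeneous or self-exciting point process by thinning
#'
#' Classic acceptance-rejection (Ogata-style) thinning against a constant
#' dominating rate: candidate points are drawn from a homogeneous Poisson
#' process at \code{upperBound} and accepted with probability
#' \code{intensity(t, accepted)/upperBound}, visiting candidates in time
#' order so self-exciting intensities see the correct history.
#'
#' @param intensity function \code{(t, history)} returning the conditional
#'   intensity at time \code{t} (same time unit as \code{horizon}) given the
#'   accepted points so far; must never exceed \code{upperBound}.
#' @param horizon length of the observation window, starting at 0.
#' @param upperBound constant dominating rate.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return sorted numeric vector of accepted event times in (0, horizon].
#' @export
thinningSampler <- function(intensity, horizon, upperBound, seed = NULL) {
  stopifnot(horizon > 0, upperBound >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (upperBound == 0) return(numeric())
  times <- numeric()
  t <- 0
  repeat {
    t <- t + rexp(1, rate = upperBound)
    if (t > horizon) break
    lam <- intensity(t, times)
    if (lam > upperBound * (1 + 1e-12))
      stop(sprintf("intensity %.6g exceeds its stated bound %.6g at t = %.6g",
                   lam, upperBound, t))
    if (lam < 0) lam <- 0
    if (runif(1) < lam / upperBound) times <- c(times, t)
  }
  times
}

## One animal's event times (days since injection), exact adaptive thinning.
## Kernel heights are normalised by the animal's baseline rate so that the
## expected number of extra events triggered per event (the branching ratio)
## equals excitationGain irrespective of r_i; excitationGain < 1 then
## guarantees a subcritical, non-explosive process for every animal.
.simulateEventTimes <- function(rate, latency, durationDays, cfg, clockOffset) {
  tauE <- cfg@excitationTimescaleH / 24
  tauS <- cfg@suppressionTimescaleD
  gE <- cfg@excitationGain / (rate * tauE)
  gS <- cfg@suppressionGain / (rate * tauS)
  wMax <- max(cfg@weeklyShape / mean(cfg@weeklyShape))
  cMax <- 1 + cfg@circadianAmplitude
  ## the latent period ends with the first seizure: it falls on the drawn
  ## latency day, at a clock hour drawn (by rejection) from the circadian
  ## density, and the window of spontaneous recurrence runs from it
  repeat {
    h <- runif(1, 0, 24)
    if (runif(1) * cMax <= .circadianGate(h, cfg@circadianAmplitude,
                                          cfg@circadianPeakClockH)) break
  }
  first <- latency + ((h - clockOffset) %% 24) / 24
  end <- first + durationDays
  times <- first
  t <- first
  E <- gE; S <- gS  # excitation/suppression sums at time t
  maxEvents <- 50000L
  repeat {
    bound <- rate * wMax * cMax * (1 + E)
    t2 <- t + rexp(1, rate = bound)
    decay <- function(x, tau) x * exp(-(t2 - t) / tau)
    E2 <- decay(E, tauE); S2 <- decay(S, tauS)
    if (t2 > end) break
    lam <- rate * .weeklyMult(t2 - first, cfg@weeklyShape) *
      .circadianGate((clockOffset + t2 * 24) %% 24,
                     cfg@circadianAmplitude, cfg@circadianPeakClockH) *
      max(0, 1 + E2 - S2)
    if (lam > bound * (1 + 1e-9))
      stop("internal error: thinning bound violated")
    accept <- runif(1) < lam / bound
    t <- t2; E <- E2; S <- S2
    if (accept) {
      times <- c(times, t2)
      E <- E + gE; S <- S + gS
      if (length(times) >= maxEvents)
        stop("simulated diary exceeded ", maxEvents,
             " events; configuration appears unstable")
    }
  }
  times
}

## Bimodal lognormal durations with a saturating early ramp. The ramp starts
## at 40% of plateau (young epilepsies show ~40 s median) and approaches 1
## with e-folding time rampupDays/3, so the plateau is reached by ~rampupDays.
## Draws are truncated below at the 10 s inclusion criterion (shorter
## discharges are not scored as seizures), via the inverse CDF per event.
.simulateDurations <- function(tSinceOnsetDays, cfg) {
  n <- length(tSinceOnsetDays)
  if (n == 0) return(numeric())
  w <- cfg@durationMix[1]; sdl <- cfg@durationMix[4]
  muShort <- log(cfg@durationMix[2]) + sdl^2  # lognormal mode = exp(mu - s^2)
  muLong <- log(cfg@durationMix[3]) + sdl^2
  mu <- ifelse(runif(n) < w, muShort, muLong)
  f <- if (cfg@durationRampupDays > 0) {
    f0 <- 0.4
    f0 + (1 - f0) * (1 - exp(-tSinceOnsetDays / (cfg@durationRampupDays / 3)))
  } else rep(1, n)
  lo <- stats::plnorm(.MIN_DURATION_S / f, mu, sdl)
  u <- lo + runif(n) * (1 - lo)
  pmax(f * stats::qlnorm(pmin(u, 1 - 1e-12), mu, sdl), .MIN_DURATION_S)
}

#' Simulate a seizure cohort
#'
#' Draws one diary per animal from the modulated Hawkes process described in
#' \code{\linkS4class{SimulatorConfig}}. With probability
#' \code{1 - inductionSuccessP} an animal never develops seizures and
#' contributes an empty diary (it still counts in the induction denominator).
#' The latent period ends with the first seizure, which is placed exactly at
#' the drawn latency; durations are drawn truncated above the 10 s
#' electrographic inclusion criterion (shorter discharges would not be
#' scored as seizures). Deterministic for a fixed config seed; each animal
#' uses an independent substream derived from \code{(seed, animal index)}.
#'
#' @param config a \code{\link{simulatorConfig}}.
#' @return a \code{SeizureCohort} on the \code{"injection"} epoch; simulated
#'   animals are injected at midday (clock offset 12 h) under a 7 am - 7 pm
#'   light cycle.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  maxLat <- config@latencyDaysRange[2]
  recEnd <- (maxLat + 1 + config@durationDays) * 86400
  ds <- lapply(seq_len(as.integer(config@nAnimals)), function(i) {
    set.seed((as.integer(config@seed) + 104729L * i) %% 2147483647L)
    id <- sprintf("sim%03d", i)
    induced <- runif(1) < config@inductionSuccessP
    lat <- sample(seq(config@latencyDaysRange[1], config@latencyDaysRange[2]),
                  1)
    rate <- rlnorm(1, config@logRateMean, config@logRateSd)
    clockOffset <- 12
    if (!induced)
      return(SeizureDiary(id, epoch = "injection", recordingStart = 0,
                          recordingEnd = recEnd, clockOffset = clockOffset))
    tt <- .simulateEventTimes(rate, lat, config@durationDays, config,
                              clockOffset)
    dur <- .simulateDurations(tt - tt[1], config)
    sem <- sample(.semiologyLevels, length(tt), replace = TRUE,
                  prob = config@semiologyProbs)
    SeizureDiary(id, onset_s = tt * 86400, duration_s = dur, semiology = sem,
                 epoch = "injection", recordingStart = 0, recordingEnd = recEnd,
                 clockOffset = clockOffset)
  })
  SeizureCohort(ds, label = sprintf("simulated-seed%d",
                                    as.integer(config@seed)))
}
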