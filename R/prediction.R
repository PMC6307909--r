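## Prediction of remaining seizure burden from early counts: Gaussian-process
## regression with a linear kernel, fitted in log-log space.
##
## Kernel: k(x, x') = sigmaB2 + sigmaV2 * x * x', plus observation noise
## sigmaN2 on the diagonal. This GP is mathematically identical to Bayesian
## linear regression y = b0 + b1 x + eps with independent zero-mean Gaussian
## priors Var(b0) = sigmaB2, Var(b1) = sigmaV2 and noise variance sigmaN2 —
## the closed-form equivalence is the module's correctness oracle in the
## test suite.

#' GPCountModel: linear-kernel GP relating early to late seizure counts
#'
#' @slot x,y training pairs: natural-log first-week count and natural-log
#'   remaining-window count per animal.
#' @slot sigmaB2,sigmaV2,sigmaN2 bias variance, slope variance, and noise
#'   variance of the kernel.
#' @slot alpha cached \code{K^{-1} y}.
#' @slot Kinv cached inverse of the training covariance.
#' @slot pearson Pearson correlation of the training pairs.
#' @slot logMarginal log marginal likelihood at the fitted hyperparameters.
#' @slot animals animal ids of the training pairs.
#' @name GPCountModel-class
#' @aliases GPCountModel-class
#' @exportClass GPCountModel
setClass("GPCountModel",
  representation(x = "numeric", y = "numeric",
                 sigmaB2 = "numeric", sigmaV2 = "numeric", sigmaN2 = "numeric",
                 alpha = "numeric", Kinv = "matrix",
                 pearson = "numeric", logMarginal = "numeric",
                 animals = "character"))

setValidity("GPCountModel", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (any(c(object@sigmaB2, object@sigmaV2, object@sigmaN2) < 0))
    msg <- c(msg, "kernel variances must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GPCountModel", function(object) {
  cat(sprintf("GPCountModel: %d animals; k(x,x') = %.3g + %.3g x x', noise %.3g\n",
              length(object@x), object@sigmaB2, object@sigmaV2,
              object@sigmaN2))
  cat(sprintf("  Pearson r of log-log training pairs: %.3f; log marginal likelihood %.3f\n",
              object@pearson, object@logMarginal))
})

#' Split a diary's counts into first week and remaining window
#'
#' @param diary a \code{SeizureDiary} (rebased internally to the
#'   first-seizure epoch).
#' @param TDays analysis window in days; the split is the half-open
#'   \code{[0, 7)} / \code{[7, TDays)} convention, so an event at exactly
#'   day 7.0 counts as "remaining".
#' @return named vector \code{c(firstWeek, remaining)}; if the recording
#'   window is shorter than \code{TDays} an attribute \code{"truncated"}
#'   records the actual span.
#' @export
splitCounts <- function(diary, TDays = 30) {
  stopifnot(is(diary, "SeizureDiary"))
  d <- rebaseEpochIfNeeded(diary)
  t <- .days(d@events$onset_s)
  out <- c(firstWeek = sum(t >= 0 & t < 7),
           remaining = sum(t >= 7 & t < TDays))
  span <- (d@recordingEnd - max(d@recordingStart, d@events$onset_s[1])) / 86400
  if (span < TDays - 1e-9) attr(out, "truncated") <- span
  out
}

.gpKernel <- function(x1, x2, sigmaB2, sigmaV2) {
  sigmaB2 + sigmaV2 * outer(x1, x2)
}

.gpLogMarginal <- function(x, y, sigmaB2, sigmaV2, sigmaN2) {
  n <- length(x)
  K <- .gpKernel(x, x, sigmaB2, sigmaV2) + diag(sigmaN2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
}

#' Fit a linear-kernel Gaussian process to first-week / remaining counts
#'
#' Training pairs are \code{(log firstWeek, log remaining)} per animal;
#' animals whose first-week (or remaining) count is zero are excluded with a
#' warning, since their logarithm is undefined. Hyperparameters are chosen
#' by maximising the log marginal likelihood over a log-spaced multi-start
#' grid followed by local (L-BFGS-B) refinement, unless fixed values are
#' supplied (the reproducible-test mode).
#'
#' @param x a \code{SeizureCohort}, or a numeric vector of log first-week
#'   counts (then \code{y} must be given).
#' @param y optional numeric vector of log remaining counts.
#' @param TDays analysis window used by \code{\link{splitCounts}}.
#' @param hyper optional fixed \code{c(sigmaB2, sigmaV2, sigmaN2)}; when
#'   supplied no optimisation is done.
#' @param noiseFloor lower bound for \code{sigmaN2} during optimisation.
#' @return a \code{\linkS4class{GPCountModel}}.
#' @export
fitGPLinear <- function(x, y = NULL, TDays = 30, hyper = NULL,
                        noiseFloor = 1e-8) {
  if (is(x, "SeizureCohort")) {
    ds <- .eventDiaries(x)
    sc <- vapply(ds, splitCounts, numeric(2), TDays = TDays)
    ok <- sc[1, ] > 0 & sc[2, ] > 0
    if (!all(ok))
      warning(sprintf("excluding %d animal(s) with zero first-week or remaining counts (log undefined): %s",
                      sum(!ok), paste(colnames(sc)[!ok], collapse = ", ")))
    xv <- log(sc[1, ok]); yv <- log(sc[2, ok])
    animals <- names(ds)[ok]
  } else {
    xv <- x; yv <- y; animals <- character(length(xv))
    stopifnot(!is.null(y), length(x) == length(y))
  }
  if (length(xv) < 3) stop("at least 3 usable animals are required")
  if (is.null(hyper)) {
    grid <- expand.grid(b = log(c(1e-3, 1, 100)),
                        v = log(c(0.01, 1)),
                        n = log(c(0.05, 1)))
    obj <- function(p) -.gpLogMarginal(xv, yv, exp(p[1]), exp(p[2]),
                                       max(exp(p[3]), noiseFloor))
    best <- NULL
    for (i in seq_len(nrow(grid))) {
      p0 <- as.numeric(grid[i, ])
      fit <- tryCatch(
        optim(p0, obj, method = "L-BFGS-B",
              lower = c(-20, -20, log(noiseFloor)), upper = c(20, 20, 20)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    hyper <- pmax(exp(best$par), c(0, 0, noiseFloor))
  } else {
    stopifnot(length(hyper) == 3, all(hyper >= 0))
    hyper[3] <- max(hyper[3], noiseFloor)
  }
  n <- length(xv)
  K <- .gpKernel(xv, xv, hyper[1], hyper[2]) + diag(hyper[3], n)
  Kinv <- chol2inv(chol(K))
  new("GPCountModel", x = unname(xv), y = unname(yv),
      sigmaB2 = unname(hyper[1]), sigmaV2 = unname(hyper[2]),
      sigmaN2 = unname(hyper[3]),
      alpha = as.numeric(Kinv %*% yv), Kinv = Kinv,
      pearson = cor(xv, yv),
      logMarginal = .gpLogMarginal(xv, yv, hyper[1], hyper[2], hyper[3]),
      animals = animals)
}

#' Posterior of the fitted GP at new points
#'
#' @param object a \code{GPCountModel}.
#' @param xstar log first-week counts to predict at.
#' @param predictive include the observation-noise variance (the posterior
#'   predictive for a new animal) rather than the latent-function posterior.
#' @return data.frame with \code{x}, \code{mean}, \code{sd} on the log
#'   scale.
#' @export
gpPosterior <- function(object, xstar, predictive = TRUE) {
  stopifnot(is(object, "GPCountModel"))
  Ks <- .gpKernel(xstar, object@x, object@sigmaB2, object@sigmaV2)
  mean <- as.numeric(Ks %*% object@alpha)
  kss <- object@sigmaB2 + object@sigmaV2 * xstar^2
  var <- kss - rowSums((Ks %*% object@Kinv) * Ks)
  var <- pmax(var, 0) + if (predictive) object@sigmaN2 else 0
  data.frame(x = xstar, mean = mean, sd = sqrt(var))
}

#' Leave-one-out posterior predictive of a fitted GP
#'
#' The standard closed-form GP leave-one-out identities: for training pair i,
#' the predictive distribution obtained from the other n-1 pairs has mean
#' \code{y_i - [K^{-1}y]_i / [K^{-1}]_{ii}} and variance
#' \code{1 / [K^{-1}]_{ii}} (noise included). This is the calibration
#' diagnostic for the predictive intervals: for a well-calibrated model about
#' half the animals fall inside their central 50\% interval.
#'
#' @param model a \code{GPCountModel}.
#' @return data.frame with \code{x}, \code{y}, \code{mean}, \code{sd} and
#'   \code{inside50}: whether the held-out target lies inside the central
#'   50\% predictive interval.
#' @export
gpLooPredictive <- function(model) {
  stopifnot(is(model, "GPCountModel"))
  dK <- diag(model@Kinv)
  mu <- model@y - model@alpha / dK
  sd <- sqrt(1 / dK)
  data.frame(x = model@x, y = model@y, mean = mu, sd = sd,
             inside50 = abs(model@y - mu) <= qnorm(0.75) * sd)
}

#' Probability that the remaining count falls in a target interval
#'
#' Integrates the lognormal posterior predictive of the remaining count at a
#' given first-week count over a target interval \code{[a, b]}:
#' \code{pnorm((log b - m)/s) - pnorm((log a - m)/s)} with \code{m, s} the
#' posterior predictive mean and s.d. at \code{log x}.
#'
#' @param model a \code{GPCountModel}.
#' @param x first-week seizure count(s), >= 1 (counts, not logs).
#' @param interval \code{c(a, b)}, the target remaining-count interval,
#'   0 < a < b.
#' @return numeric vector of probabilities in [0, 1].
#' @export
intervalProbability <- function(model, x, interval) {
  stopifnot(length(interval) == 2, interval[1] > 0,
            interval[1] < interval[2], all(x >= 1))
  post <- gpPosterior(model, log(x), predictive = TRUE)
  pnorm((log(interval[2]) - post$mean) / post$sd) -
    pnorm((log(interval[1]) - post$mean) / post$sd)
}

#' First-week-count range giving a target interval more than 50% probability
#'
#' Scans an integer grid of first-week counts and returns the set where the
#' probability of landing in the target remaining-count interval exceeds the
#' threshold — the enrollment criterion for prospective study designs.
#'
#' @param model a \code{GPCountModel}.
#' @param interval target remaining-count interval \code{c(a, b)}.
#' @param pThreshold probability threshold (default 0.5).
#' @param xGrid integer grid of first-week counts (default 1 to twice the
#'   largest training count).
#' @return list with \code{counts} (the qualifying integer counts, possibly
#'   empty), \code{range} (\code{c(min, max)} or \code{NULL}),
#'   \code{contiguous} (logical), and the probability \code{curve}
#'   data.frame.
#' @export
thresholdInterval <- function(model, interval, pThreshold = 0.5,
                              xGrid = NULL) {
  if (is.null(xGrid))
    xGrid <- seq(1L, max(3L, ceiling(2 * exp(max(model@x)))))
  p <- intervalProbability(model, xGrid, interval)
  sel <- xGrid[p > pThreshold]
  list(counts = sel,
       range = if (length(sel)) range(sel) else NULL,
       contiguous = length(sel) <= 1 ||
         all(diff(sel) == min(diff(xGrid))),
       curve = data.frame(firstWeekCount = xGrid, probability = p))
}

#' Per-animal prediction and stratified enrollment table
#'
#' For each animal with a usable first-week count: the predicted remaining
#' count median and central 50%/95% ranges (lognormal predictive), in/out
#' status for each target interval, and an alternating two-arm assignment by
#' ranked predicted median, which balances expected seizure burden across
#' arms.
#'
#' @param cohort a \code{SeizureCohort}.
#' @param intervals list of target intervals, each \code{c(a, b)}.
#' @param model optional pre-fitted \code{GPCountModel}; fitted from the
#'   cohort if missing.
#' @param TDays analysis window.
#' @return data.frame, one row per animal.
#' @export
enrollmentReport <- function(cohort, intervals = list(c(20, 100)),
                             model = NULL, TDays = 30) {
  if (is.null(model)) model <- fitGPLinear(cohort, TDays = TDays)
  ds <- .eventDiaries(cohort)
  sc <- vapply(ds, splitCounts, numeric(2), TDays = TDays)
  ok <- sc[1, ] > 0
  ds <- ds[ok]; sc <- sc[, ok, drop = FALSE]
  post <- gpPosterior(model, log(sc[1, ]), predictive = TRUE)
  tab <- data.frame(animal = names(ds), firstWeek = sc[1, ],
                    observedRemaining = sc[2, ],
                    predictedMedian = exp(post$mean),
                    lo50 = exp(post$mean + qnorm(0.25) * post$sd),
                    hi50 = exp(post$mean + qnorm(0.75) * post$sd),
                    lo95 = exp(post$mean + qnorm(0.025) * post$sd),
                    hi95 = exp(post$mean + qnorm(0.975) * post$sd),
                    row.names = NULL)
  for (iv in intervals) {
    p <- intervalProbability(model, sc[1, ], iv)
    tab[[sprintf("pIn_%g_%g", iv[1], iv[2])]] <- p
    tab[[sprintf("in_%g_%g", iv[1], iv[2])]] <- p > 0.5
  }
  tab$arm <- integer(nrow(tab))
  tab$arm[order(-tab$predictedMedian)] <-
    rep_len(c(1L, 2L), nrow(tab))  # alternate down the ranking
  tab
}
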