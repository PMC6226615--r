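#' @include AllClasses.R constructors.R utils.R
NULL

#' dF/F0 of a calcium trace
#'
#' The baseline F0 is the mean fluorescence over the window (default 2 s)
#' immediately preceding the stimulus onset (the valve switch);
#' \code{dff_t = (F_t - F0) / F0}.
#'
#' @param trace a \linkS4class{CalciumTrace}.
#' @param baselineWindow s before onset used for F0 (default 2).
#' @return A list of class \code{ResponseSummary}: \code{roiId, condition,
#'   F0, dff, samplePeriod, stimulusOnset, onsetSample}.
#' @export
dff <- function(trace, baselineWindow = 2) {
  dt <- trace@samplePeriod
  # first sample acquired at or after the valve switch (sample i is at
  # time (i - 1) * dt)
  onsetSample <- as.integer(ceiling(trace@stimulusOnset / dt - 1e-9)) + 1L
  nBase <- round(baselineWindow / dt)
  i0 <- onsetSample - nBase
  if (i0 < 1L || nBase < 1L)
    stop("baseline window does not fit before the stimulus onset",
         call. = FALSE)
  F0 <- mean(trace@values[i0:(onsetSample - 1L)])
  if (F0 <= 0) stop("non-positive baseline F0", call. = FALSE)
  structure(list(roiId = trace@roiId, condition = trace@condition,
                 F0 = F0, dff = (trace@values - F0) / F0,
                 samplePeriod = dt, stimulusOnset = trace@stimulusOnset,
                 onsetSample = onsetSample),
            class = "ResponseSummary")
}

#' Response integral of a dF/F0 trace
#'
#' Plain sum of dF/F0 over \code{nPoints} consecutive samples (default 10,
#' approx. 2 s at 128-256 ms sampling) starting at the stimulus-onset
#' sample — the valve switch, not a detected physiological onset. Set
#' \code{detectOnset = TRUE} to start instead at the first sample after
#' onset where dF/F0 exceeds \code{onsetThreshold}.
#'
#' @param summary a \code{ResponseSummary} from \code{\link{dff}}.
#' @param onsetSample explicit start sample (1-based); default the
#'   stimulus-onset sample.
#' @param nPoints number of samples summed (default 10).
#' @param detectOnset use a threshold-crossing onset instead.
#' @param onsetThreshold dF/F0 threshold for detection (default 0.05).
#' @return Dimensionless integral (numeric(1)).
#' @export
responseIntegral <- function(summary, onsetSample = NULL, nPoints = 10,
                             detectOnset = FALSE, onsetThreshold = 0.05) {
  stopifnot(inherits(summary, "ResponseSummary"))
  if (is.null(onsetSample)) {
    onsetSample <- summary$onsetSample
    if (detectOnset) {
      post <- which(summary$dff > onsetThreshold)
      post <- post[post >= summary$onsetSample]
      if (length(post)) onsetSample <- post[1]
    }
  }
  last <- onsetSample + nPoints - 1L
  if (onsetSample < 1L || last > length(summary$dff))
    stop("response window overruns the trace", call. = FALSE)
  sum(summary$dff[onsetSample:last])
}

#' Normalize permissive/restrictive trial sets to the low-temperature peak
#'
#' Trial-averages the dF/F0 traces of each condition, divides both averages
#' by the maximum of the permissive (low-temperature) average, and returns
#' per-trial integrals of the absolute normalized responses over the
#' response window.
#'
#' @param permissive,restrictive lists of \code{ResponseSummary} (trials at
#'   23 C and 33 C respectively).
#' @param nPoints response-window length in samples for the integrals.
#' @return list: \code{permissiveAvg}, \code{restrictiveAvg} (normalized
#'   trial-average dF/F0 traces), \code{scale} (the low-temperature
#'   maximum), \code{permissiveIntegrals}, \code{restrictiveIntegrals}.
#' @export
normalizePair <- function(permissive, restrictive, nPoints = 10) {
  if (!length(permissive) || !length(restrictive))
    stop("both conditions must be present", call. = FALSE)
  avg <- function(trials) rowMeans(vapply(trials, `[[`, "dff",
                                          FUN.VALUE = permissive[[1]]$dff))
  pAvg <- avg(permissive)
  rAvg <- avg(restrictive)
  scale <- max(pAvg)
  if (scale <= 0)
    stop("low-temperature trace maximum must be positive", call. = FALSE)
  integ <- function(s) {
    i0 <- s$onsetSample
    sum(abs(s$dff[i0:(i0 + nPoints - 1L)])) / scale
  }
  list(permissiveAvg = pAvg / scale, restrictiveAvg = rAvg / scale,
       scale = scale,
       permissiveIntegrals = vapply(permissive, integ, numeric(1)),
       restrictiveIntegrals = vapply(restrictive, integ, numeric(1)))
}

#' Thermogenetic activation magnitude
#'
#' Mean of the dF/F0 trace over a 20 s window starting 5 s after the
#' temperature-setpoint change (640 ms acquisition).
#'
#' @param summary a \code{ResponseSummary} from \code{\link{dff}}.
#' @param setpointChangeTime s from trace start.
#' @param delay,windowLength s (defaults 5 and 20).
#' @return Mean dF/F0 over the window.
#' @export
activationMagnitude <- function(summary, setpointChangeTime, delay = 5,
                                windowLength = 20) {
  stopifnot(inherits(summary, "ResponseSummary"))
  dt <- summary$samplePeriod
  i0 <- floor((setpointChangeTime + delay) / dt) + 1L
  i1 <- floor((setpointChangeTime + delay + windowLength) / dt)
  if (i0 < 1L || i1 > length(summary$dff))
    stop("activation window overruns the trace", call. = FALSE)
  mean(summary$dff[i0:i1])
}
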