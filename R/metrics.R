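# Trace-level summary statistics: peak response, extent of
# desensitization, the deactivation segment in the percent convention,
# and model-derived concentration-response data.

#' Peak response within a time window
#'
#' Maximum open probability of a trace within a window, on the sampled
#' grid (no interpolation); ties are broken by the earliest time.
#'
#' @param trace an \code{\link{occupancy_trace}}.
#' @param window numeric length-2 interval (seconds) inside the trace;
#'   defaults to the whole trace.
#' @return list with \code{value} (peak p_open) and \code{time} (seconds).
#' @export
peak_response <- function(trace, window = range(trace$time)) {
  stopifnot(inherits(trace, "occupancy_trace"), length(window) == 2L)
  sel <- trace$time >= window[1L] - 1e-12 & trace$time <= window[2L] + 1e-12
  if (!any(sel)) stop("empty window: no trace samples between ",
                      window[1L], " and ", window[2L], " s", call. = FALSE)
  p <- trace$p_open[sel]
  tt <- trace$time[sel]
  i <- which.max(p)                       # which.max returns the first max
  list(value = p[i], time = tt[i])
}

#' Extent of desensitization during an agonist application
#'
#' The decline of the response during sustained agonist application,
#' reported in percent of the peak: \code{(1 - residual/peak) * 100},
#' where the peak is taken over the application up to the measurement
#' time and the residual is the open probability at the measurement
#' time.  0\% means no desensitization.  The standard convention for
#' rho1 receptors is to measure at 60 s of saturating agonist (20 s for
#' fast-desensitizing heteromers); pass \code{measure_at} accordingly.
#'
#' @param trace an \code{\link{occupancy_trace}}.
#' @param application_start start of the agonist application (seconds).
#' @param measure_at time at which the residual response is read
#'   (seconds, within the application).
#' @return Percent desensitization (scalar).
#' @export
desensitization_extent <- function(trace, application_start, measure_at) {
  stopifnot(inherits(trace, "occupancy_trace"))
  if (measure_at <= application_start)
    stop("'measure_at' must lie after 'application_start'", call. = FALSE)
  pk <- peak_response(trace, c(application_start, measure_at))
  i <- which.min(abs(trace$time - measure_at))
  residual <- trace$p_open[i]
  if (pk$value <= 0)
    stop("peak response is zero; desensitization extent is undefined",
         call. = FALSE)
  (1 - residual / pk$value) * 100
}

#' Construct a deactivation segment
#'
#' A deactivation segment holds the current decay after agonist removal
#' in the paper's percent convention: time restarts at zero at washout
#' and the response is expressed as a negative-going percentage of the
#' current at the moment of removal, starting at exactly -100 and
#' relaxing toward 0.
#'
#' @param time seconds since agonist removal (first element 0).
#' @param percent_current percent of the washout-time current; must start
#'   at -100.
#' @return Object of class \code{"deactivation_segment"} (a data.frame).
#' @export
deactivation_segment <- function(time, percent_current) {
  stopifnot(length(time) == length(percent_current), length(time) >= 2L)
  if (abs(time[1L]) > 1e-12)
    stop("deactivation segment must start at time 0", call. = FALSE)
  if (abs(percent_current[1L] + 100) > 1e-6)
    stop("deactivation segment must start at -100 percent", call. = FALSE)
  structure(data.frame(time = as.numeric(time),
                       percent_current = as.numeric(percent_current)),
            class = c("deactivation_segment", "data.frame"))
}

#' Extract the deactivation segment from a trace
#'
#' Re-zeroes time at the washout boundary and rescales the open
#' probability to the percent convention
#' \code{percent_current(t) = -100 * p_open(t) / p_open(0)}, so the
#' segment starts at exactly -100 and relaxes toward 0 as the receptor
#' deactivates.
#'
#' @param trace an \code{\link{occupancy_trace}}.
#' @param washout_start time (seconds) at which the agonist concentration
#'   drops to zero; must coincide with a trace sample with positive
#'   \code{p_open}.
#' @return A \code{\link{deactivation_segment}}.
#' @export
extract_deactivation <- function(trace, washout_start) {
  stopifnot(inherits(trace, "occupancy_trace"))
  i0 <- which.min(abs(trace$time - washout_start))
  if (abs(trace$time[i0] - washout_start) > 1e-6 * max(1, washout_start))
    stop("'washout_start' does not coincide with a trace sample",
         call. = FALSE)
  p0 <- trace$p_open[i0]
  if (p0 <= 0)
    stop("p_open at washout is zero; deactivation is undefined",
         call. = FALSE)
  idx <- i0:length(trace$time)
  deactivation_segment(trace$time[idx] - trace$time[i0],
                       -100 * trace$p_open[idx] / p0)
}

#' Construct a concentration-response dataset
#'
#' @param concentrations strictly positive molar concentrations, sorted
#'   ascending.
#' @param responses normalized responses (I/Imax), one per concentration.
#' @param mode \code{"activation"} (agonist) or \code{"inhibition"}
#'   (blocker).
#' @return Object of class \code{"crc_data"} (a data.frame with columns
#'   \code{conc} and \code{response} and a \code{mode} attribute).
#' @export
crc_data <- function(concentrations, responses,
                     mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be sorted strictly ascending", call. = FALSE)
  structure(data.frame(conc = as.numeric(concentrations),
                       response = as.numeric(responses)),
            mode = mode, class = c("crc_data", "data.frame"))
}

#' Model-derived concentration-response curve
#'
#' Simulates a concentration jump from rest for each concentration, takes
#' the peak open probability over the application, and normalizes all
#' peaks to their maximum (activation-mode data, max response 1).
#'
#' @param scheme a \code{\link{gating_scheme}}.
#' @param concentrations strictly positive molar grid, sorted ascending.
#' @param application_duration agonist application length in seconds
#'   (default 60 s, the rho1 protocol).
#' @param dt sampling interval for the peak search (default 0.01 s).
#' @return A \code{\link{crc_data}} with \code{mode = "activation"}.
#' @export
crc_from_model <- function(scheme, concentrations,
                           application_duration = 60, dt = 0.01) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (any(concentrations <= 0) ||
      is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and sorted ascending",
         call. = FALSE)
  times <- .segment_times(application_duration, dt)
  peaks <- vapply(concentrations, function(conc)
    max(.popen_constant(scheme, conc, times)), numeric(1L))
  if (max(peaks) <= 0)
    stop("all peak responses are zero; cannot build a ",
         "concentration-response curve", call. = FALSE)
  crc_data(concentrations, peaks / max(peaks), mode = "activation")
}
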