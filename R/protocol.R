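# Piecewise-constant agonist concentration protocols.

#' Define a concentration-jump protocol
#'
#' A protocol is an ordered sequence of segments, each holding the bath
#' agonist concentration constant for a stated duration (a concentration
#' jump occurs instantaneously at each segment boundary), together with
#' the output sampling interval and the initial occupancy condition.
#'
#' @param segments two-column matrix or data.frame with columns
#'   \code{duration} (seconds, > 0) and \code{conc} (molar, >= 0); one row
#'   per segment.
#' @param dt output sampling interval in seconds; must be positive and no
#'   larger than the shortest segment.  Default 0.01 s (rho1 kinetics are
#'   seconds-scale).
#' @param init initial occupancy: \code{"all-R"} (resting, agonist free;
#'   the default), \code{"equilibrium"} (stationary distribution at the
#'   first segment's concentration), or a numeric probability vector of
#'   length 6 over the states (R, AR, AF, AO, AFD, AOD).
#' @return An object of class \code{"concentration_protocol"}.
#' @seealso \code{\link{parse_protocol}} for the compact string syntax.
#' @export
concentration_protocol <- function(segments, dt = 0.01, init = "all-R") {
  segments <- as.data.frame(segments)
  if (!all(c("duration", "conc") %in% names(segments)))
    stop("'segments' needs columns 'duration' and 'conc'", call. = FALSE)
  segments <- segments[, c("duration", "conc")]
  if (nrow(segments) < 1L) stop("protocol needs at least one segment",
                                call. = FALSE)
  if (!all(is.finite(segments$duration)) || any(segments$duration <= 0))
    stop("segment durations must be positive and finite", call. = FALSE)
  if (!all(is.finite(segments$conc)) || any(segments$conc < 0))
    stop("concentrations must be non-negative and finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number", call. = FALSE)
  if (dt > min(segments$duration) + 1e-12)
    stop("'dt' must not exceed the shortest segment duration", call. = FALSE)
  if (is.character(init)) {
    init <- match.arg(init, c("all-R", "equilibrium"))
  } else {
    init <- as.numeric(init)
    if (length(init) != 6L || any(init < 0) ||
        abs(sum(init) - 1) > 1e-8)
      stop("numeric 'init' must be a length-6 probability vector",
           call. = FALSE)
    names(init) <- SCHEME_STATES
  }
  structure(list(segments = segments, dt = dt, init = init),
            class = "concentration_protocol")
}

#' Parse a compact protocol string
#'
#' Parses the segment syntax \code{"conc_molar@duration_s"} with
#' semicolon-separated segments, e.g. \code{"0@5;0.001@60;0@600"} for
#' 5 s of wash, 60 s of 1 mM agonist, and 600 s of washout.
#'
#' @param text protocol string.
#' @inheritParams concentration_protocol
#' @return A \code{\link{concentration_protocol}}.
#' @export
parse_protocol <- function(text, dt = 0.01, init = "all-R") {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (!length(parts)) stop("empty protocol string", call. = FALSE)
  seg <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), "@", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("bad protocol segment '", p, "' (expected conc@duration)",
           call. = FALSE)
    c(conc = as.numeric(kv[1]), duration = as.numeric(kv[2]))
  })
  seg <- as.data.frame(do.call(rbind, seg))
  concentration_protocol(seg, dt = dt, init = init)
}

#' @export
print.concentration_protocol <- function(x, ...) {
  cat("Concentration-jump protocol (", nrow(x$segments), " segment(s), dt = ",
      x$dt, " s)\n", sep = "")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %2d: %.6g M for %.6g s\n", i, x$segments$conc[i],
                x$segments$duration[i]))
  if (is.character(x$init)) cat("  init:", x$init, "\n")
  else cat("  init: explicit occupancy vector\n")
  invisible(x)
}
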