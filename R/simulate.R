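# Q-matrix construction, stationary distributions and deterministic
# propagation of state occupancies through concentration-jump protocols.

#' Build the rate generator (Q matrix) at a given agonist concentration
#'
#' Returns the 6x6 generator of the continuous-time Markov gating model:
#' off-diagonal entries are the per-second transition rates of the seven
#' scheme edges (binding \code{R -> AR} enters as \code{k1 * conc}), and
#' each diagonal entry makes its row sum to zero.
#'
#' @param scheme a \code{\link{gating_scheme}}.
#' @param conc agonist concentration in molar (>= 0).
#' @return 6x6 numeric matrix with dimnames (R, AR, AF, AO, AFD, AOD).
#' @export
build_generator <- function(scheme, conc) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!is.numeric(conc) || length(conc) != 1L || !is.finite(conc) || conc < 0)
    stop("'conc' must be a single non-negative concentration in molar",
         call. = FALSE)
  r <- scheme_rates(scheme)
  Q <- matrix(0, 6, 6, dimnames = list(SCHEME_STATES, SCHEME_STATES))
  Q["R", "AR"]   <- r[["k1"]] * conc
  Q["AR", "R"]   <- r[["k_minus1"]]
  Q["AR", "AF"]  <- r[["f1"]]
  Q["AF", "AR"]  <- r[["f_minus1"]]
  Q["AF", "AO"]  <- r[["beta"]]
  Q["AO", "AF"]  <- r[["alpha"]]
  Q["AF", "AFD"] <- r[["dAF_on"]]
  Q["AFD", "AF"] <- r[["dAF_off"]]
  Q["AO", "AOD"] <- r[["dAO_on"]]
  Q["AOD", "AO"] <- r[["dAO_off"]]
  diag(Q) <- -rowSums(Q)
  Q
}

# states reachable from R along edges with positive rate
.reachable_states <- function(Q) {
  adj <- Q > 0
  diag(adj) <- FALSE
  reach <- rep(FALSE, 6L)
  reach[1L] <- TRUE
  repeat {
    new <- reach | (reach %*% adj > 0)
    if (all(new == reach)) break
    reach <- as.logical(new)
  }
  which(reach)
}

#' Stationary occupancy distribution at a fixed concentration
#'
#' Computes the equilibrium occupancy of the gating scheme held at a
#' constant agonist concentration, i.e. the probability vector in the
#' null space of the transposed generator, restricted to the states
#' reachable from the resting state R.  Unreachable states (for example
#' all agonist-bound states at zero concentration) receive occupancy 0.
#'
#' @inheritParams build_generator
#' @return Named occupancy vector of length 6 summing to 1.
#' @export
steady_state <- function(scheme, conc) {
  Q <- build_generator(scheme, conc)
  idx <- .reachable_states(Q)
  p <- stats::setNames(numeric(6L), SCHEME_STATES)
  if (length(idx) == 1L) {
    p[idx] <- 1
    return(p)
  }
  Qr <- Q[idx, idx, drop = FALSE]
  sv <- svd(t(Qr))
  tol <- max(dim(Qr)) * max(sv$d) * .Machine$double.eps * 100
  null_dim <- sum(sv$d < tol)
  if (null_dim != 1L)
    stop("stationary distribution on the reachable state set is not unique",
         call. = FALSE)
  v <- sv$v[, length(sv$d)]
  v <- v / sum(v)
  if (any(v < -1e-8))
    stop("stationary solve produced a non-probability vector", call. = FALSE)
  v[v < 0] <- 0
  p[idx] <- v / sum(v)
  p
}

# Propagate occupancy p0 under constant generator Q, evaluated at the
# strictly positive times in 'times'.  Exact linear propagation via
# eigendecomposition of Q; falls back to scaling-and-squaring matrix
# exponentials (Matrix::expm) when the eigenbasis is ill-conditioned.
# Returns an length(times) x 6 matrix.
.propagate_constant <- function(Q, p0, times) {
  n <- length(times)
  out <- NULL
  ed <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ed)) {
    Vin <- tryCatch(solve(ed$vectors), error = function(e) NULL)
    if (!is.null(Vin)) {
      # p(t)^T = p0^T V exp(Lambda t) V^{-1}, so with w = V^T p0 the
      # solution is p(t)^T = sum_j w_j exp(lambda_j t) V^{-1}[j, ]
      w <- drop(t(ed$vectors) %*% p0)
      E <- exp(outer(times, ed$values))            # n x 6, possibly complex
      out <- (E * matrix(w, n, 6L, byrow = TRUE)) %*% Vin
      out <- Re(out)
      bad <- any(!is.finite(out)) ||
        max(abs(rowSums(out) - 1)) > 1e-9 ||
        min(out) < -1e-9 || max(out) > 1 + 1e-9
      if (bad) out <- NULL                          # defective/ill-conditioned
    }
  }
  if (is.null(out)) {
    # dense expm fallback; transition matrices cached per distinct step size
    out <- matrix(NA_real_, n, 6L)
    steps <- diff(c(0, times))
    ukey <- format(steps, digits = 15)
    cache <- new.env(parent = emptyenv())
    p <- p0
    for (i in seq_len(n)) {
      Tm <- cache[[ukey[i]]]
      if (is.null(Tm)) {
        Tm <- as.matrix(Matrix::expm(Q * steps[i]))
        cache[[ukey[i]]] <- Tm
      }
      p <- as.numeric(p %*% Tm)
      out[i, ] <- p
    }
  }
  if (any(!is.finite(out)))
    stop("numerical failure in occupancy propagation (non-finite values); ",
         "check the scheme rates", call. = FALSE)
  # remove round-off-scale violations so occupancies are exact probabilities
  out[out < 0] <- 0
  out[out > 1] <- 1
  colnames(out) <- SCHEME_STATES
  out
}

# output grid for one segment: dt steps, plus the segment end if the
# duration is not an integral multiple of dt
.segment_times <- function(duration, dt) {
  n <- floor(duration / dt + 1e-9)
  times <- seq_len(n) * dt
  if (n == 0L || duration - times[n] > 1e-9 * max(1, duration))
    times <- c(times, duration)
  times
}

#' Construct an occupancy trace
#'
#' Container for a simulated (or loaded) time course of state occupancies.
#' \code{p_open} is always identical to the AO occupancy column when full
#' occupancies are present.
#'
#' @param time numeric time grid in seconds.
#' @param occupancy matrix (length(time) x 6) of state occupancies, or
#'   \code{NULL} when only \code{p_open} is available.
#' @param p_open open probability; defaults to the AO column.
#' @param metadata list of provenance fields (scheme rates, protocol, seed).
#' @return Object of class \code{"occupancy_trace"}.
#' @export
occupancy_trace <- function(time, occupancy = NULL, p_open = NULL,
                            metadata = list()) {
  time <- as.numeric(time)
  if (!is.null(occupancy)) {
    occupancy <- as.matrix(occupancy)
    stopifnot(nrow(occupancy) == length(time), ncol(occupancy) == 6L)
    colnames(occupancy) <- SCHEME_STATES
    if (is.null(p_open)) p_open <- occupancy[, "AO"]
  }
  stopifnot(!is.null(p_open), length(p_open) == length(time))
  structure(list(time = time, occupancy = occupancy,
                 p_open = as.numeric(p_open), metadata = metadata),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf(
    "Occupancy trace: %d samples over %.6g s; peak p_open = %.4g\n",
    length(x$time), diff(range(x$time)), max(x$p_open)))
  invisible(x)
}

#' @export
plot.occupancy_trace <- function(x, y, ...) {
  graphics::plot(x$time, x$p_open, type = "l", xlab = "time (s)",
                 ylab = "open probability", ...)
  invisible(x)
}

#' Simulate a gating scheme through a concentration protocol
#'
#' Propagates the state occupancies of a \code{\link{gating_scheme}}
#' through a piecewise-constant agonist \code{\link{concentration_protocol}}.
#' Within each segment the solution is the exact linear propagation
#' (matrix exponential of the generator) evaluated on the \code{dt} grid;
#' segments are concatenated without duplicating boundary samples.
#' Optionally adds seeded Gaussian noise to \code{p_open} (see
#' \code{\link{gen_noisy_trace}}).
#'
#' @param object a \code{\link{gating_scheme}}.
#' @param nsim number of traces (> 1 only meaningful with noise).
#' @param seed integer seed used when \code{noise_sigma > 0}.
#' @param protocol a \code{\link{concentration_protocol}}.
#' @param noise_sigma standard deviation of additive Gaussian noise on
#'   \code{p_open} (0 = deterministic trace).
#' @param ... unused.
#' @return An \code{\link{occupancy_trace}} (or a list of them when
#'   \code{nsim > 1}).
#' @export
simulate.gating_scheme <- function(object, nsim = 1, seed = NULL,
                                   protocol, noise_sigma = 0, ...) {
  tr <- simulate_protocol(object, protocol)
  if (noise_sigma == 0 && nsim == 1L) return(tr)
  if (is.null(seed)) seed <- 1L
  out <- lapply(seq_len(nsim), function(i)
    gen_noisy_trace(tr, noise_spec(noise_sigma, seed + i - 1L)))
  if (nsim == 1L) out[[1L]] else out
}

#' @rdname simulate.gating_scheme
#' @param scheme a \code{\link{gating_scheme}}.
#' @export
simulate_protocol <- function(scheme, protocol) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(protocol, "concentration_protocol"))
  seg <- protocol$segments
  p0 <- if (is.character(protocol$init)) {
    if (protocol$init == "all-R") c(1, 0, 0, 0, 0, 0)
    else steady_state(scheme, seg$conc[1L])
  } else as.numeric(protocol$init)

  times <- 0
  occ <- matrix(p0, 1L, 6L)
  t0 <- 0
  for (i in seq_len(nrow(seg))) {
    Q <- build_generator(scheme, seg$conc[i])
    st <- .segment_times(seg$duration[i], protocol$dt)
    block <- .propagate_constant(Q, p0, st)
    times <- c(times, t0 + st)
    occ <- rbind(occ, block)
    p0 <- block[nrow(block), ]
    t0 <- t0 + seg$duration[i]
  }
  colnames(occ) <- SCHEME_STATES
  occupancy_trace(times, occ,
                  metadata = list(scheme = scheme_rates(scheme),
                                  protocol = seg, dt = protocol$dt,
                                  init = protocol$init))
}

# fast internal path: p_open only, arbitrary time grid, single constant
# concentration, starting from occupancy p0 (default all-R).  Same eigen
# solution as .propagate_constant but projected onto the AO column, with
# conservation checked on a time subsample; falls back to the full
# propagator when the eigenbasis looks ill-conditioned.
.popen_constant <- function(scheme, conc, times, p0 = c(1, 0, 0, 0, 0, 0)) {
  Q <- build_generator(scheme, conc)
  ed <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ed)) {
    Vin <- tryCatch(solve(ed$vectors), error = function(e) NULL)
    if (!is.null(Vin)) {
      w <- drop(t(ed$vectors) %*% p0)
      n <- length(times)
      probe <- unique(c(1L, n %/% 2L, n))
      Ep <- exp(outer(times[probe], ed$values))
      full <- Re((Ep * matrix(w, length(probe), 6L, byrow = TRUE)) %*% Vin)
      ok <- all(is.finite(full)) &&
        max(abs(rowSums(full) - 1)) <= 1e-9 &&
        min(full) >= -1e-9 && max(full) <= 1 + 1e-9
      if (ok) {
        po <- Re(exp(outer(times, ed$values)) %*% (w * Vin[, 4L]))
        po[po < 0] <- 0
        po[po > 1] <- 1
        return(drop(po))
      }
    }
  }
  .propagate_constant(Q, p0, times)[, "AO"]
}
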