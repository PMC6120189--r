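# Shared fixtures: schemes and random-scheme generators used across tests.

# plausible rho1-like wild type: seconds-scale kinetics with substantial
# desensitization
wt_like_scheme <- function() {
  gating_scheme(k1 = 5e6, k_minus1 = 1, f1 = 20, f_minus1 = 10,
                beta = 100, alpha = 50, dAF_on = 0.5, dAF_off = 0.05,
                dAO_on = 0.5, dAO_off = 0.05)
}

# two-state reduction R <-> AR: all gating and desensitization off
two_state_scheme <- function(k1 = 1e6, k_minus1 = 1) {
  gating_scheme(k1 = k1, k_minus1 = k_minus1, f1 = 0, f_minus1 = 0,
                beta = 0, alpha = 0, dAF_on = 0, dAF_off = 0,
                dAO_on = 0, dAO_off = 0)
}

# random scheme with log-uniform rates on moderate, well-conditioned
# ranges (first-order rates 0.05-200 /s, k1 1e5-1e7 /M/s)
random_scheme <- function() {
  r <- exp(stats::runif(9, log(0.05), log(200)))
  gating_scheme(k1 = exp(stats::runif(1, log(1e5), log(1e7))),
                k_minus1 = r[1], f1 = r[2], f_minus1 = r[3],
                beta = r[4], alpha = r[5], dAF_on = r[6], dAF_off = r[7],
                dAO_on = r[8], dAO_off = r[9])
}

# random WT-like scheme: gating fast, desensitization slow, binding in a
# physiological window
random_wt_like_scheme <- function() {
  gating_scheme(k1 = exp(stats::runif(1, log(1e6), log(1e7))),
                k_minus1 = exp(stats::runif(1, log(0.5), log(5))),
                f1 = exp(stats::runif(1, log(5), log(50))),
                f_minus1 = exp(stats::runif(1, log(5), log(50))),
                beta = exp(stats::runif(1, log(50), log(500))),
                alpha = exp(stats::runif(1, log(20), log(200))),
                dAF_on = exp(stats::runif(1, log(0.1), log(1))),
                dAF_off = exp(stats::runif(1, log(0.02), log(0.2))),
                dAO_on = exp(stats::runif(1, log(0.1), log(1))),
                dAO_off = exp(stats::runif(1, log(0.02), log(0.2))))
}

# independent stiff ODE integration of the same kinetics (deSolve),
# used as the oracle against the matrix-exponential propagator
ode_oracle_trace <- function(scheme, protocol) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  seg <- protocol$segments
  p0 <- if (identical(protocol$init, "all-R")) c(1, 0, 0, 0, 0, 0)
        else if (identical(protocol$init, "equilibrium"))
          unname(steady_state(scheme, seg$conc[1]))
        else as.numeric(protocol$init)
  times <- 0
  occ <- matrix(p0, 1)
  t0 <- 0
  deriv <- function(t, y, Q) list(as.numeric(y %*% Q))
  for (i in seq_len(nrow(seg))) {
    Q <- build_generator(scheme, seg$conc[i])
    n <- floor(seg$duration[i] / protocol$dt + 1e-9)
    st <- seq_len(n) * protocol$dt
    if (n == 0 || seg$duration[i] - st[length(st)] > 1e-9)
      st <- c(st, seg$duration[i])
    sol <- deSolve::lsoda(p0, c(0, st), deriv, Q,
                          rtol = 1e-10, atol = 1e-12)
    block <- sol[-1, -1, drop = FALSE]
    times <- c(times, t0 + st)
    occ <- rbind(occ, block)
    p0 <- block[nrow(block), ]
    t0 <- t0 + seg$duration[i]
  }
  colnames(occ) <- c("R", "AR", "AF", "AO", "AFD", "AOD")
  occupancy_trace(times, occ)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
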