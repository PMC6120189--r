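# Constrained bi-exponential fit of deactivation segments:
#   I/Imax = -100 + A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2)),
# with A1 + A2 = 100, which is algebraically
#   I/Imax = -(A1 exp(-t/tau1) + A2 exp(-t/tau2)):
# a percent inward current decaying from -100 toward 0.  The reported
# summary is the amplitude-weighted time constant
#   weighted_tau = (A1 tau1 + A2 tau2) / (A1 + A2).

# profiled residuals: given (tau1, tau2) the amplitude A1 enters linearly
# (A2 = 100 - A1), so it is solved in closed form and clamped to [0, 100]
.biexp_profile <- function(lt, t, y) {
  tau1 <- exp(lt[1L]); tau2 <- exp(lt[2L])
  e1 <- exp(-t / tau1); e2 <- exp(-t / tau2)
  u <- e1 - e2
  r <- y + 100 * e2
  su2 <- sum(u * u)
  a1 <- if (su2 > 0) min(100, max(0, -sum(u * r) / su2)) else 0
  list(a1 = a1, resid = r + a1 * u, e1 = e1, e2 = e2)
}

# NB: with A1 at its profiled optimum the envelope theorem lets the
# gradient of the profiled RSS treat A1 as fixed (see gr inside fit_biexp)

#' Fit the constrained bi-exponential deactivation function
#'
#' Fits \code{I/Imax = -100 + A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))}
#' with the constraint \code{A1 + A2 = 100} (forced by the -100 offset of
#' the percent convention) to a \code{\link{deactivation_segment}}.
#' Amplitudes are percentages; components are ordered \code{tau1 <= tau2}
#' and the amplitude-weighted time constant is reported.  The time
#' constants are optimized in log space from 8 deterministic log-spaced
#' starting pairs spanning the segment duration (amplitudes profiled out
#' in closed form); if the two components degenerate (time constants
#' within 1\%), the fit collapses to a mono-exponential with
#' \code{A1 = 100}.
#'
#' @param seg a \code{\link{deactivation_segment}} with at least 20
#'   samples.
#' @param boot number of residual-resampling bootstrap replicates for
#'   the standard errors (0, the default, uses the linearized
#'   covariance); resampled segments are re-pinned to -100 at t = 0.
#' @param boot_seed RNG seed for the bootstrap resampling.
#' @return Object of class \code{"biexp_fit"} with elements \code{A1},
#'   \code{A2} (percent), \code{tau1}, \code{tau2}, \code{weighted_tau}
#'   (seconds), \code{se} (linearized standard errors for A1, tau1,
#'   tau2), \code{rss}, \code{seg}.
#' @examples
#' t <- seq(0, 120, 0.05)
#' seg <- deactivation_segment(t, -(60 * exp(-t / 2) + 40 * exp(-t / 20)))
#' fit_biexp(seg)
#' @export
fit_biexp <- function(seg, boot = 0L, boot_seed = 1L) {
  stopifnot(inherits(seg, "deactivation_segment"))
  t <- seg$time
  y <- seg$percent_current
  if (length(t) < 20L)
    stop("need at least 20 samples to fit the bi-exponential", call. = FALSE)
  if (abs(y[1L] + 100) > 1e-6)
    stop("segment does not start at -100 percent", call. = FALSE)
  dur <- max(t)
  dt_min <- min(diff(t))
  lo <- log(dt_min)
  hi <- log(10 * dur)

  g <- exp(seq(log(max(dt_min * 5, dur / 1000)), log(dur), length.out = 4L))
  starts <- rbind(t(utils::combn(g, 2L)),            # 6 ordered pairs
                  c(g[1L] / 3, g[3L]),
                  c(g[2L], min(g[4L] * 3, 10 * dur)))

  # share the profile computation between objective and gradient calls
  last <- new.env(parent = emptyenv())
  profile_at <- function(lt) {
    if (!identical(last$lt, lt)) {
      last$pr <- .biexp_profile(lt, t, y)
      last$lt <- lt
    }
    last$pr
  }
  fn <- function(lt) sum(profile_at(lt)$resid^2)
  gr <- function(lt) {
    pr <- profile_at(lt)
    tau1 <- exp(lt[1L]); tau2 <- exp(lt[2L])
    2 * c(sum(pr$resid * pr$a1 * pr$e1 * t / tau1),
          sum(pr$resid * (100 - pr$a1) * pr$e2 * t / tau2))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(starts[i, ]), fn = fn, gr = gr,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200, factr = 100)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("bi-exponential fit failed to converge from any start",
         call. = FALSE)

  tau <- sort(exp(best$par))
  pr <- .biexp_profile(log(tau), t, y)
  a1 <- pr$a1
  if (abs(tau[2L] - tau[1L]) / tau[2L] < 0.01) {
    # degenerate pair: collapse to a mono-exponential with A1 = 100
    tau_mono <- exp(stats::optimize(function(lt)
      sum((y + 100 * exp(-t / exp(lt)))^2),
      interval = c(lo, hi), tol = 1e-12)$minimum)
    tau <- c(tau_mono, tau_mono)
    a1 <- 100
  }
  a2 <- 100 - a1
  rss <- sum((y + a1 * exp(-t / tau[1L]) + a2 * exp(-t / tau[2L]))^2)
  wt <- (a1 * tau[1L] + a2 * tau[2L]) / 100
  if (boot > 0L) {
    fitted_y <- -(a1 * exp(-t / tau[1L]) + a2 * exp(-t / tau[2L]))
    res <- y - fitted_y
    reps <- .with_seed(boot_seed, vapply(seq_len(boot), function(b) {
      yb <- fitted_y + sample(res, replace = TRUE)
      yb <- yb * (-100 / yb[1L])
      fb <- fit_biexp(deactivation_segment(t, yb))
      c(fb$A1, fb$tau1, fb$tau2)
    }, numeric(3L)))
    se <- stats::setNames(apply(reps, 1L, stats::sd),
                          c("A1", "tau1", "tau2"))
  } else {
    se <- .biexp_se(t, y, a1, tau[1L], tau[2L], rss)
  }
  structure(list(A1 = a1, A2 = a2, tau1 = tau[1L], tau2 = tau[2L],
                 weighted_tau = wt, se = se, rss = rss, seg = seg),
            class = "biexp_fit")
}

.biexp_se <- function(t, y, a1, tau1, tau2, rss) {
  n <- length(y)
  model <- function(p) -(p[1L] * exp(-t / p[2L]) +
                           (100 - p[1L]) * exp(-t / p[3L]))
  p <- c(a1, tau1, tau2)
  J <- vapply(1:3, function(k) {
    f <- function(v) { q <- p; q[k] <- v; model(q) }
    .num_deriv(f, p[k])
  }, numeric(n))
  s2 <- rss / max(n - 3L, 1L)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cov)) return(c(A1 = NA_real_, tau1 = NA_real_,
                             tau2 = NA_real_))
  stats::setNames(sqrt(pmax(diag(cov), 0)), c("A1", "tau1", "tau2"))
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Bi-exponential deactivation fit:\n",
    "  A1 = %.3g%%, tau1 = %.4g s; A2 = %.3g%%, tau2 = %.4g s\n",
    "  weighted tau = %.4g s (rss = %.3g)\n"),
    x$A1, x$tau1, x$A2, x$tau2, x$weighted_tau, x$rss))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...)
  c(A1 = object$A1, A2 = object$A2, tau1 = object$tau1, tau2 = object$tau2,
    weighted_tau = object$weighted_tau)

#' @export
summary.biexp_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$A1, object$tau1, object$tau2, object$weighted_tau),
    std_error = c(object$se[["A1"]], object$se[["tau1"]],
                  object$se[["tau2"]], NA),
    row.names = c("A1 (%)", "tau1 (s)", "tau2 (s)", "weighted tau (s)"))
  structure(list(table = tab, rss = object$rss,
                 n_points = nrow(object$seg)), class = "summary.biexp_fit")
}

#' @export
print.summary.biexp_fit <- function(x, ...) {
  cat("Constrained bi-exponential fit on", x$n_points, "samples\n")
  print(x$table)
  cat("residual sum of squares:", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' @export
predict.biexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$seg$time
       else if (is.data.frame(newdata)) newdata$time else newdata
  -(object$A1 * exp(-t / object$tau1) + object$A2 * exp(-t / object$tau2))
}

#' @export
residuals.biexp_fit <- function(object, ...)
  object$seg$percent_current - predict(object)

#' @export
plot.biexp_fit <- function(x, y, ...) {
  graphics::plot(x$seg$time, x$seg$percent_current, type = "l",
                 xlab = "time after washout (s)",
                 ylab = "current (% of washout)", ...)
  graphics::lines(x$seg$time, predict(x), lty = 2)
  invisible(x)
}
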