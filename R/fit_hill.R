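# Hill-equation fits for activation and inhibition
# concentration-response data.
#
# Activation:  I/Imax = 1 / (1 + (EC50/[A])^n)
# Inhibition:  I/Imax = 1 - 1 / (1 + (IC50/[B])^n)

.hill_eval <- function(conc, half_max, slope, mode) {
  act <- 1 / (1 + (half_max / conc)^slope)
  if (mode == "activation") act else 1 - act
}

#' Fit the Hill equation to concentration-response data
#'
#' Least-squares fit of the activation Hill equation
#' \code{I/Imax = 1/(1 + (EC50/[A])^n)} or the inhibition form
#' \code{I/Imax = 1 - 1/(1 + (IC50/[B])^n)}, exactly as used for the
#' GABA and picrotoxin concentration-response relationships.  The fit is
#' multi-start (a deterministic list of 8 starting points: half-max
#' values log-spaced over the concentration range crossed with slopes 1
#' and 2) with bounded quasi-Newton refinement in log-parameter space
#' using the analytic gradient; the best residual wins.  Bounds: half-max within
#' [min(conc)/100, max(conc)*100], slope in (0.1, 10].
#'
#' @param data a \code{\link{crc_data}} with at least 4 points.
#' @param mode \code{"activation"} or \code{"inhibition"}; defaults to
#'   the mode attribute of \code{data}.
#' @param boot number of residual-resampling bootstrap replicates for
#'   the standard errors (0, the default, uses the linearized
#'   covariance at the optimum instead).
#' @param boot_seed RNG seed for the bootstrap resampling.
#' @return Object of class \code{"hill_fit"} with elements
#'   \code{half_max} (molar; EC50 or IC50), \code{slope} (n),
#'   \code{se} (named standard errors from the linearized covariance),
#'   \code{rss}, \code{mode}, \code{data}.
#' @examples
#' d <- gen_hill_dataset(1e-5, 1.5, 10^seq(-7, -3, 0.5), "activation",
#'                       noise_spec(0))
#' fit_hill(d)
#' @export
fit_hill <- function(data, mode = attr(data, "mode"), boot = 0L,
                     boot_seed = 1L) {
  stopifnot(inherits(data, "crc_data"))
  mode <- match.arg(mode, c("activation", "inhibition"))
  if (mode != attr(data, "mode"))
    stop("'data' has mode '", attr(data, "mode"), "', not '", mode, "'",
         call. = FALSE)
  if (nrow(data) < 4L)
    stop("need at least 4 concentration points to fit the Hill equation",
         call. = FALSE)
  conc <- data$conc
  y <- data$response
  lo <- c(log(min(conc) / 100), log(0.1) + 1e-9)
  hi <- c(log(max(conc) * 100), log(10))
  lconc <- log(conc)
  sgn <- if (mode == "activation") 1 else -1
  # RSS and analytic gradient in (log half_max, log n); the curve is
  # 1/(1+exp(n (log h - log c))) up to the mode sign
  rss_fn <- function(par) {
    z <- exp(par[2L]) * (par[1L] - lconc)
    f <- 1 / (1 + exp(z))
    r <- y - (if (sgn > 0) f else 1 - f)
    df <- -f * (1 - f)                 # d f / d z
    gz_h <- exp(par[2L])               # d z / d log h
    gz_n <- z                          # d z / d log n
    g <- -2 * sgn * c(sum(r * df * gz_h), sum(r * df * gz_n))
    structure(sum(r * r), gradient = g)
  }
  fn <- function(par) as.numeric(rss_fn(par))
  gr <- function(par) attr(rss_fn(par), "gradient")

  h_starts <- exp(seq(log(min(conc)), log(max(conc)), length.out = 4L))
  h_starts[1L] <- exp(mean(log(range(conc))))    # geometric mean first
  starts <- expand.grid(h = h_starts, n = c(1, 2))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(log(starts$h[i]), log(starts$n[i])), fn = fn,
                   gr = gr, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200, factr = 10)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start (mode ", mode, ")",
         call. = FALSE)

  half_max <- exp(best$par[1L])
  slope <- exp(best$par[2L])
  rss <- best$value
  if (boot > 0L) {
    fitted_y <- .hill_eval(conc, half_max, slope, mode)
    res <- y - fitted_y
    reps <- .with_seed(boot_seed, vapply(seq_len(boot), function(b) {
      yb <- fitted_y + sample(res, replace = TRUE)
      fb <- fit_hill(crc_data(conc, yb, mode = mode), mode)
      c(fb$half_max, fb$slope)
    }, numeric(2L)))
    se <- stats::setNames(apply(reps, 1L, stats::sd),
                          c("half_max", "slope"))
  } else {
    se <- .hill_se(conc, y, half_max, slope, mode, rss)
  }
  structure(list(half_max = half_max, slope = slope, se = se, rss = rss,
                 mode = mode, data = data), class = "hill_fit")
}

# standard errors from the linearized covariance at the optimum,
# in natural (half_max, slope) units
.hill_se <- function(conc, y, half_max, slope, mode, rss) {
  n <- length(y)
  if (n <= 2L) return(c(half_max = NA_real_, slope = NA_real_))
  J <- cbind(
    .num_deriv(function(h) .hill_eval(conc, h, slope, mode), half_max),
    .num_deriv(function(s) .hill_eval(conc, half_max, s, mode), slope))
  s2 <- rss / (n - 2L)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cov)) return(c(half_max = NA_real_, slope = NA_real_))
  stats::setNames(sqrt(pmax(diag(cov), 0)), c("half_max", "slope"))
}

# central finite difference of a vector-valued function of a scalar
.num_deriv <- function(f, x, rel = 1e-6) {
  h <- rel * max(abs(x), 1e-12)
  (f(x + h) - f(x - h)) / (2 * h)
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$mode == "activation") "EC50" else "IC50"
  cat(sprintf("Hill fit (%s): %s = %.4g M (%.4g uM), n = %.4g, rss = %.3g\n",
              x$mode, lab, x$half_max, x$half_max * 1e6, x$slope, x$rss))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(half_max = object$half_max, slope = object$slope)

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- data.frame(estimate = c(object$half_max, object$slope),
                    std_error = as.numeric(object$se),
                    row.names = c(if (object$mode == "activation")
                      "EC50 (M)" else "IC50 (M)", "slope n"))
  structure(list(table = tab, mode = object$mode, rss = object$rss,
                 n_points = nrow(object$data)),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Hill", x$mode, "fit on", x$n_points, "points\n")
  print(x$table)
  cat("residual sum of squares:", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  .hill_eval(conc, object$half_max, object$slope, object$mode)
}

#' @export
residuals.hill_fit <- function(object, ...)
  object$data$response - predict(object)

#' @export
plot.hill_fit <- function(x, y, ...) {
  d <- x$data
  graphics::plot(d$conc, d$response, log = "x",
                 xlab = "concentration (M)", ylab = "I / Imax", ...)
  grid_c <- exp(seq(log(min(d$conc)), log(max(d$conc)), length.out = 200))
  graphics::lines(grid_c, .hill_eval(grid_c, x$half_max, x$slope, x$mode))
  invisible(x)
}
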