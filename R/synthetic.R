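# Synthetic data generators: noisy traces, Hill-shaped datasets and
# confocal-like two-channel cell images with exact ground-truth masks.
# All generators are bit-reproducible given (params, seed).

#' Additive Gaussian noise specification
#'
#' @param sigma standard deviation of the additive Gaussian noise, in
#'   units of the signal (>= 0).
#' @param seed integer RNG seed.
#' @return Object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  structure(list(sigma = as.numeric(sigma), seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate code with a temporary RNG seed, restoring the caller's state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Add Gaussian noise to an occupancy trace
#'
#' Adds i.i.d. Gaussian noise to the open-probability channel of a
#' trace (emulating recording noise on a normalized current); seeded and
#' reproducible, with the seed recorded in the trace metadata.
#'
#' @param trace an \code{\link{occupancy_trace}}.
#' @param noise a \code{\link{noise_spec}}.
#' @return A new \code{occupancy_trace} with noisy \code{p_open} (the
#'   occupancy matrix, if present, is left noise-free).
#' @export
gen_noisy_trace <- function(trace, noise) {
  stopifnot(inherits(trace, "occupancy_trace"),
            inherits(noise, "noise_spec"))
  if (noise$sigma == 0) {
    trace$metadata$seed <- noise$seed
    return(trace)
  }
  eps <- .with_seed(noise$seed,
                    stats::rnorm(length(trace$p_open), 0, noise$sigma))
  md <- trace$metadata
  md$seed <- noise$seed
  md$noise_sigma <- noise$sigma
  occupancy_trace(trace$time, trace$occupancy,
                  p_open = trace$p_open + eps, metadata = md)
}

#' Generate a Hill-shaped concentration-response dataset
#'
#' Evaluates the activation or inhibition Hill equation at the given
#' concentrations and adds seeded Gaussian noise.  Responses are not
#' clamped, so noisy values may fall slightly outside [0, 1] (fits must
#' tolerate this).
#'
#' @param half_max EC50 (activation) or IC50 (inhibition), molar, > 0.
#' @param n Hill slope, > 0.
#' @param concentrations strictly positive molar grid, sorted ascending.
#' @param mode \code{"activation"} or \code{"inhibition"}.
#' @param noise a \code{\link{noise_spec}}.
#' @return A \code{\link{crc_data}}.
#' @export
gen_hill_dataset <- function(half_max, n, concentrations,
                             mode = c("activation", "inhibition"),
                             noise = noise_spec(0)) {
  mode <- match.arg(mode)
  stopifnot(half_max > 0, n > 0, inherits(noise, "noise_spec"))
  y <- .hill_eval(concentrations, half_max, n, mode)
  if (noise$sigma > 0)
    y <- y + .with_seed(noise$seed,
                        stats::rnorm(length(y), 0, noise$sigma))
  crc_data(concentrations, y, mode = mode)
}

#' Default synthetic image parameters
#'
#' A 256x256 frame containing one disk-shaped cell (radius 60 px) with a
#' bright membrane ring (width 4 px, the outermost annulus of the disk),
#' diffuse intracellular signal and uniform background.  The marker
#' channel (cell marker, e.g. eGFP) fills the whole cell; the label
#' channel (receptor label) carries the membrane/interior/background
#' intensities.  A membrane-only labelling condition is emulated by
#' setting \code{interior_intensity = background_intensity}.
#'
#' @param ... overrides for any default parameter.
#' @return Named list of image parameters.
#' @export
image_params <- function(...) {
  p <- list(width = 256L, height = 256L,
            center = c(128.5, 128.5), radius = 60, ring_width = 4,
            membrane_intensity = 1000, interior_intensity = 300,
            background_intensity = 200,
            marker_cell_intensity = 800, marker_background_intensity = 50,
            sigma = 10)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown image parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  p
}

#' Generate a synthetic two-channel cell image
#'
#' Renders a disk cell with a membrane ring of stated width: the marker
#' channel fills the cell; the label channel takes the membrane
#' intensity on the ring, the interior intensity inside it, and the
#' background intensity outside the cell.  Seeded Gaussian noise is
#' added to both channels; the ground-truth masks (membrane ring, cell
#' interior, background) are exact and partition the frame.
#'
#' @param params parameter list from \code{\link{image_params}}.
#' @param seed integer RNG seed for the noise.
#' @return Object of class \code{"synthetic_image"}: list with
#'   \code{marker} and \code{label} intensity matrices, \code{masks}
#'   (logical matrices \code{membrane}, \code{interior},
#'   \code{background}), \code{params} and \code{seed}.
#' @export
gen_image <- function(params = image_params(), seed = 1L) {
  p <- params
  if (any(c(p$membrane_intensity, p$interior_intensity,
            p$background_intensity, p$marker_cell_intensity,
            p$marker_background_intensity) < 0) || p$sigma < 0)
    stop("intensities and noise sigma must be non-negative", call. = FALSE)
  if (p$center[1L] - p$radius < 1 || p$center[1L] + p$radius > p$width ||
      p$center[2L] - p$radius < 1 || p$center[2L] + p$radius > p$height)
    stop("cell geometry exceeds the image frame", call. = FALSE)
  if (p$ring_width <= 0 || p$ring_width >= p$radius)
    stop("'ring_width' must lie in (0, radius)", call. = FALSE)

  d <- sqrt(outer((seq_len(p$width) - p$center[1L])^2,
                  (seq_len(p$height) - p$center[2L])^2, "+"))
  membrane <- d <= p$radius & d > p$radius - p$ring_width
  interior <- d <= p$radius - p$ring_width
  background <- d > p$radius

  label <- matrix(p$background_intensity, p$width, p$height)
  label[interior] <- p$interior_intensity
  label[membrane] <- p$membrane_intensity
  marker <- matrix(p$marker_background_intensity, p$width, p$height)
  marker[membrane | interior] <- p$marker_cell_intensity

  if (p$sigma > 0) {
    npx <- p$width * p$height
    eps <- .with_seed(seed, stats::rnorm(2L * npx, 0, p$sigma))
    marker <- marker + matrix(eps[seq_len(npx)], p$width, p$height)
    label <- label + matrix(eps[npx + seq_len(npx)], p$width, p$height)
  }
  structure(list(marker = marker, label = label,
                 masks = list(membrane = membrane, interior = interior,
                              background = background),
                 params = p, seed = as.integer(seed)),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic two-channel cell image %dx%d (radius %g px, ring %g px)\n",
    "  label intensities: membrane %g, interior %g, background %g; ",
    "sigma %g\n"),
    x$params$width, x$params$height, x$params$radius, x$params$ring_width,
    x$params$membrane_intensity, x$params$interior_intensity,
    x$params$background_intensity, x$params$sigma))
  invisible(x)
}
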