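# Membrane fluorescence quantification: marker-channel segmentation,
# background-corrected membrane intensity (DeltaROI = ROI_CS - ROI_b)
# and normalization of condition means to a reference condition.

#' Segment the cell and define membrane / background ROIs
#'
#' Deterministic stand-in for manually drawn regions of interest: the
#' marker (cell marker, e.g. eGFP) channel is median filtered and
#' thresholded at a stated fraction of its maximum; the largest
#' connected component is taken as the cell; the membrane ROI is the
#' boundary band of stated width just inside the component edge, and the
#' background ROI is every pixel farther than a stated margin from the
#' component.
#'
#' @param marker_channel single-channel intensity matrix.
#' @param threshold fraction of the median-filtered maximum used as the
#'   segmentation threshold (default 0.5).
#' @param band_width width of the membrane band in pixels (default 4).
#' @param background_margin minimum distance (pixels) from the cell for
#'   background pixels (default 10).
#' @param median_radius radius of the median filter (default 2).
#' @return Object of class \code{"roi_masks"}: logical matrices
#'   \code{cell}, \code{membrane}, \code{background}.
#' @export
marker_mask <- function(marker_channel, threshold = 0.5, band_width = 4L,
                        background_margin = 10L, median_radius = 2L) {
  m <- as.matrix(marker_channel)
  if (max(m) <= 0)
    stop("no component above threshold: marker channel is blank",
         call. = FALSE)
  mn <- m / max(m)
  mn[mn < 0] <- 0
  mf <- EBImage::medianFilter(mn, median_radius)
  thr <- threshold * max(mf)
  if (thr <= 0)
    stop("no component above threshold in the marker channel",
         call. = FALSE)
  bw <- mf > thr
  if (!any(bw))
    stop("no component above threshold in the marker channel",
         call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  counts <- tabulate(as.integer(lab))
  cell <- matrix(as.integer(lab) == which.max(counts), nrow(m), ncol(m))

  # boundary band of exactly band_width pixels just inside the edge
  dist_inside <- as.matrix(EBImage::distmap(EBImage::Image(cell * 1)))
  membrane <- cell & dist_inside <= band_width

  dist_to_cell <- as.matrix(EBImage::distmap(EBImage::Image((!cell) * 1)))
  background <- dist_to_cell > background_margin

  if (!any(membrane) || !any(background))
    stop("degenerate segmentation: empty membrane or background ROI",
         call. = FALSE)
  structure(list(cell = cell, membrane = membrane, background = background),
            class = "roi_masks")
}

#' Background-corrected membrane fluorescence (DeltaROI)
#'
#' Mean label intensity over the membrane ROI minus the mean over the
#' background ROI: \code{delta_roi = roi_cs_mean - roi_b_mean}.
#'
#' @param label_channel single-channel intensity matrix (receptor label).
#' @param membrane,background logical ROI masks (non-empty, disjoint),
#'   e.g. from \code{\link{marker_mask}}.
#' @param image_id optional identifier recorded in the result.
#' @return Object of class \code{"roi_quant"}: \code{roi_cs_mean},
#'   \code{roi_b_mean}, \code{delta_roi}, \code{image_id}, \code{n_cs},
#'   \code{n_b} (ROI pixel counts).
#' @export
quantify_droi <- function(label_channel, membrane, background,
                          image_id = NA_character_) {
  lb <- as.matrix(label_channel)
  if (inherits(membrane, "roi_masks")) {
    background <- membrane$background
    membrane <- membrane$membrane
  }
  if (!any(membrane) || !any(background))
    stop("membrane and background ROIs must be non-empty", call. = FALSE)
  if (any(membrane & background))
    stop("membrane and background ROIs must be disjoint", call. = FALSE)
  cs <- mean(lb[membrane])
  b <- mean(lb[background])
  structure(list(roi_cs_mean = cs, roi_b_mean = b, delta_roi = cs - b,
                 image_id = image_id,
                 n_cs = sum(membrane), n_b = sum(background)),
            class = "roi_quant")
}

#' @export
print.roi_quant <- function(x, ...) {
  cat(sprintf(
    "ROI quantification%s: ROI_CS = %.4g, ROI_b = %.4g, DeltaROI = %.4g\n",
    if (is.na(x$image_id)) "" else paste0(" [", x$image_id, "]"),
    x$roi_cs_mean, x$roi_b_mean, x$delta_roi))
  invisible(x)
}

#' Normalize per-cell DeltaROI values to a reference condition
#'
#' Expresses each condition's mean background-corrected fluorescence as
#' a percentage of the reference condition's mean (e.g. labelling
#' normalized to WT receptors), and returns per-cell percentages as
#' well.
#'
#' @param values data.frame with columns \code{condition} and
#'   \code{delta_roi} (one row per cell), or a named list of numeric
#'   vectors.
#' @param reference name of the reference condition.
#' @return List with \code{summary} (data.frame: condition, n,
#'   mean_delta_roi, percent_of_reference) and \code{per_cell}
#'   (data.frame: condition, delta_roi, percent_of_reference).
#' @export
normalize_to_reference <- function(values, reference) {
  if (!is.data.frame(values)) {
    stopifnot(!is.null(names(values)))
    values <- data.frame(
      condition = rep(names(values), lengths(values)),
      delta_roi = unlist(values, use.names = FALSE))
  }
  stopifnot(all(c("condition", "delta_roi") %in% names(values)))
  if (!reference %in% values$condition)
    stop("reference condition '", reference, "' not present", call. = FALSE)
  ref_mean <- mean(values$delta_roi[values$condition == reference])
  if (ref_mean <= 0)
    stop("reference condition mean must be positive", call. = FALSE)
  agg <- stats::aggregate(delta_roi ~ condition, values, mean)
  n <- stats::aggregate(delta_roi ~ condition, values, length)
  summary <- data.frame(condition = agg$condition,
                        n = n$delta_roi,
                        mean_delta_roi = agg$delta_roi,
                        percent_of_reference = 100 * agg$delta_roi / ref_mean)
  per_cell <- data.frame(condition = values$condition,
                         delta_roi = values$delta_roi,
                         percent_of_reference =
                           100 * values$delta_roi / ref_mean)
  list(summary = summary, per_cell = per_cell)
}

# intensity scale used when storing images as 16-bit TIFF
.TIFF_SCALE <- 65535

#' Read / write a two-channel image as 16-bit TIFF
#'
#' Channels are stored as a two-page 16-bit TIFF with intensities
#' rounded to integers and scaled by 1/65535 (so raw intensities must
#' lie in [0, 65535]; quantization error is at most half an intensity
#' unit).  For a \code{\link{gen_image}} result the generation
#' parameters and seed are written to a JSON sidecar
#' (\code{<path>.json}), from which \code{read_image_tiff} rebuilds the
#' exact ground-truth masks.
#'
#' @param img \code{\link{gen_image}} result or a list with elements
#'   \code{marker} and \code{label}.
#' @param path file path.
#' @param sidecar write the ground-truth sidecar when the image carries
#'   generation parameters (default \code{TRUE}).
#' @return \code{read_image_tiff} returns a list with \code{marker} and
#'   \code{label} matrices (plus \code{masks}, \code{params} and
#'   \code{seed} when a sidecar is present); \code{write_image_tiff}
#'   returns \code{path} invisibly.
#' @export
write_image_tiff <- function(img, path, sidecar = TRUE) {
  ch <- list(marker = as.matrix(img$marker), label = as.matrix(img$label))
  for (nm in names(ch)) {
    if (min(ch[[nm]]) < 0 || max(ch[[nm]]) > .TIFF_SCALE)
      stop("channel '", nm, "' has intensities outside [0, 65535]",
           call. = FALSE)
  }
  tiff::writeTIFF(lapply(ch, function(x) round(x) / .TIFF_SCALE), path,
                  bits.per.sample = 16L)
  if (sidecar && !is.null(img$params))
    jsonlite::write_json(list(params = img$params, seed = img$seed),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop("expected a two-page (marker, label) TIFF, found ",
         length(pages), " page(s)", call. = FALSE)
  out <- list(marker = pages[[1L]] * .TIFF_SCALE,
              label = pages[[2L]] * .TIFF_SCALE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    params <- do.call(image_params, as.list(meta$params))
    truth <- gen_image(params, seed = meta$seed)
    out$masks <- truth$masks
    out$params <- params
    out$seed <- meta$seed
  }
  out
}
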