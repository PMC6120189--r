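# Delimited-text trace IO, run configuration, and the end-to-end
# reproduction run.  Files use comma separation, "." decimals, UTF-8,
# Unix newlines; units are seconds and molar throughout.

.trace_cols <- function() c("time_s", "p_open",
                            paste0("occ_", SCHEME_STATES))

#' Write / read an occupancy trace as delimited text
#'
#' Column layout: \code{time_s}, \code{p_open}, and (when full
#' occupancies are present) \code{occ_R}, \code{occ_AR}, \code{occ_AF},
#' \code{occ_AO}, \code{occ_AFD}, \code{occ_AOD}.  Values are written
#' with 17 significant digits so a write/read round trip is lossless to
#' better than 1e-12 relative.
#'
#' @param trace an \code{\link{occupancy_trace}}.
#' @param path file path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns an \code{occupancy_trace}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "occupancy_trace"))
  df <- data.frame(time_s = trace$time, p_open = trace$p_open)
  if (!is.null(trace$occupancy)) {
    occ <- as.data.frame(trace$occupancy)
    names(occ) <- paste0("occ_", SCHEME_STATES)
    df <- cbind(df, occ)
  }
  txt <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = TRUE),
                character(nrow(df)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(matrix(txt, nrow = nrow(df)), 1L, paste, collapse = ","),
             con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first) || !nzchar(first))
    stop("trace file is empty: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("trace file has no data rows: ", path, call. = FALSE)
  for (need in c("time_s", "p_open"))
    if (!need %in% names(df))
      stop("trace file is missing required column '", need, "'",
           call. = FALSE)
  bad <- setdiff(names(df), .trace_cols())
  if (length(bad))
    stop("trace file has unexpected column '", bad[1L], "'", call. = FALSE)
  occ_cols <- paste0("occ_", SCHEME_STATES)
  occ <- NULL
  if (any(occ_cols %in% names(df))) {
    missing <- setdiff(occ_cols, names(df))
    if (length(missing))
      stop("trace file is missing occupancy column '", missing[1L], "'",
           call. = FALSE)
    occ <- as.matrix(df[, occ_cols])
    colnames(occ) <- SCHEME_STATES
  }
  occupancy_trace(df$time_s, occ, p_open = df$p_open,
                  metadata = list(source = path))
}

#' Write / read concentration-response tables
#'
#' Delimited text with columns \code{conc_M} and \code{response}.
#'
#' @param data a \code{\link{crc_data}}.
#' @param path file path.
#' @param mode mode to attach when reading.
#' @return \code{read_crc} returns a \code{crc_data}.
#' @export
write_crc <- function(data, path) {
  stopifnot(inherits(data, "crc_data"))
  df <- data.frame(conc_M = format(data$conc, digits = 17, trim = TRUE),
                   response = format(data$response, digits = 17,
                                     trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_crc
#' @export
read_crc <- function(path, mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE)
  for (need in c("conc_M", "response"))
    if (!need %in% names(df))
      stop("CRC file is missing required column '", need, "'",
           call. = FALSE)
  crc_data(df$conc_M, df$response, mode = mode)
}

.CONFIG_DEFAULTS <- list(
  scheme = NULL,          # path to a scheme JSON (NULL = calibrate)
  targets = "default",    # target set name
  n_starts = 32L,
  seed = 1L,
  dt = 0.01,
  out_dir = NULL          # directory for the report files (NULL = none)
)

#' Read a run configuration
#'
#' JSON configuration for \code{\link{run_reproduction}}; unknown keys
#' and wrongly typed values are rejected, and missing keys take
#' defaults (\code{targets = "default"}, \code{n_starts = 32},
#' \code{seed = 1}, \code{dt = 0.01}).
#'
#' @param path JSON file path, or \code{NULL} for the defaults.
#' @return Named list of class \code{"run_config"}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(x), names(.CONFIG_DEFAULTS))
    if (length(bad))
      stop("unknown configuration key '", bad[1L], "'", call. = FALSE)
    cfg[names(x)] <- x
  }
  chk_num <- function(key, integer = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (integer && v != round(v)))
      stop("configuration key '", key, "' must be a single ",
           if (integer) "integer" else "number", call. = FALSE)
  }
  chk_num("n_starts", integer = TRUE)
  chk_num("seed", integer = TRUE)
  chk_num("dt")
  if (!identical(cfg$targets, "default"))
    stop("configuration key 'targets' must be \"default\"", call. = FALSE)
  if (!is.null(cfg$scheme) && !is.character(cfg$scheme))
    stop("configuration key 'scheme' must be a file path", call. = FALSE)
  if (!is.null(cfg$out_dir) && !is.character(cfg$out_dir))
    stop("configuration key 'out_dir' must be a directory path",
         call. = FALSE)
  cfg$n_starts <- as.integer(cfg$n_starts)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param config a \code{"run_config"} list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config[!vapply(config, is.null, logical(1L))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full reproduction pipeline
#'
#' Calibrates the wild-type rate set against the published rho1 summary
#' statistics (or evaluates a supplied scheme), tabulates the six
#' targets with model values and tolerance verdicts, checks the
#' EC50 fold change between W329A and WT (published values 25.76 and
#' 2.19 uM give a 11.8-fold increase; the model ratio is computed from
#' the fitted scheme), and reports per-genotype desensitization.  The
#' report is deterministic given the configuration seed.
#'
#' @param config a \code{"run_config"} from \code{\link{read_run_config}}.
#' @return List of class \code{"reproduction_report"} with elements
#'   \code{targets} (data.frame), \code{fold_change},
#'   \code{desensitization_pct}, \code{rates}, \code{loss},
#'   \code{converged}, \code{seed}.  When \code{config$out_dir} is set,
#'   \code{report.json} and \code{report.txt} are written there.
#' @export
run_reproduction <- function(config = read_run_config()) {
  stopifnot(inherits(config, "run_config"))
  targets <- default_targets()
  if (is.null(config$scheme)) {
    cal <- calibrate_scheme(targets, n_starts = config$n_starts,
                            seed = config$seed, dt = config$dt)
  } else {
    # a supplied scheme is evaluated as-is against the targets
    wt <- read_scheme(config$scheme)
    ev <- .evaluate_targets(wt, targets, dt = config$dt)
    cal <- list(scheme = wt, table = ev$table, loss = ev$loss,
                converged = ev$converged, stats = ev$stats,
                seed = config$seed)
  }
  ec50s <- vapply(cal$stats, `[[`, numeric(1L), "ec50")
  printed_fold <- 25.76e-6 / 2.19e-6
  model_fold <- unname(ec50s["W329A"] / ec50s["WT"])
  report <- structure(list(
    targets = cal$table,
    fold_change = list(printed = printed_fold,
                       model = model_fold,
                       printed_ge_10 = printed_fold >= 10,
                       model_ge_10 = model_fold >= 10),
    desensitization_pct = vapply(cal$stats, `[[`, numeric(1L),
                                 "desensitization_pct"),
    rates = scheme_rates(cal$scheme),
    loss = cal$loss,
    converged = cal$converged,
    seed = cal$seed),
    class = "reproduction_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(targets = report$targets, fold_change = report$fold_change,
           desensitization_pct = as.list(report$desensitization_pct),
           rates = as.list(report$rates), loss = report$loss,
           converged = report$converged, seed = report$seed),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    con <- file(file.path(config$out_dir, "report.txt"), open = "wb")
    sink(con)
    print(report)
    sink()
    close(con)
  }
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("Reproduction run (seed %d)\n\n", x$seed))
  tab <- x$targets
  for (i in seq_len(nrow(tab))) {
    sc <- if (tab$statistic[i] == "ec50") 1e6 else 1
    un <- if (tab$statistic[i] == "ec50") "uM" else "s"
    cat(sprintf(
      "  %-5s %-12s model %9.4g %s   printed %8.4g +/- %.3g %s  [%s]\n",
      tab$genotype[i], tab$statistic[i], tab$model_value[i] * sc, un,
      tab$printed_mean[i] * sc, tab$printed_sem[i] * sc, un,
      if (tab$within_tolerance[i]) "within 1 SEM" else "outside 1 SEM"))
  }
  cat(sprintf("\n  EC50 fold change W329A/WT: printed %.3g, model %.3g\n",
              x$fold_change$printed, x$fold_change$model))
  cat("  desensitization at 60 s (%):",
      paste(sprintf("%s %.1f", names(x$desensitization_pct),
                    x$desensitization_pct), collapse = ", "), "\n")
  cat(sprintf("  loss %.4g; %s\n", x$loss,
              if (x$converged) "all six targets within 1 SEM"
              else "not all targets within 1 SEM"))
  invisible(x)
}
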