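#' @title Plain-text readers and writers
#' @description Spike trains, conductance traces, correlograms,
#'   population configs and results bundles are exchanged as plain-text
#'   CSV/YAML. Numeric columns are written with 17 significant digits
#'   where a lossless 64-bit round trip is needed; spike times are
#'   written at microsecond precision.
#' @name io
NULL

fmt_num <- function(x, digits = 17) sprintf("%.*g", digits, x)

#' Write/read spike trains as CSV
#'
#' Long format with columns \code{source_id}, \code{time_s}; times are
#' written at 1 microsecond precision. A \code{# duration_s=} comment
#' header preserves the observation window.
#'
#' @param trains A [spike_train()] or list of them.
#' @param path File path.
#' @return \code{read_spike_trains} returns a named list of
#'   [spike_train()]s.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  duration <- max(vapply(trains, function(tr) tr$duration, numeric(1)))
  ids <- vapply(seq_along(trains), function(i) {
    id <- trains[[i]]$source_id
    if (is.na(id)) as.character(i) else as.character(id)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%s", fmt_num(duration)), con)
  writeLines("source_id,time_s", con)
  for (i in seq_along(trains))
    if (length(trains[[i]]$times))
      writeLines(sprintf("%s,%.6f", ids[i], trains[[i]]$times), con)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  first <- readLines(path, n = 1L)
  duration <- if (startsWith(first, "# duration_s="))
    as.numeric(sub("# duration_s=", "", first, fixed = TRUE)) else NA_real_
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "numeric"))
  if (is.na(duration)) duration <- max(df$time_s) + 1e-6
  lapply(split(df$time_s, factor(df$source_id, levels = unique(df$source_id))),
         function(t) spike_train(sort(t), duration))
}

#' Read raw unitary conductances from CSV
#'
#' One conductance (nS) per row; an optional single header line is
#' skipped automatically.
#'
#' @param path File path.
#' @return Numeric vector of raw conductances.
#' @export
read_conductances_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))))
    lines <- lines[-1L]
  vals <- suppressWarnings(
    as.numeric(vapply(strsplit(lines, ","), `[`, character(1), 1L)))
  if (any(is.na(vals))) stop("non-numeric conductance values in ", path)
  vals
}

#' Write/read a conductance trace as CSV
#'
#' Values are written with 17 significant digits so the 64-bit trace
#' round-trips losslessly; \code{t0}, \code{dt} and the unit live in
#' comment headers.
#'
#' @param trace A \code{conductance_trace}.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# t0=%s", fmt_num(trace$t0)),
               sprintf("# dt=%s", fmt_num(trace$dt)),
               "# unit=nS", "g_nS"), con)
  writeLines(fmt_num(trace$values), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  get <- function(key) as.numeric(sub(paste0("# ", key, "="), "",
                                      grep(paste0("^# ", key, "="), hdr,
                                           value = TRUE), fixed = TRUE))
  vals <- utils::read.csv(path, comment.char = "#")$g_nS
  new_trace(vals, dt = get("dt"), t0 = get("t0"))
}

#' Write a correlogram (or pause PSTH) as CSV
#'
#' Columns \code{lag_ms}, \code{rate_sps}, \code{probability}; bin,
#' window, reference count and baseline are recorded in comment headers.
#'
#' @param c A \code{correlogram}.
#' @param path File path.
#' @export
write_correlogram_csv <- function(c, path) {
  stopifnot(inherits(c, "correlogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_ms=%s", fmt_num(c$bin)),
               sprintf("# window_ms=%s", fmt_num(c$window)),
               sprintf("# n_ref=%d", c$n_ref),
               sprintf("# baseline_sps=%s", fmt_num(c$baseline)),
               sprintf("# baseline_window_ms=%s,%s",
                       fmt_num(c$baseline_window[1]),
                       fmt_num(c$baseline_window[2])),
               "lag_ms,rate_sps,probability"), con)
  writeLines(sprintf("%s,%s,%s", fmt_num(c$lag_ms), fmt_num(c$rate),
                     fmt_num(c$prob)), con)
  invisible(path)
}

#' Write/read an input population as a YAML config
#'
#' Records amplitudes, rates, ISI kinds, synchrony groups and
#' provenance.
#'
#' @param pop An [input_population()].
#' @param path File path.
#' @export
write_population_config <- function(pop, path) {
  stopifnot(inherits(pop, "input_population"))
  yaml::write_yaml(list(provenance = pop$provenance,
                        amplitude_nS = pop$inputs$amplitude,
                        rate_sps = pop$inputs$rate,
                        isi_kind = pop$inputs$kind,
                        sync_group = pop$inputs$sync_group), path)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  input_population(cfg$amplitude_nS, rate = cfg$rate_sps,
                   kind = cfg$isi_kind, sync_group = cfg$sync_group,
                   provenance = cfg$provenance)
}

#' Save/load a results bundle as a plain-text directory
#'
#' The configuration snapshot goes to \code{config.yaml}; every data
#' frame in the bundle goes to \code{<name>.csv} with numeric columns at
#' 17 significant digits, so the bundle round-trips losslessly.
#'
#' @param bundle A \code{results_bundle} from a \code{run_fig*} function.
#' @param dir Output directory (created if needed).
#' @export
save_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(bundle$config, file.path(dir, "config.yaml"))
  for (nm in setdiff(names(bundle), "config")) {
    df <- bundle[[nm]]
    if (!is.data.frame(df)) next
    out <- df
    for (cl in names(out))
      if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
    utils::write.csv(out, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname save_results_bundle
#' @export
read_results_bundle <- function(dir) {
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  tabs <- lapply(csvs, utils::read.csv)
  names(tabs) <- sub("\\.csv$", "", basename(csvs))
  structure(c(list(config = config), tabs), class = "results_bundle")
}
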