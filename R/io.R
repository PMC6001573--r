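# Plain-text interchange. All on-disk formats are CSV/TSV/JSON so that
# synthetic fixtures, pipeline outputs and CLI runs stay portable and
# diffable; heavyweight binary containers are intentionally not used.

#' Write / read an I/V curve as CSV
#' @param curve an [iv_curve()].
#' @param path file path.
#' @return `read_iv_csv` returns an [iv_curve()].
#' @export
write_iv_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  d <- read.csv(path)
  iv_curve(d$v_mV, d$i_pA)
}

#' Write / read a current trace as CSV
#'
#' Columns `time_s`, `current_pA`; the sampling rate is recovered from the
#' time column on read.
#' @param trace a [current_trace()].
#' @param path file path.
#' @return `read_trace_csv` returns a [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$samples)
  write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$sampling_hz,
                       current_pA = trace$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  dt <- median(diff(d$time_s))
  current_trace(d$current_pA, sampling_hz = 1 / dt)
}

#' Write / read a sweep set as long-format CSV plus a JSON protocol
#'
#' The CSV has columns `step_mV`, `time_s`, `current_pA`; the protocol is
#' stored beside it as `<path>.protocol.json`.
#' @param sweeps a `sweep_set`.
#' @param path CSV file path.
#' @return `read_sweepset_csv` returns a `sweep_set`.
#' @export
write_sweepset_csv <- function(sweeps, path) {
  vs <- protocol_steps(sweeps$protocol)
  long <- do.call(rbind, lapply(seq_along(vs), function(k) {
    tr <- sweeps$traces[[k]]
    n <- length(tr$samples)
    data.frame(step_mV = vs[k], time_s = (seq_len(n) - 1) / tr$sampling_hz,
               current_pA = tr$samples)
  }))
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(unclass(sweeps$protocol),
                       paste0(path, ".protocol.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sweepset_csv
#' @export
read_sweepset_csv <- function(path) {
  d <- read.csv(path)
  pj <- jsonlite::read_json(paste0(path, ".protocol.json"),
                            simplifyVector = TRUE)
  protocol <- do.call(voltage_step_protocol, pj)
  traces <- lapply(split(d, d$step_mV), function(s) {
    dt <- median(diff(s$time_s))
    current_trace(s$current_pA, sampling_hz = 1 / dt,
                  command_mV = s$step_mV[1])
  })
  vs <- protocol_steps(protocol)
  traces <- traces[as.character(vs)]
  structure(list(protocol = protocol, traces = traces, label = NA),
            class = "sweep_set")
}

#' Write / read an event list as CSV
#' @param events an `event_list` (or any data frame of events).
#' @param path file path.
#' @return `read_events_csv` returns a data frame.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) read.csv(path)

#' Write / read an assay table as TSV
#'
#' Values go to `<stem>.tsv` (first column the feature id, header row the
#' sample labels), flags (if any) to `<stem>.flags.tsv` and the sample
#' annotation to `<stem>.samples.csv`.
#' @param table an [assay_table()].
#' @param stem path stem without extension.
#' @return `read_assay_tsv` returns an [assay_table()].
#' @export
write_assay_tsv <- function(table, stem) {
  v <- data.frame(feature = rownames(table$values), table$values,
                  check.names = FALSE)
  write.table(v, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(table$flags)) {
    fl <- data.frame(feature = rownames(table$values), table$flags,
                     check.names = FALSE)
    write.table(fl, paste0(stem, ".flags.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  write.csv(table$samples, paste0(stem, ".samples.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_assay_tsv
#' @export
read_assay_tsv <- function(stem) {
  v <- read.delim(paste0(stem, ".tsv"), check.names = FALSE)
  values <- as.matrix(v[, -1, drop = FALSE])
  rownames(values) <- v$feature
  samples <- read.csv(paste0(stem, ".samples.csv"))
  flags <- NULL
  fp <- paste0(stem, ".flags.tsv")
  if (file.exists(fp)) {
    fl <- read.delim(fp, check.names = FALSE)
    flags <- as.matrix(fl[, -1, drop = FALSE])
    rownames(flags) <- fl$feature
    storage.mode(flags) <- "integer"
  }
  assay_table(values, samples, flags = flags)
}

#' Write / read a movie as per-frame CSV plus a JSON sidecar
#'
#' Each frame is stored as `frame_NNNN.csv` (raw numeric matrix, no
#' header) under `dir`; metadata (pixel size, frame interval, shape) goes
#' to `movie.json`. Intended for small fixtures; large movies should be
#' regenerated from their spec instead.
#' @param movie a [time_lapse_movie()].
#' @param dir output directory (created if needed).
#' @return `read_movie_dir` returns a [time_lapse_movie()].
#' @export
write_movie_dir <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(movie$frames))
    write.table(movie$frames[[f]],
                file.path(dir, sprintf("frame_%04d.csv", f)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_size_um = movie$pixel_size_um,
                            frame_interval_s = movie$frame_interval_s,
                            n_frames = length(movie$frames),
                            shape = dim(movie$frames[[1]])),
                       file.path(dir, "movie.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_movie_dir
#' @export
read_movie_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  frames <- lapply(files, function(f)
    as.matrix(read.csv(f, header = FALSE)))
  frames <- lapply(frames, function(m) {
    dimnames(m) <- NULL
    m
  })
  time_lapse_movie(frames, meta$pixel_size_um, meta$frame_interval_s)
}
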