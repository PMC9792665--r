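#' Labeled multi-channel time-series table
#'
#' The universal container for gait signals (activations, excitations, joint
#' moments). Holds a strictly increasing time vector in seconds, a numeric
#' data matrix with one column per channel, and free-form string metadata
#' (e.g. the OpenSim `inDegrees` flag).
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param data numeric matrix with `length(time)` rows; column names are used
#'   as channel labels when `labels` is missing.
#' @param labels character vector of unique channel names.
#' @param metadata named character vector of key/value pairs.
#' @return An object of class `ts_table` with fields `time`, `data`
#'   (labeled columns), and `metadata`.
#' @examples
#' tab <- ts_table(seq(0, 1, by = 0.1), cbind(a = sin(seq(0, 1, by = 0.1))))
#' n_samples(tab)
#' @export
ts_table <- function(time, data, labels = colnames(data),
                     metadata = character()) {
  time <- as.numeric(time)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- sprintf("ch%d", seq_len(ncol(data)))
  }
  if (length(time) != nrow(data)) {
    stop_trunksyn("argument_error", sprintf(
      "time has %d samples but data has %d rows", length(time), nrow(data)))
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop_trunksyn("argument_error", "time must be strictly increasing")
  }
  if (anyDuplicated(labels)) {
    stop_trunksyn("argument_error", "channel labels must be unique")
  }
  if (length(labels) != ncol(data)) {
    stop_trunksyn("argument_error", "one label per data column required")
  }
  colnames(data) <- labels
  structure(list(time = time, data = data,
                 metadata = stats::setNames(as.character(metadata),
                                            names(metadata))),
            class = "ts_table")
}

#' @rdname ts_table
#' @param x a `ts_table`.
#' @export
n_samples <- function(x) length(x$time)

#' @rdname ts_table
#' @export
channel_labels <- function(x) colnames(x$data)

#' @export
print.ts_table <- function(x, ...) {
  cat(sprintf("<ts_table> %d samples x %d channels, t in [%.4g, %.4g] s\n",
              n_samples(x), ncol(x$data),
              if (n_samples(x)) min(x$time) else NA,
              if (n_samples(x)) max(x$time) else NA))
  cat("channels:", paste(utils::head(channel_labels(x), 8), collapse = ", "),
      if (ncol(x$data) > 8) "..." else "", "\n")
  invisible(x)
}

# condition constructor shared by all modules; classes:
# argument_error, data_error, format_error, io_error, degenerate_synergy_error
stop_trunksyn <- function(class, msg) {
  stop(structure(class = c(class, "trunksyn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read an OpenSim storage (.sto/.mot) file
#'
#' Parses the storage dialect: free-form header lines (including `key=value`
#' pairs kept as metadata) terminated by `endheader`, then a delimited column
#' label row whose first column must be `time`, then a numeric body. Both tab
#' and space delimiters are tolerated.
#'
#' @param path path to an existing `.sto`/`.mot` file.
#' @return a [ts_table()].
#' @seealso [write_storage()]
#' @export
read_storage <- function(path) {
  if (!file.exists(path)) {
    stop_trunksyn("io_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) {
    stop_trunksyn("format_error",
                  sprintf("%s: no 'endheader' line found", path))
  }
  end <- end[1]
  header <- lines[seq_len(end - 1)]
  kv <- grep("=", header, fixed = TRUE, value = TRUE)
  metadata <- character()
  if (length(kv)) {
    parts <- strsplit(kv, "=", fixed = TRUE)
    metadata <- vapply(parts, function(p) trimws(paste(p[-1], collapse = "=")),
                       "")
    names(metadata) <- vapply(parts, function(p) trimws(p[1]), "")
  }
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) {
    stop_trunksyn("format_error", sprintf("%s: no column label row", path))
  }
  labels <- strsplit(trimws(body[1]), "[ \t]+")[[1]]
  if (labels[1] != "time") {
    stop_trunksyn("format_error",
                  sprintf("%s: first column must be 'time', got '%s'",
                          path, labels[1]))
  }
  rows <- body[-1]
  if (length(rows) == 0) {
    stop_trunksyn("format_error", sprintf("%s: empty numeric body", path))
  }
  fields <- strsplit(trimws(rows), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield != length(labels))
  if (length(bad)) {
    stop_trunksyn("format_error", sprintf(
      "%s: line %d has %d fields, expected %d",
      path, end + 1 + bad[1], nfield[bad[1]], length(labels)))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    badline <- ceiling(which(is.na(vals))[1] / length(labels))
    stop_trunksyn("format_error", sprintf(
      "%s: non-numeric value on line %d", path, end + 1 + badline))
  }
  mat <- matrix(vals, ncol = length(labels), byrow = TRUE)
  ts_table(mat[, 1], mat[, -1, drop = FALSE], labels[-1], metadata)
}

#' Write an OpenSim storage (.sto/.mot) file
#'
#' Emits a header with `name`, `nRows`, `nColumns`, `inDegrees` (taken from
#' the table metadata, default `no`) and `endheader`, then a tab-delimited
#' body. Values are written with 15 significant digits so that
#' `read_storage(write_storage(x))` round-trips within 1e-12.
#'
#' @param table a [ts_table()] with at least one data channel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_storage <- function(table, path) {
  stopifnot(inherits(table, "ts_table"))
  if (ncol(table$data) == 0) {
    stop_trunksyn("argument_error", "table has no data channels to write")
  }
  in_deg <- meta_get(table$metadata, "inDegrees", "no")
  name <- meta_get(table$metadata, "name", basename(path))
  header <- c(sprintf("name=%s", name),
              sprintf("nRows=%d", n_samples(table)),
              sprintf("nColumns=%d", ncol(table$data) + 1L),
              sprintf("inDegrees=%s", in_deg),
              "endheader")
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  body <- cbind(fmt(table$time), apply(table$data, 2, fmt))
  lines <- c(header,
             paste(c("time", channel_labels(table)), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_trunksyn("io_error", sprintf("cannot write %s", path))
  invisible(path)
}

meta_get <- function(metadata, key, default) {
  if (!is.null(names(metadata)) && key %in% names(metadata)) {
    metadata[[key]]
  } else {
    default
  }
}

#' Read/write a gait table as CSV
#'
#' CSV twin of the storage format: header row with `time` first, numeric
#' body. Metadata is not preserved in CSV.
#'
#' @param path file path.
#' @return `read_gait_csv` returns a [ts_table()]; `write_gait_csv` returns
#'   `path` invisibly.
#' @export
read_gait_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") {
    stop_trunksyn("format_error",
                  sprintf("%s: first CSV column must be 'time'", path))
  }
  ts_table(df[[1]], as.matrix(df[-1]))
}

#' @rdname read_gait_csv
#' @param table a [ts_table()].
#' @export
write_gait_csv <- function(table, path) {
  df <- data.frame(time = table$time, table$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Segment a trial into gait cycles at right foot strikes
#'
#' A gait cycle is the interval between two consecutive right foot strikes.
#' Samples are assigned by the half-open convention `[t_i, t_{i+1})` so no
#' sample belongs to two cycles.
#'
#' @param table a [ts_table()] covering all strike times.
#' @param footstrikes strictly increasing strike times in seconds (>= 2).
#' @return list of `ts_table` sub-tables, one per consecutive strike pair.
#' @export
segment_gait_cycles <- function(table, footstrikes) {
  stopifnot(inherits(table, "ts_table"))
  footstrikes <- as.numeric(footstrikes)
  if (length(footstrikes) < 2) {
    stop_trunksyn("argument_error", "need at least 2 foot-strike times")
  }
  if (any(diff(footstrikes) <= 0)) {
    stop_trunksyn("argument_error", "foot-strike times must be increasing")
  }
  rng <- range(table$time)
  if (any(footstrikes < rng[1] | footstrikes > rng[2])) {
    stop_trunksyn("argument_error",
                  "foot-strike times outside the table's time range")
  }
  lapply(seq_len(length(footstrikes) - 1), function(i) {
    keep <- table$time >= footstrikes[i] & table$time < footstrikes[i + 1]
    # the final cycle keeps its closing strike sample if it is the last sample
    if (i == length(footstrikes) - 1) {
      keep <- keep | table$time == footstrikes[i + 1] & footstrikes[i + 1] == rng[2]
    }
    ts_table(table$time[keep], table$data[keep, , drop = FALSE],
             metadata = table$metadata)
  })
}

#' Resample one gait cycle onto an even 0-100% grid
#'
#' Linear interpolation of every channel onto `n_pt` evenly spaced points
#' spanning the cycle; both endpoints are kept exactly. 101 points (1% steps)
#' is the gait-analysis convention.
#'
#' @param cycle a [ts_table()] with >= 2 samples.
#' @param n_pt number of output samples (>= 2), default 101.
#' @return a [ts_table()] with `n_pt` samples.
#' @export
resample_cycle <- function(cycle, n_pt = 101L) {
  stopifnot(inherits(cycle, "ts_table"))
  if (n_pt < 2) stop_trunksyn("argument_error", "n_pt must be >= 2")
  if (n_samples(cycle) < 2) {
    stop_trunksyn("argument_error", "cycle needs at least 2 samples")
  }
  tt <- seq(cycle$time[1], cycle$time[n_samples(cycle)], length.out = n_pt)
  out <- apply(cycle$data, 2, function(col) {
    stats::approx(cycle$time, col, xout = tt)$y
  })
  ts_table(tt, matrix(out, nrow = n_pt,
                      dimnames = list(NULL, channel_labels(cycle))),
           metadata = cycle$metadata)
}

#' Ensemble mean and standard deviation across gait cycles
#'
#' All cycles must share labels and sample count (time-normalize with
#' [resample_cycle()] first). Returns the per-sample, per-channel mean and
#' the sample standard deviation (denominator n-1; 0 for a single cycle).
#'
#' @param cycles list of [ts_table()] objects on a common grid.
#' @return list with `ts_table` elements `mean` and `sd` on the mean time
#'   base of the cycles.
#' @export
ensemble_stats <- function(cycles) {
  if (length(cycles) < 1) {
    stop_trunksyn("argument_error", "need at least one cycle")
  }
  labs <- channel_labels(cycles[[1]])
  np <- n_samples(cycles[[1]])
  for (cy in cycles) {
    if (!identical(channel_labels(cy), labs) || n_samples(cy) != np) {
      stop_trunksyn("argument_error",
                    "cycles differ in labels or sample count")
    }
  }
  arr <- vapply(cycles, function(cy) cy$data, cycles[[1]]$data)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(cycles) == 1) {
    matrix(0, np, length(labs), dimnames = list(NULL, labs))
  } else {
    apply(arr, c(1, 2), stats::sd)
  }
  tmean <- rowMeans(vapply(cycles, function(cy) cy$time, cycles[[1]]$time))
  # percent-of-cycle base: relabel as 0..100% over the mean duration
  list(mean = ts_table(tmean, mu), sd = ts_table(tmean, sdv))
}

#' Band-pass, rectify and envelope raw EMG
#'
#' Standard surface-EMG conditioning: zero-phase Butterworth band-pass,
#' full-wave rectification, zero-phase Butterworth low-pass envelope, and
#' optional normalization of each channel to its trial maximum. The filter
#' defaults are package conventions, not a reproduction of any particular
#' laboratory chain, and are all configurable.
#'
#' @param raw a [ts_table()] of raw EMG sampled at a constant rate.
#' @param band band-pass corner frequencies in Hz (default `c(30, 300)`).
#' @param envelope_cutoff low-pass envelope cutoff in Hz (default 6).
#' @param normalize divide each channel by its trial maximum (default TRUE).
#' @param order Butterworth order (default 4; applied forward-backward).
#' @return a [ts_table()] of nonnegative envelopes.
#' @export
process_emg <- function(raw, band = c(30, 300), envelope_cutoff = 6,
                        normalize = TRUE, order = 4L) {
  stopifnot(inherits(raw, "ts_table"))
  fs <- 1 / stats::median(diff(raw$time))
  nyq <- fs / 2
  if (any(band >= nyq) || envelope_cutoff >= nyq) {
    stop_trunksyn("argument_error", sprintf(
      "filter corner at or above Nyquist (%.4g Hz)", nyq))
  }
  bp <- signal::butter(order, band / nyq, type = "pass")
  lp <- signal::butter(order, envelope_cutoff / nyq, type = "low")
  env <- apply(raw$data, 2, function(col) {
    rect <- abs(signal::filtfilt(bp, col))
    e <- signal::filtfilt(lp, rect)
    pmax(e, 0)
  })
  env <- matrix(env, nrow = n_samples(raw),
                dimnames = list(NULL, channel_labels(raw)))
  if (normalize) {
    mx <- apply(env, 2, max)
    sel <- mx > 0
    env[, sel] <- sweep(env[, sel, drop = FALSE], 2, mx[sel], "/")
  }
  ts_table(raw$time, env, metadata = raw$metadata)
}
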