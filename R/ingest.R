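KINEMATIC_SEGMENTS <- c("head", "hand_L", "hand_R", "shoulder_L", "shoulder_R", "pelvis")

#' Read and validate a motif segmentation table
#'
#' Expects a CSV with columns `motif_id`, `performance_id`, `performer_id`,
#' `start_s`, `end_s` (and optionally `raga_id`). Validation rejects, with
#' messages naming the offending row: missing columns, duplicate motif ids,
#' non-positive durations, durations under the 1.5 s segmentation floor,
#' and overlapping motifs within one performance.
#'
#' @param path CSV file path.
#' @param min_duration_s Minimum motif duration (s), default 1.5.
#' @return A validated data.frame of motif records.
#' @export
read_motif_table <- function(path, min_duration_s = 1.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_motif_table(df, min_duration_s, where = path)
}

validate_motif_table <- function(df, min_duration_s = 1.5, where = "motif table") {
  need <- c("motif_id", "performance_id", "performer_id", "start_s", "end_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: missing required column(s): %s", where, paste(missing, collapse = ", "))
  if (!"raga_id" %in% names(df)) df$raga_id <- NA_character_
  df$raga_id <- as.character(df$raga_id)
  df$motif_id <- as.character(df$motif_id)
  if (anyDuplicated(df$motif_id))
    stopf("%s: duplicate motif_id in row %d", where, anyDuplicated(df$motif_id))
  bad <- which(!is.finite(df$start_s) | !is.finite(df$end_s) |
                 df$end_s <= df$start_s)
  if (length(bad))
    stopf("%s: non-positive duration in row %d (motif %s)", where, bad[1L],
          df$motif_id[bad[1L]])
  short <- which(df$end_s - df$start_s < min_duration_s - 1e-9)
  if (length(short))
    stopf("%s: duration below %.2f s floor in row %d (motif %s)", where,
          min_duration_s, short[1L], df$motif_id[short[1L]])
  for (perf in unique(df$performance_id)) {
    sub <- df[df$performance_id == perf, , drop = FALSE]
    o <- order(sub$start_s)
    s <- sub$start_s[o]; e <- sub$end_s[o]
    ov <- which(s[-1L] < e[-length(e)] - 1e-9)
    if (length(ov))
      stopf("%s: overlapping motifs %s and %s in performance %s", where,
            sub$motif_id[o][ov[1L]], sub$motif_id[o][ov[1L] + 1L], perf)
  }
  df[need[c(1:3)]] <- lapply(df[need[c(1:3)]], as.character)
  df
}

#' Write a motif table CSV
#' @param table Motif table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read per-frame motion tracking data
#'
#' Long-format CSV with columns `t`, `segment`, `px,py,pz`, `vx,vy,vz`,
#' `ax,ay,az`: one row per (frame, tracked segment). Rows are returned
#' sorted by time; unknown segment labels and duplicated time stamps
#' within a segment are rejected, and frame-grid gaps beyond one-sample
#' jitter are reported via the `gaps` attribute.
#'
#' @param path CSV file path.
#' @param rate Nominal frame rate (Hz) used for gap detection, default 60.
#' @return Data.frame sorted by `t` with an attribute `gaps` (data.frame
#'   of detected gaps per segment; zero rows when the grid is uniform).
#' @export
read_kinematics <- function(path, rate = 60) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "segment", "px", "py", "pz", "vx", "vy", "vz", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  unknown <- setdiff(unique(df$segment), KINEMATIC_SEGMENTS)
  if (length(unknown))
    stopf("%s: unknown segment label(s) %s; allowed: %s", path,
          paste(unknown, collapse = ", "),
          paste(KINEMATIC_SEGMENTS, collapse = ", "))
  num <- setdiff(need, "segment")
  if (any(!vapply(df[num], is.numeric, logical(1))) ||
      any(vapply(df[num], function(x) any(!is.finite(x)), logical(1))))
    stopf("%s: non-finite or non-numeric values in frame data", path)
  df <- df[order(df$segment, df$t), , drop = FALSE]
  rownames(df) <- NULL
  gaps <- do.call(rbind, lapply(split(df$t, df$segment), function(tt) {
    if (anyDuplicated(tt)) stopf("%s: duplicated time stamps within a segment", path)
    d <- diff(tt)
    bad <- which(d > 2 / rate + 1e-9)   # > one-sample jitter
    if (!length(bad)) return(NULL)
    data.frame(from_s = tt[bad], to_s = tt[bad + 1L])
  }))
  if (!is.null(gaps) && nrow(gaps))
    warnf("%s: %d frame-grid gap(s) detected", path, nrow(gaps))
  attr(df, "gaps") <- gaps %||% data.frame(from_s = numeric(), to_s = numeric())
  df
}

#' Write per-frame motion tracking data
#' @param frames Long-format frame data.frame (see [read_kinematics()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(frames, path) {
  write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' Slice a uniform series to a motif's time span
#'
#' Half-open slice `[start_s, end_s)` at the series' native rate, so
#' adjacent motifs never share a frame. Sample i (1-based) lives at time
#' `t0 + (i - 1) / rate`.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @param rate Sampling rate of `x` (Hz).
#' @param record List or one-row data.frame with `start_s` and `end_s`.
#' @param t0 Time of the first sample of `x` (s), default 0.
#' @return The sliced series (same type as `x`).
#' @export
slice_motif <- function(x, rate, record, t0 = 0) {
  m <- as_series_matrix(x)
  n <- nrow(m)
  t_end <- t0 + n / rate                     # half-open coverage of x
  if (record$start_s < t0 - 1e-9 || record$end_s > t_end + 1e-9)
    stopf("slice_motif: motif [%g, %g) outside series extent [%g, %g)",
          record$start_s, record$end_s, t0, t_end)
  i0 <- ceiling((record$start_s - t0) * rate - 1e-9) + 1L
  i1 <- ceiling((record$end_s - t0) * rate - 1e-9)    # last index with t < end
  if (i1 < i0) stopf("slice_motif: empty slice")
  out <- m[i0:i1, , drop = FALSE]
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Write / read the all-pairs distance table
#'
#' Lossless CSV round trip of the pair metadata and all 10 DTW distance
#' columns; the reader validates the exact column set and rejects tables
#' with missing distance columns.
#'
#' @param table A `distance_table` (see [build_distance_table()]).
#' @param path CSV path.
#' @return `write_distance_table`: `path` invisibly; `read_distance_table`:
#'   the validated `distance_table`.
#' @export
write_distance_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("motif_i", "motif_j", "performer_i", "performer_j",
            "same_performer", distance_feature_names())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: distance table missing column(s): %s", path,
          paste(missing, collapse = ", "))
  dc <- distance_feature_names()
  bad <- vapply(df[dc], function(x) any(!is.finite(x)) || any(x < 0), logical(1))
  if (any(bad))
    stopf("%s: non-finite or negative distances in column(s): %s", path,
          paste(dc[bad], collapse = ", "))
  df <- df[c(need, setdiff(names(df), need))]
  class(df) <- c("distance_table", "data.frame")
  df
}

#' Write per-motif feature series as CSV
#'
#' Sonic series are written as `(t, value)`; kinematic series as
#' `(t, x, y, z)`.
#'
#' @param x Numeric vector (sonic) or n x 3 matrix (kinematic).
#' @param rate Frame rate (Hz).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(x, rate, path) {
  m <- as_series_matrix(x)
  t <- (seq_len(nrow(m)) - 1) / rate
  df <- if (ncol(m) == 1L) data.frame(t = t, value = m[, 1L])
        else data.frame(t = t, x = m[, 1L], y = m[, 2L], z = m[, 3L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_series
#' @param path CSV path to read.
#' @return `read_feature_series`: list with `series` and `rate` (inferred
#'   from the time column).
#' @export
read_feature_series <- function(path) {
  df <- read.csv(path)
  if (!"t" %in% names(df)) stopf("%s: feature series needs a 't' column", path)
  if (nrow(df) > 1L) {
    dt <- diff(df$t)
    if (max(abs(dt - dt[1L])) > 1e-6) stopf("%s: non-uniform time grid", path)
    rate <- 1 / dt[1L]
  } else rate <- NA_real_
  series <- if ("value" %in% names(df)) df$value else as.matrix(df[c("x", "y", "z")])
  list(series = series, rate = rate)
}

#' Minimal mono WAV I/O (16-bit PCM)
#'
#' Reads and writes single-channel RIFF/WAVE files with 16-bit integer
#' samples; multichannel files are averaged to mono on read. Samples are
#' scaled to [-1, 1].
#'
#' @param path WAV file path.
#' @return `read_wav`: list with `samples` (numeric in [-1, 1]) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("%s: not a RIFF file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stopf("%s: not a WAVE file", path)
  rate <- NULL; n_chan <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      n_chan <- fmt[2L]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      if (is.null(bits) || bits != 16L) stopf("%s: only 16-bit PCM supported", path)
      samples <- readBin(con, "integer", size / 2L, 2L, endian = "little")
      break
    } else invisible(readBin(con, "raw", size))
  }
  if (is.null(samples)) stopf("%s: no data chunk found", path)
  x <- samples / 32767
  if (n_chan > 1L) {
    n <- floor(length(x) / n_chan) * n_chan
    x <- rowMeans(matrix(x[1:n], ncol = n_chan, byrow = TRUE))
  }
  list(samples = x, rate = rate)
}

#' @rdname read_wav
#' @param samples Numeric waveform in [-1, 1] (clipped otherwise).
#' @param rate Sampling rate (Hz).
#' @export
write_wav <- function(samples, rate, path) {
  x <- as.integer(round(pmax(-1, pmin(1, as.numeric(samples))) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  data_size <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")            # PCM, mono
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4L, endian = "little") # byte rate
  writeBin(2L, con, 2L, endian = "little")                    # block align
  writeBin(16L, con, 2L, endian = "little")                   # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(x, con, 2L, endian = "little")
  invisible(path)
}

#' Write a synthetic dataset to the on-disk layout consumed by the readers
#'
#' Emits the motif table, one long-format kinematic frame CSV per
#' performance (requires `keep_raw = TRUE` at generation), and per-motif
#' sonic feature CSVs, under `dir`.
#'
#' @param dataset A `synth_dataset` generated with `keep_raw = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (is.null(dataset$raw))
    stopf("write_synth_dataset: generate with keep_raw = TRUE to export frames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_motif_table(dataset$motif_table, file.path(dir, "motifs.csv"))
  rate <- dataset$config$kinematic_rate_hz
  mt <- dataset$motif_table
  for (perf in unique(mt$performance_id)) {
    rows <- which(mt$performance_id == perf)
    frames <- do.call(rbind, lapply(rows, function(i) {
      segs <- dataset$raw[[mt$motif_id[i]]]
      do.call(rbind, lapply(names(segs), function(sn) {
        pos <- segs[[sn]]
        der <- derive_kinematics(pos, rate)
        nf <- nrow(pos)
        data.frame(t = mt$start_s[i] + (seq_len(nf) - 1) / rate, segment = sn,
                   px = pos[, 1], py = pos[, 2], pz = pos[, 3],
                   vx = der$velocity[, 1], vy = der$velocity[, 2],
                   vz = der$velocity[, 3],
                   ax = der$acceleration[, 1], ay = der$acceleration[, 2],
                   az = der$acceleration[, 3])
      }))
    }))
    write_kinematics(frames, file.path(dir, sprintf("kinematics_%s.csv", perf)))
  }
  sonic_dir <- file.path(dir, "sonic")
  dir.create(sonic_dir, showWarnings = FALSE)
  for (id in mt$motif_id) {
    s <- dataset$sonic[[id]]
    for (f in sonic_feature_names())
      write_feature_series(s[[f]], s$rate,
                           file.path(sonic_dir, sprintf("%s_%s.csv", id, f)))
  }
  invisible(dir)
}
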