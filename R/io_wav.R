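# Minimal RIFF/WAVE reader and writer for IEEE-float32 PCM, the cohort
# exchange format (2 channels per knee). Little-endian throughout.

#' Write a waveform matrix as a float32 WAV file
#'
#' @param channels numeric matrix, one column per channel.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(channels, fs, path) {
  channels <- as.matrix(channels)
  n <- nrow(channels); nch <- ncol(channels)
  data_bytes <- 4L * n * nch
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(x) writeChar(x, con, eos = NULL)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wc("RIFF"); wi(36L + data_bytes, 4L); wc("WAVE")
  wc("fmt "); wi(16L, 4L)
  wi(3L, 2L)                      # format 3 = IEEE float
  wi(nch, 2L)
  wi(round(fs), 4L)
  wi(round(fs) * nch * 4L, 4L)    # byte rate
  wi(nch * 4L, 2L)                # block align
  wi(32L, 2L)                     # bits per sample
  wc("data"); wi(data_bytes, 4L)
  interleaved <- as.numeric(t(channels))
  writeBin(interleaved, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a float32 WAV file
#'
#' Accepts IEEE-float32 WAV as written by [write_wav()]; unknown chunks are
#' skipped.
#'
#' @param path WAV file path.
#' @return list with \code{channels} (matrix, one column per channel) and
#'   \code{fs}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(size, signed = TRUE)
    readBin(con, "integer", n = 1L, size = size, endian = "little",
            signed = signed)
  tag <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(tag, "RIFF")) stop("not a RIFF file: ", path)
  ri(4L)
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- ri(4L)
    if (id == "fmt ") {
      fmt <- list(format = ri(2L), nch = ri(2L), fs = ri(4L))
      ri(4L); ri(2L)
      fmt$bits <- ri(2L)
      if (sz > 16L) readBin(con, "raw", n = sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt$format != 3L || fmt$bits != 32L)
        stop("only IEEE-float32 WAV is supported")
      samples <- readBin(con, "numeric", n = sz %/% 4L, size = 4L,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", n = sz + sz %% 2L)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  channels <- matrix(samples, ncol = fmt$nch, byrow = TRUE)
  list(channels = channels, fs = fmt$fs)
}

#' Write a cohort to disk
#'
#' One float32 stereo WAV per knee, named \code{<subject>_<side>.wav}, plus
#' \code{metadata.csv} (subject_id, knee_side, group, activity, wav_path,
#' seed).
#'
#' @param cohort a \code{jae_cohort}.
#' @param dir output directory (created if needed).
#' @return path of the metadata CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$metadata
  meta$wav_path <- paste0(meta$subject_id, "_", meta$knee_side, ".wav")
  meta$seed <- cohort$config$seed
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    write_wav(rec$channels, rec$fs, file.path(dir, meta$wav_path[i]))
  }
  csv <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort from disk
#'
#' Reads the layout written by [write_cohort()] (or externally collected
#' data in the same layout) back into a \code{jae_cohort}.
#'
#' @param dir directory containing WAV files and \code{metadata.csv}.
#' @return a \code{jae_cohort} (without simulation config).
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "metadata.csv")
  if (!file.exists(csv)) stop("metadata.csv not found in ", dir)
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  recordings <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    w <- read_wav(file.path(dir, meta$wav_path[i]))
    recordings[[i]] <- structure(
      list(subject_id = meta$subject_id[i], knee_side = meta$knee_side[i],
           group = meta$group[i], activity = meta$activity[i],
           channels = w$channels, fs = w$fs),
      class = "jae_recording")
  }
  if (is.null(meta$knee_id))
    meta$knee_id <- paste(meta$subject_id, meta$knee_side, sep = "_")
  structure(list(recordings = recordings, metadata = meta, config = NULL),
            class = "jae_cohort")
}

#' Validate and ingest an external recording directory
#'
#' Checks every knee against the pipeline's assumptions — a metadata row,
#' exactly two channels, a consistent sampling rate — and rejects failing
#' knees with per-knee messages while keeping the rest.
#'
#' @param dir directory with WAV files.
#' @param metadata_csv metadata CSV path (default \code{metadata.csv} in
#'   \code{dir}).
#' @return a \code{jae_cohort} of the accepted knees, with attribute
#'   \code{rejected} (character vector of per-knee messages).
#' @export
ingest_external <- function(dir, metadata_csv = file.path(dir, "metadata.csv")) {
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  wavs <- list.files(dir, pattern = "\\.wav$")
  rejected <- character(0)
  keep <- logical(nrow(meta))
  recs <- vector("list", nrow(meta))
  extra <- setdiff(wavs, meta$wav_path)
  for (w in extra)
    rejected <- c(rejected, sprintf("%s: no metadata row, skipped", w))
  fs_seen <- NULL
  for (i in seq_len(nrow(meta))) {
    id <- paste(meta$subject_id[i], meta$knee_side[i], sep = "_")
    p <- file.path(dir, meta$wav_path[i])
    if (!file.exists(p)) {
      rejected <- c(rejected, sprintf("%s: missing WAV %s", id, meta$wav_path[i]))
      next
    }
    w <- tryCatch(read_wav(p), error = function(e)
      conditionMessage(e))
    if (is.character(w)) {
      rejected <- c(rejected, sprintf("%s: %s", id, w)); next
    }
    if (ncol(w$channels) != 2L) {
      rejected <- c(rejected, sprintf("%s: expected 2 channels, found %d",
                                      id, ncol(w$channels)))
      next
    }
    if (is.null(fs_seen)) fs_seen <- w$fs
    if (w$fs != fs_seen) {
      rejected <- c(rejected, sprintf("%s: sampling rate %g differs from %g",
                                      id, w$fs, fs_seen))
      next
    }
    keep[i] <- TRUE
    recs[[i]] <- structure(
      list(subject_id = meta$subject_id[i], knee_side = meta$knee_side[i],
           group = meta$group[i], activity = meta$activity[i],
           channels = w$channels, fs = w$fs),
      class = "jae_recording")
  }
  meta <- meta[keep, , drop = FALSE]
  if (is.null(meta$knee_id))
    meta$knee_id <- paste(meta$subject_id, meta$knee_side, sep = "_")
  rownames(meta) <- NULL
  structure(list(recordings = recs[keep], metadata = meta, config = NULL),
            class = "jae_cohort", rejected = rejected)
}
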