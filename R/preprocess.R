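#' Split a recording into flexion-extension cycles
#'
#' Fixed-grid slicing at \code{cycle_period}: the motion protocol is
#' metronome-guided, so cycles are taken as contiguous, non-overlapping
#' blocks of \code{round(cycle_period * fs)} samples; a trailing partial
#' cycle is discarded.
#'
#' @param rec a \code{jae_recording} (or any list with \code{channels}
#'   matrix and \code{fs}).
#' @param cycle_period cycle duration in seconds (default 4).
#' @return list of cycles; each has \code{cycle_index}, \code{channels}
#'   (matrix slice) and \code{fs}.
#' @export
segment_cycles <- function(rec, cycle_period = 4.0) {
  fs <- rec$fs
  len <- round(cycle_period * fs)
  n <- nrow(rec$channels)
  if (n < len) stop("recording shorter than one cycle")
  k <- n %/% len
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    list(cycle_index = i, channels = rec$channels[idx, , drop = FALSE],
         fs = fs)
  })
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth per pass, applied forward and backward
#' (\code{signal::filtfilt}) so click timing is preserved. If the upper
#' edge reaches 0.45 fs it is clipped there with a warning (desk-scale
#' sampling rates below ~26.7 kHz cannot represent the full 12 kHz band).
#'
#' @param x numeric waveform.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz); defaults 100 and 12000.
#' @return filtered waveform, same length.
#' @export
bandpass <- function(x, fs, low = 100, high = 12000) {
  if (high >= 0.45 * fs) {
    high <- 0.45 * fs
    warning(sprintf("bandpass: upper edge clipped to %.0f Hz (0.45 fs)", high))
  }
  if (low >= high) stop("bandpass: low edge must be below the (clipped) high edge")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Frame one cycle into overlapping segments
#'
#' Frames of \code{frame_len} seconds advancing by
#' \code{frame_len * (1 - overlap)}; per channel the count is
#' \code{floor((T - L) / H) + 1}. A cycle shorter than one frame yields an
#' empty result (not an error).
#'
#' @param cycle one element of [segment_cycles()] output.
#' @param frame_len frame length in seconds (default 0.2).
#' @param overlap fractional overlap in [0, 1) (default 0.5).
#' @return list with \code{frames} (matrix, one row per frame),
#'   \code{info} (data.frame: cycle_index, channel, start) — empty if the
#'   cycle is too short.
#' @export
frame_cycle <- function(cycle, frame_len = 0.2, overlap = 0.5) {
  fs <- cycle$fs
  L <- round(frame_len * fs)
  H <- round(frame_len * (1 - overlap) * fs)
  n <- nrow(cycle$channels)
  if (n < L) {
    return(list(frames = matrix(numeric(0), 0, L),
                info = data.frame(cycle_index = integer(0),
                                  channel = integer(0), start = numeric(0))))
  }
  k <- (n - L) %/% H + 1L
  starts <- (seq_len(k) - 1L) * H
  frames <- matrix(0, nrow = 2L * k, ncol = L)
  info <- data.frame(cycle_index = rep(cycle$cycle_index, 2L * k),
                     channel = rep(1:2, each = k),
                     start = rep(starts / fs, 2L))
  for (chn in 1:2) {
    for (j in seq_len(k)) {
      frames[(chn - 1L) * k + j, ] <-
        cycle$channels[(starts[j] + 1L):(starts[j] + L), chn]
    }
  }
  list(frames = frames, info = info)
}

#' Preprocess a recording into denoised, band-limited frames
#'
#' The full chain in order: per-channel wavelet denoising on the whole
#' recording (threshold estimation benefits from long records), zero-phase
#' band-pass (100 Hz - 12 kHz, clipped at 0.45 fs when necessary), fixed-grid
#' cycle segmentation, then 200-ms frames with 50% overlap. Medial and
#' lateral channel frames enter one pool.
#'
#' @param rec a \code{jae_recording}.
#' @param cycle_period seconds per cycle.
#' @param frame_len,overlap framing parameters (seconds, fraction).
#' @param band numeric length-2 band edges in Hz.
#' @param denoise a [denoise_config()] or \code{NULL} to skip denoising.
#' @return list of class \code{jae_frames}: \code{frames} (matrix, rows =
#'   frames pooled over cycles and channels), \code{info} (frame index
#'   table), \code{fs}, \code{knee_id}.
#' @export
preprocess_recording <- function(rec, cycle_period = 4.0, frame_len = 0.2,
                                 overlap = 0.5, band = c(100, 12000),
                                 denoise = denoise_config()) {
  ch <- rec$channels
  for (i in seq_len(ncol(ch))) {
    v <- ch[, i]
    if (!is.null(denoise)) v <- wavelet_denoise(v, denoise)
    ch[, i] <- bandpass(v, rec$fs, band[1], band[2])
  }
  cycles <- segment_cycles(list(channels = ch, fs = rec$fs), cycle_period)
  parts <- lapply(cycles, frame_cycle, frame_len = frame_len, overlap = overlap)
  frames <- do.call(rbind, lapply(parts, `[[`, "frames"))
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  structure(list(frames = frames, info = info, fs = rec$fs,
                 knee_id = paste(rec$subject_id, rec$knee_side, sep = "_")),
            class = "jae_frames")
}

#' @export
print.jae_frames <- function(x, ...) {
  cat(sprintf("Preprocessed knee %s: %d frames of %d samples at %g Hz\n",
              x$knee_id, nrow(x$frames), ncol(x$frames), x$fs))
  invisible(x)
}
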