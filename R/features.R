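#' Frame-level feature catalogue
#'
#' Versioned, ordered list of the scalar features computed on every 200-ms
#' frame. Version \code{"v1"} (273 features) comprises:
#' \itemize{
#'   \item 11 time-domain: RMS, peak, crest factor, zero-crossing rate,
#'     skewness, kurtosis, Shannon entropy of the 32-bin amplitude
#'     histogram, line length, Hjorth activity / mobility / complexity;
#'   \item 10 spectral scalars on a Hann-windowed FFT (length = next power
#'     of two above the frame length): centroid, spread, skewness,
#'     kurtosis, flatness, slope, roll-off at 85\% and 95\%, flux versus
#'     the previous frame, normalized spectral entropy;
#'   \item 98 band-energy ratios over log-spaced sub-bands of
#'     100 Hz - 12 kHz (a constant-Q-like log-frequency energy profile);
#'   \item 26 cepstral: 13 mel-frequency cepstral coefficients (26
#'     triangular mel filters, DCT-II) plus their frame-to-frame deltas;
#'   \item 128 wavelet-packet: relative energies and log-energies of the 64
#'     depth-6 db4 packet sub-bands.
#' }
#' Degenerate frames are mapped to documented limits: an all-zero frame has
#' RMS, ZCR, centroid, roll-offs and band ratios equal to 0 and flatness 1.
#'
#' @param version catalogue version id; only \code{"v1"}.
#' @return object of class \code{jae_feature_catalogue} with \code{names},
#'   \code{count}, \code{version}.
#' @export
feature_catalogue <- function(version = "v1") {
  version <- match.arg(version, "v1")
  nm <- c(
    c("time_rms", "time_peak", "time_crest", "time_zcr", "time_skewness",
      "time_kurtosis", "time_amp_entropy", "time_line_length",
      "time_hjorth_activity", "time_hjorth_mobility",
      "time_hjorth_complexity"),
    c("spec_centroid", "spec_spread", "spec_skewness", "spec_kurtosis",
      "spec_flatness", "spec_slope", "spec_rolloff85", "spec_rolloff95",
      "spec_flux", "spec_entropy"),
    sprintf("cq_ratio_%02d", 1:98),
    sprintf("mfcc_%02d", 1:13),
    sprintf("dmfcc_%02d", 1:13),
    sprintf("wp_rel_%02d", 1:64),
    sprintf("wp_loge_%02d", 1:64))
  structure(list(version = version, names = nm, count = length(nm)),
            class = "jae_feature_catalogue")
}

#' @export
print.jae_feature_catalogue <- function(x, ...) {
  cat(sprintf("Feature catalogue %s: %d frame-level features\n",
              x$version, x$count))
  invisible(x)
}

# Precomputed per-(frame length, fs) machinery: window, FFT freqs, band
# assignments, mel filterbank, DCT matrix. Cached in a package-local env.
.plan_cache <- new.env(parent = emptyenv())

feature_plan <- function(n, fs) {
  key <- paste(n, fs, sep = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  nfft <- 2L^ceiling(log2(n))
  window <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))  # Hann
  nb <- nfft %/% 2L + 1L
  freq <- (seq_len(nb) - 1L) * fs / nfft

  # 98 log-spaced sub-bands of 100 Hz - 12 kHz; bins above Nyquist unused
  edges <- exp(seq(log(100), log(12000), length.out = 99L))
  band <- rep(NA_integer_, nb)
  usable <- freq >= edges[1] & freq < edges[99] & freq < fs / 2
  band[usable] <- findInterval(freq[usable], edges, rightmost.closed = TRUE)

  # mel filterbank: 26 triangular filters, 100 Hz to min(12 kHz, fs/2)
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  fmax <- min(12000, fs / 2)
  mpts <- mel2hz(seq(hz2mel(100), hz2mel(fmax), length.out = 28L))
  melfb <- matrix(0, nrow = 26L, ncol = nb)
  for (i in 1:26) {
    lo <- mpts[i]; ce <- mpts[i + 1L]; hi <- mpts[i + 2L]
    up <- freq >= lo & freq <= ce
    dn <- freq > ce & freq <= hi
    melfb[i, up] <- (freq[up] - lo) / (ce - lo)
    melfb[i, dn] <- (hi - freq[dn]) / (hi - ce)
  }
  # orthogonal DCT-II, coefficients 0..12
  dct <- matrix(0, nrow = 13L, ncol = 26L)
  for (k in 0:12)
    dct[k + 1L, ] <- cos(pi * k * (2 * (0:25) + 1) / (2 * 26)) *
      sqrt(2 / 26) * (if (k == 0) 1 / sqrt(2) else 1)

  plan <- list(n = n, fs = fs, nfft = nfft, window = window, freq = freq,
               band = band, melfb = melfb, dct = dct)
  .plan_cache[[key]] <- plan
  plan
}

moment_skew <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
moment_kurt <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

time_features <- function(x) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  crest <- if (rms > 0) peak / rms else 0
  s <- x >= 0
  zcr <- sum(s[-1L] != s[-n]) / (n - 1L)
  if (peak > 0) {
    h <- tabulate(pmin(32L, 1L + floor(32 * (x - min(x)) /
                                         (max(x) - min(x) + 1e-300))), 32L)
    p <- h / sum(h)
    p <- p[p > 0]
    ent <- -sum(p * log(p))
  } else ent <- 0
  ll <- mean(abs(diff(x)))
  v0 <- stats::var(x)
  d1 <- diff(x); v1 <- stats::var(d1)
  mob <- if (v0 > 0) sqrt(v1 / v0) else 0
  v2 <- stats::var(diff(d1))
  mob2 <- if (v1 > 0) sqrt(v2 / v1) else 0
  cmplx <- if (mob > 0) mob2 / mob else 0
  c(rms, peak, crest, zcr, moment_skew(x), moment_kurt(x), ent, ll,
    v0, mob, cmplx)
}

spectral_features <- function(P, plan, prevA = NULL) {
  f <- plan$freq
  tot <- sum(P)
  if (tot <= 0) {
    return(list(vec = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                A = rep(0, length(P))))
  }
  p <- P / tot
  cen <- sum(f * p)
  spr <- sqrt(sum((f - cen)^2 * p))
  sk <- if (spr > 0) sum((f - cen)^3 * p) / spr^3 else 0
  ku <- if (spr > 0) sum((f - cen)^4 * p) / spr^4 else 0
  flat <- exp(mean(log(P + 1e-300))) / mean(P)
  A <- sqrt(P)
  slope <- sum((f - mean(f)) * (A - mean(A))) / sum((f - mean(f))^2)
  cs <- cumsum(p)
  r85 <- f[which(cs >= 0.85)[1L]]
  r95 <- f[which(cs >= 0.95)[1L]]
  An <- A / sum(A)
  flux <- if (is.null(prevA)) 0 else sqrt(sum((An - prevA)^2))
  pe <- p[p > 0]
  sent <- -sum(pe * log(pe)) / log(length(P))
  list(vec = c(cen, spr, sk, ku, flat, slope, r85, r95, flux, sent), A = An)
}

#' Extract the catalogue features of one frame
#'
#' Computes every catalogue feature on a single frame. Two features are
#' sequential by definition (spectral flux and the MFCC deltas): they
#' compare against the previous frame of the same channel and cycle, passed
#' via \code{context} (the \code{context} element of a previous call); with
#' \code{context = NULL} both are 0.
#'
#' @param frame numeric waveform (>= 2 samples, finite).
#' @param fs sampling rate (Hz).
#' @param catalogue a [feature_catalogue()].
#' @param context \code{NULL} or the \code{context} of the preceding frame.
#' @return list with \code{features} (named numeric vector, catalogue
#'   order) and \code{context} to thread into the next call.
#' @export
extract_frame_features <- function(frame, fs, catalogue = feature_catalogue(),
                                   context = NULL) {
  if (length(frame) < 2L) stop("frame must have at least 2 samples")
  if (anyNA(frame) || !all(is.finite(frame))) stop("frame contains non-finite values")
  plan <- feature_plan(length(frame), fs)
  tf <- time_features(frame)

  xw <- c(frame * plan$window, numeric(plan$nfft - length(frame)))
  X <- stats::fft(xw)[seq_along(plan$freq)]
  P <- Re(X * Conj(X))
  sf <- spectral_features(P, plan, prevA = context$A)

  bsum <- rep(0, 98L)
  use <- !is.na(plan$band)
  if (any(use)) {
    agg <- rowsum(P[use], plan$band[use])
    bsum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  btot <- sum(bsum)
  cq <- if (btot > 0) bsum / btot else bsum

  mele <- as.numeric(plan$melfb %*% P)
  mfcc <- as.numeric(plan$dct %*% log(mele + 1e-300))
  dmfcc <- if (is.null(context)) rep(0, 13L) else mfcc - context$mfcc

  e <- wpt_energies(frame, 6L)
  etot <- sum(e)
  rel <- if (etot > 0) e / etot else e
  loge <- log(e + 1e-20)

  feats <- c(tf, sf$vec, cq, mfcc, dmfcc, rel, loge)
  names(feats) <- catalogue$names
  list(features = feats, context = list(A = sf$A, mfcc = mfcc))
}

#' Extract features for all frames of a preprocessed knee
#'
#' Applies [extract_frame_features()] to every frame, threading the
#' sequential context (flux, MFCC deltas) along consecutive frames of each
#' (cycle, channel) run and resetting it at run boundaries.
#'
#' @param fr a \code{jae_frames} object from [preprocess_recording()].
#' @param catalogue a [feature_catalogue()].
#' @return numeric matrix, one row per frame, \code{catalogue$count} columns.
#' @export
extract_features <- function(fr, catalogue = feature_catalogue()) {
  n <- nrow(fr$frames)
  if (n == 0L) stop("no frames to featurize")
  out <- matrix(NA_real_, nrow = n, ncol = catalogue$count,
                dimnames = list(NULL, catalogue$names))
  grp <- paste(fr$info$cycle_index, fr$info$channel)
  ctx <- NULL
  for (i in seq_len(n)) {
    if (i > 1L && grp[i] != grp[i - 1L]) ctx <- NULL
    r <- extract_frame_features(fr$frames[i, ], fr$fs, catalogue, ctx)
    out[i, ] <- r$features
    ctx <- r$context
  }
  out
}

#' Aggregate frame features into one per-knee summary
#'
#' Mean and population standard deviation of every catalogue feature over
#' the pooled frames of all cycles and both channels.
#'
#' @param feat_matrix frame-by-feature matrix from [extract_features()].
#' @param knee_id identifier attached to the summary.
#' @return object of class \code{jae_knee_summary}: named vector of
#'   \code{2 * ncol} values (\code{mean_*} then \code{sd_*}) with
#'   attributes \code{knee_id} and \code{n_frames}.
#' @export
summarize_knee <- function(feat_matrix, knee_id = NA_character_) {
  if (is.null(dim(feat_matrix)) || nrow(feat_matrix) == 0L)
    stop("summarize_knee: empty frame list")
  m <- colMeans(feat_matrix)
  n <- nrow(feat_matrix)
  sd_pop <- sqrt(colMeans(feat_matrix^2) - m^2)
  sd_pop[sd_pop < 0 | is.na(sd_pop)] <- 0
  v <- c(m, sd_pop)
  names(v) <- c(paste0("mean_", colnames(feat_matrix)),
                paste0("sd_", colnames(feat_matrix)))
  structure(v, knee_id = knee_id, n_frames = n, class = "jae_knee_summary")
}

#' Assemble the knee-by-feature design matrix
#'
#' Rows are knees sorted by subject id then knee side; columns are the
#' summary features (mean and sd per catalogue entry). Labels come from the
#' metadata table.
#'
#' @param summaries list of \code{jae_knee_summary}.
#' @param metadata cohort metadata data.frame with columns knee_id,
#'   subject_id, knee_side, group, activity.
#' @return list of class \code{jae_feature_matrix}: \code{x} (numeric
#'   matrix, rownames = knee ids), \code{meta} (metadata aligned to rows).
#' @export
build_feature_matrix <- function(summaries, metadata) {
  if (length(summaries) == 0L) stop("no knee summaries supplied")
  ids <- vapply(summaries, attr, "", "knee_id")
  if (anyDuplicated(ids)) stop("duplicate knee ids in summaries")
  missing <- setdiff(ids, metadata$knee_id)
  if (length(missing))
    stop("knees absent from metadata: ", paste(missing, collapse = ", "))
  meta <- metadata[match(ids, metadata$knee_id), , drop = FALSE]
  ord <- order(meta$subject_id, meta$knee_side)
  x <- do.call(rbind, lapply(summaries, as.numeric))
  colnames(x) <- names(unclass(summaries[[1L]]))
  rownames(x) <- ids
  x <- x[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta), class = "jae_feature_matrix")
}

#' @export
print.jae_feature_matrix <- function(x, ...) {
  cat(sprintf("Knee feature matrix: %d knees x %d summary features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}
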