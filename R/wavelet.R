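# Daubechies-4 analysis filters (orthonormal, 8 taps).
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)

#' One level of the periodized discrete wavelet transform
#'
#' Circular convolution with the Daubechies-4 analysis pair followed by
#' dyadic downsampling. The input length must be even; the periodized
#' convention keeps the transform orthonormal so that
#' \code{sum(cA^2) + sum(cD^2) == sum(x^2)}.
#'
#' @param x numeric vector of even length.
#' @return list with approximation \code{cA} and detail \code{cD}, each of
#'   length \code{length(x)/2}.
#' @keywords internal
dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2L != 0L) stop("dwt_step: input length must be even")
  L <- 8L
  half <- n %/% 2L
  # y[k] = sum_m f[m+1] * x[(2k + 4 - m) mod n], k = 0..n/2-1 (periodized layout)
  cA <- numeric(half)
  cD <- numeric(half)
  base <- 2L * seq_len(half) + 2L            # 2k+4 for k = 0..half-1
  for (m in 0:(L - 1L)) {
    idx <- (base - m) %% n + 1L
    xv <- x[idx]
    cA <- cA + .db4_dec_lo[m + 1L] * xv
    cD <- cD + .db4_dec_hi[m + 1L] * xv
  }
  list(cA = cA, cD = cD)
}

#' Inverse of one periodized DWT level
#'
#' @param cA,cD approximation and detail coefficients of equal length.
#' @return reconstructed vector of length \code{2 * length(cA)}.
#' @keywords internal
idwt_step <- function(cA, cD) {
  half <- length(cA)
  if (length(cD) != half) stop("idwt_step: coefficient lengths differ")
  n <- 2L * half
  x <- numeric(n)
  # transpose of the analysis operator (orthonormal => inverse)
  for (m in 0:7L) {
    pos <- (2L * seq_len(half) + 2L - m) %% n + 1L
    contrib <- .db4_dec_lo[m + 1L] * cA + .db4_dec_hi[m + 1L] * cD
    # accumulate with possible repeated positions (n >= 8 keeps them unique per m)
    x[pos] <- x[pos] + contrib
  }
  x
}

#' Multi-level periodized DWT (Daubechies-4)
#'
#' @param x numeric vector; length must be divisible by \code{2^levels}.
#' @param levels decomposition depth (>= 1).
#' @return list with final approximation \code{cA} and details
#'   \code{details} (list, finest level first).
#' @keywords internal
dwt_db4 <- function(x, levels) {
  stopifnot(levels >= 1L)
  if (length(x) %% (2L^levels) != 0L)
    stop("dwt_db4: length must be divisible by 2^levels")
  details <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(cur)
    details[[l]] <- st$cD
    cur <- st$cA
  }
  list(cA = cur, details = details)
}

#' @keywords internal
idwt_db4 <- function(decomp) {
  cur <- decomp$cA
  for (l in rev(seq_along(decomp$details)))
    cur <- idwt_step(cur, decomp$details[[l]])
  cur
}

#' Wavelet denoising configuration
#'
#' Parameters of the shrinkage denoiser: wavelet family (only \code{"db4"}
#' is built in), decomposition depth, thresholding rule and the noise-scale
#' estimator. Defaults follow common practice for broadband transient
#' signals: universal threshold \eqn{\sigma \sqrt{2 \log N}} applied softly
#' to all detail coefficients, with \eqn{\sigma} estimated as
#' MAD(finest details) / 0.6745.
#'
#' @param wavelet wavelet family name; \code{"db4"}.
#' @param levels decomposition depth, default 6.
#' @param rule threshold rule; \code{"universal"}.
#' @param mode threshold mode; \code{"soft"}.
#' @return an object of class \code{jae_denoise_config}.
#' @export
denoise_config <- function(wavelet = "db4", levels = 6L,
                           rule = "universal", mode = "soft") {
  wavelet <- match.arg(wavelet, "db4")
  rule <- match.arg(rule, "universal")
  mode <- match.arg(mode, "soft")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  structure(list(wavelet = wavelet, levels = levels, rule = rule,
                 mode = mode), class = "jae_denoise_config")
}

soft_threshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)

#' Wavelet shrinkage denoising
#'
#' Multi-level periodized db4 decomposition, soft thresholding of every
#' detail band at the universal threshold \eqn{\hat\sigma \sqrt{2 \log N}},
#' where \eqn{\hat\sigma} is the median absolute deviation of the finest
#' detail coefficients divided by 0.6745, then reconstruction. The signal is
#' zero-padded internally to a multiple of \code{2^levels}; the output has
#' the input length.
#'
#' @param x numeric waveform (finite values).
#' @param config a [denoise_config()] object.
#' @return denoised waveform, same length as \code{x}.
#' @export
wavelet_denoise <- function(x, config = denoise_config()) {
  if (!all(is.finite(x))) stop("wavelet_denoise: input contains non-finite samples")
  n0 <- length(x)
  levels <- config$levels
  if (n0 < 2L^levels) levels <- max(1L, floor(log2(max(n0, 2L))))
  block <- 2L^levels
  npad <- ceiling(n0 / block) * block
  xp <- if (npad > n0) c(x, numeric(npad - n0)) else x
  dec <- dwt_db4(xp, levels)
  sigma <- stats::mad(dec$details[[1L]], center = 0, constant = 1) / 0.6745
  thr <- sigma * sqrt(2 * log(npad))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  out <- idwt_db4(dec)
  out[seq_len(n0)]
}

#' Wavelet-packet sub-band energies
#'
#' Full wavelet-packet decomposition (db4, periodized) to the given depth;
#' returns the energy of each of the \code{2^depth} leaf nodes in natural
#' (filter-bank) order. The input is zero-padded to a multiple of
#' \code{2^depth}. Orthonormality makes the energies sum to the padded
#' signal energy.
#'
#' @param x numeric vector.
#' @param depth packet depth (default 6, i.e. 64 sub-bands).
#' @return numeric vector of \code{2^depth} non-negative energies.
#' @keywords internal
wpt_energies <- function(x, depth = 6L) {
  block <- 2L^depth
  n0 <- length(x)
  npad <- max(block, ceiling(n0 / block) * block)
  xp <- c(x, numeric(npad - n0))
  nodes <- list(xp)
  for (l in seq_len(depth)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      st <- dwt_step(nodes[[i]])
      nxt[[2L * i - 1L]] <- st$cA
      nxt[[2L * i]] <- st$cD
    }
    nodes <- nxt
  }
  vapply(nodes, function(v) sum(v * v), numeric(1))
}
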