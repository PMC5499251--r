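# Signal-adaptive frequency slice wavelet transform.
#
# The transform is computed in the frequency domain: each observed frequency
# omega selects a Gaussian frequency slice window around itself, whose width
# is governed by a scale function q(u) adapted to the signal's own spectrum,
# and the windowed spectrum is carried back to the time axis. With the window
# equal to 1 at zero argument the spectrogram is exactly invertible.

#' Gaussian frequency slice function
#'
#' The window `exp(-x^2 / 2)` applied around each observed frequency: even,
#' equal to 1 at 0, and strictly decreasing in `|x|`.
#'
#' @param x numeric argument (dimensionless frequency offset).
#' @return window value in (0, 1].
#' @export
fsf <- function(x) exp(-x^2 / 2)

#' Signed DFT bin frequencies
#'
#' Frequencies (Hz) of the length-`n` DFT bins in FFT order, with bins above
#' `n/2` mapped to their negative aliases (the Nyquist bin, if present, stays
#' positive).
#'
#' @param n DFT length.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `n`.
#' @export
dft_frequencies <- function(n, fs) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) * fs / n
}

#' Signal-adaptive scale function q(u)
#'
#' `q(u) = delta + sign(d|f^(u)|/du)`, where `delta` is the frequency (Hz) of
#' the spectral magnitude maximum (DC bin excluded) and the derivative is
#' approximated by the forward difference of the magnitude along the
#' frequency grid (the last grid point copies its neighbour's derivative).
#' The result is clamped below at `q_min` so the window width stays positive
#' even when `delta` is small.
#'
#' @param magnitude nonnegative spectral magnitudes on `u_grid`.
#' @param u_grid ascending nonnegative frequencies (Hz), first bin = DC.
#' @param q_min lower clamp (Hz).
#' @return numeric vector `q(u)` over `u_grid`.
#' @export
scale_q <- function(magnitude, u_grid, q_min = 0.5) {
  stopifnot(length(magnitude) == length(u_grid), q_min > 0,
            all(magnitude >= 0))
  if (all(magnitude == 0)) {
    stop("degenerate input: all-zero spectral magnitude", call. = FALSE)
  }
  if (length(magnitude) < 2) {
    stop("need at least two frequency bins", call. = FALSE)
  }
  delta <- u_grid[which.max(magnitude[-1]) + 1L]
  grad <- diff(magnitude)
  grad <- c(grad, grad[length(grad)])
  pmax(delta + sign(grad), q_min)
}

# q over all n DFT bins (FFT order), evaluated on the nonnegative half-grid
# and mirrored onto negative bins.
.q_all_bins <- function(spectrum, n, fs, q_min) {
  half <- floor(n / 2)
  u_nonneg <- (0:half) * fs / n
  q_nn <- scale_q(Mod(spectrum)[1:(half + 1)], u_nonneg, q_min)
  k <- 0:(n - 1)
  q_nn[ifelse(k <= half, k, n - k) + 1L]
}

#' Forward signal-adaptive frequency slice transform
#'
#' For each observed frequency in `w_grid`, windows the signal's DFT with
#' the Gaussian slice function centred at that frequency (width `q(u)` per
#' input-frequency bin) and returns the windowed spectrum to the time axis.
#' The DFT carries the conjugate-symmetric negative-frequency half of a real
#' input, so rows at `-omega` are the conjugates of rows at `+omega`.
#' With `w_grid = NULL` the full signed DFT grid is used (in FFT bin order),
#' which makes the transform exactly invertible by [mfswt_inverse()].
#'
#' @param signal numeric signal, length at least 8.
#' @param fs sampling rate in Hz.
#' @param w_grid observed frequencies (Hz); `NULL` for the full DFT grid.
#' @param q_min lower clamp of the scale function (Hz).
#' @param q optional fixed scale function: vector of length `n` over the DFT
#'   bins (FFT order). When supplied the transform is linear in the signal;
#'   by default `q` adapts to the signal spectrum.
#' @return object of class `mfswt_spectrogram`: list with complex matrix
#'   `values` (`length(w_grid)` x `n`), `w_grid`, `t_grid` (s), `fs`, `n`,
#'   and the `q` actually used.
#' @export
mfswt <- function(signal, fs, w_grid = NULL, q_min = 0.5, q = NULL) {
  n <- length(signal)
  if (n < 8) stop("signal length must be at least 8", call. = FALSE)
  spectrum <- stats::fft(signal)
  u <- dft_frequencies(n, fs)
  if (is.null(q)) {
    # a zero signal has no spectral maximum; any window gives a zero result
    q <- if (all(signal == 0)) rep(q_min, n) else
      .q_all_bins(spectrum, n, fs, q_min)
  }
  stopifnot(length(q) == n, all(q > 0))
  full_grid <- is.null(w_grid)
  if (full_grid) w_grid <- u
  if (length(w_grid) == 0) stop("w_grid must be non-empty", call. = FALSE)

  # one column per omega: windowed spectrum, then inverse DFT over u
  g <- vapply(w_grid, function(w) spectrum * fsf((u - w) / q),
              complex(n))
  rows <- t(stats::mvfft(g, inverse = TRUE) / n) # length(w_grid) x n
  structure(
    list(
      values = rows,
      w_grid = w_grid,
      t_grid = (seq_len(n) - 1) / fs,
      fs = fs,
      n = n,
      q = q,
      full_grid = full_grid
    ),
    class = "mfswt_spectrogram"
  )
}

#' Inverse transform (signal reconstruction)
#'
#' Discretizes the double integral over observed time and frequency with the
#' DFT grid spacings as measures and returns the real part. Reconstruction is
#' exact (percentage root-mean-square difference numerically zero) when the
#' spectrogram was produced on the full DFT frequency grid.
#'
#' @param spectrogram an `mfswt_spectrogram`.
#' @return reconstructed real signal of the original length.
#' @export
mfswt_inverse <- function(spectrogram) {
  stopifnot(inherits(spectrogram, "mfswt_spectrogram"))
  n <- spectrogram$n
  if (!isTRUE(spectrogram$full_grid) || nrow(spectrogram$values) != n) {
    warning("spectrogram not on the full DFT frequency grid; ",
            "exact reconstruction is not guaranteed")
  }
  # DFT each frequency row over time, evaluated at its own bin
  b <- stats::mvfft(t(spectrogram$values)) # n_t x n_w, DFT over time
  m <- min(n, ncol(b))
  a <- complex(n)
  a[seq_len(m)] <- b[cbind(seq_len(m), seq_len(m))]
  Re(stats::fft(a, inverse = TRUE) / n)
}

#' Direct-summation forward transform (reference implementation)
#'
#' Literal O(n^2) discretization of the forward transform, including a direct
#' DFT of the input, kept as an independent cross-check of the FFT path.
#' Intended for short signals only.
#'
#' @inheritParams mfswt
#' @return an `mfswt_spectrogram`.
#' @export
mfswt_direct <- function(signal, fs, w_grid = NULL, q_min = 0.5, q = NULL) {
  n <- length(signal)
  if (n < 8) stop("signal length must be at least 8", call. = FALSE)
  idx <- 0:(n - 1)
  spectrum <- vapply(idx, function(k) {
    sum(signal * exp(-2i * pi * k * idx / n))
  }, complex(1))
  u <- dft_frequencies(n, fs)
  if (is.null(q)) {
    q <- if (all(signal == 0)) rep(q_min, n) else
      .q_all_bins(spectrum, n, fs, q_min)
  }
  full_grid <- is.null(w_grid)
  if (full_grid) w_grid <- u
  values <- matrix(0i, nrow = length(w_grid), ncol = n)
  for (j in seq_along(w_grid)) {
    g <- spectrum * fsf((u - w_grid[j]) / q)
    for (m in seq_len(n)) {
      values[j, m] <- sum(g * exp(2i * pi * idx * (m - 1) / n)) / n
    }
  }
  structure(
    list(values = values, w_grid = w_grid, t_grid = idx / fs, fs = fs,
         n = n, q = q, full_grid = full_grid),
    class = "mfswt_spectrogram"
  )
}

#' Direct-summation inverse transform (reference implementation)
#'
#' Literal O(n^3) double sum over observed time and frequency; the
#' independent cross-check of [mfswt_inverse()].
#'
#' @param spectrogram an `mfswt_spectrogram` on the full DFT grid.
#' @return reconstructed real signal.
#' @export
mfswt_inverse_direct <- function(spectrogram) {
  n <- spectrogram$n
  w <- spectrogram$values
  idx <- 0:(n - 1)
  out <- vapply(idx, function(t_i) {
    acc <- 0i
    for (j in seq_len(n)) {
      acc <- acc + sum(w[j, ] * exp(2i * pi * (j - 1) * (t_i - idx) / n))
    }
    acc / n
  }, complex(1))
  Re(out)
}

#' Percentage root-mean-square difference
#'
#' `100 * sqrt(sum((x - x_hat)^2) / sum(x^2))`, the standard reconstruction
#' fidelity measure; 0 means exact reconstruction.
#'
#' @param x reference signal (must have nonzero energy).
#' @param x_hat reconstruction, same length.
#' @return PRD in percent.
#' @export
prd <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat))
  e <- sum(x^2)
  if (e == 0) stop("reference signal has zero energy", call. = FALSE)
  100 * sqrt(sum((x - x_hat)^2) / e)
}

# 1D area-average resampling matrix mapping src cells onto tgt cells.
.resample_matrix <- function(src, tgt) {
  b <- seq(0, src, length.out = tgt + 1)
  m <- matrix(0, tgt, src)
  width <- src / tgt
  for (i in seq_len(tgt)) {
    lo <- b[i]; hi <- b[i + 1]
    for (k in (floor(lo) + 1):min(ceiling(hi), src)) {
      overlap <- min(hi, k) - max(lo, k - 1)
      if (overlap > 0) m[i, k] <- overlap / width
    }
  }
  m
}

#' Convert a spectrogram to a normalized time-frequency image
#'
#' Takes the spectrogram magnitude, keeps rows with nonnegative observed
#' frequency up to `f_max`, resamples to `n_freq` x `n_time` by area
#' averaging, and min-max normalizes the result to \[0, 1\] per image. An
#' identically constant magnitude (including all-zero) maps to an all-zero
#' image.
#'
#' @param spectrogram an `mfswt_spectrogram`.
#' @param n_freq,n_time target resolution (each at least 2).
#' @param f_max retained frequency ceiling (Hz); must not exceed the
#'   spectrogram grid ceiling.
#' @return object of class `tf_image`: list with `pixels` (`n_freq` x
#'   `n_time`, frequency ascending along rows), `n_freq`, `n_time`, `f_max`.
#' @export
tf_image <- function(spectrogram, n_freq = 45, n_time = 64, f_max = 64) {
  stopifnot(n_freq >= 2, n_time >= 2)
  wg <- spectrogram$w_grid
  if (f_max > max(wg)) {
    stop("f_max exceeds the spectrogram frequency ceiling", call. = FALSE)
  }
  keep <- which(wg >= 0 & wg <= f_max)
  keep <- keep[order(wg[keep])]
  mag <- Mod(spectrogram$values[keep, , drop = FALSE])
  px <- .resample_matrix(nrow(mag), n_freq) %*% mag %*%
    t(.resample_matrix(ncol(mag), n_time))
  rng <- range(px)
  # treat a numerically constant magnitude as degenerate: min-max scaling
  # would only amplify resampling round-off
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1e-300)) rng[2] <- rng[1]
  if (rng[2] > rng[1]) {
    px <- (px - rng[1]) / (rng[2] - rng[1])
  } else {
    px[] <- 0
  }
  structure(list(pixels = px, n_freq = n_freq, n_time = n_time,
                 f_max = f_max),
            class = "tf_image")
}

#' Time-frequency images for a matrix of beat segments
#'
#' Runs the forward transform of each segment on the nonnegative frequency
#' bins up to `f_max` and converts it to a flattened, normalized image; the
#' classifier input representation.
#'
#' @param segments matrix of beat waveforms, one row per beat (e.g. from
#'   [segment_beats()]).
#' @param fs sampling rate in Hz.
#' @param n_freq,n_time image resolution.
#' @param f_max frequency ceiling in Hz.
#' @param q_min scale-function clamp.
#' @return numeric matrix with one row per beat and `n_freq * n_time`
#'   columns, entries in \[0, 1\].
#' @export
beat_images <- function(segments, fs, n_freq = 45, n_time = 64,
                        f_max = 64, q_min = 0.5) {
  n <- ncol(segments)
  bins <- sort(dft_frequencies(n, fs)[dft_frequencies(n, fs) >= 0])
  # keep one bin above f_max so the image crop sees the full ceiling
  w_grid <- bins[seq_len(min(length(bins), sum(bins <= f_max) + 1))]
  out <- matrix(0, nrow = nrow(segments), ncol = n_freq * n_time)
  for (i in seq_len(nrow(segments))) {
    x <- segments[i, ]
    if (all(x == 0)) next
    sg <- mfswt(x, fs, w_grid = w_grid, q_min = q_min)
    out[i, ] <- as.numeric(t(tf_image(sg, n_freq, n_time, f_max)$pixels))
  }
  out
}
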