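#' Morlet decomposition specification
#'
#' Frequency layers at 1 Hz steps between `f_min` and `f_max` and the
#' cycles parameter `c` of the complex Morlet wavelet (temporal sd
#' `c / (2 pi f)`).  `gamma_band()` (35-80 Hz) and `theta_band()`
#' (4-12 Hz) give the two canonical bands; `c = 5` throughout.
#'
#' @param f_min,f_max band edges in Hz.
#' @param step layer spacing in Hz.
#' @param c Morlet cycles parameter (> 0).
#' @export
morlet_spec <- function(f_min, f_max, step = 1, c = 5) {
  stopifnot(f_min > 0, f_min < f_max, c > 0, step > 0)
  structure(list(freqs = seq(f_min, f_max, by = step), c = c,
                 f_min = f_min, f_max = f_max),
            class = "morlet_spec")
}

#' @rdname morlet_spec
#' @export
gamma_band <- function(c = 5) morlet_spec(35, 80, 1, c)

#' @rdname morlet_spec
#' @export
theta_band <- function(c = 5) morlet_spec(4, 12, 1, c)

#' Sampled complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential at frequency `f`, truncated at
#' `n_sd` temporal standard deviations and normalized to unit energy
#' (`sum |psi|^2 / fs = 1`).
#'
#' @param f frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param c cycles parameter.
#' @param n_sd truncation half-width in units of the temporal sd.
#' @return complex vector of odd length `2*half + 1`, with attribute
#'   `half` (the one-sided support in samples).
#' @export
morlet_wavelet <- function(f, fs, c = 5, n_sd = 4) {
  sigma_t <- c / (2 * pi * f)
  half <- as.integer(ceiling(n_sd * sigma_t * fs))
  tt <- (-half:half) / fs
  psi <- exp(-tt^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * tt)
  psi <- psi / sqrt(sum(Mod(psi)^2) / fs)
  attr(psi, "half") <- half
  psi
}

# FFT linear convolution of x with kernel h (odd length), 'same' alignment.
fft_convolve_same <- function(x, h) {
  nx <- length(x); nh <- length(h)
  N <- stats::nextn(nx + nh - 1L, 2)
  X <- stats::fft(c(x, rep(0, N - nx)))
  H <- stats::fft(c(h, rep(0, N - nh)))
  y <- stats::fft(X * H, inverse = TRUE) / N
  off <- (nh - 1L) / 2L
  y[(off + 1L):(off + nx)]
}

# Precompute the frequency responses of a layer set for FFT length N.
# Returns list(N, halves, H = list of kernel DFTs).
cwt_kernels <- function(spec, fs, nx, n_sd = 4) {
  psis <- lapply(spec$freqs, morlet_wavelet, fs = fs, c = spec$c, n_sd = n_sd)
  halves <- vapply(psis, attr, 0L, "half")
  N <- stats::nextn(nx + 2L * max(halves), 2)
  H <- lapply(psis, function(psi) {
    h <- rev(Conj(psi))
    stats::fft(c(h, rep(0, N - length(h))))
  })
  list(N = N, halves = halves, H = H)
}

# CWT of one real vector: complex matrix n_freqs x n_times, coefficient
# = sum_tau x(tau) conj(psi(tau - t)) * dt.  `kernels` (from cwt_kernels)
# can be supplied to amortize the kernel DFTs across many signals.
cwt_vector <- function(x, spec, fs, n_sd = 4, kernels = NULL) {
  if (is.null(kernels)) kernels <- cwt_kernels(spec, fs, length(x), n_sd)
  nx <- length(x)
  N <- kernels$N
  X <- stats::fft(c(x, rep(0, N - nx)))
  out <- matrix(0i, nrow = length(spec$freqs), ncol = nx)
  for (k in seq_along(spec$freqs)) {
    y <- stats::fft(X * kernels$H[[k]], inverse = TRUE) / N
    off <- kernels$halves[k]
    out[k, ] <- y[(off + 1L):(off + nx)] / fs
  }
  attr(out, "halves") <- kernels$halves
  out
}

#' Complex Morlet wavelet transform of epochs
#'
#' Per-layer complex coefficients for every kept trial and channel.
#' Coefficients whose wavelet support crosses an epoch boundary are marked
#' invalid (no zero-padding bias); an error lists the usable layers when
#' no layer has any valid coefficient.  To bound memory, only the time
#' columns inside `times_keep_ms` are stored.
#'
#' @param epochs an `epoch_set`.
#' @param spec a [morlet_spec()].
#' @param times_keep_ms optional `c(from, to)` window of epoch times to
#'   retain (default: all).
#' @param channel `"mean"` is not offered here: coefficients are kept per
#'   channel and reduced by downstream summaries.
#' @return a `tfr_result`: list with complex array `coef`
#'   (trials x channels x freqs x times), `freqs`, `times_ms`, logical
#'   `valid` (freqs x times) and `fs`.
#' @export
morlet_transform <- function(epochs, spec, times_keep_ms = NULL,
                             channel = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "morlet_spec"))
  d <- dim(epochs$data)
  times <- epochs$times_ms
  keep_cols <- if (is.null(times_keep_ms)) seq_along(times)
    else which(times >= times_keep_ms[1] & times <= times_keep_ms[2])
  if (!length(keep_cols))
    stop("times_keep_ms selects no samples", call. = FALSE)
  trials <- which(epochs$keep)
  nf <- length(spec$freqs)
  coef <- array(0i, dim = c(length(trials), d[2], nf, length(keep_cols)))
  psis <- lapply(spec$freqs, morlet_wavelet, fs = epochs$fs, c = spec$c)
  halves <- vapply(psis, attr, 0L, "half")
  if (length(keep_cols) * 3L < d[3]) {
    # narrow output window: direct inner products beat full convolutions
    for (k in seq_len(nf)) {
      psi_row <- Conj(psis[[k]]) / epochs$fs
      half <- halves[k]
      idx <- outer(-half:half, keep_cols, `+`)      # support x times
      oob <- idx < 1L | idx > d[3]
      idx[oob] <- 1L                                # masked invalid anyway
      for (i in seq_along(trials)) for (ch in seq_len(d[2])) {
        sl <- matrix(epochs$data[trials[i], ch, ][idx], nrow = 2L * half + 1L)
        coef[i, ch, k, ] <- as.vector(psi_row %*% sl)
      }
    }
  } else {
    kern <- cwt_kernels(spec, epochs$fs, d[3])
    for (i in seq_along(trials)) {
      for (ch in seq_len(d[2])) {
        W <- cwt_vector(epochs$data[trials[i], ch, ], spec, epochs$fs,
                        kernels = kern)
        coef[i, ch, , ] <- W[, keep_cols, drop = FALSE]
      }
    }
  }
  # validity: full wavelet support inside the epoch
  col_idx <- keep_cols
  valid <- matrix(FALSE, nrow = nf, ncol = length(keep_cols))
  for (k in seq_len(nf))
    valid[k, ] <- col_idx > halves[k] & col_idx <= d[3] - halves[k]
  if (!any(valid)) {
    usable <- spec$freqs[halves < d[3] / 2]
    stop("epoch shorter than the wavelet support at every requested layer; ",
         if (length(usable)) paste("usable layers (Hz):",
                                   paste(usable, collapse = ", "))
         else "no usable layers", call. = FALSE)
  }
  structure(list(coef = coef, freqs = spec$freqs,
                 times_ms = times[keep_cols], valid = valid,
                 fs = epochs$fs, trials = trials),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<tfr_result> %d trials x %d ch x %d layers x %d times (%g..%g Hz)\n",
              d[1], d[2], d[3], d[4], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Mean band power of a time-frequency result
#'
#' Mean of `|coef|^2` over valid layer/time cells (optionally restricted
#' to a time window), averaged across trials and channels.
#'
#' @param tfr a `tfr_result`.
#' @param window_ms optional `c(from, to)` time restriction.
#' @return scalar mean power in µV².
#' @export
tfr_band_power <- function(tfr, window_ms = NULL) {
  stopifnot(inherits(tfr, "tfr_result"))
  cols <- if (is.null(window_ms)) seq_along(tfr$times_ms)
    else which(tfr$times_ms >= window_ms[1] & tfr$times_ms <= window_ms[2])
  v <- tfr$valid[, cols, drop = FALSE]
  if (!any(v)) stop("no valid coefficients in the requested window",
                    call. = FALSE)
  d <- dim(tfr$coef)
  p <- 0; nsum <- 0
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pw <- matrix(Mod(tfr$coef[i, ch, , cols])^2, nrow = d[3])
    p <- p + sum(pw[v])
    nsum <- nsum + sum(v)
  }
  p / nsum
}
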