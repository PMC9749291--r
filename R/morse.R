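#' Generalized Morse wavelet parameters
#'
#' The generalized Morse family is defined in the frequency domain by
#' `psi(omega) = U(omega) * alpha * omega^beta * exp(-omega^gamma)`, where
#' `U` is the unit step (the wavelet is exactly analytic: identically zero
#' at non-positive frequencies). `gamma` controls time-domain symmetry
#' (gamma = 3 gives the zero-skewness "Airy" wavelets) and the
#' time-bandwidth product `P2 = gamma * beta` controls how many
#' oscillations fit in the envelope, hence the time-frequency trade-off.
#'
#' @param gamma symmetry parameter, > 0 (default 3).
#' @param P2 time-bandwidth product, > 0 (default 60; 55 is the other
#'   value used for FHR representation).
#' @param beta decay parameter; derived as `P2 / gamma` unless given, in
#'   which case `P2` is derived as `gamma * beta`.
#' @param voices_per_octave scales per frequency doubling (default 12).
#' @return an object of class `morse_params`.
#' @export
morse_params <- function(gamma = 3, P2 = 60, beta = NULL,
                         voices_per_octave = 12) {
  if (!is.null(beta)) P2 <- gamma * beta else beta <- P2 / gamma
  stopifnot(gamma > 0, P2 > 0, beta > 0, voices_per_octave >= 1)
  structure(list(gamma = gamma, beta = beta, P2 = P2,
                 voices_per_octave = as.integer(voices_per_octave)),
            class = "morse_params")
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf("<morse_params> gamma=%g beta=%g (P2=%g), %d voices/octave\n",
              x$gamma, x$beta, x$P2, x$voices_per_octave))
  invisible(x)
}

#' Peak frequency of a Morse wavelet
#'
#' The angular frequency maximizing `omega^beta * exp(-omega^gamma)`,
#' namely `(beta/gamma)^(1/gamma)` (radians per unit time at scale 1).
#'
#' @param params a [morse_params()].
#' @return peak angular frequency.
#' @export
morse_peak_frequency <- function(params) {
  (params$beta / params$gamma)^(1 / params$gamma)
}

#' Morse normalizing constant
#'
#' `alpha = 2 (e * gamma / beta)^(beta/gamma)`, the convention that sets
#' the frequency-domain peak value of the wavelet to 2 so tone amplitudes
#' are recoverable from CWT magnitudes.
#'
#' @param params a [morse_params()].
#' @return alpha.
#' @export
morse_normalizing_constant <- function(params) {
  b <- params$beta; g <- params$gamma
  2 * exp((b / g) * (1 + log(g) - log(b)))
}

#' Frequency-domain Morse wavelet
#'
#' Evaluates `U(omega) * alpha * omega^beta * exp(-omega^gamma)`.
#' Computed in log space so large `beta` does not overflow; exactly zero
#' for `omega <= 0`.
#'
#' @param omega angular frequency vector (radians per unit time).
#' @param params a [morse_params()].
#' @return filter values, same length as `omega`.
#' @export
morse_psi_hat <- function(omega, params) {
  out <- numeric(length(omega))
  pos <- omega > 0
  if (any(pos)) {
    w <- omega[pos]
    la <- log(morse_normalizing_constant(params))
    out[pos] <- exp(la + params$beta * log(w) - w^params$gamma)
  }
  out
}

#' Demodulate skewness of a Morse wavelet
#'
#' Third standardized moment of the demodulated wavelet (the time-domain
#' wavelet multiplied by `exp(-i omega_peak t)`), computed numerically
#' from frequency-domain moments: the time moments of the demodulated
#' wavelet are derivatives of the spectrum at the peak frequency, which
#' are evaluated by central differences. The returned value is the
#' imaginary part of the standardized third central moment (the real part
#' vanishes identically for this real-spectrum family). It is zero for
#' gamma = 3, the "Airy" choice used for FHR representation, and nonzero
#' for e.g. the Cauchy family gamma = 1.
#'
#' @param params a [morse_params()].
#' @param rel_h finite-difference step relative to the peak frequency.
#' @return dimensionless skewness.
#' @export
morse_demodulate_skewness <- function(params, rel_h = 1e-3) {
  wp <- morse_peak_frequency(params)
  h <- rel_h * wp
  f <- function(w) morse_psi_hat(w, params)
  f0 <- f(wp)
  # central differences: second and third derivatives of psi at the peak
  d2 <- (f(wp + h) - 2 * f0 + f(wp - h)) / h^2
  d3 <- (-f(wp - 2 * h) + 2 * f(wp - h) - 2 * f(wp + h) + f(wp + 2 * h)) /
    (2 * h^3)
  mu2 <- -d2 / f0          # time-domain variance of the demodulated wavelet
  -(d3 / f0) / mu2^1.5     # Im(mu3) / mu2^(3/2); Re(mu3) is identically 0
}

#' Half-power bandwidth of the Morse frequency response
#'
#' Width of the interval where the frequency response exceeds its peak
#' value over sqrt(2), found by root bracketing on each flank. Strictly
#' decreasing in the time-bandwidth product at fixed gamma: larger P2
#' means a narrower filter (better frequency, worse time resolution).
#'
#' @param params a [morse_params()].
#' @return bandwidth in angular frequency units.
#' @export
morse_half_power_bandwidth <- function(params) {
  wp <- morse_peak_frequency(params)
  target <- morse_psi_hat(wp, params) / sqrt(2)
  g <- function(w) morse_psi_hat(w, params) - target
  lo <- stats::uniroot(g, c(wp * 1e-6, wp), tol = 1e-12 * wp)$root
  up <- wp * 2
  while (g(up) > 0) up <- up * 2
  hi <- stats::uniroot(g, c(wp, up), tol = 1e-12 * wp)$root
  hi - lo
}

#' Build a Morse CWT filter bank
#'
#' Frequency-domain filters on a geometric scale grid with
#' `voices_per_octave` scales per octave. The smallest scale places the
#' wavelet peak at the Nyquist frequency; the largest is chosen so two
#' time-domain standard deviations of the wavelet
#' (`sqrt(beta * gamma) / omega_peak` at scale 1) fit in the signal.
#' Each filter row is evaluated on the discrete angular-frequency grid of
#' an `n_samples`-point transform and is identically zero at non-positive
#' frequencies.
#'
#' @param n_samples transform length (>= 2).
#' @param fs sampling rate in Hz.
#' @param params a [morse_params()].
#' @return an object of class `morse_filterbank` with fields `params`,
#'   `fs`, `n_samples`, `scales`, `psi_hat` (scale x frequency-bin
#'   matrix, high frequency first), `center_frequencies` (Hz).
#' @export
morse_filterbank <- function(n_samples, fs = 4, params = morse_params()) {
  stopifnot(n_samples >= 2)
  wp <- morse_peak_frequency(params)
  s_min <- wp / pi                                   # peak at Nyquist
  sd_t <- sqrt(params$beta * params$gamma) / wp      # time spread, scale 1
  s_max <- n_samples / (2 * sd_t)                    # 2 sds fit the signal
  if (s_max < s_min) stop("n_samples too small to fit one wavelet")
  n_scales <- floor(params$voices_per_octave * log2(s_max / s_min)) + 1L
  scales <- s_min * 2^((seq_len(n_scales) - 1) / params$voices_per_octave)
  n_pos <- floor(n_samples / 2)
  omega <- 2 * pi * (0:n_pos) / n_samples            # rad/sample, >= 0
  psi <- matrix(0, nrow = n_scales, ncol = n_samples)
  for (k in seq_len(n_scales)) {
    psi[k, 1:(n_pos + 1L)] <- morse_psi_hat(scales[k] * omega, params)
    psi[k, 1L] <- 0                                  # exact zero at DC
  }
  structure(list(params = params, fs = fs, n_samples = as.integer(n_samples),
                 scales = scales,
                 center_frequencies = wp / (2 * pi * scales) * fs,
                 psi_hat = psi),
            class = "morse_filterbank")
}

#' @export
print.morse_filterbank <- function(x, ...) {
  cat(sprintf(
    "<morse_filterbank> %d scales, n=%d @ %g Hz, f_c %0.4g..%0.4g Hz (P2=%g, gamma=%g)\n",
    length(x$scales), x$n_samples, x$fs,
    max(x$center_frequencies), min(x$center_frequencies),
    x$params$P2, x$params$gamma))
  invisible(x)
}

#' Continuous wavelet transform of an FHR segment
#'
#' The signal mean is removed, the spectrum multiplied by each (real)
#' frequency-domain filter row, and the inverse FFT taken; the magnitude
#' of the resulting analytic coefficients forms the scalogram. Boundary
#' handling is periodic (FFT-native).
#'
#' @param segment an `fhr_segment`, `fhr_signal`, or numeric vector whose
#'   length equals `bank$n_samples`.
#' @param bank a [morse_filterbank()].
#' @return an object of class `fhr_scalogram` with fields `magnitude`
#'   (scale x time), `time_axis` (s), `freq_axis` (Hz), `params`.
#' @export
fhr_cwt <- function(segment, bank) {
  x <- if (inherits(segment, c("fhr_segment", "fhr_signal"))) {
    segment$samples
  } else {
    as.numeric(segment)
  }
  n <- length(x)
  if (n != bank$n_samples) {
    stop(sprintf("length mismatch: segment has %d samples, bank expects %d",
                 n, bank$n_samples))
  }
  xh <- stats::fft(x - mean(x))
  mag <- matrix(0, nrow = nrow(bank$psi_hat), ncol = n)
  for (k in seq_len(nrow(bank$psi_hat))) {
    mag[k, ] <- Mod(stats::fft(xh * bank$psi_hat[k, ], inverse = TRUE)) / n
  }
  structure(list(magnitude = mag,
                 time_axis = (seq_len(n) - 1) / bank$fs,
                 freq_axis = bank$center_frequencies,
                 params = bank$params),
            class = "fhr_scalogram")
}

#' @export
print.fhr_scalogram <- function(x, ...) {
  cat(sprintf("<fhr_scalogram> %d scales x %d samples, f %0.4g..%0.4g Hz%s\n",
              nrow(x$magnitude), ncol(x$magnitude),
              max(x$freq_axis), min(x$freq_axis),
              if (is.null(x$image)) "" else ", rendered"))
  invisible(x)
}

#' Render a scalogram as a fixed-size RGB image
#'
#' The magnitude matrix is min-max normalized per image, mapped through a
#' 256-level colormap and resized with bilinear interpolation to the
#' classifier input size (224 x 224 x 3 by default). The rendering is
#' deterministic and invariant to positive rescaling of the magnitude.
#'
#' @param scal an `fhr_scalogram`.
#' @param size `c(height, width)` of the output image.
#' @param colormap `"jet"` (the only built-in) or a `n x 3` RGB matrix in
#'   0..255.
#' @return the scalogram with an `image` field added: an integer array
#'   `height x width x 3` with values in 0..255, highest frequency in the
#'   top row.
#' @export
render_scalogram <- function(scal, size = c(224, 224), colormap = "jet") {
  stopifnot(inherits(scal, "fhr_scalogram"))
  lut <- if (is.character(colormap)) {
    if (!identical(colormap, "jet")) stop("unknown colormap: ", colormap)
    jet_lut(256)
  } else {
    as.matrix(colormap)
  }
  m <- scal$magnitude
  rng <- range(m)
  if (rng[2] <= rng[1]) {
    warning("all-constant scalogram magnitude; rendering uniform image")
    u <- matrix(0, nrow(m), ncol(m))
  } else {
    u <- (m - rng[1]) / (rng[2] - rng[1])
  }
  idx <- pmin(nrow(lut), 1L + floor(u * nrow(lut)))
  rgb_small <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) rgb_small[, , ch] <- matrix(lut[idx, ch], nrow(m), ncol(m))
  img <- EBImage::resize(EBImage::Image(rgb_small / 255, colormode = "Color"),
                         w = size[1], h = size[2], filter = "bilinear")
  arr <- round(EBImage::imageData(img) * 255)
  arr[arr < 0] <- 0; arr[arr > 255] <- 255
  scal$image <- arr
  scal
}

#' Compute a rendered scalogram image for a segment
#'
#' Convenience wrapper: CWT then render.
#'
#' @param segment segment or numeric vector.
#' @param bank a [morse_filterbank()] matching the segment length.
#' @param size image size `c(height, width)`.
#' @return the `height x width x 3` image array (0..255).
#' @export
scalogram_image <- function(segment, bank, size = c(224, 224)) {
  render_scalogram(fhr_cwt(segment, bank), size = size)$image
}

#' Write a rendered scalogram image as PNG
#'
#' @param image `H x W x 3` array in 0..255 (as produced by
#'   [render_scalogram()]), or an `fhr_scalogram` carrying one.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(image, path) {
  if (inherits(image, "fhr_scalogram")) image <- image$image
  if (is.null(image)) stop("scalogram has not been rendered")
  # image dims are (x, y, channel); PNG wants (row, column, channel)
  png::writePNG(aperm(image / 255, c(2, 1, 3)), path)
  invisible(path)
}
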