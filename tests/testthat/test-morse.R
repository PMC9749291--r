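test_that("morse parameters keep P2 = gamma * beta exactly", {
  p <- morse_params(gamma = 3, P2 = 60)
  expect_identical(p$beta, 20)
  expect_identical(p$P2, p$gamma * p$beta)
  p2 <- morse_params(gamma = 3, beta = 55 / 3)
  expect_identical(p2$P2, 55)
})

test_that("the frequency-domain wavelet is zero at non-positive frequencies", {
  p <- morse_params()
  expect_identical(morse_psi_hat(c(-1, 0, -1e-12), p), c(0, 0, 0))
  expect_gt(morse_psi_hat(1, p), 0)
})

test_that("peak frequency matches brute-force maximization", {
  for (P2 in c(55, 60)) {
    p <- morse_params(gamma = 3, P2 = P2)
    wp <- morse_peak_frequency(p)
    grid <- seq(0.01, 6, by = 1e-4)
    wp_brute <- grid[which.max(morse_psi_hat(grid, p))]
    expect_equal(wp, wp_brute, tolerance = 1e-3)
  }
  expect_equal(morse_peak_frequency(morse_params(gamma = 3, P2 = 60)),
               (20 / 3)^(1 / 3), tolerance = 1e-12)
  expect_equal(morse_peak_frequency(morse_params(gamma = 3, beta = 3)), 1)
  # monotone: larger beta -> larger peak at fixed gamma
  peaks <- sapply(seq(5, 40, by = 5), function(b)
    morse_peak_frequency(morse_params(gamma = 3, beta = b)))
  expect_true(all(diff(peaks) > 0))
})

test_that("the normalizing constant sets the peak value to 2", {
  p31 <- morse_params(gamma = 3, beta = 1)
  expect_equal(morse_normalizing_constant(p31), 2 * (3 * exp(1))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(morse_normalizing_constant(morse_params(gamma = 1, beta = 1)),
               2 * exp(1), tolerance = 1e-12)
  for (g in c(1, 2, 3)) {
    for (b in c(5, 20, 55 / 3)) {
      p <- morse_params(gamma = g, beta = b)
      expect_equal(morse_psi_hat(morse_peak_frequency(p), p), 2,
                   tolerance = 1e-9)
    }
  }
})

test_that("demodulate skewness vanishes at gamma 3 and not elsewhere", {
  expect_lt(abs(morse_demodulate_skewness(morse_params(gamma = 3, beta = 20))),
            1e-6)
  expect_lt(abs(morse_demodulate_skewness(morse_params(gamma = 3, beta = 55 / 3))),
            1e-6)
  expect_gt(abs(morse_demodulate_skewness(morse_params(gamma = 1, beta = 20))),
            0.1)
  # independent oracle: closed form -(2 - (g-1)(g-2)) / (g^(3/2) sqrt(b))
  for (g in c(1, 2, 4)) {
    for (b in c(10, 20)) {
      closed <- -(2 - (g - 1) * (g - 2)) / (g^1.5 * sqrt(b))
      expect_equal(morse_demodulate_skewness(morse_params(gamma = g, beta = b)),
                   closed, tolerance = 1e-3)
    }
  }
})

test_that("half-power bandwidth strictly decreases in P2 at gamma 3", {
  bw <- sapply(c(4, 60, 120), function(P2)
    morse_half_power_bandwidth(morse_params(gamma = 3, P2 = P2)))
  expect_true(all(diff(bw) < 0))
})

test_that("the filter bank uses a geometric 12-voice grid of analytic filters", {
  bank <- morse_filterbank(4800, fs = 4)
  expect_equal(max(bank$center_frequencies), 2)  # peak at Nyquist
  ratios <- bank$center_frequencies[-1] / head(bank$center_frequencies, -1)
  expect_equal(ratios, rep(2^(-1 / 12), length(ratios)), tolerance = 1e-12)
  # analyticity on the discrete grid: zero at DC and all negative bins
  n <- bank$n_samples
  neg_bins <- (floor(n / 2) + 2):n
  expect_true(all(bank$psi_hat[, neg_bins] == 0))
  expect_true(all(bank$psi_hat[, 1] == 0))
  # largest scale respects the two-standard-deviation support rule
  p <- bank$params
  sd1 <- sqrt(p$beta * p$gamma) / morse_peak_frequency(p)
  expect_lte(max(bank$scales) * 2 * sd1, n)
  expect_gt(max(bank$scales) * 2^(1 / 12) * 2 * sd1, n)
  # shorter signal: same high end, low end shrinks with support
  bank2 <- morse_filterbank(3600, fs = 4)
  expect_equal(max(bank2$center_frequencies), 2)
  expect_error(morse_filterbank(4, fs = 4), "too small")
})

test_that("cwt localizes tones within one voice step across the band", {
  bank <- morse_filterbank(4800, fs = 4)
  interior <- 400:4400  # stay clear of the periodic boundary
  for (f in c(0.05, 0.1, 0.25, 0.5, 1.0, 1.5)) {
    sc <- fhr_cwt(tone_segment(f), bank)
    ridge <- bank$center_frequencies[
      which.max(rowSums(sc$magnitude[, interior]^2))]
    expect_lte(abs(log2(ridge / f)), 1 / 12 + 1e-9)
  }
})

test_that("cwt magnitude is linear in amplitude and vanishes for constants", {
  bank <- morse_filterbank(1024, fs = 4)
  x <- tone_segment(0.4, n = 1024) + 0.3 * tone_segment(1.1, n = 1024)
  m1 <- fhr_cwt(x, bank)$magnitude
  m3 <- fhr_cwt(3 * x, bank)$magnitude
  expect_equal(m3, 3 * m1, tolerance = 1e-9)
  flat <- fhr_cwt(rep(120, 1024), bank)$magnitude
  expect_lt(max(flat), 1e-9)
  expect_error(fhr_cwt(rep(1, 100), bank), "length mismatch")
})

test_that("a two-tone signal produces two distinct ridges", {
  bank <- morse_filterbank(4800, fs = 4)
  x <- tone_segment(0.2) + tone_segment(1.0)
  mag <- fhr_cwt(x, bank)$magnitude[, 400:4400]
  energy <- rowSums(mag^2)
  # local maxima over scale
  locmax <- which(diff(sign(diff(energy))) == -2) + 1L
  ridge_f <- bank$center_frequencies[locmax]
  expect_true(any(abs(log2(ridge_f / 0.2)) <= 1 / 12 + 1e-9))
  expect_true(any(abs(log2(ridge_f / 1.0)) <= 1 / 12 + 1e-9))
})

test_that("rendering is shaped, scale-invariant and deterministic", {
  bank <- morse_filterbank(1200, fs = 4)
  sc <- fhr_cwt(tone_segment(0.5, n = 1200) + 0.2 * tone_segment(0.1, n = 1200),
                bank)
  r1 <- render_scalogram(sc)
  expect_equal(dim(r1$image), c(224, 224, 3))
  expect_true(all(r1$image >= 0 & r1$image <= 255))
  # positive rescaling of magnitude leaves the image unchanged
  sc_scaled <- sc; sc_scaled$magnitude <- sc$magnitude * 37.5
  expect_identical(render_scalogram(sc_scaled)$image, r1$image)
  # byte-identical PNG across runs
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_scalogram_png(r1, p1)
  write_scalogram_png(render_scalogram(sc), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # degenerate all-constant magnitude renders uniformly, with a warning
  sc0 <- sc; sc0$magnitude[] <- 0
  expect_warning(r0 <- render_scalogram(sc0), "constant")
  expect_lte(length(unique(as.vector(r0$image))), 3L)
})
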