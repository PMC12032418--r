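flat_response <- function() {
  frequency_response(c(20, 100, 1000, 10000, 20000), rep(1 + 0i, 5))
}

test_that("a flat response designs to a pure delay of 200 samples", {
  fir <- build_fir(flat_response())
  expect_s3_class(fir, "fir_filter")
  expect_equal(which.max(abs(fir$h)) - 1L, 200L)
  expect_lte(fir$mse, 1e-4)
  gd <- group_delay(fir, 100, 10000)
  expect_equal(round(gd), 200)
  expect_lt(abs(gd - 200), 0.01)
})

test_that("the designed response matches the interpolated target within the MSE bound", {
  fr <- frequency_response(c(20, 500, 2000, 8000, 20000),
                           complex(modulus = c(1, 1, 0.5, 0.2, 0.1),
                                   argument = c(0, -0.5, -1.5, -3, -5)))
  fir <- build_fir(fr, mse_tol = 1e-5)
  expect_lte(fir$mse, 1e-5)
  # independent check by direct discrete-Fourier evaluation on a subsample
  ext <- extend_response(fr, fir$fs)
  grid <- seq(0, fir$fs / 2, length.out = fir$n_interp)
  sub <- seq(1, length(grid), by = 257)
  mag <- stats::spline(ext$frequencies, Mod(ext$values),
                       xout = grid[sub], method = "natural")$y
  ph <- stats::spline(ext$frequencies,
                      fetalsound:::unwrap_phase(Arg(ext$values)),
                      xout = grid[sub], method = "natural")$y
  target <- complex(modulus = pmax(mag, 0), argument = ph) *
    exp(-2i * pi * grid[sub] * 200 / fir$fs)
  H <- vapply(grid[sub], function(f) {
    n <- seq_along(fir$h) - 1
    sum(fir$h * exp(-2i * pi * f * n / fir$fs))
  }, complex(1))
  expect_lt(mean(Mod(H - target)^2) / mean(Mod(target)^2), 2e-5)
})

test_that("an unreachable design tolerance reports the achieved MSE", {
  fr <- frequency_response(c(20, 150, 151, 20000),
                           c(1 + 0i, 1 + 0i, 1e-3 + 0i, 1e-3 + 0i))
  expect_error(build_fir(fr, mse_tol = 1e-12, max_order = 64),
               "MSE .* order cap")
})

test_that("response extension is flat into infrasound and untouched in band", {
  fr <- frequency_response(c(30, 1000, 18000),
                           complex(modulus = c(0.8, 0.6, 0.2),
                                   argument = c(-0.1, -1, -4)))
  ext <- extend_response(fr, 44100)
  expect_equal(min(ext$frequencies), 0)
  expect_equal(max(ext$frequencies), 22050)
  expect_true(all(diff(ext$frequencies) > 0))
  expect_equal(Mod(ext$values[1]), 0.8)        # 0 Hz takes the lowest band
  inb <- match(c(30, 1000, 18000), ext$frequencies)
  expect_equal(ext$values[inb], fr$values)
  expect_equal(Mod(ext$values[length(ext$values)]), 0)  # Nyquist roll-off
  # an already-complete response is returned unchanged
  expect_identical(extend_response(ext, 44100), ext)
})

test_that("filtering is linear, causal and scales tones by the filter magnitude", {
  fir <- build_fir(flat_response())
  set.seed(7)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_equal(apply_fir(fir, a + b), apply_fir(fir, a) + apply_fir(fir, b),
               tolerance = 1e-12)
  # causality: output of a shifted impulse is the shifted impulse response
  x <- rep(0, 500); x[101] <- 1
  y <- apply_fir(fir, x)
  expect_lt(max(abs(y[1:100])), 1e-12)
  expect_equal(y[101:(100 + fir$order)], fir$h, tolerance = 1e-12)
  # steady-state tone at a design frequency
  f0 <- 1000
  n <- 0:44099
  tone <- sin(2 * pi * f0 * n / 44100)
  out <- apply_fir(fir, tone)
  Hmag <- abs(sum(fir$h * exp(-2i * pi * f0 * (seq_along(fir$h) - 1) / 44100)))
  seg <- out[10000:30000]
  expect_lt(abs(max(abs(seg)) - Hmag) / Hmag, 0.01)
})

test_that("WAV files round-trip in 16-bit PCM and 32-bit float", {
  x <- cbind(sin(2 * pi * 440 * (0:999) / 44100),
             sin(2 * pi * 880 * (0:999) / 44100)) * 0.5
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 44100, p16, bits = 16)
  w <- read_wav(p16)
  expect_equal(w$rate, 44100)
  expect_equal(dim(w$samples), dim(x))
  expect_lt(max(abs(w$samples - x)), 2 / 32768)
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 48000, p32, bits = 32)
  w32 <- read_wav(p32)
  expect_equal(w32$rate, 48000)
  expect_lt(max(abs(w32$samples - x)), 1e-6)
})

test_that("convolving audio delays, normalises and respects the rate contract", {
  fir <- build_fir(flat_response())
  x <- sin(2 * pi * 440 * (0:999) / 44100) * 0.5
  pin <- withr::local_tempfile(fileext = ".wav")
  pout <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 44100, pin)
  info <- convolve_audio(fir, pin, pout, peak_dbfs = -1)
  expect_equal(info$n_samples_out, 1000L + fir$order - 1L)
  out <- read_wav(pout)
  expect_equal(max(abs(out$samples)), 10^(-1 / 20), tolerance = 1e-3)
  # mismatched rate is an error unless resampling is allowed
  pin48 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 48000, pin48)
  expect_error(convolve_audio(fir, pin48, pout), "mismatch")
  info2 <- convolve_audio(fir, pin48, pout, resample = TRUE)
  expect_equal(info2$rate, 44100)
})

test_that("filters round-trip through the two-column text format", {
  fr <- frequency_response(c(20, 1000, 20000),
                           complex(modulus = c(1, 0.7, 0.2),
                                   argument = c(0, -1, -3)))
  fir <- build_fir(fr)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fir(fir, path)
  back <- read_fir(path)
  expect_equal(back$h, fir$h)
  expect_equal(back$fs, fir$fs)
  expect_equal(back$order, fir$order)
  # identical inputs give bit-identical impulse responses
  expect_identical(build_fir(fr)$h, fir$h)
})
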