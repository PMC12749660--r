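test_that("CAR removes the instantaneous cross-channel mean", {
  rec <- eeg_recording(rbind(rep(3, 50), rep(5, 50)), fs = 10)
  out <- rereference_car(rec)
  expect_equal(out$data[1, ], rep(-1, 50))
  expect_equal(out$data[2, ], rep(1, 50))
  expect_identical(out$reference, "car")

  set.seed(11)
  m <- matrix(rnorm(300), 3)
  car <- rereference_car(eeg_recording(m, fs = 100))
  expect_equal(car$data, sweep(m, 2, colMeans(m)), tolerance = 1e-12)
  expect_lt(max(abs(colSums(car$data))), 1e-10)

  # idempotence
  twice <- rereference_car(car)
  expect_equal(twice$data, car$data, tolerance = 1e-12)

  expect_error(rereference_car(eeg_recording(matrix(rnorm(50), 1), fs = 10)),
               "single-channel")
})

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  fs <- 500
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs = fs)
  mid <- 5000:10000

  inband <- bandpass_fir(tone, 7, 12)
  expect_gt(max(abs(inband$data[1, mid])), 0.95)

  stopband <- bandpass_fir(tone, 1, 3)
  expect_lt(max(abs(stopband$data[1, mid])), 0.01)  # >= 40 dB down

  set.seed(4)
  wn <- eeg_recording(matrix(rnorm(length(t)), 1), fs = fs)
  filt <- bandpass_fir(wn, 1, 3)
  spec <- Mod(fft(filt$data[1, ]))^2
  freqs <- seq(0, fs - fs / length(t), by = fs / length(t))
  keep <- freqs <= fs / 2
  inside <- keep & freqs >= 0.5 & freqs <= 4
  expect_lt(sum(spec[keep & !inside]) / sum(spec[keep]), 0.01)

  expect_error(bandpass_fir(tone, 7, 260), "Nyquist")
})

test_that("canonical bands tile broadband energy within 10%", {
  fs <- 500
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(2 * 120 * fs), 2), fs = fs)
  bands <- eeg_bands(c("delta", "theta", "alpha", "beta1", "beta2",
                       "beta3", "gamma"))
  pows <- purrr::pmap_dbl(bands, function(band, lo, hi) {
    sum(apply(bandpass_fir(rec, lo, hi)$data, 1, var))
  })
  broad <- sum(apply(bandpass_fir(rec, 1, 45)$data, 1, var))
  expect_gt(sum(pows) / broad, 0.9)
  expect_lt(sum(pows) / broad, 1.1)
})

test_that("epoching yields the documented geometry", {
  rec <- eeg_recording(matrix(rnorm(2 * 160 * 500), 2), fs = 500)
  ep <- epoch_recording(rec, epoch_len = 8, fs_out = 200)
  expect_equal(dim(ep$x), c(20, 2, 1600))
  expect_equal(ep$fs, 200)

  short <- eeg_recording(matrix(rnorm(2 * round(7.9 * 500)), 2), fs = 500)
  expect_error(epoch_recording(short, 8, 200), "shorter than one epoch")

  mid <- eeg_recording(matrix(rnorm(2 * 23 * 500), 2), fs = 500)
  expect_equal(dim(epoch_recording(mid, 8, 200)$x)[1], 2)

  expect_error(epoch_recording(rec, epoch_len = 8.0003, fs_out = 200),
               "integer sample count")
  # sample-count bound: n_epochs * 1600 <= duration * 200
  expect_lte(20 * 1600, 160 * 200)
})

test_that("downsampling preserves in-band content", {
  fs <- 500
  t <- seq(0, 16 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs = fs)
  ep <- epoch_recording(rec, 8, 200)
  x <- ep$x[1, 1, ]
  # amplitude and frequency survive the 500 -> 200 Hz resample
  expect_gt(max(x[200:1400]), 0.95)
  spec <- Mod(fft(x))^2
  peak_bin <- which.max(spec[2:800]) + 1
  expect_equal((peak_bin - 1) * 200 / 1600, 10, tolerance = 0.2)
})

test_that("amplitude screening drops exactly the offending epochs", {
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(2 * 24 * 200, sd = 10), 2), fs = 200)
  ep <- epoch_recording(rec, 8, 200)
  expect_equal(dim(reject_noisy_epochs(ep, 1e6)$x), dim(ep$x))

  spiked <- ep
  spiked$x[2, 1, 100] <- 500
  out <- reject_noisy_epochs(spiked, 200)
  expect_equal(dim(out$x)[1], dim(ep$x)[1] - 1)
  expect_equal(out$x[1, , ], spiked$x[1, , ])

  # brute-force survivor count on a mixed set
  mixed <- ep
  mixed$x[1, 2, 5] <- 300
  mixed$x[3, 1, 9] <- 250
  thr <- 220
  keep_oracle <- vapply(seq_len(dim(mixed$x)[1]),
                        function(e) max(abs(mixed$x[e, , ])) <= thr,
                        logical(1))
  expect_equal(dim(reject_noisy_epochs(mixed, thr)$x)[1], sum(keep_oracle))

  expect_error(reject_noisy_epochs(ep, 1e-6), "review the threshold")
  expect_error(reject_noisy_epochs(ep, -1), "amp_thresh")
})

test_that("recordings round-trip through the TSV + sidecar format", {
  rec <- eeg_recording(matrix(rnorm(60), 3), fs = 120,
                       labels = c("T7", "Cz", "P8"))
  expect_identical(rec$labels, c("T3", "Cz", "T6"))  # synonym mapping
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
})
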