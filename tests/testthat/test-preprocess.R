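sine_recording <- function(freq, rate = 5000, secs = 2, amp = 10) {
  m <- fx_montage()
  t <- seq_len(rate * secs) / rate
  dat <- matrix(rep(amp * sin(2 * pi * freq * t), each = 32), 32)
  new_recording(dat, rate = rate,
                events = data.frame(sample = as.integer(rate),
                                    nerve = "median", side = "left"),
                montage = m)
}

mid <- function(x) {           # central portion, away from filter edges
  n <- length(x)
  x[round(n * 0.25):round(n * 0.75)]
}

test_that("the 50 Hz notch removes line noise and the band-pass leaves 100 Hz untouched", {
  r50 <- sine_recording(50)
  f50 <- filter_recording(r50, notch50 = TRUE)
  expect_lt(sqrt(mean(mid(f50$data[1, ])^2)) /
              sqrt(mean(mid(r50$data[1, ])^2)), 0.05)

  r100 <- sine_recording(100)
  f100 <- filter_recording(r100, notch50 = FALSE)
  gain <- sqrt(mean(mid(f100$data[1, ])^2)) /
    sqrt(mean(mid(r100$data[1, ])^2))
  expect_gt(gain, 10^(-1 / 20))          # < 1 dB attenuation in-band
  expect_equal(f100$events, r100$events)
})

test_that("constant channels are zeroed and invalid bands are rejected", {
  m <- fx_montage()
  rec <- new_recording(matrix(7.3, 32, 2000), rate = 1000,
                       events = data.frame(sample = 500L, nerve = "median",
                                           side = "left"), montage = m)
  f <- filter_recording(rec, 8, 300)
  expect_lt(max(abs(f$data)), 1e-8)
  expect_error(filter_recording(rec, 8, 600), "Nyquist")
  expect_error(filter_recording(rec, 300, 100), "below hi")
})

test_that("average re-referencing appends the reference as a 33rd channel with zero-mean frames", {
  m <- fx_montage()
  set.seed(20)
  dat <- matrix(rnorm(32 * 40), 32, 40)
  rownames(dat) <- recorded_channels(m)
  ev <- new_evoked(dat, c(-10, 30), 1000, m)
  av <- average_reference(ev)
  expect_equal(nrow(av$data), 33)
  expect_lt(max(abs(colMeans(av$data))), 1e-10)
  # brute-force recomputation: zero ref row appended, per-frame mean removed
  full <- rbind(dat, ref = 0)
  full <- sweep(full, 2, colMeans(full))
  expect_equal(unname(av$data[m$labels, ]), unname(full[m$labels, ]),
               tolerance = 1e-12)
  expect_error(average_reference(av), "already")

  z <- new_evoked(matrix(0, 32, 5,
                         dimnames = list(recorded_channels(m), NULL)),
                  c(-1, 4), 1000, m)
  expect_equal(max(abs(average_reference(z)$data)), 0)
})

test_that("epoching rejects strictly above 100 uV and keeps boundary trials", {
  m <- fx_montage()
  set.seed(21)
  rate <- 500
  dat <- matrix(rnorm(32 * rate * 10, 0, 5), 32)
  onsets <- as.integer(seq(rate, rate * 9, by = rate))
  # trial 2 peaks exactly at 100, trial 4 just above
  dat[3, onsets[2] + 10] <- 100
  dat[7, onsets[4] + 10] <- 100.1
  rec <- new_recording(dat, rate,
                       data.frame(sample = onsets, nerve = "median",
                                  side = "left"), m)
  ep <- epoch_and_reject(rec, c(-100, 200), 100)
  expect_true(ep$kept[2])
  expect_false(ep$kept[4])
  expect_equal(sum(!ep$kept), 1)
  ep_all <- epoch_and_reject(rec, c(-100, 200), Inf)
  expect_true(all(ep_all$kept))
  rec0 <- rec; rec0$events <- rec0$events[0, ]
  expect_error(epoch_and_reject(rec0), "no events")
})

test_that("averaging with baseline correction matches the defining arithmetic", {
  sc <- fx_script()
  quiet <- noise_spec(sensor_sd = 0, background_amp = 0,
                      latency_jitter_sd = 0, amplitude_jitter_sd = 0)
  syn <- synthesize_epochs(sc, quiet, n_trials = 3, rate = 1000, seed = 2)
  ev <- average_epochs(syn$epochs, baseline = c(-80, -30))
  one <- syn$epochs$data[1, , ]
  bsel <- in_window(syn$epochs$times, c(-80, -30))
  expect_equal(unname(ev$data), one - rowMeans(one[, bsel]),
               tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(ev$data[, bsel]))), 1e-10)
  expect_equal(ev$n_sweeps, 3L)
  bad <- syn$epochs; bad$kept[] <- FALSE
  expect_error(average_epochs(bad), "no kept trials")
  expect_error(average_epochs(syn$epochs, baseline = c(-150, -30)),
               "baseline outside")
})

test_that("averaging n trials reduces white sensor noise like 1/sqrt(n)", {
  m <- fx_montage()
  set.seed(30)
  n <- 80
  dat <- array(rnorm(n * 32 * 100), dim = c(n, 32, 100))
  ep <- new_epochset(dat, c(-50, 50), 1000, m)
  ev <- average_epochs(ep, baseline = c(-50, -40))
  sel <- in_window(ep$times, c(0, 50))     # away from the baseline window
  ratio <- sqrt(mean(ev$data[, sel]^2)) / sqrt(mean(dat[, , sel]^2))
  expect_lt(abs(ratio - 1 / sqrt(n)) / (1 / sqrt(n)), 0.2)
})

test_that("zero-phase filtering leaves a planted symmetric peak latency within one sample", {
  m <- fx_montage()
  rate <- 5000
  t_ms <- (seq_len(3 * rate) / rate) * 1000
  bump <- 20 * exp(-((t_ms - 1500) / 2)^2)    # 2 ms Gaussian at t = 1.5 s
  set.seed(31)
  pat <- rnorm(32)
  dat <- outer(pat, bump)
  rec <- new_recording(dat, rate,
                       data.frame(sample = as.integer(1.4 * rate),
                                  nerve = "median", side = "left"), m)
  f <- filter_recording(rec, 8, 300)
  peak_raw <- which.max(gfp(dat))
  peak_f <- which.max(gfp(f$data))
  expect_lte(abs(peak_f - peak_raw), 1)
})

test_that("the full preprocessing chain reports its bookkeeping", {
  sc <- fx_script()
  ses <- synthesize_session(sc, noise_spec(artifact_fraction = 0.1),
                            duration_min = 0.5, rate = 2000, seed = 6)
  cfg <- default_config()
  cfg$filter_hi <- 300
  out <- preprocess_recording(ses$recording, cfg)
  expect_equal(out$report$n_trials, 15)
  expect_equal(out$report$n_rejected, 1)   # floor(0.1 * 15)
  expect_equal(out$evoked$n_sweeps, out$report$n_kept)
  expect_equal(out$evoked$reference_mode, "average")
  expect_equal(nrow(out$evoked$data), 33)
})
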