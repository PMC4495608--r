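test_that("component detection finds the scripted peaks at the right latency", {
  sc <- fx_script()
  ev <- synthesize_evoked(sc, snr = Inf)
  bs <- detect_component(ev, "e32", c(4, 10), "neg", "brainstem")
  expect_lte(abs(bs$latency - 6.9), 0.2)      # within one 0.2 ms frame
  expect_lt(bs$amplitude, 0)
  gf <- detect_component(ev, "GFP", c(4, 10), "max")
  expect_lte(abs(gf$latency - 6.9), 0.2)
  cx <- detect_component(ev, "e12", c(12, 25), "pos", "cortical")
  expect_gt(cx$amplitude, 0)
  expect_false(bs$boundary_hit || cx$boundary_hit)
})

test_that("an impulse is located exactly; flat and edge cases are flagged", {
  m <- fx_montage()
  dat <- matrix(0, 33, 150)
  rownames(dat) <- m$labels
  dat[, 95] <- random_map()          # impulse at 18 ms under a -1 ms origin
  ev <- new_evoked(dat, c(-1, 29), 5000, m, reference_mode = "average")
  expect_equal(ev$times[95], 17.8)
  d <- detect_component(ev, "GFP", c(10, 25), "max")
  expect_equal(d$latency, 17.8)
  # window that excludes the impulse: extremum lands on the edge, flagged
  d2 <- detect_component(ev, "GFP", c(19, 25), "max")
  expect_true(d2$boundary_hit)
  flat <- detect_component(ev, m$labels[1], c(0, 10), "pos")
  expect_true(flat$missing)
  expect_error(detect_component(ev, "nope", c(0, 10), "pos"), "unknown")
})

test_that("peak measures are invariant to a baseline offset removed by preprocessing", {
  sc <- fx_script()
  quiet <- noise_spec(sensor_sd = 0, background_amp = 0,
                      latency_jitter_sd = 0, amplitude_jitter_sd = 0)
  syn <- synthesize_epochs(sc, quiet, n_trials = 2, rate = 5000, seed = 1)
  shifted <- syn$epochs
  shifted$data <- shifted$data + 15          # constant offset on every channel
  ev1 <- average_reference(average_epochs(syn$epochs))
  ev2 <- average_reference(average_epochs(shifted))
  d1 <- detect_component(ev1, "e32", c(4, 10), "neg")
  d2 <- detect_component(ev2, "e32", c(4, 10), "neg")
  expect_equal(d1$latency, d2$latency)
  expect_equal(d1$amplitude, d2$amplitude, tolerance = 1e-10)
})

make_null_group <- function(n, frames = 30, seed) {
  m <- fx_montage()
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    X <- matrix(rnorm(33 * frames), 33)
    X <- sweep(X, 2, colMeans(X))
    rownames(X) <- m$labels
    new_evoked(X, c(0, frames / 5), 5000, m, reference_mode = "average")
  })
}

test_that("electrodewise t-maps: empty under identity, localized under a planted offset, symmetric under swap", {
  gA <- make_null_group(4, seed = 80)
  same <- electrodewise_ttest(gA, gA)
  expect_equal(sum(same$mask), 0)
  expect_true(all(same$t == 0))

  gB <- make_null_group(4, seed = 81)
  # plant a large offset on one electrode over 10 frames in group B
  gB <- lapply(gB, function(ev) { ev$data[7, 11:20] <- ev$data[7, 11:20] + 30
                                  ev })
  res <- electrodewise_ttest(gA, gB)
  expect_true(all(res$mask[7, 11:20]))
  expect_equal(sum(res$mask[-7, ]), 0)
  sw <- electrodewise_ttest(gB, gA)
  expect_equal(sw$mask, res$mask)
  expect_equal(sw$t, -res$t, tolerance = 1e-12)
  # agrees with stats::t.test cell by cell on a few cells
  for (cell in list(c(7, 15), c(1, 1), c(20, 25))) {
    a <- sapply(gA, function(e) e$data[cell[1], cell[2]])
    b <- sapply(gB, function(e) e$data[cell[1], cell[2]])
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(res$t[cell[1], cell[2]]), unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(res$p[cell[1], cell[2]]), tt$p.value,
                 tolerance = 1e-10)
  }
})

test_that("per-frame family-wise false-positive rate stays at the nominal level under the null", {
  n_rep <- 1000
  frames <- 8
  fam_hits <- 0
  set.seed(90)
  for (r in seq_len(n_rep)) {
    A <- lapply(1:4, function(i) matrix(rnorm(33 * frames), 33))
    B <- lapply(1:4, function(i) matrix(rnorm(33 * frames), 33))
    res <- ssepmap:::cellwise_ttest(A, B)
    sig <- res$p < 0.01 / 33
    fam_hits <- fam_hits + sum(colSums(sig) > 0)
  }
  rate <- fam_hits / (n_rep * frames)
  se <- sqrt(0.01 * 0.99 / (n_rep * frames))
  expect_lte(rate, 0.01 + 2 * se)
})

test_that("component measure comparison: null passes, a planted latency shift is caught", {
  sc <- fx_script()
  study <- synthesize_study(sc, noise_spec(), n_sessions = 4,
                            n_trials = 30, rate = 5000, seed = 91)
  specs <- default_component_specs(fx_montage())
  same <- compare_component_measures(study$sessions, study$sessions, specs)
  expect_equal(sum(same$significant, na.rm = TRUE), 0)

  # shift group B by 2 ms: latency rows become significant
  shift_ms <- 2
  shifted <- lapply(study$sessions, function(ev) {
    k <- round(shift_ms / 1000 * ev$rate)
    ev$data <- cbind(ev$data[, rep(1, k)], ev$data[, 1:(ncol(ev$data) - k)])
    ev
  })
  res <- compare_component_measures(study$sessions, shifted, specs)
  lat <- res[res$measure == "latency", ]
  expect_true(any(lat$significant))
  # reported means equal direct recomputation from the detections
  d <- do.call(rbind, lapply(study$sessions, function(ev)
    detect_component(ev, specs[[1]]$channel, specs[[1]]$window,
                     specs[[1]]$polarity, specs[[1]]$component)))
  expect_equal(res$mean_A[res$channel == specs[[1]]$channel &
                            res$measure == "latency" &
                            res$component == "brainstem"],
               mean(d$latency), tolerance = 1e-12)
})
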