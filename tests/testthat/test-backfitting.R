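test_that("self-fit of the noise-free script recovers the ground-truth labeling", {
  sc <- fx_script()
  ev <- synthesize_evoked(sc, snr = Inf)
  lab <- fit_templates(ev, sc$templates, c(6, 50))
  truth <- script_labels(sc, lab$times)
  expect_equal(lab$labels, truth)
})

test_that("runs of two frames or fewer are rejected as unlabeled, not reassigned", {
  m <- fx_montage()
  set.seed(50)
  tA <- random_map(); tA <- tA / gfp(tA)
  tB <- random_map(); tB <- tB - sum(tA * tB) / sum(tA^2) * tA
  tB <- tB / gfp(tB)
  # A for 10 frames, B for exactly 2 frames, A for 10 frames
  X <- cbind(tA %o% rep(1, 10), tB %o% rep(1, 2), tA %o% rep(1, 10))
  ev <- new_evoked(sweep(X, 2, colMeans(X)), c(0, 22), 1000, m,
                   reference_mode = "average")
  lab <- fit_templates(ev, cbind(tA, tB), c(0, 22), min_frames = 2)
  expect_true(all(is.na(lab$labels[11:12])))
  expect_true(all(lab$labels[c(1:10, 13:22)] == 1L))
  # a 3-frame run survives
  X3 <- cbind(tA %o% rep(1, 10), tB %o% rep(1, 3), tA %o% rep(1, 9))
  ev3 <- new_evoked(sweep(X3, 2, colMeans(X3)), c(0, 22), 1000, m,
                    reference_mode = "average")
  lab3 <- fit_templates(ev3, cbind(tA, tB), c(0, 22), min_frames = 2)
  expect_true(all(lab3$labels[11:13] == 2L))
  # zero-field frames are unlabeled
  X0 <- X; X0[, 5] <- 0
  ev0 <- new_evoked(X0, c(0, 22), 1000, m, reference_mode = "average")
  expect_true(is.na(fit_templates(ev0, cbind(tA, tB), c(0, 22))$labels[5]))
})

test_that("the eight map parameters match a naive frame-loop recomputation", {
  m <- fx_montage()
  set.seed(51)
  X <- matrix(rnorm(33 * 40), 33)
  X <- sweep(X, 2, colMeans(X))
  ev <- new_evoked(X, c(0, 8), 5000, m, reference_mode = "average")
  tmpl <- sapply(1:3, function(i) random_map())
  lab_vec <- sample(c(NA, 1:3), 40, replace = TRUE)
  labeling <- structure(list(labels = lab_vec, times = ev$times,
                             window = c(0, 8), K = 3L, frame_ms = 0.2),
                        class = "ssep_labeling")
  fit <- suppressWarnings(map_parameters(ev, tmpl, labeling))
  g <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  gv <- naive_gev(X, tmpl, lab_vec)
  for (k in 1:3) {
    idx <- which(!is.na(lab_vec) & lab_vec == k)
    if (!length(idx)) next
    scs <- sapply(idx, function(t) {
      u <- X[, t]; v <- tmpl[, k]
      sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    })
    expect_equal(fit$latency_first_onset[k], ev$times[min(idx)])
    expect_equal(fit$duration[k], length(idx) * 0.2)
    expect_equal(fit$gev[k], gv$per_map[k], tolerance = 1e-12)
    expect_equal(fit$latency_best_sc[k], ev$times[idx[which.max(scs)]])
    expect_equal(fit$mean_sc[k], mean(scs), tolerance = 1e-12)
    expect_equal(fit$max_gfp[k], max(g[idx]), tolerance = 1e-12)
    expect_equal(fit$latency_max_gfp[k], ev$times[idx[which.max(g[idx])]])
    expect_equal(fit$mean_gfp[k], mean(g[idx]), tolerance = 1e-12)
  }
})

test_that("noise-free self-fit reproduces the scripted onsets, and a single map spans the window", {
  sc <- fx_script()
  ev <- synthesize_evoked(sc, snr = Inf)
  lab <- fit_templates(ev, sc$templates, c(6, 50))
  fit <- map_parameters(ev, sc$templates, lab)
  expect_equal(fit$latency_first_onset, c(6, 12.8, 15.2, 25.6))
  expect_equal(sum(fit$duration), 44)     # the whole 6-50 ms window

  one <- fit_templates(ev, sc$templates[, 3, drop = FALSE], c(15.2, 25.6))
  f1 <- map_parameters(ev, sc$templates[, 3, drop = FALSE], one)
  expect_equal(f1$duration, 25.6 - 15.2)
})

test_that("back-fitting a noisy session stays above 90 % frame accuracy", {
  sc <- fx_script()
  study <- synthesize_study(sc, noise_spec(), n_sessions = 1,
                            n_trials = 90, seed = 13)
  lab <- fit_templates(study$sessions[[1]], sc$templates, c(6, 50))
  truth <- script_labels(sc, lab$times)
  acc <- mean(lab$labels == truth, na.rm = TRUE)
  expect_gt(acc, 0.9)
})

test_that("successive-map latency comparisons detect a planted gap and calibrate under the null", {
  mk_fits <- function(onsets, n = 9, sd = 0.5, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(onsets), function(k)
      data.frame(session = 1:n, map = k,
                 latency_first_onset = rnorm(n, onsets[k], sd),
                 latency_best_sc = rnorm(n, onsets[k] + 2, sd))))
  }
  # true 10 ms gap, SD 0.5 ms: significant after Bonferroni-by-33
  st <- compare_successive_map_latencies(mk_fits(c(10, 20), seed = 60))
  expect_true(all(st$significant))
  # identical distributions: type-I rate within binomial slack of the
  # adjusted alpha over seeded replicates
  n_rep <- 400
  rej <- 0; tests <- 0
  for (r in seq_len(n_rep)) {
    st0 <- compare_successive_map_latencies(mk_fits(c(15, 15), seed = r))
    rej <- rej + sum(st0$significant)
    tests <- tests + nrow(st0)
  }
  a <- 0.01 / 33
  expect_lte(rej / tests, a + 2 * sqrt(a * (1 - a) / tests))
})

test_that("degenerate zero-variance groups take the rank-test path", {
  fits <- rbind(data.frame(session = 1:9, map = 1,
                           latency_first_onset = 6,
                           latency_best_sc = 8),
                data.frame(session = 1:9, map = 2,
                           latency_first_onset = 13,
                           latency_best_sc = 14))
  st <- compare_successive_map_latencies(fits)
  expect_true(all(st$test == "mann-whitney"))
  expect_true(all(st$significant))        # perfectly separated groups
  few <- fits[fits$session <= 2, ]
  st2 <- compare_successive_map_latencies(few)
  expect_true(all(st2$test == "skipped"))
})

test_that("group comparison of the eight parameters: null, planted effect, symmetry", {
  sc <- fx_script()
  study <- synthesize_study(sc, noise_spec(), n_sessions = 4,
                            n_trials = 30, rate = 1000, seed = 70)
  fits <- backfit_sessions(study$sessions, sc$templates, c(6, 50))
  # A = B: nothing can be significant
  same <- compare_groups(fits, fits)
  expect_equal(sum(same$significant, na.rm = TRUE), 0)
  # planted GEV shift in map 2 only
  fitsB <- fits
  fitsB$gev[fitsB$map == 2] <- fitsB$gev[fitsB$map == 2] + 0.08 +
    rnorm(4, 0, 0.002)
  shift <- compare_groups(fits, fitsB)
  sig <- shift[which(shift$significant), ]
  expect_true(all(sig$map == 2 & sig$parameter == "gev"))
  expect_gte(nrow(sig), 1)
  # swapping the groups flips t but not the decisions
  sw <- compare_groups(fitsB, fits)
  expect_equal(abs(sw$t), abs(shift$t), tolerance = 1e-12)
  expect_equal(sw$significant, shift$significant)
})
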