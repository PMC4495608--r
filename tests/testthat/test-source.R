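test_that("the source grid hits the target count inside the brain shell", {
  h <- fx_head()
  sp <- build_source_space(h, 3000)
  expect_gte(nrow(sp$points), 2900)
  expect_lte(nrow(sp$points), 3100)
  expect_true(all(sqrt(rowSums(sp$points^2)) < 0.68 * h$scalp_radius))
  # deterministic
  expect_identical(sp$points, build_source_space(h, 3000)$points)
  # halving the density target ~doubles... rather: 1/8 the points at twice
  # the spacing
  sp8 <- build_source_space(h, 375)
  expect_lt(abs(nrow(sp$points) / nrow(sp8$points) - 8) / 8, 0.2)
  expect_error(build_source_space(h, 5), "too small")
  # 6-connectivity: interior points have exactly 6 neighbors
  inner <- which(sqrt(rowSums(sp$points^2)) < 0.4 * h$scalp_radius)
  expect_true(all(lengths(sp$neighbors[inner]) == 6))
})

test_that("the lead field shares the simulator's forward solution and is average-referenced", {
  h <- fx_head()
  m <- fx_montage()
  sp <- build_source_space(h, 60)
  lf <- compute_leadfield(h, m, sp)
  expect_identical(lf$gain, forward_gain(h, m, sp$points))
  expect_lt(max(abs(colSums(lf$gain))), 1e-12)
  expect_equal(dim(lf$gain), c(33, 3 * nrow(sp$points)))
})

op_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- build_source_space(fx_head(), 150)
      cache <<- loreta_operator(compute_leadfield(fx_head(), fx_montage(),
                                                  sp))
    }
    cache
  }
})

test_that("the inverse operator satisfies its normal equations and the ridge limit", {
  op <- op_small()
  expect_length(op$alphas, 13)
  expect_true(all(diff(op$alphas) > 0))
  for (i in c(3, 7, 11)) {
    lhs <- (op$M + op$alphas[i] * op$H) %*% (op$gain %*% op$T_list[[i]])
    expect_lt(max(abs(lhs - op$M)) / max(abs(op$M)), 1e-8)
  }
  set.seed(100)
  v <- random_map()
  nrm <- vapply(seq_along(op$alphas), function(i)
    sqrt(sum((op$T_list[[i]] %*% v)^2)), 0)
  expect_true(all(diff(nrm) < 0))
})

test_that("current density estimation is linear and zero-preserving", {
  op <- op_small()
  m <- fx_montage()
  h <- fx_head()
  z <- new_evoked(matrix(0, 33, 5, dimnames = list(m$labels, NULL)),
                  c(0, 1), 5000, m, reference_mode = "average")
  expect_equal(max(estimate_cd(op, z, "fixed", 5)$magnitude), 0)
  v <- forward_topography(h, m, c(5, -5, 8), c(1, 1, 0))
  ev <- new_evoked(matrix(v, 33, 1), c(0, 0.2), 5000, m,
                   reference_mode = "average")
  ev3 <- new_evoked(matrix(-3 * v, 33, 1), c(0, 0.2), 5000, m,
                    reference_mode = "average")
  cd1 <- estimate_cd(op, ev, "fixed", 5)
  cd3 <- estimate_cd(op, ev3, "fixed", 5)
  expect_equal(cd3$magnitude, 3 * cd1$magnitude, tolerance = 1e-10)
})

test_that("with fixed regularization, inverting the average equals averaging the inverses", {
  op <- op_small()
  m <- fx_montage()
  set.seed(101)
  n_ep <- 6; nt <- 8
  dat <- array(rnorm(n_ep * 33 * nt), dim = c(n_ep, 33, nt))
  for (i in seq_len(n_ep)) dat[i, , ] <- sweep(dat[i, , ], 2,
                                               colMeans(dat[i, , ]))
  ep <- new_epochset(dat, c(-1, 0.6), 5000, m, reference_mode = "average")
  avg <- new_evoked(apply(dat, c(2, 3), mean), c(-1, 0.6), 5000, m,
                    reference_mode = "average")
  Javg <- estimate_cd(op, avg, "fixed", 5, keep_components = TRUE)$components
  # averaging the per-epoch components must give the same J
  flatJ <- lapply(seq_len(n_ep), function(i) {
    evi <- new_evoked(dat[i, , ], c(-1, 0.6), 5000, m,
                      reference_mode = "average")
    estimate_cd(op, evi, "fixed", 5, keep_components = TRUE)$components
  })
  expect_equal(Reduce(`+`, flatJ) / n_ep, Javg, tolerance = 1e-10)
})

test_that("GCV chooses more regularization for noisier data", {
  op <- op_small()
  sc <- fx_script()
  idx <- sapply(1:6, function(s) {
    sapply(c(20, 2, 0.5), function(snr)
      estimate_cd(op, synthesize_evoked(sc, snr = snr, seed = s),
                  "gcv")$alpha_index)
  })
  expect_true(all(apply(idx, 2, diff) >= 0))
})

test_that("baseline-vs-post paired t statistics behave on degenerate and labeled input", {
  # constant magnitudes: t = 0 everywhere, flagged zero variance
  cdc <- structure(list(magnitude = array(1, dim = c(5, 4, 30)),
                        alpha_index = 1, alpha = 1,
                        times = epoch_times(c(-10, 20), 1000),
                        window = c(-10, 20)),
                   class = "ssep_cd")
  st <- cd_stats(cdc, baseline = c(-10, 0), post = c(0, 20))
  expect_true(all(st$t == 0))
  expect_true(all(st$zero_variance))
  expect_equal(sum(st$mask), 0)

  # window averages equal brute-force per-window means
  set.seed(110)
  mag <- array(abs(rnorm(20 * 6 * 30)), dim = c(20, 6, 30))
  cdr <- structure(list(magnitude = mag, alpha_index = 1, alpha = 1,
                        times = epoch_times(c(-10, 20), 1000),
                        window = c(-10, 20)),
                   class = "ssep_cd")
  str <- cd_stats(cdr, baseline = c(-10, 0), post = c(0, 20))
  lab <- structure(list(labels = rep(c(1L, 2L), each = 8),
                        times = epoch_times(c(2, 18), 1000),
                        window = c(2, 18), K = 2L, frame_ms = 1),
                   class = "ssep_labeling")
  wa <- window_average_t(str, lab)
  f <- match(round(lab$times, 6), round(str$times, 6))
  expect_equal(wa$mean_t[, 1], rowMeans(str$t[, f[1:8]]), tolerance = 1e-12)
  expect_equal(wa$mean_t[, 2], rowMeans(str$t[, f[9:16]]), tolerance = 1e-12)
  # a labeling with one map over all frames equals the frame mean
  lab1 <- structure(list(labels = rep(1L, 16), times = lab$times,
                         window = c(2, 18), K = 1L, frame_ms = 1),
                    class = "ssep_labeling")
  expect_equal(window_average_t(str, lab1)$mean_t[, 1],
               rowMeans(str$t[, f]), tolerance = 1e-12)
  # an all-nonsignificant map yields an empty masked output
  stns <- str
  stns$mask[] <- FALSE
  expect_true(all(is.na(window_average_t(stns, lab)$masked_t)))
})

test_that("a strongly planted source produces a significant cluster at the true location", {
  h <- fx_head(); m <- fx_montage()
  sp <- build_source_space(h, 80)
  op <- loreta_operator(compute_leadfield(h, m, sp))
  set.seed(111)
  truth <- c(6, -6, 8)
  v <- forward_topography(h, m, truth, c(0, 1, 1))
  v <- v / max(abs(v))
  nt <- 60
  times <- epoch_times(c(-30, 30), 1000)
  post_on <- times >= 5 & times < 25
  dat <- array(0, dim = c(30, 33, nt))
  for (i in 1:30) {
    n <- matrix(rnorm(33 * nt, 0, 0.2), 33, nt)
    n <- sweep(n, 2, colMeans(n))
    dat[i, , ] <- outer(v, as.numeric(post_on) * 5) + n
  }
  ep <- new_epochset(dat, c(-30, 30), 1000, m, reference_mode = "average")
  st <- cd_stats(estimate_cd(op, ep, "fixed", 5),
                 baseline = c(-30, 0), post = c(0, 30))
  on_cols <- which(st$times >= 5 & st$times < 25)
  peak <- which.max(rowMeans(st$t[, on_cols]))
  expect_lt(sqrt(sum((sp$points[peak, ] - truth)^2)), 2 * sp$spacing)
  expect_true(all(st$mask[peak, on_cols]))
})
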