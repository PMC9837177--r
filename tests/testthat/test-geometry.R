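test_that("axis angles are folded to [0, 90] with the expected values", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(axis_angle(e1, e1), 0)
  expect_equal(axis_angle(e1, e2), 90)
  expect_equal(axis_angle(e1, (e1 + e2) / sqrt(2)), 45, tolerance = 1e-10)
  expect_equal(axis_angle(e1, -e1), 0)        # directionless
  expect_error(axis_angle(e1, c(0, 0, 0)), "zero")
  M <- axis_angle_matrix(list(a = e1, b = e2, c = (e1 + e2) / sqrt(2)))
  expect_equal(unclass(M), t(unclass(M)))
  expect_equal(diag(unclass(M)), c(a = 0, b = 0, c = 0))
  expect_true(all(M >= 0 & M <= 90))
})

test_that("surrogate null widens at low dimension and concentrates at high", {
  with_seed(31, {
    lo_dim <- surrogate_angle_null(unitize(stats::rnorm(2)),
                                   n_surrogates = 1000L, seed = 1L)
    expect_gt(lo_dim$hi - lo_dim$lo, 30)
    hi_dim <- surrogate_angle_null(unitize(stats::rnorm(200)),
                                   n_surrogates = 1000L, seed = 1L)
    expect_lt(hi_dim$hi - hi_dim$lo, 15)
    expect_gt(mean(hi_dim$angles, na.rm = TRUE), 75)
    # interval width shrinks with dimension for iid zero-mean axes
    widths <- vapply(c(5, 20, 80), function(K) {
      s <- surrogate_angle_null(unitize(stats::rnorm(K)),
                                n_surrogates = 800L, seed = 2L)
      s$hi - s$lo
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  })
})

test_that("angles of independent planted axes fall in the null band;
           correlated axes fall below it", {
  with_seed(32, {
    K <- 60L
    a <- unitize(stats::rnorm(K))
    b <- unitize(stats::rnorm(K))              # independent of a
    c_corr <- unitize(0.9 * a + 0.45 * unitize(stats::rnorm(K)))
    null <- surrogate_angle_null(a, n_surrogates = 2000L, seed = 3L)
    ang_ab <- axis_angle(a, b)
    expect_gt(ang_ab, null$lo)
    expect_lt(axis_angle(a, c_corr), null$lo)
  })
})

test_that("hierarchical clustering groups nearby axes first", {
  e <- diag(6)
  pre <- unitize(e[, 1] + 0.1 * e[, 2])
  post <- unitize(e[, 1] + 0.12 * e[, 3])     # close to pre
  move <- e[, 4]; stim <- e[, 5]
  M <- axis_angle_matrix(list(choice_pre = pre, choice_post = post,
                              move = move, stim = stim))
  hc <- cluster_axes(M)
  merged_first <- hc$merge[1, ]
  expect_setequal(abs(merged_first), c(1, 2))  # pre/post cluster together
  # identical axes merge at height 0
  M2 <- axis_angle_matrix(list(a = pre, b = pre, c = move))
  hc2 <- cluster_axes(M2)
  expect_equal(hc2$height[1], 0, tolerance = 1e-10)
  # permuting the inputs permutes leaves but not the merge structure
  M3 <- axis_angle_matrix(list(stim = stim, move = move,
                               choice_post = post, choice_pre = pre))
  hc3 <- cluster_axes(M3)
  expect_equal(sort(hc3$height), sort(hc$height), tolerance = 1e-10)
  expect_setequal(hc3$labels, hc$labels)
})

test_that("SDI follows its defining formula and invariances", {
  expect_equal(sdi(1.2, c(1.2, 0, 0)), 0)
  expect_equal(sdi(1.3, c(1, 0.4, 0.2)), 30, tolerance = 1e-10)
  expect_equal(sdi(2.6, 2 * c(1, 0.4, 0.2)), 30, tolerance = 1e-10)
  expect_error(sdi(1, c(0, 0)), "nonpositive")
})

test_that("SDI grows as the same signal energy spreads over more areas", {
  # fixed total separation ||u|| spread over 1, 3, or 10 areas
  K <- 20L; area <- rep(1:10, each = 2L)
  at <- small_atlas()
  sdis <- vapply(c(1L, 3L, 10L), function(n_areas) {
    u <- numeric(K)
    on <- which(area <= n_areas)
    u[on] <- 1 / sqrt(length(on))
    gp <- gaussian_pair(K = K, delta = 1.5, n_per_group = 700L,
                        seed = 33L + n_areas, u = u)
    dec <- structure(list(temporal = gp$carray, component_area = area,
                          atlas = at, spatial = NULL),
                     class = "decomposition")
    glob <- mean(dprime_curve(gp$carray, gp$pair, seed = 34L)$dprime)
    area_dp <- vapply(1:10, function(a)
      mean(area_axis(dec, gp$pair, a, seed = 34L)$curve$dprime), numeric(1))
    sdi(glob, area_dp)
  }, numeric(1))
  expect_lt(abs(sdis[1]), 12)                 # single area: ~0% up to CV noise
  expect_true(all(diff(sdis) > 0))            # monotone with spreading
})

test_that("piecewise fit recovers exact two-line data and flags flat curves", {
  tt <- seq(-1, 0.4, by = 1 / 30)
  knot <- -0.06
  y <- ifelse(tt < knot, 0.5 + 0.2 * (tt - knot), 0.5 + 2.5 * (tt - knot))
  fit <- piecewise_fit(list(times = tt, dprime = y), upper = 0.4)
  expect_equal(fit$knot_time, knot, tolerance = 1e-3)
  expect_equal(fit$pre_slope, 0.2, tolerance = 1e-3)
  expect_equal(fit$post_slope, 2.5, tolerance = 1e-3)
  expect_false(fit$degenerate)
  # the 95%-of-peak rule truncates the window after the rise
  fit2 <- piecewise_fit(list(times = tt, dprime = y))
  expect_lt(fit2$fit_window[2], 0.41)
  expect_equal(fit2$knot_time, knot, tolerance = 0.02)
  # flat curve: slopes ~0 and degenerate flag
  with_seed(35, {
    flat <- piecewise_fit(list(times = tt,
                               dprime = rep(0.3, length(tt)) +
                                 stats::rnorm(length(tt), sd = 1e-4)),
                          upper = 0.4)
    expect_lt(abs(flat$pre_slope), 0.01)
    expect_lt(abs(flat$post_slope), 0.01)
    expect_true(flat$degenerate)
  })
})

test_that("knot recovery on noisy ramps is within 0.05 s", {
  tt <- seq(-1, 0.4, by = 1 / 30)
  knot <- -0.05
  truth <- ifelse(tt < knot, 0.4 + 0.2 * (tt - knot),
                  0.4 + 2.0 * (tt - knot))
  errs <- vapply(1:20, function(s) {
    y <- truth + with_seed(100 + s, stats::rnorm(length(tt), sd = 0.05))
    piecewise_fit(list(times = tt, dprime = y), upper = 0.4)$knot_time - knot
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("a strong single-pixel signal appears in the pixel-wise map", {
  at <- small_atlas()
  spec <- planted_signal_spec(bg_sd = 0, global_amplitude = 0)
  for (v in c("stimulus", "wheel", "saccade", "attention", "choice"))
    spec[[v]]$amplitude <- 0
  sim <- simulate_session(at, spec, n_trials = 160L, seed = 36L)
  s <- sim$session
  # plant delta = 1 on one pixel for right vs left choices, post-movement
  tr <- sim$trials
  moved <- !is.na(tr$first_move_time)
  sgn <- ifelse(tr$choice == "right", 1, ifelse(tr$choice == "left", -1, 0))
  px <- 123L
  for (i in which(moved)) {
    f <- 31L + round(tr$first_move_time[i] * 30)
    idx <- f:min(90L, f + 12L)
    s$data[i, px, idx] <- s$data[i, px, idx] + sgn[i] * spec$noise_sd / 2
  }
  pair <- build_group_pair(tr, "choice", 30, 1, 90, seed = 37L)
  pm <- pixelwise_dprime(s, pair)
  post <- pm$times >= 0.1
  planted_dp <- mean(pm$dprime[px, post])
  expect_equal(planted_dp, 1, tolerance = 0.35)  # separation/sd = 1
  expect_lt(max(abs(pm$dprime[-px, ])), planted_dp + 0.5)
  # permuted labels: near-zero map
  null_pair <- pair
  half <- seq_len(pair$n_per_group %/% 2L)
  null_pair$trials_A <- c(pair$trials_A[half],
                          pair$trials_B[-half])[seq_len(pair$n_per_group)]
  null_pair$trials_B <- c(pair$trials_B[half],
                          pair$trials_A[-half])[seq_len(pair$n_per_group)]
  null_pair$align_A <- c(pair$align_A[half],
                         pair$align_B[-half])[seq_len(pair$n_per_group)]
  null_pair$align_B <- c(pair$align_B[half],
                         pair$align_A[-half])[seq_len(pair$n_per_group)]
  pm0 <- pixelwise_dprime(s, null_pair)
  expect_lt(mean(abs(pm0$dprime[px, post])), 0.5)
})

test_that("five-group d' coordinates localize a planted ventral signal", {
  K <- 20L; area <- rep(1:10, each = 2L)
  u <- numeric(K); u[area == 9L] <- c(0.8, 0.6)   # area "L" = ventral
  gp <- gaussian_pair(K = K, delta = 1.4, n_per_group = 500L, seed = 51L,
                      u = u)
  dec <- structure(list(temporal = gp$carray, component_area = area,
                        atlas = small_atlas(), spatial = NULL),
                   class = "decomposition")
  dp5 <- group_dprime_5d(dec, gp$pair, seed = 52L)
  expect_named(dp5, c("dorsal", "ventral", "parietal", "somatosensory",
                      "retrosplenial"))
  expect_equal(unname(which.max(dp5)), 2L)       # ventral dominates
  expect_gt(dp5["ventral"], 2 * max(dp5[-2]))
  # a uniformly planted signal gives near-equal coordinates
  u2 <- rep(1 / sqrt(K), K)
  gp2 <- gaussian_pair(K = K, delta = 1.4, n_per_group = 500L, seed = 53L,
                       u = u2)
  dec$temporal <- gp2$carray
  dp5u <- group_dprime_5d(dec, gp2$pair, seed = 54L)
  expect_lt(max(dp5u) / min(dp5u), 2.5)
  glob <- max(abs(dprime_curve(gp2$carray, gp2$pair, seed = 54L)$dprime))
  expect_true(all(dp5u <= glob + 0.25))
})
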