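# hand-built trial table with known rule-qualifying sets
rule_table <- function() {
  tr <- data.frame(
    trial = 1:12,
    theta = c(90, -90, 15, -15, 0, 30, 45, -45, 60, -60, 75, -75),
    left_angle = c(50, -50, 10, -10, 50, -50, 10, -10, 50, -50, 10, -10),
    choice = c("left", "right", "left", "right", "timeout", "left",
               "right", "left", "right", "left", "right", "left"),
    first_move_time = c(0.8, 0.3, 0.9, 1.1, NA, 0.7, 0.6, 1.2, 0.55,
                        0.85, 0.95, 1.0),
    pupil_change = c(2, 1.5, 1, 0.5, 0.2, 0, -0.2, -0.5, -1, -1.5, -2, 0.8),
    attention = c("high", "high", "high", "high", "mid", "mid", "mid",
                  "mid", "low", "low", "low", "high"),
    stringsAsFactors = FALSE)
  tr$difficulty <- abs(tr$theta)
  tr$correct <- TRUE
  tr$first_move_dir <- ifelse(is.na(tr$first_move_time), NA,
                              ifelse(tr$choice == "left", "ccw", "cw"))
  # trial 3 has a saccade 0.2 s before its movement; trial 6 saccades late
  tr$saccades <- list(numeric(0), numeric(0), 0.7, numeric(0), numeric(0),
                      6, numeric(0), numeric(0), numeric(0), numeric(0),
                      numeric(0), numeric(0))
  tr
}

test_that("group rules match a brute-force evaluation of the stated criteria", {
  tr <- rule_table()
  fs <- 30; n_frames <- 300                   # long tensor: no window drops
  # choice: movement >= 0.5 s after onset, no saccade in the prior 0.5 s
  # trial 2 moves at 0.3 s (excluded), trial 3 has a saccade at mt-0.2
  # (excluded), trial 5 timed out
  p <- build_group_pair(tr, "choice", fs, 1, n_frames, seed = 1)
  qualifying <- c(1, 4, 6, 7, 8, 9, 10, 11, 12)
  expect_true(all(c(p$trials_A, p$trials_B) %in% qualifying))
  expect_true(all(tr$choice[p$trials_A] == "right"))
  expect_true(all(tr$choice[p$trials_B] == "left"))
  expect_equal(length(p$trials_A), length(p$trials_B))
  # wheel group A: same movement rule; group B: no movement in the horizon
  p <- build_group_pair(tr, "wheel", fs, 1, n_frames, seed = 1)
  expect_setequal(union(p$trials_A, qualifying), qualifying)
  expect_true(all(p$trials_B %in% 5))
  # alignment of group A is the movement frame
  i <- match(p$trials_A, tr$trial)
  expect_equal(p$align_A,
               31L + as.integer(round(tr$first_move_time[i] * fs)))
  # attention tertiles are balanced by definition
  p <- build_group_pair(tr, "attention", fs, 1, n_frames, seed = 1)
  expect_true(all(tr$attention[p$trials_A] == "high"))
  expect_true(all(tr$attention[p$trials_B] == "low"))
  expect_equal(length(p$trials_A), length(p$trials_B))
})

test_that("attention split of a generated session is balanced tertiles", {
  sim <- shared_sim()
  p <- build_group_pair(sim$trials, "attention", 30, 1, 90, seed = 2)
  n_third <- sum(sim$trials$attention == "high")
  expect_equal(length(p$trials_A), min(n_third,
                                       sum(sim$trials$attention == "low")))
  expect_equal(length(p$trials_A), length(p$trials_B))
})

test_that("empty groups raise an informative error", {
  tr <- rule_table()
  tr$choice <- "left"                          # no right choices at all
  expect_error(build_group_pair(tr, "choice", 30, 1, 300, seed = 1),
               "empty")
})

test_that("state axis recovers a planted separation direction", {
  gp <- gaussian_pair(K = 8L, delta = 1.5, n_per_group = 500L, seed = 3L,
                      u = c(1, rep(0, 7)))
  ax <- state_axis(gp$carray, gp$pair, window = TRUE)
  expect_equal(sqrt(sum(ax$weights^2)), 1, tolerance = 1e-10)
  expect_gt(abs(ax$weights[1]), 0.99)
  # per-time axes have unit columns
  axt <- state_axis(gp$carray, gp$pair)
  expect_equal(colSums(axt$weights^2), rep(1, 6), tolerance = 1e-10)
  # identical groups have no axis
  carray0 <- gp$carray
  carray0[, , gp$pair$trials_B] <- carray0[, , gp$pair$trials_A]
  expect_error(suppressWarnings(state_axis(carray0, gp$pair, window = TRUE)))
})

test_that("projection is the plain dot product, linear, un-centered", {
  gp <- gaussian_pair(K = 5L, n_per_group = 20L, seed = 4L)
  e1 <- c(1, 0, 0, 0, 0)
  P <- project_axis(e1, gp$carray, 1:10, rep(0L, 10), 1:6)
  expect_equal(P, gp$carray[1, 1:6, 1:10])
  expect_equal(project_axis(3 * e1, gp$carray, 1:10, rep(0L, 10), 1:6),
               3 * P)
  # matches a brute-force loop over components
  w <- unitize(c(0.3, -1, 2, 0.5, -0.2))
  P2 <- project_axis(w, gp$carray, 4:9, rep(0L, 6), 2:5)
  brute <- matrix(0, 4, 6)
  for (j in seq_along(4:9)) for (tt in seq_along(2:5))
    brute[tt, j] <- sum(w * gp$carray[, (2:5)[tt], (4:9)[j]])
  expect_equal(P2, brute)
})

test_that("held-out d' matches the planted Gaussian separation", {
  gp <- gaussian_pair(K = 10L, delta = 1, n_per_group = 1000L, seed = 5L)
  cur <- dprime_curve(gp$carray, gp$pair, seed = 6L)
  expect_equal(mean(cur$dprime), 1, tolerance = 0.15)
  expect_equal(ncol(cur$per_fold), 5L)
  # d' is invariant to a global rescaling of all components
  cur2 <- dprime_curve(gp$carray * 7, gp$pair, seed = 6L)
  expect_equal(cur2$dprime, cur$dprime, tolerance = 1e-10)
  # shuffled labels: null-level d'
  n <- gp$pair$n_per_group
  null_pair <- manual_pair(seq(1, 2 * n, by = 2), seq(2, 2 * n, by = 2),
                           gp$pair$win_frames, seed = 7L)
  cur0 <- dprime_curve(gp$carray, null_pair, seed = 8L)
  expect_lt(max(abs(cur0$dprime)), 0.25)
})

test_that("d' is antisymmetric under group swap for a fixed axis, and the
           reported cross-validated curve is swap-invariant", {
  gp <- gaussian_pair(K = 6L, delta = 1.2, n_per_group = 400L, seed = 9L)
  ax <- state_axis(gp$carray, gp$pair, window = TRUE)
  PA <- project_axis(ax, gp$carray, gp$pair$trials_A, gp$pair$align_A,
                     gp$pair$win_frames)
  PB <- project_axis(ax, gp$carray, gp$pair$trials_B, gp$pair$align_B,
                     gp$pair$win_frames)
  expect_equal(mesochoice:::.dprime_of_proj(PB, PA),
               -mesochoice:::.dprime_of_proj(PA, PB), tolerance = 1e-12)
  # when the axis is re-derived from the swapped groups it flips too, so
  # the cross-validated curve is unchanged up to fold assignment noise
  swapped <- gp$pair
  swapped$trials_A <- gp$pair$trials_B
  swapped$trials_B <- gp$pair$trials_A
  c1 <- dprime_curve(gp$carray, gp$pair, seed = 10L)
  c2 <- dprime_curve(gp$carray, swapped, seed = 10L)
  expect_equal(c2$dprime, c1$dprime, tolerance = 0.15)
})

test_that("axis stability flags a planted rotation and is symmetric", {
  K <- 12L; nt <- 24L
  W <- matrix(0, K, nt)
  W[1, 1:11] <- 1; W[2, 12:nt] <- 1          # 90 degree rotation at t0
  R <- axis_stability(W, smoothing = 3L)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, nt))
  expect_gt(min(R[3:10, 3:10]), 0.99)
  expect_gt(min(R[15:24, 15:24]), 0.99)
  expect_lt(max(R[3:10, 15:24]), 0.01)
  # constant axis: all entries 1
  Wc <- matrix(rep(unitize(stats::rnorm(K)), nt), K, nt)
  expect_equal(min(axis_stability(Wc)), 1, tolerance = 1e-10)
  # the largest stability cluster is found on either side
  st <- stable_time(R, seq_len(nt))
  expect_true(st$index >= 12)
})

test_that("area-restricted axes localize a planted single-area signal", {
  # fake decomposition in component space: 20 components over 10 areas,
  # signal planted only on the components of area 9 ("L")
  K <- 20L
  area <- rep(1:10, each = 2L)
  u <- numeric(K); u[area == 9L][1:2] <- c(0.8, 0.6)
  gp <- gaussian_pair(K = K, delta = 1.2, n_per_group = 600L, seed = 12L,
                      u = u)
  dec <- structure(list(temporal = gp$carray, component_area = area,
                        atlas = small_atlas(), spatial = NULL),
                   class = "decomposition")
  aL <- area_axis(dec, gp$pair, "L", seed = 13L)
  expect_length(aL$components, 2L)
  glob <- dprime_curve(gp$carray, gp$pair, seed = 13L)
  expect_equal(mean(aL$curve$dprime), mean(glob$dprime), tolerance = 0.15)
  aV <- area_axis(dec, gp$pair, "V1", seed = 13L)
  expect_lt(max(abs(aV$curve$dprime)), 0.3)
  # union of all areas reproduces the global analysis
  all_areas <- area_axis(dec, gp$pair, 1:10, seed = 13L)
  expect_equal(all_areas$curve$dprime, glob$dprime, tolerance = 1e-10)
  # area d' cannot exceed the global d' beyond CV noise
  expect_lt(mean(aL$curve$dprime), mean(glob$dprime) + 0.2)
})

test_that("orthogonalization behaves at its limits and preserves signal", {
  gp <- gaussian_pair(K = 10L, delta = 1.2, n_per_group = 500L, seed = 14L)
  # a nuisance basis spanning the whole component space swallows any axis
  expect_error(orthogonalized_dprime(gp$carray, gp$pair, diag(10L),
                                     seed = 15L),
               "nuisance span")
  # a nuisance orthogonal to the signal leaves d' unchanged
  nuis <- unitize(stats::rnorm(10) -
                    sum(stats::rnorm(10) * gp$u) * gp$u)
  nuis <- unitize(nuis - sum(nuis * gp$u) * gp$u)
  c_orth <- orthogonalized_dprime(gp$carray, gp$pair, nuis, seed = 15L)
  c_ref <- dprime_curve(gp$carray, gp$pair, seed = 15L)
  expect_equal(mean(c_orth$dprime), mean(c_ref$dprime), tolerance = 0.1)
})

test_that("two correlated planted signals survive mutual orthogonalization", {
  # two independent directions whose trial occurrences are correlated
  K <- 12L
  with_seed(16, {
    u1 <- unitize(stats::rnorm(K))
    u2 <- unitize(stats::rnorm(K) - sum(stats::rnorm(K) * u1) * u1)
    u2 <- unitize(u2 - sum(u2 * u1) * u1)
    n <- 500L; nf <- 5L
    lab1 <- rep(c(1, -1), each = n)            # group structure for signal 1
    flip <- stats::runif(2 * n) < 0.25         # 75% co-occurrence
    lab2 <- ifelse(flip, -lab1, lab1)
    carray <- array(stats::rnorm(K * nf * 2 * n), dim = c(K, nf, 2 * n))
    for (i in seq_len(2 * n))
      carray[, , i] <- carray[, , i] +
        outer(u1 * 0.6 * lab1[i] + u2 * 0.6 * lab2[i], rep(1, nf))
    pair1 <- manual_pair(which(lab1 > 0), which(lab1 < 0), seq_len(nf),
                         seed = 17L)
    pair2 <- manual_pair(which(lab2 > 0), which(lab2 < 0), seq_len(nf),
                         seed = 17L)
    ax2 <- state_axis(carray, pair2, window = TRUE)
    d1 <- orthogonalized_dprime(carray, pair1, ax2$weights, seed = 18L)
    ax1 <- state_axis(carray, pair1, window = TRUE)
    d2 <- orthogonalized_dprime(carray, pair2, ax1$weights, seed = 18L)
    expect_gt(mean(d1$dprime), 0.5)
    expect_gt(mean(d2$dprime), 0.5)
  })
})

test_that("attention axes transfer across outcome subsets", {
  # the planted attention signal is outcome-independent, so an axis fit on
  # correct trials must discriminate attention states among error trials
  sim <- shared_sim()
  dec <- shared_decomp()
  tr <- sim$trials
  mk <- function(sel, seed) {
    A <- tr$trial[sel & tr$attention == "high"]
    B <- tr$trial[sel & tr$attention == "low"]
    manual_pair(A, B, win_frames = 32:75, seed = seed)
  }
  p_correct <- mk(tr$correct, 21L)
  p_error <- mk(!tr$correct & tr$choice != "timeout", 22L)
  ax <- suppressWarnings(state_axis(dec, p_correct, window = TRUE))
  PA <- project_axis(ax, dec, p_error$trials_A, p_error$align_A,
                     p_error$win_frames)
  PB <- project_axis(ax, dec, p_error$trials_B, p_error$align_B,
                     p_error$win_frames)
  transfer <- mean(mesochoice:::.dprime_of_proj(PA, PB))
  expect_gt(abs(transfer), 0.4)
})
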