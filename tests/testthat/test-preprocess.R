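make_raw <- function(vals, n_trials = 2L, npx = 5L, nt = 20L) {
  array(vals, dim = c(n_trials, npx, nt))
}

test_that("dF/F normalization uses the per-trial grand-average baseline", {
  raw <- make_raw(100)
  expect_true(all(compute_dff(raw) == 0))
  # I = 1.1 F0 against a known baseline mixture: two values averaging to F0
  raw <- array(rep(c(90, 110), each = 1), dim = c(1, 2, 50))
  out <- compute_dff(raw)
  expect_equal(mean(out), 0, tolerance = 1e-12)      # algebraic identity
  expect_equal(out[1, 2, 1], 0.1, tolerance = 1e-12) # (110-100)/100
  expect_error(compute_dff(make_raw(-1)), "positive")
})

test_that("band-pass is zero-phase, removes DC, and attenuates 20 Hz", {
  fs <- 50
  nt <- 500
  tt <- (1:nt) / fs
  # DC offset removed by the 0.1 Hz high-pass
  x <- matrix(3, nt, 1)
  y <- mesochoice:::.bandpass_fft(x, fs, 0.1, 8)
  expect_lt(max(abs(y)), 0.2)
  # 20 Hz tone attenuated by > 20 dB
  x <- matrix(sin(2 * pi * 20 * tt), nt, 1)
  y <- mesochoice:::.bandpass_fft(x, fs, 0.1, 8)
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(x^2)), 10^(-20 / 20))
  # an in-band impulse keeps its peak position (zero phase)
  x <- matrix(0, nt, 1); x[250, 1] <- 1
  y <- mesochoice:::.bandpass_fft(x, fs, 0.1, 8)
  expect_equal(which.max(abs(y)), 250)
  # a 2 Hz in-band tone passes nearly unchanged
  x <- matrix(sin(2 * pi * 2 * tt), nt, 1)
  y <- mesochoice:::.bandpass_fft(x, fs, 0.1, 8)
  expect_gt(stats::cor(x, y), 0.99)
})

test_that("spatially constant frames are unchanged by overlapping binning", {
  at <- small_atlas()
  sim <- simulate_session(at, n_trials = 3L, seed = 6L)
  s <- sim$session
  s$data[] <- 0
  s$data[2, , ] <- 1                       # constant frame in trial 2
  out <- bandpass_and_bin(s, low = 0, high = 14, bin_um = 130,
                          target_fps = s$frame_rate)
  expect_true(all(abs(out$data[2, , ] - 1) < 1e-9))
  expect_true(all(abs(out$data[1, , ]) < 1e-9))
  # bin-level atlas keeps all ten areas
  expect_true(all(1:10 %in% out$atlas$label_map))
  expect_error(bandpass_and_bin(s, high = 20), "Nyquist")
})

test_that("50 fps sessions are resampled to 30 fps", {
  at <- small_atlas()
  tp <- trial_params(frame_rate = 50)
  sim <- simulate_session(at, tparams = tp, n_trials = 2L, seed = 7L)
  out <- bandpass_and_bin(sim$session, target_fps = 30)
  expect_equal(out$frame_rate, 30)
  expect_equal(dim(out$data)[3], floor(dim(sim$session$data)[3] / 50 * 30),
               tolerance = 0.012)   # within one frame of the nominal count
})

test_that("wheel events need a zero-crossing followed by threshold crossing", {
  fs <- 100
  expect_equal(nrow(detect_wheel_movements(rep(0, 200), fs)$events), 0L)
  # crossing then peak +25: one clockwise event at the crossing
  v <- c(rep(-5, 50), seq(-5, 25, length.out = 30), rep(25, 20),
         rep(0, 10))
  ev <- detect_wheel_movements(v, fs, threshold = 20)$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "cw")
  expect_equal(ev$time_s, 55 / fs, tolerance = 2 / fs)
  # sub-threshold peak: no event
  v2 <- c(rep(-5, 50), seq(-5, 15, length.out = 30), rep(15, 20))
  expect_equal(nrow(detect_wheel_movements(v2, fs, 20)$events), 0L)
  # amplitude scaling above threshold does not change the event count
  ev2 <- detect_wheel_movements(v * 3, fs, threshold = 20)$events
  expect_equal(nrow(ev2), 1L)
})

test_that("saccade duration and magnitude filters are applied as stated", {
  fs <- 1000
  mk <- function(dur_ms, mag) {
    n <- 2000
    pos <- rep(0, n)
    ramp <- seq(0, mag, length.out = dur_ms)
    pos[500 + seq_along(ramp)] <- ramp
    pos[(500 + dur_ms + 1):n] <- mag
    pos + stats::rnorm(n, sd = 1e-4)
  }
  with_seed(1, {
    # 50 ms duration: discarded even though large
    expect_equal(nrow(detect_saccades(mk(50, 5), fs)$events), 0L)
    # 1.0 degree amplitude: discarded even though long
    expect_equal(nrow(detect_saccades(mk(100, 1.0), fs)$events), 0L)
    # 3 degrees, 100 ms: retained with correct time and magnitude
    ev <- detect_saccades(mk(100, 3), fs)$events
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$magnitude, 3, tolerance = 0.1)
    expect_equal(ev$time_s, 0.55, tolerance = 0.06)
  })
})

test_that("pupil metric is max(open loop) minus pre-onset baseline, z-scored", {
  fs <- 30; onset <- 31L
  n <- 31 + 45
  flat <- rep(1, n + 10)
  expect_equal(pupil_attention_metric(flat, fs, onset)$pa, 0)
  step <- c(rep(1, 30), rep(3, n - 20))
  expect_equal(pupil_attention_metric(step, fs, onset)$pa, 2)
  # Gaussian step sizes -> z-scores with mean 0, sd 1
  amps <- with_seed(4, stats::rnorm(50, 2, 0.5))
  traces <- t(vapply(amps, function(a) c(rep(1, 30), rep(1 + a, n - 30 + 10)),
                     numeric(n + 10)))
  out <- pupil_attention_metric(traces, fs, onset)
  expect_equal(out$pa, amps, tolerance = 1e-12)
  expect_equal(mean(out$pa_z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(out$pa_z), 1, tolerance = 1e-10)
  expect_error(pupil_attention_metric(flat, fs, 10L), "out of range")
})

test_that("hemodynamic correction removes a shared artifact, keeps signal", {
  fs <- 30; nt <- 600; npx <- 12
  tt <- (1:nt) / fs
  with_seed(8, {
    artifact <- sin(2 * pi * 1 * tt) + 0.3 * sin(2 * pi * 2.5 * tt + 1)
    gain <- stats::runif(npx, 0.5, 1.5)
    sig <- t(vapply(seq_len(npx), function(p)
      sin(2 * pi * 3 * tt + stats::runif(1, 0, 2 * pi)), numeric(nt)))
    blue <- 1000 * (1 + 0.05 * sig + 0.05 * outer(gain, artifact))
    violet <- 800 * (1 + 0.04 * outer(gain, artifact))
    out <- hemodynamic_correct(blue, violet, fs)
    core <- 50:(nt - 50)                       # avoid filter edges
    for (p in c(1, 7)) {
      expect_gt(stats::cor(out$corrected[p, core], sig[p, core]), 0.9)
      # artifact power reduced at least 10-fold vs uncorrected dF/F
      res_unc <- stats::lm(blue[p, core] / mean(blue[p, ]) ~ sig[p, core])
      res_cor <- stats::lm(out$corrected[p, core] ~ sig[p, core])
      expect_lt(stats::var(stats::resid(res_cor)),
                stats::var(stats::resid(res_unc)) / 10)
    }
  })
})

test_that("perfect regression and absent violet behave as limits", {
  fs <- 30; nt <- 400
  tt <- (1:nt) / fs
  v <- sin(2 * pi * 1 * tt)
  blue <- rbind(1000 * (1 + 0.1 * v), 500 * (1 + 0.06 * v))
  violet <- rbind(400 * (1 + 0.05 * v), 400 * (1 + 0.03 * v))
  out <- hemodynamic_correct(blue, violet, fs)
  core <- 40:(nt - 40)
  expect_lt(max(abs(out$corrected[, core])), 1e-3)
  # violet constant: regression skipped with warning, c = 0, and the
  # output is the (low-passed) detrended blue minus its mean
  w <- capture_warnings(
    out2 <- hemodynamic_correct(blue, matrix(500, 2, nt), fs))
  expect_match(w, "degenerate violet", all = TRUE)
  expect_equal(out2$fit$c, c(0, 0))
  expect_gt(stats::cor(out2$corrected[1, core], v[core]), 0.99)
})

test_that("event lists export to CSV with their attributes", {
  v <- c(rep(-5, 50), seq(-5, 30, length.out = 30), rep(30, 20))
  ev <- detect_wheel_movements(v, 100, threshold = 20)
  p <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, p)
  back <- utils::read.csv(p)
  expect_equal(back$kind, "wheel")
  expect_equal(back$time_s, ev$events$time_s)
  expect_equal(back$direction, ev$events$direction)
})
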