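#' Planted-signal specification for the session generator
#'
#' Describes, per task variable, where in the cortical sheet a signal lives
#' (carrier areas and the fraction of those areas' activity modes it
#' recruits), how strong it is, and its temporal profile relative to its
#' alignment event.
#'
#' The generator emulates the low-rank spatial structure of widefield
#' calcium data: each area carries a small number of smooth non-negative
#' activity modes with ongoing temporal fluctuations, and every planted
#' task signal is a weighted mixture of those modes. `amplitude` is the
#' projected dF/F amplitude along the signal's unit-norm spatial pattern
#' (so downstream discriminability scales directly with it). Defaults give
#' a strong stimulus response in V1, movement transients over
#' parietal/somatosensory areas, a weak sustained attention offset, and a
#' weak choice signal distributed across all ten areas with random-sign
#' loadings at roughly one fifth of the stimulus amplitude.
#'
#' @param stimulus,wheel,saccade,attention,choice per-variable lists with
#'   fields `carrier_areas` (area names), `spatial_sparsity` (fraction of
#'   carrier-area modes recruited, in (0, 1\]), `amplitude` (projected
#'   dF/F), `profile` (`"step"`, `"transient"`, `"ramp"`, `"constant"`),
#'   profile timing parameters (seconds, relative to the alignment event),
#'   `signed` (loadings drawn with random signs), and optionally
#'   `coef_range` (range of the uniform mode-loading magnitudes,
#'   default c(0.5, 1.5)).
#' @param n_modes_per_area smooth activity modes per area.
#' @param mode_shape `"gaussian"` (smooth bumps) or `"flat"` (uniform
#'   indicators of areas and contiguous sub-areas, giving homogeneous
#'   per-pixel amplitudes).
#' @param bg_sd SD of each mode's ongoing temporal fluctuation (dF/F).
#' @param noise_sd iid per-pixel, per-frame Gaussian noise SD (dF/F).
#' @param global_amplitude SD of a slow shared fluctuation added uniformly
#'   to all in-window pixels (dF/F); 0 disables.
#' @return object of class `planted_signal_spec`.
#' @export
planted_signal_spec <- function(
    stimulus = list(carrier_areas = "V1", spatial_sparsity = 1,
                    amplitude = 0.25, profile = "step",
                    onset = 0, duration = 1.5),
    wheel = list(carrier_areas = c("A", "RL", "AL", "SSt", "SSb"),
                 spatial_sparsity = 1, amplitude = 0.15,
                 profile = "transient", width = 0.3),
    saccade = list(carrier_areas = c("V1", "RL"), spatial_sparsity = 1,
                   amplitude = 0.06, profile = "transient", width = 0.2),
    attention = list(carrier_areas = c("V1", "PM", "AM", "A", "SSt", "RL",
                                       "SSb", "AL", "L", "RS"),
                     spatial_sparsity = 1, amplitude = 0.08,
                     profile = "ramp", ramp_start = 0, ramp_peak = 0.3),
    choice = list(carrier_areas = c("V1", "PM", "AM", "A", "SSt", "RL",
                                    "SSb", "AL", "L", "RS"),
                  spatial_sparsity = 0.6, amplitude = 0.05,
                  profile = "ramp", ramp_start = -0.5, ramp_peak = 0.3,
                  signed = TRUE),
    n_modes_per_area = 2L, mode_shape = c("gaussian", "flat"),
    bg_sd = 0.02, noise_sd = 0.02, global_amplitude = 0.002) {
  mode_shape <- match.arg(mode_shape)
  spec <- list(stimulus = stimulus, wheel = wheel, saccade = saccade,
               attention = attention, choice = choice,
               n_modes_per_area = as.integer(n_modes_per_area),
               mode_shape = mode_shape,
               bg_sd = bg_sd, noise_sd = noise_sd,
               global_amplitude = global_amplitude)
  for (v in c("stimulus", "wheel", "saccade", "attention", "choice")) {
    s <- spec[[v]]
    stopifnot(s$amplitude >= 0, s$spatial_sparsity > 0,
              s$spatial_sparsity <= 1)
  }
  stopifnot(spec$n_modes_per_area >= 1L, bg_sd >= 0, noise_sd >= 0)
  structure(spec, class = "planted_signal_spec")
}

#' Trial-timing parameters
#'
#' @param frame_rate imaging frame rate (Hz).
#' @param pre_stim pre-stimulus baseline duration (s).
#' @param open_loop open-loop interval after stimulus onset (s), during
#'   which wheel rotation does not move the stimulus.
#' @param closed_loop simulated closed-loop duration retained in the tensor
#'   (s); real closed-loop periods are longer but only their onset matters
#'   for the analyses here.
#' @param timeout_prob probability of a timeout (no-response) trial.
#' @param n_levels number of signed difficulty levels (odd).
#' @return list of timing parameters.
#' @export
trial_params <- function(frame_rate = 30, pre_stim = 1, open_loop = 1.5,
                         closed_loop = 0.5, timeout_prob = 0.05,
                         n_levels = 13L) {
  stopifnot(frame_rate > 0, pre_stim > 0, open_loop > 0, closed_loop >= 0)
  list(frame_rate = frame_rate, pre_stim = pre_stim, open_loop = open_loop,
       closed_loop = closed_loop, timeout_prob = timeout_prob,
       n_levels = as.integer(n_levels))
}

# temporal kernel on the trial's frame grid, aligned at `align_s` seconds
# from trial start; errors if the kernel extends beyond the trial
.kernel_trace <- function(profile, pars, align_s, t_grid, check = TRUE) {
  k <- numeric(length(t_grid))
  rel <- t_grid - align_s
  if (profile == "step") {
    a <- pars$onset %||% 0; b <- a + (pars$duration %||% 1)
    if (check && align_s + b > max(t_grid) + 1e-9)
      stop("kernel extends beyond trial length")
    k[rel >= a & rel < b] <- 1
  } else if (profile == "transient") {
    w <- pars$width %||% 0.3
    if (check && (align_s + w / 2 > max(t_grid) + 1e-9 ||
                  align_s - w / 2 < min(t_grid) - 1e-9))
      stop("kernel extends beyond trial length")
    sel <- abs(rel) <= w / 2
    k[sel] <- 0.5 * (1 + cos(pi * rel[sel] / (w / 2)))   # raised cosine
  } else if (profile == "ramp") {
    a <- pars$ramp_start %||% -0.5; b <- pars$ramp_peak %||% 0.3
    if (check && align_s + b > max(t_grid) + 1e-9)
      stop("kernel extends beyond trial length")
    rise <- rel >= a & rel < b
    k[rise] <- (rel[rise] - a) / (b - a)
    k[rel >= b] <- 1
  } else if (profile == "constant") {
    k[] <- 1
  } else stop("unknown temporal profile: ", profile)
  k
}

# non-negative spatial modes per area, unit L2 norm. "gaussian" modes are
# smooth bumps clipped to the area's own pixels; "flat" modes are uniform
# indicators of the area (mode 1) and of random contiguous halves of it
# (further modes), giving spatially homogeneous per-pixel amplitudes.
.make_modes <- function(atlas, inwin, n_modes, sample_fun,
                        shape = c("gaussian", "flat")) {
  shape <- match.arg(shape)
  nx <- nrow(atlas$label_map)
  lab_px <- atlas$label_map[inwin]
  px <- cbind((inwin - 1L) %% nx + 1L, (inwin - 1L) %/% nx + 1L)
  n_areas <- length(atlas$area_names)
  npx <- length(inwin)
  modes <- NULL; mode_area <- integer(0)
  for (a in seq_len(n_areas)) {
    own <- which(lab_px == a)
    apx <- px[own, , drop = FALSE]
    r_eq <- sqrt(length(own) / pi)
    for (m in seq_len(n_modes)) {
      v <- numeric(npx)
      if (shape == "gaussian") {
        if (m == 1L) { ctr <- colMeans(apx); w <- 0.6 * r_eq }
        else { ctr <- apx[sample_fun(length(own), 1L), ]; w <- 0.35 * r_eq }
        d2 <- (apx[, 1] - ctr[1])^2 + (apx[, 2] - ctr[2])^2
        v[own] <- exp(-d2 / (2 * w^2))
      } else {
        if (m == 1L) v[own] <- 1
        else {
          ctr <- apx[sample_fun(length(own), 1L), ]
          d2 <- (apx[, 1] - ctr[1])^2 + (apx[, 2] - ctr[2])^2
          half <- own[order(d2)[seq_len(max(2L, length(own) %/% 2L))]]
          v[half] <- 1
        }
      }
      modes <- cbind(modes, v / l2(v))
      mode_area <- c(mode_area, a)
    }
  }
  list(modes = modes, mode_area = mode_area)
}

#' Simulate a synthetic imaging session
#'
#' Generates a per-trial dF/F tensor over the atlas's in-window pixels plus
#' a matching trial table. Ongoing activity is a sum of per-area smooth
#' spatial modes with slow temporal fluctuations; each planted task
#' variable adds (unit spatial pattern in the mode span) x (temporal
#' kernel) x (per-trial condition factor): the choice signal's sign follows
#' the trial's left/right choice, the attention offset scales with the
#' trial's latent pupil state, and movement/saccade transients are locked
#' to the behavioral event times written to the trial table. iid Gaussian
#' pixel noise and an optional slow shared fluctuation are added. Fully
#' reproducible from `seed`.
#'
#' @param atlas an [make_area_atlas()] atlas.
#' @param spec a [planted_signal_spec()].
#' @param tparams a [trial_params()] list.
#' @param n_trials number of trials (>= 2).
#' @param psych a [psychometric_params()] used to draw choices.
#' @param seed integer seed.
#' @return list with `session` (class `session_tensor`: `data` array
#'   trial x pixel x frame over in-window pixels, timing fields, `atlas`,
#'   `pixel_index`, and `planted` ground truth: modes, unit patterns,
#'   per-trial temporal factors) and `trials` (the trial table data.frame;
#'   `saccades` is a list column of event times in seconds relative to
#'   stimulus onset).
#' @export
simulate_session <- function(atlas, spec = planted_signal_spec(),
                             tparams = trial_params(), n_trials = 200L,
                             psych = psychometric_params(), seed = 1L) {
  stopifnot(inherits(atlas, "area_atlas"), n_trials >= 2L)
  fs <- tparams$frame_rate
  t_total <- tparams$pre_stim + tparams$open_loop + tparams$closed_loop
  n_t <- round(t_total * fs)
  t_grid <- (seq_len(n_t) - 0.5) / fs        # frame centers, s from trial start
  onset_s <- tparams$pre_stim
  inwin <- which(atlas$label_map > 0L)
  npx <- length(inwin)

  with_seed(seed, {
    ## ---- behavior ----
    levels <- difficulty_grid(tparams$n_levels)
    theta <- sample(levels, n_trials, replace = TRUE)
    pupil_latent <- stats::rnorm(n_trials)
    qs <- stats::quantile(pupil_latent, c(1 / 3, 2 / 3))
    attention <- ifelse(pupil_latent >= qs[2], "high",
                        ifelse(pupil_latent <= qs[1], "low", "mid"))
    alpha <- c(high = psych$slope_high, low = psych$slope_low,
               mid = mean(c(psych$slope_high, psych$slope_low)))[attention]
    p_left <- stats::plogis(alpha * theta) * (1 - psych$lapse) +
      psych$lapse / 2
    timeout <- stats::runif(n_trials) < tparams$timeout_prob
    left <- stats::runif(n_trials) < p_left
    choice <- ifelse(timeout, "timeout", ifelse(left, "left", "right"))
    rewarded_left <- ifelse(theta > 0, TRUE,
                            ifelse(theta < 0, FALSE,
                                   stats::runif(n_trials) < 0.5))
    correct <- !timeout & (left == rewarded_left)
    # movement latencies: lognormal, clipped inside the trial
    mt_max <- tparams$open_loop + tparams$closed_loop - 0.35
    first_move_time <- pmin(pmax(
      stats::rlnorm(n_trials, meanlog = log(0.8), sdlog = 0.35), 0.15),
      mt_max)
    first_move_time[timeout] <- NA_real_
    first_move_dir <- ifelse(timeout, NA_character_,
                             ifelse(left, "ccw", "cw"))
    sacc_w <- (spec$saccade$width %||% 0.2) / 2
    saccades <- lapply(seq_len(n_trials), function(i) {
      k <- stats::rpois(1L, 0.3)
      if (k == 0L) return(numeric(0))
      sort(stats::runif(k, -tparams$pre_stim + sacc_w,
                        tparams$open_loop + tparams$closed_loop - sacc_w))
    })
    left_angle <- theta / 2 + sample(c(-45, 45), n_trials, replace = TRUE)
    right_angle <- left_angle - theta

    trials <- data.frame(
      trial = seq_len(n_trials), theta = theta, difficulty = abs(theta),
      left_angle = left_angle, right_angle = right_angle,
      choice = choice, correct = correct,
      first_move_time = first_move_time, first_move_dir = first_move_dir,
      pupil_change = as.numeric(scale(pupil_latent)),
      attention = attention, stringsAsFactors = FALSE)
    trials$saccades <- saccades

    ## ---- spatial structure ----
    md <- .make_modes(atlas, inwin, spec$n_modes_per_area,
                      function(n, k) sample.int(n, k),
                      shape = spec$mode_shape %||% "gaussian")
    modes <- md$modes; mode_area <- md$mode_area
    n_modes <- ncol(modes)

    # unit spatial pattern for each variable: random mixture of the
    # recruited carrier-area modes
    draw_pattern <- function(s) {
      ids <- match(s$carrier_areas, atlas$area_names)
      if (anyNA(ids)) stop("unknown carrier area")
      cand <- which(mode_area %in% ids)
      n_on <- max(1L, round(s$spatial_sparsity * length(cand)))
      on <- if (n_on < length(cand)) sort(sample(cand, n_on)) else cand
      cr <- s$coef_range %||% c(0.5, 1.5)
      coef <- stats::runif(length(on), cr[1], cr[2])
      if (isTRUE(s$signed)) coef <- coef * sample(c(-1, 1), length(on),
                                                  replace = TRUE)
      w <- as.numeric(modes[, on, drop = FALSE] %*% coef)
      unitize(w)
    }
    vars <- c("stimulus", "wheel", "saccade", "attention", "choice")
    patterns <- lapply(spec[vars], draw_pattern)

    ## ---- per-trial temporal factors (frames x trials) ----
    tf <- list()
    tf$stimulus <- if (spec$stimulus$amplitude > 0) matrix(
      .kernel_trace("step", spec$stimulus, onset_s, t_grid), n_t, n_trials)
    else matrix(0, n_t, n_trials)
    # sustained attention: the trial's latent pupil state scales a kernel
    # locked to stimulus onset (absent during the pre-stimulus baseline,
    # like the stimulus-evoked pupil change it emulates)
    tf$attention <- outer(
      .kernel_trace(spec$attention$profile, spec$attention, onset_s, t_grid),
      pupil_latent)
    tf$wheel <- matrix(0, n_t, n_trials)
    tf$choice <- matrix(0, n_t, n_trials)
    tf$saccade <- matrix(0, n_t, n_trials)
    for (i in seq_len(n_trials)) {
      if (!is.na(first_move_time[i])) {
        mt <- onset_s + first_move_time[i]
        tf$wheel[, i] <- .kernel_trace("transient", spec$wheel, mt, t_grid,
                                       check = FALSE)
        sgn <- if (left[i]) -1 else 1
        tf$choice[, i] <- sgn *
          .kernel_trace("ramp", spec$choice, mt, t_grid, check = FALSE)
      }
      for (st in saccades[[i]])
        tf$saccade[, i] <- tf$saccade[, i] +
          .kernel_trace("transient", spec$saccade, onset_s + st, t_grid,
                        check = FALSE)
    }

    ## ---- assemble tensor ----
    smooth_traces <- function(n_col) {
      g <- matrix(stats::rnorm(n_t * n_col), n_t, n_col)
      ker <- stats::dnorm(seq(-2.5, 2.5, length.out = max(3L, round(fs / 3))))
      ker <- ker / sum(ker)
      g <- apply(g, 2L, function(x) {
        y <- stats::filter(x, ker, sides = 2L)
        y[is.na(y)] <- 0
        y
      })
      g / max(stats::sd(g), 1e-12)
    }
    dat <- array(stats::rnorm(n_trials * npx * n_t, sd = spec$noise_sd),
                 dim = c(n_trials, npx, n_t))
    for (i in seq_len(n_trials)) {
      tr <- matrix(0, npx, n_t)
      if (spec$bg_sd > 0)                       # ongoing mode fluctuations
        tr <- tr + modes %*% t(smooth_traces(n_modes)) * spec$bg_sd
      if (spec$global_amplitude > 0)            # shared slow fluctuation
        tr <- tr + rep(smooth_traces(1L) * spec$global_amplitude,
                       each = npx)
      for (v in vars) {
        f <- tf[[v]][, i]
        if (spec[[v]]$amplitude > 0 && any(f != 0))
          tr <- tr + outer(patterns[[v]] * spec[[v]]$amplitude, f)
      }
      dat[i, , ] <- dat[i, , ] + tr
    }

    session <- structure(
      list(data = dat, frame_rate = fs, pre_stim = tparams$pre_stim,
           open_loop = tparams$open_loop, closed_loop = tparams$closed_loop,
           atlas = atlas, pixel_index = inwin,
           planted = list(modes = modes, mode_area = mode_area,
                          patterns = patterns, temporal = tf,
                          spec = spec, seed = seed)),
      class = "session_tensor")
    list(session = session, trials = trials)
  })
}

#' @export
print.session_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "session_tensor: %d trials x %d pixels x %d frames @ %g Hz (pre %gs, OL %gs)\n",
    d[1], d[2], d[3], x$frame_rate, x$pre_stim, x$open_loop))
  invisible(x)
}

#' Frame index of stimulus onset within a trial
#' @param session a `session_tensor`.
#' @return integer frame index (first frame at/after onset).
#' @export
stim_onset_frame <- function(session) {
  as.integer(round(session$pre_stim * session$frame_rate)) + 1L
}
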