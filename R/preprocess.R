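#' Normalize raw fluorescence to dF/F
#'
#' For every trial the scalar baseline F0 is the grand mean of the trial's
#' raw tensor over pixels and frames; the output is (I - F0) / F0. By
#' construction the grand mean of each trial's dF/F is then exactly zero.
#'
#' @param raw array trial x pixel x frame of raw fluorescence (> 0), or a
#'   `session_tensor` whose `data` holds raw fluorescence.
#' @return object of the same shape with normalized values.
#' @export
compute_dff <- function(raw) {
  if (inherits(raw, "session_tensor")) {
    raw$data <- compute_dff(raw$data)
    return(raw)
  }
  stopifnot(is.array(raw), length(dim(raw)) == 3L)
  if (any(raw <= 0)) stop("raw fluorescence must be positive")
  for (i in seq_len(dim(raw)[1])) {
    f0 <- mean(raw[i, , ])
    if (f0 <= 0) stop("nonpositive F0 in trial ", i)
    raw[i, , ] <- (raw[i, , ] - f0) / f0
  }
  raw
}

# zero-phase Butterworth-magnitude band-pass applied in the frequency
# domain, vectorized over columns of `mat` (time x series). Equivalent in
# magnitude response to forward-backward filtering of an order-`order`
# Butterworth band-pass, with exactly zero phase.
.bandpass_fft <- function(mat, fs, low, high, order = 3L) {
  n <- nrow(mat)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  g <- rep(1, n)
  if (!is.null(high) && is.finite(high))
    g <- g / (1 + (f / high)^(2L * order))
  if (!is.null(low) && low > 0) {
    r <- (f / low)^(2L * order)
    g <- g * r / (1 + r)
  }
  Re(stats::mvfft(stats::mvfft(mat) * g, inverse = TRUE)) / n
}

# zero-phase IIR low-pass (Butterworth, forward-backward) per column
.lowpass_iir <- function(mat, fs, cutoff, order = 6L) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  apply(mat, 2L, function(x) signal::filtfilt(bf, x))
}

#' Band-pass filter, spatially bin, and resample a session
#'
#' Per trial and pixel the dF/F trace is band-pass filtered with a
#' zero-phase Butterworth-magnitude response (default 0.1-8 Hz), so planted
#' event times are not shifted by filter delay. The tensor is then
#' compressed by overlapping-mean spatial binning (default 130 um bins with
#' 50% overlap) and, if acquired above `target_fps`, linearly resampled in
#' time to `target_fps`.
#'
#' @param session a `session_tensor`.
#' @param low,high band edges (Hz); `low = 0` disables the high-pass.
#' @param bin_um spatial bin side (um); bins at or below the pixel size
#'   leave the grid unchanged.
#' @param overlap fractional bin overlap (0.5 = half-window stride).
#' @param target_fps output frame rate (Hz).
#' @param order Butterworth order of each pass.
#' @return a new `session_tensor` on the binned grid, with a bin-level
#'   atlas (majority area label per bin; edge bins truncated).
#' @export
bandpass_and_bin <- function(session, low = 0.1, high = 8, bin_um = 130,
                             overlap = 0.5, target_fps = 30, order = 3L) {
  fs <- session$frame_rate
  if (!is.null(high) && high >= fs / 2) stop("cutoff exceeds Nyquist")
  dat <- session$data
  nd <- dim(dat)
  for (i in seq_len(nd[1]))
    dat[i, , ] <- t(.bandpass_fft(t(dat[i, , , drop = TRUE]),
                                  fs, low, high, order))

  ## spatial binning
  atlas <- session$atlas
  w <- round(bin_um / atlas$pixel_size_um)
  if (w > 1L) {
    lab <- atlas$label_map
    nx <- nrow(lab); ny <- ncol(lab)
    stride <- max(1L, round(w * (1 - overlap)))
    x0 <- seq(1L, nx - w + 1L, by = stride)
    y0 <- seq(1L, ny - w + 1L, by = stride)
    full <- matrix(0L, nx, ny)
    full[session$pixel_index] <- seq_along(session$pixel_index)
    members <- list(); blab <- integer(0); keep_xy <- NULL
    for (jy in seq_along(y0)) for (jx in seq_along(x0)) {
      xs <- x0[jx]:(x0[jx] + w - 1L); ys <- y0[jy]:(y0[jy] + w - 1L)
      idx <- full[xs, ys]; idx <- idx[idx > 0L]
      if (length(idx) < ceiling(w * w / 2)) next   # mostly outside window
      members[[length(members) + 1L]] <- idx
      labs <- lab[xs, ys]; labs <- labs[labs > 0L]
      blab <- c(blab, as.integer(names(which.max(table(labs)))))
      keep_xy <- rbind(keep_xy, c(jx, jy))
    }
    if (length(members) == 0L) stop("binning removed all pixels")
    nb <- length(members)
    dat2 <- array(0, dim = c(nd[1], nb, nd[3]))
    for (b in seq_len(nb)) {
      m <- members[[b]]
      if (length(m) == 1L) dat2[, b, ] <- dat[, m, ]
      else dat2[, b, ] <- apply(dat[, m, , drop = FALSE], c(1, 3), mean)
    }
    bin_map <- matrix(0L, length(x0), length(y0))
    bin_map[cbind(keep_xy[, 1], keep_xy[, 2])] <- blab
    atlas <- structure(
      list(label_map = bin_map, area_names = atlas$area_names,
           pixel_size_um = atlas$pixel_size_um * stride,
           centers = atlas$centers / stride),
      class = "area_atlas")
    pixel_index <- (keep_xy[, 2] - 1L) * length(x0) + keep_xy[, 1]
    dat <- dat2
  } else {
    pixel_index <- session$pixel_index
  }

  ## temporal resampling
  if (fs > target_fps) {
    n_t <- dim(dat)[3]
    t_old <- (seq_len(n_t) - 0.5) / fs
    n_new <- floor(max(t_old) * target_fps)
    t_new <- (seq_len(n_new) - 0.5) / target_fps
    d3 <- array(0, dim = c(dim(dat)[1], dim(dat)[2], n_new))
    for (i in seq_len(dim(dat)[1]))
      d3[i, , ] <- t(apply(dat[i, , , drop = TRUE], 1L, function(x)
        stats::approx(t_old, x, xout = t_new, rule = 2)$y))
    dat <- d3
    fs <- target_fps
  }

  structure(
    list(data = dat, frame_rate = fs, pre_stim = session$pre_stim,
         open_loop = session$open_loop, closed_loop = session$closed_loop,
         atlas = atlas, pixel_index = pixel_index, planted = NULL),
    class = "session_tensor")
}

.event_list <- function(kind, events) {
  structure(list(kind = kind, events = events), class = "event_list")
}

#' Detect wheel movements from a velocity trace
#'
#' Flags time points where the velocity has a zero-crossing (sign change)
#' and subsequently exceeds the fixed threshold before the next crossing.
#' Event direction is the sign of the velocity after the crossing
#' (`"cw"` positive, `"ccw"` negative).
#'
#' @param velocity uniformly sampled wheel velocity (trace units; the
#'   threshold is in the same units).
#' @param fs sampling rate (Hz).
#' @param threshold detection threshold (default 20).
#' @return an `event_list` with columns time_s, direction, peak.
#' @export
detect_wheel_movements <- function(velocity, fs, threshold = 20) {
  n <- length(velocity)
  ev <- NULL
  if (n >= 2L) {
    s <- sign(velocity)
    cross <- which(s[-n] != s[-1] & s[-1] != 0)   # index before new sign
    bounds <- c(cross, n)
    for (j in seq_along(cross)) {
      i0 <- cross[j] + 1L
      i1 <- bounds[j + 1L]
      seg <- velocity[i0:i1]
      if (max(abs(seg)) >= threshold)
        ev <- rbind(ev, data.frame(
          time_s = cross[j] / fs,
          direction = if (s[i0] > 0) "cw" else "ccw",
          peak = seg[which.max(abs(seg))]))
    }
  }
  if (is.null(ev))
    ev <- data.frame(time_s = numeric(0), direction = character(0),
                     peak = numeric(0))
  .event_list("wheel", ev)
}

#' Detect saccades from an eye-position trace
#'
#' Candidate events are contiguous runs where the eye velocity magnitude
#' exceeds an adaptive threshold (`k` times the MAD of the velocity).
#' Candidates lasting <= 60 ms or smaller than 1.5 degrees are discarded.
#'
#' @param position uniformly sampled eye position (degrees).
#' @param fs sampling rate (Hz).
#' @param k adaptive threshold multiplier on the velocity MAD.
#' @param min_duration_ms events at or below this duration are discarded.
#' @param min_magnitude_deg events below this amplitude are discarded.
#' @return an `event_list` with columns time_s (peak velocity time),
#'   magnitude, duration_ms, start_pos, end_pos, peak_velocity.
#' @export
detect_saccades <- function(position, fs, k = 6,
                            min_duration_ms = 60, min_magnitude_deg = 1.5) {
  v <- c(0, diff(position)) * fs
  thr <- k * stats::mad(v)
  above <- abs(v) > max(thr, 1e-12)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- NULL
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- (i1 - i0 + 1L) / fs * 1000
    p0 <- position[max(i0 - 1L, 1L)]
    p1 <- position[min(i1 + 1L, length(position))]
    mag <- abs(p1 - p0)
    if (dur <= min_duration_ms || mag < min_magnitude_deg) next
    pk <- i0 - 1L + which.max(abs(v[i0:i1]))
    ev <- rbind(ev, data.frame(
      time_s = pk / fs, magnitude = mag, duration_ms = dur,
      start_pos = p0, end_pos = p1, peak_velocity = v[pk]))
  }
  if (is.null(ev))
    ev <- data.frame(time_s = numeric(0), magnitude = numeric(0),
                     duration_ms = numeric(0), start_pos = numeric(0),
                     end_pos = numeric(0), peak_velocity = numeric(0))
  .event_list("saccade", ev)
}

#' Stimulus-evoked pupil change (sustained-attention metric)
#'
#' Per trial, pA = max pupil area over the open-loop period (0, 1.5 s]
#' after stimulus onset minus the mean area over the second before onset.
#' Trial values are then z-scored against the session mean.
#'
#' @param traces matrix trials x samples of pupil area (a single trace is
#'   treated as one trial and returned un-z-scored).
#' @param fs sampling rate (Hz).
#' @param onset_index sample index of stimulus onset.
#' @param open_loop open-loop duration (s).
#' @param baseline pre-onset baseline duration (s).
#' @return data.frame with `pa` (raw) and `pa_z` (session z-score; NA for a
#'   single trial).
#' @export
pupil_attention_metric <- function(traces, fs, onset_index,
                                   open_loop = 1.5, baseline = 1) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  n <- ncol(traces)
  i_base <- (onset_index - round(baseline * fs)):(onset_index - 1L)
  i_ol <- (onset_index + 1L):(onset_index + round(open_loop * fs))
  if (min(i_base) < 1L || max(i_ol) > n) stop("window out of range")
  pa <- apply(traces[, i_ol, drop = FALSE], 1L, max) -
    rowMeans(traces[, i_base, drop = FALSE])
  pa_z <- if (length(pa) > 1L) as.numeric(scale(pa)) else NA_real_
  data.frame(pa = pa, pa_z = pa_z)
}

#' Dual-wavelength hemodynamic correction
#'
#' Per pixel, both channels are converted to relative fluorescence by
#' removing a linear trend: dF/F = (F - a t - b) / b with (a, b) from the
#' least-squares fit F(t) ~ a t + b. The violet (calcium-independent)
#' channel is low-pass filtered at 5 Hz (zero-phase 6th-order Butterworth)
#' and regressed onto the blue channel; the corrected signal is
#' blue - (c violet_lp + d). The result is low-pass filtered at 8 Hz.
#'
#' @param blue,violet matrices pixels x time, co-registered, equal size.
#' @param fs frame rate of each channel (Hz).
#' @param lp_violet,lp_final low-pass cutoffs (Hz).
#' @param order IIR order.
#' @return list with `corrected` (pixels x time) and `fit` (per-pixel
#'   data.frame of detrend a, b for both channels and regression c, d).
#' @export
hemodynamic_correct <- function(blue, violet, fs, lp_violet = 5,
                                lp_final = 8, order = 6L) {
  stopifnot(is.matrix(blue), all(dim(blue) == dim(violet)))
  nt <- ncol(blue)
  tt <- seq_len(nt)
  detrend <- function(m) {
    a <- as.numeric((m %*% (tt - mean(tt))) / sum((tt - mean(tt))^2))
    b <- rowMeans(m) - a * mean(tt)
    if (any(b == 0)) stop("zero detrend intercept")
    list(dff = (m - outer(a, tt) - b) / b, a = a, b = b)
  }
  db <- detrend(blue)
  dv <- detrend(violet)
  v_lp <- t(.lowpass_iir(t(dv$dff), fs, lp_violet, order))
  n_px <- nrow(blue)
  cc <- numeric(n_px); dd <- numeric(n_px)
  corrected <- db$dff
  for (p in seq_len(n_px)) {
    v <- v_lp[p, ]
    if (stats::sd(v) < 1e-12) {
      warning("degenerate violet channel in pixel ", p,
              "; regression skipped (c = 0)")
      cc[p] <- 0; dd[p] <- mean(db$dff[p, ])
    } else {
      f <- stats::lm.fit(cbind(1, v), db$dff[p, ])
      dd[p] <- f$coefficients[1]; cc[p] <- f$coefficients[2]
    }
    corrected[p, ] <- db$dff[p, ] - (cc[p] * v + dd[p])
  }
  corrected <- t(.lowpass_iir(t(corrected), fs, lp_final, order))
  list(corrected = corrected,
       fit = data.frame(a_blue = db$a, b_blue = db$b,
                        a_violet = dv$a, b_violet = dv$b,
                        c = cc, d = dd))
}
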