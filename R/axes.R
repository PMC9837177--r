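#' Build the two balanced trial groups for a task variable
#'
#' Applies the per-variable inclusion rules and alignment conventions:
#' \describe{
#'   \item{stimulus}{all trials, aligned to stimulus onset; group B is the
#'     same trials with the alignment shifted 0.5 s earlier so its window
#'     covers the final second of the (randomized) inter-trial interval,
#'     serving as the no-stimulus condition.}
#'   \item{contra_orientation}{trials split by the left (contralateral)
#'     stimulus orientation (horizontal-like vs vertical-like), aligned to
#'     stimulus onset.}
#'   \item{wheel}{A: first movement at least 0.5 s after onset with no
#'     saccade in the preceding 0.5 s, aligned to movement onset. B: no
#'     movement within the first `no_event_horizon` seconds, aligned to a
#'     random frame in (0.5 s, horizon\].}
#'   \item{saccade}{as wheel with the roles of saccades and wheel movements
#'     swapped.}
#'   \item{attention}{A/B: top/bottom tertile of the session's z-scored
#'     pupil change, aligned to stimulus onset (balanced by definition).}
#'   \item{choice}{A: right-choice, B: left-choice trials, restricted to
#'     first movement at least 0.5 s after onset with no saccade in the
#'     preceding 0.5 s, aligned to movement onset.}
#' }
#' Trials whose aligned analysis window would leave the recorded tensor are
#' dropped, then the larger group is subsampled at random to the size of
#' the smaller one.
#'
#' @param trials trial table (from [simulate_session()]).
#' @param variable one of `"stimulus"`, `"contra_orientation"`, `"wheel"`,
#'   `"saccade"`, `"attention"`, `"choice"`.
#' @param fs frame rate (Hz) of the component array the pair will index.
#' @param pre_stim pre-stimulus duration (s); stimulus onset is at frame
#'   `round(pre_stim * fs) + 1`.
#' @param n_frames frames per trial in the component array.
#' @param window analysis window (s) relative to the alignment event;
#'   `NULL` picks a per-variable default.
#' @param no_event_horizon no-movement/no-saccade horizon (s) for the
#'   control groups, truncated to the trial length.
#' @param seed integer seed for the random alignment frames and balancing.
#' @return object of class `trial_group_pair` with integer trial ids
#'   `trials_A`/`trials_B`, per-trial alignment frames `align_A`/`align_B`,
#'   `window`, `win_frames` (frame offsets), `fs` and `variable`.
#' @export
build_group_pair <- function(trials, variable, fs, pre_stim, n_frames,
                             window = NULL, no_event_horizon = 5,
                             seed = 1L) {
  variable <- match.arg(variable, c("stimulus", "contra_orientation",
                                    "wheel", "saccade", "choice",
                                    "attention"))
  if (nrow(trials) < 4L) stop("trial table too small")
  f0 <- as.integer(round(pre_stim * fs)) + 1L
  t_avail <- (n_frames - f0) / fs            # seconds after onset
  horizon <- min(no_event_horizon, t_avail)
  if (is.null(window))
    window <- switch(variable,
                     stimulus = c(-0.5, 0.5),
                     contra_orientation = c(0, 1),
                     attention = c(-0.5, 1.5),
                     c(-1, 0.5))
  win_frames <- seq.int(round(window[1] * fs), round(window[2] * fs))

  has_move <- !is.na(trials$first_move_time)
  move_ok <- has_move & trials$first_move_time >= 0.5 &
    !vapply(seq_len(nrow(trials)), function(i) {
      st <- trials$saccades[[i]]
      mt <- trials$first_move_time[i]
      !is.na(mt) && any(st >= mt - 0.5 & st < mt)
    }, logical(1))
  first_sacc <- vapply(seq_len(nrow(trials)), function(i) {
    st <- trials$saccades[[i]]
    st <- st[st >= 0.5]
    mt <- trials$first_move_time[i]
    st <- st[vapply(st, function(s)
      is.na(mt) || !(mt >= s - 0.5 & mt < s), logical(1))]
    if (length(st)) st[1] else NA_real_
  }, numeric(1))

  rng <- local_rng(seed)
  rand_align <- function(n) {
    hi <- max(horizon - 1 / fs, 0.5 + 2 / fs)
    f0 + as.integer(round(rng$runif(n, 0.5 + 1 / fs, hi) * fs))
  }

  sel <- switch(variable,
    stimulus = {
      ids <- trials$trial
      list(A = ids, B = ids, aA = rep(f0, length(ids)),
           aB = rep(f0 - as.integer(round(0.5 * fs)), length(ids)))
    },
    contra_orientation = {
      A <- trials$trial[abs(trials$left_angle) >= 45]
      B <- trials$trial[abs(trials$left_angle) < 45]
      list(A = A, B = B, aA = rep(f0, length(A)), aB = rep(f0, length(B)))
    },
    attention = {
      A <- trials$trial[trials$attention == "high"]
      B <- trials$trial[trials$attention == "low"]
      list(A = A, B = B, aA = rep(f0, length(A)), aB = rep(f0, length(B)))
    },
    wheel = {
      A <- trials$trial[move_ok]
      no_move <- !has_move | trials$first_move_time > horizon
      B <- trials$trial[no_move]
      list(A = A, B = B,
           aA = f0 + as.integer(round(
             trials$first_move_time[match(A, trials$trial)] * fs)),
           aB = rand_align(length(B)))
    },
    saccade = {
      A <- trials$trial[!is.na(first_sacc)]
      no_sacc <- vapply(trials$saccades, function(st)
        !any(st > 0 & st <= horizon), logical(1))
      B <- trials$trial[no_sacc]
      list(A = A, B = B,
           aA = f0 + as.integer(round(
             first_sacc[match(A, trials$trial)] * fs)),
           aB = rand_align(length(B)))
    },
    choice = {
      ok <- move_ok & trials$choice %in% c("left", "right")
      A <- trials$trial[ok & trials$choice == "right"]
      B <- trials$trial[ok & trials$choice == "left"]
      al <- function(ids) f0 + as.integer(round(
        trials$first_move_time[match(ids, trials$trial)] * fs))
      list(A = A, B = B, aA = al(A), aB = al(B))
    })

  fits <- function(a) a + min(win_frames) >= 1L & a + max(win_frames) <= n_frames
  okA <- fits(sel$aA); okB <- fits(sel$aB)
  A <- sel$A[okA]; aA <- sel$aA[okA]
  B <- sel$B[okB]; aB <- sel$aB[okB]
  if (length(A) == 0L || length(B) == 0L)
    stop(sprintf("empty %s group for variable '%s' after applying its rule",
                 if (length(A) == 0L) "A" else "B", variable))
  n <- min(length(A), length(B))
  if (length(A) > n) { i <- sort(rng$sample(length(A), n)); A <- A[i]; aA <- aA[i] }
  if (length(B) > n) { i <- sort(rng$sample(length(B), n)); B <- B[i]; aB <- aB[i] }
  structure(list(variable = variable, trials_A = A, trials_B = B,
                 align_A = aA, align_B = aB, window = window,
                 win_frames = win_frames, fs = fs, n_per_group = n),
            class = "trial_group_pair")
}

#' @export
print.trial_group_pair <- function(x, ...) {
  cat(sprintf("trial_group_pair '%s': %d vs %d trials, window [%g, %g] s\n",
              x$variable, length(x$trials_A), length(x$trials_B),
              x$window[1], x$window[2]))
  invisible(x)
}

# slice the component array [K, T, trials] around per-trial align frames:
# returns [K, n_window_frames, n_selected_trials]
aligned_array <- function(carray, trial_ids, align_frames, win_frames) {
  K <- dim(carray)[1]
  out <- array(0, dim = c(K, length(win_frames), length(trial_ids)))
  for (j in seq_along(trial_ids))
    out[, , j] <- carray[, align_frames[j] + win_frames, trial_ids[j]]
  out
}

# temporal component array from a decomposition or a raw [K, T, trials] array
as_carray <- function(x) {
  if (inherits(x, "decomposition")) x$temporal
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("need a decomposition or a K x frames x trials array")
}

# raw (un-normalized) discrimination vectors per window frame:
# (meanA - meanB) / pooled sd, one column per frame
.raw_axis <- function(XA, XB) {
  mA <- apply(XA, c(1, 2), mean); mB <- apply(XB, c(1, 2), mean)
  vA <- apply(XA, c(1, 2), stats::var); vB <- apply(XB, c(1, 2), stats::var)
  pooled <- sqrt((vA + vB) / 2)
  num <- mA - mB
  bad <- pooled < 1e-14
  if (any(bad)) {
    warning("zero pooled SD in ", sum(bad),
            " component-time entries; set to 0")
    num[bad] <- 0
    pooled[bad] <- 1
  }
  num / pooled
}

#' Compute a state axis for a group pair
#'
#' Per component and time, the difference of group means divided by the
#' pooled standard deviation sqrt((var_A + var_B) / 2); the resulting
#' vector is normalized to unit length at each time point. In window mode
#' the per-component ratio is first averaged over the window frames and
#' then renormalized, giving a single time-independent axis.
#'
#' @param x a `decomposition` or a K x frames x trials array.
#' @param pair a [build_group_pair()] object.
#' @param window if `TRUE` return one window-averaged axis; otherwise one
#'   axis per window frame.
#' @return object of class `state_axis`: `weights` (K-vector, or K x time
#'   matrix with unit-norm columns), `times` (s), `variable`.
#' @export
state_axis <- function(x, pair, window = FALSE) {
  carray <- as_carray(x)
  XA <- aligned_array(carray, pair$trials_A, pair$align_A, pair$win_frames)
  XB <- aligned_array(carray, pair$trials_B, pair$align_B, pair$win_frames)
  raw <- .raw_axis(XA, XB)
  times <- pair$win_frames / pair$fs
  if (window) {
    w <- unitize(rowMeans(raw))
    structure(list(weights = w, times = NULL, variable = pair$variable),
              class = "state_axis")
  } else {
    w <- apply(raw, 2L, unitize)
    structure(list(weights = w, times = times, variable = pair$variable),
              class = "state_axis")
  }
}

#' Project trials onto a state axis
#'
#' The per-trial projection P_i(t) is the dot product of the axis at each
#' time with the trial's component vector; components are not
#' mean-centered in time.
#'
#' @param axis a `state_axis` (or a bare numeric K-vector).
#' @param x a `decomposition` or K x frames x trials array.
#' @param trial_ids trials to project.
#' @param align_frames per-trial alignment frames.
#' @param win_frames frame offsets of the window.
#' @return matrix time x trials of projections.
#' @export
project_axis <- function(axis, x, trial_ids, align_frames, win_frames) {
  carray <- as_carray(x)
  W <- if (inherits(axis, "state_axis")) axis$weights else axis
  X <- aligned_array(carray, trial_ids, align_frames, win_frames)
  K <- dim(X)[1]
  if (is.matrix(W)) {
    stopifnot(nrow(W) == K, ncol(W) == dim(X)[2])
    out <- matrix(0, dim(X)[2], dim(X)[3])
    for (tt in seq_len(dim(X)[2]))
      out[tt, ] <- crossprod(W[, tt], X[, tt, ])
    out
  } else {
    stopifnot(length(W) == K)
    apply(X, 3L, function(m) as.numeric(crossprod(W, m)))  # time x trials
  }
}

# d' between two projection matrices (time x trials)
.dprime_of_proj <- function(PA, PB) {
  m <- rowMeans(PA) - rowMeans(PB)
  s <- sqrt((apply(PA, 1L, stats::var) + apply(PB, 1L, stats::var)) / 2)
  ifelse(s < 1e-14, 0, m / s)
}

#' Cross-validated discriminability (d') curve
#'
#' Five-fold cross-validation in the paper's sense: per fold, the state
#' axis is defined from a 20% training split of each group and d'(t) is
#' computed from the held-out trials' projections as the difference of
#' group means over their pooled standard deviation. The reported curve is
#' the mean across folds.
#'
#' @inheritParams state_axis
#' @param cv_folds number of folds.
#' @param train_frac fraction of trials (per group) used to define the axis
#'   in each fold.
#' @param seed integer seed for the fold assignment.
#' @param window use a single window-averaged axis instead of per-time axes.
#' @param baseline_time if non-`NULL`, subtract the curve value at this
#'   time (s) from the whole curve (used to impose zero discriminability at
#'   stimulus onset for the sustained-attention axis).
#' @return object of class `dprime_curve`: `times`, `dprime` (fold mean),
#'   `per_fold` (time x fold), `variable`, `n_per_group`.
#' @export
dprime_curve <- function(x, pair, cv_folds = 5L, train_frac = 0.2,
                         seed = 1L, window = FALSE, baseline_time = NULL) {
  carray <- as_carray(x)
  n <- pair$n_per_group
  n_train <- max(2L, round(train_frac * n))
  if (n - n_train < 2L) stop("not enough trials for the train/test split")
  rng <- local_rng(seed)
  ordA <- rng$sample(n); ordB <- rng$sample(n)
  nt <- length(pair$win_frames)
  per_fold <- matrix(0, nt, cv_folds)
  for (f in seq_len(cv_folds)) {
    # fold f's training block: a contiguous run of the permuted order
    i0 <- floor((f - 1L) * n / cv_folds) + 1L
    trA <- ordA[(seq_len(n_train) + i0 - 2L) %% n + 1L]
    trB <- ordB[(seq_len(n_train) + i0 - 2L) %% n + 1L]
    teA <- setdiff(seq_len(n), trA); teB <- setdiff(seq_len(n), trB)
    sub <- function(ids, al, idx) list(ids = ids[idx], al = al[idx])
    pa <- sub(pair$trials_A, pair$align_A, trA)
    pb <- sub(pair$trials_B, pair$align_B, trB)
    train_pair <- pair
    train_pair$trials_A <- pa$ids; train_pair$align_A <- pa$al
    train_pair$trials_B <- pb$ids; train_pair$align_B <- pb$al
    ax <- state_axis(carray, train_pair, window = window)
    PA <- project_axis(ax, carray, pair$trials_A[teA], pair$align_A[teA],
                       pair$win_frames)
    PB <- project_axis(ax, carray, pair$trials_B[teB], pair$align_B[teB],
                       pair$win_frames)
    per_fold[, f] <- .dprime_of_proj(PA, PB)
  }
  dp <- rowMeans(per_fold)
  times <- pair$win_frames / pair$fs
  if (!is.null(baseline_time)) {
    i0 <- which.min(abs(times - baseline_time))
    dp <- dp - dp[i0]
    per_fold <- sweep(per_fold, 2L, per_fold[i0, ])
  }
  structure(list(times = times, dprime = dp, per_fold = per_fold,
                 variable = pair$variable, n_per_group = n),
            class = "dprime_curve")
}

#' @export
print.dprime_curve <- function(x, ...) {
  cat(sprintf(
    "dprime_curve '%s': %d frames, peak |d'| = %.2f at t = %.2f s (n = %d/group)\n",
    x$variable, length(x$times), max(abs(x$dprime)),
    x$times[which.max(abs(x$dprime))], x$n_per_group))
  invisible(x)
}

#' Temporal stability of a time-dependent state axis
#'
#' Axes are smoothed with a backward three-frame averaging window and the
#' matrix of cosine similarities between all time pairs is returned.
#'
#' @param axis a per-time `state_axis` (or K x time weight matrix).
#' @param smoothing backward smoothing window (frames).
#' @return symmetric matrix of cosine similarities (diagonal 1; entries for
#'   zero-norm axes are `NA`).
#' @export
axis_stability <- function(axis, smoothing = 3L) {
  W <- if (inherits(axis, "state_axis")) axis$weights else axis
  stopifnot(is.matrix(W), ncol(W) >= 2L)
  nt <- ncol(W)
  Ws <- W
  for (tt in seq_len(nt))
    Ws[, tt] <- rowMeans(W[, max(1L, tt - smoothing + 1L):tt, drop = FALSE])
  nrm <- sqrt(colSums(Ws^2))
  R <- crossprod(Ws) / outer(nrm, nrm)
  R[, nrm < 1e-12] <- NA_real_
  R[nrm < 1e-12, ] <- NA_real_
  diag(R)[nrm >= 1e-12] <- 1
  R
}

#' Reference time of the largest stability cluster
#'
#' Finds the longest contiguous run of time points whose mean off-diagonal
#' stability exceeds `threshold` and returns its center (used to pick the
#' time-independent axis for sensory, movement and attention variables).
#'
#' @param stability matrix from [axis_stability()].
#' @param times time axis (s), one per row of `stability`.
#' @param threshold stability threshold.
#' @return list with `t_star` (s), `index`, and `in_cluster` (logical).
#' @export
stable_time <- function(stability, times, threshold = 0.8) {
  nt <- nrow(stability)
  m <- vapply(seq_len(nt), function(i)
    mean(stability[i, -i], na.rm = TRUE), numeric(1))
  ok <- !is.na(m) & m > threshold
  if (!any(ok)) {
    i <- which.max(m)
    return(list(t_star = times[i], index = i, in_cluster = ok))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i <- round((ends[best] - r$lengths[best] + 1L + ends[best]) / 2)
  list(t_star = times[i], index = i, in_cluster = ok)
}

#' Area-restricted state axis and d' curve
#'
#' Runs the identical axis pipeline using only the components assigned to
#' one area (or a union of areas).
#'
#' @param decomp a `decomposition`.
#' @param pair a `trial_group_pair`.
#' @param areas area name(s) or id(s).
#' @param ... passed to [dprime_curve()].
#' @return list with `axis` (window-averaged), `curve` (a `dprime_curve`),
#'   and `components` (indices used).
#' @export
area_axis <- function(decomp, pair, areas, ...) {
  stopifnot(inherits(decomp, "decomposition"))
  if (is.character(areas)) {
    ids <- match(areas, decomp$atlas$area_names)
    if (anyNA(ids)) stop("unknown area name")
  } else ids <- as.integer(areas)
  keep <- which(decomp$component_area %in% ids)
  if (length(keep) == 0L) stop("area has no components")
  sub <- decomp$temporal[keep, , , drop = FALSE]
  list(axis = state_axis(sub, pair, window = TRUE),
       curve = dprime_curve(sub, pair, ...),
       components = keep)
}

#' d' after orthogonalizing the target axis against nuisance axes
#'
#' Per cross-validation fold, the window-averaged target axis is projected
#' out of the span of the nuisance axes (Gram-Schmidt via QR), renormalized
#' and applied to the held-out trials.
#'
#' @inheritParams dprime_curve
#' @param nuisance matrix of nuisance axis vectors (K x m) or a single
#'   K-vector or a list of `state_axis` objects.
#' @return a `dprime_curve`.
#' @export
orthogonalized_dprime <- function(x, pair, nuisance, cv_folds = 5L,
                                  train_frac = 0.2, seed = 1L) {
  carray <- as_carray(x)
  if (is.list(nuisance) && !is.matrix(nuisance))
    nuisance <- vapply(nuisance, function(a)
      if (inherits(a, "state_axis")) a$weights else a,
      numeric(dim(carray)[1]))
  if (is.vector(nuisance)) nuisance <- matrix(nuisance, ncol = 1L)
  Q <- qr.Q(qr(nuisance))
  n <- pair$n_per_group
  n_train <- max(2L, round(train_frac * n))
  rng <- local_rng(seed)
  ordA <- rng$sample(n); ordB <- rng$sample(n)
  nt <- length(pair$win_frames)
  per_fold <- matrix(0, nt, cv_folds)
  for (f in seq_len(cv_folds)) {
    i0 <- floor((f - 1L) * n / cv_folds) + 1L
    trA <- ordA[(seq_len(n_train) + i0 - 2L) %% n + 1L]
    trB <- ordB[(seq_len(n_train) + i0 - 2L) %% n + 1L]
    teA <- setdiff(seq_len(n), trA); teB <- setdiff(seq_len(n), trB)
    train_pair <- pair
    train_pair$trials_A <- pair$trials_A[trA]
    train_pair$align_A <- pair$align_A[trA]
    train_pair$trials_B <- pair$trials_B[trB]
    train_pair$align_B <- pair$align_B[trB]
    w <- state_axis(carray, train_pair, window = TRUE)$weights
    w_perp <- w - Q %*% crossprod(Q, w)
    if (l2(w_perp) < 1e-8)
      stop("target axis lies in the nuisance span")
    w_perp <- unitize(as.numeric(w_perp))
    PA <- project_axis(w_perp, carray, pair$trials_A[teA],
                       pair$align_A[teA], pair$win_frames)
    PB <- project_axis(w_perp, carray, pair$trials_B[teB],
                       pair$align_B[teB], pair$win_frames)
    per_fold[, f] <- .dprime_of_proj(PA, PB)
  }
  structure(list(times = pair$win_frames / pair$fs,
                 dprime = rowMeans(per_fold), per_fold = per_fold,
                 variable = paste0(pair$variable, "_orth"),
                 n_per_group = n),
            class = "dprime_curve")
}
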