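.axis_vec <- function(a) {
  v <- if (inherits(a, "state_axis")) a$weights else a
  if (is.matrix(v)) stop("need a single (window-averaged) axis vector")
  v
}

#' Angle between two state axes
#'
#' Axes are directionless, so the angle is folded to \[0, 90\] degrees via
#' the absolute cosine.
#'
#' @param a1,a2 `state_axis` objects or numeric vectors of equal length.
#' @return angle in degrees.
#' @export
axis_angle <- function(a1, a2) {
  v1 <- .axis_vec(a1); v2 <- .axis_vec(a2)
  n1 <- l2(v1); n2 <- l2(v2)
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-norm axis")
  acos(min(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

#' Pairwise angle matrix for a set of axes
#'
#' @param axes named list of axes (vectors or `state_axis`).
#' @return object of class `angle_stats`: symmetric matrix of angles in
#'   degrees with zero diagonal.
#' @export
axis_angle_matrix <- function(axes) {
  V <- lapply(axes, .axis_vec)
  n <- length(V)
  M <- matrix(0, n, n, dimnames = list(names(axes), names(axes)))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) M[i, j] <- axis_angle(V[[i]], V[[j]])
  structure(M, class = c("angle_stats", "matrix"))
}

#' Surrogate null for the angle between independent axes
#'
#' Resamples the axis's own components with replacement to generate
#' surrogate axes of matched dimensionality and weight distribution,
#' renormalizes them, and returns the empirical 2.5% and 97.5% percentiles
#' of the angle to the original axis. Angles to other, statistically
#' independent axes are expected to fall inside this interval.
#'
#' @param axis a `state_axis` or numeric vector (dimension >= 2).
#' @param n_surrogates number of bootstrap axes.
#' @param seed integer seed.
#' @return list with `lo`, `hi` (degrees) and `angles` (all surrogate
#'   angles).
#' @export
surrogate_angle_null <- function(axis, n_surrogates = 2000L, seed = 1L) {
  v <- unitize(.axis_vec(axis))
  K <- length(v)
  stopifnot(K >= 2L)
  ang <- with_seed(seed, vapply(seq_len(n_surrogates), function(i) {
    s <- v[sample.int(K, K, replace = TRUE)]
    n <- l2(s)
    if (n < 1e-12) return(NA_real_)
    acos(min(1, abs(sum(v * s)) / n)) * 180 / pi
  }, numeric(1)))
  q <- stats::quantile(ang, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lo = q[1], hi = q[2], angles = ang)
}

#' Hierarchical clustering of axes from their angle matrix
#'
#' Average-linkage clustering with the pairwise angle (degrees) as the
#' distance.
#'
#' @param angles an `angle_stats` matrix from [axis_angle_matrix()].
#' @return an [stats::hclust] object.
#' @export
cluster_axes <- function(angles) {
  stats::hclust(stats::as.dist(unclass(angles)), method = "average")
}

#' Spatial-Distribution Index
#'
#' SDI(%) = (d'_global / max(d'_area) - 1) * 100: the relative gain of the
#' all-areas state axis over the best single-area axis. 0% when a single
#' area carries all the discriminative signal.
#'
#' @param global_dprime discriminability of the full (all-components) axis.
#' @param area_dprimes vector of per-area discriminabilities.
#' @return SDI in percent.
#' @export
sdi <- function(global_dprime, area_dprimes) {
  m <- max(area_dprimes)
  if (!is.finite(m) || m <= 0) stop("nonpositive maximum area d'")
  (global_dprime / m - 1) * 100
}

#' Default five-group partition of the nine analysis areas
#'
#' Dorsal (PM, AM), ventral (L), parietal (A, AL, RL), somatosensory
#' (SSt, SSb) and retrosplenial (RS) groups; V1 is excluded because its
#' strong sensory drive dominates any grouped coordinate.
#' @return named list of area-name vectors.
#' @export
area_groups_5d <- function() {
  list(dorsal = c("PM", "AM"), ventral = "L",
       parietal = c("A", "AL", "RL"), somatosensory = c("SSt", "SSb"),
       retrosplenial = "RS")
}

#' Five-dimensional d' coordinates over area groups
#'
#' Runs the area-restricted axis pipeline on each group union and reports
#' the peak absolute held-out d' per group.
#'
#' @param decomp a `decomposition`.
#' @param pair a `trial_group_pair`.
#' @param groups named list of area-name vectors (default
#'   [area_groups_5d()]).
#' @param ... passed to [dprime_curve()].
#' @return named numeric vector of d' values, one per group.
#' @export
group_dprime_5d <- function(decomp, pair, groups = area_groups_5d(), ...) {
  vapply(groups, function(g) {
    if (length(g) == 0L) stop("empty area group")
    max(abs(area_axis(decomp, pair, g, ...)$curve$dprime))
  }, numeric(1))
}

#' Two-segment piecewise linear fit of a d' curve
#'
#' Continuous two-slope least-squares fit with one free knot, over the
#' window from `lower` (default -1 s before movement onset) up to the
#' earliest time the curve reaches 95% of its post-movement maximum. The
#' knot is located by golden-section search over the window with the
#' per-knot segment fit solved in closed form.
#'
#' @param curve a `dprime_curve`, or a list/data.frame with `times` and
#'   `dprime`.
#' @param lower lower edge of the fit window (s).
#' @param upper optional fixed upper edge; `NULL` applies the 95% rule.
#' @return object of class `piecewise_fit`: `pre_slope`, `post_slope`
#'   (d'/s), `knot_time` (s), `fit_window`, `r2`, `degenerate` flag.
#' @export
piecewise_fit <- function(curve, lower = -1, upper = NULL) {
  tt <- curve$times; y <- curve$dprime
  stopifnot(length(tt) == length(y), length(tt) >= 5L)
  if (is.null(upper)) {
    post <- which(tt >= 0)
    if (length(post) < 2L) stop("curve does not cover post-movement times")
    pk <- max(y[post])
    upper <- tt[post[which(y[post] >= 0.95 * pk)[1]]]
  }
  sel <- tt >= lower - 1e-9 & tt <= upper + 1e-9
  if (sum(sel) < 5L) stop("degenerate fit window")
  tt <- tt[sel]; y <- y[sel]

  sse_at <- function(c0) {
    X <- cbind(1, pmin(tt - c0, 0), pmax(tt - c0, 0))
    f <- stats::lm.fit(X, y)
    list(sse = sum(f$residuals^2), coef = f$coefficients)
  }
  # coarse grid then golden-section refinement around the best knot
  dt <- min(diff(tt))
  grid <- seq(tt[2], tt[length(tt) - 1L], length.out = 60L)
  sses <- vapply(grid, function(c0) sse_at(c0)$sse, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  for (it in seq_len(40L)) {
    if (hi - lo < dt * 1e-3) break
    c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
    if (sse_at(c1)$sse < sse_at(c2)$sse) hi <- c2 else lo <- c1
  }
  knot <- (lo + hi) / 2
  best <- sse_at(knot)
  tot <- sum((y - mean(y))^2)
  r2 <- if (tot > 1e-20) 1 - best$sse / tot else 0
  degenerate <- tot < 1e-12 || r2 < 0.1
  structure(list(pre_slope = unname(best$coef[2]),
                 post_slope = unname(best$coef[3]),
                 knot_time = knot, fit_window = c(lower, upper),
                 r2 = r2, degenerate = degenerate),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "piecewise_fit: slopes %.3f -> %.3f d'/s, knot %.3f s (R2 = %.2f%s)\n",
    x$pre_slope, x$post_slope, x$knot_time, x$r2,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Pixel-wise d' maps (negative control for distributed signals)
#'
#' For each pixel and aligned time point, d' of the dF/F values between the
#' two groups with the pooled-SD denominator, with no spatial integration.
#' A signal too weak at any single pixel to be detected here can still be
#' read out by a component-space state axis that pools across pixels.
#'
#' @param session a `session_tensor`.
#' @param pair a `trial_group_pair` (frame indices must refer to the
#'   session's frame grid).
#' @return list with `dprime` (pixels x time matrix), `times` (s),
#'   `variable`.
#' @export
pixelwise_dprime <- function(session, pair) {
  dat <- session$data                         # trial x px x frame
  wf <- pair$win_frames
  npx <- dim(dat)[2]; nt <- length(wf)
  grab <- function(ids, al) {
    X <- array(0, dim = c(length(ids), npx, nt))
    for (j in seq_along(ids))
      X[j, , ] <- dat[ids[j], , al[j] + wf]
    X
  }
  XA <- grab(pair$trials_A, pair$align_A)
  XB <- grab(pair$trials_B, pair$align_B)
  mA <- apply(XA, c(2, 3), mean); mB <- apply(XB, c(2, 3), mean)
  vA <- apply(XA, c(2, 3), stats::var); vB <- apply(XB, c(2, 3), stats::var)
  s <- sqrt((vA + vB) / 2)
  dp <- (mA - mB) / pmax(s, 1e-14)
  list(dprime = dp, times = wf / pair$fs, variable = pair$variable)
}
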