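# helpers to view a session as a pixels x time matrix (trials concatenated)
session_matrix <- function(session) {
  d <- dim(session$data)                     # trial x px x frame
  Y <- matrix(0, d[2], d[1] * d[3])
  for (i in seq_len(d[1]))
    Y[, ((i - 1L) * d[3] + 1L):(i * d[3])] <- session$data[i, , ]
  Y
}

#' SVD compression of a concatenated session
#'
#' Reduces the pixels x time matrix (all trials concatenated) to the
#' smallest rank whose cumulative squared singular values reach the
#' requested fraction of the total sum of squares.
#'
#' @param Y pixels x time matrix, or a `session_tensor`.
#' @param ev fraction of variance (sum of squares) to retain.
#' @param max_rank optional cap on the retained rank (useful when most
#'   variance is unstructured pixel noise and the structured signal is
#'   known to be low-dimensional).
#' @return object of class `svd_basis`: `L` (pixels x r, = U diag(d)),
#'   `R` (time x r, = V), `d` (all singular values), `rank`,
#'   `ev_retained`, `total_ss`.
#' @export
svd_compress <- function(Y, ev = 0.99, max_rank = NULL) {
  if (inherits(Y, "session_tensor")) Y <- session_matrix(Y)
  stopifnot(is.matrix(Y), length(Y) > 0, ev > 0, ev <= 1)
  npx <- nrow(Y); nt <- ncol(Y)
  if (npx <= nt) {
    e <- eigen(tcrossprod(Y), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    r <- which(cumsum(d2) / sum(d2) >= ev - 1e-12)[1]
    if (!is.null(max_rank)) r <- min(r, as.integer(max_rank))
    d <- sqrt(d2)
    U <- e$vectors[, seq_len(r), drop = FALSE]
    V <- crossprod(Y, U) %*% diag(1 / d[seq_len(r)], r)
  } else {
    e <- eigen(crossprod(Y), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    r <- which(cumsum(d2) / sum(d2) >= ev - 1e-12)[1]
    if (!is.null(max_rank)) r <- min(r, as.integer(max_rank))
    d <- sqrt(d2)
    V <- e$vectors[, seq_len(r), drop = FALSE]
    U <- Y %*% V %*% diag(1 / d[seq_len(r)], r)
  }
  structure(list(L = U %*% diag(d[seq_len(r)], r), R = V, d = d, rank = r,
                 ev_retained = sum(d2[seq_len(r)]) / sum(d2),
                 total_ss = sum(d2)),
            class = "svd_basis")
}

# products through the compressed factors Y = L R^T
.y_ct <- function(cmp, C) cmp$L %*% crossprod(cmp$R, t(C))      # px x K
.at_y <- function(cmp, A) crossprod(A, cmp$L) %*% t(cmp$R)      # K x time
.row_ss <- function(cmp) rowSums((cmp$L %*% crossprod(cmp$R)) * cmp$L)
.row_mean <- function(cmp) as.numeric(cmp$L %*% colMeans(cmp$R))

#' Seeded localized non-negative matrix factorization
#'
#' Decomposes a session into K spatial maps (non-negative, anchored to the
#' ten seeding areas) and unconstrained per-trial temporal components:
#' a semi-NMF fit by alternating least squares on the temporal part and
#' penalized HALS on the spatial part, where each spatial column pays an L1
#' penalty proportional to 1 - D of its seed mask. The penalty weight of a
#' component is raised geometrically until at least `loc_threshold` of its
#' spatial energy lies within the seed's D > 0.5 support. A greedy rank
#' line search adds one component at a time to the region with the largest
#' residual sum of squares until the explained variance target is met.
#'
#' @param session a `session_tensor` (or an `svd_basis` from
#'   [svd_compress()], in which case `atlas` metadata must be supplied via
#'   the `session` argument of a prior call -- normally pass the session).
#' @param seed_masks list from [make_seed_masks()]; computed from the
#'   session's atlas when `NULL`.
#' @param loc_threshold minimum within-support fraction of spatial energy.
#' @param ev_target explained-variance stopping target of the line search.
#' @param svd_ev variance retained by the initial SVD compression.
#' @param svd_rank optional cap on the compression rank (see
#'   [svd_compress()]).
#' @param max_per_area cap on components per seeding region.
#' @param rank_per_area if given, fit exactly this many components per
#'   region and skip the line search. Use for noise-dominated data where
#'   the generative rank is known and an explained-variance target would be
#'   dominated by unstructured pixel noise.
#' @param decay_length passed to [make_seed_masks()].
#' @param inner_iter alternating updates per line-search step.
#' @return object of class `decomposition`: `spatial` (pixels x K, >= 0),
#'   `temporal` (K x frames x trials), `component_area`, `ev_total`,
#'   `localization`, `converged` flag, timing metadata, `atlas`,
#'   `pixel_index`, and the compressed basis used.
#' @export
loca_nmf <- function(session, seed_masks = NULL, loc_threshold = 0.75,
                     ev_target = 0.99, svd_ev = 0.99, svd_rank = NULL,
                     max_per_area = 8L, rank_per_area = NULL,
                     decay_length = NULL, inner_iter = 40L) {
  stopifnot(inherits(session, "session_tensor"))
  atlas <- session$atlas
  if (is.null(seed_masks)) seed_masks <- make_seed_masks(atlas, decay_length)
  cmp <- svd_compress(session, ev = svd_ev, max_rank = svd_rank)
  d <- dim(session$data)
  npx <- d[2]; n_trials <- d[1]; n_frames <- d[3]
  nt <- n_trials * n_frames
  n_areas <- length(seed_masks)
  total_ss <- cmp$total_ss
  rtr <- crossprod(cmp$R)

  fixed_rank <- !is.null(rank_per_area)
  comp_area <- if (fixed_rank) rep(seq_len(n_areas), each = rank_per_area)
  else seq_len(n_areas)                      # start: one component per region
  seed_shape <- function(a) {
    m <- seed_masks[[a]]
    v <- m$D^2
    v / l2(v)
  }
  A <- vapply(comp_area, seed_shape, numeric(npx))
  lam <- rep(0, length(comp_area))

  # all alternating updates run in the compressed r-space: with B = A'L,
  # M = A'A, the LS temporal part is C = M^-1 B R', so C C' and Y C' reduce
  # to small products through RtR = R'R
  L <- cmp$L
  row_ss <- rowSums((L %*% rtr) * L)

  localization <- function(A) {
    vapply(seq_len(ncol(A)), function(k) {
      e <- A[, k]^2
      s <- sum(e)
      if (s == 0) return(1)
      sum(e[seed_masks[[comp_area[k]]]$support]) / s
    }, numeric(1))
  }

  # (W, G) = (Y C', C C') for the LS-optimal C given A
  wg <- function(A) {
    K <- ncol(A)
    B <- crossprod(A, L)
    M <- crossprod(A)
    Mi <- solve(M + diag(1e-10 * max(diag(M)) + 1e-30, K))
    T1 <- Mi %*% (B %*% rtr)                  # K x r, = C R
    list(W = L %*% t(T1), G = T1 %*% crossprod(B, Mi), B = B, Mi = Mi)
  }

  refit <- function(A, lam, iters) {
    for (outer in seq_len(6L)) {
      for (it in seq_len(iters)) {
        p <- wg(A)
        for (k in seq_len(ncol(A))) {
          gkk <- p$G[k, k]
          if (gkk < 1e-12) { A[, k] <- seed_shape(comp_area[k]); next }
          pen <- lam[k] * seed_masks[[comp_area[k]]]$penalty
          ak <- (p$W[, k] - A %*% p$G[, k] + A[, k] * gkk - pen) / gkk
          ak <- pmax(ak, 0)
          if (all(ak == 0)) ak <- seed_shape(comp_area[k])
          A[, k] <- ak
        }
      }
      loc <- localization(A)
      bad <- loc < loc_threshold - 1e-9
      if (!any(bad)) break
      # raise the penalty of delocalized components and refit warm
      p <- wg(A)
      for (k in which(bad))
        lam[k] <- max(lam[k] * 3, 0.05 * max(abs(p$W[, k])) /
                        max(mean(seed_masks[[comp_area[k]]]$penalty), 1e-6))
      iters <- max(10L, iters %/% 2L)
    }
    list(A = A, lam = lam, loc = localization(A))
  }

  converged <- TRUE
  repeat {
    f <- refit(A, lam, inner_iter)
    A <- f$A; lam <- f$lam
    p <- wg(A)
    ev <- (2 * sum(A * p$W) - sum(crossprod(A) * p$G)) / total_ss
    if (fixed_rank || ev >= ev_target) break
    if (length(comp_area) >= n_areas * max_per_area) {
      converged <- FALSE
      warning(sprintf(
        "explained-variance target %.3f unreachable at max rank (got %.3f)",
        ev_target, ev))
      break
    }
    # residual SS per region -> add a component where it is largest
    ss_px <- row_ss - 2 * rowSums(p$W * A) + rowSums((A %*% p$G) * A)
    lab_px <- atlas$label_map[session$pixel_index]
    reg_ss <- vapply(seq_len(n_areas), function(a) {
      if (sum(comp_area == a) >= max_per_area) return(-Inf)
      sum(ss_px[lab_px == a])
    }, numeric(1))
    a_new <- which.max(reg_ss)
    comp_area <- c(comp_area, a_new)
    A <- cbind(A, seed_shape(a_new))
    lam <- c(lam, 0)
  }

  p <- wg(A)
  ev_final <- (2 * sum(A * p$W) - sum(crossprod(A) * p$G)) / total_ss
  C <- (p$Mi %*% p$B) %*% t(cmp$R)
  # normalize spatial maps to unit L2, fold scale into C
  sc <- apply(A, 2L, l2)
  A <- sweep(A, 2L, sc, "/")
  C <- sweep(C, 1L, sc, "*")
  temporal <- array(0, dim = c(ncol(A), n_frames, n_trials))
  for (i in seq_len(n_trials))
    temporal[, , i] <- C[, ((i - 1L) * n_frames + 1L):(i * n_frames),
                         drop = FALSE]

  structure(
    list(spatial = A, temporal = temporal, component_area = comp_area,
         ev_total = ev_final, localization = f$loc,
         converged = converged, atlas = atlas,
         pixel_index = session$pixel_index,
         frame_rate = session$frame_rate, pre_stim = session$pre_stim,
         open_loop = session$open_loop, compressed = cmp),
    class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "decomposition: %d components over %d areas, EV = %.3f, min loc = %.2f\n",
    ncol(x$spatial), length(unique(x$component_area)), x$ev_total,
    min(x$localization)))
  invisible(x)
}

#' Explained variance of a component subset
#'
#' Per pixel, the variance over concatenated time of the partial
#' reconstruction from the chosen components, summed across pixels and
#' divided by the summed per-pixel variance of the original signal.
#'
#' @param decomp a `decomposition`.
#' @param subset integer component indices (empty allowed, giving 0).
#' @param session optional original `session_tensor`; when omitted the
#'   SVD-compressed representation stored in `decomp` is used as the
#'   reference (it holds >= the compression EV of the original variance).
#' @return fraction in \[0, 1\] (up to sampling noise).
#' @export
explained_variance <- function(decomp, subset, session = NULL) {
  if (length(subset) == 0L) return(0)
  A <- decomp$spatial[, subset, drop = FALSE]
  dims <- dim(decomp$temporal)
  nt <- dims[2] * dims[3]
  C <- matrix(decomp$temporal[subset, , ], nrow = length(subset))
  # per-pixel variance of A C through the Gram matrix
  G <- tcrossprod(C)
  m <- rowMeans(C)
  ss_rec <- rowSums((A %*% G) * A)
  mean_rec <- as.numeric(A %*% m)
  var_rec <- (ss_rec - nt * mean_rec^2) / (nt - 1)
  if (is.null(session)) {
    cmp <- decomp$compressed
    ss <- .row_ss(cmp)
    mu <- .row_mean(cmp)
    var_orig <- (ss - nt * mu^2) / (nt - 1)
  } else {
    Y <- session_matrix(session)
    var_orig <- apply(Y, 1L, stats::var)
  }
  sum(var_rec) / sum(var_orig)
}
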