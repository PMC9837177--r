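#' Procedural 10-area cortical atlas
#'
#' Draws a Voronoi-style partition of a rectangular imaging window into the
#' ten posterior-cortex areas used throughout the package (V1, PM, AM, A,
#' SSt, RL, SSb, AL, L, RS). Area shapes are contiguous and disjoint by
#' construction; pixels outside the circular imaging window are labeled 0.
#'
#' @param nx,ny grid size in pixels.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param seed integer seed for the jittered seed-point placement.
#' @param circular if `TRUE`, pixels outside the inscribed circle are
#'   excluded from the window (label 0), mimicking a round cranial window.
#' @return An object of class `area_atlas`: list with `label_map` (nx-by-ny
#'   integer matrix, 0 = outside window), `area_names`, `pixel_size_um`,
#'   and `centers` (n-by-2 matrix of seed points, pixel units).
#' @export
make_area_atlas <- function(nx = 64L, ny = 64L, pixel_size_um = 50,
                            seed = 1L, circular = TRUE) {
  stopifnot(nx >= 8L, ny >= 8L, pixel_size_um > 0)
  area_names <- c("V1", "PM", "AM", "A", "SSt", "RL", "SSb", "AL", "L", "RS")
  n_areas <- length(area_names)
  rng <- local_rng(seed)

  # jittered 2 x 5 lattice of seed points keeps all ten areas nonempty and
  # roughly equal in size for any grid >= 8 x 8
  gx <- rep(seq(0.15, 0.85, length.out = 5L), times = 2L)
  gy <- rep(c(0.3, 0.7), each = 5L)
  jit <- matrix(rng$runif(2L * n_areas, -0.05, 0.05), ncol = 2L)
  centers <- cbind(gx * nx, gy * ny) + jit * c(nx, ny)

  px <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  d2 <- outer(px[, 1], centers[, 1], "-")^2 + outer(px[, 2], centers[, 2], "-")^2
  lab <- max.col(-d2, ties.method = "first")
  if (circular) {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    r2 <- (min(nx, ny) / 2)^2
    outside <- (px[, 1] - cx)^2 + (px[, 2] - cy)^2 > r2
    lab[outside] <- 0L
  }
  label_map <- matrix(as.integer(lab), nrow = nx, ncol = ny)
  counts <- tabulate(label_map[label_map > 0L], nbins = n_areas)
  if (any(counts == 0L))
    stop("atlas degenerate: some areas received no pixels; use a larger grid")
  structure(
    list(label_map = label_map, area_names = area_names,
         pixel_size_um = pixel_size_um, centers = centers),
    class = "area_atlas")
}

#' @export
print.area_atlas <- function(x, ...) {
  counts <- tabulate(x$label_map[x$label_map > 0L], nbins = length(x$area_names))
  cat(sprintf("area_atlas: %d x %d grid (%g um/px), %d areas\n",
              nrow(x$label_map), ncol(x$label_map), x$pixel_size_um,
              length(x$area_names)))
  cat(paste(sprintf("%s=%d", x$area_names, counts), collapse = " "), "\n")
  invisible(x)
}

#' Number of labeled pixels in an atlas
#' @param atlas an `area_atlas`.
#' @return integer count of in-window pixels.
#' @export
n_window_pixels <- function(atlas) sum(atlas$label_map > 0L)

#' Seeding masks with exponential localization penalty
#'
#' For each area the seeding distance field is D = 1 on the area's own
#' pixels and exp(-dist / decay_length) outside, where dist is the Euclidean
#' distance (in pixels) to the nearest pixel of the area. The localization
#' penalty applied during the factorization is 1 - D, so it vanishes inside
#' the seed region and saturates far away.
#'
#' @param atlas an `area_atlas`.
#' @param decay_length e-folding length of the decay, in pixels. The default
#'   (`NULL`) uses 15% of the mean equivalent area diameter, approximately
#'   matching the spatial correlation length of the smooth signals the
#'   generator plants.
#' @return list of `seed_mask` objects, one per area, each with `area_id`,
#'   `D` (vector over in-window pixels), `penalty` (= 1 - D), and `support`
#'   (logical, D > 0.5).
#' @export
make_seed_masks <- function(atlas, decay_length = NULL) {
  lab <- atlas$label_map
  nx <- nrow(lab); ny <- ncol(lab)
  inwin <- which(lab > 0L)
  px <- cbind((inwin - 1L) %% nx + 1L, (inwin - 1L) %/% nx + 1L)
  n_areas <- length(atlas$area_names)
  if (is.null(decay_length)) {
    mean_area <- mean(tabulate(lab[inwin], nbins = n_areas))
    decay_length <- 0.15 * 2 * sqrt(mean_area / pi)
  }
  stopifnot(decay_length > 0)
  lapply(seq_len(n_areas), function(a) {
    own <- lab[inwin] == a
    apx <- px[own, , drop = FALSE]
    # min distance from every in-window pixel to the area's pixel set
    d <- sqrt(.min_dist2(px, apx))
    D <- exp(-d / decay_length)
    D[own] <- 1
    structure(list(area_id = a, area_name = atlas$area_names[a],
                   D = D, penalty = 1 - D, support = D > 0.5,
                   decay_length = decay_length),
              class = "seed_mask")
  })
}

# squared min distance from each row of p to the point set q, chunked to
# bound memory on large grids
.min_dist2 <- function(p, q) {
  n <- nrow(p)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / max(1L, nrow(q))))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    blk <- p[i:j, , drop = FALSE]
    d2 <- outer(blk[, 1], q[, 1], "-")^2 + outer(blk[, 2], q[, 2], "-")^2
    out[i:j] <- apply(d2, 1L, min)
    i <- j + 1L
  }
  out
}
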