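# shared fixtures, built once per test session
.fx <- new.env(parent = emptyenv())

small_atlas <- function(n = 40L, seed = 2L) {
  key <- sprintf("atlas_%d_%d", n, seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- make_area_atlas(n, n, seed = seed)
  .fx[[key]]
}

# a moderately sized synthetic session reused across axes/geometry tests
shared_sim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- simulate_session(small_atlas(), n_trials = 240L, seed = 11L)
  .fx$sim
}

# its decomposition (fixed generative rank)
shared_decomp <- function() {
  if (is.null(.fx$dec))
    .fx$dec <- loca_nmf(shared_sim()$session, rank_per_area = 2L,
                        svd_ev = 0.9)
  .fx$dec
}

# two Gaussian clouds in K-dim component space separated by `delta` along a
# direction `u` (defaults to a random unit vector), unit isotropic noise;
# returns the component array and a balanced pair over all frames
gaussian_pair <- function(K = 10L, delta = 1, n_per_group = 200L,
                          n_frames = 6L, seed = 1L, u = NULL) {
  with_seed(seed, {
    if (is.null(u)) u <- unitize(stats::rnorm(K))
    n <- 2L * n_per_group
    carray <- array(stats::rnorm(K * n_frames * n), dim = c(K, n_frames, n))
    shift <- outer(u * (delta / 2), rep(1, n_frames))
    for (i in seq_len(n_per_group)) {
      carray[, , i] <- carray[, , i] + shift
      carray[, , n_per_group + i] <- carray[, , n_per_group + i] - shift
    }
    pair <- manual_pair(seq_len(n_per_group),
                        n_per_group + seq_len(n_per_group),
                        win_frames = seq_len(n_frames), seed = seed)
    list(carray = carray, pair = pair, u = u)
  })
}
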