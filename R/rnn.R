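#' Configuration of the recurrent decision model
#'
#' A single recurrent layer of `n_units` ReLU neurons receives 3 input
#' channels (left stimulus, right stimulus, binary attention) over
#' `n_frames` frames; its output sequence passes through a batch
#' normalization layer and a dense softmax head with three classes
#' (left, right, no-choice). Training uses the Adam optimizer and a loss
#' consisting of the categorical cross-entropy at the stimulus-presentation
#' frame (target no-choice) plus at the final frame (target the simulated
#' choice).
#'
#' @param n_units recurrent units.
#' @param n_frames frames per trial.
#' @param stim_onset_frame last pre-stimulus frame; stimulus channels are
#'   nonzero from the next frame on, and the no-choice loss is applied
#'   here.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param input_noise_sd SD of the Gaussian noise added to the stimulus
#'   channels at every frame.
#' @param grad_clip global gradient-norm clip.
#' @return list of class `rnn_config`.
#' @export
rnn_config <- function(n_units = 50L, n_frames = 25L,
                       stim_onset_frame = 10L, epochs = 25L,
                       batch_size = 640L, learning_rate = 2e-3,
                       input_noise_sd = 0.1, grad_clip = 5) {
  stopifnot(n_units > 0L, n_frames > 0L, stim_onset_frame < n_frames,
            epochs > 0L, batch_size > 0L)
  structure(list(n_units = as.integer(n_units),
                 n_frames = as.integer(n_frames),
                 stim_onset_frame = as.integer(stim_onset_frame),
                 n_inputs = 3L, n_outputs = 3L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 input_noise_sd = input_noise_sd, grad_clip = grad_clip,
                 bn_eps = 1e-5, bn_momentum = 0.99),
            class = "rnn_config")
}

#' Generate an input/target dataset for the decision model
#'
#' Trials are laid out as 25-frame sequences with three channels. Stimulus
#' channels are zero (noise only) through the first `stim_onset_frame`
#' frames, then constant at angle/90 (so -90..+90 degrees maps to -1..+1);
#' Gaussian noise of SD `input_noise_sd` is added to both stimulus channels
#' at every frame. The attention channel is a noiseless constant 0 (low) or
#' 1 (high). Simulated choices are drawn from the lapse-logistic
#' psychometric generator with the attention-dependent slope; targets are
#' the no-choice class (0,0,1) at the stimulus-presentation frame and the
#' choice class (1,0,0)/(0,1,0) at the final frame.
#'
#' @param params a [psychometric_params()].
#' @param n_per_level trials per difficulty level and attention state.
#' @param difficulties signed angle differences (degrees, within
#'   \[-90, 90\]).
#' @param attention_states subset of `c("low", "high")`.
#' @param config an [rnn_config()].
#' @param seed integer seed.
#' @return list with `X` (trials x 3 x frames input array), `meta`
#'   (data.frame: theta, attention, choice, p_left), and `config`.
#' @export
make_rnn_dataset <- function(params = psychometric_params(),
                             n_per_level = 640L,
                             difficulties = difficulty_grid(),
                             attention_states = c("low", "high"),
                             config = rnn_config(), seed = 1L) {
  stopifnot(all(abs(difficulties) <= 90), n_per_level >= 1L)
  attention_states <- match.arg(attention_states, c("low", "high"),
                                several.ok = TRUE)
  grid <- expand.grid(theta = difficulties, attention = attention_states,
                      stringsAsFactors = FALSE)
  theta <- rep(grid$theta, each = n_per_level)
  attn <- rep(grid$attention, each = n_per_level)
  n <- length(theta)
  Tn <- config$n_frames; f_on <- config$stim_onset_frame
  with_seed(seed, {
    base <- sample(c(-45, 45), n, replace = TRUE)
    left_angle <- theta / 2 + base
    right_angle <- left_angle - theta
    alpha <- ifelse(attn == "high", params$slope_high, params$slope_low)
    p_left <- stats::plogis(alpha * theta) * (1 - params$lapse) +
      params$lapse / 2
    chose_left <- stats::runif(n) < p_left
    X <- array(0, dim = c(n, 3L, Tn))
    stim_frames <- (f_on + 1L):Tn
    X[, 1L, stim_frames] <- rep(left_angle / 90, times = length(stim_frames))
    X[, 2L, stim_frames] <- rep(right_angle / 90, times = length(stim_frames))
    X[, 1L, ] <- X[, 1L, ] + stats::rnorm(n * Tn, sd = config$input_noise_sd)
    X[, 2L, ] <- X[, 2L, ] + stats::rnorm(n * Tn, sd = config$input_noise_sd)
    X[, 3L, ] <- rep(as.numeric(attn == "high"), times = Tn)
    meta <- data.frame(theta = theta, attention = attn,
                       choice = ifelse(chose_left, "left", "right"),
                       p_left = p_left, stringsAsFactors = FALSE)
    list(X = X, meta = meta, config = config)
  })
}

#' Build an untrained recurrent decision model
#'
#' Vanilla (Elman) recurrent layer with ReLU activations, batch
#' normalization on the hidden sequence, and a dense 3-class softmax head.
#' The recurrent matrix uses the standard orthogonal initialization for
#' recurrent layers, which keeps ReLU recurrence stable.
#'
#' @param config an [rnn_config()].
#' @param seed integer seed for the weight initialization.
#' @return object of class `rnn_model`.
#' @export
build_rnn <- function(config = rnn_config(), seed = 1L) {
  N <- config$n_units; ni <- config$n_inputs; no <- config$n_outputs
  with_seed(seed, {
    gx <- sqrt(6 / (ni + N)); go <- sqrt(6 / (N + no))
    qr_ <- qr(matrix(stats::rnorm(N * N), N, N))
    ortho <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    w <- list(
      Wx = matrix(stats::runif(ni * N, -gx, gx), ni, N),
      Wh = ortho,
      bh = numeric(N),
      gamma = rep(1, N), beta = numeric(N),
      Wo = matrix(stats::runif(N * no, -go, go), N, no),
      bo = numeric(no))
    structure(list(weights = w, config = config,
                   bn_mean = numeric(N), bn_var = rep(1, N),
                   adam = NULL, trained = FALSE),
              class = "rnn_model")
  })
}

#' Number of trainable parameters of the model
#' @param model an `rnn_model`.
#' @return integer parameter count (input, recurrent and output weights,
#'   biases, and the batch-norm scale/shift).
#' @export
n_rnn_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

# forward pass. X: [B, 3, T]. Returns hidden sequence, batch-norm cache and
# softmax outputs; `train` selects batch statistics vs running statistics.
rnn_forward <- function(model, X, train = FALSE) {
  w <- model$weights; cfg <- model$config
  B <- dim(X)[1]; Tn <- dim(X)[3]; N <- cfg$n_units
  H <- array(0, dim = c(B, N, Tn))
  h <- matrix(0, B, N)
  for (tt in seq_len(Tn)) {
    a <- X[, , tt] %*% w$Wx + h %*% w$Wh +
      matrix(w$bh, B, N, byrow = TRUE)
    h <- pmax(a, 0)
    H[, , tt] <- h
  }
  Hm <- matrix(aperm(H, c(1, 3, 2)), B * Tn, N)   # samples x units
  if (train) {
    mu <- colMeans(Hm)
    vv <- colMeans(Hm^2) - mu^2
  } else {
    mu <- model$bn_mean; vv <- model$bn_var
  }
  std <- sqrt(vv + cfg$bn_eps)
  Xhat <- sweep(sweep(Hm, 2L, mu), 2L, std, "/")
  Z <- sweep(sweep(Xhat, 2L, w$gamma, "*"), 2L, w$beta, "+")
  logits <- Z %*% w$Wo + matrix(w$bo, nrow(Z), length(w$bo), byrow = TRUE)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  P <- el / rowSums(el)
  probs <- aperm(array(P, dim = c(B, Tn, 3L)), c(1, 3, 2))
  list(H = H, Xhat = Xhat, mu = mu, var = vv, std = std,
       probs = probs, P_flat = P, B = B, Tn = Tn)
}

# index into the flattened (B*T) x N batch-norm layout
.flat_idx <- function(B, frame) (frame - 1L) * B + seq_len(B)

# one Adam gradient step on a batch; returns updated model and batch loss
.rnn_step <- function(model, Xb, target_choice_left, lr) {
  w <- model$weights; cfg <- model$config
  fw <- rnn_forward(model, Xb, train = TRUE)
  B <- fw$B; Tn <- fw$Tn; N <- cfg$n_units
  f_stim <- cfg$stim_onset_frame
  # targets: class 3 (no-choice) at stimulus frame, class 1/2 at end
  Yst <- matrix(0, B, 3L); Yst[, 3L] <- 1
  Yend <- matrix(0, B, 3L)
  Yend[cbind(seq_len(B), ifelse(target_choice_left, 1L, 2L))] <- 1

  i_st <- .flat_idx(B, f_stim); i_end <- .flat_idx(B, Tn)
  P_st <- fw$P_flat[i_st, , drop = FALSE]
  P_end <- fw$P_flat[i_end, , drop = FALSE]
  loss <- -(sum(log(pmax(P_st[, 3L], 1e-12))) +
              sum(log(pmax(P_end[cbind(seq_len(B),
                                       ifelse(target_choice_left, 1L, 2L))],
                           1e-12)))) / B
  if (!is.finite(loss)) stop("divergent loss")

  dlog <- matrix(0, B * Tn, 3L)
  dlog[i_st, ] <- (P_st - Yst) / B
  dlog[i_end, ] <- (P_end - Yend) / B
  Zin <- sweep(sweep(fw$Xhat, 2L, w$gamma, "*"), 2L, w$beta, "+")
  gWo <- crossprod(Zin, dlog)
  gbo <- colSums(dlog)
  dZ <- dlog %*% t(w$Wo)
  ggamma <- colSums(dZ * fw$Xhat)
  gbeta <- colSums(dZ)
  # batch-norm backward (statistics over all B*T samples per unit)
  dXhat <- sweep(dZ, 2L, w$gamma, "*")
  m <- nrow(dXhat)
  s1 <- colSums(dXhat); s2 <- colSums(dXhat * fw$Xhat)
  dH_flat <- sweep(
    dXhat - matrix(s1 / m, m, N, byrow = TRUE) -
      fw$Xhat * matrix(s2 / m, m, N, byrow = TRUE),
    2L, fw$std, "/")
  dH <- aperm(array(dH_flat, dim = c(B, Tn, N)), c(1, 3, 2))

  gWx <- matrix(0, cfg$n_inputs, N); gWh <- matrix(0, N, N)
  gbh <- numeric(N)
  dh_next <- matrix(0, B, N)
  for (tt in rev(seq_len(Tn))) {
    dh <- dH[, , tt] + dh_next
    da <- dh * (fw$H[, , tt] > 0)
    h_prev <- if (tt > 1L) fw$H[, , tt - 1L] else matrix(0, B, N)
    gWx <- gWx + crossprod(Xb[, , tt], da)
    gWh <- gWh + crossprod(h_prev, da)
    gbh <- gbh + colSums(da)
    dh_next <- da %*% t(w$Wh)
  }
  grads <- list(Wx = gWx, Wh = gWh, bh = gbh, gamma = ggamma, beta = gbeta,
                Wo = gWo, bo = gbo)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (gn > cfg$grad_clip)
    grads <- lapply(grads, function(g) g * cfg$grad_clip / gn)

  if (is.null(model$adam))
    model$adam <- list(m = lapply(grads, function(g) g * 0),
                       v = lapply(grads, function(g) g * 0), t = 0L)
  ad <- model$adam
  ad$t <- ad$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    ad$m[[nm]] <- b1 * ad$m[[nm]] + (1 - b1) * grads[[nm]]
    ad$v[[nm]] <- b2 * ad$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- ad$m[[nm]] / (1 - b1^ad$t)
    vhat <- ad$v[[nm]] / (1 - b2^ad$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- ad
  model$weights <- w
  mom <- cfg$bn_momentum
  model$bn_mean <- mom * model$bn_mean + (1 - mom) * fw$mu
  model$bn_var <- mom * model$bn_var + (1 - mom) * fw$var
  acc <- mean(max.col(fw$P_flat[i_end, , drop = FALSE]) ==
                ifelse(target_choice_left, 1L, 2L))
  list(model = model, loss = loss, acc = acc)
}

#' Train the recurrent decision model
#'
#' Minimizes the two-frame categorical cross-entropy (no-choice at the
#' stimulus frame, simulated choice at the final frame) with Adam.
#' Training accuracy is the categorical accuracy at the end of the trial
#' against the (stochastic) simulated choices, so it converges to the
#' generator's label consistency rather than to 1.
#'
#' @param model an `rnn_model` from [build_rnn()].
#' @param dataset from [make_rnn_dataset()].
#' @param epochs,batch_size,learning_rate override the model's config.
#' @param lr_schedule `"cosine"` decays the learning rate from its peak to
#'   1/20 of it over the epochs (stabilizes the final representation
#'   geometry at small training-set sizes); `"constant"` keeps it fixed.
#' @param seed integer seed for batch shuffling.
#' @param verbose print per-epoch loss/accuracy.
#' @return the trained model, with `history` (per-epoch data.frame) and
#'   `trained = TRUE`.
#' @export
train_rnn <- function(model, dataset, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL,
                      lr_schedule = c("cosine", "constant"),
                      seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr0 <- learning_rate %||% cfg$learning_rate
  X <- dataset$X
  left <- dataset$meta$choice == "left"
  n <- dim(X)[1]
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  rng <- local_rng(seed)
  for (ep in seq_len(epochs)) {
    lr <- if (lr_schedule == "cosine" && epochs > 1L)
      lr0 / 20 + (lr0 - lr0 / 20) * 0.5 *
        (1 + cos(pi * (ep - 1) / (epochs - 1)))
    else lr0
    ord <- rng$sample(n)
    losses <- c(); accs <- c()
    i <- 1L
    while (i <= n) {
      j <- min(n, i + batch_size - 1L)
      idx <- ord[i:j]
      st <- .rnn_step(model, X[idx, , , drop = FALSE], left[idx], lr)
      model <- st$model
      losses <- c(losses, st$loss); accs <- c(accs, st$acc)
      i <- j + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   accuracy = mean(accs)))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, end-accuracy %.3f",
                      ep, mean(losses), mean(accs)))
  }
  # freeze inference batch-norm statistics on the full training set (the
  # exponential running average is biased after short schedules)
  s1 <- numeric(cfg$n_units); s2 <- numeric(cfg$n_units); m <- 0
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    fw <- rnn_forward(model, X[i:j, , , drop = FALSE], train = TRUE)
    Hm <- matrix(aperm(fw$H, c(1, 3, 2)), length(i:j) * cfg$n_frames,
                 cfg$n_units)
    s1 <- s1 + colSums(Hm); s2 <- s2 + colSums(Hm^2); m <- m + nrow(Hm)
    i <- j + 1L
  }
  model$bn_mean <- s1 / m
  model$bn_var <- pmax(s2 / m - (s1 / m)^2, 0)
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Evaluate the model on a dataset
#'
#' Runs the forward pass in inference mode (frozen batch-norm statistics)
#' and extracts the hidden-unit traces and the network's choices. The
#' model's continuous output determines the choice: by default the larger
#' of the left/right softmax probabilities at the final frame; with
#' `sample_choices = TRUE` the choice is instead drawn from that
#' probability, reproducing lapse-like stochastic responding.
#'
#' @param model a trained `rnn_model`.
#' @param dataset from [make_rnn_dataset()].
#' @param sample_choices draw choices from the softmax instead of taking
#'   the maximum.
#' @param seed integer seed for sampled choices.
#' @return object of class `rnn_trace`: `hidden` (units x frames x trials),
#'   `probs` (trials x 3 x frames), `p_left` (left probability among L/R at
#'   the final frame), `choice`, `meta`.
#' @export
rnn_trace <- function(model, dataset, sample_choices = FALSE, seed = 1L) {
  fw <- rnn_forward(model, dataset$X, train = FALSE)
  Tn <- model$config$n_frames
  p_end <- fw$probs[, , Tn]
  p_left <- p_end[, 1L] / (p_end[, 1L] + p_end[, 2L])
  choice <- if (sample_choices)
    with_seed(seed, ifelse(stats::runif(length(p_left)) < p_left,
                           "left", "right"))
  else ifelse(p_left > 0.5, "left", "right")
  structure(list(hidden = aperm(fw$H, c(2, 3, 1)), probs = fw$probs,
                 p_left = p_left, choice = choice, meta = dataset$meta,
                 config = model$config),
            class = "rnn_trace")
}

#' Psychometric curve of a trained model
#'
#' Fraction of left responses per signed angle difference and attention
#' level, from freshly generated noisy inputs (the evaluation grid may
#' include difficulties and attention levels never seen in training).
#'
#' @param model a trained `rnn_model`.
#' @param theta_grid signed angle differences (degrees).
#' @param attention_levels numeric attention channel levels (0 = low,
#'   1 = high; intermediate values probe generalization).
#' @param n_trials trials per grid point.
#' @param seed integer seed.
#' @return data.frame with theta, attention_level, p_left.
#' @export
rnn_psychometric <- function(model, theta_grid = difficulty_grid(),
                             attention_levels = c(0, 1), n_trials = 200L,
                             seed = 1L) {
  cfg <- model$config
  out <- NULL
  for (al in attention_levels) {
    grid <- expand.grid(theta = theta_grid)
    theta <- rep(grid$theta, each = n_trials)
    n <- length(theta)
    X <- with_seed(seed + round(1000 * al), {
      base <- sample(c(-45, 45), n, replace = TRUE)
      la <- theta / 2 + base; ra <- la - theta
      Tn <- cfg$n_frames
      X <- array(0, dim = c(n, 3L, Tn))
      sf <- (cfg$stim_onset_frame + 1L):Tn
      X[, 1L, sf] <- rep(la / 90, times = length(sf))
      X[, 2L, sf] <- rep(ra / 90, times = length(sf))
      X[, 1L, ] <- X[, 1L, ] + stats::rnorm(n * Tn, sd = cfg$input_noise_sd)
      X[, 2L, ] <- X[, 2L, ] + stats::rnorm(n * Tn, sd = cfg$input_noise_sd)
      X[, 3L, ] <- al
      X
    })
    fw <- rnn_forward(model, X, train = FALSE)
    p_end <- fw$probs[, , cfg$n_frames]
    # expected fraction of left responses = softmax left probability
    agg <- tapply(p_end[, 1L] / (p_end[, 1L] + p_end[, 2L]), theta, mean)
    out <- rbind(out, data.frame(theta = as.numeric(names(agg)),
                                 attention_level = al,
                                 p_left = as.numeric(agg)))
  }
  out
}

#' Build a balanced group pair directly from trial index sets
#'
#' Low-level constructor for analyses on arbitrary component arrays (for
#' example the recurrent model's hidden units, where frames are the
#' clock): both groups are aligned at frame 0 and the window is given as
#' absolute frame indices. The larger group is subsampled to the size of
#' the smaller one.
#'
#' @param ids_A,ids_B trial indices of the two groups.
#' @param win_frames frame indices of the analysis window.
#' @param fs frame rate used to express times (default 1 = frames).
#' @param variable label for the pair.
#' @param seed integer seed for the balancing subsample.
#' @return a `trial_group_pair`.
#' @export
manual_pair <- function(ids_A, ids_B, win_frames, fs = 1, variable = "choice",
                        seed = 1L) {
  if (length(ids_A) == 0L || length(ids_B) == 0L)
    stop("empty group for variable '", variable, "'")
  rng <- local_rng(seed)
  n <- min(length(ids_A), length(ids_B))
  if (length(ids_A) > n) ids_A <- sort(ids_A[rng$sample(length(ids_A), n)])
  if (length(ids_B) > n) ids_B <- sort(ids_B[rng$sample(length(ids_B), n)])
  structure(list(variable = variable, trials_A = ids_A, trials_B = ids_B,
                 align_A = rep(0L, n), align_B = rep(0L, n),
                 window = range(win_frames) / fs, win_frames = win_frames,
                 fs = fs, n_per_group = n),
            class = "trial_group_pair")
}

#' State-axis analysis of the model's hidden units
#'
#' Applies the population axes machinery to the 50 hidden-unit time series
#' exactly as to imaging components: per difficulty level (|theta|) a
#' choice state axis is computed from the network's own left/right choices
#' in the post-stimulus window, and per attention state likewise; pairwise
#' angles between the per-difficulty axes and cross-validated d' per
#' difficulty and attention are returned.
#'
#' @param trace an [rnn_trace()].
#' @param win_frames absolute frame window for the axes (default: from two
#'   frames after stimulus onset to the last frame).
#' @param difficulties difficulty levels (|theta|) to analyze. The default
#'   uses the trained nonzero levels: at zero evidence the response is
#'   unrelated to the stimulus (and, for sampled choices, to the network
#'   state), so no choice axis is defined there, mirroring the behavioral
#'   task whose hardest condition is a small but nonzero orientation
#'   difference.
#' @param cv_folds,train_frac,seed cross-validation settings (see
#'   [dprime_curve()]).
#' @return list with `difficulty_axes` (named list of unit K-vectors),
#'   `angles` (`angle_stats` matrix across difficulty levels),
#'   `attention_axes`, `attention_angle` (degrees, high vs low),
#'   `dprime` (data.frame: difficulty, attention, mean held-out |d'|).
#' @export
rnn_state_axes <- function(trace, win_frames = NULL, difficulties = NULL,
                           cv_folds = 5L, train_frac = 0.2, seed = 1L) {
  stopifnot(inherits(trace, "rnn_trace"))
  cfg <- trace$config
  if (is.null(win_frames))
    win_frames <- (cfg$stim_onset_frame + 2L):cfg$n_frames
  H <- trace$hidden
  meta <- trace$meta
  choice <- trace$choice
  diffs <- difficulties %||%
    setdiff(sort(unique(abs(meta$theta))), 0)

  pair_for <- function(sel, tag, s) {
    manual_pair(which(sel & choice == "right"),
                which(sel & choice == "left"),
                win_frames, fs = 1, variable = tag, seed = s)
  }
  difficulty_axes <- list()
  for (d in diffs) {
    p <- pair_for(abs(meta$theta) == d, paste0("choice_d", d), seed)
    difficulty_axes[[sprintf("d%g", d)]] <-
      state_axis(H, p, window = TRUE)$weights
  }
  angles <- axis_angle_matrix(difficulty_axes)

  attention_axes <- list()
  att_states <- unique(meta$attention)
  for (a in att_states) {
    p <- pair_for(meta$attention == a, paste0("choice_", a), seed + 1L)
    attention_axes[[a]] <- state_axis(H, p, window = TRUE)$weights
  }
  attention_angle <- if (length(attention_axes) == 2L)
    axis_angle(attention_axes[[1]], attention_axes[[2]]) else NA_real_

  dp <- NULL
  for (a in att_states) for (d in diffs) {
    sel <- meta$attention == a & abs(meta$theta) == d
    p <- try(pair_for(sel, "choice", seed + 2L), silent = TRUE)
    if (inherits(p, "try-error") || p$n_per_group < 10L) next
    cur <- dprime_curve(H, p, cv_folds = cv_folds, train_frac = train_frac,
                        seed = seed, window = TRUE)
    dp <- rbind(dp, data.frame(difficulty = d, attention = a,
                               dprime = mean(abs(cur$dprime))))
  }
  list(difficulty_axes = difficulty_axes, angles = angles,
       attention_axes = attention_axes, attention_angle = attention_angle,
       dprime = dp)
}
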