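#' Loss decomposition for the RNN objective
#'
#' The training objective is `E = E_task + alpha * R_L2 + beta * R_FR`,
#' where `E_task` is the squared output error averaged over trials, time
#' and readout units, `R_L2 = mean(B^2) + mean(W^2)` penalizes input and
#' output weights (per-element means, so the penalty scale is independent
#' of network size), and `R_FR = mean(r^2) * dt` (mean over trials, time
#' and units) is the metabolic penalty on rates.
#'
#' @param z Readout array, trials x time x N_out.
#' @param targets Target array of the same shape.
#' @param params An `rnn_params` (supplies `B`, `W` and the regime unless
#'   `regime` is given).
#' @param regime Optional [constraint_regime()] override.
#' @param rates Optional rate array (trials x time x N) for `R_FR`;
#'   `R_FR = 0` when omitted.
#' @param dt Time step in tau units (default 0.1).
#' @return A list of class `loss_breakdown`: `E_task`, `R_L2`, `R_FR`, `E`,
#'   `M`, `T`.
#' @export
compute_loss <- function(z, targets, params, regime = params$regime,
                         rates = NULL, dt = 0.1) {
  if (!identical(dim(z), dim(targets))) stop("shape mismatch: z vs targets")
  e_task <- mean((z - targets)^2)
  r_l2 <- mean(params$B^2) + mean(params$W^2)
  r_fr <- if (is.null(rates)) 0 else mean(rates^2) * dt
  structure(list(
    E_task = e_task, R_L2 = r_l2, R_FR = r_fr,
    E = e_task + regime$alpha * r_l2 + regime$beta * r_fr,
    M = dim(z)[1], T = dim(z)[2]),
    class = "loss_breakdown")
}

#' Train an RNN on delay TI
#'
#' Adam + backpropagation through time on batches of 128 trials sampled
#' uniformly from the adjacent-pair (training) trial types, respecting the
#' variant's trainability mask. Training stops when the noise-free network
#' responds correctly on all 42 trial types (for the variable delay
#' variant, additionally with the item-2 pulse advanced by 67% of the
#' longest delay), when batch `E_task` drops below `etask_stop`, or at
#' `max_epochs`.
#'
#' @param params An `rnn_params` from [init_network()].
#' @param panel Item panel matching `N_in`.
#' @param timing A [ti_timing()]; its `delay_variant` selects the input
#'   format (variable-delay batches draw a fresh delay per trial).
#' @param seed Integer seed for batch sampling and training noise.
#' @param noise_sd Intrinsic noise during training (default 0.2).
#' @param batch_size Trials per parameter update (default 128).
#' @param max_epochs Maximum number of updates (default 30000).
#' @param lr Adam learning rate (default 1e-3).
#' @param etask_stop Task-loss stopping threshold (default 0.1).
#' @param eval_every Epoch interval of the noise-free all-correct check.
#' @param z_active Activated target value (default 5).
#' @param threshold Response threshold on the saturated readout (0.85).
#' @return A list of class `training_report`: the trained `params`,
#'   `epochs`, `stop_reason` (`"all-correct"`, `"task-loss"` or
#'   `"epoch-cap"`), loss traces, and the noise-free `generalization`
#'   table from [evaluate_generalization()].
#' @export
train_rnn <- function(params, panel, timing = ti_timing(), seed = 1L,
                      noise_sd = 0.2, batch_size = 128L,
                      max_epochs = 30000L, lr = 1e-3, etask_stop = 0.1,
                      eval_every = 1L, z_active = 5, threshold = 0.85) {
  stopifnot(inherits(params, "rnn_params"))
  tt <- enumerate_trial_types(panel$n_items)
  train_tt <- tt[tt$is_training, ]
  # evaluation sets: all 42 types at the analysis delay (max for variable)
  eval_timing <- analysis_timing(timing)
  eval_sets <- list(trial_spec(tt, eval_timing))
  if (timing$delay_variant == "variable") {
    # item-2 pulse advanced by 67% of the longest delay
    adv <- ti_timing("variable", dt = timing$dt,
                     delay_steps = as.integer(round(
                       timing$delay_lim[2] * (1 - 0.67))))
    eval_sets <- c(eval_sets, list(trial_spec(tt, adv)))
  }
  p2rng <- if (timing$delay_variant == "variable") {
    timing$pulse1 + timing$delay_lim + 1L
  } else rep(timing$pulse2, 2L)
  fit <- rnn_train_cpp(
    params$J, params$B, params$W, params$b, params$c, params$x0,
    t(panel$u),
    as.integer(train_tt$rank1 - 1L), as.integer(train_tt$rank2 - 1L),
    as.integer(train_tt$correct_choice == 1L),
    timing$pulse1, p2rng[1], p2rng[2], eval_timing$n_steps,
    eval_sets,
    unname(params$mask[c("J", "B", "W", "biases", "x0")]),
    timing$dt, params$regime$alpha, params$regime$beta,
    noise_sd, z_active, threshold,
    as.integer(batch_size), as.integer(max_epochs), lr, etask_stop,
    as.integer(eval_every), seed_from(seed))
  trained <- params
  for (nm in c("J", "B", "W", "b", "c", "x0")) trained[[nm]] <- fit[[nm]]
  trained$b <- drop(trained$b); trained$c <- drop(trained$c)
  trained$x0 <- drop(trained$x0)
  gen <- evaluate_generalization(trained, panel, timing = eval_timing,
                                 z_active = z_active, threshold = threshold)
  structure(list(
    params = trained, epochs = fit$epochs, stop_reason = fit$stop_reason,
    E_task_trace = fit$E_task_trace, E_trace = fit$E_trace,
    generalization = gen, seed = seed),
    class = "training_report")
}

# timing used for evaluation/analysis: variable-trained networks are
# analyzed at the maximum delay
analysis_timing <- function(timing) {
  if (timing$delay_variant == "variable") {
    tm <- ti_timing("variable", dt = timing$dt,
                    delay_steps = timing$delay_lim[2])
    tm$realized <- TRUE
    tm
  } else timing
}

#' Train a feedforward baseline on traditional TI
#'
#' Adam with cross-entropy loss on batches sampled from the 12 training
#' types, plus an L2 weight-decay penalty on all parameters (`0.1` for LR,
#' `0.001` for MLP by default). The LR is trained to convergence (no new
#' best loss for `patience` epochs); the MLP additionally stops as soon as
#' it responds correctly on all 42 types noise-free.
#'
#' @param params An `ff_params`.
#' @param panel Item panel.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty scale; default 0.1 (LR) / 0.001 (MLP).
#' @param batch_size Batch size (default 128).
#' @param max_epochs Epoch cap (default 20000).
#' @param patience Convergence patience in epochs (default 1000).
#' @return A `training_report` (with `loss_trace`).
#' @export
train_feedforward <- function(params, panel, seed = 1L, lr = 1e-3,
                              weight_decay = NULL, batch_size = 128L,
                              max_epochs = 20000L, patience = 1000L) {
  stopifnot(inherits(params, "ff_params"))
  if (is.null(weight_decay))
    weight_decay <- if (params$type == "LR") 0.1 else 0.001
  tt <- enumerate_trial_types(panel$n_items)
  train_tt <- tt[tt$is_training, ]
  U <- t(vapply(seq_len(nrow(train_tt)),
                function(i) build_traditional_input(panel, train_tt[i, ]),
                numeric(2 * panel$N_in)))          # 12 x 2N_in
  y <- train_tt$correct_choice                      # 1 or 2
  Uall <- t(vapply(seq_len(nrow(tt)),
                   function(i) build_traditional_input(panel, tt[i, ]),
                   numeric(2 * panel$N_in)))
  theta <- params[intersect(names(params),
                            c("A", "a0", "Win", "bh", "Wout"))]
  adam <- lapply(theta, function(p) list(m = p * 0, v = p * 0))
  stepn <- 0L
  best <- Inf; since <- 0L; trace <- numeric(0)
  stop_reason <- "epoch-cap"; epoch <- 0L
  withr_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(nrow(train_tt), batch_size, replace = TRUE)
      u <- t(U[idx, , drop = FALSE])               # d x M
      yb <- y[idx]
      gr <- ff_loss_grad(params, theta, u, yb, weight_decay)
      trace[epoch] <- gr$loss
      stepn <- stepn + 1L
      for (nm in names(theta)) {
        st <- adam[[nm]]
        st$m <- 0.9 * st$m + 0.1 * gr$grads[[nm]]
        st$v <- 0.999 * st$v + 0.001 * gr$grads[[nm]]^2
        mhat <- st$m / (1 - 0.9^stepn)
        vhat <- st$v / (1 - 0.999^stepn)
        theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        adam[[nm]] <- st
      }
      if (gr$loss < best - 1e-12) { best <- gr$loss; since <- 0L }
      else since <- since + 1L
      if (since >= patience) { stop_reason <- "converged"; break }
      if (params$type == "MLP") {
        pz <- ff_readout(utils::modifyList(params, theta), Uall)
        if (all((apply(pz, 1, which.max)) == tt$correct_choice)) {
          stop_reason <- "all-correct"; break
        }
      }
    }
  })
  trained <- utils::modifyList(params, theta)
  class(trained) <- "ff_params"
  gen <- evaluate_generalization(trained, panel)
  structure(list(params = trained, epochs = epoch, stop_reason = stop_reason,
                 loss_trace = trace, generalization = gen, seed = seed),
            class = "training_report")
}

ff_readout <- function(params, U) {
  simulate_feedforward(params, U, noise_sd = 0)
}

# cross-entropy + weight decay loss and analytic gradients, inputs u: d x M
ff_loss_grad <- function(params, theta, u, y, wd) {
  M <- ncol(u)
  onehot <- rbind(as.numeric(y == 1L), as.numeric(y == 2L))
  if (params$type == "LR") {
    z <- theta$A %*% u + theta$a0
    p <- apply(z, 2, function(col) exp(col - max(col)))
    p <- sweep(p, 2, colSums(p), "/")
    loss <- -mean(log(pmax(p[cbind(y, seq_len(M))], 1e-300)))
    dz <- (p - onehot) / M
    grads <- list(A = dz %*% t(u) + 2 * wd * theta$A,
                  a0 = rowSums(dz) + 2 * wd * theta$a0)
  } else {
    h <- tanh(theta$Win %*% u + theta$bh)
    z <- theta$Wout %*% h + theta$a0
    p <- apply(z, 2, function(col) exp(col - max(col)))
    p <- sweep(p, 2, colSums(p), "/")
    loss <- -mean(log(pmax(p[cbind(y, seq_len(M))], 1e-300)))
    dz <- (p - onehot) / M
    dh <- (t(theta$Wout) %*% dz) * (1 - h^2)
    grads <- list(Win = dh %*% t(u) + 2 * wd * theta$Win,
                  bh = rowSums(dh) + 2 * wd * theta$bh,
                  Wout = dz %*% t(h) + 2 * wd * theta$Wout,
                  a0 = rowSums(dz) + 2 * wd * theta$a0)
  }
  loss <- loss + wd * sum(vapply(theta, function(p) sum(p^2), numeric(1)))
  list(loss = loss, grads = grads)
}

#' Noise-free generalization evaluation
#'
#' Simulates all 42 trial types without noise and scores each with the
#' task's response rule (threshold crossing for RNNs, argmax for the
#' feedforward models). A "full generalizer" answers every type correctly;
#' a "memorizer" answers all 12 training types but not all test types.
#'
#' @param params `rnn_params` or `ff_params`.
#' @param panel Item panel.
#' @param timing Timing for RNNs (variable-delay networks are evaluated at
#'   the maximum delay).
#' @param z_active,threshold Response-rule constants (RNN only).
#' @return A list of class `generalization_table`: per-type data.frame
#'   (`responded`, `choice`, `correct`), `n_correct`, `n_training_correct`,
#'   `full_generalizer`, `memorizer`.
#' @export
evaluate_generalization <- function(params, panel, timing = ti_timing(),
                                    z_active = 5, threshold = 0.85) {
  tt <- enumerate_trial_types(panel$n_items)
  if (inherits(params, "rnn_params")) {
    timing <- analysis_timing(timing)
    ts <- trial_spec(tt, timing)
    dec <- rnn_decide_cpp(params$J, params$B, params$W, params$b, params$c,
                          params$x0, t(panel$u),
                          ts$item1, ts$item2, ts$p1, ts$p2, ts$T,
                          timing$dt, 0, z_active, threshold, 0)
    tt$responded <- dec$choice > 0L
    tt$choice <- ifelse(dec$choice > 0L, dec$choice, NA_integer_)
  } else {
    U <- t(vapply(seq_len(nrow(tt)),
                  function(i) build_traditional_input(panel, tt[i, ]),
                  numeric(2 * panel$N_in)))
    z <- ff_readout(params, U)
    tt$responded <- TRUE
    tt$choice <- apply(z, 1, which.max)
  }
  tt$correct <- tt$responded & tt$choice == tt$correct_choice
  n_corr <- sum(tt$correct)
  n_train <- sum(tt$correct & tt$is_training)
  structure(list(
    table = tt, n_correct = n_corr, n_training_correct = n_train,
    full_generalizer = n_corr == nrow(tt),
    memorizer = n_train == sum(tt$is_training) && n_corr < nrow(tt)),
    class = "generalization_table")
}
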