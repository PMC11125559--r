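#' Constraint regimes
#'
#' A constraint regime fixes the initial connectivity gains and the
#' regularization strengths of an RNN: `h0` (input gain), `g0` (recurrent
#' gain), `alpha` (L2 penalty on input/output weights) and `beta`
#' (metabolic penalty on rates). The five named regimes are:
#'
#' | name         | h0  | g0  | alpha | beta |
#' |--------------|-----|-----|-------|------|
#' | highest      | 1.0 | 0.5 | 1.0   | 1.0  |
#' | high         | 1.0 | 0.5 | 0.01  | 0.01 |
#' | intermediate | 1.0 | 1.0 | 0.01  | 0.01 |
#' | low          | 1.0 | 2.0 | 0     | 0    |
#' | lowest       | 1.5 | 4.0 | 0     | 0    |
#'
#' @param name Regime name.
#' @return List with `name`, `h0`, `g0`, `alpha`, `beta`.
#' @export
constraint_regime <- function(name = c("highest", "high", "intermediate",
                                       "low", "lowest")) {
  name <- match.arg(name)
  tab <- list(
    highest      = c(1.0, 0.5, 1.0, 1.0),
    high         = c(1.0, 0.5, 0.01, 0.01),
    intermediate = c(1.0, 1.0, 0.01, 0.01),
    low          = c(1.0, 2.0, 0, 0),
    lowest       = c(1.5, 4.0, 0, 0))[[name]]
  list(name = name, h0 = tab[1], g0 = tab[2], alpha = tab[3], beta = tab[4])
}

rnn_variants <- c("f-RNN", "r-RNN", "ff-RNN", "r-RNN+W")

variant_mask <- function(variant) {
  switch(variant,
    "f-RNN"   = c(J = TRUE,  B = TRUE,  W = TRUE,  biases = TRUE, x0 = TRUE),
    "r-RNN"   = c(J = TRUE,  B = FALSE, W = FALSE, biases = TRUE, x0 = TRUE),
    "ff-RNN"  = c(J = FALSE, B = TRUE,  W = TRUE,  biases = TRUE, x0 = TRUE),
    "r-RNN+W" = c(J = TRUE,  B = FALSE, W = TRUE,  biases = TRUE, x0 = TRUE),
    stop("unknown variant: ", variant))
}

#' Initialize an RNN instance
#'
#' Recurrent weights `J` are drawn i.i.d. N(0, g0^2/N), input weights `B`
#' i.i.d. N(0, h0^2/N_in); the readout `W`, all biases and the initial
#' state `x0` start at 0, except that a frozen readout (r-RNN) keeps
#' i.i.d. N(0, h0^2/N) draws — frozen feedforward weights stay at their
#' initial random values. The trainability mask follows the variant:
#' `f-RNN` trains everything, `r-RNN` freezes `B` and `W`, `ff-RNN`
#' freezes `J`, and `r-RNN+W` freezes only `B`. Biases and `x0` are
#' trainable in all variants.
#'
#' @param variant One of `"f-RNN"`, `"r-RNN"`, `"ff-RNN"`, `"r-RNN+W"`.
#' @param regime A regime name or [constraint_regime()] list.
#' @param N Number of recurrent units (default 100).
#' @param N_in Input dimensionality (default 100).
#' @param N_out Number of readout units (default 3).
#' @param seed Integer seed for the weight draws.
#' @return An object of class `rnn_params`.
#' @export
init_network <- function(variant = "f-RNN", regime = "highest",
                         N = 100L, N_in = 100L, N_out = 3L, seed = 1L) {
  if (is.character(regime)) regime <- constraint_regime(regime)
  variant <- match.arg(variant, rnn_variants)
  mask <- variant_mask(variant)
  params <- withr_seed(seed, list(
    J = matrix(stats::rnorm(N * N, 0, regime$g0 / sqrt(N)), N, N),
    B = matrix(stats::rnorm(N * N_in, 0, regime$h0 / sqrt(N_in)), N, N_in),
    # a trainable readout starts at 0; a frozen one (r-RNN) keeps random
    # Gaussian draws, otherwise the network could never produce output
    W = if (mask[["W"]])
      matrix(0, N_out, N)
    else
      matrix(stats::rnorm(N_out * N, 0, regime$h0 / sqrt(N)), N_out, N),
    b = numeric(N), c = numeric(N_out), x0 = numeric(N)))
  structure(c(params, list(
    N = as.integer(N), N_in = as.integer(N_in), N_out = as.integer(N_out),
    variant = variant, regime = regime, mask = mask,
    seed = seed)),
    class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params> %s, %s regime, N=%d, N_in=%d, N_out=%d\n",
              x$variant, x$regime$name, x$N, x$N_in, x$N_out))
  invisible(x)
}

# trial-type table -> the integer vectors the C++ core wants (0-based items)
trial_spec <- function(trials, timing) {
  list(item1 = as.integer(trials$rank1 - 1L),
       item2 = as.integer(trials$rank2 - 1L),
       p1 = rep(timing$pulse1, nrow(trials)),
       p2 = rep(timing$pulse2, nrow(trials)),
       T = timing$n_steps,
       correct1 = as.integer(trials$correct_choice == 1L))
}

#' Simulate an RNN on a set of trial types
#'
#' Forward Euler integration of the rate network (`dt = tau/10` by
#' default). Per-unit Gaussian noise of the given s.d. is drawn at every
#' step and enters the right-hand side of the dynamics (the literal Euler
#' discretization of the model equation).
#'
#' @param params An `rnn_params`.
#' @param panel An `item_panel` with `N_in` matching the network.
#' @param trials Trial-type rows ([enumerate_trial_types()] subset); each
#'   row is simulated once (replicate rows for repeated stochastic trials).
#' @param timing A [ti_timing()].
#' @param noise_sd Intrinsic noise s.d. (0 = deterministic).
#' @param seed Seed for the noise stream.
#' @param return_state If `TRUE`, return the activity tensor.
#' @return A list of class `rnn_sim`: `z` (trials x time x 3 array),
#'   `x` (trials x time x N array or `NULL`), `trials`, `timing`.
#' @export
simulate_rnn <- function(params, panel, trials, timing = ti_timing(),
                         noise_sd = 0, seed = 1L, return_state = TRUE) {
  stopifnot(inherits(params, "rnn_params"), inherits(panel, "item_panel"))
  if (params$N_in != panel$N_in)
    stop("panel dimensionality does not match network N_in")
  ts <- trial_spec(trials, timing)
  out <- rnn_forward_cpp(params$J, params$B, params$W, params$b, params$c,
                         params$x0, t(panel$u),
                         ts$item1, ts$item2, ts$p1, ts$p2, ts$T,
                         timing$dt, noise_sd, return_state,
                         seed_from(seed))
  z <- aperm(out$Z, c(2, 3, 1))          # trials x time x N_out
  x <- NULL
  if (return_state) {
    x <- aperm(out$X[, , -1L, drop = FALSE], c(2, 3, 1))  # drop t=0 state
    if (!all(is.finite(x))) {
      bad <- which(apply(!is.finite(x), 2, any))[1]
      stop("divergence error: non-finite state at step ", bad)
    }
  }
  structure(list(z = z, x = x, trials = trials, timing = timing,
                 noise_sd = noise_sd),
            class = "rnn_sim")
}

# map an R seed (any integer) to a 64-bit stream seed for the C++ RNG
seed_from <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  if (s < 0) s <- s + 2147483647
  s
}

#' Initialize a feedforward baseline (LR or MLP)
#'
#' Both baselines take the traditional (simultaneous) input of length
#' `2 * N_in` and have two readouts (choice 1 and choice 2). The LR is a
#' linear readout pair initialized at zero. The MLP has one tanh hidden
#' layer of `N` units, input weights drawn i.i.d. N(0, h0^2 / (2 N_in))
#' with `h0 = 1`, readout weights and biases zero.
#'
#' @param type `"LR"` or `"MLP"`.
#' @param N_in Per-item input dimensionality (default 100).
#' @param N Hidden width for the MLP (default 100).
#' @param seed Integer seed.
#' @return An object of class `ff_params`.
#' @export
init_feedforward <- function(type = c("LR", "MLP"), N_in = 100L, N = 100L,
                             seed = 1L) {
  type <- match.arg(type)
  d <- 2L * N_in
  p <- if (type == "LR") {
    list(A = matrix(0, 2L, d), a0 = numeric(2L))
  } else {
    withr_seed(seed, list(
      Win = matrix(stats::rnorm(N * d, 0, 1 / sqrt(d)), N, d),
      bh = numeric(N),
      Wout = matrix(0, 2L, N), a0 = numeric(2L)))
  }
  structure(c(p, list(type = type, N_in = as.integer(N_in),
                      N = as.integer(N), seed = seed)),
            class = "ff_params")
}

#' Simulate a feedforward model
#'
#' Gaussian noise of the given s.d. is added to the readouts (LR) or to
#' the hidden-unit activities (MLP).
#'
#' @param params An `ff_params`.
#' @param input Flat input vector of length `2 * N_in`, or a matrix with
#'   one input per row.
#' @param noise_sd Noise s.d.
#' @param seed Seed for the noise stream.
#' @return Matrix of readouts (one row per input, columns choice 1/2).
#' @export
simulate_feedforward <- function(params, input, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "ff_params"))
  u <- if (is.matrix(input)) t(input) else matrix(input, ncol = 1L)
  if (nrow(u) != 2L * params$N_in) stop("input width must be 2 * N_in")
  M <- ncol(u)
  withr_seed(seed, {
    if (params$type == "LR") {
      z <- params$A %*% u + params$a0
      if (noise_sd > 0) z <- z + matrix(stats::rnorm(2 * M, 0, noise_sd), 2, M)
    } else {
      h <- tanh(params$Win %*% u + params$bh)
      if (noise_sd > 0)
        h <- h + matrix(stats::rnorm(params$N * M, 0, noise_sd), params$N, M)
      z <- params$Wout %*% h + params$a0
    }
    t(z)
  })
}
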