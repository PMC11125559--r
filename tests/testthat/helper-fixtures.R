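# Small fixtures shared across test files. Everything is generated in code;
# expensive artifacts are cached for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small trained full generalizer (desk-scale network, low regime trains
# in a few hundred epochs)
trained_small_rnn <- function() {
  memo("trained_small_rnn", {
    panel <- make_item_panel(N_in = 60L, seed = 401)
    net <- init_network("f-RNN", "low", N = 60L, N_in = 60L, seed = 402)
    rep <- train_rnn(net, panel, seed = 403, max_epochs = 4000,
                     eval_every = 10)
    list(panel = panel, report = rep, params = rep$params)
  })
}

# random rank-1-ish configurations for geometry property tests
random_config <- function(n = 7, d = 10) {
  matrix(rnorm(n * d), n, d)
}

random_orthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d)))
}

# brute-force geometry oracles: explicit loops, no linear-algebra shortcuts
bf_cos <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (k in seq_along(a)) {
    num <- num + a[k] * b[k]
    na <- na + a[k]^2
    nb <- nb + b[k]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

bf_collinearity <- function(states, xcm, ranks) {
  v <- list()
  for (i in ranks) v[[length(v) + 1]] <- states[i, ] - xcm
  tot <- 0; np <- 0
  for (i in seq_along(v)) for (j in seq_along(v)) {
    if (j > i) { tot <- tot + abs(bf_cos(v[[i]], v[[j]])); np <- np + 1 }
  }
  tot / np
}

bf_ordered <- function(states, xcm, high, low) {
  tot <- 0; np <- 0
  for (i in high) for (j in low) {
    tot <- tot + bf_cos(states[i, ] - xcm, states[j, ] - xcm)
    np <- np + 1
  }
  -tot / np
}

bf_mean_angle_change <- function(se, sl, xe, xl, ranks) {
  tot <- 0; np <- 0
  for (i in ranks) for (j in ranks) {
    if (j > i) {
      tot <- tot + bf_cos(sl[i, ] - xl, sl[j, ] - xl) -
                   bf_cos(se[i, ] - xe, se[j, ] - xe)
      np <- np + 1
    }
  }
  tot / np
}

bf_mean_distance_change <- function(se, sl, ranks) {
  tot <- 0; np <- 0
  for (i in ranks) for (j in ranks) {
    if (j > i) {
      dl <- sqrt(sum((sl[i, ] - sl[j, ])^2))
      de <- sqrt(sum((se[i, ] - se[j, ])^2))
      tot <- tot + dl - de
      np <- np + 1
    }
  }
  tot / np
}

# brute-force trial-type oracle: enumerate ordered pairs directly
bf_trial_counts <- function(n) {
  train <- 0; test <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (abs(i - j) == 1) train <- train + 1 else test <- test + 1
  }
  c(train = train, test = test)
}
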