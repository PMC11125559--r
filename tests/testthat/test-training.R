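test_that("loss decomposition matches the optimizer's objective", {
  panel <- make_item_panel(5, 8, seed = 1)
  tt <- enumerate_trial_types(5)
  tm <- ti_timing("basic")
  net <- init_network("f-RNN", "highest", N = 6, N_in = 8, seed = 2)
  net$W <- matrix(rnorm(18, 0, 0.2), 3, 6)
  ts <- delayti:::trial_spec(tt, tm)
  gr <- delayti:::rnn_loss_grad_cpp(
    net$J, net$B, net$W, net$b, net$c, net$x0, t(panel$u),
    ts$item1, ts$item2, ts$p1, ts$p2, ts$T, ts$correct1,
    0.1, net$regime$alpha, net$regime$beta, 5)
  # components recompose the total to 1e-10 relative error
  expect_lt(abs(gr$E - (gr$E_task + net$regime$alpha * gr$R_L2 +
                          net$regime$beta * gr$R_FR)) / gr$E, 1e-10)
  # and agree with the R-side computation on the same simulation
  sim <- simulate_rnn(net, panel, tt, tm, noise_sd = 0)
  targets <- array(0, dim(sim$z))
  for (i in seq_len(nrow(tt))) {
    targets[i, , ] <- build_trial_input(panel, tt[i, ], tm)$target
  }
  lb <- compute_loss(sim$z, targets, net, rates = tanh(sim$x))
  expect_equal(lb$E_task, gr$E_task, tolerance = 1e-10)
  expect_equal(lb$R_L2, gr$R_L2, tolerance = 1e-10)
  expect_equal(lb$R_FR, gr$R_FR, tolerance = 1e-10)
  # trivial cases
  expect_equal(compute_loss(targets, targets, net)$E_task, 0)
  expect_equal(compute_loss(targets + 1, targets, net)$E_task, 1)
  low <- compute_loss(sim$z, targets, net,
                      regime = constraint_regime("low"),
                      rates = tanh(sim$x))
  expect_identical(low$E, low$E_task)       # alpha = beta = 0
})

test_that("BPTT gradients match finite differences on a tiny network", {
  set.seed(42)
  N <- 7; Nin <- 5
  panel <- make_item_panel(4, Nin, seed = 3)
  net <- init_network("f-RNN", "high", N = N, N_in = Nin, seed = 5)
  net$J <- matrix(rnorm(N * N, 0, 0.3), N, N)
  net$W <- matrix(rnorm(3 * N, 0, 0.1), 3, N)
  net$b <- rnorm(N, 0, 0.1); net$c <- rnorm(3, 0, 0.1)
  net$x0 <- rnorm(N, 0, 0.1)
  tt <- enumerate_trial_types(4)
  ts <- delayti:::trial_spec(tt, ti_timing("basic"))
  loss_grad <- function(p) delayti:::rnn_loss_grad_cpp(
    p$J, p$B, p$W, p$b, p$c, p$x0, t(panel$u),
    ts$item1, ts$item2, ts$p1, ts$p2, ts$T, ts$correct1,
    0.1, 0.01, 0.01, 5)
  g <- loss_grad(net)
  h <- 1e-6
  blocks <- list(J = "gJ", B = "gB", W = "gW", b = "gb", c = "gc",
                 x0 = "gx0")
  for (blk in names(blocks)) {
    for (i in c(1L, min(3L, length(net[[blk]])))) {
      p1 <- net; p2 <- net
      p1[[blk]][i] <- p1[[blk]][i] + h
      p2[[blk]][i] <- p2[[blk]][i] - h
      num <- (loss_grad(p1)$E - loss_grad(p2)$E) / (2 * h)
      expect_equal(g[[blocks[[blk]]]][i], num, tolerance = 1e-4,
                   label = paste("grad", blk, i))
    }
  }
})

test_that("frozen parameter blocks never move during training", {
  panel <- make_item_panel(N_in = 30, seed = 6)
  cases <- list(
    list(variant = "r-RNN", frozen = c("B", "W"), moving = "J"),
    list(variant = "ff-RNN", frozen = "J", moving = "B"),
    list(variant = "r-RNN+W", frozen = "B", moving = c("J", "W")))
  for (cs in cases) {
    net <- init_network(cs$variant, "low", N = 20, N_in = 30, seed = 7)
    rep <- train_rnn(net, panel, seed = 8, max_epochs = 30,
                     eval_every = 100)
    for (blk in cs$frozen) {
      expect_identical(rep$params[[blk]], net[[blk]],
                       label = paste(cs$variant, blk, "frozen"))
    }
    for (blk in cs$moving) {
      expect_false(identical(rep$params[[blk]], net[[blk]]),
                   label = paste(cs$variant, blk, "trainable"))
    }
  }
})

test_that("stopping rules fire for the stated reasons", {
  panel <- make_item_panel(N_in = 20, seed = 9)
  net <- init_network("f-RNN", "low", N = 15, N_in = 20, seed = 10)
  # an absurdly high task-loss threshold stops at the first epoch
  rep <- train_rnn(net, panel, seed = 11, max_epochs = 100,
                   etask_stop = 100)
  expect_equal(rep$stop_reason, "task-loss")
  expect_equal(rep$epochs, 1L)
  expect_lt(rep$E_task_trace[rep$epochs], 100)
  # epoch cap
  rep2 <- train_rnn(net, panel, seed = 11, max_epochs = 5,
                    eval_every = 100)
  expect_equal(rep2$stop_reason, "epoch-cap")
  expect_equal(rep2$epochs, 5L)
  # variable-delay training runs with per-trial delays and evaluates at
  # the maximum delay (127-step trials)
  rep3 <- train_rnn(net, panel, ti_timing("variable"), seed = 12,
                    max_epochs = 3, eval_every = 100)
  expect_equal(rep3$stop_reason, "epoch-cap")
  expect_equal(nrow(rep3$generalization$table), 42L)
})

test_that("a desk-scale RNN trains to full generalization", {
  fx <- trained_small_rnn()
  expect_equal(fx$report$stop_reason, "all-correct")
  gen <- fx$report$generalization
  expect_true(gen$full_generalizer)
  expect_equal(gen$n_correct, 42L)
  expect_false(gen$memorizer)
  # an untrained network (W = 0) produces no responses at all
  net0 <- init_network("f-RNN", "low", N = 60, N_in = 60, seed = 99)
  gen0 <- evaluate_generalization(net0, fx$panel)
  expect_equal(sum(gen0$table$responded), 0L)
  expect_equal(gen0$n_correct, 0L)
})

test_that("feedforward training solves toy and full problems", {
  # linearly separable 2-item toy problem: zero training error
  panel2 <- make_item_panel(2, 10, seed = 12)
  lr <- init_feedforward("LR", N_in = 10)
  rep <- train_feedforward(lr, panel2, seed = 13, max_epochs = 3000,
                           patience = 200)
  expect_equal(rep$generalization$n_correct, 2L)
  # trained LR readout difference is antisymmetric under item swap
  panel <- make_item_panel(seed = 14)
  lr7 <- train_feedforward(init_feedforward("LR"), panel, seed = 15)
  tt <- enumerate_trial_types(7)
  U <- t(vapply(seq_len(nrow(tt)),
                function(i) build_traditional_input(panel, tt[i, ]),
                numeric(200)))
  z <- simulate_feedforward(lr7$params, U)
  d <- z[, 1] - z[, 2]
  m <- match(paste(tt$rank2, tt$rank1), paste(tt$rank1, tt$rank2))
  expect_lt(max(abs(d + d[m])) / max(abs(d)), 0.1)
})

test_that("the memorizer phenotype is represented distinctly", {
  # construct an LR that interpolates the training pairs but carries a
  # large component orthogonal to their span: training-perfect, test-poor
  panel <- make_item_panel(seed = 16)
  tt <- enumerate_trial_types(7)
  train_tt <- tt[tt$is_training, ]
  U <- t(vapply(seq_len(nrow(train_tt)),
                function(i) build_traditional_input(panel, train_tt[i, ]),
                numeric(200)))
  y <- ifelse(train_tt$correct_choice == 1L, 1, -1)
  w <- qr.solve(U %*% t(U), y)            # min-norm interpolator weights
  w <- drop(t(U) %*% w)
  q <- rnorm(200)
  q <- q - t(U) %*% qr.solve(U %*% t(U), U %*% q)  # orthogonal to span(U)
  w_mem <- w + 60 * drop(q) / sqrt(sum(q^2))
  lr <- init_feedforward("LR")
  lr$A <- rbind(w_mem / 2, -w_mem / 2)
  gen <- evaluate_generalization(lr, panel)
  expect_equal(gen$n_training_correct, 12L)
  expect_lt(gen$n_correct, 42L)
  expect_true(gen$memorizer)
  expect_false(gen$full_generalizer)
})
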