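test_that("collinearity indices hit their anchor configurations", {
  g <- item_groups(7)
  u <- rnorm(10)
  # scalar multiples of one direction, referenced to the origin
  states <- outer(seq(-3, 3), u)
  expect_equal(collinearity_index(states, xcm = rep(0, 10)), 1)
  # mutually orthogonal vectors
  ortho <- diag(10)[1:7, ]
  expect_equal(collinearity_index(ortho, xcm = rep(0, 10)), 0)
  # rank-ordered line: +1 ordered collinearity (invariant to negation);
  # a folded arrangement (high and low groups parallel) scores -1
  line <- outer(4 - (1:7), u)
  expect_equal(ordered_collinearity_index(line, xcm = rep(0, 10)), 1)
  expect_equal(ordered_collinearity_index(-line, xcm = rep(0, 10)), 1)
  folded <- outer(abs(4 - (1:7)), u)
  expect_equal(ordered_collinearity_index(folded, xcm = rep(0, 10)), -1)
  # orthogonal high and low groups: 0
  vh <- c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  vl <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0)
  orth <- rbind(vh, vh, vh, rep(0, 10), vl, vl, vl)
  expect_equal(ordered_collinearity_index(orth, xcm = rep(0, 10)), 0)
})

test_that("mean angle and distance changes behave as defined", {
  set.seed(7)
  early <- random_config()
  expect_equal(mean_angle_change(early, early), 0)
  expect_equal(mean_distance_change(early, early), 0)
  # alignment destroyed: aligned early, orthogonalized late -> negative
  u <- rnorm(10)
  aligned <- outer(1:7, u)
  expect_lt(mean_angle_change(aligned, diag(10)[1:7, ],
                              xcm_early = rep(0, 10),
                              xcm_late = rep(0, 10)), 0)
  # homogeneity: doubling all states adds the mean early pairwise distance
  d0 <- mean(dist(early))
  expect_equal(mean_distance_change(early, 2 * early), d0)
  # rigid rotation leaves distances unchanged
  Q <- random_orthogonal(10)
  expect_equal(mean_distance_change(early, early %*% Q), 0,
               tolerance = 1e-10)
})

test_that("every index matches its brute-force oracle on random configs", {
  set.seed(8)
  g <- item_groups(7)
  for (i in 1:100) {
    se <- random_config(); sl <- random_config()
    xe <- colMeans(se); xl <- colMeans(sl)
    expect_equal(collinearity_index(se), bf_collinearity(se, xe, g$S_outer),
                 tolerance = 1e-10)
    expect_equal(ordered_collinearity_index(se),
                 bf_ordered(se, xe, g$S_high, g$S_low), tolerance = 1e-10)
    expect_equal(mean_angle_change(se, sl),
                 bf_mean_angle_change(se, sl, xe, xl, g$S),
                 tolerance = 1e-10)
    expect_equal(mean_distance_change(se, sl),
                 bf_mean_distance_change(se, sl, g$S), tolerance = 1e-10)
  }
})

test_that("indices are invariant to rotation and positive rescaling", {
  set.seed(9)
  for (i in 1:20) {
    se <- random_config(); sl <- random_config()
    Q <- random_orthogonal(10); s <- runif(1, 0.1, 5)
    tr <- function(m) s * m %*% Q
    expect_equal(collinearity_index(tr(se)), collinearity_index(se),
                 tolerance = 1e-10)
    expect_equal(ordered_collinearity_index(tr(se)),
                 ordered_collinearity_index(se), tolerance = 1e-10)
    expect_equal(mean_angle_change(tr(se), tr(sl)),
                 mean_angle_change(se, sl), tolerance = 1e-10)
    # mean distance change scales linearly
    expect_equal(mean_distance_change(tr(se), tr(sl)),
                 s * mean_distance_change(se, sl), tolerance = 1e-10)
  }
})

test_that("zero-norm vectors are excluded with a warning", {
  states <- random_config()
  xcm <- colMeans(states)
  states[2, ] <- xcm                # rank 2 collapses onto the XCM
  expect_warning(v <- collinearity_index(states, xcm = xcm), "zero-norm")
  expect_true(is.finite(v))
})

test_that("axis angles and their random references are computed in PCs", {
  k <- 10
  fake_axes <- structure(list(
    choice = c(1, rep(0, k - 1)),
    xcm_axis = c(0, 1, rep(0, k - 2)),
    readout = c(1, rep(0, k - 1)),
    pca = list(rotation = diag(k), center = rep(0, k))),
    class = "activity_axes")
  plane <- cbind(c(1, rep(0, k - 1)), c(0, 1, rep(0, k - 2)))
  osc <- structure(list(oscillatory = TRUE, plane = plane),
                   class = "oscillation_mode")
  tab <- axis_angle_table(fake_axes, osc, n_random = 500, seed = 2)
  obs <- setNames(tab$observed, tab$comparison)
  # choice = e1 lies in the plane: mean of |<e1,p1>|, |<e1,p2>| = 0.5
  expect_equal(obs[["choice_vs_plane"]], 0.5)
  expect_equal(obs[["xcm_vs_plane"]], 0.5)
  expect_equal(obs[["xcm_vs_choice"]], 0)      # orthogonal axes
  expect_equal(obs[["choice_vs_readout"]], 1)  # identical axes
  # random |cos| reference in 10-D: Gamma(k/2)/(sqrt(pi) Gamma((k+1)/2))
  e_cos <- gamma(k / 2) / (sqrt(pi) * gamma((k + 1) / 2))
  expect_lt(abs(tab$random_mean[3] - e_cos), 0.02)
  # axis orthogonal to the plane scores 0
  fake_axes$choice <- c(rep(0, 2), 1, rep(0, k - 3))
  tab2 <- axis_angle_table(fake_axes, osc, n_random = 10)
  expect_equal(tab2$observed[tab2$comparison == "choice_vs_plane"], 0)
})

test_that("the encoding index reports gains on the log2 scale", {
  d <- array(0, c(7, 5, 4))
  axis <- c(1, 0, 0, 0)
  # equal start/end magnitudes -> 0; doubled -> 1; halved -> -1
  d[, 1, 1] <- c(2, 1, 1, 0.5, 1, 1, 2)
  d[, 5, 1] <- c(2, 1, 1, 0.5, 1, 1, 2)
  expect_equal(encoding_index(d, axis)$index, 0)
  d[, 5, 1] <- 2 * d[, 1, 1]
  enc <- encoding_index(d, axis)
  expect_equal(enc$index, 1)
  expect_equal(unname(enc$gain_per_item), c(1, 1))
  expect_equal(enc$predicted_version, "1st-faster")
  d[, 5, 1] <- d[, 1, 1] / 2
  enc2 <- encoding_index(d, axis)
  expect_equal(enc2$index, -1)
  expect_equal(enc2$predicted_version, "2nd-faster")
  d[1, 1, 1] <- 0
  expect_warning(enc3 <- encoding_index(d, axis), "zero-magnitude")
  expect_true(is.na(enc3$index))
})

test_that("activity axes are extracted from trained-network simulations", {
  fx <- trained_small_rnn()
  tt <- enumerate_trial_types(7)
  sim <- simulate_rnn(fx$params, fx$panel, tt, noise_sd = 0)
  axes <- compute_axes(sim, fx$params$W)
  for (a in c("choice", "xcm_axis", "readout")) {
    expect_equal(sqrt(sum(axes[[a]]^2)), 1, tolerance = 1e-12)
  }
  expect_equal(axes$readout, fx$params$W[1, ] / sqrt(sum(fx$params$W[1, ]^2)))
  # readout axis of W1 = e1 normalizes to e1
  W <- matrix(0, 3, fx$params$N); W[1, 1] <- 2
  expect_equal(compute_axes(sim, W)$readout,
               c(1, rep(0, fx$params$N - 1)))
  # degenerate activity (all-zero states) gives a named error
  sim0 <- sim
  sim0$x[] <- 0
  expect_error(compute_axes(sim0, fx$params$W), "choice axis")
  # PCA variance accounting: non-decreasing cumulative, sums to 1
  ve <- axes$pca$var_explained
  expect_true(all(diff(cumsum(ve)) >= -1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-8)
  # in a trained full generalizer the choice and readout axes align well
  # above the random |cos| reference
  fit <- fit_linear_dynamics(delay_activity(sim))
  osc <- identify_comparison_oscillation(fit)
  tab <- axis_angle_table(axes, osc, n_random = 200, seed = 5)
  row <- tab[tab$comparison == "choice_vs_readout", ]
  expect_gt(row$observed, row$random_q95)
})
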