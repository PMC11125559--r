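#' Delay-period activity by item-1 condition
#'
#' During the delay, noise-free activity depends only on item 1, so the 42
#' trial types collapse to 7 conditions (one per item-1 rank).
#'
#' @param sim An `rnn_sim` from [simulate_rnn()] covering all trial types,
#'   simulated noise-free with `return_state = TRUE`.
#' @return Array `n_items x n_delay_steps x N` with attribute `dt`.
#' @export
delay_activity <- function(sim) {
  stopifnot(inherits(sim, "rnn_sim"), !is.null(sim$x))
  timing <- sim$timing
  n <- max(sim$trials$rank1)
  rows <- match(seq_len(n), sim$trials$rank1)
  out <- sim$x[rows, timing$delay_idx, , drop = FALSE]
  attr(out, "dt") <- timing$dt
  out
}

#' PCA basis of delay-period activity
#'
#' PCs are computed from activity pooled over all delay timesteps and the
#' 7 item-1 conditions (mean-centered, unscaled).
#'
#' @param delay_act Array from [delay_activity()].
#' @param k Number of PCs retained.
#' @return List with `rotation` (N x k), `center` (length N),
#'   `var_explained` (all PCs, proportions).
#' @export
delay_pca <- function(delay_act, k = 10L) {
  d <- dim(delay_act)
  m <- matrix(delay_act, d[1] * d[2], d[3])
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$rotation))
  list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center, var_explained = ve)
}

# project states (rows) into a PCA basis
pca_project <- function(m, pca) {
  sweep(m, 2, pca$center) %*% pca$rotation
}

#' Task-defined activity axes
#'
#' Computes the choice axis (unit vector from the mean of choice-1 to the
#' mean of choice-2 trial activity, averaged over the first quarter of the
#' choice period), the XCM axis (from the cross-condition mean over the
#' first quarter of the delay to that over the last quarter) and the
#' readout axis (unit-normalized choice-1 readout weights), together with
#' the delay-period PC basis.
#'
#' @param sim Noise-free `rnn_sim` over all 42 trial types.
#' @param W Readout weight matrix of the network (`params$W`).
#' @param k PCs retained for the basis (default 10).
#' @return List of class `activity_axes`: `choice`, `xcm_axis`, `readout`
#'   (unit vectors in ambient N-space), `xcm_traj` (time x N), `pca`, and
#'   `in_pcs(axis)` helper results via [axes_in_pcs()].
#' @export
compute_axes <- function(sim, W, k = 10L) {
  stopifnot(inherits(sim, "rnn_sim"), !is.null(sim$x))
  timing <- sim$timing
  q_choice <- timing$choice_idx[seq_len(max(1L, timing$n_choice %/% 4L))]
  c1 <- sim$trials$correct_choice == 1L
  # mean over trials and time, per unit
  mean_state <- function(rows, steps)
    apply(sim$x[rows, steps, , drop = FALSE], 3, mean)
  ch1 <- mean_state(which(c1), q_choice)
  ch2 <- mean_state(which(!c1), q_choice)
  choice <- unitize(ch2 - ch1, "choice axis")
  nq <- max(1L, timing$n_delay %/% 4L)
  d_first <- timing$delay_idx[seq_len(nq)]
  d_last <- timing$delay_idx[seq.int(timing$n_delay - nq + 1L,
                                     timing$n_delay)]
  all_rows <- seq_len(nrow(sim$trials))
  xcm_axis <- unitize(mean_state(all_rows, d_last) -
                      mean_state(all_rows, d_first), "XCM axis")
  xcm_traj <- apply(sim$x, c(2, 3), mean)
  readout <- unitize(W[1, ], "readout axis")
  pca <- delay_pca(delay_activity(sim), k = k)
  structure(list(choice = choice, xcm_axis = xcm_axis, readout = readout,
                 xcm_traj = xcm_traj, pca = pca),
            class = "activity_axes")
}

unitize <- function(v, what = "axis") {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate (zero-norm) ", what)
  v / n
}

#' Project the activity axes into the delay PC basis
#'
#' @param axes An `activity_axes`.
#' @return List with unit vectors `choice`, `xcm_axis`, `readout` in the
#'   top-k PC space.
#' @export
axes_in_pcs <- function(axes) {
  R <- axes$pca$rotation
  lapply(axes[c("choice", "xcm_axis", "readout")],
         function(v) unitize(drop(crossprod(R, v))))
}

#' Least-squares linear dynamics fit to delay activity
#'
#' Fits `Xdot = X A` (states as rows) in the top-k PCs of delay-period
#' activity, with derivatives estimated by forward differences over `dt`.
#' Eigen-analysis is performed on `t(A)` so eigenvectors live in state
#' space; imaginary parts are reported in cycles/delay using the delay
#' duration of the fitted window.
#'
#' @param delay_act Array from [delay_activity()].
#' @param k Number of PCs (default 10).
#' @param pca Optional precomputed [delay_pca()] basis.
#' @return List of class `lindyn_fit`: `A` (k x k), `R2`, `eigenvalues`
#'   (complex, 1/tau units), `eigenvalues_cycles` (scaled by
#'   delay/(2*pi)), `eigenvectors` (k x k complex, state space), `pca`,
#'   `delay_duration`, `dt`.
#' @export
fit_linear_dynamics <- function(delay_act, k = 10L, pca = NULL) {
  dt <- attr(delay_act, "dt")
  d <- dim(delay_act)
  if (is.null(pca)) pca <- delay_pca(delay_act, k = k)
  Y <- array(pca_project(matrix(delay_act, d[1] * d[2], d[3]), pca),
             c(d[1], d[2], ncol(pca$rotation)))
  X <- NULL; Xdot <- NULL
  for (i in seq_len(d[1])) {
    yi <- Y[i, , ]
    X <- rbind(X, yi[-d[2], , drop = FALSE])
    Xdot <- rbind(Xdot, (yi[-1, , drop = FALSE] -
                         yi[-d[2], , drop = FALSE]) / dt)
  }
  if (sum(Xdot^2) == 0) stop("degenerate fit: constant delay activity")
  A <- qr.solve(X, Xdot)
  res <- Xdot - X %*% A
  # uncentered R^2: the null model of a through-origin dynamics fit is
  # "no dynamics" (Xdot = 0), not the mean-drift model
  r2 <- 1 - sum(res^2) / sum(Xdot^2)
  eg <- eigen(t(A))
  delay_dur <- d[2] * dt
  structure(list(
    A = A, R2 = r2, eigenvalues = eg$values,
    eigenvalues_cycles = eg$values * delay_dur / (2 * pi),
    eigenvectors = eg$vectors, pca = pca,
    delay_duration = delay_dur, dt = dt),
    class = "lindyn_fit")
}

#' Identify the comparison oscillation
#'
#' Among eigenvalues with a nonzero imaginary part, selects the one
#' nearest `0 + 0.5i` on the real-imaginary plane with the imaginary part
#' in cycles/delay (positive-frequency representative of each conjugate
#' pair). The 2D oscillation plane is spanned by the real and imaginary
#' parts of the selected eigenvector, Gram-Schmidt orthonormalized in that
#' order.
#'
#' @param fit A `lindyn_fit`, or a list with `eigenvalues_cycles` and
#'   `eigenvectors`.
#' @param target Complex target (default `0 + 0.5i`).
#' @param im_tol Minimum |imaginary part| (cycles/delay) for a mode to
#'   count as oscillatory.
#' @return List of class `oscillation_mode`: `oscillatory` (logical),
#'   `eigenvalue_cycles`, `frequency` (cycles/delay, >= 0), `decay`
#'   (real part), `plane` (k x 2 orthonormal), `index`. When the spectrum
#'   is purely real, `oscillatory = FALSE` and the other fields are `NA`.
#' @export
identify_comparison_oscillation <- function(fit, target = 0 + 0.5i,
                                            im_tol = 1e-9) {
  lam <- fit$eigenvalues_cycles
  cand <- which(Im(lam) > im_tol)   # positive-frequency representatives
  if (!length(cand))
    return(structure(list(oscillatory = FALSE, eigenvalue_cycles = NA,
                          frequency = NA_real_, decay = NA_real_,
                          plane = NULL, index = NA_integer_),
                     class = "oscillation_mode"))
  dist <- Mod(lam[cand] - target)
  sel <- cand[which.min(dist)]
  v <- fit$eigenvectors[, sel]
  b1 <- unitize(Re(v), "oscillation plane vector")
  b2 <- Im(v) - sum(Im(v) * b1) * b1
  b2 <- unitize(b2, "oscillation plane vector")
  structure(list(oscillatory = TRUE, eigenvalue_cycles = lam[sel],
                 frequency = Im(lam[sel]), decay = Re(lam[sel]),
                 plane = unname(cbind(b1, b2)), index = sel),
            class = "oscillation_mode")
}

#' Find fixed points of the autonomous RNN dynamics
#'
#' Minimizes the speed `q(x) = mean(((-x + J tanh(x) + b)/tau)^2)` by Adam
#' (optionally polished by Newton steps), seeded from (a) listed
#' trial-time states of noise-free simulations of all trial types (trial
#' start, the two pulses, mid-delay, trial end, and the end of a trial
#' extended by 100 steps) and (b) `n_batches` batches of `batch_size`
#' random trial states with jittered item timing. Candidates with speed
#' below `speed_tol` are kept and deduplicated.
#'
#' With the `"all-units"` rule (default) two candidates are distinct only
#' when every unit differs by more than `dedup_tol`; `"any-unit"` requires
#' only one unit to differ by more than `dedup_tol`.
#'
#' @param params Trained `rnn_params`.
#' @param panel Item panel.
#' @param timing A [ti_timing()].
#' @param n_batches,batch_size Random-seed batches (default 5 x 50).
#' @param max_iter,patience Adam iteration budget per batch.
#' @param lr Adam learning rate.
#' @param speed_tol Acceptance threshold on speed (default 1e-5).
#' @param dedup_tol Per-unit deduplication tolerance (default 1e-5).
#' @param dedup_rule `"all-units"` or `"any-unit"`.
#' @param newton_polish Apply Newton refinement to converged candidates.
#' @param seed Integer seed.
#' @return A data.frame-free list of class `fixed_points`: `x` (matrix
#'   N x n_fp), `speed`, `classification`, `jacobian_spectra` (list),
#'   `unstable_axes` (list; non-NULL for saddle-1 points).
#' @export
find_fixed_points <- function(params, panel, timing = ti_timing(),
                              n_batches = 5L, batch_size = 50L,
                              max_iter = 50000L, patience = 5000L,
                              lr = 0.01, speed_tol = 1e-5,
                              dedup_tol = 1e-5,
                              dedup_rule = c("all-units", "any-unit"),
                              newton_polish = TRUE, seed = 1L) {
  stopifnot(inherits(params, "rnn_params"))
  dedup_rule <- match.arg(dedup_rule)
  timing <- analysis_timing(timing)
  tt <- enumerate_trial_types(panel$n_items)
  sim <- simulate_rnn(params, panel, tt, timing, noise_sd = 0)
  T_ <- timing$n_steps
  listed_steps <- unique(c(1L, timing$pulse1, timing$pulse2,
                           timing$delay_idx[max(1L, timing$n_delay %/% 2L)],
                           T_))
  seeds <- NULL
  for (s in listed_steps) seeds <- cbind(seeds, t(sim$x[, s, ]))
  # extended trial: continue autonomously for 100 extra steps
  xe <- t(sim$x[, T_, ])
  for (i in seq_len(100L)) {
    xe <- xe + timing$dt * (-xe + params$J %*% tanh(xe) + params$b)
  }
  seeds <- cbind(seeds, xe)
  cands <- list(seeds)
  withr_seed(seed, {
    for (b in seq_len(n_batches)) {
      jit <- tt[sample.int(nrow(tt), batch_size, replace = TRUE), ]
      p1 <- sample.int(T_ - 2L, batch_size, replace = TRUE)
      gap <- T_ - p1
      p2 <- p1 + vapply(gap, function(g) sample.int(g, 1L), integer(1))
      ts <- list(item1 = as.integer(jit$rank1 - 1L),
                 item2 = as.integer(jit$rank2 - 1L),
                 p1 = p1, p2 = p2, T = T_)
      out <- rnn_forward_cpp(params$J, params$B, params$W, params$b,
                             params$c, params$x0, t(panel$u),
                             ts$item1, ts$item2, ts$p1, ts$p2, ts$T,
                             timing$dt, 0, TRUE, 0)
      steps <- sample.int(T_, batch_size, replace = TRUE)
      xs <- vapply(seq_len(batch_size),
                   function(m) out$X[, m, steps[m] + 1L],
                   numeric(params$N))
      cands[[b + 1L]] <- xs
    }
  })
  found_x <- NULL; found_speed <- numeric(0)
  for (X0 in cands) {
    fp <- fp_find_cpp(params$J, params$b, X0, 1, lr,
                      as.integer(max_iter), as.integer(patience),
                      newton_polish)
    ok <- fp$speed < speed_tol
    if (any(ok)) {
      found_x <- cbind(found_x, fp$X[, ok, drop = FALSE])
      found_speed <- c(found_speed, fp$speed[ok])
    }
  }
  if (is.null(found_x))
    return(structure(list(x = matrix(numeric(0), params$N, 0),
                          speed = numeric(0), classification = character(0),
                          jacobian_spectra = list(), unstable_axes = list()),
                     class = "fixed_points"))
  ord <- order(found_speed)
  keep <- integer(0)
  for (i in ord) {
    distinct <- TRUE
    for (j in keep) {
      dd <- abs(found_x[, i] - found_x[, j])
      same <- if (dedup_rule == "all-units") any(dd <= dedup_tol)
              else all(dd <= dedup_tol)
      if (same) { distinct <- FALSE; break }
    }
    if (distinct) keep <- c(keep, i)
  }
  x <- found_x[, keep, drop = FALSE]
  lins <- lapply(seq_len(ncol(x)), function(i) linearize(params, x[, i]))
  structure(list(
    x = x, speed = found_speed[keep],
    classification = vapply(lins, `[[`, character(1), "classification"),
    jacobian_spectra = lapply(lins, `[[`, "eigenvalues"),
    unstable_axes = lapply(lins, `[[`, "unstable_axis")),
    class = "fixed_points")
}

#' Linearize the dynamics around a state
#'
#' Analytic Jacobian `(-I + J diag(1 - tanh(x)^2)) / tau`, cross-checked
#' against central finite differences. Classification: `attractor` when
#' all eigenvalue real parts are negative, `saddle-1` when exactly one is
#' positive (its real eigenvector is returned as the unstable axis),
#' otherwise `other`.
#'
#' @param params An `rnn_params`.
#' @param xstar State vector (length N).
#' @param tau Time constant (default 1).
#' @param check Numerical cross-check tolerance (`NA` disables the check).
#' @return List: `jacobian`, `eigenvalues`, `classification`,
#'   `unstable_axis` (or `NULL`).
#' @export
linearize <- function(params, xstar, tau = 1, check = 1e-6) {
  r <- tanh(xstar)
  A <- (params$J %*% diag(1 - r^2) - diag(params$N)) / tau
  if (!is.na(check)) {
    f <- function(x) (-x + params$J %*% tanh(x) + params$b) / tau
    h <- 1e-6
    idx <- seq_len(min(5L, params$N))  # spot-check a few columns
    for (j in idx) {
      e <- numeric(params$N); e[j] <- h
      num <- (f(xstar + e) - f(xstar - e)) / (2 * h)
      if (max(abs(num - A[, j])) > check)
        stop("consistency error: analytic vs numerical Jacobian mismatch")
    }
  }
  eg <- eigen(A)
  re <- Re(eg$values)
  cls <- if (all(re < 0)) "attractor"
         else if (sum(re > 0) == 1) "saddle-1" else "other"
  ua <- NULL
  if (cls == "saddle-1") {
    v <- eg$vectors[, which(re > 0)]
    ua <- unitize(Re(v), "unstable axis")
  }
  list(jacobian = A, eigenvalues = eg$values, classification = cls,
       unstable_axis = ua)
}

#' Reduced simulation of the comparison oscillation
#'
#' Evolves only the oscillatory mode: item encodings are injected as
#' pulses, the components in the oscillation plane rotate at `frequency`
#' cycles/delay (no decay), and components orthogonal to the plane
#' persist unchanged. After the second item, states evolve a quarter of
#' the choice period before the choice-1 vs choice-2 classes are tested
#' for linear separability (hard-margin feasibility via convex-hull
#' distance).
#'
#' @param frequency Oscillation frequency in cycles/delay.
#' @param encodings `n_items x D` matrix of item encoding vectors. For
#'   the subtractive solution use ordered collinear encodings in the
#'   plane; `D = 2` gives the reduced-2D mode, larger `D` (with the plane
#'   spanned by the first two coordinates) the full-activity mode.
#' @param timing A [ti_timing()] supplying the delay and choice-period
#'   durations.
#' @param choice_frac Fraction of the choice period evolved before the
#'   separability test (default 0.25).
#' @return List of class `reduced_sim`: `states` (42 x D), `labels`
#'   (correct choice per type), `separable` (logical), `margin`,
#'   `trials`.
#' @export
simulate_reduced_oscillation <- function(frequency, encodings,
                                         timing = ti_timing(),
                                         choice_frac = 0.25) {
  if (timing$n_delay <= 0) stop("zero-length delay")
  n_items <- nrow(encodings)
  D <- ncol(encodings)
  if (D < 2) stop("encodings must have at least 2 dimensions")
  tt <- enumerate_trial_types(n_items)
  rot_by <- function(S, ang) {
    R2 <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    S[, 1:2] <- S[, 1:2, drop = FALSE] %*% t(R2)
    S
  }
  delay_ang <- 2 * pi * frequency
  choice_ang <- 2 * pi * frequency *
    (choice_frac * timing$n_choice / timing$n_delay)
  S <- encodings[tt$rank1, , drop = FALSE]     # item-1 pulse
  S <- rot_by(S, delay_ang)                     # delay rotation
  S <- S + encodings[tt$rank2, , drop = FALSE]  # item-2 pulse
  S <- rot_by(S, choice_ang)                    # into the choice period
  y <- ifelse(tt$correct_choice == 1L, 1, -1)
  sep <- linear_separability(S, y)
  structure(list(states = S, labels = tt$correct_choice,
                 separable = sep$separable, margin = sep$margin,
                 trials = tt),
            class = "reduced_sim")
}

#' Certified linear-separability check
#'
#' Tries to produce a separating hyperplane (minimum-norm least-squares
#' interpolation of the labels, then a perceptron pass); any candidate is
#' verified against every point, so a `TRUE` answer is a hard-margin
#' certificate. If no candidate verifies, the distance between the convex
#' hulls of the two classes is estimated by Frank-Wolfe iteration; a
#' (near-)zero hull distance means the classes are not linearly separable.
#'
#' @param X Point matrix (rows = points).
#' @param y Labels in `{-1, +1}`.
#' @param max_iter Frank-Wolfe / perceptron iteration budget.
#' @param tol Hull distance below which hulls are considered intersecting.
#' @return List: `separable` (logical), `margin` (certified geometric
#'   margin, or 0 when inseparable), `w`, `b` (the certified hyperplane,
#'   or `NULL`).
#' @export
linear_separability <- function(X, y, max_iter = 20000L, tol = 1e-8) {
  A <- X[y > 0, , drop = FALSE]
  B <- X[y < 0, , drop = FALSE]
  certify <- function(w, b) {
    if (min(A %*% w + b) > 0 && max(B %*% w + b) < 0) {
      m <- min(abs(X %*% w + b)) / sqrt(sum(w^2))
      list(separable = TRUE, margin = m, w = w, b = b)
    } else NULL
  }
  Xa <- cbind(X, 1)
  # candidate 1: minimum-norm least squares on the augmented data
  sv <- svd(Xa)
  pos <- sv$d > max(sv$d) * 1e-10
  wb <- drop(sv$v[, pos, drop = FALSE] %*%
               (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos]))
  res <- certify(wb[-length(wb)], wb[length(wb)])
  if (!is.null(res)) return(res)
  # candidate 2: perceptron on row-normalized data
  Xn <- Xa / sqrt(rowSums(Xa^2))
  wb <- numeric(ncol(Xa))
  for (it in seq_len(max_iter)) {
    miss <- which(y * (Xn %*% wb) <= 0)
    if (!length(miss)) break
    i <- miss[1]
    wb <- wb + y[i] * Xn[i, ]
  }
  res <- certify(wb[-length(wb)], wb[length(wb)])
  if (!is.null(res)) return(res)
  la <- rep(1 / nrow(A), nrow(A))
  mb <- rep(1 / nrow(B), nrow(B))
  for (it in seq_len(max_iter)) {
    u <- drop(crossprod(A, la)); v <- drop(crossprod(B, mb))
    d <- u - v
    if (sum(d^2) < tol^2) break
    sa <- which.min(A %*% d); sb <- which.max(B %*% d)
    # Frank-Wolfe direction: vertex pair (sa, sb)
    ga <- numeric(nrow(A)); ga[sa] <- 1
    gb <- numeric(nrow(B)); gb[sb] <- 1
    du <- drop(crossprod(A, ga - la)); dv <- drop(crossprod(B, gb - mb))
    dir <- du - dv
    denom <- sum(dir^2)
    if (denom < 1e-30) break
    step <- max(0, min(1, -sum(d * dir) / denom))
    if (step == 0) break
    la <- la + step * (ga - la)
    mb <- mb + step * (gb - mb)
  }
  u <- drop(crossprod(A, la)); v <- drop(crossprod(B, mb))
  w <- u - v
  dist <- sqrt(sum(w^2))
  if (dist > tol) {
    b <- -sum(w * (u + v)) / 2
    if (min(A %*% w + b) > 0 && max(B %*% w + b) < 0)
      return(list(separable = TRUE, margin = dist / 2, w = w, b = b))
  }
  list(separable = FALSE, margin = 0, w = NULL, b = NULL)
}
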