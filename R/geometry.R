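#' Item groupings for the geometry indices
#'
#' For an odd number of items: `S` = all items, `S_outer` = all but the
#' middle item, `S_high` / `S_low` = the items above / below the middle.
#'
#' @param n_items Number of items (odd).
#' @return List of rank vectors `S`, `S_outer`, `S_high`, `S_low`.
#' @export
item_groups <- function(n_items = 7L) {
  if (n_items %% 2L == 0L) stop("item groups are defined for odd n_items")
  mid <- (n_items + 1L) %/% 2L
  list(S = seq_len(n_items),
       S_outer = setdiff(seq_len(n_items), mid),
       S_high = seq_len(mid - 1L),
       S_low = seq.int(mid + 1L, n_items))
}

# XCM-referenced condition vectors, dropping zero-norm rows with a warning
ref_vectors <- function(states, xcm, ranks) {
  v <- sweep(states[ranks, , drop = FALSE], 2, xcm)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) {
    warning("zero-norm condition vector(s) excluded")
    v <- v[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  v / nrm
}

#' Collinearity index
#'
#' Mean absolute cosine between XCM-referenced condition vectors over
#' unordered pairs of the outer items; 1 = perfectly linear arrangement,
#' i.i.d. random vectors in 10-D give about 0.28.
#'
#' @param states Condition states, `n_items x d` matrix (row i = rank i).
#' @param xcm Cross-condition mean vector (length d); defaults to the
#'   mean of the rows of `states`.
#' @param groups [item_groups()] list.
#' @return Value in `[0, 1]`, or `NA` if fewer than two usable vectors.
#' @export
collinearity_index <- function(states, xcm = colMeans(states),
                               groups = item_groups(nrow(states))) {
  v <- ref_vectors(states, xcm, groups$S_outer)
  if (nrow(v) < 2) return(NA_real_)
  cc <- abs(tcrossprod(v))
  mean(cc[upper.tri(cc)])
}

#' Ordered collinearity index
#'
#' `-mean(cos(v_i, v_j))` over high-group x low-group pairs of
#' XCM-referenced vectors; +1 when the two halves of the rank ordering
#' point in opposite directions along a line, -1 for the reversed
#' arrangement, ~0 for unstructured activity.
#'
#' @inheritParams collinearity_index
#' @return Value in `[-1, 1]`.
#' @export
ordered_collinearity_index <- function(states, xcm = colMeans(states),
                                       groups = item_groups(nrow(states))) {
  vh <- ref_vectors(states, xcm, groups$S_high)
  vl <- ref_vectors(states, xcm, groups$S_low)
  if (!nrow(vh) || !nrow(vl)) return(NA_real_)
  -mean(tcrossprod(vh, vl))
}

#' Mean angle change across the delay
#'
#' Mean over unordered pairs of all items of the change in pairwise
#' cosine (late minus early) of XCM-referenced condition vectors.
#'
#' @param states_early,states_late `n_items x d` state matrices at the
#'   first and last delay timesteps.
#' @param xcm_early,xcm_late Matching cross-condition means.
#' @param groups [item_groups()] list.
#' @return The mean pairwise cosine change.
#' @export
mean_angle_change <- function(states_early, states_late,
                              xcm_early = colMeans(states_early),
                              xcm_late = colMeans(states_late),
                              groups = item_groups(nrow(states_early))) {
  ve <- ref_vectors(states_early, xcm_early, groups$S)
  vl <- ref_vectors(states_late, xcm_late, groups$S)
  if (nrow(ve) != nrow(vl) || nrow(ve) < 2) return(NA_real_)
  ce <- tcrossprod(ve); cl <- tcrossprod(vl)
  mean((cl - ce)[upper.tri(ce)])
}

#' Mean distance change across the delay
#'
#' Mean over unordered pairs of the change in pairwise Euclidean distance
#' (late minus early) of the raw condition states (no XCM reference).
#'
#' @inheritParams mean_angle_change
#' @return The mean pairwise distance change.
#' @export
mean_distance_change <- function(states_early, states_late,
                                 groups = item_groups(nrow(states_early))) {
  pd <- function(m) as.matrix(stats::dist(m[groups$S, , drop = FALSE]))
  de <- pd(states_early); dl <- pd(states_late)
  mean((dl - de)[upper.tri(de)])
}

#' Delay-geometry report for one network
#'
#' Computes the collinearity-family indices at the first (early) and last
#' (late) delay timesteps in the top-k PCs of delay activity, together
#' with their change, and optional random baselines (Gaussian vectors
#' substituted for every state).
#'
#' @param delay_act Array from [delay_activity()].
#' @param k PCs used (default 10).
#' @param window `"timestep"` (first/last delay step, default) or
#'   `"quarter"` (average over the first/last quarter of the delay).
#' @param n_random Random-baseline draws (0 disables).
#' @param seed Seed for the baselines.
#' @return List of class `geometry_report` with `collinearity`,
#'   `ordered_collinearity` (each early/late/change), `mean_angle_change`,
#'   `mean_distance_change`, `k`, and `random` (baseline draws per index).
#' @export
geometry_report <- function(delay_act, k = 10L,
                            window = c("timestep", "quarter"),
                            n_random = 0L, seed = 1L) {
  window <- match.arg(window)
  d <- dim(delay_act)
  pca <- delay_pca(delay_act, k = k)
  states_at <- function(steps) {
    m <- apply(delay_act[, steps, , drop = FALSE], c(1, 3), mean)
    pca_project(m, pca)
  }
  nq <- max(1L, d[2] %/% 4L)
  idx_early <- if (window == "timestep") 1L else seq_len(nq)
  idx_late <- if (window == "timestep") d[2] else seq.int(d[2] - nq + 1L, d[2])
  early <- states_at(idx_early)
  late <- states_at(idx_late)
  groups <- item_groups(d[1])
  rep1 <- function(early, late) {
    list(
      collinearity = list(early = collinearity_index(early, groups = groups),
                          late = collinearity_index(late, groups = groups)),
      ordered = list(early = ordered_collinearity_index(early, groups = groups),
                     late = ordered_collinearity_index(late, groups = groups)),
      mac = mean_angle_change(early, late, groups = groups),
      mdc = mean_distance_change(early, late, groups = groups))
  }
  obs <- rep1(early, late)
  random <- NULL
  if (n_random > 0) {
    random <- withr_seed(seed, {
      draws <- lapply(seq_len(n_random), function(i) {
        re <- matrix(stats::rnorm(length(early)), nrow(early))
        rl <- matrix(stats::rnorm(length(late)), nrow(late))
        r <- rep1(re, rl)
        c(collinearity_early = r$collinearity$early,
          collinearity_late = r$collinearity$late,
          ordered_early = r$ordered$early, ordered_late = r$ordered$late,
          mean_angle_change = r$mac, mean_distance_change = r$mdc)
      })
      do.call(rbind, draws)
    })
  }
  structure(list(
    collinearity = c(obs$collinearity,
                     change = obs$collinearity$late - obs$collinearity$early),
    ordered_collinearity = c(obs$ordered,
                             change = obs$ordered$late - obs$ordered$early),
    mean_angle_change = obs$mac,
    mean_distance_change = obs$mdc,
    k = k, window = window, random = random),
    class = "geometry_report")
}

#' Axis-angle table with random references
#'
#' Cosine angles (dot-product magnitudes) between the task axes and the
#' comparison-oscillation plane, all in the same top-k PC space: axis vs
#' plane = mean |dot| with the two plane vectors; axis vs axis = |dot|.
#' Random references replace each axis (and each plane vector, then
#' re-orthonormalized) with random unit vectors.
#'
#' @param axes An `activity_axes` (projected into PCs internally).
#' @param osc An `oscillation_mode` with a plane in the same PC space.
#' @param n_random Number of randomizations (default 1000).
#' @param seed Seed for the randomizations.
#' @return A data.frame of class `axis_angle_table`: one row per
#'   comparison (`choice_vs_plane`, `xcm_vs_plane`, `xcm_vs_choice`,
#'   `choice_vs_readout`) with `observed`, `random_mean`, `random_q95`.
#' @export
axis_angle_table <- function(axes, osc, n_random = 1000L, seed = 1L) {
  ax <- axes_in_pcs(axes)
  k <- length(ax$choice)
  if (!is.null(osc$plane) && nrow(osc$plane) != k)
    stop("dimension mismatch between axes and oscillation plane")
  ang_plane <- function(a, P) mean(abs(drop(crossprod(P, a))))
  ang_axis <- function(a, b) abs(sum(a * b))
  obs <- c(
    choice_vs_plane = if (is.null(osc$plane)) NA_real_
                      else ang_plane(ax$choice, osc$plane),
    xcm_vs_plane = if (is.null(osc$plane)) NA_real_
                   else ang_plane(ax$xcm_axis, osc$plane),
    xcm_vs_choice = ang_axis(ax$xcm_axis, ax$choice),
    choice_vs_readout = ang_axis(ax$choice, ax$readout))
  rnd <- withr_seed(seed, {
    runit <- function() unitize(stats::rnorm(k))
    draws <- vapply(seq_len(n_random), function(i) {
      p1 <- runit(); p2 <- stats::rnorm(k)
      p2 <- unitize(p2 - sum(p2 * p1) * p1)
      P <- cbind(p1, p2)
      c(ang_plane(runit(), P), ang_plane(runit(), P),
        ang_axis(runit(), runit()), ang_axis(runit(), runit()))
    }, numeric(4))
    t(draws)
  })
  out <- data.frame(
    comparison = names(obs), observed = unname(obs),
    random_mean = colMeans(rnd),
    random_q95 = apply(rnd, 2, stats::quantile, 0.95))
  class(out) <- c("axis_angle_table", "data.frame")
  out
}

#' End-item encoding index
#'
#' Projects delay activity onto a behaviorally relevant axis and compares
#' the projection magnitude of the end items (highest and lowest rank) at
#' the end vs the start of the delay:
#' `gain = log2(|proj(last step)| / |proj(first step)|)`, averaged over
#' the two end items. Positive gain means item-1 encodings dominate
#' (1st-dominant), negative gain 2nd-dominant.
#'
#' @param delay_act Array from [delay_activity()].
#' @param axis Projection axis. Either length N (ambient space; e.g. the
#'   readout weights, with optional `bias`) or length k matching `pca`.
#' @param pca Optional [delay_pca()] basis; when supplied, activity is
#'   projected into PCs first (use for the choice axis).
#' @param bias Constant added to the projection (readout bias; default 0).
#' @param groups [item_groups()] list.
#' @return List of class `encoding_report`: `projections` (items x time),
#'   `gain_per_item` (named, end items), `index` (mean log2 gain),
#'   `ratio` (mean raw ratio), `predicted_version` (`"1st-faster"` /
#'   `"2nd-faster"`).
#' @export
encoding_index <- function(delay_act, axis, pca = NULL, bias = 0,
                           groups = item_groups(dim(delay_act)[1])) {
  d <- dim(delay_act)
  m <- matrix(delay_act, d[1] * d[2], d[3])
  proj <- if (is.null(pca)) m %*% axis else pca_project(m, pca) %*% axis
  proj <- matrix(proj + bias, d[1], d[2])
  ends <- c(groups$S[1], groups$S[length(groups$S)])
  start_mag <- abs(proj[ends, 1])
  end_mag <- abs(proj[ends, d[2]])
  if (any(start_mag == 0)) {
    warning("zero-magnitude start projection; encoding index is NA")
    gain <- rep(NA_real_, 2)
  } else {
    gain <- log2(end_mag / start_mag)
  }
  idx <- mean(gain)
  structure(list(
    projections = proj,
    gain_per_item = stats::setNames(gain, rownames(delay_act)[ends]),
    index = idx, ratio = mean(end_mag / start_mag),
    predicted_version = if (is.na(idx)) NA_character_
                        else if (idx > 0) "1st-faster" else "2nd-faster"),
    class = "encoding_report")
}
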