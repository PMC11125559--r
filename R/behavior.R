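#' Saturating output transform
#'
#' Maps a readout value onto (0, 1) via
#' `ztilde = tanh(z - z_active/2)/2 + 1/2`, where `z_active` is the
#' activated target value (5 by default). The midpoint (`ztilde = 0.5`)
#' sits at half the activated target, so an output rising from rest (0)
#' toward its target (5) crosses the 85% response threshold at
#' `z = z_active/2 + atanh(0.7)`, about 3.37.
#'
#' @param z Numeric readout values.
#' @param z_active Activated target value.
#' @return Values in (0, 1).
#' @export
saturate <- function(z, z_active = 5) {
  0.5 * tanh(z - z_active / 2) + 0.5
}

#' Convert a readout time series into a trial record
#'
#' The response is the first of the two saturated choice readouts to reach
#' the threshold (0.85) during the choice period; simultaneous crossings
#' are broken by the larger saturated value, then by unit index. RT is the
#' time from the item-2 pulse to the crossing, as a proportion of the
#' choice period. If neither readout crosses, the trial is a no-response
#' record.
#'
#' @param z Time x N_out readout matrix for one trial (full trial length).
#' @param timing The trial's [ti_timing()].
#' @param z_active,threshold Response-rule constants.
#' @return A one-row data.frame: `responded`, `choice`, `rt`.
#' @export
decide <- function(z, timing, z_active = 5, threshold = 0.85) {
  zt <- saturate(z[timing$choice_idx, 1:2, drop = FALSE], z_active)
  hit <- zt >= threshold
  first <- apply(hit, 2, function(h) if (any(h)) which(h)[1] else Inf)
  if (all(is.infinite(first)))
    return(data.frame(responded = FALSE, choice = NA_integer_,
                      rt = NA_real_))
  step <- min(first)
  tied <- which(first == step)
  choice <- if (length(tied) == 1L) tied else tied[which.max(zt[step, tied])]
  data.frame(responded = TRUE, choice = as.integer(choice),
             rt = step / timing$n_choice)
}

#' Titrate intrinsic noise to sub-asymptotic performance
#'
#' Sweeps the noise s.d. over the model family's grid (RNN: 0.5 to 5 in
#' steps of 0.05; LR/MLP: 1 to 128 in powers of 2) and returns the first
#' level at which simulated performance is above 50% on both the choice-1
#' and choice-2 training-trial pools and below 96% on the largest
#' symbolic-distance types (the two extreme-pair trials). Non-response
#' trials count as random choices for performance.
#'
#' @param params Trained `rnn_params` or `ff_params`.
#' @param panel Item panel.
#' @param timing [ti_timing()] (RNN only).
#' @param n_per_type Simulated trials per trial type per level (full
#'   scale: 500).
#' @param seed Integer seed.
#' @param grid Optional explicit grid of noise levels.
#' @return The selected noise s.d. (scalar). Errors with class
#'   `titration_failure` if no grid level satisfies the criteria.
#' @export
titrate_noise <- function(params, panel, timing = ti_timing(),
                          n_per_type = 500L, seed = 1L, grid = NULL) {
  if (is.null(grid)) {
    grid <- if (inherits(params, "rnn_params")) seq(0.5, 5, by = 0.05)
            else 2^(0:7)
  }
  tt <- enumerate_trial_types(panel$n_items)
  # only the training types and the two extreme pairs enter the criteria
  need <- tt[tt$is_training | tt$symbolic_distance == panel$n_items - 1L, ]
  for (i in seq_along(grid)) {
    rec <- simulate_behavior(params, panel, grid[i], timing = timing,
                             n_per_type = n_per_type,
                             seed = seed + i - 1L, trials = need)
    perf <- titration_performance(rec)
    if (perf$train1 > 0.5 && perf$train2 > 0.5 && perf$extreme < 0.96)
      return(grid[i])
  }
  stop(structure(class = c("titration_failure", "error", "condition"),
                 list(message = "titration failure: no noise level met the performance criteria",
                      call = sys.call())))
}

titration_performance <- function(rec) {
  n <- max(rec$rank1, rec$rank2)
  tr <- rec[rec$is_training, ]
  ext <- rec[rec$symbolic_distance == n - 1L, ]
  list(
    train1 = mean(tr$correct[tr$correct_choice == 1L]),
    train2 = mean(tr$correct[tr$correct_choice == 2L]),
    extreme = mean(ext$correct))
}

#' Simulate behavior across all trial types
#'
#' Runs `n_per_type` noisy simulations of every trial type and converts
#' the outputs into trial records. Non-responding trials are randomly
#' assigned choice 1 or 2 (they count for performance but are excluded
#' from RT statistics downstream).
#'
#' @inheritParams titrate_noise
#' @param noise_sd Intrinsic noise s.d. (typically from [titrate_noise()]).
#' @param trials Optional subset of trial types to simulate (default all).
#' @return A data.frame of trial records: trial-type columns plus
#'   `responded`, `choice`, `rt`, `correct`.
#' @export
simulate_behavior <- function(params, panel, noise_sd,
                              timing = ti_timing(), n_per_type = 500L,
                              seed = 1L, trials = NULL) {
  tt <- if (is.null(trials)) enumerate_trial_types(panel$n_items) else trials
  reps <- tt[rep(seq_len(nrow(tt)), each = n_per_type), ]
  rownames(reps) <- NULL
  if (inherits(params, "behavior_oracle")) {
    # analytic stand-in: a known accuracy function of noise, realized with
    # exact per-type counts so titration can be checked in closed form
    p <- pmin(pmax(params$p_correct(tt, noise_sd), 0), 1)
    k <- round(p * n_per_type)
    correct <- unlist(lapply(k, function(ki)
      rep(c(TRUE, FALSE), c(ki, n_per_type - ki))))
    reps$responded <- TRUE
    reps$choice <- ifelse(correct, reps$correct_choice,
                          3L - reps$correct_choice)
    reps$rt <- 0.5
    reps$correct <- correct
    class(reps) <- "data.frame"
    return(reps)
  }
  if (inherits(params, "rnn_params")) {
    timing <- analysis_timing(timing)
    ts <- trial_spec(reps, timing)
    dec <- rnn_decide_cpp(params$J, params$B, params$W, params$b, params$c,
                          params$x0, t(panel$u),
                          ts$item1, ts$item2, ts$p1, ts$p2, ts$T,
                          timing$dt, noise_sd, 5, 0.85, seed_from(seed))
    reps$responded <- dec$choice > 0L
    reps$choice <- ifelse(reps$responded, dec$choice, NA_integer_)
    reps$rt <- ifelse(reps$responded,
                      (dec$step - timing$pulse2) / timing$n_choice,
                      NA_real_)
  } else {
    U <- t(vapply(seq_len(nrow(tt)),
                  function(i) build_traditional_input(panel, tt[i, ]),
                  numeric(2 * panel$N_in)))
    U <- U[rep(seq_len(nrow(tt)), each = n_per_type), , drop = FALSE]
    z <- simulate_feedforward(params, U, noise_sd = noise_sd, seed = seed)
    reps$responded <- TRUE
    reps$choice <- apply(z, 1, which.max)
    reps$rt <- NA_real_
  }
  nr <- !reps$responded
  if (any(nr)) {
    reps$choice[nr] <- withr_seed(seed + 104729L,
                                  sample(1:2, sum(nr), replace = TRUE))
  }
  reps$correct <- reps$choice == reps$correct_choice
  class(reps) <- "data.frame"
  reps
}

#' Summarize behavioral patterns from trial records
#'
#' Computes per-trial-type performance and RT matrices, symbolic-distance
#' curves split by correct choice, end-item contrasts and the end-order
#' index
#' `(RT_1st - RT_2nd) / (RT_1st + RT_2nd)`,
#' where `RT_1st` / `RT_2nd` are mean RTs pooled over trials with an end
#' item presented first / second (the two extreme-pair types, which
#' contain both end items, are excluded). Negative index = 1st-faster.
#' RT statistics use responded trials only; empty cells yield `NA`.
#'
#' @param records Trial records from [simulate_behavior()] (or any table
#'   with the same columns).
#' @return A list of class `behavior_summary`: `perf_matrix`, `rt_matrix`
#'   (n x n, diagonal `NA`), `distance` (data.frame by symbolic distance
#'   and correct choice), `end_item` (data.frame), `end_order`
#'   (`rt_1st`, `rt_2nd`, `index`), `n_records`, `p_no_response`.
#' @export
summarize_behavior <- function(records) {
  n <- max(records$rank1, records$rank2)
  perf <- matrix(NA_real_, n, n)
  rtm <- matrix(NA_real_, n, n)
  resp <- records[records$responded, ]
  agg_p <- stats::aggregate(correct ~ rank1 + rank2, records, mean)
  perf[cbind(agg_p$rank1, agg_p$rank2)] <- agg_p$correct
  if (nrow(resp)) {
    agg_rt <- stats::aggregate(rt ~ rank1 + rank2, resp, mean)
    rtm[cbind(agg_rt$rank1, agg_rt$rank2)] <- agg_rt$rt
  }
  dist_perf <- stats::aggregate(correct ~ symbolic_distance + correct_choice,
                                records, mean)
  dist_rt <- stats::aggregate(rt ~ symbolic_distance + correct_choice,
                              resp, mean)
  distance <- merge(dist_perf, dist_rt, all = TRUE)
  end_item <- data.frame(
    has_end_item = c(FALSE, TRUE),
    perf = c(mean(records$correct[!records$has_end_item]),
             mean(records$correct[records$has_end_item])),
    rt = c(mean(resp$rt[!resp$has_end_item]),
           mean(resp$rt[resp$has_end_item])))
  rt1 <- mean(resp$rt[resp$end_item_order == "1"])
  rt2 <- mean(resp$rt[resp$end_item_order == "2"])
  idx <- if (isTRUE(rt1 + rt2 > 0)) (rt1 - rt2) / (rt1 + rt2) else NA_real_
  structure(list(
    perf_matrix = perf, rt_matrix = rtm, distance = distance,
    end_item = end_item,
    end_order = list(rt_1st = rt1, rt_2nd = rt2, index = idx),
    n_records = nrow(records),
    p_no_response = mean(!records$responded)),
    class = "behavior_summary")
}

#' End-order index from two RT pools
#'
#' @param rt_1st,rt_2nd Mean RTs for end-item-first / end-item-second
#'   trials.
#' @return `(rt_1st - rt_2nd) / (rt_1st + rt_2nd)`.
#' @export
end_order_index <- function(rt_1st, rt_2nd) {
  (rt_1st - rt_2nd) / (rt_1st + rt_2nd)
}

#' Subject-level analysis of a trial table
#'
#' Applies the study's inclusion criteria, then computes per-subject block
#' performance, first-presentation performance on critical trials (test
#' types containing no end item), and the per-subject end-order index,
#' with two-sided non-parametric cohort tests (sign test on index signs;
#' Wilcoxon signed-rank against 0).
#'
#' Inclusion criteria (defaults follow the human study): (i) fewer than
#' `max_no_response` non-response trials; (ii) fewer than `max_blur`
#' attention-lapse events (only if a `blur_events` column is present);
#' (iii) fewer than `max_quiz_failures` comprehension-quiz failures (only
#' if a `quiz_failures` column is present); (iv) above `min_training_perf`
#' performance on training trials in the final training block
#' (non-responses count as incorrect).
#'
#' @param table A `subject_trials` table (see [generate_subjects()]).
#' @param max_no_response,max_blur,max_quiz_failures,min_training_perf
#'   Inclusion thresholds.
#' @param model_index Optional vector of model end-order indices to compare
#'   against the subject index distribution (1D Wasserstein distance).
#' @return A list of class `cohort_report`: `included` (logical by
#'   subject), `exclusion_reason`, `block_perf` (subject x block matrix),
#'   `first_presentation` (per-subject critical-trial first-presentation
#'   performance), `end_order` (per-subject index), `tests` (sign test and
#'   signed-rank p-values, cohort median), and `wasserstein` (or `NA`).
#' @export
analyze_subjects <- function(table, max_no_response = 20L, max_blur = 20L,
                             max_quiz_failures = 10L,
                             min_training_perf = 0.5,
                             model_index = NULL) {
  need <- c("subject", "phase", "block", "rank1", "rank2",
            "correct_choice", "symbolic_distance", "is_training",
            "has_end_item", "end_item_order", "choice", "responded",
            "correct", "rt")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  subjects <- sort(unique(table$subject))
  last_train_block <- max(table$block[table$phase == "training"])
  reason <- stats::setNames(rep(NA_character_, length(subjects)),
                            subjects)
  for (s in subjects) {
    d <- table[table$subject == s, ]
    if (sum(!d$responded) >= max_no_response) {
      reason[as.character(s)] <- "no-response"
    } else if (!is.null(d$blur_events) &&
               max(d$blur_events) >= max_blur) {
      reason[as.character(s)] <- "blur"
    } else if (!is.null(d$quiz_failures) &&
               max(d$quiz_failures) >= max_quiz_failures) {
      reason[as.character(s)] <- "quiz"
    } else {
      tb <- d[d$phase == "training" & d$block == last_train_block, ]
      if (mean(tb$correct) <= min_training_perf)
        reason[as.character(s)] <- "training-performance"
    }
  }
  included <- is.na(reason)
  inc <- table[table$subject %in% subjects[included], ]
  blocks <- sort(unique(table$block))
  block_perf <- t(vapply(subjects[included], function(s) {
    d <- inc[inc$subject == s, ]
    vapply(blocks, function(b) mean(d$correct[d$block == b]), numeric(1))
  }, numeric(length(blocks))))
  dimnames(block_perf) <- list(subjects[included], blocks)
  crit <- inc[!inc$is_training & !inc$has_end_item &
                inc$phase == "testing", ]
  first_pres <- vapply(subjects[included], function(s) {
    d <- crit[crit$subject == s, ]
    d <- d[order(d$trial), ]
    first <- !duplicated(d[, c("rank1", "rank2")])
    mean(d$correct[first])
  }, numeric(1))
  eo <- vapply(subjects[included], function(s) {
    d <- inc[inc$subject == s & inc$responded, ]
    end_order_index(mean(d$rt[d$end_item_order == "1"]),
                    mean(d$rt[d$end_item_order == "2"]))
  }, numeric(1))
  eo_ok <- eo[is.finite(eo)]
  nz <- eo_ok[eo_ok != 0]
  tests <- list(
    median_index = stats::median(eo_ok),
    sign_p = if (length(nz)) stats::binom.test(sum(nz < 0),
                                               length(nz))$p.value else NA,
    signed_rank_p = if (length(eo_ok) > 1)
      stats::wilcox.test(eo_ok, exact = length(eo_ok) < 30)$p.value else NA)
  wass <- if (is.null(model_index)) NA_real_
          else wasserstein1d(eo_ok, model_index)
  structure(list(
    included = stats::setNames(included, subjects),
    exclusion_reason = reason,
    block_perf = block_perf, first_presentation = first_pres,
    end_order = eo, tests = tests, wasserstein = wass),
    class = "cohort_report")
}

#' 1D Wasserstein (earth mover's) distance
#'
#' @param a,b Numeric samples (empirical distributions, equal weights).
#' @return The W1 distance between the empirical distributions.
#' @export
wasserstein1d <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  # exact: integrate |Qa(p) - Qb(p)| over the union of CDF breakpoints
  p <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  w <- diff(c(0, p))
  mid <- p - w / 2
  sum(w * abs(a[ceiling(mid * n)] - b[ceiling(mid * m)]))
}
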