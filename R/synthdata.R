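#' Random item panel
#'
#' Each abstract item (A, B, ...) is embedded as an `N_in`-dimensional
#' vector with i.i.d. standard-normal entries, modeling arbitrary
#' sensory-driven input patterns with no rank-informative features.
#'
#' @param n_items Number of items (default 7).
#' @param N_in Input dimensionality (default 100).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return An `item_panel`: list with `u` (n_items x N_in matrix, rows named
#'   by item) and `seed`.
#' @export
make_item_panel <- function(n_items = 7L, N_in = 100L, seed = 1L) {
  stopifnot(N_in >= 1L)
  sch <- ti_schema(n_items)
  u <- withr_seed(seed, {
    matrix(stats::rnorm(n_items * N_in), n_items, N_in)
  })
  rownames(u) <- sch$items
  structure(list(u = u, n_items = as.integer(n_items),
                 N_in = as.integer(N_in), seed = seed),
            class = "item_panel")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for synthetic subject cohorts
#'
#' Describes a cohort of synthetic subjects whose trial records follow the
#' human study's structure: a training phase of 3 blocks x 48 trials (each
#' of the 12 training types four times per block, subject-specific order)
#' and a testing phase of 6 blocks x 42 trials (each type once per block).
#'
#' Response times are generated additively (seconds):
#' `RT = rt_base - rt_distance_slope * (distance - 1) - rt_end_bonus *
#' has_end + rt_order_offset * (end item 1st) + N(0, rt_noise_sd)`,
#' truncated to `(0, rt_window]`. A negative `rt_order_offset` therefore
#' plants a 1st-faster cohort (negative end-order index). Accuracy follows
#' a lapse-mixed logistic model in symbolic distance with an end-item bonus:
#' `P(correct) = lapse/2 + (1 - lapse) * plogis(acc_intercept +
#' acc_distance_slope * (distance - 1) + acc_end_bonus * has_end)`.
#' Non-response is an independent Bernoulli per trial.
#'
#' @param n_subjects Cohort size.
#' @param rt_base Baseline RT in seconds.
#' @param rt_distance_slope RT decrease per unit symbolic distance (s).
#' @param rt_end_bonus RT decrease on end-item trials (s).
#' @param rt_order_offset Signed end-order offset (s), added when the end
#'   item is presented first; negative plants 1st-faster behavior.
#' @param rt_noise_sd Gaussian RT noise s.d. (s); must be non-negative.
#' @param rt_window Response window in seconds; RTs are truncated into
#'   `(0, rt_window]`.
#' @param acc_intercept,acc_distance_slope,acc_end_bonus Logistic accuracy
#'   model coefficients (distance enters as `distance - 1`).
#' @param lapse Lapse rate: probability of a uniformly random choice.
#' @param p_no_response Per-trial non-response probability.
#' @param seed Integer seed.
#' @return A `subject_config` list.
#' @export
subject_config <- function(n_subjects = 100L,
                           rt_base = 0.55,
                           rt_distance_slope = 0.02,
                           rt_end_bonus = 0.03,
                           rt_order_offset = -0.04,
                           rt_noise_sd = 0.10,
                           rt_window = 1.0,
                           acc_intercept = 0.5,
                           acc_distance_slope = 0.5,
                           acc_end_bonus = 0.5,
                           lapse = 0.05,
                           p_no_response = 0.02,
                           seed = 1L) {
  if (rt_noise_sd < 0) stop("config error: rt_noise_sd must be >= 0")
  stopifnot(lapse >= 0, lapse <= 1, p_no_response >= 0, p_no_response <= 1)
  structure(as.list(environment()), class = "subject_config")
}

#' Generate a synthetic subject trial table
#'
#' @param cfg A [subject_config()].
#' @return A data.frame (class `subject_trials`) with one row per trial:
#'   `subject`, `phase` ("training"/"testing"), `block`, `trial`, the
#'   trial-type columns of [enumerate_trial_types()], `choice` (1, 2 or NA),
#'   `responded`, `correct`, `rt` (seconds; NA when no response).
#' @export
generate_subjects <- function(cfg = subject_config()) {
  stopifnot(inherits(cfg, "subject_config"))
  tt <- enumerate_trial_types(7L)
  train_tt <- tt[tt$is_training, ]
  withr_seed(cfg$seed, {
    per_subject <- function(s) {
      blocks <- c(
        lapply(1:3, function(b)
          cbind(train_tt[sample(rep(seq_len(nrow(train_tt)), 4L)), ],
                phase = "training", block = b)),
        lapply(4:9, function(b)
          cbind(tt[sample(seq_len(nrow(tt))), ],
                phase = "testing", block = b)))
      d <- do.call(rbind, blocks)
      d$subject <- s
      d$trial <- seq_len(nrow(d))
      n <- nrow(d)
      end1 <- d$end_item_order %in% c("1", "both")
      # accuracy
      p_corr <- cfg$lapse / 2 +
        (1 - cfg$lapse) * stats::plogis(
          cfg$acc_intercept +
            cfg$acc_distance_slope * (d$symbolic_distance - 1) +
            cfg$acc_end_bonus * d$has_end_item)
      is_corr <- stats::runif(n) < p_corr
      d$choice <- ifelse(is_corr, d$correct_choice, 3L - d$correct_choice)
      # RT
      rt <- cfg$rt_base -
        cfg$rt_distance_slope * (d$symbolic_distance - 1) -
        cfg$rt_end_bonus * d$has_end_item +
        cfg$rt_order_offset * end1 +
        stats::rnorm(n, 0, cfg$rt_noise_sd)
      d$rt <- pmin(pmax(rt, 1e-3), cfg$rt_window)
      # non-response
      d$responded <- stats::runif(n) >= cfg$p_no_response
      d$choice[!d$responded] <- NA_integer_
      d$rt[!d$responded] <- NA_real_
      d$correct <- !is.na(d$choice) & d$choice == d$correct_choice
      d
    }
    out <- do.call(rbind, lapply(seq_len(cfg$n_subjects), per_subject))
    rownames(out) <- NULL
    cols <- c("subject", "phase", "block", "trial", "rank1", "rank2",
              "item1", "item2", "correct_choice", "symbolic_distance",
              "is_training", "has_end_item", "end_item_order",
              "choice", "responded", "correct", "rt")
    out <- out[, cols]
    class(out) <- c("subject_trials", "data.frame")
    out
  })
}

#' Gaussian random stand-in for an activity tensor
#'
#' Replaces every activity value with an i.i.d. standard-normal draw while
#' preserving the shape and metadata; used as the minimally structured
#' reference for the geometry indices.
#'
#' @param states A numeric array (e.g. an activity tensor).
#' @param seed Integer seed.
#' @return An array of the same shape (attributes preserved).
#' @export
random_activity_like <- function(states, seed = 1L) {
  out <- states
  out[] <- withr_seed(seed, stats::rnorm(length(states)))
  out
}
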