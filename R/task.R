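#' Transitive schema over n ranked items
#'
#' Items are labelled `A`, `B`, ... in rank order; rank 1 (`A`) is the
#' "highest" item under the transitive `>` relation, rank `n_items` the
#' lowest. The correct response to any ordered pair is the higher-ranked
#' (smaller-rank) item.
#'
#' @param n_items Number of items in the schema (default 7).
#' @return An object of class `ti_schema` with elements `n_items`, `items`
#'   (letter labels) and `rank` (named integer vector).
#' @export
ti_schema <- function(n_items = 7L) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 2L)
    stop("invalid schema: n_items must be an integer >= 2")
  items <- make.unique(rep(LETTERS, length.out = n_items), sep = "")
  structure(
    list(n_items = n_items, items = items,
         rank = stats::setNames(seq_len(n_items), items)),
    class = "ti_schema")
}

#' Enumerate all trial types of the TI task
#'
#' A trial type is an ordered pair of distinct items (item 1, item 2).
#' Adjacent pairs (symbolic distance 1) are training types; all others are
#' test types. For 7 items this gives 12 training and 30 test types.
#'
#' @param n_items Number of items, or a `ti_schema`.
#' @return A data.frame of class `ti_trial_types` in canonical row-major
#'   order (by `rank1`, then `rank2`) with columns `rank1`, `rank2`, `item1`,
#'   `item2`, `correct_choice`, `symbolic_distance`, `is_training`,
#'   `has_end_item`, `end_item_order` (`1`, `2` or `"none"`; `"both"` for
#'   the two extreme-pair types).
#' @export
enumerate_trial_types <- function(n_items = 7L) {
  sch <- if (inherits(n_items, "ti_schema")) n_items else ti_schema(n_items)
  n <- sch$n_items
  grid <- expand.grid(rank2 = seq_len(n), rank1 = seq_len(n))
  grid <- grid[grid$rank1 != grid$rank2, c("rank1", "rank2")]
  grid <- grid[order(grid$rank1, grid$rank2), ]
  rownames(grid) <- NULL
  end1 <- grid$rank1 %in% c(1L, n)
  end2 <- grid$rank2 %in% c(1L, n)
  tt <- data.frame(
    rank1 = grid$rank1,
    rank2 = grid$rank2,
    item1 = sch$items[grid$rank1],
    item2 = sch$items[grid$rank2],
    correct_choice = ifelse(grid$rank1 < grid$rank2, 1L, 2L),
    symbolic_distance = abs(grid$rank1 - grid$rank2),
    stringsAsFactors = FALSE)
  tt$is_training <- tt$symbolic_distance == 1L
  tt$has_end_item <- end1 | end2
  tt$end_item_order <- ifelse(end1 & end2, "both",
                       ifelse(end1, "1", ifelse(end2, "2", "none")))
  class(tt) <- c("ti_trial_types", "data.frame")
  tt
}

#' Correct choice for a trial type
#'
#' @param rank1,rank2 Integer ranks of items 1 and 2 (1 = highest).
#' @return `1L` if item 1 is the higher item (smaller rank), else `2L`.
#' @export
correct_choice <- function(rank1, rank2) {
  if (any(rank1 == rank2)) stop("undefined choice: rank1 == rank2")
  ifelse(rank1 < rank2, 1L, 2L)
}

#' Trial timing for delay TI
#'
#' Times are in units of the network time constant tau, discretized at
#' `dt` (default tau/10). The three delay variants are: `basic` with rest,
#' delay and choice periods of 0.5, 2 and 2 tau; `extended` with 0.5, 6 and
#' 6 tau; and `variable`, with the rest period and total trial duration of
#' the extended variant but the delay drawn uniformly over `[2, 6]` tau by
#' shifting the item-2 pulse (the choice period absorbs the difference).
#'
#' The item-1 pulse occupies the single timestep between rest and delay, the
#' item-2 pulse the single timestep between delay and choice, so the basic
#' variant has 5 + 1 + 20 + 1 + 20 = 47 steps.
#'
#' @param delay_variant One of `"basic"`, `"extended"`, `"variable"`.
#' @param dt Time step in units of tau (default 0.1).
#' @param delay_steps For `variable` only: realized delay in steps; `NULL`
#'   leaves it unset (per-trial draws happen at input-building time).
#' @return An object of class `ti_timing` with period step counts and the
#'   index layout (`pulse1`, `pulse2`, `rest_idx`, `delay_idx`,
#'   `choice_idx`, `n_steps`).
#' @export
ti_timing <- function(delay_variant = c("basic", "extended", "variable"),
                      dt = 0.1, delay_steps = NULL) {
  delay_variant <- match.arg(delay_variant)
  stopifnot(dt > 0)
  steps <- function(dur) as.integer(round(dur / dt))
  rest <- steps(0.5)
  lims <- c(steps(2), steps(6))
  if (delay_variant == "basic") {
    delay <- steps(2); choice <- steps(2); total <- rest + 2L + delay + choice
  } else {
    total <- rest + 2L + steps(6) + steps(6)
    if (delay_variant == "extended" || is.null(delay_steps)) {
      delay <- steps(6)
    } else {
      delay <- as.integer(delay_steps)
      if (delay < lims[1] || delay > lims[2])
        stop("timing error: variable delay outside [2 tau, 6 tau]")
    }
    choice <- total - rest - 2L - delay
  }
  p1 <- rest + 1L
  p2 <- p1 + delay + 1L
  structure(
    list(delay_variant = delay_variant, dt = dt,
         n_rest = rest, n_delay = delay, n_choice = choice,
         delay_lim = lims,
         pulse1 = p1, pulse2 = p2,
         rest_idx = seq_len(rest),
         delay_idx = seq.int(p1 + 1L, p1 + delay),
         choice_idx = seq.int(p2 + 1L, p2 + choice),
         n_steps = p2 + choice),
    class = "ti_timing")
}

#' Build the time-resolved input and target for one delay-TI trial
#'
#' Items are presented as instantaneous single-timestep pulses; the input is
#' zero at all other times. Targets are piecewise constant: the rest output
#' unit is held at the activated value (5) from trial start through the
#' item-2 pulse, and the correct choice unit at 5 during the choice period;
#' all other targets are 0.
#'
#' @param panel An `item_panel` (see [make_item_panel()]).
#' @param trial One row of [enumerate_trial_types()] (or a list with
#'   `rank1`, `rank2`).
#' @param timing A `ti_timing`. For the `variable` variant with unset delay,
#'   a per-trial delay is drawn uniformly over the allowed steps.
#' @param z_active Activated target value (default 5).
#' @return A list with `input` (n_steps x N_in matrix), `target`
#'   (n_steps x 3 matrix: choice 1, choice 2, rest) and `timing` (the
#'   realized `ti_timing`).
#' @export
build_trial_input <- function(panel, trial, timing = ti_timing(),
                              z_active = 5) {
  stopifnot(inherits(panel, "item_panel"))
  if (timing$delay_variant == "variable" && is.null(timing$realized)) {
    d <- sample(seq.int(timing$delay_lim[1], timing$delay_lim[2]), 1L)
    timing <- ti_timing("variable", dt = timing$dt, delay_steps = d)
    timing$realized <- TRUE
  }
  T_ <- timing$n_steps
  u <- matrix(0, T_, ncol(panel$u))
  u[timing$pulse1, ] <- panel$u[trial$rank1, ]
  u[timing$pulse2, ] <- panel$u[trial$rank2, ]
  target <- matrix(0, T_, 3L)
  target[seq_len(timing$pulse2), 3L] <- z_active
  target[timing$choice_idx, correct_choice(trial$rank1, trial$rank2)] <- z_active
  list(input = u, target = target, timing = timing)
}

#' Build the flat input vector for traditional (simultaneous) TI
#'
#' Feedforward models receive both items jointly, concatenated as
#' `c(u_item1, u_item2)`, doubling the input dimensionality.
#'
#' @inheritParams build_trial_input
#' @return Numeric vector of length `2 * N_in`.
#' @export
build_traditional_input <- function(panel, trial) {
  stopifnot(inherits(panel, "item_panel"))
  c(panel$u[trial$rank1, ], panel$u[trial$rank2, ])
}

#' Export the trial-type table as CSV
#'
#' @param tt A `ti_trial_types` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_types <- function(tt, path) {
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE)
  invisible(path)
}
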