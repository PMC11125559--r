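#' Experiment configuration for a sweep
#'
#' @param variants Character vector of RNN variants.
#' @param regimes Character vector of constraint regimes.
#' @param delay_variant `"basic"`, `"extended"` or `"variable"`.
#' @param n_instances Instances per (variant, regime) cell.
#' @param seed Base seed; each instance gets a unique derived seed.
#' @param n_per_type Behavioral simulations per trial type (full scale
#'   500; reduce for desk-scale runs).
#' @param N,N_in Network size and input dimensionality (reduce for
#'   desk-scale runs).
#' @param n_per_type_titrate Simulations per type during noise titration
#'   (defaults to `n_per_type`).
#' @param eval_every Epoch interval of the noise-free all-correct stopping
#'   check (1 = every epoch; larger values trade at most `eval_every - 1`
#'   extra epochs for a faster loop).
#' @param max_epochs Training epoch cap.
#' @param analyses Analysis toggles: subset of `"behavior"`, `"geometry"`,
#'   `"dynamics"`, `"encoding"`.
#' @param out_dir Run directory for checkpoints and the manifest.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(variants = c("f-RNN", "r-RNN"),
                              regimes = c("highest", "lowest"),
                              delay_variant = "basic",
                              n_instances = 3L, seed = 1L,
                              n_per_type = 500L,
                              n_per_type_titrate = n_per_type,
                              N = 100L, N_in = 100L,
                              eval_every = 1L, max_epochs = 30000L,
                              analyses = c("behavior", "geometry",
                                           "dynamics", "encoding"),
                              out_dir = tempfile("ti_sweep_")) {
  stopifnot(all(variants %in% rnn_variants))
  structure(as.list(environment()), class = "experiment_config")
}

instance_seed <- function(base, cell, inst) {
  (as.numeric(base) * 7919 + cell * 611953 + inst * 104729) %% 2147483647
}

#' Run a (variant x regime x instance) sweep
#'
#' Trains each instance, keeps full generalizers, titrates noise, runs
#' behavioral simulations and the dynamics/geometry/encoding analyses per
#' the toggles. Per-instance artifacts are cached under `out_dir`; rerun
#' with the same config resumes from the cache. Per-instance failures
#' (e.g. titration failure) are recorded, never fatal.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-instance progress lines.
#' @return A data.frame of class `run_manifest`: one row per instance with
#'   status fields and summary statistics (end-order index, collinearity
#'   early/late/change, mean angle change, oscillation frequency, encoding
#'   index, linear-fit R2, PC variance), plus attribute `out_dir`.
#' @export
run_sweep <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(file.path(cfg$out_dir, "instances"), recursive = TRUE,
             showWarnings = FALSE)
  cells <- expand.grid(variant = cfg$variants, regime = cfg$regimes,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    for (inst in seq_len(cfg$n_instances)) {
      variant <- cells$variant[ci]; regime <- cells$regime[ci]
      sd <- instance_seed(cfg$seed, ci, inst)
      tag <- sprintf("%s_%s_i%02d_s%.0f", variant, regime, inst, sd)
      cache <- file.path(cfg$out_dir, "instances", paste0(tag, ".rds"))
      if (file.exists(cache)) {
        rows[[tag]] <- readRDS(cache)$row
        next
      }
      if (progress) message("instance ", tag)
      res <- analyze_instance(variant, regime, cfg, sd)
      res$row <- cbind(data.frame(variant = variant, regime = regime,
                                  instance = inst, seed = sd,
                                  stringsAsFactors = FALSE),
                       res$stats)
      saveRDS(res, cache)
      rows[[tag]] <- res$row
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(0), regime = character(0),
               instance = integer(0), seed = numeric(0))
  rownames(manifest) <- NULL
  attr(manifest, "out_dir") <- cfg$out_dir
  class(manifest) <- c("run_manifest", "data.frame")
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# train + analyze one instance; returns list(stats=..., params=..., ...)
analyze_instance <- function(variant, regime, cfg, sd) {
  timing <- ti_timing(cfg$delay_variant)
  panel <- make_item_panel(N_in = cfg$N_in, seed = sd)
  net <- init_network(variant, regime, N = cfg$N, N_in = cfg$N_in,
                      seed = sd + 1)
  rep <- train_rnn(net, panel, timing, seed = sd + 2,
                   max_epochs = cfg$max_epochs,
                   eval_every = cfg$eval_every)
  stats <- data.frame(
    trained = TRUE, epochs = rep$epochs, stop_reason = rep$stop_reason,
    generalized = rep$generalization$full_generalizer,
    n_correct = rep$generalization$n_correct,
    noise_level = NA_real_, end_order_index = NA_real_,
    coll_early = NA_real_, coll_late = NA_real_, coll_change = NA_real_,
    ordered_early = NA_real_, ordered_late = NA_real_,
    mean_angle_change = NA_real_, mean_distance_change = NA_real_,
    osc_frequency = NA_real_, linfit_R2 = NA_real_,
    encoding_index = NA_real_, pc3_var = NA_real_,
    note = "", stringsAsFactors = FALSE)
  out <- list(params = rep$params, report = rep)
  if (!stats$generalized) {
    stats$note <- "not a full generalizer"
    out$stats <- stats
    return(out)
  }
  atiming <- analysis_timing(timing)
  tt <- enumerate_trial_types(panel$n_items)
  sim <- simulate_rnn(rep$params, panel, tt, atiming, noise_sd = 0)
  dact <- delay_activity(sim)
  if ("behavior" %in% cfg$analyses) {
    lev <- tryCatch(titrate_noise(rep$params, panel, timing,
                                  n_per_type = cfg$n_per_type_titrate,
                                  seed = sd + 3),
                    titration_failure = function(e) NA_real_)
    stats$noise_level <- lev
    if (!is.na(lev)) {
      recs <- simulate_behavior(rep$params, panel, lev, timing,
                                n_per_type = cfg$n_per_type, seed = sd + 4)
      bs <- summarize_behavior(recs)
      stats$end_order_index <- bs$end_order$index
      out$behavior <- bs
    } else stats$note <- "titration failure"
  }
  if ("geometry" %in% cfg$analyses) {
    geo <- geometry_report(dact)
    stats$coll_early <- geo$collinearity$early
    stats$coll_late <- geo$collinearity$late
    stats$coll_change <- geo$collinearity$change
    stats$ordered_early <- geo$ordered_collinearity$early
    stats$ordered_late <- geo$ordered_collinearity$late
    stats$mean_angle_change <- geo$mean_angle_change
    stats$mean_distance_change <- geo$mean_distance_change
    out$geometry <- geo
  }
  if ("dynamics" %in% cfg$analyses) {
    fit <- fit_linear_dynamics(dact)
    osc <- identify_comparison_oscillation(fit)
    stats$linfit_R2 <- fit$R2
    stats$osc_frequency <- osc$frequency
    # dimensionality of the comprehensive activity set (all times/types)
    full <- matrix(sim$x, prod(dim(sim$x)[1:2]), dim(sim$x)[3])
    ev <- stats::prcomp(full, center = TRUE)$sdev^2
    stats$pc3_var <- 100 * sum(ev[1:3]) / sum(ev)
    out$lindyn <- fit; out$oscillation <- osc
  }
  if ("encoding" %in% cfg$analyses) {
    # readout encoding is z1 = W1 r + c1, i.e. projection of the rates
    enc <- encoding_index(tanh(dact), rep$params$W[1, ],
                          bias = rep$params$c[1])
    stats$encoding_index <- enc$index
    out$encoding <- enc
  }
  out$stats <- stats
  out
}

#' Build a summary report from a run manifest
#'
#' Aggregates per (variant, regime) cell: generalizer counts, cohort means
#' of the behavioral and geometric statistics, and a qualitative grid
#' (sign/threshold calls mirroring the main-predictions table: end-order
#' version, collinearity early/late above 0.5, change sign, mean-angle
#' -change sign, oscillation near 0.5 cycles/delay, encoding version).
#' Optionally compares the cohort end-order distribution to a subject
#' cohort by Wasserstein distance.
#'
#' @param manifest A `run_manifest`.
#' @param subject_table Optional `subject_trials` table.
#' @param coll_threshold Collinearity threshold for the grid (default 0.5).
#' @param out_dir Optional directory to write `report.json` and
#'   `report.csv` into.
#' @return List of class `sweep_report`: `cells` (aggregate data.frame),
#'   `grid` (qualitative calls), `wasserstein` (or `NA`), `n_flagged`
#'   (cells with n = 1).
#' @export
build_report <- function(manifest, subject_table = NULL,
                         coll_threshold = 0.5, out_dir = NULL) {
  stopifnot(inherits(manifest, "run_manifest") || is.data.frame(manifest))
  if (!nrow(manifest)) {
    return(structure(list(cells = manifest, grid = NULL,
                          wasserstein = NA_real_, n_flagged = 0L),
                     class = "sweep_report"))
  }
  key <- interaction(manifest$variant, manifest$regime, drop = TRUE)
  agg <- function(f, col) tapply(manifest[[col]], key, f)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  cells <- data.frame(
    cell = levels(key),
    n = as.integer(table(key)),
    n_generalized = as.integer(agg(sum, "generalized")),
    end_order_index = as.numeric(agg(mean_na, "end_order_index")),
    coll_early = as.numeric(agg(mean_na, "coll_early")),
    coll_late = as.numeric(agg(mean_na, "coll_late")),
    coll_change = as.numeric(agg(mean_na, "coll_change")),
    mean_angle_change = as.numeric(agg(mean_na, "mean_angle_change")),
    osc_frequency = as.numeric(agg(mean_na, "osc_frequency")),
    encoding_index = as.numeric(agg(mean_na, "encoding_index")),
    pc3_var = as.numeric(agg(mean_na, "pc3_var")),
    stringsAsFactors = FALSE)
  grid <- data.frame(
    cell = cells$cell,
    end_order = ifelse(is.na(cells$end_order_index), NA,
                       ifelse(cells$end_order_index > 0, "2nd-faster",
                              "1st-faster")),
    coll_early = ifelse(is.na(cells$coll_early), NA,
                        ifelse(cells$coll_early > coll_threshold,
                               ">0.5", "<=0.5")),
    coll_late = ifelse(is.na(cells$coll_late), NA,
                       ifelse(cells$coll_late > coll_threshold,
                              ">0.5", "<=0.5")),
    coll_change = ifelse(is.na(cells$coll_change), NA,
                         ifelse(cells$coll_change > 0, ">0", "<0")),
    mean_angle_change = ifelse(is.na(cells$mean_angle_change), NA,
                               ifelse(cells$mean_angle_change > 0,
                                      ">0", "<0")),
    oscillation = ifelse(is.na(cells$osc_frequency), NA,
                         ifelse(abs(cells$osc_frequency - 0.5) < 0.15,
                                "~0.5 cycles/delay", "other")),
    encoding = ifelse(is.na(cells$encoding_index), NA,
                      ifelse(cells$encoding_index > 0,
                             "1st-dominant", "2nd-dominant")),
    stringsAsFactors = FALSE)
  wass <- NA_real_
  if (!is.null(subject_table)) {
    rep_s <- analyze_subjects(subject_table)
    model_idx <- manifest$end_order_index[!is.na(manifest$end_order_index)]
    if (length(model_idx))
      wass <- wasserstein1d(rep_s$end_order[is.finite(rep_s$end_order)],
                            model_idx)
  }
  rep <- structure(list(cells = cells, grid = grid, wasserstein = wass,
                        n_flagged = sum(cells$n == 1L)),
                   class = "sweep_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(cells = cells, grid = grid, wasserstein = wass),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    utils::write.csv(cells, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
  }
  rep
}
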