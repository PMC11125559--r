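# Shared trained cohorts for the acceptance criteria. Training dominates
# the acceptance-suite runtime, so everything is desk-scale and stated:
# 5 instances per fully-trainable cell and 3 per recurrent-only cell
# (full scale: 200); behavioral simulation at 100
# trials per type with titration at 50 (full scale: 500); the stopping
# check runs every 5 epochs instead of every epoch (at most 4 extra
# epochs per instance); and the r-RNN cell is capped at 5000 epochs
# (full-scale cap 30000) — instances that have not converged by then are
# excluded exactly like the full-scale study's non-generalizers. Cohorts are trained
# once per test run via run_sweep's cache.

acceptance_sweep <- function() {
  memo("acceptance_sweep", {
    out_dir <- file.path(tempdir(), "delayti-acceptance-sweep")
    cfg_f <- experiment_config(
      variants = "f-RNN", regimes = c("highest", "lowest"),
      n_instances = 5L, seed = 20260910L, n_per_type = 100L,
      n_per_type_titrate = 50L, eval_every = 5L,
      max_epochs = 25000L, out_dir = out_dir)
    cfg_r <- experiment_config(
      variants = "r-RNN", regimes = "highest",
      n_instances = 3L, seed = 20260910L, n_per_type = 100L,
      n_per_type_titrate = 50L, eval_every = 5L,
      max_epochs = 5000L, out_dir = out_dir)
    m <- rbind(run_sweep(cfg_f, progress = FALSE),
               run_sweep(cfg_r, progress = FALSE))
    attr(m, "out_dir") <- out_dir
    m
  })
}

cohort <- function(manifest, variant, regime) {
  manifest[manifest$variant == variant & manifest$regime == regime &
             manifest$generalized, , drop = FALSE]
}

# full per-instance artifacts (behavior summaries, linear fits, params)
instance_artifacts <- function(manifest) {
  dir <- file.path(attr(manifest, "out_dir"), "instances")
  files <- list.files(dir, full.names = TRUE)
  arts <- lapply(files, readRDS)
  names(arts) <- sub("\\.rds$", "", basename(files))
  arts
}
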