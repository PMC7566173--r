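# Experiment runners: per-condition Monte Carlo, 5x5 capability grids,
# behavioral indices, fit statistics against a reference grid, and the
# synthetic reference-grid generator.

#' Default capability levels
#'
#' Five levels from 30% to 70% for both the auto and the manual command
#' success probability, giving the 25-condition factorial design.
#' @export
CAPABILITY_LEVELS <- seq(0.3, 0.7, by = 0.1)

#' Enumerate the factorial design
#'
#' @param ca_levels,cm_levels capability levels for the two axes.
#' @return data.frame with columns `ca`, `cm`, one row per condition.
#' @export
grid_conditions <- function(ca_levels = CAPABILITY_LEVELS,
                            cm_levels = CAPABILITY_LEVELS) {
  stopifnot(length(ca_levels) > 0, length(cm_levels) > 0)
  g <- expand.grid(cm = cm_levels, ca = ca_levels,
                   KEEP.OUT.ATTRS = FALSE)[, c("ca", "cm")]
  rownames(g) <- NULL
  g
}

# Deterministic per-trial seed from (master seed, condition, run index).
# Exact in double arithmetic (products stay far below 2^53) and below
# 2^31, so any single trial is reproducible in isolation and conditions
# can be run in any order.
derive_trial_seed <- function(master_seed, ca, cm, run, tag = 0) {
  key <- tag * 1e8 + round(ca * 10) * 1e6 + round(cm * 10) * 1e4 + run
  v <- ((master_seed %% 2147483647) * 48271 + key * 7919) %% 2147483587
  as.integer(v)
}

agent_tag <- function(agent) {
  if (is.character(agent))
    return(match(agent, c("auto_only", "do_nothing", "hold_left",
                          "hold_right")))
  4L + match(agent$rewarding, c("default", "smdp")) * 2L +
    match(agent$conflict, c("default", "gating")) +
    if (isTRUE(agent$manual_only)) 8L else 0L
}

agent_label <- function(agent) {
  if (is.character(agent)) return(agent)
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  lab <- paste0(cap(agent$conflict), "-",
                ifelse(agent$rewarding == "smdp", "SMDP", "Default"))
  if (isTRUE(agent$manual_only)) paste0(lab, " (manual-only)") else lab
}

#' Run one (Ca, Cm) condition
#'
#' Runs `n_runs` independent trials with per-trial seeds derived from
#' `(master_seed, ca, cm, run index)` and summarizes the three behavioral
#' indices.
#'
#' @param agent an `lf_model` or scripted-agent name (see [run_trial()]).
#' @param ca,cm capability levels.
#' @param n_runs number of trials (`>= 1`).
#' @param master_seed integer master seed.
#' @param config an [env_config()]; its `ca`/`cm` are overridden.
#' @return one-row data.frame (class `lf_condition_summary`): `ca`, `cm`,
#'   `model`, means and standard deviations of the three indices, and
#'   `n_runs`.  With `n_runs = 1` the standard deviations are 0 by
#'   convention.
#' @export
run_condition <- function(agent, ca, cm, n_runs = 500, master_seed = 1,
                          config = env_config()) {
  stopifnot(n_runs >= 1)
  config$ca <- ca
  config$cm <- cm
  tag <- agent_tag(agent)
  perf <- auto <- sw <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    s <- derive_trial_seed(master_seed, ca, cm, i, tag)
    tr <- run_trial(agent, config, seed = s)
    perf[i] <- tr$performance
    auto[i] <- tr$auto_use_ratio
    sw[i] <- tr$n_switches
  }
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  out <- data.frame(
    ca = ca, cm = cm, model = agent_label(agent),
    performance_mean = mean(perf), performance_sd = sd0(perf),
    auto_use_mean = mean(auto), auto_use_sd = sd0(auto),
    switches_mean = mean(sw), switches_sd = sd0(sw),
    n_runs = n_runs)
  class(out) <- c("lf_condition_summary", "data.frame")
  out
}

#' Run a full factorial capability sweep
#'
#' The full `length(ca_levels) x length(cm_levels)` factorial (25
#' conditions at the defaults).  Per-condition seeding makes the grid
#' exchangeable: any execution order yields identical summaries.
#'
#' @inheritParams run_condition
#' @param ca_levels,cm_levels capability levels.
#' @return data.frame of condition summaries (class `lf_grid`), one row
#'   per condition, with attributes `master_seed` and `config_hash`.
#' @export
run_grid <- function(agent, ca_levels = CAPABILITY_LEVELS,
                     cm_levels = CAPABILITY_LEVELS,
                     n_runs = 500, master_seed = 1, config = env_config()) {
  design <- grid_conditions(ca_levels, cm_levels)
  rows <- lapply(seq_len(nrow(design)), function(i)
    run_condition(agent, design$ca[i], design$cm[i], n_runs,
                  master_seed, config))
  out <- do.call(rbind, rows)
  attr(out, "master_seed") <- master_seed
  attr(out, "config_hash") <- config_hash(config)
  class(out) <- c("lf_grid", "data.frame")
  out
}

#' Baseline sweep: auto-only controller and manual-only model
#'
#' The base-level comparison: the scripted auto controller swept over the
#' `ca` levels and the manual-only cognitive model (the `ToAuto` rule
#' removed, initial mode manual) swept over the `cm` levels.
#'
#' @param levels capability levels for both sweeps.
#' @param n_runs trials per level.
#' @param master_seed integer master seed.
#' @param config an [env_config()].
#' @param rewarding rewarding scheme of the manual-only model.
#' @return data.frame with one row per (agent, level).
#' @export
run_baseline <- function(levels = CAPABILITY_LEVELS, n_runs = 500,
                         master_seed = 1, config = env_config(),
                         rewarding = "default") {
  manual_model <- build_model(rewarding = rewarding, manual_only = TRUE)
  rows <- list()
  for (lv in levels)
    rows[[length(rows) + 1L]] <-
      run_condition("auto_only", ca = lv, cm = lv, n_runs, master_seed, config)
  for (lv in levels)
    rows[[length(rows) + 1L]] <-
      run_condition(manual_model, ca = lv, cm = lv, n_runs, master_seed, config)
  out <- do.call(rbind, rows)
  out$agent <- rep(c("auto_only", "manual_model"), each = length(levels))
  out$level <- rep(levels, 2)
  out
}

#' Fit statistics between a model grid and a reference grid
#'
#' For each behavioral index, the squared Pearson correlation across the
#' paired condition means and the root-mean-square error.  R^2 is the
#' squared Pearson correlation throughout; with zero variance in either
#' vector it is undefined and reported as `NA`.
#'
#' @param model_grid an `lf_grid` (columns `*_mean`) or a plain grid with
#'   columns `performance`, `auto_use`, `switches`.
#' @param reference_grid a reference grid (`ca`, `cm`, `performance`,
#'   `auto_use`, `switches`), e.g. from [load_reference()] or
#'   [synth_reference()].
#' @return data.frame with columns `index`, `r_squared`, `rmse`.
#' @export
fit_stats <- function(model_grid, reference_grid) {
  m <- normalize_grid(model_grid)
  r <- normalize_grid(reference_grid)
  key_m <- paste(m$ca, m$cm)
  key_r <- paste(r$ca, r$cm)
  if (nrow(m) != nrow(r) || !all(sort(key_m) == sort(key_r)))
    stop("model and reference grids must cover identical (ca, cm) cells")
  r <- r[match(key_m, key_r), ]
  one <- function(index) {
    x <- m[[index]]; y <- r[[index]]
    r2 <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)^2
    data.frame(index = index, r_squared = r2,
               rmse = sqrt(mean((x - y)^2)))
  }
  do.call(rbind, lapply(c("performance", "auto_use", "switches"), one))
}

normalize_grid <- function(g) {
  if (all(c("performance_mean", "auto_use_mean", "switches_mean") %in% names(g)))
    return(data.frame(ca = g$ca, cm = g$cm,
                      performance = g$performance_mean,
                      auto_use = g$auto_use_mean,
                      switches = g$switches_mean))
  need <- c("ca", "cm", "performance", "auto_use", "switches")
  if (!all(need %in% names(g)))
    stop("grid must have columns ", paste(need, collapse = ", "))
  g[, need]
}

#' Load a reference behavioral grid from CSV
#'
#' Expects columns `ca`, `cm`, `performance`, `auto_use`, `switches` and
#' exactly one row per cell of the factorial design.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @param ca_levels,cm_levels the expected design.
#' @return validated reference grid keyed by (ca, cm).
#' @export
load_reference <- function(path, ca_levels = CAPABILITY_LEVELS,
                           cm_levels = CAPABILITY_LEVELS) {
  g <- read.csv(path, comment.char = "#")
  need <- c("ca", "cm", "performance", "auto_use", "switches")
  if (!all(need %in% names(g)))
    stop("reference grid must have columns ", paste(need, collapse = ", "))
  design <- grid_conditions(ca_levels, cm_levels)
  key <- paste(g$ca, g$cm)
  want <- paste(design$ca, design$cm)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicated cell(s): (ca, cm) = ", paste(dup, collapse = "; "))
  missing <- setdiff(want, key)
  if (length(missing))
    stop("missing cell(s): (ca, cm) = ", paste(missing, collapse = "; "))
  extra <- setdiff(key, want)
  if (length(extra))
    stop("unexpected cell(s): (ca, cm) = ", paste(extra, collapse = "; "))
  bad <- g$performance < 0 | g$performance > 1
  if (any(bad))
    stop("performance outside [0, 1] at (ca, cm) = ",
         paste(key[bad], collapse = "; "))
  bad <- g$auto_use < 0 | g$auto_use > 1
  if (any(bad))
    stop("auto_use outside [0, 1] at (ca, cm) = ",
         paste(key[bad], collapse = "; "))
  if (any(g$switches < 0))
    stop("negative switch count at (ca, cm) = ",
         paste(key[g$switches < 0], collapse = "; "))
  g[match(want, key), need]
}

#' Synthesize a reference grid with configured monotone trends
#'
#' A fixture emulating the qualitative shape of the behavioral surfaces:
#' performance increasing in both capabilities, auto use increasing in Ca
#' and decreasing in Cm, switch count decreasing in both; Gaussian noise
#' on top.  Used to exercise the fit machinery without participant data.
#'
#' @param seed integer seed.
#' @param trend list of linear trend coefficients and noise scales; see
#'   the defaults in the function body.
#' @param ca_levels,cm_levels the design.
#' @return a reference grid (`ca`, `cm`, `performance`, `auto_use`,
#'   `switches`).
#' @export
synth_reference <- function(seed = 1,
                            trend = list(
                              performance = c(base = 0.50, ca = 0.75, cm = 0.40),
                              auto_use    = c(base = 0.55, ca = 0.60, cm = -0.50),
                              switches    = c(base = 14,   ca = -20,  cm = -12),
                              noise       = c(performance = 0.02,
                                              auto_use = 0.03, switches = 1)),
                            ca_levels = CAPABILITY_LEVELS,
                            cm_levels = CAPABILITY_LEVELS) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  g <- grid_conditions(ca_levels, cm_levels)
  lin <- function(cf, noise) {
    v <- cf[["base"]] + cf[["ca"]] * (g$ca - 0.5) + cf[["cm"]] * (g$cm - 0.5)
    v + rnorm(nrow(g), 0, noise)
  }
  g$performance <- pmin(pmax(lin(trend$performance,
                                 trend$noise[["performance"]]), 0), 1)
  g$auto_use <- pmin(pmax(lin(trend$auto_use, trend$noise[["auto_use"]]), 0), 1)
  g$switches <- pmax(lin(trend$switches, trend$noise[["switches"]]), 0)
  g
}

# Small polynomial hash over the serialized object; used to stamp output
# CSVs so a grid can be traced back to its exact configuration.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a grid (or any summary table) to CSV with provenance
#'
#' Embeds the master seed and the configuration hash as leading comment
#' lines.
#'
#' @param grid a data.frame, typically an `lf_grid`.
#' @param path output path.
#' @param master_seed,config optional overrides; defaults come from the
#'   grid's attributes.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, master_seed = NULL, config = NULL) {
  seed <- master_seed %||% attr(grid, "master_seed")
  hash <- if (!is.null(config)) config_hash(config) else attr(grid, "config_hash")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("# master_seed: ", seed %||% NA),
               paste0("# config_hash: ", hash %||% NA)), con)
  write.csv(as.data.frame(grid), con, row.names = FALSE)
  invisible(path)
}
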