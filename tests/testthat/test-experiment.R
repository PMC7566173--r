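test_that("the factorial design enumerates every capability cell once", {
  g <- grid_conditions()
  expect_identical(nrow(g), 25L)
  expect_identical(anyDuplicated(g), 0L)
  expect_setequal(unique(g$ca), CAPABILITY_LEVELS)
  expect_setequal(unique(g$cm), CAPABILITY_LEVELS)
  g2 <- grid_conditions(c(0.3, 0.7), 0.5)
  expect_identical(nrow(g2), 2L)
})

test_that("condition summaries are deterministic in the master seed", {
  m <- build_model("smdp", "gating")
  a <- run_condition(m, 0.5, 0.5, n_runs = 4, master_seed = 9)
  b <- run_condition(m, 0.5, 0.5, n_runs = 4, master_seed = 9)
  expect_identical(a, b)
  c1 <- run_condition(m, 0.5, 0.5, n_runs = 4, master_seed = 10)
  expect_false(identical(a$performance_mean, c1$performance_mean))
  # single run: standard deviations are 0 by convention
  one <- run_condition("auto_only", 0.5, 0.5, n_runs = 1, master_seed = 1)
  expect_identical(one$performance_sd, 0)
  expect_identical(one$n_runs, 1)
})

test_that("grids are exchangeable across execution order", {
  m <- build_model("default", "default")
  g <- run_grid(m, ca_levels = c(0.3, 0.7), cm_levels = c(0.4, 0.6),
                n_runs = 3, master_seed = 5)
  expect_identical(nrow(g), 4L)
  # re-run one cell in isolation: identical to its row in the grid
  cell <- run_condition(m, 0.7, 0.4, n_runs = 3, master_seed = 5)
  row <- g[g$ca == 0.7 & g$cm == 0.4, ]
  rownames(row) <- rownames(cell) <- NULL
  expect_equal(as.data.frame(row), as.data.frame(cell), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fit statistics match hand arithmetic", {
  mk <- function(v) data.frame(ca = c(0.3, 0.5, 0.7), cm = 0.5,
                               performance = v, auto_use = v,
                               switches = v * 10)
  ident <- fit_stats(mk(c(0.2, 0.5, 0.8)), mk(c(0.2, 0.5, 0.8)))
  expect_equal(ident$r_squared, rep(1, 3), tolerance = 1e-12)
  expect_equal(ident$rmse, rep(0, 3), tolerance = 1e-12)
  # model (0.2, 0.5, 0.8) vs reference (0.3, 0.5, 0.7)
  fs <- fit_stats(mk(c(0.2, 0.5, 0.8)), mk(c(0.3, 0.5, 0.7)))
  expect_equal(fs$r_squared[1], 1, tolerance = 1e-12)
  expect_equal(fs$rmse[1], sqrt(mean(c(-0.1, 0, 0.1)^2)), tolerance = 1e-12)
  expect_equal(fs$rmse[1], 0.0816497, tolerance = 1e-6)
  # adding a constant offset leaves r^2 and shifts rmse by the offset
  off <- fit_stats(mk(c(0.2, 0.5, 0.8)), mk(c(0.2, 0.5, 0.8) + 0.1))
  expect_equal(off$r_squared[1], 1, tolerance = 1e-12)
  expect_equal(off$rmse[1:2], c(0.1, 0.1), tolerance = 1e-12)
  # zero variance: undefined correlation is reported as NA, not 0
  flat <- fit_stats(mk(c(0.5, 0.5, 0.5)), mk(c(0.3, 0.5, 0.7)))
  expect_true(all(is.na(flat$r_squared)))
  expect_error(fit_stats(mk(1:3 / 10), mk(1:3 / 10)[-1, ]), "identical")
})

test_that("reference grids are validated cell by cell", {
  ref <- synth_reference(seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(ref, path, row.names = FALSE)
  g <- load_reference(path)
  expect_identical(nrow(g), 25L)
  # missing cell is named
  write.csv(ref[-7, ], path, row.names = FALSE)
  expect_error(load_reference(path), "missing cell")
  # duplicated cell
  write.csv(rbind(ref, ref[3, ]), path, row.names = FALSE)
  expect_error(load_reference(path), "duplicated cell")
  # out-of-range value
  bad <- ref; bad$performance[2] <- 1.2
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_reference(path), "outside \\[0, 1\\]")
})

test_that("the synthetic reference obeys its configured monotone trends", {
  tr <- list(performance = c(base = 0.5, ca = 0.75, cm = 0.4),
             auto_use = c(base = 0.55, ca = 0.6, cm = -0.5),
             switches = c(base = 14, ca = -20, cm = -12),
             noise = c(performance = 0, auto_use = 0, switches = 0))
  g <- synth_reference(seed = 1, trend = tr)
  for (cm in CAPABILITY_LEVELS) {
    sub <- g[g$cm == cm, ]
    expect_true(all(diff(sub$performance) > 0))
    expect_true(all(diff(sub$auto_use) > 0))
    expect_true(all(diff(sub$switches) < 0))
  }
  for (ca in CAPABILITY_LEVELS) {
    sub <- g[g$ca == ca, ]
    expect_true(all(diff(sub$performance) > 0))
    expect_true(all(diff(sub$auto_use) < 0))
    expect_true(all(diff(sub$switches) < 0))
  }
  expect_identical(synth_reference(seed = 3), synth_reference(seed = 3))
  fs <- fit_stats(synth_reference(seed = 4), synth_reference(seed = 4))
  expect_equal(fs$r_squared, rep(1, 3), tolerance = 1e-12)
  expect_equal(fs$rmse, rep(0, 3), tolerance = 1e-12)
})

test_that("grid CSVs carry seed and configuration provenance", {
  m <- build_model()
  g <- run_grid(m, ca_levels = 0.5, cm_levels = 0.5, n_runs = 2,
                master_seed = 77)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_grid_csv(g, path)
  head2 <- readLines(path, n = 2)
  expect_match(head2[1], "master_seed: 77")
  expect_match(head2[2], "config_hash: [0-9a-f]+")
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$performance_mean, g$performance_mean, tolerance = 1e-12)
})
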