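write_fixture_model <- function(dir) {
  path <- file.path(dir, "cascade.tt")
  write_truth_tables(motif_fixtures()$and_cascade, path)
  path
}

fixture_conditions <- function(dir) {
  path <- file.path(dir, "conds.yaml")
  writeLines(c("conditions:", "  envA:", "    E: [35, 85]"), path)
  path
}

test_that("cmd_screen writes a complete, re-runnable run directory", {
  dir <- withr::local_tempdir()
  model_path <- write_fixture_model(dir)
  conds <- fixture_conditions(dir)
  rc <- run_config(model_path, format = "truth-table", condition = "envA",
                   direction = "inactivate", n_combinations = 6,
                   config = sim_config(steps = 100, window = 40,
                                       replicates = 3, seed = 11),
                   out_dir = file.path(dir, "run1"), conditions_file = conds)
  out <- cmd_screen(rc)
  expect_length(out, 1)
  files <- list.files(out)
  expect_true(all(c("WT.csv", "H_0.csv", "A_0.csv", "B_0.csv", "C_0.csv",
                    "dv_matrix.csv", "influence.csv", "samples.csv",
                    "manifest.json") %in% files))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 11)
  expect_equal(manifest$condition, "envA")
  expect_true(nzchar(manifest$config_hash))

  # head node tops the ranking CSV
  infl <- readr::read_csv(file.path(out, "influence.csv"),
                          show_col_types = FALSE)
  expect_equal(infl$perturbation[infl$rank == 1], "H")

  # re-running the same config reproduces byte-identical numeric outputs
  rc2 <- rc
  rc2$out_dir <- file.path(dir, "run2")
  out2 <- cmd_screen(rc2)
  for (f in c("WT.csv", "dv_matrix.csv", "influence.csv", "samples.csv")) {
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("cmd_screen validates inputs up front", {
  dir <- withr::local_tempdir()
  expect_error(run_config(file.path(dir, "missing.tt")), "not found")
  model_path <- write_fixture_model(dir)
  rc <- run_config(model_path, condition = "nonsense",
                   out_dir = file.path(dir, "x"))
  expect_error(cmd_screen(rc), "unknown condition")
})

test_that("cmd_combo reports single and joint folds side by side", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mutual.tt")
  write_truth_tables(motif_fixtures()$mutual_antagonism, path)
  conds <- file.path(dir, "conds.yaml")
  writeLines(c("conditions:", "  envB:",
               "    EX: [60, 95]", "    EY: [60, 95]"), conds)
  rc <- run_config(path, condition = "envB", n_combinations = 6,
                   config = sim_config(steps = 120, window = 60,
                                       replicates = 3, seed = 3),
                   out_dir = file.path(dir, "combo"),
                   conditions_file = conds)
  out <- cmd_combo(rc, perturbation(X = 0, Y = 1))
  tbl <- readr::read_csv(file.path(out, "combo_folds.csv"),
                         show_col_types = FALSE)
  expect_true(all(c("fold_X_0", "fold_Y_1", "fold_X_0_Y_1") %in%
                    names(tbl)))
  # the joint clamp de-represses Y's reporter at least as much as X:0 alone
  ry <- tbl[tbl$component == "RY", ]
  expect_gte(ry$fold_X_0_Y_1, ry$fold_X_0)
  expect_error(cmd_combo(rc, wild_type()), "empty perturbation")
})

test_that("cmd_report aggregates runs and flags incomplete directories", {
  dir <- withr::local_tempdir()
  model_path <- write_fixture_model(dir)
  conds <- fixture_conditions(dir)
  cfg <- sim_config(steps = 100, window = 40, replicates = 3, seed = 7)
  rc <- run_config(model_path, condition = "envA", direction = "both",
                   n_combinations = 6, config = cfg,
                   out_dir = file.path(dir, "runs"),
                   conditions_file = conds)
  outs <- cmd_screen(rc)
  expect_length(outs, 2)
  rep <- cmd_report(outs, out_path = file.path(dir, "report.json"))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_length(rep$runs, 2)
  expect_true(!is.null(rep$overlap))
  counts <- rep$runs[[1]]$affected_counts
  expect_true(all(c("perturbation", "n_affected") %in% names(counts)))

  # missing file -> named error
  file.remove(file.path(outs[1], "influence.csv"))
  expect_error(cmd_report(outs), "missing influence.csv")
})

test_that("result objects expose tidy/glance/autoplot interfaces", {
  m <- motif_fixtures()$and_cascade
  cond <- environment_condition("e", list(E = c(35, 85)))
  cfg <- sim_config(steps = 100, window = 40, replicates = 3, seed = 2)
  sc <- single_perturbation_screen(m, cond, "inactivate",
                                   n_combinations = 5, config = cfg)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$perturbation), c("WT", "H:0", "A:0", "B:0", "C:0"))
  g <- glance(sc)
  expect_equal(g$n_perturbations, 4)

  dvm <- screen_difference_values(sc)
  expect_s3_class(glance(dvm), "tbl_df")
  rk <- influence_scores(dvm)
  expect_s3_class(tidy(rk), "tbl_df")
  expect_equal(glance(rk)$M, 4)
  expect_s3_class(autoplot(dvm), "ggplot")
  expect_s3_class(autoplot(rk), "ggplot")
  expect_s3_class(plot_activity(sc$wild_type, "C"), "ggplot")
})
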