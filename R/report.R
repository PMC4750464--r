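#' Assemble a run configuration
#'
#' Collects everything a screen run needs: model, condition, directions,
#' sampling sizes and the simulation configuration. The configuration (and
#' its hash) is written into every output manifest so a run can be repeated
#' bit-identically.
#'
#' @param model_path Path to the model file.
#' @param format `"truth-table"` or `"sbml-qual"`.
#' @param condition Condition name (one of [builtin_conditions()]) or an
#'   [environment_condition()].
#' @param direction `"inactivate"`, `"activate"`, or `"both"`.
#' @param n_combinations Environment combinations per experiment.
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param conditions_file Optional YAML/JSON conditions config (see
#'   [load_conditions()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(model_path, format = c("truth-table", "sbml-qual"),
                       condition = "growth",
                       direction = c("inactivate", "activate", "both"),
                       n_combinations = 100, config = sim_config(),
                       out_dir = ".", conditions_file = NULL) {
  format <- match.arg(format)
  direction <- match.arg(direction)
  if (!file.exists(model_path)) {
    abort(paste0("model file not found: ", model_path))
  }
  structure(list(model_path = model_path, format = format,
                 condition = condition, direction = direction,
                 n_combinations = n_combinations, config = config,
                 out_dir = out_dir, conditions_file = conditions_file),
            class = "run_config")
}

load_model_any <- function(path, format) {
  switch(format,
         "truth-table" = load_truth_tables(path),
         "sbml-qual" = load_sbml_qual(path),
         abort(paste0("unknown model format: ", format)))
}

resolve_condition <- function(condition, conditions_file = NULL) {
  if (inherits(condition, "environment_condition")) return(condition)
  conds <- if (is.null(conditions_file)) builtin_conditions() else
    load_conditions(conditions_file)
  if (!condition %in% names(conds)) {
    abort(paste0("unknown condition '", condition, "'; available: ",
                 paste(names(conds), collapse = ", ")))
  }
  conds[[condition]]
}

manifest_for <- function(rc, model, extra = list()) {
  cfg <- rc$config
  c(list(
    model_path = rc$model_path,
    format = rc$format,
    condition = if (inherits(rc$condition, "environment_condition"))
      rc$condition$name else rc$condition,
    direction = rc$direction,
    n_combinations = rc$n_combinations,
    steps = cfg$steps, window = cfg$window, replicates = cfg$replicates,
    seed = cfg$seed,
    n_components = nrow(model$components),
    n_interactions = n_interactions(model),
    config_hash = rlang::hash(list(rc$format, rc$n_combinations,
                                   unclass(cfg)))
  ), extra)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# all-or-nothing CSV write: build in a temp file, then rename into place
write_csv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_csv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run a full perturbation screen to disk
#'
#' Orchestrates the screen end to end: loads the model, samples environment
#' combinations, simulates the wild type and every single perturbation in
#' the requested direction(s), computes the DV matrix and influence ranking,
#' and writes one activity CSV per perturbation plus `dv_matrix.csv`,
#' `influence.csv`, `samples.csv` and `manifest.json` under
#' `out_dir/<condition>_<direction>/`. Outputs are deterministic given the
#' seed; a failure in any stage aborts before any partial CSV is left
#' behind.
#'
#' @param rc A [run_config()].
#' @param alpha DV significance threshold.
#' @return Invisibly, a list of the output directories (one per direction).
#' @export
cmd_screen <- function(rc, alpha = 0.05) {
  model <- load_model_any(rc$model_path, rc$format)
  condition <- resolve_condition(rc$condition, rc$conditions_file)
  directions <- if (rc$direction == "both") c("inactivate", "activate") else
    rc$direction
  dirs <- character()
  for (direction in directions) {
    screen <- single_perturbation_screen(
      model, condition, direction = direction,
      n_combinations = rc$n_combinations, config = rc$config
    )
    dvm <- screen_difference_values(screen, alpha = alpha)
    ranking <- influence_scores(dvm)
    out <- file.path(rc$out_dir, paste0(condition$name, "_", direction))
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_csv_atomic(screen$wild_type, file.path(out, "WT.csv"))
    for (lab in names(screen$perturbed)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
      write_csv_atomic(screen$perturbed[[lab]],
                       file.path(out, paste0(safe, ".csv")))
    }
    write_csv_atomic(screen$samples, file.path(out, "samples.csv"))
    write_csv_atomic(as_tibble(dvm), file.path(out, "dv_matrix.csv"))
    write_csv_atomic(tidy(ranking), file.path(out, "influence.csv"))
    write_manifest(
      manifest_for(rc, model, list(direction = direction, alpha = alpha)),
      file.path(out, "manifest.json")
    )
    dirs <- c(dirs, out)
  }
  invisible(dirs)
}

#' Run a combinatorial perturbation comparison to disk
#'
#' Simulates the wild type, each single clamp of `spec`, and the joint
#' clamp under common random numbers, then writes a side-by-side fold table
#' (`combo_folds.csv`: per component, the fold under each single
#' perturbation and under the double) plus the manifest.
#'
#' @param rc A [run_config()].
#' @param spec A [perturbation()] with >= 1 clamp.
#' @param alpha DV significance threshold.
#' @return Invisibly, the output directory.
#' @export
cmd_combo <- function(rc, spec, alpha = 0.05) {
  spec <- as_perturbation(spec)
  if (length(spec$clamps) == 0) abort("empty perturbation spec")
  model <- load_model_any(rc$model_path, rc$format)
  condition <- resolve_condition(rc$condition, rc$conditions_file)
  singles <- purrr::imap(as.list(spec$clamps),
                         ~ perturbation(setNames(.x, .y)))
  specs <- c(singles, list(spec))
  screen <- run_screen(model, condition, specs, rc$n_combinations, rc$config)
  folds <- purrr::imap(screen$perturbed, function(tbl, lab) {
    dv <- difference_values(screen$wild_type, tbl, alpha = alpha,
                            clamped = names(parse_perturbation(lab)$clamps))
    fold_differences(screen$wild_type, tbl, dvm = dv) |>
      select("component", "fold", "classification") |>
      rename_with_label(lab)
  })
  combined <- purrr::reduce(folds, ~ left_join(.x, .y, by = "component"))
  out <- file.path(rc$out_dir, paste0(condition$name, "_combo"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_csv_atomic(combined, file.path(out, "combo_folds.csv"))
  write_csv_atomic(screen$wild_type, file.path(out, "WT.csv"))
  for (lab in names(screen$perturbed)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
    write_csv_atomic(screen$perturbed[[lab]],
                     file.path(out, paste0(safe, ".csv")))
  }
  write_manifest(
    manifest_for(rc, model, list(spec = perturbation_label(spec),
                                 alpha = alpha)),
    file.path(out, "manifest.json")
  )
  invisible(out)
}

rename_with_label <- function(tbl, lab) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
  dplyr::rename(tbl,
                !!paste0("fold_", safe) := "fold",
                !!paste0("class_", safe) := "classification")
}

#' Summarise one or more screen run directories
#'
#' Reads the `influence.csv` and `dv_matrix.csv` of each run directory
#' produced by [cmd_screen()], and writes `report.json` containing the
#' most/least influential lists per run, the cross-condition overlap sets,
#' and per-perturbation affected-component counts (DV = 1). Optionally saves
#' a DV heatmap per run.
#'
#' @param run_dirs Character vector of run directories.
#' @param out_path Output JSON path (default `report.json` in the first
#'   run's parent).
#' @param heatmap Write `dv_heatmap.png` into each run directory.
#' @return Invisibly, the report list.
#' @export
cmd_report <- function(run_dirs, out_path = NULL, heatmap = FALSE) {
  runs <- purrr::map(run_dirs, function(d) {
    for (f in c("influence.csv", "dv_matrix.csv", "manifest.json")) {
      if (!file.exists(file.path(d, f))) {
        abort(paste0("incomplete run directory '", d, "': missing ", f))
      }
    }
    list(
      dir = d,
      manifest = jsonlite::read_json(file.path(d, "manifest.json")),
      influence = readr::read_csv(file.path(d, "influence.csv"),
                                  show_col_types = FALSE),
      dvm = readr::read_csv(file.path(d, "dv_matrix.csv"),
                            show_col_types = FALSE)
    )
  })
  names(runs) <- vapply(runs, function(r) {
    paste0(r$manifest$condition, "_", r$manifest$direction)
  }, "")
  per_run <- purrr::map(runs, function(r) {
    list(
      condition = r$manifest$condition,
      direction = r$manifest$direction,
      most_influential = r$influence$perturbation[r$influence$most_influential],
      least_influential = r$influence$perturbation[r$influence$least_influential],
      affected_counts = r$dvm |>
        group_by(.data$perturbation) |>
        summarise(n_affected = sum(.data$dv == 1), .groups = "drop")
    )
  })
  report <- list(runs = per_run)
  if (length(runs) >= 2) {
    report$overlap <- cross_condition_overlap(
      purrr::map(per_run, "most_influential")
    )
  }
  out_path <- out_path %||% file.path(dirname(run_dirs[1]), "report.json")
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  if (heatmap) {
    for (r in runs) {
      p <- autoplot(new_dv_matrix(r$dvm, alpha = NA_real_,
                                  condition = r$manifest$condition))
      ggplot2::ggsave(file.path(r$dir, "dv_heatmap.png"), p,
                      width = 7, height = 6, dpi = 150)
    }
  }
  invisible(report)
}
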