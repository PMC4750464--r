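#' Simulation configuration
#'
#' @param steps Total synchronous iterations per simulation (default 800).
#' @param window Trailing iterations over which the activity level is the
#'   fraction of active states (default 300; must be <= `steps`).
#' @param replicates Simulations per environment combination (default 30).
#' @param seed Integer seed for the counter-based generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(steps = 800, window = 300, replicates = 30, seed = 1) {
  stopifnot(window <= steps, replicates >= 1)
  structure(list(steps = as.integer(steps), window = as.integer(window),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Boolean model under an environment sample
#'
#' Runs `config$replicates` synchronous simulations of `config$steps` steps.
#' Internal states start Bernoulli(0.5) (unless `init` is given); at every
#' step each external component is an independent Bernoulli(`p`/100) draw
#' from its own substream, and all internal components update simultaneously
#' from the states at the previous step via their truth tables. Clamped
#' components are held at the clamp value at every step, including step 0.
#' The activity level (AL) of a component is 100 times the fraction of active
#' states over the last `config$window` iterations.
#'
#' @param model A [boolean_model()].
#' @param env Named numeric vector: activity level (0-100) per external
#'   component; must cover every external component of the model. May also be
#'   a one-combination tibble from [sample_combinations()].
#' @param clamps A [perturbation()] (or `NULL`/[wild_type()] for none).
#'   Clamping an external component overrides its stochastic draw.
#' @param config A [sim_config()].
#' @param env_index Integer tag identifying the environment combination; part
#'   of the RNG key, so WT and perturbed runs with the same seed and
#'   `env_index` share all random draws (common random numbers).
#' @param condition,label Metadata recorded in the output table.
#' @param init Optional named vector of 0/1 initial states for internal
#'   components (deterministic start; used e.g. to compare against an
#'   exhaustive trajectory).
#' @return A tidy activity table: tibble with columns `condition`,
#'   `perturbation`, `env_index`, `replicate`, `component`, `al`.
#' @examples
#' m <- motif_fixtures()$pass_through
#' simulate_activity(m, c(E = 50), config = sim_config(steps = 100, window = 50,
#'                                                     replicates = 3))
#' @export
simulate_activity <- function(model, env, clamps = NULL, config = sim_config(),
                              env_index = 1L, condition = NA_character_,
                              label = NULL, init = NULL) {
  enc <- model_encoding(model)
  if (is.data.frame(env)) env <- setNames(env$p, env$component)
  ext <- external_components(model)
  missing_ext <- setdiff(ext, names(env))
  if (length(missing_ext) > 0) {
    abort(paste0("environment sample missing external component(s): ",
                 paste(missing_ext, collapse = ", ")))
  }
  enc$ext_p[match(ext, enc$ids)] <- as.numeric(env[ext])
  clamp_vec <- rep(-1L, length(enc$ids))
  clamps <- as_perturbation(clamps)
  if (length(clamps$clamps) > 0) {
    unknown <- setdiff(names(clamps$clamps), enc$ids)
    if (length(unknown) > 0) {
      abort(paste0("clamp references unknown component(s): ",
                   paste(unknown, collapse = ", ")))
    }
    clamp_vec[match(names(clamps$clamps), enc$ids)] <- as.integer(clamps$clamps)
  }
  init_vec <- NULL
  if (!is.null(init)) {
    init_vec <- rep(0L, length(enc$ids))
    unknown <- setdiff(names(init), enc$ids)
    if (length(unknown) > 0) abort("init references unknown component(s)")
    init_vec[match(names(init), enc$ids)] <- as.integer(init)
  }
  res <- simulate_cpp(enc$kind, enc$reg_idx, enc$tt_out, enc$ext_p, clamp_vec,
                      config$steps, config$window, config$replicates,
                      config$seed, as.integer(env_index), init_vec, FALSE)
  al <- res$al
  tibble(
    condition = condition,
    perturbation = label %||% perturbation_label(clamps),
    env_index = as.integer(env_index),
    replicate = rep(seq_len(ncol(al)), each = nrow(al)),
    component = rep(enc$ids, times = ncol(al)),
    al = as.vector(al)
  )
}

#' Full state trajectory of one replicate
#'
#' As [simulate_activity()] but records and returns the Boolean state of
#' every component at every step for each replicate. Intended for small
#' models (tests, oracles, null-influence checks).
#'
#' @inheritParams simulate_activity
#' @return A list with `al` (components x replicates matrix) and `traj`
#'   (list of components x (steps+1) 0/1 matrices, one per replicate, with
#'   component ids as rownames).
#' @export
simulate_trajectory <- function(model, env = NULL, clamps = NULL,
                                config = sim_config(), env_index = 1L,
                                init = NULL) {
  enc <- model_encoding(model)
  ext <- external_components(model)
  if (is.data.frame(env)) env <- setNames(env$p, env$component)
  if (length(ext) > 0) {
    if (is.null(env) || length(setdiff(ext, names(env))) > 0) {
      abort("environment sample must cover all external components")
    }
    enc$ext_p[match(ext, enc$ids)] <- as.numeric(env[ext])
  }
  clamp_vec <- rep(-1L, length(enc$ids))
  clamps <- as_perturbation(clamps)
  if (length(clamps$clamps) > 0) {
    clamp_vec[match(names(clamps$clamps), enc$ids)] <- as.integer(clamps$clamps)
  }
  init_vec <- NULL
  if (!is.null(init)) {
    init_vec <- rep(0L, length(enc$ids))
    init_vec[match(names(init), enc$ids)] <- as.integer(init)
  }
  res <- simulate_cpp(enc$kind, enc$reg_idx, enc$tt_out, enc$ext_p, clamp_vec,
                      config$steps, config$window, config$replicates,
                      config$seed, as.integer(env_index), init_vec, TRUE)
  res$traj <- lapply(res$traj, function(m) { rownames(m) <- enc$ids; m })
  rownames(res$al) <- enc$ids
  res
}

#' Simulate a model across sampled environment combinations
#'
#' Runs [simulate_activity()] for every environment combination in a sample
#' table and binds the results into one tidy activity table.
#'
#' @param model A [boolean_model()].
#' @param samples Tibble from [sample_combinations()] (columns `env_index`,
#'   `component`, `p`).
#' @param clamps,config,condition,label As in [simulate_activity()].
#' @return Tidy activity table (one row per component, replicate and
#'   combination).
#' @export
simulate_condition <- function(model, samples, clamps = NULL,
                               config = sim_config(),
                               condition = NA_character_, label = NULL) {
  purrr::map_dfr(split(samples, samples$env_index), function(s) {
    simulate_activity(model, s, clamps = clamps, config = config,
                      env_index = s$env_index[1], condition = condition,
                      label = label)
  })
}

#' Per-combination and overall mean activity levels
#'
#' `mean_activity()` averages replicates within each environment combination;
#' `overall_activity()` further averages those per-combination means, giving
#' the condition-level mean AL per component.
#'
#' @param table Tidy activity table from [simulate_activity()] /
#'   [simulate_condition()].
#' @param components Optional component ids to restrict to (error if any is
#'   absent from the table).
#' @return `mean_activity()`: tibble `component`, `env_index`, `al`.
#'   `overall_activity()`: tibble `component`, `al`.
#' @export
mean_activity <- function(table, components = NULL) {
  if (!is.null(components)) {
    unknown <- setdiff(components, unique(table$component))
    if (length(unknown) > 0) {
      abort(paste0("unknown component(s): ", paste(unknown, collapse = ", ")))
    }
    table <- filter(table, .data$component %in% components)
  }
  table |>
    group_by(.data$component, .data$env_index) |>
    summarise(al = mean(.data$al), .groups = "drop")
}

#' @rdname mean_activity
#' @export
overall_activity <- function(table, components = NULL) {
  mean_activity(table, components) |>
    group_by(.data$component) |>
    summarise(al = mean(.data$al), .groups = "drop")
}

#' Fligner-Killeen homogeneity of replicate variances
#'
#' For each component, tests homogeneity of the AL variance across
#' environment-combination groups (replicates within a combination form a
#' group) with the Fligner-Killeen test. Components whose AL is constant
#' everywhere (e.g. clamped components) are reported as degenerate rather
#' than tested.
#'
#' @param table Tidy activity table with >= 2 combinations of >= 2 replicates.
#' @param alpha Flagging level (default 0.05).
#' @return Tibble `component`, `statistic`, `p_value`, `degenerate`,
#'   `flagged` (p < alpha).
#' @export
replicate_homogeneity <- function(table, alpha = 0.05) {
  n_env <- length(unique(table$env_index))
  n_rep <- length(unique(table$replicate))
  if (n_env < 2 || n_rep < 2) {
    abort("need >= 2 environment combinations with >= 2 replicates each")
  }
  table |>
    group_by(.data$component) |>
    summarise(res = list({
      if (max(.data$al) == min(.data$al)) {
        tibble(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE)
      } else {
        ft <- fligner.test(.data$al, factor(.data$env_index))
        tibble(statistic = unname(ft$statistic), p_value = ft$p.value,
               degenerate = FALSE)
      }
    }), .groups = "drop") |>
    tidyr::unnest("res") |>
    mutate(flagged = !.data$degenerate & .data$p_value < alpha)
}
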