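#' Perturbation specifications
#'
#' A perturbation clamps one or more components at a constant Boolean state
#' for the whole simulation: 1 is a gain-of-function/overexpression
#' intervention, 0 a loss-of-function/knockout. `wild_type()` is the empty
#' perturbation. Labels follow the `"PI3K:0+IP3R1:1"` convention and can be
#' parsed back with `parse_perturbation()`.
#'
#' @param ... Clamp states, either as named arguments (`PI3K = 0, IP3R1 = 1`)
#'   or a single named vector/list.
#' @return An object of class `perturbation`.
#' @examples
#' perturbation(PI3K = 0, IP3R1 = 1)
#' parse_perturbation("PI3K:0+IP3R1:1")
#' wild_type()
#' @export
perturbation <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) &&
      (is.list(args[[1]]) || length(args[[1]]) > 1 ||
       !is.null(names(args[[1]])))) {
    clamps <- unlist(args[[1]])
  } else {
    clamps <- unlist(args)
  }
  clamps <- vapply(clamps, as.integer, integer(1))
  if (length(clamps) > 0 && (is.null(names(clamps)) || any(names(clamps) == ""))) {
    abort("every clamp must be named by a component id")
  }
  if (anyDuplicated(names(clamps))) {
    dups <- unique(names(clamps)[duplicated(names(clamps))])
    abort(paste0("conflicting duplicate clamp(s) for: ",
                 paste(dups, collapse = ", ")))
  }
  if (!all(clamps %in% c(0L, 1L))) abort("clamp states must be 0 or 1")
  structure(list(clamps = clamps), class = "perturbation")
}

#' @rdname perturbation
#' @export
wild_type <- function() perturbation()

#' @param label A label such as `"WT"` or `"PI3K:0+IP3R1:1"`.
#' @rdname perturbation
#' @export
parse_perturbation <- function(label) {
  if (identical(label, "WT") || identical(label, "")) return(wild_type())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2 || !x[2] %in% c("0", "1"),
                logical(1))
  if (any(bad)) abort(paste0("cannot parse perturbation label: ", label))
  perturbation(setNames(as.integer(vapply(kv, `[`, "", 2)),
                        vapply(kv, `[`, "", 1)))
}

#' @param x A perturbation.
#' @rdname perturbation
#' @export
perturbation_label <- function(x) {
  x <- as_perturbation(x)
  if (length(x$clamps) == 0) return("WT")
  paste(paste0(names(x$clamps), ":", x$clamps), collapse = "+")
}

as_perturbation <- function(x) {
  if (is.null(x)) return(wild_type())
  if (inherits(x, "perturbation")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_perturbation(x))
  perturbation(x)
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> ", perturbation_label(x), "\n", sep = "")
  invisible(x)
}

# run WT plus a list of perturbations over shared environment samples
run_screen <- function(model, condition, specs, n_combinations, config) {
  samples <- sample_combinations(condition, n_combinations, config$seed,
                                 externals = external_components(model))
  wt <- simulate_condition(model, samples, clamps = NULL, config = config,
                           condition = condition$name)
  perturbed <- purrr::map(specs, function(spec) {
    simulate_condition(model, samples, clamps = spec, config = config,
                       condition = condition$name)
  })
  names(perturbed) <- vapply(specs, perturbation_label, "")
  structure(
    list(wild_type = wt, perturbed = perturbed, samples = samples,
         condition = condition, config = config, model = model),
    class = "screen_result"
  )
}

#' Systematic single-perturbation screen
#'
#' Runs a wild-type reference experiment and one experiment per internal
#' component clamped in the given direction (`"inactivate"` = stuck at 0,
#' knockout; `"activate"` = stuck at 1, overexpression), all under the same
#' `n_combinations` environment samples and the same seeds (common random
#' numbers), so WT-vs-perturbation differences are attributable to the clamp.
#'
#' @param model A [boolean_model()].
#' @param condition An [environment_condition()].
#' @param direction `"inactivate"` or `"activate"`.
#' @param n_combinations Environment combinations per experiment (>= 2;
#'   default 100, with 2000 customary for the unconstrained random
#'   condition).
#' @param config A [sim_config()].
#' @param components Internal components to perturb (default: all).
#' @return A `screen_result`: list with `wild_type` and `perturbed` activity
#'   tables, the shared `samples`, `condition`, `config`, and `model`.
#' @seealso [screen_difference_values()], [influence_scores()]
#' @export
single_perturbation_screen <- function(model, condition,
                                       direction = c("inactivate", "activate"),
                                       n_combinations = 100,
                                       config = sim_config(),
                                       components = NULL) {
  direction <- match.arg(direction)
  stopifnot(n_combinations >= 2)
  state <- if (direction == "inactivate") 0L else 1L
  targets <- components %||% internal_components(model)
  unknown <- setdiff(targets, internal_components(model))
  if (length(unknown) > 0) {
    abort(paste0("not internal component(s): ", paste(unknown, collapse = ", ")))
  }
  specs <- purrr::map(targets, ~ perturbation(setNames(state, .x)))
  res <- run_screen(model, condition, specs, n_combinations, config)
  res$direction <- direction
  res
}

#' Combinatorial (multi-target) perturbation experiment
#'
#' Runs the wild-type reference and a single joint clamp experiment (e.g.
#' knockout of one component combined with overexpression of another) under
#' common random numbers.
#'
#' @inheritParams single_perturbation_screen
#' @param spec A [perturbation()] with >= 1 clamp.
#' @return A `screen_result` with one perturbed table.
#' @export
combinatorial_perturbation <- function(model, condition, spec,
                                       n_combinations = 100,
                                       config = sim_config()) {
  spec <- as_perturbation(spec)
  if (length(spec$clamps) == 0) abort("spec must clamp at least one component")
  run_screen(model, condition, list(spec), n_combinations, config)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> condition '", x$condition$name, "', ",
      length(x$perturbed), " perturbation(s), ",
      length(unique(x$samples$env_index)), " environment combinations x ",
      x$config$replicates, " replicates\n", sep = "")
  invisible(x)
}

#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  bind_rows(x$wild_type, bind_rows(x$perturbed))
}

#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    condition = x$condition$name,
    n_perturbations = length(x$perturbed),
    n_combinations = length(unique(x$samples$env_index)),
    replicates = x$config$replicates,
    steps = x$config$steps,
    window = x$config$window,
    seed = x$config$seed
  )
}
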