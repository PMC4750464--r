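#' Define an environmental condition
#'
#' An environmental condition names a range of activity levels (percent,
#' 0-100) for each external stimulus of a model. During simulation an
#' external component with sampled activity level `p` is active at each step
#' with probability `p/100`, emulating a ligand concentration.
#'
#' @param name Condition name.
#' @param ranges A data frame with columns `component`, `lo`, `hi`
#'   (0 <= lo <= hi <= 100), or a named list of `c(lo, hi)` pairs (a single
#'   number is a degenerate point range).
#' @return An object of class `environment_condition`.
#' @examples
#' environment_condition("starve", list(EGF = c(0, 5), ECM = 50))
#' @export
environment_condition <- function(name, ranges) {
  if (!is.data.frame(ranges)) {
    ranges <- purrr::imap_dfr(ranges, function(r, id) {
      if (length(r) == 1) r <- c(r, r)
      tibble(component = id, lo = as.numeric(r[1]), hi = as.numeric(r[2]))
    })
  }
  ranges <- as_tibble(ranges)[, c("component", "lo", "hi")]
  if (any(ranges$lo > ranges$hi) || any(ranges$lo < 0) || any(ranges$hi > 100)) {
    abort("activity ranges must satisfy 0 <= lo <= hi <= 100")
  }
  if (anyDuplicated(ranges$component)) abort("duplicate component in ranges")
  structure(list(name = name, ranges = ranges), class = "environment_condition")
}

#' @export
print.environment_condition <- function(x, ...) {
  cat("<environment_condition> ", x$name, "\n", sep = "")
  print(x$ranges)
  invisible(x)
}

#' Built-in environmental conditions
#'
#' The five extracellular conditions used in the perturbation screen —
#' stimulating cell death, growth, motility, quiescence, plus a random
#' (unconstrained) environment — as activity-level ranges for the nine
#' environmental stimuli of the signal-transduction model: extracellular
#' matrix (`ECM`), `EGF`, the calcium pump (`ExtPump`), the four GPCR ligands
#' (`alpha_qL`, `alpha_iL`, `alpha_sL`, `alpha_1213L`), `IL1_TNF`, and
#' `Stress`. Point values are degenerate ranges (lo = hi). When a condition
#' is used with a model that lacks some of these stimuli, sampling is
#' restricted to the stimuli the model declares (see [sample_combinations()]).
#'
#' @return Named list of [environment_condition()] objects
#'   (`death`, `growth`, `motility`, `quiescence`, `random`).
#' @export
builtin_conditions <- function() {
  tab <- list(
    death      = list(ECM = c(10, 72), EGF = c(3, 15), ExtPump = c(35, 87),
                      alpha_qL = c(13, 58), alpha_iL = c(1, 4),
                      alpha_sL = c(30, 87), alpha_1213L = c(14, 65),
                      IL1_TNF = c(4, 13), Stress = c(2, 5)),
    growth     = list(ECM = c(26, 82), EGF = c(72, 97), ExtPump = c(24, 83),
                      alpha_qL = c(18, 78), alpha_iL = c(15, 77),
                      alpha_sL = c(24, 80), alpha_1213L = c(18, 78),
                      IL1_TNF = c(8, 15), Stress = c(2, 5)),
    motility   = list(ECM = c(81, 99), EGF = c(29, 83), ExtPump = c(41, 92),
                      alpha_qL = c(17, 74), alpha_iL = c(30, 82),
                      alpha_sL = c(20, 77), alpha_1213L = c(12, 77),
                      IL1_TNF = c(4, 13), Stress = c(2, 5)),
    quiescence = list(ECM = c(7, 30), EGF = c(43, 56), ExtPump = c(17, 82),
                      alpha_qL = c(4, 84), alpha_iL = c(31, 83),
                      alpha_sL = c(19, 46), alpha_1213L = c(18, 67),
                      IL1_TNF = c(2, 2), Stress = c(2, 3)),
    random     = list(ECM = c(0, 100), EGF = c(0, 100), ExtPump = c(0, 100),
                      alpha_qL = c(0, 100), alpha_iL = c(0, 100),
                      alpha_sL = c(0, 100), alpha_1213L = c(0, 100),
                      IL1_TNF = c(2, 2), Stress = c(2, 2))
  )
  purrr::imap(tab, ~ environment_condition(.y, .x))
}

#' Load environmental conditions from a YAML or JSON config
#'
#' The file must contain a top-level `conditions` mapping, e.g.
#' `conditions: {death: {EGF: [3, 15], ECM: [10, 72]}}`. Single numbers are
#' degenerate point ranges. An optional top-level `aliases` mapping renames
#' stimuli to model component ids (`aliases: {CalciumPump: ExtPump}`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [environment_condition()] objects.
#' @export
load_conditions <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$conditions)) abort("config has no 'conditions' entry")
  aliases <- cfg$aliases %||% list()
  purrr::imap(cfg$conditions, function(ranges, name) {
    if (length(aliases) > 0) {
      names(ranges) <- ifelse(names(ranges) %in% names(aliases),
                              unlist(aliases[names(ranges)]), names(ranges))
    }
    environment_condition(name, ranges)
  })
}

#' Sample environment combinations from a condition
#'
#' Draws `n` independent combinations of external activity levels, each
#' stimulus uniform on its `[lo, hi]` range (a maximum-entropy reading of
#' "randomly selected"). Sampling uses the package's counter-based generator
#' (splitmix64 keyed by seed, combination and stimulus), so identical
#' `(condition, n, seed)` give identical samples on every platform,
#' independently of R's RNG state.
#'
#' @param condition An [environment_condition()].
#' @param n Number of combinations (>= 1).
#' @param seed Integer seed.
#' @param externals Optional character vector of external component ids the
#'   target model declares; sampling is restricted to these, and an error is
#'   raised if any of them is missing from the condition.
#' @return A tibble with columns `env_index`, `component`, `p`.
#' @examples
#' cond <- builtin_conditions()$growth
#' sample_combinations(cond, n = 3, seed = 1)
#' @export
sample_combinations <- function(condition, n, seed, externals = NULL) {
  stopifnot(n >= 1)
  ranges <- condition$ranges
  if (!is.null(externals)) {
    missing <- setdiff(externals, ranges$component)
    if (length(missing) > 0) {
      abort(paste0("condition '", condition$name,
                   "' has no range for external component(s): ",
                   paste(missing, collapse = ", ")))
    }
    ranges <- ranges[ranges$component %in% externals, ]
  }
  m <- nrow(ranges)
  grid <- tidyr::expand_grid(env_index = seq_len(n), j = seq_len(m))
  u <- counter_uniform_cpp(seed, grid$env_index, grid$j,
                           rep(0L, nrow(grid)), rep(1L, nrow(grid)))
  out <- tibble(
    env_index = grid$env_index,
    component = ranges$component[grid$j],
    p = ranges$lo[grid$j] + u * (ranges$hi[grid$j] - ranges$lo[grid$j])
  )
  stopifnot(all(out$p >= ranges$lo[grid$j] - 1e-12),
            all(out$p <= ranges$hi[grid$j] + 1e-12))
  out
}
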