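#' Kolmogorov-Smirnov difference values
#'
#' Compares the wild-type and perturbed activity distributions of every
#' component with a two-sample, two-sided Kolmogorov-Smirnov test. The
#' sample unit is the per-environment-combination replicate-mean AL, so each
#' group contributes one value per sampled combination. A component's
#' difference value (DV) is the KS statistic when the test's p-value is below
#' `alpha`, and 0 otherwise; the clamped component(s) themselves are forced
#' to DV 0, because interest is in the effect of a perturbation on the *rest*
#' of the network.
#'
#' Exact p-values are used when both groups have at most 25 combinations,
#' the asymptotic distribution otherwise. No multiple-testing correction is
#' applied by default (set `p_adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param wt,pert Tidy activity tables (same component set, >= 2 environment
#'   combinations each).
#' @param alpha Significance threshold (default 0.05).
#' @param clamped Component ids clamped in the perturbed run (defaults to the
#'   ids encoded in the perturbed table's `perturbation` label).
#' @param p_adjust Multiple-testing correction across components, passed to
#'   [stats::p.adjust()]; `"none"` (default) applies the raw threshold.
#' @return Tibble `component`, `statistic`, `p_value`, `dv`.
#' @examples
#' m <- motif_fixtures()$and_cascade
#' cfg <- sim_config(steps = 150, window = 50, replicates = 4, seed = 7)
#' s <- sample_combinations(environment_condition("e", list(E = c(20, 90))),
#'                          10, cfg$seed)
#' wt <- simulate_condition(m, s, config = cfg)
#' ko <- simulate_condition(m, s, clamps = perturbation(H = 0), config = cfg)
#' difference_values(wt, ko)
#' @export
difference_values <- function(wt, pert, alpha = 0.05, clamped = NULL,
                              p_adjust = "none") {
  comps_wt <- sort(unique(wt$component))
  comps_pt <- sort(unique(pert$component))
  if (!identical(comps_wt, comps_pt)) {
    abort("wild-type and perturbed tables cover different component sets")
  }
  if (length(unique(wt$env_index)) < 2) {
    abort("need >= 2 environment combinations")
  }
  if (is.null(clamped)) {
    lab <- unique(pert$perturbation)
    clamped <- if (length(lab) == 1 && !is.na(lab)) {
      names(parse_perturbation(lab)$clamps)
    } else {
      character()
    }
  }
  mw <- mean_activity(wt)
  mp <- mean_activity(pert)
  res <- purrr::map_dfr(comps_wt, function(cp) {
    x <- mw$al[mw$component == cp]
    y <- mp$al[mp$component == cp]
    exact <- length(x) <= 25 && length(y) <= 25
    kt <- suppressWarnings(ks.test(x, y, exact = exact))
    tibble(component = cp, statistic = unname(kt$statistic),
           p_value = kt$p.value)
  })
  padj <- stats::p.adjust(res$p_value, method = p_adjust)
  res |>
    mutate(
      dv = ifelse(padj < alpha, .data$statistic, 0),
      dv = ifelse(.data$component %in% clamped, 0, .data$dv)
    )
}

#' Difference-value matrix of a screen
#'
#' Applies [difference_values()] to every perturbation of a
#' [single_perturbation_screen()] (or combinatorial) result, producing the
#' long-format DV matrix that downstream influence scoring consumes.
#'
#' @param screen A `screen_result`.
#' @param alpha,p_adjust As in [difference_values()].
#' @return A `dv_matrix`: tibble `perturbation`, `component`, `statistic`,
#'   `p_value`, `dv`, with the screen's condition/direction/alpha stored as
#'   attributes.
#' @export
screen_difference_values <- function(screen, alpha = 0.05, p_adjust = "none") {
  out <- purrr::imap_dfr(screen$perturbed, function(tbl, lab) {
    clamps <- parse_perturbation(lab)$clamps
    # single-clamp rows are keyed by the bare component id, so rankings,
    # overlaps and upstream-regulator joins work on component sets directly
    key <- if (length(clamps) == 1) names(clamps) else lab
    difference_values(screen$wild_type, tbl, alpha = alpha,
                      clamped = names(clamps), p_adjust = p_adjust) |>
      mutate(perturbation = key, .before = 1)
  })
  new_dv_matrix(out, alpha = alpha,
                condition = screen$condition$name,
                direction = screen$direction %||% NA_character_,
                M = length(internal_components(screen$model)))
}

new_dv_matrix <- function(tbl, alpha, condition = NA_character_,
                          direction = NA_character_, M = NULL) {
  structure(as_tibble(tbl),
            alpha = alpha, condition = condition, direction = direction,
            M = M %||% length(unique(tbl$perturbation)),
            class = c("dv_matrix", class(as_tibble(tbl))))
}

#' @method glance dv_matrix
#' @export
glance.dv_matrix <- function(x, ...) {
  tibble(
    condition = attr(x, "condition"),
    direction = attr(x, "direction"),
    alpha = attr(x, "alpha"),
    n_perturbations = length(unique(x$perturbation)),
    n_components = length(unique(x$component)),
    n_significant = sum(x$dv > 0),
    total_dv = sum(x$dv)
  )
}

#' Influence scores and ranking
#'
#' The influence score (IS) of a perturbation is the sum of its difference
#' values over all network components, `IS_i = sum_j DV_ij`, so
#' `0 <= IS <= M`. Perturbations are ranked by descending IS (ties broken
#' lexicographically by component id). The *most influential* set is the top
#' 10% (`ceiling(0.10 * M)` components); the *least influential* set is the
#' perturbations with IS exactly 0.
#'
#' @param dvm A `dv_matrix` from [screen_difference_values()] (or any tibble
#'   with `perturbation`, `component`, `dv`).
#' @param top_fraction Fraction declared most influential (default 0.10).
#' @return An `influence_ranking`: tibble `perturbation`, `is`, `rank`,
#'   `most_influential`, `least_influential`, with `M` and the top-set size
#'   as attributes. If every IS is 0 the ranking is flagged `empty_signal`.
#' @export
influence_scores <- function(dvm, top_fraction = 0.10) {
  M <- attr(dvm, "M") %||% length(unique(dvm$perturbation))
  scores <- dvm |>
    group_by(.data$perturbation) |>
    summarise(is = sum(.data$dv), .groups = "drop") |>
    arrange(dplyr::desc(.data$is), .data$perturbation) |>
    mutate(rank = dplyr::row_number())
  n_top <- ceiling(top_fraction * M)
  scores <- scores |>
    mutate(
      most_influential = .data$rank <= n_top,
      least_influential = .data$is == 0
    )
  structure(scores,
            M = M, n_top = n_top, alpha = attr(dvm, "alpha"),
            condition = attr(dvm, "condition"),
            direction = attr(dvm, "direction"),
            empty_signal = all(scores$is == 0),
            class = c("influence_ranking", class(scores)))
}

#' @method tidy influence_ranking
#' @export
tidy.influence_ranking <- function(x, ...) as_tibble(unclass(x))

#' @method glance influence_ranking
#' @export
glance.influence_ranking <- function(x, ...) {
  tibble(
    condition = attr(x, "condition"),
    direction = attr(x, "direction"),
    M = attr(x, "M"),
    n_top = attr(x, "n_top"),
    n_most = sum(x$most_influential),
    n_least = sum(x$least_influential),
    empty_signal = attr(x, "empty_signal"),
    max_is = max(x$is)
  )
}

#' Most-influential / least-influential component sets
#'
#' @param ranking An `influence_ranking`.
#' @return Character vector of perturbation ids.
#' @export
most_influential <- function(ranking) {
  ranking$perturbation[ranking$most_influential]
}

#' @rdname most_influential
#' @export
least_influential <- function(ranking) {
  ranking$perturbation[ranking$least_influential]
}

#' Components most affected by a perturbation
#'
#' Ranks the components whose DV under the given perturbation reaches
#' `threshold`, in decreasing DV order (ties broken by component id). The
#' default threshold 1.0 selects the *most affected* components: complete
#' separation of the WT and perturbed AL distributions.
#'
#' @param dvm A `dv_matrix`.
#' @param perturbation Perturbation label (or bare component id, matched
#'   against the labels).
#' @param threshold Minimum DV (default 1.0).
#' @return Tibble `component`, `dv`, ranked.
#' @export
most_affected <- function(dvm, perturbation, threshold = 1.0) {
  labs <- unique(dvm$perturbation)
  lab <- if (perturbation %in% labs) {
    perturbation
  } else {
    hit <- labs[vapply(labs, function(l) {
      cl <- tryCatch(parse_perturbation(l)$clamps, error = function(e) NULL)
      identical(names(cl), perturbation)
    }, logical(1))]
    if (length(hit) != 1) {
      abort(paste0("unknown perturbation: ", perturbation))
    }
    hit
  }
  dvm |>
    filter(.data$perturbation == lab, .data$dv >= threshold) |>
    select("component", "dv") |>
    arrange(dplyr::desc(.data$dv), .data$component)
}

#' Fold differences between perturbed and wild-type activity
#'
#' For every component, the fold difference is the overall mean AL in the
#' perturbed experiment divided by the overall mean AL in the wild type
#' (perturbed/WT). Each pair receives exactly one classification:
#' * `"fold"` — both means positive; the numeric ratio is meaningful;
#' * `"complete_inactivation"` — perturbed mean 0, WT mean > 0;
#' * `"complete_activation"` — WT mean 0, perturbed mean > 0 (activation
#'   from zero; fold undefined);
#' * `"no_change"` — both means 0;
#' * `"NSA"` — no significant alteration: DV = 0 for the pair when a DV
#'   matrix is supplied (overrides the numeric classes).
#'
#' @param wt,pert Tidy activity tables sharing structure.
#' @param dvm Optional tibble with `component` and `dv` for this
#'   perturbation (e.g. from [difference_values()]); pairs with DV 0 are
#'   reported `"NSA"`.
#' @return Tibble `component`, `al_wt`, `al_pert`, `fold`, `classification`.
#' @export
fold_differences <- function(wt, pert, dvm = NULL) {
  ow <- overall_activity(wt) |> rename(al_wt = "al")
  op <- overall_activity(pert) |> rename(al_pert = "al")
  res <- inner_join(ow, op, by = "component") |>
    mutate(
      fold = ifelse(.data$al_wt > 0, .data$al_pert / .data$al_wt, NA_real_),
      classification = dplyr::case_when(
        .data$al_wt == 0 & .data$al_pert == 0 ~ "no_change",
        .data$al_pert == 0 ~ "complete_inactivation",
        .data$al_wt == 0 ~ "complete_activation",
        TRUE ~ "fold"
      )
    )
  if (!is.null(dvm)) {
    nsa <- dvm$component[dvm$dv == 0]
    res <- res |>
      mutate(classification = ifelse(
        .data$component %in% nsa & .data$classification != "no_change",
        "NSA", .data$classification
      ))
  }
  res
}

#' Overlap of most-influential sets across conditions
#'
#' Set algebra over the most-influential sets of several conditions: the
#' all-condition intersection, the components unique to each condition, and
#' all pairwise intersections.
#'
#' @param rankings Named list (condition -> `influence_ranking` or character
#'   vector of most-influential ids); >= 2 conditions.
#' @return List with `sets` (the per-condition sets), `intersection`,
#'   `unique` (named list), and `pairwise` (tibble `condition_a`,
#'   `condition_b`, `shared`). All orderings are deterministic
#'   (lexicographic).
#' @export
cross_condition_overlap <- function(rankings) {
  if (length(rankings) < 2) abort("need >= 2 conditions")
  sets <- purrr::map(rankings, function(r) {
    sort(if (inherits(r, "influence_ranking")) most_influential(r) else r)
  })
  conds <- sort(names(sets))
  sets <- sets[conds]
  inter <- sort(purrr::reduce(sets, intersect))
  uniq <- purrr::imap(sets, function(s, nm) {
    sort(setdiff(s, unique(unlist(sets[setdiff(conds, nm)]))))
  })
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    tibble(condition_a = p[1], condition_b = p[2],
           shared = list(sort(intersect(sets[[p[1]]], sets[[p[2]]]))))
  })
  list(sets = sets, intersection = inter, unique = uniq, pairwise = pairwise)
}

#' Perturbations that move a target component
#'
#' For each target (typically a most-influential component), lists the
#' perturbations whose DV on that target reaches `threshold`, annotated with
#' whether the perturbed component is a direct regulator of the target in
#' the interaction graph and whether it is itself most influential.
#'
#' @param dvm A `dv_matrix`.
#' @param graph Interaction graph (or [boolean_model()]) of the same model.
#' @param targets Character vector of target component ids.
#' @param threshold Minimum DV (default 1.0).
#' @param ranking Optional `influence_ranking` used for the
#'   `most_influential` annotation.
#' @return Tibble `target`, `perturbation`, `dv`, `direct_regulator`,
#'   `most_influential`.
#' @export
upstream_regulators <- function(dvm, graph, targets, threshold = 1.0,
                                ranking = NULL) {
  if (inherits(graph, "boolean_model")) graph <- interaction_graph(graph)
  mi <- if (is.null(ranking)) character() else most_influential(ranking)
  purrr::map_dfr(targets, function(tg) {
    hits <- dvm |>
      filter(.data$component == tg, .data$dv >= threshold,
             .data$perturbation != tg)
    if (nrow(hits) == 0) return(tibble())
    regs <- igraph::neighbors(graph, tg, mode = "in")$name
    hits |>
      mutate(target = tg,
             direct_regulator = .data$perturbation %in% regs,
             most_influential = .data$perturbation %in% mi) |>
      select("target", "perturbation", "dv", "direct_regulator",
             "most_influential") |>
      arrange(dplyr::desc(.data$dv), .data$perturbation)
  })
}
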