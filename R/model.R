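#' Construct a Boolean model
#'
#' A Boolean model of signal transduction consists of components that are
#' either *internal* (governed by a regulatory Boolean function of other
#' components) or *external* (stimuli/ligands whose activity is set by the
#' environment, realised during simulation as independent per-step Bernoulli
#' draws). Each internal component carries exactly one truth table; external
#' components carry none.
#'
#' Truth-table rows are ordered by reading the regulator states as a binary
#' number with the first-listed regulator most significant, so row `r`
#' (0-based) encodes regulator `j` (1-based) in bit `k - j` of `r`.
#'
#' @param components A data frame with columns `id`, `name`, `kind`
#'   (`"internal"` or `"external"`). `name` may be omitted (defaults to `id`).
#' @param functions A named list (names = internal component ids); each
#'   element is a list with `regulators` (character vector of component ids,
#'   length `k >= 1`) and `outputs` (integer vector of 0/1, length `2^k`).
#'
#' @return An object of class `boolean_model` with elements `components`
#'   (tibble) and `functions`.
#' @examples
#' m <- boolean_model(
#'   components = data.frame(id = c("E", "A"), kind = c("external", "internal")),
#'   functions = list(A = list(regulators = "E", outputs = c(0L, 1L)))
#' )
#' m
#' @export
boolean_model <- function(components, functions) {
  components <- as_tibble(components)
  if (!"name" %in% names(components)) components$name <- components$id
  components <- components[, c("id", "name", "kind")]
  components$id <- as.character(components$id)
  components$name <- as.character(components$name)
  components$kind <- as.character(components$kind)
  functions <- lapply(functions, function(f) {
    list(
      regulators = as.character(f$regulators),
      outputs = as.integer(f$outputs)
    )
  })
  internal_ids <- components$id[components$kind == "internal"]
  if (setequal(names(functions), internal_ids)) {
    functions <- functions[internal_ids]  # canonical order: component order
  }
  model <- structure(
    list(components = components, functions = functions),
    class = "boolean_model"
  )
  validate_boolean_model(model)
  model
}

#' Validate a Boolean model
#'
#' Checks the structural invariants: unique component ids, `kind` in
#' {internal, external}, exactly one truth table per internal component and
#' none for externals, every regulator resolving to a declared component,
#' `k >= 1` regulators and `2^k` rows of 0/1 outputs per table.
#'
#' @param model A [boolean_model()].
#' @return `model`, invisibly. Errors describe the first violated invariant.
#' @export
validate_boolean_model <- function(model) {
  comp <- model$components
  if (anyDuplicated(comp$id)) {
    abort(paste0(
      "duplicate component id(s): ",
      paste(unique(comp$id[duplicated(comp$id)]), collapse = ", ")
    ))
  }
  if (!all(comp$kind %in% c("internal", "external"))) {
    abort("component kind must be 'internal' or 'external'")
  }
  internal <- comp$id[comp$kind == "internal"]
  external <- comp$id[comp$kind == "external"]
  fn_targets <- names(model$functions)
  missing_fn <- setdiff(internal, fn_targets)
  if (length(missing_fn) > 0) {
    abort(paste0("internal component(s) without a regulatory function: ",
                 paste(missing_fn, collapse = ", ")))
  }
  extra_fn <- setdiff(fn_targets, internal)
  if (length(extra_fn) > 0) {
    abort(paste0("function(s) for non-internal component(s): ",
                 paste(extra_fn, collapse = ", ")))
  }
  for (target in fn_targets) {
    f <- model$functions[[target]]
    k <- length(f$regulators)
    if (k < 1) abort(paste0("component '", target, "' has no regulators (k >= 1 required)"))
    if (anyDuplicated(f$regulators)) {
      abort(paste0("component '", target, "' lists a duplicated regulator"))
    }
    unknown <- setdiff(f$regulators, comp$id)
    if (length(unknown) > 0) {
      abort(paste0("component '", target, "' references undeclared regulator(s): ",
                   paste(unknown, collapse = ", ")))
    }
    if (length(f$outputs) != 2^k) {
      abort(paste0("component '", target, "' truth table has ",
                   length(f$outputs), " rows; expected ", 2^k))
    }
    if (!all(f$outputs %in% c(0L, 1L))) {
      abort(paste0("component '", target, "' truth table outputs must be 0/1"))
    }
  }
  invisible(model)
}

#' @export
print.boolean_model <- function(x, ...) {
  n_int <- sum(x$components$kind == "internal")
  n_ext <- sum(x$components$kind == "external")
  cat("<boolean_model> ", nrow(x$components), " components (",
      n_int, " internal, ", n_ext, " external), ",
      n_interactions(x), " interactions\n", sep = "")
  invisible(x)
}

#' Component id accessors
#'
#' @param model A [boolean_model()].
#' @return Character vector of component ids.
#' @export
components <- function(model) model$components$id

#' @rdname components
#' @export
internal_components <- function(model) {
  model$components$id[model$components$kind == "internal"]
}

#' @rdname components
#' @export
external_components <- function(model) {
  model$components$id[model$components$kind == "external"]
}

#' Regulatory interactions of a model
#'
#' Interactions are the distinct directed (regulator, target) pairs appearing
#' in the truth tables; a regulator used by a target counts once regardless of
#' how many truth-table rows it switches.
#'
#' @param model A [boolean_model()].
#' @return `interactions()`: a tibble with columns `regulator`, `target`.
#'   `n_interactions()`: the interaction count.
#' @export
interactions <- function(model) {
  if (length(model$functions) == 0) {
    return(tibble(regulator = character(), target = character()))
  }
  purrr::map_dfr(names(model$functions), function(target) {
    tibble(regulator = unique(model$functions[[target]]$regulators),
           target = target)
  }) |> distinct()
}

#' @rdname interactions
#' @export
n_interactions <- function(model) nrow(interactions(model))

#' Interaction graph of a Boolean model
#'
#' Builds the directed graph whose nodes are all component ids and whose
#' edges are the distinct (regulator -> target) pairs.
#'
#' @param model A [boolean_model()].
#' @return An [igraph::igraph] directed graph.
#' @seealso [reachable_from()] for forward-reachability queries.
#' @export
interaction_graph <- function(model) {
  edges <- interactions(model)
  igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = model$components$id)
  )
}

#' Forward-reachable components
#'
#' Components reachable from `id` by following regulator -> target edges
#' (excluding `id` itself unless it lies on a cycle through itself).
#'
#' @param graph An interaction graph from [interaction_graph()], or a
#'   [boolean_model()].
#' @param id Component id.
#' @return Character vector of reachable component ids.
#' @export
reachable_from <- function(graph, id) {
  if (inherits(graph, "boolean_model")) graph <- interaction_graph(graph)
  if (!id %in% igraph::V(graph)$name) abort(paste0("unknown component: ", id))
  # nodes reachable in >= 1 step: union of forward closures of out-neighbours,
  # so id itself appears only when it lies on a cycle
  nbrs <- igraph::neighbors(graph, id, mode = "out")$name
  out <- unique(unlist(lapply(nbrs, function(v) {
    igraph::subcomponent(graph, v, mode = "out")$name
  })))
  sort(as.character(out %||% character(0)))
}

# internal: positional encoding of a model for the C++ simulator
model_encoding <- function(model) {
  ids <- model$components$id
  idx <- setNames(seq_along(ids), ids)
  kind <- as.integer(model$components$kind == "internal")
  reg_idx <- vector("list", length(ids))
  tt_out <- vector("list", length(ids))
  ext_p <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    if (kind[i] == 1L) {
      f <- model$functions[[ids[i]]]
      reg_idx[[i]] <- unname(idx[f$regulators])
      tt_out[[i]] <- f$outputs
    } else {
      reg_idx[[i]] <- integer()
      tt_out[[i]] <- integer()
    }
  }
  list(ids = ids, idx = idx, kind = kind, reg_idx = reg_idx,
       tt_out = tt_out, ext_p = ext_p)
}
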