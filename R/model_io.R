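#' Read and write the plain-text truth-table dialect
#'
#' A simple UTF-8 text format for Boolean models. The first non-comment line
#' is the header `# boolean-truth-table v1`. External components are declared
#' once each as `external <id>`. Every internal component appears as a block:
#' ```
#' target <id>
#' regulators <id1> <id2> ...
#' <bitstring> <0|1>      (2^k lines, bitstring = regulator states,
#'                         first-listed regulator most significant)
#' ```
#' Lines starting with `#` (after the header) are comments.
#'
#' @param path File path.
#' @return `load_truth_tables()` returns a [boolean_model()];
#'   `write_truth_tables()` returns `path` invisibly.
#' @examples
#' m <- motif_fixtures()$pass_through
#' f <- tempfile(fileext = ".tt")
#' write_truth_tables(m, f)
#' identical(load_truth_tables(f), m)
#' @export
load_truth_tables <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0 || !grepl("^#\\s*boolean-truth-table v1\\s*$", lines[1])) {
    abort("truth-table file must start with header '# boolean-truth-table v1'")
  }
  order_id <- character()
  order_kind <- character()
  functions <- list()
  i <- 2L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "external") {
      if (length(tok) != 2) abort(paste0("line ", i, ": expected 'external <id>'"))
      order_id <- c(order_id, tok[2])
      order_kind <- c(order_kind, "external")
      i <- i + 1L
    } else if (tok[1] == "target") {
      if (length(tok) != 2) abort(paste0("line ", i, ": expected 'target <id>'"))
      target <- tok[2]
      if (target %in% names(functions)) {
        abort(paste0("line ", i, ": duplicate target '", target, "'"))
      }
      i <- i + 1L
      while (i <= n && (trimws(lines[i]) == "" || startsWith(trimws(lines[i]), "#"))) i <- i + 1L
      rtok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(rtok) < 2 || rtok[1] != "regulators") {
        abort(paste0("line ", i, ": expected 'regulators <id> ...' for target '",
                     target, "'"))
      }
      regulators <- rtok[-1]
      k <- length(regulators)
      outputs <- integer(2^k)
      seen <- logical(2^k)
      i <- i + 1L
      rows <- 0L
      while (i <= n && rows < 2^k) {
        row <- trimws(lines[i])
        if (row == "" || startsWith(row, "#")) { i <- i + 1L; next }
        otok <- strsplit(row, "\\s+")[[1]]
        if (length(otok) != 2 || !grepl("^[01]+$", otok[1]) ||
            nchar(otok[1]) != k || !otok[2] %in% c("0", "1")) {
          abort(paste0("line ", i, ": expected ", 2^k, " rows '<", k,
                       "-bit string> <0|1>' for target '", target, "'"))
        }
        ridx <- strtoi(otok[1], base = 2L) + 1L
        if (seen[ridx]) abort(paste0("line ", i, ": duplicate row '", otok[1], "'"))
        seen[ridx] <- TRUE
        outputs[ridx] <- as.integer(otok[2])
        rows <- rows + 1L
        i <- i + 1L
      }
      if (rows < 2^k) {
        abort(paste0("target '", target, "': found ", rows,
                     " truth-table rows; expected ", 2^k))
      }
      order_id <- c(order_id, target)
      order_kind <- c(order_kind, "internal")
      functions[[target]] <- list(regulators = regulators, outputs = outputs)
    } else {
      abort(paste0("line ", i, ": unrecognised directive '", tok[1], "'"))
    }
  }
  comp <- tibble(id = order_id, kind = order_kind)
  boolean_model(comp, functions)
}

#' @param model A [boolean_model()].
#' @rdname load_truth_tables
#' @export
write_truth_tables <- function(model, path) {
  validate_boolean_model(model)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# boolean-truth-table v1", con)
  # component order of the model is preserved, so write -> read is an identity
  # (the dialect carries ids only; display names are not serialised)
  for (i in seq_len(nrow(model$components))) {
    id <- model$components$id[i]
    if (model$components$kind[i] == "external") {
      writeLines(paste("external", id), con)
    } else {
      f <- model$functions[[id]]
      k <- length(f$regulators)
      writeLines(paste("target", id), con)
      writeLines(paste("regulators", paste(f$regulators, collapse = " ")), con)
      for (r in seq_len(2^k)) {
        bits <- paste(as.integer(bitwAnd(bitwShiftR(r - 1L, (k - 1):0), 1L)),
                      collapse = "")
        writeLines(paste(bits, f$outputs[r]), con)
      }
    }
  }
  invisible(path)
}

#' Read a Boolean model from SBML-qual
#'
#' Parses an SBML Level 3 file using the `qual` extension into a
#' [boolean_model()]. Only Boolean models are supported: every qualitative
#' species must have `maxLevel` 1 (or unspecified). Species with no governing
#' transition become external components; each transition's function terms
#' (MathML over its listed inputs, plus the default term) are expanded to a
#' full truth table over those inputs.
#'
#' Supported MathML inside function terms: `and`, `or`, `not`, `xor`, the
#' comparisons `eq`, `neq`, `lt`, `leq`, `gt`, `geq` between a species (`ci`)
#' and a number (`cn`), bare `ci` (treated as "species active"), and the
#' constants `true`/`false`.
#'
#' @param path Path to an SBML-qual file.
#' @return A [boolean_model()].
#' @export
load_sbml_qual <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # elements in the qual/MathML namespaces keep their prefixes after the
  # default-namespace strip, so element queries match on local-name()
  ln <- function(name) paste0("*[local-name()='", name, "']")
  qs <- xml2::xml_find_all(
    doc, paste0(".//", ln("listOfQualitativeSpecies"), "/",
                ln("qualitativeSpecies")))
  if (length(qs) == 0) abort("no qualitative species found; not an SBML-qual model?")
  sp_id <- xml2::xml_attr(qs, "id")
  sp_name <- xml2::xml_attr(qs, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  max_level <- xml2::xml_attr(qs, "maxLevel")
  bad <- which(!is.na(max_level) & max_level != "1")
  if (length(bad) > 0) {
    abort(paste0("unsupported (non-Boolean) maxLevel for species: ",
                 paste(sp_id[bad], collapse = ", ")))
  }

  transitions <- xml2::xml_find_all(
    doc, paste0(".//", ln("listOfTransitions"), "/", ln("transition")))
  functions <- list()
  for (tr in transitions) {
    out_nodes <- xml2::xml_find_all(
      tr, paste0("./", ln("listOfOutputs"), "/", ln("output")))
    out_sp <- xml2::xml_attr(out_nodes, "qualitativeSpecies")
    if (length(out_sp) == 0) abort("transition with no output species")
    in_nodes <- xml2::xml_find_all(
      tr, paste0("./", ln("listOfInputs"), "/", ln("input")))
    in_sp <- xml2::xml_attr(in_nodes, "qualitativeSpecies")
    unknown <- setdiff(c(in_sp, out_sp), sp_id)
    if (length(unknown) > 0) {
      abort(paste0("transition references undeclared species: ",
                   paste(unknown, collapse = ", ")))
    }
    fterms <- xml2::xml_find_all(
      tr, paste0("./", ln("listOfFunctionTerms"), "/", ln("functionTerm")))
    dterm <- xml2::xml_find_first(
      tr, paste0("./", ln("listOfFunctionTerms"), "/", ln("defaultTerm")))
    if (length(fterms) == 0 && inherits(dterm, "xml_missing")) {
      abort(paste0("transition for '", paste(out_sp, collapse = ","),
                   "' declares inputs but no function terms"))
    }
    default_level <- if (inherits(dterm, "xml_missing")) 0L else
      as.integer(xml2::xml_attr(dterm, "resultLevel"))
    term_levels <- as.integer(xml2::xml_attr(fterms, "resultLevel"))
    term_math <- lapply(fterms, function(ft) {
      m <- xml2::xml_find_first(ft, "./*[local-name()='math']")
      if (inherits(m, "xml_missing")) abort("functionTerm without <math>")
      first_child_element(m)
    })
    if (length(in_sp) == 0) abort(paste0("transition for '", out_sp,
                                         "' has function terms but no inputs"))
    k <- length(in_sp)
    outputs <- integer(2^k)
    for (r in 0:(2^k - 1)) {
      states <- setNames(as.integer(bitwAnd(bitwShiftR(r, (k - 1):0), 1L)), in_sp)
      level <- default_level
      for (ti in seq_along(term_math)) {
        if (eval_mathml(term_math[[ti]], states)) {
          level <- term_levels[ti]
          break
        }
      }
      if (!level %in% c(0L, 1L)) {
        abort(paste0("non-Boolean result level ", level, " for species '",
                     out_sp[1], "'"))
      }
      outputs[r + 1L] <- level
    }
    for (target in out_sp) {
      if (!is.null(functions[[target]])) {
        abort(paste0("species '", target, "' is governed by more than one transition"))
      }
      functions[[target]] <- list(regulators = in_sp, outputs = outputs)
    }
  }
  comp <- tibble(
    id = sp_id,
    name = sp_name,
    kind = ifelse(sp_id %in% names(functions), "internal", "external")
  )
  boolean_model(comp, functions)
}

first_child_element <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) abort("empty MathML element")
  kids[[1]]
}

# evaluate a MathML expression node against named 0/1 species states
eval_mathml <- function(node, states) {
  name <- xml2::xml_name(node)
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    switch(op,
      "and" = all(vapply(args, eval_mathml, logical(1), states = states)),
      "or"  = any(vapply(args, eval_mathml, logical(1), states = states)),
      "xor" = sum(vapply(args, eval_mathml, logical(1), states = states)) %% 2 == 1,
      "not" = !eval_mathml(args[[1]], states),
      "eq"  = mathml_value(args[[1]], states) == mathml_value(args[[2]], states),
      "neq" = mathml_value(args[[1]], states) != mathml_value(args[[2]], states),
      "lt"  = mathml_value(args[[1]], states) <  mathml_value(args[[2]], states),
      "leq" = mathml_value(args[[1]], states) <= mathml_value(args[[2]], states),
      "gt"  = mathml_value(args[[1]], states) >  mathml_value(args[[2]], states),
      "geq" = mathml_value(args[[1]], states) >= mathml_value(args[[2]], states),
      abort(paste0("unsupported MathML operator: ", op))
    )
  } else if (name == "ci") {
    mathml_value(node, states) == 1
  } else if (name == "true") {
    TRUE
  } else if (name == "false") {
    FALSE
  } else {
    abort(paste0("unsupported MathML element: ", name))
  }
}

mathml_value <- function(node, states) {
  name <- xml2::xml_name(node)
  if (name == "ci") {
    sp <- trimws(xml2::xml_text(node))
    if (!sp %in% names(states)) {
      abort(paste0("function term references '", sp,
                   "', which is not a listed input"))
    }
    states[[sp]]
  } else if (name == "cn") {
    as.numeric(trimws(xml2::xml_text(node)))
  } else {
    abort(paste0("unsupported MathML value element: ", name))
  }
}
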