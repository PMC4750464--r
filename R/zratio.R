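#' Per-array Z-score standardisation
#'
#' Standardises a log2-intensity matrix array by array:
#' `z = (value - array mean) / array SD`. The default SD convention is the
#' sample SD (denominator n-1); set `sd = "population"` for the n
#' denominator.
#'
#' @param log2_matrix Numeric matrix, genes x arrays (>= 2 genes).
#' @param sd `"sample"` (default) or `"population"`.
#' @return Matrix of the same shape; every column has mean 0 and (under the
#'   chosen convention) SD 1.
#' @export
zscores <- function(log2_matrix, sd = c("sample", "population")) {
  sd <- match.arg(sd)
  log2_matrix <- as.matrix(log2_matrix)
  if (nrow(log2_matrix) < 2) abort("need >= 2 genes per array")
  if (any(!is.finite(log2_matrix))) abort("non-finite intensities")
  n <- nrow(log2_matrix)
  mu <- colMeans(log2_matrix)
  s <- apply(log2_matrix, 2, stats::sd)
  if (sd == "population") s <- s * sqrt((n - 1) / n)
  if (any(s == 0)) {
    abort(paste0("zero within-array variance in array(s): ",
                 paste(colnames(log2_matrix)[s == 0], collapse = ", ")))
  }
  sweep(sweep(log2_matrix, 2, mu, "-"), 2, s, "/")
}

#' Z-ratio differential-expression calls
#'
#' For each gene, the Z-ratio is the difference between its mean Z-score in
#' the treated group and in the control group, divided by the standard
#' deviation of those gene-wise differences across all genes. Genes with
#' Z-ratio >= `cutoff` are called `up`, <= -`cutoff` `down`, otherwise
#' `unchanged`. The default cutoff of 1.50 is the conventional robust
#' threshold for this statistic. When treated and control are identical the
#' gene-wise differences have zero spread and the Z-ratio is defined as 0
#' for every gene.
#'
#' @param z_treated,z_control Z-scored matrices (from [zscores()]) with
#'   matching genes (rownames).
#' @param cutoff Call threshold (default 1.50).
#' @return A `zratio_result` tibble: `gene`, `z_treated`, `z_control`,
#'   `diff`, `z_ratio`, `call`.
#' @examples
#' x <- synthetic_expression(n_genes = 200, n_arrays = 3, seed = 2)
#' z <- zscores(x$intensities)
#' zr <- zratios(z[, grepl("^trt", colnames(z))],
#'               z[, grepl("^ctrl", colnames(z))])
#' dplyr::count(zr, call)
#' @export
zratios <- function(z_treated, z_control, cutoff = 1.50) {
  z_treated <- as.matrix(z_treated)
  z_control <- as.matrix(z_control)
  if (nrow(z_treated) != nrow(z_control) ||
      !identical(rownames(z_treated), rownames(z_control))) {
    abort("treated and control matrices must cover the same genes")
  }
  genes <- rownames(z_treated) %||% paste0("g", seq_len(nrow(z_treated)))
  zt <- rowMeans(z_treated)
  zc <- rowMeans(z_control)
  d <- zt - zc
  s <- stats::sd(d)
  zr <- if (is.na(s) || s == 0) rep(0, length(d)) else d / s
  res <- tibble(
    gene = genes, z_treated = zt, z_control = zc, diff = d, z_ratio = zr,
    call = dplyr::case_when(
      zr >= cutoff ~ "up",
      zr <= -cutoff ~ "down",
      TRUE ~ "unchanged"
    )
  )
  structure(res, cutoff = cutoff,
            class = c("zratio_result", class(res)))
}

#' @method glance zratio_result
#' @export
glance.zratio_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    cutoff = attr(x, "cutoff")
  )
}

#' Concordance between model fold changes and expression calls
#'
#' Cross-tabulates model components whose activity changed at least
#' `fold_cutoff`-fold (up: `fold >= fold_cutoff` or complete activation;
#' down: `fold <= 1/fold_cutoff` or complete inactivation) against
#' gene-level Z-ratio calls, via a component-to-gene mapping. A component is
#' concordant when any of its mapped genes carries the matching call in at
#' least one replicate comparison (`mode = "any"`; `"all"` requires every
#' replicate comparison to agree). Components with no mapped gene are
#' excluded and tallied.
#'
#' @param model_folds Tibble from [fold_differences()].
#' @param calls A `zratio_result`, or a list of them (one per biological
#'   replicate comparison).
#' @param gene_map Data frame with columns `component`, `gene`.
#' @param fold_cutoff Model fold-change threshold (default 2.0).
#' @param mode `"any"` (default) or `"all"` across replicate comparisons.
#' @return List with `summary` (tibble `direction`, `n_components`,
#'   `n_concordant`, `fraction`), `detail` (per component), and `unmapped`
#'   (components with changed activity but no mapped gene).
#' @export
concordance <- function(model_folds, calls, gene_map, fold_cutoff = 2.0,
                        mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (inherits(calls, "zratio_result")) calls <- list(calls)
  gene_map <- as_tibble(gene_map)
  if (nrow(gene_map) == 0) abort("empty component-to-gene mapping")
  model_dir <- model_folds |>
    mutate(direction = dplyr::case_when(
      .data$classification == "complete_activation" ~ "up",
      .data$classification == "complete_inactivation" ~ "down",
      .data$classification == "fold" & .data$fold >= fold_cutoff ~ "up",
      .data$classification == "fold" & .data$fold <= 1 / fold_cutoff ~ "down",
      TRUE ~ "none"
    )) |>
    filter(.data$direction != "none")
  unmapped <- setdiff(model_dir$component, gene_map$component)
  detail <- model_dir |>
    filter(.data$component %in% gene_map$component) |>
    mutate(concordant = purrr::map2_lgl(
      .data$component, .data$direction,
      function(cp, dir) {
        genes <- gene_map$gene[gene_map$component == cp]
        per_rep <- vapply(calls, function(zr) {
          any(zr$call[zr$gene %in% genes] == dir)
        }, logical(1))
        if (mode == "any") any(per_rep) else all(per_rep)
      }
    )) |>
    select("component", "direction", "fold", "concordant")
  summary <- detail |>
    group_by(.data$direction) |>
    summarise(
      n_components = n(),
      n_concordant = sum(.data$concordant),
      fraction = mean(.data$concordant),
      .groups = "drop"
    )
  list(summary = summary, detail = detail, unmapped = unmapped)
}
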