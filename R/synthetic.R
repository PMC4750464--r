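#' Generate a random Boolean network
#'
#' Kauffman-style random network: each internal component draws `k`
#' regulators uniformly without replacement from all components, and each of
#' its `2^k` truth-table rows outputs 1 independently with probability
#' `bias`. External components have no function and are driven by the
#' environment during simulation.
#'
#' @param n_internal Number of internal components (>= 1), ids `I1..`.
#' @param n_external Number of external components (>= 0), ids `E1..`.
#' @param in_degree Regulators per internal component: a single `k` or a
#'   `c(min, max)` range sampled uniformly per component. Must satisfy
#'   `1 <= k <= n_internal + n_external`.
#' @param bias Probability a truth-table row outputs 1 (default 0.5).
#' @param seed Integer seed (deterministic output).
#' @return A [boolean_model()].
#' @examples
#' random_boolean_network(10, 2, in_degree = 2, seed = 1)
#' @export
random_boolean_network <- function(n_internal, n_external = 1, in_degree = 2,
                                   bias = 0.5, seed = 1) {
  stopifnot(n_internal >= 1, n_external >= 0, bias >= 0, bias <= 1)
  n_total <- n_internal + n_external
  if (length(in_degree) == 1) in_degree <- c(in_degree, in_degree)
  if (in_degree[1] < 1 || in_degree[2] > n_total) {
    abort(paste0("in_degree must lie in [1, ", n_total, "]"))
  }
  ids <- c(paste0("I", seq_len(n_internal)),
           if (n_external > 0) paste0("E", seq_len(n_external)))
  kind <- rep(c("internal", "external"), c(n_internal, n_external))
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  functions <- setNames(lapply(seq_len(n_internal), function(i) {
    k <- if (in_degree[1] == in_degree[2]) in_degree[1] else
      sample(in_degree[1]:in_degree[2], 1)
    list(regulators = sample(ids, k),
         outputs = as.integer(runif(2^k) < bias))
  }), ids[seq_len(n_internal)])
  boolean_model(tibble(id = ids, kind = kind), functions)
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Hand-built motif fixture models
#'
#' Small Boolean models with exhaustively understood behaviour, used as
#' ground truth throughout the test-suite and usable as worked examples:
#'
#' * `pass_through` — internal `A` copies external `E`, so `AL(A)` tracks the
#'   environmental activity level of `E`.
#' * `and_cascade` — a monotone chain `E -> H -> A -> B -> C`; clamping the
#'   head `H` to 0 drives every descendant to 0.
#' * `negative_feedback` — `A = NOT B`, `B = A`: a deterministic two-node
#'   oscillator under synchronous update.
#' * `incoherent_ffl` — `A = E`, `B = E`, `C = A AND NOT B`: an incoherent
#'   feed-forward loop (C pulses only on discordant A/B states).
#' * `mutual_antagonism` — two branches `X = EX AND NOT Y`,
#'   `Y = EY AND NOT X` (each with a downstream reporter), echoing a
#'   mutually inhibitory pair of signalling branches: knocking one branch
#'   out de-represses the other, so its activity rises above wild type.
#'
#' @return Named list of [boolean_model()] objects.
#' @export
motif_fixtures <- function() {
  list(
    pass_through = boolean_model(
      tibble(id = c("E", "A"), kind = c("external", "internal")),
      list(A = list(regulators = "E", outputs = c(0L, 1L)))
    ),
    and_cascade = boolean_model(
      tibble(id = c("E", "H", "A", "B", "C"),
             kind = c("external", rep("internal", 4))),
      list(
        H = list(regulators = "E", outputs = c(0L, 1L)),
        A = list(regulators = "H", outputs = c(0L, 1L)),
        B = list(regulators = "A", outputs = c(0L, 1L)),
        C = list(regulators = "B", outputs = c(0L, 1L))
      )
    ),
    negative_feedback = boolean_model(
      tibble(id = c("A", "B"), kind = c("internal", "internal")),
      list(
        A = list(regulators = "B", outputs = c(1L, 0L)),
        B = list(regulators = "A", outputs = c(0L, 1L))
      )
    ),
    incoherent_ffl = boolean_model(
      tibble(id = c("E", "A", "B", "C"),
             kind = c("external", rep("internal", 3))),
      list(
        A = list(regulators = "E", outputs = c(0L, 1L)),
        B = list(regulators = "E", outputs = c(0L, 1L)),
        # rows ordered A,B = 00,01,10,11: C = A AND NOT B
        C = list(regulators = c("A", "B"), outputs = c(0L, 0L, 1L, 0L))
      )
    ),
    mutual_antagonism = boolean_model(
      tibble(id = c("EX", "EY", "X", "Y", "RX", "RY"),
             kind = c("external", "external", rep("internal", 4))),
      list(
        # rows ordered EX,Y = 00,01,10,11: X = EX AND NOT Y
        X = list(regulators = c("EX", "Y"), outputs = c(0L, 0L, 1L, 0L)),
        Y = list(regulators = c("EY", "X"), outputs = c(0L, 0L, 1L, 0L)),
        RX = list(regulators = "X", outputs = c(0L, 1L)),
        RY = list(regulators = "Y", outputs = c(0L, 1L))
      )
    )
  )
}

#' Generate a synthetic log2 expression matrix with planted DE genes
#'
#' Emulates the structure of a small two-group microarray comparison on the
#' log2-intensity scale: control arrays are gene baselines plus Gaussian
#' noise; treated arrays add a +/- `effect_size` log2 shift to a planted
#' fraction of differentially expressed genes (half up, half down). Ground
#' truth is returned for recovery tests. No attempt is made to emulate
#' array normalisation artefacts.
#'
#' @param n_genes Number of genes.
#' @param n_arrays Arrays per group.
#' @param de_fraction Fraction of genes differentially expressed (0-1).
#' @param effect_size Mean log2 shift of planted DE genes (default 3).
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0, default 0.3).
#' @param seed Integer seed.
#' @return List with `intensities` (genes x arrays matrix, columns
#'   `ctrl_*`/`trt_*`, rownames `g1..`) and `truth` (tibble `gene`,
#'   `de`, `direction`).
#' @examples
#' x <- synthetic_expression(n_genes = 100, n_arrays = 3, seed = 1)
#' head(x$truth)
#' @export
synthetic_expression <- function(n_genes = 1000, n_arrays = 4,
                                 de_fraction = 0.05, effect_size = 3,
                                 noise_sd = 0.3, seed = 1) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, noise_sd > 0)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  baseline <- runif(n_genes, 6, 12)
  n_de <- round(de_fraction * n_genes)
  de_idx <- sample(n_genes, n_de)
  direction <- rep("unchanged", n_genes)
  if (n_de > 0) {
    up <- de_idx[seq_len(ceiling(n_de / 2))]
    down <- setdiff(de_idx, up)
    direction[up] <- "up"
    direction[down] <- "down"
  }
  shift <- ifelse(direction == "up", effect_size,
                  ifelse(direction == "down", -effect_size, 0))
  ctrl <- matrix(baseline, n_genes, n_arrays) +
    matrix(rnorm(n_genes * n_arrays, sd = noise_sd), n_genes)
  trt <- matrix(baseline + shift, n_genes, n_arrays) +
    matrix(rnorm(n_genes * n_arrays, sd = noise_sd), n_genes)
  intensities <- cbind(ctrl, trt)
  rownames(intensities) <- genes
  colnames(intensities) <- c(paste0("ctrl_", seq_len(n_arrays)),
                             paste0("trt_", seq_len(n_arrays)))
  list(
    intensities = intensities,
    truth = tibble(gene = genes, de = direction != "unchanged",
                   direction = direction)
  )
}
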