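# small helper: build an activity table from a per-component list of
# per-combination replicate values
mk_table <- function(values, n_rep = 1, label = "WT") {
  purrr::imap_dfr(values, function(v, cp) {
    tidyr::expand_grid(env_index = seq_along(v), replicate = seq_len(n_rep)) |>
      dplyr::mutate(condition = "c", perturbation = label, component = cp,
                    al = v[env_index])
  })
}

test_that("identity intervention yields DV = 0 everywhere", {
  m <- motif_fixtures()$and_cascade
  cond <- environment_condition("e", list(E = c(30, 90)))
  cfg <- sim_config(steps = 100, window = 40, replicates = 3, seed = 5)
  s <- sample_combinations(cond, 8, cfg$seed, externals = "E")
  wt <- simulate_condition(m, s, config = cfg)
  same <- simulate_condition(m, s, clamps = wild_type(), config = cfg)
  dv <- difference_values(wt, same, clamped = character())
  expect_true(all(dv$dv == 0))
})

test_that("disjoint supports give DV = 1 and the clamped node is zeroed", {
  wt <- mk_table(list(A = seq(10, 40, length.out = 10),
                      B = seq(10, 40, length.out = 10)))
  pt <- mk_table(list(A = seq(60, 90, length.out = 10),
                      B = seq(60, 90, length.out = 10)), label = "A:1")
  dv <- difference_values(wt, pt)
  expect_equal(dv$dv[dv$component == "B"], 1)
  expect_equal(dv$statistic[dv$component == "A"], 1)  # raw statistic
  expect_equal(dv$dv[dv$component == "A"], 0)         # forced to 0 when clamped
})

test_that("DV equals the independent ECDF oracle over random sample pairs", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100) + rnorm(1, 0, 20)
    wt <- mk_table(list(A = x))
    pt <- mk_table(list(A = y), label = "Z:0")
    dv <- difference_values(wt, pt, alpha = 1)  # alpha 1: dv = statistic
    expect_equal(dv$statistic[dv$component == "A"], ks_statistic_oracle(x, y))
    expect_equal(dv$dv[dv$component == "A"], ks_statistic_oracle(x, y))
  }
})

test_that("mismatched component sets are rejected", {
  wt <- mk_table(list(A = 1:5))
  pt <- mk_table(list(B = 1:5), label = "A:0")
  expect_error(difference_values(wt, pt), "different component sets")
})

test_that("influence scores rank, tie-break and cut the top-10% set", {
  dvm <- tibble::tibble(
    perturbation = rep(c("a", "b", "c", "d"), each = 4),
    component = rep(c("a", "b", "c", "d"), 4),
    dv = c(0, 1, 0.5, 0.5,   0, 0, 0.6, 0.4,   0, 0, 0, 0.5,   0, 0, 0, 0)
  )
  r <- influence_scores(dvm)
  expect_equal(tidy(r)$perturbation, c("a", "b", "c", "d"))
  expect_equal(tidy(r)$is, c(2, 1, 0.5, 0))
  expect_equal(least_influential(r), "d")
  expect_equal(most_influential(r), "a")  # ceiling(0.1 * 4) = 1
  expect_equal(attr(r, "n_top"), 1)

  # all-zero matrix: flagged as empty signal, least set = everything
  dvm0 <- dplyr::mutate(dvm, dv = 0)
  r0 <- influence_scores(dvm0)
  expect_true(attr(r0, "empty_signal"))
  expect_setequal(least_influential(r0), c("a", "b", "c", "d"))
  # tie-break is lexicographic
  expect_equal(tidy(r0)$perturbation, sort(c("a", "b", "c", "d")))

  # M = 130 gives a top set of 13
  dvm130 <- tidyr::expand_grid(perturbation = sprintf("p%03d", 1:130),
                               component = sprintf("p%03d", 1:130)) |>
    dplyr::mutate(dv = as.numeric(perturbation < component))
  r130 <- influence_scores(dvm130)
  expect_equal(attr(r130, "n_top"), 13)
  expect_equal(sum(tidy(r130)$most_influential), 13)
})

test_that("IS decreases down an AND-cascade under knockout screening", {
  m <- motif_fixtures()$and_cascade
  cond <- environment_condition("e", list(E = c(35, 85)))
  cfg <- sim_config(steps = 150, window = 60, replicates = 4, seed = 17)
  sc <- single_perturbation_screen(m, cond, "inactivate",
                                   n_combinations = 12, config = cfg)
  dvm <- screen_difference_values(sc)
  r <- tidy(influence_scores(dvm))
  is_of <- function(id) r$is[r$perturbation == id]
  expect_gte(is_of("H"), is_of("A"))
  expect_gte(is_of("A"), is_of("B"))
  expect_gte(is_of("B"), is_of("C"))
  expect_gt(is_of("H"), 0)
})

test_that("most_affected ranks by DV, respects threshold, and stays within reach", {
  m <- motif_fixtures()$and_cascade
  cond <- environment_condition("e", list(E = c(35, 85)))
  cfg <- sim_config(steps = 150, window = 60, replicates = 4, seed = 19)
  sc <- single_perturbation_screen(m, cond, "inactivate",
                                   n_combinations = 12, config = cfg)
  dvm <- screen_difference_values(sc)
  hit <- most_affected(dvm, "H", threshold = 1)
  expect_setequal(hit$component, c("A", "B", "C"))
  expect_true(all(hit$component %in% reachable_from(m, "H")))
  all_moved <- most_affected(dvm, "H", threshold = .Machine$double.eps)
  expect_true(all(all_moved$dv > 0))
  expect_error(most_affected(dvm, "nope"), "unknown perturbation")
})

test_that("fold classification is an exclusive partition with NSA from the DV matrix", {
  wt <- mk_table(list(up = rep(20, 6), off = rep(30, 6), dead = rep(0, 6),
                      born = rep(0, 6), same = rep(50, 6)))
  pt <- mk_table(list(up = rep(40, 6), off = rep(0, 6), dead = rep(0, 6),
                      born = rep(10, 6), same = rep(50, 6)), label = "x:0")
  dv <- tibble::tibble(component = c("up", "off", "dead", "born", "same"),
                       dv = c(1, 1, 0, 1, 0))
  fd <- fold_differences(wt, pt, dvm = dv)
  cls <- setNames(fd$classification, fd$component)
  expect_equal(cls[["up"]], "fold")
  expect_equal(fd$fold[fd$component == "up"], 2)
  expect_equal(cls[["off"]], "complete_inactivation")
  expect_equal(cls[["dead"]], "no_change")
  expect_equal(cls[["born"]], "complete_activation")
  expect_equal(cls[["same"]], "NSA")
  # exactly one label each
  expect_equal(nrow(fd), 5)
  expect_false(any(is.na(fd$classification)))
  # without a DV matrix, equal means give fold 1
  fd2 <- fold_differences(wt, pt)
  expect_equal(fd2$fold[fd2$component == "same"], 1)
})

test_that("cross-condition overlap computes intersection, unique and pairwise sets", {
  mk_rank <- function(ids) {
    influence_scores(tidyr::expand_grid(perturbation = ids, component = ids) |>
                       dplyr::mutate(dv = 1), top_fraction = 1)
  }
  same <- list(c1 = mk_rank(c("A", "B")), c2 = mk_rank(c("A", "B")))
  ov <- cross_condition_overlap(same)
  expect_equal(ov$intersection, c("A", "B"))
  expect_equal(ov$unique$c1, character(0))

  disjoint <- list(c1 = c("A"), c2 = c("B"), c3 = c("C"))
  ov2 <- cross_condition_overlap(disjoint)
  expect_equal(ov2$intersection, character(0))
  expect_equal(ov2$unique$c2, "B")

  shared <- list(c1 = c("A", "X"), c2 = c("A", "Y"), c3 = c("A", "Z"))
  ov3 <- cross_condition_overlap(shared)
  expect_equal(ov3$intersection, "A")
  expect_error(cross_condition_overlap(list(c1 = "A")), ">= 2")
})

test_that("upstream regulators are found and annotated along the cascade", {
  m <- motif_fixtures()$and_cascade
  cond <- environment_condition("e", list(E = c(35, 85)))
  cfg <- sim_config(steps = 150, window = 60, replicates = 4, seed = 23)
  sc <- single_perturbation_screen(m, cond, "inactivate",
                                   n_combinations = 12, config = cfg)
  dvm <- screen_difference_values(sc)
  rk <- influence_scores(dvm)
  up <- upstream_regulators(dvm, m, targets = "B", ranking = rk)
  expect_setequal(up$perturbation, c("H", "A"))
  expect_true(up$direct_regulator[up$perturbation == "A"])
  expect_false(up$direct_regulator[up$perturbation == "H"])
  # influencers confined to the in-reachability set of the target
  for (p in up$perturbation) expect_true("B" %in% reachable_from(m, p))
  # a node nothing can move -> empty set
  up_h <- upstream_regulators(dvm, m, targets = "H")
  expect_equal(nrow(up_h), 0)
})

test_that("WT-vs-WT DV false-positive rate matches the exact KS test size", {
  # two independent WT tables per repeat; per-combination means are continuous
  # so the exact two-sample KS null applies at n = m = 20 combinations
  m <- motif_fixtures()$pass_through
  cond <- environment_condition("e", list(E = c(10, 90)))
  cfg0 <- sim_config(steps = 80, window = 40, replicates = 2, seed = 1)
  n_comb <- 20
  n_rep <- 120
  flags <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    c1 <- sim_config(steps = 80, window = 40, replicates = 2, seed = 2 * r)
    c2 <- sim_config(steps = 80, window = 40, replicates = 2, seed = 2 * r + 1)
    s1 <- sample_combinations(cond, n_comb, c1$seed, externals = "E")
    s2 <- sample_combinations(cond, n_comb, c2$seed, externals = "E")
    t1 <- simulate_condition(m, s1, config = c1)
    t2 <- simulate_condition(m, s2, config = c2)
    dv <- difference_values(t1, t2, clamped = character())
    flags[r] <- dv$dv[dv$component == "A"] > 0
  }
  # exact size of the alpha = 0.05 KS test at n = m = 20 (attainable D = k/20)
  d <- (1:20) / 20
  pv <- vapply(d, function(q) 1 - stats::psmirnov(q - 1e-9, sizes = c(20, 20),
                                                  two.sided = TRUE),
               numeric(1))
  size <- max(pv[pv < 0.05])
  expect_lte(size, 0.05)
  rate <- mean(flags)
  expect_lt(abs(rate - size), 3 * sqrt(size * (1 - size) / n_rep))
})
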