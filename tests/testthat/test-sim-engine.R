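test_that("clamped components have AL exactly 0 or 100 and ALs stay in range", {
  m <- motif_fixtures()$and_cascade
  cfg <- sim_config(steps = 200, window = 100, replicates = 5, seed = 3)
  tbl <- simulate_activity(m, c(E = 60), clamps = perturbation(H = 1),
                           config = cfg)
  expect_true(all(tbl$al >= 0 & tbl$al <= 100))
  expect_true(all(tbl$al[tbl$component == "H"] == 100))
  tbl0 <- simulate_activity(m, c(E = 60), clamps = perturbation(A = 0),
                            config = cfg)
  expect_true(all(tbl0$al[tbl0$component == "A"] == 0))
})

test_that("pass-through node's AL tracks the external probability", {
  m <- motif_fixtures()$pass_through
  cfg <- sim_config(steps = 400, window = 300, replicates = 40, seed = 11)
  tbl <- simulate_activity(m, c(E = 50), config = cfg)
  al <- mean(tbl$al[tbl$component == "A"])
  # replicate-mean of Bernoulli(0.5) over 300 draws x 40 replicates
  se <- 100 * sqrt(0.25 / (300 * 40))
  expect_lt(abs(al - 50), 3 * se)
})

test_that("external active fraction lies within binomial bounds of p/100", {
  m <- motif_fixtures()$pass_through
  cfg <- sim_config(steps = 500, window = 500, replicates = 1, seed = 5)
  for (p in c(10, 50, 90)) {
    tr <- simulate_trajectory(m, c(E = p), config = cfg)$traj[[1]]
    frac <- mean(tr["E", -1])
    ci <- qbinom(c(0.005, 0.995), 500, p / 100) / 500
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
  }
})

test_that("deterministic models match the exhaustive synchronous oracle", {
  fx <- motif_fixtures()
  cfg <- sim_config(steps = 50, window = 20, replicates = 1, seed = 1)
  # negative feedback pair from every initial state
  for (a in 0:1) for (b in 0:1) {
    init <- c(A = a, B = b)
    got <- simulate_trajectory(fx$negative_feedback, config = cfg,
                               init = init)
    want <- oracle_trajectory(fx$negative_feedback, init, cfg$steps)
    expect_identical(got$traj[[1]], want)
    expect_equal(got$al[, 1], oracle_al(want, cfg$window))
  }
  # random 8-node model without externals, several seeds and starts
  for (seed in 1:4) {
    m <- random_boolean_network(8, 0, in_degree = 2, seed = seed)
    init <- setNames(rep(c(0L, 1L), 4), components(m))
    got <- simulate_trajectory(m, config = cfg, init = init)
    want <- oracle_trajectory(m, init, cfg$steps)
    expect_identical(got$traj[[1]], want)
    expect_equal(got$al[, 1], oracle_al(want, cfg$window))
  }
})

test_that("clamping leaves unreachable components bit-identical (common RNG)", {
  # two parallel cascades sharing nothing: clamping one must not touch the other
  m <- boolean_model(
    tibble::tibble(id = c("E1", "E2", "A1", "B1", "A2", "B2"),
                   kind = c("external", "external", rep("internal", 4))),
    list(
      A1 = list(regulators = "E1", outputs = c(0L, 1L)),
      B1 = list(regulators = "A1", outputs = c(0L, 1L)),
      A2 = list(regulators = "E2", outputs = c(0L, 1L)),
      B2 = list(regulators = "A2", outputs = c(0L, 1L))
    )
  )
  cfg <- sim_config(steps = 120, window = 60, replicates = 3, seed = 9)
  env <- c(E1 = 35, E2 = 65)
  wt <- simulate_trajectory(m, env, config = cfg)
  ko <- simulate_trajectory(m, env, clamps = perturbation(A1 = 0),
                            config = cfg)
  unreachable <- setdiff(components(m), c("A1", reachable_from(m, "A1")))
  expect_true(length(unreachable) >= 3)
  for (r in seq_len(cfg$replicates)) {
    expect_identical(wt$traj[[r]][unreachable, ], ko$traj[[r]][unreachable, ])
    expect_false(identical(wt$traj[[r]]["B1", ], ko$traj[[r]]["B1", ]))
  }
})

test_that("mean_activity and overall_activity average in the documented order", {
  tbl <- tibble::tibble(
    condition = "c", perturbation = "WT",
    env_index = rep(1:2, each = 4),
    replicate = rep(rep(1:2, each = 2), 2),
    component = rep(c("A", "B"), 4),
    al = c(0, 10, 100, 30, 50, 50, 50, 70)
  )
  m <- mean_activity(tbl)
  expect_equal(m$al[m$component == "A" & m$env_index == 1], 50)
  o <- overall_activity(tbl)
  expect_equal(o$al[o$component == "A"], mean(c(50, 50)))
  expect_equal(o$al[o$component == "B"], mean(c(20, 60)))
  expect_error(mean_activity(tbl, "Z"), "unknown component")
})

test_that("replicate homogeneity flags heteroscedastic groups, not identical ones", {
  mktab <- function(f) {
    tidyr::expand_grid(env_index = 1:10, replicate = 1:8) |>
      dplyr::mutate(condition = "c", perturbation = "WT", component = "A",
                    al = f(env_index, dplyr::n()))
  }
  set.seed(1)
  homog <- mktab(function(e, n) 50 + rnorm(n, sd = 5))
  res <- replicate_homogeneity(homog)
  expect_false(res$degenerate[1])
  expect_gt(res$p_value[1], 0.001)  # no systematic variance difference

  hetero <- mktab(function(e, n) 50 + rnorm(n, sd = ifelse(e <= 5, 1, 10)))
  res2 <- replicate_homogeneity(hetero)
  expect_lt(res2$p_value[1], 0.05)
  expect_true(res2$flagged[1])

  const <- mktab(function(e, n) rep(100, n))
  res3 <- replicate_homogeneity(const)
  expect_true(res3$degenerate[1])
})

test_that("homogeneity false-positive rate is near the nominal level", {
  # identical distributions in every group: flagged fraction ~ 5%
  set.seed(2)
  n_comp <- 150
  tab <- tidyr::expand_grid(component = paste0("c", seq_len(n_comp)),
                            env_index = 1:6, replicate = 1:6) |>
    dplyr::mutate(condition = "x", perturbation = "WT",
                  al = rnorm(dplyr::n(), 50, 8))
  res <- replicate_homogeneity(tab)
  rate <- mean(res$flagged)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_comp))
})

test_that("environment coverage and clamp targets are validated", {
  m <- motif_fixtures()$and_cascade
  expect_error(simulate_activity(m, c(X = 10)), "missing external")
  expect_error(
    simulate_activity(m, c(E = 10), clamps = perturbation(Qq = 1)),
    "unknown component"
  )
  # clamping an external overrides its stochastic draw
  cfg <- sim_config(steps = 100, window = 50, replicates = 2, seed = 4)
  tbl <- simulate_activity(m, c(E = 50), clamps = perturbation(E = 1),
                           config = cfg)
  expect_true(all(tbl$al[tbl$component == "E"] == 100))
  expect_true(all(tbl$al[tbl$component == "C"] == 100))
})
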