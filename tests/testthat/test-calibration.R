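test_that("feature histograms use the documented binning and normalize", {
  h <- make_histogram(50, "llp")
  # all mass in the (40, 60] bin
  bin <- which(h$freq > 0)
  expect_identical(length(bin), 1L)
  expect_equal(h$edges[bin], 40)
  expect_equal(h$edges[bin + 1], 60)

  hz <- make_histogram(c(0, 0, 50), "llp")
  expect_equal(hz$freq[1], 2 / 3)   # exact zeros get their own bin

  hn <- make_histogram(c(3, 3, 3), "np")
  expect_equal(sum(hn$freq), 1)
  expect_equal(hn$freq[4], 1)       # integer bin centred on 3

  set.seed(11)
  expect_equal(sum(make_histogram(runif(500, 0, 400), "llp")$freq), 1)
  expect_error(make_histogram(numeric(0), "llp"), "empty")
  expect_error(make_histogram(c(-1, 5), "np"))
})

test_that("Bhattacharyya coefficient: identities, worked value, properties", {
  h1 <- make_histogram(c(10, 30, 50), "llp")
  expect_equal(bhattacharyya(h1, h1), 1)

  d1 <- make_histogram(rep(10, 5), "llp")
  d2 <- make_histogram(rep(90, 5), "llp")
  expect_equal(bhattacharyya(d1, d2), 0)

  # two-bin worked example: sqrt(.5*.25) + sqrt(.5*.75)
  a <- make_histogram(c(10, 30), "llp")
  b <- make_histogram(c(10, 30, 30, 30), "llp")
  expect_equal(bhattacharyya(a, b), sqrt(0.125) + sqrt(0.375),
               tolerance = 1e-12)
  expect_equal(bhattacharyya(a, b), 0.96593, tolerance = 1e-5)

  # symmetry and bounds over random histogram pairs
  set.seed(12)
  for (i in 1:25) {
    p <- make_histogram(runif(40, 0, 220), "llp")
    q <- make_histogram(runif(40, 0, 220), "llp")
    bc <- bhattacharyya(p, q)
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bc, bhattacharyya(q, p))
  }

  expect_error(bhattacharyya(make_histogram(5, "llp"),
                             make_histogram(5, "np")), "edges")
})

test_that("validity filter accepts the calibrated thresholds, rejects violations", {
  expect_true(validity_filter(parametrization(s_birth = 85, s_exp = 76,
                                              s_ret = 0)))
  expect_false(validity_filter(parametrization(s_birth = 50, s_exp = 76,
                                               s_ret = 0)))
  expect_false(validity_filter(parametrization(s_birth = 85, s_exp = 76,
                                               s_ret = 76)))
  expect_false(validity_filter(parametrization(s_birth = 85, s_exp = 90,
                                               s_ret = 0)))
  # out-of-range is a different failure mode: an error, not a rejection
  expect_error(parametrization(s_birth = 101))
  expect_error(parametrization(E_protrusion = 5e6))
  expect_error(parametrization(alpha_exp = 0.5))
  expect_error(parametrization(s_binary = 12501))
})

test_that("pareto front matches the brute-force dominance oracle", {
  one <- tibble::tibble(BC_llp = 0.5, BC_np = 0.5)
  expect_identical(pareto_front(one), TRUE)

  tri <- tibble::tibble(BC_llp = c(0.9, 0.1, 0.5), BC_np = c(0.1, 0.9, 0.5))
  expect_identical(pareto_front(tri), c(TRUE, TRUE, TRUE))

  dom <- tibble::tibble(BC_llp = c(0.9, 0.8), BC_np = c(0.9, 0.8))
  expect_identical(pareto_front(dom), c(TRUE, FALSE))

  set.seed(13)
  h <- tibble::tibble(BC_llp = runif(200), BC_np = runif(200))
  expect_identical(pareto_front(h), oracle_pareto(h$BC_llp, h$BC_np))

  # ties are kept
  ties <- tibble::tibble(BC_llp = c(0.7, 0.7, 0.2), BC_np = c(0.6, 0.6, 0.1))
  expect_identical(pareto_front(ties), c(TRUE, TRUE, FALSE))
})

test_that("self-comparison scores exactly one; degenerate dynamics score zero", {
  cfg <- quick_config(horizon_min = 60)
  params <- parametrization()
  seeds <- 42L

  traj <- run_simulation(apply_parametrization(cfg, params), seeds)
  targets <- list(llp = make_histogram(traj$llp_um, "llp"),
                  np = make_histogram(traj$n_protrusions, "np"))
  m <- evaluate_parametrization(params, targets, cfg, n_sims = 1,
                                seeds = seeds)
  expect_equal(m$BC_llp, 1)
  expect_equal(m$BC_np, 1)

  # pooled-seed variant agrees on the self-comparison identity
  seeds2 <- c(42L, 43L)
  trajs <- lapply(seeds2, function(s) {
    run_simulation(apply_parametrization(cfg, params), s)
  })
  pooled <- list(
    llp = make_histogram(unlist(lapply(trajs, function(t) t$llp_um)), "llp"),
    np = make_histogram(unlist(lapply(trajs, function(t) t$n_protrusions)),
                        "np"))
  mp <- evaluate_parametrization(params, pooled, cfg, n_sims = 2,
                                 seeds = seeds2, pool_seeds = TRUE)
  expect_equal(mp$BC_llp, 1)
  expect_equal(mp$BC_np, 1)

  # a parametrization that cannot sprout (binarization level above the
  # signal reachable within the horizon) vs nonzero targets
  degen <- parametrization(s_birth = 100, s_exp = 99, s_ret = 98,
                           s_binary = 212500)
  cfg_short <- quick_config(horizon_min = 20)
  tspec <- synthetic_target_spec(n = 1000)
  tgt <- generate_targets(tspec, seed = 5)
  md <- evaluate_parametrization(degen, tgt, cfg_short, n_sims = 1,
                                 seeds = 7L)
  expect_equal(md$BC_llp, 0)
  expect_equal(md$BC_np, 0)

  expect_error(
    evaluate_parametrization(parametrization(s_birth = 10, s_exp = 76,
                                             s_ret = 0),
                             tgt, cfg, n_sims = 1, seeds = 1L),
    "invalid parametrization")
})

test_that("proposals respect the space, the filter, and explore", {
  space <- param_space()
  set.seed(14)
  p0 <- propose_next(NULL, space)
  expect_s3_class(p0, "parametrization")
  expect_true(validity_filter(p0))

  # every initialization draw is valid and inside the mixed grids
  for (i in 1:10) {
    p <- propose_next(tibble::tibble(), space)
    expect_true(validity_filter(p))
    expect_true(p$E_protrusion %in% 10^(4:10))
    expect_true(p$s_binary %in% (12500 + 2000 * (0:100)))
  }

  # with a degenerate history the proposal still moves somewhere new
  rep_row <- tibble::as_tibble(c(unclass(parametrization()),
                                 list(BC_llp = 0.5, BC_np = 0.5)))
  hist12 <- dplyr::bind_rows(replicate(12, rep_row, simplify = FALSE))
  set.seed(15)
  p_new <- propose_next(hist12, space, n_init = 10)
  expect_true(validity_filter(p_new))
  expect_false(identical(unclass(p_new)[names(space)],
                         unclass(parametrization())[names(space)]))
})

test_that("surrogate optimization finds a known two-objective optimum", {
  # analytic toy: both metrics peak where (alpha_exp, beta_ret) sit at known
  # values; only two effective dimensions so the budget is meaningful
  space <- param_space()
  f1 <- function(p) exp(-8 * ((p$alpha_exp - 0.15) / 0.19)^2 -
                          8 * ((p$beta_ret - 30) / 99.9)^2)
  f2 <- function(p) exp(-8 * ((p$alpha_exp - 0.13) / 0.19)^2 -
                          8 * ((p$beta_ret - 40) / 99.9)^2)
  hits <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    history <- NULL
    for (it in 1:60) {
      p <- propose_next(history, space, n_init = 10, n_candidates = 300)
      row <- tibble::as_tibble(c(unclass(p), list(BC_llp = f1(p),
                                                  BC_np = f2(p))))
      history <- dplyr::bind_rows(history, row)
    }
    best <- max(pmin(history$BC_llp, history$BC_np))
    # optimum of min(f1, f2) is at the midpoint; compute it directly
    pm <- parametrization(alpha_exp = 0.14, beta_ret = 35)
    opt <- min(f1(pm), f2(pm))
    if (best >= opt - 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the calibration loop bookkeeping is exact at small budgets", {
  cfg <- quick_config(horizon_min = 30)
  tgt <- generate_targets(synthetic_target_spec(n = 2000), seed = 3)
  calib <- run_calibration(tgt, cfg, budget = 10, n_sims = 2,
                           master_seed = 5, n_init = 4)
  h <- calib$history
  expect_identical(nrow(h), 10L)
  expect_true(all(h$s_ret < h$s_exp & h$s_exp < h$s_birth))
  expect_identical(h$pareto, pareto_front(h))

  # the balanced selection maximizes the minimum metric over the front
  front <- h[h$pareto, ]
  expect_equal(min(calib$best_metrics$BC_llp, calib$best_metrics$BC_np),
               max(pmin(front$BC_llp, front$BC_np)))

  # points on the front are mutually non-dominated
  expect_true(all(pareto_front(front)))

  # tidiers expose the history and the summary
  expect_identical(tidy(calib), h)
  g <- glance(calib)
  expect_identical(g$n_evaluations, 10L)
  expect_equal(g$best_min_metric,
               min(calib$best_metrics$BC_llp, calib$best_metrics$BC_np))

  path <- tempfile(fileext = ".csv")
  write_calibration_csv(calib, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(back), 10L)
})

test_that("metric noise shrinks with the ensemble size", {
  cfg <- quick_config(horizon_min = 60)
  params <- parametrization()
  tgt <- generate_targets(synthetic_target_spec(n = 5000), seed = 9)
  bc_at <- function(n_sims, reps) {
    vapply(seq_len(reps), function(r) {
      seeds <- ensemble_seeds(1000 + r * 17, n_sims)
      evaluate_parametrization(params, tgt, cfg, n_sims = n_sims,
                               seeds = seeds)$BC_llp
    }, numeric(1))
  }
  v_small <- sd(bc_at(2, 6))
  v_large <- sd(bc_at(8, 6))
  expect_lt(v_large, v_small)
})
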