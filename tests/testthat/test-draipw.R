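test_that("inverse propensity weights follow the defining formula", {
  expect_equal(ipw_weights(1, 0.5, TRUE), 2)
  expect_equal(ipw_weights(0, 0.25, TRUE), 4 / 3)
  expect_equal(ipw_weights(1, 0.5, FALSE), 0)
  expect_error(ipw_weights(1, 0, TRUE), class = "latentsens_weight_error")
})

test_that("hand-computable subgroup estimates come out exactly", {
  cfg <- run_config(class_floor = 2)
  # forced nuisances: p = 0.5, m = 0 on a 2x2 treatment-outcome layout
  data <- toy_subjects(Z = c(1, 1, 0, 0), Y = c(1, 0, 1, 0))
  est <- estimate_effect(data, toy_roles(), rep(1L, 4), 1L, cfg,
                         p_hat = 0.5, m1 = 0, m0 = 0)
  expect_identical(est$tau_hat, 0)
  # with p = 0.5, m = 0: tau = 2 [mean(ZY) - mean((1-Z)Y)]
  data2 <- toy_subjects(Z = c(1, 1, 0, 0), Y = c(1, 1, 1, 0))
  est2 <- estimate_effect(data2, toy_roles(), rep(1L, 4), 1L, cfg,
                          p_hat = 0.5, m1 = 0, m0 = 0)
  expect_equal(est2$tau_hat,
               2 * (mean(data2$Z * data2$Y) -
                      mean((1 - data2$Z) * data2$Y)))

  # zero-residual construction: Y = m(Z, X) and m1 - m0 = 0.5 everywhere
  set.seed(2)
  n <- 12
  Z <- rep(c(1, 0), 6)
  m0v <- runif(n)
  m1v <- m0v + 0.5
  Y <- ifelse(Z == 1, m1v, m0v)
  d3 <- toy_subjects(Z = Z, Y = Y)
  for (p in c(0.2, 0.5, 0.9)) {
    est3 <- estimate_effect(d3, toy_roles(), rep(1L, n), 1L, cfg,
                            p_hat = p, m1 = m1v, m0 = m0v)
    expect_equal(est3$tau_hat, 0.5, tolerance = 1e-12)
  }
})

test_that("influence-function variance uses the m(m-1) denominator", {
  cfg <- run_config(class_floor = 2)
  d <- toy_subjects(Z = c(1, 0), Y = c(1, 0))
  est <- estimate_effect(d, toy_roles(), rep(1L, 2), 1L, cfg,
                         p_hat = 0.5, m1 = 0, m0 = 0)
  # terms are (2, 0): tau = 1, centered influence (+1, -1), a = 1
  expect_equal(est$tau_hat, 1)
  expect_equal(sort(est$influence), c(-1, 1))
  expect_equal(est$var_hat, 1)  # a^2 with a = 1
  expect_equal(est$ci, c(1 - qnorm(0.975), 1 + qnorm(0.975)))
  expect_equal(sum(est$influence), 0, tolerance = 1e-8 * est$m_c)
})

test_that("degenerate subgroups return machine-readable failures", {
  d <- toy_subjects(Z = c(1, 1, 1, 1), Y = c(1, 0, 1, 0))
  cfg <- run_config(class_floor = 2)
  est <- estimate_effect(d, toy_roles(), rep(1L, 4), 1L, cfg)
  expect_false(est$defined)
  expect_equal(est$reason, "single-arm")

  est2 <- estimate_effect(d, toy_roles(), rep(2L, 4), 1L, cfg)
  expect_equal(est2$reason, "empty-class")

  est3 <- estimate_effect(d, toy_roles(), rep(1L, 4), 1L,
                          run_config(class_floor = 10))
  expect_equal(est3$reason, "too-few-members")
})

test_that("the estimator is doubly robust on synthetic data", {
  # one-class design so the subgroup is the whole sample
  spec <- synthetic_spec(
    K = 1, pi_true = 1,
    rho_true = list(lapply(rep(0.5, 3), function(p) c(p, 1 - p))),
    ps_coefs = list(list(intercept = -0.2, x = c(0.8, -0.6, 0.4))),
    out_coefs = list(list(intercept = -0.4, z = 0.6, x = c(0.7, 0.5, -0.6))),
    n = 800, seed = 1)
  tau <- true_subgroup_ate(spec, 1)
  cfg <- run_config(penalty_lambda = 0)
  reps <- 40
  bias_bad_outcome <- bias_bad_ps <- numeric(reps)
  for (r in seq_len(reps)) {
    spec$seed <- 1000 + r
    sim <- simulate_subjects(spec)
    ones <- rep(1L, nrow(sim$data))
    # outcome model deliberately misspecified (constant zero), PS fitted
    e1 <- estimate_effect(sim$data, sim$roles, ones, 1L, cfg,
                          m1 = 0, m0 = 0)
    # PS deliberately misspecified (constant 0.5), outcome model fitted
    e2 <- estimate_effect(sim$data, sim$roles, ones, 1L, cfg, p_hat = 0.5)
    bias_bad_outcome[r] <- e1$tau_hat - tau
    bias_bad_ps[r] <- e2$tau_hat - tau
  }
  expect_lt(abs(mean(bias_bad_outcome)), 0.02)
  expect_lt(abs(mean(bias_bad_ps)), 0.02)
})

test_that("interval width shrinks like one over the square root of n", {
  spec <- synthetic_spec(
    K = 1, pi_true = 1,
    rho_true = list(lapply(rep(0.5, 2), function(p) c(p, 1 - p))),
    ps_coefs = list(list(intercept = 0, x = c(0.3, -0.3))),
    out_coefs = list(list(intercept = 0, z = 0.4, x = c(0.5, 0.5))),
    n = 500, seed = 77, outcome_family = "continuous")
  cfg <- run_config(penalty_lambda = 0)
  widths <- vapply(c(500L, 2000L), function(n) {
    spec$n <- n
    sim <- simulate_subjects(spec)
    e <- estimate_effect(sim$data, sim$roles, rep(1L, n), 1L, cfg)
    diff(e$ci)
  }, numeric(1))
  expect_gt(widths[2] / widths[1], 0.4)
  expect_lt(widths[2] / widths[1], 0.6)
})

test_that("the effects table is ordered by the lower CI endpoint", {
  sim <- simulate_subjects(synthetic_template(n = 600, seed = 15))
  cfg <- run_config(seed = 15, n_starts = 3, compute_cov = FALSE,
                    penalty_lambda = 0)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  mem <- posterior_memberships(fit, sim$data)
  tab <- estimate_all_effects(sim$data, sim$roles, mem, cfg)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$class[3], "all")
  cls <- tab[tab$class != "all", ]
  expect_true(all(diff(cls$ci_lower) >= 0))
  expect_equal(sum(cls$proportion), 1, tolerance = 1e-10)
  # whole-sample row equals a direct all-ones call
  overall <- estimate_effect(sim$data, sim$roles, rep(1L, 600), 1L, cfg)
  expect_identical(tab$tau_hat[tab$class == "all"], overall$tau_hat)
})
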