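test_that("modal members precede higher-probability outsiders", {
  # two subjects: i modal for class 1 at 0.4, j modal for class 2 at 0.45
  lam <- rbind(c(0.40, 0.30, 0.30),
               c(0.45, 0.55, 0.00))
  mem <- membership_matrix(lam)
  ord <- insertion_order(mem, 1)
  expect_equal(ord, c(1L, 2L))

  lam2 <- cbind(c(0.9, 0.6, 0.2), 1 - c(0.9, 0.6, 0.2))
  expect_equal(insertion_order(membership_matrix(lam2), 1), c(1L, 2L, 3L))

  # exact ties break to the lower subject index
  lam3 <- rbind(c(0.7, 0.3), c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(insertion_order(membership_matrix(lam3), 1), c(1L, 2L, 3L))
})

test_that("insertion order matches the literal step-by-step oracle", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(3:20, 1)
    K <- sample(2:4, 1)
    lam <- matrix(stats::rgamma(n * K, 1), n, K)
    lam <- lam / rowSums(lam)
    mem <- membership_matrix(lam)
    c <- sample.int(K, 1)
    expect_equal(insertion_order(mem, c), insertion_order_oracle(lam, c))
  }
})

test_that("partitions nest and the prefix equals the modal set", {
  set.seed(66)
  lam <- matrix(stats::rgamma(90, 1), 30, 3)
  lam <- lam / rowSums(lam)
  mem <- membership_matrix(lam)
  for (c in 1:3) {
    ord <- insertion_order(mem, c)
    expect_equal(sort(ord), 1:30)  # a permutation, hence nested by prefix
    m_c <- sum(mem$modal == c)
    expect_setequal(ord[seq_len(m_c)], which(mem$modal == c))
  }
})

test_that("threshold window counts follow the 0.99/0.01 rule", {
  lam <- cbind(c(1.0, 0.995, 0.5, 0.005), 1 - c(1.0, 0.995, 0.5, 0.005))
  mem <- membership_matrix(lam)
  d <- toy_subjects(Z = c(1, 0, 1, 0), Y = c(1, 0, 0, 1))
  tr <- suppressWarnings(
    effect_trajectory(d, toy_roles(), mem, 1, run_config(class_floor = 2)))
  expect_equal(tr$m_star, 2L)
  expect_equal(tr$m_dstar, 3L)
  expect_equal(tr$steps$j, 2:3)
})

test_that("the trajectory reproduces the modal estimate exactly at m_c", {
  sim <- simulate_subjects(synthetic_template(n = 500, seed = 44))
  cfg <- run_config(seed = 44, n_starts = 3, compute_cov = FALSE,
                    max_steps = 30)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  mem <- posterior_memberships(fit, sim$data)
  for (c in 1:2) {
    tr <- effect_trajectory(sim$data, sim$roles, mem, c, cfg)
    modal <- estimate_effect(sim$data, sim$roles, mem$modal, c, cfg)
    anchor <- tr$steps[tr$steps$j == tr$m_c, ]
    expect_equal(nrow(anchor), 1L)
    expect_identical(anchor$tau_hat, modal$tau_hat)
    expect_identical(c(anchor$ci_lower, anchor$ci_upper), modal$ci)
    expect_true(tr$m_star <= tr$m_c && tr$m_c <= tr$m_dstar)
  }
})

test_that("undefined steps propagate their reason instead of failing", {
  # the eight most probable members of class 1 are all treated, so early
  # steps are single-arm
  lam1 <- c(seq(0.99, 0.92, length.out = 8), seq(0.6, 0.1, length.out = 8))
  mem <- membership_matrix(cbind(lam1, 1 - lam1))
  d <- toy_subjects(Z = c(rep(1, 8), rep(0, 8)),
                    Y = rbinom(16, 1, 0.5))
  tr <- suppressWarnings(
    effect_trajectory(d, toy_roles(), mem, 1,
                      run_config(class_floor = 2, penalty_lambda = 0)))
  early <- tr$steps[tr$steps$j <= 8, ]
  expect_true(all(!early$defined))
  expect_true(all(early$reason[early$j >= 2] == "single-arm"))
})

test_that("near-certain memberships give a flat trajectory", {
  flat_ok <- vapply(1:10, function(r) {
    spec <- synthetic_template(n = 400, seed = 300 + r)
    spec$separation <- 4  # push membership probabilities to 0/1
    sim <- simulate_subjects(spec)
    cfg <- run_config(seed = r, n_starts = 2, compute_cov = FALSE,
                      penalty_lambda = 0, max_steps = 20)
    fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
    mem <- posterior_memberships(fit, sim$data)
    tr <- suppressWarnings(
      effect_trajectory(sim$data, sim$roles, mem, 1, cfg))
    anchor <- tr$steps$tau_hat[tr$steps$j == tr$m_c]
    modal <- estimate_effect(sim$data, sim$roles, mem$modal, 1, cfg)
    dev <- abs(tr$steps$tau_hat[tr$steps$defined] - anchor)
    all(dev < 2 * sqrt(modal$var_hat))
  }, logical(1))
  expect_gte(sum(flat_ok), 9)
})

test_that("membership curves count thresholds correctly and decrease", {
  mem <- membership_matrix(cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  cv <- membership_curve(mem, 1, grid = 0.5)
  expect_equal(cv$proportion, 0.5)

  mem2 <- membership_matrix(cbind(rep(1, 5), rep(0, 5)))
  cv2 <- membership_curve(mem2, 1)
  expect_true(all(cv2$proportion == 1))

  set.seed(5)
  lam <- matrix(stats::rgamma(40, 1), 20, 2)
  lam <- lam / rowSums(lam)
  cv3 <- membership_curve(membership_matrix(lam), 2)
  expect_true(all(diff(cv3$proportion) <= 0))  # thresholds ascend
  expect_equal(attr(cv3, "modal_prop"),
               mean(membership_matrix(lam)$modal == 2))
})

test_that("plot builders return ggplot objects fed by the exact tables", {
  sim <- simulate_subjects(synthetic_template(n = 300, seed = 2))
  cfg <- run_config(seed = 2, n_starts = 2, compute_cov = FALSE,
                    penalty_lambda = 0, max_steps = 10)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  mem <- posterior_memberships(fit, sim$data)
  cv <- membership_curve(mem, 1)
  p1 <- plot_membership(cv)
  expect_s3_class(p1, "ggplot")
  expect_identical(p1$data, cv)
  tr <- effect_trajectory(sim$data, sim$roles, mem, 1, cfg)
  p2 <- plot_trajectory(tr)
  expect_s3_class(p2, "ggplot")
  expect_identical(autoplot(tr)$data, p2$data)
})
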