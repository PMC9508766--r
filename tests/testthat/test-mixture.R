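make_cat_data <- function(n = 300, seed = 3, J = 3) {
  spec <- synthetic_spec(
    K = 2, pi_true = c(0.5, 0.5),
    rho_true = lapply(c(0.85, 0.15), function(p)
      lapply(rep(p, J), function(q) c(q, 1 - q))),
    ps_coefs = lapply(1:2, function(k) list(intercept = 0, x = rep(0, J))),
    out_coefs = lapply(1:2, function(k)
      list(intercept = 0, z = 0, x = rep(0, J))),
    n = n, seed = seed)
  simulate_subjects(spec)
}

test_that("one-class fit reproduces the independence log-likelihood", {
  sim <- make_cat_data(n = 250, seed = 12)
  cfg <- run_config(seed = 12, n_starts = 2, compute_cov = FALSE)
  fit <- fit_mixture(sim$data, sim$roles, K = 1, config = cfg)
  expect_equal(fit$pi, 1)
  # oracle: sum over indicators of observed-count * log marginal frequency
  ll <- 0
  for (col in sim$roles$indicators) {
    tab <- table(sim$data[[col]])
    ll <- ll + sum(tab * log(tab / sum(tab)))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  mem <- posterior_memberships(fit, sim$data)
  expect_true(all(mem$lambda == 1))
})

test_that("posterior memberships follow Bayes rule exactly", {
  # hand case: K = 2, one binary indicator
  fit <- manual_lca_fit(pi = c(0.5, 0.5),
                        rho = list(list(c(0.8, 0.2)), list(c(0.2, 0.8))))
  data <- tibble::tibble(X1 = c(1L, 2L))
  mem <- posterior_memberships(fit, data)
  expect_equal(unname(mem$lambda[1, ]), c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(unname(mem$lambda[2, ]), c(0.2, 0.8), tolerance = 1e-10)

  # random instances with up to 4 indicators vs the explicit-product oracle
  set.seed(41)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    J <- sample(1:4, 1)
    L <- sample(2:4, J, replace = TRUE)
    pi <- as.vector(stats::rgamma(K, 2)); pi <- pi / sum(pi)
    rho <- lapply(seq_len(K), function(k)
      lapply(L, function(l) {
        r <- stats::rgamma(l, 2); r / sum(r)
      }))
    fit <- manual_lca_fit(pi, rho)
    x <- vapply(L, function(l) sample.int(l, 1), integer(1))
    data <- tibble::as_tibble(as.data.frame(t(x)))
    names(data) <- fit$indicator_names
    mem <- posterior_memberships(fit, data)
    oracle <- bayes_posterior_oracle(fit$pi, fit$rho, x)
    expect_equal(unname(mem$lambda[1, ]), oracle, tolerance = 1e-10)
  }
})

test_that("membership rows normalize and modal ties break to lowest index", {
  sim <- make_cat_data(n = 150, seed = 8)
  cfg <- run_config(seed = 8, n_starts = 2, compute_cov = FALSE)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  mem <- posterior_memberships(fit, sim$data)
  expect_true(all(abs(rowSums(mem$lambda) - 1) < 1e-10))
  # a bare-majority subject is imputed exactly like a near-certain one
  mem2 <- membership_matrix(rbind(c(0.51, 0.49), c(0.98, 0.02),
                                  c(0.5, 0.5)))
  expect_equal(mem2$modal, c(1L, 1L, 1L))
})

test_that("EM log-likelihood is monotone and the best start is retained", {
  sim <- make_cat_data(n = 400, seed = 23)
  cfg <- run_config(seed = 23, n_starts = 5, compute_cov = FALSE)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  expect_gte(fit$loglik + 1e-6, max(fit$all_loglik))
})

test_that("EM recovers the generating parameters on identifiable designs", {
  sim <- make_cat_data(n = 5000, seed = 61, J = 4)
  cfg <- run_config(seed = 61, n_starts = 4, compute_cov = FALSE)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  # classes ordered by prevalence; identify by response probabilities
  rho_hat_1 <- fit$rho[[1]][[1]][1]
  flip <- rho_hat_1 < 0.5
  rhos <- vapply(1:4, function(j)
    fit$rho[[if (flip) 2 else 1]][[j]][1], numeric(1))
  se <- sqrt(0.85 * 0.15 / 2500)  # binomial SE at the true value
  expect_true(all(abs(rhos - 0.85) < 3 * 4 * se))
  expect_lt(abs(fit$pi[1] - 0.5), 0.05)
})

test_that("unseen indicator levels raise a typed error", {
  fit <- manual_lca_fit(pi = c(0.5, 0.5),
                        rho = list(list(c(0.8, 0.2)), list(c(0.2, 0.8))))
  data <- tibble::tibble(X1 = c(1L, 3L))
  expect_error(posterior_memberships(fit, data),
               class = "latentsens_level_error")
})

test_that("perturbed draws are deterministic, unbiased, and collapse at zero covariance", {
  sim <- make_cat_data(n = 200, seed = 31)
  cfg <- run_config(seed = 31, n_starts = 3)
  fit <- fit_mixture(sim$data, sim$roles, K = 2, config = cfg)
  mem <- posterior_memberships(fit, sim$data)

  d1 <- perturb_memberships(fit, sim$data, 555)
  d2 <- perturb_memberships(fit, sim$data, 555)
  expect_identical(d1$lambda, d2$lambda)
  expect_equal(d1$kind, "perturbed")

  fit0 <- fit
  fit0$theta_cov <- matrix(0, length(fit$theta), length(fit$theta))
  expect_identical(perturb_memberships(fit0, sim$data, 9)$lambda, mem$lambda)

  # sampling-distribution check: mean of drawn parameters ~ theta_hat
  n_draw <- 400
  thetas <- t(vapply(seq_len(n_draw), function(b)
    attr(perturb_memberships(fit, sim$data, 10000 + b), "theta"),
    numeric(length(fit$theta))))
  se <- sqrt(diag(fit$theta_cov) / n_draw)
  expect_true(all(abs(colMeans(thetas) - fit$theta) < 4 * se + 1e-12))
})

test_that("label alignment maximizes modal agreement", {
  set.seed(19)
  lam <- matrix(stats::rgamma(60, 1), 20, 3)
  lam <- lam / rowSums(lam)
  ref <- membership_matrix(lam)

  ident <- align_memberships(ref, ref)
  expect_equal(ident$permutation, 1:3)
  expect_equal(ident$agreement, 1)

  swapped <- membership_matrix(lam[, c(2, 1, 3)])
  al <- align_memberships(ref, swapped)
  expect_equal(al$permutation, c(2L, 1L, 3L))
  expect_identical(al$membership$lambda[, 1], ref$lambda[, 1])
  expect_equal(al$agreement, 1)

  # brute-force enumeration oracle on random candidates
  for (rep in 1:10) {
    cand <- membership_matrix(lam[sample(20), ])
    al <- align_memberships(ref, cand)
    A <- unclass(table(factor(ref$modal, 1:3), factor(cand$modal, 1:3)))
    P <- latentsens:::perms_lex(3)
    best <- max(apply(P, 1, function(pm) sum(A[cbind(1:3, pm)])))
    expect_equal(sum(al$membership$modal == ref$modal), best)
  }
})

test_that("class-count selection minimizes BIC and screens estimability", {
  fake_fit <- function(K, loglik, n_params, n = 100) {
    structure(list(K = K, loglik = loglik, n_params = n_params,
                   aic = -2 * loglik + 2 * n_params,
                   bic = -2 * loglik + n_params * log(n)),
              class = "lcs_mixture")
  }
  f2 <- fake_fit(2L, -100, 5L)
  f3 <- fake_fit(3L, -99, 8L)
  sel <- select_classes(list(f2, f3))
  expect_equal(sel$fit$K, 2L)
  expect_equal(sel$report$bic, c(223.0259, 234.8414), tolerance = 1e-4)

  single <- select_classes(list(f3))
  expect_identical(single$fit, f3)

  # screen: a modal class holding only treated subjects is excluded
  fit <- manual_lca_fit(pi = c(0.5, 0.5),
                        rho = list(list(c(0.95, 0.05)), list(c(0.05, 0.95))))
  data <- tibble::tibble(
    X1 = rep(c(1L, 2L), each = 10),
    Z = c(rbinom(10, 1, 0.5), rep(1L, 10)),
    Y = rbinom(20, 1, 0.5))
  data$Z[1:2] <- c(0L, 1L)
  roles <- subject_roles("Z", "Y", "X1")
  expect_error(select_classes(list(fit), data, roles),
               class = "latentsens_selection_error")
  expect_error(select_classes(list(fit), data, roles), "single-arm")
})

test_that("gaussian mixtures agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(9)
  x <- c(rnorm(150, -2, 0.7), rnorm(150, 2, 0.7))
  y <- c(rnorm(150, 0, 1), rnorm(150, 1, 1))
  data <- tibble::tibble(Z = rbinom(300, 1, 0.5), Y = rnorm(300),
                         V1 = x, V2 = y)
  roles <- subject_roles("Z", "Y", c("V1", "V2"))
  cfg <- run_config(seed = 4, n_starts = 5, compute_cov = FALSE)
  fit <- fit_mixture(data, roles, K = 2, config = cfg, family = "gaussian")
  mc <- mclust::Mclust(cbind(x, y), G = 2, modelNames = "VVI",
                       verbose = FALSE)
  # same components up to label order
  ord <- order(fit$mu[, 1])
  ord_mc <- order(mc$parameters$mean[1, ])
  expect_equal(fit$mu[ord, 1], unname(mc$parameters$mean[1, ord_mc]),
               tolerance = 0.05)
  expect_equal(sort(fit$pi), sort(unname(mc$parameters$pro)),
               tolerance = 0.05)
})
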