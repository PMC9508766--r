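# Independent oracle implementations used to cross-check the package's
# estimators. These are deliberately written in the most literal form
# possible and share no code with the implementation under test.

# Textbook AIPW form: mean over the subgroup of
#   Z (Y - m1)/p - (1 - Z)(Y - m0)/(1 - p) + m1 - m0
textbook_aipw <- function(Z, Y, p, m1, m0) {
  mean(Z * (Y - m1) / p - (1 - Z) * (Y - m0) / (1 - p) + m1 - m0)
}

# Bayes-rule posterior by explicit products of categorical probabilities.
# x: integer vector of indicator levels for one subject.
bayes_posterior_oracle <- function(pi, rho, x) {
  K <- length(pi)
  f <- vapply(seq_len(K), function(k) {
    pr <- pi[k]
    for (j in seq_along(x)) pr <- pr * rho[[k]][[j]][x[j]]
    pr
  }, numeric(1))
  f / sum(f)
}

# Literal step-by-step construction of the probability-ordered insertion
# sequence: repeatedly pick the not-yet-included subject with the largest
# membership probability among those whose modal class is c; once those
# are exhausted, among everyone remaining. Ties -> lowest index.
insertion_order_oracle <- function(lambda, c) {
  n <- nrow(lambda)
  modal <- apply(lambda, 1, which.max)  # which.max = lowest-index tie-break
  included <- rep(FALSE, n)
  out <- integer(n)
  for (j in seq_len(n)) {
    cand <- which(!included & modal == c)
    if (!length(cand)) cand <- which(!included)
    pick <- cand[order(-lambda[cand, c], cand)][1]
    out[j] <- pick
    included[pick] <- TRUE
  }
  out
}

# Build a mixture-fit object with known categorical parameters, without
# running EM, so posterior computations can be checked by hand.
manual_lca_fit <- function(pi, rho, indicator_names = NULL,
                           theta_cov = NULL) {
  K <- length(pi)
  J <- length(rho[[1]])
  L <- vapply(rho[[1]], length, integer(1))
  indicator_names <- indicator_names %||% paste0("X", seq_len(J))
  levels <- lapply(seq_len(J), function(j) seq_len(L[j]))
  names(levels) <- indicator_names
  params <- list(pi = pi, rho = rho)
  skel <- list(family = "categorical", K = K, L = L, J = J)
  theta <- latentsens:::pack_params(params, "categorical")
  params <- latentsens:::unpack_params(theta, skel)
  structure(
    list(family = "categorical", K = K, pi = params$pi, rho = params$rho,
         params = params, theta = theta, skeleton = skel,
         theta_cov = theta_cov, theta_cov_method = "manual",
         loglik = NA_real_, n = NA_integer_, n_params = length(theta),
         indicator_names = indicator_names, levels = levels, L = L,
         seed = 1L),
    class = "lcs_mixture"
  )
}

# Small toy subject table with a controllable treatment/outcome pattern.
toy_subjects <- function(Z, Y, X = NULL) {
  n <- length(Z)
  if (is.null(X)) X <- rep(c(1L, 2L), length.out = n)
  tibble::tibble(subject_id = as.character(seq_len(n)), Z = Z, Y = Y,
                 X1 = X)
}

toy_roles <- function() subject_roles("Z", "Y", "X1", id = "subject_id")

`%||%` <- function(a, b) if (is.null(a)) b else a
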