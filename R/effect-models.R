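#' @title Per-subgroup nuisance models
#' @description Covariate-balancing propensity scores (logistic form, with
#'   coefficients solving the just-identified balance moment conditions by
#'   damped Newton from the maximum-likelihood warm start) and an
#'   elastic-net penalized saturated outcome regression with all
#'   treatment-by-covariate interactions.
#' @name effect_models
NULL

#' Build the covariate design matrix for the nuisance models
#'
#' Indicator columns are one-hot encoded with a first-level reference;
#' numeric adjusters enter as-is, non-numeric adjusters are one-hot encoded
#' too. Columns constant within `data` are dropped (subsets along a
#' trajectory can lose levels), and remaining collinear columns are pruned
#' to full column rank.
#'
#' @param data Subject table (or a subset of it).
#' @param roles A [subject_roles()] object.
#' @return A numeric matrix without intercept; dropped column names are in
#'   attribute `"dropped"`.
#' @export
design_matrix <- function(data, roles) {
  cols <- c(roles$indicators, roles$adjusters)
  df <- data[cols]
  for (col in roles$indicators) df[[col]] <- factor(df[[col]])
  for (col in roles$adjusters) {
    if (!is.numeric(df[[col]])) df[[col]] <- factor(df[[col]])
  }
  # factors collapsed to a single observed level carry no information
  single <- vapply(df, function(v) length(unique(v)) < 2L, logical(1))
  dropped <- names(df)[single]
  df <- df[!single]
  if (ncol(df) == 0L) {
    m <- matrix(numeric(0), nrow = nrow(data), ncol = 0L)
    attr(m, "dropped") <- dropped
    return(m)
  }
  m <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  qr_m <- qr(m)
  if (qr_m$rank < ncol(m)) {
    keep <- qr_m$pivot[seq_len(qr_m$rank)]
    dropped <- c(dropped, colnames(m)[-keep])
    m <- m[, sort(keep), drop = FALSE]
  }
  attr(m, "dropped") <- dropped
  m
}

cbps_gradient <- function(Xt, Z, p) {
  drop(crossprod(Xt, Z / p - (1 - Z) / (1 - p)))
}

weighted_balance <- function(X, Z, p) {
  w1 <- Z / p
  w0 <- (1 - Z) / (1 - p)
  m1 <- colSums(X * w1) / sum(w1)
  m0 <- colSums(X * w0) / sum(w0)
  tibble::tibble(column = colnames(X), mean_treated = m1,
                 mean_control = m0, diff = m1 - m0)
}

#' Fit a propensity score model
#'
#' Logistic-form propensity `p(x) = expit(x'beta)`. With
#' `method = "cbps"` (the default) the coefficients solve the
#' just-identified covariate-balancing moment conditions
#' `sum_i (Z_i/p_i - (1-Z_i)/(1-p_i)) x_i = 0` (intercept included) by
#' damped Newton initialized at the maximum-likelihood solution, so at
#' convergence the inverse-probability-weighted covariate means agree
#' between arms. Falls back to the MLE with a warning when the root-finding
#' fails.
#'
#' @param X Covariate design matrix without intercept (see
#'   [design_matrix()]).
#' @param Z Binary treatment vector.
#' @param config A [run_config()] object (balance tolerance, iterations).
#' @param method `"cbps"` or `"mle"`.
#' @param on_separation `"error"` (default) raises a
#'   `latentsens_separation_error` naming the offending columns when the
#'   MLE warm start diverges; `"warn"` records a separation flag on the
#'   returned fit instead.
#' @return An object of class `lcs_propensity`: `method`, `coefficients`,
#'   `p_hat`, `balance` (per-column weighted mean difference), `converged`,
#'   `separation`.
#' @export
fit_propensity <- function(X, Z, config = run_config(),
                           method = c("cbps", "mle"),
                           on_separation = c("error", "warn")) {
  method <- match.arg(method)
  on_separation <- match.arg(on_separation)
  Z <- as.numeric(Z)
  if (length(unique(Z)) < 2L) {
    abort("treatment has a single arm; propensity model unidentified",
          class = "latentsens_single_arm_error")
  }
  Xt <- cbind("(Intercept)" = 1, X)

  mle <- suppressWarnings(
    stats::glm.fit(Xt, Z, family = stats::binomial())
  )
  beta <- mle$coefficients
  beta[is.na(beta)] <- 0
  p_mle <- plogis(drop(Xt %*% beta))
  separation <- any(p_mle < 1e-8 | p_mle > 1 - 1e-8) || !mle$converged
  if (separation) {
    offending <- colnames(X)[abs(beta[-1]) > 10]
    if (!length(offending)) offending <- colnames(X)
    if (on_separation == "error") {
      abort(paste0("complete separation in the propensity model; columns: ",
                   paste(offending, collapse = ", ")),
            class = "latentsens_separation_error")
    }
    warn(paste0("separation detected in propensity model; columns: ",
                paste(offending, collapse = ", ")),
         class = "latentsens_separation_warning")
  }

  converged <- FALSE
  if (method == "cbps" && !separation) {
    bal_max <- function(p) {
      if (ncol(X) == 0L) return(0)
      max(abs(weighted_balance(X, Z, p)$diff))
    }
    p <- pmin(pmax(p_mle, 1e-12), 1 - 1e-12)
    for (it in seq_len(config$cbps_max_iter)) {
      g <- cbps_gradient(Xt, Z, p)
      if (max(abs(g)) < 1e-10 * length(Z) && bal_max(p) < config$cbps_tol) {
        converged <- TRUE
        break
      }
      wd <- Z * (1 - p) / p + (1 - Z) * p / (1 - p)
      Jm <- crossprod(Xt * wd, Xt)
      step <- tryCatch(solve(Jm, g), error = function(e) NULL)
      if (is.null(step)) break
      # damped update: halve until the moment norm does not increase
      ok <- FALSE
      for (half in 0:30) {
        beta_new <- beta + step / 2^half
        p_new <- pmin(pmax(plogis(drop(Xt %*% beta_new)), 1e-12), 1 - 1e-12)
        if (sum(cbps_gradient(Xt, Z, p_new)^2) <= sum(g^2) * (1 + 1e-12)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) break
      beta <- beta_new
      p <- p_new
    }
    if (!converged && bal_max(p) < config$cbps_tol) converged <- TRUE
    if (!converged) {
      warn("balancing equations did not converge; falling back to MLE",
           class = "latentsens_cbps_fallback")
      method <- "mle"
      beta <- mle$coefficients
      beta[is.na(beta)] <- 0
      p <- pmin(pmax(p_mle, 1e-12), 1 - 1e-12)
    }
  } else {
    method <- "mle"
    p <- pmin(pmax(p_mle, 1e-12), 1 - 1e-12)
    converged <- mle$converged && !separation
  }

  structure(
    list(method = method, coefficients = beta, p_hat = p,
         balance = if (ncol(X)) weighted_balance(X, Z, p) else
           tibble::tibble(column = character(), mean_treated = numeric(),
                          mean_control = numeric(), diff = numeric()),
         converged = converged, separation = separation),
    class = "lcs_propensity"
  )
}

#' Fit the penalized saturated outcome regression
#'
#' The design is intercept + covariates + treatment + all
#' treatment-by-covariate interactions; coefficients are estimated under an
#' elastic-net penalty (intercept unpenalized) with the penalty strength
#' chosen by seeded k-fold cross-validation, unless `config$penalty_lambda`
#' fixes it (`0` fits the unpenalized GLM). Predicted outcomes under both
#' treatment assignments are returned for every subject.
#'
#' @param X Covariate design matrix without intercept.
#' @param Z Binary treatment vector.
#' @param Y Outcome vector (binary 0/1 or continuous).
#' @param config A [run_config()] object.
#' @param family `"binary"`, `"continuous"`, or `NULL` to infer from `Y`.
#' @return An object of class `lcs_outcome`: `family`, `coefficients`,
#'   `m1_hat`, `m0_hat`, `lambda`, `alpha`, `nfolds`, `cv_seed`,
#'   `degenerate`.
#' @export
fit_outcome <- function(X, Z, Y, config = run_config(), family = NULL) {
  Z <- as.numeric(Z)
  Y <- as.numeric(Y)
  n <- length(Y)
  if (is.null(family)) family <- if (is_binary01(Y)) "binary" else "continuous"
  family <- match.arg(family, c("binary", "continuous"))

  if (length(unique(Y)) < 2L) {
    warn("constant outcome: degenerate fit with constant predictions",
         class = "latentsens_degenerate_outcome")
    return(structure(
      list(family = family, coefficients = NULL,
           m1_hat = rep(Y[1], n), m0_hat = rep(Y[1], n),
           lambda = NA_real_, alpha = config$penalty_alpha,
           nfolds = NA_integer_, cv_seed = config$cv_seed,
           degenerate = TRUE),
      class = "lcs_outcome"
    ))
  }

  if (ncol(X)) {
    ZX <- X * Z
    colnames(ZX) <- paste0("Z:", colnames(X))
    D <- cbind(X, Z = Z, ZX)
  } else {
    D <- cbind(Z = Z)
  }
  D1 <- D
  D1[, "Z"] <- 1
  D0 <- D
  D0[, "Z"] <- 0
  if (ncol(X)) {
    D1[, paste0("Z:", colnames(X))] <- X
    D0[, paste0("Z:", colnames(X))] <- 0
  }
  glm_family <- if (family == "binary") "binomial" else "gaussian"

  lam <- config$penalty_lambda
  use_glm <- (!is.null(lam) && lam == 0) || ncol(D) < 2L || n < 8L
  if (use_glm) {
    if (!is.null(lam) && lam != 0 && (ncol(D) < 2L || n < 8L)) {
      warn("design too small for penalized fitting; using unpenalized GLM",
           class = "latentsens_penalty_fallback")
    }
    fam <- if (family == "binary") stats::binomial() else stats::gaussian()
    fit <- suppressWarnings(stats::glm.fit(cbind(1, D), Y, family = fam))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    lp1 <- drop(cbind(1, D1) %*% beta)
    lp0 <- drop(cbind(1, D0) %*% beta)
    m1 <- if (family == "binary") plogis(lp1) else lp1
    m0 <- if (family == "binary") plogis(lp0) else lp0
    return(structure(
      list(family = family, coefficients = beta,
           m1_hat = m1, m0_hat = m0,
           lambda = 0, alpha = config$penalty_alpha,
           nfolds = NA_integer_, cv_seed = config$cv_seed,
           degenerate = FALSE),
      class = "lcs_outcome"
    ))
  }

  pf <- rep(1, ncol(D))
  if (!config$penalize_treatment) pf[colnames(D) == "Z"] <- 0
  nfolds <- config$cv_folds
  if (is.null(lam)) {
    if (nfolds > n) {
      warn(sprintf("reducing CV folds from %d to %d (too few subjects)",
                   nfolds, max(3L, min(n, 10L))),
           class = "latentsens_fold_reduction")
      nfolds <- max(3L, min(n, 10L))
    }
    foldid <- with_seed(config$cv_seed, sample(rep_len(seq_len(nfolds), n)))
    cv <- suppressWarnings(glmnet::cv.glmnet(
      D, Y, family = glm_family, alpha = config$penalty_alpha,
      foldid = foldid, penalty.factor = pf, standardize = TRUE))
    lam <- cv$lambda.min
    fitg <- cv$glmnet.fit
  } else {
    nfolds <- NA_integer_
    fitg <- suppressWarnings(glmnet::glmnet(
      D, Y, family = glm_family, alpha = config$penalty_alpha,
      penalty.factor = pf, standardize = TRUE))
  }
  m1 <- drop(stats::predict(fitg, newx = D1, s = lam, type = "response"))
  m0 <- drop(stats::predict(fitg, newx = D0, s = lam, type = "response"))
  cf <- drop(as.matrix(stats::coef(fitg, s = lam)))
  structure(
    list(family = family, coefficients = cf,
         m1_hat = m1, m0_hat = m0,
         lambda = lam, alpha = config$penalty_alpha,
         nfolds = nfolds, cv_seed = config$cv_seed,
         degenerate = FALSE),
    class = "lcs_outcome"
  )
}

#' Practical-positivity diagnostics for a propensity fit
#'
#' Reports, without ever raising, the warning signs that make
#' inverse-probability weighting unstable or undefined: a single treatment
#' arm, fitted propensity scores outside the configured bounds, the largest
#' inverse weight, and complete separation.
#'
#' @param fit An `lcs_propensity`, or `NULL` when no fit could be obtained.
#' @param Z Binary treatment vector.
#' @param thresholds Length-2 bounds on acceptable propensity scores.
#' @param p_hat Optional fitted probabilities overriding `fit$p_hat`.
#' @return A one-row tibble: `single_arm`, `n_extreme`, `max_weight`,
#'   `separation`.
#' @export
positivity_check <- function(fit = NULL, Z, thresholds = c(0.01, 0.99),
                             p_hat = NULL) {
  Z <- as.numeric(Z)
  single_arm <- length(unique(Z)) < 2L
  p <- p_hat %||% fit$p_hat
  if (is.null(p)) {
    return(tibble::tibble(single_arm = single_arm, n_extreme = NA_integer_,
                          max_weight = NA_real_,
                          separation = isTRUE(fit$separation)))
  }
  w <- ifelse(Z == 1, 1 / p, 1 / (1 - p))
  tibble::tibble(
    single_arm = single_arm,
    n_extreme = sum(p < thresholds[1] | p > thresholds[2]),
    max_weight = max(w),
    separation = isTRUE(fit$separation) ||
      any(p < 1e-8 | p > 1 - 1e-8)
  )
}
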