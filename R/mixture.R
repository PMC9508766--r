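#' @title Finite mixture membership models
#' @description Latent class analysis (categorical indicators under
#'   class-conditional independence) and diagonal Gaussian mixtures
#'   (continuous indicators), fitted by EM with random restarts. The fitted
#'   parameters are also stored on a packed unconstrained scale (multinomial
#'   logits for probability vectors, log scale for standard deviations) so
#'   that a multivariate-normal draw from the parameter sampling
#'   distribution always maps back to valid probabilities.
#' @name mixture
NULL

# ---- membership container ----------------------------------------------

new_membership <- function(lambda, kind = c("estimated", "perturbed"),
                           subject_id = NULL) {
  kind <- match.arg(kind)
  lambda <- as.matrix(lambda)
  colnames(lambda) <- paste0("class_", seq_len(ncol(lambda)))
  structure(
    list(lambda = lambda,
         modal = max.col(lambda, ties.method = "first"),
         kind = kind,
         subject_id = subject_id),
    class = "lcs_membership"
  )
}

#' Construct a membership matrix from given probabilities
#'
#' Wraps an `n x K` matrix of subgroup membership probabilities (rows
#' summing to 1) into the container the rest of the pipeline consumes,
#' computing modal assignments by arg-max with lowest-index tie-break.
#' Useful for probabilities produced outside [fit_mixture()].
#'
#' @param lambda Numeric matrix of membership probabilities.
#' @param kind `"estimated"` or `"perturbed"`.
#' @param subject_id Optional vector of subject labels.
#' @return An object of class `lcs_membership`.
#' @export
membership_matrix <- function(lambda, kind = "estimated",
                              subject_id = NULL) {
  lambda <- as.matrix(lambda)
  if (any(lambda < -1e-10) ||
      any(abs(rowSums(lambda) - 1) > 1e-6)) {
    abort("membership probability rows must be nonnegative and sum to 1",
          class = "latentsens_validation_error")
  }
  new_membership(lambda, kind = kind, subject_id = subject_id)
}

#' @export
print.lcs_membership <- function(x, ...) {
  cat(sprintf("<lcs_membership> %s, %d subjects x %d classes\n",
              x$kind, nrow(x$lambda), ncol(x$lambda)))
  cat("modal counts:", paste(tabulate(x$modal, ncol(x$lambda)),
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.lcs_membership <- function(x, ...) {
  out <- tibble::as_tibble(x$lambda)
  out$modal <- x$modal
  if (!is.null(x$subject_id)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id), out)
  }
  out
}

# ---- indicator coding ---------------------------------------------------

indicator_codes <- function(data, roles, levels = NULL) {
  cols <- roles$indicators
  n <- nrow(data)
  x <- matrix(0L, n, length(cols))
  if (is.null(levels)) {
    levels <- lapply(cols, function(col) sort(unique(data[[col]])))
    names(levels) <- cols
  }
  for (j in seq_along(cols)) {
    code <- match(data[[cols[j]]], levels[[cols[j]]])
    if (anyNA(code)) {
      i <- which(is.na(code))[1]
      abort(sprintf(
        "subject %s has level '%s' on indicator '%s' unseen by the fitted model",
        i, as.character(data[[cols[j]]][i]), cols[j]),
        class = "latentsens_level_error")
    }
    x[, j] <- code
  }
  list(x = x, levels = levels)
}

# ---- EM engines ---------------------------------------------------------

log_density_cat <- function(x, params) {
  K <- length(params$pi)
  n <- nrow(x)
  lf <- matrix(rep(log(pmax(params$pi, 1e-300)), each = n), n, K)
  for (k in seq_len(K)) {
    for (j in seq_len(ncol(x))) {
      lf[, k] <- lf[, k] + log(pmax(params$rho[[k]][[j]], 1e-300))[x[, j]]
    }
  }
  lf
}

m_step_cat <- function(x, L, lambda) {
  K <- ncol(lambda)
  nk <- colSums(lambda)
  rho <- rep(list(vector("list", length(L))), K)
  for (j in seq_along(L)) {
    s <- rowsum(lambda, x[, j])
    full <- matrix(0, L[j], K)
    full[as.integer(rownames(s)), ] <- s
    for (k in seq_len(K)) rho[[k]][[j]] <- full[, k] / nk[k]
  }
  list(pi = nk / nrow(x), rho = rho)
}

log_density_gauss <- function(x, params) {
  K <- length(params$pi)
  n <- nrow(x)
  lf <- matrix(rep(log(pmax(params$pi, 1e-300)), each = n), n, K)
  for (k in seq_len(K)) {
    for (j in seq_len(ncol(x))) {
      lf[, k] <- lf[, k] +
        stats::dnorm(x[, j], params$mu[k, j], params$sd[k, j], log = TRUE)
    }
  }
  lf
}

m_step_gauss <- function(x, lambda) {
  K <- ncol(lambda)
  J <- ncol(x)
  nk <- colSums(lambda)
  mu <- matrix(0, K, J)
  sd_ <- matrix(0, K, J)
  for (k in seq_len(K)) {
    mu[k, ] <- colSums(lambda[, k] * x) / nk[k]
    sd_[k, ] <- sqrt(pmax(
      colSums(lambda[, k] * sweep(x, 2, mu[k, ])^2) / nk[k], 1e-12))
  }
  list(pi = nk / nrow(x), mu = mu, sd = sd_)
}

em_run <- function(x, K, family, L = NULL, seed, tol, max_iter) {
  n <- nrow(x)
  lambda <- with_seed(seed, matrix(stats::rexp(n * K), n, K))
  lambda <- lambda / rowSums(lambda)
  params <- if (family == "categorical") m_step_cat(x, L, lambda)
            else m_step_gauss(x, lambda)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lf <- if (family == "categorical") log_density_cat(x, params)
          else log_density_gauss(x, params)
    lse <- logsumexp_rows(lf)
    ll <- sum(lse)
    lambda <- exp(lf - lse)
    if (any(colSums(lambda) < 1e-6)) {
      return(list(ok = FALSE, reason = "empty class"))
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
    params <- if (family == "categorical") m_step_cat(x, L, lambda)
              else m_step_gauss(x, lambda)
  }
  list(ok = TRUE, params = params, loglik = ll, trace = trace)
}

# ---- packed unconstrained parametrization ------------------------------

mlogit <- function(p) {
  p <- pmax(p, 1e-8)
  p <- p / sum(p)
  log(p[-length(p)] / p[length(p)])
}

inv_mlogit <- function(eta) {
  z <- c(eta, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

pack_params <- function(params, family) {
  if (family == "categorical") {
    c(mlogit(params$pi),
      unlist(lapply(params$rho, function(cls) lapply(cls, mlogit))))
  } else {
    c(mlogit(params$pi), as.vector(t(params$mu)),
      log(as.vector(t(params$sd))))
  }
}

unpack_params <- function(theta, skel) {
  K <- skel$K
  pi <- if (K == 1L) 1 else inv_mlogit(theta[seq_len(K - 1L)])
  pos <- K - 1L
  if (skel$family == "categorical") {
    rho <- vector("list", K)
    for (k in seq_len(K)) {
      rho[[k]] <- vector("list", length(skel$L))
      for (j in seq_along(skel$L)) {
        d <- skel$L[j] - 1L
        rho[[k]][[j]] <- inv_mlogit(theta[pos + seq_len(d)])
        pos <- pos + d
      }
    }
    list(pi = pi, rho = rho)
  } else {
    J <- skel$J
    mu <- matrix(theta[pos + seq_len(K * J)], K, J, byrow = TRUE)
    pos <- pos + K * J
    sd_ <- matrix(exp(theta[pos + seq_len(K * J)]), K, J, byrow = TRUE)
    list(pi = pi, mu = mu, sd = sd_)
  }
}

loglik_theta <- function(theta, x, skel) {
  params <- unpack_params(theta, skel)
  lf <- if (skel$family == "categorical") log_density_cat(x, params)
        else log_density_gauss(x, params)
  sum(logsumexp_rows(lf))
}

# Central-difference Hessian with coordinate steps 1e-5 * (1 + |theta|).
num_hessian <- function(f, th) {
  p <- length(th)
  h <- 1e-5 * (1 + abs(th))
  H <- matrix(0, p, p)
  f0 <- f(th)
  for (a in seq_len(p)) {
    ta <- th; ta[a] <- th[a] + h[a]
    tb <- th; tb[a] <- th[a] - h[a]
    H[a, a] <- (f(ta) - 2 * f0 + f(tb)) / h[a]^2
    for (b in seq_len(a - 1L)) {
      tpp <- th; tpp[a] <- th[a] + h[a]; tpp[b] <- th[b] + h[b]
      tpm <- th; tpm[a] <- th[a] + h[a]; tpm[b] <- th[b] - h[b]
      tmp <- th; tmp[a] <- th[a] - h[a]; tmp[b] <- th[b] + h[b]
      tmm <- th; tmm[a] <- th[a] - h[a]; tmm[b] <- th[b] - h[b]
      H[a, b] <- H[b, a] <-
        (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[a] * h[b])
    }
  }
  H
}

psd_project <- function(V) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1e-12)) return(NULL)
  vals <- pmax(e$values, 0)
  V2 <- e$vectors %*% (vals * t(e$vectors))
  (V2 + t(V2)) / 2
}

# Align the class labels of `params` to `ref` by minimizing squared
# parameter distance over label permutations (used for the bootstrap
# covariance fallback, where modal labels are not available on the
# original subjects).
align_params <- function(params, ref, family) {
  K <- length(params$pi)
  if (K == 1L) return(params)
  P <- perms_lex(min(K, 8L))
  dist_for <- function(pm) {
    d <- sum((params$pi[pm] - ref$pi)^2)
    if (family == "categorical") {
      for (k in seq_len(K)) {
        d <- d + sum((unlist(params$rho[[pm[k]]]) - unlist(ref$rho[[k]]))^2)
      }
    } else {
      d <- d + sum((params$mu[pm, , drop = FALSE] - ref$mu)^2)
    }
    d
  }
  best <- P[which.min(apply(P, 1, dist_for)), ]
  permute_params(params, best, family)
}

permute_params <- function(params, pm, family) {
  if (family == "categorical") {
    list(pi = params$pi[pm], rho = params$rho[pm])
  } else {
    list(pi = params$pi[pm], mu = params$mu[pm, , drop = FALSE],
         sd = params$sd[pm, , drop = FALSE])
  }
}

boot_theta_cov <- function(fit, x, config) {
  R <- config$boot_cov_resamples
  seeds <- derive_seeds(fit$seed + 31337L, R)
  p <- length(fit$theta)
  thetas <- matrix(NA_real_, R, p)
  for (r in seq_len(R)) {
    idx <- with_seed(seeds[r], sample.int(nrow(x), replace = TRUE))
    run <- em_run_warm(x[idx, , drop = FALSE], fit, config)
    if (!run$ok) next
    pr <- align_params(run$params, fit$params, fit$family)
    thetas[r, ] <- pack_params(pr, fit$family)
  }
  ok <- stats::complete.cases(thetas)
  if (sum(ok) < 10L) {
    abort("bootstrap covariance fallback failed (too few successful refits)",
          class = "latentsens_cov_error")
  }
  stats::cov(thetas[ok, , drop = FALSE])
}

# EM restarted from the fitted parameters (single start, for bootstrap).
em_run_warm <- function(x, fit, config) {
  params <- fit$params
  ll_old <- -Inf
  for (it in seq_len(config$em_max_iter)) {
    lf <- if (fit$family == "categorical") log_density_cat(x, params)
          else log_density_gauss(x, params)
    lse <- logsumexp_rows(lf)
    ll <- sum(lse)
    lambda <- exp(lf - lse)
    if (any(colSums(lambda) < 1e-6)) return(list(ok = FALSE))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < config$em_tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
    params <- if (fit$family == "categorical")
                m_step_cat(x, fit$L, lambda) else m_step_gauss(x, lambda)
  }
  list(ok = TRUE, params = params)
}

# ---- user-facing fitting ------------------------------------------------

#' Fit a finite mixture membership model
#'
#' Runs EM from `config$n_starts` seeded random initializations (per-subject
#' Dirichlet(1, ..., 1) responsibilities) and keeps the best log-likelihood.
#' Classes are ordered by decreasing prevalence for reproducibility. The
#' fitted parameters are stored both on the natural scale and as a packed
#' unconstrained vector, together with the covariance of that vector from
#' the numerically differentiated observed information (falling back to a
#' nonparametric bootstrap, with a warning, when the information matrix
#' cannot be inverted).
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object; the mixture uses only the
#'   indicator columns.
#' @param K Number of latent classes (`K >= 1`).
#' @param config A [run_config()] object (EM controls, seed, whether to
#'   compute the parameter covariance).
#' @param family `"categorical"` (latent class analysis), `"gaussian"`
#'   (diagonal Gaussian mixture), or `NULL` to infer from the indicator
#'   columns.
#' @return An object of class `lcs_mixture` with elements including `pi`,
#'   `rho` (or `mu`/`sd`), `theta`, `theta_cov`, `loglik`, `loglik_trace`
#'   (retained run), `aic`, `bic`, `n_params`.
#' @export
fit_mixture <- function(data, roles, K, config = run_config(),
                        family = NULL) {
  stopifnot(K >= 1)
  inds <- data[roles$indicators]
  if (is.null(family)) {
    discrete <- vapply(inds, function(v) {
      is.factor(v) || is.character(v) || is.logical(v) ||
        (is.numeric(v) && all(v == round(v)) && length(unique(v)) <= 12L)
    }, logical(1))
    family <- if (all(discrete)) "categorical" else "gaussian"
  }
  family <- match.arg(family, c("categorical", "gaussian"))
  n <- nrow(data)

  if (family == "categorical") {
    coding <- indicator_codes(data, roles)
    x <- coding$x
    L <- vapply(coding$levels, length, integer(1))
  } else {
    x <- as.matrix(inds)
    storage.mode(x) <- "double"
    L <- NULL
    coding <- list(levels = NULL)
  }

  seeds <- derive_seeds(config$seed + 613L * K, config$n_starts + 50L)
  runs <- list()
  attempt <- 0L
  while (length(runs) < config$n_starts && attempt < length(seeds)) {
    attempt <- attempt + 1L
    r <- em_run(x, K, family, L, seeds[attempt],
                config$em_tol, config$em_max_iter)
    if (r$ok) runs[[length(runs) + 1L]] <- r
  }
  if (!length(runs)) {
    abort("every EM start collapsed to an empty class",
          class = "latentsens_em_error")
  }
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]

  # order classes by decreasing prevalence, then canonicalize through the
  # packed scale so fitted and perturbed probabilities share one code path
  ord <- order(-best$params$pi)
  params <- permute_params(best$params, ord, family)
  skel <- list(family = family, K = as.integer(K), L = L,
               J = ncol(x))
  theta <- pack_params(params, family)
  params <- unpack_params(theta, skel)
  loglik <- loglik_theta(theta, x, skel)
  n_params <- length(theta)

  fit <- structure(
    list(family = family, K = as.integer(K),
         pi = params$pi,
         rho = params$rho, mu = params$mu, sd = params$sd,
         params = params,
         theta = theta, skeleton = skel,
         theta_cov = NULL, theta_cov_method = "none",
         loglik = loglik, loglik_trace = best$trace,
         all_loglik = lls,
         n = n, n_params = n_params,
         aic = -2 * loglik + 2 * n_params,
         bic = -2 * loglik + n_params * log(n),
         indicator_names = roles$indicators,
         levels = coding$levels,
         seed = config$seed,
         L = L),
    class = "lcs_mixture"
  )
  if (config$compute_cov) {
    fit <- compute_theta_cov(fit, x, config)
  }
  fit
}

compute_theta_cov <- function(fit, x, config) {
  H <- num_hessian(function(th) loglik_theta(th, x, fit$skeleton), fit$theta)
  V <- tryCatch(psd_project(solve(-H)), error = function(e) NULL)
  if (is.null(V)) {
    warn("observed information not invertible; using bootstrap covariance",
         class = "latentsens_cov_fallback")
    V <- psd_project(boot_theta_cov(fit, x, config))
    fit$theta_cov_method <- "bootstrap"
  } else {
    fit$theta_cov_method <- "observed_information"
  }
  fit$theta_cov <- V
  fit
}

#' @export
print.lcs_mixture <- function(x, ...) {
  cat(sprintf("<lcs_mixture> %s, K = %d, n = %d\n", x$family, x$K, x$n))
  cat(sprintf("loglik = %.3f  AIC = %.2f  BIC = %.2f  (%d parameters)\n",
              x$loglik, x$aic, x$bic, x$n_params))
  cat("prevalences:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

# shared posterior computation for fitted and perturbed parameters
memberships_from_params <- function(params, fit, data, kind) {
  coding <- indicator_codes(data, list(indicators = fit$indicator_names),
                            levels = fit$levels)
  if (fit$family == "categorical") {
    lf <- log_density_cat(coding$x, params)
  } else {
    x <- as.matrix(data[fit$indicator_names])
    storage.mode(x) <- "double"
    lf <- log_density_gauss(x, params)
  }
  lse <- logsumexp_rows(lf)
  if (any(!is.finite(lse))) {
    i <- which(!is.finite(lse))[1]
    abort(sprintf("subject %d has zero likelihood under every class", i),
          class = "latentsens_level_error")
  }
  new_membership(exp(lf - lse), kind = kind, subject_id = NULL)
}

#' Posterior membership probabilities under a fitted mixture
#'
#' Bayes rule: `lambda[i, c]` is proportional to the class prevalence times
#' the class-conditional likelihood of subject `i`'s indicators, normalized
#' across classes. Modal assignments take the arg-max with lowest-index
#' tie-break.
#'
#' @param fit An `lcs_mixture` from [fit_mixture()].
#' @param data Subject table sharing the fit's indicator schema.
#' @return An `lcs_membership` object (`kind = "estimated"`).
#' @export
posterior_memberships <- function(fit, data) {
  stopifnot(inherits(fit, "lcs_mixture"))
  memberships_from_params(fit$params, fit, data, "estimated")
}

#' Draw perturbed membership probabilities
#'
#' One parametric-bootstrap draw: the packed mixture parameters are drawn
#' from a multivariate normal centered at the estimates with the fitted
#' parameter covariance, mapped back to probabilities, and the posterior
#' memberships recomputed exactly as in [posterior_memberships()]. Draws
#' implying a prevalence below 1e-12 are rejected and redrawn (at most 100
#' times).
#'
#' @param fit An `lcs_mixture` carrying `theta_cov`.
#' @param data Subject table.
#' @param seed Seed for this draw (the caller derives per-draw seeds from
#'   the master seed).
#' @return An `lcs_membership` object (`kind = "perturbed"`).
#' @export
perturb_memberships <- function(fit, data, seed) {
  stopifnot(inherits(fit, "lcs_mixture"))
  if (is.null(fit$theta_cov)) {
    abort("fit carries no parameter covariance; refit with compute_cov = TRUE",
          class = "latentsens_cov_error")
  }
  drawn <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(100L)) {
      th <- MASS::mvrnorm(1, fit$theta, fit$theta_cov)
      pr <- unpack_params(th, fit$skeleton)
      if (all(pr$pi >= 1e-12)) { out <- list(params = pr, theta = th); break }
    }
    out
  })
  if (is.null(drawn)) {
    abort("100 consecutive draws implied an empty class",
          class = "latentsens_draw_error")
  }
  out <- memberships_from_params(drawn$params, fit, data, "perturbed")
  attr(out, "theta") <- unname(drawn$theta)
  out
}

#' Align mixture labels between two membership matrices
#'
#' Finds the column permutation of the candidate's probabilities that
#' maximizes the number of subjects whose modal label agrees with the
#' reference (exhaustive over permutations for `K <= 8`, greedy beyond;
#' ties broken by the lexicographically smallest permutation), guarding the
#' parametric bootstrap against label switching.
#'
#' @param reference,candidate `lcs_membership` objects with equal dimensions.
#' @return A list: `membership` (relabeled candidate), `permutation`
#'   (`relabeled column r` = candidate column `permutation[r]`), and
#'   `agreement` (modal agreement rate after relabeling).
#' @export
align_memberships <- function(reference, candidate) {
  stopifnot(inherits(reference, "lcs_membership"),
            inherits(candidate, "lcs_membership"),
            all(dim(reference$lambda) == dim(candidate$lambda)))
  K <- ncol(reference$lambda)
  A <- unclass(table(factor(reference$modal, seq_len(K)),
                     factor(candidate$modal, seq_len(K))))
  if (K <= 8L) {
    P <- perms_lex(K)
    scores <- apply(P, 1, function(pm) sum(A[cbind(seq_len(K), pm)]))
    perm <- P[which.max(scores), ]
  } else {
    perm <- integer(K)
    left <- seq_len(K)
    for (r in seq_len(K)) {
      pick <- left[which.max(A[r, left])]
      perm[r] <- pick
      left <- setdiff(left, pick)
    }
  }
  relabeled <- new_membership(candidate$lambda[, perm, drop = FALSE],
                              kind = candidate$kind,
                              subject_id = candidate$subject_id)
  list(membership = relabeled, permutation = perm,
       agreement = mean(relabeled$modal == reference$modal))
}

#' Select the number of latent classes
#'
#' Chooses the candidate fit with the smallest BIC. When a subject table is
#' supplied, candidates are first screened for estimability: every modal
#' class must contain both treatment arms and, for a binary outcome,
#' outcome variation — the pragmatic exclusion applied when a
#' subgroup-specific effect simply cannot be calculated.
#'
#' @param fits A list of `lcs_mixture` objects fitted to the same data.
#' @param data,roles Optional subject table and roles enabling the screen.
#' @return A list of class `lcs_selection`: `fit` (the chosen model) and
#'   `report` (a tibble with one row per candidate: `K`, `loglik`,
#'   `n_params`, `aic`, `bic`, `pass`, `reason`).
#' @export
select_classes <- function(fits, data = NULL, roles = NULL) {
  stopifnot(length(fits) >= 1L)
  rows <- purrr::map(fits, function(f) {
    pass <- TRUE
    reason <- NA_character_
    if (!is.null(data)) {
      mem <- posterior_memberships(f, data)
      msgs <- character(0)
      for (k in seq_len(f$K)) {
        idx <- mem$modal == k
        if (!any(idx)) {
          msgs <- c(msgs, sprintf("class %d: no modal members", k))
          next
        }
        z <- data[[roles$treatment]][idx]
        y <- data[[roles$outcome]][idx]
        if (length(unique(z)) < 2L) {
          msgs <- c(msgs, sprintf("class %d: single-arm class", k))
        }
        if (is_binary01(y) && length(unique(y)) < 2L) {
          msgs <- c(msgs, sprintf("class %d: no outcome variation", k))
        }
      }
      if (length(msgs)) {
        pass <- FALSE
        reason <- paste(msgs, collapse = "; ")
      }
    }
    tibble::tibble(K = f$K, loglik = f$loglik, n_params = f$n_params,
                   aic = f$aic, bic = f$bic, pass = pass, reason = reason)
  })
  report <- dplyr::bind_rows(rows)
  if (!any(report$pass)) {
    abort(paste0("no candidate passes the estimability screen: ",
                 paste(stats::na.omit(report$reason), collapse = " | ")),
          class = "latentsens_selection_error")
  }
  ok <- which(report$pass)
  best <- ok[order(report$bic[ok], report$K[ok])][1]
  structure(list(fit = fits[[best]], report = report),
            class = "lcs_selection")
}

#' @export
print.lcs_selection <- function(x, ...) {
  cat("<lcs_selection> chosen K =", x$fit$K, "\n")
  print(x$report)
  invisible(x)
}

#' Serialize a mixture fit to JSON
#'
#' @param fit An `lcs_mixture`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
mixture_to_json <- function(fit, path) {
  obj <- list(family = fit$family, K = fit$K, pi = fit$pi,
              rho = fit$rho, mu = fit$mu, sd = fit$sd,
              theta = fit$theta, theta_cov = fit$theta_cov,
              theta_cov_method = fit$theta_cov_method,
              loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
              n = fit$n, n_params = fit$n_params,
              indicator_names = fit$indicator_names,
              levels = fit$levels, L = fit$L, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}
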