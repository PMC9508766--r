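#' @importFrom rlang abort warn %||%
#' @importFrom stats plogis qnorm quantile rnorm runif rbinom sd var
#' @importFrom utils head
NULL

# Row-wise log-sum-exp for an n x K matrix of log-densities.
logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

# Derive `n` child seeds from one master seed, all below 2^31.
derive_seeds <- function(master, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(master %% 2147483646L))
  sample.int(2147483646L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483646L))
  expr
}

# All permutations of 1..k in lexicographic order, one per row.
perms_lex <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}
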