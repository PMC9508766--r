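#' Validate a subject table against its column roles
#'
#' Checks that every role-named column exists, the treatment is strictly
#' 0/1, no used column contains missing values, and every indicator shows at
#' least two observed levels.
#'
#' @param data A data frame.
#' @param roles A [subject_roles()] object.
#' @return `data` invisibly (as a tibble), if valid.
#' @export
validate_subjects <- function(data, roles) {
  stopifnot(inherits(roles, "subject_roles"))
  used <- c(roles$treatment, roles$outcome, roles$indicators, roles$adjusters)
  missing_cols <- setdiff(c(used, roles$id), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns named in roles are absent from the data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "latentsens_schema_error")
  }
  if (nrow(data) < 1L) {
    abort("no rows in the subject table", class = "latentsens_empty_error")
  }
  if (anyNA(data[used])) {
    abort("missing values remain in used columns; apply complete-case filtering first",
          class = "latentsens_validation_error")
  }
  z <- data[[roles$treatment]]
  if (!all(z %in% c(0, 1))) {
    abort(sprintf("treatment column '%s' contains values outside {0, 1}",
                  roles$treatment),
          class = "latentsens_validation_error")
  }
  for (col in roles$indicators) {
    if (length(unique(data[[col]])) < 2L) {
      abort(sprintf("indicator '%s' has fewer than 2 observed levels", col),
            class = "latentsens_validation_error")
    }
  }
  invisible(tibble::as_tibble(data))
}

#' Read a subject table from CSV with complete-case filtering
#'
#' Rows with a missing value in any used column (treatment, outcome,
#' indicators, adjusters) are dropped, matching a complete-case analysis;
#' the number of dropped rows is recorded in the `"dropped_count"` attribute
#' and messaged when nonzero.
#'
#' @param path Path to a CSV file with a header row.
#' @param roles A [subject_roles()] object naming the columns.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of surviving rows (used columns plus the id column when
#'   declared), with attribute `dropped_count`.
#' @export
read_subjects <- function(path, roles, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "latentsens_schema_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  used <- c(roles$treatment, roles$outcome, roles$indicators, roles$adjusters)
  missing_cols <- setdiff(c(used, roles$id), names(raw))
  if (length(missing_cols)) {
    abort(paste0("columns named in roles are absent from the CSV header: ",
                 paste(missing_cols, collapse = ", ")),
          class = "latentsens_schema_error")
  }
  keep <- stats::complete.cases(raw[used])
  dropped <- sum(!keep)
  out <- raw[keep, c(roles$id, used), drop = FALSE]
  if (nrow(out) == 0L) {
    abort("no rows survive complete-case filtering",
          class = "latentsens_empty_error")
  }
  if (dropped > 0L && !quiet) {
    message(sprintf("dropped %d of %d rows with missing values (complete-case)",
                    dropped, nrow(raw)))
  }
  out <- validate_subjects(out, roles)
  attr(out, "dropped_count") <- dropped
  out
}

#' Write a subject table to CSV
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Discretize a continuous variable into empirical quantile bins
#'
#' Bins values into `q` groups at the empirical `k/q` quantiles using rank
#' arithmetic: a value with (min-tie) rank `r` among `n` gets label
#' `ceiling(r * q / n)`, so tied values share the lower bin and labels are a
#' weakly increasing function of the values.
#'
#' @param values Numeric vector.
#' @param q Number of bins (default 5, sample quintiles).
#' @return Integer vector of bin labels in `1..q`. A constant input returns
#'   all-1 labels with a `latentsens_single_bin` warning; heavily tied input
#'   that fills fewer than `q` bins triggers a `latentsens_merged_bins`
#'   warning reporting the achieved bin count.
#' @export
discretize_quantiles <- function(values, q = 5L) {
  stopifnot(q >= 2L, is.numeric(values), length(values) >= 1L)
  if (anyNA(values)) {
    abort("missing values in input to discretize_quantiles",
          class = "latentsens_validation_error")
  }
  n <- length(values)
  if (length(unique(values)) == 1L) {
    warn("constant input: all values assigned to bin 1",
         class = "latentsens_single_bin")
    return(rep(1L, n))
  }
  r <- rank(values, ties.method = "min")
  labels <- as.integer(ceiling(r * q / n))
  achieved <- length(unique(labels))
  if (achieved < q) {
    warn(sprintf("ties merged bins: %d of %d bins realized", achieved, q),
         class = "latentsens_merged_bins")
  }
  labels
}

#' Profile the latent classes on the manifest indicators
#'
#' For each indicator, reports the mean value within each modal class (the
#' probability for a 0/1 indicator, the average bin index for a discretized
#' one) together with the p-value of a chi-squared test of the
#' class-by-indicator frequency table. Estimated class proportions (column
#' means of the membership probabilities) are appended as a final row.
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param memberships A membership object from [posterior_memberships()].
#' @return A tibble with columns `indicator`, `class_1..class_K` and
#'   `p_value`. Classes without modal members get `NA` means and are named
#'   in the `"undefined_classes"` attribute.
#' @export
class_profile <- function(data, roles, memberships) {
  stopifnot(inherits(memberships, "lcs_membership"))
  if (nrow(memberships$lambda) != nrow(data)) {
    abort("memberships and data have different row counts",
          class = "latentsens_validation_error")
  }
  K <- ncol(memberships$lambda)
  modal <- memberships$modal
  empty <- setdiff(seq_len(K), unique(modal))
  rows <- purrr::map(roles$indicators, function(col) {
    v <- data[[col]]
    vn <- if (is.numeric(v)) v else as.numeric(as.factor(v))
    means <- vapply(seq_len(K), function(k) {
      if (k %in% empty) NA_real_ else mean(vn[modal == k])
    }, numeric(1))
    pv <- tryCatch(
      suppressWarnings(stats::chisq.test(table(modal, v))$p.value),
      error = function(e) NA_real_
    )
    tibble::tibble(indicator = col,
                   !!!stats::setNames(as.list(means), paste0("class_", seq_len(K))),
                   p_value = pv)
  })
  props <- colMeans(memberships$lambda)
  prop_row <- tibble::tibble(
    indicator = "Class proportion",
    !!!stats::setNames(as.list(unname(props)), paste0("class_", seq_len(K))),
    p_value = NA_real_
  )
  out <- dplyr::bind_rows(rows, prop_row)
  attr(out, "undefined_classes") <- empty
  out
}
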