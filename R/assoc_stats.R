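#' @importFrom stats chisq.test fisher.test pnorm setNames
NULL

EXPECTED_COUNT_RULE <- 5  # classical chi-square requires expected counts > 5

new_test_result <- function(method, statistic, df, p_value, valid, notes = "") {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, valid = valid,
                 significant = p_value <= 0.05, notes = notes),
            class = "f8_test")
}

#' @export
print.f8_test <- function(x, ...) {
  cat(x$method, ": statistic = ",
      if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p_value, digits = 3),
      if (!x$valid) "  [expected-count rule violated]",
      "\n", sep = "")
  if (nzchar(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Collect test results into a data.frame
#'
#' @param results list of `f8_test` objects (optionally named).
#' @return data.frame with one row per test: method, statistic, df,
#'   p_value, valid, significant, notes.
#' @export
tests_to_frame <- function(results) {
  if (inherits(results, "f8_test")) results <- list(results)
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, statistic = r$statistic, df = r$df,
               p_value = r$p_value, valid = r$valid,
               significant = r$significant, notes = r$notes,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(names(results))) out <- cbind(test = names(results), out)
  rownames(out) <- NULL
  out
}

#' Build a contingency table from two cohort factors
#'
#' Cross-tabulates two annotation columns. Records whose value in either
#' factor is `"unknown"`, `"undetermined"` or `NA` are dropped and the
#' number dropped recorded in the `dropped` attribute. A factor left
#' with a single level cannot support a test and raises an error.
#'
#' @param cohort a `f8_cohort` (usually annotated).
#' @param row_factor,col_factor column names.
#' @return Integer matrix of class `f8_contingency` with labelled
#'   dimnames and a `dropped` attribute.
#' @export
build_contingency <- function(cohort, row_factor, col_factor) {
  stopifnot(inherits(cohort, "f8_cohort"),
            row_factor %in% names(cohort), col_factor %in% names(cohort))
  r <- as.character(cohort[[row_factor]])
  c_ <- as.character(cohort[[col_factor]])
  drop <- is.na(r) | is.na(c_) | r %in% c("unknown", "undetermined") |
    c_ %in% c("unknown", "undetermined")
  r <- r[!drop]; c_ <- c_[!drop]
  if (length(unique(r)) < 2L) {
    stop("factor '", row_factor, "' has fewer than two levels after dropping ",
         "unknown/undetermined records")
  }
  if (length(unique(c_)) < 2L) {
    stop("factor '", col_factor, "' has fewer than two levels after dropping ",
         "unknown/undetermined records")
  }
  tab <- table(r, c_, dnn = c(row_factor, col_factor))
  out <- unclass(as.matrix(tab))
  class(out) <- c("f8_contingency", class(out))
  attr(out, "dropped") <- sum(drop)
  out
}

expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic on an r x c table with expected counts from the
#' margins; df = (r-1)(c-1). Classical chi-square evaluation requires
#' every expected count to exceed 5; the result carries a `valid` flag
#' for that rule rather than silently switching tests. Significance is
#' flagged at p <= 0.05.
#'
#' @param tab matrix of non-negative counts (r, c >= 2).
#' @param yates apply Yates' continuity correction (2x2 only).
#' @return A `f8_test` result.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(unclass(tab))
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal total: remove empty rows/columns first")
  }
  exp <- expected_counts(tab)
  res <- suppressWarnings(chisq.test(tab, correct = yates))
  valid <- all(exp > EXPECTED_COUNT_RULE)
  new_test_result(
    method = if (yates) "chi_square_yates" else "chi_square",
    statistic = unname(res$statistic), df = as.integer(res$parameter),
    p_value = res$p.value, valid = valid,
    notes = if (valid) "" else
      "expected count <= 5 in at least one cell; consider fisher_exact")
}

#' Goodness-of-fit chi-square test
#'
#' Tests observed counts against stated expected proportions;
#' df = k - 1. The same expected-count validity rule applies.
#'
#' @param observed non-negative integer vector, length >= 2.
#' @param expected_probs probabilities summing to 1, all positive.
#' @return A `f8_test` result.
#' @export
gof_chi_square <- function(observed, expected_probs) {
  if (length(observed) != length(expected_probs) || length(observed) < 2L) {
    stop("observed and expected_probs must have equal length >= 2")
  }
  if (any(observed < 0)) stop("counts must be non-negative")
  if (abs(sum(expected_probs) - 1) > 1e-8) stop("expected_probs must sum to 1")
  if (any(expected_probs <= 0)) stop("expected cell probability of zero")
  exp <- sum(observed) * expected_probs
  res <- suppressWarnings(chisq.test(observed, p = expected_probs))
  valid <- all(exp > EXPECTED_COUNT_RULE)
  new_test_result("chi_square_gof", unname(res$statistic),
                  as.integer(res$parameter), res$p.value, valid,
                  notes = if (valid) "" else "expected count <= 5")
}

#' Two-proportion z test (normal approximation)
#'
#' Pooled-variance z statistic for comparing two binomial proportions,
#' with a two-sided p from the normal tail; an optional continuity
#' correction shrinks the observed difference by (1/n1 + 1/n2)/2.
#' For balanced 2x2 tables z^2 equals the uncorrected Pearson
#' chi-square statistic algebraically.
#'
#' @param x1,n1,x2,n2 successes and trials per group.
#' @param continuity apply the continuity correction.
#' @return A `f8_test` result (statistic is z; df is `NA`).
#' @export
two_proportion_normal_test <- function(x1, n1, x2, n2, continuity = FALSE) {
  if (n1 < 1 || n2 < 1) stop("both group sizes must be at least 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n in both groups")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(new_test_result("two_proportion_normal", 0, NA_integer_, 1, FALSE,
                           notes = "degenerate pooled proportion"))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (continuity) {
    cc <- (1 / n1 + 1 / n2) / 2
    diff <- sign(diff) * max(abs(diff) - cc, 0)
  }
  z <- diff / se
  exp_ok <- all(c(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp)) >
                EXPECTED_COUNT_RULE)
  new_test_result(
    if (continuity) "two_proportion_normal_cc" else "two_proportion_normal",
    z, NA_integer_, 2 * pnorm(-abs(z)), exp_ok,
    notes = if (exp_ok) "" else "expected count <= 5 under pooled proportion")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration; the recommended
#' fallback when the chi-square expected-count rule fails.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A `f8_test` result (statistic and df are `NA`; always valid).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(unclass(tab))
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact requires a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  res <- fisher.test(tab)
  new_test_result("fisher_exact", NA_real_, NA_integer_, res$p.value, TRUE)
}
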