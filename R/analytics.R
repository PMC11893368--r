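# Cohort-level summaries and the reconstructed test statistics.
#
# The published per-group significance marks are reproducible as exact
# two-sided binomial (sign) tests of contributed-vs-not against 1/2, and
# the overall comparison as an uncorrected Pearson chi-square on the 4x2
# contributed-by-group table. That construction is an inference from the
# printed p-values, not a procedure stated by the source study; both
# tests are implemented here and documented as such in the vignette.

#' Round half-to-even at a number of decimal places
#'
#' Display rounding used throughout the summaries (so 71.25 renders as
#' 71.2), robust to floating-point representation of the half-way cases.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_even <- function(x, digits = 0) {
  s <- 10^digits
  y <- x * s
  f <- floor(y)
  r <- y - f
  up <- r > 0.5 + 1e-9 | (abs(r - 0.5) <= 1e-9 & f %% 2 == 1)
  (f + as.numeric(up)) / s
}

#' Summarise HLA contribution per group and overall
#'
#' Tallies decisions by study group and outcome, and computes the
#' fraction of records where HLA typing contributed a conclusive
#' decision. Per-group percentages are displayed rounded to the nearest
#' integer; the overall percentage to one decimal, half-to-even. Raw
#' fractions are retained.
#'
#' @param decisions Data frame from [evaluate_cohort()].
#' @return A list of class `cohort_summary`: `per_group` (data frame with
#'   `group`, `contributed`, `n`, `percent`, `percent_display`), `overall`
#'   (same fields over Groups 1-4), and `tallies` (group x outcome count
#'   table). Groups with no records are reported as absent rather than
#'   with an undefined percentage.
#' @export
contribution_summary <- function(decisions) {
  stopifnot(is.data.frame(decisions),
            all(c("group", "outcome", "hla_contributed") %in% names(decisions)))
  eligible <- decisions[decisions$group %in% c("G1", "G2", "G3", "G4"), ]
  groups <- c("G1", "G2", "G3", "G4")
  per <- do.call(rbind, lapply(groups, function(g) {
    d <- eligible[eligible$group == g, ]
    if (nrow(d) == 0L) return(NULL)
    k <- sum(d$hla_contributed)
    data.frame(group = g, contributed = k, n = nrow(d),
               percent = 100 * k / nrow(d),
               percent_display = round_half_even(100 * k / nrow(d)),
               stringsAsFactors = FALSE)
  }))
  k <- sum(eligible$hla_contributed)
  n <- nrow(eligible)
  overall <- list(contributed = k, n = n,
                  percent = if (n > 0) 100 * k / n else NA_real_,
                  percent_display = if (n > 0)
                    round_half_even(100 * k / n, 1) else NA_real_)
  tallies <- table(group = factor(eligible$group, levels = groups),
                   outcome = factor(eligible$outcome, levels = OUTCOMES))
  structure(list(per_group = per, overall = overall, tallies = tallies),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("HLA contribution to diagnostic decisions\n")
  if (!is.null(x$per_group)) {
    for (i in seq_len(nrow(x$per_group))) {
      r <- x$per_group[i, ]
      cat(sprintf("  %s: %d/%d (%d%%)\n", r$group, r$contributed, r$n,
                  as.integer(r$percent_display)))
    }
  }
  cat(sprintf("  overall: %d/%d (%.1f%%)\n", x$overall$contributed,
              x$overall$n, x$overall$percent_display))
  invisible(x)
}

#' Exact two-sided binomial sign test against one half
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with
#' `X ~ Binomial(n, 1/2)`, computed from the exact binomial distribution.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @return A list of class `dq_test`: `statistic` (k), `n`, `df` (`NA`),
#'   `p`, `method`.
#' @examples
#' sign_test(7, 18)   # p = 0.481
#' sign_test(14, 14)  # p = 2 * 0.5^14
#' @export
sign_test <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, is.finite(k), is.finite(n))
  if (n < 1) stop("sign test requires n >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (k != round(k) || n != round(n)) stop("k and n must be integers")
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  structure(list(statistic = k, n = n, df = NA_real_, p = p,
                 method = "sign_test"), class = "dq_test")
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the row/column margins; `df = (r - 1)(c - 1)`; p-value
#' from the chi-square upper tail.
#'
#' @param table Numeric matrix of non-negative counts with positive row
#'   and column sums.
#' @return A list of class `dq_test`: `statistic`, `n` (total count),
#'   `df`, `p`, `method`.
#' @export
chi_square_independence <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("counts must be finite and non-negative")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0))
    stop(sprintf("zero margin in row %d", which(rs == 0)[1]))
  if (any(cs == 0))
    stop(sprintf("zero margin in column %d", which(cs == 0)[1]))
  e <- outer(rs, cs) / sum(x)
  stat <- sum((x - e)^2 / e)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  structure(list(statistic = stat, n = sum(x), df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "chi_square"), class = "dq_test")
}

#' @export
print.dq_test <- function(x, ...) {
  if (x$method == "sign_test") {
    cat(sprintf("Exact binomial sign test: k = %d, n = %d, p = %.4g\n",
                x$statistic, x$n, x$p))
  } else {
    cat(sprintf("Pearson chi-square: X2 = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p))
  }
  invisible(x)
}

#' HLA risk-category distribution by study group
#'
#' Counts of each risk category per group, with a `Total` column and a
#' `CeD` column counting records whose outcome was a celiac diagnosis.
#'
#' @param cohort Cohort data frame.
#' @param decisions Matching decisions from [evaluate_cohort()].
#' @return Integer matrix: one row per risk category, columns
#'   `G1 G2 G3 G4 Total CeD`.
#' @export
allele_distribution <- function(cohort, decisions) {
  stopifnot(nrow(cohort) == nrow(decisions))
  cats <- factor(decisions$risk_category, levels = RISK_CATEGORY_LABELS)
  grp <- factor(decisions$group, levels = c("G1", "G2", "G3", "G4"))
  m <- table(cats, grp)
  ced <- table(cats[decisions$outcome == "ced"])
  out <- cbind(unclass(m), Total = rowSums(m),
               CeD = as.integer(ced[RISK_CATEGORY_LABELS]))
  out[is.na(out)] <- 0L
  rownames(out) <- RISK_CATEGORY_LABELS
  out
}

# Plain-text rendering of the allele-distribution matrix.
format_allele_table <- function(mat, group_n = NULL) {
  hdr <- colnames(mat)
  if (!is.null(group_n))
    hdr[seq_along(group_n)] <- sprintf("%s (n=%d)", hdr[seq_along(group_n)],
                                       group_n)
  w <- max(nchar(rownames(mat)), 11L)
  lines <- sprintf("%-*s  %s", w, "", paste(sprintf("%11s", hdr),
                                            collapse = " "))
  for (i in seq_len(nrow(mat))) {
    lines <- c(lines, sprintf("%-*s  %s", w, rownames(mat)[i],
                              paste(sprintf("%11d", mat[i, ]),
                                    collapse = " ")))
  }
  paste(lines, collapse = "\n")
}
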