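# Contingency-table tests for differences in adverse-event counts between
# strata: Pearson chi-squared (no continuity correction) or, for sparse 2x2
# tables, a two-sided Fisher exact test. Two-tailed throughout.

as_contingency <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) < 2 || any(m < 0) || any(!is.finite(m))) {
    abort("Contingency table must be r x 2 (r >= 2) with non-negative cells",
      class = "otosignal_table_error"
    )
  }
  m
}

#' Choose between chi-squared and Fisher's exact test
#'
#' The conventional Cochran criterion: Fisher's exact test when the table is
#' 2x2 and any expected cell count is below 5; Pearson chi-squared otherwise.
#' Larger tables with small expected cells keep the chi-squared test and emit
#' a warning.
#'
#' @param table r x 2 matrix of non-negative counts (rows = strata, columns
#'   = event vs non-event).
#' @return `"FISHER_EXACT"` or `"CHI_SQUARED"`.
#' @export
choose_test_method <- function(table) {
  m <- as_contingency(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  small <- any(expected < 5)
  if (small && nrow(m) == 2) {
    return("FISHER_EXACT")
  }
  if (small) {
    warn("Expected cell count < 5 in an r x 2 table; chi-squared approximation may be poor")
  }
  "CHI_SQUARED"
}

#' Pearson chi-squared test on an r x 2 table
#'
#' No Yates continuity correction; statistic `sum((O-E)^2/E)`,
#' `df = (r-1)(c-1)`, upper-tail p-value.
#'
#' @inheritParams choose_test_method
#' @return List with `method`, `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(table) {
  m <- as_contingency(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate contingency table: zero marginal",
      class = "otosignal_table_error"
    )
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(
    method = "CHI_SQUARED",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities, over all tables with the observed
#' margins, of every table whose probability does not exceed that of the
#' observed table (the two-sided convention of the probability-ordering
#' rule). Implemented by direct enumeration over the hypergeometric support.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `method`, `statistic` (`NA`), `df` (`NA`), `p_value`.
#' @export
fisher_exact_test <- function(table) {
  m <- as_contingency(table)
  if (nrow(m) != 2) {
    abort("Fisher's exact test requires a 2x2 table",
      class = "otosignal_table_error"
    )
  }
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  # tiny relative slack guards against floating-point ties in the ordering
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(method = "FISHER_EXACT", statistic = NA_real_, df = NA_real_, p_value = p)
}

#' Test stratum differences for one adverse-event group
#'
#' Builds the r x 2 event / non-event table from per-stratum event counts
#' and stratum sample sizes, picks the test with [choose_test_method()], and
#' runs it. Degenerate tables (no events anywhere, or a zero stratum) yield
#' an `NA` p-value rather than an error, so sparse groups print blank.
#'
#' @param counts Integer vector of event counts per stratum level.
#' @param persons Stratum sample sizes (same length).
#' @return List with `method`, `statistic`, `df`, `p_value`.
#' @export
stratum_test <- function(counts, persons) {
  stopifnot(length(counts) == length(persons))
  if (any(counts > persons)) {
    abort("Event count exceeds stratum sample size",
      class = "otosignal_table_error"
    )
  }
  m <- cbind(event = counts, nonevent = persons - counts)
  if (length(counts) < 2 || sum(counts) == 0 || any(persons == 0)) {
    return(list(
      method = NA_character_, statistic = NA_real_, df = NA_real_,
      p_value = NA_real_
    ))
  }
  method <- suppressWarnings(choose_test_method(m))
  if (method == "FISHER_EXACT") fisher_exact_test(m) else chi_squared_test(m)
}
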