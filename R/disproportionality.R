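# Proportional reporting ratio (PRR) signal screening against a background
# reporting corpus.
#
# For a specific adverse-event group:
#   m = reports of the group for the index vaccine
#   n = total adverse-event reports for the index vaccine
#   M = reports of the group across the entire database (index + background)
#   N = total adverse-event reports across the entire database
# PRR = (m/n) / ((M - m)/(N - n)), the index reporting proportion over the
# background reporting proportion.

validate_prr_counts <- function(m, n, M, N) {
  ok <- m >= 0 & m <= n & m <= M & n <= N & M <= N
  if (any(!ok)) {
    abort("Invalid PRR counts: need 0 <= m <= n, m <= M, n <= N, M <= N",
      class = "otosignal_prr_error"
    )
  }
}

#' Proportional reporting ratio
#'
#' @param m,n,M,N Report counts (see the module description); `N` and `M`
#'   span the entire database, so the background proportion uses `M - m`
#'   and `N - n`.
#' @param continuity Add 0.5 to all four derived contingency cells (for
#'   zero-background groups); off by default.
#' @return The PRR at full precision. `m = 0` returns 0 (with a note);
#'   `M - m = 0` without continuity correction is an error.
#' @export
#' @examples
#' prr(10, 100, 20, 300) # 2
prr <- function(m, n, M, N, continuity = FALSE) {
  validate_prr_counts(m, n, M, N)
  if (continuity) {
    a <- m + 0.5
    b <- n - m + 0.5
    c <- M - m + 0.5
    d <- (N - n) - (M - m) + 0.5
    return((a / (a + b)) / (c / (c + d)))
  }
  if (any(N - n <= 0)) {
    abort("Empty background: N - n must be positive",
      class = "otosignal_prr_error"
    )
  }
  if (any(M - m == 0)) {
    abort("Background count M - m is zero; enable `continuity` or drop the group",
      class = "otosignal_prr_error"
    )
  }
  out <- (m / n) / ((M - m) / (N - n))
  if (any(m == 0)) {
    inform("PRR is 0 for group(s) with m = 0 index reports")
  }
  out
}

#' Log-normal confidence interval for the PRR
#'
#' `exp(log PRR +/- z * se)` with the delta-method standard error of
#' `log PRR`, `se = sqrt(1/m - 1/n + 1/(M-m) - 1/(N-n))`.
#'
#' @inheritParams prr
#' @param alpha Two-sided level (default 0.05 for a 95% interval).
#' @return Tibble with columns `ci_low`, `ci_high`, `se_log`; `NA` rows
#'   where `m = 0` or `M - m = 0` (interval undefined).
#' @export
prr_ci <- function(m, n, M, N, alpha = 0.05) {
  validate_prr_counts(m, n, M, N)
  z <- qnorm(1 - alpha / 2)
  defined <- m > 0 & (M - m) > 0 & (N - n) > 0
  se <- ifelse(defined, sqrt(1 / m - 1 / n + 1 / (M - m) - 1 / (N - n)), NA_real_)
  est <- ifelse(defined, (m / n) / ((M - m) / (N - n)), NA_real_)
  tibble(
    ci_low = est * exp(-z * se),
    ci_high = est * exp(z * se),
    se_log = se
  )
}

group_counts <- function(x, group_names = NULL) {
  if (is.data.frame(x) && "groups" %in% names(x)) {
    # n / N span ALL adverse-event reports for the corpus, mapped or not
    total <- nrow(x)
    x <- x %>% filter(lengths(.data$groups) > 0)
    counts <- tibble(group = unlist(x$groups)) %>% count(.data$group, name = "count")
  } else if (is.data.frame(x) && all(c("group", "count") %in% names(x))) {
    counts <- x %>%
      filter(.data$group != ANY_GROUP) %>%
      select("group", "count")
    any_row <- x %>% filter(.data$group == ANY_GROUP)
    total <- if (nrow(any_row) > 0) sum(any_row$count) else sum(counts$count)
  } else {
    abort("Expected a grouped-report tibble or a (group, count) table",
      class = "otosignal_prr_error"
    )
  }
  if (!is.null(group_names)) {
    counts <- counts %>%
      tidyr::complete(group = group_names, fill = list(count = 0L)) %>%
      filter(.data$group %in% group_names)
  }
  list(counts = counts, total = total)
}

#' PRR screen of every adverse-event group
#'
#' Computes one PRR, confidence interval, and signal flag per group for an
#' index corpus against a background corpus. Inputs may be grouped-report
#' tibbles with a `groups` list-column (pass the FULL corpus from
#' [assign_groups()], not just mapped reports: the totals `n` and `N` count
#' every adverse-event report in each corpus) or pre-tabulated
#' `(group, count)` tables (include an `"ANY"` row carrying the corpus
#' report total; otherwise the group counts are summed, which overcounts
#' multi-group reports).
#'
#' @param index,background Index-vaccine and background corpora.
#' @param group_names Group universe (default: groups present in either
#'   corpus).
#' @param threshold Signal threshold on the PRR point estimate (default 2).
#' @param alpha Confidence level parameter for the interval (default 0.05).
#' @param continuity Zero-cell continuity correction (default off).
#' @param classical_criteria Also require `m >= 3` and the 2x2 chi-squared
#'   statistic `>= 4` for a signal (the classical Evans rule); off by
#'   default, the bare threshold matching common practice for vaccine AEFI
#'   screens.
#' @return Tibble of class `prr_table`: `group`, `m`, `n`, `M`, `N`, `prr`,
#'   `se_log`, `ci_low`, `ci_high`, `signal`. Groups with `m = 0` carry
#'   `prr = 0` and `NA` intervals; the pseudo-group ANY is excluded.
#' @export
prr_table <- function(index, background, group_names = NULL, threshold = 2,
                      alpha = 0.05, continuity = FALSE,
                      classical_criteria = FALSE) {
  stopifnot(threshold > 0, alpha > 0, alpha < 1)
  idx <- group_counts(index, group_names)
  bkg <- group_counts(background, group_names)
  if (bkg$total == 0) {
    abort("Background corpus is empty", class = "otosignal_prr_error")
  }
  group_names <- group_names %||%
    sort(union(idx$counts$group, bkg$counts$group))
  idx <- group_counts(index, group_names)
  bkg <- group_counts(background, group_names)

  tab <- idx$counts %>%
    rename(m = "count") %>%
    left_join(bkg$counts %>% rename(bg = "count"), by = "group") %>%
    mutate(
      n = idx$total,
      M = .data$m + .data$bg,
      N = idx$total + bkg$total
    ) %>%
    filter(.data$group != ANY_GROUP)

  est <- purrr::pmap_dbl(
    tab[c("m", "n", "M", "N")],
    function(m, n, M, N) {
      if (m == 0) {
        return(0)
      }
      if (M - m == 0 && !continuity) {
        return(NA_real_)
      }
      prr(m, n, M, N, continuity = continuity)
    }
  )
  ci <- prr_ci(tab$m, tab$n, tab$M, tab$N, alpha = alpha)
  out <- tab %>%
    mutate(
      prr = est,
      se_log = ci$se_log, ci_low = ci$ci_low, ci_high = ci$ci_high,
      signal = !is.na(.data$prr) & .data$prr >= threshold
    ) %>%
    select("group", "m", "n", "M", "N", "prr", "se_log", "ci_low", "ci_high", "signal")
  if (classical_criteria) {
    chi4 <- purrr::pmap_lgl(
      out[c("m", "n", "M", "N")],
      function(m, n, M, N) {
        tb <- rbind(c(m, n - m), c(M - m, (N - n) - (M - m)))
        if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
          return(FALSE)
        }
        chi_squared_test(tb)$statistic >= 4
      }
    )
    out$signal <- out$signal & out$m >= 3 & chi4
  }
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("prr_table", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.prr_table <- function(x, ...) {
  as_tibble(x) %>%
    select("group",
      estimate = "prr", std.error = "se_log",
      conf.low = "ci_low", conf.high = "ci_high", "signal"
    )
}

#' @exportS3Method generics::glance
glance.prr_table <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_signals = sum(x$signal, na.rm = TRUE),
    n_index_reports = if (nrow(x) > 0) x$n[1] else NA_integer_,
    n_database_reports = if (nrow(x) > 0) x$N[1] else NA_integer_,
    threshold = attr(x, "threshold") %||% 2,
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @export
print.prr_table <- function(x, ...) {
  cat(sprintf(
    "<prr_table> %d groups, %d signal(s) at PRR >= %s\n",
    nrow(x), sum(x$signal, na.rm = TRUE),
    format(attr(x, "threshold") %||% 2)
  ))
  NextMethod()
}
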