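# Stratified report counts, percentage shares, and crude incidence rates
# per 100,000 vaccinated persons.

#' Crude incidence rate per 100,000 persons
#'
#' @param count Report count (non-negative).
#' @param denominator Vaccinated-person denominator (> 0).
#' @return `count / denominator * 1e5`, at full precision (display rounding
#'   to 3 decimals happens in [write_result_table()]).
#' @export
#' @examples
#' incidence_rate(106653, 226593618) # 47.068 per 100,000
incidence_rate <- function(count, denominator) {
  if (any(is.na(denominator)) || any(denominator <= 0)) {
    abort("Missing or non-positive denominator in incidence_rate()",
      class = "otosignal_missing_denominator"
    )
  }
  count / denominator * 1e5
}

#' Percentage share of a total
#'
#' @param count Numerator count.
#' @param total Total (> 0).
#' @return `count / total * 100` at full precision.
#' @export
percent_share <- function(count, total) {
  if (any(is.na(total)) || any(total == 0)) {
    abort("Undefined percentage share: total is zero or missing",
      class = "otosignal_undefined_share"
    )
  }
  count / total * 100
}

axis_level <- function(grouped, axis) {
  switch(axis,
    TOTAL = rep("ALL", nrow(grouped)),
    SEX = if_else(grouped$sex %in% c("M", "F"), grouped$sex, "UNKNOWN"),
    AGE = age_band(grouped$age_years),
    MANUFACTURER = if_else(
      grouped$manufacturer %in% c("PFIZER_BIONTECH", "MODERNA", "JANSSEN"),
      grouped$manufacturer, "UNKNOWN"
    ),
    abort(sprintf("Unknown stratum axis '%s'", axis))
  )
}

axis_levels <- function(axis) {
  switch(axis,
    TOTAL = "ALL",
    SEX = c("M", "F"),
    AGE = age_band_labels(),
    MANUFACTURER = c("PFIZER_BIONTECH", "MODERNA", "JANSSEN")
  )
}

#' Count grouped reports per (group, stratum level)
#'
#' A report adds 1 to each group it maps to and 1 to the pseudo-group
#' `"ANY"`; reports with an UNKNOWN value on the requested axis are excluded
#' from level rows but still counted in the `"TOTAL"` level.
#'
#' @param grouped Grouped-report tibble (see [select_otolaryngologic()]).
#' @param series Dose series to count (`"CPS"` or `"UBB"`); `NULL` counts all.
#' @param axis One of `"TOTAL"`, `"SEX"`, `"AGE"`, `"MANUFACTURER"`.
#' @param group_names Group universe for zero-filling (default: groups
#'   observed in the data).
#' @return Tibble `(group, level, count)` covering every group (plus ANY)
#'   at every axis level plus the `"TOTAL"` level.
#' @export
count_reports <- function(grouped, series = NULL, axis = "TOTAL",
                          group_names = NULL) {
  if (!is.null(series)) {
    grouped <- grouped %>% filter(.data$dose_series == !!series)
  }
  grouped <- grouped %>% filter(lengths(.data$groups) > 0)
  group_names <- group_names %||%
    sort(unique(unlist(grouped$groups)))
  levels_out <- axis_levels(axis)

  if (nrow(grouped) == 0) {
    return(tidyr::expand_grid(
      group = c(group_names, ANY_GROUP),
      level = unique(c(levels_out, "TOTAL"))
    ) %>% mutate(count = 0L))
  }

  long <- tibble(
    level = rep(axis_level(grouped, axis), lengths(grouped$groups)),
    group = unlist(grouped$groups)
  ) %>%
    bind_rows(tibble(level = axis_level(grouped, axis), group = ANY_GROUP))

  per_level <- long %>%
    filter(.data$level != "UNKNOWN") %>%
    count(.data$group, .data$level, name = "count")
  totals <- long %>% count(.data$group, name = "count") %>% mutate(level = "TOTAL")

  bind_rows(per_level, totals) %>%
    tidyr::complete(
      group = c(group_names, ANY_GROUP),
      level = unique(c(levels_out, "TOTAL")),
      fill = list(count = 0L)
    ) %>%
    mutate(count = as.integer(.data$count)) %>%
    arrange(.data$group != ANY_GROUP, .data$group, .data$level)
}

#' Build a stratified incidence table
#'
#' For each requested axis, reports of the given dose series are counted per
#' (group, level); each cell carries its percentage share of the level's
#' total otolaryngologic reports (the ANY count) and its incidence rate per
#' 100,000 against the matching population denominator. For the
#' `MANUFACTURER` axis of the `CPS` series, denominators come from the
#' at-least-one-dose (`ALOD`) population while counts stay series-scoped —
#' the published tracker does not break completed primary series down by
#' manufacturer. Manufacturer levels are restricted to those present in the
#' denominator table (the bivalent booster has no Janssen population).
#'
#' A Pearson chi-squared or Fisher's exact test (see [choose_test_method()])
#' compares event proportions across the axis levels for every group; its
#' p-value is attached to the group's rows.
#'
#' @param grouped Grouped-report tibble.
#' @param denominators A `denominator_table`.
#' @param series `"CPS"` or `"UBB"`.
#' @param axes Character vector of stratum axes (default sex, age,
#'   manufacturer).
#' @param group_names Group universe (default [aefi_group_names()]).
#' @param with_tests Attach association-test p-values (default TRUE).
#' @return Tibble `(group, series, axis, level, count, pct, ir_per_100k,
#'   p_value)`, one row per group x axis level plus a TOTAL row per group.
#' @export
build_incidence_table <- function(grouped, denominators, series,
                                  axes = c("SEX", "AGE", "MANUFACTURER"),
                                  group_names = aefi_group_names(),
                                  with_tests = TRUE) {
  denom_series <- function(axis) {
    if (axis == "MANUFACTURER" && series == "CPS") "ALOD" else series
  }
  purrr::map(unique(c("TOTAL", axes)), function(axis) {
    ds <- denom_series(axis)
    lv <- axis_levels(axis)
    if (axis == "MANUFACTURER") {
      avail <- denominators %>%
        filter(.data$series == ds, .data$axis == "MANUFACTURER") %>%
        pull(.data$level)
      lv <- intersect(lv, avail)
      if (length(lv) == 0) {
        abort(
          sprintf("Missing denominator for stratum (%s, MANUFACTURER, *)", ds),
          class = "otosignal_missing_denominator"
        )
      }
    }
    counts <- count_reports(grouped, series, axis, group_names) %>%
      filter(.data$level %in% lv)
    counts$persons <- purrr::map_dbl(
      counts$level,
      ~ denominator_for(
        denominators,
        if (.x == "ALL") series else ds,
        if (.x == "ALL") "TOTAL" else axis,
        .x
      )
    )
    any_totals <- counts %>%
      filter(.data$group == ANY_GROUP) %>%
      select("level", any_count = "count")
    tab <- counts %>%
      left_join(any_totals, by = "level") %>%
      mutate(
        pct = if_else(
          .data$group == ANY_GROUP | .data$any_count == 0,
          NA_real_, .data$count / .data$any_count * 100
        ),
        ir_per_100k = incidence_rate(.data$count, .data$persons),
        series = series, axis = axis
      ) %>%
      select(
        "group", "series", "axis", "level", "count", "pct", "ir_per_100k",
        "persons"
      )
    if (with_tests && axis != "TOTAL" && length(lv) >= 2) {
      pvals <- tab %>%
        group_by(.data$group) %>%
        summarise(
          p_value = stratum_test(.data$count, .data$persons)$p_value,
          .groups = "drop"
        )
      tab <- tab %>% left_join(pvals, by = "group")
    } else {
      tab$p_value <- NA_real_
    }
    tab
  }) %>%
    bind_rows() %>%
    select(-"persons") %>%
    arrange(
      .data$axis != "TOTAL", .data$axis,
      .data$group == ANY_GROUP,
      match(.data$group, c(group_names, ANY_GROUP))
    )
}
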