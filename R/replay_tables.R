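# Desk-scale replay fixture: the published per-group report counts and
# vaccinated-population sample sizes, typed in from the source tables, so
# the incidence stage can be reproduced exactly without any raw data.
# Counts are entered as printed, including known typesetting artifacts
# (e.g. the UBB hearing-loss sum cell, which is inconsistent with its own
# male + female split).

#' Published vaccinated-population denominators
#'
#' CDC COVID Data Tracker population counts by dose series and stratum:
#' completed primary series (CPS) and updated bivalent booster (UBB) by
#' total, sex and age band, and at-least-one-dose (ALOD) plus UBB by
#' manufacturer. The bivalent booster has no Janssen population (never
#' authorized as one).
#'
#' @return A `denominator_table`.
#' @export
replay_denominators <- function() {
  as_denominator_table(tribble(
    ~series, ~axis, ~level, ~persons,
    "CPS", "TOTAL", "ALL", 226593618,
    "CPS", "SEX", "M", 107987092,
    "CPS", "SEX", "F", 118606526,
    "CPS", "AGE", "0-17", 22396020,
    "CPS", "AGE", "18-49", 98160420,
    "CPS", "AGE", "50-64", 52731727,
    "CPS", "AGE", "65+", 51031000,
    "UBB", "TOTAL", "ALL", 55703085,
    "UBB", "SEX", "M", 25218543,
    "UBB", "SEX", "F", 30484542,
    "UBB", "AGE", "0-17", 3065181,
    "UBB", "AGE", "18-49", 15303884,
    "UBB", "AGE", "50-64", 13654874,
    "UBB", "AGE", "65+", 23407228,
    "UBB", "MANUFACTURER", "PFIZER_BIONTECH", 35476628,
    "UBB", "MANUFACTURER", "MODERNA", 20072000,
    "ALOD", "MANUFACTURER", "PFIZER_BIONTECH", 152590827,
    "ALOD", "MANUFACTURER", "MODERNA", 96527417,
    "ALOD", "MANUFACTURER", "JANSSEN", 7903364
  ))
}

replay_counts_wide <- function(labels, mat, series, axis, levels) {
  stopifnot(length(labels) * length(levels) == length(mat))
  tidyr::expand_grid(group = labels, level = levels) %>%
    arrange(match(.data$group, labels)) %>%
    mutate(
      series = series, axis = axis,
      count = as.integer(t(matrix(mat, ncol = length(levels), byrow = TRUE)))
    ) %>%
    select("group", "series", "axis", "level", "count")
}

group_labels_with_any <- function() c(aefi_group_names(), ANY_GROUP)

#' Published report counts by sex
#'
#' Per-group report counts for the CPS and UBB series: total, male, female
#' (the `TOTAL` level is the printed sum column). The pseudo-group `"ANY"`
#' is the all-groups row.
#'
#' @return Tibble `(group, series, axis, level, count)`.
#' @export
replay_table1 <- function() {
  labels <- group_labels_with_any()
  cps <- c( # TOTAL, M, F
    4319, 1759, 2560,
    12338, 4960, 7378,
    563, 187, 376,
    82, 25, 57,
    98, 35, 63,
    71255, 20126, 51129,
    1333, 346, 987,
    126, 49, 77,
    2085, 700, 1385,
    3652, 1237, 2415,
    15, 7, 8,
    494, 284, 210,
    5983, 1219, 4764,
    73, 20, 53,
    135, 23, 112,
    27, 6, 21,
    337, 43, 294,
    8, 3, 5,
    3730, 1159, 2571,
    106653, 32188, 74465
  )
  ubb <- c(
    19, 70, 126, # sum cell as printed; inconsistent with M + F = 196
    381, 146, 235,
    81, 24, 57,
    3, 1, 2,
    11, 4, 7,
    1610, 483, 1127,
    270, 80, 190,
    8, 2, 6,
    45, 15, 30,
    227, 64, 163,
    2, 1, 1,
    152, 84, 68,
    213, 58, 155,
    4, 1, 3,
    54, 11, 43,
    0, 0, 0,
    21, 6, 15,
    0, 0, 0,
    753, 271, 482,
    4031, 1321, 2710
  )
  bind_rows(
    replay_counts_wide(labels, cps, "CPS", "SEX", c("TOTAL", "M", "F")),
    replay_counts_wide(labels, ubb, "UBB", "SEX", c("TOTAL", "M", "F"))
  )
}

#' Published report counts by age band
#'
#' @return Tibble `(group, series, axis, level, count)` over the four age
#'   bands for CPS and UBB.
#' @export
replay_table2 <- function() {
  labels <- group_labels_with_any()
  cps <- c( # 0-17, 18-49, 50-64, 65+
    155, 429, 885, 804,
    166, 724, 3384, 2056,
    27, 49, 98, 76,
    1, 2, 19, 20,
    2, 10, 24, 15,
    3291, 11582, 11978, 9849,
    21, 76, 265, 284,
    2, 13, 24, 26,
    127, 247, 333, 348,
    53, 372, 753, 599,
    0, 2, 3, 4,
    8, 36, 64, 131,
    147, 664, 963, 998,
    3, 22, 11, 6,
    1, 10, 36, 28,
    0, 1, 10, 6,
    3, 26, 83, 39,
    0, 1, 2, 1,
    81, 335, 594, 768,
    4088, 14601, 19529, 16058
  )
  ubb <- c(
    3, 17, 36, 79,
    9, 12, 81, 109,
    5, 7, 21, 26,
    0, 1, 0, 2,
    1, 1, 2, 6,
    120, 159, 217, 537,
    3, 5, 32, 132,
    0, 2, 2, 3,
    5, 4, 4, 18,
    0, 4, 39, 98,
    0, 0, 1, 1,
    1, 5, 21, 71,
    7, 34, 33, 67,
    0, 2, 0, 0,
    0, 3, 8, 32,
    0, 0, 0, 0,
    0, 1, 1, 9,
    0, 0, 0, 0,
    8, 12, 67, 444,
    162, 269, 565, 1634
  )
  bind_rows(
    replay_counts_wide(labels, cps, "CPS", "AGE", age_band_labels()),
    replay_counts_wide(labels, ubb, "UBB", "AGE", age_band_labels())
  )
}

#' Published report counts by manufacturer
#'
#' The primary-series analysis uses at-least-one-dose denominators (the
#' tracker does not publish primary-series counts per manufacturer), so the
#' CPS-scoped counts are keyed here with `series = "CPS"` and matched to
#' ALOD denominators downstream; the UBB columns cover Pfizer-BioNTech and
#' Moderna only.
#'
#' @return Tibble `(group, series, axis, level, count)`.
#' @export
replay_table3 <- function() {
  labels <- group_labels_with_any()
  alod <- c( # PFIZER_BIONTECH, MODERNA, JANSSEN
    3391, 2455, 464,
    9308, 7049, 1516,
    453, 345, 56,
    61, 50, 7,
    89, 66, 5,
    46290, 36646, 9579,
    1029, 941, 165,
    91, 83, 9,
    1495, 1072, 336,
    2919, 2032, 416,
    8, 6, 3,
    568, 357, 58,
    4134, 3918, 439,
    50, 36, 8,
    135, 109, 15,
    29, 13, 3,
    235, 193, 22,
    6, 7, 2,
    3076, 2663, 429,
    73367, 58041, 13532
  )
  ubb <- c(
    113, 85,
    226, 168,
    51, 37,
    2, 1,
    6, 5,
    961, 668,
    154, 117,
    4, 4,
    25, 20,
    128, 101,
    1, 1,
    121, 31,
    126, 91,
    3, 1,
    31, 24,
    0, 0,
    13, 8,
    0, 0,
    408, 353,
    2373, 1715
  )
  bind_rows(
    replay_counts_wide(
      labels, alod, "CPS", "MANUFACTURER",
      c("PFIZER_BIONTECH", "MODERNA", "JANSSEN")
    ),
    replay_counts_wide(
      labels, ubb, "UBB", "MANUFACTURER",
      c("PFIZER_BIONTECH", "MODERNA")
    )
  )
}

#' Replay fixture: published counts plus denominators
#'
#' @return List with `counts` (tables 1-3 stacked) and `denominators`.
#' @export
replay_fixture_tables <- function() {
  list(
    counts = bind_rows(replay_table1(), replay_table2(), replay_table3()),
    denominators = replay_denominators()
  )
}

#' Recompute incidence rates and shares from the replay fixture
#'
#' Applies [incidence_rate()] and [percent_share()] to the published counts
#' and sample sizes, reproducing every IR and percentage cell of the source
#' tables from raw numbers.
#'
#' @param series `"CPS"` or `"UBB"`.
#' @param axis `"SEX"`, `"AGE"` or `"MANUFACTURER"`.
#' @return Tibble `(group, series, axis, level, count, pct, ir_per_100k)`;
#'   the `TOTAL` level (where published) uses the series total denominator,
#'   `pct` is the share of the level's ANY count.
#' @export
replay_incidence_table <- function(series = "CPS", axis = "SEX") {
  fix <- replay_fixture_tables()
  counts <- fix$counts %>%
    filter(.data$series == !!series, .data$axis == !!axis)
  den_series <- if (axis == "MANUFACTURER" && series == "CPS") "ALOD" else series
  any_tb <- counts %>%
    filter(.data$group == ANY_GROUP) %>%
    select("level", any_count = "count")
  persons <- purrr::map_dbl(counts$level, function(lv) {
    if (lv == "TOTAL") {
      denominator_for(fix$denominators, series, "TOTAL", "ALL")
    } else {
      denominator_for(fix$denominators, den_series, axis, lv)
    }
  })
  counts %>%
    left_join(any_tb, by = "level") %>%
    mutate(
      persons = persons,
      pct = if_else(
        .data$group == ANY_GROUP, NA_real_,
        percent_share(.data$count, .data$any_count)
      ),
      ir_per_100k = incidence_rate(.data$count, .data$persons)
    ) %>%
    select("group", "series", "axis", "level", "count", "pct", "ir_per_100k")
}
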