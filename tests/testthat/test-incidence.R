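test_that("incidence rate reproduces published per-100,000 values", {
  expect_equal(round(incidence_rate(106653, 226593618), 3), 47.068)
  expect_equal(round(incidence_rate(12338, 226593618), 3), 5.445)
  expect_equal(round(incidence_rate(13532, 7903364), 3), 171.218)
  expect_equal(incidence_rate(0, 1000), 0)
  # linear in count, inversely proportional to denominator
  expect_equal(incidence_rate(3 * 17, 3 * 12345), incidence_rate(17, 12345))
  expect_error(incidence_rate(1, 0), class = "otosignal_missing_denominator")
})

test_that("percentage share reproduces published shares", {
  expect_equal(round(percent_share(71255, 106653), 2), 66.81)
  expect_equal(round(percent_share(73367, 144940), 1), 50.6)
  expect_equal(percent_share(42, 42), 100)
  expect_error(percent_share(1, 0), class = "otosignal_undefined_share")
})

test_that("count_reports tallies per level with per-report group dedup", {
  grouped <- make_grouped(
    3,
    groups_list = list(
      "Tinnitus (Ringing in the ears)",
      "Tinnitus (Ringing in the ears)",
      "Tinnitus (Ringing in the ears)"
    ),
    sex = c("F", "F", "M")
  )
  counts <- count_reports(grouped, "CPS", "SEX")
  get <- function(g, l) counts$count[counts$group == g & counts$level == l]
  expect_equal(get("Tinnitus (Ringing in the ears)", "F"), 2L)
  expect_equal(get("Tinnitus (Ringing in the ears)", "M"), 1L)
  expect_equal(get("Tinnitus (Ringing in the ears)", "TOTAL"), 3L)
  expect_equal(get("ANY", "TOTAL"), 3L)
})

test_that("a multi-group report adds one to each group and one to ANY", {
  grouped <- make_grouped(1, list(c("Anosmia", "Epistaxis")))
  counts <- count_reports(grouped, "CPS", "TOTAL")
  get <- function(g) counts$count[counts$group == g & counts$level == "TOTAL"]
  expect_equal(get("Anosmia"), 1L)
  expect_equal(get("Epistaxis"), 1L)
  expect_equal(get("ANY"), 1L)
})

test_that("UNKNOWN-stratum reports are excluded from levels but kept in TOTAL", {
  grouped <- make_grouped(3, list("Anosmia", "Anosmia", "Anosmia"),
    sex = c("F", "UNKNOWN", "M")
  )
  counts <- count_reports(grouped, "CPS", "SEX")
  get <- function(l) counts$count[counts$group == "Anosmia" & counts$level == l]
  expect_equal(get("F") + get("M"), 2L)
  expect_equal(get("TOTAL"), 3L)
})

test_that("empty input yields an all-zero table", {
  counts <- count_reports(make_grouped(0, list()), "CPS", "SEX",
    group_names = aefi_group_names()
  )
  expect_true(all(counts$count == 0))
  expect_setequal(unique(counts$group), c(aefi_group_names(), "ANY"))
})

test_that("build_incidence_table computes IR against the matching denominator", {
  den <- as_denominator_table(tibble::tribble(
    ~series, ~axis, ~level, ~persons,
    "CPS", "TOTAL", "ALL", 1e6,
    "CPS", "SEX", "F", 6e5,
    "CPS", "SEX", "M", 4e5
  ))
  grouped <- make_grouped(
    100,
    groups_list = rep(list("Anosmia", "Epistaxis", "Sinusitis", "Laryngitis"), 25)
  )
  tab <- build_incidence_table(grouped, den, "CPS", axes = "SEX")
  totals <- tab[tab$level == "ALL" & tab$group != "ANY" & tab$count > 0, ]
  expect_equal(nrow(totals), 4)
  expect_equal(totals$ir_per_100k, rep(2.5, 4)) # 25 / 1e6 * 1e5
  expect_equal(totals$pct, rep(25, 4))

  one <- build_incidence_table(make_grouped(1, list("Anosmia")), den, "CPS",
    axes = "SEX"
  )
  expect_equal(
    one$ir_per_100k[one$group == "Anosmia" & one$level == "ALL"],
    1e5 / 1e6
  )
})

test_that("per-level counts sum to the total when no stratum value is missing", {
  cfg <- sim_config(
    seed = 42, n_index_reports = 2000, n_background_reports = 0,
    group_probs = setNames(rep(0.1, 5), sprintf("Group %02d", 1:5)),
    background_probs = setNames(rep(0.1, 5), sprintf("Group %02d", 1:5)),
    map = synthetic_map(5)
  )
  sim <- simulate_reports(cfg)
  grouped <- assign_groups(sim$index, cfg$map)
  for (axis in c("SEX", "AGE", "MANUFACTURER")) {
    counts <- count_reports(grouped, "CPS", axis)
    sums <- tapply(
      counts$count[counts$level != "TOTAL"],
      counts$group[counts$level != "TOTAL"], sum
    )
    totals <- tapply(
      counts$count[counts$level == "TOTAL"],
      counts$group[counts$level == "TOTAL"], sum
    )
    expect_equal(sums[names(totals)], totals, label = axis)
  }
})

test_that("manufacturer axis substitutes at-least-one-dose denominators for CPS", {
  den <- replay_denominators()
  grouped <- make_grouped(10, rep(list("Anosmia"), 10),
    manufacturer = "JANSSEN"
  )
  tab <- build_incidence_table(grouped, den, "CPS", axes = "MANUFACTURER")
  jan <- tab[tab$group == "Anosmia" & tab$level == "JANSSEN", ]
  expect_equal(jan$ir_per_100k, 10 / 7903364 * 1e5) # the ALOD population
})

test_that("UBB manufacturer strata cover only populations with a denominator", {
  den <- replay_denominators()
  grouped <- make_grouped(6, rep(list("Anosmia"), 6),
    series = "UBB",
    manufacturer = c(
      "PFIZER_BIONTECH", "MODERNA", "JANSSEN",
      "PFIZER_BIONTECH", "MODERNA", "JANSSEN"
    )
  )
  tab <- build_incidence_table(grouped, den, "UBB", axes = "MANUFACTURER")
  expect_setequal(
    setdiff(unique(tab$level), "ALL"),
    c("PFIZER_BIONTECH", "MODERNA")
  )
})

test_that("a missing denominator is an error naming the stratum", {
  den <- as_denominator_table(tibble::tribble(
    ~series, ~axis, ~level, ~persons,
    "CPS", "TOTAL", "ALL", 1e6,
    "CPS", "SEX", "F", 6e5
  ))
  grouped <- make_grouped(2, list("Anosmia", "Anosmia"), sex = c("F", "M"))
  expect_error(
    build_incidence_table(grouped, den, "CPS", axes = "SEX"),
    "SEX, M",
    class = "otosignal_missing_denominator"
  )
})
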