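test_that("symptom rows for the same report merge into one deduplicated PT set", {
  paths <- fixture_five_reports()
  reports <- read_vaers_reports(paths$data, paths$vax, paths$symptoms,
    vaccine_types = c("COVID19")
  )
  r1 <- reports$preferred_terms[[match("1", reports$report_id)]]
  expect_setequal(r1, c("Tinnitus", "Vertigo"))
  expect_false(anyDuplicated(r1) > 0)
})

test_that("vaccine-type filter excludes non-matching reports", {
  paths <- fixture_five_reports()
  covid <- read_vaers_reports(paths$data, paths$vax, paths$symptoms,
    vaccine_types = c("COVID19")
  )
  expect_equal(nrow(covid), 2)
  none <- read_vaers_reports(paths$data, paths$vax, paths$symptoms,
    vaccine_types = c("HPV4")
  )
  expect_equal(nrow(none), 0)
  all_types <- read_vaers_reports(paths$data, paths$vax, paths$symptoms,
    vaccine_types = NULL
  )
  expect_equal(nrow(all_types), 5)
  # enlarging the filter never loses reports
  expect_gte(
    nrow(read_vaers_reports(paths$data, paths$vax, paths$symptoms,
      vaccine_types = c("COVID19", "FLU3")
    )),
    nrow(covid)
  )
})

test_that("missing sex and age become UNKNOWN / NA", {
  paths <- fixture_five_reports()
  reports <- read_vaers_reports(paths$data, paths$vax, paths$symptoms,
    vaccine_types = NULL
  )
  r5 <- reports[reports$report_id == "5", ]
  expect_equal(r5$sex, "UNKNOWN")
  expect_true(is.na(r5$age_years))
})

test_that("reading is insensitive to input row order", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_fixture_files(dir1,
    data_rows = c("1,30,F", "2,40,M"),
    vax_rows = c("1,COVID19,MODERNA,2", "2,COVID19,PFIZER\\BIONTECH,2"),
    sym_rows = c("1,Tinnitus,,,,", "2,Vertigo,,,,", "1,Anosmia,,,,")
  )
  p2 <- write_fixture_files(dir2,
    data_rows = c("2,40,M", "1,30,F"),
    vax_rows = c("2,COVID19,PFIZER\\BIONTECH,2", "1,COVID19,MODERNA,2"),
    sym_rows = c("1,Anosmia,,,,", "2,Vertigo,,,,", "1,Tinnitus,,,,")
  )
  r1 <- read_vaers_reports(p1$data, p1$vax, p1$symptoms)
  r2 <- read_vaers_reports(p2$data, p2$vax, p2$symptoms)
  expect_equal(r1, r2)
})

test_that("missing required columns raise a structured load error naming them", {
  dir <- withr::local_tempdir()
  ok <- write_fixture_files(dir,
    data_rows = "1,30,F",
    vax_rows = "1,COVID19,MODERNA,2", sym_rows = "1,Tinnitus,,,,"
  )
  bad <- file.path(dir, "DATA_noage.csv")
  writeLines(c("VAERS_ID,SEX", "1,F"), bad)
  expect_error(
    read_vaers_reports(bad, ok$vax, ok$symptoms),
    "AGE_YRS",
    class = "otosignal_load_error"
  )
})

test_that("duplicate report keys with conflicting demographics warn, first wins", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir,
    data_rows = c("1,30,F", "1,55,M"),
    vax_rows = "1,COVID19,MODERNA,2",
    sym_rows = "1,Tinnitus,,,,"
  )
  expect_warning(
    reports <- read_vaers_reports(paths$data, paths$vax, paths$symptoms),
    "first record wins"
  )
  expect_equal(reports$sex, "F")
  expect_equal(reports$age_years, 30)
})

test_that("a report with both primary-series and booster types is assigned UBB", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir,
    data_rows = "1,30,F",
    vax_rows = c("1,COVID19,MODERNA,2", "1,COVID19-2,MODERNA,3"),
    sym_rows = "1,Tinnitus,,,,"
  )
  reports <- read_vaers_reports(paths$data, paths$vax, paths$symptoms)
  expect_equal(nrow(reports), 1)
  expect_equal(reports$dose_series, "UBB")
})

test_that("denominator reader parses totals, tolerates thousands separators, rejects bad input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "den.csv")
  writeLines(c(
    "series,axis,level,persons",
    "CPS,TOTAL,ALL,226593618",
    'UBB,TOTAL,ALL,"55,703,085"'
  ), f)
  den <- read_denominators(f)
  expect_equal(denominator_for(den, "CPS", "TOTAL", "ALL"), 226593618)
  expect_equal(denominator_for(den, "UBB", "TOTAL", "ALL"), 55703085)

  writeLines("series,axis,level,persons", f)
  empty <- read_denominators(f)
  expect_equal(nrow(empty), 0)
  expect_error(
    denominator_for(empty, "CPS", "TOTAL", "ALL"),
    class = "otosignal_missing_denominator"
  )

  writeLines(c("series,axis,level,persons", "CPS,TOTAL,ALL,-5"), f)
  expect_error(read_denominators(f), class = "otosignal_load_error")

  writeLines(c(
    "series,axis,level,persons",
    "CPS,TOTAL,ALL,10", "CPS,TOTAL,ALL,20"
  ), f)
  expect_error(read_denominators(f), class = "otosignal_load_error")
})

test_that("denominator level sums above the TOTAL are tolerated with a warning", {
  expect_warning(
    as_denominator_table(tibble::tribble(
      ~series, ~axis, ~level, ~persons,
      "CPS", "TOTAL", "ALL", 100,
      "CPS", "SEX", "M", 70,
      "CPS", "SEX", "F", 70
    )),
    "exceed"
  )
})

test_that("group-map config inverts to a PT index and rejects duplicated PTs", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "map.yaml")
  writeLines(c(
    "groups:",
    "  \"Tinnitus (Ringing in the ears)\":",
    "    - Tinnitus"
  ), f)
  map <- read_group_map(f)
  expect_equal(nrow(map$mapping), 1)
  expect_equal(map$mapping$group, "Tinnitus (Ringing in the ears)")

  writeLines(c(
    "groups:",
    "  \"Tinnitus (Ringing in the ears)\":",
    "    - Tinnitus",
    "  \"Hearing loss\":",
    "    - Tinnitus"
  ), f)
  expect_error(read_group_map(f), "Tinnitus", class = "otosignal_config_error")
})

test_that("shipped default config declares exactly the 19 canonical groups", {
  map <- read_group_map()
  expect_identical(map$group_names, aefi_group_names())
  expect_length(map$group_names, 19)
  expect_setequal(unique(map$mapping$group), aefi_group_names())
})

test_that("result tables round-trip through TSV with counts and keys intact", {
  dir <- withr::local_tempdir()
  tab <- replay_incidence_table("CPS", "SEX")
  tab$p_value <- NA_real_
  f <- file.path(dir, "t1.tsv")
  write_result_table(tab, f)
  back <- read_result_table(f)
  expect_equal(back$count, tab$count)
  expect_equal(back$group, tab$group)
  expect_equal(back$level, tab$level)
  # display rounding applied to rates and shares
  line <- readLines(f)[2]
  expect_match(line, "\t1\\.906$|\t1\\.906\t")
  # empty table -> header-only file
  write_result_table(tab[0, ], f)
  expect_length(readLines(f), 1)
})

test_that("writing into a missing directory is a structured I/O error", {
  expect_error(
    write_result_table(replay_incidence_table(), "/nonexistent-dir-xyz/t.tsv"),
    class = "otosignal_io_error"
  )
})
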