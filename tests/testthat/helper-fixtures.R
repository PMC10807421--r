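# Shared fixtures (built in code) and independent oracles.

write_fixture_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                data_rows, vax_rows, sym_rows) {
  paths <- list(
    data = file.path(dir, "DATA.csv"),
    vax = file.path(dir, "VAX.csv"),
    symptoms = file.path(dir, "SYMPTOMS.csv")
  )
  writeLines(c("VAERS_ID,AGE_YRS,SEX", data_rows), paths$data)
  writeLines(c("VAERS_ID,VAX_TYPE,VAX_MANU,VAX_DOSE_SERIES", vax_rows), paths$vax)
  writeLines(
    c("VAERS_ID,SYMPTOM1,SYMPTOM2,SYMPTOM3,SYMPTOM4,SYMPTOM5", sym_rows),
    paths$symptoms
  )
  paths
}

# five reports: two COVID19, three FLU3; id 1 has two symptom rows
fixture_five_reports <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_fixture_files(
    dir,
    data_rows = c(
      "1,34,F", "2,61,M", "3,25,F", "4,47,M", "5,,"
    ),
    vax_rows = c(
      "1,COVID19,PFIZER\\BIONTECH,2",
      "2,COVID19,MODERNA,1",
      "3,FLU3,OTHER,1",
      "4,FLU3,OTHER,1",
      "5,FLU3,OTHER,1"
    ),
    sym_rows = c(
      "1,Tinnitus,,,,",
      "1,Tinnitus,Vertigo,,,",
      "2,Anosmia,Headache,,,",
      "3,Dizziness,,,,",
      "4,Headache,,,,",
      "5,Epistaxis,,,,"
    )
  )
}

tiny_map <- function(policy = "DROP") {
  pt_group_map(
    tibble::tribble(
      ~pt, ~group,
      "Tinnitus", "Tinnitus (Ringing in the ears)",
      "Tinnitus aggravated", "Tinnitus (Ringing in the ears)",
      "Vertigo", "Dizziness or vertigo",
      "Dizziness", "Dizziness or vertigo",
      "Anosmia", "Anosmia",
      "Epistaxis", "Epistaxis"
    ),
    unmapped_policy = policy
  )
}

# grouped-report tibble built directly (no files)
make_grouped <- function(n, groups_list, series = "CPS", sex = "F",
                         age = 40, manufacturer = "PFIZER_BIONTECH") {
  tibble::tibble(
    report_id = sprintf("r%04d", seq_len(n)),
    vaccine_type = ifelse(series == "UBB", "COVID19-2", "COVID19"),
    manufacturer = rep_len(manufacturer, n),
    dose_series = rep_len(series, n),
    sex = rep_len(sex, n),
    age_years = rep_len(age, n),
    preferred_terms = replicate(n, character(), simplify = FALSE),
    groups = groups_list
  )
}

# Independent Fisher oracle: choose()-based enumeration over the support of
# tables sharing the observed margins; two-sided by the probability rule.
fisher_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# closed-form Pearson statistic for a 2x2 table
chisq_2x2_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# small synthetic map for generator-driven tests: k groups, 3 PT synonyms each
synthetic_map <- function(k = 5) {
  groups <- sprintf("Group %02d", seq_len(k))
  mapping <- tibble::tibble(
    group = rep(groups, each = 3),
    pt = paste(rep(groups, each = 3), "PT", rep(1:3, k))
  )
  pt_group_map(mapping[, c("pt", "group")])
}
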