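# Readers and writers for the VAERS-dialect three-file layout, population
# denominators, the PT->group mapping config, and pipeline output tables.

# Real VAERS exports are Latin-1; newer files are UTF-8. Try UTF-8 first and
# fall back when the decoded text is not valid UTF-8.
read_delim_encoded <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  tb <- suppressWarnings(readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = "UTF-8"), progress = FALSE,
    na = character()
  ))
  chr <- vapply(tb, is.character, logical(1))
  ok <- all(vapply(tb[chr], function(x) all(validUTF8(x)), logical(1)))
  if (!ok) {
    tb <- suppressWarnings(readr::read_delim(
      path,
      delim = delim, col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = "latin1"), progress = FALSE,
      na = character()
    ))
  }
  tb
}

require_columns <- function(tb, cols, path) {
  missing <- setdiff(cols, names(tb))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "File '%s' is missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ),
      class = "otosignal_load_error"
    )
  }
  invisible(tb)
}

normalize_manufacturer <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]+", "_", trimws(x)))
  dplyr::case_when(
    is.na(x) | key == "" ~ "UNKNOWN",
    grepl("PFIZER", key) ~ "PFIZER_BIONTECH",
    grepl("MODERNA", key) ~ "MODERNA",
    grepl("JANSSEN", key) ~ "JANSSEN",
    key %in% c("UNKNOWN", "UNKNOWN_MANUFACTURER") ~ "UNKNOWN",
    TRUE ~ "OTHER"
  )
}

#' Read a spontaneous-report corpus from the VAERS three-file layout
#'
#' Joins the demographics file (`VAERS_ID`, `AGE_YRS`, `SEX`), the vaccine
#' file (`VAERS_ID`, `VAX_TYPE`, `VAX_MANU`, `VAX_DOSE_SERIES`) and the
#' symptoms file (`VAERS_ID`, `SYMPTOM1`..`SYMPTOM5`, several rows per id
#' allowed) into one row per report. Symptom rows for the same report are
#' merged into a deduplicated preferred-term set. Reports whose vaccine types
#' all fall outside `vaccine_types` are excluded.
#'
#' Dose-series assignment follows the collection design of the source data:
#' vaccine type `COVID19` marks a report from the completed-primary-series
#' population (`CPS`) and `COVID19-2` from the updated-bivalent-booster
#' population (`UBB`); a report carrying both types is assigned `UBB`, since
#' the booster record supersedes.
#'
#' @param data_path,vax_path,symptoms_path Paths to the three delimited files.
#' @param vaccine_types Character set of `VAX_TYPE` tokens to retain
#'   (default `c("COVID19", "COVID19-2")`); `NULL` keeps every report in
#'   the database (for background corpora).
#' @return A tibble with one row per report: `report_id`, `vaccine_type`
#'   (the retained type driving the series assignment), `manufacturer`,
#'   `dose_series`, `sex`, `age_years` (`NA` when unknown), and
#'   `preferred_terms` (list-column of character sets).
#' @export
read_vaers_reports <- function(data_path, vax_path, symptoms_path,
                               vaccine_types = c("COVID19", "COVID19-2")) {
  for (p in c(data_path, vax_path, symptoms_path)) {
    if (!file.exists(p)) {
      abort(sprintf("Input file '%s' does not exist", p),
        class = "otosignal_load_error"
      )
    }
  }
  dat <- require_columns(
    read_delim_encoded(data_path), c("VAERS_ID", "AGE_YRS", "SEX"), data_path
  )
  vax <- require_columns(
    read_delim_encoded(vax_path),
    c("VAERS_ID", "VAX_TYPE", "VAX_MANU", "VAX_DOSE_SERIES"), vax_path
  )
  sym <- require_columns(
    read_delim_encoded(symptoms_path), c("VAERS_ID", "SYMPTOM1"), symptoms_path
  )

  # Duplicate demographics rows: first record wins, conflicting ones warn.
  dup <- dat$VAERS_ID[duplicated(dat$VAERS_ID)]
  if (length(dup) > 0) {
    conflicting <- dat %>%
      filter(.data$VAERS_ID %in% dup) %>%
      distinct(.data$VAERS_ID, .data$AGE_YRS, .data$SEX) %>%
      count(.data$VAERS_ID) %>%
      filter(.data$n > 1)
    if (nrow(conflicting) > 0) {
      warn(sprintf(
        "Duplicate report key(s) with conflicting demographics (first record wins): %s",
        paste(head(conflicting$VAERS_ID, 5), collapse = ", ")
      ))
    }
    dat <- dat %>% filter(!duplicated(.data$VAERS_ID))
  }

  if (!is.null(vaccine_types)) {
    vax <- vax %>% filter(.data$VAX_TYPE %in% vaccine_types)
  }
  vax_keep <- vax %>%
    group_by(.data$VAERS_ID) %>%
    summarise(
      # booster (COVID19-2) records supersede primary-series ones
      vaccine_type = if ("COVID19-2" %in% .data$VAX_TYPE) "COVID19-2"
      else first(.data$VAX_TYPE),
      manufacturer = normalize_manufacturer(first(.data$VAX_MANU)),
      .groups = "drop"
    ) %>%
    mutate(dose_series = dplyr::case_when(
      .data$vaccine_type == "COVID19" ~ "CPS",
      .data$vaccine_type == "COVID19-2" ~ "UBB",
      TRUE ~ "UNKNOWN"
    ))
  if (nrow(vax_keep) == 0) {
    return(tibble(
      report_id = character(), vaccine_type = character(),
      manufacturer = character(), dose_series = character(),
      sex = character(), age_years = numeric(),
      preferred_terms = list()
    ))
  }

  sym_cols <- grep("^SYMPTOM[0-9]+$", names(sym), value = TRUE)
  pts <- sym %>%
    select("VAERS_ID", dplyr::all_of(sym_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(sym_cols),
      names_to = NULL, values_to = "pt"
    ) %>%
    mutate(pt = trimws(.data$pt)) %>%
    filter(!is.na(.data$pt), .data$pt != "") %>%
    distinct(.data$VAERS_ID, .data$pt) %>%
    group_by(.data$VAERS_ID) %>%
    summarise(preferred_terms = list(sort(.data$pt)), .groups = "drop")

  out <- vax_keep %>%
    left_join(dat, by = "VAERS_ID") %>%
    left_join(pts, by = "VAERS_ID") %>%
    mutate(
      sex = if_else(.data$SEX %in% c("M", "F"), .data$SEX, "UNKNOWN",
        missing = "UNKNOWN"
      ),
      age_years = suppressWarnings(as.numeric(.data$AGE_YRS)),
      age_years = if_else(
        is.finite(.data$age_years) & .data$age_years >= 0 &
          .data$age_years < 130,
        .data$age_years, NA_real_
      ),
      preferred_terms = purrr::map(
        .data$preferred_terms, ~ .x %||% character()
      )
    ) %>%
    select(
      report_id = "VAERS_ID", "vaccine_type", "manufacturer",
      "dose_series", "sex", "age_years", "preferred_terms"
    ) %>%
    arrange(.data$report_id)
  out
}

#' Read a vaccinated-population denominator table
#'
#' Expects a delimited file with columns `series` (CPS/UBB/ALOD), `axis`
#' (TOTAL/SEX/AGE/MANUFACTURER), `level`, and `persons`. Thousands
#' separators in `persons` are tolerated (`"55,703,085"`).
#'
#' @param path Path to the denominator CSV.
#' @return A tibble with columns `series`, `axis`, `level`,
#'   `persons` (integer-valued double), of class `denominator_table`.
#' @export
read_denominators <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Denominator file '%s' does not exist", path),
      class = "otosignal_load_error"
    )
  }
  tb <- require_columns(
    read_delim_encoded(path), c("series", "axis", "level", "persons"), path
  )
  tb <- tb %>%
    mutate(persons = readr::parse_number(.data$persons)) %>%
    select("series", "axis", "level", "persons")
  if (any(is.na(tb$persons)) || any(tb$persons < 0)) {
    abort(sprintf("Denominator file '%s' contains negative or unparsable 'persons'", path),
      class = "otosignal_load_error"
    )
  }
  as_denominator_table(tb)
}

#' Construct a denominator table from a data frame
#'
#' @param df Data frame with columns `series`, `axis`, `level`, `persons`.
#' @return The validated tibble with class `denominator_table`.
#' @export
as_denominator_table <- function(df) {
  tb <- as_tibble(df)
  stopifnot(all(c("series", "axis", "level", "persons") %in% names(tb)))
  if (any(tb$persons < 0)) {
    abort("Denominator counts must be non-negative",
      class = "otosignal_load_error"
    )
  }
  dup <- tb %>% count(.data$series, .data$axis, .data$level) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      sprintf(
        "Duplicate denominator key(s): %s",
        paste(sprintf("(%s,%s,%s)", dup$series, dup$axis, dup$level), collapse = ", ")
      ),
      class = "otosignal_load_error"
    )
  }
  # The source publishes axis levels and totals independently; mismatches are
  # tolerated but flagged.
  chk <- tb %>%
    filter(.data$axis != "TOTAL") %>%
    group_by(.data$series, .data$axis) %>%
    summarise(level_sum = sum(.data$persons), .groups = "drop") %>%
    inner_join(
      tb %>% filter(.data$axis == "TOTAL") %>% select("series", total = "persons"),
      by = "series"
    ) %>%
    filter(.data$level_sum > .data$total)
  if (nrow(chk) > 0) {
    warn(sprintf(
      "Denominator levels exceed the series TOTAL for: %s",
      paste(sprintf("%s/%s", chk$series, chk$axis), collapse = ", ")
    ))
  }
  class(tb) <- c("denominator_table", class(tb))
  tb
}

#' Look up a single denominator
#'
#' @param denominators A `denominator_table`.
#' @param series,axis,level Stratum key.
#' @return Number of persons.
#' @export
denominator_for <- function(denominators, series, axis, level = "ALL") {
  hit <- denominators %>%
    filter(.data$series == !!series, .data$axis == !!axis, .data$level == !!level)
  if (nrow(hit) == 0 || hit$persons[1] <= 0) {
    abort(
      sprintf("Missing or zero denominator for stratum (%s, %s, %s)", series, axis, level),
      class = "otosignal_missing_denominator"
    )
  }
  hit$persons[1]
}

#' Read a preferred-term to AEFI-group mapping config
#'
#' The YAML config has a `groups:` block mapping each group name to a list
#' of MedDRA preferred terms, and optionally `group_names:` declaring the
#' full group list (defaults to the keys of `groups`). A PT listed under two
#' groups is a configuration error.
#'
#' @param path Path to the YAML config; defaults to the shipped mapping whose
#'   19 groups carry the PTs literally named in their labels (users supply a
#'   fuller PT list the same way).
#' @param unmapped_policy What [assign_groups()] does with PTs absent from
#'   the mapping: `"DROP"` (default) ignores them, `"ERROR"` aborts.
#' @return An object of class `pt_group_map`: list with `mapping` (tibble
#'   `pt`, `group`), `group_names`, `unmapped_policy`.
#' @export
read_group_map <- function(path = default_group_map_path(),
                           unmapped_policy = c("DROP", "ERROR")) {
  unmapped_policy <- match.arg(unmapped_policy)
  if (!file.exists(path)) {
    abort(sprintf("Mapping config '%s' does not exist", path),
      class = "otosignal_config_error"
    )
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) {
    abort(sprintf("Mapping config '%s' has no 'groups' block", path),
      class = "otosignal_config_error"
    )
  }
  mapping <- purrr::imap(cfg$groups, function(pts, g) {
    tibble(pt = as.character(unlist(pts)), group = g)
  }) %>% bind_rows()
  group_names <- as.character(cfg$group_names %||% names(cfg$groups))
  pt_group_map(mapping, group_names, unmapped_policy)
}

#' Construct a PT-to-group map from a mapping table
#'
#' @param mapping Data frame with columns `pt`, `group`.
#' @param group_names Declared group list; every mapped group must appear.
#' @param unmapped_policy `"DROP"` or `"ERROR"`.
#' @return `pt_group_map` object.
#' @export
pt_group_map <- function(mapping, group_names = unique(mapping$group),
                         unmapped_policy = c("DROP", "ERROR")) {
  unmapped_policy <- match.arg(unmapped_policy)
  mapping <- as_tibble(mapping)[c("pt", "group")]
  dup <- unique(mapping$pt[duplicated(mapping$pt)])
  if (length(dup) > 0) {
    abort(
      sprintf(
        "Preferred term(s) mapped to more than one group: %s",
        paste(dup, collapse = ", ")
      ),
      class = "otosignal_config_error"
    )
  }
  bad <- setdiff(unique(mapping$group), group_names)
  if (length(bad) > 0) {
    abort(
      sprintf("Mapped group(s) missing from the declared group list: %s",
        paste(bad, collapse = ", ")
      ),
      class = "otosignal_config_error"
    )
  }
  structure(
    list(
      mapping = mapping, group_names = as.character(group_names),
      unmapped_policy = unmapped_policy
    ),
    class = "pt_group_map"
  )
}

#' Path of the shipped default group-mapping config
#' @return File path inside the installed package.
#' @export
default_group_map_path <- function() {
  system.file("extdata", "aefi_groups.yaml", package = "otosignal", mustWork = TRUE)
}

#' @export
print.pt_group_map <- function(x, ...) {
  cat(sprintf(
    "<pt_group_map> %d preferred terms -> %d groups (unmapped policy: %s)\n",
    nrow(x$mapping), length(x$group_names), x$unmapped_policy
  ))
  invisible(x)
}

#' Write a stratified result table as TSV
#'
#' Incidence rates are printed to 3 decimals and percentage shares to 2,
#' matching the conventional display of per-100,000 rates; counts are
#' written exactly. P-values below 0.001 print as `<0.001`.
#'
#' @param table A tibble as produced by [build_incidence_table()] or
#'   [prr_table()].
#' @param path Output file path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Output directory '%s' does not exist", dirname(path)),
      class = "otosignal_io_error"
    )
  }
  out <- as_tibble(table)
  fmt3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", round(x, 3)))
  for (col in intersect(c("ir_per_100k", "prr", "ci_low", "ci_high"), names(out))) {
    out[[col]] <- fmt3(out[[col]])
  }
  if ("pct" %in% names(out)) {
    out$pct <- ifelse(is.na(out$pct), "", sprintf("%.2f", round(out$pct, 2)))
  }
  if ("p_value" %in% names(out)) {
    out$p_value <- format_p_value(out$p_value)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Re-read a TSV result table written by [write_result_table()]
#'
#' @param path File path.
#' @return Tibble with numeric columns restored (`<0.001` p-values become
#'   `0.0005`, the midpoint of the censored display interval).
#' @export
read_result_table <- function(path) {
  tb <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  num_cols <- intersect(
    c("count", "pct", "ir_per_100k", "m", "n", "M", "N", "prr", "ci_low", "ci_high"),
    names(tb)
  )
  for (col in num_cols) tb[[col]] <- suppressWarnings(as.numeric(tb[[col]]))
  if ("p_value" %in% names(tb)) {
    tb$p_value <- ifelse(tb$p_value == "<0.001", 5e-4,
      suppressWarnings(as.numeric(tb$p_value))
    )
  }
  if ("signal" %in% names(tb)) tb$signal <- tb$signal == "TRUE"
  tb
}

format_p_value <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", round(p, 3))))
}
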