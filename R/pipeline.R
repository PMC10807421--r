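# End-to-end orchestration: load -> group -> incidence -> tests -> PRR,
# emitting the four result tables and a run manifest. All stages are
# deterministic, so a rerun on the same inputs is byte-identical.

#' Run the full adverse-event analysis pipeline
#'
#' Reads the three-file report corpus, assigns AEFI groups, builds the
#' stratified incidence tables (with association-test p-values) for each
#' requested dose series, screens every group with the PRR against the
#' background corpus (all non-index reports in the same database), and
#' writes `table1_sex.tsv`, `table2_age.tsv`, `table3_manufacturer.tsv`,
#' `table4_prr.tsv` plus `manifest.json` to `out_dir`.
#'
#' @param data_path,vax_path,symptoms_path The VAERS-layout report files.
#' @param denominators_path Denominator CSV (see [read_denominators()]).
#' @param mapping_path PT-group mapping YAML (default: shipped mapping).
#' @param series Dose series to tabulate (default both CPS and UBB).
#' @param prr_series Series whose reports form the PRR index corpus
#'   (default `"CPS"`).
#' @param axes Stratum axes for the incidence tables.
#' @param threshold PRR signal threshold (default 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param out_dir Output directory (created if missing).
#' @param index_vaccine_types `VAX_TYPE` tokens defining the index vaccine.
#' @return Invisibly, a list with the incidence tables (per series), the
#'   `prr_table`, and the written file paths.
#' @export
run_pipeline <- function(data_path, vax_path, symptoms_path,
                         denominators_path,
                         mapping_path = default_group_map_path(),
                         series = c("CPS", "UBB"),
                         prr_series = "CPS",
                         axes = c("SEX", "AGE", "MANUFACTURER"),
                         threshold = 2, alpha = 0.05,
                         out_dir = ".",
                         index_vaccine_types = c("COVID19", "COVID19-2")) {
  stopifnot(threshold > 0, alpha > 0, alpha < 1)
  map <- read_group_map(mapping_path)
  denominators <- read_denominators(denominators_path)
  all_reports <- read_vaers_reports(data_path, vax_path, symptoms_path,
    vaccine_types = NULL
  )
  index_reports <- all_reports %>%
    filter(.data$vaccine_type %in% index_vaccine_types)
  background_reports <- all_reports %>%
    filter(!.data$vaccine_type %in% index_vaccine_types)

  grouped <- assign_groups(index_reports, map)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  tables <- purrr::map(setNames(series, series), function(s) {
    ax <- axes
    purrr::map(setNames(ax, ax), function(a) {
      build_incidence_table(grouped, denominators, s,
        axes = a, group_names = map$group_names
      )
    })
  })
  axis_file <- c(
    SEX = "table1_sex.tsv", AGE = "table2_age.tsv",
    MANUFACTURER = "table3_manufacturer.tsv"
  )
  paths <- list()
  for (a in axes) {
    tab <- bind_rows(purrr::map(tables, ~ .x[[a]]))
    paths[[axis_file[[a]]]] <- file.path(out_dir, axis_file[[a]])
    write_result_table(tab, paths[[axis_file[[a]]]])
  }

  prr_res <- prr_table(
    grouped %>% filter(.data$dose_series == prr_series),
    assign_groups(background_reports, map),
    group_names = map$group_names,
    threshold = threshold, alpha = alpha
  )
  paths[["table4_prr.tsv"]] <- file.path(out_dir, "table4_prr.tsv")
  write_result_table(prr_res %>% select(-"se_log"), paths[["table4_prr.tsv"]])

  manifest <- list(
    inputs = list(
      data = data_path, vax = vax_path, symptoms = symptoms_path,
      denominators = denominators_path, mapping = mapping_path
    ),
    config = list(
      series = series, prr_series = prr_series, axes = axes,
      threshold = threshold, alpha = alpha,
      index_vaccine_types = index_vaccine_types
    ),
    n_reports = list(
      database = nrow(all_reports),
      index = nrow(index_reports),
      index_mapped = sum(lengths(grouped$groups) > 0),
      background = nrow(background_reports)
    ),
    versions = list(
      otosignal = as.character(utils::packageVersion("otosignal")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, pretty = TRUE
  )
  paths[["manifest.json"]] <- manifest_path

  invisible(list(
    incidence = tables, prr = prr_res, paths = paths
  ))
}
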