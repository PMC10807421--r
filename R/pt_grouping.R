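# Map each report's MedDRA preferred terms to AEFI groups. A report counts
# at most once per group, however many of the group's PTs it mentions, and
# contributes to every group it maps to.

#' Assign AEFI groups to reports
#'
#' Adds a `groups` list-column to a report tibble: for each report, the
#' deduplicated set of group names its preferred terms map to. Multiple PTs
#' of the same group in one report contribute the group once.
#'
#' @param reports Report tibble as returned by [read_vaers_reports()] (needs
#'   a `preferred_terms` list-column).
#' @param map A [pt_group_map()] object.
#' @return The input tibble with a `groups` list-column appended (sorted
#'   character vectors, possibly empty).
#' @export
#' @examples
#' map <- read_group_map()
#' r <- tibble::tibble(
#'   report_id = "1", preferred_terms = list(c("Tinnitus", "Dizziness"))
#' )
#' assign_groups(r, map)$groups[[1]]
assign_groups <- function(reports, map) {
  stopifnot(inherits(map, "pt_group_map"))
  lut <- setNames(map$mapping$group, map$mapping$pt)
  n <- nrow(reports)
  flat_pt <- unlist(reports$preferred_terms, use.names = FALSE)
  idx <- rep(seq_len(n), lengths(reports$preferred_terms))
  hit <- unname(lut[flat_pt])
  if (map$unmapped_policy == "ERROR" && anyNA(hit)) {
    abort(
      sprintf(
        "Unmapped preferred term(s): %s",
        paste(unique(flat_pt[is.na(hit)]), collapse = ", ")
      ),
      class = "otosignal_mapping_error"
    )
  }
  keep <- !is.na(hit)
  pairs <- unique(data.frame(idx = idx[keep], group = hit[keep]))
  groups <- rep(list(character()), n)
  if (nrow(pairs) > 0) {
    split_groups <- split(pairs$group, pairs$idx)
    groups[as.integer(names(split_groups))] <-
      lapply(split_groups, function(g) sort(g))
  }
  out <- reports
  out$groups <- groups
  out
}

#' Select reports with at least one mapped otolaryngologic group
#'
#' Runs [assign_groups()] and keeps only reports that hit one or more
#' groups; output order is deterministic (sorted by `report_id`).
#'
#' @inheritParams assign_groups
#' @return Grouped-report tibble restricted to mapped reports.
#' @export
select_otolaryngologic <- function(reports, map) {
  assign_groups(reports, map) %>%
    filter(lengths(.data$groups) > 0) %>%
    arrange(.data$report_id)
}
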