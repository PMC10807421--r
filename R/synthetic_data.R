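# Synthetic VAERS-shaped corpora with known ground truth: an index-vaccine
# corpus, a background corpus of other vaccines, and a denominator table.
# Every pipeline stage can be exercised, and parameter recovery checked,
# without downloading anything.

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the observed structure of the real otolaryngologic AEFI
#' corpus at a tractable scale: per-group baseline inclusion probabilities
#' proportional to the published per-group report shares, the published
#' sex/age/manufacturer mixes among reports, the published CDC
#' vaccinated-population denominators, and a background corpus whose group
#' proportions imply the published disproportionality pattern.
#'
#' @param seed Integer RNG seed.
#' @param n_index_reports,n_background_reports Corpus sizes (defaults
#'   50,000 and 100,000).
#' @param group_probs Named per-group probability that an index report
#'   mentions the group (independent across groups).
#' @param background_probs Same for background reports.
#' @param planted_effects Named multipliers applied to `group_probs` for the
#'   index corpus (relative reporting-rate effects; probabilities are capped
#'   at 1 with a warning recorded in the ground truth).
#' @param series_mix Probabilities of CPS vs UBB for index reports.
#' @param sex_mix,age_mix,manufacturer_mix Stratum mixes (each must sum
#'   to 1).
#' @param missingness List with elements `sex` and `age`: probabilities of
#'   an UNKNOWN value. Defaults 0 so stratum-sum invariants hold exactly.
#' @param pt_per_group Maximum number of synonym preferred terms emitted per
#'   included group (exercises per-report deduplication).
#' @param denominators Denominator table (default: the published CDC
#'   populations from [replay_denominators()]).
#' @param map PT-group map used to pick synonym PTs (default shipped map).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_index_reports = 50000L,
                       n_background_reports = 100000L,
                       group_probs = default_group_probs(),
                       background_probs = default_background_probs(),
                       planted_effects = NULL,
                       series_mix = c(CPS = 0.96, UBB = 0.04),
                       sex_mix = c(M = 0.30, F = 0.70),
                       age_mix = c("0-17" = 0.08, "18-49" = 0.27,
                                   "50-64" = 0.36, "65+" = 0.29),
                       manufacturer_mix = c(PFIZER_BIONTECH = 0.51,
                                            MODERNA = 0.40, JANSSEN = 0.09),
                       missingness = list(sex = 0, age = 0),
                       pt_per_group = 2L,
                       denominators = replay_denominators(),
                       map = read_group_map()) {
  stopifnot(
    n_index_reports >= 0, n_background_reports >= 0,
    all(group_probs >= 0 & group_probs <= 1),
    all(background_probs >= 0 & background_probs <= 1),
    abs(sum(series_mix) - 1) < 1e-8,
    abs(sum(sex_mix) - 1) < 1e-8,
    abs(sum(age_mix) - 1) < 1e-8,
    abs(sum(manufacturer_mix) - 1) < 1e-8,
    is.null(planted_effects) || all(planted_effects > 0),
    pt_per_group >= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      n_index_reports = as.integer(n_index_reports),
      n_background_reports = as.integer(n_background_reports),
      group_probs = group_probs,
      background_probs = background_probs,
      planted_effects = planted_effects,
      series_mix = series_mix, sex_mix = sex_mix, age_mix = age_mix,
      manufacturer_mix = manufacturer_mix,
      missingness = missingness,
      pt_per_group = as.integer(pt_per_group),
      denominators = denominators,
      map = map
    ),
    class = "sim_config"
  )
}

#' Default per-group index reporting probabilities
#'
#' Proportional to the published per-group shares of otolaryngologic
#' reports, scaled so a report mentions ~1 group on average (dizziness
#' dominates at two thirds of reports).
#' @return Named probability vector over [aefi_group_names()].
#' @export
default_group_probs <- function() {
  shares <- replay_table1() %>%
    filter(.data$series == "CPS", .data$level == "TOTAL", .data$group != ANY_GROUP)
  total <- replay_table1() %>%
    filter(.data$series == "CPS", .data$level == "TOTAL", .data$group == ANY_GROUP) %>%
    pull(.data$count)
  setNames(shares$count / total, shares$group)
}

#' Default per-group background reporting probabilities
#'
#' The index probabilities divided by the published group-level PRR
#' pattern, so the generated corpus reproduces a realistic
#' disproportionality profile (tinnitus, anosmia and acid reflux elevated).
#' @return Named probability vector.
#' @export
default_background_probs <- function() {
  p <- default_group_probs()
  # published point disproportionality per group (index/background ratio)
  ratio <- c(
    "Hearing loss" = 1.554,
    "Tinnitus (Ringing in the ears)" = 2.343,
    "Ear infections (Otitis Media)" = 0.227,
    "Meniere's disease" = 1.945,
    "Vestibular neuronitis" = 1.217,
    "Dizziness or vertigo" = 1.629,
    "Sinusitis" = 0.832,
    "Rhinitis (Allergic and Non-allergic)" = 0.056,
    "Epistaxis" = 1.605,
    "Anosmia" = 3.167,
    "Nasal polyps" = 1.956,
    "Snoring or difficulty breathing through the nose and sleep apnea" = 0.205,
    "Allergies" = 0.251,
    "Tonsillitis" = 0.491,
    "Laryngitis" = 0.332,
    "Vocal cord polyps and nodules" = 1.101,
    "Laryngopharyngeal reflux (Acid Reflux)" = 2.632,
    "Epiglottitis" = 0.348,
    "Pharyngitis" = 0.573
  )
  pmin(p / ratio[names(p)], 1)
}

sample_levels <- function(n, mix) {
  if (n == 0) return(character())
  sample(names(mix), n, replace = TRUE, prob = mix)
}

age_from_band <- function(band) {
  lo <- c("0-17" = 0, "18-49" = 18, "50-64" = 50, "65+" = 65)[band]
  hi <- c("0-17" = 17, "18-49" = 49, "50-64" = 64, "65+" = 95)[band]
  out <- lo + floor(runif(length(band)) * (hi - lo + 1))
  as.numeric(out)
}

# Draw one corpus of n reports. Each report gets a stratum from the mixes,
# then each group independently with its probability; included groups emit a
# random non-empty subset (size <= pt_per_group) of the group's synonym PTs.
# Reports with no mapped group get an unmapped filler PT so every report
# still looks like an adverse-event report.
draw_corpus <- function(n, probs, config, id_prefix, index = TRUE) {
  if (n == 0) {
    return(tibble(
      report_id = character(), vaccine_type = character(),
      manufacturer = character(), dose_series = character(),
      sex = character(), age_years = numeric(), preferred_terms = list()
    ))
  }
  groups <- names(probs)
  inc <- matrix(runif(n * length(groups)) < rep(probs, each = n), nrow = n)
  colnames(inc) <- groups

  pt_lists <- split(config$map$mapping$pt, config$map$mapping$group)
  pts <- vector("list", n)
  for (g in groups) {
    hit <- which(inc[, g])
    if (length(hit) == 0) next
    pool <- pt_lists[[g]]
    maxk <- min(config$pt_per_group, length(pool))
    k <- 1 + floor(runif(length(hit)) * maxk)
    start <- 1 + floor(runif(length(hit)) * length(pool))
    for (i in seq_along(hit)) {
      sel <- pool[((start[i] + seq_len(k[i]) - 2) %% length(pool)) + 1]
      pts[[hit[i]]] <- c(pts[[hit[i]]], sel)
    }
  }
  pts <- purrr::map(pts, function(x) {
    if (is.null(x)) "Headache" else sort(unique(x))
  })

  sex <- sample_levels(n, config$sex_mix)
  if (config$missingness$sex > 0) {
    sex[runif(n) < config$missingness$sex] <- "UNKNOWN"
  }
  band <- sample_levels(n, config$age_mix)
  age <- age_from_band(band)
  if (config$missingness$age > 0) {
    age[runif(n) < config$missingness$age] <- NA_real_
  }
  if (index) {
    series <- sample_levels(n, config$series_mix)
    vaccine_type <- if_else(series == "UBB", "COVID19-2", "COVID19")
    manu <- sample_levels(n, config$manufacturer_mix)
  } else {
    series <- rep("UNKNOWN", n)
    vaccine_type <- rep("FLU3", n)
    manu <- rep("OTHER", n)
  }
  tibble(
    report_id = sprintf("%s%07d", id_prefix, seq_len(n)),
    vaccine_type = vaccine_type,
    manufacturer = manu,
    dose_series = series,
    sex = sex,
    age_years = age,
    preferred_terms = pts
  )
}

#' Generate synthetic index and background corpora with ground truth
#'
#' Deterministic given `config$seed`. The returned ground truth records the
#' effective (post-multiplier, capped) per-group probabilities, the implied
#' true PRR per group, and per-stratum true incidence rates per 100,000
#' implied by the configured denominators.
#'
#' @param config A [sim_config()].
#' @return List with `index` and `background` report tibbles (same shape as
#'   [read_vaers_reports()] output), `denominators`, and `ground_truth`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  p_idx <- config$group_probs
  capped <- character()
  if (!is.null(config$planted_effects)) {
    for (g in names(config$planted_effects)) {
      raw <- p_idx[[g]] * config$planted_effects[[g]]
      if (raw > 1) capped <- c(capped, g)
      p_idx[[g]] <- min(1, raw)
    }
    if (length(capped) > 0) {
      warn(sprintf(
        "Planted effect capped at probability 1 for: %s",
        paste(capped, collapse = ", ")
      ))
    }
  }
  index <- draw_corpus(config$n_index_reports, p_idx, config, "I", index = TRUE)
  background <- draw_corpus(
    config$n_background_reports, config$background_probs, config, "B",
    index = FALSE
  )

  p_any <- 1 - prod(1 - p_idx)
  truth <- list(
    group_probs_index = as.list(p_idx),
    group_probs_background = as.list(config$background_probs),
    implied_prr = as.list(p_idx / config$background_probs[names(p_idx)]),
    capped_groups = as.list(capped),
    expected_ir_per_100k = purrr::imap(p_idx, function(p, g) {
      den <- denominator_for(config$denominators, "CPS", "TOTAL", "ALL")
      config$n_index_reports * config$series_mix[["CPS"]] * p / den * 1e5
    }),
    expected_any_ir_cps = config$n_index_reports *
      config$series_mix[["CPS"]] * p_any /
      denominator_for(config$denominators, "CPS", "TOTAL", "ALL") * 1e5
  )
  list(
    index = index, background = background,
    denominators = config$denominators, ground_truth = truth
  )
}

pts_to_symptom_rows <- function(report_id, pts) {
  purrr::map2(report_id, pts, function(id, p) {
    if (length(p) == 0) p <- ""
    n_rows <- ceiling(length(p) / 5)
    pad <- c(p, rep("", n_rows * 5 - length(p)))
    m <- matrix(pad, ncol = 5, byrow = TRUE)
    colnames(m) <- paste0("SYMPTOM", 1:5)
    bind_cols(tibble(VAERS_ID = rep(id, n_rows)), as_tibble(m))
  }) %>% bind_rows()
}

#' Write a simulated corpus as VAERS-layout files
#'
#' Emits `DATA.csv`, `VAX.csv`, `SYMPTOMS.csv` (index + background reports
#' in one database), `denominators.csv`, and `ground_truth.json` into
#' `dir`. Output is byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of the written paths, invisibly.
#' @export
simulate_vaers <- function(config, dir) {
  sim <- simulate_reports(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  all_reports <- bind_rows(sim$index, sim$background)

  data_tb <- all_reports %>%
    mutate(
      AGE_YRS = if_else(is.na(.data$age_years), "", format(.data$age_years)),
      SEX = if_else(.data$sex == "UNKNOWN", "U", .data$sex)
    ) %>%
    select(VAERS_ID = "report_id", "AGE_YRS", "SEX")
  vax_tb <- all_reports %>%
    mutate(VAX_DOSE_SERIES = dplyr::case_when(
      .data$dose_series == "CPS" ~ "2",
      .data$dose_series == "UBB" ~ "3",
      TRUE ~ "UNK"
    )) %>%
    select(
      VAERS_ID = "report_id", VAX_TYPE = "vaccine_type",
      VAX_MANU = "manufacturer", "VAX_DOSE_SERIES"
    )
  sym_tb <- pts_to_symptom_rows(all_reports$report_id, all_reports$preferred_terms)
  den_tb <- as_tibble(sim$denominators) %>%
    mutate(persons = format(.data$persons, scientific = FALSE, trim = TRUE))

  paths <- list(
    data = file.path(dir, "DATA.csv"),
    vax = file.path(dir, "VAX.csv"),
    symptoms = file.path(dir, "SYMPTOMS.csv"),
    denominators = file.path(dir, "denominators.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(data_tb, paths$data, progress = FALSE)
  readr::write_csv(vax_tb, paths$vax, progress = FALSE)
  readr::write_csv(sym_tb, paths$symptoms, progress = FALSE)
  readr::write_csv(den_tb, paths$denominators, progress = FALSE)
  jsonlite::write_json(sim$ground_truth, paths$ground_truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
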