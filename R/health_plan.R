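intervention_terms <- c("short", "medium", "long")
intervention_costs <- c("low", "medium", "high")

#' Read a health-plan (intervention) file
#'
#' A health plan is the farm-specific list of SMART biosecurity interventions
#' drafted from the assessment. One row per intervention with columns
#' `intervention_id`, `farm_id`, `zone`, `category_id`, `description`,
#' `term` (short/medium/long), `cost` (low/medium/high), `realized`
#' (true/false), `date_planned`, `date_evaluated` (empty until evaluated).
#'
#' @param path Path to the plans file.
#' @param questionnaire Optional `beat_questionnaire`; when given, each
#'   intervention's `zone` must match the zone of its `category_id`.
#' @return Tibble of interventions.
#' @export
read_health_plans <- function(path, questionnaire = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  plans <- readr::read_csv(
    path,
    col_types = readr::cols(
      intervention_id = readr::col_character(),
      farm_id = readr::col_character(),
      zone = readr::col_character(),
      category_id = readr::col_character(),
      description = readr::col_character(),
      term = readr::col_character(),
      cost = readr::col_character(),
      realized = readr::col_logical(),
      date_planned = readr::col_date(format = "%Y-%m-%d"),
      date_evaluated = readr::col_date(format = "%Y-%m-%d")
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(plans)
  if (nrow(prob)) {
    stop("parse error in ", path, " at line ", prob$row[1] + 1L, call. = FALSE)
  }
  validate_health_plans(plans, questionnaire)
  plans
}

#' Validate an intervention table
#'
#' @param plans Intervention tibble (see [read_health_plans()]).
#' @param questionnaire Optional `beat_questionnaire` for zone/category
#'   cross-checks.
#' @return `plans`, invisibly.
#' @export
validate_health_plans <- function(plans, questionnaire = NULL) {
  assert_zone(plans$zone)
  if (anyDuplicated(plans$intervention_id)) {
    stop("duplicate intervention_id: ",
         paste(unique(plans$intervention_id[duplicated(plans$intervention_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_term <- setdiff(plans$term, intervention_terms)
  if (length(bad_term)) {
    stop("term must be one of short/medium/long, got: ",
         paste(bad_term, collapse = ", "), call. = FALSE)
  }
  bad_cost <- setdiff(plans$cost, intervention_costs)
  if (length(bad_cost)) {
    stop("cost must be one of low/medium/high, got: ",
         paste(bad_cost, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(plans$realized))) {
    stop("realized must be true/false for every intervention", call. = FALSE)
  }
  if (!is.null(questionnaire)) {
    cats <- questionnaire$categories
    idx <- match(plans$category_id, cats$category_id)
    if (any(is.na(idx))) {
      stop("intervention(s) reference unknown category_id: ",
           paste(unique(plans$category_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    mismatch <- plans$zone != cats$zone[idx]
    if (any(mismatch)) {
      stop("intervention zone does not match category zone for: ",
           paste(unique(plans$intervention_id[mismatch]), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(plans)
}

#' Rank a farm's weakest risk categories as intervention targets
#'
#' The instrument itself does not draft interventions -- that is the farmer
#' and veterinarian's job -- but it points at where to act: the
#' lowest-scoring risk categories. Categories already at full compliance are
#' filtered out; ties are broken by zone (inside to outside) and then
#' category id, so the ranking is deterministic.
#'
#' @param category_scores Tibble with `category_id`, `zone`, `relative`
#'   (one farm's scores, e.g. `score_farms()$categories`).
#' @param k Number of targets wanted.
#' @param perfection_filter Drop categories with `relative >=` this value
#'   (default 1: only full compliance is dropped).
#' @return Tibble of up to `k` rows sorted by ascending score. If fewer than
#'   `k` imperfect categories exist, all are returned with a warning.
#' @export
suggest_targets <- function(category_scores, k, perfection_filter = 1) {
  stopifnot(k >= 1)
  eligible <- category_scores[category_scores$relative < perfection_filter, ]
  ranked <- eligible[order(eligible$relative, zone_factor(eligible$zone),
                           eligible$category_id), ]
  if (nrow(ranked) < k) {
    warning("only ", nrow(ranked), " categories below the perfection filter; ",
            "returning all of them", call. = FALSE)
    return(ranked)
  }
  ranked[seq_len(k), ]
}

#' Planned interventions per zone
#'
#' @param plans Intervention tibble.
#' @return Tibble with one row per zone in reporting order (all five zones,
#'   zero-filled): `zone`, `n_planned`, `n_realized`.
#' @export
#' @examples
#' counts <- read_intervention_counts(beat_example("fieldstudy_interventions.csv"))
#' zone_totals(expand_intervention_counts(counts))
zone_totals <- function(plans) {
  if (nrow(plans) > 0) assert_zone(plans$zone)
  tallied <- plans |>
    dplyr::group_by(zone = zone_factor(.data$zone), .drop = FALSE) |>
    dplyr::summarise(n_planned = dplyr::n(),
                     n_realized = sum(.data$realized),
                     .groups = "drop")
  tallied$zone <- as.character(tallied$zone)
  tallied
}

#' Term-by-cost cross-tabulation of interventions
#'
#' The 3x3 table of time horizon (short/medium/long) against implementation
#' cost (low/medium/high): number planned and percent realized, the percent
#' rounded to a whole number and `NA` where nothing was planned.
#'
#' @param plans Intervention tibble.
#' @return Tibble with `term`, `cost`, `n_planned`, `n_realized`,
#'   `pct_realized`; 9 rows, term varying slowest, zero-filled.
#' @export
crosstab_term_cost <- function(plans) {
  grid <- tidyr::expand_grid(term = intervention_terms, cost = intervention_costs)
  tallied <- plans |>
    dplyr::group_by(.data$term, .data$cost) |>
    dplyr::summarise(n_planned = dplyr::n(),
                     n_realized = sum(.data$realized), .groups = "drop")
  out <- dplyr::left_join(grid, tallied, by = c("term", "cost"))
  out$n_planned[is.na(out$n_planned)] <- 0L
  out$n_realized[is.na(out$n_realized)] <- 0L
  out$pct_realized <- ifelse(out$n_planned > 0,
                             round(100 * out$n_realized / out$n_planned),
                             NA_real_)
  out
}

#' Realization rate of planned interventions
#'
#' Percent of planned interventions implemented by the end of follow-up,
#' overall or per group (typically country), reported to one decimal.
#'
#' @param plans Intervention tibble.
#' @param farms Optional `farm_id`/`country` table, required for
#'   `group_by = "country"`.
#' @param group_by `"overall"` or `"country"`.
#' @return Tibble: `group`, `n_planned`, `n_realized`, `pct_realized`.
#' @export
realization_rate <- function(plans, farms = NULL,
                             group_by = c("overall", "country")) {
  group_by <- match.arg(group_by)
  if (group_by == "country") {
    if (!"country" %in% names(plans)) {
      if (is.null(farms)) stop("grouping by country needs a farms table", call. = FALSE)
      plans <- dplyr::left_join(plans, farms[, c("farm_id", "country")],
                                by = "farm_id")
      if (any(is.na(plans$country))) {
        stop("farm(s) missing from the farms table: ",
             paste(unique(plans$farm_id[is.na(plans$country)]), collapse = ", "),
             call. = FALSE)
      }
    }
    plans$group <- plans$country
  } else {
    plans$group <- "overall"
  }
  out <- plans |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_planned = dplyr::n(),
                     n_realized = sum(.data$realized), .groups = "drop")
  if (nrow(out) == 0L) {
    warning("no planned interventions; realization rate undefined", call. = FALSE)
    return(tibble(group = character(), n_planned = integer(),
                  n_realized = integer(), pct_realized = numeric()))
  }
  out$pct_realized <- round(100 * out$n_realized / out$n_planned, 1)
  out
}

#' Read a per-country intervention count summary
#'
#' Cohort-level bookkeeping of a published or exported study: one row per
#' country and risk category with the number of interventions planned and
#' realized there and the country's mean relative score for the category.
#' Columns: `country`, `zone`, `category_id`, `category_label`, `n_planned`,
#' `n_realized`, `mean_score`.
#'
#' @param path Path to the counts file. The packaged
#'   `fieldstudy_interventions.csv` carries the per-category counts of the
#'   three-country broiler cohort (13 Dutch, 7 Cypriot, 15 Greek farms) that
#'   motivated the tool.
#' @return Tibble of counts.
#' @export
read_intervention_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      zone = readr::col_character(),
      category_id = readr::col_character(),
      category_label = readr::col_character(),
      n_planned = readr::col_integer(),
      n_realized = readr::col_integer(),
      mean_score = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  assert_zone(counts$zone)
  if (any(counts$n_realized > counts$n_planned)) {
    stop("n_realized exceeds n_planned in ", path, call. = FALSE)
  }
  counts
}

#' Expand an intervention count summary into one row per intervention
#'
#' Turns cohort-level counts (per country/category, or per term/cost cell)
#' back into an intervention-level table so the accounting functions
#' ([zone_totals()], [crosstab_term_cost()], [realization_rate()]) can run on
#' them. Fields absent from the summary are filled with placeholders:
#' country-level summaries get `term = "short"`, `cost = "low"`; term/cost
#' summaries get zone `green` and a placeholder category. Within each cell
#' the first `n_realized` expanded rows are marked realized.
#'
#' @param counts A tibble with `n_planned`, `n_realized` and either
#'   `country`/`zone`/`category_id` or `term`/`cost` columns.
#' @return Intervention tibble (see [read_health_plans()]) with an extra
#'   `country` column when the summary carried one.
#' @export
expand_intervention_counts <- function(counts) {
  stopifnot(all(c("n_planned", "n_realized") %in% names(counts)))
  if (any(counts$n_realized > counts$n_planned)) {
    stop("n_realized exceeds n_planned", call. = FALSE)
  }
  counts <- counts[counts$n_planned > 0, ]
  idx <- rep(seq_len(nrow(counts)), counts$n_planned)
  within <- sequence(counts$n_planned)
  out <- tibble(
    intervention_id = sprintf("iv%05d", seq_along(idx)),
    farm_id = if ("country" %in% names(counts))
      paste0(counts$country[idx], "_pool") else "pool",
    zone = if ("zone" %in% names(counts)) counts$zone[idx] else "green",
    category_id = if ("category_id" %in% names(counts))
      counts$category_id[idx] else "pooled_category",
    description = "expanded from count summary",
    term = if ("term" %in% names(counts)) counts$term[idx] else "short",
    cost = if ("cost" %in% names(counts)) counts$cost[idx] else "low",
    realized = within <= counts$n_realized[idx],
    date_planned = as.Date("2020-01-01"),
    date_evaluated = as.Date(NA)
  )
  if ("country" %in% names(counts)) out$country <- counts$country[idx]
  out
}

#' Read a term-by-cost intervention count summary
#'
#' Columns `term`, `cost`, `n_planned`, `n_realized`. The packaged
#' `fieldstudy_termcost.csv` carries the three-country cohort's cross-tab;
#' since only whole-percent realization rates were published for it, its
#' `n_realized` values are reconstructed as `round(n_planned * pct / 100)`
#' (each reproduces the published percent on re-rounding).
#'
#' @param path Path to the counts file.
#' @return Tibble of counts.
#' @export
read_termcost_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      term = readr::col_character(),
      cost = readr::col_character(),
      n_planned = readr::col_integer(),
      n_realized = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  stopifnot(all(counts$term %in% intervention_terms),
            all(counts$cost %in% intervention_costs))
  if (any(counts$n_realized > counts$n_planned)) {
    stop("n_realized exceeds n_planned in ", path, call. = FALSE)
  }
  counts
}
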