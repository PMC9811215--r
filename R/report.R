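#' Per-farm assessment report
#'
#' Bundles everything the farmer and veterinarian look at after an
#' assessment: per-zone scores with traffic lights, the weakest risk
#' categories, the health-plan status, and the cycle monitoring trend.
#' Sections whose input is absent are marked `"no data"` rather than
#' failing.
#'
#' @param farm_id The farm to report on.
#' @param questionnaire A `beat_questionnaire`.
#' @param answers Answers tibble containing the farm.
#' @param plans Optional intervention tibble.
#' @param cycles Optional cycle tibble.
#' @param k Number of weakest categories to list (default 5).
#' @param thresholds Traffic-light thresholds.
#' @return A `beat_farm_report` list: `farm_id`, `zones`, `categories`,
#'   `targets`, `plan_status`, `monitoring`.
#' @export
report_farm <- function(farm_id, questionnaire, answers, plans = NULL,
                        cycles = NULL, k = 5, thresholds = c(0.4, 0.7)) {
  if (!farm_id %in% answers$farm_id) {
    stop("unknown farm_id: ", farm_id, call. = FALSE)
  }
  own <- answers[answers$farm_id == farm_id, ]
  sc <- score_farms(questionnaire, own, thresholds)
  targets <- suppressWarnings(
    suggest_targets(sc$categories, k = k, perfection_filter = 1)
  )
  plan_status <- NULL
  if (!is.null(plans)) {
    own_plans <- plans[plans$farm_id == farm_id, ]
    plan_status <- zone_totals(own_plans)
  }
  monitoring <- NULL
  if (!is.null(cycles)) {
    own_cycles <- cycles[cycles$farm_id == farm_id, ]
    if (nrow(own_cycles)) {
      if (!"phase" %in% names(own_cycles)) {
        own_cycles$phase <- cycle_phase(own_cycles$cycle_index)
      }
      monitoring <- own_cycles[order(own_cycles$cycle_index),
                               intersect(c("cycle_index", "phase", "amu_used",
                                           "amu_days", "footpad_score",
                                           "mortality_pct"),
                                         names(own_cycles))]
    }
  }
  structure(list(farm_id = farm_id, zones = sc$zones,
                 categories = sc$categories, targets = targets,
                 plan_status = plan_status, monitoring = monitoring),
            class = "beat_farm_report")
}

#' @export
print.beat_farm_report <- function(x, ...) {
  cat("== Farm report:", x$farm_id, "==\n\nZone scores:\n")
  z <- x$zones
  for (i in seq_len(nrow(z))) {
    cat(sprintf("  %-13s %5.2f  [%s]\n", z$zone[i], round(z$relative[i], 2),
                as.character(z$traffic_light[i])))
  }
  if (nrow(x$targets)) {
    cat("\nWeakest categories (intervention targets):\n")
    t <- x$targets
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %-28s %-13s %5.2f\n", t$category_id[i], t$zone[i],
                  round(t$relative[i], 2)))
    }
  } else {
    cat("\nNo categories below full compliance.\n")
  }
  if (!is.null(x$plan_status)) {
    cat("\nHealth plan: ", sum(x$plan_status$n_realized), "/",
        sum(x$plan_status$n_planned), " interventions realized\n", sep = "")
  } else {
    cat("\nHealth plan: no data\n")
  }
  if (!is.null(x$monitoring)) {
    cat("\nMonitoring (", nrow(x$monitoring), " cycles): footpad ",
        paste(round(x$monitoring$footpad_score, 1), collapse = " -> "),
        "\n", sep = "")
  } else {
    cat("\nMonitoring: no data\n")
  }
  invisible(x)
}

#' Cohort-level report tables
#'
#' The three summary tables a multi-country evaluation reports: per-category
#' mean scores with intervention counts per country, the term-by-cost
#' cross-tab, and the per-cycle antimicrobial-use summary. Their totals obey
#' the conservation identity: zone totals and term/cost cells both sum to
#' the total number of interventions.
#'
#' @param questionnaire A `beat_questionnaire`.
#' @param answers Answers tibble (all farms).
#' @param farms `farm_id`/`country` table.
#' @param plans Optional intervention tibble.
#' @param cycles Optional cycle tibble.
#' @return A list of tibbles: `category_scores` (category x country mean/sd
#'   plus interventions planned/realized), `zone_scores`, `term_cost`,
#'   `amu`, `realization`.
#' @export
report_cohort <- function(questionnaire, answers, farms, plans = NULL,
                          cycles = NULL) {
  sc <- score_farms(questionnaire, answers)
  cat_by_country <- aggregate_scores(sc$categories, farms, "country")
  cat_overall <- aggregate_scores(sc$categories, group_by = "overall")
  zone_by_country <- aggregate_scores(sc$zones, farms, "country")
  zone_overall <- aggregate_scores(sc$zones, group_by = "overall")

  category_scores <- dplyr::bind_rows(cat_by_country, cat_overall)
  if (!is.null(plans)) {
    iv <- plans |>
      dplyr::left_join(farms[, c("farm_id", "country")], by = "farm_id") |>
      dplyr::group_by(category_id = .data$category_id, group = .data$country) |>
      dplyr::summarise(n_planned = dplyr::n(),
                       n_realized = sum(.data$realized), .groups = "drop")
    category_scores <- dplyr::left_join(category_scores, iv,
                                        by = c("category_id", "group"))
    category_scores$n_planned[is.na(category_scores$n_planned)] <- 0L
    category_scores$n_realized[is.na(category_scores$n_realized)] <- 0L
  }
  out <- list(
    category_scores = category_scores,
    zone_scores = dplyr::bind_rows(zone_by_country, zone_overall),
    term_cost = if (!is.null(plans)) crosstab_term_cost(plans),
    amu = if (!is.null(cycles)) amu_summary(cycles, farms),
    realization = if (!is.null(plans))
      realization_rate(plans, farms, "country")
  )
  structure(out, class = "beat_cohort_report")
}

#' @export
print.beat_cohort_report <- function(x, ...) {
  cat("== Cohort report ==\n")
  cat("zone scores (mean relative):\n")
  print(as.data.frame(x$zone_scores), row.names = FALSE, digits = 3)
  if (!is.null(x$realization)) {
    cat("\nrealization rates:\n")
    print(as.data.frame(x$realization), row.names = FALSE)
  }
  invisible(x)
}

#' Write cohort report tables to a directory
#'
#' @param report A `beat_cohort_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "beat_cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report)) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       progress = FALSE, na = "")
    }
  }
  invisible(dir)
}
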