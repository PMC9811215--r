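#' Read an assessment answers file
#'
#' One row per answered question: columns `farm_id`, `date` (ISO 8601),
#' `question_id`, `option_id`; an empty `option_id` cell records a
#' not-applicable answer (only allowed on questions flagged `allow_na`).
#' The file may hold several farms; each farm has at most one answer per
#' question.
#'
#' @param path Path to the answers file.
#' @param questionnaire Optional `beat_questionnaire` to validate against.
#' @return Tibble with columns `farm_id`, `date`, `question_id`, `option_id`.
#' @export
read_answers <- function(path, questionnaire = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ans <- readr::read_csv(
    path,
    col_types = readr::cols(
      farm_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      question_id = readr::col_character(),
      option_id = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(ans)
  if (nrow(prob)) {
    stop("parse error in ", path, " at line ", prob$row[1] + 1L, call. = FALSE)
  }
  if (!is.null(questionnaire)) validate_answers(ans, questionnaire)
  ans
}

#' Validate answers against a questionnaire
#'
#' Checks that every answered question exists, every chosen option belongs to
#' its question, NA answers occur only on `allow_na` questions, and no farm
#' answers a question twice.
#'
#' @param answers Tibble as returned by [read_answers()].
#' @param questionnaire A `beat_questionnaire`.
#' @return `answers`, invisibly.
#' @export
validate_answers <- function(answers, questionnaire) {
  stopifnot(inherits(questionnaire, "beat_questionnaire"))
  unknown_q <- setdiff(answers$question_id, questionnaire$questions$question_id)
  if (length(unknown_q)) {
    stop("answer(s) to unknown question_id: ",
         paste(utils::head(unknown_q, 5), collapse = ", "), call. = FALSE)
  }
  dup <- answers[duplicated(answers[, c("farm_id", "question_id")]), ]
  if (nrow(dup)) {
    stop("more than one answer per question for farm(s): ",
         paste(unique(dup$farm_id), collapse = ", "), call. = FALSE)
  }
  na_rows <- answers[is.na(answers$option_id), ]
  if (nrow(na_rows)) {
    allow <- questionnaire$questions$allow_na[
      match(na_rows$question_id, questionnaire$questions$question_id)]
    if (any(!allow)) {
      stop("NA answer on question(s) that do not allow NA: ",
           paste(unique(na_rows$question_id[!allow]), collapse = ", "),
           call. = FALSE)
    }
  }
  answered <- answers[!is.na(answers$option_id), ]
  key <- paste(answered$question_id, answered$option_id)
  valid <- paste(questionnaire$options$question_id, questionnaire$options$option_id)
  bad <- answered[!(key %in% valid), ]
  if (nrow(bad)) {
    stop("option_id not among the question's options: ",
         paste(utils::head(paste0(bad$question_id, "/", bad$option_id), 5),
               collapse = ", "), call. = FALSE)
  }
  invisible(answers)
}

#' Score a single answered question
#'
#' Returns the points of the chosen option: 1 for full compliance down to 0
#' for no compliance. A not-applicable answer returns `NA` and is excluded
#' from both numerator and denominator downstream.
#'
#' @param questionnaire A `beat_questionnaire`.
#' @param question_id,option_id The answer; `option_id = NA` for a
#'   not-applicable answer.
#' @return A single number in \[0, 1\], or `NA_real_`.
#' @export
score_question <- function(questionnaire, question_id, option_id) {
  stopifnot(inherits(questionnaire, "beat_questionnaire"), length(question_id) == 1L)
  qs <- questionnaire$questions
  if (!question_id %in% qs$question_id) {
    stop("unknown question_id: ", question_id, call. = FALSE)
  }
  if (is.na(option_id)) {
    if (!qs$allow_na[match(question_id, qs$question_id)]) {
      stop("question does not allow a not-applicable answer: ", question_id,
           call. = FALSE)
    }
    return(NA_real_)
  }
  opts <- questionnaire$options
  hit <- opts$question_id == question_id & opts$option_id == option_id
  if (!any(hit)) {
    stop("option_id ", option_id, " not among options of ", question_id,
         call. = FALSE)
  }
  opts$points[hit]
}

#' Per-question scores for one or more farms
#'
#' The long scoring table every zone/category summary is built from: one row
#' per answered question with the attained points, the question's attainable
#' maximum, and the category/zone it belongs to. Not-applicable answers keep
#' `NA` points and are dropped from numerator and denominator by the
#' summaries.
#'
#' @param questionnaire A `beat_questionnaire`.
#' @param answers Answers tibble (see [read_answers()]); may contain several
#'   farms.
#' @return Tibble: `farm_id`, `question_id`, `category_id`, `zone`, `points`,
#'   `max_points`.
#' @export
score_assessment <- function(questionnaire, answers) {
  validate_answers(answers, questionnaire)
  opts <- questionnaire$options
  key <- paste(answers$question_id, answers$option_id)
  pts <- opts$points[match(key, paste(opts$question_id, opts$option_id))]
  pts[is.na(answers$option_id)] <- NA_real_
  maxima <- question_maxima(questionnaire)
  qmeta <- dplyr::left_join(questionnaire$questions,
                            questionnaire$categories[, c("category_id", "zone")],
                            by = "category_id")
  idx <- match(answers$question_id, qmeta$question_id)
  tibble(
    farm_id = answers$farm_id,
    question_id = answers$question_id,
    category_id = qmeta$category_id[idx],
    zone = qmeta$zone[idx],
    points = pts,
    max_points = maxima$max_points[match(answers$question_id, maxima$question_id)]
  )
}

#' @noRd
summarise_relative <- function(scored, group_cols) {
  out <- scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      attained = sum(.data$points[!is.na(.data$points)]),
      attainable = sum(.data$max_points[!is.na(.data$points)]),
      n_answered = sum(!is.na(.data$points)),
      n_na = sum(is.na(.data$points)),
      .groups = "drop"
    )
  out$relative <- ifelse(out$attainable > 0, out$attained / out$attainable, NA_real_)
  out
}

#' Relative score of one zone for one farm
#'
#' Points attained over points attainable across the zone's answered
#' questions. Questions answered not-applicable are excluded from both sums,
#' so an inapplicable topic (say, outdoor areas on an indoor-only farm)
#' neither rewards nor penalises the farm.
#'
#' @param questionnaire A `beat_questionnaire`.
#' @param answers Answers tibble for a single farm.
#' @param zone One of [beat_zones()].
#' @return One-row tibble: `zone`, `attained`, `attainable`, `relative`,
#'   `n_answered`, `n_na`.
#' @export
score_zone <- function(questionnaire, answers, zone) {
  assert_zone(zone)
  stopifnot(length(unique(answers$farm_id)) <= 1L)
  scored <- score_assessment(questionnaire, answers)
  scored <- scored[scored$zone == zone, ]
  if (nrow(scored) == 0L || all(is.na(scored$points))) {
    stop("no scorable questions in zone: ", zone, call. = FALSE)
  }
  out <- summarise_relative(scored, "zone")
  out[, c("zone", "attained", "attainable", "relative", "n_answered", "n_na")]
}

#' Relative score of one risk category for one farm
#'
#' Same attained-over-attainable construction as [score_zone()], restricted
#' to the category's questions.
#'
#' @inheritParams score_zone
#' @param category_id A category of the questionnaire.
#' @return One-row tibble: `category_id`, `zone`, `attained`, `attainable`,
#'   `relative`, `n_answered`, `n_na`.
#' @export
score_category <- function(questionnaire, answers, category_id) {
  if (!category_id %in% questionnaire$categories$category_id) {
    stop("unknown category_id: ", category_id, call. = FALSE)
  }
  stopifnot(length(unique(answers$farm_id)) <= 1L)
  scored <- score_assessment(questionnaire, answers)
  scored <- scored[scored$category_id == category_id, ]
  if (nrow(scored) == 0L || all(is.na(scored$points))) {
    stop("no scorable questions in category: ", category_id, call. = FALSE)
  }
  out <- summarise_relative(scored, c("category_id", "zone"))
  out[, c("category_id", "zone", "attained", "attainable", "relative",
          "n_answered", "n_na")]
}

#' Score all zones and categories for every farm in an answers table
#'
#' @param questionnaire A `beat_questionnaire`.
#' @param answers Answers tibble, possibly many farms.
#' @param thresholds Traffic-light thresholds, see [traffic_light()].
#' @return List of two tibbles: `zones` (farm_id, zone, attained, attainable,
#'   relative, n_answered, n_na, traffic_light) and `categories` (likewise
#'   per category). Zones or categories where a farm answered nothing
#'   scorable are absent from that farm's rows.
#' @export
#' @examples
#' q <- load_questionnaire(beat_example("questionnaire.csv"))
#' coh <- generate_cohort(cohort_config(seed = 1))
#' sc <- score_farms(q, coh$answers)
#' head(sc$zones)
score_farms <- function(questionnaire, answers, thresholds = c(0.4, 0.7)) {
  scored <- score_assessment(questionnaire, answers)
  zones <- summarise_relative(scored, c("farm_id", "zone"))
  zones <- zones[zones$n_answered > 0, ]
  zones$traffic_light <- traffic_light(zones$relative, thresholds)
  zones <- dplyr::arrange(zones, .data$farm_id, zone_factor(.data$zone))
  cats <- summarise_relative(scored, c("farm_id", "category_id", "zone"))
  cats <- cats[cats$n_answered > 0, ]
  cats$traffic_light <- traffic_light(cats$relative, thresholds)
  cats <- dplyr::arrange(cats, .data$farm_id, zone_factor(.data$zone),
                         .data$category_id)
  list(zones = zones, categories = cats)
}

#' Mean and standard deviation of relative scores across farms
#'
#' Cohort aggregation of farm-level relative scores, per country or pooled
#' over all farms. The pooled column of a cohort report is the mean over all
#' farms, not the mean of country means. Groups with a single farm report an
#' `NA` standard deviation.
#'
#' @param scores Tibble of farm-level scores with at least `farm_id`,
#'   `relative`, and the unit columns (`zone` and/or `category_id`).
#' @param farms Optional tibble mapping `farm_id` to `country`; required when
#'   `group_by = "country"`.
#' @param group_by `"country"` or `"overall"`.
#' @return Tibble with the unit columns, `group`, `mean`, `sd`, `n`.
#' @export
aggregate_scores <- function(scores, farms = NULL,
                             group_by = c("country", "overall")) {
  group_by <- match.arg(group_by)
  if (nrow(scores) == 0L) stop("empty score table", call. = FALSE)
  unit_cols <- intersect(c("zone", "category_id"), names(scores))
  if (group_by == "country") {
    if (is.null(farms)) stop("grouping by country needs a farms table", call. = FALSE)
    scores <- dplyr::left_join(scores, farms[, c("farm_id", "country")],
                               by = "farm_id")
    if (any(is.na(scores$country))) {
      stop("farm(s) missing from the farms table: ",
           paste(unique(scores$farm_id[is.na(scores$country)]), collapse = ", "),
           call. = FALSE)
    }
    scores$group <- scores$country
  } else {
    scores$group <- "overall"
  }
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(unit_cols, "group")))) |>
    dplyr::summarise(
      mean = mean(.data$relative),
      sd = if (dplyr::n() > 1L) stats::sd(.data$relative) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
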