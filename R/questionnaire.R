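#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Construct a questionnaire object
#'
#' A questionnaire is the assessment instrument itself: risk categories
#' assigned to one of the five farm zones, questions within categories, and
#' predefined answer options each worth between 0 (no compliance) and 1
#' (full compliance) points.
#'
#' @param name,version Instrument name and version strings.
#' @param categories Tibble with columns `category_id`, `zone`, `label`.
#' @param questions Tibble with columns `question_id`, `category_id`, `text`,
#'   `allow_na` (logical).
#' @param options Tibble with columns `question_id`, `option_id`, `text`,
#'   `points` (numeric in \[0, 1\]).
#' @return An object of class `beat_questionnaire`: a list with elements
#'   `name`, `version`, `categories`, `questions`, `options`, validated
#'   against the structural invariants (unique ids, no dangling references,
#'   all five zones represented, every question discriminates).
#' @export
beat_questionnaire <- function(name, version, categories, questions, options) {
  q <- structure(
    list(
      name = as.character(name),
      version = as.character(version),
      categories = as_tibble(categories)[, c("category_id", "zone", "label")],
      questions = as_tibble(questions)[, c("question_id", "category_id", "text", "allow_na")],
      options = as_tibble(options)[, c("question_id", "option_id", "text", "points")]
    ),
    class = "beat_questionnaire"
  )
  q$categories$zone <- as.character(q$categories$zone)
  q$questions$allow_na <- as.logical(q$questions$allow_na)
  q$options$points <- as.numeric(q$options$points)
  validate_questionnaire(q)
  q
}

#' Validate a questionnaire against its structural invariants
#'
#' Checks id uniqueness, reference integrity between options, questions and
#' categories, the 0--1 point range, zone coverage (all five zones must carry
#' at least one category with questions), and that every question has at
#' least two options of which one is worth the full point and one less (a
#' question that cannot discriminate compliance is rejected).
#'
#' @param q A `beat_questionnaire`.
#' @return `q`, invisibly; stops with an informative message otherwise.
#' @export
validate_questionnaire <- function(q) {
  stopifnot(inherits(q, "beat_questionnaire"))
  cats <- q$categories
  qs <- q$questions
  opts <- q$options

  if (nrow(qs) == 0L) stop("invalid questionnaire: no questions", call. = FALSE)
  assert_zone(cats$zone)
  if (anyDuplicated(cats$category_id)) {
    stop("duplicate category_id: ",
         paste(unique(cats$category_id[duplicated(cats$category_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(qs$question_id)) {
    stop("duplicate question_id: ",
         paste(unique(qs$question_id[duplicated(qs$question_id)]), collapse = ", "),
         call. = FALSE)
  }
  dangling <- setdiff(qs$category_id, cats$category_id)
  if (length(dangling)) {
    stop("question(s) reference unknown category_id: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  empty_cat <- setdiff(cats$category_id, qs$category_id)
  if (length(empty_cat)) {
    stop("category without questions: ", paste(empty_cat, collapse = ", "),
         call. = FALSE)
  }
  missing_zone <- setdiff(beat_zones(), cats$zone)
  if (length(missing_zone)) {
    stop("zone(s) not represented by any category: ",
         paste(missing_zone, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(opts$question_id, qs$question_id)
  if (length(orphan)) {
    stop("option(s) reference unknown question_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(opts$points)) || any(opts$points < 0 | opts$points > 1)) {
    stop("option points must lie in [0, 1]", call. = FALSE)
  }
  dup_opt <- opts[duplicated(opts[, c("question_id", "option_id")]), ]
  if (nrow(dup_opt)) {
    stop("duplicate option_id within question: ",
         paste(unique(dup_opt$question_id), collapse = ", "), call. = FALSE)
  }
  per_q <- dplyr::summarise(
    dplyr::group_by(opts, .data$question_id),
    n = dplyr::n(), best = max(.data$points), worst = min(.data$points),
    .groups = "drop"
  )
  no_opts <- setdiff(qs$question_id, per_q$question_id)
  if (length(no_opts)) {
    stop("question without answer options: ", paste(no_opts, collapse = ", "),
         call. = FALSE)
  }
  bad <- per_q[per_q$n < 2L | per_q$best < 1 | per_q$worst >= 1, ]
  if (nrow(bad)) {
    stop("question(s) cannot discriminate (need >= 2 options, one worth 1 ",
         "and one worth < 1): ", paste(bad$question_id, collapse = ", "),
         call. = FALSE)
  }
  invisible(q)
}

#' @export
print.beat_questionnaire <- function(x, ...) {
  zc <- table(zone_factor(x$categories$zone))
  cat("<beat_questionnaire> ", x$name, " v", x$version, "\n", sep = "")
  cat("  ", nrow(x$categories), " risk categories, ", nrow(x$questions),
      " questions, ", nrow(x$options), " answer options\n", sep = "")
  cat("  categories per zone: ",
      paste(names(zc), zc, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

q_definition_cols <- c("zone", "category_id", "category_label", "question_id",
                       "question_text", "option_id", "option_text", "points",
                       "allow_na")

#' Read a questionnaire definition file
#'
#' The definition file is a UTF-8 comma-delimited table with one row per
#' answer option and columns `zone`, `category_id`, `category_label`,
#' `question_id`, `question_text`, `option_id`, `option_text`, `points`,
#' `allow_na`. The decimal separator is the point. The parsed instrument is
#' validated with [validate_questionnaire()].
#'
#' @param path Path to the definition file.
#' @param name,version Instrument name/version recorded on the object;
#'   default to the file name and `"1"`.
#' @return A `beat_questionnaire`.
#' @export
#' @examples
#' q <- load_questionnaire(beat_example("questionnaire.csv"))
#' q
load_questionnaire <- function(path, name = basename(path), version = "1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      zone = readr::col_character(),
      category_id = readr::col_character(),
      category_label = readr::col_character(),
      question_id = readr::col_character(),
      question_text = readr::col_character(),
      option_id = readr::col_character(),
      option_text = readr::col_character(),
      points = readr::col_double(),
      allow_na = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    stop("parse error in ", path, " at line ", prob$row[1] + 1L, ": expected ",
         prob$expected[1], ", got ", prob$actual[1], call. = FALSE)
  }
  missing_cols <- setdiff(q_definition_cols, names(raw))
  if (length(missing_cols)) {
    stop("definition file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("invalid questionnaire: no questions", call. = FALSE)

  categories <- dplyr::distinct(raw, category_id = .data$category_id,
                                zone = .data$zone, label = .data$category_label)
  if (anyDuplicated(categories$category_id)) {
    stop("category_id mapped to more than one zone or label: ",
         paste(unique(categories$category_id[duplicated(categories$category_id)]),
               collapse = ", "), call. = FALSE)
  }
  questions <- dplyr::distinct(raw, question_id = .data$question_id,
                               category_id = .data$category_id,
                               text = .data$question_text,
                               allow_na = .data$allow_na)
  if (anyDuplicated(questions$question_id)) {
    stop("question_id with inconsistent category/text/allow_na: ",
         paste(unique(questions$question_id[duplicated(questions$question_id)]),
               collapse = ", "), call. = FALSE)
  }
  options <- tibble(question_id = raw$question_id, option_id = raw$option_id,
                    text = raw$option_text, points = raw$points)
  beat_questionnaire(name, version, categories, questions, options)
}

#' Write a questionnaire definition file
#'
#' Inverse of [load_questionnaire()]: one row per answer option. A written
#' file parses back to a field-by-field identical instrument.
#'
#' @param q A `beat_questionnaire`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path) {
  validate_questionnaire(q)
  flat <- q$options |>
    dplyr::left_join(dplyr::rename(q$questions, question_text = "text"),
                     by = "question_id") |>
    dplyr::left_join(dplyr::rename(q$categories, category_label = "label"),
                     by = "category_id") |>
    dplyr::transmute(
      zone = .data$zone, category_id = .data$category_id,
      category_label = .data$category_label, question_id = .data$question_id,
      question_text = .data$question_text, option_id = .data$option_id,
      option_text = .data$text, points = .data$points, allow_na = .data$allow_na
    )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Maximum attainable points in a zone
#'
#' The denominator of the relative zone score: the sum, over the zone's
#' questions, of each question's best option points.
#'
#' @param q A `beat_questionnaire`.
#' @param zone One of [beat_zones()].
#' @return A positive number.
#' @export
max_points <- function(q, zone) {
  stopifnot(inherits(q, "beat_questionnaire"), length(zone) == 1L)
  assert_zone(zone)
  qids <- zone_question_ids(q, zone)
  if (length(qids) == 0L) stop("zone has no questions: ", zone, call. = FALSE)
  maxima <- question_maxima(q)
  sum(maxima$max_points[maxima$question_id %in% qids])
}

#' @noRd
zone_question_ids <- function(q, zone) {
  cat_ids <- q$categories$category_id[q$categories$zone == zone]
  q$questions$question_id[q$questions$category_id %in% cat_ids]
}

#' @noRd
question_maxima <- function(q) {
  dplyr::summarise(dplyr::group_by(q$options, .data$question_id),
                   max_points = max(.data$points), .groups = "drop")
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
#' @examples
#' beat_example()
beat_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "beatr")))
  }
  path <- system.file("extdata", file, package = "beatr")
  if (identical(path, "")) stop("no packaged file called ", file, call. = FALSE)
  path
}
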