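# Shared in-code fixtures: a small five-zone toy instrument and answer
# builders. The packaged instrument is loaded once for the heavier tests.

toy_questionnaire <- function() {
  categories <- tibble::tibble(
    category_id = c("g_hygiene", "og_access", "o_yard", "ro_gate", "r_area"),
    zone = c("green", "orange_green", "orange", "red_orange", "red"),
    label = c("House hygiene", "Access control", "Yard order", "Gate",
              "Surroundings")
  )
  questions <- tibble::tibble(
    question_id = c("g1", "g2", "og1", "o1", "ro1", "r1"),
    category_id = c("g_hygiene", "g_hygiene", "og_access", "o_yard",
                    "ro_gate", "r_area"),
    text = paste("question", c("g1", "g2", "og1", "o1", "ro1", "r1")),
    allow_na = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  options <- dplyr::bind_rows(lapply(questions$question_id, function(qid) {
    tibble::tibble(question_id = qid, option_id = c("a", "b", "c"),
                   text = c("yes", "partly", "no"), points = c(1, 0.5, 0))
  }))
  beatr::beat_questionnaire("toy", "1", categories, questions, options)
}

# answers for a single farm: named vector question_id -> option_id
# (NA_character_ marks a not-applicable answer)
make_answers <- function(choices, farm_id = "F1", date = as.Date("2020-01-15")) {
  tibble::tibble(farm_id = farm_id, date = date,
                 question_id = names(choices),
                 option_id = unname(choices))
}

# every question of a questionnaire answered with the option at `rank`
# (1 = best) in each question's option list, points-descending
uniform_answers <- function(q, rank = 1L, farm_id = "F1") {
  picks <- q$options |>
    dplyr::group_by(question_id) |>
    dplyr::arrange(dplyr::desc(points), option_id, .by_group = TRUE) |>
    dplyr::summarise(option_id = option_id[min(rank, dplyr::n())],
                     .groups = "drop")
  tibble::tibble(farm_id = farm_id, date = as.Date("2020-01-15"),
                 question_id = picks$question_id, option_id = picks$option_id)
}

fixture_questionnaire <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- beatr::load_questionnaire(beatr::beat_example("questionnaire.csv"))
    }
    cache
  }
})

# random answers over a questionnaire: each question gets a uniformly chosen
# option; allow_na questions may draw NA with probability na_prob
random_answers <- function(q, farm_id = "F1", na_prob = 0.1) {
  opts <- split(q$options$option_id, q$options$question_id)
  qids <- q$questions$question_id
  allow <- q$questions$allow_na
  picked <- vapply(seq_along(qids), function(i) {
    if (allow[i] && stats::runif(1) < na_prob) return(NA_character_)
    sample(opts[[qids[i]]], 1L)
  }, "")
  tibble::tibble(farm_id = farm_id, date = as.Date("2020-01-15"),
                 question_id = qids, option_id = picked)
}
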