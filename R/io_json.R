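#' Read a questionnaire from a structured (JSON) definition
#'
#' Accepts the key-value tree serialization of the instrument: a top-level
#' object with `name`, `version` and a `categories` array, each category
#' holding its `questions`, each question its `options`
#' (`option_id`, `text`, `points`). Validated against exactly the same
#' invariants as the delimited reader, so the two formats are
#' interchangeable.
#'
#' @param path Path to a `.json` definition file.
#' @return A `beat_questionnaire`.
#' @export
load_questionnaire_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required to read JSON definitions",
         call. = FALSE)
  }
  tree <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(tree$categories) || !length(tree$categories)) {
    stop("invalid questionnaire: no questions", call. = FALSE)
  }
  cats <- list(); qs <- list(); opts <- list()
  for (cat_node in tree$categories) {
    cats[[length(cats) + 1L]] <- tibble(
      category_id = cat_node$category_id %||% stop("category without category_id"),
      zone = cat_node$zone %||% stop("category without zone"),
      label = cat_node$label %||% cat_node$category_id
    )
    for (q_node in cat_node$questions %||% list()) {
      qs[[length(qs) + 1L]] <- tibble(
        question_id = q_node$question_id %||% stop("question without question_id"),
        category_id = cat_node$category_id,
        text = q_node$text %||% "",
        allow_na = isTRUE(q_node$allow_na %||% TRUE)
      )
      for (o_node in q_node$options %||% list()) {
        opts[[length(opts) + 1L]] <- tibble(
          question_id = q_node$question_id,
          option_id = o_node$option_id %||% stop("option without option_id"),
          text = o_node$text %||% "",
          points = as.numeric(o_node$points %||%
                                stop("option without points"))
        )
      }
    }
  }
  if (!length(qs)) stop("invalid questionnaire: no questions", call. = FALSE)
  beat_questionnaire(
    name = tree$name %||% basename(path),
    version = as.character(tree$version %||% "1"),
    categories = dplyr::bind_rows(cats),
    questions = dplyr::bind_rows(qs),
    options = dplyr::bind_rows(opts)
  )
}

#' Write a questionnaire as a structured (JSON) definition
#'
#' @param q A `beat_questionnaire`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_questionnaire_json <- function(q, path) {
  validate_questionnaire(q)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required to write JSON definitions",
         call. = FALSE)
  }
  cats <- lapply(seq_len(nrow(q$categories)), function(i) {
    cat_row <- q$categories[i, ]
    qrows <- q$questions[q$questions$category_id == cat_row$category_id, ]
    questions <- lapply(seq_len(nrow(qrows)), function(j) {
      qrow <- qrows[j, ]
      orows <- q$options[q$options$question_id == qrow$question_id, ]
      list(
        question_id = qrow$question_id, text = qrow$text,
        allow_na = qrow$allow_na,
        options = lapply(seq_len(nrow(orows)), function(k) {
          list(option_id = orows$option_id[k], text = orows$text[k],
               points = orows$points[k])
        })
      )
    })
    list(category_id = cat_row$category_id, zone = cat_row$zone,
         label = cat_row$label, questions = questions)
  })
  jsonlite::write_json(
    list(name = q$name, version = q$version, categories = cats),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
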