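#' Pre/post-intervention phase of a production cycle
#'
#' The follow-up design is four production cycles per farm: cycles 1--2
#' before the health plan is implemented, cycles 3--4 after. Phase is a pure
#' function of the cycle index.
#'
#' @param cycle_index Integer vector with values in 1..4.
#' @return Character vector, `"pre"` or `"post"`.
#' @export
cycle_phase <- function(cycle_index) {
  if (any(!cycle_index %in% 1:4)) {
    stop("cycle_index must be in 1..4", call. = FALSE)
  }
  ifelse(cycle_index <= 2L, "pre", "post")
}

#' Flock-level footpad lesion score
#'
#' Footpad dermatitis is scored per bird at slaughter in three severity
#' classes (0 none, 1 mild, 2 severe). The flock score is the weighted
#' prevalence `100 * (w0*n0 + w1*n1 + w2*n2) / (n0+n1+n2)` with the standard
#' surveillance weights 0 / 0.5 / 2, giving a 0--200 scale; the weights are
#' configurable.
#'
#' @param n_class0,n_class1,n_class2 Bird counts per lesion class
#'   (vectorised).
#' @param weights Nonnegative length-3 weights, default `c(0, 0.5, 2)`.
#' @return Numeric vector of flock scores in `[0, 100 * max(weights)]`.
#' @export
#' @examples
#' flock_footpad_score(50, 30, 20) # 55
flock_footpad_score <- function(n_class0, n_class1, n_class2,
                                weights = c(0, 0.5, 2)) {
  stopifnot(is.numeric(weights), length(weights) == 3L, all(weights >= 0))
  n0 <- as.numeric(n_class0); n1 <- as.numeric(n_class1); n2 <- as.numeric(n_class2)
  if (any(c(n0, n1, n2) < 0, na.rm = TRUE)) {
    stop("class counts must be nonnegative", call. = FALSE)
  }
  total <- n0 + n1 + n2
  if (any(total <= 0, na.rm = TRUE)) {
    stop("flock footpad score undefined for zero scored birds", call. = FALSE)
  }
  100 * (weights[1] * n0 + weights[2] * n1 + weights[3] * n2) / total
}

#' Read a production-cycle monitoring file
#'
#' One row per farm and cycle with columns `farm_id`, `cycle_index` (1--4),
#' `start_month` (1--12), `amu_used` (true/false), `amu_days` (total
#' antimicrobial treatment days in the cycle, 0 when unused),
#' `n_class0`/`n_class1`/`n_class2` (footpad lesion class counts),
#' `mortality_pct`, `slaughter_age_days`, `slaughter_weight_g`. The
#' pre/post phase and the flock footpad score are derived on read.
#'
#' @param path Path to the cycle log.
#' @param weights Footpad class weights, see [flock_footpad_score()].
#' @return Tibble with the file columns plus `phase` and `footpad_score`.
#' @export
read_cycles <- function(path, weights = c(0, 0.5, 2)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cyc <- readr::read_csv(
    path,
    col_types = readr::cols(
      farm_id = readr::col_character(),
      cycle_index = readr::col_integer(),
      start_month = readr::col_integer(),
      amu_used = readr::col_logical(),
      amu_days = readr::col_integer(),
      n_class0 = readr::col_integer(),
      n_class1 = readr::col_integer(),
      n_class2 = readr::col_integer(),
      mortality_pct = readr::col_double(),
      slaughter_age_days = readr::col_integer(),
      slaughter_weight_g = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(cyc)
  if (nrow(prob)) {
    stop("parse error in ", path, " at line ", prob$row[1] + 1L, call. = FALSE)
  }
  validate_cycles(cyc)
  cyc$phase <- cycle_phase(cyc$cycle_index)
  cyc$footpad_score <- flock_footpad_score(cyc$n_class0, cyc$n_class1,
                                           cyc$n_class2, weights)
  cyc
}

#' Validate a cycle monitoring table
#'
#' @param cycles Cycle tibble (see [read_cycles()]).
#' @return `cycles`, invisibly.
#' @export
validate_cycles <- function(cycles) {
  if (any(!cycles$cycle_index %in% 1:4)) {
    stop("cycle_index must be in 1..4", call. = FALSE)
  }
  if (any(!cycles$start_month %in% 1:12)) {
    stop("start_month must be in 1..12", call. = FALSE)
  }
  if (any(cycles$amu_days < 0)) stop("amu_days must be >= 0", call. = FALSE)
  if (any(!cycles$amu_used & cycles$amu_days > 0)) {
    stop("amu_days must be 0 when amu_used is false", call. = FALSE)
  }
  dup <- cycles[duplicated(cycles[, c("farm_id", "cycle_index")]), ]
  if (nrow(dup)) {
    stop("duplicate farm/cycle record(s): ",
         paste(unique(dup$farm_id), collapse = ", "), call. = FALSE)
  }
  if (any(cycles$mortality_pct < 0, na.rm = TRUE)) {
    stop("mortality_pct must be >= 0", call. = FALSE)
  }
  invisible(cycles)
}

#' Antimicrobial-use summary per country and cycle
#'
#' For every country-by-cycle cell: how many farms used antimicrobials, and
#' the median and mean treatment days among those users only (the mean to
#' one decimal). Cells without any user report zero farms and `NA` days;
#' farms without use never influence the day statistics.
#'
#' @param cycles Cycle tibble with a `country` column, or with a `farms`
#'   table supplied for the join.
#' @param farms Optional `farm_id`/`country` map.
#' @return Tibble: `country`, `cycle_index`, `n_farms_amu`, `median_days`,
#'   `mean_days`.
#' @export
amu_summary <- function(cycles, farms = NULL) {
  cycles <- join_country(cycles, farms)
  cycles |>
    dplyr::group_by(.data$country, .data$cycle_index) |>
    dplyr::summarise(
      n_farms_amu = sum(.data$amu_used),
      median_days = if (any(.data$amu_used))
        stats::median(.data$amu_days[.data$amu_used]) else NA_real_,
      mean_days = if (any(.data$amu_used))
        round(mean(.data$amu_days[.data$amu_used]), 1) else NA_real_,
      .groups = "drop"
    )
}

#' Percent of flock-cycles treated with antimicrobials
#'
#' Treated flock-cycles over all flock-cycles per group. The whole-percent
#' figure is reported by truncation (a group is only "43%" treated once the
#' full percent is reached); the exact value is returned alongside.
#'
#' @param cycles Cycle tibble.
#' @param farms Optional `farm_id`/`country` map.
#' @param group_by `"country"` or `"overall"`.
#' @return Tibble: `group`, `n_cycles`, `n_treated`, `prevalence_exact`
#'   (unrounded percent), `prevalence_pct` (whole percent, truncated).
#' @export
#' @examples
#' amu <- read_amu_counts(beat_example("fieldstudy_amu.csv"))
#' flock_treatment_prevalence(expand_amu_counts(amu))
flock_treatment_prevalence <- function(cycles, farms = NULL,
                                       group_by = c("country", "overall")) {
  group_by <- match.arg(group_by)
  if (nrow(cycles) == 0L) stop("empty cycle table", call. = FALSE)
  if (group_by == "country") {
    cycles <- join_country(cycles, farms)
    cycles$group <- cycles$country
  } else {
    cycles$group <- "overall"
  }
  out <- cycles |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_cycles = dplyr::n(), n_treated = sum(.data$amu_used),
                     .groups = "drop")
  out$prevalence_exact <- 100 * out$n_treated / out$n_cycles
  out$prevalence_pct <- floor(out$prevalence_exact)
  out
}

#' @noRd
join_country <- function(cycles, farms) {
  if (!"country" %in% names(cycles)) {
    if (is.null(farms)) {
      stop("cycle table has no country column and no farms table was given",
           call. = FALSE)
    }
    cycles <- dplyr::left_join(cycles, farms[, c("farm_id", "country")],
                               by = "farm_id")
    if (any(is.na(cycles$country))) {
      stop("farm(s) missing from the farms table: ",
           paste(unique(cycles$farm_id[is.na(cycles$country)]), collapse = ", "),
           call. = FALSE)
    }
  }
  cycles
}

#' Descriptive summary of mortality and slaughter parameters
#'
#' Mortality and the technical parameters are carried descriptively only:
#' mean and SD per country and phase.
#'
#' @param cycles Cycle tibble.
#' @param farms Optional `farm_id`/`country` map.
#' @return Tibble with per country/phase means and SDs of `mortality_pct`,
#'   `slaughter_age_days`, `slaughter_weight_g`.
#' @export
technical_summary <- function(cycles, farms = NULL) {
  cycles <- join_country(cycles, farms)
  if (!"phase" %in% names(cycles)) cycles$phase <- cycle_phase(cycles$cycle_index)
  cycles |>
    dplyr::group_by(.data$country, .data$phase) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("mortality_pct", "slaughter_age_days",
                                    "slaughter_weight_g")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~stats::sd(.x, na.rm = TRUE))),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Read a per-country AMU count summary
#'
#' Cohort-level antimicrobial-use bookkeeping: one row per country and cycle
#' with the number of farms in the country, the number that used
#' antimicrobials in that cycle, and the median/mean treatment days among
#' users. The packaged `fieldstudy_amu.csv` carries the three-country
#' cohort's counts.
#'
#' @param path Path to the counts file.
#' @return Tibble: `country`, `n_farms`, `cycle_index`, `n_farms_amu`,
#'   `median_days`, `mean_days`.
#' @export
read_amu_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      country = readr::col_character(),
      n_farms = readr::col_integer(),
      cycle_index = readr::col_integer(),
      n_farms_amu = readr::col_integer(),
      median_days = readr::col_double(),
      mean_days = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (any(counts$n_farms_amu > counts$n_farms)) {
    stop("n_farms_amu exceeds n_farms in ", path, call. = FALSE)
  }
  counts
}

#' Expand an AMU count summary into one row per flock-cycle
#'
#' Turns per-country/cycle counts of treated farms back into a flock-cycle
#' table (`amu_used` true for the counted farms, false for the rest) so
#' [flock_treatment_prevalence()] can run on it. Treatment days are not
#' reconstructed (`amu_days` is set to the cell median for users, 0
#' otherwise).
#'
#' @param counts Tibble as from [read_amu_counts()].
#' @return Cycle tibble with `country`, `farm_id`, `cycle_index`,
#'   `amu_used`, `amu_days`.
#' @export
expand_amu_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n_farms[i]
    k <- counts$n_farms_amu[i]
    tibble(
      country = counts$country[i],
      farm_id = sprintf("%s%02d", counts$country[i], seq_len(n)),
      cycle_index = counts$cycle_index[i],
      amu_used = seq_len(n) <= k,
      amu_days = ifelse(seq_len(n) <= k,
                        ifelse(is.na(counts$median_days[i]), 1,
                               counts$median_days[i]), 0)
    )
  })
  dplyr::bind_rows(rows)
}
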