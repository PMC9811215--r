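#' Configuration of a synthetic farm cohort
#'
#' The generator emulates the study design the evaluation pipeline expects:
#' a multi-country broiler cohort (default 13 + 7 + 15 farms in three
#' countries) followed for four production cycles, two before and two after
#' the health-plan interventions. Farm compliance is drawn per zone from a
#' Beta distribution; interventions are drafted for weak categories and
#' realized with term/cost-graded probabilities; flock footpad scores follow
#' a winter-peaking seasonal cosine plus a country offset and Gaussian
#' noise; antimicrobial use is a phase-specific Bernoulli with overdispersed
#' (negative-binomial, truncated at 1 day) treatment days.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param countries Tibble with `country`, `n_farms`.
#' @param beta_params_per_zone Tibble `zone`, `alpha`, `beta` giving each
#'   zone's compliance distribution across farms. Defaults put mean
#'   compliance near 0.7 in the green zone falling to 0.4 in the red zone,
#'   the gradient the zoning model expects.
#' @param weak_threshold Categories scoring below this are intervention
#'   targets (default 0.6).
#' @param intervention_rate Expected interventions per weak category
#'   (Poisson, default 1).
#' @param realization_probs Tibble `term`, `cost`, `prob` of realization;
#'   defaults grade from short/low 0.53 down to long/high 0.01.
#' @param footpad_baseline Mean flock footpad score (0--200 scale, default
#'   60).
#' @param footpad_month_amplitude Amplitude of the seasonal cosine (peaks in
#'   January; default 25).
#' @param footpad_country_sd SD of the per-country offset (default 15).
#' @param footpad_noise_sd Residual SD (default 20).
#' @param amu_prob_by_phase Named length-2 vector, probability a flock-cycle
#'   is treated pre/post intervention (default 0.75 / 0.65).
#' @param amu_days_mean,amu_days_size Negative-binomial mean and size for
#'   treatment days of treated flocks (truncated at >= 1; defaults 6 and 4,
#'   matching small overdispersed counts).
#' @param na_prob Probability an `allow_na` question is answered
#'   not-applicable (default 0.05).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    seed = 1L,
    countries = tibble(country = c("NL", "CY", "GR"), n_farms = c(13L, 7L, 15L)),
    beta_params_per_zone = tibble(
      zone = beat_zones(),
      alpha = c(5.6, 4.4, 5.2, 4.8, 3.2),
      beta = c(2.4, 3.6, 2.8, 3.2, 4.8)
    ),
    weak_threshold = 0.6,
    intervention_rate = 1,
    realization_probs = tibble(
      term = rep(c("short", "medium", "long"), each = 3),
      cost = rep(c("low", "medium", "high"), 3),
      prob = c(0.53, 0.43, 0.10, 0.51, 0.12, 0.21, 0.30, 0.20, 0.01)
    ),
    footpad_baseline = 60,
    footpad_month_amplitude = 25,
    footpad_country_sd = 15,
    footpad_noise_sd = 20,
    amu_prob_by_phase = c(pre = 0.75, post = 0.65),
    amu_days_mean = 6,
    amu_days_size = 4,
    na_prob = 0.05) {
  cfg <- structure(
    list(seed = as.integer(seed), countries = as_tibble(countries),
         beta_params_per_zone = as_tibble(beta_params_per_zone),
         weak_threshold = weak_threshold,
         intervention_rate = intervention_rate,
         realization_probs = as_tibble(realization_probs),
         footpad_baseline = footpad_baseline,
         footpad_month_amplitude = footpad_month_amplitude,
         footpad_country_sd = footpad_country_sd,
         footpad_noise_sd = footpad_noise_sd,
         amu_prob_by_phase = amu_prob_by_phase,
         amu_days_mean = amu_days_mean, amu_days_size = amu_days_size,
         na_prob = na_prob),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' @noRd
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  if (any(cfg$countries$n_farms < 1L)) {
    stop("every country needs n_farms >= 1", call. = FALSE)
  }
  if (anyDuplicated(cfg$countries$country)) {
    stop("duplicate country names", call. = FALSE)
  }
  bp <- cfg$beta_params_per_zone
  assert_zone(bp$zone)
  if (!setequal(bp$zone, beat_zones())) {
    stop("beta_params_per_zone must cover all five zones", call. = FALSE)
  }
  if (any(bp$alpha <= 0 | bp$beta <= 0)) {
    stop("Beta parameters must be positive", call. = FALSE)
  }
  probs <- c(cfg$realization_probs$prob, cfg$amu_prob_by_phase, cfg$na_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(cfg$realization_probs$term %in% intervention_terms),
            all(cfg$realization_probs$cost %in% intervention_costs))
  if (nrow(cfg$realization_probs) != 9L) {
    stop("realization_probs must cover all 9 term/cost cells", call. = FALSE)
  }
  if (cfg$footpad_noise_sd < 0 || cfg$footpad_country_sd < 0) {
    stop("SDs must be nonnegative", call. = FALSE)
  }
  if (cfg$amu_days_mean <= 0 || cfg$amu_days_size <= 0) {
    stop("amu_days_mean and amu_days_size must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Draws a full study data set -- farms, assessment answers, health plans,
#' and four production-cycle records per farm -- from a [cohort_config()].
#' Deterministic given the configuration (including its seed).
#'
#' Per-farm zone compliance `c` is drawn from the zone's Beta distribution;
#' each question is then answered with its best option with probability
#' chosen so the expected relative score equals `c` (mixing the best and
#' worst options). Interventions are drawn for categories scoring below the
#' weak threshold, labelled with term/cost, and realized by Bernoulli draws
#' from the graded probabilities. Flock footpad scores are
#' `baseline + amplitude * cos(2*pi*(month - 1)/12) + country offset +
#' noise` (cosine peaking in January), clamped to the 0--200 scale and
#' realised as bird-class counts over 100 scored birds.
#'
#' @param cfg A `cohort_config`.
#' @param questionnaire Instrument to answer; defaults to the packaged
#'   fixture.
#' @return List of tibbles: `farms`, `answers`, `plans`, `cycles`, plus the
#'   `questionnaire` used.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(coh$farms, country)
generate_cohort <- function(cfg = cohort_config(),
                            questionnaire = load_questionnaire(
                              beat_example("questionnaire.csv"))) {
  validate_cohort_config(cfg)
  stopifnot(inherits(questionnaire, "beat_questionnaire"))
  set.seed(cfg$seed)

  farms <- generate_farms(cfg)
  compliance <- generate_compliance(cfg, farms)
  answers <- generate_answers(cfg, questionnaire, compliance)
  plans <- generate_plans(cfg, questionnaire, answers)
  cycles <- generate_cycles(cfg, farms)
  list(farms = farms, answers = answers, plans = plans, cycles = cycles,
       questionnaire = questionnaire)
}

#' @noRd
generate_farms <- function(cfg) {
  n <- sum(cfg$countries$n_farms)
  country <- rep(cfg$countries$country, cfg$countries$n_farms)
  tibble(
    farm_id = sprintf("%s%02d", country,
                      sequence(cfg$countries$n_farms)),
    country = country,
    n_houses = sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    construction_year = sample(1980:2015, n, replace = TRUE),
    veterinarian_id = paste0("vet_", country),
    base_month = sample(1:12, n, replace = TRUE)
  )
}

#' @noRd
generate_compliance <- function(cfg, farms) {
  bp <- cfg$beta_params_per_zone
  grid <- tidyr::expand_grid(farm_id = farms$farm_id, zone = bp$zone)
  idx <- match(grid$zone, bp$zone)
  grid$compliance <- stats::rbeta(nrow(grid), bp$alpha[idx], bp$beta[idx])
  grid
}

#' @noRd
generate_answers <- function(cfg, questionnaire, compliance) {
  qmeta <- dplyr::left_join(questionnaire$questions,
                            questionnaire$categories[, c("category_id", "zone")],
                            by = "category_id")
  per_q <- questionnaire$options |>
    dplyr::group_by(.data$question_id) |>
    dplyr::summarise(
      best_id = .data$option_id[which.max(.data$points)],
      worst_id = .data$option_id[which.min(.data$points)],
      best = max(.data$points), worst = min(.data$points), .groups = "drop"
    )
  grid <- tidyr::expand_grid(farm_id = unique(compliance$farm_id),
                             question_id = qmeta$question_id)
  grid$zone <- qmeta$zone[match(grid$question_id, qmeta$question_id)]
  grid$allow_na <- qmeta$allow_na[match(grid$question_id, qmeta$question_id)]
  grid <- dplyr::left_join(grid, compliance, by = c("farm_id", "zone"))
  grid <- dplyr::left_join(grid, per_q, by = "question_id")
  # P(best option) chosen so E[points]/max = zone compliance draw
  p_best <- (grid$compliance * grid$best - grid$worst) /
    pmax(grid$best - grid$worst, .Machine$double.eps)
  p_best <- pmin(pmax(p_best, 0), 1)
  take_best <- stats::runif(nrow(grid)) < p_best
  grid$option_id <- ifelse(take_best, grid$best_id, grid$worst_id)
  is_na <- grid$allow_na & stats::runif(nrow(grid)) < cfg$na_prob
  grid$option_id[is_na] <- NA_character_
  tibble(farm_id = grid$farm_id, date = as.Date("2020-01-15"),
         question_id = grid$question_id, option_id = grid$option_id)
}

#' @noRd
generate_plans <- function(cfg, questionnaire, answers) {
  scores <- score_farms(questionnaire, answers)$categories
  weak <- scores[scores$relative < cfg$weak_threshold, ]
  if (nrow(weak) == 0L) {
    return(tibble(
      intervention_id = character(), farm_id = character(),
      zone = character(), category_id = character(),
      description = character(), term = character(), cost = character(),
      realized = logical(), date_planned = as.Date(character()),
      date_evaluated = as.Date(character())
    ))
  }
  n_iv <- stats::rpois(nrow(weak), cfg$intervention_rate)
  idx <- rep(seq_len(nrow(weak)), n_iv)
  if (length(idx) == 0L) idx <- integer()
  term <- sample(intervention_terms, length(idx), replace = TRUE,
                 prob = c(0.42, 0.34, 0.24))
  cost <- sample(intervention_costs, length(idx), replace = TRUE,
                 prob = c(0.49, 0.29, 0.22))
  rp <- cfg$realization_probs
  p_real <- rp$prob[match(paste(term, cost), paste(rp$term, rp$cost))]
  tibble(
    intervention_id = sprintf("iv%05d", seq_along(idx)),
    farm_id = weak$farm_id[idx],
    zone = weak$zone[idx],
    category_id = weak$category_id[idx],
    description = paste("improve", weak$category_id[idx]),
    term = term, cost = cost,
    realized = stats::runif(length(idx)) < p_real,
    date_planned = as.Date("2020-02-01"),
    date_evaluated = as.Date("2021-03-01")
  )
}

#' @noRd
generate_cycles <- function(cfg, farms) {
  country_offset <- stats::rnorm(nrow(cfg$countries), 0, cfg$footpad_country_sd)
  names(country_offset) <- cfg$countries$country
  grid <- tidyr::expand_grid(farm_id = farms$farm_id, cycle_index = 1:4)
  fidx <- match(grid$farm_id, farms$farm_id)
  grid$country <- farms$country[fidx]
  grid$construction_year <- farms$construction_year[fidx]
  # successive cycles start ~2 months apart (7-8 week grow-out plus downtime)
  grid$start_month <- ((farms$base_month[fidx] - 1L +
                          2L * (grid$cycle_index - 1L)) %% 12L) + 1L
  grid$phase <- cycle_phase(grid$cycle_index)

  season <- cos(2 * pi * (grid$start_month - 1) / 12)
  target <- cfg$footpad_baseline + cfg$footpad_month_amplitude * season +
    country_offset[grid$country] +
    stats::rnorm(nrow(grid), 0, cfg$footpad_noise_sd)
  target <- pmin(pmax(target, 0), 200)
  counts <- footpad_counts_for_score(target, n_birds = 100L)

  p_amu <- unname(cfg$amu_prob_by_phase[grid$phase])
  amu_used <- stats::runif(nrow(grid)) < p_amu
  days <- stats::rnbinom(nrow(grid), size = cfg$amu_days_size,
                         mu = cfg$amu_days_mean)
  days <- pmax(days, 1L) # treated flocks have at least one treatment day
  tibble(
    farm_id = grid$farm_id, country = grid$country,
    cycle_index = grid$cycle_index, phase = grid$phase,
    start_month = grid$start_month,
    amu_used = amu_used,
    amu_days = ifelse(amu_used, days, 0L),
    n_class0 = counts$n0, n_class1 = counts$n1, n_class2 = counts$n2,
    footpad_score = flock_footpad_score(counts$n0, counts$n1, counts$n2),
    mortality_pct = round(stats::rlnorm(nrow(grid), log(3), 0.35), 2),
    slaughter_age_days = as.integer(round(stats::rnorm(nrow(grid), 41, 2))),
    slaughter_weight_g = round(stats::rnorm(nrow(grid), 2500, 180)),
    construction_year = grid$construction_year
  )
}

#' @noRd
# invert the weighted-prevalence formula: pick class fractions over n_birds
# whose default-weight score is as close as possible to the target
footpad_counts_for_score <- function(score, n_birds = 100L) {
  # low scores: mix classes 0/1/2 as p1 = s/100, p2 = s/400 (score == s);
  # high scores (> 80 where that mix overflows): p0 = 0, solve on classes 1/2
  lo <- score <= 80
  p1 <- ifelse(lo, score / 100, 1 - (score / 100 - 0.5) / 1.5)
  p2 <- ifelse(lo, score / 400, (score / 100 - 0.5) / 1.5)
  n1 <- as.integer(round(p1 * n_birds))
  n2 <- as.integer(round(p2 * n_birds))
  n2 <- pmin(n2, n_birds - n1)
  n0 <- n_birds - n1 - n2
  list(n0 = n0, n1 = n1, n2 = n2)
}

#' Write a generated cohort to delimited files
#'
#' Emits the four standard files (`farms.csv`, `answers.csv`, `plans.csv`,
#' `cycles.csv`) that the corresponding readers accept, plus the
#' questionnaire definition (`questionnaire.csv`).
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$farms, file.path(dir, "farms.csv"), progress = FALSE)
  readr::write_csv(cohort$answers, file.path(dir, "answers.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(cohort$plans, file.path(dir, "plans.csv"),
                   progress = FALSE, na = "")
  cyc <- cohort$cycles[, c("farm_id", "cycle_index", "start_month", "amu_used",
                           "amu_days", "n_class0", "n_class1", "n_class2",
                           "mortality_pct", "slaughter_age_days",
                           "slaughter_weight_g")]
  readr::write_csv(cyc, file.path(dir, "cycles.csv"), progress = FALSE)
  write_questionnaire(cohort$questionnaire, file.path(dir, "questionnaire.csv"))
  invisible(dir)
}
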