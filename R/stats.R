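#' Two-sample rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' Used to compare relative zone scores between countries. Ties get
#' mid-ranks; the null distribution is exact when both samples have at most
#' 10 observations and the pooled data are tie-free, and a tie-corrected
#' normal approximation (with continuity correction) otherwise. If every
#' pooled value is identical the test is degenerate and returns p = 1 with a
#' warning.
#'
#' @param x,y Numeric samples.
#' @param labels Length-2 character vector naming the groups.
#' @return A `beat_test` list: `test_name`, `statistic` (Mann-Whitney W for
#'   `x`), `p_value`, `groups`, `n_per_group`, `exact`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
rank_sum_test <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical in both samples; rank-sum test degenerate",
            call. = FALSE)
    return(new_beat_test("rank_sum", length(x) * length(y) / 2, 1,
                         labels, c(length(x), length(y)), exact = FALSE))
  }
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- !has_ties && length(x) <= 10L && length(y) <= 10L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  new_beat_test("rank_sum", unname(wt$statistic), wt$p.value,
                labels, c(length(x), length(y)), exact = use_exact)
}

#' Kruskal-Wallis rank test across groups
#'
#' Used for the pre/post comparisons of footpad scores and mortality. The H
#' statistic carries the usual tie correction; the p-value comes from the
#' chi-square reference with k - 1 degrees of freedom. All-identical data
#' yield H = 0, p = 1 with a warning.
#'
#' @param groups A named or unnamed list of numeric samples (at least two
#'   nonempty).
#' @return A `beat_test` list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L) {
    stop("need at least two nonempty groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need at least 3 observations", call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  if (length(unique(values)) == 1L) {
    warning("all observations identical; Kruskal-Wallis test degenerate",
            call. = FALSE)
    out <- new_beat_test("kruskal_wallis", 0, 1, labels,
                         vapply(groups, length, 1L), exact = FALSE)
    out$df <- length(groups) - 1L
    return(out)
  }
  g <- factor(rep(labels, vapply(groups, length, 1L)), levels = labels)
  kt <- stats::kruskal.test(values, g)
  out <- new_beat_test("kruskal_wallis", unname(kt$statistic), kt$p.value,
                       labels, vapply(groups, length, 1L), exact = FALSE)
  out$df <- unname(kt$parameter)
  out
}

#' @noRd
new_beat_test <- function(test_name, statistic, p_value, groups, n_per_group,
                          exact) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, groups = groups,
                 n_per_group = n_per_group, exact = exact),
            class = "beat_test")
}

#' @export
print.beat_test <- function(x, ...) {
  cat("<beat_test> ", x$test_name, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  cat("  groups: ", paste(x$groups, " (n=", x$n_per_group, ")",
                          sep = "", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise between-country rank tests on zone scores
#'
#' Runs [rank_sum_test()] for every country pair within every zone of a
#' farm-level zone score table. No multiple-testing correction is applied by
#' default; Holm adjustment over the country pairs within each zone is
#' available.
#'
#' @param zone_scores Tibble with `farm_id`, `zone`, `relative`.
#' @param farms `farm_id`/`country` map.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Tibble: `zone`, `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`.
#' @export
compare_countries <- function(zone_scores, farms, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  scores <- dplyr::left_join(zone_scores, farms[, c("farm_id", "country")],
                             by = "farm_id")
  if (any(is.na(scores$country))) {
    stop("farm(s) missing from the farms table", call. = FALSE)
  }
  res <- list()
  for (z in intersect(beat_zones(), unique(scores$zone))) {
    sub <- scores[scores$zone == z, ]
    countries <- sort(unique(sub$country))
    if (length(countries) < 2L) next
    pairs <- utils::combn(countries, 2, simplify = FALSE)
    zres <- lapply(pairs, function(p) {
      xs <- sub$relative[sub$country == p[1]]
      ys <- sub$relative[sub$country == p[2]]
      tt <- rank_sum_test(xs, ys, labels = p)
      tibble(zone = z, group1 = p[1], group2 = p[2],
             n1 = length(xs), n2 = length(ys),
             statistic = tt$statistic, p_value = tt$p_value)
    })
    zres <- dplyr::bind_rows(zres)
    if (p_adjust == "holm") zres$p_value <- stats::p.adjust(zres$p_value, "holm")
    res[[z]] <- zres
  }
  dplyr::bind_rows(res)
}

#' Pre/post-intervention rank comparison of a monitoring outcome
#'
#' Kruskal-Wallis test of a per-cycle outcome (flock footpad score or
#' mortality) across the follow-up, per country: either the two
#' pre/post phases pooled (`mode = "phase"`) or the four cycles kept apart
#' (`mode = "cycle"`).
#'
#' @param cycles Cycle tibble with `country` (or `farms` given), the outcome
#'   column, and `cycle_index`.
#' @param outcome Name of the outcome column, e.g. `"footpad_score"`.
#' @param mode `"phase"` (2 groups) or `"cycle"` (4 groups).
#' @param farms Optional `farm_id`/`country` map.
#' @return Tibble: `country`, `mode`, `statistic`, `df`, `p_value`.
#' @export
compare_prepost <- function(cycles, outcome = "footpad_score",
                            mode = c("phase", "cycle"), farms = NULL) {
  mode <- match.arg(mode)
  cycles <- join_country(cycles, farms)
  if (!outcome %in% names(cycles)) {
    stop("no column called ", outcome, " in the cycle table", call. = FALSE)
  }
  if (!"phase" %in% names(cycles)) cycles$phase <- cycle_phase(cycles$cycle_index)
  key <- if (mode == "phase") "phase" else "cycle_index"
  res <- lapply(sort(unique(cycles$country)), function(ctry) {
    sub <- cycles[cycles$country == ctry, ]
    grp <- split(sub[[outcome]], sub[[key]])
    kt <- kruskal_wallis(grp)
    tibble(country = ctry, mode = mode, statistic = kt$statistic,
           df = kt$df, p_value = kt$p_value)
  })
  dplyr::bind_rows(res)
}

footpad_candidates <- c("cycle_index", "start_month", "construction_year")

#' @noRd
candidate_term <- function(name, month_encoding) {
  switch(
    name,
    cycle_index = "cycle_index",
    construction_year = "construction_year",
    start_month = if (month_encoding == "factor") "factor(start_month)"
    else "sin(2*pi*start_month/12) + cos(2*pi*start_month/12)",
    stop("unknown candidate: ", name, call. = FALSE)
  )
}

#' Linear mixed model for flock footpad scores
#'
#' Fits `footpad_score ~ fixed terms + (1 | country)` by maximum likelihood
#' (not REML, so AIC values are comparable across fixed-effect sets). Cycle
#' number and construction year enter linearly; the month in which the cycle
#' started enters as a factor by default, or as a first-order harmonic
#' (sin/cos) pair.
#'
#' @param cycles Data with columns `footpad_score`, `country`, and the
#'   candidate covariates used.
#' @param fixed Character vector out of `cycle_index`, `start_month`,
#'   `construction_year` (possibly empty: random-intercept-only model).
#' @param month_encoding `"factor"` or `"harmonic"`.
#' @param farms Optional `farm_id`/`country` map (and
#'   `construction_year`, if not already on `cycles`).
#' @return A `beat_modelfit` list: `fixed_terms`, `random_terms`, `aic`,
#'   `coefficients`, `n_obs`, `singular`, and the underlying `lme4` fit as
#'   `model`.
#' @export
fit_footpad_model <- function(cycles, fixed = character(),
                              month_encoding = c("factor", "harmonic"),
                              farms = NULL) {
  month_encoding <- match.arg(month_encoding)
  cycles <- join_country(cycles, farms)
  if (!is.null(farms) && !"construction_year" %in% names(cycles) &&
      "construction_year" %in% names(farms)) {
    cycles <- dplyr::left_join(cycles,
                               farms[, c("farm_id", "construction_year")],
                               by = "farm_id")
  }
  stopifnot(all(fixed %in% footpad_candidates))
  if (length(unique(cycles$country)) < 2L) {
    stop("need at least two countries for the country random effect",
         call. = FALSE)
  }
  needed <- c("footpad_score", "country", fixed)
  missing_cols <- setdiff(needed, names(cycles))
  if (length(missing_cols)) {
    stop("cycle data lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rhs <- vapply(fixed, candidate_term, "", month_encoding = month_encoding)
  fml <- stats::as.formula(paste(
    "footpad_score ~",
    if (length(rhs)) paste(rhs, collapse = " + ") else "1",
    "+ (1 | country)"
  ))
  fit <- lme4::lmer(fml, data = cycles, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: estimated country variance is zero; model retained",
            call. = FALSE)
  }
  structure(
    list(fixed_terms = fixed, random_terms = "country",
         aic = stats::AIC(fit),
         coefficients = lme4::fixef(fit),
         n_obs = stats::nobs(fit), singular = singular,
         month_encoding = month_encoding, model = fit),
    class = "beat_modelfit"
  )
}

#' @export
print.beat_modelfit <- function(x, ...) {
  cat("<beat_modelfit> footpad_score ~ ",
      if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ")
      else "1",
      " + (1 | country)\n", sep = "")
  cat("  ML fit, AIC = ", format(x$aic, digits = 6), ", n = ", x$n_obs,
      if (x$singular) ", singular" else "", "\n", sep = "")
  invisible(x)
}

#' Forward selection of footpad-model fixed effects by AIC
#'
#' Starts from the random-intercept-only model and greedily adds, at each
#' step, the candidate covariate that lowers the AIC most, stopping when no
#' candidate lowers it. Deterministic given the data: an exact AIC tie is
#' broken by the order of `candidates`. All fits use maximum likelihood.
#'
#' @inheritParams fit_footpad_model
#' @param candidates Candidate covariates, default all three.
#' @return The selected `beat_modelfit` with a `trace` tibble (`step`,
#'   `added`, `aic`) attached.
#' @export
forward_select_aic <- function(cycles, candidates = footpad_candidates,
                               month_encoding = c("factor", "harmonic"),
                               farms = NULL) {
  month_encoding <- match.arg(month_encoding)
  stopifnot(all(candidates %in% footpad_candidates))
  current <- fit_footpad_model(cycles, character(), month_encoding, farms)
  trace <- tibble(step = 0L, added = NA_character_, aic = current$aic)
  remaining <- candidates
  step <- 0L
  while (length(remaining)) {
    fits <- lapply(remaining, function(cand) {
      fit_footpad_model(cycles, c(current$fixed_terms, cand),
                        month_encoding, farms)
    })
    aics <- vapply(fits, function(f) f$aic, 0)
    best <- which.min(aics) # first index wins ties: candidate order
    if (aics[best] >= current$aic) break
    step <- step + 1L
    current <- fits[[best]]
    trace <- dplyr::bind_rows(trace,
                              tibble(step = step, added = remaining[best],
                                     aic = aics[best]))
    remaining <- remaining[-best]
  }
  current$trace <- trace
  current
}
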