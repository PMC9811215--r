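make_plans <- function(zone, category_id, realized,
                       term = "short", cost = "low",
                       farm_id = "F1") {
  n <- length(zone)
  tibble::tibble(
    intervention_id = sprintf("iv%03d", seq_len(n)),
    farm_id = rep_len(farm_id, n), zone = zone, category_id = category_id,
    description = "x", term = rep_len(term, n), cost = rep_len(cost, n),
    realized = realized, date_planned = as.Date("2020-02-01"),
    date_evaluated = as.Date(NA)
  )
}

test_that("suggest_targets ranks the weakest categories deterministically", {
  scores <- tibble::tibble(
    category_id = c("g_thinning", "g_depopulation", "o_yard", "r_area"),
    zone = c("green", "green", "orange", "red"),
    relative = c(0.07, 0.09, 0.45, 0.45)
  )
  top2 <- suggest_targets(scores, k = 2)
  expect_equal(top2$category_id, c("g_thinning", "g_depopulation"))
  # tie at 0.45 broken by zone order (orange before red)
  top4 <- suggest_targets(scores, k = 4)
  expect_equal(top4$category_id[3:4], c("o_yard", "r_area"))
  # perfection filter drops full-compliance categories
  perfect <- tibble::tibble(category_id = "a", zone = "green", relative = 1)
  expect_warning(out <- suggest_targets(perfect, k = 1), "returning all")
  expect_equal(nrow(out), 0L)
  # k larger than available warns and returns everything, sorted
  expect_warning(all4 <- suggest_targets(scores, k = 10), "returning all")
  expect_equal(nrow(all4), 4L)
  expect_false(is.unsorted(all4$relative))
})

test_that("suggest_targets matches a brute-force sort oracle on random scores", {
  set.seed(21)
  zones <- beat_zones()
  for (i in 1:20) {
    n <- sample(5:30, 1)
    scores <- tibble::tibble(
      category_id = sprintf("c%02d", sample(n)),
      zone = sample(zones, n, replace = TRUE),
      relative = round(stats::runif(n), 2) # rounded to force ties
    )
    k <- sample(seq_len(n), 1)
    got <- suppressWarnings(suggest_targets(scores, k = k))
    oracle <- scores[scores$relative < 1, ]
    oracle <- oracle[order(oracle$relative,
                           match(oracle$zone, zones),
                           oracle$category_id), ]
    oracle <- utils::head(oracle, k)
    expect_equal(got$category_id, oracle$category_id)
  }
})

test_that("zone totals and realization rates tally interventions exactly", {
  plans <- make_plans(
    zone = c("green", "green", "red", "orange_green"),
    category_id = c("g_a", "g_a", "r_b", "og_c"),
    realized = c(TRUE, FALSE, TRUE, TRUE)
  )
  zt <- zone_totals(plans)
  expect_equal(zt$zone, beat_zones()) # all five zones, reporting order
  expect_equal(zt$n_planned, c(2L, 1L, 0L, 0L, 1L))
  expect_equal(zt$n_realized, c(1L, 1L, 0L, 0L, 1L))
  # empty plan list -> all zeros
  expect_equal(zone_totals(plans[0, ])$n_planned, rep(0L, 5))

  rr <- realization_rate(plans)
  expect_equal(rr$pct_realized, round(100 * 3 / 4, 1))
  all_done <- make_plans("green", "g_a", realized = c(TRUE, TRUE))
  expect_equal(realization_rate(all_done)$pct_realized, 100.0)
})

test_that("term-by-cost cross-tab counts and whole-percent realization", {
  plans <- make_plans(
    zone = rep("green", 3), category_id = rep("g_a", 3),
    realized = c(TRUE, FALSE, TRUE),
    term = c("short", "short", "long"), cost = c("low", "low", "high")
  )
  ct <- crosstab_term_cost(plans)
  expect_equal(nrow(ct), 9L)
  sl <- ct[ct$term == "short" & ct$cost == "low", ]
  expect_equal(sl$n_planned, 2L)
  expect_equal(sl$pct_realized, 50)
  empty <- ct[ct$term == "medium" & ct$cost == "high", ]
  expect_equal(empty$n_planned, 0L)
  expect_true(is.na(empty$pct_realized))
})

test_that("conservation: zones and term/cost cells both sum to the plan total", {
  set.seed(5)
  coh <- generate_cohort(cohort_config(seed = 5))
  n <- nrow(coh$plans)
  expect_gt(n, 0)
  expect_equal(sum(zone_totals(coh$plans)$n_planned), n)
  expect_equal(sum(crosstab_term_cost(coh$plans)$n_planned), n)
  expect_equal(sum(zone_totals(coh$plans)$n_realized),
               sum(crosstab_term_cost(coh$plans)$n_realized))
  # realization rate equals the brute-force ratio and is bounded
  rr <- realization_rate(coh$plans, coh$farms, "country")
  brute <- tapply(coh$plans$realized,
                  coh$farms$country[match(coh$plans$farm_id, coh$farms$farm_id)],
                  mean)
  expect_equal(rr$pct_realized,
               as.numeric(round(100 * brute[rr$group], 1)))
  expect_true(all(rr$pct_realized >= 0 & rr$pct_realized <= 100))
})

test_that("plan files validate closed sets and zone/category agreement", {
  q <- toy_questionnaire()
  plans <- make_plans("green", "g_hygiene", TRUE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(plans, tmp, na = "")
  back <- read_health_plans(tmp, q)
  expect_equal(nrow(back), 1L)
  bad_term <- plans; bad_term$term <- "someday"
  readr::write_csv(bad_term, tmp, na = "")
  expect_error(read_health_plans(tmp), "short/medium/long")
  wrong_zone <- plans; wrong_zone$zone <- "red"
  readr::write_csv(wrong_zone, tmp, na = "")
  expect_error(read_health_plans(tmp, q), "does not match")
})
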