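test_that("cohort generation is deterministic given the seed", {
  c1 <- generate_cohort(cohort_config(seed = 42))
  c2 <- generate_cohort(cohort_config(seed = 42))
  expect_identical(c1$farms, c2$farms)
  expect_identical(c1$answers, c2$answers)
  expect_identical(c1$plans, c2$plans)
  expect_identical(c1$cycles, c2$cycles)
  c3 <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(c1$answers, c3$answers))
  # written files are byte-identical across runs with the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("default cohort mirrors the study design", {
  coh <- generate_cohort(cohort_config(seed = 9))
  counts <- dplyr::count(coh$farms, country)
  expect_equal(counts$n[match(c("NL", "CY", "GR"), counts$country)],
               c(13L, 7L, 15L))
  expect_equal(nrow(coh$cycles), 35L * 4L)
  expect_equal(sort(unique(coh$cycles$cycle_index)), 1:4)
  expect_equal(unique(coh$cycles$phase[coh$cycles$cycle_index <= 2]), "pre")
  expect_equal(unique(coh$cycles$phase[coh$cycles$cycle_index >= 3]), "post")
})

test_that("generated files pass every reader's validation", {
  coh <- generate_cohort(cohort_config(seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  q <- load_questionnaire(file.path(dir, "questionnaire.csv"))
  expect_no_warning(ans <- read_answers(file.path(dir, "answers.csv"), q))
  expect_no_warning(plans <- read_health_plans(file.path(dir, "plans.csv"), q))
  expect_no_warning(cyc <- read_cycles(file.path(dir, "cycles.csv")))
  expect_equal(nrow(ans), nrow(coh$answers))
  expect_equal(nrow(plans), nrow(coh$plans))
  expect_equal(nrow(cyc), nrow(coh$cycles))
  # row order is preserved and the derived footpad scores agree
  expect_equal(cyc$footpad_score, coh$cycles$footpad_score)
})

test_that("degenerate footpad config collapses within-country variation", {
  cfg <- cohort_config(seed = 6, footpad_month_amplitude = 0,
                       footpad_noise_sd = 0)
  coh <- generate_cohort(cfg)
  spread <- tapply(coh$cycles$footpad_score, coh$cycles$country,
                   function(x) diff(range(x)))
  # class counts are integers over 100 birds, so scores quantize to 0.5 steps
  expect_true(all(spread <= 1))
})

test_that("zone score means track the Beta compliance means (law of large numbers)", {
  cfg <- cohort_config(
    seed = 123,
    countries = tibble::tibble(country = "XX", n_farms = 500L)
  )
  coh <- generate_cohort(cfg)
  sc <- score_farms(coh$questionnaire, coh$answers)$zones
  bp <- cfg$beta_params_per_zone
  for (i in seq_len(nrow(bp))) {
    mu <- bp$alpha[i] / (bp$alpha[i] + bp$beta[i])
    v <- mu * (1 - mu) / (bp$alpha[i] + bp$beta[i] + 1)
    rel <- sc$relative[sc$zone == bp$zone[i]]
    # per-farm score variance >= Beta variance; 3 SE band around the mean
    se <- sqrt(v / length(rel)) * 3
    expect_lt(abs(mean(rel) - mu), 3 * sqrt(stats::var(rel) / length(rel)) + se)
  }
})

test_that("graded realization probabilities produce a monotone crosstab gradient", {
  # realization probabilities graded high (short/low) to near zero
  # (long/high): monotone along both axes in expectation
  rp <- tibble::tibble(
    term = rep(c("short", "medium", "long"), each = 3),
    cost = rep(c("low", "medium", "high"), 3),
    prob = c(0.9, 0.6, 0.3, 0.6, 0.4, 0.2, 0.3, 0.2, 0.02)
  )
  cfg <- cohort_config(
    seed = 321, realization_probs = rp,
    countries = tibble::tibble(country = c("A", "B"), n_farms = c(60L, 60L)),
    intervention_rate = 2
  )
  coh <- generate_cohort(cfg)
  ct <- crosstab_term_cost(coh$plans)
  get <- function(tm, co) ct$pct_realized[ct$term == tm & ct$cost == co]
  expect_gt(get("short", "low"), get("short", "high"))
  expect_gt(get("short", "low"), get("long", "low"))
  expect_gt(get("medium", "low"), get("long", "high"))
  expect_lt(get("long", "high"), 10)
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(cohort_config(countries = tibble::tibble(country = "A",
                                                        n_farms = 0L)),
               "n_farms")
  bad_beta <- tibble::tibble(zone = beat_zones(), alpha = c(-1, 1, 1, 1, 1),
                             beta = rep(1, 5))
  expect_error(cohort_config(beta_params_per_zone = bad_beta), "positive")
  expect_error(cohort_config(amu_prob_by_phase = c(pre = 1.2, post = 0.5)),
               "\\[0, 1\\]")
  rp <- cohort_config()$realization_probs[1:5, ]
  expect_error(cohort_config(realization_probs = rp), "9 term/cost")
})
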