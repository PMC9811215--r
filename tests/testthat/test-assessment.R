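test_that("question scores follow the 0-1 compliance point scale", {
  q <- toy_questionnaire()
  expect_equal(score_question(q, "g1", "a"), 1.0)   # fully compliant
  expect_equal(score_question(q, "g1", "c"), 0.0)   # no compliance
  expect_equal(score_question(q, "g1", "b"), 0.5)
  expect_true(is.na(score_question(q, "g1", NA)))   # allow_na question
  expect_error(score_question(q, "og1", NA), "not allow")
  expect_error(score_question(q, "g1", "z"), "not among options")
})

test_that("zone scores are attained/attainable with NA excluded from both sides", {
  q <- toy_questionnaire()
  full <- uniform_answers(q, rank = 1L)
  zs <- score_zone(q, full, "green")
  expect_equal(zs$relative, 1.0)
  expect_equal(zs$attained, zs$attainable)

  worst <- uniform_answers(q, rank = 3L)
  expect_equal(score_zone(q, worst, "green")$relative, 0.0)

  # one of two green questions NA, the other fully compliant -> 1.0
  mixed <- make_answers(c(g1 = "a", g2 = NA_character_))
  zs2 <- score_zone(q, mixed, "green")
  expect_equal(zs2$relative, 1.0)
  expect_equal(zs2$attainable, 1)
  expect_equal(zs2$n_na, 1L)

  # all answered NA -> no scorable questions
  expect_error(
    score_zone(q, make_answers(c(g1 = NA_character_, g2 = NA_character_)),
               "green"),
    "no scorable")
})

test_that("category scores reduce to zone scores for single-category zones", {
  q <- toy_questionnaire()
  ans <- make_answers(c(g1 = "a", g2 = "b", og1 = "b", o1 = "c", ro1 = "a",
                        r1 = "b"))
  cs <- score_category(q, ans, "g_hygiene")
  zs <- score_zone(q, ans, "green")
  expect_equal(cs$relative, zs$relative)
  expect_equal(cs$relative, 0.75)
  # single-question category at the middle option
  expect_equal(score_category(q, ans, "og_access")$relative, 0.5)
  expect_error(score_category(q, ans, "nope"), "unknown category")
})

test_that("category relative equals an independent brute-force re-summation", {
  q <- fixture_questionnaire()
  set.seed(11)
  ans <- random_answers(q, na_prob = 0.15)
  scored_brute <- merge(
    merge(as.data.frame(ans), as.data.frame(q$questions),
          by = "question_id"),
    as.data.frame(q$options), by = c("question_id", "option_id")
  )
  maxima <- tapply(q$options$points, q$options$question_id, max)
  for (cid in sample(q$categories$category_id, 8)) {
    qids <- q$questions$question_id[q$questions$category_id == cid]
    sub <- scored_brute[scored_brute$question_id %in% qids, ]
    if (nrow(sub) == 0) next
    expected <- sum(sub$points) / sum(maxima[sub$question_id])
    expect_equal(score_category(q, ans, cid)$relative, expected)
  }
})

test_that("traffic lights map the score scale red through green", {
  expect_equal(as.character(traffic_light(1.0)), "green")
  expect_equal(as.character(traffic_light(0.0)), "red")
  expect_equal(as.character(traffic_light(0.55)), "amber")
  expect_equal(as.character(traffic_light(c(0.39, 0.4, 0.7))),
               c("red", "amber", "green"))
  # ordering of lights is monotone in the score
  x <- seq(0, 1, by = 0.01)
  expect_true(!is.unsorted(traffic_light(x)))
  expect_error(traffic_light(1.2), "outside")
  expect_error(traffic_light(0.5, thresholds = c(0.8, 0.2)), "thresholds")
  # configurable cuts move the boundary
  expect_equal(as.character(traffic_light(0.55, thresholds = c(0.6, 0.9))),
               "red")
})

test_that("cross-farm aggregation reports mean, sample SD, and pooled overall", {
  scores <- tibble::tibble(
    farm_id = c("A", "B", "C"),
    zone = "green",
    relative = c(1, 1, 1)
  )
  farms <- tibble::tibble(farm_id = c("A", "B", "C"),
                          country = c("NL", "NL", "CY"))
  agg <- aggregate_scores(scores, farms, "country")
  expect_equal(agg$mean, c(1, 1))
  expect_equal(agg$sd[agg$group == "NL"], 0)
  expect_true(is.na(agg$sd[agg$group == "CY"])) # single farm -> SD undefined

  overall <- aggregate_scores(scores, group_by = "overall")
  expect_equal(overall$mean, 1)
  expect_equal(overall$n, 3L)

  # pooled mean is the farm-pooled mean, not the mean of country means
  scores2 <- tibble::tibble(farm_id = c("A", "B", "C"), zone = "red",
                            relative = c(0.2, 0.4, 0.9))
  expect_equal(aggregate_scores(scores2, group_by = "overall")$mean, 0.5)
  expect_error(aggregate_scores(scores2[0, ], group_by = "overall"), "empty")
})

test_that("relative scores are scale-free in the option points", {
  # doubling all option points (and hence maxima) must not change `relative`;
  # points live in [0,1], so halve instead
  q <- toy_questionnaire()
  half <- q
  half$options$points <- q$options$points / 2
  # halving breaks the best-option==1 invariant; bypass the constructor and
  # recompute via raw sums to check the invariance property itself
  ans <- make_answers(c(g1 = "a", g2 = "b"))
  zs <- score_zone(q, ans, "green")
  pts <- q$options$points[match(paste(ans$question_id, ans$option_id),
                                paste(q$options$question_id, q$options$option_id))]
  maxima <- tapply(q$options$points, q$options$question_id, max)
  for (k in c(0.5, 0.1, 2)) {
    expect_equal(sum(k * pts) / sum(k * maxima[ans$question_id]), zs$relative)
  }
})

test_that("answer files round-trip through the reader with NA cells", {
  q <- toy_questionnaire()
  ans <- make_answers(c(g1 = "a", g2 = NA_character_, og1 = "b"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ans, tmp, na = "")
  back <- read_answers(tmp, q)
  expect_equal(back$option_id, ans$option_id)
  # invalid option in file is rejected on validation
  bad <- ans; bad$option_id[1] <- "zz"
  readr::write_csv(bad, tmp, na = "")
  expect_error(read_answers(tmp, q), "not among")
  # duplicate answer per question rejected
  dup <- dplyr::bind_rows(ans, ans[1, ])
  readr::write_csv(dup, tmp, na = "")
  expect_error(read_answers(tmp, q), "more than one answer")
})
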