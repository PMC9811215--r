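# oracles perm_rank_sum_p / kw_h_formula live in helper-oracles.R

test_that("rank-sum p equals exhaustive enumeration on all tie-free n <= 6 splits", {
  for (n1 in 1:5) {
    for (n2 in 1:(6 - n1)) {
      data <- seq_len(n1 + n2)
      splits <- utils::combn(n1 + n2, n1, simplify = FALSE)
      for (idx in splits) {
        x <- data[idx]; y <- data[-idx]
        got <- rank_sum_test(x, y)
        expect_true(got$exact)
        expect_equal(got$p_value, perm_rank_sum_p(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("the separated 3-vs-3 case gives exact two-sided p = 0.1", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)
})

test_that("degenerate and tied rank-sum inputs are handled", {
  expect_warning(res <- rank_sum_test(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(res$p_value, 1)
  # identical samples (not all tied) give p = 1 under the exact rule
  expect_equal(rank_sum_test(c(1, 2, 3), c(1.5, 2.5, 0.5))$p_value >= 0.5, TRUE)
  # ties fall back to the corrected normal approximation
  res2 <- rank_sum_test(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_false(res2$exact)
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
  expect_error(rank_sum_test(numeric(), 1:3), "nonempty")
})

test_that("rank tests are invariant under strictly monotone transformations", {
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:9, 1))
    y <- stats::rnorm(sample(3:9, 1))
    p0 <- rank_sum_test(x, y)$p_value
    expect_equal(rank_sum_test(exp(x), exp(y))$p_value, p0)
    expect_equal(rank_sum_test(x^3, y^3)$p_value, p0)
    g <- list(a = x, b = y, c = stats::rnorm(4))
    h0 <- kruskal_wallis(g)
    g2 <- lapply(g, function(v) atan(v))
    expect_equal(kruskal_wallis(g2)$statistic, h0$statistic)
  }
})

test_that("Kruskal-Wallis H matches the rank-formula oracle, p is chi-square", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(2:3, 1)
    groups <- lapply(seq_len(k), function(j) stats::rnorm(sample(2:4, 1)))
    res <- kruskal_wallis(groups)
    expect_equal(res$statistic, kw_h_formula(groups), tolerance = 1e-10)
    expect_equal(res$p_value,
                 stats::pchisq(res$statistic, df = k - 1, lower.tail = FALSE))
  }
  # tie correction agrees with the oracle too
  g <- list(c(1, 2, 2, 3), c(2, 3, 4, 4), c(1, 1, 5))
  expect_equal(kruskal_wallis(g)$statistic, kw_h_formula(g), tolerance = 1e-10)
  # degenerate all-equal input
  expect_warning(res0 <- kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(kruskal_wallis(list(1:5)), "two nonempty")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum normal approximation", {
  # both reduce to the same standardized rank statistic asymptotically:
  # H equals Z^2 (without continuity correction), so p-values converge
  set.seed(41)
  x <- stats::rnorm(60); y <- stats::rnorm(60, 0.4)
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_rs <- rank_sum_test(x, y)$p_value
  expect_equal(p_kw, p_rs, tolerance = 0.02)
})

test_that("pairwise country comparisons cover every pair within each zone", {
  set.seed(8)
  coh <- generate_cohort(cohort_config(seed = 8))
  sc <- score_farms(coh$questionnaire, coh$answers)
  res <- compare_countries(sc$zones, coh$farms)
  expect_equal(nrow(res), 5 * 3) # 5 zones x 3 country pairs
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # holm adjustment never lowers a p-value
  resh <- compare_countries(sc$zones, coh$farms, p_adjust = "holm")
  expect_true(all(resh$p_value >= res$p_value - 1e-12))
})

test_that("mixed model recovers coefficients and is ML-fitted", {
  set.seed(13)
  # zero-noise data with a pure linear cycle effect: exact recovery
  cfg <- cohort_config(seed = 13, footpad_month_amplitude = 0,
                       footpad_noise_sd = 0, footpad_country_sd = 10)
  coh <- generate_cohort(cfg)
  cyc <- coh$cycles
  cyc$footpad_score <- 40 + 5 * cyc$cycle_index +
    c(NL = 0, CY = 8, GR = -4)[cyc$country]
  fit <- suppressWarnings(fit_footpad_model(cyc, "cycle_index"))
  expect_equal(unname(fit$coefficients["cycle_index"]), 5, tolerance = 1e-6)
  expect_lt(stats::sigma(fit$model), 1e-3)
  expect_false(lme4::isREML(fit$model))
  expect_equal(fit$n_obs, nrow(cyc))
})

test_that("month-effect recovery: harmonic fit finds the seasonal amplitude", {
  set.seed(99)
  cfg <- cohort_config(
    seed = 99,
    countries = tibble::tibble(country = c("A", "B", "C"),
                               n_farms = c(17L, 17L, 16L)),
    footpad_month_amplitude = 25, footpad_noise_sd = 10
  )
  coh <- generate_cohort(cfg) # 50 farms x 4 cycles = 200 flock-cycles
  fit <- fit_footpad_model(coh$cycles, "start_month",
                           month_encoding = "harmonic")
  # generating seasonal term is amplitude * cos(2*pi*(m-1)/12); the harmonic
  # basis is sin/cos of 2*pi*m/12, so the generating signal projects onto it
  # with total amplitude ~= 25 (clamping at 0/200 is negligible here)
  cs <- fit$coefficients
  i_sin <- grep("^sin", names(cs)); i_cos <- grep("^cos", names(cs))
  expect_length(i_sin, 1); expect_length(i_cos, 1)
  amp <- sqrt(cs[[i_sin]]^2 + cs[[i_cos]]^2)
  se <- sqrt(sum(diag(as.matrix(stats::vcov(fit$model)))[c(i_sin, i_cos)]))
  expect_lt(abs(amp - 25), 2 * se + 1)
})

test_that("forward selection reduces to a pairwise AIC choice for one candidate", {
  set.seed(55)
  coh <- generate_cohort(cohort_config(seed = 55))
  sel <- forward_select_aic(coh$cycles, candidates = "start_month")
  null_fit <- fit_footpad_model(coh$cycles, character())
  alt_fit <- fit_footpad_model(coh$cycles, "start_month")
  if (alt_fit$aic < null_fit$aic) {
    expect_equal(sel$fixed_terms, "start_month")
    expect_equal(sel$aic, alt_fit$aic)
  } else {
    expect_equal(sel$fixed_terms, character())
    expect_equal(sel$aic, null_fit$aic)
  }
  # selection never worsens AIC relative to the null model
  sel_all <- forward_select_aic(coh$cycles)
  expect_lte(sel_all$aic, null_fit$aic)
  expect_equal(sel_all$trace$aic[1], null_fit$aic)
})

test_that("greedy forward selection is compared against exhaustive subset search", {
  set.seed(77)
  coh <- generate_cohort(cohort_config(seed = 77))
  cyc <- coh$cycles
  sel <- forward_select_aic(cyc)
  cands <- c("cycle_index", "start_month", "construction_year")
  subsets <- unlist(lapply(0:3, function(k) {
    utils::combn(cands, k, simplify = FALSE)
  }), recursive = FALSE)
  aics <- vapply(subsets, function(s) fit_footpad_model(cyc, s)$aic, 0)
  best <- subsets[[which.min(aics)]]
  # greedy may legitimately differ from the exhaustive optimum; if it does,
  # it must still be AIC-coherent (no candidate addition can improve it)
  if (!setequal(sel$fixed_terms, best)) {
    remaining <- setdiff(c("cycle_index", "start_month", "construction_year"),
                         sel$fixed_terms)
    for (cand in remaining) {
      expect_gte(fit_footpad_model(cyc, c(sel$fixed_terms, cand))$aic,
                 sel$aic)
    }
  } else {
    expect_setequal(sel$fixed_terms, best)
  }
})

test_that("pre/post comparison runs per country in both pooling modes", {
  set.seed(4)
  coh <- generate_cohort(cohort_config(seed = 4))
  r2 <- compare_prepost(coh$cycles, "footpad_score", mode = "phase")
  r4 <- compare_prepost(coh$cycles, "footpad_score", mode = "cycle")
  expect_equal(nrow(r2), 3L)
  expect_equal(nrow(r4), 3L)
  expect_true(all(r2$df == 1))
  expect_true(all(r4$df == 3))
  expect_true(all(c(r2$p_value, r4$p_value) <= 1))
})

test_that("Kruskal-Wallis detects a large injected shift across three groups", {
  set.seed(61)
  hits <- vapply(1:20, function(i) {
    g <- list(stats::rnorm(15, 50, 10), stats::rnorm(15, 70, 10),
              stats::rnorm(15, 90, 10))
    kruskal_wallis(g)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("forward selection on no-effect data keeps the null model in most runs", {
  # with three 1-df-equivalent noise candidates, plain AIC admits each with
  # probability ~ P(chisq_1 > 2) ~ 0.16, so an empty fixed set is expected
  # in roughly 0.84^3 ~ 59% of replicates
  empty <- vapply(1:20, function(i) {
    cfg <- cohort_config(seed = 4000 + i, footpad_month_amplitude = 0,
                         countries = tibble::tibble(
                           country = c("A", "B", "C"),
                           n_farms = c(12L, 12L, 11L)))
    coh <- generate_cohort(cfg)
    sel <- suppressWarnings(forward_select_aic(coh$cycles))
    length(sel$fixed_terms) == 0L
  }, TRUE)
  expect_gte(mean(empty), 0.5)
})
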