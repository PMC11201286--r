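test_that("rank_vector implements both tie dialects", {
  expect_equal(rank_vector(c(10, 20, 20, 30), "average"), c(1, 2.5, 2.5, 4))
  # spreadsheet minimum-rank semantics: ties share the first rank
  expect_equal(rank_vector(c(10, 20, 20, 30), "rank_eq"), c(1, 2, 2, 4))
  expect_equal(rank_vector(5, "average"), 1)
  expect_equal(rank_vector(5, "rank_eq"), 1)
  expect_error(rank_vector(numeric()), "empty")
  # fixture set frozen against counting semantics
  fixtures <- list(c(3, 1, 4, 1, 5), c(2, 2, 2), c(7, 7, 1, 7, 3))
  for (x in fixtures) {
    expect_equal(rank_vector(x, "rank_eq"), brute_min_ranks(x))
    expect_equal(rank_vector(x, "average"), brute_average_ranks(x))
  }
})

test_that("spearman_corr gives exact results on monotone vectors", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30))$estimate, 1.0)
  expect_equal(spearman_corr(1:3, c(3, 2, 1))$estimate, -1.0)
  r <- spearman_corr(c(1, 2, 2, 3), c(1, 3, 2, 4), "average")
  expect_equal(r$estimate, brute_spearman(c(1, 2, 2, 3), c(1, 3, 2, 4)))
  expect_error(spearman_corr(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
  expect_error(spearman_corr(1:4, 1:3), "equal length")
})

test_that("spearman is symmetric and invariant to increasing transforms", {
  set.seed(31)
  for (i in 1:25) {
    x <- sample(0:8, 30, replace = TRUE)  # plenty of ties
    y <- x + sample(0:5, 30, replace = TRUE)
    for (mode in c("average", "rank_eq")) {
      a <- spearman_corr(x, y, mode)$estimate
      expect_equal(spearman_corr(y, x, mode)$estimate, a)
      expect_equal(spearman_corr(exp(x / 3), y^3 + 2 * y, mode)$estimate, a)
    }
  }
})

test_that("p-values follow the large-sample t approximation", {
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40, sd = 2)
  r <- spearman_corr(x, y, "average")
  tstat <- r$estimate * sqrt((r$n - 2) / (1 - r$estimate^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), r$n - 2))
  expect_lt(spearman_corr(1:20, 1:20 + rnorm(20, sd = 1))$p_value, 0.01)
})

test_that("OLS fit recovers coefficients and satisfies the normal equations", {
  x <- c(0, 5, 12, 19, 25, 33)
  m <- fit_duration_model(x, 6.2995 * x + 49.459)
  expect_equal(coef(m)[["slope"]], 6.2995, tolerance = 1e-12)
  expect_equal(coef(m)[["intercept"]], 49.459, tolerance = 1e-12)
  m2 <- fit_duration_model(c(0, 1), c(1, 2))
  expect_equal(unname(coef(m2)), c(1, 1))
  expect_error(fit_duration_model(c(2, 2, 2), 1:3), "degenerate")
  set.seed(12)
  for (i in 1:20) {
    xs <- rnorm(30); ys <- 3 * xs + rnorm(30, sd = 5)
    fit <- fit_duration_model(xs, ys)
    res <- residuals(fit)
    expect_lt(abs(sum(res)), 1e-9)
    expect_lt(abs(sum(res * xs)), 1e-9)
  }
})

test_that("duration prediction is affine in the E-score", {
  m <- duration_model()
  expect_equal(predict_duration(m, 0), 49.459)
  expect_equal(predict_duration(m, 19), 169.1495)
  expect_equal(predict_duration(m, 29), 232.1445)
  expect_equal(predict(m, 10), m$slope * 10 + m$intercept)
  a <- runif(1, 0, 40); b <- runif(1, 0, 40)
  expect_equal(predict_duration(m, a) + predict_duration(m, b),
               predict_duration(m, a + b) + m$intercept)
  expect_error(predict_duration(m, -1), "non-negative")
})

test_that("r-ASRM totals use the component points and adhesion category map", {
  allmax <- rasrm_findings(6, 40, 40, "gt_two_thirds", "gt_two_thirds", 32)
  expect_identical(rasrm_total(allmax), 150L)
  expect_identical(
    rasrm_total(rasrm_findings(right_ovary_adhesion = "gt_two_thirds")), 16L)
  expect_identical(
    rasrm_total(rasrm_findings(left_ovary_adhesion = "lt_third")), 4L)
  expect_identical(
    rasrm_total(rasrm_findings(right_ovary_adhesion = "third_to_two_thirds")),
    8L)
  expect_identical(rasrm_total(rasrm_findings()), 0L)
  expect_error(rasrm_findings(peritoneal_points = 7), "\\[0, 6\\]")
  expect_error(rasrm_findings(endometrioma_points = 41), "\\[0, 40\\]")
})

test_that("stage bins partition 1-150 and are monotone", {
  expect_identical(as.character(rasrm_stage(c(1, 5, 6, 10, 15, 16, 40, 41, 150))),
                   c("I", "I", "II", "II", "II", "III", "III", "IV", "IV"))
  stages <- rasrm_stage(1:150)
  expect_false(anyNA(stages))
  expect_true(all(diff(as.integer(stages)) >= 0))
  expect_identical(as.vector(table(stages)), c(5L, 10L, 25L, 110L))
  expect_error(rasrm_stage(0), "\\[1, 150\\]")
  expect_error(rasrm_stage(151), "\\[1, 150\\]")
})

test_that("correlation_table matches direct spearman calls cell by cell", {
  set.seed(17)
  exams <- lapply(1:12, function(i) {
    ex <- random_exam(sprintf("c%02d", i))
    e <- e_score(ex)$e_score
    ex$outcomes <- outcomes(6.2995 * e + 49.459 + rnorm(1, 0, 30),
                            max(0, 3 * e + rnorm(1, 0, 40)),
                            sample(10:150, 1))
    ex
  })
  co <- cohort(exams)
  tab <- correlation_table(co)
  e <- vapply(co$exams, function(x) e_score(x)$e_score, numeric(1))
  dur <- vapply(co$exams, function(x) x$outcomes$duration_min, numeric(1))
  expect_equal(tab$estimate["E-score", "duration_min"],
               spearman_corr(e, dur, "average")$estimate)
  ad <- vapply(co$exams, function(x) adhesion_score(x$adhesions), numeric(1))
  expect_equal(tab$estimate["Adhesion score", "duration_min"],
               spearman_corr(ad, dur, "average")$estimate)
  # a score identical to the outcome correlates exactly 1
  co2 <- cohort(lapply(co$exams, function(x) {
    x$outcomes$duration_min <- e_score(x)$e_score + 1
    x
  }))
  expect_equal(correlation_table(co2)$estimate["E-score", "duration_min"], 1)
  expect_error(correlation_table(co, outcomes = "vas"), "vas")
})

test_that("cohort descriptives summarise scores, prevalence and outcomes", {
  ex1 <- random_exam("a"); ex2 <- random_exam("b")
  # force known E-scores via a fresh pair of simple exams
  e1 <- patient_exam("a", pain = pain_map(c(10, 0, 0, 0, 0, 0, 0)))
  e2 <- patient_exam("b", uterus = uterine_findings(retroverted = TRUE,
                                                    adenomyosis = TRUE))
  co <- cohort(list(e1, e2))
  d <- cohort_descriptives(co)
  esc <- d$scores[d$scores$score == "e_score", ]
  expect_equal(esc$mean, 8)       # (10 + 6) / 2
  expect_equal(c(esc$min, esc$max), c(6, 10))
  expect_equal(d$prevalence$n, c(0, 1, 1, 0))
  single <- cohort_descriptives(cohort(list(e1)))
  expect_equal(single$scores$mean, single$scores$min)
  expect_error(cohort_descriptives(cohort()), "empty")
})
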