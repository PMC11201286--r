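test_that("latent correlation transform matches the copula identity", {
  expect_equal(latent_correlation_from_spearman(0), 0)
  expect_equal(latent_correlation_from_spearman(1), 1)
  expect_equal(latent_correlation_from_spearman(-1), -1)
  expect_equal(round(latent_correlation_from_spearman(0.724), 4), 0.7401)
  expect_error(latent_correlation_from_spearman(1.2), "at most 1")
})

test_that("marginal quantile functions invert their distributions", {
  pmf <- marginal_spec("m", "discrete_pmf", support = c(0L, 3L, 6L),
                       probs = c(0.5, 0.3, 0.2))
  expect_identical(marginal_quantile(pmf, c(0, 0.49, 0.5, 0.79, 0.81, 1)),
                   c(0L, 0L, 0L, 3L, 6L, 6L))
  tn <- marginal_spec("t", "truncated_normal", mean = 5, sd = 2,
                      min = 0, max = 10)
  q <- marginal_quantile(tn, c(0, 0.5, 1))
  expect_equal(q, c(0, 5, 10))
  be <- marginal_spec("b", "bernoulli", prevalence = 0.25)
  expect_identical(marginal_quantile(be, c(0.74, 0.76)), c(0L, 1L))
  expect_error(marginal_spec("x", "discrete_pmf", support = 1:2,
                             probs = c(0.6, 0.5)), "sum to 1")
  expect_error(marginal_spec("x", "truncated_normal", mean = 0, sd = 1,
                             min = 2, max = 1), "min < max")
})

test_that("default marginals hit the configured means exactly", {
  m <- default_marginals()
  means <- vapply(m, nmse:::marginal_mean, numeric(1))
  expect_equal(means[["cyst"]], 6.32, tolerance = 1e-8)
  expect_equal(means[["adhesion"]], 3.96, tolerance = 1e-8)
  expect_equal(means[["pain"]], 6.07, tolerance = 1e-8)
  # uterine mean implied by lesion prevalences: 3 * (0.522 + 0.396 + 0.243)
  expect_equal(means[["uterine"]], 3.483, tolerance = 1e-8)
  expect_identical(m$uterine$support, c(0L, 3L, 6L, 9L))
})

test_that("sampled component scores are deterministic and within support", {
  spec <- cohort_spec(n = 400, seed = 20)
  s1 <- sample_component_scores(spec)
  s2 <- sample_component_scores(spec)
  expect_identical(s1, s2)
  expect_true(all(s1$cyst %in% 0:12))
  expect_true(all(s1$adhesion %in% 0:9))
  expect_true(all(s1$pain %in% 1:10))
  expect_true(all(s1$uterine %in% c(0L, 3L, 6L, 9L)))
  expect_length(attr(s1, "severity"), 400)
})

test_that("an identity target yields near-independent components", {
  spec <- cohort_spec(n = 5000, seed = 77,
                      target_spearman = diag(4))
  s <- sample_component_scores(spec)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(spearman_corr(s[[i]], s[[j]])$estimate), 0.05)
})

test_that("a strong pairwise target is recovered empirically", {
  ts <- default_target_spearman()
  ts["adhesion", "pain"] <- ts["pain", "adhesion"] <- 0.9
  spec <- cohort_spec(n = 5000, seed = 78, target_spearman = ts)
  s <- sample_component_scores(spec)
  expect_lt(abs(spearman_corr(s$adhesion, s$pain)$estimate - 0.9), 0.05)
})

test_that("an invalid target matrix is repaired or rejected", {
  ts <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  # wrong size
  expect_error(cohort_spec(target_spearman = ts), "4x4")
  bad <- matrix(0.9, 4, 4); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.9
  bad[1, 3] <- bad[3, 1] <- 0.9  # inconsistent triangle, not PSD
  expect_warning(sp <- cohort_spec(target_spearman = bad), "nearest")
  ev <- eigen(sp$latent_correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("back-filled exams reproduce the sampled scores exactly", {
  spec <- cohort_spec(n = 250, seed = 31)
  scores <- sample_component_scores(spec)
  set.seed(123)
  for (i in seq_len(nrow(scores))) {
    ex <- backfill_exam(scores[i, ], spec)
    expect_identical(validate_exam(ex), character(0))
    br <- e_score(ex, "flat3")
    expect_identical(br$cyst_score, scores$cyst[i])
    expect_identical(br$adhesion_score, scores$adhesion[i])
    expect_identical(br$pain_score, scores$pain[i])
    expect_identical(br$uterine_score, scores$uterine[i])
  }
  # the worked example's component row is reachable and rescores to 29
  set.seed(5)
  ex <- backfill_exam(list(cyst = 8, adhesion = 7, pain = 8, uterine = 6),
                      spec)
  expect_identical(e_score(ex, "flat3")$e_score, 29L)
  # empty row gives an empty exam
  ex0 <- backfill_exam(list(cyst = 0, adhesion = 0, pain = 0, uterine = 0),
                       cohort_spec(n = 1, seed = 1, rare_prevalence = 0,
                                   myoma_prevalence = 0))
  expect_identical(e_score(ex0, "flat3")$e_score, 0L)
  expect_error(backfill_exam(list(cyst = 0, adhesion = 0, pain = 0,
                                  uterine = 4), spec), "3")
})

test_that("tubal lesions absorb combined cyst scores above 10", {
  spec <- cohort_spec(n = 1, seed = 1)
  set.seed(61)
  for (cy in 11:12) {
    ex <- backfill_exam(list(cyst = cy, adhesion = 0, pain = 0, uterine = 0),
                        spec)
    expect_identical(combined_cyst_score(ex$right, ex$left), as.integer(cy))
    expect_gte(tubal_score(ex$right, ex$left), 3L)
  }
})

test_that("generated cohorts are deterministic and carry provenance", {
  spec <- cohort_spec(n = 60, seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(c1$provenance$seed, 9L)
  c3 <- generate_cohort(cohort_spec(n = 60, seed = 10))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  expect_identical(length(generate_cohort(cohort_spec(n = 0, seed = 1))), 0L)
})

test_that("zero duration noise makes duration a monotone map of the E-score", {
  spec <- cohort_spec(n = 40, seed = 14, duration_noise_sd = 0,
                      duration_bounds = c(-Inf, Inf))
  co <- generate_cohort(spec)
  e <- vapply(co$exams, function(x) e_score(x)$e_score, numeric(1))
  dur <- vapply(co$exams, function(x) x$outcomes$duration_min, numeric(1))
  expect_equal(spearman_corr(e, dur)$estimate, 1.0)
})

test_that("rank correlation with duration degrades as noise grows", {
  mean_rho <- function(noise_sd) {
    rhos <- vapply(1:10, function(s) {
      co <- generate_cohort(cohort_spec(n = 150, seed = 1000 + s,
                                        duration_noise_sd = noise_sd))
      e <- vapply(co$exams, function(x) e_score(x)$e_score, numeric(1))
      dur <- vapply(co$exams, function(x) x$outcomes$duration_min, numeric(1))
      spearman_corr(e, dur)$estimate
    }, numeric(1))
    mean(rhos)
  }
  grid <- c(10, 60, 150)
  rho <- vapply(grid, mean_rho, numeric(1))
  expect_true(all(diff(rho) < 0))
})

test_that("config files override the simulation defaults", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 12", "seed: 4", "duration_noise_sd: 5",
               "lesion_prevalence: {E: 0.9, R: 0.05, A: 0.05}",
               "marginals:",
               "  pain: {mean: 4.0, sd: 2.0, min: 0, max: 10}"), cfg)
  sp <- read_cohort_spec(cfg)
  expect_identical(sp$n, 12L)
  expect_identical(sp$seed, 4L)
  expect_equal(sp$duration_noise_sd, 5)
  expect_equal(nmse:::marginal_mean(sp$marginals$pain), 4.0, tolerance = 1e-8)
  expect_equal(sp$lesion_prevalence[["E"]], 0.9)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n": 7, "seed": 2, "rare_prevalence": 0}', js)
  spj <- read_cohort_spec(js)
  expect_identical(spj$n, 7L)
  expect_equal(spj$rare_prevalence, 0)
})
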