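endo <- function(side, d) ovary_finding(side, d, "endometrioma")

test_that("per-side cyst score is min(5, ceiling(d)) for endometriomas only", {
  expect_identical(cyst_side_score(endo("right", 6.5)), 5L)
  expect_identical(cyst_side_score(endo("left", 2.4)), 3L)
  expect_identical(cyst_side_score(ovary_finding("right")), 0L)
  # non-endometrioma cysts are recorded but never scored
  expect_identical(
    cyst_side_score(ovary_finding("right", 4.0, "other", cyst_label = "d")),
    0L)
  # closed form against a brute-force table at 0.1 cm steps
  for (d in seq(0.1, 49.9, by = 0.1)) {
    expect_identical(cyst_side_score(endo("right", d)),
                     as.integer(min(5, ceiling(round(d * 10) / 10))))
  }
})

test_that("tubal lesions score 3 points per affected side", {
  hydro <- ovary_finding("right", tubal_lesion = "hydrosalpinx")
  none_r <- ovary_finding("right"); none_l <- ovary_finding("left")
  pyo_l <- ovary_finding("left", tubal_lesion = "pyosalpinx")
  expect_identical(tubal_score(hydro, none_l), 3L)
  expect_identical(tubal_score(hydro, pyo_l), 6L)
  expect_identical(tubal_score(none_r, none_l), 0L)
})

test_that("combined cyst score caps the ovarian part at 10", {
  expect_identical(combined_cyst_score(endo("right", 6.5), endo("left", 2.4)), 8L)
  expect_identical(combined_cyst_score(endo("right", 9), endo("left", 9)), 10L)
  expect_identical(
    combined_cyst_score(ovary_finding("right", tubal_lesion = "hydrosalpinx"),
                        ovary_finding("left", tubal_lesion = "hydrosalpinx")),
    6L)
})

test_that("adhesion score counts positive sites and pain score is the max NRS", {
  expect_identical(adhesion_score(worked_example_exam()$adhesions), 7L)
  expect_identical(adhesion_score(adhesion_map()), 0L)
  expect_identical(adhesion_score(adhesion_map(canonical_adhesion_sites())), 10L)
  expect_identical(pain_score(worked_example_exam()$pain), 8L)
  expect_identical(pain_score(pain_map()), 0L)
  expect_identical(pain_map(c(10, 0, 0, 0, 0, 0, 0))[["I"]], 10)
})

test_that("uterine score follows the flat and size-graded nodule schemes", {
  u <- uterine_findings(adenomyosis = TRUE, nodules_cm = 2.6)
  expect_identical(uterine_score(u, "flat3"), 6L)
  expect_identical(uterine_score(u, "sized"), 9L)  # 3 (A) + 6 (2-3 cm band)
  all3 <- uterine_findings(retroverted = TRUE, adenomyosis = TRUE,
                           nodules_cm = 1.5)
  expect_identical(uterine_score(all3, "flat3"), 9L)
  # cumulative size-graded bands: 1.5 -> 3, 3.5 -> 10
  two <- uterine_findings(nodules_cm = c(1.5, 3.5))
  expect_identical(uterine_score(two, "sized"), 13L)
  # flat scheme scores nodules once regardless of count
  expect_identical(uterine_score(two, "flat3"), 3L)
  expect_identical(uterine_score(uterine_findings(myoma = TRUE)), 0L)
})

test_that("flat uterine scores live in {0,3,6,9}; sized steps at 2 and 3 cm", {
  combos <- expand.grid(r = c(FALSE, TRUE), a = c(FALSE, TRUE),
                        nod = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    u <- uterine_findings(combos$r[i], combos$a[i],
                          if (combos$nod[i]) 2.0 else numeric())
    expect_true(uterine_score(u, "flat3") %in% c(0L, 3L, 6L, 9L))
  }
  one_nod <- function(d) uterine_score(uterine_findings(nodules_cm = d), "sized")
  ds <- seq(1.0, 4.0, by = 0.1)
  got <- vapply(ds, one_nod, integer(1))
  expect_identical(got, ifelse(ds >= 3, 10L, ifelse(ds >= 2, 6L, 3L)))
  expect_identical(one_nod(1.9), 3L)
  expect_identical(one_nod(2.0), 6L)
  expect_identical(one_nod(2.9), 6L)
  expect_identical(one_nod(3.0), 10L)
})

test_that("rare-site score is a flat 10 for any involvement", {
  expect_identical(rare_score(rare_site_findings("vaginal")), 10L)
  expect_identical(rare_score(rare_site_findings()), 0L)
  expect_identical(rare_score(rare_site_findings(c("vaginal", "umbilical"))),
                   10L)
})

test_that("E-score totals the components and matches the worked example", {
  br <- e_score(worked_example_exam(), "flat3")
  expect_identical(br$cyst_score, 8L)
  expect_identical(br$adhesion_score, 7L)
  expect_identical(br$pain_score, 8L)
  expect_identical(br$uterine_score, 6L)
  expect_identical(br$rare_score, 0L)
  expect_identical(br$e_score, 29L)
  expect_identical(e_score(worked_example_exam(), "sized")$e_score, 32L)
  expect_identical(e_score(patient_exam())$e_score, 0L)
})

test_that("decomposition holds on random exams under both schemes", {
  set.seed(42)
  for (i in 1:50) {
    ex <- random_exam()
    for (scheme in c("flat3", "sized")) {
      br <- e_score(ex, scheme)
      expect_identical(br$e_score,
                       br$cyst_score + br$adhesion_score + br$pain_score +
                         br$uterine_score + br$rare_score)
      expect_identical(br$cyst_score, br$cyst_right + br$cyst_left + br$tubal)
      # full-variant consistency oracle
      expect_equal(variant_score(ex, full_escore_variant(scheme)),
                   as.numeric(br$e_score))
    }
  }
})

test_that("variant scores sum only the included components", {
  ex <- worked_example_exam()
  expect_equal(variant_score(ex, variant_spec(include_adhesion = TRUE)), 7)
  expect_equal(variant_score(ex, variant_spec(include_adhesion = TRUE,
                                              include_pain = TRUE)), 15)
  expect_equal(variant_score(ex, full_escore_variant()), 29)
  # uterine term restricted to listed elements
  expect_equal(variant_score(ex, variant_spec(include_uterine = TRUE,
                                              uterine_elements = "A")), 3)
  expect_equal(variant_score(ex, variant_spec(include_uterine = TRUE,
                                              uterine_elements = "E",
                                              e_scheme = "sized")), 6)
  expect_error(variant_spec(uterine_elements = "A"), "include_uterine")
})

test_that("every variant score is monotone in disease burden", {
  base <- worked_example_exam()
  variants <- c(default_variants(), list(sized = full_escore_variant("sized")))
  worse <- list(
    bigger_cyst = {
      ex <- base; ex$left$cyst_diameter_cm <- 4.9; ex
    },
    more_adhesions = {
      ex <- base
      ex$adhesions <- adhesion_map(c(canonical_adhesion_sites()[1:8])); ex
    },
    more_pain = { ex <- base; ex$pain[["I"]] <- 10; ex },
    extra_lesion = { ex <- base; ex$uterus$retroverted <- TRUE; ex },
    rare_site = { ex <- base; ex$rare <- rare_site_findings("bladder"); ex })
  for (v in variants) {
    s0 <- variant_score(base, v)
    for (ex in worse)
      expect_gte(variant_score(ex, v), s0)
  }
})
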