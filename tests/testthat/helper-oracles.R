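# Independent oracles, deliberately built from first principles rather
# than from the package's own code paths.

# Average ranks by counting: r_i = #(x_j < x_i) + (#(x_j == x_i) + 1) / 2.
brute_average_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Minimum-rank (spreadsheet RANK.EQ ascending) by counting smaller values.
brute_min_ranks <- function(x) {
  vapply(seq_along(x), function(i) sum(x < x[i]) + 1, numeric(1))
}

# Pearson correlation from raw sums.
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

brute_spearman <- function(x, y, ranker = brute_average_ranks) {
  brute_pearson(ranker(x), ranker(y))
}

# Random valid exam generator for property tests (uses the ambient RNG;
# wrap in withr::with_seed or set.seed at the call site).
random_exam <- function(id = "prop") {
  side <- function(s) {
    kind <- sample(c("none", "endometrioma", "other"), 1,
                   prob = c(0.35, 0.55, 0.10))
    d <- if (kind == "none") 0 else round(stats::runif(1, 0.5, 12), 1)
    tub <- sample(c("none", "hydrosalpinx", "pyosalpinx"), 1,
                  prob = c(0.85, 0.1, 0.05))
    ovary_finding(s, d, kind,
                  cyst_label = if (kind == "other") sample(letters, 1),
                  tubal_lesion = tub)
  }
  n_adh <- sample(0:10, 1)
  n_nod <- sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
  rare <- if (stats::runif(1) < 0.1)
    rare_site_findings(sample(c("intestinal", "bladder", "vaginal",
                                "umbilical"), 1))
  else rare_site_findings()
  patient_exam(
    patient_id = id,
    right = side("right"), left = side("left"),
    adhesions = adhesion_map(sample(canonical_adhesion_sites(), n_adh)),
    pain = pain_map(sample(0:10, 7, replace = TRUE)),
    uterus = uterine_findings(
      retroverted = stats::runif(1) < 0.4,
      adenomyosis = stats::runif(1) < 0.25,
      nodules_cm = if (n_nod) round(stats::runif(n_nod, 1, 4.5), 1)
                   else numeric(),
      myoma = stats::runif(1) < 0.15),
    rare = rare)
}
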