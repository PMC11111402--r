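test_that("dichotomization follows the CI rule and the prevalence median split", {
  # CI (0, 40) -> absent; CI (5, 40) -> present
  tab <- data.frame(
    sample_id = c("a", "b"),
    signature = "S1",
    exposure = c(20, 20),
    ci_low = c(0, 5), ci_high = c(40, 40),
    present = c(FALSE, TRUE))
  d <- dichotomize(tab)
  expect_identical(d$S1, c(FALSE, TRUE))
  expect_identical(unname(attr(d, "rule")["S1"]), "ci_presence")
  # 80% prevalent signature switches to median split with ~50/50 balance
  set.seed(3)
  n <- 100
  tab2 <- data.frame(
    sample_id = sprintf("s%03d", 1:n), signature = "S2",
    exposure = rlnorm(n, 6, 0.5),
    ci_low = ifelse(seq_len(n) <= 80, 1, 0), ci_high = 50,
    present = seq_len(n) <= 80)
  d2 <- dichotomize(tab2)
  expect_identical(unname(attr(d2, "rule")["S2"]), "median_split")
  expect_equal(sum(d2$S2), 50, tolerance = 2)
})

test_that("BH adjustment equals the step-up closed form and p.adjust invariants", {
  # worked example of the step-up rule
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # closed form q_i = min_{j>=i} m p_(j) / j on random inputs,
  # permutation-invariant
  set.seed(5)
  for (i in 1:10) {
    p <- runif(12)^2
    o <- order(p)
    m <- length(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    q_oracle <- pmin(1, q_sorted)[order(o)]
    expect_equal(bh_adjust(p), q_oracle)
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), q_oracle[perm])
  }
})

test_that("exact Wilcoxon signed-rank matches full sign-assignment enumeration", {
  set.seed(7)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.3, 1), 3)
      d <- d[d != 0]
      if (any(duplicated(abs(d)))) next
      w <- wilcoxon_signed_rank(d, rep(0, length(d)))
      expect_true(w$exact)
      expect_equal(w$p_value, wilcoxon_enum_p(d), tolerance = 1e-12)
    }
  }
  # zero differences give p = 1
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
})

test_that("Fisher exact matches the hypergeometric closed form", {
  # toy table mirroring a T>A driver enrichment contrast
  cls <- rep(c("T>A", "C>T", "T>A", "C>T"), c(25, 75, 13, 87))
  exp_flag <- rep(c(TRUE, FALSE), c(100, 100))
  de <- driver_spectrum_enrichment(cls, exp_flag)
  expect_equal(de$prop_exposed, 0.25)
  expect_equal(de$prop_unexposed, 0.13)
  # oracle: two-sided Fisher p as the sum of hypergeometric point
  # probabilities not exceeding the observed one
  m <- 38; nn <- 162; k <- 100; x <- 25
  probs <- dhyper(0:min(m, k), m, nn, k)
  p_oracle <- sum(probs[probs <= dhyper(x, m, nn, k) * (1 + 1e-7)])
  expect_equal(de$p_value, p_oracle, tolerance = 1e-9)
  # all-or-nothing split has the closed-form single-tail probability
  cls2 <- rep(c("T>A", "C>T"), c(10, 10))
  exp2 <- rep(c(TRUE, FALSE), c(10, 10))
  de2 <- driver_spectrum_enrichment(cls2, exp2)
  expect_equal(de2$p_value, 2 * dhyper(10, 10, 10, 10), tolerance = 1e-9)
  # identical proportions -> maximal p
  de3 <- driver_spectrum_enrichment(rep(c("T>A", "C>T"), 10),
                                    rep(c(TRUE, FALSE), each = 10))
  expect_equal(de3$p_value, 1)
  expect_error(driver_spectrum_enrichment("T>A", TRUE), "empty")
})

test_that("risk-factor logistic regression recovers a planted smoking effect", {
  set.seed(11)
  n <- 500
  cohort <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    country = sample(c("X", "Y"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_dx = round(rnorm(n, 60, 8)),
    smoking = sample(c("current", "ex", "never"), n, replace = TRUE))
  lp <- -1 + log(3) * (cohort$smoking == "current")
  outcome <- runif(n) < plogis(lp)
  res <- risk_factor_regression(outcome, cohort$smoking == "current",
                                cohort, family_size = 224L)
  expect_gt(res$estimate, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$family_size, 224L)
  expect_error(risk_factor_regression(outcome, rep(1, n), cohort),
               "constant")
})

test_that("ASR regression recovers a planted slope and rejects degenerate cohorts", {
  set.seed(13)
  n <- 400
  asrs <- c(2, 5, 8, 12, 14.5)
  country <- sample(letters[1:5], n, replace = TRUE)
  asr <- asrs[match(country, letters[1:5])]
  cohort <- data.frame(sample_id = seq_len(n), country = country,
                       asr = asr,
                       sex = sample(c("male", "female"), n, TRUE),
                       age_dx = round(rnorm(n, 60, 9)))
  b <- 120
  y <- 1000 + b * asr + rnorm(n, 0, 400)
  res <- asr_regression(y, cohort)
  se <- abs(res$estimate - b) # recovered within 2 standard errors
  fit <- lm(y ~ asr + sex + age_dx, data = cbind(cohort, y = y))
  expect_lt(se, 2 * summary(fit)$coefficients["asr", 2])
  expect_lt(res$p_value, 1e-10)
  # perfectly collinear response
  expect_lt(suppressWarnings(asr_regression(asr, cohort))$p_value, 1e-200)
  one <- cohort[cohort$country == "a", ]
  expect_error(asr_regression(y[cohort$country == "a"], one), "single")
})

test_that("country burden test flags shifted countries and rejects degenerate input", {
  set.seed(17)
  burden <- c(rlnorm(30, 8, 0.4), rlnorm(30, 8, 0.4) * 5)
  country <- rep(c("P", "Q"), each = 30)
  res <- country_burden_test(burden, country)
  expect_lt(res$p_value, 0.001)
  expect_error(country_burden_test(rlnorm(30, 8, 0.4), rep("P", 30)),
               "2 countries")
  expect_warning(
    country_burden_test(c(burden, 100), c(country, "solo")), "solo")
})

test_that("identical clone and subclone mixes give null enrichment", {
  set.seed(19)
  panel <- test_panel()[, 1:3]
  n <- 12
  counts <- vapply(1:n, function(i)
    mixture_spectrum(panel, c(1, 1, 1), 2000), integer(96))
  colnames(counts) <- sprintf("s%02d", 1:n)
  rownames(counts) <- rownames(panel)
  res <- clonal_subclonal_enrichment(counts, counts, panel)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$q_value == 1))
  expect_error(
    clonal_subclonal_enrichment(counts[, 1:3], counts[, 1:3], panel),
    "paired samples")
})
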