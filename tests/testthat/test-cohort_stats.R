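test_that("prevalence reports counts, fractions and rounded percentages", {
  # grade-wise counts 83/87, 70/79, 20/24 with one initiating gene each
  M <- matrix(0L, nrow = 3, ncol = 87 + 79 + 24,
              dimnames = list(c("KRAS", "BRAF", "CDKN2A"), NULL))
  groups <- rep(c("G1", "G2", "G3"), c(87, 79, 24))
  M["KRAS", c(1:83, 87 + 1:70, 87 + 79 + 1:20)] <- 1L
  out <- prevalence_by_grade(M, groups)
  expect_equal(out$n_event, c(83, 70, 20))
  expect_equal(out$n, c(87, 79, 24))
  expect_equal(out$percent, c(95.4, 88.6, 83.3))

  zero <- matrix(0L, 3, 10, dimnames = list(c("KRAS", "BRAF", "CDKN2A"),
                                            NULL))
  out0 <- prevalence_by_grade(zero, rep("G1", 10))
  expect_equal(out0$percent, 0)
  expect_error(prevalence_by_grade(M[1:2, , drop = FALSE] * 0,
                                   groups, genes = "NOPE"), "none of")
})

test_that("Fisher co-occurrence equals enumeration and handles edge tables", {
  sym <- fisher_cooccurrence(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)

  skewed <- matrix(c(1, 9, 9, 1), 2)
  res <- fisher_cooccurrence(skewed)
  expect_equal(res$p_value, fisher_brute_force(skewed), tolerance = 1e-9)
  # 202 / 184756 by direct hypergeometric enumeration
  expect_equal(res$p_value, 202 / 184756, tolerance = 1e-9)

  # random tables with n <= 40: exact p equals full enumeration
  set.seed(97)
  for (i in 1:60) {
    n <- sample(4:40, 1)
    tab <- matrix(tabulate(sample(4, n, replace = TRUE), 4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_cooccurrence(tab)$p_value, fisher_brute_force(tab),
                 tolerance = 1e-9)
  }

  # zero cell: finite bound on one side only
  z <- fisher_cooccurrence(matrix(c(0, 10, 10, 5), 2))
  expect_equal(z$conf_int[1], 0)
  expect_true(is.finite(z$conf_int[2]))
  expect_error(fisher_cooccurrence(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_cooccurrence(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(13)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  res <- anova_tukey(c(x, y), rep(c("a", "b"), c(20, 25)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a planted FGA gradient is detected by ANOVA and Tukey", {
  build <- load_genome_build("hg19")
  spec <- cohort_spec(seed = 2)
  set.seed(23)
  sim <- lapply(rep(c("BEN", "G1", "G3"), c(25, 25, 25)), function(g) {
    cn <- simulate_case_cn_sv(g, spec, build, with_svs = FALSE)
    list(g = g, fga = cn$truth$fga_realized)
  })
  fga <- vapply(sim, `[[`, 0, "fga")
  grp <- vapply(sim, `[[`, "", "g")
  res <- anova_tukey(fga, grp)
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$tukey["G3-BEN", "p adj"], 0.01)
})

test_that("logrank matches a textbook hand computation", {
  # group A: deaths at 1, 2, 3; group B: deaths at 4, 5, 6
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  # hand-computed O-E and variance over the six event times
  n <- 6; o_a <- 3; e_a <- 0; v_a <- 0
  at_risk_a <- c(3, 2, 1, 0, 0, 0)
  at_risk <- c(6, 5, 4, 3, 2, 1)
  for (i in 1:6) {
    e_a <- e_a + at_risk_a[i] / at_risk[i]
    if (at_risk[i] > 1)
      v_a <- v_a + (at_risk_a[i] / at_risk[i]) *
        (1 - at_risk_a[i] / at_risk[i]) *
        (at_risk[i] - 1) / (at_risk[i] - 1)
  }
  chisq_hand <- (o_a - e_a)^2 / v_a
  res <- km_logrank(time, event, grp)
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # duplicated data in both groups: statistic 0
  same <- km_logrank(c(time, time), c(event, event),
                     rep(c("A", "B"), each = 6))
  expect_equal(same$chisq, 0, tolerance = 1e-12)

  expect_error(km_logrank(time, event, factor(grp, levels = c("A", "B", "C"))),
               "zero records")
})

test_that("KM estimate without censoring equals the empirical survivor", {
  set.seed(71)
  t <- sort(rexp(30, 0.1))
  fit <- km_logrank(c(t, t + 1), rep(1, 60),
                    rep(c("A", "B"), each = 30))$fit
  sf <- summary(fit)
  a <- sf$surv[sf$strata == "g=A"]
  emp <- 1 - seq_along(t) / length(t)
  expect_equal(a, emp, tolerance = 1e-12)
})

test_that("profile chi-square matches hand computation and reports df", {
  hand <- profile_chisq(matrix(c(30, 10, 10, 30), 2))
  expect_equal(hand$chisq, 20)
  expect_equal(hand$df, 1)

  even <- profile_chisq(matrix(c(10, 10, 10, 10, 10, 10), 2))
  expect_equal(even$chisq, 0)
  expect_equal(even$df, 2)

  set.seed(99)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  res <- profile_chisq(tab)
  expect_gte(res$chisq, 0)
  expect_equal(res$df, (3 - 1) * (4 - 1))
  expect_error(profile_chisq(matrix(c(0, 0, 5, 5), 2,
                                    byrow = TRUE)), "zero-margin")
  expect_warning(profile_chisq(matrix(c(2, 3, 3, 2), 2)), "below 5")
})

test_that("median split dichotomizes around the recorded cut point", {
  x <- c(1, 2, 3, 4, 5)
  ms <- median_split(x)
  expect_equal(ms$cut, 3)
  expect_equal(as.character(ms$group), c("low", "low", "low", "high", "high"))
})
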