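test_that("balancer intercross and driver crosses give the textbook fractions", {
  # construct/CyO x construct/CyO with CyO/CyO inviable: 1/3 vs 2/3
  sch <- cross_scheme(c("KI", "CyO"), c("KI", "CyO"), lethal = "CyO/CyO")
  ef <- expected_fractions(sch)
  expect_equal(unname(ef["KI/KI"]), 1 / 3)
  expect_equal(unname(ef["CyO/KI"]), 2 / 3)
  expect_equal(sum(ef), 1)

  # balanced GAL4 driver x homozygous UAS responder: 50/50
  sch2 <- cross_scheme(c("GAL4", "Bal"), c("UAS", "UAS"),
                       classes = c("GAL4/UAS" = "driver>UAS",
                                   "Bal/UAS" = "balancer"))
  ef2 <- expected_fractions(sch2)
  expect_equal(unname(ef2["driver>UAS"]), 0.5)
  expect_equal(unname(ef2["balancer"]), 0.5)

  # homozygous x homozygous
  expect_equal(unname(expected_fractions(cross_scheme(c("A", "A"),
                                                      c("A", "A")))["A/A"]), 1)

  # all progeny lethal errors
  expect_error(expected_fractions(
    cross_scheme(c("CyO", "CyO"), c("CyO", "CyO"), lethal = "CyO/CyO")),
    "lethal")
})

test_that("two-locus enumeration equals the 16-cell Punnett oracle", {
  p1 <- list(c("A", "a"), c("B", "b"))
  p2 <- list(c("A", "a"), c("B", "b"))
  ef <- expected_fractions(cross_scheme(p1, p2))
  want <- oracle_punnett_2locus(p1, p2)
  expect_equal(sort(names(ef)), sort(names(want)))
  expect_equal(ef[sort(names(ef))], want[sort(names(want))])
  expect_equal(sum(ef), 1)
})

test_that("expected fractions sum to 1 after lethality on randomized schemes", {
  set.seed(71)
  alleles <- c("w", "KI", "CyO", "Sb", "TM3")
  for (i in 1:25) {
    p1 <- sample(alleles, 2, replace = TRUE)
    p2 <- sample(alleles, 2, replace = TRUE)
    lethal <- paste(sort(sample(alleles, 2, replace = TRUE)), collapse = "/")
    sch <- cross_scheme(p1, p2, lethal = lethal)
    ef <- tryCatch(expected_fractions(sch), error = function(e) NULL)
    if (is.null(ef)) next   # fully lethal draws are legitimately rejected
    expect_equal(sum(ef), 1)
    expect_false(any(names(ef) == lethal))
  }
})

test_that("deviation test: exact binomial behavior and oracle agreement", {
  # observed exactly proportional to expected
  expect_equal(deviation_test(c(a = 50, b = 50),
                              c(a = 0.5, b = 0.5))$p_value, 1)
  # 19/100 hatched against an expected 50%: rejected far below alpha = 0.001
  dt <- deviation_test(c(hatched = 19, other = 81),
                       c(hatched = 0.5, other = 0.5))
  expect_equal(dt$method, "exact binomial")
  expect_lt(dt$p_value, 0.001)
  expect_equal(dt$p_value, oracle_binom_p(19, 100, 0.5), tolerance = 1e-10)
  # two-class result equals the multinomial computation restricted to 2 classes
  p_multi <- mipepscan:::exact_multinomial_p(c(19L, 81L), c(0.5, 0.5))
  expect_equal(dt$p_value, p_multi, tolerance = 1e-10)

  expect_error(deviation_test(c(a = 1, b = 1), c(a = 1, b = 0)), "zero")
  expect_error(deviation_test(c(a = 0, b = 0), c(a = .5, b = .5)), "positive")
})

test_that("multi-class deviation uses chi-square or exact fallback sensibly", {
  # large counts: chi-square
  dt <- deviation_test(c(a = 30, b = 65, c = 25),
                       c(a = 0.25, b = 0.5, c = 0.25))
  expect_equal(dt$method, "chi-square goodness of fit")
  expect_equal(dt$statistic,
               unname(suppressWarnings(chisq.test(
                 c(30, 65, 25), p = c(0.25, 0.5, 0.25))$statistic)))
  # small counts: exact multinomial, consistent with chi-square direction
  dt2 <- deviation_test(c(a = 8, b = 1, c = 1),
                        c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
  expect_equal(dt2$method, "exact multinomial")
  expect_lt(dt2$p_value, 0.05)
  # exact multinomial sums outcome probabilities no larger than observed
  p_unif <- mipepscan:::exact_multinomial_p(c(3L, 3L, 4L),
                                            rep(1 / 3, 3))
  expect_gt(p_unif, 0.9)
})

test_that("deviation-test p-values are approximately uniform under the null", {
  sch <- cross_scheme(c("GAL4", "Bal"), c("UAS", "UAS"))
  set.seed(72)
  pvals <- vapply(1:500, function(i) {
    obs <- simulate_progeny(sch, 60)
    deviation_test(obs, expected_fractions(sch))$p_value
  }, numeric(1))
  # sub-uniformity (validity) at a grid of levels, plus a coarse lower
  # bound; exact-test discreteness rules out a sharp KS comparison
  for (alpha in c(0.05, 0.1, 0.2, 0.5)) {
    expect_lte(mean(pvals <= alpha), alpha + 0.05)
  }
  expect_gte(mean(pvals <= 0.5), 0.3)
})

test_that("the battery takes the parametric branch on Gaussian equal-variance data", {
  d <- simulate_phenotypes(c("ctrl", "miR", "miPEP"), n_per_group = 25,
                           effects = c(miR = -2, miPEP = -0.8), seed = 73)
  b <- stats_battery(d)
  expect_equal(b$branch, "parametric")
  expect_equal(b$global_test, "one-way ANOVA")
  expect_lt(b$global_p, 0.05)
  expect_true(all(b$normality_p > 0.05))
  # pairwise Bonferroni matrix present with both comparisons vs ctrl small
  expect_false(is.null(b$pairwise))
})

test_that("the battery takes the nonparametric branch on heavy-tailed data", {
  d <- simulate_phenotypes(c("ctrl", "miR", "miPEP"), n_per_group = 25,
                           effects = c(miR = -1), dist = "lognormal",
                           seed = 74)
  b <- stats_battery(d)
  expect_equal(b$branch, "nonparametric")
  expect_equal(b$global_test, "Kruskal-Wallis")
  # planted one-sd median shift is detected
  expect_lt(b$global_p, 0.05)
})

test_that("two-group comparisons choose t-test or Mann-Whitney by normality", {
  dg <- simulate_phenotypes(c("ctrl", "treat"), n_per_group = 20,
                            effects = c(treat = 1.5), seed = 75)
  bg <- stats_battery(dg)
  expect_true(bg$global_test %in% c("t-test (pooled)", "Mann-Whitney"))
  if (bg$branch == "parametric") expect_equal(bg$global_test, "t-test (pooled)")

  dl <- simulate_phenotypes(c("ctrl", "treat"), n_per_group = 20,
                            dist = "lognormal", seed = 76)
  bl <- stats_battery(dl)
  if (bl$branch == "nonparametric") expect_equal(bl$global_test, "Mann-Whitney")
})

test_that("small groups force the nonparametric branch; tiny groups error", {
  d <- data.frame(group = rep(c("a", "b"), each = 5),
                  value = c(rnorm(5), rnorm(5)))
  b <- stats_battery(d)
  expect_equal(b$branch, "nonparametric")
  expect_true(any(grepl("n < 8", b$notes)))
  expect_error(stats_battery(data.frame(group = c("a", "a", "a", "b", "b"),
                                        value = rnorm(5))), "'b'")
})

test_that("identical samples are never declared different", {
  d <- data.frame(group = rep(c("a", "b"), each = 10),
                  value = rep(c(1, 2, 3, 4, 5), 4))
  b <- stats_battery(d)
  expect_gt(b$global_p, 0.9)
})

test_that("battery branch choice is deterministic and group-order invariant", {
  d <- simulate_phenotypes(c("g1", "g2", "g3"), n_per_group = 15,
                           effects = c(g2 = 1), seed = 77)
  b1 <- stats_battery(d)
  b2 <- stats_battery(d[sample(nrow(d)), ])
  expect_equal(b1$branch, b2$branch)
  expect_equal(b1$global_p, b2$global_p)
})

test_that("the normality test itself discriminates Gaussian from skewed data", {
  set.seed(78)
  # calibration: uniform-ish p under the null
  p_norm <- vapply(1:200, function(i)
    dagostino_pearson(rnorm(30))$p_value, numeric(1))
  expect_gt(mean(p_norm > 0.05), 0.85)
  # power against a strongly skewed alternative
  p_lnorm <- vapply(1:100, function(i)
    dagostino_pearson(rlnorm(30))$p_value, numeric(1))
  expect_gt(mean(p_lnorm < 0.05), 0.8)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("group summaries match the direct mean/sem formulas", {
  d <- data.frame(group = c("a", "a", "a", "b"), value = c(2, 4, 6, 10))
  s <- summarize_groups(d)
  expect_equal(s$mean[s$group == "a"], 4)
  expect_equal(s$sem[s$group == "a"], 2 / sqrt(3))
  expect_true(is.na(s$sem[s$group == "b"]))
  set.seed(79)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    s1 <- summarize_groups(data.frame(group = "g", value = v))
    expect_equal(s1$mean, mean(v), tolerance = 1e-12)
    expect_equal(s1$sem, sd(v) / sqrt(length(v)), tolerance = 1e-12)
  }
  expect_error(summarize_groups(data.frame(group = character(),
                                           value = numeric())), "empty")
})
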