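test_that("the synthetic survey has the documented shape and is reproducible", {
  s1 <- generate_survey(300, seed = 1)
  s2 <- generate_survey(300, seed = 1)
  expect_identical(dim(s1), c(300L, 10L))
  expect_identical(s1, s2)
  expect_setequal(levels(s1$BMI), c("<18.5", "18.5~", "24.0~", "28.0~"))
  expect_setequal(levels(s1$PhysicalActivity), c("Insufficient", "Normal", "Sufficient"))
})

test_that("survey sampling and MLE refitting recover the outcome CPT", {
  net <- load_fixture("lipid10")$network
  s <- generate_survey(500000, seed = 6)
  # empirical detection rate in the highest-risk stratum of the outcome CPT
  stratum <- s$PhysicalActivity == "Insufficient" & s$Gender == "male" & s$BMI == "28.0~"
  expect_lt(abs(mean(s$Hyperlipidemia[stratum] == "yes") - 0.75273), 0.01)
  # full-CPT recovery through the MLE refit of the true graph (the refit
  # declares parents in graph order, so align axes before comparing)
  fitted <- fit_mle(net$dag, s)
  got <- align_cpt_prob(fitted$cpts$Hyperlipidemia, net$cpts$Hyperlipidemia)
  expect_lt(max(abs(got - net$cpts$Hyperlipidemia$prob)), 0.01)
})

test_that("chi-square screening matches hand arithmetic and the entry rule", {
  d <- tibble::tibble(
    x = factor(rep(c("u", "u", "v", "v"), c(30, 10, 10, 30)), levels = c("u", "v")),
    y = factor(rep(c("a", "b", "a", "b"), c(30, 10, 10, 30)), levels = c("a", "b"))
  )
  res <- chi2_screen(d, "y")
  expect_equal(res$statistic, 20, tolerance = 1e-9) # all expected counts 20
  expect_identical(as.integer(res$df), 1L)

  ind <- tibble::tibble(
    x = factor(rep(c("u", "v"), each = 20)),
    y = factor(rep(c("a", "b"), 20))
  )
  res0 <- chi2_screen(ind, "y")
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  # the liberal p < 0.5 candidate rule
  expect_true(chi2_screen(d, "y")$candidate)
  expect_false(res0$candidate)

  const <- tibble::tibble(
    x = factor(rep("u", 40), levels = c("u", "v")),
    y = factor(rep(c("a", "b"), 20))
  )
  expect_error(chi2_screen(const, "y"), class = "bnhybrid_error_degenerate")
})

test_that("the trend test detects monotone proportions and is antisymmetric", {
  make_trend <- function(props, n_per = 100, lev = c("l1", "l2", "l3")) {
    tibble::tibble(
      g = factor(rep(lev, each = n_per), levels = lev),
      y = factor(unlist(lapply(props, function(p) {
        rep(c("no", "yes"), round(c((1 - p) * n_per, p * n_per)))
      })), levels = c("no", "yes"))
    )
  }
  steep <- make_trend(c(0.1, 0.5, 0.9))
  res <- trend_test(steep, "g", "y")
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$z, 0)

  flat <- make_trend(c(0.4, 0.4, 0.4))
  expect_lt(abs(trend_test(flat, "g", "y")$z), 1e-9)

  rev <- steep
  rev$g <- factor(rev$g, levels = c("l3", "l2", "l1"))
  expect_equal(trend_test(rev, "g", "y")$z, -res$z, tolerance = 1e-9)

  # cross-check the statistic against the standard trend test
  tab <- table(steep$g, steep$y)
  pt <- suppressWarnings(stats::prop.trend.test(tab[, 2], rowSums(tab)))
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-9)
})

test_that("stepwise selection keeps a strong predictor and drops pure noise", {
  correct <- 0L
  for (s in 1:10) {
    withr::local_seed(1200 + s)
    n <- 2000
    x1 <- sample(1:3, n, TRUE)
    y <- stats::rbinom(n, 1, stats::plogis(-2 + 1.2 * x1))
    d <- tibble::tibble(
      outcome = factor(ifelse(y == 1, "yes", "no"), levels = c("no", "yes")),
      x1 = factor(x1),
      !!!stats::setNames(
        lapply(1:5, function(i) factor(sample(c("a", "b"), n, TRUE))),
        paste0("noise", 1:5)
      )
    )
    fit <- stepwise_logistic(d, "outcome", c("x1", paste0("noise", 1:5)))
    if (identical(fit$retained, "x1")) correct <- correct + 1L
  }
  expect_gte(correct, 9L)
})

test_that("the final stepwise model equals a direct refit of the retained set", {
  s <- generate_survey(3000, seed = 4)
  scr <- chi2_screen(s, "Hyperlipidemia")
  fit <- stepwise_logistic(s, "Hyperlipidemia", scr$variable[scr$candidate])
  df <- data.frame(.y = as.integer(s$Hyperlipidemia) - 1L,
    lapply(s[fit$retained], as.integer))
  refit <- stats::glm(
    stats::as.formula(paste(".y ~", paste(fit$retained, collapse = " + "))),
    family = stats::binomial(), data = df
  )
  got <- fit$table$estimate[match(names(stats::coef(refit)), fit$table$term)]
  expect_equal(unname(got), unname(stats::coef(refit)), tolerance = 1e-8)
  # OR/CI/Wald identities hold for every term
  expect_equal(fit$table$or, exp(fit$table$estimate), tolerance = 1e-12)
  expect_equal(fit$table$or_lower,
    exp(fit$table$estimate - 1.959964 * fit$table$std_error),
    tolerance = 1e-12
  )
  expect_equal(fit$table$wald_chisq,
    (fit$table$estimate / fit$table$std_error)^2,
    tolerance = 1e-12
  )
})

test_that("a constant outcome is reported as separation", {
  d <- tibble::tibble(
    outcome = factor(rep("no", 100), levels = c("no", "yes")),
    x = factor(sample(c("a", "b"), 100, TRUE))
  )
  expect_error(
    stepwise_logistic(d, "outcome", "x"),
    class = "bnhybrid_error_separation"
  )
})

test_that("odds ratios follow the exp(beta) identities", {
  got <- or_from_coef(0, 0.1)
  expect_equal(got$or, 1)
  expect_equal(got$lower, exp(-1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(got$upper, exp(1.959964 * 0.1), tolerance = 1e-12)
  expect_error(or_from_coef(0.1, -1), class = "bnhybrid_error_invalid")
})

test_that("proportion intervals cover the textbook cases", {
  edge <- proportion_ci(100, 100)
  expect_equal(edge$estimate, 1)
  expect_equal(edge$upper, 1)

  half <- proportion_ci(50, 100)
  expect_equal(half$estimate, 0.5)
  expect_equal(half$upper - half$estimate, 0.098, tolerance = 1e-3)

  rate <- proportion_ci(2114, 4567)
  expect_equal(100 * rate$estimate, 46.3, tolerance = 0.1)
  expect_equal(100 * rate$lower, 44.8, tolerance = 0.1)
  expect_equal(100 * rate$upper, 47.7, tolerance = 0.1)

  w <- proportion_ci(0, 20, method = "wilson")
  expect_gt(w$upper, 0) # Wilson never collapses at the boundary
})

test_that("comparison reports separate direct from indirect covariates", {
  net <- load_fixture("lipid10")$network
  s <- generate_survey(3000, seed = 4)
  scr <- chi2_screen(s, "Hyperlipidemia")
  logit <- stepwise_logistic(s, "Hyperlipidemia", scr$variable[scr$candidate])
  rep <- comparison_report(net, logit, "Hyperlipidemia")
  cl <- rep$classification
  direct <- cl$variable[cl$role == "direct"]
  indirect <- cl$variable[cl$role == "indirect"]
  expect_setequal(direct, c("Gender", "BMI", "PhysicalActivity", "Hypertension", "Diabetes"))
  expect_setequal(indirect, c("Smoking", "SaltIntake", "OilIntake", "CentralObesity"))

  # an edgeless graph leaves every covariate unconnected
  bare <- bn_dag(net$dag$nodes)
  rep0 <- comparison_report(bare, logit, "Hyperlipidemia")
  expect_true(all(rep0$classification$role == "unconnected"))

  # JSON round-trip preserves the report
  f <- tempfile(fileext = ".json")
  write_comparison_json(rep, f)
  back <- read_comparison_json(f)
  expect_identical(back$outcome, rep$outcome)
  expect_setequal(back$parents, rep$parents)
  expect_equal(
    as.data.frame(back$classification),
    as.data.frame(rep$classification),
    tolerance = 1e-12
  )
})
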