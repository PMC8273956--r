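test_that("MLE recovers simple proportions", {
  d <- tibble::tibble(a = factor(rep(c("x", "y"), c(30, 70)), levels = c("x", "y")))
  net <- fit_mle(bn_dag("a"), d)
  expect_equal(as.vector(net$cpts$a$prob), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("unseen parent configurations are backfilled uniformly and flagged", {
  d <- tibble::tibble(
    p = factor(rep("u", 20), levels = c("u", "v")),
    c = factor(rep(c("x", "y"), 10), levels = c("x", "y"))
  )
  g <- bn_dag(c("p", "c"), data.frame(from = "p", to = "c"))
  net <- fit_mle(g, d)
  mat <- matrix(as.vector(net$cpts$c$prob), nrow = 2)
  expect_equal(mat[, 2], c(0.5, 0.5)) # the never-observed p = v column
  flagged <- attr(net, "backfilled_rows")
  expect_identical(flagged$node, "c")
  expect_match(flagged$configuration, "p=v")
})

test_that("MLE on a large sprinkler sample recovers the generating CPTs", {
  truth <- sprinkler_net()
  d <- forward_sample(truth, 200000, seed = 3)
  fitted <- fit_mle(truth$dag, d)
  for (v in names(truth$cpts)) {
    got <- align_cpt_prob(fitted$cpts[[v]], truth$cpts[[v]])
    expect_lt(max(abs(got - truth$cpts[[v]]$prob)), 0.01)
  }
})

test_that("smoothing moves estimates toward uniform", {
  d <- tibble::tibble(a = factor(rep(c("x", "y"), c(90, 10)), levels = c("x", "y")))
  raw <- fit_mle(bn_dag("a"), d, smoothing = 0)
  lap <- fit_mle(bn_dag("a"), d, smoothing = 1)
  expect_equal(as.vector(lap$cpts$a$prob), c(91, 11) / 102, tolerance = 1e-12)
  expect_lt(lap$cpts$a$prob[1], raw$cpts$a$prob[1])
})

test_that("fitted CPT rows are local maxima of the training likelihood", {
  truth <- sprinkler_net()
  d <- forward_sample(truth, 2000, seed = 10)
  net <- fit_mle(truth$dag, d)
  base_ll <- train_loglik(net, d)
  withr::local_seed(55)
  for (k in 1:20) {
    v <- sample(names(net$cpts), 1)
    cpt <- net$cpts[[v]]
    mat <- matrix(as.vector(cpt$prob), nrow = 2)
    j <- sample(ncol(mat), 1)
    eps <- sample(c(-0.01, 0.01), 1)
    row <- pmin(pmax(mat[, j] + c(eps, -eps), 1e-9), 1)
    mat[, j] <- row / sum(row)
    pert <- net
    pert$cpts[[v]] <- bn_cpt(v, cpt$parents, cpt$levels,
      array(mat, dim = dim(cpt$prob)))
    expect_lte(train_loglik(pert, d), base_ll + 1e-9)
  }
})

test_that("query matches brute-force enumeration on all fixtures", {
  cases <- list(
    list(fix = "sprinkler4", target = "Rain", ev = list(WetGrass = "T")),
    list(fix = "sprinkler4", target = "Cloudy", ev = list(Sprinkler = "T", WetGrass = "F")),
    list(fix = "lipid10", target = "Hyperlipidemia", ev = list(CentralObesity = "yes")),
    list(
      fix = "lipid10", target = "BMI",
      ev = list(Hypertension = "yes", Gender = "female")
    ),
    list(fix = "car20", target = "CarStarts", ev = list(BatteryAge = "bad")),
    list(
      fix = "car20", target = "BatteryVoltage",
      ev = list(CarStarts = "bad", Headlights = "ok")
    )
  )
  for (case in cases) {
    net <- load_fixture(case$fix)$network
    got <- query(net, case$target, case$ev)
    want <- query_brute(net, case$target, case$ev)
    expect_lt(max(abs(got$probability - unname(want))), 1e-9)
    expect_equal(sum(got$probability), 1, tolerance = 1e-9)
  }
})

test_that("the sprinkler posterior matches the closed-form value", {
  got <- query(sprinkler_net(), "Rain", list(WetGrass = "T"))
  expect_equal(got$probability[got$level == "T"], 0.7079, tolerance = 1e-4)
})

test_that("observing all parents reduces the posterior to the CPT row", {
  net <- load_fixture("lipid10")$network
  got <- query(net, "Hyperlipidemia", list(
    PhysicalActivity = "Insufficient", Gender = "male", BMI = "28.0~"
  ))
  expect_equal(got$probability[got$level == "yes"], 0.75273, tolerance = 1e-12)
  # prior of a root with no evidence equals its CPT
  prior <- query(net, "Gender")
  expect_equal(prior$probability, c(0.49, 0.51), tolerance = 1e-12)
})

test_that("impossible evidence raises a zero-probability error", {
  net <- sprinkler_net()
  expect_error(
    query(net, "Cloudy", list(Sprinkler = "F", Rain = "F", WetGrass = "T")),
    class = "bnhybrid_error_zero_evidence"
  )
  expect_error(
    query(net, "Rain", list(Rain = "T")),
    class = "bnhybrid_error_invalid"
  )
})

test_that("risk chains are cumulative, consistent with query, and start at the prior", {
  net <- load_fixture("lipid10")$network
  prior_only <- risk_chain(net, "Hyperlipidemia")
  expect_identical(unique(prior_only$step), 0L)
  expect_equal(
    prior_only$probability,
    query(net, "Hyperlipidemia")$probability,
    tolerance = 1e-12
  )

  seq_ev <- list(
    list(CentralObesity = "yes"), list(Diabetes = "yes"),
    list(BMI = "28.0~"), list(PhysicalActivity = "Insufficient")
  )
  chain <- risk_chain(net, "Hyperlipidemia", seq_ev)
  cum <- list()
  for (k in seq_along(seq_ev)) {
    cum <- c(cum, seq_ev[[k]])
    ind <- query(net, "Hyperlipidemia", cum)
    step_rows <- chain[chain$step == k, ]
    expect_equal(step_rows$probability, ind$probability, tolerance = 1e-12)
  }
  expect_error(
    risk_chain(net, "Hyperlipidemia", list(list(BMI = "28.0~"), list(BMI = "24.0~"))),
    class = "bnhybrid_error_invalid"
  )
})
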