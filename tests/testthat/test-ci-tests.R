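balanced_2x2 <- function(counts) {
  # counts = c(n_xu_yu, n_xu_yv, n_xv_yu, n_xv_yv)
  tibble::tibble(
    x = factor(rep(c("u", "u", "v", "v"), counts), levels = c("u", "v")),
    y = factor(rep(c("a", "b", "a", "b"), counts), levels = c("a", "b"))
  )
}

test_that("G2 is zero on a perfectly independent balanced table", {
  d <- balanced_2x2(c(25, 25, 25, 25))
  res <- g2_test(d, "x", "y")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_equal(res$p_value, 1)
})

test_that("G2 matches the hand-derived value on a strongly dependent table", {
  d <- balanced_2x2(c(30, 10, 10, 30))
  res <- g2_test(d, "x", "y")
  # all expected counts are 20: 2 * (2*30*ln(3/2) + 2*10*ln(1/2))
  expect_equal(res$statistic, 20.92993, tolerance = 1e-4)
  expect_lt(res$p_value, 1e-5)
})

test_that("degrees of freedom follow (rx-1)(ry-1)*prod(rz)", {
  withr::local_seed(5)
  d <- tibble::tibble(
    x = factor(sample(c("1", "2", "3"), 400, TRUE)),
    y = factor(sample(c("a", "b"), 400, TRUE)),
    z1 = factor(sample(c("u", "v"), 400, TRUE)),
    z2 = factor(sample(c("u", "v"), 400, TRUE))
  )
  expect_identical(g2_test(d, "x", "y", c("z1", "z2"))$df, 8L)
})

test_that("g2_test agrees with a brute-force contingency cube", {
  withr::local_seed(42)
  for (case in 1:20) {
    n <- sample(50:500, 1)
    p <- sample(2:4, 1)
    card <- sample(2:3, p, replace = TRUE)
    cols <- lapply(seq_len(p), function(i) {
      factor(sample(letters[seq_len(card[i])], n, TRUE), levels = letters[seq_len(card[i])])
    })
    names(cols) <- paste0("V", seq_len(p))
    d <- tibble::as_tibble(cols)
    z <- if (p > 2) names(d)[3:p] else character(0)
    got <- g2_test(d, "V1", "V2", z)
    want <- g2_brute(d, "V1", "V2", z)
    expect_lt(abs(got$statistic - want$statistic), 1e-9)
    expect_identical(got$df, as.integer(want$df))
    expect_lt(abs(got$p_value - want$p_value), 1e-9)
  }
})

test_that("p-values are invariant to row permutation and x/y swap", {
  withr::local_seed(11)
  d <- tibble::tibble(
    x = factor(sample(c("u", "v"), 200, TRUE)),
    y = factor(sample(c("a", "b", "c"), 200, TRUE))
  )
  base <- g2_test(d, "x", "y")
  perm <- g2_test(d[sample(nrow(d)), ], "x", "y")
  swap <- g2_test(d, "y", "x")
  expect_equal(base$p_value, perm$p_value, tolerance = 1e-12)
  expect_equal(base$p_value, swap$p_value, tolerance = 1e-12)
})

test_that("constant variables degrade to independence instead of failing", {
  d <- tibble::tibble(
    x = factor(rep("u", 50), levels = c("u", "v")),
    y = factor(rep(c("a", "b"), 25), levels = c("a", "b"))
  )
  res <- g2_test(d, "x", "y")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$reliable)
})

test_that("assoc is zero under independence and large for a duplicated column", {
  d <- balanced_2x2(c(25, 25, 25, 25))
  expect_equal(assoc(d, "x", "y"), 0, tolerance = 1e-12)

  dup <- tibble::tibble(
    a = factor(rep(c("u", "v"), each = 50), levels = c("u", "v"))
  )
  dup$c <- dup$a
  expect_gt(assoc(dup, "a", "c"), 20)
})

test_that("assoc is monotone in dependence strength at fixed n and df", {
  weak <- balanced_2x2(c(28, 22, 22, 28))
  strong <- balanced_2x2(c(40, 10, 10, 40))
  expect_gt(assoc(strong, "x", "y"), assoc(weak, "x", "y"))
})

test_that("conditioning on the middle of a chain removes the dependence", {
  net <- make_chain_net(p_flip = 0.1)
  marg_sig <- 0L
  cond_ind <- 0L
  for (s in 1:10) {
    d <- forward_sample(net, 20000, seed = 100 + s)
    if (g2_test(d, "X", "Z")$p_value < 0.05) marg_sig <- marg_sig + 1L
    if (g2_test(d, "X", "Z", "Y")$p_value > 0.05) cond_ind <- cond_ind + 1L
  }
  expect_gte(marg_sig, 9L)
  expect_gte(cond_ind, 8L)
})
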