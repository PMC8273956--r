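test_that("topological_order handles empty, chain, and cyclic graphs", {
  g <- bn_dag(c("A", "B"))
  expect_setequal(topological_order(g), c("A", "B"))

  chain <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_identical(topological_order(chain), c("A", "B", "C"))

  expect_error(
    bn_dag(c("A", "B"), data.frame(from = c("A", "B"), to = c("B", "A"))),
    class = "bnhybrid_error_cycle"
  )
})

test_that("DAG construction rejects self-loops and undeclared nodes", {
  expect_error(
    bn_dag("A", data.frame(from = "A", to = "A")),
    class = "bnhybrid_error_invalid"
  )
  expect_error(
    bn_dag(c("A", "B"), data.frame(from = "A", to = "Z")),
    class = "bnhybrid_error_unknown_node"
  )
})

test_that("is_acyclic_after classifies single-edge moves without mutating", {
  chain <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_false(is_acyclic_after(chain, "add", "C", "A"))
  expect_true(is_acyclic_after(chain, "add", "A", "C"))
  expect_true(is_acyclic_after(chain, "reverse", "A", "B"))
  # reversing A->B in A->B, A->C, C->B closes a cycle
  g <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "A", "C"), to = c("B", "C", "B")))
  expect_false(is_acyclic_after(g, "reverse", "A", "B"))
  expect_error(
    is_acyclic_after(chain, "delete", "C", "A"),
    class = "bnhybrid_error_unknown_edge"
  )
  # original graph untouched
  expect_identical(nrow(chain$edges), 2L)
})

test_that("parents and children match the hyperlipidemia fixture's structure", {
  net <- load_fixture("lipid10")$network
  expect_setequal(parents(net, "Hyperlipidemia"), c("Gender", "BMI", "PhysicalActivity"))
  expect_setequal(children(net, "Hyperlipidemia"), c("Hypertension", "Diabetes"))
  iso <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  g <- bn_dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  expect_identical(parents(g, "C"), character(0))
  expect_identical(children(g, "C"), character(0))
  expect_error(parents(g, "Z"), class = "bnhybrid_error_unknown_node")
})

test_that("CPT construction enforces normalisation and level sanity", {
  lev <- list(A = c("x", "y"))
  expect_silent(bn_cpt("A", character(0), lev, c(0.3, 0.7)))
  expect_error(
    bn_cpt("A", character(0), lev, c(0.3, 0.6)),
    class = "bnhybrid_error_validation"
  )
  lev2 <- list(A = c("x", "y"), B = c("u", "v"))
  expect_error(
    bn_cpt("A", "B", lev2, rbind(c(0.5, 1.2), c(0.5, -0.2))),
    class = "bnhybrid_error_validation"
  )
})

test_that("joint probabilities of every bundled fixture sum to one", {
  for (nm in c("sprinkler4", "lipid10", "car20")) {
    j <- enumerate_joint(load_fixture(nm)$network)
    expect_equal(sum(j$prob), 1, tolerance = 1e-6)
  }
})

test_that("enumerate_joint reproduces hand-computed sprinkler probabilities", {
  j <- enumerate_joint(sprinkler_net())
  pick <- function(c_, s, r, w) {
    j$prob[j$Cloudy == c_ & j$Sprinkler == s & j$Rain == r & j$WetGrass == w]
  }
  expect_equal(pick("T", "T", "T", "T"), 0.5 * 0.1 * 0.8 * 0.99, tolerance = 1e-12)
  expect_equal(pick("F", "F", "F", "T"), 0.5 * 0.5 * 0.8 * 0.00, tolerance = 1e-12)
  expect_equal(pick("F", "T", "F", "F"), 0.5 * 0.5 * 0.8 * 0.10, tolerance = 1e-12)
})

test_that("datasets reject missing values unless listwise deletion is requested", {
  d <- data.frame(
    a = factor(c("x", "y", NA), levels = c("x", "y")),
    b = factor(c("u", "u", "v"), levels = c("u", "v"))
  )
  expect_error(as_bn_dataset(d), class = "bnhybrid_error_missing")
  kept <- as_bn_dataset(d, drop_incomplete = TRUE)
  expect_identical(nrow(kept), 2L)
})

test_that("datasets validate declared levels and warn on inferred ones", {
  d <- data.frame(a = c("x", "y", "z"), stringsAsFactors = FALSE)
  expect_warning(as_bn_dataset(d), "first-appearance")
  expect_error(
    as_bn_dataset(d, levels = list(a = c("x", "y"))),
    class = "bnhybrid_error_schema"
  )
})
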