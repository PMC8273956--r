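#' Conditional independence tests for categorical data
#'
#' `g2_test()` performs the likelihood-ratio test of `Ind(x; y | z)` on a
#' categorical dataset. The statistic is
#' `2 * sum O * ln(O * N_z / (N_xz * N_yz))` over all cells of the
#' `x` by `y` by `z`-configuration contingency cube, with `0 * ln(.) = 0`;
#' under independence it is asymptotically chi-squared with
#' `(|x| - 1) (|y| - 1) prod |z_i|` degrees of freedom. Degrees of freedom
#' are not reduced for empty `z` strata (set `drop_empty_strata = TRUE` to
#' subtract them). A test is flagged `reliable` when the sample supports it
#' (`n / df >= reliability_ratio`, the classic heuristic from the IAMB
#' literature); constraint-based learners treat unreliable tests as
#' "independence not established".
#'
#' A variable observed at a single level makes the test degenerate; instead
#' of failing, the result is independence (`statistic = 0`, `p_value = 1`)
#' with `reliable = FALSE`, so learners degrade gracefully.
#'
#' @param data A data frame of factors (see [as_bn_dataset()]).
#' @param x,y Column names of the two tested variables (distinct).
#' @param z Character vector of conditioning column names (default none).
#' @param test `"g2"` for the likelihood-ratio statistic (default) or
#'   `"x2"` for Pearson's chi-square on the same cube.
#' @param reliability_ratio Minimum `n / df` for a reliable test.
#' @param drop_empty_strata Subtract unobserved `z` configurations from the
#'   degrees of freedom.
#' @return A one-row tibble: `x`, `y`, `z` (list column), `statistic`, `df`,
#'   `p_value`, `reliable`.
#' @examples
#' d <- data.frame(
#'   a = factor(rep(c("0", "1"), each = 50)),
#'   b = factor(rep(c("0", "1"), times = 50))
#' )
#' g2_test(d, "a", "b")
#' @export
g2_test <- function(data, x, y, z = character(), test = c("g2", "x2"),
                    reliability_ratio = 5, drop_empty_strata = FALSE) {
  test <- match.arg(test)
  codes <- dataset_codes(data)
  check_ci_args(codes, x, y, z)
  res <- ci_kernel(codes, x, y, z,
    test = test, reliability_ratio = reliability_ratio,
    drop_empty_strata = drop_empty_strata
  )
  tibble::tibble(
    x = x, y = y, z = list(z),
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    reliable = res$reliable
  )
}

#' Association strength between two variables
#'
#' The heuristic ranking score used by the constraint-based learners: the
#' negative natural log of the [g2_test()] p-value, so larger means stronger
#' dependence and 0 means no evidence against independence. Computed on the
#' log scale throughout, so astronomically small p-values do not underflow.
#'
#' @inheritParams g2_test
#' @param t Target variable name.
#' @param cond Conditioning set.
#' @return A non-negative number.
#' @export
assoc <- function(data, x, t, cond = character(), test = c("g2", "x2"),
                  reliability_ratio = 5) {
  test <- match.arg(test)
  codes <- dataset_codes(data)
  check_ci_args(codes, x, t, cond)
  res <- ci_kernel(codes, x, t, cond, test = test, reliability_ratio = reliability_ratio)
  -res$log_p
}

check_ci_args <- function(codes, x, y, z) {
  vars <- colnames(codes$m)
  missing <- setdiff(c(x, y, z), vars)
  if (length(missing) > 0) {
    rlang::abort(paste0("variable(s) not in data: ", paste(missing, collapse = ", ")),
      class = "bnhybrid_error_unknown_node"
    )
  }
  if (x == y || x %in% z || y %in% z) {
    rlang::abort("x, y and z must be disjoint", class = "bnhybrid_error_invalid")
  }
  invisible(TRUE)
}

# Counting kernel shared by the learners. Works on the integer-coded view
# from dataset_codes(); x, y are column names, z a character vector.
ci_kernel <- function(codes, x, y, z = character(), test = "g2",
                      reliability_ratio = 5, drop_empty_strata = FALSE) {
  m <- codes$m
  card <- codes$card
  n <- codes$n
  rx <- card[[x]]
  ry <- card[[y]]
  qz <- if (length(z) > 0) prod(card[z]) else 1L

  # combined z-configuration code (1-based mixed radix)
  if (length(z) > 0) {
    zc <- m[, z[1]]
    stride <- card[[z[1]]]
    if (length(z) > 1) {
      for (k in 2:length(z)) {
        zc <- zc + (m[, z[k]] - 1L) * stride
        stride <- stride * card[[z[k]]]
      }
    }
  } else {
    zc <- rep(1L, n)
  }

  cell <- m[, x] + (m[, y] - 1L) * rx + (zc - 1L) * (rx * ry)
  counts <- array(tabulate(cell, nbins = rx * ry * qz), dim = c(rx, ry, qz))

  nz <- apply(counts, 3, sum)
  nxz <- apply(counts, c(1, 3), sum) # rx x qz
  nyz <- apply(counts, c(2, 3), sum) # ry x qz

  degenerate <- (sum(rowSums(nxz) > 0) < 2) || (sum(rowSums(nyz) > 0) < 2)

  df <- as.integer((rx - 1L) * (ry - 1L) * qz)
  if (drop_empty_strata) {
    df <- as.integer((rx - 1L) * (ry - 1L) * max(sum(nz > 0), 1L))
  }

  if (degenerate) {
    return(list(
      statistic = 0, df = df, p_value = 1, log_p = 0,
      reliable = FALSE, degenerate = TRUE
    ))
  }

  pos <- which(counts > 0)
  o <- counts[pos]
  ix <- (pos - 1L) %% rx + 1L
  iy <- ((pos - 1L) %/% rx) %% ry + 1L
  iz <- (pos - 1L) %/% (rx * ry) + 1L
  e <- nxz[cbind(ix, iz)] * nyz[cbind(iy, iz)] / nz[iz]
  stat <- if (test == "g2") {
    2 * sum(o * log(o / e))
  } else {
    # Pearson on the same cube; cells with zero expectation are skipped
    x2 <- 0
    for (s in which(nz > 0)) {
      es <- outer(nxz[, s], nyz[, s]) / nz[s]
      os <- counts[, , s]
      nz_cells <- es > 0
      x2 <- x2 + sum((os[nz_cells] - es[nz_cells])^2 / es[nz_cells])
    }
    x2
  }
  stat <- max(stat, 0)
  log_p <- stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
  list(
    statistic = stat, df = df,
    p_value = exp(log_p), log_p = log_p,
    reliable = n / df >= reliability_ratio,
    degenerate = FALSE
  )
}
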