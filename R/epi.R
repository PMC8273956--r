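#' Generate a synthetic hyperlipidemia survey
#'
#' Forward-samples the `lipid10` network: 10 categorical variables (gender,
#' smoking, physical activity, salt and oil intake, BMI class, central
#' obesity, hyperlipidemia, hypertension, diabetes) linked by 14 arcs, with
#' the hyperlipidemia CPT taken from the published conditional probability
#' table and surrogate parameters elsewhere. The default size matches the
#' complete-case count of the survey the fixture emulates.
#'
#' @param n Number of respondents.
#' @param seed Integer seed (default 2015, the survey year).
#' @return A tibble of factors with 10 columns.
#' @export
generate_survey <- function(n = 4567, seed = 2015) {
  forward_sample(load_fixture("lipid10")$network, n, seed = seed)
}

#' Univariate chi-square screening
#'
#' Pearson chi-square test (no continuity correction) of each covariate
#' against a binary outcome, plus the liberal candidate screen used before
#' stepwise modelling: covariates with `p < candidate_p` (default 0.5) are
#' flagged as candidates.
#'
#' @param data A data frame of factors.
#' @param outcome Binary outcome column name.
#' @param candidate_p Entry screen threshold.
#' @return A tibble: `variable`, `statistic`, `df`, `p_value`, `candidate`.
#' @export
chi2_screen <- function(data, outcome, candidate_p = 0.5) {
  data <- as_bn_dataset(data)
  if (!outcome %in% names(data)) {
    rlang::abort(paste0("unknown outcome: ", outcome), class = "bnhybrid_error_unknown_node")
  }
  if (nlevels(data[[outcome]]) != 2 || length(unique(data[[outcome]])) != 2) {
    rlang::abort("outcome must be binary and non-constant", class = "bnhybrid_error_degenerate")
  }
  covs <- setdiff(names(data), outcome)
  rows <- lapply(covs, function(v) {
    if (length(unique(data[[v]])) < 2) {
      rlang::abort(paste0("covariate '", v, "' is constant"),
        class = "bnhybrid_error_degenerate"
      )
    }
    tab <- table(droplevels(data[[v]]), droplevels(data[[outcome]]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(
      variable = v,
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = unname(ct$p.value)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$candidate <- out$p_value < candidate_p
  out
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in the proportion of a binary outcome across the
#' ordered levels of an ordinal covariate, with equally spaced scores. The
#' signed statistic `z` is positive when the proportion of the outcome's
#' *second* level increases along the declared level order; `z^2` equals the
#' usual trend chi-square. The p-value is two-sided.
#'
#' @param data A data frame of factors.
#' @param ordinal Ordinal covariate (at least 3 levels, declared order).
#' @param outcome Binary outcome column name.
#' @return A one-row tibble: `z`, `p_value`.
#' @export
trend_test <- function(data, ordinal, outcome) {
  data <- as_bn_dataset(data)
  for (v in c(ordinal, outcome)) {
    if (!v %in% names(data)) {
      rlang::abort(paste0("unknown variable: ", v), class = "bnhybrid_error_unknown_node")
    }
  }
  if (nlevels(data[[ordinal]]) < 3) {
    rlang::abort("ordinal variable needs at least 3 levels", class = "bnhybrid_error_invalid")
  }
  if (nlevels(data[[outcome]]) != 2 || length(unique(data[[outcome]])) != 2) {
    rlang::abort("outcome must be binary and non-constant", class = "bnhybrid_error_degenerate")
  }
  tab <- table(data[[ordinal]], data[[outcome]])
  n_i <- rowSums(tab)
  keep <- n_i > 0
  tab <- tab[keep, , drop = FALSE]
  n_i <- n_i[keep]
  r_i <- tab[, 2] # successes = second outcome level
  s <- seq_len(nrow(tab)) # equally spaced scores
  n <- sum(n_i)
  pbar <- sum(r_i) / n
  sbar <- sum(n_i * s) / n
  num <- sum(r_i * (s - sbar))
  den <- pbar * (1 - pbar) * sum(n_i * (s - sbar)^2)
  z <- if (den > 0) num / sqrt(den) else 0
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Odds ratio with 95 percent confidence interval from a coefficient
#'
#' `OR = exp(beta)` with Wald bounds `exp(beta -/+ 1.959964 * se)`.
#'
#' @param beta Coefficient estimate(s).
#' @param se Standard error(s), non-negative.
#' @return A tibble: `or`, `lower`, `upper` (one row per coefficient).
#' @examples
#' or_from_coef(0.417, 0.048)
#' @export
or_from_coef <- function(beta, se) {
  if (any(se < 0)) {
    rlang::abort("standard errors must be non-negative", class = "bnhybrid_error_invalid")
  }
  z <- 1.959964
  tibble::tibble(
    or = exp(beta),
    lower = exp(beta - z * se),
    upper = exp(beta + z * se)
  )
}

#' Confidence interval for a proportion
#'
#' Wald interval `p -/+ z * sqrt(p (1 - p) / n)` clipped to `[0, 1]`
#' (default), or Wilson's score interval.
#'
#' @param k Success count.
#' @param n Trials (>= 1).
#' @param level Confidence level.
#' @param method `"wald"` or `"wilson"`.
#' @return A one-row tibble: `estimate`, `lower`, `upper`.
#' @export
proportion_ci <- function(k, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  tibble::tibble(estimate = p, lower = lo, upper = hi)
}

# single numeric code per categorical variable (level index), the
# one-coefficient-per-variable encoding of the published regression table
encode_ordinal <- function(data, vars) {
  out <- lapply(data[vars], as.integer)
  tibble::as_tibble(out)
}

glm_wald <- function(fit) {
  cf <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    wald_chisq = (cf[, 1] / cf[, 2])^2,
    p_value = stats::pchisq((cf[, 1] / cf[, 2])^2, df = 1, lower.tail = FALSE)
  )
}

check_separation <- function(fit) {
  p <- stats::fitted(fit)
  if (!fit$converged) {
    rlang::abort("logistic fit did not converge", class = "bnhybrid_error_nonconvergence")
  }
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    rlang::abort("complete or quasi-complete separation detected",
      class = "bnhybrid_error_separation"
    )
  }
  invisible(fit)
}

#' Stepwise logistic regression
#'
#' Forward-entry / backward-removal stepwise selection for a binary outcome,
#' in the convention of classic survey software: candidates enter by the
#' score (Rao) test at `p <= alpha_in` and retained terms are removed by the
#' Wald test at `p >= alpha_out`, iterating until the model is stable.
#' Each categorical covariate is entered as a single numeric term (its level
#' index in declared order), so the fit reports one coefficient per
#' variable; set `likelihood_ratio = TRUE` to use likelihood-ratio tests for
#' both entry and removal instead.
#'
#' @param data A data frame of factors.
#' @param outcome Binary outcome column; its second level is the event.
#' @param candidates Covariate names eligible for entry.
#' @param alpha_in Entry significance threshold.
#' @param alpha_out Removal significance threshold.
#' @param likelihood_ratio Use LR tests in place of score/Wald.
#' @return A `bn_logistic_fit`: list with `table` (per retained term:
#'   `estimate`, `std_error`, `wald_chisq`, `p_value`, `or`, `or_lower`,
#'   `or_upper`, including the intercept), `retained`, `steps` (the fitting
#'   log), and `model` (the final `glm`).
#' @export
stepwise_logistic <- function(data, outcome, candidates,
                              alpha_in = 0.05, alpha_out = 0.10,
                              likelihood_ratio = FALSE) {
  data <- as_bn_dataset(data)
  missing <- setdiff(c(outcome, candidates), names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("unknown variable(s): ", paste(missing, collapse = ", ")),
      class = "bnhybrid_error_unknown_node"
    )
  }
  y <- as.integer(data[[outcome]]) - 1L
  if (length(unique(y)) < 2) {
    rlang::abort("outcome is constant; the model is separated by construction",
      class = "bnhybrid_error_separation"
    )
  }
  x <- encode_ordinal(data, candidates)
  df <- cbind(data.frame(.y = y), as.data.frame(x))

  current <- character(0)
  steps <- list()
  fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  repeat {
    changed <- FALSE
    # forward entry
    pool <- setdiff(candidates, current)
    if (length(pool) > 0) {
      scope <- stats::as.formula(paste("~ . +", paste(pool, collapse = " + ")))
      a1 <- stats::add1(fit, scope = scope, test = if (likelihood_ratio) "LRT" else "Rao")
      pcol <- if (likelihood_ratio) "Pr(>Chi)" else "Pr(>Chi)"
      cand_p <- a1[pool, pcol]
      names(cand_p) <- pool
      best <- names(which.min(cand_p))
      if (length(best) == 1 && !is.na(cand_p[best]) && cand_p[best] <= alpha_in) {
        current <- c(current, best)
        fit <- stats::glm(
          stats::as.formula(paste(".y ~", paste(current, collapse = " + "))),
          family = stats::binomial(), data = df
        )
        check_separation(fit)
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "enter", variable = best,
          p_value = unname(cand_p[best])
        )
        changed <- TRUE
      }
    }
    # backward removal
    if (length(current) > 0) {
      if (likelihood_ratio) {
        d1 <- stats::drop1(fit, test = "LRT")
        rem_p <- d1[current, "Pr(>Chi)"]
        names(rem_p) <- current
      } else {
        wt <- glm_wald(fit)
        rem_p <- stats::setNames(wt$p_value[match(current, wt$term)], current)
      }
      worst <- names(which.max(rem_p))
      if (length(worst) == 1 && !is.na(rem_p[worst]) && rem_p[worst] >= alpha_out) {
        current <- setdiff(current, worst)
        fit <- stats::glm(
          stats::as.formula(paste(
            ".y ~",
            if (length(current)) paste(current, collapse = " + ") else "1"
          )),
          family = stats::binomial(), data = df
        )
        check_separation(fit)
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "remove", variable = worst,
          p_value = unname(rem_p[worst])
        )
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  check_separation(fit)
  tab <- glm_wald(fit)
  ors <- or_from_coef(tab$estimate, tab$std_error)
  tab$or <- ors$or
  tab$or_lower <- ors$lower
  tab$or_upper <- ors$upper
  structure(
    list(
      table = tab,
      retained = current,
      steps = if (length(steps)) {
        dplyr::bind_rows(steps)
      } else {
        tibble::tibble(
          step = integer(), action = character(),
          variable = character(), p_value = numeric()
        )
      },
      outcome = outcome,
      model = fit
    ),
    class = "bn_logistic_fit"
  )
}

#' @export
print.bn_logistic_fit <- function(x, ...) {
  cat("<bn_logistic_fit> outcome ", x$outcome, "; retained: ",
    if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
    "\n",
    sep = ""
  )
  print(x$table)
  invisible(x)
}

#' Contrast a network's graph roles with logistic odds ratios
#'
#' Classifies each covariate relative to the outcome in the network's DAG --
#' `direct` (graph-adjacent: a parent or child of the outcome), `indirect`
#' (connected through the undirected skeleton but not adjacent), or
#' `unconnected` -- and juxtaposes the logistic fit's odds ratios with those
#' roles. This is the comparison a regression alone cannot make: it flags
#' association but cannot separate direct from mediated pathways.
#'
#' @param bn A [discrete_bn()] (or [bn_dag()]) containing the outcome.
#' @param logit A `bn_logistic_fit` from [stepwise_logistic()].
#' @param outcome Outcome variable name.
#' @return A `bn_comparison`: list with `outcome`, `parents`, `children`,
#'   and `classification` (tibble: `variable`, `role`, `retained`, `or`,
#'   `or_lower`, `or_upper`).
#' @export
comparison_report <- function(bn, logit, outcome) {
  dag <- if (inherits(bn, "discrete_bn")) bn$dag else bn
  stopifnot(inherits(dag, "bn_dag"))
  node_in_graph(dag, outcome)
  pa <- parents(dag, outcome)
  ch <- children(dag, outcome)
  adj <- union(pa, ch)
  # connected component of the outcome in the undirected skeleton
  s <- skeleton_amat(dag_skeleton(dag))
  reach <- stats::setNames(rep(FALSE, length(dag$nodes)), dag$nodes)
  stack <- outcome
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (reach[v]) next
    reach[v] <- TRUE
    stack <- c(stack, dag$nodes[s[v, ] & !reach])
  }
  covs <- setdiff(dag$nodes, outcome)
  role <- ifelse(covs %in% adj, "direct",
    ifelse(reach[covs], "indirect", "unconnected")
  )
  tab <- logit$table
  idx <- match(covs, tab$term)
  classification <- tibble::tibble(
    variable = covs,
    role = role,
    retained = covs %in% logit$retained,
    or = tab$or[idx],
    or_lower = tab$or_lower[idx],
    or_upper = tab$or_upper[idx]
  )
  structure(
    list(
      outcome = outcome, parents = pa, children = ch,
      classification = classification
    ),
    class = "bn_comparison"
  )
}

#' @export
print.bn_comparison <- function(x, ...) {
  cat("<bn_comparison> outcome ", x$outcome, "\n", sep = "")
  cat("  parents: ", paste(x$parents, collapse = ", "), "\n", sep = "")
  cat("  children: ", paste(x$children, collapse = ", "), "\n", sep = "")
  print(x$classification)
  invisible(x)
}

#' JSON round-trip for comparison reports
#'
#' @param x A `bn_comparison`.
#' @param path Output file.
#' @return For the writer, `path` invisibly; for the reader, the
#'   reconstructed `bn_comparison`.
#' @export
write_comparison_json <- function(x, path) {
  stopifnot(inherits(x, "bn_comparison"))
  jsonlite::write_json(
    list(
      outcome = x$outcome, parents = x$parents, children = x$children,
      classification = x$classification
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_comparison_json
#' @export
read_comparison_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- tibble::as_tibble(obj$classification)
  for (col in c("or", "or_lower", "or_upper")) {
    if (!col %in% names(cl)) cl[[col]] <- NA_real_
    cl[[col]] <- as.numeric(cl[[col]])
  }
  structure(
    list(
      outcome = obj$outcome,
      parents = as.character(unlist(obj$parents)),
      children = as.character(unlist(obj$children)),
      classification = cl[, c("variable", "role", "retained", "or", "or_lower", "or_upper")]
    ),
    class = "bn_comparison"
  )
}
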