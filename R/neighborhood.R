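# Constraint-based neighbourhood discovery: MMPC and the IAMB family.
#
# All learners work on the integer-coded dataset view (dataset_codes()) and
# share one convention: a conditional test whose sample support is inadequate
# (n/df below the reliability ratio) is treated as if it had returned
# independence (effective p = 1), so growing stops rather than admitting
# variables on evidence the data cannot support.

eff_test <- function(codes, x, y, z, reliability_ratio = 5) {
  res <- ci_kernel(codes, x, y, z, reliability_ratio = reliability_ratio)
  res$p_eff <- if (res$reliable) res$p_value else 1
  res$log_p_eff <- if (res$reliable) res$log_p else 0
  res
}

# all subsets of `pool` with size <= k (including the empty set), as a list
subsets_upto <- function(pool, k) {
  out <- list(character(0))
  if (length(pool) == 0 || k == 0) return(out)
  for (s in seq_len(min(k, length(pool)))) {
    cmb <- utils::combn(pool, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

new_neighborhood <- function(target, members, trace) {
  structure(
    list(target = target, members = members, trace = trace),
    class = "bn_neighborhood"
  )
}

#' @export
print.bn_neighborhood <- function(x, ...) {
  cat("<bn_neighborhood> target ", x$target, ": {",
    paste(x$members, collapse = ", "), "}\n",
    sep = ""
  )
  invisible(x)
}

trace_row <- function(candidate, action, p_value, cond) {
  tibble::tibble(
    candidate = candidate, action = action, p_value = p_value,
    cond = list(cond)
  )
}

# ---------------------------------------------------------------------------
# MMPC

mmpc_nbr_codes <- function(codes, target, alpha = 0.05, max_sx = 3,
                           reliability_ratio = 5) {
  vars <- colnames(codes$m)
  cpc <- character(0)
  rejected <- character(0)
  trace <- list()

  # Phase I: max-min growing. A candidate found independent of the target
  # given some subset of the current CPC can never re-enter (supersets of a
  # separating set stay available), so it is dropped permanently.
  repeat {
    cands <- setdiff(vars, c(target, cpc, rejected))
    if (length(cands) == 0) break
    best_x <- NA_character_
    best_minassoc <- -Inf
    best_maxp <- NA_real_
    for (x in cands) {
      max_p <- -Inf # p of the weakest association over subsets
      min_logp_neg <- Inf
      separated <- FALSE
      for (s in subsets_upto(cpc, max_sx)) {
        res <- eff_test(codes, x, target, s, reliability_ratio)
        if (-res$log_p_eff < min_logp_neg) {
          min_logp_neg <- -res$log_p_eff
          max_p <- res$p_eff
        }
        if (res$p_eff >= alpha) {
          separated <- TRUE
          break
        }
      }
      if (separated) {
        rejected <- c(rejected, x)
        next
      }
      if (min_logp_neg > best_minassoc) {
        best_minassoc <- min_logp_neg
        best_x <- x
        best_maxp <- max_p
      }
    }
    if (is.na(best_x)) break
    cpc <- c(cpc, best_x)
    trace[[length(trace) + 1]] <- trace_row(best_x, "add", best_maxp, cpc[-length(cpc)])
  }

  # Phase II: backward false-positive removal against subsets of the CPC.
  for (x in cpc) {
    others <- setdiff(cpc, x)
    for (s in subsets_upto(others, max_sx)) {
      res <- eff_test(codes, x, target, s, reliability_ratio)
      if (res$p_eff >= alpha) {
        cpc <- setdiff(cpc, x)
        trace[[length(trace) + 1]] <- trace_row(x, "remove", res$p_eff, s)
        break
      }
    }
  }

  new_neighborhood(
    target, intersect(vars, cpc),
    if (length(trace)) dplyr::bind_rows(trace) else trace_row(character(0), character(0), numeric(0), list())[0, ]
  )
}

#' MMPC candidate parents-and-children discovery
#'
#' Two-stage max-min scheme for the set of candidate parents and children
#' (CPC) of a target variable. Phase I repeatedly admits the candidate whose
#' *minimum* association with the target over all subsets of the current CPC
#' is largest, stopping when every remaining variable is independent of the
#' target given some subset. Phase II removes false positives: any member
#' independent of the target given some subset of the other members.
#'
#' @param data A data frame of factors.
#' @param target Target variable name.
#' @param alpha Significance level for the conditional independence tests.
#' @param max_sx Maximum conditioning-subset size examined (bounds runtime;
#'   set to `Inf` for the unbounded scheme).
#' @param reliability_ratio Minimum `n / df` for a test to count as reliable.
#' @return A `bn_neighborhood`: `target`, `members` (the CPC), and a `trace`
#'   tibble of add/remove steps with their p-values.
#' @export
mmpc_neighborhood <- function(data, target, alpha = 0.05, max_sx = 3,
                              reliability_ratio = 5) {
  codes <- dataset_codes(data)
  if (!target %in% colnames(codes$m)) {
    rlang::abort(paste0("unknown target: ", target), class = "bnhybrid_error_unknown_node")
  }
  stopifnot(alpha > 0, alpha < 1)
  mmpc_nbr_codes(codes, target, alpha, max_sx, reliability_ratio)
}

# ---------------------------------------------------------------------------
# IAMB family

iamb_shrink <- function(codes, target, cmb, alpha, reliability_ratio, trace,
                        keep = character(0)) {
  repeat {
    removed <- FALSE
    for (x in setdiff(cmb, keep)) {
      res <- eff_test(codes, x, target, setdiff(cmb, x), reliability_ratio)
      if (res$p_eff >= alpha) {
        cmb <- setdiff(cmb, x)
        trace[[length(trace) + 1]] <- trace_row(x, "remove", res$p_eff, setdiff(cmb, x))
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  list(cmb = cmb, trace = trace)
}

iamb_nbr_codes <- function(codes, target, alpha = 0.05,
                           variant = c("plain", "inter", "fast"),
                           reliability_ratio = 5) {
  variant <- match.arg(variant)
  vars <- colnames(codes$m)
  cmb <- character(0)
  trace <- list()

  if (variant %in% c("plain", "inter")) {
    repeat {
      cands <- setdiff(vars, c(target, cmb))
      if (length(cands) == 0) break
      best_x <- NA_character_
      best_assoc <- 0
      best_p <- 1
      for (x in cands) {
        res <- eff_test(codes, x, target, cmb, reliability_ratio)
        if (-res$log_p_eff > best_assoc) {
          best_assoc <- -res$log_p_eff
          best_x <- x
          best_p <- res$p_eff
        }
      }
      if (is.na(best_x) || best_p >= alpha) break
      cmb <- c(cmb, best_x)
      trace[[length(trace) + 1]] <- trace_row(best_x, "add", best_p, setdiff(cmb, best_x))
      if (variant == "inter") {
        sh <- iamb_shrink(codes, target, cmb, alpha, reliability_ratio, trace)
        cmb <- sh$cmb
        trace <- sh$trace
      }
    }
    if (variant == "plain") {
      sh <- iamb_shrink(codes, target, cmb, alpha, reliability_ratio, trace)
      cmb <- sh$cmb
      trace <- sh$trace
    }
  } else {
    # fast: per pass, rank candidates by G2 significance (ascending p) under
    # the blanket at the start of the pass, then speculatively admit them in
    # that order while the test against the growing blanket stays significant
    # and reliable; shrink; repeat until the blanket is stable.
    repeat {
      before <- cmb
      cands <- setdiff(vars, c(target, cmb))
      if (length(cands) > 0) {
        ranked <- vapply(cands, function(x) {
          res <- eff_test(codes, x, target, cmb, reliability_ratio)
          res$log_p_eff
        }, numeric(1))
        ord <- cands[order(ranked)]
        ord <- ord[ranked[order(ranked)] < log(alpha)]
        for (x in ord) {
          res <- ci_kernel(codes, x, target, cmb, reliability_ratio = reliability_ratio)
          if (!res$reliable || res$p_value >= alpha) break
          cmb <- c(cmb, x)
          trace[[length(trace) + 1]] <- trace_row(x, "add", res$p_value, setdiff(cmb, x))
        }
      }
      sh <- iamb_shrink(codes, target, cmb, alpha, reliability_ratio, trace)
      cmb <- sh$cmb
      trace <- sh$trace
      if (setequal(cmb, before)) break
    }
  }

  new_neighborhood(
    target, intersect(vars, cmb),
    if (length(trace)) dplyr::bind_rows(trace) else trace_row(character(0), character(0), numeric(0), list())[0, ]
  )
}

#' Markov blanket discovery with the IAMB family
#'
#' Incremental association Markov blanket search for a target variable.
#' All variants alternate a growing phase (admit the candidate most strongly
#' associated with the target given the current blanket, while significant)
#' with a shrinking phase (remove members independent of the target given the
#' rest of the blanket). `"plain"` shrinks once after growing finishes;
#' `"inter"` interleaves a full shrinking pass after every admission, pruning
#' false positives early; `"fast"` ranks all candidates by the significance
#' of their G-squared test per pass and speculatively admits them in that
#' order while the test stays significant and reliable, reducing the number
#' of passes.
#'
#' @inheritParams mmpc_neighborhood
#' @param variant `"plain"`, `"inter"`, or `"fast"`.
#' @return A `bn_neighborhood` whose `members` estimate the Markov blanket
#'   (parents, children, and spouses) of `target`.
#' @export
iamb_neighborhood <- function(data, target, alpha = 0.05,
                              variant = c("plain", "inter", "fast"),
                              reliability_ratio = 5) {
  variant <- match.arg(variant)
  codes <- dataset_codes(data)
  if (!target %in% colnames(codes$m)) {
    rlang::abort(paste0("unknown target: ", target), class = "bnhybrid_error_unknown_node")
  }
  stopifnot(alpha > 0, alpha < 1)
  iamb_nbr_codes(codes, target, alpha, variant, reliability_ratio)
}

# ---------------------------------------------------------------------------
# skeleton extraction

#' Build an undirected skeleton from per-node neighbourhoods
#'
#' Combines one neighbourhood result per node into a skeleton with the
#' symmetry AND-rule: `{X, Y}` is adjacent iff each appears in the other's
#' member set. Markov-blanket results (the IAMB family) additionally contain
#' spouse links (co-parents), which are not skeleton edges; when `data` is
#' supplied, a one-step screening pass removes any surviving adjacency
#' `{X, Y}` for which some subset `S` of `members(X) \ {Y}` (or of
#' `members(Y) \ {X}`) renders the pair conditionally independent.
#'
#' @param results Named list of `bn_neighborhood` objects, one per node, all
#'   over the same node universe.
#' @param data Optional data frame enabling the spouse screen.
#' @param alpha,max_sx,reliability_ratio Screening-test controls.
#' @return A [bn_skeleton()].
#' @export
skeleton_from_neighborhoods <- function(results, data = NULL, alpha = 0.05,
                                        max_sx = 3, reliability_ratio = 5) {
  nodes <- names(results)
  if (is.null(nodes) || anyDuplicated(nodes) > 0) {
    rlang::abort("results must be a named list, one entry per node",
      class = "bnhybrid_error_universe"
    )
  }
  for (v in nodes) {
    r <- results[[v]]
    if (!inherits(r, "bn_neighborhood") || r$target != v) {
      rlang::abort("each entry must be a bn_neighborhood for its own name",
        class = "bnhybrid_error_universe"
      )
    }
    if (length(setdiff(r$members, nodes)) > 0) {
      rlang::abort("neighbourhood members outside the shared node universe",
        class = "bnhybrid_error_universe"
      )
    }
  }
  adj <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      x <- nodes[i]
      y <- nodes[j]
      if (y %in% results[[x]]$members && x %in% results[[y]]$members) {
        adj[[length(adj) + 1]] <- c(x, y)
      }
    }
  }
  if (length(adj) > 0 && !is.null(data)) {
    codes <- dataset_codes(data)
    keep <- vapply(adj, function(pair) {
      x <- pair[1]
      y <- pair[2]
      pools <- list(
        setdiff(results[[x]]$members, y),
        setdiff(results[[y]]$members, x)
      )
      for (pool in pools) {
        for (s in subsets_upto(pool, max_sx)) {
          res <- eff_test(codes, x, y, s, reliability_ratio)
          if (res$p_eff >= alpha) return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    adj <- adj[keep]
  }
  bn_skeleton(
    nodes,
    if (length(adj)) {
      data.frame(
        a = vapply(adj, `[`, character(1), 1),
        b = vapply(adj, `[`, character(1), 2)
      )
    } else {
      NULL
    }
  )
}
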