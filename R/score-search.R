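# Decomposable network scores and the two local searches that use them.
#
# Scores are sums of per-family terms (one per node given its parent set),
# so move deltas touch at most two families; family scores are memoised per
# (child, parent-set) in an environment shared across the whole search.

make_scorer <- function(codes, score = c("bic", "bde"), iss = 1) {
  score <- match.arg(score)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  m <- codes$m
  card <- codes$card
  n <- codes$n

  family_counts <- function(child, parents) {
    r <- card[[child]]
    q <- if (length(parents) > 0) prod(card[parents]) else 1L
    cc <- m[, child]
    if (length(parents) > 0) {
      stride <- r
      for (p in parents) {
        cc <- cc + (m[, p] - 1L) * stride
        stride <- stride * card[[p]]
      }
    }
    matrix(tabulate(cc, nbins = r * q), nrow = r, ncol = q)
  }

  function(child, parents) {
    parents <- sort(parents)
    key <- paste(child, paste(parents, collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    counts <- family_counts(child, parents)
    r <- nrow(counts)
    q <- ncol(counts)
    val <- if (score == "bic") {
      tot <- colSums(counts)
      pos <- counts > 0
      ll <- sum(counts[pos] * log(counts[pos] / rep(tot, each = r)[pos]))
      ll - (r - 1) * q / 2 * log(n)
    } else {
      a_jk <- iss / (r * q)
      a_j <- iss / q
      tot <- colSums(counts)
      sum(lgamma(a_j) - lgamma(a_j + tot)) +
        sum(lgamma(a_jk + counts) - lgamma(a_jk))
    }
    cache[[key]] <- val
    val
  }
}

#' BIC network score
#'
#' Decomposable Bayesian information criterion of a DAG on categorical data:
#' the maximised log-likelihood of the factorisation minus
#' `(d / 2) * ln(n)` with `d = sum_i (r_i - 1) q_i` free parameters
#' (`r_i` child levels, `q_i` parent configurations). Larger is better;
#' unobserved cells contribute zero to the log-likelihood. `score = "bde"`
#' swaps in the BDeu marginal likelihood with equivalent sample size `iss`.
#'
#' @param data A data frame of factors.
#' @param g A [bn_dag()] over the data's columns.
#' @param score `"bic"` (default) or `"bde"`.
#' @param iss Equivalent sample size for `"bde"`.
#' @return A single number.
#' @examples
#' d <- data.frame(a = factor(rep(c("0", "1"), each = 4)))
#' bic_score(d, bn_dag("a")) # 8 ln .5 - .5 ln 8
#' @export
bic_score <- function(data, g, score = c("bic", "bde"), iss = 1) {
  score <- match.arg(score)
  codes <- dataset_codes(data)
  if (!setequal(g$nodes, colnames(codes$m))) {
    rlang::abort("graph and data must cover the same variables",
      class = "bnhybrid_error_invalid"
    )
  }
  fam <- make_scorer(codes, score, iss)
  a <- dag_amat(g)
  sum(vapply(g$nodes, function(v) fam(v, g$nodes[a[, v]]), numeric(1)))
}

# ---------------------------------------------------------------------------
# move machinery (shared by hill climbing and tabu search)

# enumerate legal moves and their score deltas on adjacency matrix `a`;
# `allowed` is a symmetric logical matrix restricting *additions* only.
legal_moves <- function(a, allowed, fam) {
  nodes <- rownames(a)
  p <- length(nodes)
  pa_of <- function(v) nodes[a[, v]]
  moves <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      u <- nodes[i]
      v <- nodes[j]
      if (a[i, j]) {
        # delete u -> v
        moves[[length(moves) + 1]] <- list(
          op = "delete", from = u, to = v,
          delta = fam(v, setdiff(pa_of(v), u)) - fam(v, pa_of(v))
        )
        # reverse u -> v
        a2 <- a
        a2[i, j] <- FALSE
        if (!amat_has_path(a2, u, v)) {
          moves[[length(moves) + 1]] <- list(
            op = "reverse", from = u, to = v,
            delta = (fam(v, setdiff(pa_of(v), u)) - fam(v, pa_of(v))) +
              (fam(u, c(pa_of(u), v)) - fam(u, pa_of(u)))
          )
        }
      } else if (!a[j, i] && allowed[i, j]) {
        # add u -> v
        if (!amat_has_path(a, v, u)) {
          moves[[length(moves) + 1]] <- list(
            op = "add", from = u, to = v,
            delta = fam(v, c(pa_of(v), u)) - fam(v, pa_of(v))
          )
        }
      }
    }
  }
  moves
}

apply_move <- function(a, mv) {
  switch(mv$op,
    add = a[mv$from, mv$to] <- TRUE,
    delete = a[mv$from, mv$to] <- FALSE,
    reverse = {
      a[mv$from, mv$to] <- FALSE
      a[mv$to, mv$from] <- TRUE
    }
  )
  a
}

# deterministic order: score descending, then (op, parent, child) ascending
order_moves <- function(moves) {
  if (length(moves) == 0) return(moves)
  deltas <- vapply(moves, `[[`, numeric(1), "delta")
  ops <- vapply(moves, `[[`, character(1), "op")
  from <- vapply(moves, `[[`, character(1), "from")
  to <- vapply(moves, `[[`, character(1), "to")
  moves[order(-deltas, ops, from, to, method = "radix")]
}

search_setup <- function(data, restrict, seed_graph, score, iss) {
  codes <- dataset_codes(data)
  nodes <- colnames(codes$m)
  if (!is.null(restrict)) {
    if (!setequal(restrict$nodes, nodes)) {
      rlang::abort("restriction skeleton must cover the data's variables",
        class = "bnhybrid_error_invalid"
      )
    }
    allowed <- skeleton_amat(restrict)[nodes, nodes, drop = FALSE]
  } else {
    allowed <- matrix(TRUE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    diag(allowed) <- FALSE
  }
  a <- if (is.null(seed_graph)) {
    matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  } else {
    if (!setequal(seed_graph$nodes, nodes)) {
      rlang::abort("seed graph must cover the data's variables",
        class = "bnhybrid_error_invalid"
      )
    }
    dag_amat(seed_graph)[nodes, nodes, drop = FALSE]
  }
  fam <- make_scorer(codes, score, iss)
  cur <- sum(vapply(nodes, function(v) fam(v, nodes[a[, v]]), numeric(1)))
  list(nodes = nodes, allowed = allowed, a = a, fam = fam, score = cur)
}

#' Greedy hill-climbing structure search
#'
#' Best-improvement local search over single-edge moves (add, delete,
#' reverse) that preserve acyclicity and, when a restriction skeleton is
#' given, keep every added edge inside the skeleton's adjacencies (deleting
#' and reversing existing edges is always permitted). Stops at the first
#' local optimum. Deterministic: equally scoring moves are broken by the
#' lexicographically smallest (operation, parent, child) triple.
#'
#' @param data A data frame of factors.
#' @param restrict Optional [bn_skeleton()] confining edge additions.
#' @param seed_graph Optional starting [bn_dag()] (default: empty graph).
#' @param score,iss Score settings, see [bic_score()].
#' @param max_iter Safety cap on the number of accepted moves.
#' @return A [bn_dag()] with attribute `score` (the final network score).
#' @export
hill_climb <- function(data, restrict = NULL, seed_graph = NULL,
                       score = c("bic", "bde"), iss = 1, max_iter = 10000) {
  score <- match.arg(score)
  st <- search_setup(data, restrict, seed_graph, score, iss)
  for (iter in seq_len(max_iter)) {
    moves <- order_moves(legal_moves(st$a, st$allowed, st$fam))
    if (length(moves) == 0 || moves[[1]]$delta <= 1e-12) break
    st$a <- apply_move(st$a, moves[[1]])
    st$score <- st$score + moves[[1]]$delta
  }
  out <- amat_to_dag(st$a)
  attr(out, "score") <- st$score
  out
}

#' Tabu-search parameters
#'
#' @param tabu_length Capacity of the FIFO tabu list of structure
#'   fingerprints (canonical sorted edge lists of visited networks).
#' @param max_stagnant Stop after this many consecutive iterations without
#'   improving the best score.
#' @param max_iter Overall iteration budget.
#' @return A `tabu_params` list.
#' @export
tabu_params <- function(tabu_length = 10, max_stagnant = 15, max_iter = 200) {
  stopifnot(tabu_length >= 1, max_stagnant >= 1, max_iter >= 1)
  structure(
    list(
      tabu_length = as.integer(tabu_length),
      max_stagnant = as.integer(max_stagnant),
      max_iter = as.integer(max_iter)
    ),
    class = "tabu_params"
  )
}

amat_fingerprint <- function(a) {
  idx <- which(a)
  paste(idx, collapse = ",")
}

#' Tabu-search structure learning
#'
#' Iterated local search over the same move set as [hill_climb()], but at
#' each step the best legal *non-tabu* move is applied even when it worsens
#' the score, letting the search climb out of local optima. Every visited
#' structure's fingerprint enters a bounded FIFO tabu list; the aspiration
#' criterion pardons a tabu move whenever it would strictly beat the best
#' score seen so far. The best structure encountered is returned after
#' `max_stagnant` non-improving iterations or `max_iter` total iterations.
#'
#' @inheritParams hill_climb
#' @param params A [tabu_params()] list.
#' @return A [bn_dag()] with attributes `score` (best score found) and
#'   `iterations`.
#' @export
tabu_search <- function(data, restrict = NULL, seed_graph = NULL,
                        params = tabu_params(), score = c("bic", "bde"), iss = 1) {
  score <- match.arg(score)
  if (!inherits(params, "tabu_params")) params <- do.call(tabu_params, params)
  st <- search_setup(data, restrict, seed_graph, score, iss)
  best_a <- st$a
  best_score <- st$score
  tabu <- amat_fingerprint(st$a)
  stagnant <- 0L
  iterations <- 0L
  for (iter in seq_len(params$max_iter)) {
    moves <- order_moves(legal_moves(st$a, st$allowed, st$fam))
    chosen <- NULL
    for (mv in moves) {
      a2 <- apply_move(st$a, mv)
      fp <- amat_fingerprint(a2)
      if (!(fp %in% tabu) || st$score + mv$delta > best_score + 1e-12) {
        chosen <- mv
        chosen_fp <- fp
        chosen_a <- a2
        break
      }
    }
    if (is.null(chosen)) break
    st$a <- chosen_a
    st$score <- st$score + chosen$delta
    tabu <- c(tabu, chosen_fp)
    if (length(tabu) > params$tabu_length) {
      tabu <- tabu[(length(tabu) - params$tabu_length + 1):length(tabu)]
    }
    iterations <- iter
    if (st$score > best_score + 1e-12) {
      best_score <- st$score
      best_a <- st$a
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= params$max_stagnant) break
    }
  }
  out <- amat_to_dag(best_a)
  attr(out, "score") <- best_score
  attr(out, "iterations") <- iterations
  out
}
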