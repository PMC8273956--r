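# Exact inference by variable elimination over table factors.
#
# A factor is a list(vars = character, val = numeric array with one
# dimension per variable). Products expand both operands to the union
# scope; elimination sums a variable out. Correctness is independent of the
# elimination order; the greedy smallest-intermediate-factor order only
# affects speed.

new_fac <- function(vars, val) list(vars = vars, val = val)

fac_from_cpt <- function(cpt) {
  new_fac(c(cpt$child, cpt$parents), cpt$prob)
}

# expand a factor to scope `vars` (a superset, any order) given cards
fac_expand <- function(f, vars, card) {
  if (length(f$vars) == 0) {
    s <- as.vector(f$val)[1]
    if (length(vars) == 0) return(new_fac(character(0), array(s, dim = 1L)))
    return(new_fac(vars, array(s, dim = card[vars])))
  }
  missing <- setdiff(vars, f$vars)
  val <- f$val
  if (!is.array(val)) val <- array(val, dim = length(val))
  if (length(missing) > 0) {
    val <- array(rep(as.vector(val), times = prod(card[missing])),
      dim = c(dim(val), card[missing])
    )
  }
  have <- c(f$vars, missing)
  perm <- match(vars, have)
  if (!identical(perm, seq_along(vars))) val <- aperm(val, perm)
  new_fac(vars, array(val, dim = card[vars]))
}

fac_product <- function(f, g, card) {
  vars <- union(f$vars, g$vars)
  fe <- fac_expand(f, vars, card)
  ge <- fac_expand(g, vars, card)
  new_fac(vars, fe$val * ge$val)
}

fac_marginalize <- function(f, var, card) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0) {
    return(new_fac(character(0), array(sum(f$val), dim = 1L)))
  }
  pos <- match(var, f$vars)
  perm <- c(setdiff(seq_along(f$vars), pos), pos)
  val <- aperm(f$val, perm)
  dim(val) <- c(prod(card[keep]), card[[var]])
  new_fac(keep, array(rowSums(val), dim = card[keep]))
}

# condition on var = level index (drops the variable from scope)
fac_reduce <- function(f, var, lev_idx) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- lev_idx
  val <- do.call(`[`, c(list(f$val), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  if (length(keep) == 0) {
    new_fac(character(0), array(as.vector(val), dim = 1L))
  } else {
    new_fac(f$vars[keep], array(as.vector(val), dim = dim(f$val)[keep]))
  }
}

check_evidence <- function(net, evidence) {
  evidence <- as.list(evidence)
  if (length(evidence) == 0) return(evidence)
  if (is.null(names(evidence)) || any(names(evidence) == "") ||
    anyDuplicated(names(evidence)) > 0) {
    rlang::abort("evidence must be uniquely named", class = "bnhybrid_error_invalid")
  }
  for (v in names(evidence)) {
    if (!v %in% names(net$levels)) {
      rlang::abort(paste0("evidence variable not in network: ", v),
        class = "bnhybrid_error_unknown_node"
      )
    }
    if (!evidence[[v]] %in% net$levels[[v]]) {
      rlang::abort(
        paste0("'", evidence[[v]], "' is not a level of ", v),
        class = "bnhybrid_error_invalid"
      )
    }
  }
  evidence
}

#' Maximum-likelihood parameter fitting
#'
#' Estimates every CPT of a given DAG from data: each row is
#' `(count + smoothing) / (row total + smoothing * levels)`, so
#' `smoothing = 0` is the pure maximum-likelihood estimate and
#' `smoothing = 1` is Laplace smoothing. A parent configuration never
#' observed in the data gets the uniform distribution; such rows are
#' recorded in the result's `backfilled_rows` attribute (a tibble naming the
#' node and configuration).
#'
#' @param graph A [bn_dag()] over the data's columns.
#' @param data A data frame of factors.
#' @param smoothing Pseudo-count added to every cell (>= 0).
#' @return A [discrete_bn()] carrying attribute `backfilled_rows`.
#' @export
fit_mle <- function(graph, data, smoothing = 0) {
  stopifnot(smoothing >= 0)
  codes <- dataset_codes(data)
  if (!setequal(graph$nodes, colnames(codes$m))) {
    rlang::abort("graph and data must cover the same variables",
      class = "bnhybrid_error_invalid"
    )
  }
  levels <- codes$levels[graph$nodes]
  card <- codes$card
  backfilled <- list()
  cpts <- lapply(graph$nodes, function(v) {
    pa <- parents(graph, v)
    r <- card[[v]]
    q <- if (length(pa) > 0) prod(card[pa]) else 1L
    cc <- codes$m[, v]
    if (length(pa) > 0) {
      stride <- r
      for (p in pa) {
        cc <- cc + (codes$m[, p] - 1L) * stride
        stride <- stride * card[[p]]
      }
    }
    counts <- matrix(tabulate(cc, nbins = r * q), nrow = r)
    tot <- colSums(counts)
    prob <- sweep(counts + smoothing, 2, tot + smoothing * r, "/")
    empty <- which(tot + smoothing * r == 0)
    if (length(empty) > 0) {
      prob[, empty] <- 1 / r
      cfg <- expand.grid(levels[pa], KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      backfilled[[length(backfilled) + 1]] <<- tibble::tibble(
        node = v,
        configuration = vapply(empty, function(j) {
          paste(paste0(pa, "=", unlist(cfg[j, ])), collapse = ", ")
        }, character(1))
      )
    }
    bn_cpt(v, pa, levels, array(prob, dim = c(r, if (length(pa)) card[pa] else NULL)))
  })
  names(cpts) <- graph$nodes
  net <- discrete_bn(levels, graph, cpts)
  attr(net, "backfilled_rows") <- if (length(backfilled)) {
    dplyr::bind_rows(backfilled)
  } else {
    tibble::tibble(node = character(), configuration = character())
  }
  net
}

#' Exact posterior query
#'
#' Computes `P(target | evidence)` exactly by variable elimination: the
#' network's CPT factors are conditioned on the evidence, all remaining
#' variables except the target are summed out (greedily eliminating the
#' variable whose intermediate factor is smallest), and the result is
#' normalised. Evidence with probability zero under the network is an
#' error of class `bnhybrid_error_zero_evidence`.
#'
#' @param net A [discrete_bn()].
#' @param target Variable to query (must not be in the evidence).
#' @param evidence Named list or character vector `variable = level`.
#' @return A `bn_posterior`: tibble with columns `level` and `probability`
#'   (summing to 1) plus attributes `target` and `evidence`.
#' @examples
#' net <- load_fixture("sprinkler4")$network
#' query(net, "Rain", list(WetGrass = "T"))
#' @export
query <- function(net, target, evidence = list()) {
  stopifnot(inherits(net, "discrete_bn"))
  if (!target %in% names(net$levels)) {
    rlang::abort(paste0("unknown target: ", target), class = "bnhybrid_error_unknown_node")
  }
  evidence <- check_evidence(net, evidence)
  if (target %in% names(evidence)) {
    rlang::abort("target must not be part of the evidence", class = "bnhybrid_error_invalid")
  }
  card <- lengths(net$levels)
  facs <- lapply(net$cpts, fac_from_cpt)
  for (v in names(evidence)) {
    lev_idx <- match(evidence[[v]], net$levels[[v]])
    facs <- lapply(facs, fac_reduce, var = v, lev_idx = lev_idx)
  }
  to_eliminate <- setdiff(names(net$levels), c(target, names(evidence)))
  while (length(to_eliminate) > 0) {
    # greedy: eliminate the variable with the smallest intermediate factor
    sizes <- vapply(to_eliminate, function(v) {
      scope <- unique(unlist(lapply(facs, function(f) if (v %in% f$vars) f$vars)))
      prod(card[scope])
    }, numeric(1))
    v <- to_eliminate[which.min(sizes)]
    involved <- vapply(facs, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) fac_product(a, b, card), facs[involved])
    facs <- c(facs[!involved], list(fac_marginalize(prod_f, v, card)))
    to_eliminate <- setdiff(to_eliminate, v)
  }
  res <- Reduce(function(a, b) fac_product(a, b, card), facs)
  res <- fac_expand(res, target, card)
  mass <- sum(res$val)
  if (mass <= 0) {
    rlang::abort("evidence has probability zero under the network",
      class = "bnhybrid_error_zero_evidence"
    )
  }
  out <- tibble::tibble(
    level = net$levels[[target]],
    probability = as.vector(res$val) / mass
  )
  attr(out, "target") <- target
  attr(out, "evidence") <- evidence
  class(out) <- c("bn_posterior", class(out))
  out
}

#' Sequential risk reasoning
#'
#' Reproduces the sequential reasoning style of epidemiological risk
#' chains: evidence arrives in increments, and after each increment the
#' posterior of the target is recomputed with the *cumulative* evidence so
#' far. Step 0 is the prior (no evidence). Increments must name disjoint
#' variables, and each step's posterior equals an independent [query()] with
#' the same cumulative evidence.
#'
#' @param net A [discrete_bn()].
#' @param target Variable of interest.
#' @param evidence_sequence List of evidence increments (each a named list).
#' @return A `bn_risk_chain` tibble: one row per step and target level,
#'   with columns `step`, `added` (the increment, as a label), `level`,
#'   `probability`.
#' @export
risk_chain <- function(net, target, evidence_sequence = list()) {
  cum <- list()
  rows <- list()
  label <- function(ev) paste(paste0(names(ev), "=", unlist(ev)), collapse = ", ")
  post <- query(net, target, cum)
  rows[[1]] <- tibble::tibble(
    step = 0L, added = "(prior)",
    level = post$level, probability = post$probability
  )
  for (k in seq_along(evidence_sequence)) {
    inc <- as.list(evidence_sequence[[k]])
    clash <- intersect(names(inc), names(cum))
    if (length(clash) > 0) {
      rlang::abort(paste0("evidence increment re-states: ", paste(clash, collapse = ", ")),
        class = "bnhybrid_error_invalid"
      )
    }
    cum <- c(cum, inc)
    post <- query(net, target, cum)
    rows[[k + 1]] <- tibble::tibble(
      step = k, added = label(inc),
      level = post$level, probability = post$probability
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "target") <- target
  class(out) <- c("bn_risk_chain", class(out))
  out
}
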