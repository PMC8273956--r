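#' Conditional probability tables
#'
#' A `bn_cpt` holds the distribution of one categorical child variable for
#' every configuration of its parents. Probabilities are stored as an array
#' whose first dimension runs over the child's levels and whose remaining
#' dimensions follow the declared parent order, so a single parent
#' configuration indexes one column that must sum to 1. Level order is the
#' declaration order, never lexicographic, so file round-trips are
#' bit-stable.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty), in the
#'   order parent configurations are enumerated.
#' @param levels Named list mapping `child` and each parent to its ordered
#'   level labels.
#' @param prob Numeric array (or vector for a root node) of probabilities,
#'   dimension `c(length(levels[[child]]), lengths(levels[parents]))`.
#' @return A `bn_cpt` object.
#' @export
bn_cpt <- function(child, parents, levels, prob) {
  stopifnot(is.list(levels), child %in% names(levels))
  if (!all(parents %in% names(levels))) {
    rlang::abort("missing level declaration for a parent", class = "bnhybrid_error_invalid")
  }
  lev <- levels[c(child, parents)]
  if (any(lengths(lev) < 2L)) {
    rlang::abort("every variable needs at least 2 levels", class = "bnhybrid_error_invalid")
  }
  if (any(vapply(lev, anyDuplicated, integer(1)) > 0)) {
    rlang::abort("duplicate level labels", class = "bnhybrid_error_invalid")
  }
  dims <- lengths(lev)
  prob <- array(as.numeric(prob), dim = dims, dimnames = lev)
  names(dimnames(prob)) <- c(child, parents)
  colsum <- if (length(parents) == 0L) sum(prob) else apply(prob, seq_along(dims)[-1], sum)
  if (any(abs(colsum - 1) > 1e-9) || any(prob < 0) || any(prob > 1)) {
    rlang::abort(
      paste0("CPT for ", child, " does not normalise (or has entries outside [0,1])"),
      class = "bnhybrid_error_validation"
    )
  }
  structure(
    list(child = child, parents = as.character(parents), levels = lev, prob = prob),
    class = "bn_cpt"
  )
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat("<bn_cpt> ", x$child,
    if (length(x$parents) > 0) paste0(" | ", paste(x$parents, collapse = ", ")),
    "\n",
    sep = ""
  )
  print(round(x$prob, 4))
  invisible(x)
}

#' Discrete Bayesian networks
#'
#' A `discrete_bn` couples a [bn_dag()] with one [bn_cpt()] per node whose
#' parents equal that node's graph parents: the network `B = (G, theta)`.
#' The joint distribution factorises as the product of the CPT rows, and for
#' networks small enough to enumerate the constructor's invariant (total
#' probability 1) can be checked with [enumerate_joint()].
#'
#' @param levels Named list: each variable's ordered level labels.
#' @param dag A [bn_dag()] over `names(levels)`.
#' @param cpts Named list of [bn_cpt()] objects, one per node.
#' @return A `discrete_bn` object.
#' @export
discrete_bn <- function(levels, dag, cpts) {
  if (!setequal(names(levels), dag$nodes) || !setequal(names(cpts), dag$nodes)) {
    rlang::abort("levels, dag and cpts must cover the same variables",
      class = "bnhybrid_error_invalid"
    )
  }
  for (v in dag$nodes) {
    cpt <- cpts[[v]]
    if (!inherits(cpt, "bn_cpt") || cpt$child != v) {
      rlang::abort(paste0("cpts[['", v, "']] must be a bn_cpt for ", v),
        class = "bnhybrid_error_invalid"
      )
    }
    if (!identical(sort(cpt$parents), sort(parents(dag, v)))) {
      rlang::abort(paste0("CPT parents for ", v, " disagree with the graph"),
        class = "bnhybrid_error_invalid"
      )
    }
    if (!identical(cpt$levels[[v]], levels[[v]])) {
      rlang::abort(paste0("CPT level order for ", v, " disagrees with the declaration"),
        class = "bnhybrid_error_invalid"
      )
    }
  }
  structure(
    list(levels = levels[dag$nodes], dag = dag, cpts = cpts[dag$nodes]),
    class = "discrete_bn"
  )
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("<discrete_bn> ", length(x$dag$nodes), " variables, ",
    nrow(x$dag$edges), " edges\n",
    sep = ""
  )
  cat("  variables: ", paste(x$dag$nodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate the joint distribution of a small network
#'
#' Materialises every joint configuration and its probability under the
#' factorisation; intended as a brute-force oracle for inference tests and
#' for checking that a network's joint mass sums to 1. The state space must
#' have at most `max_states` configurations.
#'
#' @param net A [discrete_bn()].
#' @param max_states Guard against accidental huge enumerations.
#' @return A tibble with one factor column per variable plus `prob`.
#' @export
enumerate_joint <- function(net, max_states = 2^21) {
  card <- lengths(net$levels)
  if (prod(card) > max_states) {
    rlang::abort("joint state space too large to enumerate", class = "bnhybrid_error_invalid")
  }
  grid <- expand.grid(net$levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prob <- rep(1, nrow(grid))
  for (v in net$dag$nodes) {
    cpt <- net$cpts[[v]]
    idx <- lapply(c(v, cpt$parents), function(u) match(grid[[u]], net$levels[[u]]))
    flat <- idx[[1]]
    stride <- length(net$levels[[v]])
    if (length(cpt$parents) > 0) {
      for (k in seq_along(cpt$parents)) {
        flat <- flat + (idx[[k + 1L]] - 1L) * stride
        stride <- stride * length(net$levels[[cpt$parents[k]]])
      }
    }
    prob <- prob * as.vector(cpt$prob)[flat]
  }
  out <- tibble::as_tibble(grid)
  for (v in names(net$levels)) out[[v]] <- factor(out[[v]], levels = net$levels[[v]])
  out$prob <- prob
  out
}

#' Validate (and optionally coerce) a categorical dataset
#'
#' Datasets are ordinary data frames with one factor column per variable;
#' the factor level order is the declared level order. Non-factor columns
#' are converted with levels in order of first appearance (with a warning,
#' because first-appearance order is data-dependent). Missing values are
#' rejected unless `drop_incomplete = TRUE`, which performs listwise
#' deletion.
#'
#' @param data A data frame.
#' @param levels Optional named list fixing each column's level order.
#' @param drop_incomplete Drop rows containing `NA` instead of aborting.
#' @return A tibble of factors.
#' @export
as_bn_dataset <- function(data, levels = NULL, drop_incomplete = FALSE) {
  data <- tibble::as_tibble(data)
  if (ncol(data) == 0L || nrow(data) == 0L) {
    rlang::abort("dataset must have at least one row and one column",
      class = "bnhybrid_error_invalid"
    )
  }
  if (anyNA(data)) {
    if (drop_incomplete) {
      data <- data[stats::complete.cases(data), , drop = FALSE]
      if (nrow(data) == 0L) {
        rlang::abort("no complete rows left after listwise deletion",
          class = "bnhybrid_error_invalid"
        )
      }
    } else {
      rlang::abort("dataset contains missing values (use drop_incomplete = TRUE)",
        class = "bnhybrid_error_missing"
      )
    }
  }
  for (v in names(data)) {
    want <- levels[[v]]
    col <- data[[v]]
    if (is.null(want)) {
      if (!is.factor(col)) {
        rlang::warn(paste0(
          "column '", v, "' is not a factor; levels taken in first-appearance order"
        ))
        col <- factor(as.character(col), levels = unique(as.character(col)))
      }
    } else {
      vals <- as.character(col)
      bad <- setdiff(unique(vals), want)
      if (length(bad) > 0) {
        rlang::abort(
          paste0("column '", v, "' has values outside its declared levels: ",
            paste(bad, collapse = ", ")),
          class = "bnhybrid_error_schema"
        )
      }
      col <- factor(vals, levels = want)
    }
    data[[v]] <- col
  }
  data
}

# integer-coded view of a dataset used by the counting kernels:
# list(m = integer matrix n x p, card = integer cards, levels = list)
dataset_codes <- function(data) {
  data <- as_bn_dataset(data)
  m <- vapply(data, as.integer, integer(nrow(data)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(data))
  colnames(m) <- names(data)
  list(
    m = m,
    card = vapply(data, nlevels, integer(1)),
    levels = lapply(data, base::levels),
    n = nrow(data)
  )
}
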