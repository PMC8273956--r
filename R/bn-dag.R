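#' Directed acyclic graphs over named nodes
#'
#' A `bn_dag` stores a set of node names and a directed edge list, and is
#' guaranteed acyclic on construction. It is the structural half of a
#' discrete Bayesian network `B = (G, theta)`: nodes are categorical
#' variables, an edge `u -> v` states that `u` is a parent of `v` in the
#' factorisation of the joint distribution.
#'
#' @param nodes Character vector of unique node names.
#' @param edges A data frame with columns `from` and `to` (one row per
#'   directed edge), or `NULL` for an edgeless graph.
#'
#' @return A `bn_dag` object: a list with elements `nodes` (character) and
#'   `edges` (a tibble with columns `from`, `to`).
#'
#' @examples
#' g <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
#' topological_order(g)
#' parents(g, "B")
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) > 0) {
    rlang::abort("duplicate node names in DAG", class = "bnhybrid_error_invalid")
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(as.data.frame(edges)[, c("from", "to")])
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("edge references undeclared node(s): ", paste(bad, collapse = ", ")),
      class = "bnhybrid_error_unknown_node"
    )
  }
  if (any(edges$from == edges$to)) {
    rlang::abort("self-loops are not allowed", class = "bnhybrid_error_invalid")
  }
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")) > 0) {
    rlang::abort("duplicate edges", class = "bnhybrid_error_invalid")
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  topological_order(g) # aborts with the offending cycle if not a DAG
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("<bn_dag> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

# adjacency matrix (logical, parents in rows: amat[u, v] == TRUE iff u -> v)
dag_amat <- function(g) {
  p <- length(g$nodes)
  a <- matrix(FALSE, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) a[cbind(g$edges$from, g$edges$to)] <- TRUE
  a
}

amat_to_dag <- function(a) {
  idx <- which(a, arr.ind = TRUE)
  bn_dag(rownames(a), data.frame(
    from = rownames(a)[idx[, 1]],
    to = colnames(a)[idx[, 2]]
  ))
}

# Kahn's algorithm on a logical adjacency matrix; returns node order or NULL
kahn_order <- function(a) {
  nodes <- rownames(a)
  indeg <- colSums(a)
  order <- character(0)
  avail <- nodes[indeg == 0]
  indeg_left <- indeg
  active <- rep(TRUE, length(nodes))
  names(active) <- nodes
  while (length(avail) > 0) {
    v <- avail[1] # deterministic: declaration order among the available
    avail <- avail[-1]
    order <- c(order, v)
    active[v] <- FALSE
    ch <- nodes[a[v, ]]
    for (w in ch) {
      indeg_left[w] <- indeg_left[w] - 1L
      if (indeg_left[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

# extract one directed cycle for the error message (walk back along a cycle)
find_cycle <- function(a) {
  nodes <- rownames(a)
  state <- integer(length(nodes)) # 0 unseen, 1 in stack, 2 done
  names(state) <- nodes
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  cyc <- NULL
  visit <- function(v) {
    state[v] <<- 1L
    for (w in nodes[a[v, ]]) {
      if (!is.null(cyc)) return(invisible())
      if (state[w] == 0L) {
        parent[w] <<- v
        visit(w)
      } else if (state[w] == 1L) {
        path <- v
        while (path[1] != w) path <- c(parent[path[1]], path)
        cyc <<- c(path, w)
        return(invisible())
      }
    }
    state[v] <<- 2L
  }
  for (v in nodes) {
    if (state[v] == 0L && is.null(cyc)) visit(v)
  }
  cyc
}

#' Topological ordering of a DAG
#'
#' Orders the nodes so that every edge points forward. Uses Kahn's algorithm;
#' ties are broken by node declaration order, so the result is deterministic.
#'
#' @param g A [bn_dag()].
#' @return Character vector of node names in topological order.
#'   Aborts with class `bnhybrid_error_cycle` (naming one cycle) if the edge
#'   list contains a directed cycle.
#' @export
topological_order <- function(g) {
  a <- dag_amat(g)
  ord <- kahn_order(a)
  if (is.null(ord)) {
    cyc <- find_cycle(a)
    rlang::abort(
      paste0("graph contains a cycle: ", paste(cyc, collapse = " -> ")),
      class = "bnhybrid_error_cycle",
      cycle = cyc
    )
  }
  ord
}

# does the matrix contain a directed path from `from` to `to`? (DFS)
amat_has_path <- function(a, from, to) {
  if (from == to) return(TRUE)
  nodes <- rownames(a)
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  stack <- from
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, nodes[a[v, ] & !seen])
  }
  FALSE
}

#' Would a single-edge move keep the graph acyclic?
#'
#' Checks, without mutating `g`, whether adding, deleting, or reversing one
#' edge yields a DAG. Deletion is always safe; addition of `u -> v` is safe
#' iff there is no directed path `v ~> u`; reversal of `u -> v` is safe iff
#' after removing it there is no other path `u ~> v`.
#'
#' @param g A [bn_dag()].
#' @param op One of `"add"`, `"delete"`, `"reverse"`.
#' @param from,to Node names of the edge the move operates on.
#' @return `TRUE` or `FALSE`. Aborts with class `bnhybrid_error_unknown_edge`
#'   when deleting/reversing an edge that is not present, and
#'   `bnhybrid_error_unknown_node` for undeclared nodes.
#' @export
is_acyclic_after <- function(g, op = c("add", "delete", "reverse"), from, to) {
  op <- match.arg(op)
  bad <- setdiff(c(from, to), g$nodes)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown node(s): ", paste(bad, collapse = ", ")),
      class = "bnhybrid_error_unknown_node"
    )
  }
  a <- dag_amat(g)
  if (op %in% c("delete", "reverse") && !a[from, to]) {
    rlang::abort(paste0("edge ", from, " -> ", to, " is not in the graph"),
      class = "bnhybrid_error_unknown_edge"
    )
  }
  switch(op,
    delete = TRUE,
    add = {
      if (from == to) return(FALSE)
      if (a[from, to]) return(FALSE) # already present: not a legal add
      !amat_has_path(a, to, from)
    },
    reverse = {
      a[from, to] <- FALSE
      !amat_has_path(a, from, to)
    }
  )
}

node_in_graph <- function(g, node) {
  if (!node %in% g$nodes) {
    rlang::abort(paste0("unknown node: ", node), class = "bnhybrid_error_unknown_node")
  }
}

#' Parents and children of a node
#'
#' @param g A [bn_dag()] or [discrete_bn()].
#' @param node A node name.
#' @return Character vector of parent (resp. child) node names, in node
#'   declaration order.
#' @export
parents <- function(g, node) UseMethod("parents")

#' @rdname parents
#' @export
children <- function(g, node) UseMethod("children")

#' @export
parents.bn_dag <- function(g, node) {
  node_in_graph(g, node)
  intersect(g$nodes, g$edges$from[g$edges$to == node])
}

#' @export
children.bn_dag <- function(g, node) {
  node_in_graph(g, node)
  intersect(g$nodes, g$edges$to[g$edges$from == node])
}

#' @export
parents.discrete_bn <- function(g, node) parents(g$dag, node)

#' @export
children.discrete_bn <- function(g, node) children(g$dag, node)

#' Undirected skeletons
#'
#' A `bn_skeleton` is the undirected adjacency structure of a network before
#' edge orientation: a set of nodes plus unordered adjacent pairs. It is the
#' object the constraint-based phase of a hybrid learner hands to the
#' score-based phase as a search restriction.
#'
#' @param nodes Character vector of node names.
#' @param adjacencies Data frame with columns `a`, `b` (one row per unordered
#'   adjacency), or `NULL` for an empty skeleton. Pairs are stored with
#'   `a < b` in node declaration order; duplicates and self-adjacencies are
#'   rejected.
#' @return A `bn_skeleton` object.
#' @export
bn_skeleton <- function(nodes, adjacencies = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) > 0) {
    rlang::abort("duplicate node names in skeleton", class = "bnhybrid_error_invalid")
  }
  if (is.null(adjacencies) || nrow(as.data.frame(adjacencies)) == 0L) {
    adj <- tibble::tibble(a = character(), b = character())
  } else {
    adj <- as.data.frame(adjacencies)[, c("a", "b")]
    bad <- setdiff(c(adj$a, adj$b), nodes)
    if (length(bad) > 0) {
      rlang::abort(paste0("adjacency references undeclared node(s): ", paste(bad, collapse = ", ")),
        class = "bnhybrid_error_unknown_node"
      )
    }
    if (any(adj$a == adj$b)) {
      rlang::abort("self-adjacency is not allowed", class = "bnhybrid_error_invalid")
    }
    pos <- match(adj$a, nodes)
    posb <- match(adj$b, nodes)
    swap <- pos > posb
    tmp <- adj$a[swap]
    adj$a[swap] <- adj$b[swap]
    adj$b[swap] <- tmp
    adj <- unique(adj)
    adj <- adj[order(match(adj$a, nodes), match(adj$b, nodes)), , drop = FALSE]
    adj <- tibble::as_tibble(adj)
  }
  structure(list(nodes = nodes, adjacencies = adj), class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat("<bn_skeleton> ", length(x$nodes), " nodes, ", nrow(x$adjacencies),
    " adjacencies\n",
    sep = ""
  )
  invisible(x)
}

# symmetric logical adjacency matrix of a skeleton
skeleton_amat <- function(s) {
  p <- length(s$nodes)
  a <- matrix(FALSE, p, p, dimnames = list(s$nodes, s$nodes))
  if (nrow(s$adjacencies) > 0) {
    a[cbind(s$adjacencies$a, s$adjacencies$b)] <- TRUE
    a[cbind(s$adjacencies$b, s$adjacencies$a)] <- TRUE
  }
  a
}

# skeleton of a DAG (drop orientations)
dag_skeleton <- function(g) {
  e <- g$edges
  bn_skeleton(g$nodes, data.frame(a = e$from, b = e$to))
}
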