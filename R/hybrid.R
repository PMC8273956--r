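#' Hybrid structure learning: constraint-based skeleton, score-based orientation
#'
#' Two-phase learning of a DAG from categorical data. Phase 1 runs a
#' constraint-based neighbourhood learner per node ([mmpc_neighborhood()] or
#' an [iamb_neighborhood()] variant) and combines the results into an
#' undirected skeleton with [skeleton_from_neighborhoods()] (for the IAMB
#' family the spouse screen is applied, since Markov blankets contain
#' co-parent links that are not skeleton edges). Phase 2 orients the skeleton
#' by a restricted score search: [tabu_search()] or [hill_climb()], which may
#' only add edges inside the skeleton. `(mmpc, hc)` is the classic MMHC
#' algorithm; `(inter.iamb, tabu)` is the headline hybrid this package is
#' built around.
#'
#' @param data A data frame of factors.
#' @param skeleton_method `"mmpc"`, `"iamb"`, `"inter.iamb"`, or
#'   `"fast.iamb"`.
#' @param search_method `"tabu"` or `"hc"`.
#' @param alpha Significance level of the phase-1 independence tests.
#' @param params [tabu_params()] for the tabu phase.
#' @param max_sx Conditioning-subset cap for MMPC and the spouse screen.
#' @param score,iss Score settings for phase 2 (see [bic_score()]).
#' @param reliability_ratio Minimum `n / df` for a reliable test.
#' @return A `bn_hybrid_fit`: list with `dag` (the learned [bn_dag()]),
#'   `skeleton` (phase-1 [bn_skeleton()]), `neighborhoods` (per-node
#'   `bn_neighborhood`s), `score` (phase-2 network score), and `provenance`
#'   (methods, alpha, tabu parameters, sample size).
#' @examples
#' \donttest{
#' net <- load_fixture("sprinkler4")$network
#' d <- forward_sample(net, 5000, seed = 1)
#' fit <- learn_hybrid(d, "inter.iamb", "tabu")
#' tidy(fit)
#' }
#' @export
learn_hybrid <- function(data, skeleton_method = c("mmpc", "iamb", "inter.iamb", "fast.iamb"),
                         search_method = c("tabu", "hc"), alpha = 0.05,
                         params = tabu_params(), max_sx = 3,
                         score = c("bic", "bde"), iss = 1,
                         reliability_ratio = 5) {
  skeleton_method <- match.arg(skeleton_method)
  search_method <- match.arg(search_method)
  score <- match.arg(score)
  codes <- dataset_codes(data)
  nodes <- colnames(codes$m)

  nbrs <- lapply(nodes, function(v) {
    switch(skeleton_method,
      mmpc = mmpc_nbr_codes(codes, v, alpha, max_sx, reliability_ratio),
      iamb = iamb_nbr_codes(codes, v, alpha, "plain", reliability_ratio),
      inter.iamb = iamb_nbr_codes(codes, v, alpha, "inter", reliability_ratio),
      fast.iamb = iamb_nbr_codes(codes, v, alpha, "fast", reliability_ratio)
    )
  })
  names(nbrs) <- nodes

  is_mb <- skeleton_method != "mmpc"
  skel <- skeleton_from_neighborhoods(
    nbrs,
    data = if (is_mb) data else NULL,
    alpha = alpha, max_sx = max_sx, reliability_ratio = reliability_ratio
  )

  dag <- if (search_method == "tabu") {
    tabu_search(data, restrict = skel, params = params, score = score, iss = iss)
  } else {
    hill_climb(data, restrict = skel, score = score, iss = iss)
  }

  structure(
    list(
      dag = dag,
      skeleton = skel,
      neighborhoods = nbrs,
      score = attr(dag, "score"),
      provenance = list(
        skeleton_method = skeleton_method,
        search_method = search_method,
        alpha = alpha,
        max_sx = max_sx,
        score = score,
        tabu = if (search_method == "tabu") unclass(params) else NULL,
        n = nrow(data)
      )
    ),
    class = "bn_hybrid_fit"
  )
}

#' @export
print.bn_hybrid_fit <- function(x, ...) {
  cat("<bn_hybrid_fit> ", x$provenance$skeleton_method, " + ",
    x$provenance$search_method, "; ", length(x$dag$nodes), " nodes, ",
    nrow(x$dag$edges), " edges, score ", format(x$score), "\n",
    sep = ""
  )
  invisible(x)
}

# canonical learner names used by the benchmark driver and the CLI
hybrid_algorithms <- c(
  "mmhc", "mmpc-tabu", "fast.iamb-tabu", "inter.iamb-tabu", "hc", "tabu"
)

#' Run a named learning algorithm
#'
#' Dispatches the algorithm names used throughout the benchmark and the
#' command line: `"mmhc"` (MMPC + hill climbing), `"mmpc-tabu"`,
#' `"fast.iamb-tabu"`, `"inter.iamb-tabu"`, and the unrestricted score
#' searches `"hc"` and `"tabu"`.
#'
#' @param data A data frame of factors.
#' @param algo Algorithm name.
#' @param ... Passed on to [learn_hybrid()], [hill_climb()] or
#'   [tabu_search()].
#' @return A `bn_hybrid_fit` for hybrid algorithms, a [bn_dag()] for the
#'   plain searches.
#' @export
learn_bn <- function(data, algo = "inter.iamb-tabu", ...) {
  if (!algo %in% hybrid_algorithms) {
    rlang::abort(
      paste0(
        "unknown algorithm '", algo, "'; available: ",
        paste(hybrid_algorithms, collapse = ", ")
      ),
      class = "bnhybrid_error_usage"
    )
  }
  switch(algo,
    "mmhc" = learn_hybrid(data, "mmpc", "hc", ...),
    "mmpc-tabu" = learn_hybrid(data, "mmpc", "tabu", ...),
    "fast.iamb-tabu" = learn_hybrid(data, "fast.iamb", "tabu", ...),
    "inter.iamb-tabu" = learn_hybrid(data, "inter.iamb", "tabu", ...),
    "hc" = hill_climb(data, ...),
    "tabu" = tabu_search(data, ...)
  )
}
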