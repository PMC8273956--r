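# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DAG into its edge table
#'
#' @param x A [bn_dag()].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`.
#' @method tidy bn_dag
#' @export
tidy.bn_dag <- function(x, ...) x$edges

#' @method tidy bn_skeleton
#' @export
tidy.bn_skeleton <- function(x, ...) x$adjacencies

#' Tidy a network into a long CPT table
#'
#' @param x A [discrete_bn()].
#' @param ... Unused.
#' @return A tibble: `node`, `level`, `parents` (configuration label, `""`
#'   for roots), `probability`.
#' @method tidy discrete_bn
#' @export
tidy.discrete_bn <- function(x, ...) {
  rows <- lapply(names(x$cpts), function(v) {
    cpt <- x$cpts[[v]]
    r <- length(x$levels[[v]])
    mat <- matrix(as.vector(cpt$prob), nrow = r)
    cfg_label <- if (length(cpt$parents) == 0) {
      ""
    } else {
      cfg <- expand.grid(x$levels[cpt$parents],
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      vapply(seq_len(nrow(cfg)), function(j) {
        paste(paste0(cpt$parents, "=", unlist(cfg[j, ])), collapse = ", ")
      }, character(1))
    }
    tibble::tibble(
      node = v,
      level = rep(x$levels[[v]], times = ncol(mat)),
      parents = rep(cfg_label, each = r),
      probability = as.vector(mat)
    )
  })
  dplyr::bind_rows(rows)
}

#' @method glance discrete_bn
#' @export
glance.discrete_bn <- function(x, ...) {
  tibble::tibble(
    nodes = length(x$dag$nodes),
    edges = nrow(x$dag$edges),
    parameters = sum(vapply(x$cpts, function(cpt) {
      (length(cpt$levels[[cpt$child]]) - 1) * prod(lengths(cpt$levels[cpt$parents]))
    }, numeric(1)))
  )
}

#' @method tidy bn_neighborhood
#' @export
tidy.bn_neighborhood <- function(x, ...) x$trace

#' @method glance bn_neighborhood
#' @export
glance.bn_neighborhood <- function(x, ...) {
  tibble::tibble(
    target = x$target, n_members = length(x$members),
    members = paste(x$members, collapse = ",")
  )
}

#' Tidy a hybrid fit into its learned edge table
#'
#' @param x A `bn_hybrid_fit` from [learn_hybrid()].
#' @param ... Unused.
#' @return The learned DAG's edge tibble.
#' @method tidy bn_hybrid_fit
#' @export
tidy.bn_hybrid_fit <- function(x, ...) tidy(x$dag)

#' @method glance bn_hybrid_fit
#' @export
glance.bn_hybrid_fit <- function(x, ...) {
  tibble::tibble(
    skeleton_method = x$provenance$skeleton_method,
    search_method = x$provenance$search_method,
    alpha = x$provenance$alpha,
    n = x$provenance$n,
    skeleton_adjacencies = nrow(x$skeleton$adjacencies),
    edges = nrow(x$dag$edges),
    score = x$score
  )
}

#' @method tidy bn_benchmark
#' @export
tidy.bn_benchmark <- function(x, ...) x$cells

#' @method glance bn_benchmark
#' @export
glance.bn_benchmark <- function(x, ...) {
  tibble::tibble(
    fixture = x$fixture, reps = x$reps, base_seed = x$base_seed,
    runs = nrow(x$cells), failed = sum(!is.na(x$cells$error))
  )
}

#' Plot benchmark error against sample size
#'
#' Mean weighted structural error S(E) per algorithm as a function of the
#' training sample size (log scale).
#'
#' @param object A `bn_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bn_benchmark
#' @export
autoplot.bn_benchmark <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(
    x = .data$size, y = .data$total,
    colour = .data$algorithm, group = .data$algorithm
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "sample size", y = "mean S(E)",
      colour = NULL,
      title = paste0("Structural error vs sample size (", object$fixture, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a logistic fit into its coefficient table
#'
#' One row per model term: estimate, standard error, Wald chi-square,
#' p-value, odds ratio, and its 95 percent confidence bounds.
#'
#' @param x A `bn_logistic_fit` from [stepwise_logistic()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bn_logistic_fit
#' @export
tidy.bn_logistic_fit <- function(x, ...) x$table

#' @method glance bn_logistic_fit
#' @export
glance.bn_logistic_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n = length(x$model$y),
    retained = length(x$retained),
    steps = nrow(x$steps),
    deviance = x$model$deviance,
    aic = x$model$aic,
    converged = x$model$converged
  )
}

#' Plot a posterior distribution
#'
#' @param object A `bn_posterior` from [query()].
#' @param ... Unused.
#' @return A ggplot bar chart of the posterior.
#' @method autoplot bn_posterior
#' @export
autoplot.bn_posterior <- function(object, ...) {
  ev <- attr(object, "evidence")
  sub <- if (length(ev)) {
    paste("evidence:", paste(paste0(names(ev), "=", unlist(ev)), collapse = ", "))
  } else {
    "prior (no evidence)"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = attr(object, "target"), y = "posterior probability", subtitle = sub
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sequential risk-reasoning chain
#'
#' Posterior probability of each target level after each cumulative
#' evidence increment.
#'
#' @param object A `bn_risk_chain` from [risk_chain()].
#' @param level Optional single level to display (default: all levels).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bn_risk_chain
#' @export
autoplot.bn_risk_chain <- function(object, level = NULL, ...) {
  d <- if (is.null(level)) object else object[object$level == level, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$step, y = .data$probability,
    colour = .data$level, group = .data$level
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = unique(d$step),
      labels = unique(object$added)[match(unique(d$step), unique(object$step))]
    ) +
    ggplot2::labs(
      x = "cumulative evidence", y = "posterior probability",
      colour = attr(object, "target")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
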