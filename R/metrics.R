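#' Structural error between a learned and a true DAG
#'
#' Classifies every unordered node pair: adjacent in both graphs with
#' opposite orientation counts as *reversed* R(E); adjacent only in the
#' truth as *missing* M(E); adjacent only in the learned graph as *extra*
#' A(E). The weighted total is `S(E) = A(E) + M(E) + 0.5 * R(E)` -- a
#' reversed edge is half an error, since the adjacency itself was found.
#' The comparison is DAG-vs-DAG: an edge oriented against the truth counts
#' as reversed even when the two orientations are Markov-equivalent.
#'
#' @param learned,truth Two [bn_dag()]s over the same node set.
#' @return A one-row tibble: `reversed`, `missing`, `extra` (integer counts)
#'   and `total` (the weighted sum).
#' @examples
#' truth <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
#' flipped <- bn_dag(c("A", "B"), data.frame(from = "B", to = "A"))
#' compare_structures(flipped, truth) # one reversal, S(E) = 0.5
#' @export
compare_structures <- function(learned, truth) {
  if (!setequal(learned$nodes, truth$nodes)) {
    rlang::abort("learned and true graphs must share the same node set",
      class = "bnhybrid_error_node_mismatch"
    )
  }
  al <- dag_amat(learned)[truth$nodes, truth$nodes, drop = FALSE]
  at <- dag_amat(truth)
  upper <- upper.tri(at)
  adj_l <- (al | t(al))[upper]
  adj_t <- (at | t(at))[upper]
  same_dir <- (al & at) | (t(al) & t(at))
  reversed <- sum(adj_l & adj_t & !same_dir[upper])
  missing <- sum(adj_t & !adj_l)
  extra <- sum(adj_l & !adj_t)
  tibble::tibble(
    reversed = as.integer(reversed),
    missing = as.integer(missing),
    extra = as.integer(extra),
    total = weighted_total(reversed, missing, extra)
  )
}

#' Weighted total structural error S(E)
#'
#' `S(E) = A(E) + M(E) + 0.5 * R(E)`: extra plus missing edges plus half the
#' reversed edges. Accepts real-valued components so that means over
#' replicates can be totalled the same way.
#'
#' @param reversed,missing,extra Non-negative components (vectorised).
#' @return Numeric vector of weighted totals.
#' @export
weighted_total <- function(reversed, missing, extra) {
  if (any(c(reversed, missing, extra) < 0)) {
    rlang::abort("error components must be non-negative",
      class = "bnhybrid_error_negative"
    )
  }
  extra + missing + 0.5 * reversed
}

#' Benchmark a set of learners against a true network
#'
#' The simulation protocol behind the benchmark table: for every (sample
#' size, replicate) cell, forward-sample a dataset from the true network
#' (seeds derived as in [replicate_datasets()]), run each algorithm, and
#' score the learned DAG against the truth with [compare_structures()].
#' Per-algorithm means over replicates are reported per sample size. A
#' failed learner run is recorded with its error message and excluded from
#' the means (never silently replaced by an empty graph); a warning reports
#' the failure count.
#'
#' @param fixture A fixture name (see [load_fixture()]), a
#'   `benchmark_fixture`, or a [discrete_bn()] used as the truth.
#' @param algorithms Character vector of learner names (see [learn_bn()]).
#' @param sizes Integer vector of sample sizes.
#' @param reps Replicates per size.
#' @param base_seed Base seed for the dataset seed derivation.
#' @param ... Passed to [learn_bn()] (e.g. `alpha`, `params`).
#' @return A `bn_benchmark`: list with `cells` (per-run tibble: size,
#'   algorithm, rep, seed, the four error components, `error`), `summary`
#'   (per size-algorithm means plus counts), `fixture`, `reps`,
#'   `base_seed`.
#' @export
run_benchmark <- function(fixture, algorithms = c("mmhc", "inter.iamb-tabu"),
                          sizes = c(100, 1000), reps = 10, base_seed = 1, ...) {
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  truth_net <- if (inherits(fixture, "benchmark_fixture")) fixture$network else fixture
  fixture_name <- if (inherits(fixture, "benchmark_fixture")) fixture$name else "custom"
  stopifnot(inherits(truth_net, "discrete_bn"))
  bad <- setdiff(algorithms, hybrid_algorithms)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown algorithm(s): ", paste(bad, collapse = ", ")),
      class = "bnhybrid_error_usage"
    )
  }
  truth <- truth_net$dag
  datasets <- replicate_datasets(truth_net, sizes, reps, base_seed)
  cells <- list()
  for (i in seq_len(nrow(datasets))) {
    d <- datasets$data[[i]]
    for (algo in algorithms) {
      res <- tryCatch(
        {
          fit <- learn_bn(d, algo, ...)
          dag <- if (inherits(fit, "bn_hybrid_fit")) fit$dag else fit
          cmp <- compare_structures(dag, truth)
          cmp$error <- NA_character_
          cmp
        },
        error = function(e) {
          tibble::tibble(
            reversed = NA_integer_, missing = NA_integer_, extra = NA_integer_,
            total = NA_real_, error = conditionMessage(e)
          )
        }
      )
      res$size <- datasets$size[i]
      res$rep <- datasets$rep[i]
      res$seed <- datasets$seed[i]
      res$algorithm <- algo
      cells[[length(cells) + 1]] <- res
    }
  }
  cells <- dplyr::bind_rows(cells)[, c(
    "size", "algorithm", "rep", "seed",
    "reversed", "missing", "extra", "total", "error"
  )]
  n_failed <- sum(!is.na(cells$error))
  if (n_failed > 0) {
    rlang::warn(paste0(n_failed, " learner run(s) failed and were excluded from the means"))
  }
  summary <- cells |>
    dplyr::group_by(.data$size, .data$algorithm) |>
    dplyr::summarise(
      reversed = mean(.data$reversed, na.rm = TRUE),
      missing = mean(.data$missing, na.rm = TRUE),
      extra = mean(.data$extra, na.rm = TRUE),
      total = mean(.data$total, na.rm = TRUE),
      n_ok = sum(is.na(.data$error)),
      n_failed = sum(!is.na(.data$error)),
      .groups = "drop"
    )
  summary$algorithm <- factor(summary$algorithm, levels = algorithms)
  summary <- summary[order(summary$size, summary$algorithm), ]
  summary$algorithm <- as.character(summary$algorithm)
  structure(
    list(
      cells = cells, summary = summary,
      fixture = fixture_name, reps = reps, base_seed = base_seed
    ),
    class = "bn_benchmark"
  )
}

#' Render a benchmark as a plain-text table
#'
#' Prints per sample size and algorithm the mean R(E), M(E), A(E), S(E) over
#' replicates, to two decimals, in the conventional column order.
#'
#' @param x A `bn_benchmark`.
#' @return The formatted lines, invisibly (they are also printed).
#' @export
render_benchmark_table <- function(x) {
  stopifnot(inherits(x, "bn_benchmark"))
  s <- x$summary
  widths <- c(12, 18, 8, 8, 8, 8)
  fmt_row <- function(cells) {
    paste(mapply(formatC, cells, width = widths, flag = "-"), collapse = "")
  }
  lines <- c(
    paste0(
      "Benchmark: ", x$fixture, " (", x$reps,
      " replicates per sample size, base seed ", x$base_seed, ")"
    ),
    fmt_row(c("Sample size", "algorithm", "R(E)", "M(E)", "A(E)", "S(E)")),
    vapply(seq_len(nrow(s)), function(i) {
      fmt_row(c(
        format(s$size[i], scientific = FALSE), s$algorithm[i],
        formatC(s$reversed[i], format = "f", digits = 2),
        formatC(s$missing[i], format = "f", digits = 2),
        formatC(s$extra[i], format = "f", digits = 2),
        formatC(s$total[i], format = "f", digits = 2)
      ))
    }, character(1))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.bn_benchmark <- function(x, ...) {
  render_benchmark_table(x)
  invisible(x)
}

# machine-readable report (External interface shape)
benchmark_to_list <- function(x) {
  list(
    fixture = x$fixture,
    reps = x$reps,
    base_seed = x$base_seed,
    cells = lapply(seq_len(nrow(x$summary)), function(i) {
      s <- x$summary[i, ]
      list(
        size = s$size, algorithm = s$algorithm,
        R = s$reversed, M = s$missing, A = s$extra, S = s$total
      )
    })
  )
}

#' Write a benchmark report as JSON
#'
#' Full-precision means in the documented shape
#' `{"fixture":..., "reps":..., "cells":[{"size":..., "algorithm":...,
#' "R":..., "M":..., "A":..., "S":...}]}`.
#'
#' @param x A `bn_benchmark`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_benchmark_json <- function(x, path) {
  jsonlite::write_json(benchmark_to_list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
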