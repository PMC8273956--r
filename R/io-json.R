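# JSON network dialect: a one-to-one mirror of the in-memory types, handy
# for debugging and language interop. Probabilities are stored flat in
# column-major order (child levels fastest), matching the CPT array layout.

bn_to_list <- function(net, name = "network") {
  list(
    name = name,
    variables = lapply(names(net$levels), function(v) {
      list(name = v, levels = as.list(net$levels[[v]]))
    }),
    edges = lapply(seq_len(nrow(net$dag$edges)), function(i) {
      list(net$dag$edges$from[i], net$dag$edges$to[i])
    }),
    cpts = stats::setNames(lapply(names(net$cpts), function(v) {
      cpt <- net$cpts[[v]]
      list(parents = as.list(cpt$parents), prob = as.vector(cpt$prob))
    }), names(net$cpts))
  )
}

#' Read and write networks in the JSON dialect
#'
#' The JSON dialect mirrors the type model one-to-one: `variables` (name +
#' ordered levels), `edges` (from/to pairs), and `cpts` (declared parent
#' order plus the flat column-major probability vector). It is a loss-less
#' alternative to BIF for debugging.
#'
#' @param net A [discrete_bn()].
#' @param path File path.
#' @param name Network name.
#' @return `write_bn_json()` returns `path` invisibly; `read_bn_json()`
#'   returns a [discrete_bn()].
#' @export
write_bn_json <- function(net, path, name = "network") {
  stopifnot(inherits(net, "discrete_bn"))
  jsonlite::write_json(bn_to_list(net, name), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  levels <- list()
  for (v in obj$variables) {
    levels[[v$name]] <- vapply(v$levels, as.character, character(1))
  }
  edges <- if (length(obj$edges)) {
    data.frame(
      from = vapply(obj$edges, function(e) as.character(e[[1]]), character(1)),
      to = vapply(obj$edges, function(e) as.character(e[[2]]), character(1))
    )
  } else {
    NULL
  }
  dag <- bn_dag(names(levels), edges)
  cpts <- list()
  for (v in names(levels)) {
    spec <- obj$cpts[[v]]
    pars <- vapply(spec$parents, as.character, character(1))
    prob <- vapply(spec$prob, as.numeric, numeric(1))
    cpts[[v]] <- bn_cpt(v, pars, levels, array(
      prob,
      dim = c(length(levels[[v]]), if (length(pars)) lengths(levels[pars]) else NULL)
    ))
  }
  discrete_bn(levels, dag, cpts)
}

#' Run configurations
#'
#' A `run_config` captures everything needed to reproduce a learning run:
#' algorithm, significance level, score, tabu parameters, seed, and paths.
#' Serialisation is strict: reading rejects unknown keys.
#'
#' @param algorithm Learner name (see [learn_bn()]).
#' @param alpha Significance level.
#' @param score Score name.
#' @param tabu A [tabu_params()] list.
#' @param seed Integer seed or `NULL`.
#' @param input,output Optional paths.
#' @param format `"bif"` or `"json"`.
#' @return A `run_config` list.
#' @export
run_config <- function(algorithm = "inter.iamb-tabu", alpha = 0.05,
                       score = "bic", tabu = tabu_params(), seed = NULL,
                       input = NULL, output = NULL, format = "bif") {
  structure(
    list(
      algorithm = algorithm, alpha = alpha, score = score,
      tabu = unclass(tabu), seed = seed, input = input, output = output,
      format = format
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param x A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("algorithm", "alpha", "score", "tabu", "seed", "input", "output", "format")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown run_config key(s): ", paste(unknown, collapse = ", ")),
      class = "bnhybrid_error_parse"
    )
  }
  tb <- obj$tabu
  run_config(
    algorithm = obj$algorithm, alpha = obj$alpha, score = obj$score,
    tabu = tabu_params(tb$tabu_length, tb$max_stagnant, tb$max_iter),
    seed = obj$seed, input = obj$input, output = obj$output,
    format = obj$format %||% "bif"
  )
}
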