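#' Read and write categorical datasets as CSV
#'
#' CSV files have one header row and one column per variable; every cell is
#' a level label. With a `schema` (named list of ordered level vectors) the
#' values are validated and the level order is fixed; without one, levels
#' are inferred in first-appearance order (with a warning, since that order
#' is data-dependent). Values outside the declared levels abort with class
#' `bnhybrid_error_schema`, listing each offending (row, column, value).
#'
#' @param path CSV file path.
#' @param schema Optional named list of level vectors.
#' @return A tibble of factors.
#' @export
read_csv_dataset <- function(path, schema = NULL) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(schema)) {
    extra <- setdiff(names(schema), names(raw))
    if (length(extra) > 0) {
      rlang::abort(paste0("schema names columns absent from the file: ",
        paste(extra, collapse = ", ")), class = "bnhybrid_error_schema")
    }
    violations <- list()
    for (v in names(schema)) {
      bad <- which(!(raw[[v]] %in% schema[[v]]) & !is.na(raw[[v]]))
      if (length(bad) > 0) {
        violations[[length(violations) + 1]] <- tibble::tibble(
          row = bad, column = v, value = raw[[v]][bad]
        )
      }
    }
    if (length(violations) > 0) {
      vio <- dplyr::bind_rows(violations)
      rlang::abort(
        paste0(
          "values outside declared levels (first: row ", vio$row[1], ", column '",
          vio$column[1], "', value '", vio$value[1], "'; ", nrow(vio), " in total)"
        ),
        class = "bnhybrid_error_schema", violations = vio
      )
    }
  }
  as_bn_dataset(raw, levels = schema)
}

#' @rdname read_csv_dataset
#' @param data A data frame of factors.
#' @export
write_csv_dataset <- function(data, path) {
  out <- as.data.frame(lapply(data, as.character), check.names = FALSE,
    stringsAsFactors = FALSE
  )
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Export a graph in DOT format
#'
#' Writes the directed graph of a DAG (or network) for rendering with
#' Graphviz; rendering itself is out of scope.
#'
#' @param g A [bn_dag()] or [discrete_bn()].
#' @param path Output file.
#' @param name Graph name.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path, name = "bn") {
  dag <- if (inherits(g, "discrete_bn")) g$dag else g
  stopifnot(inherits(dag, "bn_dag"))
  quote_id <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c(
    paste0("digraph ", name, " {"),
    paste0("  ", quote_id(dag$nodes), ";"),
    if (nrow(dag$edges) > 0) {
      paste0("  ", quote_id(dag$edges$from), " -> ", quote_id(dag$edges$to), ";")
    },
    "}"
  )
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}
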