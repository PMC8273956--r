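# BIF 0.15 reader/writer (network, variable, probability blocks).
# The tokenizer accepts any non-delimiter run as a word, so level labels
# such as "<18.5" or unicode comparisons survive a round-trip; probabilities
# are written with 12 significant digits.

bif_tokenize <- function(lines) {
  toks <- list()
  for (i in seq_along(lines)) {
    line <- sub("//.*$", "", lines[i])
    pat <- "[]{}()|,;[]|[^]{}()|,;[[:space:]]+"
    m <- gregexpr(pat, line)[[1]]
    if (m[1] == -1) next
    words <- regmatches(line, gregexpr(pat, line))[[1]]
    for (w in words) toks[[length(toks) + 1]] <- list(tok = w, line = i)
  }
  toks
}

bif_parse_error <- function(msg, line) {
  rlang::abort(paste0("BIF parse error at line ", line, ": ", msg),
    class = "bnhybrid_error_parse", line = line
  )
}

#' Read a Bayesian network from a BIF file
#'
#' Parses the Bayesian Interchange Format (BIF 0.15): a `network` block,
#' one `variable` block per node (`type discrete`), and one `probability`
#' block per node giving either a `table` row (roots) or one row per parent
#' configuration. `property` entries are ignored. Malformed input aborts
#' with class `bnhybrid_error_parse` naming the offending line; tables whose
#' rows do not normalise abort with class `bnhybrid_error_validation`.
#'
#' @param path Path to a BIF file.
#' @return A [discrete_bn()].
#' @export
read_bif <- function(path) {
  toks <- bif_tokenize(readLines(path, warn = FALSE, encoding = "UTF-8"))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else list(tok = "<eof>", line = NA)
  nxt <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(what) {
    t <- nxt()
    if (!identical(t$tok, what)) bif_parse_error(paste0("expected '", what, "', got '", t$tok, "'"), t$line)
    t
  }
  skip_block <- function() {
    # consumes a balanced { ... } (network properties etc.)
    expect("{")
    depth <- 1L
    while (depth > 0) {
      t <- nxt()
      if (identical(t$tok, "<eof>")) bif_parse_error("unexpected end of file", t$line)
      if (t$tok == "{") depth <- depth + 1L
      if (t$tok == "}") depth <- depth - 1L
    }
  }

  levels <- list()
  cpt_spec <- list()
  t <- nxt()
  if (t$tok != "network") bif_parse_error("file must start with a network block", t$line)
  nxt() # network name
  skip_block()
  while (peek()$tok != "<eof>") {
    t <- nxt()
    if (t$tok == "variable") {
      name <- nxt()$tok
      expect("{")
      expect("type")
      expect("discrete")
      expect("[")
      n_lev <- suppressWarnings(as.integer(nxt()$tok))
      expect("]")
      expect("{")
      levs <- character(0)
      repeat {
        tt <- nxt()
        if (tt$tok == "}") break
        if (tt$tok != ",") levs <- c(levs, tt$tok)
      }
      expect(";")
      while (peek()$tok != "}") nxt() # skip properties
      expect("}")
      if (is.na(n_lev) || length(levs) != n_lev) {
        bif_parse_error(paste0("variable ", name, ": declared ", n_lev,
          " levels but listed ", length(levs)), t$line)
      }
      levels[[name]] <- levs
    } else if (t$tok == "probability") {
      expect("(")
      child <- nxt()$tok
      pars <- character(0)
      tt <- nxt()
      if (tt$tok == "|") {
        repeat {
          tt <- nxt()
          if (tt$tok == ")") break
          if (tt$tok != ",") pars <- c(pars, tt$tok)
        }
      } else if (tt$tok != ")") {
        bif_parse_error("expected '|' or ')'", tt$line)
      }
      expect("{")
      rows <- list()
      repeat {
        tt <- nxt()
        if (tt$tok == "}") break
        if (tt$tok == "table") {
          vals <- character(0)
          repeat {
            v <- nxt()
            if (v$tok == ";") break
            if (v$tok != ",") vals <- c(vals, v$tok)
          }
          rows[[length(rows) + 1]] <- list(config = NULL, values = vals, line = tt$line)
        } else if (tt$tok == "(") {
          cfg <- character(0)
          repeat {
            v <- nxt()
            if (v$tok == ")") break
            if (v$tok != ",") cfg <- c(cfg, v$tok)
          }
          vals <- character(0)
          repeat {
            v <- nxt()
            if (v$tok == ";") break
            if (v$tok != ",") vals <- c(vals, v$tok)
          }
          rows[[length(rows) + 1]] <- list(config = cfg, values = vals, line = tt$line)
        } else if (tt$tok == "property") {
          while (nxt()$tok != ";") NULL
        } else {
          bif_parse_error(paste0("unexpected token '", tt$tok, "' in probability block"), tt$line)
        }
      }
      cpt_spec[[child]] <- list(parents = pars, rows = rows, line = t$line)
    } else {
      bif_parse_error(paste0("unexpected token '", t$tok, "'"), t$line)
    }
  }

  nodes <- names(levels)
  edges <- list()
  for (child in names(cpt_spec)) {
    for (p in cpt_spec[[child]]$parents) {
      edges[[length(edges) + 1]] <- c(p, child)
    }
  }
  dag <- bn_dag(nodes, if (length(edges)) {
    data.frame(
      from = vapply(edges, `[`, character(1), 1),
      to = vapply(edges, `[`, character(1), 2)
    )
  } else {
    NULL
  })

  cpts <- list()
  for (child in nodes) {
    spec <- cpt_spec[[child]]
    if (is.null(spec)) {
      rlang::abort(paste0("no probability block for variable ", child),
        class = "bnhybrid_error_validation"
      )
    }
    pars <- spec$parents
    r <- length(levels[[child]])
    q <- if (length(pars) > 0) prod(lengths(levels[pars])) else 1L
    prob <- matrix(NA_real_, nrow = r, ncol = q)
    for (row in spec$rows) {
      vals <- suppressWarnings(as.numeric(row$values))
      if (anyNA(vals) || length(vals) != r) {
        bif_parse_error(paste0("bad probability row for ", child), row$line)
      }
      if (is.null(row$config)) {
        if (q != 1L) bif_parse_error(paste0("'table' row for conditioned variable ", child), row$line)
        prob[, 1] <- vals
      } else {
        if (length(row$config) != length(pars)) {
          bif_parse_error(paste0("parent configuration arity mismatch for ", child), row$line)
        }
        col <- 1L
        stride <- 1L
        for (k in seq_along(pars)) {
          idx <- match(row$config[k], levels[[pars[k]]])
          if (is.na(idx)) {
            bif_parse_error(paste0(
              "'", row$config[k], "' is not a level of ", pars[k]
            ), row$line)
          }
          col <- col + (idx - 1L) * stride
          stride <- stride * length(levels[[pars[k]]])
        }
        prob[, col] <- vals
      }
    }
    if (anyNA(prob)) {
      rlang::abort(paste0("probability block for ", child, " leaves configurations undefined"),
        class = "bnhybrid_error_validation"
      )
    }
    cpt <- tryCatch(
      bn_cpt(child, pars, levels,
        array(prob, dim = c(r, if (length(pars)) lengths(levels[pars]) else NULL))
      ),
      error = function(e) {
        rlang::abort(paste0("CPT for ", child, " failed validation: ", conditionMessage(e)),
          class = "bnhybrid_error_validation"
        )
      }
    )
    cpts[[child]] <- cpt
  }
  discrete_bn(levels, dag, cpts)
}

#' Write a Bayesian network as a BIF file
#'
#' @param net A [discrete_bn()].
#' @param path Output file.
#' @param name Network name written in the header.
#' @return `path`, invisibly.
#' @export
write_bif <- function(net, path, name = "network") {
  stopifnot(inherits(net, "discrete_bn"))
  fmt <- function(x) sprintf("%.12g", x)
  out <- c(paste0("network ", name, " {"), "}")
  for (v in names(net$levels)) {
    out <- c(
      out,
      paste0("variable ", v, " {"),
      paste0(
        "  type discrete [ ", length(net$levels[[v]]), " ] { ",
        paste(net$levels[[v]], collapse = ", "), " };"
      ),
      "}"
    )
  }
  for (v in names(net$levels)) {
    cpt <- net$cpts[[v]]
    r <- length(net$levels[[v]])
    header <- if (length(cpt$parents) == 0) {
      paste0("probability ( ", v, " ) {")
    } else {
      paste0("probability ( ", v, " | ", paste(cpt$parents, collapse = ", "), " ) {")
    }
    out <- c(out, header)
    mat <- matrix(as.vector(cpt$prob), nrow = r)
    if (length(cpt$parents) == 0) {
      out <- c(out, paste0("  table ", paste(fmt(mat[, 1]), collapse = ", "), ";"))
    } else {
      cfg <- expand.grid(net$levels[cpt$parents],
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      for (j in seq_len(ncol(mat))) {
        out <- c(out, paste0(
          "  (", paste(unlist(cfg[j, ]), collapse = ", "), ") ",
          paste(fmt(mat[, j]), collapse = ", "), ";"
        ))
      }
    }
    out <- c(out, "}")
  }
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}
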