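# Independent oracles and small builders shared across the test files.

# Brute-force G2: materialise the full x * y * z contingency cube with
# table() and evaluate the definition with explicit loops. Deliberately slow
# and structurally unrelated to the package's counting kernel.
g2_brute <- function(data, x, y, z = character()) {
  if (length(z) == 0) {
    tab <- table(data[[x]], data[[y]])
    cube <- array(tab, dim = c(dim(tab), 1))
  } else {
    zf <- interaction(data[z], drop = FALSE, lex.order = TRUE)
    tab <- table(data[[x]], data[[y]], zf)
    cube <- tab
  }
  stat <- 0
  for (k in seq_len(dim(cube)[3])) {
    slice <- cube[, , k]
    nz <- sum(slice)
    if (nz == 0) next
    for (i in seq_len(nrow(slice))) {
      for (j in seq_len(ncol(slice))) {
        o <- slice[i, j]
        if (o == 0) next
        e <- sum(slice[i, ]) * sum(slice[, j]) / nz
        stat <- stat + 2 * o * log(o / e)
      }
    }
  }
  df <- (nlevels(data[[x]]) - 1) * (nlevels(data[[y]]) - 1) *
    prod(vapply(z, function(v) nlevels(data[[v]]), numeric(1)))
  list(statistic = max(stat, 0), df = df,
    p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

# Posterior oracle: full joint enumeration, filter on evidence, renormalise.
query_brute <- function(net, target, evidence = list()) {
  j <- enumerate_joint(net)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & (j[[v]] == evidence[[v]])
  mass <- sum(j$prob[keep])
  vapply(net$levels[[target]], function(l) {
    sum(j$prob[keep & j[[target]] == l]) / mass
  }, numeric(1))
}

# total log-likelihood of a dataset under a network
train_loglik <- function(net, data) {
  ll <- 0
  for (v in names(net$levels)) {
    cpt <- net$cpts[[v]]
    r <- length(net$levels[[v]])
    mat <- matrix(as.vector(cpt$prob), nrow = r)
    cfg <- rep(1L, nrow(data))
    stride <- 1L
    for (p in cpt$parents) {
      cfg <- cfg + (as.integer(data[[p]]) - 1L) * stride
      stride <- stride * length(net$levels[[p]])
    }
    pr <- mat[cbind(as.integer(data[[v]]), cfg)]
    ll <- ll + sum(log(pr))
  }
  ll
}

# X -> Y -> Z chain of binary variables with strong links
make_chain_net <- function(p_flip = 0.1) {
  lev <- list(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b"))
  dag <- bn_dag(c("X", "Y", "Z"), data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  link <- rbind(c(1 - p_flip, p_flip), c(p_flip, 1 - p_flip))
  discrete_bn(lev, dag, list(
    X = bn_cpt("X", character(0), lev, c(0.5, 0.5)),
    Y = bn_cpt("Y", "X", lev, link),
    Z = bn_cpt("Z", "Y", lev, link)
  ))
}

# X -> Z <- Y collider with X, Y independent
make_collider_net <- function() {
  lev <- list(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b"))
  dag <- bn_dag(c("X", "Y", "Z"), data.frame(from = c("X", "Y"), to = c("Z", "Z")))
  # P(Z = a | X, Y): strong interaction so both parents matter
  pz <- c(0.9, 0.5, 0.5, 0.1) # (X,Y) = (a,a), (b,a), (a,b), (b,b)
  discrete_bn(lev, dag, list(
    X = bn_cpt("X", character(0), lev, c(0.5, 0.5)),
    Y = bn_cpt("Y", character(0), lev, c(0.5, 0.5)),
    Z = bn_cpt("Z", c("X", "Y"), lev, rbind(pz, 1 - pz))
  ))
}

# n mutually independent binary columns
make_independent_data <- function(n, p = 4, seed = 1) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(p), function(i) {
      factor(sample(c("u", "v"), n, replace = TRUE), levels = c("u", "v"))
    })
    names(out) <- paste0("V", seq_len(p))
    tibble::as_tibble(out)
  })
}

sprinkler_net <- function() load_fixture("sprinkler4")$network

# permute a CPT's probability array to another CPT's (child, parent) axis
# order so entries can be compared elementwise
align_cpt_prob <- function(cpt, ref) {
  perm <- match(names(dimnames(ref$prob)), names(dimnames(cpt$prob)))
  aperm(cpt$prob, perm)
}
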