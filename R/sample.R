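#' Forward (ancestral) sampling from a discrete Bayesian network
#'
#' Draws `n` complete observations by visiting nodes in topological order
#' and sampling each from its CPT row given the already-sampled parents.
#' With a `seed`, sampling is exactly reproducible and leaves the caller's
#' RNG state untouched; the generator is R's default Mersenne-Twister, which
#' is part of the reproducibility contract.
#'
#' @param net A [discrete_bn()].
#' @param n Number of observations (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble of factors, columns in the network's declaration order.
#' @examples
#' net <- load_fixture("sprinkler4")$network
#' forward_sample(net, 5, seed = 1)
#' @export
forward_sample <- function(net, n, seed = NULL) {
  stopifnot(inherits(net, "discrete_bn"), n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, forward_sample(net, n, seed = NULL)))
  }
  ord <- topological_order(net$dag)
  cols <- vector("list", length(net$levels))
  names(cols) <- names(net$levels)
  codes <- matrix(0L, nrow = n, ncol = length(net$levels),
    dimnames = list(NULL, names(net$levels))
  )
  for (v in ord) {
    cpt <- net$cpts[[v]]
    r <- length(net$levels[[v]])
    pa <- cpt$parents
    prob2d <- matrix(as.vector(cpt$prob), nrow = r)
    if (length(pa) == 0) {
      cfg <- rep(1L, n)
    } else {
      cfg <- rep(1L, n)
      stride <- 1L
      for (p in pa) {
        cfg <- cfg + (codes[, p] - 1L) * stride
        stride <- stride * length(net$levels[[p]])
      }
    }
    u <- stats::runif(n)
    out <- integer(n)
    for (j in unique(cfg)) {
      rows <- which(cfg == j)
      cum <- cumsum(prob2d[, j])
      out[rows] <- 1L + findInterval(u[rows], cum[-r])
    }
    codes[, v] <- out
  }
  res <- tibble::as_tibble(as.data.frame(codes))
  for (v in names(net$levels)) {
    res[[v]] <- factor(net$levels[[v]][codes[, v]], levels = net$levels[[v]])
  }
  res
}

#' Replicated simulation datasets across sample sizes
#'
#' Generates `reps` independent datasets per sample size, mirroring the
#' benchmark protocol of repeating each sample size 10 times. Seeds are
#' derived deterministically -- `seed = base_seed * 10000 + size_index * 100
#' + rep` -- so any cell of the design can be regenerated in isolation; the
#' derivation rule is part of the public contract.
#'
#' @param net A [discrete_bn()].
#' @param sizes Integer vector of sample sizes.
#' @param reps Replicates per size (>= 1).
#' @param base_seed Integer base seed.
#' @return A tibble with columns `size`, `rep`, `seed`, and a `data`
#'   list-column of sampled tibbles.
#' @export
replicate_datasets <- function(net, sizes, reps, base_seed = 1) {
  stopifnot(length(sizes) >= 1, reps >= 1)
  grid <- tidyr::expand_grid(
    size_index = seq_along(sizes),
    rep = seq_len(reps)
  )
  grid$size <- sizes[grid$size_index]
  grid$seed <- base_seed * 10000 + grid$size_index * 100 + grid$rep
  grid$data <- purrr::map2(grid$size, grid$seed, function(s, sd) {
    forward_sample(net, s, seed = sd)
  })
  grid[, c("size", "rep", "seed", "data")]
}
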