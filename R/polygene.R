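#' Discretized polygene grid
#'
#' The normally distributed polygenic component is approximated by the
#' hypergeometric polygenic model: an individual carries `2k` exchangeable
#' binary "polygene alleles", so the allele count follows Binomial(2k, 1/2) in
#' the population and the standardized level for count `i` is
#' `(i - k) / sqrt(k / 2)`, giving mean 0 and variance 1 exactly. Transmission
#' samples k alleles without replacement from each parent's 2k, which keeps
#' the population distribution invariant under random mating and makes the
#' offspring mean equal the midparent mean.
#'
#' @param n_levels odd number of grid levels `2k + 1`.
#' @return An object of class `canpros_polygrid` with fields `k`, `values`,
#'   `probs`, and the transmission array `trans[father, mother, child]`.
#' @export
polygene_grid <- function(n_levels = 7L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L || n_levels %% 2L == 0L)
    stop("n_levels must be an odd positive integer")
  k <- (n_levels - 1L) %/% 2L
  if (k == 0L) {
    # degenerate single-level grid: level 0 with certainty
    return(structure(list(k = 0L, n = 1L, values = 0, probs = 1,
                          trans = array(1, c(1, 1, 1))),
                     class = "canpros_polygrid"))
  }
  counts <- 0:(2L * k)
  probs <- stats::dbinom(counts, 2L * k, 0.5)
  values <- (counts - k) / sqrt(k / 2)
  trans <- polygene_transmission(k)
  structure(list(k = k, n = n_levels, values = values, probs = probs,
                 trans = trans),
            class = "canpros_polygrid")
}

# trans[f, m, c]: P(child count = c-1 | father count f-1, mother count m-1)
# child count = (k drawn from father's 2k alleles) + (k drawn from mother's).
polygene_transmission <- function(k) {
  n <- 2L * k + 1L
  # gamete distribution: h ~ Hypergeometric(drawn k of 2k, i of them "high")
  gam <- matrix(0, n, k + 1L)  # gam[i+1, h+1] = P(h | parent count i)
  for (i in 0:(2L * k))
    gam[i + 1L, ] <- stats::dhyper(0:k, i, 2L * k - i, k)
  trans <- array(0, c(n, n, n))
  for (f in 1:n) for (m in 1:n) {
    child <- rep(0, n)
    for (h in 0:k) {
      idx <- h + (0:k) + 1L
      child[idx] <- child[idx] + gam[f, h + 1L] * gam[m, ]
    }
    trans[f, m, ] <- child
  }
  trans
}
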