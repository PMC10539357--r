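#' Fritz-Purvis D statistic for phylogenetic clustering of a binary trait
#'
#' The observed clumping score d_obs is the sum of sister-clade differences
#' in the trait: nodal values are estimated bottom-up as the mean of
#' daughter values, and each node contributes the absolute difference
#' between its two daughters (for a polytomy, the sum of absolute daughter
#' deviations from the nodal mean). d_obs is scaled between two simulated
#' nulls matched to the observed prevalence:
#'
#'   D = (d_obs - mean(d_BM)) / (mean(d_random) - mean(d_BM))
#'
#' where d_random comes from permuting tip labels (phylogenetically random,
#' E(D) = 1) and d_BM from thresholding Brownian-motion simulations so that
#' exactly the observed number of tips score 1 (clumped as under Brownian
#' evolution, E(D) = 0). Used here to test whether species missing trait
#' data are phylogenetically clustered.
#'
#' @param tree a `phylo`.
#' @param indicator named binary (0/1 or logical) vector per tip, e.g.
#'   `TRUE` = trait value missing.
#' @param n_perm number of draws for each null (>= 100).
#' @param seed optional integer seed for the permutation/simulation draws.
#' @return list with `d` (the D statistic), `d_obs`, `mean_d_random`,
#'   `mean_d_bm`, `p_d_less_1` (probability of observing as small a d under
#'   the random null) and `p_d_greater_0` (probability of as large a d
#'   under the Brownian null).
#' @export
missingness_d <- function(tree, indicator, n_perm = 999L, seed = NULL) {
  validate_phylo(tree)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  x <- as.numeric(indicator)[match(tree$tip.label, names(indicator))]
  if (anyNA(x)) stop("indicator must name every tip", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("indicator must be binary", call. = FALSE)
  n1 <- sum(x)
  n <- length(x)
  if (n1 == 0L || n1 == n) {
    stop("indicator has a single class; D is undefined", call. = FALSE)
  }
  d_obs <- sister_diff_sum(tree, x)
  d_rand <- vapply(seq_len(n_perm), function(i) {
    sister_diff_sum(tree, sample(x))
  }, numeric(1))
  one_regime <- uniform_painting(tree, sigma2 = 1)
  d_bm <- vapply(seq_len(n_perm), function(i) {
    b <- simulate_bm_traits(tree, one_regime, root_state = 0)
    # threshold toward the observed prevalence: top n1 tips score 1
    thr <- as.numeric(rank(-b, ties.method = "random") <= n1)
    sister_diff_sum(tree, thr)
  }, numeric(1))
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  list(d = D, d_obs = d_obs,
       mean_d_random = mean(d_rand), mean_d_bm = mean(d_bm),
       p_d_less_1 = (1 + sum(d_rand <= d_obs)) / (n_perm + 1),
       p_d_greater_0 = (1 + sum(d_bm >= d_obs)) / (n_perm + 1))
}

# Sum of sister-clade differences with nodal values estimated as the mean
# of daughter values (bottom-up pass).
sister_diff_sum <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  children_full <- vector("list", nnode)
  children_full[as.integer(names(children))] <- children
  depths <- ape::node.depth.edgelength(tree)
  val <- numeric(nnode)
  val[seq_len(ntip)] <- x
  d <- 0
  internal <- ntip + seq_len(tree$Nnode)
  for (node in internal[order(depths[internal], decreasing = TRUE)]) {
    kids <- children_full[[node]]
    v <- val[kids]
    val[node] <- mean(v)
    d <- d + if (length(v) == 2L) abs(v[1L] - v[2L]) else
      sum(abs(v - mean(v)))
  }
  d
}
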