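#' Equal-splits (ES) and inverse equal-splits (DR) tip rates
#'
#' For tip i with root-to-tip edge lengths l_1 (pendant) ... l_N (rootmost),
#' the equal-splits measure is ES_i = sum_j l_j * 2^-(j-1) and the DR
#' speciation-rate statistic is its inverse, DR_i = 1/ES_i. Weights halve at
#' each split moving rootward starting from the pendant edge; at a
#' k-furcation the weight is divided by 2^(k-1), i.e. a polytomy counts as
#' (k - 1) simultaneous splits.
#'
#' @param tree a `phylo` with strictly positive branch lengths.
#' @return data frame with columns `species`, `es` (My) and `dr` (My^-1),
#'   one row per tip, in tip order.
#' @export
equal_splits_rate <- function(tree) {
  validate_phylo(tree)
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  nchild <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)

  es <- vapply(seq_len(ntip), function(tip) {
    w <- 1
    node <- tip
    acc <- 0
    while (parent[node] != 0L) {
      acc <- acc + w * elen[node]
      # crossing the parent node rootward: k-furcation = (k - 1) splits
      w <- w / 2^(nchild[parent[node]] - 1L)
      node <- parent[node]
    }
    acc
  }, numeric(1))

  data.frame(species = tree$tip.label, es = es, dr = 1 / es,
             stringsAsFactors = FALSE)
}

#' Node-density tip speciation rate
#'
#' The number of internal nodes on the root-to-tip path (root included,
#' with a k-furcation counted as k - 1 splits) divided by the root-to-tip
#' distance. A fast, estimator-independent alternative to DR used for
#' cross-method concordance checks.
#'
#' @param tree a `phylo` with strictly positive branch lengths.
#' @return data frame with columns `species` and `node_density` (My^-1).
#' @export
node_density_rate <- function(tree) {
  validate_phylo(tree)
  ntip <- length(tree$tip.label)
  nchild <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  if (any(depths <= 0)) stop("zero root-to-tip distance", call. = FALSE)
  paths <- root_to_tip_nodes(tree)
  nsplit <- vapply(paths, function(p) sum(nchild[p] - 1L), numeric(1))
  data.frame(species = tree$tip.label, node_density = nsplit / depths,
             stringsAsFactors = FALSE)
}

#' Combined per-tip speciation-rate table
#'
#' Joins the equal-splits/DR and node-density estimators into the table
#' consumed by the assemblage module, and checks the DR * ES = 1 identity.
#'
#' @param tree a `phylo` object.
#' @return data frame with columns `species`, `es`, `dr`, `node_density`.
#' @export
tip_rates <- function(tree) {
  es <- equal_splits_rate(tree)
  nd <- node_density_rate(tree)
  stopifnot(identical(es$species, nd$species))
  stopifnot(max(abs(es$dr * es$es - 1)) < 1e-12)
  cbind(es, node_density = nd$node_density)
}
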