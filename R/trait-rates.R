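#' Log10-transform the body-size column of a trait table
#'
#' Body size is log10-transformed before rate estimation, the standard
#' treatment for size data. The operation records a `log10_transformed`
#' attribute and refuses to run twice on the same table.
#'
#' @param traits data frame with a `species` column and trait columns.
#' @param column name of the body-size column.
#' @return the trait table with the column replaced by its log10 and the
#'   transform recorded in `attr(, "log10_transformed")`.
#' @export
log10_body_size <- function(traits, column = "body_size") {
  stopifnot(is.data.frame(traits), column %in% names(traits))
  if (column %in% attr(traits, "log10_transformed")) {
    stop("column '", column, "' is already log10-transformed", call. = FALSE)
  }
  x <- traits[[column]]
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    stop("non-positive body size for species: ",
         paste(traits$species[bad], collapse = ", "), call. = FALSE)
  }
  traits[[column]] <- log10(x)
  attr(traits, "log10_transformed") <-
    c(attr(traits, "log10_transformed"), column)
  traits
}

#' Per-tip trait-evolution-rate proxy from terminal contrasts
#'
#' For each tip, ancestral values are obtained by the standard Felsenstein
#' pruning (contrasts) down-pass and the tip's rate is the square of its
#' standardized terminal contrast: s_i = (x_i - x_sib) / sqrt(v_i + v_sib),
#' where x_sib and v_sib are the pruned value and adjusted branch length of
#' the tip's sibling subtree (for a polytomy, the precision-weighted
#' combination of the other daughters). Under single-rate Brownian motion
#' each s_i^2 has expectation sigma^2, making the tip mean an unbiased
#' rate proxy; regime differences in Brownian rate show up as differences
#' in mean tip rate.
#'
#' @param tree a `phylo`.
#' @param x named numeric vector of complete trait values for every tip.
#' @return data frame `species`, `rate` (trait-units^2 My^-1, >= 0).
#' @export
tip_trait_rate <- function(tree, x) {
  validate_phylo(tree)
  if (anyNA(x)) {
    stop("trait has missing values; impute first (impute_traits_bm)",
         call. = FALSE)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("no trait value for tips: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pr <- pruning_pass(tree, x[tree$tip.label])
  ntip <- length(tree$tip.label)
  rate <- vapply(seq_len(ntip), function(tip) {
    p <- pr$parent[tip]
    sibs <- setdiff(pr$children[[p]], tip)
    prec <- sum(1 / pr$vhat[sibs])
    x_sib <- sum(pr$xhat[sibs] / pr$vhat[sibs]) / prec
    v_sib <- 1 / prec
    ((pr$xhat[tip] - x_sib)^2) / (pr$vhat[tip] + v_sib)
  }, numeric(1))
  data.frame(species = tree$tip.label, rate = rate, stringsAsFactors = FALSE)
}

# Standardized phylogenetically independent contrasts by the pruning
# algorithm; a k-furcation yields k - 1 contrasts by sequential pairing
# of its daughters (equals the standard contrasts on binary trees).
bm_contrasts <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode); elen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  children_full <- vector("list", nnode)
  children_full[as.integer(names(children))] <- children
  xhat <- numeric(nnode); vhat <- numeric(nnode)
  xhat[seq_len(ntip)] <- x[tree$tip.label]
  vhat[seq_len(ntip)] <- elen[seq_len(ntip)]
  depths <- ape::node.depth.edgelength(tree)
  internal <- ntip + seq_len(tree$Nnode)
  contrasts <- numeric(0)
  for (node in internal[order(depths[internal], decreasing = TRUE)]) {
    kids <- children_full[[node]]
    cx <- xhat[kids[1L]]; cv <- vhat[kids[1L]]
    for (k in kids[-1L]) {
      contrasts <- c(contrasts,
                     (cx - xhat[k]) / sqrt(cv + vhat[k]))
      cx <- (cx / cv + xhat[k] / vhat[k]) / (1 / cv + 1 / vhat[k])
      cv <- cv * vhat[k] / (cv + vhat[k])
    }
    xhat[node] <- cx
    vhat[node] <- elen[node] + cv
  }
  contrasts
}

# Felsenstein pruning pass. Returns, for every node, the pruned (GLS)
# value xhat and adjusted branch length vhat (= own branch + pooled
# daughter variance; for tips, the pendant branch), plus parent pointers
# and children lists.
pruning_pass <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode); elen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  children_full <- vector("list", nnode)
  children_full[as.integer(names(children))] <- children
  xhat <- numeric(nnode); vhat <- numeric(nnode)
  xhat[seq_len(ntip)] <- x
  vhat[seq_len(ntip)] <- elen[seq_len(ntip)]
  depths <- ape::node.depth.edgelength(tree)
  internal <- ntip + seq_len(tree$Nnode)
  for (node in internal[order(depths[internal], decreasing = TRUE)]) {
    kids <- children_full[[node]]
    prec <- 1 / vhat[kids]
    xhat[node] <- sum(xhat[kids] * prec) / sum(prec)
    vhat[node] <- elen[node] + 1 / sum(prec)
  }
  list(xhat = xhat, vhat = vhat, parent = parent,
       children = children_full)
}

#' Per-tip rates for every trait column
#'
#' @param tree a `phylo`.
#' @param traits complete trait table (`species` + trait columns).
#' @return data frame `species` plus one `rate_<trait>` column per trait.
#' @export
tip_trait_rates_table <- function(tree, traits) {
  stopifnot(is.data.frame(traits), "species" %in% names(traits))
  trait_cols <- setdiff(names(traits), "species")
  out <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    x <- stats::setNames(traits[[tc]], traits$species)
    out[[paste0("rate_", tc)]] <-
      tip_trait_rate(tree, x)$rate[match(out$species, tree$tip.label)]
  }
  out
}
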