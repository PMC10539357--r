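#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the structural
#' contract every downstream rate estimator relies on: a single rooted tree,
#' branch lengths present on every edge and strictly positive (a zero-length
#' root stem is tolerated), and unique tip labels. Polytomies are accepted;
#' rate estimators treat a k-furcation as (k - 1) simultaneous splits.
#'
#' Branch lengths are mandatory because all rates downstream carry per-My
#' units; there is no unit-length defaulting.
#'
#' @param text a Newick string (must end in `;`).
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("malformed Newick: ", n_open, " '(' vs ", n_close, " ')' ",
         "(first imbalance near character ",
         newick_imbalance_pos(text), ")", call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: no terminating ';' (string has ",
         nchar(text), " characters)", call. = FALSE)
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick: could not be parsed as a single tree",
         call. = FALSE)
  }
  validate_phylo(tree)
  tree
}

# 1-based character position where the parenthesis nesting first goes
# negative, or position of the last '(' if the string ends unbalanced.
newick_imbalance_pos <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  last_open <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      last_open <- i
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (is.na(last_open)) 1L else last_open
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks the invariants assumed throughout: class `phylo`, at least two
#' tips, unique tip labels, branch lengths present and positive on all
#' edges.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2L) stop("tree has fewer than 2 tips",
                                        call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("branch lengths are missing (branch lengths are required)",
         call. = FALSE)
  }
  bad <- !is.finite(tree$edge.length)
  if (any(bad)) {
    stop(sum(bad), " edge(s) have missing/non-finite branch lengths ",
         "(branch lengths are required on every edge)", call. = FALSE)
  }
  if (any(tree$edge.length <= 0)) {
    stop(sum(tree$edge.length <= 0),
         " edge(s) have non-positive branch lengths", call. = FALSE)
  }
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' Emits branch lengths with 9 significant digits so that a
#' parse-write-parse round trip preserves lengths to within 1e-9
#' relative error.
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `""` the string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = "") {
  ape::write.tree(tree, file = file, digits = 9)
}

#' Prune a phylogeny to a set of taxa, preserving tip depths
#'
#' Keeps exactly the requested tips, suppresses resulting degree-2 nodes by
#' summing branch lengths, and stores the stem from the original root to the
#' new root in `root.edge` so that root-to-tip distances of retained tips
#' are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s) in 'keep': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("'keep' must contain at least 2 tips",
                              call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  depths <- ape::node.depth.edgelength(tree)
  pruned <- ape::keep.tip(tree, keep)
  # keep.tip re-roots at the MRCA of `keep`; restore the stem so that
  # root-to-tip distances keep their original values.
  mrca_old <- ape::getMRCA(tree, keep)
  stem <- depths[mrca_old] + if (is.null(tree$root.edge)) 0 else tree$root.edge
  if (stem > 0) pruned$root.edge <- stem
  pruned
}

#' Test whether a tree is ultrametric, reporting the deviation
#'
#' All root-to-tip distances are compared to their maximum; the tree is
#' called ultrametric when the largest relative shortfall is within
#' `rel_tol`.
#'
#' @param tree a `phylo` object.
#' @param rel_tol relative tolerance (fraction of the maximum depth).
#' @return list with `ultrametric` (logical) and `max_deviation`
#'   (largest relative shortfall, `(max - min) / max`).
#' @export
is_ultrametric_dev <- function(tree, rel_tol = 1e-6) {
  validate_phylo(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  dev <- (max(depths) - min(depths)) / max(depths)
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

# Ordered root-to-tip paths. Returns, per tip, the vector of node ids from
# the root down to the tip's parent (internal nodes on the path).
root_to_tip_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- parent[tip]
    while (node != 0L) {
      path <- c(node, path)
      node <- parent[node]
    }
    path
  })
}
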