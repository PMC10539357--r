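#' Assemble a dataset from files
#'
#' Reads the four pipeline inputs: a Newick tree, a TSV trait table
#' (`species` column + trait columns, empty/NA = missing), an incidence
#' table in wide (first column basin id, one column per species, 0/1) or
#' long (`basin`, `species`) form, and a basin covariate TSV (`basin`,
#' `x`, `y`, `elevation`, `temperature`, `area`, `runoff`,
#' `stream_gradient`, `soil_*` columns). Species are matched to the tree:
#' the tree is pruned to the species present in both the trait table and
#' the incidence matrix.
#'
#' @param tree_file,traits_file,incidence_file,basins_file paths.
#' @return a `basin_dataset`-shaped list usable by [analyze_dataset()].
#' @export
read_dataset <- function(tree_file, traits_file, incidence_file,
                         basins_file) {
  tree <- parse_newick(paste(readLines(tree_file), collapse = ""))
  traits <- utils::read.delim(traits_file, stringsAsFactors = FALSE)
  stopifnot("species" %in% names(traits))
  inc_raw <- utils::read.delim(incidence_file, stringsAsFactors = FALSE,
                               check.names = FALSE)
  inc <- if (ncol(inc_raw) == 2L &&
             all(c("basin", "species") %in% names(inc_raw))) {
    tab <- table(inc_raw$basin, inc_raw$species)
    m <- matrix(as.integer(tab > 0), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    m
  } else {
    m <- as.matrix(inc_raw[, -1L, drop = FALSE])
    rownames(m) <- inc_raw[[1L]]
    storage.mode(m) <- "integer"
    m
  }
  basins <- utils::read.delim(basins_file, stringsAsFactors = FALSE)
  stopifnot("basin" %in% names(basins))

  keep <- Reduce(intersect, list(tree$tip.label, traits$species,
                                 colnames(inc)))
  if (length(keep) < 3L) {
    stop("fewer than 3 species shared by tree, traits and incidence",
         call. = FALSE)
  }
  tree <- prune_to_taxa(tree, keep)
  traits <- traits[traits$species %in% keep, , drop = FALSE]
  inc <- inc[, keep, drop = FALSE]
  list(tree = tree, traits = traits, incidence = inc, basins = basins,
       config = list(seed = NA_integer_))
}
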