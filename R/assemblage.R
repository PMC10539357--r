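#' Summarize a per-species value over the assemblage of each basin
#'
#' Applies the chosen statistic to the values of the species present in
#' each basin. With `weights` (per species, e.g. inverse range size to damp
#' wide-ranging species) the mean becomes a weighted mean; weights are
#' ignored by the order statistics. Basins with no species are dropped with
#' a warning.
#'
#' @param incidence binary basins x species matrix with dimnames.
#' @param values named numeric vector, one value per species.
#' @param stat one of `"mean"`, `"median"`, `"min"`, `"max"`.
#' @param weights optional named positive weights per species.
#' @return named numeric vector, one entry per (occupied) basin.
#' @export
summarize_rates_by_basin <- function(incidence, values,
                                     stat = c("mean", "median", "min",
                                              "max"),
                                     weights = NULL) {
  stat <- match.arg(stat)
  check_incidence(incidence)
  lacking <- setdiff(colnames(incidence), names(values))
  if (length(lacking)) {
    stop("species without a value: ", paste(lacking, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(weights)) {
    lacking_w <- setdiff(colnames(incidence), names(weights))
    if (length(lacking_w) || any(weights[colnames(incidence)] <= 0)) {
      stop("weights must be positive and cover every species",
           call. = FALSE)
    }
  }
  v <- values[colnames(incidence)]
  w <- if (is.null(weights)) NULL else weights[colnames(incidence)]
  occ <- rowSums(incidence) > 0
  if (any(!occ)) {
    warning(sum(!occ), " empty basin(s) excluded from summaries")
  }
  out <- apply(incidence[occ, , drop = FALSE], 1L, function(row) {
    present <- row > 0
    vi <- v[present]
    switch(stat,
           mean = if (is.null(w)) mean(vi) else
             sum(vi * w[present]) / sum(w[present]),
           median = stats::median(vi),
           min = min(vi),
           max = max(vi))
  })
  out
}

#' Species richness and area-corrected species density per basin
#'
#' SR is the incidence row sum; species density follows the species-area
#' power function SD = SR / A^z with scaling exponent z (empirically
#' 0.25-0.50).
#'
#' @param incidence binary basins x species matrix.
#' @param areas named basin areas (m^2), > 0.
#' @param z species-area exponent in `[0, 1]`.
#' @return data frame `basin`, `sr`, `sd`.
#' @export
richness_and_density <- function(incidence, areas, z = 0.25) {
  check_incidence(incidence)
  stopifnot(z >= 0, z <= 1)
  a <- areas[rownames(incidence)]
  if (anyNA(a)) stop("areas must name every basin", call. = FALSE)
  if (any(a <= 0)) stop("non-positive basin area", call. = FALSE)
  sr <- rowSums(incidence)
  data.frame(basin = rownames(incidence), sr = sr, sd = sr / a^z,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shannon diversity of soil/substrate types
#'
#' H = -sum p_k log p_k (nats) over types with nonzero counts.
#'
#' @param counts matrix (basins x types) or vector of nonnegative counts.
#' @return numeric vector of H, one per row (named if `counts` has
#'   rownames).
#' @export
shannon_soil_diversity <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative soil counts", call. = FALSE)
  if (any(rowSums(counts) == 0)) {
    stop("all-zero soil count row", call. = FALSE)
  }
  h <- apply(counts, 1L, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p))
  })
  stats::setNames(h, rownames(counts))
}

#' Filter basins and exclude taxa/basins from an incidence matrix
#'
#' Applies, in order: removal of listed taxa, removal of listed basins, a
#' minimum-richness filter on the remaining basins, and removal of species
#' left with no occurrence. A provenance log of exactly what was dropped is
#' attached as `attr(, "provenance")`.
#'
#' @param incidence binary basins x species matrix.
#' @param min_species basins with fewer species are dropped.
#' @param drop_taxa,drop_basins identifiers to exclude (e.g. a burst clade
#'   such as Orestias, or basins it dominates).
#' @return the filtered incidence matrix.
#' @export
filter_and_exclude <- function(incidence, min_species = 0L,
                               drop_taxa = character(),
                               drop_basins = character()) {
  check_incidence(incidence)
  stopifnot(min_species >= 0)
  bad_t <- setdiff(drop_taxa, colnames(incidence))
  bad_b <- setdiff(drop_basins, rownames(incidence))
  if (length(bad_t) || length(bad_b)) {
    stop("unknown identifiers in drop lists: ",
         paste(c(bad_t, bad_b), collapse = ", "), call. = FALSE)
  }
  out <- incidence[!rownames(incidence) %in% drop_basins,
                   !colnames(incidence) %in% drop_taxa, drop = FALSE]
  low <- rowSums(out) < min_species
  dropped_low <- rownames(out)[low]
  out <- out[!low, , drop = FALSE]
  empty_sp <- colSums(out) == 0
  dropped_sp <- colnames(out)[empty_sp]
  out <- out[, !empty_sp, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L) {
    stop("filtering emptied the incidence matrix", call. = FALSE)
  }
  attr(out, "provenance") <- list(
    dropped_taxa = as.character(drop_taxa),
    dropped_basins = as.character(drop_basins),
    dropped_low_richness = dropped_low,
    dropped_unoccupied_species = dropped_sp,
    min_species = min_species)
  out
}

#' Inverse range-size weights
#'
#' w_s = 1 / (number of basins occupied by species s); used to damp the
#' influence of wide-ranging species on basin means.
#'
#' @param incidence binary basins x species matrix.
#' @return named weight vector per species.
#' @export
inverse_range_weights <- function(incidence) {
  check_incidence(incidence)
  occ <- colSums(incidence)
  if (any(occ == 0)) stop("species with no occurrence", call. = FALSE)
  1 / occ
}

check_incidence <- function(incidence) {
  if (!is.matrix(incidence) || is.null(rownames(incidence)) ||
      is.null(colnames(incidence))) {
    stop("incidence must be a matrix with basin rownames and species ",
         "colnames", call. = FALSE)
  }
  if (!all(incidence %in% c(0, 1))) {
    stop("incidence must be binary", call. = FALSE)
  }
  invisible(incidence)
}
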