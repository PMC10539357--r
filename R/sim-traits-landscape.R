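#' Simulate Brownian-motion trait values under a regime painting
#'
#' Trait increments along each branch are drawn from
#' Normal(0, sigma2_regime * branch_length) with the Brownian rate of the
#' branch's painted regime; tip values are the root state plus the summed
#' increments along the root-to-tip path. A mid-branch regime change is not
#' modelled: the whole branch evolves at its painted (tipward) rate.
#'
#' Uses the current R RNG stream.
#'
#' @param tree a `phylo`.
#' @param painting a `regime_painting` covering every edge of `tree`.
#' @param root_state trait value at the root.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_traits <- function(tree, painting, root_state = 0) {
  validate_phylo(tree)
  if (!inherits(painting, "regime_painting") ||
      length(painting$edge_regime) != nrow(tree$edge)) {
    stop("painting does not cover every branch of the tree", call. = FALSE)
  }
  sigma2 <- painting$regimes$sigma2[painting$edge_regime]
  if (anyNA(sigma2)) stop("unpainted branch (unknown regime id)",
                          call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  ord <- order(depths[tree$edge[, 1L]])  # parents before children
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  state <- numeric(nnode)
  state[ntip + 1L] <- root_state
  for (e in ord) {
    state[tree$edge[e, 2L]] <- state[tree$edge[e, 1L]] + inc[e]
  }
  stats::setNames(state[seq_len(ntip)], tree$tip.label)
}

#' Simulate an elevation-structured landscape and species occupancy
#'
#' Basins sit on a near-square 2-D lattice of centroids with an elevation
#' gradient along the y axis. Covariates are generated with stated noise:
#' temperature decreases with elevation (lapse rate) and trends along the
#' orthogonal (latitudinal) lattice axis, stream gradient
#' increases with it, area is log-normal, runoff Gaussian, and soil-type
#' counts multinomial with basin-specific random mixtures (so Shannon soil
#' diversity is pure noise). Occupancy couples geography to the regime
#' structure through clade cohesion for burst clades: each fast regime
#' (rate above `fast_mult_threshold` times the base rate) gets a regional
#' anchor basin drawn with log-weights
#' `pref_strength * pref_scale * z(elevation)`, and its species seed
#' their ranges near that anchor (exponential distance decay, scale
#' `cohesion_scale`, plus a 10% uniform floor). Background (non-burst)
#' species seed independently with a mild lowland bias
#' (`-lowland_affinity * z(elevation)`): burst clades are montane
#' specialists, the widespread background fauna is richest in the
#' lowlands; `pref_strength` scales both affinities, so strength 0 turns
#' all rate-geography coupling off;
#' every species occupies its log-normally drawn number of basins nearest
#' to its seed (a contiguous range). Because burst regimes are few,
#' anchor placement leaves regional variation in assemblage composition
#' that elevation does not explain - the localized-burst geography seen
#' in real faunas. Occupancy draws leaving any basin empty are redone up
#' to `occupancy_retries`.
#'
#' Uses the current R RNG stream.
#'
#' @param tree a `phylo` (extant species = tips).
#' @param painting a `regime_painting` giving each tip's true speciation
#'   regime.
#' @param config a [sim_config()].
#' @return list with `basins` (data frame: `basin`, `x`, `y`, `elevation`,
#'   `temperature`, `area`, `runoff`, `stream_gradient`, `soil_1` ...) and
#'   `incidence` (binary basins x species matrix with dimnames).
#' @export
simulate_landscape_and_ranges <- function(tree, painting, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_basins
  if (n < 10L) stop("n_basins must be >= 10", call. = FALSE)
  nx <- ceiling(sqrt(n))
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ceiling(n / nx)))
  grid <- grid[seq_len(n), ]
  x <- grid$x + stats::runif(n, -0.05, 0.05)
  y <- grid$y + stats::runif(n, -0.05, 0.05)
  elev <- pmax(0, config$elevation_range * (y - min(y)) /
                 max(y - min(y)) + stats::rnorm(n, 0, config$elev_noise_sd))
  # latitudinal trend along x plus elevational lapse
  temp <- config$temp_sea_level - config$temp_lapse * elev / 1000 +
    config$temp_lat_slope * (x - mean(x)) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  area <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  runoff <- pmax(0, stats::rnorm(n, config$runoff_mean, config$runoff_sd))
  grad <- pmax(0, config$gradient_slope * elev +
                 stats::rnorm(n, 0, config$gradient_noise_sd))
  soil <- t(vapply(seq_len(n), function(i) {
    p <- stats::rgamma(config$n_soil_types, shape = 1)
    as.integer(stats::rmultinom(1L, config$soil_total, p / sum(p)))
  }, integer(config$n_soil_types)))
  colnames(soil) <- paste0("soil_", seq_len(config$n_soil_types))

  basins <- data.frame(basin = paste0("b", seq_len(n)), x = x, y = y,
                       elevation = elev, temperature = temp, area = area,
                       runoff = runoff, stream_gradient = grad,
                       stringsAsFactors = FALSE)
  basins <- cbind(basins, as.data.frame(soil))

  truth <- tip_truth(tree, painting)
  zelev <- (elev - mean(elev)) / stats::sd(elev)
  dmat <- as.matrix(stats::dist(cbind(x, y)))

  # fast regimes (rate above fast_mult_threshold times the base rate)
  # anchor with an elevation affinity; all others anchor uniformly
  regs <- sort(unique(truth$regime))
  reg_lambda <- painting$regimes$lambda[match(regs,
                                              painting$regimes$regime)]
  base_lambda <- min(painting$regimes$lambda)
  is_fast <- reg_lambda > config$fast_mult_threshold * base_lambda

  nsp <- length(tree$tip.label)
  reg_idx <- match(truth$regime, regs)
  w_background <- exp(-config$pref_strength * config$lowland_affinity *
                        zelev)
  for (attempt in seq_len(config$occupancy_retries)) {
    anchors <- vapply(seq_along(regs), function(i) {
      if (!is_fast[i]) return(NA_integer_)
      w <- exp(config$pref_strength * config$pref_scale * zelev)
      sample.int(n, 1L, prob = w)
    }, integer(1))
    sizes <- pmin(n, pmax(1L, round(stats::rlnorm(
      nsp, config$range_meanlog, config$range_sdlog))))
    inc <- matrix(0L, n, nsp,
                  dimnames = list(basins$basin, tree$tip.label))
    for (s in seq_len(nsp)) {
      a <- anchors[reg_idx[s]]
      w <- if (is.na(a)) {
        # background (non-burst) species seed independently with a mild
        # lowland bias - the widespread, species-rich default fauna
        w_background
      } else {
        # burst-clade species seed near their regime anchor, with a
        # uniform floor so remote basins stay reachable
        wa <- exp(-dmat[a, ] / config$cohesion_scale)
        0.9 * wa / sum(wa) + 0.1 / n
      }
      seed_b <- sample.int(n, 1L, prob = w)
      range_b <- order(dmat[seed_b, ])[seq_len(sizes[s])]
      inc[range_b, s] <- 1L
    }
    if (all(rowSums(inc) >= 1L)) {
      return(list(basins = basins, incidence = inc))
    }
  }
  stop("some basins remained unoccupied after ", config$occupancy_retries,
       " occupancy draws; increase range sizes or species count",
       call. = FALSE)
}

#' Mask trait values for a fraction of tips
#'
#' Masks exactly `floor(fraction * n)` tips (all trait columns of the
#' selected rows become NA). Random mode selects tips uniformly; clustered
#' mode concentrates the masked tips inside a single clade — the smallest
#' clade with at least that many tips — emulating phylogenetically
#' structured missingness.
#'
#' Uses the current R RNG stream.
#'
#' @param traits a data frame with a `species` column and trait columns.
#' @param fraction fraction of tips to mask, in `[0, 1)`.
#' @param mode `"random"` or `"clustered"`.
#' @param tree required for `mode = "clustered"`.
#' @return list with `traits` (masked copy), `masked` (logical per row)
#'   and `truth` (the original table).
#' @export
introduce_missingness <- function(traits, fraction, mode = c("random",
                                  "clustered"), tree = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(traits), "species" %in% names(traits))
  if (fraction < 0 || fraction >= 1) {
    stop("'fraction' must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(traits)
  m <- floor(fraction * n)
  if (m >= n) stop("masking would remove all tips", call. = FALSE)
  masked <- logical(n)
  if (m > 0L) {
    if (mode == "random") {
      idx <- sample.int(n, m)
    } else {
      if (is.null(tree)) stop("clustered mode requires 'tree'",
                              call. = FALSE)
      idx <- clustered_tip_sample(tree, traits$species, m)
    }
    masked[idx] <- TRUE
    trait_cols <- setdiff(names(traits), "species")
    out <- traits
    out[masked, trait_cols] <- NA
  } else {
    out <- traits
  }
  list(traits = out, masked = masked, truth = traits)
}

# Pick m species concentrated in one clade: the smallest clade holding at
# least m of the listed species, sampling within it if larger.
clustered_tip_sample <- function(tree, species, m) {
  ntip <- length(tree$tip.label)
  clades <- lapply(ntip + seq_len(tree$Nnode), function(node) {
    tips <- tree$tip.label[tip_descendants(tree, node)]
    intersect(tips, species)
  })
  sizes <- lengths(clades)
  ok <- which(sizes >= m & sizes < length(species))  # not the whole set
  if (!length(ok)) ok <- which(sizes >= m)
  best <- ok[which.min(sizes[ok])]
  pool <- match(clades[[best]], species)
  if (length(pool) == m) pool else sample(pool, m)
}

# Tip indices descending from a node.
tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tip_descendants, tree = tree))
}
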