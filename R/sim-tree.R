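#' Configuration for the synthetic data generator
#'
#' Bundles every parameter of the generative model: a constant-rate
#' birth-death process with Poisson rate-shift regimes on a crown-age
#' timescale, regime-linked Brownian trait evolution, and an
#' elevation-structured landscape in which high-rate species preferentially
#' occupy high-elevation basins. Defaults describe a clade of several
#' hundred extant species over 25 My carrying a few recent fast-speciating
#' burst clades against a widespread lowland background - the condition
#' the downstream analysis is designed for.
#'
#' @param seed integer seed; with a fixed seed all generator outputs are
#'   reproducible bit-for-bit.
#' @param crown_age crown age in My.
#' @param lambda,mu base speciation and extinction rates (My^-1); mu is
#'   shared by all regimes.
#' @param shift_rate Poisson rate of regime shifts per My per lineage.
#' @param shift_mult_meanlog,shift_mult_sdlog log-normal distribution of
#'   the speciation-rate multiplier drawn at each shift (applied to the
#'   base rate, so regime rates are lambda * multiplier, capped at
#'   `lambda_max`).
#' @param lambda_max cap on per-regime speciation rate, guarding against
#'   runaway compounding of multipliers.
#' @param sigma2_base Brownian rate (trait units^2 My^-1) of the focal
#'   (body size, log10 scale) trait in the base regime.
#' @param trait_link_exponent exponent of the power link sigma2 =
#'   sigma2_base * (lambda/lambda_base)^exponent tying trait rate to
#'   speciation rate within a regime.
#' @param root_state root value of the focal trait (log10 cm).
#' @param n_other_traits,sigma2_other number and (constant, regime-free)
#'   Brownian rate of the accessory morphological traits.
#' @param n_basins number of basins (laid out on a near-square lattice).
#' @param elevation_range,elev_noise_sd elevation gradient span (m) across
#'   the lattice and Gaussian noise around it.
#' @param temp_sea_level,temp_lapse,temp_lat_slope,temp_noise_sd air
#'   temperature (deg C) at zero elevation, lapse rate per km, latitudinal
#'   trend per lattice unit along x, and noise.
#' @param area_meanlog,area_sdlog log-normal basin area (m^2).
#' @param runoff_mean,runoff_sd Gaussian land-surface runoff (mm yr^-1),
#'   truncated at 0.
#' @param gradient_slope,gradient_noise_sd stream gradient increases with
#'   elevation at this slope (m/km per m) plus noise.
#' @param n_soil_types,soil_total number of substrate classes and total
#'   soil-patch count per basin (multinomial, basin-specific mixtures).
#' @param range_meanlog,range_sdlog log-normal range size (number of
#'   basins occupied), truncated to `[1, n_basins]`.
#' @param pref_strength elevation-preference strength in `[0, 1]`: 0 means
#'   a regime's speciation rate has no bearing on where its clade anchors;
#'   1 is the strongest coupling between regime rate and anchor elevation.
#' @param pref_scale logit scale applied to the regime's elevation
#'   preference in the anchor-basin weights.
#' @param lowland_affinity logit scale of the background (non-fast)
#'   species' lowland seeding bias (scaled by `pref_strength`).
#' @param cohesion_scale exponential distance-decay scale (lattice units)
#'   of species' range seeds around their regime's anchor; smaller values
#'   give tighter, more localized clades.
#' @param miss_fraction,miss_mode fraction of tips whose trait values are
#'   masked in the generated trait table, and the masking mode
#'   (`"random"` or `"clustered"`; see [introduce_missingness()]).
#' @param min_tips,max_tips accepted range of extant tip counts; trees
#'   outside it are redrawn (min) or an error is raised (max).
#' @param min_regimes,min_regime_tips conditioning on a realized
#'   radiation: accepted trees must carry at least `min_regimes` distinct
#'   regimes with `min_regime_tips` extant tips each (1/0 disables).
#' @param fast_mult_threshold,fast_frac_range a tip is "fast" when its
#'   regime rate exceeds `fast_mult_threshold * lambda`; accepted trees
#'   must have a fast-tip fraction inside `fast_frac_range` (set to
#'   c(0, 1) to disable), so the radiation is neither absent nor
#'   saturating.
#' @param min_fast_regimes accepted trees must carry at least this many
#'   distinct fast regimes with `min_regime_tips` extant tips each
#'   (0 disables), so the montane radiation is polyphyletic.
#' @param max_retries cap on redraws when the clade dies before the crown
#'   age or misses `min_tips`.
#' @param occupancy_retries cap on redraws of the occupancy matrix when a
#'   basin ends up unoccupied.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       crown_age = 25,
                       lambda = 0.28,
                       mu = 0.05,
                       shift_rate = 0.003,
                       shift_mult_meanlog = log(4),
                       shift_mult_sdlog = 0.4,
                       lambda_max = 1.2,
                       sigma2_base = 0.005,
                       trait_link_exponent = 1,
                       root_state = 1.3,
                       n_other_traits = 4L,
                       sigma2_other = 0.003,
                       n_basins = 120L,
                       elevation_range = 3000,
                       elev_noise_sd = 150,
                       temp_sea_level = 26,
                       temp_lapse = 5.5,
                       temp_lat_slope = 0,
                       temp_noise_sd = 8,
                       area_meanlog = log(5e9),
                       area_sdlog = 1,
                       runoff_mean = 800,
                       runoff_sd = 250,
                       gradient_slope = 0.004,
                       gradient_noise_sd = 6.5,
                       n_soil_types = 6L,
                       soil_total = 200L,
                       range_meanlog = log(6),  # ~6-basin median range
                       range_sdlog = 0.7,
                       pref_strength = 0.8,
                       pref_scale = 1.5,
                       lowland_affinity = 0.5,
                       cohesion_scale = 1.1,
                       miss_fraction = 0.1,
                       miss_mode = "random",
                       min_tips = 500L,
                       max_tips = 2500L,
                       min_regimes = 1L,
                       min_regime_tips = 15L,
                       fast_mult_threshold = 1.5,
                       fast_frac_range = c(0.1, 0.5),
                       min_fast_regimes = 2L,
                       max_retries = 500L,
                       occupancy_retries = 20L) {
  cfg <- as.list(environment())
  stopifnot(cfg$lambda > 0, cfg$mu >= 0, cfg$shift_rate >= 0,
            cfg$sigma2_base > 0, cfg$crown_age > 0,
            cfg$pref_strength >= 0, cfg$pref_strength <= 1,
            cfg$n_basins >= 10L, cfg$min_tips >= 2L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an extant-only birth-death tree with rate-shift regimes
#'
#' Forward Gillespie simulation from two crown lineages: each extant
#' lineage speciates at its regime's lambda, goes extinct at mu, and picks
#' up a new regime at `shift_rate` (a Poisson process along branches). At a
#' shift the lineage's new speciation rate is the base rate times a
#' log-normal draw (capped at `lambda_max`), and the regime's Brownian
#' trait rate follows the power link in the config. The complete history is then pruned to
#' extant lineages. Simulations are conditioned on both crown lineages
#' surviving and on the extant tip count falling in
#' `[min_tips, max_tips]` (a draw that dies out, stays too small, or
#' overflows the cap is rejected); failed draws are retried up to
#' `max_retries`.
#'
#' Regime painting convention: each branch of the pruned tree carries the
#' regime that was active at its tipward end (mid-branch shift positions
#' are not retained).
#'
#' Uses the current R RNG stream; callers seed via `set.seed()` (the
#' pipeline seeds from `config$seed`).
#'
#' @param config a [sim_config()].
#' @return list with `tree` (extant-only ultrametric `phylo`), `painting`
#'   (class `regime_painting`: `edge_regime`, `tip_regime`, `regimes`
#'   table with `lambda`, `mu`, `sigma2`), and `n_shifts`.
#' @export
simulate_shift_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  exp_tips <- 2 * exp((config$lambda - config$mu) * config$crown_age)
  if (exp_tips > config$max_tips) {
    stop("expected tip count (", round(exp_tips), ") exceeds max_tips (",
         config$max_tips, ")", call. = FALSE)
  }
  for (try in seq_len(config$max_retries)) {
    res <- sim_shift_tree_once(config)
    if (!is.null(res)) return(res)
  }
  stop("clade failed to survive to the crown age with >= ", config$min_tips,
       " tips in ", config$max_retries, " attempts", call. = FALSE)
}

# One conditioned draw; NULL signals a rejected attempt.
sim_shift_tree_once <- function(config) {
  Tmax <- config$crown_age
  cap <- 4L * config$max_tips + 64L
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- numeric(cap)
  regime <- integer(cap); status <- integer(cap)  # 0 alive 1 speciated 2 extinct
  reg_lambda <- config$lambda; reg_mu <- config$mu
  reg_sigma2 <- config$sigma2_base
  n_lin <- 2L
  parent[1:2] <- 0L; t_birth[1:2] <- 0; regime[1:2] <- 1L; status[1:2] <- 0L
  alive <- c(1L, 2L)
  t <- 0
  n_shifts <- 0L
  repeat {
    if (length(alive) == 0L) return(NULL)
    if (length(alive) > config$max_tips) return(NULL)  # overflow: reject draw
    lin_rate <- reg_lambda[regime[alive]] + reg_mu[regime[alive]] +
      config$shift_rate
    total <- sum(lin_rate)
    t <- t + stats::rexp(1L, total)
    if (t >= Tmax) break
    i <- alive[sample.int(length(alive), 1L, prob = lin_rate)]
    r <- regime[i]
    u <- stats::runif(1L) * (reg_lambda[r] + reg_mu[r] + config$shift_rate)
    if (u < reg_lambda[r]) {                       # speciation
      status[i] <- 1L; t_end[i] <- t
      kids <- n_lin + 1:2
      if (kids[2L] > cap) stop("lineage capacity exceeded", call. = FALSE)
      parent[kids] <- i; t_birth[kids] <- t; regime[kids] <- r
      status[kids] <- 0L
      n_lin <- n_lin + 2L
      alive <- c(alive[alive != i], kids)
    } else if (u < reg_lambda[r] + reg_mu[r]) {    # extinction
      status[i] <- 2L; t_end[i] <- t
      alive <- alive[alive != i]
    } else {                                       # regime shift
      mult <- stats::rlnorm(1L, config$shift_mult_meanlog,
                            config$shift_mult_sdlog)
      new_lambda <- min(config$lambda_max, config$lambda * mult)
      reg_lambda <- c(reg_lambda, new_lambda)
      reg_mu <- c(reg_mu, config$mu)
      reg_sigma2 <- c(reg_sigma2, config$sigma2_base *
                        (new_lambda / config$lambda)^config$trait_link_exponent)
      regime[i] <- length(reg_lambda)
      n_shifts <- n_shifts + 1L
    }
  }
  t_end[alive] <- Tmax
  extant <- alive
  if (length(extant) < config$min_tips) return(NULL)
  # both crown lineages must have extant descendants
  crown_of <- integer(n_lin)
  crown_of[1:2] <- 1:2
  for (j in 3:n_lin) crown_of[j] <- crown_of[parent[j]]
  if (length(unique(crown_of[extant])) < 2L) return(NULL)

  if (config$min_regimes > 1L) {
    tab <- table(regime[extant])
    if (sum(tab >= config$min_regime_tips) < config$min_regimes) {
      return(NULL)
    }
  }
  fast <- mean(reg_lambda[regime[extant]] >
                 config$fast_mult_threshold * config$lambda)
  if (fast < config$fast_frac_range[1L] ||
      fast > config$fast_frac_range[2L]) return(NULL)
  if (config$min_fast_regimes > 0L) {
    tab <- table(regime[extant])
    fast_reg <- reg_lambda[as.integer(names(tab))] >
      config$fast_mult_threshold * config$lambda
    if (sum(fast_reg & tab >= config$min_regime_tips) <
        config$min_fast_regimes) return(NULL)
  }
  tree <- build_pruned_phylo(parent[1:n_lin], t_birth[1:n_lin],
                             t_end[1:n_lin], regime[1:n_lin], extant)
  painting <- structure(list(
    edge_regime = tree$edge_regime,
    tip_regime = tree$tip_regime,
    regimes = data.frame(regime = seq_along(reg_lambda),
                         lambda = reg_lambda, mu = reg_mu,
                         sigma2 = reg_sigma2)),
    class = "regime_painting")
  phy <- tree$phy
  list(tree = phy, painting = painting, n_shifts = n_shifts)
}

# Prune the lineage table to the extant set and assemble a phylo.
# Chains of single-surviving-child lineages are merged; a merged branch is
# painted with the regime of its tipward lineage.
build_pruned_phylo <- function(parent, t_birth, t_end, regime, extant) {
  n_lin <- length(parent)
  kept <- logical(n_lin)
  for (e in extant) {
    j <- e
    while (j != 0L && !kept[j]) { kept[j] <- TRUE; j <- parent[j] }
  }
  kids <- vector("list", n_lin)
  for (j in which(kept)) {
    p <- parent[j]
    if (p != 0L) kids[[p]] <- c(kids[[p]], j)
  }
  is_extant <- logical(n_lin); is_extant[extant] <- TRUE

  # resolve(id): follow single-child chains; returns terminal lineage and
  # accumulated branch length
  resolve <- function(id) {
    len <- 0
    repeat {
      len <- len + t_end[id] - t_birth[id]
      if (is_extant[id]) return(list(id = id, len = len, tip = TRUE))
      k <- kids[[id]]
      if (length(k) == 2L) return(list(id = id, len = len, tip = FALSE))
      id <- k[1L]
    }
  }

  ntip <- length(extant)
  n_internal_max <- ntip  # crown root + at most ntip - 1 internals
  edge <- matrix(0L, 2L * ntip, 2L)
  edge_len <- numeric(2L * ntip)
  edge_reg <- integer(2L * ntip)
  tip_labels <- character(ntip)
  tip_reg <- integer(ntip)
  next_tip <- 0L
  next_node <- ntip + 1L  # root gets ntip + 1
  n_edge <- 0L

  # stack of (resolved lineage id at an internal node, its node number)
  root_num <- next_node; next_node <- next_node + 1L
  # the crown root joins lineages 1 and 2 (both kept by conditioning)
  stack <- list(list(children = c(1L, 2L), node = root_num))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (child in fr$children) {
      r <- resolve(child)
      n_edge <- n_edge + 1L
      edge_len[n_edge] <- r$len
      edge_reg[n_edge] <- regime[r$id]
      if (r$tip) {
        next_tip <- next_tip + 1L
        edge[n_edge, ] <- c(fr$node, next_tip)
        tip_labels[next_tip] <- paste0("t", r$id)
        tip_reg[next_tip] <- regime[r$id]
      } else {
        node_num <- next_node; next_node <- next_node + 1L
        edge[n_edge, ] <- c(fr$node, node_num)
        stack[[length(stack) + 1L]] <- list(children = kids[[r$id]],
                                            node = node_num)
      }
    }
  }
  edge <- edge[seq_len(n_edge), , drop = FALSE]
  phy <- structure(list(edge = edge,
                        edge.length = edge_len[seq_len(n_edge)],
                        tip.label = tip_labels,
                        Nnode = next_node - ntip - 1L),
                   class = "phylo", order = "cladewise")
  list(phy = phy, edge_regime = edge_reg[seq_len(n_edge)],
       tip_regime = tip_reg)
}

#' Paint every branch of a tree with a single regime
#'
#' Convenience constructor for a one-regime painting, mainly for tests and
#' for running the trait simulator on externally supplied trees.
#'
#' @param tree a `phylo`.
#' @param lambda,mu,sigma2 the regime's rates.
#' @return a `regime_painting`.
#' @export
uniform_painting <- function(tree, lambda = 0.1, mu = 0, sigma2 = 1) {
  structure(list(
    edge_regime = rep(1L, nrow(tree$edge)),
    tip_regime = rep(1L, length(tree$tip.label)),
    regimes = data.frame(regime = 1L, lambda = lambda, mu = mu,
                         sigma2 = sigma2)),
    class = "regime_painting")
}

#' Per-tip truth table from a regime painting
#'
#' @param tree a `phylo`.
#' @param painting a `regime_painting` for `tree`.
#' @return data frame `species`, `regime`, `true_lambda`, `true_sigma2`.
#' @export
tip_truth <- function(tree, painting) {
  stopifnot(inherits(painting, "regime_painting"),
            length(painting$tip_regime) == length(tree$tip.label))
  r <- painting$tip_regime
  data.frame(species = tree$tip.label,
             regime = r,
             true_lambda = painting$regimes$lambda[r],
             true_sigma2 = painting$regimes$sigma2[r],
             stringsAsFactors = FALSE)
}
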