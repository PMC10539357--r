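test_that("pure-birth tip counts agree with the Yule closed form", {
  # eta = 0, mu = 0: each crown lineage grows as E[N] = exp(lambda * t)
  set.seed(101)
  cfg <- sim_config(seed = 101, lambda = 0.1, mu = 0, shift_rate = 0,
                    crown_age = 40, min_tips = 2L, max_tips = 10000L,
                    min_fast_regimes = 0L, fast_frac_range = c(0, 1))
  n_rep <- 300L
  counts <- vapply(seq_len(n_rep), function(i) {
    length(simulate_shift_tree(cfg)$tree$tip.label)
  }, numeric(1))
  expected <- 2 * exp(0.1 * 40)  # ~109
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.05 * expected)
})

test_that("birth-death tip counts match a naive event-by-event simulator", {
  set.seed(102)
  cfg <- sim_config(seed = 102, lambda = 0.1, mu = 0.05, shift_rate = 0,
                    crown_age = 30, min_tips = 2L, max_tips = 10000L,
                    max_retries = 1000L,
                    min_fast_regimes = 0L, fast_frac_range = c(0, 1))
  n_rep <- 400L
  mine <- vapply(seq_len(n_rep), function(i) {
    length(simulate_shift_tree(cfg)$tree$tip.label)
  }, numeric(1))
  naive <- stats::na.omit(vapply(seq_len(4L * n_rep), function(i) {
    as.numeric(naive_bd_count(0.1, 0.05, 30))
  }, numeric(1)))
  se <- sqrt(stats::var(mine) / length(mine) +
               stats::var(naive) / length(naive))
  expect_lt(abs(mean(mine) - mean(naive)), 4 * se)
})

test_that("fraction of tips in shifted regimes increases with shift rate", {
  set.seed(103)
  frac_shifted <- vapply(c(0.005, 0.02, 0.08), function(eta) {
    cfg <- sim_config(seed = 103, lambda = 0.2, crown_age = 15,
                      shift_rate = eta, lambda_max = 0.45,
                      shift_mult_meanlog = log(4), shift_mult_sdlog = 0,
                      min_tips = 30L, max_tips = 5000L,
                      min_regime_tips = 0L,
                      min_fast_regimes = 0L, fast_frac_range = c(0, 1))
    mean(vapply(1:10, function(i) {
      sim <- simulate_shift_tree(cfg)
      mean(sim$painting$tip_regime != 1L)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac_shifted) > 0))
})

test_that("Brownian trait simulation has the closed-form tip covariance", {
  tr <- tree_4tip_balanced()
  pt <- uniform_painting(tr, sigma2 = 1)
  expect_equal(unname(simulate_bm_traits(tr, uniform_painting(tr,
               sigma2 = 1e-24), root_state = 5)), rep(5, 4),
               tolerance = 1e-6)
  set.seed(104)
  reps <- t(vapply(seq_len(5000), function(i) {
    simulate_bm_traits(tr, pt, root_state = 0)
  }, numeric(4)))
  emp <- stats::cov(reps)
  theory <- matrix(c(2, 1, 0, 0,
                     1, 2, 0, 0,
                     0, 0, 2, 1,
                     0, 0, 1, 2), 4, 4)
  expect_lt(max(abs(emp - theory)), 0.15)
})

test_that("a high-sigma2 regime inflates within-clade trait variance", {
  tr <- tree_4tip_balanced()
  # clade (A,B) evolves 10x faster than (C,D)
  ab <- match(c("A", "B"), tr$tip.label)
  ab_node <- ape::getMRCA(tr, c("A", "B"))
  painting <- structure(list(
    edge_regime = ifelse(tr$edge[, 2] %in% c(ab, ab_node), 2L, 1L),
    tip_regime = ifelse(seq_len(4) %in% ab, 2L, 1L),
    regimes = data.frame(regime = 1:2, lambda = c(0.1, 0.1),
                         mu = 0, sigma2 = c(1, 10))),
    class = "regime_painting")
  set.seed(105)
  wins <- mean(vapply(seq_len(200), function(i) {
    x <- simulate_bm_traits(tr, painting)
    stats::var(x[c("A", "B")]) > stats::var(x[c("C", "D")])
  }, logical(1)))
  expect_gte(wins, 0.8)
})

test_that("landscape occupancy couples rate regimes to elevation", {
  set.seed(106)
  basin_cor <- function(pref, n_seeds = 15) {
    mean(vapply(seq_len(n_seeds), function(i) {
      tr <- ape::rcoal(120)
      tr$tip.label <- paste0("s", 1:120)
      # two clear regimes: half the tips at 8x the base rate
      painting <- uniform_painting(tr, lambda = 0.1)
      painting$regimes <- data.frame(regime = 1:2,
                                     lambda = c(0.1, 0.8), mu = 0,
                                     sigma2 = c(1, 8))
      painting$tip_regime <- rep(1:2, each = 60)
      cfg <- sim_config(seed = i, n_basins = 100L,
                        pref_strength = pref)  # landscape params only
      land <- simulate_landscape_and_ranges(tr, painting, cfg)
      lam <- stats::setNames(painting$regimes$lambda[painting$tip_regime],
                             tr$tip.label)
      mlam <- summarize_rates_by_basin(land$incidence, lam)
      stats::cor(mlam, land$basins$elevation[match(names(mlam),
                                                   land$basins$basin)])
    }, numeric(1)))
  }
  expect_lt(abs(basin_cor(0)), 0.1)
  expect_gt(basin_cor(1), 0.5)
})

test_that("heavier-tailed range sizes increase range-size dispersion", {
  set.seed(107)
  tr <- ape::rcoal(80)
  tr$tip.label <- paste0("s", 1:80)
  pt <- uniform_painting(tr)
  vars <- vapply(c(0.3, 0.7, 1.1), function(sdl) {
    cfg <- sim_config(seed = 107, range_sdlog = sdl, n_basins = 40L,
                      range_meanlog = log(4))
    mean(vapply(1:10, function(i) {
      land <- simulate_landscape_and_ranges(tr, pt, cfg)
      stats::var(colSums(land$incidence))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("missingness masking is exact, seeded, and mode-aware", {
  traits <- data.frame(species = paste0("s", 1:200),
                       a = rnorm(200), b = rnorm(200))
  expect_identical(introduce_missingness(traits, 0)$traits, traits)
  set.seed(108)
  m <- introduce_missingness(traits, 0.1)
  expect_equal(sum(m$masked), 20L)
  expect_equal(sum(is.na(m$traits$a)), 20L)
  expect_identical(m$truth, traits)
  expect_error(introduce_missingness(traits, 1), "fraction")

  set.seed(109)
  tr <- ape::rcoal(200)
  tr$tip.label <- paste0("s", 1:200)
  mc <- introduce_missingness(traits, 0.1, mode = "clustered", tree = tr)
  expect_equal(sum(mc$masked), 20L)
  # clustered masking concentrates in a small clade: the masked tips span
  # a much smaller patristic neighbourhood than a random draw would
  coph <- ape::cophenetic.phylo(tr)
  masked_sp <- traits$species[mc$masked]
  mean_masked <- mean(coph[masked_sp, masked_sp])
  mean_all <- mean(coph)
  expect_lt(mean_masked, 0.5 * mean_all)
})

test_that("the full generator is deterministic under a fixed seed", {
  d1 <- simulate_dataset(light_config(99))
  d2 <- simulate_dataset(light_config(99))
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$incidence, d2$incidence)
  expect_identical(d1$basins, d2$basins)
})
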