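test_that("log10 transform is exact, guarded, and error-reporting", {
  traits <- data.frame(species = c("a", "b", "c"),
                       body_size = c(10, 1, 100), other = 1:3)
  out <- log10_body_size(traits)
  expect_equal(out$body_size, c(1, 0, 2))
  expect_equal(out$other, traits$other)
  expect_error(log10_body_size(out), "already")
  bad <- data.frame(species = c("a", "b"), body_size = c(-1, 2))
  expect_error(log10_body_size(bad), "a")
})

test_that("tip trait rates are zero without variation and unbiased under
          single-rate Brownian motion", {
  tr <- tree_4tip_balanced()
  x <- stats::setNames(rep(3.3, 4), tr$tip.label)
  expect_equal(tip_trait_rate(tr, x)$rate, rep(0, 4))

  set.seed(31)
  means <- vapply(seq_len(100), function(i) {
    phy <- ape::rcoal(200)
    x <- simulate_bm_traits(phy, uniform_painting(phy, sigma2 = 1))
    mean(tip_trait_rate(phy, x)$rate)
  }, numeric(1))
  expect_lt(abs(mean(means) - 1), 0.2)
})

test_that("tip trait rates separate high- and low-rate clades", {
  set.seed(32)
  wins <- vapply(seq_len(50), function(i) {
    phy <- ape::rcoal(100)
    phy$tip.label <- paste0("s", 1:100)
    # paint one mid-sized clade (and all edges inside it) at 10x rate
    sizes <- vapply(101:(100 + phy$Nnode), function(nd)
      length(clade_nodes(phy, nd)), numeric(1))
    node_a <- (101:(100 + phy$Nnode))[which.min(abs(sizes - 60))]
    sub <- clade_nodes(phy, node_a)
    clade_tips <- sub[sub <= 100]
    painting <- uniform_painting(phy, sigma2 = 1)
    painting$regimes <- data.frame(regime = 1:2, lambda = 0.1, mu = 0,
                                   sigma2 = c(1, 10))
    painting$edge_regime[phy$edge[, 2] %in% sub] <- 2L
    painting$tip_regime[clade_tips] <- 2L
    x <- simulate_bm_traits(phy, painting)
    r <- tip_trait_rate(phy, x)
    mean(r$rate[clade_tips]) > mean(r$rate[-clade_tips])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Brownian imputation equals the GLS grand mean on a star tree", {
  tr <- tree_star(6)
  x <- c(1, 2, 3, 4, NA, NA)
  traits <- data.frame(species = tr$tip.label, tr1 = x)
  res <- impute_traits_bm(tr, traits)
  expect_equal(unname(res$traits$tr1[5:6]), rep(mean(x[1:4]), 2))
  expect_equal(res$report$species, c("t5", "t6"))
})

test_that("imputation reproduces the conditional-normal closed form", {
  tr <- tree_4tip_balanced()
  traits <- data.frame(species = c("A", "B", "C", "D"),
                       tr1 = c(0, 2, 1, NA))
  res <- impute_traits_bm(tr, traits)
  # oracle: conditional mean of the BM MVN with the shared-path matrix
  C <- matrix(c(2, 1, 0, 0,
                1, 2, 0, 0,
                0, 0, 2, 1,
                0, 0, 1, 2), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  obs <- c("A", "B", "C")
  xo <- c(0, 2, 1)
  Ci <- solve(C[obs, obs])
  mu <- sum(Ci %*% xo) / sum(Ci)
  cond <- mu + C["D", obs] %*% Ci %*% (xo - mu)
  expect_equal(res$traits$tr1[4], drop(cond), tolerance = 1e-8)

  # identity when nothing is missing
  full <- data.frame(species = c("A", "B", "C", "D"), tr1 = 1:4 / 2)
  expect_identical(impute_traits_bm(tr, full)$traits, full)
  # too few observed
  few <- data.frame(species = c("A", "B", "C", "D"),
                    tr1 = c(1, 2, NA, NA))
  expect_error(impute_traits_bm(tr, few), "50%")
})

test_that("imputation error shrinks as phylogenetic signal grows", {
  # shorter terminal branches relative to depth = stronger signal
  set.seed(33)
  rmse_at <- function(stretch) {
    mean(vapply(seq_len(20), function(i) {
      phy <- ape::rcoal(60)
      phy$edge.length <- phy$edge.length /
        max(ape::node.depth.edgelength(phy))
      pend <- phy$edge[, 2] <= 60
      phy$edge.length[pend] <- phy$edge.length[pend] * stretch
      x <- simulate_bm_traits(phy, uniform_painting(phy, sigma2 = 1))
      traits <- data.frame(species = phy$tip.label, tr1 = unname(x))
      m <- introduce_missingness(traits, 0.2)
      res <- impute_traits_bm(phy, m$traits)
      imp <- res$traits$tr1[m$masked]
      sqrt(mean((imp - x[m$masked])^2))
    }, numeric(1)))
  }
  r <- vapply(c(0.05, 0.5, 2), rmse_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("D statistic is calibrated on its two nulls", {
  set.seed(34)
  phy <- ape::rcoal(150)
  phy$tip.label <- paste0("s", 1:150)
  n_data <- 30L
  d_rand <- vapply(seq_len(n_data), function(i) {
    ind <- stats::setNames(sample(rep(c(0, 1), c(110, 40))),
                           phy$tip.label)
    missingness_d(phy, ind, n_perm = 120L)$d
  }, numeric(1))
  expect_lt(abs(mean(d_rand) - 1), 0.15)

  d_bm <- vapply(seq_len(n_data), function(i) {
    b <- simulate_bm_traits(phy, uniform_painting(phy, sigma2 = 1))
    ind <- stats::setNames(as.numeric(rank(-b) <= 40), phy$tip.label)
    missingness_d(phy, ind, n_perm = 120L)$d
  }, numeric(1))
  expect_lt(abs(mean(d_bm)), 0.15)
})

test_that("clustered missingness yields low D, random missingness D near 1", {
  set.seed(35)
  phy <- ape::rcoal(200)
  phy$tip.label <- paste0("s", 1:200)
  traits <- data.frame(species = phy$tip.label, tr1 = rnorm(200))
  low_d <- vapply(seq_len(10), function(i) {
    m <- introduce_missingness(traits, 0.2, mode = "clustered",
                               tree = phy)
    ind <- stats::setNames(as.numeric(m$masked), traits$species)
    missingness_d(phy, ind, n_perm = 150L)$d
  }, numeric(1))
  expect_gte(mean(low_d < 0.5), 0.9)
})
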