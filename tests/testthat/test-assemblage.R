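make_incidence <- function(mat, basins, species) {
  m <- matrix(as.integer(mat), nrow = length(basins), byrow = TRUE,
              dimnames = list(basins, species))
  m
}

test_that("basin summaries apply the requested statistic", {
  inc <- make_incidence(c(1, 0, 0,
                          1, 1, 1), c("b1", "b2"), c("x", "y", "z"))
  v <- c(x = 0.1, y = 0.2, z = 0.7)
  expect_equal(unname(summarize_rates_by_basin(inc, v, "mean")),
               c(0.1, mean(c(0.1, 0.2, 0.7))))
  expect_equal(unname(summarize_rates_by_basin(inc, v, "median")[2]), 0.2)
  expect_equal(unname(summarize_rates_by_basin(inc, v, "min")[2]), 0.1)
  expect_equal(unname(summarize_rates_by_basin(inc, v, "max")[2]), 0.7)
  expect_error(summarize_rates_by_basin(inc, v[1:2]), "z")
})

test_that("weighted means match hand computation; uniform weights reduce
          to the unweighted mean", {
  inc <- make_incidence(c(1, 1, 0, 0,
                          0, 1, 1, 0,
                          1, 1, 1, 1), c("b1", "b2", "b3"),
                        c("s1", "s2", "s3", "s4"))
  v <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  w <- inverse_range_weights(inc)   # ranges: 2, 3, 2, 1
  expect_equal(unname(w), 1 / c(2, 3, 2, 1))
  got <- summarize_rates_by_basin(inc, v, "mean", weights = w)
  hand <- c((1 / 2 * 1 + 1 / 3 * 2) / (1 / 2 + 1 / 3),
            (1 / 3 * 2 + 1 / 2 * 3) / (1 / 3 + 1 / 2),
            (1 / 2 * 1 + 1 / 3 * 2 + 1 / 2 * 3 + 1 * 4) /
              (1 / 2 + 1 / 3 + 1 / 2 + 1))
  expect_equal(unname(got), hand, tolerance = 1e-12)
  uni <- summarize_rates_by_basin(
    inc, v, "mean", weights = stats::setNames(rep(2, 4), names(v)))
  expect_equal(uni, summarize_rates_by_basin(inc, v, "mean"))
})

test_that("order statistics obey min <= median <= mean <= max per basin", {
  set.seed(41)
  for (i in 1:5) {
    inc <- matrix(rbinom(20 * 30, 1, 0.4), 20, 30,
                  dimnames = list(paste0("b", 1:20), paste0("s", 1:30)))
    inc[rowSums(inc) == 0, 1] <- 1L
    v <- stats::setNames(rexp(30), colnames(inc))
    mn <- summarize_rates_by_basin(inc, v, "min")
    md <- summarize_rates_by_basin(inc, v, "median")
    mx <- summarize_rates_by_basin(inc, v, "max")
    expect_true(all(mn <= md + 1e-12 & md <= mx + 1e-12))
  }
})

test_that("richness and species density follow the power law", {
  inc <- make_incidence(rep(1, 6), c("b1", "b2"),
                        c("s1", "s2", "s3"))
  areas <- c(b1 = 1e4, b2 = 1)
  rd0 <- richness_and_density(inc, areas, z = 0)
  expect_equal(rd0$sd, rd0$sr)
  inc2 <- matrix(1L, 1, 100, dimnames = list("b1", paste0("s", 1:100)))
  rd <- richness_and_density(inc2, c(b1 = 1e4), z = 0.5)
  expect_equal(rd$sd, 1)
  expect_error(richness_and_density(inc, c(b1 = -1, b2 = 1)), "area")
})

test_that("species density decouples from richness as z grows", {
  set.seed(42)
  inc <- matrix(rbinom(50 * 200, 1, 0.2), 50, 200,
                dimnames = list(paste0("b", 1:50), paste0("s", 1:200)))
  inc[rowSums(inc) == 0, 1] <- 1L
  areas <- stats::setNames(rlnorm(50, log(1e9), 1.5), rownames(inc))
  cors <- vapply(c(0.25, 0.5), function(z) {
    rd <- richness_and_density(inc, areas, z)
    stats::cor(rd$sd, rd$sr, method = "spearman")
  }, numeric(1))
  expect_lt(cors[2], cors[1])
})

test_that("Shannon soil diversity closed forms", {
  expect_equal(unname(shannon_soil_diversity(c(7, 0, 0))), 0)
  expect_equal(unname(shannon_soil_diversity(c(5, 5, 5, 5))), log(4))
  h <- shannon_soil_diversity(c(5, 3, 2))
  p <- c(0.5, 0.3, 0.2)
  expect_equal(unname(h), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_soil_diversity(c(0, 0)), "all-zero")
})

test_that("filtering removes low-richness basins and logs provenance", {
  set.seed(43)
  sr_target <- c(3, 10, 15, 20, 30)
  inc <- matrix(0L, 5, 30, dimnames = list(paste0("b", 1:5),
                                           paste0("s", 1:30)))
  for (i in 1:5) inc[i, seq_len(sr_target[i])] <- 1L
  out <- filter_and_exclude(inc, min_species = 15)
  expect_equal(nrow(out), 3L)
  prov <- attr(out, "provenance")
  expect_setequal(prov$dropped_low_richness, c("b1", "b2"))

  ident <- filter_and_exclude(inc, min_species = 0)
  expect_equal(dim(ident), dim(inc))

  # dropping a ubiquitous taxon lowers SR by exactly 1 everywhere
  inc2 <- inc
  inc2[, "s1"] <- 1L
  dropped <- filter_and_exclude(inc2, drop_taxa = "s1")
  expect_equal(rowSums(dropped), rowSums(inc2) - 1)
  expect_error(filter_and_exclude(inc, min_species = 100), "emptied")
})
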