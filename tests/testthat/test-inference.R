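test_that("standardization centres, scales, logs area, and is idempotent", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 100, 1000))
  out <- standardize(d, log_columns = "b")
  expect_equal(out$a, c(-1, 0, 1))     # sample SD of (1,2,3) is 1
  expect_equal(out$b, c(-1, 0, 1))     # log10 then z-score
  expect_equal(standardize(out), out, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = c(1, 1, 1))), "zero-variance")
})

test_that("VIF matches its closed form and screening removes the
          collinear member", {
  set.seed(51)
  ortho <- ortho_design(4000, 3)
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-10)
  sc <- vif_screen(ortho)
  expect_equal(ncol(sc$design), 3L)
  expect_equal(nrow(sc$removed), 0L)

  # x2 = x1 + noise with R^2 = 0.96 => VIF = 25 for both
  x1 <- rnorm(1e5)
  x2 <- sqrt(0.96) * x1 + sqrt(0.04) * rnorm(1e5)
  d <- standardize(data.frame(x1 = x1, x2 = x2))
  v <- vif(d)
  r2 <- summary(stats::lm(x2 ~ x1, d))$r.squared
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-8)
  expect_equal(unname(v), c(25, 25), tolerance = 1)
})

test_that("iterative screening leaves the same survivors as brute force
          on a near-duplicate pair", {
  set.seed(52)
  n <- 500
  a <- rnorm(n)
  d <- data.frame(a = a, b = a + 0.05 * rnorm(n), c = rnorm(n))
  sc <- vif_screen(standardize(d), threshold = 5)
  expect_equal(ncol(sc$design), 2L)
  expect_true("c" %in% names(sc$design))
  expect_true(all(sc$vif < 5))
  # brute force: among all subsets of size 2 containing c, both are valid;
  # the screen must have removed exactly one of the duplicated pair
  expect_equal(sum(c("a", "b") %in% names(sc$design)), 1L)
})

test_that("standardized OLS recovers exact fits and textbook identities", {
  set.seed(53)
  n <- 100
  d <- standardize(random_design(n, 3))
  y_exact <- 2 * d$x1 - d$x2 + 0.5 * d$x3
  fit <- fit_standardized_ols(y_exact, d)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  x <- standardize(data.frame(x = rnorm(n)))
  y <- rnorm(n)
  ys <- (y - mean(y)) / stats::sd(y)
  f1 <- fit_standardized_ols(ys, x)
  expect_equal(f1$coefficients$estimate, stats::cor(y, x$x),
               tolerance = 1e-12)
})

test_that("OLS confidence intervals cover a known coefficient at the
          nominal rate", {
  set.seed(54)
  hits <- vapply(seq_len(200), function(i) {
    n <- 200
    elev <- rnorm(n)
    y <- 0.6 * elev + rnorm(n, 0, 0.6)
    fit <- fit_standardized_ols(y, data.frame(elev = elev))
    co <- fit$coefficients
    co$ci_lower[1] <= 0.6 && 0.6 <= co$ci_upper[1]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("lmg equals all-orderings brute force and sums to R^2", {
  set.seed(55)
  n <- 120
  d <- random_design(n, 4, rho = 0.5)
  y <- d$x1 + 0.5 * d$x2 + rnorm(n)
  got <- lmg_partition(y, d)
  oracle <- lmg_all_orderings(y, d)
  expect_equal(got$shares, oracle, tolerance = 1e-10)
  expect_equal(sum(got$shares), got$r_squared, tolerance = 1e-10)
  expect_true(all(got$shares >= -1e-12))

  # single predictor: share equals R^2
  one <- lmg_partition(y, d["x1"])
  expect_equal(unname(one$shares),
               summary(stats::lm(y ~ x1, d))$r.squared)
})

test_that("lmg reduces to squared correlations for orthogonal predictors", {
  set.seed(56)
  d <- ortho_design(3000, 3)
  y <- d$x1 + 2 * d$x2 + 0.5 * d$x3 + rnorm(3000)
  got <- lmg_partition(y, d)
  r2s <- vapply(d, function(col) stats::cor(y, col)^2, numeric(1))
  expect_equal(got$shares, r2s, tolerance = 1e-10)
})

test_that("lmg shares sum to R^2 across many random designs", {
  set.seed(57)
  for (i in seq_len(100)) {
    p <- sample(2:6, 1)
    d <- random_design(40, p, rho = runif(1, 0, 0.8))
    y <- rnorm(40) + rowSums(d) * runif(1)
    got <- lmg_partition(y, d)
    expect_equal(sum(got$shares), got$r_squared, tolerance = 1e-8)
  }
})

test_that("commonality components match the defining linear system", {
  set.seed(58)
  n <- 150
  d <- random_design(n, 6, rho = 0.5)
  groups <- c(x1 = "g1", x2 = "g1", x3 = "g2", x4 = "g2", x5 = "g3",
              x6 = "g3")
  y <- d$x1 + d$x3 + 0.3 * d$x5 + rnorm(n)
  got <- group_commonality(y, d, groups)
  oracle <- commonality_by_solve(y, d, groups)
  expect_equal(stats::setNames(got$components$component,
                               got$components$groups),
               oracle[got$components$groups], tolerance = 1e-10)
  expect_equal(sum(got$components$component), got$r_squared,
               tolerance = 1e-10)
})

test_that("commonality handles orthogonal and fully redundant groups", {
  set.seed(59)
  n <- 5000
  Q <- ortho_design(n, 2)
  d <- data.frame(a = Q$x1, b = Q$x2)
  y <- d$a + 0.5 * d$b + rnorm(n)
  got <- group_commonality(y, d, c(a = "g1", b = "g2"))
  comp <- stats::setNames(got$components$component,
                          got$components$groups)
  expect_lt(abs(comp[["g1+g2"]]), 1e-10)
  r2a <- summary(stats::lm(y ~ a, d))$r.squared
  r2b <- summary(stats::lm(y ~ b, d))$r.squared
  expect_equal(comp[["g1"]], r2a, tolerance = 1e-10)
  expect_equal(comp[["g2"]], r2b, tolerance = 1e-10)

  # duplicated group: no unique contribution, everything shared
  d2 <- data.frame(a = d$a, a2 = d$a)
  got2 <- suppressWarnings(
    group_commonality(y, d2, c(a = "g1", a2 = "g2")))
  comp2 <- stats::setNames(got2$components$component,
                           got2$components$groups)
  expect_lt(abs(comp2[["g1"]]), 1e-10)
  expect_lt(abs(comp2[["g2"]]), 1e-10)
  expect_equal(comp2[["g1+g2"]], r2a, tolerance = 1e-10)
})
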