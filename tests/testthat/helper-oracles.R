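# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive enumeration and closed forms only.

# Event-by-event constant-rate birth-death count simulator (no topology):
# two independent crown lineages, accept only if both survive to Tmax.
# Returns the extant count or NA when the draw is rejected.
naive_bd_count <- function(lambda, mu, Tmax) {
  counts <- integer(2)
  for (crown in 1:2) {
    n <- 1L
    t <- 0
    repeat {
      if (n == 0L) break
      t <- t + stats::rexp(1L, n * (lambda + mu))
      if (t >= Tmax) break
      if (stats::runif(1L) < lambda / (lambda + mu)) n <- n + 1L
      else n <- n - 1L
    }
    counts[crown] <- n
  }
  if (any(counts == 0L)) NA_integer_ else sum(counts)
}

# lmg by explicit averaging over all p! orderings of predictor entry.
lmg_all_orderings <- function(y, design) {
  p <- ncol(design)
  perms <- gtools_permutations(p)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm(y ~ ., data = design[, cols, drop = FALSE])
    summary(fit)$r.squared
  }
  shares <- numeric(p)
  for (i in seq_len(nrow(perms))) {
    prev <- integer(0)
    for (k in perms[i, ]) {
      shares[k] <- shares[k] + r2_of(c(prev, k)) - r2_of(prev)
      prev <- c(prev, k)
    }
  }
  stats::setNames(shares / nrow(perms), colnames(design))
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# Commonality components by solving the defining linear system:
# for every nonempty union U of groups, R2(U) = sum of components C(S)
# over subsets S of groups that intersect U.
commonality_by_solve <- function(y, design, groups) {
  labels <- sort(unique(groups[colnames(design)]))
  g <- length(labels)
  masks <- seq_len(2^g - 1L)
  in_mask <- function(mask) labels[bitwAnd(mask, 2^(seq_len(g) - 1L)) > 0L]
  r2_of <- function(labs) {
    cols <- names(groups)[groups %in% labs]
    cols <- intersect(cols, colnames(design))
    fit <- stats::lm(y ~ ., data = design[, cols, drop = FALSE])
    summary(fit)$r.squared
  }
  rhs <- vapply(masks, function(m) r2_of(in_mask(m)), numeric(1))
  A <- outer(masks, masks,
             Vectorize(function(u, s) as.numeric(bitwAnd(u, s) > 0L)))
  sol <- solve(A, rhs)
  names(sol) <- vapply(masks, function(m)
    paste(in_mask(m), collapse = "+"), character(1))
  sol
}

# all nodes (tips + internals) strictly inside the clade rooted at `node`
clade_nodes <- function(phy, node) {
  out <- integer(0)
  stack <- node
  ntip <- length(phy$tip.label)
  while (length(stack)) {
    nd <- stack[1]
    stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

# exactly centered, mutually orthogonal design (orthogonal to the
# intercept too, so with-intercept fits see them as uncorrelated)
ortho_design <- function(n, p) {
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  as.data.frame(stats::setNames(as.data.frame(Q * sqrt(n)),
                                paste0("x", seq_len(p))))
}

# random correlated design matrix for regression tests
random_design <- function(n, p, rho = 0.4) {
  z <- rnorm(n)
  X <- sapply(seq_len(p), function(k) rho * z + sqrt(1 - rho^2) * rnorm(n))
  as.data.frame(stats::setNames(as.data.frame(X), paste0("x", seq_len(p))))
}

# a fast generator configuration for pipeline-level tests: same process,
# smaller clade and landscape
light_config <- function(seed, ...) {
  sim_config(seed = seed, crown_age = 20, lambda = 0.28,
             min_tips = 120L, max_tips = 1500L,
             min_regime_tips = 10L, min_fast_regimes = 1L,
             fast_frac_range = c(0.02, 0.9), n_basins = 40L, ...)
}

# small balanced test trees
tree_2tip <- function(len = 1) {
  parse_newick(sprintf("(A:%g,B:%g);", len, len))
}
tree_4tip_balanced <- function() {
  parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
}
# star tree: every tip pendant from the root
tree_star <- function(n = 6, len = 1) {
  parse_newick(paste0("(", paste0("t", seq_len(n), ":", len,
                                  collapse = ","), ");"))
}
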