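#' Z-score standardization of a design table
#'
#' Columns listed in `log_columns` (typically basin area) are
#' log10-transformed first; every column is then centred and scaled to
#' unit variance using the sample (n - 1) standard deviation, making OLS
#' coefficients comparable effect sizes.
#'
#' @param data data frame of numeric columns (no missing values).
#' @param log_columns columns to log10-transform before scaling.
#' @return data frame of standardized columns.
#' @export
standardize <- function(data, log_columns = character()) {
  stopifnot(is.data.frame(data))
  if (anyNA(data)) stop("missing values in design table", call. = FALSE)
  for (lc in log_columns) {
    if (!lc %in% names(data)) stop("unknown column '", lc, "'",
                                   call. = FALSE)
    if (any(data[[lc]] <= 0)) {
      stop("column '", lc, "' must be positive for log transform",
           call. = FALSE)
    }
    data[[lc]] <- log10(data[[lc]])
  }
  for (cn in names(data)) {
    s <- stats::sd(data[[cn]])
    if (!is.finite(s) || s == 0) {
      stop("zero-variance column '", cn, "' cannot be standardized",
           call. = FALSE)
    }
    data[[cn]] <- (data[[cn]] - mean(data[[cn]])) / s
  }
  data
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) where R^2_k comes from regressing predictor k
#' on all the others.
#'
#' @param design data frame of predictors (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  stopifnot(is.data.frame(design), ncol(design) >= 2L)
  X <- as.matrix(design)
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, k] - mean(X[, k]))^2)
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(design))
}

#' Iterative VIF screening of a design matrix
#'
#' Removes, one at a time, the predictor with the highest VIF while any
#' VIF is at or above `threshold`, refitting after each removal, then
#' re-verifies that every survivor's VIF is below the threshold.
#'
#' @param design data frame of predictors.
#' @param threshold removal threshold (default 5).
#' @return list with `design` (reduced), `removed` (data frame: `step`,
#'   `predictor`, `vif` at removal) and `vif` (final VIFs).
#' @export
vif_screen <- function(design, threshold = 5) {
  removed <- list()
  step <- 0L
  repeat {
    v <- vif(design)
    if (max(v) < threshold) break
    step <- step + 1L
    worst <- names(v)[which.max(v)]
    removed[[step]] <- data.frame(step = step, predictor = worst,
                                  vif = unname(max(v)))
    design <- design[setdiff(names(design), worst)]
    if (ncol(design) < 2L) {
      stop("VIF screening collapsed the design to a single predictor",
           call. = FALSE)
    }
  }
  stopifnot(all(vif(design) < threshold))
  list(design = design,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(step = integer(), predictor = character(),
                    vif = numeric()),
       vif = vif(design))
}

#' Standardized OLS fit with confidence intervals
#'
#' Ordinary least squares of a (typically z-scored) response on a
#' (typically z-scored) design, with t-based confidence intervals,
#' per-coefficient two-sided significance flags at `alpha` (no
#' multiplicity correction), R^2, and the residual vector retained for
#' spatial diagnostics.
#'
#' @param y numeric response.
#' @param design data frame of predictors.
#' @param conf_level confidence level for the intervals.
#' @param alpha significance level for the flags.
#' @return list of class `ols_fit`: `coefficients` (data frame:
#'   `predictor`, `estimate`, `ci_lower`, `ci_upper`, `p_value`,
#'   `significant`), `r_squared`, `residuals`, `n`, `model`.
#' @export
fit_standardized_ols <- function(y, design, conf_level = 0.95,
                                 alpha = 0.05) {
  stopifnot(is.data.frame(design), length(y) == nrow(design))
  if (length(y) <= ncol(design) + 1L) {
    stop("need n > p + 1 observations", call. = FALSE)
  }
  df <- data.frame(.y = y, design, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("singular design matrix",
                                    call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  keep <- rownames(ci) != "(Intercept)"
  coefs <- data.frame(
    predictor = rownames(ci)[keep],
    estimate = unname(stats::coef(fit)[keep]),
    ci_lower = unname(ci[keep, 1L]),
    ci_upper = unname(ci[keep, 2L]),
    p_value = unname(sm$coefficients[keep, 4L]),
    stringsAsFactors = FALSE)
  coefs$significant <- coefs$p_value < alpha
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 residuals = unname(stats::residuals(fit)),
                 n = length(y), model = fit),
            class = "ols_fit")
}

# R^2 of y on every subset of predictors, from the joint correlation
# matrix (scale-invariant): r2[mask] for bitmask over columns of design.
subset_r2 <- function(y, design) {
  p <- ncol(design)
  R <- stats::cor(cbind(y, as.matrix(design)))
  ryx <- R[1L, -1L]
  Rxx <- R[-1L, -1L, drop = FALSE]
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    r2[mask + 1L] <- drop(crossprod(
      ryx[s], solve(Rxx[s, s, drop = FALSE], ryx[s])))
  }
  r2
}

#' lmg hierarchical partitioning of explained variance
#'
#' Decomposes the full-model R^2 into one nonnegative share per predictor
#' by averaging each predictor's incremental R^2 over all orders of entry
#' (the lmg metric). Computed by weighted subset enumeration (2^p fits)
#' rather than enumerating the p! orderings:
#' share_k = sum over subsets S not containing k of
#' w(|S|) * (R^2(S + k) - R^2(S)), with w(s) = s! (p-s-1)! / p!.
#'
#' @param y numeric response.
#' @param design data frame of predictors (p <= 20).
#' @return list with `shares` (named, summing to R^2), `pct_of_r2`
#'   (shares as % of explained variance), `r_squared`.
#' @export
lmg_partition <- function(y, design) {
  stopifnot(is.data.frame(design), length(y) == nrow(design))
  p <- ncol(design)
  if (p > 20L) {
    stop("p > 20: group predictors before partitioning (2^p fits)",
         call. = FALSE)
  }
  r2 <- subset_r2(y, design)
  bits <- bitwShiftL(1L, 0:(p - 1L))
  wts <- exp(lfactorial(0:(p - 1L)) + lfactorial(p - 1L - 0:(p - 1L)) -
               lfactorial(p))
  shares <- numeric(p)
  sizes <- vapply(0:(2^p - 1L), function(m) sum(bitwAnd(m, bits) > 0L),
                  numeric(1))
  for (k in seq_len(p)) {
    without_k <- which(bitwAnd(0:(2^p - 1L), bits[k]) == 0L) - 1L
    gain <- r2[without_k + bits[k] + 1L] - r2[without_k + 1L]
    shares[k] <- sum(wts[sizes[without_k + 1L] + 1L] * gain)
  }
  names(shares) <- colnames(design)
  full <- r2[2^p]
  stopifnot(abs(sum(shares) - full) < 1e-8)
  list(shares = shares, pct_of_r2 = 100 * shares / full,
       r_squared = full)
}

#' Commonality analysis over predictor groups
#'
#' Partitions the full-model R^2 into unique and shared components across
#' groups of predictors by inclusion-exclusion over the R^2 of all
#' nonempty group unions: for each nonempty set S of groups,
#' C(S) = -sum over T subset of S of (-1)^|T| R^2(T union (all \ S)).
#' C of a singleton is that group's unique contribution,
#' R^2(all) - R^2(all minus the group); the components sum to R^2(all).
#' Shared components can be negative under suppression; they are reported
#' raw with a flag rather than truncated.
#'
#' @param y numeric response.
#' @param design data frame of predictors.
#' @param groups named character vector mapping every predictor to a group
#'   label (>= 2 distinct labels).
#' @return list with `components` (data frame: `groups`, `n_groups`,
#'   `component`, `unique`, `negative`), `r_squared`, and
#'   `any_negative_shared`.
#' @export
group_commonality <- function(y, design, groups) {
  stopifnot(is.data.frame(design))
  unlabeled <- setdiff(colnames(design), names(groups))
  if (length(unlabeled)) {
    stop("unlabeled predictor(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  }
  glab <- groups[colnames(design)]
  labels <- sort(unique(glab))
  g <- length(labels)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  # R^2 of every nonempty union of groups (bitmask over labels)
  union_r2 <- numeric(2^g)
  for (mask in seq_len(2^g - 1L)) {
    sel <- glab %in% labels[bitwAnd(mask, bitwShiftL(1L, 0:(g - 1L))) > 0L]
    cols <- as.matrix(design[, sel, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, cols), y)
    union_r2[mask + 1L] <- 1 - sum(fit$residuals^2) /
      sum((y - mean(y))^2)
  }
  full_mask <- 2^g - 1L
  comp <- lapply(seq_len(2^g - 1L), function(smask) {
    in_s <- which(bitwAnd(smask, bitwShiftL(1L, 0:(g - 1L))) > 0L)
    rest <- bitwAnd(full_mask, bitwNot(smask))
    subsets_t <- 0L
    cval <- 0
    # iterate over subsets T of smask
    t_mask <- smask
    repeat {
      sz <- sum(bitwAnd(t_mask, bitwShiftL(1L, 0:(g - 1L))) > 0L)
      cval <- cval - (-1)^sz * union_r2[bitwOr(t_mask, rest) + 1L]
      if (t_mask == 0L) break
      t_mask <- bitwAnd(t_mask - 1L, smask)
    }
    data.frame(groups = paste(labels[in_s], collapse = "+"),
               n_groups = length(in_s), component = cval,
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp)
  comp$unique <- comp$n_groups == 1L
  comp$negative <- comp$component < -1e-12
  full <- union_r2[2^g]
  stopifnot(abs(sum(comp$component) - full) < 1e-8)
  if (any(comp$negative)) {
    warning("negative shared commonality component(s) (suppression)")
  }
  list(components = comp, r_squared = full,
       any_negative_shared = any(comp$negative & !comp$unique))
}
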