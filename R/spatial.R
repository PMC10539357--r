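#' Spatial weights matrix from basin centroids
#'
#' Binary weights by k-nearest-neighbours (each row has exactly k
#' nonzeros; ties in distance are broken toward the lower basin index) or
#' by a distance band (symmetric: linked iff 0 < d_ij <= d). The diagonal
#' is zero. With `row_standardize` each row is scaled to sum to 1.
#'
#' @param centroids 2-column matrix or data frame of x, y coordinates
#'   (>= 3 rows, finite).
#' @param method `"knn"` or `"distance_band"`.
#' @param k neighbours for knn (k < n).
#' @param d band radius for distance_band.
#' @param row_standardize scale rows to sum 1.
#' @return n x n weights matrix.
#' @export
spatial_weights <- function(centroids, method = c("knn", "distance_band"),
                            k = 8L, d = NULL, row_standardize = TRUE) {
  method <- match.arg(method)
  xy <- as.matrix(centroids)
  n <- nrow(xy)
  if (n < 3L || !all(is.finite(xy))) {
    stop("need >= 3 finite centroids", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(xy))
  W <- matrix(0, n, n)
  if (method == "knn") {
    if (k >= n) stop("k must be < number of basins", call. = FALSE)
    for (i in seq_len(n)) {
      nb <- order(dm[i, -i])  # ties broken by index (order is stable)
      idx <- seq_len(n)[-i][nb[seq_len(k)]]
      W[i, idx] <- 1
    }
  } else {
    if (is.null(d) || d <= 0) stop("distance band 'd' required",
                                   call. = FALSE)
    W[dm > 0 & dm <= d] <- 1
    if (any(rowSums(W) == 0)) {
      stop("distance band leaves isolated basin(s)", call. = FALSE)
    }
  }
  if (row_standardize) W <- W / rowSums(W)
  rn <- if (is.data.frame(centroids)) rownames(centroids) else
    rownames(xy)
  if (!is.null(rn)) dimnames(W) <- list(rn, rn)
  W
}

#' Moran's I with permutation p-value
#'
#' I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2 with null expectation -1/(n-1). The two-sided p-value is the
#' permutation-null probability of a deviation from the expectation at
#' least as large as observed (with the +1 small-sample correction).
#' Applied here to regression residuals to diagnose residual spatial
#' autocorrelation.
#'
#' @param x numeric values (e.g. residuals), non-constant.
#' @param weights spatial weights matrix (from [spatial_weights()]).
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutations.
#' @return list with `i`, `expectation`, `p_value`, `n_perm`.
#' @export
morans_i <- function(x, weights, n_perm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("constant values: Moran's I undefined",
                       call. = FALSE)
  w_sum <- sum(weights)
  stat <- function(z) (n / w_sum) * drop(z %*% weights %*% z) / sum(z^2)
  i_obs <- stat(z)
  e_i <- -1 / (n - 1)
  i_perm <- vapply(seq_len(n_perm), function(j) stat(sample(z)),
                   numeric(1))
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
  list(i = i_obs, expectation = e_i, p_value = p, n_perm = n_perm)
}

#' Correlation of a basin-level value with centroid coordinates
#'
#' Pearson r and two-sided t-test p-value of the value against the x
#' (longitude) and y (latitude) coordinate, the standard check for plain
#' geographic trends in assemblage rates.
#'
#' @param values numeric per basin.
#' @param centroids 2-column x, y coordinates.
#' @return data frame `axis` (`x`, `y`), `r`, `p_value`.
#' @export
coordinate_correlation <- function(values, centroids) {
  xy <- as.matrix(centroids)
  stopifnot(length(values) == nrow(xy), nrow(xy) >= 3L)
  if (stats::sd(values) == 0) stop("constant values", call. = FALSE)
  res <- lapply(1:2, function(j) {
    ct <- stats::cor.test(values, xy[, j])
    data.frame(axis = c("x", "y")[j], r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
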