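#' Impute missing trait values under single-rate Brownian motion
#'
#' For each trait independently: the Brownian rate sigma^2 is estimated by
#' the standard contrasts estimator (mean squared standardized contrast) on
#' the tree pruned to observed tips, the root mean by GLS, and each missing
#' tip is imputed as the conditional mean of the Brownian multivariate
#' normal given the observed tips, with covariance sigma^2 times the
#' shared-path-length (phylogenetic variance-covariance) matrix. The
#' conditional standard deviation of each imputed value is reported.
#'
#' Imputation is univariate per trait; covariation among traits is not
#' used.
#'
#' @param tree a bifurcating `phylo` covering all species in `traits`.
#' @param traits data frame with `species` and trait columns; `NA` marks
#'   missing values.
#' @return list with `traits` (complete table), `report` (data frame:
#'   `species`, `trait`, `imputed`, `conditional_sd`) and `params`
#'   (per-trait `sigma2_hat`, `root_mean`, `n_observed`).
#' @export
impute_traits_bm <- function(tree, traits) {
  validate_phylo(tree)
  stopifnot(is.data.frame(traits), "species" %in% names(traits))
  extra <- setdiff(traits$species, tree$tip.label)
  if (length(extra)) stop("species not in tree: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  trait_cols <- setdiff(names(traits), "species")
  if (!anyNA(traits[trait_cols])) {
    return(list(traits = traits,
                report = data.frame(species = character(),
                                    trait = character(),
                                    imputed = numeric(),
                                    conditional_sd = numeric()),
                params = NULL))
  }
  C <- ape::vcv(tree)
  out <- traits
  report <- list()
  params <- list()
  # traits sharing a missingness pattern share the factorization of the
  # observed-tip covariance block and the observed-tip subtree
  pattern_of <- vapply(trait_cols, function(tc)
    paste(which(is.na(traits[[tc]])), collapse = ","), character(1))
  for (pat in unique(pattern_of)) {
    in_pat <- trait_cols[pattern_of == pat]
    obs <- traits$species[!is.na(traits[[in_pat[1L]]])]
    mis <- setdiff(traits$species, obs)
    if (length(mis) / nrow(traits) >= 0.5) {
      stop("trait '", in_pat[1L], "': >= 50% missing", call. = FALSE)
    }
    if (length(obs) < 3L) {
      stop("trait '", in_pat[1L], "': fewer than 3 observed tips",
           call. = FALSE)
    }
    Coo <- C[obs, obs, drop = FALSE]
    R <- chol(Coo)
    solve_oo <- function(b) backsolve(R, forwardsolve(t(R), b))
    sub <- if (length(obs) < length(tree$tip.label)) {
      prune_to_taxa(tree, obs)
    } else tree
    Ci_1 <- solve_oo(rep(1, length(obs)))
    A <- NULL
    if (length(mis)) {
      Cmo <- C[mis, obs, drop = FALSE]
      A <- t(solve_oo(t(Cmo)))            # Cmo %*% Coo^-1
      cvar_unit <- diag(C)[mis] - rowSums(A * Cmo)
    }
    for (tc in in_pat) {
      x <- stats::setNames(traits[[tc]], traits$species)
      pics <- bm_contrasts(sub, x[obs][sub$tip.label])
      sigma2 <- mean(pics^2)
      mu <- sum(solve_oo(x[obs])) / sum(Ci_1)
      params[[tc]] <- data.frame(trait = tc, sigma2_hat = sigma2,
                                 root_mean = mu,
                                 n_observed = length(obs))
      if (length(mis)) {
        imputed <- mu + drop(A %*% (x[obs] - mu))
        cvar <- sigma2 * cvar_unit
        out[[tc]][match(mis, out$species)] <- imputed
        report[[tc]] <- data.frame(species = mis, trait = tc,
                                   imputed = imputed,
                                   conditional_sd = sqrt(pmax(0, cvar)),
                                   stringsAsFactors = FALSE,
                                   row.names = NULL)
      }
    }
  }
  report <- report[intersect(trait_cols, names(report))]
  list(traits = out,
       report = do.call(rbind, c(report, list(make.row.names = FALSE))),
       params = do.call(rbind, params[intersect(trait_cols,
                                                names(params))]))
}
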