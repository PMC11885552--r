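# Symmetric inverse square root of a PD covariance matrix.
inv_sqrt <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop("covariance matrix is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Phylogenetic Procrustes ANOVA / PGLS with residual randomization
#'
#' Generalized least squares fit of multivariate shape on the predation
#' strategy factor and (log) centroid size with their interaction, with
#' phylogenetic error covariance from the tree. Terms are assessed by
#' sequential (type I) sums of squares; p-values and effect sizes come from
#' residual randomization of the reduced model (RRPP) in the
#' GLS-transformed space, with Z computed on log-transformed F statistics.
#'
#' @param Y n x m response matrix (scores or Procrustes coordinates), rows
#'   named by taxon.
#' @param tree `phylo` matching the rows of `Y`.
#' @param tps_factor `strategy_table` or named character vector giving the
#'   type-of-predation-strategy regime per taxon.
#' @param centroid_size named numeric vector of centroid sizes per taxon.
#' @param n_perm number of RRPP permutations.
#' @param seed integer seed.
#' @param log_size enter centroid size log-transformed (standard allometric
#'   practice)?
#' @param size_first put the size term before the factor term in the
#'   sequential decomposition? Default `FALSE` (factor first).
#' @return object of class `pgls_anova`: an ANOVA-style table with SS, df,
#'   R-squared, F, Z and p per term.
#' @export
pgls_anova <- function(Y, tree, tps_factor, centroid_size, n_perm = 999,
                       seed = 1, log_size = TRUE, size_first = FALSE) {
  Y <- align_to_tips(Y, tree)
  n <- nrow(Y)
  f <- factor(unclass(tps_factor)[tree$tip.label])
  if (anyNA(f)) stop("strategy labels missing for some tips")
  cs <- centroid_size[tree$tip.label]
  if (anyNA(cs)) stop("centroid sizes missing for some tips")
  sz <- if (log_size) log(cs) else cs

  fd <- stats::model.matrix(~f)[, -1, drop = FALSE]
  terms_list <- if (size_first)
    list(size = cbind(sz), TPS = fd, `TPS:size` = fd * sz)
  else
    list(TPS = fd, size = cbind(sz), `TPS:size` = fd * sz)

  P <- inv_sqrt(vcv_matrix(tree))
  Yt <- P %*% Y
  X <- P %*% matrix(1, n, 1)
  hats <- vector("list", length(terms_list) + 1L)
  hats[[1]] <- tcrossprod(qr.Q(qr(X)))
  dfs <- integer(length(terms_list))
  for (i in seq_along(terms_list)) {
    X <- cbind(X, P %*% terms_list[[i]])
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient design at term '", names(terms_list)[i], "'")
    hats[[i + 1]] <- tcrossprod(qr.Q(qrX))
    dfs[i] <- ncol(terms_list[[i]])
  }
  df_res <- n - ncol(X)

  ss_terms <- function(Ystar) {
    tot <- sum(Ystar * ((diag(n) - hats[[1]]) %*% Ystar))
    ss <- vapply(seq_along(terms_list), function(i) {
      sum(Ystar * ((hats[[i + 1]] - hats[[i]]) %*% Ystar))
    }, numeric(1))
    sse <- sum(Ystar * ((diag(n) - hats[[length(hats)]]) %*% Ystar))
    list(ss = ss, sse = sse, sst = tot)
  }

  obs <- ss_terms(Yt)
  F_obs <- (obs$ss / dfs) / (obs$sse / df_res)

  perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n)))
  F_perm <- matrix(NA_real_, n_perm, length(terms_list))
  for (i in seq_along(terms_list)) {
    fitted_red <- hats[[i]] %*% Yt
    resid_red <- Yt - fitted_red
    for (b in seq_len(n_perm)) {
      Ystar <- fitted_red + resid_red[perm_idx[, b], , drop = FALSE]
      st <- ss_terms(Ystar)
      F_perm[b, i] <- (st$ss[i] / dfs[i]) / (st$sse / df_res)
    }
  }
  p <- (colSums(sweep(F_perm, 2, F_obs, `>=`)) + 1) / (n_perm + 1)
  Z <- vapply(seq_along(F_obs), function(i) {
    lf <- log(F_perm[, i])
    (log(F_obs[i]) - mean(lf)) / stats::sd(lf)
  }, numeric(1))

  tab <- data.frame(
    df = c(dfs, df_res, n - 1L),
    SS = c(obs$ss, obs$sse, obs$sst),
    Rsq = c(obs$ss, obs$sse, obs$sst) / obs$sst,
    F = c(F_obs, NA, NA),
    Z = c(Z, NA, NA),
    p = c(p, NA, NA),
    row.names = c(names(terms_list), "Residuals", "Total"))
  structure(list(table = tab, n_permutations = n_perm, seed = seed,
                 formula = paste("shape ~", paste(names(terms_list),
                                                  collapse = " + ")),
                 log_size = log_size),
            class = "pgls_anova")
}

#' @export
print.pgls_anova <- function(x, ...) {
  cat("Phylogenetic Procrustes ANOVA (RRPP,", x$n_permutations,
      "permutations, seed", x$seed, ")\n")
  cat(" ", x$formula,
      if (x$log_size) "  [size = log centroid size]" else "", "\n")
  print(round(x$table, 4))
  invisible(x)
}

#' Compare PGLS fits under two regime hypotheses
#'
#' Fits [pgls_anova()] under two alternative strategy tables with an
#' identical permutation schedule and reports the change in effect size and
#' explained variance of the strategy term.
#'
#' @inheritParams pgls_anova
#' @param prior_table,posterior_table two `strategy_table`s.
#' @return list with both `pgls_anova` fits and `delta` (`dZ`, `dRsq` for
#'   the strategy term, posterior minus prior), class `pgls_comparison`.
#' @export
compare_hypotheses_pgls <- function(Y, tree, prior_table, posterior_table,
                                    centroid_size, n_perm = 999, seed = 1,
                                    log_size = TRUE) {
  prior <- pgls_anova(Y, tree, prior_table, centroid_size, n_perm, seed,
                      log_size)
  posterior <- pgls_anova(Y, tree, posterior_table, centroid_size, n_perm,
                          seed, log_size)
  delta <- c(dZ = posterior$table["TPS", "Z"] - prior$table["TPS", "Z"],
             dRsq = posterior$table["TPS", "Rsq"] - prior$table["TPS", "Rsq"])
  structure(list(prior = prior, posterior = posterior, delta = delta),
            class = "pgls_comparison")
}

#' @export
print.pgls_comparison <- function(x, ...) {
  cat("PGLS hypothesis comparison (strategy term):\n")
  cat(sprintf("  prior:     Z = %.3f, Rsq = %.3f\n",
              x$prior$table["TPS", "Z"], x$prior$table["TPS", "Rsq"]))
  cat(sprintf("  posterior: Z = %.3f, Rsq = %.3f\n",
              x$posterior$table["TPS", "Z"], x$posterior$table["TPS", "Rsq"]))
  cat(sprintf("  delta:     dZ = %+.3f, dRsq = %+.3f\n",
              x$delta["dZ"], x$delta["dRsq"]))
  invisible(x)
}
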