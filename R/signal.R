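# Multivariate BM log-likelihood profile in lambda (ML rate estimate),
# used both to optimize the tree-scaling lambda and to report logL.
mv_bm_loglik <- function(Y, C) {
  n <- nrow(Y); m <- ncol(Y)
  Cinv <- solve(C)
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  R <- crossprod(Yc, Cinv %*% Yc) / n
  R <- (R + t(R)) / 2
  ldR <- tryCatch(logdet_pd(R), error = function(e) NA_real_)
  if (is.na(ldR)) return(-Inf)
  -0.5 * (n * m * log(2 * pi) + m * logdet_pd(C) + n * ldR + n * m)
}

kmult_stat <- function(Y, C, Cinv) {
  n <- nrow(Y)
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  num <- sum(Yc^2) / sum(Yc * (Cinv %*% Yc))
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  num / expected
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' The multivariate generalization of Blomberg's K: the ratio of observed to
#' GLS-weighted sums of squares around the phylogenetic mean, scaled so that
#' data evolving by Brownian motion on the tree give K near 1. Significance
#' comes from permuting specimens across tips; the effect size Z is computed
#' on log-transformed permutation statistics. Optionally the phylogenetic
#' covariance is first rescaled by a maximum-likelihood Pagel lambda; a
#' boundary estimate `lambda = 0` means the data carry no phylogenetic
#' signal, in which case K, p, Z and logL are reported as `NA` sentinels.
#'
#' @param Y n x m matrix (scores or Procrustes coordinates), rows named by
#'   taxon. Using m >= n variables triggers a warning (prefer scores).
#' @param tree `phylo` with tips matching the rows of `Y`.
#' @param n_perm number of row permutations.
#' @param seed integer seed for the permutations.
#' @param optimize_lambda maximize the multivariate BM likelihood over
#'   `lambda` in `[0, 1]` before computing K?
#' @return object of class `phylo_signal` with fields `Kmult`, `p_value`,
#'   `Z`, `scaling_lambda`, `logL_lambda`, `n_permutations`, `seed`.
#' @export
kmult <- function(Y, tree, n_perm = 999, seed = 1, optimize_lambda = FALSE) {
  Y <- align_to_tips(Y, tree)
  n <- nrow(Y)
  if (ncol(Y) >= n)
    warning("more variables (", ncol(Y), ") than specimens (", n,
            "); consider ordination scores")
  C0 <- vcv_matrix(tree)
  lambda <- 1
  logL <- NA_real_
  if (optimize_lambda) {
    # with m >= n the ML rate matrix is singular; profile lambda on the
    # non-degenerate principal axes of the data instead (a rotation that
    # drops only zero-variance directions)
    Yl <- Y
    if (ncol(Yl) >= n) {
      sv <- svd(sweep(Yl, 2, colMeans(Yl)))
      r <- sum(sv$d > sv$d[1] * 1e-10)
      r <- min(r, n - 2L)
      Yl <- sweep(Y, 2, colMeans(Y)) %*% sv$v[, seq_len(r), drop = FALSE]
      rownames(Yl) <- rownames(Y)
    }
    prof <- function(l) mv_bm_loglik(Yl, lambda_transform(C0, l))
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, prof(0), prof(1))
    lambda <- cand[which.max(vals)]
    logL <- max(vals)
    if (lambda <= 1e-6) {
      return(structure(list(Kmult = NA_real_, p_value = NA_real_,
                            Z = NA_real_, scaling_lambda = 0,
                            logL_lambda = NA_real_, n_permutations = n_perm,
                            seed = seed), class = "phylo_signal"))
    }
  }
  C <- lambda_transform(C0, lambda)
  Cinv <- solve(C)
  K_obs <- kmult_stat(Y, C, Cinv)
  K_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    kmult_stat(Y[sample.int(n), , drop = FALSE], C, Cinv)
  }, numeric(1)))
  p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  lk <- log(K_perm)
  Z <- (log(K_obs) - mean(lk)) / stats::sd(lk)
  structure(list(Kmult = K_obs, p_value = p, Z = Z,
                 scaling_lambda = lambda, logL_lambda = logL,
                 n_permutations = n_perm, seed = seed),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Multivariate phylogenetic signal\n")
  if (!is.na(x$scaling_lambda) && x$scaling_lambda == 0) {
    cat("  scaling lambda = 0: no phylogenetic signal in the data;",
        "K, Z, p and logL not returned\n")
    return(invisible(x))
  }
  cat(sprintf("  Kmult = %.3f, Z = %.3f, p = %.3f (%d permutations)\n",
              x$Kmult, x$Z, x$p_value, x$n_permutations))
  if (!is.na(x$logL_lambda))
    cat(sprintf("  scaling lambda = %.3f (logL = %.2f)\n",
                x$scaling_lambda, x$logL_lambda))
  invisible(x)
}
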