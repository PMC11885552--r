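# Run an expression with a temporary RNG state; NULL seed leaves the
# current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cholesky-like factor of a symmetric PSD matrix, tolerant of tiny negative
# eigenvalues from numerical error; returns upper-triangular-like factor L
# with t(L) %*% L = M.
chol_psd <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

# Log-determinant of a positive definite matrix via Cholesky.
logdet_pd <- function(M) 2 * sum(log(diag(chol(M))))

# Deterministically derive a per-stage seed below 2^31 from a master seed
# and a stage name.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
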