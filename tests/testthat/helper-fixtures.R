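# Shared helpers: tiny trees, random configurations and independent
# brute-force oracles used across the test files.

tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_tree <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

random_config <- function(k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(2 * k), k, 2)
}

# apply a random similarity transform (rotation + scale + translation)
similarity_transform <- function(cfg, theta, s, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(cfg %*% R * s, 2, -shift)
}

# Brute-force Mk-ER log-likelihood: sum over all internal node state
# assignments (stationary uniform root prior).
mk_brute_loglik <- function(tree, tip_states, q, levels) {
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  tip_idx <- match(tip_states[tree$tip.label], levels)
  pmat <- function(t) matrix(c(0.5 + 0.5 * exp(-2 * q * t),
                               0.5 - 0.5 * exp(-2 * q * t),
                               0.5 - 0.5 * exp(-2 * q * t),
                               0.5 + 0.5 * exp(-2 * q * t)), 2, 2)
  total <- 0
  for (assign_idx in 0:(2^n_int - 1)) {
    int_states <- as.integer(intToBits(assign_idx))[seq_len(n_int)] + 1L
    state_of <- function(node) if (node <= n) tip_idx[node]
                               else int_states[node - n]
    lik <- 0.5
    for (ei in seq_len(nrow(tree$edge))) {
      P <- pmat(tree$edge.length[ei])
      lik <- lik * P[state_of(tree$edge[ei, 1]), state_of(tree$edge[ei, 2])]
    }
    total <- total + lik
  }
  log(total)
}

# Independent dense-Gaussian likelihood oracle: builds the nm x nm
# covariance by direct per-tip-pair path integration (numerical quadrature
# for OU), evaluates the multivariate normal density at the GLS mean that
# maximizes it, i.e. the same profile likelihood by a different route.
oracle_loglik <- function(model, tree, Y, params, painting = NULL) {
  n <- nrow(Y); m <- ncol(Y)
  C <- ape::vcv.phylo(tree)
  C <- C[rownames(Y), rownames(Y)]
  depth <- diag(C)
  cov_pair <- function(i, j, a, b) {
    s <- C[i, j]
    if (model == "BM") return(params$R[a, b] * s)
    if (model == "EB") {
      bb <- params$b
      if (abs(bb) < 1e-14) return(params$R[a, b] * s)
      return(params$R[a, b] * (exp(bb * s) - 1) / bb)
    }
    if (model == "BMM") {
      # integrate regime-specific rates along the shared root path of the
      # lineage leading to the MRCA, via the painting's path segments
      segs <- phylomorph:::node_path_segments(painting)
      mr <- ape::mrca(tree)[rownames(Y)[i], rownames(Y)[j]]
      sp <- segs[[mr]]
      tot <- 0
      if (i == j) sp <- segs[[match(rownames(Y)[i], painting$tree$tip.label)]]
      if (nrow(sp))
        for (r in seq_len(nrow(sp)))
          tot <- tot + params$R_list[[sp[r, 3]]][a, b] * (sp[r, 2] - sp[r, 1])
      return(tot)
    }
    # OU (OU1/OUM share the covariance form): numerical quadrature
    al_a <- params$alpha[a]; al_b <- params$alpha[b]
    ti <- depth[i]; tj <- depth[j]
    if (s <= 0) return(0)
    f <- function(u) exp(-al_a * (ti - u) - al_b * (tj - u))
    params$R[a, b] * stats::integrate(f, 0, s, rel.tol = 1e-12)$value
  }
  V <- matrix(NA_real_, n * m, n * m)
  for (a in seq_len(m)) for (b in seq_len(m))
    for (i in seq_len(n)) for (j in seq_len(n))
      V[(a - 1) * n + i, (b - 1) * n + j] <- cov_pair(i, j, a, b)
  D <- if (model == "OUM")
    phylomorph:::mean_design("OUM", tree, m, painting, params$alpha)
  else diag(m) %x% matrix(1, n, 1)
  y <- as.vector(Y)
  Vi <- solve(V)
  beta <- solve(t(D) %*% Vi %*% D, t(D) %*% Vi %*% y)
  r <- y - D %*% beta
  as.numeric(-0.5 * (n * m * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% Vi %*% r))
}

# build a landmark_set from a list of k x 2 configurations
lmset_from <- function(configs, ids = paste0("s", seq_along(configs)),
                       missing = NULL, curves = list()) {
  k <- nrow(configs[[1]])
  arr <- array(NA_real_, c(length(configs), k, 2))
  for (i in seq_along(configs)) arr[i, , ] <- configs[[i]]
  landmark_set(arr, ids, curves = curves, missing = missing)
}
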