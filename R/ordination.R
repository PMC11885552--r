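# Shared helpers -----------------------------------------------------------

# GLS mean of Y under phylogenetic covariance C: a = (1' Cinv 1)^-1 1' Cinv Y
gls_mean <- function(Y, Cinv) {
  one <- rep(1, nrow(Y))
  w <- Cinv %*% one
  as.vector(crossprod(w, Y)) / sum(w)
}

# Fix column signs so the largest-magnitude loading of each axis is positive.
fix_signs <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

new_ordination <- function(kind, scores, rotation, eigenvalues, gls_mean,
                           tree = NULL) {
  pv <- eigenvalues / sum(eigenvalues)
  disp <- colSums(scores^2)
  ptd <- disp / sum(disp)
  colnames(scores) <- colnames(rotation) <-
    paste0(switch(kind, PCA = "PC", PhyloPCA = "pPC", PACA = "C"),
           seq_len(ncol(scores)))
  structure(list(kind = kind, scores = scores, rotation = rotation,
                 eigenvalues = eigenvalues, proportion_variance = pv,
                 proportion_tip_dispersion = ptd, gls_mean = gls_mean,
                 tree = tree),
            class = "phylo_ordination")
}

#' @export
print.phylo_ordination <- function(x, ...) {
  cat(x$kind, "ordination:", nrow(x$scores), "specimens,",
      ncol(x$scores), "axes\n")
  m <- min(5L, ncol(x$scores))
  tab <- rbind(variance = x$proportion_variance[1:m],
               tip_dispersion = x$proportion_tip_dispersion[1:m])
  colnames(tab) <- colnames(x$scores)[1:m]
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.phylo_ordination <- function(object, ...) {
  data.frame(axis = colnames(object$scores),
             eigenvalue = object$eigenvalues,
             prop_variance = object$proportion_variance,
             cum_variance = cumsum(object$proportion_variance),
             prop_tip_dispersion = object$proportion_tip_dispersion,
             cum_tip_dispersion = cumsum(object$proportion_tip_dispersion),
             row.names = NULL)
}

#' @export
plot.phylo_ordination <- function(x, axes = c(1, 2), groups = NULL,
                                  labels = TRUE, ...) {
  sc <- x$scores[, axes, drop = FALSE]
  prop <- round(100 * x$proportion_variance[axes], 1)
  col <- if (is.null(groups)) "black"
         else c("black", "red")[as.integer(factor(groups[rownames(sc)]))]
  plot(sc, col = col, pch = 19,
       xlab = paste0(colnames(sc)[1], " (", prop[1], "%)"),
       ylab = paste0(colnames(sc)[2], " (", prop[2], "%)"), ...)
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      pts <- sc[rownames(sc) %in% names(groups)[groups == g], , drop = FALSE]
      if (nrow(pts) >= 3) {
        h <- grDevices::chull(pts)
        graphics::polygon(pts[h, ], border = NA,
                          col = grDevices::adjustcolor(
                            c("red", "blue")[1 + (g == unique(groups)[1])],
                            alpha.f = 0.15))
      }
    }
  }
  if (labels) graphics::text(sc, rownames(sc), cex = 0.6, pos = 3)
  invisible(x)
}

# Order a data matrix to tree tips, erroring on mismatch.
align_to_tips <- function(Y, tree) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("data matrix must have taxon row names")
  missing <- setdiff(tree$tip.label, rownames(Y))
  if (length(missing)) stop("no data for tips: ",
                            paste(missing, collapse = ", "))
  Y[tree$tip.label, , drop = FALSE]
}

#' Ordinary principal component analysis of shape variables
#'
#' @param Y n x p data matrix (rows named by specimen).
#' @return `phylo_ordination` of kind `"PCA"`.
#' @export
shape_pca <- function(Y) {
  Y <- as.matrix(Y)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  S <- crossprod(Yc) / (nrow(Y) - 1)
  e <- eigen(S, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10)
  rot <- e$vectors[, keep, drop = FALSE]
  sc <- Yc %*% rot
  fs <- fix_signs(rot, sc)
  rownames(fs$scores) <- rownames(Y)
  new_ordination("PCA", fs$scores, fs$rotation, e$values[keep], ctr)
}

#' Phylogenetic principal component analysis
#'
#' Principal components of the evolutionary (GLS) trait covariance: the data
#' are centered at the phylogenetic GLS mean, the rate matrix
#' `R = Yc' Cinv Yc / (n-1)` is eigendecomposed, and the centered data are
#' projected onto its eigenvectors. Early axes are decorrelated from
#' phylogenetic structure. Reduces exactly to ordinary PCA on a star
#' phylogeny (`C = I`).
#'
#' @param Y n x p matrix of flattened Procrustes coordinates or other traits,
#'   rows named by taxon.
#' @param tree time-calibrated `phylo` whose tips match the rows of `Y`.
#' @return `phylo_ordination` of kind `"PhyloPCA"`; `proportion_variance`
#'   comes from the eigenvalues of the GLS covariance,
#'   `proportion_tip_dispersion` from the variance of tip scores.
#' @export
phylo_pca <- function(Y, tree) {
  Y <- align_to_tips(Y, tree)
  C <- vcv_matrix(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  R <- crossprod(Yc, Cinv %*% Yc) / (nrow(Y) - 1)
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10)
  rot <- e$vectors[, keep, drop = FALSE]
  sc <- Yc %*% rot
  fs <- fix_signs(rot, sc)
  rownames(fs$scores) <- rownames(Y)
  new_ordination("PhyloPCA", fs$scores, fs$rotation, e$values[keep], a, tree)
}

#' Phylogenetically aligned component analysis
#'
#' Rotation of the GLS-centered data maximizing alignment of the leading
#' axes with phylogenetic covariance: eigenvectors of `Yc' C Yc`. Axis
#' importance is measured as the proportion of tip dispersion (summed
#' squared tip scores). Reduces exactly to ordinary PCA when `C = I`.
#'
#' @inheritParams phylo_pca
#' @return `phylo_ordination` of kind `"PACA"`.
#' @export
paca <- function(Y, tree) {
  Y <- align_to_tips(Y, tree)
  C <- vcv_matrix(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  A <- crossprod(Yc, C %*% Yc)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10)
  rot <- e$vectors[, keep, drop = FALSE]
  sc <- Yc %*% rot
  fs <- fix_signs(rot, sc)
  rownames(fs$scores) <- rownames(Y)
  new_ordination("PACA", fs$scores, fs$rotation, e$values[keep], a, tree)
}

#' Select leading axes reaching a cumulative proportion threshold
#'
#' @param ordination a `phylo_ordination`.
#' @param threshold cumulative proportion to reach (default 0.90).
#' @param basis `"variance"` (eigenvalue proportions) or `"tip_dispersion"`.
#' @return integer vector `1:m`, the smallest prefix of axes whose cumulative
#'   proportion reaches the threshold.
#' @export
select_axes <- function(ordination, threshold = 0.90,
                        basis = c("variance", "tip_dispersion")) {
  basis <- match.arg(basis)
  p <- switch(basis, variance = ordination$proportion_variance,
              tip_dispersion = ordination$proportion_tip_dispersion)
  m <- which(cumsum(p) >= threshold - 1e-12)[1]
  if (is.na(m)) m <- length(p)
  seq_len(m)
}

# Disparity of a set of rows: mean pairwise squared Euclidean distance.
disparity_of <- function(Y) {
  n <- nrow(Y)
  if (is.null(n) || n < 2) return(0)
  sum(stats::dist(Y)^2) / (n * (n - 1) / 2)
}

# Mean relative subclade disparity at each divergence time.  A lineage is
# "present" at time t if its edge spans t (the lineage splitting exactly at
# t counts, its daughters do not yet); at the root the single lineage is the
# whole clade, so the curve starts at 1.
dtt_curve <- function(tree, Y, depths, tip_sets, times) {
  total <- disparity_of(Y)
  if (total == 0) return(rep(0, length(times)))
  parent_depth <- depths[tree$edge[, 1]]
  child_depth <- depths[tree$edge[, 2]]
  vapply(times, function(t) {
    if (t <= 1e-12) return(1)
    cross <- which(parent_depth < t - 1e-12 & child_depth >= t - 1e-12)
    if (!length(cross)) return(0)
    mean(vapply(cross, function(ei) {
      tips <- tip_sets[[tree$edge[ei, 2]]]
      disparity_of(Y[tips, , drop = FALSE]) / total
    }, numeric(1)))
  }, numeric(1))
}

#' Disparity through time with a Brownian-motion envelope
#'
#' At each internal-node divergence time, the disparity (mean pairwise
#' squared distance) of every subclade whose stem crosses that time is
#' divided by the total disparity of the clade and averaged; the curve
#' starts at 1 at the root and is compared to a pointwise 95% envelope from
#' multivariate Brownian-motion simulations whose rate matrix is the GLS
#' estimate from the data.
#'
#' @param tree time-calibrated `phylo`.
#' @param scores n x m matrix (rows named by taxon), typically the retained
#'   Phylo-PC scores.
#' @param n_sim number of Brownian-motion simulations for the envelope.
#' @param seed integer seed for the simulations.
#' @return object of class `dtt_result` with `times` (relative 0-1),
#'   `observed`, `sim_mean`, `lower`, `upper`.
#' @export
dtt <- function(tree, scores, n_sim = 1000, seed = 1) {
  Y <- align_to_tips(scores, tree)
  if (nrow(Y) < 4) stop("dtt requires at least 4 tips")
  depths <- node_depths(tree)
  n <- length(tree$tip.label)
  tip_sets <- tip_descendants(tree)
  internal <- (n + 1):(n + tree$Nnode)
  times <- sort(unique(depths[internal]))
  max_t <- max(depths[1:n])

  obs <- dtt_curve(tree, Y, depths, tip_sets, times)

  C <- vcv_matrix(tree)
  Cinv <- solve(C)
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  R <- crossprod(Yc, Cinv %*% Yc) / (nrow(Y) - 1)
  R <- (R + t(R)) / 2
  sims <- with_seed(seed, {
    L_C <- chol_psd(C)
    L_R <- chol_psd(R)
    replicate(n_sim, {
      Z <- matrix(stats::rnorm(n * ncol(Y)), n, ncol(Y))
      Ysim <- t(L_C) %*% Z %*% L_R
      rownames(Ysim) <- tree$tip.label
      dtt_curve(tree, Ysim, depths, tip_sets, times)
    })
  })
  structure(list(times = times / max_t, observed = obs,
                 sim_mean = rowMeans(sims),
                 lower = apply(sims, 1, stats::quantile, 0.025),
                 upper = apply(sims, 1, stats::quantile, 0.975),
                 n_sim = n_sim, seed = seed),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat("Disparity through time:", length(x$times), "divergence times,",
      x$n_sim, "BM simulations (seed", x$seed, ")\n")
  breach <- sum(x$observed > x$upper | x$observed < x$lower)
  cat("  observed curve outside 95% envelope at", breach, "of",
      length(x$times), "times\n")
  invisible(x)
}

#' @export
plot.dtt_result <- function(x, ...) {
  plot(x$times, x$observed, type = "l", lwd = 2, ylim = c(0, max(1, x$upper)),
       xlab = "relative time", ylab = "mean relative subclade disparity", ...)
  graphics::polygon(c(x$times, rev(x$times)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$times, x$sim_mean, lty = 2)
  graphics::lines(x$times, x$observed, lwd = 2)
  invisible(x)
}

# tips (labels) descending from every node, as a list indexed by node number
tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- rev(preorder_edges(tree))
  for (ei in ord) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
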