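# --- univariate Hansen (OU) machinery for the forward shift search --------
#
# The forward search treats each trait as an independent univariate OU
# process sharing the regime painting: per trait a pull rate alpha, a
# diffusion sigma2, and one optimum per regime (profiled by GLS); per-trait
# small-sample AIC values are summed across traits.

# Painting implied by a set of shifts: a named integer vector mapping edge
# index -> regime id; regime of any point is the most recent shift above it
# (root regime 1).
shifts_to_painting <- function(tree, shifts) {
  K <- length(shifts) + 1L
  regimes <- paste0("regime_", seq_len(K))
  reg_of_edge <- integer(nrow(tree$edge))
  node_reg <- integer(length(tree$tip.label) + tree$Nnode)
  node_reg[length(tree$tip.label) + 1L] <- 1L
  for (ei in preorder_edges(tree)) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    r <- node_reg[p]
    hit <- match(ei, shifts)
    if (!is.na(hit)) r <- hit + 1L
    reg_of_edge[ei] <- r
    node_reg[ch] <- r
  }
  maps <- lapply(seq_len(nrow(tree$edge)), function(ei)
    stats::setNames(tree$edge.length[ei], regimes[reg_of_edge[ei]]))
  regime_painting(tree, maps, regimes)
}

# Univariate OU logL maximized over alpha, with the diffusion sigma2 and
# the optima profiled analytically (sigma2 scales the whole covariance, so
# its ML estimate is the whitened mean squared residual).
hansen_fit_1d <- function(yvec, tree, painting, C, segs = NULL) {
  n <- length(yvec)
  Tmax <- max(diag(C))
  if (is.null(segs)) segs <- node_path_segments(painting)
  prof <- function(la) {
    alpha <- exp(la)
    V1 <- ou_cov(tree, matrix(1, 1, 1), alpha, C)
    D <- mean_design("OUM", tree, 1, painting, alpha, segs)
    used <- colSums(abs(D)) > 1e-14
    ch <- tryCatch(chol(V1), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Li_y <- backsolve(ch, yvec, transpose = TRUE)
    Li_D <- backsolve(ch, D[, used, drop = FALSE], transpose = TRUE)
    beta <- tryCatch(qr.solve(Li_D, Li_y), error = function(e) NULL)
    if (is.null(beta)) return(-Inf)
    rss <- sum((Li_y - Li_D %*% beta)^2)
    s2 <- rss / n
    if (s2 <= 0) return(-Inf)
    -0.5 * (n * log(2 * pi) + n * log(s2) + 2 * sum(log(diag(ch))) + n)
  }
  opt <- stats::optimize(prof, log(c(1e-4, 50) / Tmax), maximum = TRUE,
                         tol = 1e-6)
  list(logL = opt$objective)
}

# Joint small-sample AIC over all traits: per trait an alpha, a sigma2 and
# one optimum per regime, plus one location parameter per accepted shift;
# the sample size is the total number of observations (tips x traits).
surface_score <- function(Y, tree, painting, C) {
  segs <- node_path_segments(painting)
  logL <- sum(vapply(seq_len(ncol(Y)), function(j)
    hansen_fit_1d(Y[, j], tree, painting, C, segs)$logL, numeric(1)))
  K <- length(unique(unlist(lapply(painting$maps, names))))
  m <- ncol(Y)
  p <- 2 * m + K * m + (K - 1)
  n_tot <- nrow(Y) * m
  aicc_den <- n_tot - p - 1
  if (aicc_den <= 0) return(Inf)
  -2 * logL + 2 * p + 2 * p * (p + 1) / aicc_den
}

#' Forward stepwise regime-shift search (stepwise AICc on Hansen models)
#'
#' Starting from a single-regime Ornstein-Uhlenbeck model, repeatedly
#' proposes a new selective regime originating at every branch, keeps the
#' proposal with the best summed per-trait small-sample AIC, and stops when
#' no proposal improves the criterion by more than `min_improvement`. This
#' estimates an adaptive landscape painting without any prior hypothesis;
#' only the forward (shift-adding) phase is performed.
#'
#' @param tree `phylo`.
#' @param Y n x m matrix of retained ordination scores (traits treated as
#'   independent univariate OU processes).
#' @param min_improvement AICc decrease required to accept a shift
#'   (default 2, the conventional substantial-support cutoff for stepwise
#'   information-criterion searches).
#' @param max_shifts cap on accepted shifts.
#' @param seed integer seed (recorded; the search itself is deterministic).
#' @return object of class `surface_result`: `steps` (per-step log),
#'   `shifts` (edge indices), `painting`, `final_aicc`.
#' @export
surface_forward <- function(tree, Y, min_improvement = 2, max_shifts = 8,
                            seed = 1) {
  Y <- align_to_tips(Y, tree)
  C <- vcv_matrix(tree)
  shifts <- integer(0)
  cur_paint <- shifts_to_painting(tree, shifts)
  cur_aicc <- surface_score(Y, tree, cur_paint, C)
  steps <- data.frame(step = 0L, shift_edge = NA_integer_,
                      aicc = cur_aicc)
  repeat {
    if (length(shifts) >= max_shifts) break
    cand <- setdiff(seq_len(nrow(tree$edge)), shifts)
    scores <- vapply(cand, function(ei) {
      p <- shifts_to_painting(tree, c(shifts, ei))
      tryCatch(surface_score(Y, tree, p, C), error = function(e) Inf)
    }, numeric(1))
    best <- which.min(scores)
    if (!is.finite(scores[best]) ||
        cur_aicc - scores[best] < min_improvement) break
    shifts <- c(shifts, cand[best])
    cur_aicc <- scores[best]
    steps <- rbind(steps, data.frame(step = length(shifts),
                                     shift_edge = cand[best],
                                     aicc = cur_aicc))
  }
  structure(list(steps = steps, shifts = shifts,
                 painting = shifts_to_painting(tree, shifts),
                 final_aicc = cur_aicc, seed = seed, tree = tree),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat("Forward regime-shift search:", length(x$shifts),
      "shift(s) accepted\n")
  print(x$steps, row.names = FALSE)
  if (length(x$shifts)) {
    for (ei in x$shifts) {
      tips <- tip_descendants(x$tree)[[x$tree$edge[ei, 2]]]
      cat("  shift on edge", ei, "-> clade of", length(tips), "tips (",
          paste(utils::head(tips, 3), collapse = ", "),
          if (length(tips) > 3) ", ..." else "", ")\n")
    }
  }
  invisible(x)
}

#' Taxa subtended by the stem edge where a shift was placed
#' @param x a `surface_result`.
#' @return list of character vectors, one per accepted shift.
#' @export
shift_clades <- function(x) {
  sets <- tip_descendants(x$tree)
  lapply(x$shifts, function(ei) sets[[x$tree$edge[ei, 2]]])
}
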