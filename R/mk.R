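# --- 2-state equal-rates Markov chain on a tree ---------------------------

# Transition probability matrix of the symmetric 2-state chain.
er_pmat <- function(q, t) {
  e <- exp(-2 * q * t)
  matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e,
           0.5 - 0.5 * e, 0.5 + 0.5 * e), 2, 2)
}

# Downward (Felsenstein pruning) partial likelihoods; rows = nodes in ape
# numbering, columns = states.  tip_states: named character vector.
mk_partials <- function(tree, tip_states, q, levels) {
  n <- length(tree$tip.label)
  L <- matrix(1, n + tree$Nnode, 2)
  st <- match(tip_states[tree$tip.label], levels)
  if (anyNA(st)) stop("tip states missing or outside declared levels")
  L[cbind(seq_len(n), st)] <- 1
  L[cbind(seq_len(n), 3 - st)] <- 0
  for (ei in rev(preorder_edges(tree))) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    P <- er_pmat(q, tree$edge.length[ei])
    L[p, ] <- L[p, ] * as.vector(P %*% L[ch, ])
  }
  L
}

mk_loglik <- function(tree, tip_states, q, levels) {
  L <- mk_partials(tree, tip_states, q, levels)
  log(sum(0.5 * L[length(tree$tip.label) + 1L, ]))
}

#' Fit the equal-rates 2-state Markov model
#'
#' Maximum-likelihood estimate of the single transition rate of the
#' symmetric (equal rates) continuous-time Markov chain for a binary
#' character on a time-calibrated tree, with a stationary (uniform) root
#' prior, via Felsenstein pruning. Monomorphic characters return a boundary
#' estimate near zero rather than an error.
#'
#' @param tree `phylo` with branch lengths in Myr.
#' @param tip_states named character vector of states for every tip.
#' @param q_max upper bound of the rate search; defaults to 500 divided by
#'   the tree height.
#' @return object of class `mk_fit` with `q`, `logL`, `levels`.
#' @export
fit_mk_er <- function(tree, tip_states, q_max = NULL) {
  tip_states <- stats::setNames(as.character(tip_states),
                                normalize_labels(names(tip_states)))
  levels <- sort(unique(tip_states[tree$tip.label]))
  if (length(levels) == 1L) levels <- c(levels, paste0(".absent_", levels))
  if (length(levels) != 2L) stop("fit_mk_er requires a binary character")
  if (is.null(q_max)) q_max <- 500 / max(node_depths(tree))
  f <- function(lq) mk_loglik(tree, tip_states, exp(lq), levels)
  opt <- stats::optimize(f, c(log(1e-9), log(q_max)), maximum = TRUE,
                         tol = 1e-10)
  q <- exp(opt$maximum)
  if (f(log(1e-9)) >= opt$objective - 1e-10) q <- 1e-9  # boundary: q -> 0
  structure(list(q = q, logL = mk_loglik(tree, tip_states, q, levels),
                 levels = levels, tip_states = tip_states[tree$tip.label]),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Equal-rates Mk fit: q = %.5g (logL = %.3f); states: %s\n",
              x$q, x$logL, paste(x$levels, collapse = "/")))
  invisible(x)
}

# Marginal ancestral state probabilities at every node (pruning up + down);
# independent of the stochastic-mapping sampler, used as its check.
mk_marginals <- function(tree, tip_states, q, levels) {
  n <- length(tree$tip.label)
  D <- mk_partials(tree, tip_states, q, levels)
  U <- matrix(NA_real_, n + tree$Nnode, 2)
  root <- n + 1L
  U[root, ] <- 0.5
  for (ei in preorder_edges(tree)) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    P <- er_pmat(q, tree$edge.length[ei])
    below_ch <- as.vector(P %*% D[ch, ])
    other <- U[p, ] * D[p, ] / ifelse(below_ch > 0, below_ch, 1)
    U[ch, ] <- as.vector(t(P) %*% other)
  }
  marg <- U * D
  marg / rowSums(marg)
}

# --- regime paintings -----------------------------------------------------

#' Regime painting of a tree
#'
#' A painting assigns a regime label to every branch segment: `maps` is a
#' list (one entry per row of `tree$edge`) of named duration vectors, in
#' order from the parent end to the child end of the branch, exactly as in
#' SIMMAP-style annotated trees.
#'
#' @param tree `phylo`.
#' @param maps list of named numeric vectors (durations summing to each
#'   branch length).
#' @param regimes character vector of regime levels.
#' @return object of class `regime_painting`.
#' @export
regime_painting <- function(tree, maps, regimes) {
  if (length(maps) != nrow(tree$edge))
    stop("one maps entry per edge required")
  for (ei in seq_along(maps)) {
    if (abs(sum(maps[[ei]]) - tree$edge.length[ei]) > 1e-8)
      stop("segment durations on edge ", ei, " do not sum to its length")
    if (!all(names(maps[[ei]]) %in% regimes))
      stop("unknown regime label on edge ", ei)
  }
  structure(list(tree = tree, maps = maps, regimes = regimes),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  me <- mapped_edge(x)
  cat("Regime painting:", length(x$regimes), "regimes on",
      nrow(x$tree$edge), "branches\n")
  tot <- colSums(me)
  cat(" ", paste(sprintf("%s: %.1f Myr", colnames(me), tot),
                 collapse = ", "), "\n")
  tr <- table(tip_states_from_painting(x))
  cat("  tip states:", paste(sprintf("%s (%d)", names(tr), tr),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Time spent in each regime per branch
#' @param painting a `regime_painting`.
#' @return matrix edges x regimes of durations.
#' @export
mapped_edge <- function(painting) {
  out <- matrix(0, nrow(painting$tree$edge), length(painting$regimes),
                dimnames = list(NULL, painting$regimes))
  for (ei in seq_along(painting$maps)) {
    m <- painting$maps[[ei]]
    for (j in seq_along(m)) out[ei, names(m)[j]] <- out[ei, names(m)[j]] + m[j]
  }
  out
}

#' Tip states implied by a painting (regime of each terminal segment)
#' @param painting a `regime_painting`.
#' @return named character vector over tips.
#' @export
tip_states_from_painting <- function(painting) {
  tree <- painting$tree
  n <- length(tree$tip.label)
  out <- character(n)
  for (ei in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[ei, 2]
    if (ch <= n) {
      m <- painting$maps[[ei]]
      out[ch] <- names(m)[length(m)]
    }
  }
  stats::setNames(out, tree$tip.label)
}

# Cumulative time spent in each regime from the root to every node.
regime_times_to_nodes <- function(painting) {
  tree <- painting$tree
  K <- length(painting$regimes)
  n <- length(tree$tip.label)
  out <- matrix(0, n + tree$Nnode, K,
                dimnames = list(NULL, painting$regimes))
  for (ei in preorder_edges(tree)) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    out[ch, ] <- out[p, ]
    m <- painting$maps[[ei]]
    for (j in seq_along(m))
      out[ch, names(m)[j]] <- out[ch, names(m)[j]] + m[j]
  }
  out
}

# Absolute-time segments (start, end, regime index) along the root-to-node
# path for every node; used by OU mean weights.
node_path_segments <- function(painting) {
  tree <- painting$tree
  depths <- node_depths(tree)
  n <- length(tree$tip.label)
  segs <- vector("list", n + tree$Nnode)
  root <- n + 1L
  segs[[root]] <- matrix(numeric(0), 0, 3)
  for (ei in preorder_edges(tree)) {
    p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    m <- painting$maps[[ei]]
    t0 <- depths[p]
    rows <- matrix(NA_real_, length(m), 3)
    for (j in seq_along(m)) {
      rows[j, ] <- c(t0, t0 + m[j], match(names(m)[j], painting$regimes))
      t0 <- t0 + m[j]
    }
    segs[[ch]] <- rbind(segs[[p]], rows)
  }
  segs
}

#' Deterministic regime painting from a clade hypothesis
#'
#' Places a single regime shift at the stem of the smallest clade containing
#' all taxa of the derived regime; the labels must therefore be paintable as
#' one monophyletic group against the background regime, otherwise an error
#' asks for stochastic mapping instead.
#'
#' @param tree `phylo`.
#' @param strategy `strategy_table` (two levels, all tips labelled).
#' @param stem_convention `"stem"` paints the entire stem branch of the
#'   clade in the derived regime; `"node"` starts the derived regime at the
#'   crown node.
#' @return a [regime_painting()].
#' @export
paint_from_hypothesis <- function(tree, strategy,
                                  stem_convention = c("stem", "node")) {
  stem_convention <- match.arg(stem_convention)
  st <- unclass(strategy)[tree$tip.label]
  if (anyNA(st)) stop("strategy labels missing for some tips")
  levels <- sort(unique(st))
  n <- length(tree$tip.label)
  maps <- vector("list", nrow(tree$edge))
  if (length(levels) == 1L) {
    for (ei in seq_len(nrow(tree$edge)))
      maps[[ei]] <- stats::setNames(tree$edge.length[ei], levels)
    return(regime_painting(tree, maps, levels))
  }
  sets <- tip_descendants(tree)
  derived <- NULL
  for (lv in levels) {
    tips_lv <- tree$tip.label[st == lv]
    if (length(tips_lv) == n) next
    node <- if (length(tips_lv) == 1L) match(tips_lv, tree$tip.label)
            else ape::getMRCA(tree, tips_lv)
    if (setequal(sets[[node]], tips_lv) && node != n + 1L) {
      derived <- lv; dnode <- node
      break
    }
  }
  if (is.null(derived))
    stop("neither regime forms a paintable (monophyletic, non-root) clade; ",
         "use simmap_sample() for a stochastic painting")
  background <- setdiff(levels, derived)
  inside <- c(dnode,
              which(vapply(seq_along(sets), function(v)
                all(sets[[v]] %in% sets[[dnode]]) && v != dnode,
                logical(1))))
  for (ei in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[ei, 2]
    len <- tree$edge.length[ei]
    if (ch == dnode) {
      maps[[ei]] <- if (stem_convention == "stem")
        stats::setNames(len, derived)
      else stats::setNames(len, background)
    } else if (ch %in% inside) {
      maps[[ei]] <- stats::setNames(len, derived)
    } else {
      maps[[ei]] <- stats::setNames(len, background)
    }
  }
  regime_painting(tree, maps, levels)
}

# Endpoint-conditioned path on one branch of the 2-state ER chain via
# uniformization: with rate q the uniformized chain is the deterministic
# state swap, so the number of transitions is Poisson(q t) restricted to
# the parity of the endpoints and transition times are uniform.
sample_er_path <- function(a, b, t, q, levels) {
  lam <- q * t
  parity <- as.integer(a != b)
  nmax <- max(10, ceiling(lam + 12 * sqrt(lam + 1)))
  ns <- seq(parity, nmax, by = 2)
  w <- stats::dpois(ns, lam)
  if (sum(w) <= 0) {
    if (parity == 1) stop("endpoint-conditioned path impossible at q ~ 0")
    ns <- 0; w <- 1
  }
  nj <- sample(length(ns), 1, prob = w)
  njumps <- ns[nj]
  if (njumps == 0) return(stats::setNames(t, levels[a]))
  cuts <- sort(stats::runif(njumps, 0, t))
  durs <- diff(c(0, cuts, t))
  states <- levels[((a - 1 + 0:njumps) %% 2) + 1]
  stats::setNames(durs, states)
}

#' Stochastic character maps of a binary regime
#'
#' Samples regime histories consistent with the tip states under the fitted
#' equal-rates Markov chain: node states are drawn from their conditional
#' distributions (pruning partials, stationary root prior), then each branch
#' history is drawn exactly by endpoint-conditioned uniformization.
#'
#' @param tree `phylo`.
#' @param tip_states named character vector of binary states.
#' @param q transition rate (e.g. from [fit_mk_er()]).
#' @param n_maps number of maps to sample.
#' @param seed integer seed.
#' @return list of [regime_painting()] objects.
#' @export
simmap_sample <- function(tree, tip_states, q, n_maps = 1, seed = 1) {
  tip_states <- stats::setNames(as.character(tip_states),
                                normalize_labels(names(tip_states)))
  levels <- sort(unique(tip_states[tree$tip.label]))
  if (length(levels) == 1L) {
    maps <- lapply(tree$edge.length, function(l)
      stats::setNames(l, levels))
    return(replicate(n_maps, regime_painting(tree, maps, levels),
                     simplify = FALSE))
  }
  q <- max(q, 1e-9)
  n <- length(tree$tip.label)
  D <- mk_partials(tree, tip_states, q, levels)
  pre <- preorder_edges(tree)
  with_seed(seed, lapply(seq_len(n_maps), function(dummy) {
    states <- integer(n + tree$Nnode)
    root <- n + 1L
    pr <- 0.5 * D[root, ]
    states[root] <- sample(2, 1, prob = pr / sum(pr))
    maps <- vector("list", nrow(tree$edge))
    for (ei in pre) {
      p <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
      P <- er_pmat(q, tree$edge.length[ei])
      w <- P[states[p], ] * D[ch, ]
      states[ch] <- sample(2, 1, prob = w / sum(w))
      maps[[ei]] <- sample_er_path(states[p], states[ch],
                                   tree$edge.length[ei], q, levels)
    }
    regime_painting(tree, maps, levels)
  }))
}

#' Serialize a painting to a per-branch segment table
#'
#' @param painting a `regime_painting`.
#' @param path optional CSV path; when given the table is written there.
#' @return data frame with columns `parent`, `child`, `segment`, `regime`,
#'   `duration`.
#' @export
painting_segments <- function(painting, path = NULL) {
  tree <- painting$tree
  rows <- do.call(rbind, lapply(seq_along(painting$maps), function(ei) {
    m <- painting$maps[[ei]]
    data.frame(parent = tree$edge[ei, 1], child = tree$edge[ei, 2],
               segment = seq_along(m), regime = names(m),
               duration = unname(m))
  }))
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}

#' SIMMAP-annotated Newick string for a painting
#' @param painting a `regime_painting`.
#' @return character scalar.
#' @export
as_simmap_newick <- function(painting) {
  tree <- painting$tree
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    paste0("(", paste(vapply(kids[[as.character(node)]], function(ei) {
      m <- painting$maps[[ei]]
      paste0(lab(tree$edge[ei, 2]), ":{",
             paste(sprintf("%s,%g", names(m), unname(m)), collapse = ":"),
             "}")
    }, character(1)), collapse = ","), ")")
  }
  paste0(lab(n + 1L), ";")
}
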