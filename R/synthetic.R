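# --- seeded generators for trees, regimes and landmark data ---------------

#' Simulate a birth-death tree with fossil (non-ultrametric) tips
#'
#' A birth-death tree conditioned on `n_tips` extant taxa is simulated and a
#' stated fraction of its tips is truncated back in time (their terminal
#' branches shortened by a uniform fraction) to emulate fossil sampling, so
#' root-to-tip depths differ as in a paleontological tree.
#'
#' @param n_tips number of tips (>= 4).
#' @param birth,death speciation and extinction rates.
#' @param fossil_fraction fraction of tips truncated before the present.
#' @param seed integer seed.
#' @param retries resimulation attempts if the process dies out.
#' @return `phylo` with strictly positive branch lengths.
#' @export
sim_tree <- function(n_tips, birth = 1, death = 0, fossil_fraction = 0,
                     seed = 1, retries = 20) {
  if (n_tips < 4) stop("n_tips must be at least 4")
  with_seed(seed, {
    tr <- NULL
    for (r in seq_len(retries)) {
      tr <- tryCatch(ape::rphylo(n_tips, birth = birth, death = death,
                                 fossils = FALSE),
                     error = function(e) NULL)
      if (!is.null(tr)) break
    }
    if (is.null(tr)) stop("birth-death simulation failed after ", retries,
                          " attempts")
    tr$tip.label <- paste0("t", seq_len(n_tips))
    if (fossil_fraction > 0) {
      n_fossil <- max(1L, round(fossil_fraction * n_tips))
      pick <- sample(n_tips, n_fossil)
      for (tip in pick) {
        ei <- which(tr$edge[, 2] == tip)
        tr$edge.length[ei] <- tr$edge.length[ei] *
          stats::runif(1, 0.05, 0.8)
      }
    }
    fix_zero_branches(tr, 1e-3)
  })
}

#' Simulate landmark configurations evolving on a tree
#'
#' Shape deviations are drawn from a multivariate evolutionary model
#' ([simulate_from_model()]) in the Procrustes tangent space of the mean
#' configuration, added to the mean, optionally displaced per regime
#' (emulating an adaptive jump at a regime shift), perturbed by i.i.d.
#' digitization noise, and optionally masked to create missing landmarks.
#'
#' @param tree `phylo`.
#' @param mean_config k x 2 mean configuration.
#' @param model list passed to [simulate_from_model()] (`model` plus
#'   parameters) describing evolution of the 2k tangent coordinates, or of
#'   `m < 2k` latent axes via element `basis` (2k x m orthonormal matrix).
#' @param painting optional regime painting for multi-rate models.
#' @param regime_shift optional named list regime -> length-m displacement
#'   added to tips whose terminal segment is in that regime.
#' @param noise_sd standard deviation of isotropic digitization noise added
#'   to every coordinate.
#' @param missing_fraction fraction of (specimen, landmark) cells masked,
#'   never removing more than half the landmarks of a specimen.
#' @param curves curve structure passed to the returned [landmark_set()].
#' @param seed integer seed.
#' @return a `landmark_set`.
#' @export
sim_landmarks <- function(tree, mean_config, model, painting = NULL,
                          regime_shift = NULL, noise_sd = 0,
                          missing_fraction = 0, curves = list(), seed = 1) {
  mean_config <- as.matrix(mean_config)
  k <- nrow(mean_config)
  n <- length(tree$tip.label)
  dev <- simulate_from_model(model, tree, painting = painting, seed = seed)
  m <- ncol(dev)
  basis <- model$basis
  if (is.null(basis)) {
    if (m != 2 * k) stop("model dimension must be 2k when no basis given")
    basis <- diag(2 * k)
  }
  if (!is.null(regime_shift)) {
    if (is.null(painting)) stop("regime_shift requires a painting")
    ts <- tip_states_from_painting(painting)
    for (rg in names(regime_shift)) {
      hit <- which(ts[tree$tip.label] == rg)
      if (length(hit))
        dev[hit, ] <- sweep(dev[hit, , drop = FALSE], 2,
                            -regime_shift[[rg]])
    }
  }
  flat_mean <- as.vector(t(mean_config))  # landmark-major (x1,y1,x2,y2,...)
  coords <- array(NA_real_, c(n, k, 2))
  with_seed(seed + 1L, {
    for (i in seq_len(n)) {
      v <- flat_mean + as.vector(basis %*% dev[i, ])
      if (noise_sd > 0) v <- v + stats::rnorm(2 * k, 0, noise_sd)
      coords[i, , ] <- matrix(v, k, 2, byrow = TRUE)
    }
  })
  miss <- matrix(FALSE, n, k)
  if (missing_fraction > 0) {
    with_seed(seed + 2L, {
      n_cells <- round(missing_fraction * n * k)
      cand <- which(matrix(TRUE, n, k))
      pick <- sample(cand, n_cells)
      for (cell in pick) {
        i <- (cell - 1) %% n + 1; j <- (cell - 1) %/% n + 1
        if (sum(miss[i, ]) < k / 2) miss[i, j] <- TRUE
      }
    })
  }
  landmark_set(coords, tree$tip.label, curves = curves, missing = miss)
}

# Maxilla-like mean configuration: an elongate outline with a tall
# triangular ascending process and a notched posterior (jugal) ramus.
# 6 fixed landmarks followed by 13 curve semilandmarks.
maxilla_mean_config <- function() {
  fixed <- rbind(
    c(0.0, 0.0),    # 1 anteroventral corner
    c(0.2, 1.8),    # 2 anterodorsal (premaxillary) contact
    c(3.0, 3.8),    # 3 apex of ascending ramus
    c(5.2, 1.2),    # 4 posterior base of ascending ramus
    c(9.5, 0.6),    # 5 posterior tip of jugal ramus
    c(9.3, 0.0))    # 6 posteroventral corner
  ventral <- rbind(c(1.6, -0.15), c(3.2, -0.25), c(4.8, -0.30),
                   c(6.4, -0.25), c(8.0, -0.15))          # 7-11 (1 -> 6)
  antero <- rbind(c(0.8, 2.2), c(1.5, 2.8), c(2.2, 3.4))  # 12-14 (2 -> 3)
  postasc <- rbind(c(3.6, 3.2), c(4.2, 2.5), c(4.8, 1.8)) # 15-17 (3 -> 4)
  jugal <- rbind(c(6.6, 1.0), c(8.1, 0.8))                # 18-19 (4 -> 5)
  rbind(fixed, ventral, antero, postasc, jugal)
}

maxilla_curves <- function() list(7:11, 12:14, 15:17, 18:19)

maxilla_curve_anchors <- function() list(c(1, 6), c(2, 3), c(3, 4), c(4, 5))

#' Slider table for the maxilla landmark template
#'
#' All 13 semilandmarks slide, anchored at the fixed landmarks bounding
#' their curves.
#' @return 3-column before/slide/after matrix.
#' @export
maxilla_sliders <- function()
  sliders_from_curves(maxilla_curves(), maxilla_curve_anchors())

fixture_newick <- function() {
  paste0(
    "(Herrerasaurus:5,(Syntarsus:33,(Dilophosaurus:30,(Allosaurus:60,",
    "(Ceratosaurus:50,((Elaphrosaurus:13,(Noasaurus:50,Masiakasaurus:52)",
    ":45):20,(Spectrovenator:15,(Majungasaurus:57,(Skorpiovenator:15,",
    "(Ekrixinatosaurus:8,((Carnotaurus:17,Aucasaurus:8):10,(Abelisaurus:14,",
    "(Llukalkan:5,Viavenator:2):4):6):7):5):15):15):45):15):10):10):8):7);")
}

fixture_specialists <- function()
  c("Majungasaurus", "Skorpiovenator", "Ekrixinatosaurus", "Carnotaurus",
    "Aucasaurus", "Abelisaurus", "Llukalkan", "Viavenator")

fixture_abelisaurids <- function()
  c("Spectrovenator", fixture_specialists())

#' Deterministic synthetic study fixture
#'
#' A fully reproducible dataset dimensioned like the abelisaurid maxilla
#' study: a 17-taxon time-calibrated non-ultrametric tree (9 abelisaurids +
#' 8 outgroups, branch lengths in Myr), a 19-point (6 fixed + 13
#' semilandmark) maxilla-like landmark template, landmark data simulated
#' under a two-rate Brownian model painted by the Abelisauridae clade (the
#' derived regime evolving faster and displaced at the clade stem), missing
#' landmarks on *Llukalkan* and *Abelisaurus*, and the two predation
#' strategy codings: the Prior hypothesis (only Late Cretaceous
#' abelisaurids are specialists) and the Posterior hypothesis (the Early
#' Cretaceous *Spectrovenator* included among the specialists).
#'
#' @return list with elements `landmarks` (`landmark_set`), `tree`
#'   (`phylo`), `prior` and `posterior` (`strategy_table`s), `sliders`,
#'   and `painting` (the generating posterior-clade painting).
#' @export
study_fixture <- function() {
  tree <- validate_tree(ape::read.tree(text = fixture_newick()))
  prior <- strategy_table(stats::setNames(
    ifelse(tree$tip.label %in% fixture_specialists(), "specialist",
           "generalist"), tree$tip.label), tree = tree)
  posterior <- strategy_table(stats::setNames(
    ifelse(tree$tip.label %in% fixture_abelisaurids(), "specialist",
           "generalist"), tree$tip.label), tree = tree)
  painting <- paint_from_hypothesis(tree, posterior)

  mean_cfg <- maxilla_mean_config()
  k <- nrow(mean_cfg)
  # latent shape axes: smooth orthonormal deformation basis over 2k coords
  m <- 4
  basis <- with_seed(910245L, {
    raw <- matrix(stats::rnorm(2 * k * m), 2 * k, m)
    qr.Q(qr(raw))
  })
  # decaying variance spectrum typical of shape data: half the evolutionary
  # variance on the leading latent axis, tapering off on later axes
  rate_total <- 8.0e-5  # summed per-Myr variance of latent axes (generalists)
  spectrum <- c(0.50, 0.25, 0.15, 0.10)
  R_gen <- diag(rate_total * spectrum)
  R_spec <- 3 * R_gen
  model <- list(model = "BMM",
                R_list = list(generalist = R_gen, specialist = R_spec),
                mu = rep(0, m), basis = basis * centroid_size(mean_cfg))
  lm <- sim_landmarks(tree, mean_cfg, model, painting = painting,
                      regime_shift = list(specialist = c(0.12, -0.08,
                                                         0.05, 0)),
                      noise_sd = 0.01, curves = maxilla_curves(),
                      seed = 472931L)
  # per-specimen similarity transforms + size variation emulate digitization
  lm <- with_seed(815371L, {
    for (i in seq_len(nrow(lm$missing))) {
      th <- stats::runif(1, -pi, pi)
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sc <- exp(stats::rnorm(1, 0, 0.3))
      shift <- stats::runif(2, -5, 5)
      lm$coords[i, , ] <- sweep(lm$coords[i, , ] %*% Rm * sc, 2, -shift)
    }
    lm
  })
  # the two taxa whose maxillae are incomplete in the study
  miss_spec <- list(Llukalkan = c(5, 11, 18, 19), Abelisaurus = c(3, 14, 15))
  for (nm in names(miss_spec))
    lm$missing[match(nm, lm$specimen_ids), miss_spec[[nm]]] <- TRUE

  list(landmarks = lm, tree = tree, prior = prior, posterior = posterior,
       sliders = maxilla_sliders(), painting = painting,
       estimated_taxa = names(miss_spec))
}
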