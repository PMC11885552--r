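#' Configuration for a full macroevolutionary run
#'
#' Collects the inputs and tuning parameters of the end-to-end analysis.
#' Defaults mirror the standard workflow: 90% axis retention, 999
#' permutations, 1000 disparity-through-time simulations, 500 adequacy
#' simulations, 10 stochastic maps.
#'
#' @param landmarks `landmark_set` or path to a TPS file.
#' @param tree `phylo` or path to a Newick file.
#' @param prior `strategy_table` (or path) for the prior regime hypothesis.
#' @param posterior optional `strategy_table` (or path); when `NULL` the
#'   posterior hypothesis is derived from the forward shift search.
#' @param clade `"all_taxa"` or `"dilophosaurus_clade"` (drops the
#'   earliest-diverging outgroup taxa in `clade_drop`).
#' @param clade_drop taxa dropped under the `dilophosaurus_clade` variant.
#' @param remove_estimated drop taxa with estimated (missing) landmarks and
#'   re-run from alignment onward?
#' @param estimated_taxa taxa treated as estimated; defaults to specimens
#'   with any missing landmark.
#' @param sliders semilandmark slider table (3 columns) or `NULL`.
#' @param axis_threshold cumulative proportion for axis retention.
#' @param n_perm permutations for signal and PGLS tests.
#' @param n_sim_dtt Brownian simulations for the dtt envelope.
#' @param n_sim_adequacy parametric-bootstrap simulations.
#' @param n_simmap stochastic maps drawn when exercising simmap machinery.
#' @param n_starts optimizer multi-starts per evolutionary-model fit.
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it and the stage name.
#' @param out_dir optional directory where result tables are written.
#' @return list of class `run_config`.
#' @export
run_config <- function(landmarks, tree, prior, posterior = NULL,
                       clade = c("all_taxa", "dilophosaurus_clade"),
                       clade_drop = c("Herrerasaurus", "Syntarsus"),
                       remove_estimated = FALSE, estimated_taxa = NULL,
                       sliders = NULL, axis_threshold = 0.90, n_perm = 999,
                       n_sim_dtt = 1000, n_sim_adequacy = 500,
                       n_simmap = 10, n_starts = 5, seed = 1,
                       out_dir = NULL) {
  clade <- match.arg(clade)
  if (is.character(landmarks)) landmarks <- read_tps(landmarks)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(prior) && !inherits(prior, "strategy_table"))
    prior <- read_strategy_table(prior, tree)
  if (is.character(posterior) && !inherits(posterior, "strategy_table"))
    posterior <- read_strategy_table(posterior, tree)
  structure(list(landmarks = landmarks, tree = tree, prior = prior,
                 posterior = posterior, clade = clade,
                 clade_drop = clade_drop,
                 remove_estimated = remove_estimated,
                 estimated_taxa = estimated_taxa, sliders = sliders,
                 axis_threshold = axis_threshold, n_perm = n_perm,
                 n_sim_dtt = n_sim_dtt, n_sim_adequacy = n_sim_adequacy,
                 n_simmap = n_simmap, n_starts = n_starts, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

subset_strategy <- function(strategy, taxa) {
  if (is.null(strategy)) return(NULL)
  strategy_table(unclass(strategy)[taxa])
}

#' Run the full macroevolutionary analysis
#'
#' Executes the published workflow end to end on one clade variant:
#' missing-landmark estimation, Procrustes alignment with sliding
#' semilandmarks, ordinary and phylogenetic ordinations with 90% axis
#' retention, multivariate phylogenetic signal, PGLS under the prior and
#' posterior regime hypotheses, disparity through time, the forward
#' regime-shift search (defining the posterior hypothesis when none is
#' supplied), the seven-model comparison with Akaike weights, and
#' parametric-bootstrap adequacy of the best model.
#'
#' @param config a [run_config()].
#' @return object of class `phylomorph_run`; see the elements `gpa`,
#'   `ordinations`, `signal`, `pgls`, `dtt`, `surface`, `models`,
#'   `model_table`, `best_models`, `adequacy`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed_of <- function(stage) derive_seed(config$seed, stage)
  lm <- config$landmarks
  tree <- config$tree
  estimated <- config$estimated_taxa %||%
    lm$specimen_ids[rowSums(lm$missing) > 0]

  keep <- tree$tip.label
  if (config$clade == "dilophosaurus_clade")
    keep <- setdiff(keep, config$clade_drop)
  if (config$remove_estimated) keep <- setdiff(keep, estimated)
  if (length(keep) < 4) stop("fewer than 4 taxa left after pruning")
  if (!setequal(keep, tree$tip.label)) {
    tree <- prune_tree(tree, keep)
    sel <- match(keep, lm$specimen_ids)
    lm <- landmark_set(lm$coords[sel, , , drop = FALSE],
                       lm$specimen_ids[sel], curves = lm$curves,
                       missing = lm$missing[sel, , drop = FALSE])
  }
  tree <- fix_zero_branches(tree)
  prior <- subset_strategy(config$prior, tree$tip.label)
  posterior <- subset_strategy(config$posterior, tree$tip.label)
  check_taxon_match(lm, tree, prior)

  # 1. completion + alignment
  lm_full <- estimate_missing_tps(lm)
  gpa <- gpa_align(lm_full, sliders = config$sliders,
                   slide_semilandmarks = !is.null(config$sliders) ||
                     length(lm$curves) > 0)
  Y <- flatten_shapes(gpa)

  # 2. ordinations and axis retention
  ords <- list(PCA = shape_pca(Y), PhyloPCA = phylo_pca(Y, tree),
               PACA = paca(Y, tree))
  ax_ppca <- select_axes(ords$PhyloPCA, config$axis_threshold, "variance")
  ax_paca <- select_axes(ords$PACA, config$axis_threshold, "tip_dispersion")
  scores_ppca <- ords$PhyloPCA$scores[, ax_ppca, drop = FALSE]
  scores_paca <- ords$PACA$scores[, ax_paca, drop = FALSE]

  # 3. phylogenetic signal table: raw coordinates + both
  #    ordinations, with ML lambda scaling
  signal <- list(
    PC = suppressWarnings(kmult(Y, tree, config$n_perm,
                                seed_of("kmult_pc"), TRUE)),
    PhyloPCA = kmult(scores_ppca, tree, config$n_perm,
                     seed_of("kmult_ppca"), TRUE),
    PACA = kmult(scores_paca, tree, config$n_perm,
                 seed_of("kmult_paca"), TRUE))

  # 4. regime machinery: Mk fit + stochastic maps on the prior labels
  mk <- fit_mk_er(tree, unclass(prior))
  simmaps <- simmap_sample(tree, unclass(prior), mk$q,
                           n_maps = config$n_simmap,
                           seed = seed_of("simmap"))

  # 5. disparity through time on retained Phylo-PCs
  dtt_res <- dtt(tree, scores_ppca, n_sim = config$n_sim_dtt,
                 seed = seed_of("dtt"))

  # 6. forward shift search -> posterior hypothesis
  surf <- surface_forward(tree, scores_ppca, seed = seed_of("surface"))
  if (is.null(posterior)) {
    shifted <- unique(unlist(shift_clades(surf)))
    lab <- stats::setNames(
      ifelse(tree$tip.label %in% shifted, "specialist", "generalist"),
      tree$tip.label)
    posterior <- if (length(shifted)) strategy_table(lab) else prior
  }

  # 7. PGLS under both hypotheses on all three data sets
  cs <- stats::setNames(gpa$centroid_sizes, gpa$specimen_ids)
  pgls <- list(
    PC = compare_hypotheses_pgls(Y, tree, prior, posterior, cs,
                                 config$n_perm, seed_of("pgls_pc")),
    PhyloPCA = compare_hypotheses_pgls(scores_ppca, tree, prior, posterior,
                                       cs, config$n_perm,
                                       seed_of("pgls_ppca")),
    PACA = compare_hypotheses_pgls(scores_paca, tree, prior, posterior, cs,
                                   config$n_perm, seed_of("pgls_paca")))

  # 8. evolutionary model set on retained Phylo-PCs
  paint_prior <- paint_from_hypothesis(tree, prior)
  paint_post <- paint_from_hypothesis(tree, posterior)
  mseed <- seed_of("models")
  ns <- config$n_starts %||% 5
  fits <- list(
    OU1 = fit_evo_model("OU1", tree, scores_ppca, n_starts = ns,
                        seed = mseed),
    OUM = fit_evo_model("OUM", tree, scores_ppca, paint_prior,
                        n_starts = ns, seed = mseed),
    BM = fit_evo_model("BM", tree, scores_ppca, seed = mseed),
    BMM = fit_evo_model("BMM", tree, scores_ppca, paint_prior,
                        n_starts = ns, seed = mseed),
    EB = fit_evo_model("EB", tree, scores_ppca, seed = mseed),
    BMMS = fit_evo_model("BMM", tree, scores_ppca, paint_post,
                         n_starts = ns, seed = mseed),
    OUMS = fit_evo_model("OUM", tree, scores_ppca, paint_post,
                         n_starts = ns, seed = mseed))
  fits <- aic_weights(fits)
  tab <- attr(fits, "table")
  best <- tab$model[tab$AIC - min(tab$AIC) < 2]

  # 9. adequacy of the best model
  best_fit <- fits[[which.max(tab$AICw)]]
  adequacy <- adequacy_bootstrap(best_fit, tree,
                                 n_sim = config$n_sim_adequacy,
                                 seed = seed_of("adequacy"))

  run <- structure(list(
    config = config, tree = tree, estimated_taxa = estimated, gpa = gpa,
    ordinations = ords, retained_axes = list(PhyloPCA = ax_ppca,
                                             PACA = ax_paca),
    scores = list(PhyloPCA = scores_ppca, PACA = scores_paca),
    signal = signal, mk = mk, simmaps = simmaps, dtt = dtt_res,
    surface = surf, prior = prior, posterior = posterior, pgls = pgls,
    models = fits, model_table = tab, best_models = best,
    adequacy = adequacy, seed = config$seed,
    version = as.character(utils::packageVersion("phylomorph"))),
    class = "phylomorph_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Re-run the model comparison after removing estimated taxa
#'
#' Prunes the taxa whose landmark configurations were completed by
#' thin-plate-spline estimation, re-aligns, re-ordinates and refits the
#' whole model set (the estimated-taxa-removal analysis).
#'
#' @param config a [run_config()].
#' @return a `phylomorph_run` for the reduced data set.
#' @export
run_taxa_removal <- function(config) {
  config$remove_estimated <- TRUE
  run_full(config)
}

#' @export
print.phylomorph_run <- function(x, ...) {
  cat("phylomorph run (seed", x$seed, ", clade:", x$config$clade,
      if (x$config$remove_estimated) ", estimated taxa removed" else "",
      ")\n")
  cat(" taxa:", length(x$tree$tip.label),
      "; retained Phylo-PCs:", length(x$retained_axes$PhyloPCA),
      "; retained PACs:", length(x$retained_axes$PACA), "\n")
  cat(" shift search:", length(x$surface$shifts), "shift(s)\n")
  cat(" model comparison (AIC weights):\n")
  print(within(x$model_table, {
    logL <- round(logL, 2); AIC <- round(AIC, 2); AICc <- round(AICc, 2)
    AICw <- round(AICw, 3)
  }), row.names = FALSE)
  cat(" best model(s):", paste(x$best_models, collapse = ", "), "\n")
  cat(" adequacy:", if (x$adequacy$adequate) "adequate"
      else "not adequate", "\n")
  invisible(x)
}

#' Write the result tables of a run to a directory
#'
#' Emits CSV tables (ordination summaries, signal table, PGLS tables, model
#' comparison, shift-search step log, painting segments, adequacy
#' intervals, dtt curve) plus a machine-readable JSON-like summary.
#'
#' @param run a `phylomorph_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  for (nm in names(run$ordinations))
    w(summary(run$ordinations[[nm]]), paste0("ordination_", nm, ".csv"))
  sig <- do.call(rbind, lapply(names(run$signal), function(nm) {
    s <- run$signal[[nm]]
    data.frame(data = nm, scaling_lambda = s$scaling_lambda,
               logL = s$logL_lambda, Z = s$Z, Kmult = s$Kmult,
               p = s$p_value)
  }))
  w(sig, "signal_table.csv")
  for (nm in names(run$pgls)) {
    w(cbind(term = rownames(run$pgls[[nm]]$prior$table),
            run$pgls[[nm]]$prior$table),
      paste0("pgls_prior_", nm, ".csv"))
    w(cbind(term = rownames(run$pgls[[nm]]$posterior$table),
            run$pgls[[nm]]$posterior$table),
      paste0("pgls_posterior_", nm, ".csv"))
  }
  w(run$model_table, "model_comparison.csv")
  w(run$surface$steps, "surface_steps.csv")
  painting_segments(run$surface$painting,
                    file.path(dir, "surface_painting.csv"))
  w(data.frame(time = run$dtt$times, observed = run$dtt$observed,
               sim_mean = run$dtt$sim_mean, lower = run$dtt$lower,
               upper = run$dtt$upper), "dtt_curve.csv")
  w(data.frame(parameter = names(run$adequacy$observed),
               observed = run$adequacy$observed,
               lower = run$adequacy$lower, upper = run$adequacy$upper,
               inside = run$adequacy$inside), "adequacy.csv")
  summary_lines <- c(
    paste0("package_version,", run$version),
    paste0("seed,", run$seed),
    paste0("clade,", run$config$clade),
    paste0("remove_estimated,", run$config$remove_estimated),
    paste0("n_taxa,", length(run$tree$tip.label)),
    paste0("best_models,", paste(run$best_models, collapse = ";")),
    paste0("n_shifts,", length(run$surface$shifts)),
    paste0("adequate,", run$adequacy$adequate))
  writeLines(summary_lines, file.path(dir, "summary.csv"))
  invisible(dir)
}
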