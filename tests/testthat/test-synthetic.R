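test_that("simulated trees honor their knobs and are reproducible", {
  tr <- sim_tree(20, birth = 1, death = 0, fossil_fraction = 0, seed = 3)
  expect_equal(length(tr$tip.label), 20)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  trf <- sim_tree(20, birth = 1, death = 0.3, fossil_fraction = 0.5,
                  seed = 3)
  d <- ape::node.depth.edgelength(trf)[1:20]
  expect_gte(sum(d < max(d) - 1e-8), 1)
  expect_true(all(trf$edge.length > 0))
  expect_identical(ape::write.tree(sim_tree(12, seed = 9)),
                   ape::write.tree(sim_tree(12, seed = 9)))
  expect_error(sim_tree(3), "at least 4")
})

test_that("landmark simulation is deterministic and respects degenerate knobs", {
  tr <- sim_tree(8, seed = 2)
  cfg <- phylomorph:::maxilla_mean_config()
  model0 <- list(model = "BM", R = diag(0, 38), mu = rep(0, 38))
  lm0 <- sim_landmarks(tr, cfg, model0, noise_sd = 0, seed = 4)
  for (i in 1:8)
    expect_equal(lm0$coords[i, , ], cfg, tolerance = 1e-12,
                 ignore_attr = TRUE)
  model <- list(model = "BM", R = diag(1e-4, 38), mu = rep(0, 38))
  a <- sim_landmarks(tr, cfg, model, noise_sd = 0.01, seed = 7)
  b <- sim_landmarks(tr, cfg, model, noise_sd = 0.01, seed = 7)
  expect_identical(a$coords, b$coords)
  m <- sim_landmarks(tr, cfg, model, missing_fraction = 0.05, seed = 7)
  expect_gt(sum(m$missing), 0)
  expect_true(all(rowSums(m$missing) <= nrow(cfg) / 2))
})

test_that("missing-landmark recovery error shrinks with digitization noise", {
  tr <- sim_tree(10, seed = 5)
  cfg <- phylomorph:::maxilla_mean_config()
  model <- list(model = "BM", R = diag(5e-5, 38), mu = rep(0, 38))
  rms_at <- function(noise) {
    lm <- sim_landmarks(tr, cfg, model, noise_sd = noise, seed = 11)
    truth <- lm$coords
    lm$missing[2, c(4, 9)] <- TRUE
    lm$missing[5, c(15)] <- TRUE
    est <- estimate_missing_tps(lm)
    sqrt(mean((est$coords[lm$missing] - truth[lm$missing])^2))
  }
  errs <- vapply(c(0.2, 0.02, 0.002), rms_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the study fixture is deterministic and correctly dimensioned", {
  fx1 <- study_fixture()
  fx2 <- study_fixture()
  expect_identical(fx1$landmarks$coords, fx2$landmarks$coords)
  expect_identical(ape::write.tree(fx1$tree), ape::write.tree(fx2$tree))
  expect_equal(dim(fx1$landmarks$coords), c(17, 19, 2))
  expect_equal(length(fx1$tree$tip.label), 17)
  expect_equal(length(semilandmark_indices(fx1$landmarks)), 13)
  expect_equal(sum(unclass(fx1$prior) == "specialist"), 8)
  expect_equal(sum(unclass(fx1$posterior) == "specialist"), 9)
  expect_false(ape::is.ultrametric(fx1$tree))
  expect_true(check_taxon_match(fx1$landmarks, fx1$tree, fx1$prior))
  # generated data pass the I/O validations on a write/read round trip
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(fx1$landmarks, f)
  back <- read_tps(f)
  expect_equal(back$coords[!back$missing], fx1$landmarks$coords[!fx1$landmarks$missing],
               tolerance = 1e-9)
})

test_that("end-to-end shape simulation carries Brownian signal (Kmult near 1)", {
  tr <- phylomorph:::validate_tree(
    ape::read.tree(text = phylomorph:::fixture_newick()))
  cfg <- phylomorph:::maxilla_mean_config()
  model <- list(model = "BM", R = diag(2e-5, 4), mu = rep(0, 4),
                basis = qr.Q(qr(matrix(rnorm(38 * 4), 38, 4))) * 13)
  Ks <- vapply(1:40, function(s) {
    lm <- sim_landmarks(tr, cfg, model, noise_sd = 0, seed = 6000 + s)
    g <- gpa_align(lm, slide_semilandmarks = FALSE)
    pp <- phylo_pca(flatten_shapes(g), tr)
    S <- pp$scores[, select_axes(pp, 0.9, "variance"), drop = FALSE]
    C <- vcv_matrix(tr)
    phylomorph:::kmult_stat(S, C, solve(C))
  }, numeric(1))
  expect_gt(mean(Ks), 0.8)
  expect_lt(mean(Ks), 1.2)
})
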