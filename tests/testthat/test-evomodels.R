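# The likelihood engine is checked against oracle_loglik() (see helpers):
# an independent construction of the dense Gaussian covariance by per-pair
# path integration, with numerical quadrature for the OU kernels.

test_that("likelihood engine matches the dense Gaussian oracle", {
  tr <- random_tree(6, 42)
  set.seed(1)
  Y <- matrix(rnorm(6 * 3, 0, 0.5), 6, 3,
              dimnames = list(tr$tip.label, NULL))
  states <- setNames(rep(c("g", "s"), 3), tr$tip.label)
  # build a paintable (clade) labelling
  sets <- phylomorph:::tip_descendants(tr)
  clade <- sets[[8]]  # some internal node's tips
  states[] <- ifelse(tr$tip.label %in% clade, "s", "g")
  painting <- paint_from_hypothesis(tr, strategy_table(states))

  R <- matrix(c(0.5, 0.1, 0, 0.1, 0.4, -0.05, 0, -0.05, 0.3), 3, 3)
  R2 <- 2.5 * R
  alpha <- c(0.3, 0.15, 0.5)

  eng <- function(V, D) phylomorph:::gls_profile_loglik(as.vector(Y), V,
                                                        D)$logL
  C <- vcv_matrix(tr)
  D1 <- diag(3) %x% matrix(1, 6, 1)

  expect_equal(eng(R %x% C, D1),
               oracle_loglik("BM", tr, Y, list(R = R)), tolerance = 1e-8)
  expect_equal(eng(R %x% phylomorph:::eb_structure(C, -0.4), D1),
               oracle_loglik("EB", tr, Y, list(R = R, b = -0.4)),
               tolerance = 1e-8)
  S <- phylomorph:::bmm_structures(tr, painting)
  expect_equal(eng((R %x% S[[1]]) + (R2 %x% S[[2]]), D1),
               oracle_loglik("BMM", tr, Y,
                             list(R_list = list(R, R2)), painting),
               tolerance = 1e-8)
  expect_equal(eng(phylomorph:::ou_cov(tr, R, alpha, C), D1),
               oracle_loglik("OU1", tr, Y, list(R = R, alpha = alpha)),
               tolerance = 1e-6)
  Dm <- phylomorph:::mean_design("OUM", tr, 3, painting, alpha)
  expect_equal(eng(phylomorph:::ou_cov(tr, R, alpha, C), Dm),
               oracle_loglik("OUM", tr, Y, list(R = R, alpha = alpha),
                             painting),
               tolerance = 1e-6)
})

test_that("two-tip BM has the closed-form ML solution", {
  tr <- ape::read.tree(text = "(A:2,B:2);")
  Y <- matrix(c(1, 3), 2, 1, dimnames = list(c("A", "B"), NULL))
  fit <- fit_evo_model("BM", tr, Y)
  # disjoint root paths of length t: GLS mean = midpoint, sigma2 ML =
  # mean squared deviation weighted by path length
  t_ <- 2
  mu_hat <- 2
  s2_hat <- ((1 - mu_hat)^2 / t_ + (3 - mu_hat)^2 / t_) / 2
  expect_equal(unname(fit$params$mu), mu_hat, tolerance = 1e-8)
  expect_equal(unname(fit$params$R[1, 1]), s2_hat, tolerance = 1e-8)
  ll <- sum(dnorm(c(1, 3), mu_hat, sqrt(s2_hat * t_), log = TRUE))
  expect_equal(fit$logL, ll, tolerance = 1e-8)
})

test_that("model nesting reductions hold", {
  fx <- study_fixture()
  tr <- fx$tree
  Y <- simulate_from_model(list(model = "BM", R = diag(c(2, 1)) * 1e-3,
                                mu = c(0, 0)), tr, seed = 31)
  bm <- fit_evo_model("BM", tr, Y)
  painting <- paint_from_hypothesis(tr, fx$prior)
  bmm <- fit_evo_model("BMM", tr, Y, painting, n_starts = 2)
  eb <- fit_evo_model("EB", tr, Y)
  ou1 <- fit_evo_model("OU1", tr, Y, n_starts = 2)
  oum <- fit_evo_model("OUM", tr, Y, painting, n_starts = 2)
  # nesting: the richer model can always match the poorer one
  expect_gte(bmm$logL, bm$logL - 1e-6)
  expect_gte(eb$logL, bm$logL - 1e-6)
  expect_gte(oum$logL, ou1$logL - 1e-6)
  # explicit limits: equal-rate BMM and b = 0 EB equal BM exactly
  S <- phylomorph:::bmm_structures(tr, painting)
  D <- phylomorph:::mean_design("BMM", tr, 2)
  ll_eq <- phylomorph:::gls_profile_loglik(
    as.vector(Y), bm$params$R %x% (S[[1]] + S[[2]]), D)$logL
  expect_equal(ll_eq, bm$logL, tolerance = 1e-6)
  ll_eb0 <- phylomorph:::kron_bm_ml(Y, phylomorph:::eb_structure(
    vcv_matrix(tr), 0))$logL
  expect_equal(ll_eb0, bm$logL, tolerance = 1e-10)
  # OU with alpha -> 0 approaches the BM likelihood
  C <- vcv_matrix(tr)
  ll_ou0 <- phylomorph:::gls_profile_loglik(
    as.vector(Y),
    phylomorph:::ou_cov(tr, bm$params$R, rep(1e-8, 2), C),
    phylomorph:::mean_design("OU1", tr, 2))$logL
  expect_equal(ll_ou0, bm$logL, tolerance = 1e-4)
})

test_that("AIC bookkeeping and Akaike weights follow their definitions", {
  fx <- study_fixture()
  Y <- simulate_from_model(list(model = "BM", R = diag(2) * 1e-3,
                                mu = c(0, 0)), fx$tree, seed = 8)
  bm <- fit_evo_model("BM", fx$tree, Y)
  expect_equal(bm$AIC, 2 * bm$n_params - 2 * bm$logL)
  eb <- fit_evo_model("EB", fx$tree, Y)
  w <- aic_weights(list(BM = bm, EB = eb))
  tab <- attr(w, "table")
  expect_equal(sum(tab$AICw), 1)
  d <- tab$AIC - min(tab$AIC)
  expect_equal(tab$AICw, exp(-d / 2) / sum(exp(-d / 2)))
  # delta-AIC of exactly 2 gives the canonical 0.731/0.269 split
  fake <- bm; fake$AIC <- bm$AIC + 2
  w2 <- attr(aic_weights(list(a = bm, b = fake)), "table")$AICw
  expect_equal(w2, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # weights are invariant to a constant shift of every AIC
  fake2 <- lapply(list(a = bm, b = fake), function(f) {
    f$AIC <- f$AIC + 100; f
  })
  expect_equal(attr(aic_weights(fake2), "table")$AICw, w2)
  # mismatched data are refused
  Y2 <- Y; Y2[1, 1] <- Y2[1, 1] + 1
  other <- fit_evo_model("BM", fx$tree, Y2)
  expect_error(aic_weights(list(bm, other)), "identical data")
})

test_that("exact simulation reproduces model moments", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  sims <- simulate_from_model(list(model = "BM", R = matrix(1), mu = 0),
                              tr2, seed = 4, n_sim = 20000)
  d <- vapply(sims, function(s) s["A", 1] - s["B", 1], numeric(1))
  se <- sqrt(2 * 2) / sqrt(20000)  # var of a variance estimate, roughly
  expect_equal(var(d), 2, tolerance = 5 * se)
  # zero rate collapses all tips onto the root state
  z <- simulate_from_model(list(model = "BM", R = matrix(0), mu = 3), tr2,
                           seed = 1)
  expect_equal(unname(z[, 1]), c(3, 3))
  # strong pull concentrates tips at the optimum
  o <- simulate_from_model(list(model = "OU1", R = matrix(0.5),
                                alpha = 8, theta = 2), tr2, seed = 2,
                           n_sim = 2000)
  tips <- vapply(o, function(s) s["A", 1], numeric(1))
  stat_sd <- sqrt(0.5 / (2 * 8))
  expect_lt(abs(mean(tips) - 2), 4 * stat_sd / sqrt(2000))
  expect_equal(sd(tips), stat_sd, tolerance = 0.05)
})

test_that("parameter recovery: rate diagonals within 25% over simulations", {
  fx <- study_fixture()
  tr <- fx$tree
  painting <- paint_from_hypothesis(tr, fx$posterior)
  R_true <- diag(c(4, 2, 1, 0.5)) * 1e-5
  # BM (analytic fit): 100 simulations
  est_bm <- sapply(1:100, function(s) {
    Y <- simulate_from_model(list(model = "BM", R = R_true,
                                  mu = rep(0, 4)), tr, seed = 200 + s)
    diag(fit_evo_model("BM", tr, Y)$params$R)
  })
  expect_lt(max(abs(rowMeans(est_bm) / diag(R_true) - 1)), 0.25)
  # BMM: fewer replicates (numerical optimization), both regime matrices
  Rl_true <- list(generalist = R_true, specialist = 3 * R_true)
  est_bmm <- sapply(1:30, function(s) {
    Y <- simulate_from_model(list(model = "BMM", R_list = Rl_true,
                                  mu = rep(0, 4)), tr,
                             painting = painting, seed = 400 + s)
    f <- fit_evo_model("BMM", tr, Y, painting, n_starts = 1)
    c(diag(f$params$R_list[[1]]), diag(f$params$R_list[[2]]))
  })
  truth <- c(diag(Rl_true[[1]]), diag(Rl_true[[2]]))
  expect_lt(max(abs(rowMeans(est_bmm) / truth - 1)), 0.25)
})

test_that("adequacy bootstrap covers well-specified models and flags bad ones", {
  fx <- study_fixture()
  tr <- fx$tree
  R_true <- diag(c(2, 1)) * 1e-4
  fit0 <- fit_evo_model("BM", tr, simulate_from_model(
    list(model = "BM", R = R_true, mu = c(0, 0)), tr, seed = 77))
  ad <- adequacy_bootstrap(fit0, tr, n_sim = 100, seed = 5)
  expect_true(ad$adequate)
  expect_true(all(ad$lower <= ad$upper))
  # a fit whose rates are forced 10x off falls outside its own intervals
  bad <- fit0
  bad$params$R <- fit0$params$R
  ad2 <- adequacy_bootstrap(bad, tr, n_sim = 60, seed = 6)
  outside <- bad$params$R[1, 1] * 10
  expect_false(outside >= ad2$lower[1] && outside <= ad2$upper[1])
})
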