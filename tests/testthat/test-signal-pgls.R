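test_that("Kmult is calibrated to 1 under Brownian motion", {
  fx <- study_fixture()
  tr <- fx$tree
  C <- vcv_matrix(tr)
  Cinv <- solve(C)
  Ks <- vapply(1:200, function(s) {
    Y <- simulate_from_model(list(model = "BM", R = diag(0.01, 4),
                                  mu = rep(0, 4)), tr, seed = 5000 + s)
    phylomorph:::kmult_stat(Y, C, Cinv)
  }, numeric(1))
  expect_gt(mean(Ks), 0.9)
  expect_lt(mean(Ks), 1.1)
})

test_that("Kmult on a star tree equals the C = I formula; null p uniform", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:10, ":1",
                                                   collapse = ","), ");"))
  set.seed(8)
  Y <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(star$tip.label, NULL))
  C <- vcv_matrix(star)
  K_star <- phylomorph:::kmult_stat(Y, C, solve(C))
  n <- 10
  Yc <- sweep(Y, 2, colMeans(Y))
  K_manual <- (sum(Yc^2) / sum(Yc^2)) / ((n - n / n) / (n - 1))
  expect_equal(K_star, K_manual, tolerance = 1e-12)

  # permutation p-values are uniform under the no-signal null: iid data
  # (exchangeable across tips) on a structured tree
  tr <- random_tree(10, 19)
  ps <- vapply(1:400, function(s) {
    set.seed(31000 + s)
    Yr <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(tr$tip.label,
                                                       NULL))
    kmult(Yr, tr, n_perm = 49, seed = s)$p_value
  }, numeric(1))
  # p-values live on the lattice (b+1)/(n_perm+1); bin them so the bins
  # align with the lattice and test uniformity by chi-square
  counts <- table(cut(ps, breaks = seq(0, 1, 0.1)))
  expect_gt(suppressWarnings(stats::chisq.test(counts)$p.value), 0.01)
})

test_that("lambda optimization reports the star-tree sentinel on noise", {
  fx <- study_fixture()
  # data generated under the lambda = 0 model itself: independent tips
  # with variance proportional to root-to-tip depth
  d <- diag(vcv_matrix(fx$tree))
  set.seed(77)
  Y <- matrix(rnorm(17 * 4, 0, sqrt(0.01 * d)), 17, 4,
              dimnames = list(fx$tree$tip.label, NULL))
  res <- kmult(Y, fx$tree, n_perm = 99, seed = 1, optimize_lambda = TRUE)
  expect_equal(res$scaling_lambda, 0)
  expect_true(is.na(res$Kmult) && is.na(res$p_value) && is.na(res$Z))
  # strong BM signal keeps lambda at the upper bound
  Yb <- simulate_from_model(list(model = "BM", R = diag(0.01, 4),
                                 mu = rep(0, 4)), fx$tree, seed = 99)
  resb <- kmult(Yb, fx$tree, n_perm = 99, seed = 1,
                optimize_lambda = TRUE)
  expect_gt(resb$scaling_lambda, 0.9)
  expect_false(is.na(resb$Kmult))
})

test_that("Kmult permutations are reproducible given a seed", {
  fx <- study_fixture()
  Y <- simulate_from_model(list(model = "BM", R = diag(0.01, 3),
                                mu = rep(0, 3)), fx$tree, seed = 12)
  a <- kmult(Y, fx$tree, n_perm = 199, seed = 42)
  b <- kmult(Y, fx$tree, n_perm = 199, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$Z, b$Z)
})

test_that("PGLS on a star tree reproduces ordinary sequential ANOVA", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:14, ":1",
                                                   collapse = ","), ");"))
  set.seed(5)
  y <- matrix(rnorm(14), 14, 1, dimnames = list(star$tip.label, NULL))
  f <- strategy_table(setNames(rep(c("u", "v"), 7), star$tip.label))
  cs <- setNames(exp(rnorm(14)), star$tip.label)
  fit <- pgls_anova(y, star, f, cs, n_perm = 19, seed = 1)
  ref <- anova(lm(y ~ factor(unclass(f)[star$tip.label]) *
                    log(cs[star$tip.label])))
  expect_equal(unname(fit$table[1:3, "F"]), ref$`F value`[1:3],
               tolerance = 1e-10)
  expect_equal(unname(fit$table[1:3, "SS"]), ref$`Sum Sq`[1:3],
               tolerance = 1e-10)
})

test_that("PGLS R-squared partitions sum to one; permutations reproducible", {
  fx <- study_fixture()
  g <- gpa_align(estimate_missing_tps(fx$landmarks), sliders = fx$sliders)
  Y <- flatten_shapes(g)
  pp <- phylo_pca(Y, fx$tree)
  S <- pp$scores[, 1:4]
  cs <- setNames(g$centroid_sizes, g$specimen_ids)
  fit <- pgls_anova(S, fx$tree, fx$prior, cs, n_perm = 99, seed = 7)
  expect_equal(sum(fit$table[c("TPS", "size", "TPS:size", "Residuals"),
                             "Rsq"]), 1, tolerance = 1e-10)
  fit2 <- pgls_anova(S, fx$tree, fx$prior, cs, n_perm = 99, seed = 7)
  expect_identical(fit$table, fit2$table)
  cmp <- compare_hypotheses_pgls(S, fx$tree, fx$prior, fx$prior, cs,
                                 n_perm = 49, seed = 3)
  expect_equal(unname(cmp$delta), c(0, 0))
})

test_that("the strategy-term test holds its nominal type-I error", {
  fx <- study_fixture()
  tr <- fx$tree
  cs <- setNames(exp(rnorm(17)), tr$tip.label)
  labs <- unclass(fx$prior)
  rejections <- vapply(1:300, function(s) {
    Y <- simulate_from_model(list(model = "BM", R = diag(0.01, 3),
                                  mu = rep(0, 3)), tr, seed = 70000 + s)
    fit <- pgls_anova(Y, tr, fx$prior, cs, n_perm = 99, seed = s)
    fit$table["TPS", "p"] <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("the lambda profile likelihood matches an independent implementation", {
  skip_if_not_installed("phytools")
  fx <- study_fixture()
  y <- simulate_from_model(list(model = "BM", R = matrix(0.02), mu = 0),
                           fx$tree, seed = 55)[, 1]
  ps <- phytools::phylosig(fx$tree, y, method = "lambda")
  C <- vcv_matrix(fx$tree)
  prof <- function(l) phylomorph:::mv_bm_loglik(
    matrix(y, ncol = 1, dimnames = list(names(y), NULL)),
    lambda_transform(C, l))
  opt <- optimize(prof, c(0, 1), maximum = TRUE)
  expect_equal(opt$maximum, ps$lambda, tolerance = 1e-3)
  expect_equal(opt$objective, ps$logL, tolerance = 1e-6)
})
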