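test_that("mirroring reflects across the stated axis and is an involution", {
  cfg <- rbind(c(1, 2), c(3, 4))
  expect_equal(mirror_config(cfg, "x"), rbind(c(-1, 2), c(-3, 4)))
  expect_equal(mirror_config(mirror_config(cfg, "y"), "y"), cfg)
  # a configuration whose mirror image is one of its own rotations (label
  # correspondence preserved) aligns back onto itself exactly
  sym <- rbind(c(1, 0), c(-1, 0), c(0, 0))
  expect_lt(procrustes_distance(mirror_config(sym, "x"), sym), 1e-10)
})

test_that("centroid size follows its definition and scale equivariance", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(square), sqrt(2))
  cfg <- random_config(7, 2)
  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("TPS interpolation restores deleted points of (affine) copies", {
  ref <- phylomorph:::maxilla_mean_config()
  k <- nrow(ref)
  # identical specimen with 2 deletions: restored exactly
  lm <- lmset_from(list(ref, ref), c("full", "gappy"),
                   missing = rbind(rep(FALSE, k),
                                   seq_len(k) %in% c(4, 12)))
  est <- estimate_missing_tps(lm, reference = ref)
  expect_equal(est$coords[2, , ], ref, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(any(est$missing))

  # affine image with 3 deletions: TPS reproduces affine maps exactly
  A <- matrix(c(1.3, 0.4, -0.2, 0.9), 2, 2)
  aff <- ref %*% A + matrix(c(2, -1), k, 2, byrow = TRUE)
  lm2 <- lmset_from(list(ref, aff), c("full", "gappy"),
                    missing = rbind(rep(FALSE, k),
                                    seq_len(k) %in% c(1, 9, 17)))
  est2 <- estimate_missing_tps(lm2, reference = ref)
  expect_lt(max(abs(est2$coords[2, , ] - aff)), 1e-8)

  lm3 <- lm2
  lm3$missing[2, ] <- c(FALSE, FALSE, rep(TRUE, k - 2))
  expect_error(estimate_missing_tps(lm3, reference = ref), "fewer than 3")
})

test_that("GPA is invariant to per-specimen similarity transforms", {
  cfg <- phylomorph:::maxilla_mean_config()
  k <- nrow(cfg)
  set.seed(21)
  base <- lapply(1:10, function(i) cfg + matrix(rnorm(2 * k, 0, 0.08), k, 2))
  lm_a <- lmset_from(base, paste0("s", 1:10))
  lm_b <- lmset_from(lapply(base, function(cfg)
    similarity_transform(cfg, runif(1, -pi, pi), exp(rnorm(1, 0, 0.5)),
                         runif(2, -10, 10))), paste0("s", 1:10))
  ga <- gpa_align(lm_a, slide_semilandmarks = FALSE)
  gb <- gpa_align(lm_b, slide_semilandmarks = FALSE)
  da <- as.matrix(dist(flatten_shapes(ga)))
  db <- as.matrix(dist(flatten_shapes(gb)))
  expect_lt(max(abs(da - db)), 1e-8)

  # two identical triangles under a similarity transform align exactly
  tri <- rbind(c(0, 0), c(1, 0), c(0.3, 0.9))
  tri2 <- similarity_transform(tri, 0.7, 2.2, c(5, -3))
  lm_tri <- lmset_from(list(tri, tri2), c("t1", "t2"))
  g <- gpa_align(lm_tri, slide_semilandmarks = FALSE)
  expect_lt(procrustes_distance(g$aligned[1, , ], g$aligned[2, , ]), 1e-10)
})

test_that("aligned configurations are centered with unit centroid size", {
  fx <- study_fixture()
  lmf <- estimate_missing_tps(fx$landmarks)
  g <- gpa_align(lmf, slide_semilandmarks = FALSE, project = FALSE)
  for (i in seq_along(g$specimen_ids)) {
    expect_lt(max(abs(colMeans(g$aligned[i, , ]))), 1e-9)
    expect_equal(sqrt(sum(g$aligned[i, , ]^2)), 1, tolerance = 1e-9)
  }
  # Procrustes residual sum of squares descends across plain iterations
  expect_true(all(diff(g$ss_history) < 1e-10))
})

test_that("semilandmark sliding lowers bending energy, never raises SS", {
  fx <- study_fixture()
  lmf <- estimate_missing_tps(fx$landmarks)
  g_slide <- gpa_align(lmf, sliders = fx$sliders)
  g_plain <- gpa_align(lmf, slide_semilandmarks = FALSE)
  bend_tot <- function(g) sum(vapply(seq_along(g$specimen_ids), function(i)
    phylomorph:::bending_energy(g$aligned[i, , ], g$consensus), numeric(1)))
  expect_lt(bend_tot(g_slide), bend_tot(g_plain))
  expect_gt(g_slide$slide_iterations, 0)
  # with the Procrustes-distance criterion the residual SS cannot exceed
  # the unslid residual SS
  g_pd <- gpa_align(lmf, sliders = fx$sliders, slide_criterion = "procrustes")
  ss_of <- function(g) sum(vapply(seq_along(g$specimen_ids), function(i)
    sum((g$aligned[i, , ] - g$consensus)^2), numeric(1)))
  expect_lte(ss_of(g_pd), ss_of(g_plain) + 1e-12)
})
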