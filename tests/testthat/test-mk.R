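test_that("pruning likelihood equals brute-force enumeration on small trees", {
  for (seed in c(2, 7, 13)) {
    tr <- random_tree(6, seed)
    set.seed(seed + 100)
    states <- setNames(sample(c("a", "b"), 6, replace = TRUE),
                       tr$tip.label)
    if (length(unique(states)) == 1) states[1] <- setdiff(c("a", "b"),
                                                          states[1])
    for (q in c(0.05, 0.4, 2)) {
      expect_equal(
        phylomorph:::mk_loglik(tr, states, q, c("a", "b")),
        mk_brute_loglik(tr, states, q, c("a", "b")),
        tolerance = 1e-10)
    }
  }
})

test_that("ML rate beats a fine grid search; two-tip likelihood is closed form", {
  # mixed pattern (cherries monomorphic, deep change required) so the
  # likelihood has an interior optimum to find
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = "0", B = "0", C = "1", D = "1")
  fit <- fit_mk_er(tr, states)
  grid <- exp(seq(log(1e-4), log(50), length.out = 4000))
  ll <- vapply(grid, function(q)
    phylomorph:::mk_loglik(tr, states, q, c("0", "1")), numeric(1))
  expect_gte(fit$logL, max(ll) - 1e-6)
  # two differing tips: L(q) = 0.5 * P_diff(total path length)
  tr2 <- ape::read.tree(text = "(A:1.5,B:2.5);")
  t_tot <- sum(tr2$edge.length)
  for (q in c(0.1, 0.5, 2))
    expect_equal(phylomorph:::mk_loglik(tr2, c(A = "0", B = "1"), q,
                                        c("0", "1")),
                 log(0.5 * 0.5 * (1 - exp(-2 * q * t_tot))),
                 tolerance = 1e-10)
})

test_that("monomorphic characters give a boundary rate near zero", {
  tr <- random_tree(8, 1)
  fit <- fit_mk_er(tr, setNames(rep("a", 8), tr$tip.label))
  expect_lt(fit$q, 1e-6)
  maps <- simmap_sample(tr, setNames(rep("a", 8), tr$tip.label), fit$q,
                        n_maps = 3, seed = 5)
  for (p in maps)
    expect_setequal(unique(unlist(lapply(p$maps, names))), "a")
})

test_that("sampled maps are consistent with tip states and branch lengths", {
  fx <- study_fixture()
  fit <- fit_mk_er(fx$tree, unclass(fx$prior))
  expect_gt(fit$q, 0)
  expect_true(is.finite(fit$logL))
  maps <- simmap_sample(fx$tree, unclass(fx$prior), fit$q, n_maps = 10,
                        seed = 11)
  for (p in maps) {
    expect_identical(tip_states_from_painting(p)[names(fx$prior)],
                     unclass(fx$prior)[names(fx$prior)])
    me <- mapped_edge(p)
    expect_equal(unname(rowSums(me)), fx$tree$edge.length,
                 tolerance = 1e-8)
  }
  # a two-tip tree with differing states must host at least one transition
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  maps2 <- simmap_sample(tr2, c(A = "x", B = "y"), q = 0.3, n_maps = 50,
                         seed = 2)
  for (p in maps2)
    expect_gte(sum(lengths(p$maps)) - 2, 1)
})

test_that("node-state frequencies across maps match marginal probabilities", {
  tr <- random_tree(5, 9)
  states <- setNames(c("a", "a", "b", "b", "a"), tr$tip.label)
  q <- 0.5
  marg <- phylomorph:::mk_marginals(tr, states, q, c("a", "b"))
  n_maps <- 1000
  maps <- simmap_sample(tr, states, q, n_maps = n_maps, seed = 3)
  # state at each internal node = name of last segment on its parent edge
  node_state <- function(p, node) {
    ei <- which(p$tree$edge[, 2] == node)
    m <- p$maps[[ei]]
    names(m)[length(m)]
  }
  for (node in (5 + 2):(5 + tr$Nnode)) {
    freq_a <- mean(vapply(maps, node_state, character(1), node) == "a")
    p_true <- marg[node, 1]
    se <- sqrt(p_true * (1 - p_true) / n_maps)
    expect_lt(abs(freq_a - p_true), 3 * se + 1e-6)
  }
})

test_that("hypothesis paintings place the shift at the clade stem", {
  fx <- study_fixture()
  p <- paint_from_hypothesis(fx$tree, fx$prior)
  ts <- tip_states_from_painting(p)
  expect_identical(ts[names(fx$prior)], unclass(fx$prior)[names(fx$prior)])
  # stem edge of the specialist clade carries the derived regime over its
  # whole length; its parent edge stays generalist
  spec_node <- ape::getMRCA(fx$tree, phylomorph:::fixture_specialists())
  stem_edge <- which(fx$tree$edge[, 2] == spec_node)
  expect_identical(names(p$maps[[stem_edge]]), "specialist")
  parent_edge <- which(fx$tree$edge[, 2] == fx$tree$edge[stem_edge, 1])
  expect_identical(names(p$maps[[parent_edge]]), "generalist")
  # node convention keeps the stem in the background regime
  p2 <- paint_from_hypothesis(fx$tree, fx$prior, stem_convention = "node")
  expect_identical(names(p2$maps[[stem_edge]]), "generalist")

  # uniform labels give a uniform painting
  uni <- strategy_table(setNames(rep("g", 17), fx$tree$tip.label))
  pu <- paint_from_hypothesis(fx$tree, uni)
  expect_setequal(unique(unlist(lapply(pu$maps, names))), "g")

  # non-monophyletic labels are rejected with a pointer to simmap
  bad <- unclass(fx$prior)
  bad["Herrerasaurus"] <- "specialist"
  expect_error(paint_from_hypothesis(fx$tree, strategy_table(bad)),
               "simmap")
})

test_that("paintings serialize to segment tables and simmap strings", {
  fx <- study_fixture()
  p <- paint_from_hypothesis(fx$tree, fx$prior)
  seg <- painting_segments(p)
  expect_equal(nrow(seg), nrow(fx$tree$edge))
  expect_setequal(unique(seg$regime), c("specialist", "generalist"))
  s <- as_simmap_newick(p)
  expect_match(s, "^\\(.*\\);$")
  expect_match(s, "Carnotaurus:\\{specialist,")
})
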