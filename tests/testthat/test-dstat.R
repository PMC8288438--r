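test_that("nodal values are unweighted child means, tips kept as observed", {
  tr <- balanced4()
  nv <- nodal_values(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(nv[c("A", "B", "C", "D")]), c(1, 1, 0, 0))
  expect_equal(unname(nv["6"]), 1)     # node above (A,B)
  expect_equal(unname(nv["7"]), 0)     # node above (C,D)
  expect_equal(unname(nv["5"]), 0.5)   # root

  nv2 <- nodal_values(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(unname(nv2[c("6", "7", "5")]), c(0.5, 0.5, 0.5))

  expect_true(all(nodal_values(tr, c(A = 0, B = 0, C = 0, D = 0)) == 0))
  expect_error(nodal_values(tr, c(A = 1, B = 1, C = 0)), "D")
})

test_that("d_value matches hand computations and the brute-force oracle", {
  tr <- balanced4()
  expect_equal(d_value(tr, c(A = 1, B = 1, C = 0, D = 0)), 1.0)  # clumped
  expect_equal(d_value(tr, c(A = 1, B = 0, C = 1, D = 0)), 2.0)  # dispersed
  expect_equal(d_value(tr, c(A = 1, B = 1, C = 1, D = 1)), 0.0)  # constant

  # random small trees, all labelings, against the independent recursion
  for (seed in 1:4) {
    tr <- simulate_yule_tree(6, seed = seed)
    for (bits in 0:63) {
      x <- stats::setNames(as.integer(intToBits(bits)[1:6]), tr$tip.label)
      expect_equal(d_value(tr, x), d_oracle(tr, x), tolerance = 1e-12)
    }
  }
})

test_that("d_value is invariant to tip order and child swaps", {
  tr <- balanced8()
  x <- stats::setNames(c(1, 1, 1, 0, 0, 1, 0, 0), tr$tip.label)
  d0 <- d_value(tr, x)
  for (i in 1:5) {
    expect_equal(d_value(tr, sample(x)), d0)           # named input order
    rot <- ape::rotate(tr, sample(9:15, 1))            # swap children of a node
    expect_equal(d_value(rot, x), d0)
  }
})

test_that("moving a presence out of the clump never decreases d on a balanced tree", {
  tr <- balanced8()
  base <- stats::setNames(c(1, 1, 1, 1, 0, 0, 0, 0), tr$tip.label)
  d0 <- d_value(tr, base)
  for (from in c("A", "B", "C", "D")) for (to in c("E", "F", "G", "H")) {
    x <- base
    x[from] <- 0
    x[to] <- 1
    expect_gte(d_value(tr, x), d0)
  }
})

test_that("random_null preserves prevalence, reproduces by seed, errors on constants", {
  tr <- balanced4()
  x <- c(A = 1, B = 1, C = 0, D = 0)
  n1 <- random_null(tr, x, B = 50, seed = 9)
  n2 <- random_null(tr, x, B = 50, seed = 9)
  expect_identical(n1$d_values, n2$d_values)
  expect_equal(n1$B, 50L)
  # on the 4-tip balanced tree every k=2 labeling has d in {1, 2}
  expect_true(all(n1$d_values %in% c(1, 2)))
  expect_error(random_null(tr, c(A = 1, B = 1, C = 1, D = 1), B = 10),
               "trait invariant")
})

test_that("Brownian null approaches the shuffle null on a star-like tree", {
  # near-zero internal edges: thresholded BM values nearly exchangeable
  star <- read_newick("((A:1,B:1):1e-9,(C:1,D:1):1e-9);")
  bn <- brownian_threshold_null(star, 2, B = 2000, seed = 21)
  expect_equal(mean(bn$d_values), 5 / 3,
               tolerance = 3 * stats::sd(bn$d_values) / sqrt(2000) / (5 / 3))
})

test_that("Brownian null concentrates presences in one clade on a two-clade tree", {
  # two deeply separated clades of 4: the clade split dominates the liability,
  # so draws overwhelmingly place all four presences in one clade (d = 1)
  two <- read_newick(paste0("(((A:1,B:1):1,(C:1,D:1):1):10000,",
                            "((E:1,F:1):1,(G:1,H:1):1):10000);"))
  bn <- brownian_threshold_null(two, 4, B = 1000, seed = 33)
  clumped_d <- d_value(two, c(A = 1, B = 1, C = 1, D = 1,
                              E = 0, F = 0, G = 0, H = 0))
  expect_gt(mean(bn$d_values == clumped_d), 0.95)
  expect_lt(abs(mean(bn$d_values) - clumped_d), 0.1)

  b1 <- brownian_threshold_null(two, 4, B = 1, seed = 5)
  b2 <- brownian_threshold_null(two, 4, B = 1, seed = 5)
  expect_identical(b1$d_values, b2$d_values)

  noblen <- ape::rtree(8, br = NULL)
  expect_warning(brownian_threshold_null(noblen, 3, B = 5, seed = 1),
                 "unit lengths")
  zero <- read_newick("((A:0,B:0):0,(C:0,D:0):0);")
  expect_error(brownian_threshold_null(zero, 2, B = 5, seed = 1),
               "no Brownian variance")
})

test_that("phylo_d assembles D, p-values and classification coherently", {
  tr <- simulate_yule_tree(60, seed = 11)
  x <- simulate_trait(tr, regime_spec("clumped", 0.3))
  fit <- phylo_d(tr, x, B = 200, seed = 7)
  expect_s3_class(fit, "phylo_d")
  expect_equal(fit$D,
               (fit$d_obs - fit$mean_d_brownian) /
                 (fit$mean_d_random - fit$mean_d_brownian))
  expect_equal(fit$p_random, mean(fit$null_random$d_values <= fit$d_obs))
  expect_equal(fit$p_brownian, mean(fit$null_brownian$d_values >= fit$d_obs))
  expect_equal(unname(coef(fit)), fit$D)
  expect_lt(fit$D, 0)                         # clumped trait
  expect_equal(fit$classification, "S")
  expect_true(fit$significant)

  # identical master seed -> identical fit; plus-one correction bounds p away from 0
  fit2 <- phylo_d(tr, x, B = 200, seed = 7)
  expect_identical(fit$D, fit2$D)
  fit3 <- phylo_d(tr, x, B = 200, seed = 7, plus_one = TRUE)
  expect_gt(fit3$p_random, 0)
  expect_equal(fit3$p_random, (sum(fit$null_random$d_values <= fit$d_obs) + 1) / 201)

  expect_warning(phylo_d(balanced8(), stats::setNames(c(1, 1, 0, 0, 1, 0, 1, 0),
                                                      LETTERS[1:8]),
                         B = 20, seed = 1), "low power|fewer than 25")
  expect_error(phylo_d(tr, stats::setNames(rep(1, 60), tr$tip.label), B = 10),
               "trait invariant")
})

test_that("degenerate normalization is caught", {
  # a 4-tip star resolved with zero-length internals has no Brownian contrast
  # between the nulls only in pathological cases; force the guard directly
  tr <- simulate_yule_tree(30, seed = 2)
  x <- simulate_trait(tr, regime_spec("random", 0.5, seed = 3))
  fit <- suppressWarnings(phylo_d(tr, x, B = 100, seed = 1))
  expect_gt(abs(fit$mean_d_random - fit$mean_d_brownian), 1e-9)
})

test_that("classify_regime maps D and tail probabilities onto the reading scale", {
  # published whole-tree style values: weak clustering, significant
  lab <- classify_regime(0.785424, p_random = 0.016)
  expect_equal(as.character(lab), "W")
  expect_true(attr(lab, "significant"))

  # near-random, not significant
  lab2 <- classify_regime(0.975770, p_random = 0.400)
  expect_equal(as.character(lab2), "W")
  expect_false(attr(lab2, "significant"))

  expect_equal(as.character(classify_regime(-0.5)), "S")
  expect_equal(as.character(classify_regime(0)), "B0")
  expect_equal(as.character(classify_regime(1.0, p_random = 0.5)), "R")
  expect_equal(as.character(classify_regime(1.4, p_random = 0.99,
                                            p_overdispersion = 0.01)), "OD")
  expect_equal(as.character(classify_regime(1.4, p_random = 0.6,
                                            p_overdispersion = 0.4)), "R")
})

test_that("simulate() draws from the fitted nulls at the observed prevalence", {
  tr <- simulate_yule_tree(40, seed = 6)
  x <- simulate_trait(tr, regime_spec("random", 0.25, seed = 2))
  fit <- suppressWarnings(phylo_d(tr, x, B = 50, seed = 3))
  for (kind in c("brownian", "random")) {
    s <- simulate(fit, nsim = 7, seed = 11, kind = kind)
    expect_equal(dim(s), c(40, 7))
    expect_true(all(colSums(s) == fit$prevalence_k))
  }
})
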