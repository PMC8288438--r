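# a small two-clade study shared across screen tests
screen_fixture <- function(seed = 5) {
  st <- make_synthetic_study(80, list(
    alk = regime_spec("clumped", 0.4),
    flav = regime_spec("random", 0.5)), seed = seed)
  tips <- st$tree$tip.label
  # a mid-sized subclade (15-40 tips), chosen deterministically
  n <- length(tips)
  sizes <- vapply((n + 2):(n + st$tree$Nnode), function(v)
    length(ape::extract.clade(st$tree, v)$tip.label), numeric(1))
  node <- ((n + 2):(n + st$tree$Nnode))[which(sizes >= 15 & sizes <= 40)[1]]
  left <- ape::extract.clade(st$tree, node)
  clades <- list(
    all = clade_definition("all", members = tips),
    left = clade_definition("left", members = left$tip.label))
  list(st = st, clades = clades)
}

test_that("run_screen produces one row per clade x class with per-cell seeds", {
  fx <- screen_fixture()
  st <- run_screen(fx$st$tree, fx$st$matrix, fx$clades, B = 100, seed = 11,
                   min_tips = 10)
  expect_s3_class(st, "screen_table")
  expect_equal(nrow(st), 4)
  expect_setequal(unique(st$clade), c("all", "left"))
  done <- st[is.na(st$skip_reason), ]
  expect_true(all(!is.na(done$D)))
  expect_true(all(done$seed != 11))   # derived, not the master seed itself
  expect_equal(done$D[done$clade == "all" & done$class == "alk"] < 0, TRUE)
})

test_that("screen tables are bit-reproducible and independent of cell order", {
  fx <- screen_fixture()
  a <- run_screen(fx$st$tree, fx$st$matrix, fx$clades, B = 60, seed = 3,
                  min_tips = 10)
  b <- run_screen(fx$st$tree, fx$st$matrix, rev(fx$clades), B = 60, seed = 3,
                  min_tips = 10)
  key <- function(d) paste(d$clade, d$class)
  b2 <- b[match(key(a), key(b)), ]
  rownames(b2) <- NULL
  expect_equal(as.data.frame(a), as.data.frame(b2))
})

test_that("ineligible cells become skip rows, never aborts", {
  fx <- screen_fixture()
  # min_tips above the small clade size -> skip with reason
  st <- run_screen(fx$st$tree, fx$st$matrix, fx$clades, B = 50, seed = 2,
                   min_tips = 70)
  expect_true(all(st$skip_reason[st$clade == "left"] == "min_tips"))

  # a class absent everywhere in the clade -> degenerate_prevalence
  m <- fx$st$matrix
  m[, "flav"] <- "absent"
  st2 <- run_screen(fx$st$tree, m, fx$clades, B = 50, seed = 2, min_tips = 10)
  expect_true(all(st2$skip_reason[st2$class == "flav"] == "degenerate_prevalence"))

  # unresolvable clade -> skip rows; all unresolvable -> error
  ghost <- list(clade_definition("ghost", members = c("nope1", "nope2")))
  st3 <- run_screen(fx$st$tree, fx$st$matrix, c(fx$clades["all"], ghost),
                    B = 50, seed = 2, min_tips = 10)
  expect_true(all(st3$skip_reason[st3$clade == "ghost"] == "clade_not_found"))
  expect_error(run_screen(fx$st$tree, fx$st$matrix, ghost, B = 50, seed = 2),
               "no clade")
})

test_that("subsample_presences enforces the retained-count contract", {
  m <- trait_matrix(paste0("f", 1:5), c("x", "y"))
  m[cbind(paste0("f", 1:5), "x")] <- "present"
  m[cbind(paste0("f", 1:5), "y")] <- "present"   # 10 present cells

  expect_identical(unclass(subsample_presences(m, 1.0, seed = 1)), unclass(m))
  s5 <- subsample_presences(m, 0.5, seed = 1)
  expect_equal(sum(s5 == "present"), 5)
  expect_equal(sum(s5 == "unknown"), 5)          # demoted, not absent
  expect_equal(sum(s5 == "absent"), 0)
  # round-half-up: 0.95 * 10 -> 10 retained
  expect_equal(sum(subsample_presences(m, 0.95, seed = 1) == "present"), 10)
  # 0.25 * 10 -> floor(2.5 + 0.5) = 3
  expect_equal(sum(subsample_presences(m, 0.25, seed = 1) == "present"), 3)

  strat <- subsample_presences(m, 0.5, seed = 2, stratified = TRUE)
  expect_equal(unname(colSums(unclass(strat) == "present")), c(3, 3))

  empty <- trait_matrix("f1", "x")
  expect_error(subsample_presences(empty, 0.5), "no present cells")
  expect_error(subsample_presences(m, 0), "fraction")
  expect_error(subsample_presences(m, 1.2), "fraction")
})

test_that("robustness at fraction 1.0 reproduces the plain screen bit-for-bit", {
  fx <- screen_fixture()
  rb <- run_robustness(fx$st$tree, fx$st$matrix, fx$clades["all"],
                       fractions = 1.0, reps = 2, B = 60, seed = 9,
                       min_tips = 10)
  expect_s3_class(rb, "robustness_result")
  expect_true(all(rb$details$delta_D == 0))
  expect_true(all(!rb$details$flip))
  expect_equal(rb$details$D[rb$details$rep == 1], rb$full$D)
  expect_true(all(rb$summary$mean_abs_delta_D == 0))
  expect_true(all(rb$summary$flip_rate == 0))

  expect_error(run_robustness(fx$st$tree, fx$st$matrix, fx$clades,
                              fractions = numeric(0), reps = 2, B = 10, seed = 1),
               "empty fractions")
})

test_that("clade_presence_summary reports straight counts per clade", {
  tr <- simulate_yule_tree(5, seed = 2)
  m <- trait_matrix(tr$tip.label, "x")
  m[cbind(tr$tip.label[1:2], "x")] <- "present"
  cl <- list(all = clade_definition("all", members = tr$tip.label),
             ghost = clade_definition("ghost", members = c("zz1", "zz2")))
  cs <- clade_presence_summary(tr, m, cl)
  row <- cs[cs$clade == "all", ]
  expect_equal(row$n_present, 2)
  expect_equal(row$n_families, 5)
  expect_equal(row$fraction_present, 0.4)
  expect_equal(cs$skip_reason[cs$clade == "ghost"], "clade_not_found")

  all_present <- trait_matrix(tr$tip.label, "x",
                              matrix("present", 5, 1))
  expect_equal(clade_presence_summary(tr, all_present, cl["all"])$fraction_present, 1)
})
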