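test_that("read_newick parses, validates and preserves structure", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(tr$edge.length, rep(1, 6))

  poly <- read_newick("(A:1,B:1,C:1);")
  expect_equal(length(poly$tip.label), 3)
  expect_equal(poly$Nnode, 1)          # root trichotomy preserved on read

  expect_error(read_newick("((A,A),B);"), "duplicate tip labels")
  expect_error(read_newick("((A,B;"), "malformed Newick")
  expect_error(read_newick("((A,B),C));"), "character")

  # bracket comments and quoted labels are accepted and stripped
  tr2 <- read_newick("((A[a comment]:1,B:1):1,'C x':1);")
  expect_true("C x" %in% tr2$tip.label)
})

test_that("newick round-trip preserves topology, labels and lengths", {
  for (seed in 1:5) {
    tr <- simulate_yule_tree(20, birth_rate = 2, seed = seed)
    tr2 <- read_newick(write_newick(tr))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
  }
})

test_that("collapse_to_families keeps one exemplar tip per family", {
  tr <- read_newick("(((s1:1,s2:1):1,(s3:1,s4:1):1):1,(s5:1,s6:1):2);")
  map <- data.frame(species = paste0("s", 1:6),
                    family = rep(c("FamA", "FamB", "FamC"), each = 2))
  fam <- collapse_to_families(tr, map)
  expect_setequal(fam$tip.label, c("FamA", "FamB", "FamC"))
  expect_equal(length(fam$tip.label), 3)

  # species not in the mapping are pruned, with a message
  map2 <- map[map$species != "s6", ]
  expect_message(collapse_to_families(tr, map2), "pruned 1")

  expect_error(collapse_to_families(tr, data.frame(species = "zz", family = "F")),
               "no mappable tips")
})

test_that("non-monophyletic families collapse by the first-tip rule, with warning", {
  # left-to-right tips: s1 s2 s3 s4 s5; FamA = {s1, s3} is not monophyletic
  tr <- read_newick("((s1:1,(s2:1,s3:1):1):1,(s4:1,s5:1):1);")
  map <- data.frame(species = paste0("s", 1:5),
                    family = c("FamA", "FamB", "FamA", "FamB", "FamC"))
  expect_warning(fam <- collapse_to_families(tr, map), "FamA")
  expect_setequal(fam$tip.label, c("FamA", "FamB", "FamC"))
  # hand-trace: exemplars are s1 -> FamA, s2 -> FamB, s5 -> FamC, so FamA and
  # FamB form a cherry with FamC outside
  expect_true(ape::is.monophyletic(fam, c("FamA", "FamB")))
})

test_that("binarize resolves polytomies deterministically with zero-length edges", {
  poly <- read_newick("(A:1,B:1,C:1);")
  bin <- binarize(poly, seed = 1)
  expect_true(ape::is.binary.phylo(bin))
  expect_equal(sum(bin$edge.length == 0), 1)

  tr <- balanced4()
  expect_identical(binarize(tr), tr)     # already binary -> unchanged

  star5 <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  bin5 <- binarize(star5)
  expect_equal(bin5$Nnode, 4)            # 3 new nodes + original root
  expect_equal(sum(bin5$edge.length == 0), 3)

  # tip-to-root path lengths are never changed
  for (seed in 1:3) {
    tr <- simulate_yule_tree(15, seed = seed)
    tr$edge.length <- round(tr$edge.length, 1)
    poly <- ape::di2multi(tr, tol = 0.11)
    if (ape::is.binary.phylo(poly)) next
    before <- ape::node.depth.edgelength(poly)[seq_along(poly$tip.label)]
    names(before) <- poly$tip.label
    bin <- binarize(poly)
    after <- ape::node.depth.edgelength(bin)[seq_along(bin$tip.label)]
    names(after) <- bin$tip.label
    expect_equal(after[names(before)], before, tolerance = 1e-12)
  }
})

test_that("extract_clade handles member sets, MRCA anchors and errors", {
  tr <- balanced4()
  cherry <- extract_clade(tr, clade_definition("ab", members = c("A", "B")))
  expect_setequal(cherry$tip.label, c("A", "B"))

  whole <- extract_clade(tr, clade_definition("all", mrca_anchors = c("A", "D")))
  expect_equal(length(whole$tip.label), 4)   # MRCA(A, D) is the root

  sub <- extract_clade(tr, clade_definition("cd", mrca_anchors = c("C", "D")))
  expect_setequal(sub$tip.label, c("C", "D"))

  expect_error(extract_clade(tr, clade_definition("bad", members = c("A", "Z"))),
               "Z")
})

test_that("collapse-then-extract commutes with extract-then-collapse on clean trees", {
  tr <- read_newick("(((s1:1,s2:1):1,(s3:1,s4:1):1):1,(s5:1,s6:1):2);")
  map <- data.frame(species = paste0("s", 1:6),
                    family = rep(c("FamA", "FamB", "FamC"), each = 2))
  fam_first <- extract_clade(collapse_to_families(tr, map),
                             clade_definition("ab", members = c("FamA", "FamB")))
  sub_first <- collapse_to_families(
    extract_clade(tr, clade_definition("ab", members = paste0("s", 1:4))), map)
  expect_setequal(fam_first$tip.label, sub_first$tip.label)
  expect_equal(ape::cophenetic.phylo(fam_first)[fam_first$tip.label, fam_first$tip.label],
               ape::cophenetic.phylo(sub_first)[fam_first$tip.label, fam_first$tip.label])
})

test_that("lineages_at_time counts crossing branches with the stated conventions", {
  tr <- read_newick("((A:5,B:5):5,(C:5,D:5):5);")  # depth 10, splits at age 5
  expect_equal(lineages_at_time(tr, 0), 4)
  expect_equal(lineages_at_time(tr, 7), 2)
  expect_equal(lineages_at_time(tr, 12), 1)    # beyond the root age
  expect_equal(lineages_at_time(tr, 10), 1)    # at the root age
  expect_equal(lineages_at_time(tr, 5), 2)     # at a node age the edge above counts

  bad <- read_newick("((A:5,B:3):5,(C:5,D:5):5);")
  expect_error(lineages_at_time(bad, 1), "not ultrametric")

  # non-increasing step function of t
  yt <- simulate_yule_tree(40, seed = 4)
  ages <- seq(0, max(ape::node.depth.edgelength(yt)), length.out = 60)
  counts <- vapply(ages, function(t) lineages_at_time(yt, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 40)
})

test_that("clade and mapping TSV readers parse both dialects", {
  f1 <- tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tmember_family", "ab\tA", "ab\tB", "cd\tC", "cd\tD"), f1)
  cl <- read_clade_definitions(f1)
  expect_named(cl, c("ab", "cd"))
  expect_setequal(cl$ab$members, c("A", "B"))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tanchor1\tanchor2", "all\tA\tD"), f2)
  cl2 <- read_clade_definitions(f2)
  expect_equal(cl2$all$mrca_anchors, c("A", "D"))

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("species\tfamily", "s1\tFamA"), f3)
  expect_equal(read_species_mapping(f3)$family, "FamA")
})
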