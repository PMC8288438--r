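#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward-time simulation: starting from the root split (two lineages at time
#' 0), each of the m extant lineages splits independently at rate
#' `birth_rate`, so inter-event waiting times are Exponential(m * birth_rate);
#' after the n-th lineage is born one final Exponential(n * birth_rate)
#' waiting time is appended and all pendant edges are extended to the present.
#' The expected root-to-tip depth is therefore (H_n - 1) / birth_rate with
#' H_n the n-th harmonic number, i.e. it grows like log(n) / birth_rate.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per time unit (> 0).
#' @param seed integer seed.
#' @param tip_prefix tips are labelled `<prefix>001`, `<prefix>002`, ...
#' @return an ultrametric `phylo` with `n_tips` tips.
#' @export
#' @examples
#' tr <- simulate_yule_tree(10, birth_rate = 1, seed = 1)
#' ape::is.ultrametric(tr)
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_prefix = "F") {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0) stop("birth_rate must be > 0")
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)

  # lineage records: parent internal node, birth time; splitting creates an
  # internal node and two child lineages
  max_lin <- 2L * n_tips
  parent_node <- integer(max_lin)   # internal node id a lineage descends from
  birth <- numeric(max_lin)
  node_child <- vector("list", n_tips - 1L)  # two lineage ids per internal node
  node_time <- numeric(n_tips - 1L)

  # internal node 1 = root at time 0, spawning lineages 1 and 2
  node_time[1] <- 0
  node_child[[1]] <- c(1L, 2L)
  parent_node[1:2] <- 1L
  birth[1:2] <- 0
  active <- c(1L, 2L)
  n_lin <- 2L
  n_int <- 1L
  t <- 0

  while (length(active) < n_tips) {
    m <- length(active)
    t <- t + stats::rexp(1, rate = m * birth_rate)
    i <- active[sample.int(m, 1)]
    n_int <- n_int + 1L
    node_time[n_int] <- t
    kids <- c(n_lin + 1L, n_lin + 2L)
    node_child[[n_int]] <- kids
    parent_node[kids] <- n_int
    birth[kids] <- t
    n_lin <- n_lin + 2L
    active <- c(setdiff(active, i), kids)
    # record which node the split lineage ends at
    parent_node[i] <- -n_int  # negative marks "ends at internal node n_int"
  }
  t_end <- t + stats::rexp(1, rate = n_tips * birth_rate)

  # assemble the ape edge matrix: tips 1..n, internal nodes n+1 .. 2n-1 in
  # creation order (root = n+1)
  tip_ids <- active[order(active)]  # lineage ids that survive to the present
  tip_no <- stats::setNames(seq_len(n_tips), tip_ids)
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  row <- 0L
  for (v in seq_len(n_int)) {
    for (lin in node_child[[v]]) {
      row <- row + 1L
      edge[row, 1] <- n_tips + v
      ends_at <- parent_node[lin]
      if (ends_at < 0) {           # lineage split later: edge to that node
        w <- -ends_at
        edge[row, 2] <- n_tips + w
        elen[row] <- node_time[w] - node_time[v]
      } else {                     # surviving tip
        edge[row, 2] <- tip_no[[as.character(lin)]]
        elen[row] <- t_end - node_time[v]
      }
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = sprintf("%s%03d", tip_prefix, seq_len(n_tips)),
                         Nnode = n_tips - 1L), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
  tree
}

#' Specify a trait-generation regime
#'
#' @param regime one of `"brownian_threshold"`, `"random"`, `"clumped"`,
#'   `"overdispersed"` — the generating regimes matching the D interpretation
#'   scale (D = 0, D = 1, D < 0, D > 1 respectively).
#' @param prevalence fraction of present tips, strictly between 0 and 1.
#' @param seed integer seed.
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(regime = c("brownian_threshold", "random", "clumped",
                                   "overdispersed"),
                        prevalence, seed = NULL) {
  regime <- match.arg(regime)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be strictly between 0 and 1")
  structure(list(regime = regime, prevalence = prevalence, seed = seed),
            class = "regime_spec")
}

# tips of each subtree, and the postorder tip sequence, for the clumped /
# overdispersed constructions
subtree_tip_sets <- function(tree) {
  enc <- tree_encoding(tree)
  sets <- vector("list", enc$n_nodes)
  for (i in seq_len(enc$n_tips)) sets[[i]] <- i
  for (v in enc$ord) sets[[v]] <- c(sets[[enc$child1[v]]], sets[[enc$child2[v]]])
  sets
}

#' Simulate a binary trait under a known signal regime
#'
#' Generates a presence/absence pattern with exactly
#' `k = round(prevalence * n_tips)` present tips (round-half-up):
#' * `brownian_threshold` — the threshold-Brownian draw, sharing its code path
#'   (and, for equal seeds, its exact output) with [brownian_threshold_null()];
#' * `random` — a uniform k-subset of tips;
#' * `clumped` — the subtree whose tip count is closest to k is filled, then
#'   deterministically topped up with the topologically nearest outside tips
#'   (or trimmed to the k tips nearest the subtree's first tip), ties broken
#'   by label order;
#' * `overdispersed` — alternate tips of the left-to-right tip sequence, so
#'   sister pairs disagree wherever possible.
#'
#' @param tree a `phylo` (binarized internally if needed).
#' @param spec a [regime_spec()].
#' @return named integer 0/1 vector over the tips.
#' @export
simulate_trait <- function(tree, spec) {
  stopifnot(inherits(spec, "regime_spec"))
  tree <- binarize(tree)
  n <- length(tree$tip.label)
  k <- as.integer(round_half_up(spec$prevalence * n))
  if (k <= 0 || k >= n)
    stop("degenerate prevalence: k = ", k, " for n = ", n)
  x <- integer(n)
  names(x) <- tree$tip.label

  if (spec$regime == "brownian_threshold") {
    states <- bm_binary_draws(tree, k, B = 1L, seed = spec$seed)
    x[] <- states[, 1]
  } else if (spec$regime == "random") {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    x[sample.int(n, k)] <- 1L
  } else if (spec$regime == "clumped") {
    x <- clumped_trait(tree, k)
  } else {
    x <- overdispersed_trait(tree, k)
  }
  stopifnot(sum(x) == k)
  x
}

clumped_trait <- function(tree, k) {
  n <- length(tree$tip.label)
  sets <- subtree_tip_sets(tree)
  sizes <- lengths(sets)
  # candidate clades: any node's tip set (tips themselves allowed when k small)
  best <- which.min(abs(sizes - k))  # ties -> smallest node id, deterministic
  clade_tips <- sets[[best]]

  # topological distances on the unit-branch-length tree
  ut <- tree
  ut$edge.length <- rep(1, nrow(tree$edge))
  dmat <- ape::dist.nodes(ut)

  x <- integer(n)
  names(x) <- tree$tip.label
  if (length(clade_tips) >= k) {
    anchor <- clade_tips[1]
    ordv <- clade_tips[order(dmat[anchor, clade_tips], tree$tip.label[clade_tips])]
    x[ordv[seq_len(k)]] <- 1L
  } else {
    x[clade_tips] <- 1L
    outside <- setdiff(seq_len(n), clade_tips)
    mrca <- if (length(clade_tips) == 1L) clade_tips else best
    ordv <- outside[order(dmat[mrca, outside], tree$tip.label[outside])]
    x[ordv[seq_len(k - length(clade_tips))]] <- 1L
  }
  x
}

# evenly spaced subset of 1..m (strictly increasing, deterministic)
spread_pick <- function(m, k) {
  if (k >= m) return(seq_len(m))
  floor((0:(k - 1)) * m / k) + 1L
}

overdispersed_trait <- function(tree, k) {
  n <- length(tree$tip.label)
  enc <- tree_encoding(tree)
  seq_tips <- tip_sequence(tree)           # left-to-right; sisters adjacent
  is_tip <- function(v) v <= n
  # cherries in left-to-right order: internal nodes with two tip children
  cherry_first <- integer(0)
  cherry_second <- integer(0)
  seen <- logical(enc$n_nodes)
  for (tp in seq_tips) {
    par <- enc$pre_parent[match(tp, enc$pre_child)]
    if (seen[par]) next
    seen[par] <- TRUE
    a <- enc$child1[par]; b <- enc$child2[par]
    if (is_tip(a) && is_tip(b)) {
      cherry_first <- c(cherry_first, tp)
      cherry_second <- c(cherry_second, if (a == tp) b else a)
    }
  }
  loners <- setdiff(seq_tips, c(cherry_first, cherry_second))
  # one tip per cherry, spread across the whole tree; then loner tips (whose
  # sister is a clade); only at very high prevalence fill cherry sisters
  pool <- list(cherry_first, loners, cherry_second)
  pick <- integer(0)
  need <- k
  for (cand in pool) {
    if (need == 0L || length(cand) == 0L) next
    take <- cand[spread_pick(length(cand), min(need, length(cand)))]
    pick <- c(pick, take)
    need <- need - length(take)
  }
  if (need > 0L) pick <- c(pick, setdiff(seq_tips, pick)[seq_len(need)])
  x <- integer(n)
  names(x) <- tree$tip.label
  x[pick] <- 1L
  x
}

#' The eight-class "paperlike" prevalence preset
#'
#' Named present-family counts for a 437-family study emulating the published
#' seed-plant PSM survey column sums: flavonoids 245, alkaloids 221,
#' terpenoids 206, tannins 175, phenolic acids 167, phenylpropanoids 162,
#' steroids 153, quinones 82.
#'
#' @return named integer vector of target counts (out of 437 families).
#' @export
paperlike_prevalences <- function() {
  c(flavonoids = 245L, alkaloids = 221L, terpenoids = 206L, tannins = 175L,
    phenolic_acids = 167L, phenylpropanoids = 162L, steroids = 153L,
    quinones = 82L)
}

#' Generate a complete synthetic study (tree + trait matrix + truth)
#'
#' Bundles a Yule family-level tree with one simulated trait column per class,
#' recording the generating regime of every class, so each pipeline stage can
#' be exercised against known ground truth. The `"paperlike"` preset gives 437
#' families and the eight PSM classes at the published prevalence counts
#' (see [paperlike_prevalences()]), all under the threshold-Brownian regime.
#'
#' @param n_families number of tips/families, or the string `"paperlike"`.
#' @param classes_with_regimes named list of [regime_spec()] per class
#'   (ignored for the preset).
#' @param birth_rate Yule speciation rate.
#' @param seed master seed; tree and per-class trait seeds are derived from it.
#' @return object of class `synthetic_study`: list with `tree` (`phylo`),
#'   `matrix` ([trait_matrix()], cells present/absent), `truth` (list of
#'   `regime_spec`).
#' @export
#' @examples
#' st <- make_synthetic_study(50, list(
#'   alkaloids = regime_spec("clumped", 0.3),
#'   flavonoids = regime_spec("random", 0.5)), seed = 2)
#' class_prevalence(st$matrix)
make_synthetic_study <- function(n_families, classes_with_regimes = NULL,
                                 birth_rate = 1, seed = NULL) {
  if (identical(n_families, "paperlike")) {
    counts <- paperlike_prevalences()
    n_families <- 437L
    classes_with_regimes <- lapply(counts / n_families, function(p)
      regime_spec("brownian_threshold", prevalence = p))
  }
  if (!is.numeric(n_families) || n_families < 2) stop("need n_families >= 2")
  if (is.null(classes_with_regimes) || length(classes_with_regimes) == 0L)
    stop("need at least one class with a regime_spec")
  stopifnot(all(vapply(classes_with_regimes, inherits, logical(1), "regime_spec")))
  classes <- names(classes_with_regimes)
  if (is.null(classes) || any(!nzchar(classes))) stop("classes must be named")
  seed <- seed %||% sample.int(2147483646L, 1)

  tree <- simulate_yule_tree(n_families, birth_rate, seed = stable_hash(seed, "tree"))
  cells <- matrix("absent", length(tree$tip.label), length(classes))
  truth <- list()
  for (j in seq_along(classes)) {
    sp <- classes_with_regimes[[j]]
    sp$seed <- sp$seed %||% stable_hash(seed, "trait", classes[j])
    x <- simulate_trait(tree, sp)
    cells[x[tree$tip.label] == 1L, j] <- "present"
    truth[[classes[j]]] <- sp
  }
  m <- trait_matrix(tree$tip.label, classes, cells)
  structure(list(tree = tree, matrix = m, truth = truth, seed = seed,
                 birth_rate = birth_rate),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: ", length(x$tree$tip.label), " families, ",
      ncol(x$matrix), " classes (seed ", x$seed, ")\n", sep = "")
  regs <- vapply(x$truth, `[[`, character(1), "regime")
  for (cl in names(regs))
    cat(sprintf("  %-18s %-19s k = %d\n", cl, regs[[cl]],
                class_prevalence(x$matrix, cl)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Materializes the same Newick and TSV formats the pipeline reads: `tree.nwk`,
#' `traits.tsv`, and `truth.json`.
#'
#' @param study a [make_synthetic_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write_trait_matrix(study$matrix, file.path(dir, "traits.tsv"))
  truth <- lapply(study$truth, function(sp)
    list(regime = sp$regime, prevalence = sp$prevalence, seed = sp$seed))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
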