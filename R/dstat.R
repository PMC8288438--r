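#' @useDynLib psmsignal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Encode a fully dichotomous tree for the C++ kernels: internal nodes in a
# children-first order (decreasing root distance), per-node child pointers,
# and the preorder edge list used by the Brownian simulator. Branch lengths
# enter ONLY the Brownian simulation; missing lengths become unit lengths
# (the caller warns).
tree_encoding <- function(tree) {
  if (!is_dichotomous(tree))
    stop("tree must be fully dichotomous; call binarize() first")
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  cw <- ape::reorder.phylo(tree, "cladewise")  # true preorder: parents first
  pre <- cw$edge
  root <- setdiff(pre[, 1], pre[, 2])

  depth <- integer(n_nodes)
  for (e in seq_len(nrow(pre))) depth[pre[e, 2]] <- depth[pre[e, 1]] + 1L

  internal <- sort(unique(pre[, 1]))
  ord <- internal[order(-depth[internal], internal)]  # children before parents

  child1 <- integer(n_nodes)
  child2 <- integer(n_nodes)
  first <- !duplicated(pre[, 1])
  child1[pre[first, 1]] <- pre[first, 2]
  child2[pre[!first, 1]] <- pre[!first, 2]

  elen <- cw$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(pre))
  list(ord = as.integer(ord), child1 = child1, child2 = child2,
       pre_parent = as.integer(pre[, 1]), pre_child = as.integer(pre[, 2]),
       pre_len = as.numeric(elen),
       n_tips = n, n_nodes = n_nodes, root = as.integer(root))
}

# validate a named binary trait vector against the tree's tips; returns the
# 0/1 vector in tip order
match_trait <- function(tree, tip_values) {
  tips <- tree$tip.label
  if (is.null(names(tip_values))) {
    if (length(tip_values) != length(tips))
      stop("unnamed trait vector must have one value per tip")
    x <- tip_values
  } else {
    miss <- setdiff(tips, names(tip_values))
    if (length(miss) > 0L)
      stop("missing trait value for tip(s): ", paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ...")
    x <- tip_values[tips]
  }
  x <- as.numeric(x)
  if (anyNA(x) || !all(x %in% c(0, 1))) stop("trait values must be 0/1 with no NA")
  x
}

#' Estimated nodal values of a binary trait
#'
#' Assigns each tip its observed 0/1 state and each internal node the
#' unweighted mean of its two children's values, working from the tips toward
#' the root. This is the nodal-estimation convention underlying [d_value()];
#' branch lengths are deliberately ignored (the statistic is topological).
#'
#' @param tree a fully dichotomous `phylo` (see [binarize()]).
#' @param tip_values named 0/1 vector over the tips (or unnamed, in tip order).
#' @return numeric vector over all nodes (tips first, ape numbering), named by
#'   tip label / node id.
#' @export
nodal_values <- function(tree, tip_values) {
  enc <- tree_encoding(tree)
  x <- match_trait(tree, tip_values)
  val <- numeric(enc$n_nodes)
  val[seq_len(enc$n_tips)] <- x
  for (v in enc$ord)
    val[v] <- (val[enc$child1[v]] + val[enc$child2[v]]) / 2
  names(val) <- c(tree$tip.label, as.character((enc$n_tips + 1L):enc$n_nodes))
  val
}

#' Observed d: summed sister-clade differences of a binary trait
#'
#' The raw clustering statistic: with nodal values estimated as in
#' [nodal_values()], d is the sum over all edges of the absolute difference
#' between parent and child values. A perfectly clumped trait changes state
#' along few edges and yields a small d; a trait scattered across the tips
#' yields a large d; a constant trait yields d = 0.
#'
#' @inheritParams nodal_values
#' @return a single non-negative number, invariant to tip input order.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' d_value(tr, c(A = 1, B = 1, C = 0, D = 0))  # clumped: 1
#' d_value(tr, c(A = 1, B = 0, C = 1, D = 0))  # dispersed: 2
d_value <- function(tree, tip_values) {
  enc <- tree_encoding(tree)
  x <- match_trait(tree, tip_values)
  cpp_d_value(enc$ord, enc$child1, enc$child2, x, enc$n_nodes)
}

new_null_distribution <- function(kind, d_values, B, seed) {
  structure(list(kind = kind, d_values = as.numeric(d_values),
                 B = as.integer(B), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution (", x$kind, "): B = ", x$B,
      ", mean d = ", format(mean(x$d_values), digits = 6),
      ", seed = ", x$seed %||% NA, "\n", sep = "")
  invisible(x)
}

check_prevalence <- function(x) {
  k <- sum(x)
  if (k == 0 || k == length(x))
    stop("trait invariant: prevalence must satisfy 0 < k < n_tips (k = ", k, ")")
  k
}

#' Tip-shuffling null distribution of d
#'
#' Each replicate permutes the observed multiset of tip states uniformly at
#' random over the tips (prevalence preserved exactly) and records [d_value()].
#'
#' @inheritParams nodal_values
#' @param B number of randomizations (the reference analysis used 1000).
#' @param seed integer seed; every replicate stream is reproducible from it.
#' @return a `null_distribution` object (fields `kind`, `d_values`, `B`, `seed`).
#' @export
random_null <- function(tree, tip_values, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  enc <- tree_encoding(tree)
  x <- match_trait(tree, tip_values)
  check_prevalence(x)
  if (!is.null(seed)) set.seed(seed)
  d <- cpp_random_null(enc$ord, enc$child1, enc$child2, x, enc$n_nodes, as.integer(B))
  new_null_distribution("random_shuffle", d, B, seed)
}

# shared threshold-Brownian tip-state draws (also used by simulate_trait);
# columns are replicates
bm_binary_draws <- function(tree, k, B, seed = NULL) {
  enc <- tree_encoding(tree)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths for the Brownian model")
  } else if (all(tree$edge.length == 0)) {
    stop("no Brownian variance: all branch lengths are zero")
  }
  if (k <= 0 || k >= enc$n_tips)
    stop("trait invariant: prevalence must satisfy 0 < k < n_tips (k = ", k, ")")
  if (!is.null(seed)) set.seed(seed)
  states <- cpp_bm_states(enc$pre_parent, enc$pre_child, enc$pre_len, enc$root,
                          enc$n_tips, enc$n_nodes, as.integer(k), as.integer(B))
  rownames(states) <- tree$tip.label
  states
}

#' Threshold-Brownian null distribution of d
#'
#' Each replicate simulates a continuous character along the tree by Brownian
#' motion (root value 0, increment variance equal to branch length; both the
#' root value and the variance scale are irrelevant because the threshold is
#' set by rank) and marks the k highest-valued tips present, so the simulated
#' prevalence reproduces the observed one exactly; [d_value()] of the binary
#' pattern is recorded. Trees without branch lengths get unit lengths with a
#' warning.
#'
#' @inheritParams random_null
#' @param prevalence_k number of present tips to reproduce (0 < k < n_tips).
#' @return a `null_distribution` object.
#' @export
brownian_threshold_null <- function(tree, prevalence_k, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  enc <- tree_encoding(tree)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths for the Brownian model")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (all(tree$edge.length == 0)) {
    stop("no Brownian variance: all branch lengths are zero")
  }
  k <- as.integer(prevalence_k)
  if (k <= 0 || k >= enc$n_tips)
    stop("trait invariant: prevalence must satisfy 0 < k < n_tips (k = ", k, ")")
  if (!is.null(seed)) set.seed(seed)
  d <- cpp_brownian_null(enc$ord, enc$child1, enc$child2,
                         enc$pre_parent, enc$pre_child, enc$pre_len, enc$root,
                         enc$n_tips, enc$n_nodes, k, as.integer(B))
  new_null_distribution("brownian_threshold", d, B, seed)
}

#' Phylogenetic signal of a binary trait: the D statistic
#'
#' Fits the D statistic of Fritz & Purvis for a presence/absence trait on a
#' rooted phylogeny. The observed clustering statistic d ([d_value()]) is
#' rescaled between the means of two null distributions computed with the
#' identical d operator:
#'
#' \deqn{D = \frac{d_{obs} - \bar d_{Brownian}}{\bar d_{random} - \bar d_{Brownian}}}
#'
#' so that D = 1 when the trait is arranged as if shuffled at random across
#' the tips, D = 0 when arranged as expected for a Brownian-motion liability
#' thresholded to the observed prevalence, D < 0 for extreme clumping and
#' D > 1 for overdispersion. Two empirical p-values accompany the estimate:
#' `p_random`, the fraction of tip-shuffling replicates with d at or below the
#' observed value (small = more clustered than random), and `p_brownian`, the
#' fraction of Brownian replicates with d at or above it (small = more
#' dispersed than Brownian).
#'
#' Polytomies are resolved deterministically via [binarize()] before
#' computation. A warning is issued for trees with fewer than 25 tips, where
#' the statistic has little power.
#'
#' @param tree a rooted `phylo`; branch lengths are used only by the Brownian
#'   null (unit lengths substituted, with a warning, when absent).
#' @param trait named 0/1 vector over the tips, with 0 < sum(trait) < n.
#' @param B replicates per null (default 1000).
#' @param seed master seed; the two null streams are derived from it
#'   deterministically. If `NULL`, a seed is drawn and recorded.
#' @param alpha significance level for the classification flag.
#' @param plus_one if `TRUE`, p-values use the (r+1)/(B+1) correction.
#' @return an object of class `phylo_d` with components `D`, `d_obs`,
#'   `mean_d_random`, `mean_d_brownian`, `p_random`, `p_brownian`, `n_tips`,
#'   `prevalence_k`, `B`, `seed`, `classification`, `significant`, plus the
#'   two `null_distribution` objects and the (binarized) tree.
#' @references Fritz, S. A. & Purvis, A. (2010) Selectivity in mammalian
#'   extinction risk and threat types: a new measure of phylogenetic signal
#'   strength in binary traits. Conservation Biology 24:1042-1051.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_yule_tree(60, birth_rate = 1, seed = 7)
#' x <- simulate_trait(tr, regime_spec("clumped", prevalence = 0.3, seed = 3))
#' fit <- phylo_d(tr, x, B = 200, seed = 11)
#' fit
phylo_d <- function(tree, trait, B = 1000, seed = NULL, alpha = 0.05,
                    plus_one = FALSE) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n < 4) stop("need at least 4 tips")
  if (n < 25)
    warning("the D statistic has low power for trees with fewer than 25 tips (n = ",
            n, ")")
  tree <- binarize(tree)
  x <- match_trait(tree, trait)
  k <- check_prevalence(x)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)

  d_obs <- d_value(tree, x)
  rn <- random_null(tree, x, B = B, seed = stable_hash(seed, "random"))
  bn <- brownian_threshold_null(tree, k, B = B, seed = stable_hash(seed, "brownian"))

  mr <- mean(rn$d_values)
  mb <- mean(bn$d_values)
  if (abs(mr - mb) < 1e-9)
    stop("degenerate normalization: null means differ by less than 1e-9")
  D <- (d_obs - mb) / (mr - mb)
  pr <- if (plus_one) (sum(rn$d_values <= d_obs) + 1) / (B + 1) else mean(rn$d_values <= d_obs)
  pb <- if (plus_one) (sum(bn$d_values >= d_obs) + 1) / (B + 1) else mean(bn$d_values >= d_obs)
  p_over <- if (plus_one) (sum(rn$d_values >= d_obs) + 1) / (B + 1) else mean(rn$d_values >= d_obs)

  res <- structure(list(
    D = D, d_obs = d_obs, mean_d_random = mr, mean_d_brownian = mb,
    p_random = pr, p_brownian = pb, p_overdispersion = p_over,
    n_tips = n, prevalence_k = k, B = as.integer(B), seed = seed,
    alpha = alpha, plus_one = plus_one,
    null_random = rn, null_brownian = bn, tree = tree,
    trait = stats::setNames(as.integer(x), tree$tip.label),
    call = match.call()), class = "phylo_d")
  res$classification <- as.vector(classify_regime(res, alpha = alpha))
  res$significant <- pr < alpha
  res
}

#' Classify a D estimate into the interpretation regimes
#'
#' Maps a fitted [phylo_d()] object (or a bare D value) onto the standard
#' reading scale: `"S"` strong clustering (D < 0), `"B0"` Brownian-like
#' clustering (D = 0 exactly), `"W"` weak clustering (0 < D < 1), `"R"` random
#' arrangement (D >= 1), upgraded to `"OD"` overdispersed when D > 1 and the
#' upper tail of the shuffling null is significant at `alpha`.
#'
#' @param result a `phylo_d` object, or a numeric D value.
#' @param alpha significance level (default 0.05).
#' @param p_random,p_overdispersion optional tail probabilities when `result`
#'   is a bare number.
#' @return a single label among `"S"`, `"B0"`, `"W"`, `"R"`, `"OD"`, with
#'   attribute `"significant"` (`p_random < alpha`, `NA` when unknown).
#' @export
classify_regime <- function(result, alpha = 0.05, p_random = NA_real_,
                            p_overdispersion = NA_real_) {
  if (inherits(result, "phylo_d")) {
    D <- result$D
    p_random <- result$p_random
    p_overdispersion <- result$p_overdispersion
  } else {
    D <- as.numeric(result)
  }
  label <- if (D < 0) "S"
  else if (D == 0) "B0"
  else if (D < 1) "W"
  else "R"
  if (label == "R" && D > 1 && !is.na(p_overdispersion) && p_overdispersion < alpha)
    label <- "OD"
  attr(label, "significant") <- if (is.na(p_random)) NA else p_random < alpha
  label
}

#' @export
print.phylo_d <- function(x, digits = 4, ...) {
  cat("Phylogenetic signal (D statistic) for a binary trait\n")
  cat(sprintf("  tips: %d   present: %d   replicates per null: %d\n",
              x$n_tips, x$prevalence_k, x$B))
  cat(sprintf("  d observed: %s   E[d | random]: %s   E[d | Brownian]: %s\n",
              format(x$d_obs, digits = digits), format(x$mean_d_random, digits = digits),
              format(x$mean_d_brownian, digits = digits)))
  cat(sprintf("  D = %s\n", format(x$D, digits = digits)))
  cat(sprintf("  p (clustered vs random shuffle):   %s\n", format(x$p_random, digits = digits)))
  cat(sprintf("  p (dispersed vs Brownian threshold): %s\n", format(x$p_brownian, digits = digits)))
  lab <- c(S = "strong clustering (D < 0)", B0 = "Brownian-like clustering (D = 0)",
           W = "weak clustering (0 < D < 1)", R = "random arrangement (D >= 1)",
           OD = "overdispersed (D > 1, significant)")[[x$classification]]
  cat(sprintf("  regime: %s [%s]%s\n", x$classification, lab,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' @export
summary.phylo_d <- function(object, ...) {
  qs <- function(nd) stats::quantile(nd$d_values, c(0.025, 0.5, 0.975))
  out <- list(result = as.data.frame(object),
              null_random_quantiles = qs(object$null_random),
              null_brownian_quantiles = qs(object$null_brownian))
  class(out) <- "summary.phylo_d"
  out
}

#' @export
print.summary.phylo_d <- function(x, ...) {
  print(x$result, row.names = FALSE)
  cat("\nnull d quantiles (2.5% / 50% / 97.5%):\n")
  cat("  random shuffle:     ", paste(format(x$null_random_quantiles, digits = 5),
                                      collapse = "  "), "\n")
  cat("  Brownian threshold: ", paste(format(x$null_brownian_quantiles, digits = 5),
                                      collapse = "  "), "\n")
  invisible(x)
}

#' @export
coef.phylo_d <- function(object, ...) c(D = object$D)

#' One-row data frame serialization of a fitted D statistic
#'
#' Columns match the screen-table layout: `n_tips, k, d_obs, mean_d_random,
#' mean_d_brownian, D, p_random, p_brownian, B, seed, classification,
#' significant`.
#'
#' @param x a `phylo_d` object.
#' @param ... unused.
#' @export
as.data.frame.phylo_d <- function(x, ...) {
  data.frame(n_tips = x$n_tips, k = x$prevalence_k, d_obs = x$d_obs,
             mean_d_random = x$mean_d_random, mean_d_brownian = x$mean_d_brownian,
             D = x$D, p_random = x$p_random, p_brownian = x$p_brownian,
             B = x$B, seed = x$seed, classification = x$classification,
             significant = x$significant, stringsAsFactors = FALSE)
}

#' @export
plot.phylo_d <- function(x, breaks = 30, ...) {
  dr <- x$null_random$d_values
  db <- x$null_brownian$d_values
  rng <- range(dr, db, x$d_obs)
  br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks)
  hr <- graphics::hist(dr, breaks = br, plot = FALSE)
  hb <- graphics::hist(db, breaks = br, plot = FALSE)
  ylim <- c(0, max(hr$density, hb$density))
  graphics::plot(hb, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, ylim = ylim, main = "d under the two null models",
                 xlab = "d (summed sister-clade differences)", ...)
  graphics::plot(hr, freq = FALSE, col = grDevices::adjustcolor("tomato", 0.5),
                 border = NA, add = TRUE)
  graphics::abline(v = x$d_obs, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   fill = grDevices::adjustcolor(c("steelblue", "tomato"), 0.5),
                   legend = c("Brownian threshold", "random shuffle"))
  graphics::mtext(sprintf("observed d = %.3f,  D = %.3f", x$d_obs, x$D), side = 3)
  invisible(x)
}

#' Simulate binary tip patterns from a fitted null model
#'
#' Draws `nsim` replicate presence/absence patterns at the fitted prevalence
#' from either null model of a [phylo_d()] fit.
#'
#' @param object a `phylo_d` object.
#' @param nsim number of replicate patterns.
#' @param seed optional seed.
#' @param kind `"brownian"` (threshold-Brownian, default) or `"random"`.
#' @param ... unused.
#' @return integer matrix (n_tips x nsim) of 0/1 states, rownames = tip labels.
#' @export
simulate.phylo_d <- function(object, nsim = 1, seed = NULL,
                             kind = c("brownian", "random"), ...) {
  kind <- match.arg(kind)
  tree <- object$tree
  if (kind == "brownian")
    return(bm_binary_draws(tree, object$prevalence_k, B = nsim, seed = seed))
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_tips
  out <- vapply(seq_len(nsim), function(i) {
    s <- integer(n); s[sample.int(n, object$prevalence_k)] <- 1L; s
  }, integer(n))
  rownames(out) <- tree$tip.label
  out
}
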