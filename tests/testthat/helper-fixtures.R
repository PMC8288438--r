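# shared fixtures and the independent brute-force oracle for d

balanced4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

balanced8 <- function()
  read_newick("(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")

# Brute-force d: direct recursion over the phylo edge table, written
# independently of the production encoding/traversal. Nodal value of an
# internal node = unweighted mean of its children's values; d = sum over
# edges of |parent - child|. Exponential recomputation; tiny trees only.
d_oracle <- function(tree, x) {
  n <- length(tree$tip.label)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  val <- function(v) {
    if (v <= n) return(unname(x[tree$tip.label[v]]))
    mean(vapply(kids(v), val, numeric(1)))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  tot <- 0
  stack <- root
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    for (ch in kids(v)) {
      tot <- tot + abs(val(v) - val(ch))
      stack <- c(stack, ch)
    }
  }
  tot
}

# small trait matrix used across traitkit tests: rows of richness 0, 1, 1, 3
richness_fixture <- function() {
  cells <- rbind(c("unknown", "unknown", "unknown"),
                 c("present", "absent", "absent"),
                 c("absent", "present", "absent"),
                 c("present", "present", "present"))
  trait_matrix(c("f1", "f2", "f3", "f4"), c("c1", "c2", "c3"), cells)
}
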