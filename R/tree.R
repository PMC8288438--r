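#' Read and validate a rooted Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Accepts either a file
#' path or a literal Newick string, strips square-bracket comments, and checks
#' the invariants the rest of the package relies on: a single rooted tree,
#' unique non-empty tip labels, and non-negative branch lengths.
#'
#' @param source path to a Newick file, or a Newick string (recognised by the
#'   presence of `(`/`;`).
#' @return an object of class `phylo` (ape), tips in the order encountered.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tr$tip.label
read_newick <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  txt <- if (grepl("[(;]", source)) source else {
    if (!file.exists(source)) stop("tree file not found: ", source)
    paste(readLines(source, warn = FALSE), collapse = "")
  }
  txt <- strip_newick_comments(txt)
  check_newick_syntax(txt)
  # protect quoted labels (ape's parser does not understand quotes)
  quoted <- unique(regmatches(txt, gregexpr("'[^']*'", txt))[[1]])
  tokens <- character(0)
  if (length(quoted) > 0) {
    tokens <- sprintf("xQUOTEDx%dx", seq_along(quoted))
    for (i in seq_along(quoted))
      txt <- gsub(quoted[i], tokens[i], txt, fixed = TRUE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (!is.null(tree) && length(tokens) > 0) {
    restore <- stats::setNames(substr(quoted, 2, nchar(quoted) - 1), tokens)
    hit <- tree$tip.label %in% tokens
    tree$tip.label[hit] <- restore[tree$tip.label[hit]]
  }
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got ", length(tree))
  validate_phylogeny(tree)
  tree
}

# square-bracket comments are stripped outside quoted labels
strip_newick_comments <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  out <- character(0)
  in_quote <- FALSE
  depth <- 0L
  for (ch in chars) {
    if (ch == "'" && depth == 0L) { in_quote <- !in_quote; out <- c(out, ch); next }
    if (!in_quote && ch == "[") { depth <- depth + 1L; next }
    if (!in_quote && ch == "]") {
      if (depth == 0L) stop("malformed Newick: unmatched ']'")
      depth <- depth - 1L; next
    }
    if (depth == 0L) out <- c(out, ch)
  }
  if (depth > 0L) stop("malformed Newick: unclosed '[' comment")
  paste(out, collapse = "")
}

check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ", length(chars))
  if (!grepl(";", txt)) stop("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

#' Validate the phylogeny invariants
#'
#' Checks that `tree` is a rooted `phylo` object with unique, non-empty tip
#' labels and (when present) non-negative branch lengths. Called by every
#' reader; exported so user-constructed trees can be checked too.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels are not allowed")
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ", paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  # exactly one root: one node that never appears as an edge child
  parents <- tree$edge[, 1]
  children <- tree$edge[, 2]
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root, found ", length(roots))
  if (anyDuplicated(children)) stop("a node has more than one parent")
  invisible(tree)
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Left-to-right tip sequence (order tips are encountered in a depth-first
# traversal taking children in stored order). Used as the deterministic
# exemplar order when collapsing to families.
tip_sequence <- function(tree) {
  cw <- ape::reorder.phylo(tree, "cladewise")
  kids <- cw$edge[, 2]
  kids[kids <= length(tree$tip.label)]
}

#' Collapse a species-level tree to one exemplar tip per family
#'
#' Reduces a species-level phylogeny to the family level: each family is
#' represented by a single exemplar species tip, relabelled with the family
#' name. The exemplar is the family's first tip in a left-to-right depth-first
#' traversal (deterministic; the choice is arbitrary but documented). Species
#' absent from the mapping are pruned and their count reported via `message()`;
#' families whose species are not monophyletic in the tree trigger a warning
#' naming them, and the exemplar rule applies unchanged.
#'
#' @param tree a `phylo` with species tip labels.
#' @param mapping data frame with columns `species` and `family` (see
#'   [read_species_mapping()]).
#' @return a `phylo` with exactly one tip per family, labelled by family.
#' @export
collapse_to_families <- function(tree, mapping) {
  validate_phylogeny(tree)
  if (!all(c("species", "family") %in% names(mapping)))
    stop("mapping must have columns 'species' and 'family'")
  mapping$species <- trimws(as.character(mapping$species))
  mapping$family <- trimws(as.character(mapping$family))
  fam_of <- stats::setNames(mapping$family, mapping$species)

  labs <- tree$tip.label
  mapped <- labs[labs %in% names(fam_of)]
  if (length(mapped) == 0L) stop("no mappable tips: tree and mapping share no species")
  n_unmapped <- length(labs) - length(mapped)
  if (n_unmapped > 0L)
    message("pruned ", n_unmapped, " species tip(s) absent from the mapping")

  seq_labs <- labs[tip_sequence(tree)]
  seq_labs <- seq_labs[seq_labs %in% names(fam_of)]
  fams <- fam_of[seq_labs]
  exemplar <- seq_labs[!duplicated(fams)]
  names(exemplar) <- fams[!duplicated(fams)]

  # warn about non-monophyletic families (>=2 species only)
  by_fam <- split(mapped, fam_of[mapped])
  multi <- by_fam[lengths(by_fam) > 1L]
  bad <- names(multi)[!vapply(multi, function(sp) ape::is.monophyletic(tree, sp),
                              logical(1))]
  if (length(bad) > 0L)
    warning("non-monophyletic families collapsed by the exemplar rule: ",
            paste(bad, collapse = ", "))

  fam_tree <- ape::keep.tip(tree, exemplar)
  fam_tree$tip.label <- names(exemplar)[match(fam_tree$tip.label, exemplar)]
  validate_phylogeny(fam_tree)
  fam_tree
}

#' Resolve polytomies into dichotomies with zero-length branches
#'
#' Every polytomy of k children is replaced by k-1 nested dichotomies, nesting
#' left-to-right in stored child order and inserting zero-length internal
#' branches, so every root-to-tip path length is unchanged. The resolution is
#' fully deterministic; `seed` is accepted for interface stability but unused.
#'
#' @param tree a `phylo`.
#' @param seed ignored (the resolution is deterministic).
#' @return a fully dichotomous `phylo` with the same tip set.
#' @export
binarize <- function(tree, seed = NULL) {
  validate_phylogeny(tree)
  if (is_dichotomous(tree)) return(tree)
  out <- ape::multi2di(tree, random = FALSE)
  validate_phylogeny(out)
  out
}

# every internal node (including the root) has exactly two children;
# ape::is.binary.phylo calls a basal trichotomy "binary unrooted", which is
# not good enough for sister-pair computations
is_dichotomous <- function(tree) {
  tab <- tabulate(tree$edge[, 1], nbins = length(tree$tip.label) + tree$Nnode)
  all(tab[tab > 0] == 2L) && tree$Nnode == length(tree$tip.label) - 1L
}

#' Extract the subtree for a named clade
#'
#' A clade is defined either by an explicit member set (the induced subtree is
#' returned, with degree-2 nodes suppressed and their branch lengths summed) or
#' by two anchor tips whose most recent common ancestor roots the full subtree.
#'
#' @param tree a `phylo`.
#' @param clade a [clade_definition()].
#' @return a `phylo`.
#' @export
extract_clade <- function(tree, clade) {
  stopifnot(inherits(clade, "clade_definition"))
  labs <- tree$tip.label
  if (!is.null(clade$members)) {
    missing <- setdiff(clade$members, labs)
    if (length(missing) > 0L)
      stop("clade not found: '", clade$name, "' is missing families: ",
           paste(missing, collapse = ", "))
    if (length(clade$members) == length(labs)) return(tree)
    if (length(clade$members) < 2L)
      stop("clade '", clade$name, "' needs at least 2 member tips")
    return(ape::keep.tip(tree, clade$members))
  }
  anchors <- clade$mrca_anchors
  missing <- setdiff(anchors, labs)
  if (length(missing) > 0L)
    stop("clade not found: '", clade$name, "' anchor(s) missing: ",
         paste(missing, collapse = ", "))
  node <- ape::getMRCA(tree, anchors)
  root <- length(labs) + 1L
  if (node == root) return(tree)
  ape::extract.clade(tree, node)
}

#' Define a clade by members or by MRCA anchors
#'
#' @param name clade name.
#' @param members character vector of member tip (family) names, or `NULL`.
#' @param mrca_anchors length-2 character vector of anchor tips, or `NULL`.
#'   Exactly one of `members` / `mrca_anchors` must be given.
#' @return an object of class `clade_definition`.
#' @export
clade_definition <- function(name, members = NULL, mrca_anchors = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(members) == is.null(mrca_anchors))
    stop("give exactly one of 'members' or 'mrca_anchors'")
  if (!is.null(members) && length(members) == 0L)
    stop("'members' must be non-empty")
  if (!is.null(mrca_anchors) && length(mrca_anchors) != 2L)
    stop("'mrca_anchors' must name exactly two tips")
  structure(list(name = name, members = members, mrca_anchors = mrca_anchors),
            class = "clade_definition")
}

# node ages measured backward from the tips (tips at age 0)
node_ages <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

check_ultrametric <- function(tree, rel_tol = 1e-6) {
  ages <- node_ages(tree)
  tip_ages <- ages[seq_along(tree$tip.label)]
  dev <- max(abs(tip_ages))
  total_depth <- max(ages)
  if (total_depth <= 0) stop("tree has zero depth")
  if (dev > rel_tol * total_depth)
    stop(sprintf("tree is not ultrametric: max tip-age deviation %.6g (tolerance %.6g)",
                 dev, rel_tol * total_depth))
  ages
}

#' Count lineages crossing a given age
#'
#' On an ultrametric, time-calibrated tree, counts the edges whose parent is
#' older than `t` and whose child is at age `t` or younger (ages measured
#' backward from the tips, tips at age 0). At `t = 0` this is the tip count;
#' for `t` at or beyond the root age the single root lineage is counted.
#'
#' @param tree an ultrametric `phylo` with branch lengths.
#' @param t age, same units as the branch lengths (e.g. Myr); `t >= 0`.
#' @param rel_tol relative ultrametricity tolerance (fraction of tree depth).
#' @return integer lineage count.
#' @export
lineages_at_time <- function(tree, t, rel_tol = 1e-6) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  ages <- check_ultrametric(tree, rel_tol)
  root_age <- max(ages)
  if (t >= root_age) return(1L)
  parent_age <- ages[tree$edge[, 1]]
  child_age <- ages[tree$edge[, 2]]
  sum(parent_age > t & child_age <= t)
}

#' Read a species-to-family mapping table
#'
#' @param path TSV with header columns `species` and `family`.
#' @return data frame with those two character columns, whitespace-trimmed.
#' @export
read_species_mapping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("species", "family") %in% names(df)))
    stop("mapping TSV must have header columns 'species' and 'family'")
  df$species <- trimws(df$species)
  df$family <- trimws(df$family)
  df
}

#' Names of the major seed-plant clades usually screened
#'
#' Returns the reference roster of 18 named seed-plant clades (seed plants,
#' angiosperms, gymnosperms, magnoliids, monocots, commelinids, eudicots,
#' core eudicots, superrosids, rosids, fabids, malvids, superasterids,
#' asterids, lamiids, campanulids, Malpighiales, Caryophyllales) shipped with
#' the package as a names-only synthetic stand-in: which families belong to
#' each clade depends on the tree in hand, so memberships are always supplied
#' by the user as a [read_clade_definitions()] TSV.
#'
#' @return character vector of clade names.
#' @export
clade_roster_names <- function() {
  path <- system.file("extdata", "clade_roster_synthetic.tsv",
                      package = "psmsignal")
  utils::read.delim(path, header = TRUE, colClasses = "character")$clade_name
}

#' Read clade definitions from a TSV file
#'
#' Two dialects are accepted: long member lists with columns
#' `clade_name`, `member_family` (one row per member), or MRCA anchors with
#' columns `clade_name`, `anchor1`, `anchor2` (one row per clade).
#'
#' @param path TSV path (header required).
#' @return named list of [clade_definition()] objects.
#' @export
read_clade_definitions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (all(c("clade_name", "member_family") %in% names(df))) {
    sets <- split(trimws(df$member_family), df$clade_name)
    clades <- lapply(names(sets), function(nm) clade_definition(nm, members = sets[[nm]]))
  } else if (all(c("clade_name", "anchor1", "anchor2") %in% names(df))) {
    clades <- lapply(seq_len(nrow(df)), function(i)
      clade_definition(trimws(df$clade_name[i]),
                       mrca_anchors = c(trimws(df$anchor1[i]), trimws(df$anchor2[i]))))
  } else {
    stop("clade TSV must have columns (clade_name, member_family) or ",
         "(clade_name, anchor1, anchor2)")
  }
  stats::setNames(clades, vapply(clades, `[[`, character(1), "name"))
}
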