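#' Build and validate an analysis configuration
#'
#' The declarative description of one full analysis run. Inputs may be given
#' as file paths (Newick tree, trait-matrix TSV, clade TSV) or as in-memory
#' objects (`phylo`, [trait_matrix()], list of [clade_definition()]).
#'
#' @param tree tree path or `phylo`.
#' @param traits trait-matrix TSV path or [trait_matrix()].
#' @param clades clade TSV path, list of [clade_definition()], or `NULL` for a
#'   single whole-tree clade.
#' @param B replicates per null (>= 1).
#' @param seed master seed.
#' @param alpha significance level, in (0, 1).
#' @param min_tips minimum clade size for estimation.
#' @param fractions subsampling fractions, each in (0, 1].
#' @param reps subsample repetitions per fraction; `0` disables the
#'   robustness stage.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param stratified stratify subsampling within classes.
#' @param plus_one use the (r+1)/(B+1) p-value correction.
#' @param ltt_points number of ages in the lineages-through-time grid.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(tree, traits, clades = NULL, B = 1000, seed = 1,
                            alpha = 0.05, min_tips = 25,
                            fractions = c(0.5, 0.7, 0.8, 0.95), reps = 0,
                            outdir = NULL, stratified = FALSE,
                            plus_one = FALSE, ltt_points = 50) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(fractions) > 0 && any(fractions <= 0 | fractions > 1))
    stop("all fractions must be in (0, 1]")
  if (!is.numeric(reps) || reps < 0) stop("reps must be >= 0")
  structure(list(tree = tree, traits = traits, clades = clades,
                 B = as.integer(B), seed = as.integer(seed), alpha = alpha,
                 min_tips = min_tips, fractions = fractions,
                 reps = as.integer(reps), outdir = outdir,
                 stratified = isTRUE(stratified), plus_one = isTRUE(plus_one),
                 ltt_points = as.integer(ltt_points)),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' The JSON object may contain any [analysis_config()] field; `tree`,
#' `traits` and `clades` are interpreted as file paths relative to the
#' config file's directory.
#'
#' @param path JSON file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  raw$tree <- rel(raw$tree)
  raw$traits <- rel(raw$traits)
  raw$clades <- rel(raw$clades)
  do.call(analysis_config, raw)
}

load_config_inputs <- function(config) {
  tree <- if (inherits(config$tree, "phylo")) config$tree else read_newick(config$tree)
  traits <- if (inherits(config$traits, "trait_matrix")) config$traits
  else read_trait_matrix(config$traits)
  clades <- config$clades
  if (is.character(clades)) clades <- read_clade_definitions(clades)
  list(tree = tree, traits = traits, clades = clades)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: align the trait matrix to the tree,
#' distribution summaries (class prevalences, richness histogram, usable
#' family count), the clade-by-class D-statistic screen, the subsampling
#' robustness experiment (when `reps > 0`), per-class trait
#' lineages-through-time curves (when the tree is ultrametric), the ring
#' annotation export, and a run manifest (seeds, parameters, input hashes)
#' sufficient to reproduce every table bit-for-bit. Per-cell failures become
#' skip rows, never aborts. When `config$outdir` is set, all tables are also
#' written there as TSV/JSON.
#'
#' @param config an [analysis_config()].
#' @return object of class `report_bundle`: list with `alignment`,
#'   `summaries`, `screen`, `robustness` (or `NULL`), `ltt` (long data frame
#'   or `NULL`), `annotation`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inp <- load_config_inputs(config)
  tree <- inp$tree
  al <- align_to_tree(inp$traits, tree)
  m <- al$matrix
  if (length(al$dropped_from_tree) > 0L) tree <- ape::keep.tip(tree, rownames(m))

  summaries <- list(
    n_families = nrow(m), n_classes = ncol(m),
    class_prevalence = as.list(class_prevalence(m)),
    richness_histogram = as.list(richness_histogram(m)),
    usable_family_count = usable_family_count(m))

  screen <- run_screen(tree, m, inp$clades, B = config$B, seed = config$seed,
                       min_tips = config$min_tips, alpha = config$alpha,
                       plus_one = config$plus_one)

  robustness <- NULL
  if (config$reps > 0L && length(config$fractions) > 0L)
    robustness <- run_robustness(tree, m, inp$clades,
                                 fractions = config$fractions,
                                 reps = config$reps, B = config$B,
                                 seed = config$seed, min_tips = config$min_tips,
                                 alpha = config$alpha,
                                 stratified = config$stratified,
                                 plus_one = config$plus_one)

  ltt <- NULL
  ultra <- !inherits(tryCatch(check_ultrametric(tree), error = function(e) e), "error")
  if (ultra) {
    root_age <- max(node_ages(tree))
    grid <- seq(0, root_age, length.out = config$ltt_points)
    ltt <- do.call(rbind, lapply(colnames(m), function(cl) {
      tab <- trait_lineages_through_time(tree, m, cl, time_grid = grid)
      cbind(data.frame(class = cl, stringsAsFactors = FALSE), tab)
    }))
  }

  annotation <- export_tree_annotation(tree, m, palette = default_palette(colnames(m)))

  manifest <- list(
    package = "psmsignal",
    version = as.character(utils::packageVersion("psmsignal")),
    seed = config$seed, B = config$B, alpha = config$alpha,
    min_tips = config$min_tips, fractions = config$fractions,
    reps = config$reps, stratified = config$stratified,
    plus_one = config$plus_one, ltt_points = config$ltt_points,
    tree_hash = stable_hash(write_newick(tree)),
    matrix_hash = stable_hash(paste(unclass(m), collapse = "")),
    n_families = nrow(m), n_classes = ncol(m),
    ultrametric = ultra,
    dropped_from_tree = al$dropped_from_tree,
    dropped_from_matrix = al$dropped_from_matrix)

  bundle <- structure(list(alignment = al, summaries = summaries,
                           screen = screen, robustness = robustness,
                           ltt = ltt, annotation = annotation,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir, config)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle: ", x$manifest$n_families, " families x ",
      x$manifest$n_classes, " classes; seed ", x$manifest$seed, "\n", sep = "")
  cat("usable families: ", x$summaries$usable_family_count, "\n", sep = "")
  print(x$screen)
  invisible(x)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

write_report_bundle <- function(bundle, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(bundle$screen), file.path(outdir, "screen.tsv"))
  jsonlite::write_json(as.data.frame(bundle$screen), file.path(outdir, "screen.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(bundle$summaries, file.path(outdir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$robustness)) {
    write_tsv(bundle$robustness$summary, file.path(outdir, "robustness_summary.tsv"))
    write_tsv(bundle$robustness$details, file.path(outdir, "robustness_details.tsv"))
  }
  if (!is.null(bundle$ltt)) write_tsv(bundle$ltt, file.path(outdir, "ltt.tsv"))
  write_tsv(bundle$annotation, file.path(outdir, "annotation.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path_or_tag <- function(x, tag)
    if (is.character(x) && is.null(dim(x)) && length(x) == 1L) x else tag
  resolved <- config
  resolved$tree <- path_or_tag(config$tree, "<in-memory phylo>")
  resolved$traits <- path_or_tag(config$traits, "<in-memory trait_matrix>")
  resolved$clades <- if (is.null(config$clades)) "<whole tree>"
  else path_or_tag(config$clades, "<in-memory clade definitions>")
  jsonlite::write_json(unclass(resolved), file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}

#' Lineages through time carrying a trait class
#'
#' A temporal-mapping surrogate: at each age t, counts the branches crossing t
#' that lead to at least one present tip of the class (a Dollo-style minimal
#' mapping, i.e. the class is assumed carried by every edge ancestral to a
#' present tip). At t = 0 this equals the class prevalence on the tree; for
#' an all-present class it reduces exactly to [lineages_at_time()]. The curve
#' is a coarse upper-bound-free summary of when the extant carriers' lineages
#' diversified — not an ancestral-state reconstruction.
#'
#' @param tree an ultrametric `phylo`.
#' @param matrix a [trait_matrix()] containing `class_name`.
#' @param class_name one class column.
#' @param time_grid ages at which to evaluate; default 50 points from 0 to
#'   the root age.
#' @param rel_tol ultrametricity tolerance.
#' @return data frame with columns `t` and `lineages`.
#' @export
trait_lineages_through_time <- function(tree, matrix, class_name,
                                        time_grid = NULL, rel_tol = 1e-6) {
  ages <- check_ultrametric(tree, rel_tol)
  al <- align_to_tree(matrix, tree)
  if (!class_name %in% colnames(al$matrix)) stop("unknown class: ", class_name)
  if (length(al$dropped_from_tree) > 0L)
    stop("every tree tip needs a trait row for the temporal mapping")
  x <- binary_view(al$matrix)[tree$tip.label, class_name]

  root_age <- max(ages)
  if (is.null(time_grid)) time_grid <- seq(0, root_age, length.out = 50)
  stopifnot(all(time_grid >= 0))

  # does any descendant tip of each node carry the class? (postorder OR)
  n <- length(tree$tip.label)
  tree_bin <- binarize(tree)   # carrier flags are topology-only, safe to reuse
  enc <- tree_encoding(tree_bin)
  carrier <- logical(enc$n_nodes)
  carrier[seq_len(n)] <- x[tree_bin$tip.label] == 1L
  for (v in enc$ord)
    carrier[v] <- carrier[enc$child1[v]] || carrier[enc$child2[v]]
  # map carrier flags back to the original (possibly multifurcating) node ids:
  # binarize() keeps tip numbering; for safety evaluate on the binarized tree,
  # whose crossing counts at any age equal the original's (zero-length edges
  # add no crossings except exactly at their parent's age, where the original
  # node also crosses).
  ages_b <- node_ages(tree_bin)
  parent_age <- ages_b[tree_bin$edge[, 1]]
  child_age <- ages_b[tree_bin$edge[, 2]]
  child_carries <- carrier[tree_bin$edge[, 2]]

  count_at <- function(t) {
    if (t >= root_age) return(as.integer(any(carrier)))
    sum(parent_age > t & child_age <= t & child_carries)
  }
  data.frame(t = time_grid,
             lineages = vapply(time_grid, count_at, numeric(1)))
}

default_palette <- function(classes)
  stats::setNames(grDevices::hcl.colors(max(length(classes), 2L), "Dark 3")[seq_along(classes)],
                  classes)

#' Export a ring-annotation table for tree viewers
#'
#' One row per family in tree tip order, one colour column per class: the
#' class colour where the class is present, the neutral colour (gray) where it
#' is absent or unknown — the same conflation the published figure draws.
#' The TSV (`family` + one hex-colour column per class) can be joined to any
#' circular-tree viewer's annotation input.
#'
#' @param tree a `phylo`.
#' @param matrix a [trait_matrix()] aligned to the tree.
#' @param palette named vector of hex colours, one per class (default: a
#'   colour-blind-safe qualitative palette).
#' @param neutral colour for absent/unknown cells.
#' @param path optional TSV output path.
#' @return data frame of the annotation table (invisibly when written).
#' @export
export_tree_annotation <- function(tree, matrix, palette = NULL,
                                   neutral = "#BEBEBE", path = NULL) {
  al <- align_to_tree(matrix, tree)
  m <- al$matrix
  classes <- colnames(m)
  if (is.null(palette)) palette <- default_palette(classes)
  missing_cl <- setdiff(classes, names(palette))
  if (length(missing_cl) > 0L)
    stop("palette missing class(es): ", paste(missing_cl, collapse = ", "))
  bv <- binary_view(m)
  cols <- vapply(classes, function(cl)
    ifelse(bv[, cl] == 1L, palette[[cl]], neutral), character(nrow(m)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  df <- data.frame(family = rownames(m), cols, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("family", classes)
  if (!is.null(path)) { write_tsv(df, path); return(invisible(df)) }
  df
}
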