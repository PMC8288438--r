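STATES <- c("present", "absent", "unknown")

#' Construct a family-by-class trait matrix
#'
#' The container for presence/absence chemotaxonomic data: rows are families,
#' columns are trait classes (e.g. the eight PSM classes), and each cell is one
#' of `"present"`, `"absent"`, `"unknown"`. Analysis collapses the ternary
#' states to binary (present -> 1, absent and unknown -> 0), mirroring the
#' coding convention in which a class is scored 1 if recorded in at least one
#' taxon of the family and 0 if absent from, or unclear in, all known taxa.
#' The unknown/absent distinction is kept in storage so it is never lost.
#'
#' @param families ordered, unique family names.
#' @param classes ordered, unique trait-class names (non-empty).
#' @param cells optional character matrix (families x classes) of states;
#'   defaults to all-`"unknown"`.
#' @return object of class `trait_matrix` (a character matrix with dimnames).
#' @export
#' @examples
#' m <- trait_matrix(c("Pinaceae", "Lamiaceae"), c("alkaloids", "flavonoids"))
#' m["Lamiaceae", "alkaloids"] <- "present"
#' binary_view(m)
trait_matrix <- function(families, classes, cells = NULL) {
  families <- trimws(as.character(families))
  classes <- trimws(as.character(classes))
  if (length(classes) == 0L) stop("no classes")
  if (length(families) == 0L) stop("no families")
  if (anyDuplicated(families)) stop("duplicate family names")
  if (anyDuplicated(classes)) stop("duplicate class names")
  if (is.null(cells))
    cells <- matrix("unknown", length(families), length(classes))
  stopifnot(nrow(cells) == length(families), ncol(cells) == length(classes))
  if (!all(cells %in% STATES))
    stop("cells must be one of: ", paste(STATES, collapse = ", "))
  dimnames(cells) <- list(families, classes)
  structure(cells, class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix: ", nrow(x), " families x ", ncol(x), " classes\n", sep = "")
  cat("present ", sum(x == "present"), ", absent ", sum(x == "absent"),
      ", unknown ", sum(x == "unknown"), "\n", sep = "")
  invisible(x)
}

#' @export
`[.trait_matrix` <- function(x, i, j, ..., drop = TRUE) {
  xs <- unclass(x)
  if (!missing(i) && missing(j) && is.matrix(i))   # cell form, m[cbind(f, c)]
    return(xs[i])
  out <- if (missing(i) && missing(j)) xs[, , drop = drop]
  else if (missing(i)) xs[, j, drop = drop]
  else if (missing(j)) xs[i, , drop = drop]
  else xs[i, j, drop = drop]
  if (is.matrix(out)) class(out) <- "trait_matrix"
  out
}

#' Binary 0/1 view of a trait matrix
#'
#' @param matrix a [trait_matrix()].
#' @return integer matrix, `present -> 1`, `absent`/`unknown -> 0`.
#' @export
binary_view <- function(matrix) {
  out <- (unclass(matrix) == "present") * 1L
  storage.mode(out) <- "integer"
  out
}

#' Code presence records into a trait matrix
#'
#' Applies the family-level coding rule: a (family, class) cell is `present`
#' iff at least one record mentions that class for that family (duplicate
#' records are idempotent). Families with at least one record get `absent` in
#' their unrecorded classes; families with no records at all keep all-`unknown`
#' rows. Records whose family is not in `families` are returned in a rejects
#' report (attribute `"rejects"`), never silently dropped; records whose class
#' is not in `classes` violate the precondition and raise an error.
#'
#' @param records data frame with columns `family` and `class` (optionally
#'   `taxon`, `evidence`).
#' @param families family roster (matrix rows).
#' @param classes class roster (matrix columns).
#' @return a [trait_matrix()] with attribute `"rejects"` (data frame).
#' @export
code_matrix <- function(records, families, classes) {
  m <- trait_matrix(families, classes)
  if (nrow(records) == 0L) {
    attr(m, "rejects") <- records
    return(m)
  }
  if (!all(c("family", "class") %in% names(records)))
    stop("records need columns 'family' and 'class'")
  records$family <- trimws(as.character(records$family))
  records$class <- trimws(as.character(records$class))
  bad_class <- setdiff(unique(records$class), colnames(m))
  if (length(bad_class) > 0L)
    stop("record classes not in the class roster: ", paste(bad_class, collapse = ", "))
  keep <- records$family %in% rownames(m)
  rejects <- records[!keep, , drop = FALSE]
  ok <- records[keep, , drop = FALSE]
  recorded_fams <- unique(ok$family)
  m[rownames(m) %in% recorded_fams, ] <- "absent"
  m[cbind(ok$family, ok$class)] <- "present"
  attr(m, "rejects") <- rejects
  m
}

#' Number of families in which a class is present
#'
#' @param matrix a [trait_matrix()].
#' @param class_name a single class name, or `NULL` for all classes.
#' @return integer count (named vector over classes when `class_name = NULL`).
#' @export
class_prevalence <- function(matrix, class_name = NULL) {
  bv <- binary_view(matrix)
  if (is.null(class_name)) return(colSums(bv))
  if (!class_name %in% colnames(bv)) stop("unknown class: ", class_name)
  sum(bv[, class_name])
}

#' Histogram of per-family class richness
#'
#' For k = 0..n_classes, the number of families with exactly k classes present.
#'
#' @param matrix a [trait_matrix()].
#' @return named integer vector over `0:n_classes`; sums to `n_families`.
#' @export
richness_histogram <- function(matrix) {
  k <- rowSums(binary_view(matrix))
  kk <- 0:ncol(matrix)
  stats::setNames(vapply(kk, function(v) sum(k == v), integer(1)), kk)
}

#' Families with usable data
#'
#' A family counts as usable when at least one class is recorded present
#' (equivalently `n_families - richness_histogram[0]`).
#'
#' @param matrix a [trait_matrix()].
#' @return integer count.
#' @export
usable_family_count <- function(matrix) {
  sum(rowSums(binary_view(matrix)) > 0L)
}

#' Restrict a trait matrix to the families on a tree
#'
#' @param matrix a [trait_matrix()].
#' @param tree a `phylo` with family tip labels.
#' @return list with `matrix` (rows reordered to tree tip order),
#'   `dropped_from_tree` and `dropped_from_matrix` (character vectors).
#' @export
align_to_tree <- function(matrix, tree) {
  fams <- rownames(matrix)
  tips <- tree$tip.label
  shared <- intersect(tips, fams)
  if (length(shared) == 0L) stop("tree and trait matrix share no family names")
  keep <- tips[tips %in% shared]
  list(matrix = matrix[keep, , drop = FALSE],
       dropped_from_tree = setdiff(tips, fams),
       dropped_from_matrix = setdiff(fams, tips))
}

#' Read / write a trait matrix as TSV
#'
#' Format: header row `family` + one column per class; cells `1` (present),
#' `0` (absent) or `NA` (unknown). The reader also accepts the literal words
#' `present`/`absent`/`unknown`. The writer emits `1/0/NA` in the stored
#' family and class order, bit-exactly reproducible.
#'
#' @param path TSV path.
#' @return [read_trait_matrix()]: a [trait_matrix()].
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  if (names(df)[1] != "family") stop("first column of a trait matrix TSV must be 'family'")
  cells <- as.matrix(df[, -1, drop = FALSE])
  dec <- function(v) {
    v <- trimws(v)
    out <- rep(NA_character_, length(v))
    out[v %in% c("1", "present")] <- "present"
    out[v %in% c("0", "absent")] <- "absent"
    out[v %in% c("NA", "", "unknown")] <- "unknown"
    if (anyNA(out)) stop("unrecognised cell value(s): ",
                         paste(unique(v[is.na(out)]), collapse = ", "))
    out
  }
  cells <- apply(cells, 2, dec)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(df))
  trait_matrix(df$family, names(df)[-1], cells)
}

#' @rdname read_trait_matrix
#' @param matrix a [trait_matrix()].
#' @export
write_trait_matrix <- function(matrix, path) {
  enc <- c(present = "1", absent = "0", unknown = "NA")
  cells <- matrix(enc[unclass(matrix)], nrow(matrix), ncol(matrix))
  df <- data.frame(family = rownames(matrix), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("family", colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize family names through a synonym table
#'
#' Matching between tree tips and matrix rows is exact (case-sensitive, after
#' whitespace trimming): taxonomy drift is a data problem, not something to
#' guess at in code. This hook applies an explicit synonym table — columns
#' `from`, `to`, e.g. pre-APG names to accepted ones — to a character vector
#' or to the families of a [trait_matrix()].
#'
#' @param x character vector of family names, or a [trait_matrix()].
#' @param synonyms data frame with columns `from` and `to`, or a TSV path.
#' @return `x` with every `from` name replaced by its `to` name.
#' @export
normalize_family_names <- function(x, synonyms) {
  if (is.character(synonyms) && length(synonyms) == 1L)
    synonyms <- utils::read.delim(synonyms, header = TRUE, sep = "\t",
                                  colClasses = "character")
  if (!all(c("from", "to") %in% names(synonyms)))
    stop("synonym table needs columns 'from' and 'to'")
  map <- stats::setNames(trimws(synonyms$to), trimws(synonyms$from))
  swap <- function(v) {
    hit <- v %in% names(map)
    v[hit] <- map[v[hit]]
    v
  }
  if (inherits(x, "trait_matrix")) {
    fams <- swap(rownames(x))
    if (anyDuplicated(fams))
      stop("synonym mapping collapses distinct families: ",
           paste(unique(fams[duplicated(fams)]), collapse = ", "))
    rownames(x) <- fams
    return(x)
  }
  swap(x)
}

#' Read presence records from TSV
#'
#' @param path TSV with header columns `taxon`, `family`, `class`, `evidence`
#'   (only `family` and `class` are required).
#' @return data frame of records.
#' @export
read_psm_records <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("family", "class") %in% names(df)))
    stop("records TSV needs columns 'family' and 'class'")
  df
}
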