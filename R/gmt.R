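#' Construct an annotation database
#'
#' Maps term ids to term names and member gene sets, together with the gene
#' universe used as the enrichment background. By default the universe is the
#' union of all term members (every gene annotated to at least one term).
#'
#' @param terms named list, one element per term id, each a list with
#'   elements `name` (description) and `members` (character vector of gene
#'   symbols).
#' @param namespace label for the annotation namespace (e.g. `"BP"`,
#'   `"pathway"`); BH adjustment is applied within one namespace at a time.
#' @param universe optional explicit background gene set; defaults to the
#'   union of all members.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(terms, namespace = "BP", universe = NULL) {
  if (length(terms) == 0L) stop("annotation database has no terms")
  ids <- names(terms)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("term ids must be unique non-empty names")
  terms <- lapply(terms, function(t) {
    m <- sym_sort(unique(toupper(trimws(t$members))))
    m <- m[nzchar(m)]
    if (length(m) == 0L) stop("every term must have at least one member")
    list(name = t$name, members = m)
  })
  all_members <- sym_sort(unique(unlist(lapply(terms, `[[`, "members"),
                                        use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_members
  } else {
    universe <- sym_sort(unique(toupper(trimws(universe))))
    missing <- setdiff(all_members, universe)
    if (length(missing))
      stop("term members outside the supplied universe: ",
           paste(head(missing, 5L), collapse = ", "))
  }
  structure(list(namespace = namespace, terms = terms, universe = universe),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$members), 1L)
  cat(sprintf("annotation_db [%s]: %d terms, universe of %d genes\n",
              x$namespace, length(x$terms), length(x$universe)))
  cat(sprintf("  term sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Read a GMT annotation file
#'
#' Standard Gene Matrix Transposed dialect: one term per line,
#' `term_id TAB description TAB gene1 TAB gene2 ...`. The universe defaults
#' to the union of all member genes.
#'
#' @param path path to the GMT file.
#' @inheritParams annotation_db
#' @return An [annotation_db()].
#' @export
read_gmt <- function(path, namespace = "BP", universe = NULL) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L))
    stop("GMT parse error: line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in GMT: ", ids[duplicated(ids)][1L])
  terms <- lapply(parts, function(p)
    list(name = p[[2L]], members = p[-c(1L, 2L)]))
  names(terms) <- ids
  annotation_db(terms, namespace = namespace, universe = universe)
}

#' Write an annotation database to GMT
#'
#' @param db an [annotation_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  lines <- vapply(names(db$terms), function(id) {
    t <- db$terms[[id]]
    paste(c(id, t$name, t$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Term sizes of an annotation database
#'
#' @param db an [annotation_db()].
#' @return Named integer vector of member counts per term.
#' @export
term_sizes <- function(db) {
  stopifnot(inherits(db, "annotation_db"))
  vapply(db$terms, function(t) length(t$members), 1L)
}
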