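#' Construct a gene set
#'
#' A `gene_set` holds a named collection of canonical gene symbols with set
#' semantics: symbols are whitespace-stripped, uppercased, deduplicated and
#' kept sorted. This is the vocabulary every downstream stage (enrichment,
#' crosstalk, interactome expansion) operates on.
#'
#' @param members character vector of gene symbols.
#' @param name short label for the set.
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `members` (sorted unique uppercase symbols).
#' @examples
#' gene_set(c("mpz", "PMP22", "MPZ "), name = "demo")
#' @export
gene_set <- function(members, name = "gene_set") {
  if (!is.character(members)) stop("members must be a character vector")
  members <- trimws(members)
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("empty gene set")
  if (any(grepl("[[:space:]]", members)))
    stop("gene symbols must not contain internal whitespace")
  members <- sym_sort(unique(toupper(members)))
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d symbols\n", x$name, length(x$members)))
  shown <- head(x$members, 10L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$members) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#' Symbols are uppercased, trimmed and deduplicated, so the result does not
#' depend on line order, case or trailing blank lines.
#'
#' @param path path to the gene list file.
#' @param name label for the resulting set (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read gene list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene set")
  gene_set(lines, name = name)
}

#' Read an alias-to-canonical symbol map
#'
#' Two-column TSV (alias, canonical), no header, `#` comments allowed. The
#' map must be single-valued and idempotent: no canonical symbol may itself
#' be remapped to a different symbol, so one application reaches the fixed
#' point.
#'
#' @param path path to the TSV file.
#' @return Named character vector mapping alias -> canonical (both
#'   uppercase). An empty file yields an empty map.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) stop("cannot read alias map: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("alias map line ", bad[1L], " has fewer than 2 columns")
  alias <- toupper(trimws(vapply(parts, `[[`, "", 1L)))
  canon <- toupper(trimws(vapply(parts, `[[`, "", 2L)))
  map <- stats::setNames(canon, alias)
  if (anyDuplicated(alias)) {
    dup <- alias[duplicated(alias)]
    conflicting <- vapply(unique(dup), function(a)
      length(unique(canon[alias == a])) > 1L, logical(1))
    if (any(conflicting))
      stop("alias map is not single-valued for: ",
           paste(unique(dup)[conflicting], collapse = ", "))
    map <- map[!duplicated(alias)]
  }
  # idempotence: a canonical target must not itself be an alias of something else
  chained <- names(map)[!is.na(map[map]) & map[map] != map]
  chained <- chained[!is.na(chained)]
  if (length(chained))
    stop("alias map is not idempotent (chained remapping) for: ",
         paste(chained, collapse = ", "))
  map
}

#' Normalize gene symbols through an alias map
#'
#' Replaces every member found in the alias map by its canonical symbol and
#' deduplicates the result. Symbols absent from the map pass through
#' unchanged — they are reported, never dropped, so downstream counts stay
#' faithful to the curated input.
#'
#' @param genes a [gene_set()].
#' @param aliases named character vector from [read_alias_map()] (alias ->
#'   canonical), or an empty vector for the identity map.
#' @return A list with elements `gene_set` (the normalized set) and `report`,
#'   a `curation_report` with counts, remapped (alias, canonical) pairs and
#'   symbols not recognized by the map.
#' @export
normalize_symbols <- function(genes, aliases = character(0)) {
  stopifnot(inherits(genes, "gene_set"))
  members <- genes$members
  hit <- members %in% names(aliases)
  out <- members
  out[hit] <- unname(aliases[members[hit]])
  remapped <- data.frame(alias = members[hit], canonical = out[hit],
                         stringsAsFactors = FALSE)
  remapped <- remapped[remapped$alias != remapped$canonical, , drop = FALSE]
  known <- unique(c(names(aliases), unname(aliases)))
  unmapped <- members[!hit & !(members %in% known)]
  gs <- gene_set(out, name = genes$name)
  report <- structure(list(
    n_input = length(members),
    n_canonical = length(gs$members),
    remapped = remapped,
    unmapped = unmapped
  ), class = "curation_report")
  list(gene_set = gs, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("curation report: %d input -> %d canonical symbols\n",
              x$n_input, x$n_canonical))
  if (nrow(x$remapped))
    cat("  remapped:", paste(sprintf("%s->%s", x$remapped$alias,
                                     x$remapped$canonical), collapse = ", "), "\n")
  if (length(x$unmapped))
    cat("  not in alias map (kept):", paste(x$unmapped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a gene set to a plain-text file
#'
#' @param genes a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  writeLines(genes$members, path)
  invisible(path)
}
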