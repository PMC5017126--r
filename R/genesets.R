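#' Construct a gene-set collection
#'
#' A collection is an ordered, named list of gene sets (character vectors of
#' gene symbols). Symbols are compared case-insensitively and stored
#' upper-case, because array annotation sources mix cases. Each set carries a
#' free-text description (preserved from GMT input, otherwise empty).
#'
#' @param sets named list of character vectors of gene symbols. Names must be
#'   unique, every set non-empty.
#' @param descriptions optional character vector, one per set (recycled "" if
#'   missing).
#' @param universe optional character vector: the gene universe the sets have
#'   been restricted to (`NULL` until [restrict_to_universe()] is applied).
#' @return An object of class `geneset_collection`.
#' @seealso [read_gmt()], [restrict_to_universe()]
#' @export
#' @examples
#' gs <- geneset_collection(list(S1 = c("a", "B"), S2 = c("C", "D", "E")))
#' gs$S1
geneset_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets) || length(sets) == 0) {
    abort("`sets` must be a non-empty named list of character vectors.")
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    abort(sprintf(
      "duplicate gene-set name(s): %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  sets <- lapply(sets, normalize_symbols)
  if (any(lengths(sets) == 0L)) {
    abort("gene sets must be non-empty after case normalization")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  if (!is.null(universe)) universe <- normalize_symbols(universe)
  structure(sets,
    descriptions = setNames(descriptions, nm),
    universe = universe,
    class = "geneset_collection"
  )
}

# upper-case, duplicates collapsed, input order of first occurrence kept
normalize_symbols <- function(x) {
  x <- toupper(as.character(x))
  x <- x[nzchar(x)]
  x[!duplicated(x)]
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf(
    "<geneset_collection> %d set(s), sizes %d-%d%s\n",
    length(x), min(lengths(x)), max(lengths(x)),
    if (is.null(attr(x, "universe"))) {
      ""
    } else {
      sprintf(", universe of %d genes", length(attr(x, "universe")))
    }
  ))
  invisible(x)
}

#' @export
`[.geneset_collection` <- function(x, i) {
  geneset_collection(
    unclass(x)[i],
    descriptions = attr(x, "descriptions")[i],
    universe = attr(x, "universe")
  )
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Symbols are upper-cased and duplicates within a line collapsed.
#'
#' @param path path to a GMT file.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "malformed GMT line %d: fewer than 3 tab-separated fields", bad[1]
    ))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  geneset_collection(sets, descriptions = desc)
}

#' Write a gene-set collection to a GMT file
#'
#' Canonical form: name, description, genes in stored order.
#'
#' @param coll a [geneset_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "geneset_collection"))
  desc <- attr(coll, "descriptions")
  lines <- vapply(
    names(coll),
    function(nm) paste(c(nm, desc[[nm]], coll[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a gene universe and size bounds
#'
#' Each set is intersected with `universe` (the genes actually present on the
#' platform / in the expression matrix); sets whose restricted size falls
#' outside `[min_size, max_size]` are dropped. Defaults 5-500 follow common
#' enrichment-analysis practice. The operation is idempotent.
#'
#' @param coll a [geneset_collection()].
#' @param universe character vector of gene symbols (case-insensitive).
#' @param min_size,max_size inclusive size bounds applied after restriction.
#' @return A restricted `geneset_collection`; the dropped sets are reported in
#'   attribute `"dropped"` as a tibble (set, size_after_restriction, reason).
#' @export
restrict_to_universe <- function(coll, universe, min_size = 5, max_size = 500) {
  stopifnot(inherits(coll, "geneset_collection"))
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (min_size < 1 || max_size < min_size) {
    abort("need 1 <= min_size <= max_size")
  }
  universe <- normalize_symbols(universe)
  restricted <- lapply(unclass(coll), function(g) g[g %in% universe])
  sz <- lengths(restricted)
  keep <- sz >= min_size & sz <= max_size
  dropped <- tibble::tibble(
    set = names(restricted)[!keep],
    size_after_restriction = unname(sz[!keep]),
    reason = unname(ifelse(sz[!keep] < min_size, "below min_size", "above max_size"))
  )
  if (!any(keep)) {
    abort("no gene set survives universe restriction and size bounds")
  }
  out <- geneset_collection(
    restricted[keep],
    descriptions = attr(coll, "descriptions")[keep],
    universe = universe
  )
  attr(out, "dropped") <- dropped
  out
}

#' @describeIn geneset_collection long tibble (set, description, gene) view.
#' @param x a `geneset_collection`.
#' @param ... unused.
#' @method tidy geneset_collection
#' @export
tidy.geneset_collection <- function(x, ...) {
  desc <- attr(x, "descriptions")
  tibble::tibble(
    set = rep(names(x), lengths(x)),
    description = rep(unname(desc), lengths(x)),
    gene = unlist(unclass(x), use.names = FALSE)
  )
}
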