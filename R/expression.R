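#' Construct an expression set
#'
#' Holds a genes x samples matrix of normalized log-scale intensities together
#' with optional two-class sample labels. Gene symbols are upper-cased.
#' Missing values are rejected at construction: the downstream running-sum
#' statistics have no principled missing-data handling.
#'
#' @param values numeric matrix, rownames = gene symbols, colnames = sample
#'   identifiers.
#' @param labels optional named character vector (names = sample identifiers)
#'   with exactly two distinct class tags when present.
#' @return An object of class `expression_set` with fields `values` and
#'   `labels`.
#' @export
expression_set <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs gene rownames and sample colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    warn(sprintf(
      "duplicate gene symbol(s) collapsed to first occurrence: %s",
      paste(head(dup, 5), collapse = ", ")
    ))
    values <- values[!duplicated(rownames(values)), , drop = FALSE]
  }
  if (anyDuplicated(colnames(values))) abort("duplicate sample identifiers")
  if (anyNA(values)) abort("expression matrix contains missing values")
  if (!is.null(labels)) {
    labels <- as.character(labels) |> setNames(names(labels))
    if (is.null(names(labels)) || !setequal(names(labels), colnames(values))) {
      abort("`labels` must be named by the sample identifiers of `values`")
    }
    labels <- labels[colnames(values)]
    if (length(unique(labels)) != 2) {
      abort("`labels` must contain exactly two distinct class tags")
    }
  }
  structure(list(values = values, labels = labels), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "<expression_set> %d genes x %d samples%s\n",
    nrow(x$values), ncol(x$values),
    if (is.null(x$labels)) {
      ""
    } else {
      sprintf(
        ", classes: %s",
        paste(sprintf("%s (n=%d)", names(table(x$labels)), table(x$labels)),
          collapse = " vs "
        )
      )
    }
  ))
  invisible(x)
}

#' @describeIn expression_set long tibble (gene, sample, value, class) view.
#' @param x an `expression_set`.
#' @param ... unused.
#' @method tidy expression_set
#' @export
tidy.expression_set <- function(x, ...) {
  out <- tibble::tibble(
    gene = rep(rownames(x$values), ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  if (!is.null(x$labels)) out$class <- unname(x$labels[out$sample])
  out
}

#' Rank-transform one sample
#'
#' Ranks a single sample's expression values, rank 1 = lowest expression, ties
#' receiving the average of the ranks they span. The rank sum therefore always
#' equals N(N+1)/2.
#'
#' @param expr an [expression_set()].
#' @param sample a sample identifier present in `expr`.
#' @return Named numeric vector of ranks (names = gene symbols), with
#'   attribute `"sample"`.
#' @export
rank_transform <- function(expr, sample) {
  stopifnot(inherits(expr, "expression_set"))
  if (!sample %in% colnames(expr$values)) {
    abort(sprintf("unknown sample: %s", sample))
  }
  r <- rank(expr$values[, sample], ties.method = "average")
  structure(setNames(r, rownames(expr$values)), sample = sample)
}

#' Rank-transform every sample
#'
#' @param expr an [expression_set()].
#' @return Matrix of per-column average ranks, same dimnames as the input.
#' @export
rank_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_set"))
  apply(expr$values, 2, rank, ties.method = "average")
}

#' Signal-to-noise ranking metric
#'
#' Two-class metric `(mean_A - mean_B) / (sd_A + sd_B)` with each class
#' standard deviation floored at `max(0.2 * |class mean|, 0.2)`, so genes with
#' vanishing within-class variance cannot dominate the ranking. Class A is the
#' first element of `class_order`.
#'
#' @param expr an [expression_set()] with labels.
#' @param genes genes to compute the metric for (default: all).
#' @param class_order length-2 character giving (A, B); default: label order
#'   of first appearance.
#' @return Named numeric vector of metric values.
#' @export
signal_to_noise <- function(expr, genes = NULL, class_order = NULL) {
  stopifnot(inherits(expr, "expression_set"))
  if (is.null(expr$labels)) abort("signal_to_noise requires class labels")
  if (is.null(class_order)) class_order <- unique(expr$labels)
  if (!setequal(class_order, unique(expr$labels)) || length(class_order) != 2) {
    abort("`class_order` must name the two class tags")
  }
  a <- expr$values[, expr$labels == class_order[1], drop = FALSE]
  b <- expr$values[, expr$labels == class_order[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    abort(paste(
      "each class needs >= 2 samples for the signal-to-noise metric;",
      "use a difference-of-means metric for singleton classes"
    ))
  }
  if (!is.null(genes)) {
    genes <- toupper(genes)
    missing <- setdiff(genes, rownames(expr$values))
    if (length(missing)) {
      abort(sprintf("unknown gene(s): %s", paste(head(missing, 5), collapse = ", ")))
    }
    a <- a[genes, , drop = FALSE]
    b <- b[genes, , drop = FALSE]
  }
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  sa <- floored_sd(a, ma)
  sb <- floored_sd(b, mb)
  (ma - mb) / (sa + sb)
}

floored_sd <- function(m, mu) {
  s <- apply(m, 1, sd)
  pmax(s, pmax(0.2 * abs(mu), 0.2))
}

#' Build a ranked gene list for enrichment analysis
#'
#' Orders the whole gene universe best-to-worst by a per-gene metric,
#' non-increasing, with deterministic lexicographic tie-breaking on the gene
#' symbol.
#'
#' @param metric named numeric vector (names = gene symbols) or an
#'   [expression_set()] with labels, in which case [signal_to_noise()] is used.
#' @param class_order passed to [signal_to_noise()] when `metric` is an
#'   expression set.
#' @return Named numeric vector of class `ranked_list`, sorted.
#' @export
ranked_list <- function(metric, class_order = NULL) {
  if (inherits(metric, "expression_set")) {
    metric <- signal_to_noise(metric, class_order = class_order)
  }
  if (is.null(names(metric)) || anyNA(metric)) {
    abort("`metric` must be a named numeric vector without NAs")
  }
  names(metric) <- toupper(names(metric))
  if (anyDuplicated(names(metric))) abort("duplicate gene symbols in metric")
  ord <- order(-metric, names(metric), method = "radix")
  structure(metric[ord], class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf(
    "<ranked_list> %d genes, metric range [%.4g, %.4g]\n",
    length(x), min(x), max(x)
  ))
  invisible(x)
}

#' Read an expression matrix from plain TSV
#'
#' First column = gene symbol, header row = sample identifiers.
#'
#' @param path TSV path.
#' @param labels optional named character vector of class labels.
#' @return An [expression_set()].
#' @export
read_expression_tsv <- function(path, labels = NULL) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  expression_set(m, labels = labels)
}

#' Read / write the GCT v1.2 expression dialect
#'
#' Two header lines (`#1.2`, then `n_genes <tab> n_samples`), then a table
#' with NAME and Description columns followed by one column per sample.
#'
#' @param path file path.
#' @return `read_gct()`: an [expression_set()]; `write_gct()`: `path`,
#'   invisibly.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort(sprintf("GCT file not found: %s", path))
  header <- readLines(path, n = 2)
  if (length(header) < 2 || !startsWith(header[1], "#1.2")) {
    abort("not a GCT v1.2 file (missing '#1.2' header)")
  }
  dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
  d <- read.delim(path, skip = 2, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) != dims[1] || ncol(d) - 2 != dims[2]) {
    abort("GCT dimension header does not match the table")
  }
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d[[1]]
  expression_set(m)
}

#' @rdname read_gct
#' @param expr an [expression_set()].
#' @export
write_gct <- function(expr, path) {
  stopifnot(inherits(expr, "expression_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(expr$values), ncol(expr$values), sep = "\t")), con)
  d <- data.frame(
    NAME = rownames(expr$values),
    Description = "na",
    expr$values,
    check.names = FALSE
  )
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the CLS two-class label dialect
#'
#' Line 1: `n_samples n_classes 1`; line 2: `# classA classB`; line 3:
#' space-separated class tags in sample order.
#'
#' @param path file path.
#' @param samples sample identifiers to attach to the tags, in file order.
#' @return `read_cls()`: named character vector of class tags.
#' @export
read_cls <- function(path, samples = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("CLS file needs 3 lines")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  tags <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(tags) != hdr[1]) {
    abort("CLS header sample count does not match the label line")
  }
  if (!is.null(samples)) {
    if (length(samples) != length(tags)) {
      abort("`samples` length does not match CLS labels")
    }
    names(tags) <- samples
  }
  tags
}

#' @rdname read_cls
#' @param labels named character vector of class tags in sample order.
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  writeLines(c(
    paste(length(labels), length(classes), 1),
    paste("#", paste(classes, collapse = " ")),
    paste(labels, collapse = " ")
  ), path)
  invisible(path)
}
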