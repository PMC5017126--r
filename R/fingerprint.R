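#' One-sided single-sample pathway score
#'
#' Orders a sample's genes by descending rank (highest expression first) and
#' runs the same hit/miss running sum as [enrichment_score()], but returns the
#' maximum *positive* deviation only (0 if the running sum never rises above
#' 0). This is the modified one-sided Kolmogorov-Smirnov pathway activity
#' score applied to a single sample rather than a two-class comparison. With
#' the default `exponent = 0` the score depends on the sample only through its
#' gene ranks, so it is invariant under any monotone transformation of the
#' expression values.
#'
#' @param ranks named numeric vector of per-sample gene ranks (1 = lowest),
#'   as returned by [rank_transform()].
#' @param set character vector of gene symbols.
#' @param exponent non-negative weight exponent; 0 (default) gives the
#'   unweighted one-sided KS statistic, positive values weight hits by
#'   `rank^exponent`.
#' @return Score in `[0, 1]` (for `exponent = 0`).
#' @export
single_sample_score <- function(ranks, set, exponent = 0) {
  ord <- rank_order(ranks)
  n <- length(ord)
  hit_pos <- which(ord %in% normalize_symbols(set))
  if (length(hit_pos) == 0 || length(hit_pos) == n) {
    abort("gene set must be neither empty nor the whole universe")
  }
  w <- if (exponent == 0) NULL else ranks[ord][hit_pos]^exponent
  es_stat_fast(hit_pos, n, w)[3]
}

# descending rank value, lexicographic gene-symbol tie-break
rank_order <- function(ranks) {
  if (is.null(names(ranks))) abort("`ranks` must be named by gene symbol")
  names(ranks)[order(-ranks, names(ranks), method = "radix")]
}

#' Calibrate the gene-name-permutation null for single-sample scores
#'
#' Each permutation draws a uniformly random gene subset of size `set_size`
#' (equivalent to permuting gene names while holding the sample's ranks
#' fixed) and records its [single_sample_score()]. The sorted null is the
#' reference distribution used by [normalize_score()] to put raw scores on
#' the N(0,1) scale. The default permutation count is 10,000.
#'
#' @inheritParams single_sample_score
#' @param set_size gene-set size the null is calibrated for.
#' @param n_perm number of gene-name permutations (>= 100).
#' @param seed integer seed.
#' @return A `null_calibration`: list with `set_size`, `n_perm`, sorted
#'   `null_scores`, `exponent`, `seed`.
#' @export
calibrate_null <- function(ranks, set_size, n_perm = 10000, exponent = 0,
                           seed = 1) {
  n <- length(ranks)
  stopifnot(n_perm >= 100, set_size >= 1, set_size < n)
  sorted_vals <- if (exponent == 0) NULL else ranks[rank_order(ranks)]^exponent
  scores <- with_seed_(seed, vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(n, set_size))
    es_stat_fast(pos, n, sorted_vals[pos])[3]
  }, numeric(1)))
  structure(
    list(
      set_size = set_size, n_perm = n_perm,
      null_scores = sort(scores), exponent = exponent, seed = seed
    ),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "<null_calibration> set size %d, %d permutations, null range [%.3f, %.3f]\n",
    x$set_size, x$n_perm, min(x$null_scores), max(x$null_scores)
  ))
  invisible(x)
}

#' Map a raw score onto the N(0,1) scale through the null CDF
#'
#' `z = qnorm((r + 0.5) / (n_perm + 1))` where `r` counts null scores
#' strictly below `raw` plus half the ties. The continuity correction keeps
#' the probit finite even for scores outside the null range, and applied to
#' the null scores themselves yields an approximately standard normal sample.
#'
#' @param raw numeric vector of raw scores.
#' @param cal a [calibrate_null()] result.
#' @return Numeric vector of finite z scores, monotone in `raw`.
#' @export
normalize_score <- function(raw, cal) {
  stopifnot(inherits(cal, "null_calibration"))
  sn <- cal$null_scores
  if (length(unique(sn)) < 2) {
    abort("degenerate null (all scores identical); increase n_perm")
  }
  n_le <- findInterval(raw, sn)
  n_lt <- findInterval(raw, sn, left.open = TRUE)
  r <- n_lt + (n_le - n_lt) / 2
  qnorm((r + 0.5) / (cal$n_perm + 1))
}

#' Score every sample of an expression set against a collection
#'
#' Rank-transforms each sample, computes the one-sided single-sample score
#' for every gene set, and normalizes each score against a gene-name-
#' permutation null. Nulls are calibrated once per distinct set size and
#' shared across samples: with `exponent = 0` the null depends on the sample
#' only through its universe size, so sharing is exact for tie-free ranks.
#'
#' @param expr an [expression_set()].
#' @param collection a [geneset_collection()].
#' @param exponent weight exponent (default 0, the one-sided KS score).
#' @param n_perm gene-name permutations per set size.
#' @param seed integer seed.
#' @param min_size,max_size set size bounds after universe restriction.
#' @return A `pathway_scores` tibble (sample, set, raw, z) with the
#'   calibrations in attribute `"calibrations"`.
#' @export
score_pathways <- function(expr, collection, exponent = 0, n_perm = 1000,
                           seed = 1, min_size = 5, max_size = 500) {
  stopifnot(inherits(expr, "expression_set"))
  coll <- restrict_to_universe(
    collection, rownames(expr$values), min_size, max_size
  )
  rmat <- rank_matrix(expr)
  sizes <- lengths(coll)
  cals <- lapply(setNames(nm = sort(unique(sizes))), function(k) {
    calibrate_null(rmat[, 1], as.integer(k),
      n_perm = n_perm,
      exponent = exponent, seed = seed + as.integer(k)
    )
  })
  res <- purrr::map_dfr(colnames(rmat), function(smp) {
    ranks <- setNames(rmat[, smp], rownames(rmat))
    ord <- rank_order(ranks)
    sorted_vals <- if (exponent == 0) NULL else ranks[ord]^exponent
    n <- length(ord)
    idx <- match(ord, names(ranks))
    raw <- vapply(unclass(coll), function(s) {
      pos <- which(ord %in% s)
      es_stat_fast(pos, n, sorted_vals[pos])[3]
    }, numeric(1))
    z <- vapply(names(raw), function(s) {
      normalize_score(raw[[s]], cals[[as.character(sizes[[s]])]])
    }, numeric(1))
    tibble::tibble(
      sample = smp, set = names(raw), raw = unname(raw), z = unname(z)
    )
  })
  structure(res,
    calibrations = cals,
    class = c("pathway_scores", class(res))
  )
}

#' Corpus-derived ternary thresholds
#'
#' For each gene set, the `tail` and `1 - tail` empirical percentiles (linear
#' interpolation between order statistics) of the corpus z scores. Samples
#' standardized against these thresholds code +1 above the upper threshold,
#' -1 below the lower, 0 otherwise, reproducing a 15/70/15 split on the
#' corpus itself when its values are distinct.
#'
#' @param scores a `pathway_scores` tibble (from [score_pathways()]) or any
#'   tibble with columns sample, set, z.
#' @param tail tail fraction (default 0.15).
#' @param min_corpus minimum corpus size (default 20).
#' @return Tibble (set, low, high) with attributes `corpus_size`, `tail`.
#' @export
corpus_thresholds <- function(scores, tail = 0.15, min_corpus = 20) {
  stopifnot(all(c("sample", "set", "z") %in% names(scores)), tail > 0, tail < 0.5)
  n_samples <- length(unique(scores$sample))
  if (n_samples < min_corpus) {
    abort(sprintf(
      "corpus has %d samples; at least %d required", n_samples, min_corpus
    ))
  }
  out <- scores |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      low = quantile(.data$z, tail, type = 7, names = FALSE),
      high = quantile(.data$z, 1 - tail, type = 7, names = FALSE),
      .groups = "drop"
    )
  attr(out, "corpus_size") <- n_samples
  attr(out, "tail") <- tail
  out
}

#' Ternary standardization of a normalized score
#'
#' @param z numeric vector of normalized scores.
#' @param low,high thresholds for the set; boundary values code 0.
#' @return Integer vector in `{-1, 0, +1}`; +1 = above the upper threshold
#'   (high pathway activity).
#' @export
ternarize <- function(z, low, high) {
  stopifnot(all(low <= high))
  as.integer(ifelse(z > high, 1L, ifelse(z < low, -1L, 0L)))
}

#' Ternary fingerprints for a table of scores
#'
#' @param scores tibble with columns sample, set, z.
#' @param thresholds a [corpus_thresholds()] tibble.
#' @return Tibble (sample, set, code) — one fingerprint per sample.
#' @export
ternary_codes <- function(scores, thresholds) {
  scores |>
    dplyr::inner_join(thresholds, by = "set") |>
    dplyr::mutate(code = ternarize(.data$z, .data$low, .data$high)) |>
    dplyr::select("sample", "set", "code")
}

# accepts a named code vector or a (set, code) tibble for one sample
as_code_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("set", "code") %in% names(x)))
    return(setNames(as.integer(x$code), x$set))
  }
  if (is.null(names(x))) abort("fingerprint codes must be named by set")
  setNames(as.integer(x), names(x))
}

#' Consensus fingerprint of a group of samples
#'
#' Elementwise modal code across fingerprints; ties (including the empty
#' majority of a two-way split) yield 0.
#'
#' @param codes tibble (sample, set, code) for one or more samples.
#' @return Named integer vector (one code per set).
#' @export
consensus_fingerprint <- function(codes) {
  stopifnot(all(c("sample", "set", "code") %in% names(codes)))
  if (nrow(codes) == 0) abort("at least one fingerprint required")
  modal <- function(v) {
    tab <- table(factor(v, levels = c(-1, 0, 1)))
    top <- which(tab == max(tab))
    if (length(top) > 1) 0L else as.integer(names(tab)[top])
  }
  out <- tapply(codes$code, codes$set, modal)
  setNames(as.integer(out), names(out))
}

#' Distance between two ternary fingerprints
#'
#' Scaled Manhattan distance: mean absolute code difference divided by 2, so
#' 0 = identical and 1 = fully opposite.
#'
#' @param a,b fingerprints over the same sets (named code vectors or
#'   (set, code) tibbles).
#' @return Distance in `[0, 1]`.
#' @export
fingerprint_distance <- function(a, b) {
  a <- as_code_vector(a)
  b <- as_code_vector(b)
  if (!setequal(names(a), names(b))) {
    abort("fingerprints are defined over different gene-set domains")
  }
  mean(abs(a - b[names(a)])) / 2
}

#' Stemness-distance spectrum
#'
#' Places every corpus and query sample on a one-dimensional axis: its
#' fingerprint distance to the consensus fingerprint of the stem reference
#' samples. Corpus distances form the background distribution; queries are
#' positioned on the same axis (0 = indistinguishable from the stem
#' consensus).
#'
#' @param corpus_codes tibble (sample, set, code): the background corpus.
#' @param stem_codes tibble (sample, set, code): stem reference samples
#'   (e.g. embryonic / induced-pluripotent stem profiles).
#' @param query_codes optional tibble (sample, set, code) of query samples.
#' @param groups optional named character vector mapping samples to display
#'   group tags; defaults to "corpus" / "query".
#' @return A `stem_spectrum` tibble (sample, group, distance), with the stem
#'   consensus in attribute `"consensus"`.
#' @export
stem_spectrum <- function(corpus_codes, stem_codes, query_codes = NULL,
                          groups = NULL) {
  if (is.null(stem_codes) || nrow(stem_codes) == 0) {
    abort("at least one stem reference fingerprint is required")
  }
  consensus <- consensus_fingerprint(stem_codes)
  dist_tbl <- function(codes, default_group) {
    codes |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(
        distance = fingerprint_distance(
          setNames(.data$code, .data$set), consensus
        ),
        .groups = "drop"
      ) |>
      dplyr::mutate(group = default_group)
  }
  out <- dist_tbl(corpus_codes, "corpus")
  if (!is.null(query_codes)) {
    out <- dplyr::bind_rows(out, dist_tbl(query_codes, "query"))
  }
  if (!is.null(groups)) {
    hit <- out$sample %in% names(groups)
    out$group[hit] <- unname(groups[out$sample[hit]])
  }
  out <- dplyr::select(out, "sample", "group", "distance")
  structure(out,
    consensus = consensus,
    class = c("stem_spectrum", class(out))
  )
}
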