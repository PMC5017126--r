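#' Weighted KS running-sum enrichment score
#'
#' Walks the ranked list from best to worst, incrementing by the gene's
#' `|metric|^exponent` (normalized over set members) at set hits and
#' decrementing by `1/(N - n_hits)` at misses. The enrichment score is the
#' signed deviation of maximum absolute value; the peak index is the earliest
#' position attaining it. The running sum returns to 0 at the end of the list.
#' With `exponent = 0` the statistic reduces to the signed classical
#' two-sample Kolmogorov-Smirnov D between the in-set and out-of-set rank
#' distributions.
#'
#' @param ranking a [ranked_list()] (named metric vector sorted best-to-worst).
#' @param set character vector of gene symbols.
#' @param exponent non-negative weight exponent; 1 = classic metric weighting,
#'   0 = unweighted KS.
#' @return List with `es`, `running_sum` (length-N numeric) and `peak_index`.
#' @export
#' @examples
#' rl <- ranked_list(setNames(10:1, LETTERS[1:10]))
#' enrichment_score(rl, LETTERS[1:3], exponent = 0)$es # 1
enrichment_score <- function(ranking, set, exponent = 1) {
  stopifnot(exponent >= 0)
  genes <- names(ranking)
  n <- length(genes)
  hit <- genes %in% normalize_symbols(set)
  nh <- sum(hit)
  if (nh == 0 || nh == n) {
    abort("gene set must be neither empty nor the whole universe after restriction")
  }
  w <- abs(ranking[hit])^exponent
  sw <- sum(w)
  if (sw <= 0) w[] <- 1 / nh else w <- w / sw
  inc <- numeric(n)
  inc[hit] <- w
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  list(es = unname(rs[peak]), running_sum = unname(rs), peak_index = peak)
}

# Fast ES on hit positions only. The running sum is piecewise linear with
# extrema only at positions just after (maxima) / just before (minima) a hit,
# so candidates at those points suffice; earliest position wins ties.
# pos: sorted hit positions; w: weights at those positions (or NULL = equal).
# Returns c(es, peak_index, max_positive_deviation).
es_stat_fast <- function(pos, n, w = NULL) {
  k <- length(pos)
  if (is.null(w)) {
    cw <- seq_len(k) / k
  } else {
    sw <- sum(w)
    cw <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  }
  dec <- (pos - seq_len(k)) / (n - k)
  top <- cw - dec
  keep <- pos > 1L
  vals <- c(top, (c(0, cw[-k]) - dec)[keep])
  posn <- c(pos, (pos - 1L)[keep])
  av <- abs(vals)
  i <- which(av == max(av))
  if (length(i) > 1L) i <- i[which.min(posn[i])]
  c(vals[i], posn[i], max(0, top))
}

#' Gene-set permutation null for the enrichment score
#'
#' Draws `n_perm` uniformly random gene subsets of size `set_size` (without
#' replacement) from the ranked universe, keeping the ranking fixed, and
#' records each subset's enrichment score. This is the gene-set permutation
#' null (as opposed to phenotype permutation).
#'
#' @inheritParams enrichment_score
#' @param set_size subset size, `1 <= set_size < N`.
#' @param n_perm number of permutations.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
geneset_permutation_null <- function(ranking, set_size, exponent = 1,
                                     n_perm = 1000, seed = 1) {
  n <- length(ranking)
  stopifnot(n_perm >= 1, set_size >= 1, set_size < n)
  absw <- abs(unname(ranking))^exponent
  with_seed_(seed, vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(n, set_size))
    es_stat_fast(pos, n, absw[pos])[1]
  }, numeric(1)))
}

#' Nominal permutation p value for an enrichment score
#'
#' One-tailed on the side of the observed sign, with the add-one estimator:
#' `p = (1 + #same-signed null at least as extreme) / (1 + #same-signed null)`,
#' so p is never below `1/(n_same + 1)`.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null enrichment scores.
#' @return p value in (0, 1].
#' @export
nominal_p <- function(es, null) {
  if (length(null) == 0) abort("`null` must be non-empty")
  if (es == 0) {
    warn("observed enrichment score is 0; nominal p set to 1")
    return(1)
  }
  same <- null[sign(null) == sign(es)]
  if (length(same) == 0) {
    warn("no same-signed null enrichment scores; nominal p set to 1")
    return(1)
  }
  (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
}

#' Normalized enrichment scores and GSEA-style FDR q values
#'
#' Each score is normalized by the mean magnitude of its own same-signed null
#' scores (`nes = es / mean(|same-signed null es|)`). The null scores,
#' normalized the same way, are pooled; the q value for a set is the ratio of
#' the same-signed pooled-null tail fraction beyond its NES to the observed
#' tail fraction, capped at 1 and made monotone non-increasing in |NES| within
#' each sign by a cumulative minimum. Sets whose null contains no same-signed
#' values have undefined NES and are flagged and excluded from the FDR
#' computation.
#'
#' @param es named numeric vector of observed enrichment scores.
#' @param nulls named list of null enrichment-score vectors, one per set (sets
#'   of the same size may share a null).
#' @return Tibble with columns `set`, `es`, `nes`, `fdr_q`, `flagged`.
#' @export
nes_and_fdr <- function(es, nulls) {
  stopifnot(!is.null(names(es)), setequal(names(es), names(nulls)))
  nulls <- nulls[names(es)]
  mean_pos <- vapply(nulls, function(x) mean(x[x > 0]), numeric(1))
  mean_neg <- vapply(nulls, function(x) mean(abs(x[x < 0])), numeric(1))
  nes <- ifelse(es > 0, es / mean_pos, es / mean_neg)
  nes[es == 0] <- 0
  flagged <- !is.finite(nes)
  if (any(flagged)) {
    warn(sprintf(
      "NES undefined (no same-signed null) for: %s",
      paste(names(es)[flagged], collapse = ", ")
    ))
  }
  pool <- unlist(lapply(names(es), function(s) {
    x <- nulls[[s]]
    c(
      if (is.finite(mean_pos[s])) x[x > 0] / mean_pos[s],
      if (is.finite(mean_neg[s])) x[x < 0] / mean_neg[s]
    )
  }), use.names = FALSE)
  obs <- nes[!flagged]
  q <- rep(NA_real_, length(es))
  names(q) <- names(es)
  for (s in names(obs)) {
    v <- nes[s]
    if (v > 0) {
      num <- mean(pool[pool > 0] >= v)
      den <- mean(obs[obs > 0] >= v)
    } else if (v < 0) {
      num <- mean(pool[pool < 0] <= v)
      den <- mean(obs[obs < 0] <= v)
    } else {
      num <- den <- 1
    }
    q[s] <- min(1, num / den)
  }
  # enforce monotonicity: larger |NES| never gets a larger q
  for (sgn in c(1, -1)) {
    idx <- names(obs)[sign(obs) == sgn]
    if (length(idx) > 1) {
      ord <- idx[order(abs(nes[idx]))]
      q[ord] <- cummin(q[ord])
    }
  }
  tibble::tibble(
    set = names(es), es = unname(es), nes = unname(nes),
    fdr_q = unname(q), flagged = unname(flagged)
  )
}

#' Leading-edge subset and contribution category
#'
#' For a positive enrichment score the leading edge comprises the set members
#' at ranked positions up to and including the running-sum peak; for a
#' negative score, the members at positions from the peak onwards. The
#' contribution fraction is the leading-edge size over the (universe-
#' restricted) set size, binned into the reporting categories
#' `<20%`, `20-50%`, `50-75%`, `75-100%`.
#'
#' @inheritParams enrichment_score
#' @param peak_index running-sum peak position from [enrichment_score()].
#' @param es the signed enrichment score (only its sign is used).
#' @return List with `genes`, `contribution_fraction`, `contribution_category`.
#' @export
leading_edge <- function(ranking, set, peak_index, es) {
  if (es == 0) abort("leading edge undefined for a zero enrichment score")
  genes <- names(ranking)
  members <- genes[genes %in% normalize_symbols(set)]
  pos <- match(members, genes)
  le <- if (es > 0) members[pos <= peak_index] else members[pos >= peak_index]
  frac <- length(le) / length(members)
  list(
    genes = le,
    contribution_fraction = frac,
    contribution_category = contribution_category(frac)
  )
}

contribution_category <- function(frac) {
  ifelse(frac > 0.75, "75-100%",
    ifelse(frac > 0.50, "50-75%",
      ifelse(frac > 0.20, "20-50%", "<20%")
    )
  )
}

significance_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Two-class gene set enrichment analysis
#'
#' Ranks the universe by the signal-to-noise metric (or a caller-supplied
#' metric), computes each set's weighted KS enrichment score, builds a
#' gene-set permutation null (shared across sets of equal size), and reports
#' NES, nominal p, FDR q, and the leading-edge contribution per set.
#'
#' @param x an [expression_set()] with two-class labels, or a named metric
#'   vector / [ranked_list()].
#' @param collection a [geneset_collection()].
#' @param class_order length-2 character, (A, B): positive scores mean
#'   enrichment towards class A.
#' @param exponent weight exponent for the running sum (default 1).
#' @param n_perm gene-set permutations per set size (default 1000).
#' @param seed integer seed for the permutation null.
#' @param min_size,max_size set size bounds after universe restriction.
#' @param fdr_cutoff FDR threshold recorded in the result (default 0.05).
#' @return A `gsea_result`: use [tidy()] for the per-set table (sorted by
#'   decreasing |NES|), [glance()] for a one-row summary, [autoplot()] for the
#'   NES bar chart, [plot_running_sum()] for a set's running-sum profile.
#' @export
gsea <- function(x, collection, class_order = NULL, exponent = 1,
                 n_perm = 1000, seed = 1, min_size = 5, max_size = 500,
                 fdr_cutoff = 0.05) {
  rl <- if (inherits(x, "ranked_list")) x else ranked_list(x, class_order)
  coll <- restrict_to_universe(collection, names(rl), min_size, max_size)
  n <- length(rl)
  absw <- abs(unname(rl))^exponent
  genes <- names(rl)

  obs <- lapply(unclass(coll), function(s) {
    pos <- sort.int(match(s, genes))
    es_stat_fast(pos, n, absw[pos])
  })
  es <- vapply(obs, `[`, numeric(1), 1)
  peak <- vapply(obs, `[`, numeric(1), 2)

  sizes <- lengths(coll)
  nulls_by_size <- lapply(
    setNames(nm = sort(unique(sizes))),
    function(k) {
      geneset_permutation_null(rl, as.integer(k),
        exponent = exponent,
        n_perm = n_perm, seed = seed + as.integer(k)
      )
    }
  )
  nulls <- nulls_by_size[as.character(sizes)]
  names(nulls) <- names(sizes)

  stats <- nes_and_fdr(es, nulls)
  p_nom <- vapply(names(es), function(s) nominal_p(es[[s]], nulls[[s]]), numeric(1))
  le <- lapply(names(es), function(s) {
    if (es[[s]] == 0) {
      list(genes = character(0), contribution_fraction = 0, contribution_category = "<20%")
    } else {
      leading_edge(rl, coll[[s]], peak[[s]], es[[s]])
    }
  })

  tab <- stats |>
    dplyr::mutate(
      size = unname(sizes[.data$set]),
      p_nominal = unname(p_nom[.data$set]),
      significance_code = significance_code(.data$p_nominal),
      leading_edge = vapply(le, function(z) paste(z$genes, collapse = ","), character(1)),
      contribution_fraction = vapply(le, `[[`, numeric(1), "contribution_fraction"),
      contribution_category = vapply(le, `[[`, character(1), "contribution_category"),
      peak_index = unname(peak[.data$set])
    ) |>
    dplyr::select(
      "set", "size", "es", "nes", "p_nominal", "fdr_q",
      "significance_code", "contribution_fraction", "contribution_category",
      "leading_edge", "flagged", "peak_index"
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$nes)))

  structure(
    list(
      table = tab, ranking = rl, collection = coll,
      params = list(
        exponent = exponent, n_perm = n_perm, seed = seed,
        min_size = min_size, max_size = max_size, fdr_cutoff = fdr_cutoff
      )
    ),
    class = "gsea_result"
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "<gsea_result> %d gene sets, %d-gene universe, %d permutations/size\n",
    nrow(x$table), length(x$ranking), x$params$n_perm
  ))
  print(x$table, n = 10)
  invisible(x)
}

#' @describeIn gsea per-set result tibble.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) x$table

#' @describeIn gsea one-row summary: set counts, significant sets at the FDR
#'   cutoff, parameters.
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$table),
    n_genes = length(x$ranking),
    n_sig_fdr = sum(x$table$fdr_q < x$params$fdr_cutoff, na.rm = TRUE),
    fdr_cutoff = x$params$fdr_cutoff,
    n_perm = x$params$n_perm,
    exponent = x$params$exponent,
    seed = x$params$seed
  )
}
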