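#' Synthetic study design
#'
#' Generative parameters for the synthetic inputs the pipeline consumes: a
#' gene universe, a gene-set collection, a two-class expression experiment
#' with planted differential pathways (emulating paired sorted-population
#' profiles, e.g. CD133+ proliferative vs CD133- invasive signatures), and a
#' stemness-gradient corpus in which designated stem sets are progressively
#' activated. Defaults mirror the study scale: 7 profile pairs for the
#' two-class arm, a 300-sample corpus for the fingerprint arm, log-scale
#' baselines N(7, 2) with unit noise (Affymetrix-like dynamic range;
#' irrelevant to the rank-based scores).
#'
#' @param n_genes universe size.
#' @param n_sets number of gene sets.
#' @param set_size_range inclusive (min, max) set size.
#' @param n_per_group samples per class in the two-class experiment.
#' @param groups length-2 character: the two class tags.
#' @param planted named list of planted effects, one entry per planted set:
#'   `list(direction = "up"|"down", delta = <log-scale shift>, group = <tag>)`.
#' @param baseline_mean,baseline_sd per-gene baseline means are drawn from
#'   N(baseline_mean, baseline_sd) on the log scale.
#' @param noise_sd Gaussian noise sd (log scale); 0 allowed for noiseless
#'   limiting checks.
#' @param overlap fraction of each set's genes drawn from the full universe
#'   (0 = pairwise disjoint sets when feasible).
#' @param n_corpus samples in the gradient corpus.
#' @param seed integer seed; all generators are reproducible given
#'   (design, seed).
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_genes = 1000, n_sets = 20,
                             set_size_range = c(15, 50), n_per_group = 7,
                             groups = c("CD133pos", "CD133neg"),
                             planted = NULL,
                             baseline_mean = 7, baseline_sd = 2,
                             noise_sd = 1, overlap = 0, n_corpus = 300,
                             seed = 1) {
  stopifnot(
    n_genes >= 10, n_sets >= 1,
    length(set_size_range) == 2, set_size_range[1] >= 1,
    set_size_range[2] >= set_size_range[1], set_size_range[2] <= n_genes,
    n_per_group >= 1, length(groups) == 2, !anyDuplicated(groups),
    noise_sd >= 0, overlap >= 0, overlap <= 1, n_corpus >= 1
  )
  for (p in planted) {
    stopifnot(
      p$direction %in% c("up", "down"), p$delta > 0, p$group %in% groups
    )
  }
  structure(
    list(
      n_genes = n_genes, n_sets = n_sets, set_size_range = set_size_range,
      n_per_group = n_per_group, groups = groups, planted = planted,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd, overlap = overlap, n_corpus = n_corpus,
      seed = seed
    ),
    class = "synthetic_design"
  )
}

design_universe <- function(design) {
  sprintf("G%05d", seq_len(design$n_genes))
}

#' Generate a gene-set collection from a design
#'
#' Set sizes are drawn uniformly from the design's size range. With
#' `overlap = 0` sets are carved from the still-unused part of the universe,
#' so they are pairwise disjoint; a positive overlap fraction lets that share
#' of each set be drawn from the whole universe instead.
#'
#' @param design a [synthetic_design()].
#' @param seed seed (defaults to the design seed).
#' @return A [geneset_collection()] with sets `SET01`, `SET02`, ...
#' @export
make_collection <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  universe <- design_universe(design)
  with_seed_(seed, {
    size_choices <- seq(design$set_size_range[1], design$set_size_range[2])
    sizes <- size_choices[
      sample.int(length(size_choices), design$n_sets, replace = TRUE)
    ]
    unused <- universe
    sets <- vector("list", design$n_sets)
    for (i in seq_len(design$n_sets)) {
      n_shared <- round(design$overlap * sizes[i])
      n_fresh <- sizes[i] - n_shared
      if (n_fresh > length(unused)) {
        abort("gene universe too small for the requested disjoint sets")
      }
      fresh <- sample(unused, n_fresh)
      shared <- if (n_shared > 0) {
        sample(setdiff(universe, fresh), n_shared)
      } else {
        character(0)
      }
      sets[[i]] <- c(fresh, shared)
      unused <- setdiff(unused, fresh)
    }
    names(sets) <- sprintf("SET%02d", seq_len(design$n_sets))
    geneset_collection(sets,
      descriptions = rep("synthetic", design$n_sets)
    )
  })
}

#' Generate a two-class expression experiment with planted pathways
#'
#' `value(gene, sample) = baseline(gene) + planted effect + N(0, noise_sd)`,
#' where the planted effect is `+delta` (up) or `-delta` (down) for genes of
#' a planted set in samples of its target group, on the log scale. Class
#' labels are attached.
#'
#' @param design a [synthetic_design()].
#' @param collection the design's collection (regenerated from the design
#'   seed by default); planted set names must be members.
#' @param seed seed (defaults to the design seed).
#' @return An [expression_set()] with two-class labels.
#' @export
make_two_class_experiment <- function(design,
                                      collection = make_collection(design),
                                      seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  bad <- setdiff(names(design$planted), names(collection))
  if (length(bad)) {
    abort(sprintf(
      "planted set(s) not in the collection: %s", paste(bad, collapse = ", ")
    ))
  }
  universe <- design_universe(design)
  samples <- paste0(
    rep(design$groups, each = design$n_per_group), "_",
    rep(seq_len(design$n_per_group), 2)
  )
  labels <- setNames(rep(design$groups, each = design$n_per_group), samples)
  with_seed_(seed + 1L, {
    baseline <- rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
    m <- matrix(baseline,
      nrow = design$n_genes, ncol = length(samples),
      dimnames = list(universe, samples)
    )
    for (s in names(design$planted)) {
      p <- design$planted[[s]]
      shift <- if (p$direction == "up") p$delta else -p$delta
      m[collection[[s]], labels == p$group] <-
        m[collection[[s]], labels == p$group] + shift
    }
    if (design$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, design$noise_sd), nrow = nrow(m))
    }
    expression_set(m, labels = labels)
  })
}

#' Generate a stemness-gradient corpus
#'
#' Each corpus sample sits at a position in `[0, 1]` (1 = fully stem-like,
#' 0 = differentiated); the genes of the designated stem sets are shifted by
#' `position * delta` on the log scale, on top of baseline and noise, so stem
#' pathways are progressively activated along the gradient. Samples are
#' tagged stem-like / intermediate / differentiated by position tertile.
#'
#' @param design a [synthetic_design()].
#' @param collection the design's collection; `stem_sets` must be members.
#' @param stem_sets names of the stem gene sets.
#' @param delta log-scale activation at position 1 (default
#'   `1.5 * noise_sd`).
#' @param positions optional numeric vector in `[0, 1]`. The default mimics a
#'   public-repository corpus: most samples differentiated (positions drawn
#'   from a Beta(1, `skew`) grid over `[0, 1]`, extremes included) plus a
#'   dedicated block of `ref_frac * n_corpus` stem reference samples pinned
#'   at position 1 (the embryonic / induced-pluripotent stem cluster), tagged
#'   `"stem_ref"`.
#' @param ref_frac fraction of corpus samples used as dedicated stem
#'   references when `positions` is not supplied (default 0.1).
#' @param skew second Beta shape parameter of the default position grid
#'   (larger = more differentiated-heavy corpus; default 2.5).
#' @param seed seed (defaults to the design seed).
#' @return An [expression_set()] (no class labels) whose attribute
#'   `"design_groups"` is a tibble (sample, position, group).
#' @export
make_gradient_corpus <- function(design,
                                 collection = make_collection(design),
                                 stem_sets, delta = 1.5 * design$noise_sd,
                                 positions = NULL, ref_frac = 0.1,
                                 skew = 2.5, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  bad <- setdiff(stem_sets, names(collection))
  if (length(bad)) {
    abort(sprintf("unknown stem set(s): %s", paste(bad, collapse = ", ")))
  }
  ref_idx <- integer(0)
  if (is.null(positions)) {
    n_ref <- max(3, round(ref_frac * design$n_corpus))
    base <- stats::qbeta(stats::ppoints(design$n_corpus - n_ref), 1, skew)
    base[1] <- 0
    positions <- c(base, rep(1, n_ref))
    ref_idx <- seq(design$n_corpus - n_ref + 1, design$n_corpus)
  }
  stopifnot(all(positions >= 0 & positions <= 1))
  n <- length(positions)
  universe <- design_universe(design)
  samples <- sprintf("C%04d", seq_len(n))
  stem_genes <- unique(unlist(unclass(collection)[stem_sets], use.names = FALSE))
  with_seed_(seed + 2L, {
    baseline <- rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
    m <- matrix(baseline,
      nrow = design$n_genes, ncol = n,
      dimnames = list(universe, samples)
    )
    m[stem_genes, ] <- m[stem_genes, ] +
      rep(positions * delta, each = length(stem_genes))
    if (design$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, design$noise_sd), nrow = nrow(m))
    }
    out <- expression_set(m)
    group <- as.character(cut(positions,
      breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
      labels = c("differentiated", "intermediate", "stem_like")
    ))
    group[ref_idx] <- "stem_ref"
    attr(out, "design_groups") <- tibble::tibble(
      sample = samples, position = positions, group = group
    )
    out
  })
}
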