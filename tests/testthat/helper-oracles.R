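# Independent brute-force oracles: sequential accumulation over every
# position of the ranked list, no shortcuts shared with the implementation.

# signed max-magnitude running-sum statistic; earliest position on ties
brute_es <- function(ordered_genes, set, metric = NULL, exponent = 0) {
  n <- length(ordered_genes)
  hit <- ordered_genes %in% toupper(set)
  nh <- sum(hit)
  w <- if (exponent == 0) rep(1, n) else abs(metric[ordered_genes])^exponent
  nr <- sum(w[hit])
  s <- 0
  rs <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (hit[i]) s + w[i] / nr else s - 1 / (n - nh)
    rs[i] <- s
  }
  peak <- which.max(abs(rs))
  list(es = rs[peak], running_sum = rs, peak_index = peak,
       max_pos = max(0, max(rs)))
}

# exact rational running-sum extrema for exponent 0 on the integer lattice:
# hit step = (n - k), miss step = -k, all over k (n - k)
lattice_es <- function(n, pos) {
  k <- length(pos)
  steps <- rep(-k, n)
  steps[pos] <- n - k
  rs <- cumsum(steps)
  peak <- which.max(abs(rs))
  list(
    es = rs[peak] / (k * (n - k)),
    max_pos = max(0, max(rs)) / (k * (n - k))
  )
}

# signed classical two-sample KS D between in-set and out-of-set positions
signed_ks <- function(n, pos) {
  rest <- setdiff(seq_len(n), pos)
  d <- vapply(seq_len(n), function(t) {
    mean(pos <= t) - mean(rest <= t)
  }, numeric(1))
  i <- which.max(abs(d))
  d[i]
}

# all subsets of sizes 1..max_k of 1..n
all_subsets <- function(n, max_k) {
  out <- list()
  for (k in seq_len(max_k)) {
    cm <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  out
}

tiny_ranked_list <- function(n, seed = 42) {
  with_test_seed(seed, {
    m <- sort(rnorm(n), decreasing = TRUE)
    names(m) <- sprintf("G%03d", seq_len(n))
    ranked_list(m)
  })
}

with_test_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
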