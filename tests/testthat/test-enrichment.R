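test_that("perfectly concordant and discordant sets attain ES = +/-1 at exponent 0", {
  rl <- tiny_ranked_list(10)
  top <- names(rl)[1:3]
  bottom <- names(rl)[8:10]
  expect_equal(enrichment_score(rl, top, exponent = 0)$es, 1)
  expect_equal(enrichment_score(rl, bottom, exponent = 0)$es, -1)
})

test_that("running sum starts from 0 increments and returns to 0", {
  rl <- tiny_ranked_list(40)
  with_test_seed(7, {
    for (i in 1:10) {
      set <- sample(names(rl), sample(3:15, 1))
      for (expo in c(0, 1, 1.5)) {
        rs <- enrichment_score(rl, set, exponent = expo)$running_sum
        expect_lt(abs(rs[length(rs)]), 1e-9)
      }
    }
  })
})

test_that("ES matches brute-force enumeration and the fast path matches the full path", {
  rl5 <- tiny_ranked_list(5)
  set <- names(rl5)[c(2, 4)]
  full <- enrichment_score(rl5, set, exponent = 0)
  oracle <- brute_es(names(rl5), set, exponent = 0)
  expect_equal(full$es, oracle$es)
  expect_equal(full$running_sum, oracle$running_sum)
  expect_equal(full$peak_index, oracle$peak_index)

  with_test_seed(11, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      rl <- tiny_ranked_list(n, seed = 1000 + i)
      k <- sample(2:(n %/% 2), 1)
      set <- sample(names(rl), k)
      for (expo in c(0, 1)) {
        full <- enrichment_score(rl, set, exponent = expo)
        oracle <- brute_es(names(rl), set, metric = rl, exponent = expo)
        expect_equal(full$es, oracle$es, tolerance = 1e-12)
        pos <- sort(match(toupper(set), names(rl)))
        w <- if (expo == 0) NULL else abs(unname(rl))[pos]^expo
        fast <- stemprint:::es_stat_fast(pos, n, if (expo == 0) NULL else abs(unname(rl))[pos])
        expect_equal(unname(fast[1]), full$es, tolerance = 1e-12)
        expect_equal(unname(fast[2]), full$peak_index)
      }
    }
  })
})

test_that("ES agrees with an independent weighted-KS implementation", {
  with_test_seed(5, {
    for (i in 1:10) {
      n <- sample(30:80, 1)
      stats <- sort(rnorm(n), decreasing = TRUE)
      names(stats) <- sprintf("G%03d", seq_len(n))
      rl <- ranked_list(stats)
      sel <- sample(names(stats), sample(5:15, 1))
      for (param in c(0, 1)) {
        expect_equal(
          enrichment_score(rl, sel, exponent = param)$es,
          fgsea::calcGseaStat(stats, sort(match(sel, names(stats))),
            gseaParam = param
          ),
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("exponent-0 ES equals the signed two-sample KS statistic", {
  with_test_seed(13, {
    for (i in 1:50) {
      n <- sample(12:50, 1)
      rl <- tiny_ranked_list(n, seed = 2000 + i)
      k <- sample(2:(n - 2), 1)
      set <- sample(names(rl), k)
      pos <- sort(match(toupper(set), names(rl)))
      expect_equal(
        enrichment_score(rl, set, exponent = 0)$es,
        signed_ks(n, pos),
        tolerance = 1e-12
      )
    }
  })
})

test_that("gene-set permutation null is reproducible and matches exhaustive enumeration", {
  rl <- tiny_ranked_list(6)
  null1 <- geneset_permutation_null(rl, 2, exponent = 0, n_perm = 50, seed = 9)
  null2 <- geneset_permutation_null(rl, 2, exponent = 0, n_perm = 50, seed = 9)
  expect_length(null1, 50)
  expect_identical(null1, null2)
  expect_true(all(abs(null1) <= 1))

  # exhaustive: all 15 subsets of size 2 from a 6-gene universe
  exact <- sort(vapply(
    all_subsets(6, 2)[7:21],
    function(pos) lattice_es(6, pos)$es, numeric(1)
  ))
  big <- geneset_permutation_null(rl, 2, exponent = 0, n_perm = 4000, seed = 4)
  expect_true(all(vapply(
    big,
    function(v) any(abs(v - exact) < 1e-12), logical(1)
  )))
  # empirical CDF close to the uniform-over-subsets CDF (ties respected)
  uv <- unique(exact)
  emp <- vapply(uv, function(v) mean(big <= v + 1e-12), numeric(1))
  thy <- vapply(uv, function(v) mean(exact <= v + 1e-12), numeric(1))
  expect_lt(max(abs(emp - thy)), 0.05)
})

test_that("nominal p uses the one-tailed add-one estimator", {
  # hand count: null {0.1, 0.2, 0.3, -0.2}, es 0.25 -> (1+1)/(1+3)
  expect_equal(nominal_p(0.25, c(0.1, 0.2, 0.3, -0.2)), 0.5)
  # extreme observed among 99 same-signed nulls -> 1/100
  expect_equal(nominal_p(0.9, seq(0.001, 0.5, length.out = 99)), 1 / 100)
  # es at the null median -> ~0.5 (add-one estimator: 51/100)
  null <- seq(0.01, 1, length.out = 99)
  expect_equal(nominal_p(median(null), null), 0.51)
  expect_warning(p <- nominal_p(0.5, c(-0.1, -0.4)), "no same-signed")
  expect_equal(p, 1)
  expect_warning(p0 <- nominal_p(0, c(0.1)), "p set to 1")
  expect_equal(p0, 1)
})

test_that("NES normalizes by same-signed null means and FDR follows the tail-ratio rule", {
  # one set: es equal to the mean positive null -> NES 1
  nulls <- list(S1 = c(0.2, 0.4, -0.3))
  out <- nes_and_fdr(c(S1 = 0.3), nulls)
  expect_equal(out$nes, 1)
  # single set exceeding all nulls: observed tail fraction 1 -> q = null tail = 0
  out2 <- nes_and_fdr(c(S1 = 0.9), nulls)
  expect_equal(out2$fdr_q, 0)

  # three sets, hand-evaluated ratio formula
  es <- c(A = 0.6, B = 0.3, C = -0.5)
  nl <- list(
    A = c(0.1, 0.2, 0.3, -0.2),
    B = c(0.1, 0.3, -0.1, -0.3),
    C = c(0.2, -0.1, -0.3, -0.4)
  )
  out3 <- nes_and_fdr(es, nl)
  # hand: mean-pos A = .2, B = .2, C = .2 ; mean |neg| A = .2, B = .2, C = .8/3
  nes_hand <- c(0.6 / 0.2, 0.3 / 0.2, -0.5 / (0.8 / 3))
  expect_equal(out3$nes, unname(nes_hand))
  # pooled positive null NES: A {.5, 1, 1.5}, B {.5, 1.5}, C {1}; none >= 3 -> q(A)=0
  expect_equal(out3$fdr_q[out3$set == "A"], 0)
  # q(B): null tail (#>=1.5)/6 = 2/6, obs tail (#>=1.5)/2 = 2/2 -> 1/3
  expect_equal(out3$fdr_q[out3$set == "B"], (2 / 6) / (2 / 2))
  # q(C): pooled negative null NES: A {-1}, B {-.5,-1.5}, C {-.375,-1.125,-1.5};
  # #<= -1.875 = 0 -> 0
  expect_equal(out3$fdr_q[out3$set == "C"], 0)
})

test_that("FDR q is monotone non-increasing in |NES| within each sign", {
  with_test_seed(17, {
    rl <- tiny_ranked_list(200)
    sets <- lapply(1:12, function(i) sample(names(rl), sample(8:20, 1)))
    names(sets) <- sprintf("S%02d", 1:12)
    es <- vapply(sets, function(s) enrichment_score(rl, s, exponent = 0)$es, numeric(1))
    nulls <- lapply(sets, function(s) {
      geneset_permutation_null(rl, length(s), exponent = 0, n_perm = 100, seed = 3)
    })
    out <- nes_and_fdr(es, nulls)
    for (sgn in c(1, -1)) {
      sub <- out[sign(out$nes) == sgn, ]
      if (nrow(sub) > 1) {
        sub <- sub[order(abs(sub$nes)), ]
        expect_true(all(diff(sub$fdr_q) <= 1e-12))
      }
    }
  })
})

test_that("nominal p under gene-set permutation is uniform on its grid", {
  rl <- tiny_ranked_list(100)
  # each trial draws its own null so the p values are marginally uniform
  with_test_seed(23, {
    ps <- vapply(1:1000, function(i) {
      null <- geneset_permutation_null(rl, 10,
        exponent = 0, n_perm = 199,
        seed = 30000 + i
      )
      set <- sample(names(rl), 10)
      suppressWarnings(
        nominal_p(enrichment_score(rl, set, exponent = 0)$es, null)
      )
    }, numeric(1))
  })
  # chi-square goodness of fit over deciles
  counts <- table(cut(ps, breaks = seq(0, 1, 0.1), include.lowest = TRUE))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("leading edge splits at the peak and bins into the reporting categories", {
  rl5 <- tiny_ranked_list(5)
  set <- names(rl5)[c(2, 4)]
  es <- enrichment_score(rl5, set, exponent = 0)
  le <- leading_edge(rl5, set, es$peak_index, es$es)
  oracle <- brute_es(names(rl5), set, exponent = 0)
  members <- names(rl5)[c(2, 4)]
  pos <- c(2, 4)
  expected <- if (oracle$es > 0) {
    members[pos <= oracle$peak_index]
  } else {
    members[pos >= oracle$peak_index]
  }
  expect_equal(le$genes, expected)
  expect_equal(le$contribution_fraction, length(expected) / 2)

  # a set entirely ahead of the peak contributes fully
  rl <- tiny_ranked_list(10)
  top <- names(rl)[1:3]
  es_top <- enrichment_score(rl, top, exponent = 0)
  le_top <- leading_edge(rl, top, es_top$peak_index, es_top$es)
  expect_equal(le_top$contribution_fraction, 1)
  expect_equal(le_top$contribution_category, "75-100%")
  expect_equal(stemprint:::contribution_category(0.6), "50-75%")
  expect_equal(stemprint:::contribution_category(0.2), "<20%")
  expect_equal(stemprint:::contribution_category(0.21), "20-50%")
  expect_error(leading_edge(rl, top, 3, 0), "zero enrichment")
})

test_that("significance codes follow the reporting thresholds", {
  expect_equal(
    stemprint:::significance_code(c(0.2, 0.049, 0.009, 0.0009)),
    c("", "*", "**", "***")
  )
})

test_that("gsea() recovers a planted pathway and is seed-deterministic", {
  d <- synthetic_design(
    seed = 41,
    planted = list(SET01 = list(direction = "up", delta = 2, group = "CD133pos"))
  )
  coll <- make_collection(d)
  expr <- make_two_class_experiment(d, coll)
  fit <- gsea(expr, coll, n_perm = 200, seed = 8)
  tab <- tidy(fit)
  expect_equal(tab$set[which.max(tab$nes)], "SET01")
  expect_lt(tab$fdr_q[tab$set == "SET01"], 0.05)
  expect_true(all(diff(abs(tab$nes)) <= 1e-12)) # sorted by |NES| desc
  expect_true(all(tab$p_nominal >= 1 / (fit$params$n_perm + 1)))
  # leading edge is always a subset of the restricted set
  for (i in seq_len(nrow(tab))) {
    le <- strsplit(tab$leading_edge[i], ",")[[1]]
    expect_true(all(le %in% fit$collection[[tab$set[i]]]))
  }
  fit2 <- gsea(expr, coll, n_perm = 200, seed = 8)
  expect_identical(tidy(fit), tidy(fit2))
  g <- glance(fit)
  expect_equal(g$n_sets, nrow(tab))
  expect_equal(g$n_sig_fdr, sum(tab$fdr_q < 0.05, na.rm = TRUE))
})
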