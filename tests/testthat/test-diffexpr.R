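test_that("log2 fold change matches closed forms and reference values", {
  # islet vs ALT-graft FPKM of a reference isoform; frozen from
  # high-precision arithmetic log2(1.48629 / 60.2895)
  mat <- make_matrix(list(Islet = matrix(60.2895), ALT = matrix(1.48629)),
                     ids = "lnc-CTRB1-1:1")
  lfc <- compute_log2fc(mat, "Islet", "ALT", pseudocount = 0)
  expect_equal(unname(lfc), -5.342119, tolerance = 1e-6)
  # identical means -> 0; closed form with pseudocount
  mat2 <- make_matrix(list(A = matrix(c(4, 0), 2), B = matrix(c(4, 7), 2)))
  expect_equal(unname(compute_log2fc(mat2, "A", "B", 1)), c(0, 3))
  expect_error(compute_log2fc(mat2, "A", "missing"), "group not present")
  expect_warning(compute_log2fc(mat2, "A", "B", 0), "pseudocount 0")
})

test_that("fold changes are antisymmetric in the group order", {
  set.seed(8)
  for (i in 1:5) {
    mat <- make_matrix(list(A = matrix(runif(30, 0, 50), 10),
                            B = matrix(runif(30, 0, 50), 10)))
    pc <- runif(1, 0.5, 2)
    expect_equal(compute_log2fc(mat, "A", "B", pc),
                 -compute_log2fc(mat, "B", "A", pc))
  }
})

test_that("the stand-in DE test agrees with stats::t.test and handles edge cases", {
  set.seed(21)
  mat <- make_matrix(list(A = matrix(2 ^ rnorm(40, 5), 10),
                          B = matrix(2 ^ rnorm(40, 5), 10)))
  res <- test_de(mat, "A", "B")
  la <- log2(mat$values[, 1:4] + 1); lb <- log2(mat$values[, 5:8] + 1)
  for (i in 1:10) {
    expect_equal(res$p[i],
                 t.test(lb[i, ], la[i, ], var.equal = TRUE)$p.value)
  }
  res_w <- test_de(mat, "A", "B", var_equal = FALSE)
  for (i in 1:10)
    expect_equal(res_w$p[i], t.test(lb[i, ], la[i, ])$p.value)
  # BH agrees with the reference implementation and is monotone in rank
  expect_equal(res$q, p.adjust(res$p, "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_gte(min(res$q), min(res$p))
  expect_equal(res$fold_change, 2 ^ res$log2fc)

  # identical replicate values -> p = 1, log2fc = 0 by convention
  same <- make_matrix(list(A = matrix(rep(c(3, 7), 3), 2),
                           B = matrix(rep(c(3, 7), 3), 2)))
  rs <- test_de(same, "A", "B")
  expect_equal(rs$p, c(1, 1))
  expect_equal(rs$log2fc, c(0, 0))

  # single replicate -> LOWDATA, no p or q
  low <- make_matrix(list(A = matrix(c(1, 2), 2), B = matrix(c(2, 3), 2)))
  rl <- test_de(low, "A", "B")
  expect_true(all(rl$status == "LOWDATA"))
  expect_true(all(is.na(rl$p)))
})

test_that("threshold presets apply their printed operators at the boundary", {
  # inclusive rnaseq_de: FC exactly 2 and q exactly 0.05 is retained
  r <- make_de("t1", log2fc = 1.0, p = 0.01, q = 0.05)
  expect_equal(filter_de(r, "rnaseq_de")$n_total, 1)
  # strict cis_screen: |log2fc| exactly 1.5 is excluded
  r2 <- make_de(c("t1", "t2"), log2fc = c(1.5, 1.6), p = 0.04, q = 0.2)
  f2 <- filter_de(r2, "cis_screen")
  expect_equal(f2$results$transcript_id, "t2")
  # OR combination of the plotting rule
  r3 <- make_de(c("a", "b", "c"), log2fc = c(0.1, 2, 0.1),
                p = c(0.04, 0.5, 0.5), q = 1)
  expect_setequal(filter_de(r3, "plot_inclusion")$results$transcript_id,
                  c("a", "b"))
  # status gating
  r4 <- make_de("t1", log2fc = 3, p = 0, q = 0, status = "FAIL")
  expect_equal(filter_de(r4, "rnaseq_de")$n_total, 0)
  expect_error(filter_de(rbind(make_de("x", 1), make_de("y", 1,
    comparison = "C vs D")), "rnaseq_de"), "mix comparisons")
})

test_that("tightening a threshold never adds survivors", {
  set.seed(13)
  res <- make_de(sprintf("t%03d", 1:200), log2fc = rnorm(200, 0, 2),
                 p = runif(200), q = runif(200))
  base <- threshold_preset("cis_screen")
  loose <- filter_de(res, base)$results$transcript_id
  tight_fc <- base; tight_fc$min_abs_log2fc <- 2.5
  tight_p <- base; tight_p$max_p <- 0.01
  expect_true(all(filter_de(res, tight_fc)$results$transcript_id %in% loose))
  expect_true(all(filter_de(res, tight_p)$results$transcript_id %in% loose))
})

test_that("zero-noise planted truth is recovered exactly by the DE filter", {
  cfg <- truth_config(seed = 17, n_mrna = 80, n_lncrna = 40, n_up = 10,
                      n_down = 12, n_up_lnc = 5, n_down_lnc = 6,
                      noise_sd_log2 = 0)
  truth <- generate_annotation(cfg)
  expr <- generate_expression(truth, cfg)
  res <- test_de(expr$matrix, "Islet", "ALT")
  f <- filter_de(res, "rnaseq_de")
  dt <- truth$de_truth
  expect_setequal(f$up_ids, dt$transcript_id[dt$direction == "up"])
  expect_setequal(f$down_ids, dt$transcript_id[dt$direction == "down"])
  expect_equal(f$n_total, f$n_up + f$n_down)
})

test_that("Fisher enrichment equals the exact hypergeometric tail", {
  # frozen: sum_{k>=8} dhyper(k; 10, 90, 20) computed by enumeration
  universe <- sprintf("g%03d", 1:100)
  de <- universe[1:20]
  gs <- list(S = universe[c(1:8, 51, 52)])  # overlap 8 of set size 10
  res <- enrichment_fisher(de, universe, gs)
  oracle <- sum(dhyper(8:10, 10, 90, 20))
  expect_equal(res$p, oracle)
  expect_equal(res$p, 2.378275e-05, tolerance = 1e-6)
  expect_equal(res$neg_log10_p, -log10(oracle))
  expect_equal(res$overlap, 8)
  # zero overlap and set == universe both give p = 1
  none <- enrichment_fisher(de, universe, list(S = universe[90:100]))
  expect_equal(none$overlap, 0)
  expect_equal(none$p, 1)
  all_set <- enrichment_fisher(de, universe, list(S = universe))
  expect_equal(all_set$overlap, 20)
  expect_equal(all_set$p, 1)
  expect_error(enrichment_fisher(character(0), character(0), gs),
               "empty universe")
})

test_that("Fisher p equals brute-force enumeration on small universes", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(5:50, 1)
    universe <- sprintf("u%02d", seq_len(N))
    de <- sample(universe, sample.int(N, 1))
    gs <- sample(universe, sample.int(N, 1))
    res <- enrichment_fisher(de, universe, list(S = gs))
    k <- length(intersect(gs, de))
    brute <- sum(sapply(k:min(length(gs), length(de)), function(x)
      choose(length(gs), x) * choose(N - length(gs), length(de) - x) /
        choose(N, length(de))))
    expect_equal(res$p, brute, tolerance = 1e-12)
  }
})

test_that("the stand-in test is calibrated on null transcripts", {
  # 10,000 nulls at alpha 0.05, log-normal noise 0.3, 3 vs 3
  cfg <- truth_config(seed = 1, n_mrna = 9999, n_lncrna = 1, n_up = 0,
                      n_down = 0, n_up_lnc = 0, n_down_lnc = 0,
                      n_pairs_planted = 0, n_decoy_pairs = 0,
                      noise_sd_log2 = 0.3, n_islet_specific = 0)
  truth <- generate_annotation(cfg)
  expr <- generate_expression(truth, cfg)
  res <- test_de(expr$matrix, "Islet", "ALT")
  expect_equal(mean(res$p < 0.05), 0.05, tolerance = 0.01 / 0.05)
})
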