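test_that("locus strings parse to internal coordinates and round-trip", {
  loc <- parse_locus("chr11:65266530-65273915")
  expect_equal(loc$chrom, "chr11")
  expect_equal(loc$start, 65266529)
  expect_equal(loc$end, 65273915)
  expect_equal(loc$end - loc$start, 7386)  # printed interval length
  expect_equal(sprintf("%s:%d-%d", loc$chrom, loc$start + 1, loc$end),
               "chr11:65266530-65273915")
  single <- parse_locus("chr1:1-1")
  expect_equal(c(single$start, single$end), c(0, 1))
  expect_error(parse_locus("chr1:10-5"), "malformed")
  expect_error(parse_locus("not a locus"), "malformed")
  # thousands separators as printed in locus columns are tolerated
  expect_equal(parse_locus("chr2:1,000-2,000")$start, 999)
})

test_that("TSS and signed distances follow the orientation convention", {
  # interval covering the TSS -> 0
  expect_equal(pair_distance(rec("c", 1000, 2000, "+"),
                             rec("c", 1400, 3000, "+")), 0)
  # lncRNA 500 bp genomically upstream of a +strand TSS: magnitude from
  # the half-open edge, negative because upstream in mRNA orientation
  d <- pair_distance(rec("c", 1000, 2000, "+"), rec("c", 2500, 4000, "+"))
  expect_equal(abs(d), 500)
  expect_equal(d, -500)
  # beyond the screen radius
  d2 <- pair_distance(rec("c", 1000, 2000, "+"), rec("c", 60001, 62000, "+"))
  expect_equal(abs(d2), 58001)
  expect_gt(abs(d2), 50000)
  # reference-anchored sign check: lncRNA ending at 75,262,093 with a
  # minus-strand mRNA TSS at 75,270,228 lies downstream -> +8,135
  lnc <- rec("chr16", 75259971, 75262093, "+")
  mrna <- rec("chr16", 75263000, 75270229, "-")
  expect_equal(pair_distance(lnc, mrna), 8135)
  # the 5' anchor measures from the lncRNA TSS instead
  expect_equal(pair_distance(rec("c", 1000, 2000, "+"),
                             rec("c", 2500, 4000, "+"), anchor = "tss5p"),
               -1500)
  expect_equal(pair_distance(rec("c", 1000, 2000, "-"),
                             rec("c", 2500, 4000, "+"), anchor = "tss5p"),
               -501)
  # different chromosomes -> no distance
  expect_true(is.na(pair_distance(rec("c1", 1, 10, "+"),
                                  rec("c2", 1, 10, "+"))))
})

test_that("distances are invariant under coordinate translation", {
  set.seed(12)
  for (i in 1:10) {
    s1 <- sample.int(1e5, 1); l1 <- sample(200:2000, 1)
    s2 <- sample.int(1e5, 1); l2 <- sample(200:2000, 1)
    st <- sample(c("+", "-"), 2, replace = TRUE)
    shift <- sample.int(1e6, 1)
    d0 <- pair_distance(rec("c", s1, s1 + l1, st[1]),
                        rec("c", s2, s2 + l2, st[2]))
    d1 <- pair_distance(rec("c", s1 + shift, s1 + l1 + shift, st[1]),
                        rec("c", s2 + shift, s2 + l2 + shift, st[2]))
    expect_equal(d0, d1)
  }
})

test_that("pattern classification partitions sign combinations", {
  expect_equal(classify_pair(-2.0, -1.8), "co_down")
  expect_equal(classify_pair(1.7, 2.2), "co_up")
  expect_equal(classify_pair(1.6, -1.9), "opposite")
  expect_equal(classify_pair(-1.6, 1.9), "opposite")
  expect_error(classify_pair(0, 1), "zero")
})

test_that("the distance screen equals the brute-force oracle on small instances", {
  for (seed in c(3, 14, 159)) {
    ann <- random_annotation(sample(10:50, 1), seed)
    lnc_ids <- ann$transcript_id[ann$biotype == "lncRNA"]
    mrna_ids <- ann$transcript_id[ann$biotype == "mRNA"]
    if (length(lnc_ids) == 0 || length(mrna_ids) == 0) next
    set.seed(seed + 1)
    de_lnc <- make_de(lnc_ids,
                      sample(c(-1, 1), length(lnc_ids), TRUE) *
                        runif(length(lnc_ids), 1.6, 4))
    de_mrna <- make_de(mrna_ids,
                       sample(c(-1, 1), length(mrna_ids), TRUE) *
                         runif(length(mrna_ids), 1.6, 4))
    got <- screen_cis_pairs(de_lnc, de_mrna, ann)
    want <- brute_force_pairs(de_lnc, de_mrna, ann, 50000)
    key <- function(df) sort(paste(df$lnc_id, df$mrna_id, df$signed_distance))
    expect_identical(key(got), key(want))
  }
})

test_that("planted pairs are recovered and decoys excluded at zero noise", {
  cfg <- truth_config(seed = 23, n_mrna = 60, n_lncrna = 30,
                      n_pairs_planted = 5, n_decoy_pairs = 3,
                      noise_sd_log2 = 0)
  truth <- generate_annotation(cfg)
  expr <- generate_expression(truth, cfg)
  res <- test_de(expr$matrix, "Islet", "ALT")
  biotype <- truth$annotation$biotype[
    match(res$transcript_id, truth$annotation$transcript_id)]
  lnc <- filter_de(res[biotype == "lncRNA", ], "cis_screen")$results
  mrna <- filter_de(res[biotype == "mRNA", ], "cis_screen")$results
  pairs <- screen_cis_pairs(lnc, mrna, truth$annotation)
  pt <- truth$pair_truth
  key <- function(l, m) paste(l, m)
  expect_setequal(key(pairs$lnc_id, pairs$mrna_id),
                  key(pt$lnc_id[!pt$is_decoy], pt$mrna_id[!pt$is_decoy]))
  # raising the radius keeps every pair and eventually admits decoys
  wider <- screen_cis_pairs(lnc, mrna, truth$annotation,
                            max_distance = cfg$decoy_max_distance)
  expect_true(all(key(pairs$lnc_id, pairs$mrna_id) %in%
                    key(wider$lnc_id, wider$mrna_id)))
  expect_true(all(key(pt$lnc_id[pt$is_decoy], pt$mrna_id[pt$is_decoy])
                  %in% key(wider$lnc_id, wider$mrna_id)))
  # max_distance 0 keeps only TSS-overlapping pairs
  zero <- screen_cis_pairs(lnc, mrna, truth$annotation, max_distance = 0)
  expect_true(all(zero$signed_distance == 0))
  expect_error(
    screen_cis_pairs(make_de("GHOST", 2), mrna, truth$annotation),
    "GHOST")
})

test_that("antisense placement overlaps on the opposite strand", {
  cfg <- truth_config(seed = 6, n_mrna = 40, n_lncrna = 20,
                      n_pairs_planted = 4, n_antisense_pairs = 2,
                      n_decoy_pairs = 0, noise_sd_log2 = 0)
  truth <- generate_annotation(cfg)
  pt <- truth$pair_truth
  expect_equal(sum(pt$antisense), 2)
  expect_true(all(pt$signed_distance[pt$antisense] == 0))
  ann <- truth$annotation
  for (i in which(pt$antisense)) {
    lnc <- ann[ann$transcript_id == pt$lnc_id[i], ]
    mrna <- ann[ann$transcript_id == pt$mrna_id[i], ]
    expect_true(lnc$strand != mrna$strand)
    expect_true(lnc$start < mrna$end && mrna$start < lnc$end)
  }
})

test_that("pair summaries partition counts and report exact Pearson inference", {
  # partition identity on the printed-count scale
  pairs <- data.frame(
    lnc_log2fc = c(rep(-2, 170), rep(2, 62), rep(2, 135)),
    mrna_log2fc = c(rep(-2, 170), rep(2, 62), rep(-2, 135)))
  pairs$pattern <- classify_pair(pairs$lnc_log2fc, pairs$mrna_log2fc)
  s <- summarize_pairs(pairs, "ALT vs PBS")
  expect_equal(s$n_pairs, 367)
  expect_equal(s$n_co_down + s$n_co_up + s$n_opposite, s$n_pairs)
  expect_equal(c(s$n_co_down, s$n_co_up, s$n_opposite), c(170, 62, 135))

  # colinear fold changes -> r exactly 1, and p matches cor.test
  line <- data.frame(lnc_log2fc = 1:6, mrna_log2fc = 2 * (1:6) + 3)
  line$pattern <- "co_up"
  sl <- summarize_pairs(line)
  expect_equal(sl$pearson_r, 1)

  # r is invariant under positive affine transforms of either vector
  set.seed(77)
  base <- data.frame(lnc_log2fc = rnorm(50), mrna_log2fc = rnorm(50))
  base$pattern <- "co_up"
  r0 <- summarize_pairs(base)$pearson_r
  tr <- base
  tr$lnc_log2fc <- 3 * tr$lnc_log2fc + 7
  tr$mrna_log2fc <- 0.5 * tr$mrna_log2fc - 2
  expect_equal(summarize_pairs(tr)$pearson_r, r0)
  expect_true(abs(r0) <= 1)

  # fewer than two pairs: counts only, correlation undefined
  one <- data.frame(lnc_log2fc = 2, mrna_log2fc = 2, pattern = "co_up")
  s1 <- summarize_pairs(one)
  expect_equal(s1$n_pairs, 1)
  expect_true(is.na(s1$pearson_r))
})

test_that("a planted pair correlation of 0.5 is recovered at n = 400", {
  set.seed(404)
  n <- 400; rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  pairs <- data.frame(lnc_log2fc = x + sign(x) * 0.01,
                      mrna_log2fc = y + sign(y) * 0.01)
  pairs$pattern <- classify_pair(pairs$lnc_log2fc, pairs$mrna_log2fc)
  s <- summarize_pairs(pairs)
  # Fisher z 95% CI of the estimate must cover the planted value
  z <- atanh(s$pearson_r)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_true(rho >= ci[1] && rho <= ci[2])
  expect_lt(s$p_two_tailed, 1e-4)
})
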