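# Shared fixture builders and independent oracles.

# expression_matrix from a named list of per-group replicate matrices
make_matrix <- function(group_values, ids = NULL) {
  groups <- names(group_values)
  mats <- lapply(group_values, as.matrix)
  values <- do.call(cbind, mats)
  n <- nrow(values)
  ids <- ids %||% sprintf("T%03d", seq_len(n))
  rownames(values) <- ids
  samples <- do.call(rbind, lapply(groups, function(g) {
    k <- ncol(mats[[g]])
    data.frame(sample = paste0(g, "_", seq_len(k)), group = g,
               replicate = seq_len(k), stringsAsFactors = FALSE)
  }))
  colnames(values) <- samples$sample
  expression_matrix(values, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal DE-result row set
make_de <- function(ids, log2fc, p = 0, q = p, status = "OK",
                    comparison = "B vs A") {
  data.frame(transcript_id = ids, comparison = comparison,
             log2fc = log2fc, fold_change = 2 ^ log2fc, p = p, q = q,
             status = status, stringsAsFactors = FALSE)
}

# Independent all-pairs distance oracle: plain loops, its own gap and
# sign arithmetic (positive = lncRNA downstream of the TSS in mRNA
# orientation), nearest-edge anchor.
brute_force_pairs <- function(de_lnc, de_mrna, ann, max_distance) {
  hits <- list()
  for (i in seq_len(nrow(de_lnc))) {
    la <- ann[ann$transcript_id == de_lnc$transcript_id[i], ]
    for (j in seq_len(nrow(de_mrna))) {
      ma <- ann[ann$transcript_id == de_mrna$transcript_id[j], ]
      if (la$chrom != ma$chrom) next
      t <- if (ma$strand == "+") ma$start else ma$end - 1
      gap <- max(0, la$start - t, t - la$end)
      genomic_sign <- if (gap == 0) 0 else if (la$start > t) 1 else -1
      d <- gap * genomic_sign * (if (ma$strand == "+") 1 else -1)
      if (abs(d) <= max_distance)
        hits[[length(hits) + 1]] <- data.frame(
          lnc_id = la$transcript_id, mrna_id = ma$transcript_id,
          signed_distance = d, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      signed_distance = numeric(0)))
  do.call(rbind, hits)
}

# random small annotation for oracle-equivalence tests
random_annotation <- function(n, seed) {
  set.seed(seed)
  biotype <- sample(c("lncRNA", "mRNA"), n, replace = TRUE)
  start <- sort(sample.int(3e5, n))
  len <- sample(200:5000, n, replace = TRUE)
  data.frame(transcript_id = sprintf("R%03d", seq_len(n)),
             gene_id = sprintf("G%03d", seq_len(n)),
             biotype = biotype,
             chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# single transcript records for pair_distance tests
rec <- function(chrom, start, end, strand, id = "X") {
  data.frame(transcript_id = id, gene_id = id, biotype = "lncRNA",
             chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}
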