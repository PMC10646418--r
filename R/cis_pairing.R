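# CIS lncRNA-mRNA pairing: locus parsing, signed TSS distances,
# distance screening of differentially expressed pairs, co-regulation
# classification and per-comparison summaries.

#' Parse genome-browser locus strings
#'
#' Converts `"chr:start-end"` strings (1-based, end-inclusive, as
#' printed by genome browsers; thousands separators tolerated) to the
#' package's internal 0-based half-open convention.
#'
#' @param locus character vector like `"chr11:65266530-65273915"`.
#' @return data.frame: chrom, start (0-based), end (half-open exclusive).
#' @export
#' @examples
#' parse_locus("chr11:65266530-65273915")  # start 65266529, end 65273915
parse_locus <- function(locus) {
  s <- gsub(",", "", trimws(locus))
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$", s))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop_cislnc("malformed locus string: ",
                paste(locus[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  start1 <- as.numeric(vapply(m, `[`, "", 3L))
  end1 <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(start1 < 1) || any(end1 < start1))
    stop_cislnc("malformed locus string: start must be >= 1 and <= end")
  data.frame(chrom = chrom, start = start1 - 1, end = end1,
             stringsAsFactors = FALSE)
}

#' Transcription start site of a transcript record
#'
#' With 0-based half-open coordinates the TSS is `start` on the plus
#' strand and `end - 1` on the minus strand.
#'
#' @param record data.frame with columns start, end, strand (vectorized).
#' @return numeric vector of TSS coordinates.
#' @export
transcript_tss <- function(record) {
  ifelse(record$strand == "+", record$start, record$end - 1)
}

# Signed nearest-edge / 5'-anchor distance from a lncRNA interval to an
# mRNA TSS, vectorized over lncRNAs against one TSS. Positive when the
# lncRNA anchor lies downstream of the TSS in mRNA orientation.
signed_tss_distance <- function(lnc_start, lnc_end, lnc_tss, tss,
                                mrna_strand, anchor) {
  if (anchor == "tss5p") {
    g <- lnc_tss - tss
  } else {
    # nearest edge; 0 when the interval covers the TSS
    g <- ifelse(tss < lnc_start, lnc_start - tss,
         ifelse(tss >= lnc_end, -(tss - lnc_end), 0))
  }
  if (mrna_strand == "+") g else -g
}

#' Signed genomic distance from a lncRNA to an mRNA TSS
#'
#' Measures from the lncRNA anchor (default: nearest transcript edge,
#' i.e. the minimum distance over the lncRNA interval, 0 when the
#' interval covers the TSS; alternative `"tss5p"`: the lncRNA's own 5'
#' end) to the mRNA transcription start site. The sign is oriented by
#' the mRNA: positive when the lncRNA anchor lies downstream of the TSS
#' in the mRNA's direction of transcription, negative upstream.
#' Different chromosomes give `NA`.
#'
#' @param lnc,mrna single transcript records (data.frame rows with
#'   chrom, start, end, strand).
#' @param anchor `"nearest_edge"` (default) or `"tss5p"`.
#' @return signed distance in bp, or `NA` across chromosomes.
#' @export
pair_distance <- function(lnc, mrna,
                          anchor = c("nearest_edge", "tss5p")) {
  anchor <- match.arg(anchor)
  if (lnc$chrom != mrna$chrom) return(NA_real_)
  tss <- transcript_tss(mrna)
  signed_tss_distance(lnc$start, lnc$end, transcript_tss(lnc), tss,
                      mrna$strand, anchor)
}

#' Classify the co-regulation pattern of a pair
#'
#' Both fold changes negative: `co_down`; both positive: `co_up`;
#' discordant signs: `opposite`. Zero input violates the screen's
#' precondition (the CIS screen requires |log2fc| > 1.5) and errors.
#'
#' @param lnc_log2fc,mrna_log2fc nonzero log2 fold changes (vectorized).
#' @return character vector of patterns.
#' @export
classify_pair <- function(lnc_log2fc, mrna_log2fc) {
  if (any(lnc_log2fc == 0) || any(mrna_log2fc == 0))
    stop_cislnc("zero log2 fold change cannot be classified")
  ifelse(lnc_log2fc < 0 & mrna_log2fc < 0, "co_down",
  ifelse(lnc_log2fc > 0 & mrna_log2fc > 0, "co_up", "opposite"))
}

#' Screen lncRNA-mRNA pairs by TSS distance
#'
#' Forms every (lncRNA, mRNA) combination from two pre-filtered DE lists
#' whose signed distance to the mRNA TSS is at most `max_distance` in
#' absolute value. A lncRNA may pair with several mRNAs and vice versa;
#' multiple isoforms are kept (transcript model, no gene collapsing).
#' The antisense flag marks pairs whose transcripts overlap on opposite
#' strands (`antisense = "overlap"`) or merely lie on opposite strands
#' within the screen distance (`antisense = "opposite_strand"`).
#'
#' @param de_lnc,de_mrna DE result data.frames (as from [test_de()],
#'   already filtered with the `cis_screen` preset) for lncRNAs and
#'   mRNAs respectively.
#' @param annotation transcript annotation data.frame (transcript_id,
#'   chrom, start, end, strand, biotype).
#' @param max_distance screen radius in bp (default 50 kb).
#' @param anchor lncRNA anchor mode, see [pair_distance()].
#' @param antisense convention for the antisense flag.
#' @return data.frame of pairs: lnc_id, mrna_id, chrom, signed_distance,
#'   lnc_log2fc, mrna_log2fc, pattern, antisense_flag.
#' @export
screen_cis_pairs <- function(de_lnc, de_mrna, annotation,
                             max_distance = 50000,
                             anchor = c("nearest_edge", "tss5p"),
                             antisense = c("overlap", "opposite_strand")) {
  anchor <- match.arg(anchor)
  antisense <- match.arg(antisense)
  ids <- c(de_lnc$transcript_id, de_mrna$transcript_id)
  missing <- setdiff(ids, annotation$transcript_id)
  if (length(missing) > 0)
    stop_cislnc("transcripts absent from annotation: ",
                paste(missing, collapse = ", "))
  ann <- annotation[match(ids, annotation$transcript_id), ]
  la <- ann[seq_len(nrow(de_lnc)), , drop = FALSE]
  ma <- ann[nrow(de_lnc) + seq_len(nrow(de_mrna)), , drop = FALSE]
  m_tss <- transcript_tss(ma)
  l_tss <- transcript_tss(la)

  out <- vector("list", nrow(de_mrna))
  for (j in seq_len(nrow(de_mrna))) {
    d <- signed_tss_distance(la$start, la$end, l_tss, m_tss[j],
                             ma$strand[j], anchor)
    d[la$chrom != ma$chrom[j]] <- NA_real_
    hit <- which(!is.na(d) & abs(d) <= max_distance)
    if (length(hit) == 0) next
    overlap <- la$start[hit] < ma$end[j] & ma$start[j] < la$end[hit]
    anti <- if (antisense == "overlap")
      overlap & la$strand[hit] != ma$strand[j]
    else la$strand[hit] != ma$strand[j]
    out[[j]] <- data.frame(
      lnc_id = la$transcript_id[hit], mrna_id = ma$transcript_id[j],
      chrom = ma$chrom[j], signed_distance = d[hit],
      lnc_log2fc = de_lnc$log2fc[hit], mrna_log2fc = de_mrna$log2fc[j],
      antisense_flag = anti, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- data.frame(lnc_id = character(0), mrna_id = character(0),
                        chrom = character(0), signed_distance = numeric(0),
                        lnc_log2fc = numeric(0), mrna_log2fc = numeric(0),
                        antisense_flag = logical(0),
                        stringsAsFactors = FALSE)
  pairs$pattern <- if (nrow(pairs) > 0)
    classify_pair(pairs$lnc_log2fc, pairs$mrna_log2fc)
  else character(0)
  rownames(pairs) <- NULL
  pairs[, c("lnc_id", "mrna_id", "chrom", "signed_distance",
            "lnc_log2fc", "mrna_log2fc", "pattern", "antisense_flag")]
}

#' Summarize screened pairs for one comparison
#'
#' Counts the co-regulation patterns (which always partition the pairs)
#' and computes the Pearson correlation between the lncRNA and mRNA
#' log2 fold changes with an exact two-tailed p from the
#' t-distribution. With fewer than two pairs the counts are returned
#' and the correlation is flagged undefined (`NA`).
#'
#' @param pairs data.frame from [screen_cis_pairs()].
#' @param comparison label for the contrast the pairs came from.
#' @return list of class `"cis_summary"`: comparison, n_pairs,
#'   n_co_down, n_co_up, n_opposite, pearson_r, p_two_tailed.
#' @export
summarize_pairs <- function(pairs, comparison = NA_character_) {
  n <- nrow(pairs)
  counts <- c(n_co_down = sum(pairs$pattern == "co_down"),
              n_co_up = sum(pairs$pattern == "co_up"),
              n_opposite = sum(pairs$pattern == "opposite"))
  if (n >= 2 && stats::sd(pairs$lnc_log2fc) > 0 &&
      stats::sd(pairs$mrna_log2fc) > 0) {
    if (n >= 3) {
      ct <- cor.test(pairs$lnc_log2fc, pairs$mrna_log2fc,
                     method = "pearson", alternative = "two.sided")
      r <- unname(ct$estimate); pv <- ct$p.value
    } else {
      # two points define r but leave no degrees of freedom for p
      r <- stats::cor(pairs$lnc_log2fc, pairs$mrna_log2fc)
      pv <- NA_real_
    }
  } else {
    r <- NA_real_; pv <- NA_real_
  }
  structure(list(comparison = comparison, n_pairs = n,
                 n_co_down = unname(counts["n_co_down"]),
                 n_co_up = unname(counts["n_co_up"]),
                 n_opposite = unname(counts["n_opposite"]),
                 pearson_r = r, p_two_tailed = pv),
            class = "cis_summary")
}

#' @export
print.cis_summary <- function(x, ...) {
  cat("CIS pair summary", if (!is.na(x$comparison)) paste0("(", x$comparison, ")"),
      "\n  pairs:", x$n_pairs,
      "= co-down", x$n_co_down, "+ co-up", x$n_co_up,
      "+ opposite", x$n_opposite, "\n")
  if (!is.na(x$pearson_r))
    cat(sprintf("  Pearson r = %.4f, two-tailed p = %.3g\n",
                x$pearson_r, x$p_two_tailed))
  invisible(x)
}
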