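# Differential expression: ratio-of-means fold changes, a Welch-t
# stand-in significance test with BH correction, the study's threshold
# presets, and right-tailed Fisher gene-set enrichment.

#' Construct a validated expression matrix
#'
#' Transcripts-by-samples abundance container (FPKM or any nonnegative
#' normalized expression) with per-sample group labels and replicate
#' indices.
#'
#' @param values numeric matrix, transcripts in rows (rownames =
#'   transcript ids), samples in columns.
#' @param samples data.frame with columns sample, group, replicate;
#'   rows aligned with `colnames(values)`.
#' @return object of class `"expression_matrix"` (list with `values`,
#'   `samples`).
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)))
    stop_cislnc("values must have transcript ids as rownames")
  if (nrow(values) < 1) stop_cislnc("at least one transcript required")
  if (any(values < 0)) stop_cislnc("expression values must be >= 0")
  if (!all(c("sample", "group", "replicate") %in% names(samples)))
    stop_cislnc("samples needs columns sample, group, replicate")
  if (nrow(samples) != ncol(values))
    stop_cislnc("samples rows must match value columns")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(samples$sample)))
    stop_cislnc("colnames(values) disagree with samples$sample")
  colnames(values) <- samples$sample
  if (anyNA(samples$group)) stop_cislnc("every sample needs a group")
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples;",
      "groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

group_columns <- function(mat, group) {
  idx <- which(mat$samples$group == group)
  if (length(idx) == 0) stop_cislnc("group not present: ", group)
  idx
}

#' Per-transcript log2 fold change between two groups
#'
#' Ratio-of-group-means definition:
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, finite for
#' any positive pseudocount. With `pseudocount = 0` and a zero group
#' mean the result is infinite/undefined and a warning is raised.
#'
#' @param mat an [expression_matrix()].
#' @param group_a reference group (denominator).
#' @param group_b treatment group (numerator).
#' @param pseudocount nonnegative stabilizer added to both means.
#' @return named numeric vector of log2 fold changes (B vs A).
#' @export
compute_log2fc <- function(mat, group_a, group_b, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  ia <- group_columns(mat, group_a)
  ib <- group_columns(mat, group_b)
  ma <- rowMeans(mat$values[, ia, drop = FALSE])
  mb <- rowMeans(mat$values[, ib, drop = FALSE])
  lfc <- log2((mb + pseudocount) / (ma + pseudocount))
  if (pseudocount == 0 && any(ma == 0 | mb == 0))
    warning("zero group mean with pseudocount 0: ",
            "infinite/undefined log2 fold change emitted", call. = FALSE)
  lfc
}

# Vectorized two-sample t over matrix rows; pooled-variance Student's t
# by default (exactly calibrated for the homoscedastic log2 noise
# model), Welch with var_equal = FALSE. Zero-variance conventions:
# equal means -> p = 1; different means -> p = 0.
ttest_rows <- function(xa, xb, var_equal = TRUE) {
  n1 <- ncol(xa); n2 <- ncol(xb)
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- apply(xa, 1, stats::var); v2 <- apply(xb, 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- rep(NA_real_, length(m1))
  zero <- se2 == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  ok <- !zero
  if (any(ok)) {
    tstat <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
    p[ok] <- 2 * pt(-abs(tstat), df[ok])
  }
  p
}

#' Differential-expression test between two groups
#'
#' Stand-in per-transcript test: a two-sample t-test on
#' `log2(value + pseudocount)` replicates, with Benjamini-Hochberg
#' adjustment across all status-`OK` transcripts of the comparison. The
#' default is the pooled-variance Student's t, which is exactly
#' calibrated for homoscedastic log-scale noise even at triplicate
#' depth; `var_equal = FALSE` switches to Welch's t for unequal
#' variances. Transcripts with fewer than two replicates in either
#' group get status `LOWDATA` and no q. Identical zero-variance groups
#' give p = 1 by convention.
#'
#' @inheritParams compute_log2fc
#' @param var_equal pool the group variances (Student's t) instead of
#'   Welch's approximation.
#' @return data.frame of per-transcript results with columns
#'   transcript_id, comparison, log2fc, fold_change, p, q, status.
#' @export
test_de <- function(mat, group_a, group_b, pseudocount = 1,
                    var_equal = TRUE) {
  ia <- group_columns(mat, group_a)
  ib <- group_columns(mat, group_b)
  status <- if (length(ia) >= 2 && length(ib) >= 2) "OK" else "LOWDATA"
  lfc <- compute_log2fc(mat, group_a, group_b, pseudocount)
  la <- log2(mat$values[, ia, drop = FALSE] + pseudocount)
  lb <- log2(mat$values[, ib, drop = FALSE] + pseudocount)
  p <- if (status == "OK") ttest_rows(la, lb, var_equal) else NA_real_
  res <- data.frame(
    transcript_id = rownames(mat$values),
    comparison = comparison_label(group_b, group_a),
    log2fc = unname(lfc), fold_change = unname(2 ^ lfc),
    p = p, q = NA_real_, status = status,
    stringsAsFactors = FALSE)
  ok <- res$status == "OK"
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res
}

#' Threshold presets used across the analysis
#'
#' Four named rule sets, each encoding the inclusion rule verbatim as
#' its source states it (inclusive vs strict operators preserved):
#' \describe{
#'   \item{rnaseq_de}{fold change >= 2 (|log2fc| >= 1), q <= 0.05, and
#'     test status OK; the sequencing-level DE call.}
#'   \item{cis_screen}{|log2(fold change)| > 1.5 and p < 0.05; the CIS
#'     pre-screen (note this is a stronger fold cutoff, about 2.83x).}
#'   \item{ipa_upload}{fold change > 1.5 (|log2fc| > log2 1.5) and
#'     p < 0.05; the pathway-upload rule.}
#'   \item{plot_inclusion}{fold change > 1.5 OR p < 0.05; the
#'     permissive plotting rule.}
#' }
#'
#' @param name one of `"rnaseq_de"`, `"cis_screen"`, `"ipa_upload"`,
#'   `"plot_inclusion"`.
#' @return list of class `"threshold_preset"`.
#' @export
threshold_preset <- function(name = c("rnaseq_de", "cis_screen",
                                      "ipa_upload", "plot_inclusion")) {
  name <- match.arg(name)
  preset <- switch(name,
    rnaseq_de = list(min_abs_log2fc = 1, fc_strict = FALSE,
                     max_q = 0.05, max_p = NULL, p_strict = FALSE,
                     combine = "AND", require_status_ok = TRUE),
    cis_screen = list(min_abs_log2fc = 1.5, fc_strict = TRUE,
                      max_q = NULL, max_p = 0.05, p_strict = TRUE,
                      combine = "AND", require_status_ok = FALSE),
    ipa_upload = list(min_abs_log2fc = log2(1.5), fc_strict = TRUE,
                      max_q = NULL, max_p = 0.05, p_strict = TRUE,
                      combine = "AND", require_status_ok = FALSE),
    plot_inclusion = list(min_abs_log2fc = log2(1.5), fc_strict = TRUE,
                          max_q = NULL, max_p = 0.05, p_strict = TRUE,
                          combine = "OR", require_status_ok = FALSE))
  preset$name <- name
  class(preset) <- "threshold_preset"
  preset
}

#' Filter DE results by a threshold preset
#'
#' Applies a [threshold_preset()] to one comparison's results and
#' partitions the survivors into up- (log2fc > 0) and down-regulated
#' (log2fc < 0) sets.
#'
#' @param results data.frame from [test_de()] (one comparison only).
#' @param preset a [threshold_preset()] or its name.
#' @return list with `results` (surviving rows), `n_up`, `n_down`,
#'   `n_total`, `up_ids`, `down_ids`.
#' @export
filter_de <- function(results, preset) {
  if (is.character(preset)) preset <- threshold_preset(preset)
  if (length(unique(results$comparison)) > 1)
    stop_cislnc("results mix comparisons; filter one comparison at a time")
  fc_pass <- if (preset$fc_strict)
    abs(results$log2fc) > preset$min_abs_log2fc
  else abs(results$log2fc) >= preset$min_abs_log2fc
  pq <- if (!is.null(preset$max_q)) {
    if (preset$p_strict) results$q < preset$max_q
    else results$q <= preset$max_q
  } else {
    if (preset$p_strict) results$p < preset$max_p
    else results$p <= preset$max_p
  }
  pq[is.na(pq)] <- FALSE
  keep <- if (preset$combine == "AND") fc_pass & pq else fc_pass | pq
  if (preset$require_status_ok) keep <- keep & results$status == "OK"
  out <- results[keep, , drop = FALSE]
  list(results = out,
       n_up = sum(out$log2fc > 0), n_down = sum(out$log2fc < 0),
       n_total = nrow(out),
       up_ids = out$transcript_id[out$log2fc > 0],
       down_ids = out$transcript_id[out$log2fc < 0])
}

#' Right-tailed Fisher gene-set enrichment
#'
#' For each gene set, tests over-representation of `de_set` inside the
#' universe with the hypergeometric right tail
#' `P(X >= overlap)` (identical to a one-sided Fisher exact test).
#' Gene sets are intersected with the universe before testing.
#'
#' @param de_set character vector of selected ids (subset of universe).
#' @param universe character vector of all testable ids.
#' @param gene_sets named list of character vectors.
#' @return data.frame: set, overlap, set_size, de_size, universe_size,
#'   p, neg_log10_p.
#' @export
enrichment_fisher <- function(de_set, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_cislnc("empty universe")
  de_set <- unique(de_set)
  if (!all(de_set %in% universe))
    stop_cislnc("de_set must be a subset of the universe")
  N <- length(universe); n <- length(de_set)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(gs)
    k <- length(intersect(gs, de_set))
    # right tail including the observed count
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, de_size = n,
               universe_size = N, p = p, neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
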