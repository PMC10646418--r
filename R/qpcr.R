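# Relative quantification of qPCR data: reference normalization (delta
# Ct), delta-delta-Ct fold changes with replicate-level t-tests, and the
# fold-regulation transform.

#' Normalize cycle thresholds against reference genes
#'
#' Per sample, subtracts the arithmetic mean of the reference-target Cts
#' from every target Ct. On the quantity scale this normalizes each
#' target by the geometric mean of the reference quantities (the
#' standard multi-reference scheme, e.g. GAPDH + ACTB); a single
#' reference gives plain single-gene normalization.
#'
#' @param plate data.frame with columns target, sample, group,
#'   replicate, ct (NA = not detected).
#' @param reference_targets character vector of reference gene names.
#' @return data.frame (target, sample, group, replicate, dct) for all
#'   non-reference targets; detected Cts only, absent Cts propagate NA.
#' @export
normalize_ct <- function(plate, reference_targets = c("GAPDH", "ACTB")) {
  stopifnot(all(c("target", "sample", "group", "replicate", "ct")
                %in% names(plate)))
  if (length(reference_targets) == 0)
    stop_cislnc("at least one reference target required")
  out <- plate[!plate$target %in% reference_targets, , drop = FALSE]
  ref_mean <- numeric(0)
  for (s in unique(plate$sample)) {
    for (rt in reference_targets) {
      ct <- plate$ct[plate$sample == s & plate$target == rt]
      if (length(ct) == 0 || anyNA(ct))
        stop_cislnc("missing reference Ct: sample '", s,
                    "', reference '", rt, "'")
    }
    ref_mean[s] <- mean(plate$ct[plate$sample == s &
                                   plate$target %in% reference_targets])
  }
  out$dct <- out$ct - ref_mean[out$sample]
  out$ct <- NULL
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-replicate `2^-ddCt` values for the treatment arm against
#' the calibrator-arm mean dCt, transforms the calibrator replicates
#' against their own mean (so their expected value is 1), and compares
#' the two sets of `2^-ddCt` values with a Student's t-test (paired for
#' donor-matched designs). The fold change is the mean treatment
#' `2^-ddCt`; zero-variance identical arms give p = 1 by convention.
#'
#' @param dct_treatment,dct_calibrator numeric replicate dCt values
#'   (>= 2 each; equal lengths when `paired`).
#' @param paired use a paired t-test.
#' @param target,comparison optional labels carried into the result.
#' @return list of class `"relative_expression"`: target, comparison,
#'   ddct, replicate_2neg_ddct, calibrator_2neg_ddct, fold_change, se,
#'   fold_regulation, p, paired, n_replicates.
#' @export
relative_expression <- function(dct_treatment, dct_calibrator,
                                paired = FALSE, target = NA_character_,
                                comparison = NA_character_) {
  if (length(dct_treatment) < 2 || length(dct_calibrator) < 2)
    stop_cislnc("at least two replicates per arm required")
  if (paired && length(dct_treatment) != length(dct_calibrator))
    stop_cislnc("paired test needs equal replicate counts")
  if (anyNA(dct_treatment) || anyNA(dct_calibrator))
    stop_cislnc("absent dCt among replicates; make detection calls first")
  cal_mean <- mean(dct_calibrator)
  ddct_t <- dct_treatment - cal_mean
  ddct_c <- dct_calibrator - cal_mean
  rel_t <- 2 ^ -ddct_t
  rel_c <- 2 ^ -ddct_c
  fc <- mean(rel_t)
  se <- sd(rel_t) / sqrt(length(rel_t))
  diffs <- if (paired) rel_t - rel_c else NULL
  zero_var <- if (paired) sd(diffs) == 0 else
    sd(rel_t) == 0 && sd(rel_c) == 0
  if (zero_var) {
    same <- if (paired) all(diffs == 0) else rel_t[1] == rel_c[1]
    p <- if (same) 1 else 0
  } else {
    p <- if (paired) t.test(rel_t, rel_c, paired = TRUE)$p.value
    else t.test(rel_t, rel_c, var.equal = TRUE)$p.value
  }
  structure(list(target = target, comparison = comparison,
                 ddct = mean(ddct_t),
                 replicate_2neg_ddct = rel_t,
                 calibrator_2neg_ddct = rel_c,
                 fold_change = fc, se = se,
                 fold_regulation = fold_regulation(fc),
                 p = p, paired = paired,
                 n_replicates = length(rel_t)),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf(
    "relative expression%s%s: fold change %.4g (fold regulation %.4g), p = %.3g [%s t-test, n = %d]\n",
    if (is.na(x$target)) "" else paste0(" of ", x$target),
    if (is.na(x$comparison)) "" else paste0(" (", x$comparison, ")"),
    x$fold_change, x$fold_regulation, x$p,
    if (x$paired) "paired" else "unpaired", x$n_replicates))
  invisible(x)
}

#' Fold regulation (signed fold change)
#'
#' Identity for fold changes at or above 1; the negative inverse below 1
#' (e.g. 0.25 becomes -4), so magnitude always reads as a multiple.
#'
#' @param fold_change positive fold change(s).
#' @return signed fold regulation, `|value| >= 1`.
#' @export
fold_regulation <- function(fold_change) {
  if (any(fold_change <= 0))
    stop_cislnc("fold change must be positive")
  ifelse(fold_change >= 1, fold_change, -1 / fold_change)
}

#' Expression on the 2^-dCt scale
#'
#' Transforms reference-normalized Ct values to the relative expression
#' scale used for tissue-panel plots; strictly decreasing in dCt.
#'
#' @param dct numeric dCt values.
#' @return `2^-dct`.
#' @export
expression_2negdct <- function(dct) 2 ^ -dct
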