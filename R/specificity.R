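# Tissue specificity and expression-pattern calls: islet ranking, the
# more-than-double islet-specificity rule, graft pattern classification,
# qPCR detection calls, and nuclear/cytoplasmic localization calls.

panel_tissue_columns <- function(panel, focal_tissue) {
  tissues <- setdiff(names(panel), "transcript_id")
  if (!focal_tissue %in% tissues)
    stop_cislnc("focal tissue not in panel: ", focal_tissue)
  if (length(tissues) < 2)
    stop_cislnc("panel needs at least one non-focal tissue")
  vals <- as.matrix(panel[, tissues, drop = FALSE])
  if (any(vals < 0)) stop_cislnc("panel values must be >= 0")
  list(tissues = tissues, values = vals)
}

#' Rank transcripts by focal-tissue expression
#'
#' Orders a tissue panel descending by expression in the focal tissue
#' (ties broken lexicographically by transcript id) and returns the top
#' of the ranking, as used to shortlist islet-enriched candidates.
#'
#' @param panel data.frame with a `transcript_id` column and one numeric
#'   column per tissue.
#' @param top_n how many transcripts to return (default: all).
#' @param focal_tissue the ranking tissue (default `"islet"`).
#' @return character vector of transcript ids, highest expression first.
#' @export
rank_by_focal_expression <- function(panel, top_n = nrow(panel),
                                     focal_tissue = "islet") {
  pc <- panel_tissue_columns(panel, focal_tissue)
  if (top_n > nrow(panel))
    stop_cislnc("top_n exceeds the number of transcripts")
  ord <- order(-pc$values[, focal_tissue], panel$transcript_id)
  head(panel$transcript_id[ord], top_n)
}

#' Call islet specificity with the more-than-double rule
#'
#' A transcript is islet-specific when its focal-tissue expression is
#' strictly more than `factor` (default 2) times the highest expression
#' among all other tissues. If every other tissue is 0 and the focal
#' value is positive the call is specific with an infinite ratio; a
#' focal value of 0 is never specific.
#'
#' @inheritParams rank_by_focal_expression
#' @param factor specificity multiple (default 2, the study's
#'   more-than-double rule).
#' @return data.frame: transcript_id, focal_expr, max_other_expr,
#'   max_other_tissue, ratio, is_specific, factor.
#' @export
islet_specificity_call <- function(panel, factor = 2,
                                   focal_tissue = "islet") {
  pc <- panel_tissue_columns(panel, focal_tissue)
  other <- setdiff(pc$tissues, focal_tissue)
  ov <- pc$values[, other, drop = FALSE]
  focal <- pc$values[, focal_tissue]
  max_other <- apply(ov, 1, max)
  max_tissue <- other[apply(ov, 1, which.max)]
  ratio <- ifelse(max_other > 0, focal / max_other,
                  ifelse(focal > 0, Inf, NA_real_))
  data.frame(transcript_id = panel$transcript_id,
             focal_expr = unname(focal),
             max_other_expr = unname(max_other),
             max_other_tissue = max_tissue,
             ratio = unname(ratio),
             is_specific = unname(focal > factor * max_other & focal > 0),
             factor = factor,
             stringsAsFactors = FALSE)
}

#' Report focal/other expression ratios across a panel
#'
#' Exact focal-to-highest-other-tissue quotients per transcript, with
#' the minimum and maximum over the non-excluded rows. Rows with an
#' undefined ratio (highest other tissue 0) are flagged, excluded from
#' the min/max, and raise a warning.
#'
#' @inheritParams rank_by_focal_expression
#' @param exclude transcript ids left out of the min/max (still
#'   reported).
#' @return list with `ratios` (data.frame transcript_id, ratio,
#'   excluded, defined), `min_ratio`, `max_ratio`.
#' @export
specificity_ratio_report <- function(panel, exclude = character(0),
                                     focal_tissue = "islet") {
  calls <- islet_specificity_call(panel, factor = 2,
                                  focal_tissue = focal_tissue)
  defined <- is.finite(calls$ratio)
  excluded <- calls$transcript_id %in% exclude
  if (any(!defined & !excluded))
    warning("undefined ratio (zero in every other tissue) for: ",
            paste(calls$transcript_id[!defined & !excluded],
                  collapse = ", "), "; excluded from min/max",
            call. = FALSE)
  use <- defined & !excluded
  list(ratios = data.frame(transcript_id = calls$transcript_id,
                           ratio = calls$ratio, excluded = excluded,
                           defined = defined, stringsAsFactors = FALSE),
       min_ratio = if (any(use)) min(calls$ratio[use]) else NA_real_,
       max_ratio = if (any(use)) max(calls$ratio[use]) else NA_real_)
}

#' Classify the islet/PBS-graft/ALT-graft expression pattern
#'
#' Strict-chain classification of a transcript's expression across the
#' three conditions: `monotone_down` when islet > PBS > ALT strictly,
#' `monotone_up` when islet < PBS < ALT strictly, `other` for any tie or
#' non-monotone shape.
#'
#' @param islet,pbs,alt nonnegative expression values (vectorized).
#' @return character vector of patterns.
#' @export
classify_graft_pattern <- function(islet, pbs, alt) {
  if (any(c(islet, pbs, alt) < 0))
    stop_cislnc("expression values must be >= 0")
  ifelse(islet > pbs & pbs > alt, "monotone_down",
  ifelse(islet < pbs & pbs < alt, "monotone_up", "other"))
}

#' qPCR detection call from replicate cycle thresholds
#'
#' A target is undetected when every replicate Ct is absent or at/after
#' the cycle limit (inclusive, default 40), or when the dissociation
#' curve failed; otherwise detected.
#'
#' @param ct_values numeric replicate Cts (NA = no amplification).
#' @param max_cycles detection limit in cycles.
#' @param dissociation_ok single-product dissociation-curve flag.
#' @return `"detected"` or `"undetected"`.
#' @export
detection_call <- function(ct_values, max_cycles = 40,
                           dissociation_ok = TRUE) {
  if (!dissociation_ok) return("undetected")
  if (all(is.na(ct_values) | ct_values >= max_cycles)) "undetected"
  else "detected"
}

#' Subcellular localization call from fraction signals
#'
#' Two-signal fold rule over cytoplasmic and nuclear RNA-fraction
#' signals: nuclear if the nuclear signal exceeds `fold` times the
#' cytoplasmic one, cytoplasmic for the converse, otherwise both.
#'
#' @param cyto_signal,nuc_signal nonnegative signals, not both zero.
#' @param fold enrichment multiple (default 2).
#' @return `"nuclear"`, `"cytoplasmic"`, or `"both"`.
#' @export
localization_call <- function(cyto_signal, nuc_signal, fold = 2) {
  if (cyto_signal < 0 || nuc_signal < 0)
    stop_cislnc("signals must be >= 0")
  if (cyto_signal == 0 && nuc_signal == 0)
    stop_cislnc("both signals are zero; no call possible")
  if (nuc_signal > fold * cyto_signal) "nuclear"
  else if (cyto_signal > fold * nuc_signal) "cytoplasmic"
  else "both"
}
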