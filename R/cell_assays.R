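# Apoptosis quantification: TUNEL-positive beta-cell fractions and
# Annexin-V/PI flow-cytometry quadrant summaries.

#' TUNEL-positive beta-cell fractions
#'
#' Per islet/graft unit, the percentage of insulin-positive (beta) cells
#' that are TUNEL-positive; optional per-group aggregation (mean and
#' standard error) and a two-group t-test (paired for donor-matched
#' designs). Units with no beta cells are excluded with a warning.
#'
#' @param counts data.frame with columns unit_id, n_beta, n_tunel_beta
#'   and optionally group.
#' @param paired paired t-test for the two-group comparison (requires a
#'   `group` column with exactly two groups of equal size).
#' @return list with `per_unit` (counts + percent), `group_summary`
#'   (group, n, mean, se) or NULL, and `test` (list: groups, p) or NULL.
#' @export
tunel_fraction <- function(counts, paired = FALSE) {
  stopifnot(all(c("unit_id", "n_beta", "n_tunel_beta") %in% names(counts)))
  if (any(counts$n_tunel_beta > counts$n_beta) ||
      any(counts$n_beta < 0) || any(counts$n_tunel_beta < 0))
    stop_cislnc("need 0 <= n_tunel_beta <= n_beta")
  drop <- counts$n_beta == 0
  if (any(drop)) {
    warning("excluding units with no beta cells: ",
            paste(counts$unit_id[drop], collapse = ", "), call. = FALSE)
    counts <- counts[!drop, , drop = FALSE]
  }
  counts$percent <- 100 * counts$n_tunel_beta / counts$n_beta
  group_summary <- NULL
  test <- NULL
  if ("group" %in% names(counts)) {
    groups <- unique(counts$group)
    group_summary <- do.call(rbind, lapply(groups, function(g) {
      x <- counts$percent[counts$group == g]
      data.frame(group = g, n = length(x), mean = mean(x),
                 se = sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
    }))
    if (length(groups) == 2) {
      xa <- counts$percent[counts$group == groups[1]]
      xb <- counts$percent[counts$group == groups[2]]
      p <- if (paired) t.test(xa, xb, paired = TRUE)$p.value
      else t.test(xa, xb, var.equal = TRUE)$p.value
      test <- list(groups = groups, p = p, paired = paired)
    }
  }
  list(per_unit = counts, group_summary = group_summary, test = test)
}

#' Annexin-V/PI quadrant summary and apoptotic rate
#'
#' Partitions flow events into the four rectangular quadrants by the two
#' thresholds, or accepts precomputed quadrant counts, and reports
#' quadrant percentages plus the apoptotic rate (early + late apoptotic).
#'
#' Two quadrant labelings are supported. `"methods"` (default): early =
#' AnnexinV+/PI-, late = AnnexinV+/PI+, necrotic = AnnexinV-/PI+.
#' `"legend"`: the alternative labeling that swaps the two
#' double/PI-only quadrant names (necrotic = AnnexinV+/PI+, late =
#' AnnexinV-/PI+). The apoptotic rate is early + late under the chosen
#' labeling.
#'
#' @param events data.frame with numeric columns annexin and pi (one row
#'   per cell), or NULL when `counts` is given.
#' @param counts named numeric of precomputed quadrant counts
#'   (viable/early/late/necrotic), bypassing thresholding.
#' @param annexin_threshold,pi_threshold positive gate positions.
#' @param labeling `"methods"` or `"legend"` (see Details).
#' @return list of class `"quadrant_summary"`: counts, percent (both
#'   named over the four quadrants), n_events, apoptotic_rate (percent),
#'   thresholds, labeling.
#' @export
flow_quadrant_summary <- function(events = NULL, counts = NULL,
                                  annexin_threshold = 100,
                                  pi_threshold = 100,
                                  labeling = c("methods", "legend")) {
  labeling <- match.arg(labeling)
  labels <- c("viable", "early", "late", "necrotic")
  if (is.null(counts)) {
    if (is.null(events) || nrow(events) == 0)
      stop_cislnc("no events to summarize")
    if (annexin_threshold <= 0 || pi_threshold <= 0)
      stop_cislnc("thresholds must be positive")
    a_pos <- events$annexin > annexin_threshold
    p_pos <- events$pi > pi_threshold
    counts <- c(
      viable = sum(!a_pos & !p_pos),
      early = sum(a_pos & !p_pos),
      late = if (labeling == "methods") sum(a_pos & p_pos)
             else sum(!a_pos & p_pos),
      necrotic = if (labeling == "methods") sum(!a_pos & p_pos)
                 else sum(a_pos & p_pos))
  } else {
    if (!all(labels %in% names(counts)))
      stop_cislnc("counts must be named viable/early/late/necrotic")
    counts <- counts[labels]
  }
  n <- sum(counts)
  if (n == 0) stop_cislnc("no events to summarize")
  percent <- 100 * counts / n
  structure(list(counts = counts, percent = percent, n_events = n,
                 apoptotic_rate = unname(percent["early"] +
                                           percent["late"]),
                 thresholds = c(annexin = annexin_threshold,
                                pi = pi_threshold),
                 labeling = labeling),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat("flow quadrant summary (", x$n_events, " events, ",
      x$labeling, " labeling)\n", sep = "")
  for (q in names(x$percent))
    cat(sprintf("  %-9s %7d  %6.2f%%\n", q, x$counts[[q]],
                x$percent[[q]]))
  cat(sprintf("  apoptotic rate (early + late): %.2f%%\n",
              x$apoptotic_rate))
  invisible(x)
}
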