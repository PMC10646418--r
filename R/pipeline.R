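# End-to-end orchestration: synthetic data -> differential expression ->
# CIS pairing -> specificity -> qPCR -> apoptosis assays, with all
# tables, a JSON summary and a provenance log written to a run directory.

#' Pipeline configuration
#'
#' Global constants and stage toggles for [run_pipeline()]. Defaults
#' encode the analysis constants: 50-kb CIS screen radius,
#' more-than-double specificity factor, alpha 0.05, GAPDH/ACTB
#' references.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param truth a [truth_config()]; its seed is overridden by `seed`.
#' @param preset_de,preset_cis threshold preset names for the DE call
#'   and the CIS pre-screen.
#' @param max_distance CIS screen radius in bp.
#' @param specificity_factor specificity multiple.
#' @param focal_tissue focal tissue of the specificity panel.
#' @param reference_targets qPCR reference genes.
#' @param pseudocount fold-change stabilizer.
#' @param anchor lncRNA anchor mode for distances.
#' @param alpha significance level, in (0, 1).
#' @param flow_proportions planted quadrant proportions for the flow
#'   stage.
#' @param flow_events number of flow events to draw.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            truth = truth_config(seed = seed),
                            preset_de = "rnaseq_de",
                            preset_cis = "cis_screen",
                            max_distance = 50000,
                            specificity_factor = 2,
                            focal_tissue = "islet",
                            reference_targets = c("GAPDH", "ACTB"),
                            pseudocount = 1,
                            anchor = "nearest_edge",
                            alpha = 0.05,
                            flow_proportions = c(viable = 0.85,
                                                 early = 0.10,
                                                 late = 0.03,
                                                 necrotic = 0.02),
                            flow_events = 10000L) {
  if (alpha <= 0 || alpha >= 1) stop_cislnc("alpha must be in (0, 1)")
  truth$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), truth = truth,
                 preset_de = preset_de, preset_cis = preset_cis,
                 max_distance = max_distance,
                 specificity_factor = specificity_factor,
                 focal_tissue = focal_tissue,
                 reference_targets = reference_targets,
                 pseudocount = pseudocount, anchor = anchor,
                 alpha = alpha, flow_proportions = flow_proportions,
                 flow_events = as.integer(flow_events)),
            class = "pipeline_config")
}

log_line <- function(state, stage, message, ...) {
  entry <- list(stage = stage, message = message, ...)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = state$log_path, append = TRUE)
  invisible(entry)
}

run_stage <- function(state, stage, fun) {
  log_line(state, stage, "start")
  out <- tryCatch(fun(), error = function(e) {
    log_line(state, stage, paste("error:", conditionMessage(e)))
    stop_cislnc("pipeline stage '", stage, "' failed: ",
                conditionMessage(e))
  })
  log_line(state, stage, "done")
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Generates annotation and expression with planted truth, tests and
#' filters differential expression for every pairwise group comparison,
#' screens CIS pairs on the focal comparison, makes specificity and
#' graft-pattern calls, quantifies a planted qPCR plate, summarizes a
#' synthetic Annexin-V/PI experiment, and writes every table plus a
#' machine-readable `summary.json` and a JSON-lines provenance log to
#' `outdir`. Deterministic for a fixed config (including seed).
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return the summary list, invisibly; all artifacts are in `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log_path = file.path(outdir, "run_log.jsonl"))
  if (file.exists(state$log_path)) file.remove(state$log_path)
  log_line(state, "config", "parameters",
           seed = config$seed, max_distance = config$max_distance,
           specificity_factor = config$specificity_factor,
           alpha = config$alpha, preset_de = config$preset_de,
           preset_cis = config$preset_cis,
           pseudocount = config$pseudocount, anchor = config$anchor)

  cfg <- config$truth
  synth <- run_stage(state, "synth", function() {
    truth <- generate_annotation(cfg)
    expr <- generate_expression(truth, cfg)
    write_annotation(truth$annotation,
                     gtf_path = file.path(outdir, "annotation.gtf"),
                     bed_path = file.path(outdir, "annotation.bed"))
    write_tsv(truth$pair_truth, file.path(outdir, "pair_truth.tsv"))
    write_tsv(truth$de_truth, file.path(outdir, "de_truth.tsv"))
    write_expression_matrix(expr$matrix,
                            file.path(outdir, "expression.tsv"),
                            file.path(outdir, "samples.tsv"))
    write_tsv(expr$panel, file.path(outdir, "tissue_panel.tsv"))
    list(truth = truth, expr = expr)
  })
  ann <- synth$truth$annotation
  mat <- synth$expr$matrix
  groups <- cfg$groups
  contrasts <- list(c(groups[1], groups[2]),
                    c(groups[1], groups[3]),
                    c(groups[2], groups[3]))

  de <- run_stage(state, "de", function() {
    res <- list()
    for (ct in contrasts) {
      r <- test_de(mat, ct[1], ct[2], config$pseudocount)
      label <- comparison_label(ct[2], ct[1])
      write_de_table(r, file.path(outdir, paste0(
        "de_", gsub(" ", "_", label), ".tsv")))
      res[[label]] <- r
    }
    res
  })

  de_summary <- lapply(de, function(r) {
    biotype <- ann$biotype[match(r$transcript_id, ann$transcript_id)]
    f_m <- filter_de(r[biotype == "mRNA", ], config$preset_de)
    f_l <- filter_de(r[biotype == "lncRNA", ], config$preset_de)
    list(mrna = list(n_up = f_m$n_up, n_down = f_m$n_down,
                     n_total = f_m$n_total),
         lncrna = list(n_up = f_l$n_up, n_down = f_l$n_down,
                       n_total = f_l$n_total))
  })

  focal <- comparison_label(groups[3], groups[1])
  cis <- run_stage(state, "cis", function() {
    r <- de[[focal]]
    biotype <- ann$biotype[match(r$transcript_id, ann$transcript_id)]
    lnc <- filter_de(r[biotype == "lncRNA", ], config$preset_cis)$results
    mrna <- filter_de(r[biotype == "mRNA", ], config$preset_cis)$results
    pairs <- screen_cis_pairs(lnc, mrna, ann,
                              max_distance = config$max_distance,
                              anchor = config$anchor)
    write_pairs(pairs, ann,
                tsv_path = file.path(outdir, "cis_pairs.tsv"),
                bedpe_path = file.path(outdir, "cis_pairs.bedpe"))
    list(pairs = pairs, summary = summarize_pairs(pairs, focal))
  })

  spec <- run_stage(state, "specificity", function() {
    calls <- islet_specificity_call(synth$expr$panel,
                                    factor = config$specificity_factor,
                                    focal_tissue = config$focal_tissue)
    write_tsv(calls, file.path(outdir, "specificity_calls.tsv"))
    gm <- vapply(groups, function(g) rowMeans(
      mat$values[, mat$samples$group == g, drop = FALSE]), numeric(nrow(mat$values)))
    patterns <- data.frame(
      transcript_id = rownames(mat$values),
      pattern = classify_graft_pattern(gm[, groups[1]], gm[, groups[2]],
                                       gm[, groups[3]]),
      stringsAsFactors = FALSE)
    write_tsv(patterns, file.path(outdir, "graft_patterns.tsv"))
    list(calls = calls, patterns = patterns)
  })

  qpcr <- run_stage(state, "qpcr", function() {
    # plate planted with a 2-fold down and a 2-fold up target
    abundances <- data.frame(
      target = rep(c("TARGET_DOWN", "TARGET_UP"), each = 2),
      group = rep(c("control", "treated"), 2),
      abundance = c(64, 32, 64, 128), stringsAsFactors = FALSE)
    plate <- generate_qpcr_plate(abundances, cfg)
    write_tsv(plate, file.path(outdir, "qpcr_plate.tsv"))
    dct <- normalize_ct(plate, config$reference_targets)
    rows <- lapply(unique(dct$target), function(tg) {
      tr <- dct$dct[dct$target == tg & dct$group == "treated"]
      ca <- dct$dct[dct$target == tg & dct$group == "control"]
      re <- relative_expression(tr, ca, target = tg,
                                comparison = "treated vs control")
      data.frame(target = tg, comparison = re$comparison,
                 fold_change = re$fold_change,
                 fold_regulation = re$fold_regulation, se = re$se,
                 p = re$p, n_replicates = re$n_replicates,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    write_tsv(res, file.path(outdir, "qpcr_results.tsv"))
    res
  })

  assays <- run_stage(state, "assays", function() {
    events <- generate_flow_events(config$flow_proportions,
                                   config$flow_events,
                                   seed = config$seed + 3L)
    write.table(events, file.path(outdir, "flow_events.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    flow <- flow_quadrant_summary(events)
    tunel <- tunel_fraction(data.frame(
      unit_id = paste0("islet", 1:6),
      group = rep(c("cytokine", "control"), each = 3),
      n_beta = c(100, 100, 200, 100, 200, 200),
      n_tunel_beta = c(24, 26, 53, 7, 15, 15)))
    list(flow = flow, tunel = tunel)
  })

  summary <- list(
    seed = config$seed,
    de = de_summary,
    cis = list(comparison = focal,
               n_pairs = cis$summary$n_pairs,
               n_co_down = cis$summary$n_co_down,
               n_co_up = cis$summary$n_co_up,
               n_opposite = cis$summary$n_opposite,
               pearson_r = cis$summary$pearson_r,
               p_two_tailed = cis$summary$p_two_tailed),
    specificity = list(
      n_specific = sum(spec$calls$is_specific),
      specific_ids = spec$calls$transcript_id[spec$calls$is_specific],
      pattern_counts = as.list(table(spec$patterns$pattern))),
    qpcr = qpcr,
    assays = list(
      apoptotic_rate = assays$flow$apoptotic_rate,
      quadrant_percent = as.list(assays$flow$percent),
      tunel_group_means = if (!is.null(assays$tunel$group_summary))
        setNames(as.list(assays$tunel$group_summary$mean),
                 assays$tunel$group_summary$group) else NULL,
      tunel_p = assays$tunel$test$p))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(state, "summary", "written")
  invisible(summary)
}
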