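# Synthetic-data generator: annotation, expression, qPCR plates and
# flow-cytometry events with planted ground truth, so that every
# downstream stage of the pipeline can be tested against known answers.

#' Configuration for the synthetic-truth generator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults emulate the study design the package targets: three sample
#' groups (isolated human islets, PBS-treated islet grafts, ALT-treated
#' islet grafts), three biological replicates per group, log-normal FPKM
#' noise, lncRNA--mRNA pairs planted within 50 kb of an mRNA
#' transcription start site plus decoys beyond 50 kb, and a nine-tissue
#' human panel plus islet in which a subset of lncRNAs is made
#' islet-specific.
#'
#' @param seed integer seed; the same config (including seed) always
#'   produces byte-identical output.
#' @param n_mrna,n_lncrna number of mRNA / lncRNA transcripts.
#' @param n_pairs_planted number of true CIS pairs placed with
#'   `|TSS distance|` inside `pair_distance_range`.
#' @param pair_distance_range length-2 numeric, bp interval within
#'   (0, 50000] from which planted pair distances are drawn.
#' @param n_decoy_pairs lncRNAs placed 50,001--`decoy_max_distance` bp
#'   from the nearest differentially expressed mRNA TSS.
#' @param decoy_max_distance upper bound for decoy distances (bp).
#' @param n_antisense_pairs how many of the planted pairs overlap their
#'   mRNA on the opposite strand (distance 0, antisense flag set).
#' @param n_up,n_down planted up-/down-regulated mRNA counts in the
#'   focal comparison.
#' @param n_up_lnc,n_down_lnc planted up-/down-regulated lncRNA counts.
#' @param effect_log2fc planted absolute log2 fold change (> 0).
#' @param noise_sd_log2 replicate noise standard deviation on the log2
#'   scale (log-normal FPKM noise); 0 gives exact group means.
#' @param n_replicates replicates per group (>= 2).
#' @param groups character(3): reference group, control graft, treated
#'   graft; the planted effect separates `groups[3]` from `groups[1]`.
#' @param tissue_panel tissue labels for the specificity panel; the
#'   first entry is the focal tissue.
#' @param n_islet_specific lncRNAs planted as islet-specific in the
#'   panel.
#' @param specificity_factor_planted planted islet/max-other expression
#'   factor (> 2 so the study's more-than-double rule recovers them).
#' @param chrom_length synthetic chromosome length in bp, or `NULL` to
#'   size it automatically from the transcript count.
#' @param ct_intercept qPCR cycle threshold at unit abundance.
#' @param ct_max_cycles detection limit in cycles.
#'
#' @return A validated list of class `"truth_config"`.
#' @export
#' @examples
#' cfg <- truth_config(seed = 1, n_mrna = 40, n_lncrna = 20,
#'                     noise_sd_log2 = 0)
truth_config <- function(seed = 1L,
                         n_mrna = 300L,
                         n_lncrna = 150L,
                         n_pairs_planted = 5L,
                         pair_distance_range = c(1000L, 40000L),
                         n_decoy_pairs = 3L,
                         decoy_max_distance = 150000L,
                         n_antisense_pairs = 0L,
                         n_up = 20L,
                         n_down = 20L,
                         n_up_lnc = 10L,
                         n_down_lnc = 10L,
                         effect_log2fc = 2.5,
                         noise_sd_log2 = 0.25,
                         n_replicates = 3L,
                         groups = c("Islet", "PBS", "ALT"),
                         tissue_panel = c("islet", "brain", "heart",
                                          "kidney", "liver", "lung",
                                          "colon", "thyroid", "testes",
                                          "placenta"),
                         n_islet_specific = 10L,
                         specificity_factor_planted = 4,
                         chrom_length = NULL,
                         ct_intercept = 35,
                         ct_max_cycles = 40) {
  cfg <- list(seed = as.integer(seed), n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna),
              n_pairs_planted = as.integer(n_pairs_planted),
              pair_distance_range = as.numeric(pair_distance_range),
              n_decoy_pairs = as.integer(n_decoy_pairs),
              decoy_max_distance = as.numeric(decoy_max_distance),
              n_antisense_pairs = as.integer(n_antisense_pairs),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              n_up_lnc = as.integer(n_up_lnc),
              n_down_lnc = as.integer(n_down_lnc),
              effect_log2fc = as.numeric(effect_log2fc),
              noise_sd_log2 = as.numeric(noise_sd_log2),
              n_replicates = as.integer(n_replicates),
              groups = as.character(groups),
              tissue_panel = as.character(tissue_panel),
              n_islet_specific = as.integer(n_islet_specific),
              specificity_factor_planted =
                as.numeric(specificity_factor_planted),
              chrom_length = if (is.null(chrom_length)) NULL
                             else as.numeric(chrom_length),
              ct_intercept = as.numeric(ct_intercept),
              ct_max_cycles = as.numeric(ct_max_cycles))
  validate_truth_config(cfg)
  class(cfg) <- "truth_config"
  cfg
}

validate_truth_config <- function(cfg) {
  stopifnot(cfg$n_mrna >= 1, cfg$n_lncrna >= 1,
            cfg$n_pairs_planted >= 0, cfg$n_decoy_pairs >= 0,
            cfg$effect_log2fc > 0, cfg$noise_sd_log2 >= 0,
            cfg$n_replicates >= 2, length(cfg$groups) == 3,
            cfg$specificity_factor_planted > 2,
            length(cfg$pair_distance_range) == 2)
  if (cfg$n_pairs_planted + cfg$n_decoy_pairs > cfg$n_lncrna)
    stop_cislnc("n_pairs_planted + n_decoy_pairs exceeds n_lncrna")
  if (cfg$n_up + cfg$n_down > cfg$n_mrna)
    stop_cislnc("planted DE mRNA count exceeds n_mrna")
  if (cfg$n_up_lnc + cfg$n_down_lnc > cfg$n_lncrna)
    stop_cislnc("planted DE lncRNA count exceeds n_lncrna")
  if (cfg$n_pairs_planted + cfg$n_decoy_pairs >
      cfg$n_up_lnc + cfg$n_down_lnc)
    stop_cislnc("planted pairs + decoys need at least as many DE lncRNAs")
  if (cfg$n_antisense_pairs > cfg$n_pairs_planted)
    stop_cislnc("n_antisense_pairs exceeds n_pairs_planted")
  r <- cfg$pair_distance_range
  if (r[1] < 0 || r[2] > 50000 || r[1] > r[2])
    stop_cislnc("pair_distance_range must lie within [0, 50000]")
  if (cfg$n_islet_specific > cfg$n_lncrna)
    stop_cislnc("n_islet_specific exceeds n_lncrna")
  if (!identical(tolower(cfg$tissue_panel[1]), "islet") &&
      !"islet" %in% cfg$tissue_panel)
    stop_cislnc("tissue_panel must contain the focal 'islet' tissue")
  invisible(cfg)
}

# One genomic slot per mRNA or orphan lncRNA keeps unrelated
# transcripts far apart, so the only pairs within 50 kb are planted.
SLOT_WIDTH <- 4e5

#' Generate a synthetic transcript annotation with planted CIS pairs
#'
#' Lays mRNAs and lncRNAs on one synthetic chromosome. Each planted
#' pair's lncRNA sits at a controlled signed distance (nearest edge to
#' the mRNA TSS, oriented by the mRNA strand) inside
#' `cfg$pair_distance_range`; decoy lncRNAs sit beyond 50 kb from every
#' differentially expressed mRNA TSS; all other transcripts occupy
#' isolated slots so no accidental pair can fall within 50 kb.
#'
#' @param cfg a [truth_config()].
#' @return list with elements `annotation` (data.frame: transcript_id,
#'   gene_id, biotype, chrom, start, end, strand; 0-based half-open
#'   coordinates), `pair_truth` (data.frame: lnc_id, mrna_id,
#'   signed_distance, is_decoy, antisense), and `de_truth` (data.frame:
#'   transcript_id, biotype, comparison, direction).
#' @export
generate_annotation <- function(cfg) {
  validate_truth_config(cfg)
  set.seed(cfg$seed)
  n_slots <- cfg$n_mrna + cfg$n_lncrna
  needed <- SLOT_WIDTH * (n_slots + 1)
  chrom_length <- cfg$chrom_length %||% needed
  if (chrom_length < needed)
    stop_cislnc("infeasible placement: ", n_slots, " transcripts need ",
                format(needed, scientific = FALSE), " bp but chrom_length is ",
                format(chrom_length, scientific = FALSE))

  mrna_id <- sprintf("MRNA%04d", seq_len(cfg$n_mrna))
  lnc_id  <- sprintf("LNC%04d", seq_len(cfg$n_lncrna))

  # planted DE identities: first ids carry the effect; directions are
  # interleaved so planted pairs cover all co-regulation patterns
  interleave_dirs <- function(n_up, n_down) {
    d <- character(n_up + n_down)
    u <- 0L; v <- 0L
    for (i in seq_along(d)) {
      if ((i %% 2 == 1 && u < n_up) || v >= n_down) {
        d[i] <- "up"; u <- u + 1L
      } else {
        d[i] <- "down"; v <- v + 1L
      }
    }
    d
  }
  n_de_m <- cfg$n_up + cfg$n_down
  n_de_l <- cfg$n_up_lnc + cfg$n_down_lnc
  de_mrna <- data.frame(
    transcript_id = mrna_id[seq_len(n_de_m)],
    biotype = rep("mRNA", n_de_m),
    direction = interleave_dirs(cfg$n_up, cfg$n_down),
    stringsAsFactors = FALSE)
  de_lnc <- data.frame(
    transcript_id = lnc_id[seq_len(n_de_l)],
    biotype = rep("lncRNA", n_de_l),
    direction = interleave_dirs(cfg$n_up_lnc, cfg$n_down_lnc),
    stringsAsFactors = FALSE)
  de_truth <- rbind(de_mrna, de_lnc)
  de_truth$comparison <- rep(comparison_label(cfg$groups[3], cfg$groups[1]),
                             nrow(de_truth))

  # mRNA placement: one slot each; the offset leaves room upstream of
  # the first slot for the farthest decoy
  if (cfg$decoy_max_distance + 55000 > SLOT_WIDTH)
    stop_cislnc("decoy_max_distance too large for the slot layout")
  base_offset <- cfg$decoy_max_distance + 10000
  mrna_len <- round(runif(cfg$n_mrna, 1500, 3000))
  mrna_start <- (seq_len(cfg$n_mrna) - 1) * SLOT_WIDTH + base_offset
  mrna_strand <- rep(c("+", "-"), length.out = cfg$n_mrna)
  mrna <- data.frame(transcript_id = mrna_id,
                     gene_id = sub(":.*$", "", mrna_id),
                     biotype = "mRNA", chrom = "chrS",
                     start = mrna_start, end = mrna_start + mrna_len,
                     strand = mrna_strand, stringsAsFactors = FALSE)

  lnc_len <- round(runif(cfg$n_lncrna, 500, 2000))
  lnc_strand <- rep(c("-", "+"), length.out = cfg$n_lncrna)
  lnc_start <- numeric(cfg$n_lncrna)

  n_paired <- cfg$n_pairs_planted
  n_decoy <- cfg$n_decoy_pairs
  # paired/decoy lncRNAs anchor on DE mRNAs; DE mRNAs are the first ids
  if (n_paired + n_decoy > nrow(de_mrna))
    stop_cislnc("not enough planted DE mRNAs to host pairs and decoys")
  host <- seq_len(n_paired + n_decoy)

  pair_truth <- data.frame(lnc_id = character(0), mrna_id = character(0),
                           signed_distance = numeric(0),
                           is_decoy = logical(0), antisense = logical(0),
                           stringsAsFactors = FALSE)
  tss <- ifelse(mrna$strand == "+", mrna$start, mrna$end - 1)

  place_lnc_at <- function(i, m, d) {
    # nearest-edge signed distance d (mRNA-orientation; downstream > 0)
    g <- if (mrna$strand[m] == "+") d else -d  # genomic offset
    if (g > 0) {           # lncRNA genomically right of the TSS
      lnc_start[i] <<- tss[m] + g
    } else {               # genomically left: gap measured to lnc end
      lnc_start[i] <<- tss[m] + g - lnc_len[i]
    }
  }

  i_lnc <- 0L
  for (k in seq_len(n_paired)) {
    i_lnc <- i_lnc + 1L
    m <- host[k]
    if (k <= cfg$n_antisense_pairs) {
      # overlap the mRNA TSS on the opposite strand -> distance 0
      lnc_strand[i_lnc] <- if (mrna$strand[m] == "+") "-" else "+"
      lnc_start[i_lnc] <- tss[m] - floor(lnc_len[i_lnc] / 2)
      d <- 0
      anti <- TRUE
    } else {
      mag <- round(runif(1, cfg$pair_distance_range[1],
                         cfg$pair_distance_range[2]))
      d <- mag * sample(c(-1, 1), 1)
      place_lnc_at(i_lnc, m, d)
      anti <- FALSE
    }
    pair_truth <- rbind(pair_truth, data.frame(
      lnc_id = lnc_id[i_lnc], mrna_id = mrna_id[m],
      signed_distance = d, is_decoy = FALSE, antisense = anti,
      stringsAsFactors = FALSE))
  }
  for (k in seq_len(n_decoy)) {
    i_lnc <- i_lnc + 1L
    m <- host[n_paired + k]
    mag <- round(runif(1, 50001, cfg$decoy_max_distance))
    d <- mag * sample(c(-1, 1), 1)
    place_lnc_at(i_lnc, m, d)
    pair_truth <- rbind(pair_truth, data.frame(
      lnc_id = lnc_id[i_lnc], mrna_id = mrna_id[m],
      signed_distance = d, is_decoy = TRUE, antisense = FALSE,
      stringsAsFactors = FALSE))
  }
  # remaining lncRNAs get their own isolated slots after the mRNA block
  n_rest <- cfg$n_lncrna - i_lnc
  if (n_rest > 0) {
    rest <- seq(i_lnc + 1L, cfg$n_lncrna)
    lnc_start[rest] <-
      (cfg$n_mrna + seq_len(n_rest) - 1) * SLOT_WIDTH + base_offset
  }
  lnc <- data.frame(transcript_id = lnc_id,
                    gene_id = sub(":[0-9]+$", "", lnc_id),
                    biotype = "lncRNA", chrom = "chrS",
                    start = lnc_start, end = lnc_start + lnc_len,
                    strand = lnc_strand, stringsAsFactors = FALSE)
  annotation <- rbind(mrna, lnc)
  rownames(annotation) <- NULL
  if (any(annotation$start < 0))
    stop_cislnc("infeasible placement: a planted lncRNA fell before ",
                "the chromosome origin; increase transcript spacing")
  list(annotation = annotation, pair_truth = pair_truth,
       de_truth = de_truth)
}

#' Generate synthetic expression with planted differential expression
#'
#' Draws replicate FPKM values as log-normal noise around per-group
#' means. Group means of planted DE transcripts differ by exactly
#' `effect_log2fc` between the treated and reference groups; the control
#' graft group shares the reference mean so the planted effect lives in
#' one focal comparison. Also emits a tissue panel in which the first
#' `n_islet_specific` lncRNAs exceed `specificity_factor_planted` times
#' every non-islet tissue.
#'
#' @param truth output of [generate_annotation()].
#' @param cfg the same [truth_config()].
#' @return list with `matrix` (an [expression_matrix()]), `panel`
#'   (data.frame: transcript_id + one column per tissue), `de_truth`,
#'   and `specific_truth` (character vector of planted islet-specific
#'   ids).
#' @export
generate_expression <- function(truth, cfg) {
  validate_truth_config(cfg)
  ann <- truth$annotation
  set.seed(cfg$seed + 1L)
  n <- nrow(ann)
  base_log2 <- runif(n, 3, 9)
  names(base_log2) <- ann$transcript_id

  dir <- setNames(rep(0, n), ann$transcript_id)
  dt <- truth$de_truth
  dir[dt$transcript_id] <- ifelse(dt$direction == "up", 1, -1)

  groups <- cfg$groups
  nrep <- cfg$n_replicates
  samples <- data.frame(
    sample = paste0(rep(groups, each = nrep), "_",
                    rep(seq_len(nrep), times = length(groups))),
    group = rep(groups, each = nrep),
    replicate = rep(seq_len(nrep), times = length(groups)),
    stringsAsFactors = FALSE)

  # group means on log2 scale; effect carried by groups[3] vs groups[1]
  mean_log2 <- cbind(base_log2, base_log2,
                     base_log2 + dir * cfg$effect_log2fc)
  colnames(mean_log2) <- groups

  vals <- matrix(0, nrow = n, ncol = nrow(samples),
                 dimnames = list(ann$transcript_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- mean_log2[, samples$group[j]]
    vals[, j] <- 2 ^ (mu + rnorm(n, 0, cfg$noise_sd_log2))
  }

  # tissue panel: planted islet-specific lncRNAs plus non-specific rows
  tissues <- cfg$tissue_panel
  other <- setdiff(tissues, tissues[1])
  lnc_ids <- ann$transcript_id[ann$biotype == "lncRNA"]
  spec_ids <- head(lnc_ids, cfg$n_islet_specific)
  panel_ids <- head(lnc_ids, min(length(lnc_ids),
                                 cfg$n_islet_specific + 20L))
  pv <- matrix(0, nrow = length(panel_ids), ncol = length(tissues),
               dimnames = list(panel_ids, tissues))
  for (id in panel_ids) {
    ov <- 2 ^ runif(length(other), 0, 3)
    pv[id, other] <- ov
    pv[id, tissues[1]] <-
      if (id %in% spec_ids)
        cfg$specificity_factor_planted * max(ov) * 1.02
      else stats::median(ov)
  }
  panel <- data.frame(transcript_id = panel_ids, pv,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)

  list(matrix = expression_matrix(vals, samples),
       panel = panel, de_truth = truth$de_truth,
       specific_truth = spec_ids)
}

#' Generate a synthetic qPCR plate from planted abundances
#'
#' Emits well-level cycle thresholds under the standard exponential
#' amplification model `Ct = intercept - log2(abundance) + noise`.
#' Reference genes (GAPDH and ACTB by default) are planted with
#' group-constant abundance. Abundance 0 or a Ct beyond the detection
#' limit is emitted as an absent (`NA`) Ct.
#'
#' @param abundances data.frame with columns target, group, abundance
#'   (relative quantity, >= 0).
#' @param cfg a [truth_config()] (supplies seed, replicate count,
#'   Ct intercept, detection limit).
#' @param ct_noise_sd Gaussian noise on the Ct scale (cycles).
#' @param reference_targets reference genes to plant; set to character(0)
#'   if `abundances` already contains them.
#' @param reference_abundance named abundances for the references.
#' @return data.frame: target, sample, group, replicate, ct (NA = not
#'   detected).
#' @export
generate_qpcr_plate <- function(abundances, cfg, ct_noise_sd = 0.15,
                                reference_targets = c("GAPDH", "ACTB"),
                                reference_abundance =
                                  c(GAPDH = 1024, ACTB = 512)) {
  stopifnot(all(c("target", "group", "abundance") %in% names(abundances)))
  if (any(abundances$abundance < 0))
    stop_cislnc("abundances must be nonnegative")
  set.seed(cfg$seed + 2L)
  groups <- unique(abundances$group)
  for (rt in reference_targets) {
    ab <- reference_abundance[[rt]] %||% 1024
    abundances <- rbind(abundances, data.frame(
      target = rt, group = groups, abundance = ab,
      stringsAsFactors = FALSE))
  }
  nrep <- cfg$n_replicates
  rows <- abundances[rep(seq_len(nrow(abundances)), each = nrep), ]
  rows$replicate <- rep(seq_len(nrep), times = nrow(abundances))
  rows$sample <- paste0(rows$group, "_", rows$replicate)
  ct <- ifelse(rows$abundance > 0,
               cfg$ct_intercept - log2(rows$abundance) +
                 rnorm(nrow(rows), 0, ct_noise_sd),
               NA_real_)
  ct[!is.na(ct) & ct >= cfg$ct_max_cycles] <- NA_real_
  out <- data.frame(target = rows$target, sample = rows$sample,
                    group = rows$group, replicate = rows$replicate,
                    ct = ct, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate synthetic Annexin-V/PI flow-cytometry events
#'
#' Draws event counts multinomially over the four quadrant populations
#' (viable, early apoptotic, late apoptotic, necrotic) and fluorescence
#' intensities from well-separated log-normal clusters. The quadrant
#' populations use the methods-text marker combinations: early =
#' AnnexinV+/PI-, late = AnnexinV+/PI+, necrotic = AnnexinV-/PI+.
#'
#' @param proportions named numeric over viable/early/late/necrotic,
#'   summing to 1 (tolerance 1e-9).
#' @param n_events number of cells to draw.
#' @param seed integer seed.
#' @return data.frame: event_id, annexin, pi, truth (quadrant label);
#'   intensities on the raw fluorescence scale, negative population
#'   around 10^1.5, positive around 10^3 (threshold 100 separates them).
#' @export
generate_flow_events <- function(proportions, n_events, seed = 1L) {
  labels <- c("viable", "early", "late", "necrotic")
  if (!all(labels %in% names(proportions)))
    stop_cislnc("proportions must be named viable/early/late/necrotic")
  proportions <- proportions[labels]
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_cislnc("proportions must sum to 1 (tolerance 1e-9)")
  set.seed(as.integer(seed))
  if (n_events == 0)
    return(data.frame(event_id = integer(0), annexin = numeric(0),
                      pi = numeric(0), truth = character(0),
                      stringsAsFactors = FALSE))
  counts <- as.vector(rmultinom(1, n_events, proportions))
  truth <- rep(labels, counts)
  # methods-text quadrants: annexin+ for early/late, pi+ for late/necrotic
  a_pos <- truth %in% c("early", "late")
  p_pos <- truth %in% c("late", "necrotic")
  draw <- function(pos) 10 ^ ifelse(pos, rnorm(length(pos), 3.0, 0.25),
                                    rnorm(length(pos), 1.5, 0.2))
  out <- data.frame(event_id = seq_along(truth),
                    annexin = draw(a_pos), pi = draw(p_pos),
                    truth = truth, stringsAsFactors = FALSE)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
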