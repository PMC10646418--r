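# File formats: TSV tables with schema validation, GTF/BED6/BEDPE
# export through rtracklayer/GenomicRanges, GMT gene sets, and the
# packaged islet lncRNA reference table.

DE_TABLE_COLUMNS <- c("transcript_id", "comparison", "log2fc",
                      "fold_change", "p", "q", "status")

#' Read a TSV table with schema validation
#'
#' @param path file path.
#' @param required_columns column names that must be present.
#' @param numeric_columns columns coerced to numeric; a value that does
#'   not parse raises an error naming the column and line.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required_columns,
                               numeric_columns = character(0)) {
  if (!file.exists(path)) stop_cislnc("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required_columns, names(df))
  if (length(missing) > 0)
    stop_cislnc("missing column(s) in ", path, ": ",
                paste(missing, collapse = ", "))
  for (col in intersect(numeric_columns, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0)
      stop_cislnc("non-numeric value in column '", col, "' of ", path,
                  " at data line ", bad[1])
    df[[col]] <- v
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write DE result tables
#'
#' Fixed-header TSV round-tripping for [test_de()] output.
#' @param path file path.
#' @return data.frame of DE results.
#' @export
read_de_table <- function(path) {
  read_table_checked(path, DE_TABLE_COLUMNS,
                     numeric_columns = c("log2fc", "fold_change",
                                         "p", "q"))
}

#' @rdname read_de_table
#' @param results DE result data.frame.
#' @export
write_de_table <- function(results, path) {
  missing <- setdiff(DE_TABLE_COLUMNS, names(results))
  if (length(missing) > 0)
    stop_cislnc("DE results missing column(s): ",
                paste(missing, collapse = ", "))
  write_tsv(results[, DE_TABLE_COLUMNS], path)
}

#' Read an expression matrix with its sample sheet
#'
#' @param values_path TSV with a `transcript_id` column plus one numeric
#'   column per sample.
#' @param samples_path TSV sample sheet (sample, group, replicate).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(values_path, samples_path) {
  vdf <- read_table_checked(values_path, "transcript_id")
  sdf <- read_table_checked(samples_path,
                            c("sample", "group", "replicate"))
  mat <- as.matrix(vdf[, setdiff(names(vdf), "transcript_id"),
                       drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- vdf$transcript_id
  expression_matrix(mat[, sdf$sample, drop = FALSE], sdf)
}

#' @rdname read_expression_matrix
#' @param mat an [expression_matrix()].
#' @export
write_expression_matrix <- function(mat, values_path, samples_path) {
  vdf <- data.frame(transcript_id = rownames(mat$values), mat$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(vdf, values_path)
  write_tsv(mat$samples, samples_path)
  invisible(values_path)
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1,
                              end = annotation$end),
    strand = annotation$strand,
    transcript_id = annotation$transcript_id,
    gene_id = annotation$gene_id,
    biotype = annotation$biotype)
}

#' Write a transcript annotation as GTF and BED6
#'
#' Converts the internal 0-based half-open records to GRanges and
#' exports one transcript feature per record with transcript_id,
#' gene_id and biotype attributes.
#'
#' @param annotation annotation data.frame (see [generate_annotation()]).
#' @param gtf_path,bed_path output paths (NULL skips a format).
#' @return invisibly, the GRanges used for export.
#' @export
write_annotation <- function(annotation, gtf_path = NULL,
                             bed_path = NULL) {
  gr <- annotation_granges(annotation)
  if (!is.null(gtf_path)) {
    gr_gtf <- gr
    S4Vectors::mcols(gr_gtf)$type <- "transcript"
    S4Vectors::mcols(gr_gtf)$source <- "cislnc"
    rtracklayer::export(gr_gtf, gtf_path, format = "gtf")
  }
  if (!is.null(bed_path)) {
    gr_bed <- gr
    S4Vectors::mcols(gr_bed) <-
      S4Vectors::DataFrame(name = annotation$transcript_id, score = 0)
    rtracklayer::export(gr_bed, bed_path, format = "bed")
  }
  invisible(gr)
}

#' Read an annotation from GTF
#'
#' Imports transcript features and returns the internal 0-based
#' half-open annotation data.frame.
#'
#' @param path GTF file.
#' @return annotation data.frame.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "transcript"]
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("biotype" %in% names(mc)) mc$biotype
             else mc$transcript_biotype
  data.frame(transcript_id = mc$transcript_id,
             gene_id = mc$gene_id,
             biotype = biotype,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write screened pairs as TSV and BEDPE
#'
#' @param pairs data.frame from [screen_cis_pairs()].
#' @param annotation the annotation the pairs came from.
#' @param tsv_path,bedpe_path output paths (NULL skips a format).
#' @return invisibly, `tsv_path`.
#' @export
write_pairs <- function(pairs, annotation, tsv_path = NULL,
                        bedpe_path = NULL) {
  if (!is.null(tsv_path)) write_tsv(pairs, tsv_path)
  if (!is.null(bedpe_path)) {
    a <- annotation[match(pairs$lnc_id, annotation$transcript_id), ]
    b <- annotation[match(pairs$mrna_id, annotation$transcript_id), ]
    bedpe <- data.frame(chrom1 = a$chrom, start1 = a$start, end1 = a$end,
                        chrom2 = b$chrom, start2 = b$start, end2 = b$end,
                        name = paste(pairs$lnc_id, pairs$mrna_id,
                                     sep = "|"),
                        score = pairs$signed_distance,
                        strand1 = a$strand, strand2 = b$strand,
                        stringsAsFactors = FALSE)
    write.table(bedpe, bedpe_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_cislnc("malformed GMT line: ", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Packaged islet lncRNA reference table
#'
#' The 10 islet-enriched lncRNA isoforms with their hg19 loci, strands,
#' FPKM in isolated islets and in PBS-/ALT-treated grafts, the
#' highest-expressing other human tissue (with its FPKM) from the
#' NONCODE/Human BodyMap compilation, and the nearest-gene TSS
#' distances. Used by the specificity and pattern examples and tests.
#'
#' @return data.frame, one row per isoform.
#' @export
#' @examples
#' t1 <- islet_table1()
#' sum(islet_specificity_call(islet_table1_panel(t1))$is_specific)
islet_table1 <- function() {
  path <- system.file("extdata", "table1_islet_lncrnas.tsv",
                      package = "cislnc", mustWork = TRUE)
  read_table_checked(path,
    c("transcript_id", "gene_id", "n_isoforms", "locus", "strand",
      "class", "fpkm_islet", "fpkm_pbs_graft", "fpkm_alt_graft",
      "noncode_tissue", "noncode_fpkm", "nearest_genes"),
    numeric_columns = c("fpkm_islet", "fpkm_pbs_graft",
                        "fpkm_alt_graft", "noncode_fpkm"))
}

#' Two-tissue specificity panel from the reference table
#'
#' Reduces the reference table to the panel the more-than-double rule is
#' applied to: islet FPKM against the FPKM of the highest-expressing
#' other tissue. The non-focal column is named per row's tissue in the
#' table but collapsed to a single `other_top_tissue` column, which is
#' exactly the quantity the rule compares against.
#'
#' @param table1 data.frame from [islet_table1()].
#' @return panel data.frame (transcript_id, islet, other_top_tissue).
#' @export
islet_table1_panel <- function(table1 = islet_table1()) {
  data.frame(transcript_id = table1$transcript_id,
             islet = table1$fpkm_islet,
             other_top_tissue = table1$noncode_fpkm,
             stringsAsFactors = FALSE)
}

#' Transcript records parsed from the reference table
#'
#' @param table1 data.frame from [islet_table1()].
#' @return annotation data.frame in internal coordinates.
#' @export
islet_table1_annotation <- function(table1 = islet_table1()) {
  loc <- parse_locus(table1$locus)
  data.frame(transcript_id = table1$transcript_id,
             gene_id = table1$gene_id,
             biotype = "lncRNA",
             chrom = loc$chrom, start = loc$start, end = loc$end,
             strand = table1$strand, stringsAsFactors = FALSE)
}
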