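## On-disk formats.
##
## Coordinate conventions: point variants are 1-based (VCF convention); CNVs,
## transcripts and exons are 0-based half-open (BED convention) on disk and in
## the gene-model / CNV data frames.

PEDIGREE_COLUMNS <- c("child_id", "family_id", "collection", "affected", "sex",
                      "dna_source", "mother_age", "father_age", "mean_coverage")
SMALLVAR_COLUMNS <- c("child_id", "chrom", "pos", "ref", "alt",
                      "ref_reads", "alt_reads")
CNV_COLUMNS <- c("chrom", "start", "end", "child_id", "change")

#' Read a pedigree / sample table
#'
#' One row per sequenced child with the covariates used throughout the
#' pipeline: collection of origin, affected status, sex, DNA source (whole
#' blood or lymphoblastoid cell line), parental ages and mean sequencing
#' coverage.
#'
#' @param path Path to a tab-separated file with header columns
#'   `child_id, family_id, collection, affected (0/1), sex (M/F),
#'   dna_source (WB/LCL), mother_age, father_age, mean_coverage`.
#'   Extra columns are preserved but ignored by the analysis.
#' @return A data frame with one validated row per child; `affected` is
#'   logical, ages and coverage numeric.
#' @export
read_pedigree <- function(path) {
  ## read everything as character first: "T"/"F" alleles and sexes must not
  ## become logicals
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  missing <- setdiff(PEDIGREE_COLUMNS, names(df))
  if (length(missing) > 0) {
    stopf("pedigree file %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  for (col in c("mother_age", "father_age", "mean_coverage")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      stopf("pedigree column '%s' is non-numeric at row %d ('%s')",
            col, bad[1], df[[col]][bad[1]])
    }
    df[[col]] <- v
  }
  df$affected <- as.logical(as.integer(df$affected))
  validate_pedigree(df)
  df
}

validate_pedigree <- function(df) {
  dup <- df$child_id[duplicated(df$child_id)]
  if (length(dup) > 0) {
    stopf("duplicated child_id in pedigree: %s",
          paste(unique(dup), collapse = ", "))
  }
  if (!all(df$collection %in% c("SSC", "AGRE", "OTHER"))) {
    stopf("collection must be one of SSC, AGRE, OTHER")
  }
  if (!all(df$sex %in% c("M", "F"))) stopf("sex must be M or F")
  if (!all(df$dna_source %in% c("WB", "LCL"))) {
    stopf("dna_source must be WB or LCL")
  }
  for (col in c("mother_age", "father_age")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 10 | v > 80))
    if (length(bad) > 0) {
      stopf("%s out of plausible range [10, 80] for child %s",
            col, df$child_id[bad[1]])
    }
  }
  if (any(!is.na(df$mean_coverage) & df$mean_coverage < 0)) {
    stopf("mean_coverage must be non-negative")
  }
  invisible(df)
}

#' Write a pedigree table
#'
#' @param cohort Data frame as returned by [read_pedigree()] or
#'   [simulate_children()].
#' @param path Output TSV path.
#' @export
write_pedigree <- function(cohort, path) {
  out <- cohort
  out$affected <- as.integer(out$affected)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a de novo variant table
#'
#' Small variants are accepted either as a TSV (columns `child_id, chrom, pos,
#' ref, alt, ref_reads, alt_reads`) or as a VCF 4.x file whose sample columns
#' are child ids with `GT` and `AD` fields; a row is attributed to every
#' sample carrying the alternative allele. CNVs are accepted as a BED-like TSV
#' (`chrom, start, end, child_id, change`).
#'
#' @param path Input file.
#' @param kind `"small"` for substitutions/indels, `"cnv"` for copy-number
#'   events.
#' @return For `kind = "small"`, a data frame with 1-based `pos`, inferred
#'   `var_type` (`SUB` iff both alleles are single bases) and read counts.
#'   For `kind = "cnv"`, a data frame with 0-based half-open `start`/`end`,
#'   `change` in `{DEL, DUP}` and `size_bp = end - start`.
#' @export
read_variant_table <- function(path, kind = c("small", "cnv")) {
  kind <- match.arg(kind)
  if (kind == "cnv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            colClasses = "character")
    for (col in intersect(c("start", "end"), names(df))) {
      df[[col]] <- suppressWarnings(as.integer(df[[col]]))
    }
    missing <- setdiff(CNV_COLUMNS, names(df))
    if (length(missing) > 0) {
      stopf("CNV table missing column(s): %s", paste(missing, collapse = ", "))
    }
    bad <- which(df$end <= df$start)
    if (length(bad) > 0) {
      stopf("CNV record %d has end <= start (%s:%d-%d)",
            bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
    }
    if (!all(df$change %in% c("DEL", "DUP"))) {
      stopf("CNV change must be DEL or DUP")
    }
    df <- drop_unknown_chroms(df)
    df$chrom <- normalize_chrom(df$chrom)
    df$size_bp <- df$end - df$start
    return(df)
  }
  if (is_vcf_file(path)) {
    return(read_small_variants_vcf(path))
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in intersect(c("pos", "ref_reads", "alt_reads"), names(df))) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  missing <- setdiff(SMALLVAR_COLUMNS, names(df))
  if (length(missing) > 0) {
    stopf("variant table missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  df <- drop_unknown_chroms(df)
  df$chrom <- normalize_chrom(df$chrom)
  finish_small_variants(df)
}

drop_unknown_chroms <- function(df) {
  known <- grepl("^(chr)?([0-9]+|X|Y|M|MT)$", df$chrom)
  if (any(!known)) {
    warnf("skipping %d record(s) on unknown chromosome(s): %s",
          sum(!known), paste(unique(df$chrom[!known]), collapse = ", "))
    df <- df[known, , drop = FALSE]
  }
  df
}

finish_small_variants <- function(df) {
  df$pos <- as.integer(df$pos)
  df$ref_reads <- as.integer(df$ref_reads)
  df$alt_reads <- as.integer(df$alt_reads)
  df$var_type <- ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1, "SUB", "INDEL")
  depth <- df$ref_reads + df$alt_reads
  if (any(!is.na(depth) & depth <= 0)) {
    stopf("variant with zero total read depth for child %s",
          df$child_id[which(depth <= 0)[1]])
  }
  df$alt_ratio <- df$alt_reads / depth
  rownames(df) <- NULL
  df
}

is_vcf_file <- function(path) {
  first <- readLines(path, n = 1)
  grepl("^##fileformat=VCF", first)
}

read_small_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(gt) || is.null(ad)) {
    stopf("VCF %s must carry GT and AD genotype fields", path)
  }
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  ref <- as.character(VariantAnnotation::ref(vcf))
  rows <- list()
  for (j in seq_len(ncol(gt))) {
    carrier <- grepl("1", gt[, j], fixed = TRUE)
    if (!any(carrier)) next
    idx <- which(carrier)
    adj <- ad[idx, j]
    if (is.list(adj)) adj <- do.call(rbind, adj)
    else adj <- matrix(adj, ncol = 2, byrow = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      child_id = colnames(gt)[j],
      chrom = as.character(GenomicRanges::seqnames(rr))[idx],
      pos = GenomicRanges::start(rr)[idx],
      ref = ref[idx],
      alt = alt[idx],
      ref_reads = adj[, 1],
      alt_reads = adj[, 2],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$child_id, df$chrom, df$pos), , drop = FALSE]
  df$chrom <- normalize_chrom(df$chrom)
  finish_small_variants(df)
}

#' Write a de novo variant table
#'
#' @param variants Data frame of small variants or CNVs (see
#'   [read_variant_table()]).
#' @param path Output TSV path.
#' @param kind `"small"` or `"cnv"`.
#' @export
write_variant_table <- function(variants, path, kind = c("small", "cnv")) {
  kind <- match.arg(kind)
  cols <- if (kind == "small") SMALLVAR_COLUMNS else CNV_COLUMNS
  extra <- setdiff(names(variants), c(cols, "var_type", "alt_ratio", "size_bp"))
  out <- variants[, c(cols, extra), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' Exons are reconstructed from the block columns and the CDS from
#' thickStart/thickEnd (clipped to the transcript span; equal thick bounds
#' denote a noncoding transcript). The BED name field is interpreted as
#' `GENE:TRANSCRIPT`; a name without a colon serves as both.
#'
#' @param path BED12 file.
#' @return A `gene_model` data frame with 0-based half-open `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end` and list columns `exon_starts`,
#'   `exon_ends` (absolute 0-based half-open, sorted, disjoint).
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$blocks)) {
    stopf("%s is not a BED12 file (no block columns)", path)
  }
  name <- S4Vectors::mcols(gr)$name
  parts <- strsplit(name, ":", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  tx <- vapply(parts, function(p) p[length(p)], "")
  thick <- S4Vectors::mcols(gr)$thick
  blocks <- S4Vectors::mcols(gr)$blocks  # 1-based, relative to tx start
  tx_start <- GenomicRanges::start(gr) - 1L
  exon_starts <- exon_ends <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    exon_starts[[i]] <- tx_start[i] + IRanges::start(b) - 1L
    exon_ends[[i]] <- tx_start[i] + IRanges::end(b)
  }
  gm <- data.frame(
    gene_symbol = gene,
    transcript_id = tx,
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = tx_start,
    tx_end = GenomicRanges::end(gr),
    cds_start = IRanges::start(thick) - 1L,
    cds_end = IRanges::end(thick),
    stringsAsFactors = FALSE)
  ## width-0 thick ranges come back with end < start
  noncoding <- gm$cds_end <= gm$cds_start
  gm$cds_start[noncoding] <- gm$tx_start[noncoding]
  gm$cds_end[noncoding] <- gm$tx_start[noncoding]
  gm$cds_start <- pmax(gm$cds_start, gm$tx_start)
  gm$cds_end <- pmin(gm$cds_end, gm$tx_end)
  gm$exon_starts <- exon_starts
  gm$exon_ends <- exon_ends
  validate_gene_model(gm)
  class(gm) <- c("gene_model", "data.frame")
  gm
}

validate_gene_model <- function(gm) {
  for (i in seq_len(nrow(gm))) {
    s <- gm$exon_starts[[i]]; e <- gm$exon_ends[[i]]
    if (length(s) != length(e) || any(e <= s)) {
      stopf("transcript %s has malformed exons", gm$transcript_id[i])
    }
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      stopf("transcript %s exons overlap or are unsorted",
            gm$transcript_id[i])
    }
    if (s[1] < gm$tx_start[i] || e[length(e)] > gm$tx_end[i]) {
      stopf("transcript %s exons exceed transcript span",
            gm$transcript_id[i])
    }
  }
  invisible(gm)
}

#' Write transcript models to a BED12 file
#'
#' @param gm A `gene_model` data frame (see [read_gene_model()]).
#' @param path Output BED12 path.
#' @export
write_gene_model <- function(gm, path) {
  n <- nrow(gm)
  blocks <- IRanges::IRangesList(lapply(seq_len(n), function(i) {
    IRanges::IRanges(start = gm$exon_starts[[i]] - gm$tx_start[i] + 1L,
                     end = gm$exon_ends[[i]] - gm$tx_start[i])
  }))
  thick_start <- ifelse(gm$cds_end > gm$cds_start, gm$cds_start, gm$tx_start)
  thick_end <- ifelse(gm$cds_end > gm$cds_start, gm$cds_end, gm$tx_start)
  gr <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(gm$tx_start + 1L, gm$tx_end),
    strand = gm$strand,
    name = paste(gm$gene_symbol, gm$transcript_id, sep = ":"),
    score = 0L,
    thick = IRanges::IRanges(thick_start + 1L, thick_end),
    blocks = blocks)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a named gene set
#'
#' @param path Text file with one gene symbol per line; `#` comments and blank
#'   lines are ignored; duplicates are collapsed.
#' @param name Name of the set.
#' @param gene_model Optional `gene_model`; symbols absent from it trigger a
#'   warning.
#' @return A list with elements `name` and `symbols` (character vector).
#' @export
read_gene_set <- function(path, name, gene_model = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  symbols <- unique(lines[nzchar(lines)])
  if (length(symbols) == 0) stopf("gene set file %s is empty", path)
  if (!is.null(gene_model)) {
    unknown <- setdiff(symbols, gene_model$gene_symbol)
    if (length(unknown) > 0) {
      warnf("gene set '%s': %d symbol(s) not in the gene model (%s)",
            name, length(unknown), paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' Write a gene set
#' @param gene_set A `gene_set` object.
#' @param path Output path.
#' @export
write_gene_set <- function(gene_set, path) {
  writeLines(gene_set$symbols, path)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML file of key/value pairs.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
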