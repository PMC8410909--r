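test_that("pedigree round-trips losslessly and rejects malformed input", {
  spec <- cohort_spec(n_affected = 3, n_unaffected = 2, dna_source_mix = 0.5,
                      seed = 11)
  cohort <- simulate_children(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(cohort, path)
  back <- read_pedigree(path)
  expect_identical(back$child_id, cohort$child_id)
  expect_identical(back$affected, cohort$affected)
  expect_identical(back$sex, cohort$sex)
  expect_identical(back$dna_source, cohort$dna_source)
  expect_equal(back$mother_age, cohort$mother_age, tolerance = 1e-8)
  expect_equal(back$mean_coverage, cohort$mean_coverage, tolerance = 1e-8)

  dup <- cohort
  dup$child_id[2] <- dup$child_id[1]
  write_pedigree(dup, path)
  expect_error(read_pedigree(path), dup$child_id[1])

  trunc <- cohort[, setdiff(names(cohort), "father_age")]
  write_pedigree(trunc, path)
  expect_error(read_pedigree(path), "father_age")

  bad <- cohort
  bad$mother_age <- as.character(bad$mother_age)
  bad$mother_age[3] <- "young"
  write_pedigree(bad, path)
  expect_error(read_pedigree(path), "row 3")
})

test_that("small-variant TSV parsing infers type and allele ratio", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\tchrom\tpos\tref\talt\tref_reads\talt_reads",
               "c1\tchr2\t1000\tA\tT\t12\t9",
               "c1\tchr2\t2000\tAT\tA\t10\t10",
               "c2\tweird_contig\t10\tG\tC\t5\t5"), path)
  expect_warning(v <- read_variant_table(path, "small"), "unknown chromosome")
  expect_equal(nrow(v), 2)
  expect_equal(v$var_type, c("SUB", "INDEL"))
  expect_equal(v$alt_ratio[1], 9 / 21)
  expect_equal(v$chrom, c("chr2", "chr2"))
})

test_that("CNV records with end <= start are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tchild_id\tchange",
               "chr1\t100\t100\tc1\tDEL"), path)
  expect_error(read_variant_table(path, "cnv"), "end <= start")
  writeLines(c("chrom\tstart\tend\tchild_id\tchange",
               "1\t100\t5100\tc1\tDUP"), path)
  cnv <- read_variant_table(path, "cnv")
  expect_equal(cnv$size_bp, 5000)
  expect_equal(cnv$chrom, "chr1")
})

test_that("VCF and TSV encodings of the same variants parse identically", {
  v <- data.frame(
    child_id = c("c1", "c1", "c2", "c2", "c2"),
    chrom = "chr1",
    pos = c(500L, 900L, 1500L, 2500L, 3500L),
    ref = c("A", "G", "C", "TAA", "G"),
    alt = c("T", "GAA", "A", "T", "C"),
    ref_reads = c(10L, 9L, 14L, 12L, 11L),
    alt_reads = c(8L, 7L, 12L, 10L, 13L),
    stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(v, tsv, "small")
  write_test_vcf(v, vcf)
  a <- read_variant_table(tsv, "small")
  b <- read_variant_table(vcf, "small")
  cols <- c("child_id", "chrom", "pos", "ref", "alt", "ref_reads",
            "alt_reads", "var_type", "alt_ratio")
  ord <- function(d) {
    d <- d[order(d$child_id, d$pos), cols]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(a), ord(b))
})

test_that("BED12 gene models round-trip and reconstruct exon/CDS structure", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(
    c("chr1", 0, 300, "GENEA:TX1", 0, "+", 50, 250, 0, 2, "100,100", "0,200"),
    collapse = "\t"), path)
  gm <- read_gene_model(path)
  expect_equal(gm$exon_starts[[1]], c(0L, 200L))
  expect_equal(gm$exon_ends[[1]], c(100L, 300L))
  expect_equal(c(gm$cds_start, gm$cds_end), c(50L, 250L))
  expect_equal(gm$gene_symbol, "GENEA")

  ## noncoding convention: thickStart == thickEnd -> empty CDS
  writeLines(paste(
    c("chr1", 1000, 1400, "GENEB:TX2", 0, "-", 1000, 1000, 0, 2,
      "100,100", "0,300"), collapse = "\t"), path)
  nc <- read_gene_model(path)
  expect_equal(nc$cds_start, nc$cds_end)

  genome <- toy_genome_fixture()
  out <- withr::local_tempfile(fileext = ".bed")
  write_gene_model(genome$transcripts, out)
  back <- read_gene_model(out)
  for (col in c("gene_symbol", "transcript_id", "chrom", "strand",
                "tx_start", "tx_end", "cds_start", "cds_end")) {
    expect_equal(back[[col]], genome$transcripts[[col]], info = col)
  }
  expect_identical(back$exon_starts, genome$transcripts$exon_starts)
  expect_identical(back$exon_ends, genome$transcripts$exon_ends)
})

test_that("gene sets deduplicate, ignore comments, and reject empty files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# autism LGD targets", "CHD8", "SCN2A", "", "CHD8", "ARID1B"),
             path)
  gs <- read_gene_set(path, "targets")
  expect_setequal(gs$symbols, c("CHD8", "SCN2A", "ARID1B"))
  expect_equal(length(gs$symbols), 3)

  writeLines(c("# nothing", ""), path)
  expect_error(read_gene_set(path, "empty"), "empty")

  ## set difference computed by naive scan matches vector arithmetic
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CHD8", "SCN2A", "SYNGAP1"), p2)
  g2 <- read_gene_set(p2, "other")
  naive <- gs$symbols[!vapply(gs$symbols, function(s) s %in% g2$symbols, TRUE)]
  expect_setequal(setdiff(gs$symbols, g2$symbols), naive)

  genome <- toy_genome_fixture()
  writeLines(c("G001", "NOT_A_GENE"), path)
  expect_warning(read_gene_set(path, "x", genome$transcripts),
                 "not in the gene model")
})

test_that("point/interval coordinate conventions are mutually consistent", {
  ## a 1-based point converted to a length-1 half-open interval and back
  pos <- 1234L
  start0 <- pos - 1L; end0 <- pos
  expect_equal(end0 - start0, 1L)
  expect_equal(start0 + 1L, pos)
})
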