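make_variants <- function(chrom, pos, ref, alt) {
  data.frame(child_id = "c1", chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, ref_reads = 10L, alt_reads = 10L,
             var_type = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                               "SUB", "INDEL"),
             stringsAsFactors = FALSE)
}

test_that("hand-constructed variants get their defining classes", {
  g <- toy_genome_fixture()
  gm <- g$transcripts
  pools <- g$pools

  ## a known stop-gain from the enumerated pool is LGD
  lgd <- pools$sub[pools$sub$class == "LGD", ][1, ]
  v <- make_variants(lgd$chrom, lgd$pos, lgd$ref, lgd$alt)
  expect_equal(as.character(annotate_small_variants(v, g)$effect), "LGD")

  ## 2-bp deletion wholly inside an intercoding intron, clear of splice sites
  ic <- g$features$intercoding
  istart <- GenomicRanges::start(ic)[1]
  chrom <- as.character(GenomicRanges::seqnames(ic))[1]
  anchor <- istart + 5L  # deleted bases at +6, +7: > 2 bp from both ends
  chars <- g$chars[[chrom]]
  v <- make_variants(chrom, anchor,
                     paste(chars[anchor:(anchor + 2)], collapse = ""),
                     chars[anchor])
  expect_equal(as.character(annotate_small_variants(v, g)$effect), "IID")

  ## substitution in a splice window is LGD
  sp <- pools$splice[1, ]
  ref <- g$chars[[sp$chrom]][sp$pos]
  v <- make_variants(sp$chrom, sp$pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  expect_equal(as.character(annotate_small_variants(v, g)$effect), "LGD")

  ## chrX events are always OTHER
  v <- make_variants("chrX", 5000L, g$chars$chrX[5000], "A")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_equal(as.character(annotate_small_variants(v, g)$effect), "OTHER")
})

test_that("random placements agree with the brute-force annotator", {
  g <- toy_genome_fixture()
  spec <- cohort_spec(n_affected = 8, n_unaffected = 8, base_sub_rate = 40,
                      seed = 77)
  cohort <- simulate_children(spec)
  calls <- simulate_denovo_calls(cohort, g, spec)
  v <- calls$small[seq_len(min(500, nrow(calls$small))), ]
  fast <- as.character(annotate_small_variants(v, g)$effect)
  slow <- oracle_annotate_small(v, g)
  expect_identical(fast, slow)
})

test_that("uniform random substitutions agree with the brute-force annotator", {
  ## positions drawn uniformly, not from class pools: exercises boundaries
  g <- toy_genome_fixture()
  set.seed(99)
  n <- 400
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) {
    sample.int(g$chrom_lengths[[ch]] - 10L, 1) + 5L
  }, 0L)
  ref <- mapply(function(ch, p) g$chars[[ch]][p], chrom, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  v <- make_variants(chrom, pos, unname(ref), unname(alt))
  fast <- as.character(annotate_small_variants(v, g)$effect)
  slow <- oracle_annotate_small(v, g)
  expect_identical(fast, slow)
})

test_that("annotation is deterministic and order-independent", {
  g <- toy_genome_fixture()
  spec <- cohort_spec(n_affected = 5, n_unaffected = 5, seed = 13)
  cohort <- simulate_children(spec)
  v <- simulate_denovo_calls(cohort, g, spec)$small
  a1 <- annotate_small_variants(v, g)$effect
  perm <- sample(nrow(v))
  a2 <- annotate_small_variants(v[perm, ], g)$effect
  expect_identical(as.character(a1)[perm], as.character(a2))
  ## partition: every variant gets exactly one non-NA class
  expect_false(anyNA(a1))
})

test_that("CNV classes match the interval-scan oracle", {
  g <- toy_genome_fixture()
  gm <- g$transcripts

  ## spanning an entire coding gene
  i <- which(gm$cds_end > gm$cds_start)[1]
  cnv <- data.frame(chrom = gm$chrom[i], start = gm$tx_start[i] - 100L,
                    end = gm$tx_end[i] + 100L, child_id = "c1",
                    change = "DEL",
                    size_bp = gm$tx_end[i] - gm$tx_start[i] + 200L)
  a <- annotate_cnvs(cnv, g)
  expect_equal(as.character(a$cnv_effect), "CODING")
  expect_equal(a$n_genes_hit, 1L)
  expect_equal(as.character(a$single_gene_subclass), "CODING")

  ## strictly inside an intercoding intron
  ic <- g$features$intercoding
  cnv2 <- data.frame(chrom = as.character(GenomicRanges::seqnames(ic))[1],
                     start = GenomicRanges::start(ic)[1] + 4L,
                     end = GenomicRanges::start(ic)[1] + 50L,
                     child_id = "c1", change = "DEL", size_bp = 46L)
  a2 <- annotate_cnvs(cnv2, g)
  expect_equal(as.character(a2$cnv_effect), "GENIC_NONCODING")
  expect_equal(as.character(a2$single_gene_subclass), "INTERCODING_INTRONIC")

  ## 300 random intervals vs oracle
  set.seed(41)
  n <- 300
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  size <- sample(50:4000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(k) {
    sample.int(g$chrom_lengths[[chrom[k]]] - size[k] - 1L, 1)
  }, 0L)
  cnvs <- data.frame(chrom = chrom, start = start, end = start + size,
                     child_id = "c1", change = "DEL", size_bp = size,
                     stringsAsFactors = FALSE)
  a <- annotate_cnvs(cnvs, g)
  for (k in seq_len(n)) {
    o <- oracle_annotate_cnv_one(gm, cnvs$chrom[k], cnvs$start[k], cnvs$end[k])
    expect_equal(as.character(a$cnv_effect[k]), o$top)
    expect_equal(a$n_genes_hit[k], o$n_genes)
    expect_equal(as.character(a$single_gene_subclass[k]), o$sub)
  }
})

test_that("size and chromosome filters use inclusive >= and drop chrX", {
  cnvs <- data.frame(chrom = "chr1", start = 0L,
                     end = c(3999L, 4000L, 4001L), child_id = "c1",
                     change = "DEL", size_bp = c(3999L, 4000L, 4001L))
  kept <- suppressMessages(filter_events(cnvs, min_cnv_size = 4000))
  expect_equal(kept$size_bp, c(4000L, 4001L))

  v <- make_variants(c("chrX", "chr1"), c(100L, 100L), "A", "T")
  kept <- suppressMessages(filter_events(v))
  expect_equal(kept$chrom, "chr1")

  ## retained count equals a brute-force re-count on a synthetic cohort
  g <- toy_genome_fixture()
  spec <- cohort_spec(n_affected = 30, n_unaffected = 30, seed = 55)
  cohort <- simulate_children(spec)
  calls <- simulate_denovo_calls(cohort, g, spec)
  kept <- suppressMessages(filter_events(calls$cnvs, min_cnv_size = 4000))
  manual <- sum(calls$cnvs$size_bp >= 4000 & calls$cnvs$chrom != "chrX")
  expect_equal(nrow(kept), manual)
  keptv <- suppressMessages(filter_events(calls$small))
  expect_equal(nrow(keptv), sum(calls$small$chrom != "chrX"))
})

test_that("strand affects only codon interpretation, not interval classes", {
  g <- toy_genome_fixture()
  gm <- g$transcripts
  flipped <- g
  flipped$transcripts$strand <- ifelse(gm$strand == "+", "-", "+")
  flipped$features <- dnburden:::gm_features(flipped$transcripts)

  spec <- cohort_spec(n_affected = 10, n_unaffected = 10, seed = 3)
  cohort <- simulate_children(spec)
  v <- simulate_denovo_calls(cohort, g, spec)$small
  v <- v[v$sim_class %in% c("ISB", "IID", "IGSB", "IGID"), ]
  a1 <- as.character(annotate_small_variants(v, g)$effect)
  a2 <- as.character(annotate_small_variants(v, flipped)$effect)
  expect_identical(a1, a2)
})
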