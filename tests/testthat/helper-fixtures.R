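## Shared fixtures and independent oracles for the test suite.

## One toy genome reused across tests (built once per session).
toy_genome_fixture <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_toy_genome(8, seed = 42)
    g
  }
})

## ---- independent brute-force small-variant annotator -----------------------
## Scans every base of the variant footprint against every transcript using
## plain arithmetic (no interval index), and classifies coding substitutions
## by mutating the chromosome sequence and comparing whole translated
## proteins. Deliberately shares no code with the package annotator.

.in_halfopen <- function(b, s0, e0) b > s0 & b <= e0  # 1-based base in [s0,e0)

oracle_coding_sub <- function(gm, chars, i, pos, alt) {
  extract_protein <- function(chs) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    ws <- pmax(es, gm$cds_start[i]); we <- pmin(ee, gm$cds_end[i])
    keep <- we > ws
    s <- unlist(lapply(which(keep), function(j) chs[(ws[j] + 1):we[j]]))
    dna <- Biostrings::DNAString(paste(s, collapse = ""))
    if (gm$strand[i] == "-") dna <- Biostrings::reverseComplement(dna)
    L <- 3 * (length(dna) %/% 3)
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::subseq(dna, 1, L))))
  }
  orig <- chars[[gm$chrom[i]]]
  mut <- orig
  mut[pos] <- alt
  p0 <- extract_protein(orig)
  p1 <- extract_protein(mut)
  if (p0 == p1) "SYN"
  else if (grepl("*", p1, fixed = TRUE)) "LGD"
  else "MIS"
}

oracle_annotate_small_one <- function(gm, chars, chrom, pos, ref, alt) {
  if (chrom == "chrX") return("OTHER")
  lr <- nchar(ref); la <- nchar(alt)
  is_sub <- lr == 1 && la == 1
  span <- if (lr > la) (pos + 1):(pos + lr - 1)
          else if (lr > 1) pos:(pos + lr - 1)
          else if (la > 1) pos:(pos + 1)
          else pos
  coding_tx <- integer(0)
  splice_hit <- FALSE
  genic <- FALSE
  within_intercoding <- FALSE
  for (i in seq_len(nrow(gm))) {
    if (gm$chrom[i] != chrom) next
    if (!any(.in_halfopen(span, gm$tx_start[i], gm$tx_end[i]))) next
    genic <- TRUE
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
    codes <- ce > cs
    exon_coding <- codes & pmin(ee, ce) > pmax(es, cs)
    base_coding <- function(b) {
      codes && any(.in_halfopen(b, pmax(es, cs), pmin(ee, ce)) & exon_coding)
    }
    if (any(vapply(span, base_coding, TRUE))) {
      coding_tx <- c(coding_tx, i)
    }
    if (length(es) > 1) {
      for (k in seq_len(length(es) - 1)) {
        is0 <- ee[k]; ie0 <- es[k + 1]  # intron [is0, ie0), 0-based
        if (codes &&
            any(.in_halfopen(span, is0, is0 + 2) |
                  .in_halfopen(span, ie0 - 2, ie0))) {
          splice_hit <- TRUE
        }
        if (all(.in_halfopen(span, is0, ie0)) &&
            exon_coding[k] && exon_coding[k + 1]) {
          within_intercoding <- TRUE
        }
      }
    }
  }
  if (length(coding_tx) > 0) {
    if (!is_sub) {
      return(if (abs(lr - la) %% 3 != 0) "LGD" else "OTHER")
    }
    sev <- c(SYN = 1, MIS = 2, LGD = 3)
    cls <- vapply(coding_tx, function(i) oracle_coding_sub(gm, chars, i, pos, alt), "")
    return(names(sev)[max(sev[cls])])
  }
  if (splice_hit) return("LGD")
  if (within_intercoding) return(if (is_sub) "ISB" else "IID")
  if (genic) return("OTHER")
  if (is_sub) "IGSB" else "IGID"
}

oracle_annotate_small <- function(variants, genome) {
  gm <- genome$transcripts
  vapply(seq_len(nrow(variants)), function(k) {
    oracle_annotate_small_one(gm, genome$chars,
                              variants$chrom[k], variants$pos[k],
                              variants$ref[k], variants$alt[k])
  }, "")
}

## ---- independent CNV interval-scan oracle -----------------------------------

oracle_annotate_cnv_one <- function(gm, chrom, start, end) {
  genes <- character(0)
  coding_genes <- character(0)
  ic_hit <- FALSE
  for (i in seq_len(nrow(gm))) {
    if (gm$chrom[i] != chrom) next
    if (!(start < gm$tx_end[i] && end > gm$tx_start[i])) next
    genes <- c(genes, gm$gene_symbol[i])
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
    codes <- ce > cs
    ws <- pmax(es, cs); we <- pmin(ee, ce)
    exon_coding <- codes & we > ws
    if (codes && any(exon_coding & start < we & end > ws)) {
      coding_genes <- c(coding_genes, gm$gene_symbol[i])
    }
    if (length(es) > 1) {
      for (k in seq_len(length(es) - 1)) {
        if (exon_coding[k] && exon_coding[k + 1] &&
            start < es[k + 1] && end > ee[k]) {
          ic_hit <- TRUE
        }
      }
    }
  }
  genes <- unique(genes)
  top <- if (length(coding_genes) > 0) "CODING"
         else if (length(genes) > 0) "GENIC_NONCODING" else "INTERGENIC"
  sub <- NA_character_
  if (length(genes) == 1) {
    g <- genes[1]
    if (any(gm$cds_end[gm$gene_symbol == g] > gm$cds_start[gm$gene_symbol == g])) {
      sub <- if (length(coding_genes) > 0) "CODING"
             else if (ic_hit) "INTERCODING_INTRONIC" else "PERIPHERAL"
    }
  }
  list(top = top, n_genes = length(genes), sub = sub)
}

## ---- exhaustive permutation oracle ------------------------------------------
## Enumerates every affected/unaffected label assignment (no normal fit) and
## returns the inclusive and exclusive tie-handling tail probabilities.

exhaustive_permutation_tails <- function(input) {
  S <- c(input$affected$subject, input$unaffected$subject)
  N <- c(input$affected$norm, input$unaffected$norm)
  C_a <- nrow(input$affected)
  n <- length(S)
  cmb <- utils::combn(n, C_a)
  ads <- apply(cmb, 2, function(idx) {
    S_a <- sum(S[idx]); N_a <- sum(N[idx])
    100 * (S_a - (sum(S) - S_a) * N_a / (sum(N) - N_a)) / C_a
  })
  S_a <- sum(input$affected$subject); N_a <- sum(input$affected$norm)
  obs <- 100 * (S_a - sum(input$unaffected$subject) * N_a /
                  sum(input$unaffected$norm)) / C_a
  c(lo = mean(ads > obs + 1e-9), hi = mean(ads >= obs - 1e-9))
}

## ---- tiny VCF writer ---------------------------------------------------------

write_test_vcf <- function(variants, path, samples = unique(variants$child_id)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##contig=<ID=", unique(variants$chrom), ",length=10000000>"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  body <- vapply(unique(key), function(k) {
    rows <- variants[key == k, , drop = FALSE]
    geno <- vapply(samples, function(s) {
      r <- rows[rows$child_id == s, , drop = FALSE]
      if (nrow(r) == 0) "0/0:20,0"
      else sprintf("0/1:%d,%d", r$ref_reads[1], r$alt_reads[1])
    }, "")
    paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1], rows$alt[1], ".",
            "PASS", ".", "GT:AD", geno), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}
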