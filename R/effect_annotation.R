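## Functional classification of de novo events against transcript models.
##
## Small variants are assigned one of LGD, SYN, MIS, ISB, IID, IGSB, IGID or
## OTHER with severity precedence coding > splice-site > intercoding-intronic
## > intergenic, taking the most severe consequence across transcripts. CNVs
## get a top-level class (CODING / GENIC_NONCODING / INTERGENIC, any-bp
## overlap semantics) plus, for events confined to a single coding gene, a
## subclass (CODING / INTERCODING_INTRONIC / PERIPHERAL).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Derive the interval features used by both annotators. All GRanges are
## 1-based closed. "Intercoding" introns are introns both of whose flanking
## exons contain coding bases in the same transcript.
gm_features <- function(gm) {
  tx_spans <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(gm$tx_start + 1L, gm$tx_end), tx = seq_len(nrow(gm)))
  coding <- list(); splice <- list(); intercoding <- list()
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
    has_cds <- ce > cs
    if (has_cds) {
      ws <- pmax(es, cs); we <- pmin(ee, ce)
      keep <- we > ws
      if (any(keep)) {
        coding[[length(coding) + 1L]] <- data.frame(
          chrom = gm$chrom[i], start = ws[keep] + 1L, end = we[keep], tx = i)
      }
      exon_coding <- keep
    } else {
      exon_coding <- rep(FALSE, length(es))
    }
    if (length(es) > 1) {
      is_ <- ee[-length(ee)]      # 0-based intron start
      ie_ <- es[-1]               # 0-based intron end (exclusive)
      if (has_cds) {
        ## donor/acceptor 2 bp windows of every intron of a coding transcript
        splice[[length(splice) + 1L]] <- data.frame(
          chrom = gm$chrom[i],
          start = c(is_ + 1L, ie_ - 1L),
          end = c(is_ + 2L, ie_),
          tx = i)
      }
      inter <- exon_coding[-length(exon_coding)] & exon_coding[-1]
      if (any(inter)) {
        intercoding[[length(intercoding) + 1L]] <- data.frame(
          chrom = gm$chrom[i], start = is_[inter] + 1L, end = ie_[inter], tx = i)
      }
    }
  }
  ## all feature tracks share one seqlevel universe so that overlap queries
  ## against variant ranges on other chromosomes stay silent
  lv <- unique(gm$chrom)
  df2gr <- function(lst) {
    if (length(lst) == 0) {
      gr <- GenomicRanges::GRanges(
        seqinfo = GenomeInfoDb::Seqinfo(seqnames = lv))
      S4Vectors::mcols(gr)$tx <- integer(0)
      return(gr)
    }
    d <- do.call(rbind, lst)
    GenomicRanges::GRanges(factor(d$chrom, levels = lv),
                           IRanges::IRanges(d$start, d$end), tx = d$tx)
  }
  GenomeInfoDb::seqlevels(tx_spans) <- lv
  list(tx_spans = tx_spans, coding = df2gr(coding), splice = df2gr(splice),
       intercoding = df2gr(intercoding))
}

## Genomic 1-based positions of the coding sequence of transcript i, in CDS
## (5'->3') order, plus the CDS nucleotide sequence when `seqs` is given.
cds_map <- function(gm, i, seqs = NULL) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  ws <- pmax(es, gm$cds_start[i]); we <- pmin(ee, gm$cds_end[i])
  keep <- we > ws
  pos <- unlist(lapply(which(keep), function(j) seq(ws[j] + 1L, we[j])))
  seq <- NULL
  if (!is.null(seqs)) {
    chrseq <- seqs[[gm$chrom[i]]]
    seq <- unlist(strsplit(as.character(
      Biostrings::subseq(chrseq, 1, length(chrseq))), ""))[pos]
  }
  if (gm$strand[i] == "-") {
    pos <- rev(pos)
    if (!is.null(seq)) seq <- unname(COMPLEMENT[rev(seq)])
  }
  list(pos = pos, seq = seq)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

## Consequence of substituting `alt` at genomic position `pos` within the CDS
## of transcript i: "LGD" (stop gain), "SYN" or "MIS".
coding_sub_class <- function(gm, seqs, i, pos, alt, map = NULL) {
  if (is.null(map)) map <- cds_map(gm, i, seqs)
  off <- match(pos, map$pos)
  if (is.na(off)) stopf("position %d is not coding in transcript %s",
                        pos, gm$transcript_id[i])
  alt_cds <- if (gm$strand[i] == "-") unname(COMPLEMENT[alt]) else alt
  ci <- (off - 1L) %/% 3L
  w <- (off - 1L) %% 3L + 1L
  codon <- map$seq[(ci * 3L + 1L):(ci * 3L + 3L)]
  if (anyNA(codon)) return("MIS")  # truncated terminal codon: treat as missense
  old_aa <- translate_codon(paste(codon, collapse = ""))
  codon[w] <- alt_cds
  new_aa <- translate_codon(paste(codon, collapse = ""))
  if (new_aa == old_aa) return("SYN")
  if (new_aa == "*" && old_aa != "*") return("LGD")
  "MIS"
}

## Genomic footprint of a variant as a 1-based closed interval: a deleted
## block for deletions (left-anchored VCF alleles), the two flanking bases for
## insertions, the substituted base otherwise.
variant_span <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  start <- ifelse(lr > la, pos + 1L, pos)
  end <- ifelse(lr > 1L, pos + lr - 1L, ifelse(la > 1L, pos + 1L, pos))
  cbind(start = start, end = pmax(start, end))
}

#' Classify de novo small variants by functional effect
#'
#' Assigns each substitution/indel one of the classes
#' `LGD` (nonsense, frameshift or canonical splice-site), `SYN`, `MIS`,
#' `ISB`/`IID` (substitution/indel inside an intron separating two coding
#' exons of the same transcript, outside the 2-bp splice windows),
#' `IGSB`/`IGID` (fully intergenic) or `OTHER` (UTRs, non-intercoding genic
#' regions, noncoding transcripts, in-frame coding indels, and all chrX
#' events, which the burden analysis excludes).
#'
#' @param variants Small-variant data frame (see [read_variant_table()]).
#' @param genome A `toy_genome`, or a `gene_model` when `seqs` is supplied.
#' @param seqs Chromosome sequences as a [Biostrings::DNAStringSet] (required
#'   for coding substitution consequences when `genome` is a bare gene model).
#' @return `variants` with an added `effect` factor column.
#' @export
annotate_small_variants <- function(variants, genome, seqs = NULL) {
  if (inherits(genome, "toy_genome")) {
    gm <- genome$transcripts
    seqs <- genome$seqs
  } else {
    gm <- genome
  }
  feats <- if (inherits(genome, "toy_genome")) genome$features else gm_features(gm)
  n <- nrow(variants)
  span <- variant_span(variants$pos, variants$ref, variants$alt)
  vchrom <- normalize_chrom(variants$chrom)
  lv <- union(GenomeInfoDb::seqlevels(feats$tx_spans), unique(vchrom))
  vr <- GenomicRanges::GRanges(factor(vchrom, levels = lv),
                               IRanges::IRanges(span[, "start"], span[, "end"]))
  is_sub <- variants$var_type == "SUB"
  effect <- rep(NA_character_, n)

  effect[is_chrX(variants$chrom)] <- "OTHER"

  ## coding overlap, most severe consequence across transcripts
  hit <- GenomicRanges::findOverlaps(vr, feats$coding)
  qi <- S4Vectors::queryHits(hit)
  open <- is.na(effect)
  if (length(qi) > 0) {
    sel <- open[qi]
    qi <- qi[sel]
    ti <- S4Vectors::mcols(feats$coding)$tx[S4Vectors::subjectHits(hit)][sel]
    if (length(qi) > 0) {
      maps <- list()
      sev <- c(LGD = 3, MIS = 2, SYN = 1)
      cls <- character(length(qi))
      for (k in seq_along(qi)) {
        v <- qi[k]
        if (is_sub[v]) {
          key <- as.character(ti[k])
          if (is.null(maps[[key]])) maps[[key]] <- cds_map(gm, ti[k], seqs)
          cls[k] <- coding_sub_class(gm, seqs, ti[k], variants$pos[v],
                                     variants$alt[v], maps[[key]])
        } else {
          shift <- abs(nchar(variants$ref[v]) - nchar(variants$alt[v]))
          cls[k] <- if (shift %% 3L != 0L) "LGD" else "OTHER"
        }
      }
      best <- tapply(cls, qi, function(x) {
        x <- x[x != "OTHER"]
        if (length(x) == 0) "OTHER" else names(which.max(sev[unique(x)]))[1]
      })
      ## in-frame coding indels stay unclassified-by-coding but are genic
      effect[as.integer(names(best))] <- unname(best)
    }
  }

  assign_if_open <- function(effect, idx, value) {
    idx <- idx[is.na(effect[idx])]
    effect[idx] <- value
    effect
  }

  ## canonical splice sites of coding transcripts
  sp <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(vr, feats$splice)))
  effect <- assign_if_open(effect, sp, "LGD")

  ## intercoding intronic: footprint fully inside the intron
  ic <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(vr, feats$intercoding, type = "within")))
  open <- which(is.na(effect))
  take <- intersect(ic, open)
  effect[take] <- ifelse(is_sub[take], "ISB", "IID")

  ## remaining genic footprints (UTRs, peripheral/noncoding regions, partial
  ## overlaps) are OTHER; fully intergenic footprints are IGSB/IGID
  genic <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(vr, feats$tx_spans)))
  open <- which(is.na(effect))
  take <- intersect(genic, open)
  effect[take] <- "OTHER"
  open <- which(is.na(effect))
  effect[open] <- ifelse(is_sub[open], "IGSB", "IGID")

  variants$effect <- factor(effect, levels = EFFECT_CLASSES)
  variants
}

#' Classify de novo CNVs by functional effect
#'
#' Any-bp overlap semantics: a CNV is `CODING` if it overlaps any coding exon
#' base of any transcript, otherwise `GENIC_NONCODING` if it overlaps any
#' transcript, otherwise `INTERGENIC`. For events overlapping exactly one
#' gene, and that gene codes, a subclass distinguishes `CODING`,
#' `INTERCODING_INTRONIC` (confined to introns splitting two coding exons)
#' and `PERIPHERAL` (UTRs or introns splitting UTRs).
#'
#' @param cnvs CNV data frame (see [read_variant_table()]).
#' @param genome A `toy_genome` or `gene_model`.
#' @return `cnvs` with added `cnv_effect`, `n_genes_hit` and
#'   `single_gene_subclass` columns.
#' @export
annotate_cnvs <- function(cnvs, genome) {
  gm <- if (inherits(genome, "toy_genome")) genome$transcripts else genome
  feats <- if (inherits(genome, "toy_genome")) genome$features else gm_features(gm)
  cchrom <- normalize_chrom(cnvs$chrom)
  lv <- union(GenomeInfoDb::seqlevels(feats$tx_spans), unique(cchrom))
  cr <- GenomicRanges::GRanges(factor(cchrom, levels = lv),
                               IRanges::IRanges(cnvs$start + 1L, cnvs$end))
  n <- nrow(cnvs)
  hit_tx <- GenomicRanges::findOverlaps(cr, feats$tx_spans)
  genes_by_cnv <- split(
    gm$gene_symbol[S4Vectors::mcols(feats$tx_spans)$tx[S4Vectors::subjectHits(hit_tx)]],
    factor(S4Vectors::queryHits(hit_tx), levels = seq_len(n)))
  n_genes <- vapply(genes_by_cnv, function(g) length(unique(g)), 0L)
  hit_cod <- GenomicRanges::findOverlaps(cr, feats$coding)
  coding_genes_by_cnv <- split(
    gm$gene_symbol[S4Vectors::mcols(feats$coding)$tx[S4Vectors::subjectHits(hit_cod)]],
    factor(S4Vectors::queryHits(hit_cod), levels = seq_len(n)))
  has_coding <- vapply(coding_genes_by_cnv, length, 0L) > 0
  has_tx <- n_genes > 0
  top <- ifelse(has_coding, "CODING",
                ifelse(has_tx, "GENIC_NONCODING", "INTERGENIC"))
  hit_ic <- GenomicRanges::findOverlaps(cr, feats$intercoding)
  has_ic <- seq_len(n) %in% S4Vectors::queryHits(hit_ic)
  gene_codes <- vapply(genes_by_cnv, function(g) {
    g <- unique(g)
    length(g) == 1 && any(gm$cds_end[gm$gene_symbol == g] >
                            gm$cds_start[gm$gene_symbol == g])
  }, FALSE)
  sub <- rep(NA_character_, n)
  one_gene <- n_genes == 1 & gene_codes
  sub[one_gene & has_coding] <- "CODING"
  sub[one_gene & !has_coding & has_ic] <- "INTERCODING_INTRONIC"
  sub[one_gene & !has_coding & !has_ic] <- "PERIPHERAL"
  cnvs$cnv_effect <- factor(top, levels = CNV_CLASSES)
  cnvs$n_genes_hit <- unname(n_genes)
  cnvs$single_gene_subclass <- factor(sub, levels = CNV_SUBCLASSES)
  cnvs
}

#' Filter annotated events for burden analysis
#'
#' Applies the event-level exclusions used throughout the burden comparisons:
#' X-chromosome events are dropped, and CNVs below the minimum size (default
#' 4 kb, inclusive at the boundary) are dropped. Small-variant splice-site
#' exclusion from the intronic classes needs no knob here: the annotator's
#' severity precedence already routes canonical splice-site variants to LGD.
#'
#' @param events Small-variant or CNV data frame (CNVs are recognized by a
#'   `size_bp` column).
#' @param min_cnv_size Minimum CNV size in bp, inclusive.
#' @param exclude_chrX Drop events on the X chromosome.
#' @return Filtered data frame in the original order.
#' @export
filter_events <- function(events, min_cnv_size = 4000, exclude_chrX = TRUE) {
  keep <- rep(TRUE, nrow(events))
  if ("size_bp" %in% names(events)) {
    keep <- keep & events$size_bp >= min_cnv_size
  }
  if (exclude_chrX) {
    keep <- keep & !is_chrX(events$chrom)
  }
  removed <- sum(!keep)
  if (removed > 0) {
    dnb_log("filter_events: removed %d of %d events", removed, nrow(events))
  }
  events[keep, , drop = FALSE]
}
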