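## Synthetic trio cohorts with the statistical structure the burden analysis
## assumes: Poisson de novo counts modulated by paternal age and sequencing
## coverage, binomial alternative-allele read support centred on 0.47, a
## two-component cell-line drift contamination among LCL samples, and a
## plantable excess of contributory event classes in affected children.

#' Cohort simulation parameters
#'
#' @param n_affected,n_unaffected Children per group.
#' @param collection Collection label for all children.
#' @param dna_source_mix Fraction of children whose DNA source is LCL.
#' @param base_sub_rate Baseline expected de novo events per child before the
#'   paternal-age term and coverage thinning.
#' @param paternal_age_slope Additional expected events per paternal year.
#' @param coverage_mean,coverage_sd Mean sequencing coverage distribution
#'   (fold), normal truncated below at 1.
#' @param allele_ratio_p Binomial success probability for alternative-allele
#'   reads of true heterozygous de novo calls (0.47: slight reference bias).
#' @param class_proportions Named probabilities over the effect classes,
#'   summing to 1. Defaults mirror realistic per-child class magnitudes
#'   (about 0.26 synonymous and 3 intergenic indels per child).
#' @param planted_AD Named percentages: an affected child receives one extra
#'   event of class k with probability `planted_AD[k] / 100` (never more than
#'   one per class, matching the burden statistics' interpretability
#'   assumption of fewer than one contributory event per child).
#' @param drift_fraction Fraction of LCL samples affected by cell-line
#'   genetic drift.
#' @param drift_count_multiplier Event-count inflation factor in drifted
#'   samples.
#' @param drift_allele_ratio_beta `c(shape1, shape2)` of the Beta
#'   distribution that drifted samples draw per-variant allele-ratio
#'   parameters from (default Beta(2, 6), mean 0.25: subclonal culture
#'   variants).
#' @param cnv_rate Expected background de novo CNVs per child.
#' @param seed Integer seed; all simulation is deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_affected = 1869, n_unaffected = 1874,
                        collection = "SSC", dna_source_mix = 0,
                        base_sub_rate = 65, paternal_age_slope = 0.35,
                        coverage_mean = 30, coverage_sd = 5,
                        allele_ratio_p = 0.47,
                        class_proportions = NULL,
                        planted_AD = NULL,
                        drift_fraction = 0, drift_count_multiplier = 5,
                        drift_allele_ratio_beta = c(2, 6),
                        cnv_rate = 0.08, seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- c(LGD = 0.0013, SYN = 0.0040, MIS = 0.0085,
                           ISB = 0.3077, IID = 0.0323, IGSB = 0.4769,
                           IGID = 0.0477, OTHER = 0.1216)
  }
  if (is.null(planted_AD)) {
    planted_AD <- stats::setNames(numeric(length(EFFECT_CLASSES)), EFFECT_CLASSES)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stopf("class_proportions must sum to 1 (got %.12f)", sum(class_proportions))
  }
  if (!all(names(class_proportions) %in% EFFECT_CLASSES)) {
    stopf("unknown class in class_proportions")
  }
  if (any(planted_AD < 0 | planted_AD > 100)) {
    stopf("planted_AD values must lie in [0, 100]")
  }
  if (dna_source_mix < 0 || dna_source_mix > 1) {
    stopf("dna_source_mix must lie in [0, 1]")
  }
  if (allele_ratio_p <= 0 || allele_ratio_p >= 1) {
    stopf("allele_ratio_p must lie in (0, 1)")
  }
  if (drift_count_multiplier <= 1) stopf("drift_count_multiplier must exceed 1")
  structure(list(
    n_affected = n_affected, n_unaffected = n_unaffected,
    collection = collection, dna_source_mix = dna_source_mix,
    base_sub_rate = base_sub_rate, paternal_age_slope = paternal_age_slope,
    coverage_mean = coverage_mean, coverage_sd = coverage_sd,
    allele_ratio_p = allele_ratio_p,
    class_proportions = class_proportions, planted_AD = planted_AD,
    drift_fraction = drift_fraction,
    drift_count_multiplier = drift_count_multiplier,
    drift_allele_ratio_beta = drift_allele_ratio_beta,
    cnv_rate = cnv_rate, seed = as.integer(seed)), class = "cohort_spec")
}

## Gene templates used by the toy genome. Coordinates are relative 0-based
## half-open; coding lengths are multiples of 3 by construction.
TOY_TEMPLATES <- list(
  rich = list(width = 2500L,
              exon_starts = c(0L, 300L, 900L, 1500L, 2100L),
              exon_ends = c(100L, 700L, 1300L, 1900L, 2500L),
              cds = c(400L, 1802L)),
  simple = list(width = 800L,
                exon_starts = c(0L, 500L), exon_ends = c(300L, 800L),
                cds = c(60L, 740L)),
  noncoding = list(width = 600L,
                   exon_starts = c(0L, 400L), exon_ends = c(200L, 600L),
                   cds = c(0L, 0L)),
  single = list(width = 600L,
                exon_starts = 0L, exon_ends = 600L,
                cds = c(90L, 510L)))

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a deterministic toy genome
#'
#' Builds a small multi-chromosome genome (two autosomes and an X) with
#' random sequence and a set of transcripts cycling through four templates:
#' a five-exon coding gene with UTR-splitting and intercoding introns, a
#' two-exon coding gene, a noncoding gene, and a single-exon coding gene.
#' Coding sequences are rewritten free of internal stop codons. Every
#' functional-effect class therefore has eligible placement regions, which
#' are enumerated and cached for the call simulator.
#'
#' @param n_genes Number of genes (at least 5, so all templates and all
#'   effect classes are realizable).
#' @param seed Integer seed.
#' @return A `toy_genome` list: `chrom_lengths`, `transcripts` (a
#'   `gene_model`), `seqs` ([Biostrings::DNAStringSet]), cached interval
#'   `features` and placement `pools`.
#' @export
make_toy_genome <- function(n_genes = 8, seed = 1L) {
  if (n_genes < 5) {
    stopf("n_genes must be >= 5 to realize every effect class")
  }
  with_seed(seed, {
    templates <- rep(names(TOY_TEMPLATES), length.out = n_genes)
    chroms <- rep(c("chr1", "chr2"), length.out = n_genes)
    strands <- rep(c("+", "-"), length.out = n_genes)
    cursor <- c(chr1 = 3000L, chr2 = 3000L)
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      tpl <- TOY_TEMPLATES[[templates[i]]]
      chrom <- chroms[i]
      g <- cursor[[chrom]]
      rows[[i]] <- list(
        gene_symbol = sprintf("G%03d", i),
        transcript_id = sprintf("T%03d", i),
        chrom = chrom, strand = strands[i],
        tx_start = g, tx_end = g + tpl$width,
        cds_start = g + tpl$cds[1], cds_end = g + tpl$cds[2],
        exon_starts = list(g + tpl$exon_starts),
        exon_ends = list(g + tpl$exon_ends))
      cursor[[chrom]] <- g + tpl$width + 4000L
    }
    gm <- do.call(rbind, lapply(rows, function(r) {
      d <- data.frame(r[setdiff(names(r), c("exon_starts", "exon_ends"))],
                      stringsAsFactors = FALSE)
      d$exon_starts <- r$exon_starts
      d$exon_ends <- r$exon_ends
      d
    }))
    class(gm) <- c("gene_model", "data.frame")
    chrom_lengths <- c(cursor, chrX = 20000L)
    chrom_lengths[] <- as.integer(chrom_lengths)

    bases <- c("A", "C", "G", "T")
    chars <- lapply(chrom_lengths, function(L) sample(bases, L, replace = TRUE))
    ## rewrite every CDS with stop-free codons (strand-aware)
    non_stop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    for (i in seq_len(nrow(gm))) {
      if (gm$cds_end[i] <= gm$cds_start[i]) next
      map <- cds_map(gm, i)
      ncod <- length(map$pos) %/% 3L
      cds_chars <- unlist(strsplit(sample(non_stop, ncod, replace = TRUE), ""))
      cds_chars <- c(cds_chars, sample(bases, length(map$pos) - 3L * ncod,
                                       replace = TRUE))
      genomic <- if (gm$strand[i] == "-") unname(COMPLEMENT[cds_chars]) else cds_chars
      chars[[gm$chrom[i]]][map$pos] <- genomic
    }
    seqs <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
    names(seqs) <- names(chrom_lengths)

    genome <- structure(list(
      chrom_lengths = chrom_lengths, transcripts = gm, seqs = seqs,
      chars = chars, features = gm_features(gm)), class = "toy_genome")
    genome$pools <- build_placement_pools(genome)
    genome
  })
}

## Enumerate class-consistent placement sites/intervals once per genome.
build_placement_pools <- function(genome) {
  gm <- genome$transcripts
  feats <- genome$features
  chars <- genome$chars
  bases <- c("A", "C", "G", "T")

  sub_rows <- list()
  for (i in seq_len(nrow(gm))) {
    if (gm$cds_end[i] <= gm$cds_start[i]) next
    map <- cds_map(gm, i, genome$seqs)
    L <- 3L * (length(map$pos) %/% 3L)
    for (o in seq_len(L)) {
      pos <- map$pos[o]
      ref <- chars[[gm$chrom[i]]][pos]
      ci <- (o - 1L) %/% 3L
      w <- (o - 1L) %% 3L + 1L
      codon <- map$seq[(ci * 3L + 1L):(ci * 3L + 3L)]
      old_aa <- translate_codon(paste(codon, collapse = ""))
      for (alt in setdiff(bases, ref)) {
        alt_cds <- if (gm$strand[i] == "-") unname(COMPLEMENT[alt]) else alt
        codon2 <- codon
        codon2[w] <- alt_cds
        new_aa <- translate_codon(paste(codon2, collapse = ""))
        cls <- if (new_aa == old_aa) "SYN"
               else if (new_aa == "*") "LGD" else "MIS"
        sub_rows[[length(sub_rows) + 1L]] <-
          c(cls, gm$chrom[i], pos, ref, alt)
      }
    }
  }
  sub <- as.data.frame(do.call(rbind, sub_rows), stringsAsFactors = FALSE)
  names(sub) <- c("class", "chrom", "pos", "ref", "alt")
  sub$pos <- as.integer(sub$pos)

  splice <- unique(data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(feats$splice)), each = 2),
    pos = c(rbind(GenomicRanges::start(feats$splice),
                  GenomicRanges::end(feats$splice))),
    stringsAsFactors = FALSE))

  ic <- feats$intercoding
  isb <- data.frame(chrom = as.character(GenomicRanges::seqnames(ic)),
                    lo = GenomicRanges::start(ic) + 3L,
                    hi = GenomicRanges::end(ic) - 8L,
                    stringsAsFactors = FALSE)
  isb <- isb[isb$hi > isb$lo, , drop = FALSE]

  ## intergenic: autosomal complement of transcript spans, 10 bp padding
  ig <- list()
  for (chrom in c("chr1", "chr2")) {
    sel <- gm$chrom == chrom
    bounds <- sort(c(1L, gm$tx_start[sel] + 1L - 10L,
                     gm$tx_end[sel] + 10L,
                     genome$chrom_lengths[[chrom]]))
    starts <- bounds[c(TRUE, FALSE)]
    ends <- bounds[c(FALSE, TRUE)]
    keep <- ends - starts > 40
    ig[[chrom]] <- data.frame(chrom = chrom, lo = starts[keep] + 10L,
                              hi = ends[keep] - 16L, stringsAsFactors = FALSE)
  }
  ig <- do.call(rbind, ig)
  other <- data.frame(chrom = "chrX", lo = 100L,
                      hi = genome$chrom_lengths[["chrX"]] - 100L,
                      stringsAsFactors = FALSE)
  list(sub = sub, splice = splice,
       intervals = list(ISB = isb, IID = isb, IGSB = ig, IGID = ig,
                        OTHER = other))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Simulate a cohort of sequenced children
#'
#' Parental ages are drawn from a normal distribution (mean 33, sd 5,
#' truncated to 18–60 years), coverage from the spec's normal (truncated
#' below at 1x), sex at random, and DNA source LCL with probability
#' `dna_source_mix`. Among LCL children a fraction `drift_fraction` is marked
#' as affected by cell-line genetic drift; the truth flag is carried in the
#' `.drifted` column for validation purposes only — no analysis code reads it.
#'
#' @param spec A [cohort_spec()].
#' @return A pedigree data frame (see [read_pedigree()]) with the extra
#'   logical column `.drifted`.
#' @export
simulate_children <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_affected + spec$n_unaffected
    lcl <- stats::runif(n) < spec$dna_source_mix
    df <- data.frame(
      child_id = sprintf("ch%05d", seq_len(n)),
      family_id = sprintf("fam%05d", seq_len(n)),
      collection = spec$collection,
      affected = rep(c(TRUE, FALSE), c(spec$n_affected, spec$n_unaffected)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      dna_source = ifelse(lcl, "LCL", "WB"),
      mother_age = rnorm_trunc(n, 33, 5, 18, 60),
      father_age = rnorm_trunc(n, 33, 5, 18, 60),
      mean_coverage = pmax(1, stats::rnorm(n, spec$coverage_mean,
                                           spec$coverage_sd)),
      stringsAsFactors = FALSE)
    df$.drifted <- lcl & stats::runif(n) < spec$drift_fraction
    df
  })
}

#' Proxy detection probability for de novo substitutions given coverage
#'
#' Smooth monotone saturating curve `1 - exp(-coverage / 10)` used by the
#' call simulator to thin true events, and as the per-child power estimate
#' when adjusting observed counts in the drift filter.
#'
#' @param coverage Mean fold coverage.
#' @return Detection probability in (0, 1].
#' @export
detection_probability <- function(coverage) {
  1 - exp(-pmax(coverage, 0) / 10)
}

sample_interval_positions <- function(pool, n) {
  w <- pool$hi - pool$lo + 1
  row <- sample.int(nrow(pool), n, replace = TRUE, prob = w)
  pos <- pool$lo[row] + floor(stats::runif(n) * w[row])
  data.frame(chrom = pool$chrom[row], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

## Construct variant alleles for `n` events of one class.
place_events <- function(class, n, genome) {
  if (n == 0) return(NULL)
  pools <- genome$pools
  chars <- genome$chars
  bases <- c("A", "C", "G", "T")
  pick_sub <- function(df, n) {
    df[sample.int(nrow(df), n, replace = TRUE), , drop = FALSE]
  }
  if (class %in% c("SYN", "MIS")) {
    s <- pick_sub(pools$sub[pools$sub$class == class, ], n)
    return(data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                      stringsAsFactors = FALSE))
  }
  if (class == "LGD") {
    kind <- sample(c("nonsense", "splice", "frameshift"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
    out <- vector("list", 3)
    n1 <- sum(kind == "nonsense")
    if (n1 > 0) {
      s <- pick_sub(pools$sub[pools$sub$class == "LGD", ], n1)
      out[[1]] <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref,
                             alt = s$alt, stringsAsFactors = FALSE)
    }
    n2 <- sum(kind == "splice")
    if (n2 > 0) {
      s <- pick_sub(pools$splice, n2)
      ref <- mapply(function(ch, p) chars[[ch]][p], s$chrom, s$pos)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      out[[2]] <- data.frame(chrom = s$chrom, pos = s$pos, ref = unname(ref),
                             alt = unname(alt), stringsAsFactors = FALSE)
    }
    n3 <- sum(kind == "frameshift")
    if (n3 > 0) {
      ## 1-bp deletion of a coding base, left-anchored
      s <- pick_sub(pools$sub, n3)
      anchor <- s$pos - 1L
      ref <- mapply(function(ch, p) paste(chars[[ch]][p:(p + 1L)], collapse = ""),
                    s$chrom, anchor)
      alt <- substr(ref, 1, 1)
      out[[3]] <- data.frame(chrom = s$chrom, pos = anchor, ref = unname(ref),
                             alt = alt, stringsAsFactors = FALSE)
    }
    return(do.call(rbind, out))
  }
  pool <- pools$intervals[[class]]
  if (is.null(pool) || nrow(pool) == 0) {
    stopf("no eligible placement interval for class %s", class)
  }
  at <- sample_interval_positions(pool, n)
  if (class %in% c("ISB", "IGSB", "OTHER")) {
    ref <- mapply(function(ch, p) chars[[ch]][p], at$chrom, at$pos)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    return(data.frame(chrom = at$chrom, pos = at$pos, ref = unname(ref),
                      alt = unname(alt), stringsAsFactors = FALSE))
  }
  ## indel classes: deletions or insertions of 1-3 bp
  len <- sample.int(3, n, replace = TRUE)
  is_del <- stats::runif(n) < 0.5
  ref <- character(n); alt <- character(n)
  for (k in seq_len(n)) {
    ch <- at$chrom[k]; p <- at$pos[k]
    if (is_del[k]) {
      ref[k] <- paste(chars[[ch]][p:(p + len[k])], collapse = "")
      alt[k] <- chars[[ch]][p]
    } else {
      ref[k] <- chars[[ch]][p]
      alt[k] <- paste(c(chars[[ch]][p], sample(bases, len[k], replace = TRUE)),
                      collapse = "")
    }
  }
  data.frame(chrom = at$chrom, pos = at$pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Simulate de novo call sets for a cohort
#'
#' Per child, the number of de novo events is Poisson with rate
#' `(base_sub_rate + paternal_age_slope * father_age)` thinned by
#' [detection_probability()] of the child's coverage, and multiplied by
#' `drift_count_multiplier` for drifted samples. Events are assigned classes
#' by `class_proportions` and placed at class-consistent genomic sites of the
#' toy genome. Read support is drawn at Poisson(coverage) depth with
#' alternative-allele probability `allele_ratio_p` for clean samples, or a
#' Beta-distributed low ratio for drifted samples. Affected children
#' additionally receive one extra event of class k with probability
#' `planted_AD[k]/100`. Background de novo CNVs are placed uniformly on the
#' autosomes with log-uniform sizes.
#'
#' @param cohort Data frame from [simulate_children()].
#' @param genome A [make_toy_genome()] genome.
#' @param spec The [cohort_spec()] used for the cohort.
#' @return A list with data frames `small` (with truth column `sim_class`)
#'   and `cnvs`.
#' @export
simulate_denovo_calls <- function(cohort, genome, spec) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(genome, "toy_genome"))
  prop <- spec$class_proportions
  active <- names(prop)[prop > 0]
  for (cl in active) {
    if (cl %in% c("ISB", "IID", "IGSB", "IGID", "OTHER") &&
        nrow(genome$pools$intervals[[cl]]) == 0) {
      stopf("class %s has proportion > 0 but no eligible interval", cl)
    }
  }
  with_seed(spec$seed + 1L, {
    n <- nrow(cohort)
    drifted <- if (is.null(cohort$.drifted)) rep(FALSE, n) else cohort$.drifted
    lambda <- (spec$base_sub_rate +
                 spec$paternal_age_slope * cohort$father_age) *
      detection_probability(cohort$mean_coverage)
    lambda[drifted] <- lambda[drifted] * spec$drift_count_multiplier
    counts <- stats::rpois(n, lambda)

    child <- rep(cohort$child_id, counts)
    cls <- sample(names(prop), sum(counts), replace = TRUE, prob = prop)

    ## planted contributory events: at most one extra per class per child
    extra_child <- character(0); extra_cls <- character(0)
    planted <- spec$planted_AD[spec$planted_AD > 0]
    if (length(planted) > 0) {
      aff <- cohort$child_id[cohort$affected]
      for (k in names(planted)) {
        gets <- aff[stats::runif(length(aff)) < planted[[k]] / 100]
        extra_child <- c(extra_child, gets)
        extra_cls <- c(extra_cls, rep(k, length(gets)))
      }
    }
    child <- c(child, extra_child)
    cls <- c(cls, extra_cls)

    out <- list()
    for (k in unique(cls)) {
      idx <- which(cls == k)
      pl <- place_events(k, length(idx), genome)
      pl$child_id <- child[idx]
      pl$sim_class <- k
      out[[k]] <- pl
    }
    small <- do.call(rbind, out)
    rownames(small) <- NULL

    ## read support
    cov <- cohort$mean_coverage[match(small$child_id, cohort$child_id)]
    depth <- pmax(1L, stats::rpois(nrow(small), cov))
    is_drift <- drifted[match(small$child_id, cohort$child_id)]
    p <- rep(spec$allele_ratio_p, nrow(small))
    if (any(is_drift)) {
      p[is_drift] <- stats::rbeta(sum(is_drift),
                                  spec$drift_allele_ratio_beta[1],
                                  spec$drift_allele_ratio_beta[2])
    }
    alt_reads <- pmax(1L, stats::rbinom(nrow(small), depth, p))
    small$ref_reads <- depth - alt_reads
    small$alt_reads <- alt_reads
    small$var_type <- ifelse(nchar(small$ref) == 1 & nchar(small$alt) == 1,
                             "SUB", "INDEL")
    small$alt_ratio <- small$alt_reads / depth
    small <- small[, c("child_id", "chrom", "pos", "ref", "alt", "ref_reads",
                       "alt_reads", "var_type", "alt_ratio", "sim_class")]

    ## background CNVs on the autosomes
    ncnv <- stats::rpois(n, spec$cnv_rate)
    cn_child <- rep(cohort$child_id, ncnv)
    m <- length(cn_child)
    cnvs <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), child_id = character(0),
                       change = character(0), size_bp = integer(0),
                       stringsAsFactors = FALSE)
    if (m > 0) {
      size <- as.integer(round(exp(stats::runif(m, log(500), log(8000)))))
      chrom <- sample(c("chr1", "chr2"), m, replace = TRUE)
      maxs <- genome$chrom_lengths[chrom] - size
      start <- as.integer(floor(stats::runif(m) * maxs))
      cnvs <- data.frame(chrom = chrom, start = start, end = start + size,
                         child_id = cn_child,
                         change = sample(c("DEL", "DUP"), m, replace = TRUE),
                         size_bp = size, stringsAsFactors = FALSE)
    }
    list(small = small, cnvs = cnvs)
  })
}

#' Tabulate per-child event counts by class
#'
#' @param variants Annotated small-variant data frame (uses `effect` when
#'   present, otherwise the simulator's `sim_class` truth column).
#' @param cohort Pedigree data frame; children without events get zero rows.
#' @param class_col Column holding the class labels.
#' @return A data frame `child_id` x one column per effect class.
#' @export
count_events_by_class <- function(variants, cohort,
                                  class_col = if ("effect" %in% names(variants))
                                    "effect" else "sim_class") {
  tab <- table(factor(variants$child_id, levels = cohort$child_id),
               factor(as.character(variants[[class_col]]),
                      levels = EFFECT_CLASSES))
  out <- as.data.frame.matrix(tab)
  out <- cbind(data.frame(child_id = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Fast per-child count simulator for burden inference studies
#'
#' Generates child-level (subject, normalization) Poisson count pairs that
#' share a per-child exposure factor (Gamma with mean 1), emulating the joint
#' influence of coverage, parental age and residual drift on both classes
#' without placing variants on a genome. Affected children receive one extra
#' subject-class event with probability `planted_ad / 100`.
#'
#' @param n_affected,n_unaffected Group sizes.
#' @param subject_rate,norm_rate Per-child event rates (defaults mirror
#'   realistic de novo LGD and synonymous magnitudes).
#' @param planted_ad Planted ascertainment differential, percent of affected.
#' @param exposure_cv Coefficient of variation of the shared exposure factor.
#' @param mode Normalization mode of the returned input.
#' @param seed Integer seed.
#' @return A [burden_input()].
#' @export
simulate_burden_counts <- function(n_affected, n_unaffected,
                                   subject_rate = 0.085, norm_rate = 0.26,
                                   planted_ad = 0, exposure_cv = 0.15,
                                   mode = c("event_class", "child_count"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    draw <- function(n, planted) {
      e <- if (exposure_cv > 0) {
        stats::rgamma(n, shape = 1 / exposure_cv^2, rate = 1 / exposure_cv^2)
      } else rep(1, n)
      S <- stats::rpois(n, subject_rate * e)
      if (planted > 0) S <- S + (stats::runif(n) < planted / 100)
      N <- stats::rpois(n, norm_rate * e)
      data.frame(subject = S, norm = N)
    }
    a <- draw(n_affected, planted_ad)
    a$child_id <- sprintf("a%05d", seq_len(n_affected))
    u <- draw(n_unaffected, 0)
    u$child_id <- sprintf("u%05d", seq_len(n_unaffected))
    burden_input(a, u, mode = mode)
  })
}
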