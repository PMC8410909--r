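## Detection-power simulation.
##
## SNV power: for random positions, parents receive (depth, 0) ref/alt
## counts and the child an alternative count drawn Binomial(p = 0.47, N =
## child depth); the 2x3 count matrix goes through a trio genotyper and the
## detected fraction estimates the per-trio power. The genotyper here is a
## documented stand-in with a binomial likelihood-ratio score and an
## allele-ratio consistency test; its thresholds play the role of, but are
## not numerically comparable to, production de novo caller scores.
##
## CNV power: deletion-like signal is planted by transplanting a male
## child's hemizygous X-chromosome read-depth bins into a random autosomal
## window of the same size, and a read-depth deletion finder is asked to
## recover the planted window.

#' Stand-in trio genotyper configuration
#'
#' @param alt_ratio_null Expected alternative-allele read fraction of a true
#'   heterozygous de novo call (0.47).
#' @param min_denovo_score Minimum log-likelihood-ratio (natural log) of the
#'   de novo-heterozygous-child model over the all-reference model.
#' @param min_consistency Minimum two-sided binomial p-value for the child's
#'   allele-ratio consistency with `alt_ratio_null`.
#' @param min_alt_reads Minimum alternative reads in the child.
#' @param error_rate Sequencing error rate for the all-reference model.
#' @return A `genotyper_config` list.
#' @export
genotyper_config <- function(alt_ratio_null = 0.47, min_denovo_score = 20,
                             min_consistency = 0.001, min_alt_reads = 3,
                             error_rate = 0.005) {
  structure(list(alt_ratio_null = alt_ratio_null,
                 min_denovo_score = min_denovo_score,
                 min_consistency = min_consistency,
                 min_alt_reads = min_alt_reads,
                 error_rate = error_rate), class = "genotyper_config")
}

## Vectorized core: all arguments are equal-length vectors of read counts.
genotype_batch <- function(mother_ref, mother_alt, father_ref, father_alt,
                           child_ref, child_alt, config) {
  depth <- child_ref + child_alt
  p <- config$alt_ratio_null
  ## parent terms are identical under both models and cancel in the ratio
  llr <- stats::dbinom(child_alt, depth, p, log = TRUE) -
    stats::dbinom(child_alt, depth, config$error_rate, log = TRUE)
  ## two-sided exact binomial consistency p (doubled smaller tail)
  lower <- stats::pbinom(child_alt, depth, p)
  upper <- stats::pbinom(child_alt - 1, depth, p, lower.tail = FALSE)
  consistency <- pmin(1, 2 * pmin(lower, upper))
  child_alt >= config$min_alt_reads &
    mother_alt == 0 & father_alt == 0 &
    depth > 0 &
    llr >= config$min_denovo_score &
    consistency > config$min_consistency
}

#' Stand-in trio genotyper for one position
#'
#' @param counts 2x3 matrix of read counts: rows `ref`/`alt`, columns
#'   `mother`/`father`/`child`.
#' @param config A [genotyper_config()].
#' @return `"DENOVO"` or `"NOT"`.
#' @export
standin_genotyper <- function(counts, config = genotyper_config()) {
  if (!is.matrix(counts) || !all(dim(counts) == c(2, 3)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be a 2x3 matrix of non-negative integers")
  }
  ok <- genotype_batch(counts[1, 1], counts[2, 1], counts[1, 2], counts[2, 2],
                       counts[1, 3], counts[2, 3], config)
  if (ok) "DENOVO" else "NOT"
}

#' Coverage sampler for a trio
#'
#' @param mother,father,child Mean coverages; per-position depths are
#'   Poisson around these means.
#' @return A function of `n` returning a data frame of depths.
#' @export
trio_coverage_sampler <- function(mother = 30, father = 30, child = mother) {
  function(n) {
    data.frame(mother = stats::rpois(n, mother),
               father = stats::rpois(n, father),
               child = stats::rpois(n, child))
  }
}

#' Power to detect de novo substitutions for one trio
#'
#' @param coverage_sampler Function of `n` returning a data frame with
#'   columns `mother`, `father`, `child` of per-position read depths (see
#'   [trio_coverage_sampler()]), or a single number taken as a constant
#'   depth for all three.
#' @param config A [genotyper_config()].
#' @param n_positions Number of simulated positions.
#' @param seed Integer seed.
#' @return A data frame `n_sim`, `n_detected`, `power`.
#' @export
snv_power <- function(coverage_sampler, config = genotyper_config(),
                      n_positions = 10000, seed = 1L) {
  if (n_positions < 100) {
    warnf("n_positions < 100 gives an unstable power estimate")
  }
  if (is.numeric(coverage_sampler)) {
    depth <- coverage_sampler
    coverage_sampler <- function(n) {
      data.frame(mother = rep(depth, n), father = rep(depth, n),
                 child = rep(depth, n))
    }
  }
  with_seed(seed, {
    cov <- coverage_sampler(n_positions)
    child_alt <- stats::rbinom(n_positions, cov$child, config$alt_ratio_null)
    detected <- genotype_batch(cov$mother, integer(n_positions),
                               cov$father, integer(n_positions),
                               cov$child - child_alt, child_alt, config)
    data.frame(n_sim = n_positions, n_detected = sum(detected),
               power = mean(detected))
  })
}

#' Read-depth bin matrix
#'
#' @param values Numeric matrix, samples x bins, of per-sample normalized
#'   bin counts (row median 1 over the autosomes).
#' @param bins Data frame `chrom`, `start`, `end` (0-based half-open), one
#'   row per column of `values`.
#' @param bin_width Bin width in bp.
#' @param sex Per-sample sex (`M`/`F`), used to select male children for the
#'   X-swap simulation.
#' @param mask Optional logical vector marking bins excluded from region
#'   selection (pseudoautosomal/telomeric/centromeric analogues).
#' @return A `bin_matrix` object.
#' @export
bin_matrix <- function(values, bins, bin_width, sex = NULL, mask = NULL) {
  stopifnot(ncol(values) == nrow(bins))
  if (any(values < 0)) stopf("bin values must be non-negative")
  if (is.null(mask)) mask <- rep(FALSE, nrow(bins))
  structure(list(values = values, bins = bins, bin_width = bin_width,
                 sex = sex, mask = mask), class = "bin_matrix")
}

#' Simulate a read-depth bin matrix for a trio population
#'
#' Children carry Poisson bin counts around a common per-bin mean; male
#' children's X-chromosome bins run at half the autosomal mean (hemizygous).
#' Counts are normalized per sample by the autosomal median. The first and
#' last `edge_mask` bins of every chromosome are masked, standing in for
#' telomeric exclusion zones.
#'
#' @param n_children Number of children (one per trio).
#' @param autosome_bins,x_bins Bins on the single autosome and on chrX.
#' @param bin_width Bin width in bp.
#' @param mean_count Mean reads per bin.
#' @param male_fraction Fraction of male children.
#' @param edge_mask Number of masked bins at each chromosome end.
#' @param seed Integer seed.
#' @return A [bin_matrix()].
#' @export
simulate_bin_matrix <- function(n_children = 40, autosome_bins = 1200,
                                x_bins = 600, bin_width = 100,
                                mean_count = 40, male_fraction = 0.5,
                                edge_mask = 5, seed = 1L) {
  with_seed(seed, {
    sex <- sample(c("M", "F"), n_children, replace = TRUE,
                  prob = c(male_fraction, 1 - male_fraction))
    nb <- autosome_bins + x_bins
    lambda <- matrix(mean_count, n_children, nb)
    xcols <- autosome_bins + seq_len(x_bins)
    lambda[sex == "M", xcols] <- mean_count / 2
    counts <- matrix(stats::rpois(n_children * nb, lambda), n_children, nb)
    med <- apply(counts[, seq_len(autosome_bins), drop = FALSE], 1,
                 stats::median)
    values <- counts / med
    bins <- data.frame(
      chrom = rep(c("chr1", "chrX"), c(autosome_bins, x_bins)),
      start = c(seq_len(autosome_bins) - 1L, seq_len(x_bins) - 1L) * bin_width,
      stringsAsFactors = FALSE)
    bins$end <- bins$start + bin_width
    mask <- rep(FALSE, nb)
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      mask[utils::head(idx, edge_mask)] <- TRUE
      mask[utils::tail(idx, edge_mask)] <- TRUE
    }
    bin_matrix(values, bins, bin_width, sex = sex, mask = mask)
  })
}

#' Z-score deletion finder over a bin matrix
#'
#' A minimal read-depth deletion caller used by the power harness: per bin,
#' values are z-scored against the across-sample column distribution, and
#' maximal runs of at least `min_consecutive_bins` bins with
#' `z <= -z_threshold` within one chromosome become candidate deletion
#' calls. Zero-variance columns carry no signal.
#'
#' @param bins A [bin_matrix()] (at least 20 samples for stable column
#'   statistics).
#' @param z_threshold Per-bin z-score threshold (positive).
#' @param min_consecutive_bins Minimum run length.
#' @param samples Optional subset of sample indices to report calls for.
#' @param columns Optional subset of column indices to scan.
#' @return Data frame `sample`, `chrom`, `start`, `end`, `n_bins` (0-based
#'   half-open coordinates).
#' @export
zscore_deletion_finder <- function(bins, z_threshold = 3,
                                   min_consecutive_bins = 3,
                                   samples = NULL, columns = NULL) {
  stopifnot(inherits(bins, "bin_matrix"))
  v <- bins$values
  if (nrow(v) < 20) {
    stopf("need at least 20 samples for stable column statistics (got %d)",
          nrow(v))
  }
  if (is.null(columns)) columns <- seq_len(ncol(v))
  v <- v[, columns, drop = FALSE]
  bdf <- bins$bins[columns, , drop = FALSE]
  n <- nrow(v)
  mu <- colMeans(v)
  sd_ <- sqrt(pmax(0, colMeans(v^2) - mu^2) * n / (n - 1))
  if (is.null(samples)) samples <- seq_len(nrow(v))
  calls <- list()
  for (s in samples) {
    z <- ifelse(sd_ > 0, (v[s, ] - mu) / sd_, 0)
    low <- z <= -z_threshold
    if (!any(low)) next
    r <- rle(paste0(bdf$chrom, "_", low))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- grepl("_TRUE$", r$values) & r$lengths >= min_consecutive_bins
    for (j in which(hit)) {
      calls[[length(calls) + 1L]] <- data.frame(
        sample = s, chrom = bdf$chrom[starts[j]],
        start = bdf$start[starts[j]], end = bdf$end[ends[j]],
        n_bins = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) {
    return(data.frame(sample = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_bins = integer(0)))
  }
  do.call(rbind, calls)
}

#' Power to detect de novo deletions by size (X region-swap simulation)
#'
#' Per simulation: a random male child, a random unmasked X-chromosome
#' window of the requested size, and a random unmasked autosomal window of
#' the same size are chosen; the child's autosomal bin values over the
#' window are replaced by his hemizygous X-chromosome values (deletion-like
#' half-depth signal) and the deletion finder is run on the modified
#' autosomal matrix. A simulation counts as detected when any call for that
#' child overlaps the planted window by at least one bp.
#'
#' @param bins A [bin_matrix()] with chrX and at least one autosome and male
#'   children flagged in `sex`.
#' @param sizes Deletion sizes in bp (each at least one bin width).
#' @param n_sim Simulations per size.
#' @param z_threshold,min_consecutive_bins Finder parameters.
#' @param sham If TRUE, no values are replaced (false-call control).
#' @param seed Integer seed.
#' @return Data frame `size_bp`, `n_sim`, `n_detected`, `power`.
#' @export
cnv_power_by_size <- function(bins, sizes = seq(1000, 10000, by = 1000),
                              n_sim = 10000, z_threshold = 3,
                              min_consecutive_bins = 3, sham = FALSE,
                              seed = 1L) {
  stopifnot(inherits(bins, "bin_matrix"))
  if (any(sizes < bins$bin_width)) {
    stopf("region size below one bin width (%d bp)", bins$bin_width)
  }
  males <- which(bins$sex == "M")
  if (length(males) == 0) stopf("no male children in the bin matrix")
  xcols <- which(bins$bins$chrom == "chrX" & !bins$mask)
  autos <- setdiff(unique(bins$bins$chrom), "chrX")
  if (length(xcols) == 0 || length(autos) == 0) {
    stopf("bin matrix must include chrX and at least one autosome")
  }
  pick_window <- function(cols, nb) {
    ## contiguous run of nb unmasked bins
    if (nb == 1) return(cols[sample.int(length(cols), 1)])
    ok <- which(diff(cols, lag = nb - 1) == nb - 1)
    if (length(ok) == 0) stopf("no eligible region of %d bins", nb)
    st <- cols[ok[sample.int(length(ok), 1)]]
    st:(st + nb - 1L)
  }
  with_seed(seed, {
    out <- lapply(sizes, function(size) {
      nb <- as.integer(size %/% bins$bin_width)
      detected <- 0L
      for (i in seq_len(n_sim)) {
        child <- if (length(males) == 1) males else sample(males, 1)
        xw <- pick_window(xcols, nb)
        auto <- if (length(autos) == 1) autos else sample(autos, 1)
        acols <- which(bins$bins$chrom == auto & !bins$mask)
        aw <- pick_window(acols, nb)
        mod <- bins
        if (!sham) mod$values[child, aw] <- bins$values[child, xw]
        scan_cols <- which(bins$bins$chrom == auto)
        calls <- zscore_deletion_finder(mod, z_threshold,
                                        min_consecutive_bins,
                                        samples = child, columns = scan_cols)
        if (nrow(calls) > 0) {
          w_start <- bins$bins$start[aw[1]]
          w_end <- bins$bins$end[aw[nb]]
          if (any(calls$start < w_end & calls$end > w_start)) {
            detected <- detected + 1L
          }
        }
      }
      data.frame(size_bp = size, n_sim = n_sim, n_detected = detected,
                 power = detected / n_sim)
    })
    do.call(rbind, out)
  })
}
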