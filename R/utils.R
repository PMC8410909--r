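#' @keywords internal
"_PACKAGE"

## Canonical order of small-variant functional classes. OTHER absorbs
## everything outside the tested taxonomy (UTRs, non-intercoding introns,
## noncoding transcripts, in-frame coding indels, chrX events).
EFFECT_CLASSES <- c("LGD", "SYN", "MIS", "ISB", "IID", "IGSB", "IGID", "OTHER")

CNV_CLASSES <- c("INTERGENIC", "CODING", "GENIC_NONCODING")
CNV_SUBCLASSES <- c("CODING", "INTERCODING_INTRONIC", "PERIPHERAL")

dnb_log <- function(...) {
  message(sprintf("[dnburden] %s", sprintf(...)))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Normalize chromosome names to the chr-prefixed convention.
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

is_chrX <- function(chrom) normalize_chrom(chrom) == "chrX"

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
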