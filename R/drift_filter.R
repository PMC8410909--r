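## Cell-line genetic drift sample QC.
##
## Lymphoblastoid cell lines accumulate somatic variants during
## immortalization and culture; these masquerade as de novo calls, inflating
## per-child substitution counts and depressing alternative allele ratios.
## Whole-blood children define the clean reference distribution: a
## two-dimensional Gaussian over (power-adjusted substitution count, mean
## alternative allele ratio), with a pass ellipse at the 99.9% density
## contour (Mahalanobis^2 <= qchisq(0.999, df = 2) = 13.8155).

#' Per-child drift statistics
#'
#' @param variants Small-variant data frame for one child; only substitutions
#'   are used (indels are excluded).
#' @param snv_power Estimated power to detect de novo substitutions in this
#'   child, in (0, 1]; the adjusted count is `observed / snv_power`.
#' @return One-row data frame with `observed_subs`, `snv_power`,
#'   `adjusted_subs`, `mean_alt_ratio` and a `complete` flag (FALSE when the
#'   child has no substitutions, leaving the mean ratio undefined).
#' @export
compute_drift_stats <- function(variants, snv_power) {
  if (length(snv_power) != 1 || !is.finite(snv_power) ||
      snv_power <= 0 || snv_power > 1) {
    stopf("snv_power must be a single value in (0, 1]")
  }
  subs <- variants[variants$var_type == "SUB", , drop = FALSE]
  n <- nrow(subs)
  ratio <- if (n > 0) {
    mean(subs$alt_reads / (subs$alt_reads + subs$ref_reads))
  } else NA_real_
  data.frame(observed_subs = n, snv_power = snv_power,
             adjusted_subs = n / snv_power, mean_alt_ratio = ratio,
             complete = n > 0)
}

#' Drift statistics for a whole cohort
#'
#' @param variants Small-variant data frame (all children).
#' @param power Data frame with columns `child_id` and `snv_power`, or a
#'   named numeric vector.
#' @return Data frame with one row per entry of `power`.
#' @export
drift_stats <- function(variants, power) {
  if (is.numeric(power)) {
    power <- data.frame(child_id = names(power), snv_power = unname(power),
                        stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(power)), function(i) {
    v <- variants[variants$child_id == power$child_id[i], , drop = FALSE]
    s <- compute_drift_stats(v, power$snv_power[i])
    cbind(data.frame(child_id = power$child_id[i], stringsAsFactors = FALSE), s)
  })
  do.call(rbind, out)
}

#' Fit the drift reference Gaussian on whole-blood children
#'
#' Plain sample moments define the bivariate Gaussian; the pass threshold is
#' the chi-square quantile with 2 degrees of freedom at `coverage_level`.
#'
#' @param stats Drift statistics (see [drift_stats()]) of whole-blood
#'   children; incomplete rows are dropped.
#' @param coverage_level Ellipse density coverage (default 0.999).
#' @return A `drift_model` with `mean`, `covariance` and
#'   `mahalanobis_sq_threshold`.
#' @export
fit_drift_model <- function(stats, coverage_level = 0.999) {
  ok <- stats[stats$complete & is.finite(stats$mean_alt_ratio), , drop = FALSE]
  if (nrow(ok) < 10) {
    stopf("need at least 10 complete whole-blood children to fit (got %d)",
          nrow(ok))
  }
  x <- cbind(adjusted_subs = ok$adjusted_subs,
             mean_alt_ratio = ok$mean_alt_ratio)
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  ## positive definiteness, robust to very different axis scales
  pd <- all(diag(sigma) > 0) &&
    !inherits(try(chol(sigma), silent = TRUE), "try-error") &&
    det(sigma / sqrt(tcrossprod(diag(sigma)))) > 1e-12
  if (!pd) {
    stopf("singular covariance: drift statistics are degenerate")
  }
  structure(list(mean = mu, covariance = sigma,
                 coverage_level = coverage_level,
                 mahalanobis_sq_threshold = stats::qchisq(coverage_level, df = 2),
                 n_fit = nrow(ok)),
            class = "drift_model")
}

#' Classify children against a fitted drift model
#'
#' A child passes iff its squared Mahalanobis distance from the Gaussian
#' mean is at most the threshold (boundary counts as PASS); children with
#' undefined statistics are `INCOMPLETE` and excluded downstream.
#'
#' @param model A [fit_drift_model()] result.
#' @param stats Drift statistics for the children to classify.
#' @return Data frame `child_id`, `mahalanobis_sq`, `label` in
#'   `{PASS, DRIFTED, INCOMPLETE}`.
#' @export
classify_children <- function(model, stats) {
  stopifnot(inherits(model, "drift_model"))
  d2 <- rep(NA_real_, nrow(stats))
  ok <- stats$complete & is.finite(stats$mean_alt_ratio)
  if (any(ok)) {
    x <- cbind(stats$adjusted_subs[ok], stats$mean_alt_ratio[ok])
    d2[ok] <- stats::mahalanobis(x, model$mean, model$covariance)
  }
  label <- ifelse(!ok, "INCOMPLETE",
                  ifelse(d2 <= model$mahalanobis_sq_threshold,
                         "PASS", "DRIFTED"))
  data.frame(child_id = stats$child_id, mahalanobis_sq = d2, label = label,
             stringsAsFactors = FALSE)
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "drift model: n=%d, mean=(%.1f, %.3f), Mahalanobis^2 threshold=%.4f (%.1f%% ellipse)\n",
    x$n_fit, x$mean[1], x$mean[2], x$mahalanobis_sq_threshold,
    100 * x$coverage_level))
  invisible(x)
}
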