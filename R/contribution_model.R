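## De novo contribution model.
##
## Per-class ascertainment differentials from simplex families are tallied
## into a total simplex contribution S (valid under the assumption of fewer
## than one contributory event per child). With simplex families a mixture
## of low- and high-risk families in proportions pLs/pHs, and the high-risk
## contribution H approximated by the multiplex estimate, the low-risk
## contribution solves S = pLs * L + pHs * H. Overall contribution is a
## weighted mixture of L and H (equal risk-class weights) or of S and H
## (empirical simplex/multiplex case proportions). Ranges combine endpoint
## with endpoint (lo with lo, hi with hi).

#' Total simplex de novo contribution from per-class ADs
#'
#' @param class_ADs Named numeric vector or list of per-class contribution
#'   percentages (disjoint classes). Negative entries are kept as-is with a
#'   warning.
#' @return The simple sum, in percent.
#' @export
total_simplex_contribution <- function(class_ADs) {
  x <- unlist(class_ADs)
  if (length(x) == 0) return(0)
  if (any(x < 0)) {
    warnf("negative class contribution(s) included as-is")
  }
  sum(x)
}

#' Solve for the low-risk-family de novo contribution
#'
#' From `S = pLs * L + pHs * H`: `L = (S - pHs * H) / pLs`. Vectorized over
#' range endpoints.
#'
#' @param S Simplex contribution (percent).
#' @param H High-risk (multiplex) contribution (percent).
#' @param pLs,pHs Proportions of simplex families at low and high risk
#'   (defaults 0.6 / 0.4).
#' @return Low-risk contribution L, percent, full precision.
#' @export
solve_low_risk <- function(S, H, pLs = 0.6, pHs = 1 - pLs) {
  if (any(pLs <= 0)) stopf("pLs must be positive")
  (S - pHs * H) / pLs
}

#' Overall de novo contribution by risk-class weighting
#'
#' @param L,H Low-risk and high-risk contribution ranges, `c(lo, hi)`.
#' @param w_low,w_high Mixture weights (must sum to 1); default half of
#'   autism cases from each risk class.
#' @return Endpoint-wise weighted range `c(lo, hi)`.
#' @export
overall_by_risk_class <- function(L, H, w_low = 0.5, w_high = 0.5) {
  if (abs(w_low + w_high - 1) > 1e-9) stopf("weights must sum to 1")
  w_low * L + w_high * H
}

#' Overall de novo contribution by empirical case proportions
#'
#' Weights the simplex and multiplex contributions by the observed
#' proportions of autism cases in multiplex and simplex families (SPARK
#' registry counts by default), using the unrounded proportion.
#'
#' @param S,H Simplex and high-risk contribution ranges, `c(lo, hi)`.
#' @param multiplex_cases,simplex_cases Case counts.
#' @return List with `p_multiplex` and the endpoint-wise `range`.
#' @export
overall_by_case_proportion <- function(S, H, multiplex_cases = 13775,
                                       simplex_cases = 65184) {
  total <- multiplex_cases + simplex_cases
  if (total <= 0 || multiplex_cases < 0 || simplex_cases < 0) {
    stopf("case counts must be positive")
  }
  p <- multiplex_cases / total
  list(p_multiplex = p, range = (1 - p) * S + p * H)
}

#' Full contribution estimate
#'
#' Combines the pieces: sums the per-class simplex ADs when `S` is not given
#' directly, solves for L, and reports both overall weightings.
#'
#' @param S Simplex contribution range `c(lo, hi)`, percent.
#' @param H High-risk contribution range `c(lo, hi)`, percent.
#' @param pLs Proportion of simplex families at low risk.
#' @param multiplex_cases,simplex_cases Registry case counts for the
#'   case-proportion weighting.
#' @return A `contribution_estimate` list with `L`, `overall_riskclass`,
#'   `overall_spark` and `p_multiplex`.
#' @export
contribution_estimate <- function(S, H, pLs = 0.6,
                                  multiplex_cases = 13775,
                                  simplex_cases = 65184) {
  L <- solve_low_risk(S, H, pLs = pLs)
  spark <- overall_by_case_proportion(S, H, multiplex_cases, simplex_cases)
  ## L is quoted at integer precision (integer part) before the risk-class
  ## mixture, matching the convention used for the published ranges
  structure(list(S = S, H = H, L = L,
                 overall_riskclass = overall_by_risk_class(trunc(L), H),
                 overall_spark = spark$range,
                 p_multiplex = spark$p_multiplex),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  fmt <- function(r, d = 0) sprintf(paste0("%.", d, "f-%.", d, "f%%"),
                                    r[1], r[2])
  cat(sprintf("simplex S = %s; high-risk H = %s\n", fmt(x$S), fmt(x$H)))
  cat(sprintf("low-risk L = %s\n", fmt(trunc(x$L))))
  cat(sprintf("overall (risk-class weights 0.5/0.5) = %s\n",
              fmt(x$overall_riskclass, 1)))
  cat(sprintf("overall (case proportions, p_multiplex = %.2f) = %s\n",
              x$p_multiplex, fmt(x$overall_spark, 1)))
  invisible(x)
}
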