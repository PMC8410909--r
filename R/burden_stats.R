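## Normalized burden statistics for de novo event classes.
##
## For a subject class S and a presumed-neutral normalization class N, the
## expected subject count in the affected group under the null is
##   ES.a = S.u * (N.a / N.u),
## the ascertainment differential AD = 100 * (S.a - ES.a) / C.a (excess per
## 100 affected children) and the percent contributory
## PC = 100 * (S.a - ES.a) / S.a. Child-count normalization (used for CNVs)
## is the special case N = 1 per child, where ES.a = S.u * (C.a / C.u).
## Inference is by permutation of affected/unaffected labels (one-sided
## upper-tail p from a normal fitted to the permuted ADs) and by child-level
## percentile bootstrap for the AD and PC confidence intervals.

#' Expected subject-class count in the affected group
#'
#' @param S_u Observed subject-class count in the unaffected group.
#' @param N_a,N_u Observed normalization-class counts in the affected and
#'   unaffected groups (numbers of children under child-count normalization).
#' @return `S_u * N_a / N_u` at full precision.
#' @export
expected_count <- function(S_u, N_a, N_u) {
  if (any(N_u == 0)) stopf("normalization count N_u must be positive")
  S_u * (N_a / N_u)
}

#' Ascertainment differential (percent of affected children)
#'
#' @param S_a Observed subject-class count in the affected group.
#' @param ES_a Expected count under the null (see [expected_count()]).
#' @param C_a Number of affected children.
#' @return `100 * (S_a - ES_a) / C_a`; may be negative.
#' @export
ascertainment_differential <- function(S_a, ES_a, C_a) {
  if (any(C_a == 0)) stopf("C_a must be positive")
  100 * (S_a - ES_a) / C_a
}

#' Percent contributory (percent of the affected group's events in excess)
#'
#' @inheritParams ascertainment_differential
#' @return `100 * (S_a - ES_a) / S_a`, at most 100; `NA` with a warning when
#'   `S_a` is zero.
#' @export
percent_contributory <- function(S_a, ES_a) {
  out <- ifelse(S_a == 0, NA_real_, 100 * (S_a - ES_a) / S_a)
  if (anyNA(out)) warnf("percent contributory undefined when S_a = 0")
  out
}

#' Per-child burden input for one subject/normalization class pair
#'
#' @param affected,unaffected Data frames with columns `child_id`, `subject`
#'   (subject-class event count) and `norm` (normalization-class count;
#'   ignored and set to 1 under child-count normalization).
#' @param mode `"event_class"` normalizes by the event counts of a neutral
#'   class; `"child_count"` normalizes by the number of children.
#' @return A `burden_input` object.
#' @export
burden_input <- function(affected, unaffected,
                         mode = c("event_class", "child_count")) {
  mode <- match.arg(mode)
  check <- function(df, label) {
    if (!all(c("child_id", "subject") %in% names(df))) {
      stopf("%s group needs child_id and subject columns", label)
    }
    if (mode == "child_count" || is.null(df$norm)) df$norm <- 1L
    if (any(df$subject < 0) || any(df$norm < 0)) {
      stopf("%s group has negative counts", label)
    }
    df[, c("child_id", "subject", "norm")]
  }
  affected <- check(affected, "affected")
  unaffected <- check(unaffected, "unaffected")
  if (nrow(affected) == 0 || nrow(unaffected) == 0) {
    stopf("both groups must be non-empty")
  }
  structure(list(affected = affected, unaffected = unaffected, mode = mode,
                 C_a = nrow(affected), C_u = nrow(unaffected)),
            class = "burden_input")
}

#' Build a burden input from annotated calls and a pedigree
#'
#' @param variants Annotated small-variant or CNV data frame.
#' @param cohort Pedigree data frame with `affected` flags.
#' @param subject_class Effect class counted as subject events.
#' @param norm_class Effect class used for normalization, or `"children"`
#'   for child-count normalization.
#' @param class_col Column carrying class labels (e.g. `"effect"`,
#'   `"cnv_effect"` or the simulator's `"sim_class"`).
#' @return A [burden_input()].
#' @export
burden_input_from_calls <- function(variants, cohort, subject_class,
                                    norm_class = "children",
                                    class_col = "effect") {
  lab <- as.character(variants[[class_col]])
  count_for <- function(class) {
    v <- variants[lab == class, , drop = FALSE]
    as.integer(table(factor(v$child_id, levels = cohort$child_id)))
  }
  df <- data.frame(child_id = cohort$child_id,
                   subject = count_for(subject_class),
                   stringsAsFactors = FALSE)
  mode <- "child_count"
  if (!identical(norm_class, "children")) {
    df$norm <- count_for(norm_class)
    mode <- "event_class"
  }
  burden_input(df[cohort$affected, , drop = FALSE],
               df[!cohort$affected, , drop = FALSE], mode = mode)
}

burden_point <- function(input) {
  S_a <- sum(input$affected$subject); S_u <- sum(input$unaffected$subject)
  N_a <- sum(input$affected$norm); N_u <- sum(input$unaffected$norm)
  ES_a <- expected_count(S_u, N_a, N_u)
  AD <- ascertainment_differential(S_a, ES_a, input$C_a)
  PC <- if (S_a > 0) 100 * (S_a - ES_a) / S_a else NA_real_
  list(S_a = S_a, S_u = S_u, N_a = N_a, N_u = N_u, C_a = input$C_a,
       C_u = input$C_u, ES_a = ES_a, delta = S_a - ES_a, AD = AD, PC = PC)
}

## AD for permuted/bootstrapped pooled count vectors.
ad_from_sums <- function(S_a, N_a, S_u, N_u, C_a) {
  100 * (S_a - S_u * (N_a / N_u)) / C_a
}

#' Permutation p-value for the ascertainment differential
#'
#' Children (with their subject and normalization counts) are permuted
#' between the affected and unaffected groups keeping group sizes fixed; the
#' expected count and AD are recomputed per permutation; the reported p is
#' the one-sided upper-tail probability of the observed AD under a normal
#' distribution fitted to the permuted ADs.
#'
#' @param input A [burden_input()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-sided p-value in `[0, 1]`.
#' @export
permutation_p <- function(input, n_perm = 1000, seed = 1L) {
  pt <- burden_point(input)
  S <- c(input$affected$subject, input$unaffected$subject)
  N <- c(input$affected$norm, input$unaffected$norm)
  S_tot <- sum(S); N_tot <- sum(N)
  n_pool <- length(S); C_a <- input$C_a
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n_pool, C_a)
      S_a <- sum(S[idx]); N_a <- sum(N[idx])
      ad_from_sums(S_a, N_a, S_tot - S_a, N_tot - N_a, C_a)
    }, 0)
  })
  perm <- perm[is.finite(perm)]
  m <- mean(perm); s <- stats::sd(perm)
  if (!is.finite(s) || s == 0) {
    warnf("permutation ADs are constant; p-value reported as 1")
    return(1)
  }
  stats::pnorm(pt$AD, mean = m, sd = s, lower.tail = FALSE)
}

#' Bootstrap confidence intervals for AD and PC
#'
#' Children are resampled with replacement within each group (counts travel
#' with the child) and the AD and PC recomputed per iteration; intervals are
#' the 2.5/97.5 percentiles.
#'
#' @param input A [burden_input()].
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A list with numeric length-2 `AD_ci` and `PC_ci`.
#' @export
bootstrap_ci <- function(input, n_boot = 1000, seed = 1L, level = 0.95) {
  Sa <- input$affected$subject; Na <- input$affected$norm
  Su <- input$unaffected$subject; Nu <- input$unaffected$norm
  C_a <- input$C_a; C_u <- input$C_u
  res <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(C_a, C_a, replace = TRUE)
      iu <- sample.int(C_u, C_u, replace = TRUE)
      S_a <- sum(Sa[ia]); N_a <- sum(Na[ia])
      S_u <- sum(Su[iu]); N_u <- sum(Nu[iu])
      ES <- if (N_u > 0) S_u * N_a / N_u else NA_real_
      c(AD = 100 * (S_a - ES) / C_a,
        PC = if (S_a > 0) 100 * (S_a - ES) / S_a else NA_real_)
    }, c(AD = 0, PC = 0))
  })
  alpha <- (1 - level) / 2
  list(AD_ci = unname(stats::quantile(res["AD", ], c(alpha, 1 - alpha),
                                      na.rm = TRUE)),
       PC_ci = unname(stats::quantile(res["PC", ], c(alpha, 1 - alpha),
                                      na.rm = TRUE)))
}

#' Full burden analysis for one subject/normalization class pair
#'
#' Point estimates plus permutation p-value and bootstrap confidence
#' intervals. The permutation and bootstrap use independent seed streams
#' (`seed` and `seed + 1`), so adding the bootstrap does not change the
#' p-value.
#'
#' @param input A [burden_input()].
#' @param n_perm,n_boot Resampling sizes.
#' @param seed Integer seed.
#' @return A `burden_result` list with `S_a, S_u, N_a, N_u, C_a, C_u, ES_a,
#'   delta, AD, PC, p_value, AD_ci95, PC_ci95`.
#' @export
burden_test <- function(input, n_perm = 1000, n_boot = 1000, seed = 1L) {
  pt <- burden_point(input)
  p <- permutation_p(input, n_perm = n_perm, seed = seed)
  ci <- bootstrap_ci(input, n_boot = n_boot, seed = seed + 1L)
  structure(c(pt, list(p_value = p, AD_ci95 = ci$AD_ci, PC_ci95 = ci$PC_ci,
                       n_permutations = n_perm, n_bootstrap = n_boot,
                       seed = seed)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "burden: S_a=%d S_u=%d expected=%.1f delta=%.1f\n  AD=%.2f%% (%.2f-%.2f)  PC=%.1f%% (%.1f-%.1f)  p=%.3g\n",
    x$S_a, x$S_u, x$ES_a, x$delta, x$AD, x$AD_ci95[1], x$AD_ci95[2],
    x$PC, x$PC_ci95[1], x$PC_ci95[2], x$p_value))
  invisible(x)
}

#' Direct comparison of two affected groups
#'
#' Tests whether the ascertainment differential of the first affected group
#' exceeds that of the second by permuting children between the two affected
#' groups (group sizes fixed) while each group's unaffected baseline stays
#' fixed. The statistic is `AD_1 - AD_2`; the p-value is the one-sided
#' upper-tail probability under a normal fitted to the permuted differences.
#'
#' @param input_a1,input_a2 [burden_input()] objects for the two affected
#'   groups, sharing the same normalization mode.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with `AD_1`, `AD_2`, `diff` and `p_value`.
#' @export
compare_affected_groups <- function(input_a1, input_a2, n_perm = 1000,
                                    seed = 1L) {
  if (input_a1$mode != input_a2$mode) {
    stopf("the two inputs must share a normalization mode")
  }
  p1 <- burden_point(input_a1); p2 <- burden_point(input_a2)
  obs <- p1$AD - p2$AD
  S <- c(input_a1$affected$subject, input_a2$affected$subject)
  N <- c(input_a1$affected$norm, input_a2$affected$norm)
  n1 <- input_a1$C_a; n_pool <- length(S)
  ad1 <- function(S_a, N_a) {
    ad_from_sums(S_a, N_a, p1$S_u, p1$N_u, n1)
  }
  ad2 <- function(S_a, N_a) {
    ad_from_sums(S_a, N_a, p2$S_u, p2$N_u, input_a2$C_a)
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n_pool, n1)
      S_1 <- sum(S[idx]); N_1 <- sum(N[idx])
      ad1(S_1, N_1) - ad2(sum(S) - S_1, sum(N) - N_1)
    }, 0)
  })
  m <- mean(perm); s <- stats::sd(perm)
  p <- if (!is.finite(s) || s == 0) {
    warnf("permutation differences are constant; p-value reported as 1")
    1
  } else {
    stats::pnorm(obs, mean = m, sd = s, lower.tail = FALSE)
  }
  list(AD_1 = p1$AD, AD_2 = p2$AD, diff = obs, p_value = p)
}

#' Aggregate burden over disjoint event classes with per-class normalization
#'
#' Sums observed and expected counts over classes (each with its own
#' normalization mode, e.g. synonymous-normalized LGDs plus
#' child-count-normalized coding CNVs) and computes the aggregated AD over
#' the common affected-children denominator. Permutation and bootstrap
#' resample children once, jointly carrying all class counts.
#'
#' @param inputs Named list of [burden_input()] objects over the same
#'   children (identical `child_id` sets per group).
#' @param n_perm,n_boot Resampling sizes (0 skips inference).
#' @param seed Integer seed.
#' @return A `burden_result` with summed counts.
#' @export
aggregate_burden <- function(inputs, n_perm = 1000, n_boot = 1000, seed = 1L) {
  stopifnot(length(inputs) >= 1)
  ids_a <- sort(inputs[[1]]$affected$child_id)
  ids_u <- sort(inputs[[1]]$unaffected$child_id)
  for (inp in inputs[-1]) {
    if (!identical(sort(inp$affected$child_id), ids_a) ||
        !identical(sort(inp$unaffected$child_id), ids_u)) {
      stopf("all inputs must cover the same children in each group")
    }
  }
  K <- length(inputs)
  C_a <- inputs[[1]]$C_a; C_u <- inputs[[1]]$C_u
  align <- function(inp, group, ids) {
    df <- inp[[group]]
    df[match(ids, df$child_id), c("subject", "norm")]
  }
  Sa <- sapply(inputs, function(i) align(i, "affected", ids_a)$subject)
  Na <- sapply(inputs, function(i) align(i, "affected", ids_a)$norm)
  Su <- sapply(inputs, function(i) align(i, "unaffected", ids_u)$subject)
  Nu <- sapply(inputs, function(i) align(i, "unaffected", ids_u)$norm)
  Sa <- matrix(Sa, ncol = K); Na <- matrix(Na, ncol = K)
  Su <- matrix(Su, ncol = K); Nu <- matrix(Nu, ncol = K)

  pts <- lapply(inputs, burden_point)
  S_a <- sum(vapply(pts, `[[`, 0, "S_a"))
  S_u <- sum(vapply(pts, `[[`, 0, "S_u"))
  ES_a <- sum(vapply(pts, `[[`, 0, "ES_a"))
  AD <- 100 * (S_a - ES_a) / C_a
  PC <- if (S_a > 0) 100 * (S_a - ES_a) / S_a else NA_real_

  S_pool <- rbind(Sa, Su); N_pool <- rbind(Na, Nu)
  S_tot <- colSums(S_pool); N_tot <- colSums(N_pool)
  n_pool <- nrow(S_pool)

  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n_pool, C_a)
        S_ak <- colSums(S_pool[idx, , drop = FALSE])
        N_ak <- colSums(N_pool[idx, , drop = FALSE])
        ES <- sum((S_tot - S_ak) * N_ak / (N_tot - N_ak))
        100 * (sum(S_ak) - ES) / C_a
      }, 0)
    })
    m <- mean(perm); s <- stats::sd(perm)
    p <- if (!is.finite(s) || s == 0) 1 else
      stats::pnorm(AD, mean = m, sd = s, lower.tail = FALSE)
  }
  AD_ci <- PC_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    res <- with_seed(seed + 1L, {
      vapply(seq_len(n_boot), function(i) {
        ia <- sample.int(C_a, C_a, replace = TRUE)
        iu <- sample.int(C_u, C_u, replace = TRUE)
        S_ak <- colSums(Sa[ia, , drop = FALSE])
        N_ak <- colSums(Na[ia, , drop = FALSE])
        S_uk <- colSums(Su[iu, , drop = FALSE])
        N_uk <- colSums(Nu[iu, , drop = FALSE])
        ES <- sum(S_uk * N_ak / N_uk)
        s_a <- sum(S_ak)
        c(100 * (s_a - ES) / C_a,
          if (s_a > 0) 100 * (s_a - ES) / s_a else NA_real_)
      }, c(0, 0))
    })
    AD_ci <- unname(stats::quantile(res[1, ], c(0.025, 0.975), na.rm = TRUE))
    PC_ci <- unname(stats::quantile(res[2, ], c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(S_a = S_a, S_u = S_u, N_a = sum(vapply(pts, `[[`, 0, "N_a")),
                 N_u = sum(vapply(pts, `[[`, 0, "N_u")), C_a = C_a, C_u = C_u,
                 ES_a = ES_a, delta = S_a - ES_a, AD = AD, PC = PC,
                 p_value = p, AD_ci95 = AD_ci, PC_ci95 = PC_ci,
                 n_permutations = n_perm, n_bootstrap = n_boot, seed = seed),
            class = "burden_result")
}
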