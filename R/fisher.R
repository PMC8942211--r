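# Exact-test core. The reported odds ratio is the sample (cross-product)
# estimate a*d / (b*c) -- not the conditional-MLE estimate that
# stats::fisher.test() prints -- because the cross-product value is what the
# enrichment analyses here are defined on. With any zero cell, the
# Haldane-Anscombe +0.5 correction is applied to all four cells for the OR
# and its CI; the exact p-value always uses the raw counts.

#' Two-sided Fisher's exact test with the sample odds ratio
#'
#' The p-value is the classical two-sided exact probability: the sum, over
#' all 2x2 tables with the observed margins, of hypergeometric probabilities
#' no larger than that of the observed table (evaluated in log-space via
#' [stats::dhyper()], with the customary `1 + 1e-7` relative tolerance for
#' ties).
#'
#' @param a,b,c,d Cell counts: `a` = class-A residues with the feature, `b` =
#'   class-A without, `c` = class-B with, `d` = class-B without.
#' @return A list with `odds_ratio` (cross-product, Haldane-Anscombe
#'   corrected iff any cell is zero), `p`, and `corrected` (logical: was the
#'   +0.5 correction applied).
#' @export
#' @examples
#' fisher_exact(41691, 20282, 176888, 92314)$odds_ratio # ~1.07, prints as 1.1
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("cell counts must be non-negative numbers")
  }
  if (sum(cells) == 0) abort("degenerate table: all four cells are zero")

  # exact p on the raw counts
  m <- a + b # class-A margin
  n <- c + d # class-B margin
  k <- a + c # feature margin
  support <- max(0, k - n):min(k, m)
  logp <- dhyper(support, m, n, k, log = TRUE)
  p_obs <- dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
  p <- min(p, 1)

  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(odds_ratio = or, p = p, corrected = corrected)
}

#' Woolf log-normal confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the standard
#' normal quantile at `(1 + level) / 2`, computed on the Haldane-Anscombe
#' +0.5-corrected cells whenever any cell is zero (matching the corrected
#' point estimate, so the interval always contains it).
#'
#' @inheritParams fisher_exact
#' @param level Coverage level, default `0.95`.
#' @return A list with `ci_low` and `ci_high`.
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (sum(cells) == 0) abort("degenerate table: all four cells are zero")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm((1 + level) / 2)
  se <- sqrt(sum(1 / cells))
  list(ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Bonferroni correction with a reporting floor
#'
#' `q = min(1, p * m)`. Reported values are additionally floored at `1e-100`
#' (the conventional "maximum significance" cap for display); the
#' `q_floored` flag records when the exact value was smaller.
#'
#' @param p Raw p-value(s) in (0, 1].
#' @param m Number of tests, default 25 (one per feature class).
#' @return Tibble with `q` (floored) and `q_floored`.
#' @export
#' @examples
#' bonferroni(0.001)      # q = 0.025
#' bonferroni(1e-120)$q   # reported as 1e-100, flagged
bonferroni <- function(p, m = 25) {
  if (m < 1) abort("m must be >= 1")
  q <- pmin(1, p * m)
  floored <- q < 1e-100
  tibble(q = pmax(q, 1e-100), q_floored = floored)
}

#' Classify a feature association from OR and corrected p
#'
#' @param odds_ratio Sample odds ratio.
#' @param q Bonferroni-corrected p-value.
#' @param alpha Significance level, default 0.05.
#' @return `"class_a_enriched"` (OR > 1, q < alpha), `"class_b_enriched"`
#'   (OR < 1, q < alpha) or `"none"`. For the DR/NR partition class A
#'   enrichment marks a DR feature, class B an NR feature.
#' @export
classify_association <- function(odds_ratio, q, alpha = 0.05) {
  dplyr::case_when(
    is.na(odds_ratio) | is.na(q) ~ "none",
    odds_ratio > 1 & q < alpha ~ "class_a_enriched",
    odds_ratio < 1 & q < alpha ~ "class_b_enriched",
    .default = "none"
  )
}
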