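# Statistical comparisons used in the analysis and its reporting.

#' Display percentage with half-up rounding
#'
#' `100 * found / total`, rounded half-up to `digits` decimals for display
#' (half-up, not banker's rounding, so that printed percentages agree with
#' hand calculation from the integer counts). Internal computations keep
#' full precision; this is a formatting function.
#'
#' @param found,total Non-negative counts; `total` must be positive.
#' @param digits Decimals to keep (default 2).
#' @return Numeric percentage.
#' @export
percent <- function(found, total, digits = 2) {
  assert_that(all(total > 0), "`total` must be positive")
  round_half_up(100 * found / total, digits)
}

#' Wilcoxon signed-rank test for paired per-genome values
#'
#' Two-sided Wilcoxon signed-rank test on genome-paired measurements (e.g.
#' the per-genome percentage of found species-specific versus clade-specific
#' absences). Zero differences are dropped; the exact null distribution is
#' used for n <= 25 untied pairs, otherwise the normal approximation with
#' continuity correction.
#'
#' @param a,b Paired numeric vectors (same genomes, same order).
#' @return A tibble: `statistic` (V), `p_value`, `n` (non-zero pairs).
#' @export
paired_signed_rank_test <- function(a, b) {
  assert_that(length(a) == length(b), "`a` and `b` must be paired")
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  assert_that(length(d) >= 2, "fewer than 2 non-zero pairs")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(d))
}

#' Kendall rank correlation against assembly quality
#'
#' Kendall tau-b (tie-corrected) between per-genome found-absence
#' percentages and an assembly-quality proxy such as N50
#' (log-transformed by default), with a two-sided p-value.
#'
#' @param pct Per-genome percentages.
#' @param quality Per-genome quality values (e.g. N50).
#' @param log_quality Log-transform `quality` first (default TRUE).
#' @return A tibble: `tau`, `p_value`, `n`.
#' @export
rank_correlation_vs_quality <- function(pct, quality, log_quality = TRUE) {
  assert_that(length(pct) == length(quality), "vectors must be paired")
  ok <- !is.na(pct) & !is.na(quality)
  pct <- pct[ok]; quality <- quality[ok]
  if (log_quality) quality <- log(quality)
  assert_that(length(unique(pct)) > 1 && length(unique(quality)) > 1,
              "constant vector: correlation undefined")
  ht <- suppressWarnings(
    stats::cor.test(pct, quality, method = "kendall"))
  tibble::tibble(tau = unname(ht$estimate), p_value = ht$p.value,
                 n = length(pct))
}

#' Compare model lengths of the most-rescued domains against the rest
#'
#' Splits domains into the `k` with the highest found-absence counts versus
#' all others (ties broken by domain order for determinism) and compares
#' their model lengths with a two-sided Wilcoxon rank-sum test — short
#' domains are expected to be missed by gene prediction more often.
#'
#' @param model_lengths Per-domain model lengths (aa).
#' @param found_counts Per-domain counts of found (rescued) absences.
#' @param k Size of the top group (default 100); must be < number of
#'   domains.
#' @return A tibble: `median_top`, `median_rest`, `statistic` (W),
#'   `p_value`, `k`, `n`.
#' @export
length_group_comparison <- function(model_lengths, found_counts, k = 100) {
  n <- length(model_lengths)
  assert_that(length(found_counts) == n, "vectors must be paired")
  assert_that(k >= 1 && k < n, "`k` must be positive and below the number of domains")
  top <- order(found_counts, decreasing = TRUE)[seq_len(k)]
  if (length(unique(model_lengths)) == 1) {
    # degenerate: identical lengths carry no evidence either way
    ht <- list(statistic = c(W = NA_real_), p.value = 1)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(model_lengths[top], model_lengths[-top],
                         alternative = "two.sided"))
  }
  tibble::tibble(median_top = stats::median(model_lengths[top]),
                 median_rest = stats::median(model_lengths[-top]),
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 k = as.integer(k), n = as.integer(n))
}
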