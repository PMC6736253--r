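# Verification of absences in six-frame translated genomes and the
# corrected loss recount — the pipeline's headline computation.

#' Match absences against validated six-frame hits
#'
#' For each absence (a domain absent from a species' proteome but inside the
#' domain's gain subtree): `found_in_genome` is true iff the species has at
#' least one surviving non-pseudogene six-frame hit for that domain — the
#' same validation chain (cutoff, overlap, stop-codon filter) as proteome
#' hits; `pseudogene_only` is true iff hits exist but every one is
#' pseudogene-flagged (the absence stands, with a residual-homology
#' explanation).
#'
#' @param absences Tibble `domain_id`, `species_id`, `category` from
#'   [classify_absences()] (restricted to the LECA domains of interest).
#' @param sixframe_hits Hit tibble from the six-frame search after cutoff
#'   filtering and [flag_pseudogenes()] (non-pseudogene hits additionally
#'   deduplicated with [select_best_nonoverlapping()]).
#' @return The `absences` tibble with logical columns `found_in_genome` and
#'   `pseudogene_only` added. Hits for (species, domain) pairs not listed as
#'   absent are ignored with a warning — their presence is already
#'   established.
#' @export
find_absence_hits <- function(absences, sixframe_hits) {
  assert_that(all(c("domain_id", "species_id") %in% names(absences)),
              "`absences` needs domain_id and species_id")
  if (!"pseudogene" %in% names(sixframe_hits)) {
    sixframe_hits <- flag_pseudogenes(sixframe_hits)
  }
  extra <- sixframe_hits %>%
    dplyr::distinct(.data$domain_id, .data$species_id) %>%
    dplyr::anti_join(absences, by = c("domain_id", "species_id"))
  if (nrow(extra) > 0) {
    rlang::warn(sprintf(
      "%d (species, domain) pairs with six-frame hits are not marked absent; ignored",
      nrow(extra)))
  }
  per_pair <- sixframe_hits %>%
    dplyr::group_by(.data$domain_id, .data$species_id) %>%
    dplyr::summarise(n_hits = dplyr::n(),
                     n_live = sum(!.data$pseudogene), .groups = "drop")
  absences %>%
    dplyr::left_join(per_pair, by = c("domain_id", "species_id")) %>%
    dplyr::mutate(
      found_in_genome = !is.na(.data$n_live) & .data$n_live > 0,
      pseudogene_only = !is.na(.data$n_hits) & .data$n_hits > 0 &
        .data$n_live == 0) %>%
    dplyr::select(-"n_hits", -"n_live")
}

#' Correct the presence matrix and recount Dollo losses
#'
#' Flips every found absence to present, re-runs the Dollo reconstruction
#' per domain on the corrected matrix (with the LECA set frozen from the
#' uncorrected analysis, never re-derived), and reports uncorrected versus
#' corrected loss counts and the percentage reduction. Pseudogene-only
#' absences never change the matrix.
#'
#' @param tree A [species_tree] or `phylo`.
#' @param observed Observed (proteome) presence matrix.
#' @param found Absence-call tibble from [find_absence_hits()].
#' @param leca_domains Character vector of domain ids frozen as the LECA
#'   set; both recounts are restricted to it.
#' @return An object of class `loss_correction`; see [tidy.loss_correction()]
#'   and [glance.loss_correction()] for tabular views.
#' @export
correct_and_recount <- function(tree, observed, found, leca_domains) {
  validate_presence_matrix(observed)
  assert_that(all(leca_domains %in% rownames(observed)),
              "LECA domain missing from observed matrix")
  flips <- found[found$found_in_genome, c("domain_id", "species_id")]
  bad <- observed[cbind(flips$domain_id, flips$species_id)] != 0L
  assert_that(!any(bad), "found flag for a cell that is not absent")

  corrected <- observed
  corrected[cbind(flips$domain_id, flips$species_id)] <- 1L

  recs_unc <- dollo_reconstruct_all(tree, observed[leca_domains, , drop = FALSE])
  recs_cor <- dollo_reconstruct_all(tree, corrected[leca_domains, , drop = FALSE])
  unc <- count_losses(recs_unc)
  cor <- count_losses(recs_cor)
  per_domain <- dplyr::left_join(
    dplyr::rename(unc$per_domain, losses_uncorrected = "n_losses"),
    dplyr::rename(cor$per_domain, losses_corrected = "n_losses"),
    by = "domain_id") %>%
    dplyr::mutate(delta = .data$losses_uncorrected - .data$losses_corrected)

  structure(list(
    per_domain = per_domain,
    corrected_matrix = corrected,
    leca_domains = leca_domains,
    uncorrected = unc, corrected = cor,
    total_uncorrected = unc$total, total_corrected = cor$total,
    reduction_pct = 100 * (unc$total - cor$total) / unc$total,
    median_uncorrected = unc$median, median_corrected = cor$median),
    class = "loss_correction")
}

#' @export
print.loss_correction <- function(x, ...) {
  cat(sprintf(
    "<loss_correction> %d LECA domains: losses %d -> %d (-%.2f%%), median %s -> %s\n",
    length(x$leca_domains), x$total_uncorrected, x$total_corrected,
    round_half_up(x$reduction_pct), format(x$median_uncorrected),
    format(x$median_corrected)))
  invisible(x)
}

#' Tidy and one-row summaries of a loss correction
#'
#' `tidy()` returns per-domain uncorrected/corrected loss counts and their
#' difference; `glance()` returns the dataset-level totals, medians and the
#' percentage reduction in loss events.
#'
#' @param x A `loss_correction` from [correct_and_recount()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.loss_correction <- function(x, ...) x$per_domain

#' @rdname tidy.loss_correction
#' @export
glance.loss_correction <- function(x, ...) {
  tibble::tibble(
    n_domains = length(x$leca_domains),
    total_uncorrected = x$total_uncorrected,
    total_corrected = x$total_corrected,
    reduction_pct = x$reduction_pct,
    median_uncorrected = x$median_uncorrected,
    median_corrected = x$median_corrected)
}

#' Histogram overlay of uncorrected versus corrected loss counts
#'
#' @param object A `loss_correction`.
#' @param ... Unused.
#' @return A ggplot: per-domain loss-count distributions before and after
#'   rescuing found absences, medians as vertical lines.
#' @export
autoplot.loss_correction <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$uncorrected$per_domain, set = "uncorrected (proteome)"),
    dplyr::mutate(object$corrected$per_domain, set = "corrected (six-frame)"))
  med <- tibble::tibble(
    set = c("uncorrected (proteome)", "corrected (six-frame)"),
    m = c(object$median_uncorrected, object$median_corrected))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_losses, fill = .data$set)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55,
                            binwidth = 1) +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$set),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::labs(x = "losses per domain", y = "domains",
                  fill = NULL, title = "Loss distribution before/after correction")
}

#' Per-genome found-absence percentages and their medians
#'
#' For every genome, the percentage of absences with a validated six-frame
#' hit is computed within each category (all absences, clade-specific,
#' species-specific), and dataset medians are taken across genomes. A genome
#' with no absences in a category is excluded from that category's median.
#' For BUSCO-style universal domain sets (every absence a priori suspicious,
#' no clade classification), set `min_absences` so that only genomes with
#' more absences than the threshold enter the summary.
#'
#' @param absence_calls Tibble from [find_absence_hits()].
#' @param min_absences Keep only genomes with strictly more total absences
#'   than this (default 0 keeps all genomes with at least one absence).
#' @return An object of class `found_summary`: list with `per_genome`
#'   (tibble: `species_id`, per-category absence/found counts and
#'   percentages) and `medians` (tibble: `category`, `median_pct`,
#'   `n_genomes`).
#' @export
summarize_found <- function(absence_calls, min_absences = 0) {
  long <- dplyr::bind_rows(
    dplyr::mutate(absence_calls, category = "total"),
    absence_calls)
  per <- long %>%
    dplyr::group_by(.data$species_id, .data$category) %>%
    dplyr::summarise(n_absences = dplyr::n(),
                     n_found = sum(.data$found_in_genome),
                     .groups = "drop") %>%
    dplyr::mutate(pct_found = 100 * .data$n_found / .data$n_absences)
  totals <- per %>% dplyr::filter(.data$category == "total")
  keep <- totals$species_id[totals$n_absences > min_absences]
  per <- per %>% dplyr::filter(.data$species_id %in% keep)
  medians <- per %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(median_pct = stats::median(.data$pct_found),
                     n_genomes = dplyr::n(), .groups = "drop")
  structure(list(per_genome = per, medians = medians,
                 min_absences = min_absences),
            class = "found_summary")
}

#' @export
print.found_summary <- function(x, ...) {
  cat("<found_summary> median % found per genome:\n")
  for (i in seq_len(nrow(x$medians))) {
    cat(sprintf("  %-18s %6.2f%%  (n = %d genomes)\n",
                x$medians$category[i], x$medians$median_pct[i],
                x$medians$n_genomes[i]))
  }
  invisible(x)
}

#' @param x A `found_summary`.
#' @param ... Unused.
#' @rdname summarize_found
#' @export
tidy.found_summary <- function(x, ...) x$per_genome

#' @rdname summarize_found
#' @export
glance.found_summary <- function(x, ...) {
  tidyr::pivot_wider(x$medians, names_from = "category",
                     values_from = c("median_pct", "n_genomes"))
}

#' Violin-style view of per-genome found percentages by absence category
#'
#' @param object A `found_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.found_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_genome,
                  ggplot2::aes(x = .data$category, y = .data$pct_found)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_boxplot(width = 0.1, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "% absences found in six-frame DNA",
                  title = "Falsely inferred absences per genome")
}
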