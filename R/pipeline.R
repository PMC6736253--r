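# End-to-end analysis on a simulated dataset: scan proteomes, reconstruct
# ancestral content, classify absences, verify them in six-frame translated
# genomes, and recount losses.

#' Run the full falsely-inferred-absence analysis on a simulated dataset
#'
#' Chains every stage of the pipeline on a [simulate_loss_dataset()] result:
#' toy-detector proteome scan -> cutoff filter -> best non-overlapping hits
#' -> observed presence matrix -> LECA filter -> Dollo reconstruction and
#' absence classification -> six-frame translation and scan -> pseudogene
#' filter -> absence verification -> corrected loss recount and per-genome
#' summaries.
#'
#' @param sim A `loss_sim` object.
#' @param config A [loss_config()]; thresholds and the detector tolerance
#'   are taken from it.
#' @param hgt_flags Optional per-domain HGT flags (see [leca_filter()]).
#' @return An object of class `loss_run` with elements `observed`, `leca`,
#'   `leca_domains`, `reconstructions`, `losses`, `absence_calls`,
#'   `correction` (a `loss_correction`), `found` (a `found_summary`),
#'   `signed_rank` (species- vs clade-specific per-genome test), `config`,
#'   and the input `sim`.
#' @export
run_loss_analysis <- function(sim, config = loss_config(), hgt_flags = NULL) {
  assert_that(inherits(sim, "loss_sim"), "`sim` must be a loss_sim")
  st <- sim$tree
  models <- sim$models
  cutoffs <- models[, c("domain_id", "score_cutoff")]
  species <- st$meta$species_id
  domains <- models$domain_id

  # proteome scan -> observed presence matrix
  prot_hits <- toy_detect_proteome(sim$proteomes, models,
                                   config$max_mismatches) %>%
    apply_score_cutoffs(cutoffs) %>%
    flag_pseudogenes() %>%
    select_best_nonoverlapping()
  observed <- hits_to_matrix(prot_hits, domains, species)

  # ancestral content: LECA filter on the observed profiles
  leca <- leca_filter(st, observed,
                      min_supergroups = config$min_supergroups,
                      require_both_sides = config$require_both_sides,
                      hgt_flags = hgt_flags)
  leca_domains <- leca$domain_id[leca$in_leca_strict]
  assert_that(length(leca_domains) > 0, "no domain passes the LECA filter")

  recs <- dollo_reconstruct_all(st, observed[leca_domains, , drop = FALSE])
  losses <- count_losses(recs)
  idx <- tree_index(st$tree)
  absences <- purrr::map(recs, classify_absences, tree = st, .idx = idx) %>%
    dplyr::bind_rows()

  # six-frame verification of absences
  contig_species <- setNames(species, paste0(species, "_ctg"))
  trans <- translate_six_frames(sim$genomes, sim$params$codon_table)
  trans$species_id <- unname(contig_species[trans$contig_id])
  six_hits <- toy_detect_sixframe(trans, models, config$max_mismatches) %>%
    apply_score_cutoffs(cutoffs) %>%
    flag_pseudogenes()
  six_processed <- dplyr::bind_rows(
    select_best_nonoverlapping(six_hits[!six_hits$pseudogene, , drop = FALSE]),
    six_hits[six_hits$pseudogene, , drop = FALSE])
  six_for_absences <- dplyr::semi_join(six_processed, absences,
                                       by = c("domain_id", "species_id"))
  calls <- find_absence_hits(absences, six_for_absences)

  correction <- correct_and_recount(st, observed, calls, leca_domains)
  found <- summarize_found(calls)

  signed_rank <- tryCatch({
    wide <- found$per_genome %>%
      dplyr::filter(.data$category != "total") %>%
      tidyr::pivot_wider(id_cols = "species_id", names_from = "category",
                         values_from = "pct_found")
    ok <- !is.na(wide$species_specific) & !is.na(wide$clade_specific)
    paired_signed_rank_test(wide$species_specific[ok],
                            wide$clade_specific[ok])
  }, error = function(e) NULL)

  structure(list(
    sim = sim, config = config, observed = observed,
    proteome_hits = prot_hits, sixframe_hits = six_processed,
    leca = leca, leca_domains = leca_domains,
    reconstructions = recs, losses = losses,
    absence_calls = calls, correction = correction, found = found,
    signed_rank = signed_rank),
    class = "loss_run")
}

#' Score a run against the planted ground truth
#'
#' Compares the found-absence calls of a [run_loss_analysis()] result with
#' the generator's planted statuses: precision and recall of
#' `found_in_genome` against the planted unpredicted cells (restricted to
#' the absences the run examined), and agreement of `pseudogene_only` flags
#' with the planted pseudogenes.
#'
#' @param run A `loss_run`.
#' @return A one-row tibble: `n_absences`, `n_found`, `precision`, `recall`,
#'   `pseudogene_flags_exact` (logical), `n_pseudogene_planted`.
#' @export
score_against_truth <- function(run) {
  joined <- run$absence_calls %>%
    dplyr::left_join(run$sim$statuses, by = c("domain_id", "species_id"))
  planted_unp <- joined$status == "unpredicted"
  found <- joined$found_in_genome
  tibble::tibble(
    n_absences = nrow(joined),
    n_found = sum(found),
    precision = sum(found & planted_unp) / max(1L, sum(found)),
    recall = sum(found & planted_unp) / max(1L, sum(planted_unp)),
    pseudogene_flags_exact =
      all(joined$pseudogene_only == (joined$status == "pseudogene")),
    n_pseudogene_planted = sum(joined$status == "pseudogene"))
}

#' @export
print.loss_run <- function(x, ...) {
  cat(sprintf("<loss_run> %d species, %d domains (%d in LECA set)\n",
              ncol(x$observed), nrow(x$observed), length(x$leca_domains)))
  print(x$found)
  print(x$correction)
  invisible(x)
}

#' @rdname run_loss_analysis
#' @param x,object A `loss_run`.
#' @param ... Unused.
#' @export
glance.loss_run <- function(x, ...) {
  med <- glance(x$found)
  dplyr::bind_cols(
    tibble::tibble(
      n_species = ncol(x$observed),
      n_domains = nrow(x$observed),
      n_leca_domains = length(x$leca_domains),
      n_absences = nrow(x$absence_calls),
      n_found = sum(x$absence_calls$found_in_genome)),
    dplyr::select(glance(x$correction), -"n_domains"),
    med,
    tibble::tibble(
      signed_rank_p = if (is.null(x$signed_rank)) NA_real_ else
        x$signed_rank$p_value))
}
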