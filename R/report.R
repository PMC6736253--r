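# Report assembly: a summary table shaped like the headline results table,
# plus deterministic JSON/TSV serialisation.

#' Summary table of a pipeline run
#'
#' Assembles the dataset-level counts and percentages of a [run_loss_analysis()]
#' result into a two-column metric/value tibble: LECA domain count, absence
#' counts by category, found counts with overall and median percentages, and
#' uncorrected/corrected loss totals and medians. Percentages are displayed
#' with half-up rounding to two decimals (see [percent()]); the partition
#' identity `species_specific + clade_specific = total absences` holds on
#' every run.
#'
#' @param run A `loss_run`.
#' @return A tibble with columns `metric`, `value`.
#' @export
summarize_run <- function(run) {
  calls <- run$absence_calls
  n_abs <- nrow(calls)
  n_sp <- sum(calls$category == "species_specific")
  n_cl <- sum(calls$category == "clade_specific")
  found_sp <- sum(calls$found_in_genome & calls$category == "species_specific")
  found_cl <- sum(calls$found_in_genome & calls$category == "clade_specific")
  found_all <- sum(calls$found_in_genome)
  med <- setNames(run$found$medians$median_pct, run$found$medians$category)
  cor <- run$correction
  tibble::tibble(metric = c(
    "leca_domains", "absences", "species_specific_absences",
    "clade_specific_absences", "found_species_specific_absences",
    "pct_found_species_specific_absences",
    "median_pct_found_species_specific_absences",
    "found_clade_specific_absences", "pct_found_clade_specific_absences",
    "median_pct_found_clade_specific_absences", "found_total_absences",
    "pct_found_total_absences", "median_pct_found_total_absences",
    "loss_uncorrected", "median_loss_uncorrected", "loss_corrected",
    "median_loss_corrected", "loss_reduction_pct"),
    value = c(
      length(run$leca_domains), n_abs, n_sp, n_cl,
      found_sp, if (n_sp > 0) percent(found_sp, n_sp) else NA_real_,
      round_half_up(med[["species_specific"]]),
      found_cl, if (n_cl > 0) percent(found_cl, n_cl) else NA_real_,
      round_half_up(med[["clade_specific"]]),
      found_all, if (n_abs > 0) percent(found_all, n_abs) else NA_real_,
      round_half_up(med[["total"]]),
      cor$total_uncorrected, cor$median_uncorrected,
      cor$total_corrected, cor$median_corrected,
      percent(cor$total_uncorrected - cor$total_corrected,
              cor$total_uncorrected)))
}

#' Write a run report to disk
#'
#' Serialises the run deterministically: `report.json` (the summary table
#' plus the loss-count distributions before and after correction),
#' `summary.tsv`, `per_genome.tsv`, `absence_calls.tsv` and
#' `corrected_matrix.tsv` under `out_dir`.
#'
#' @param run A `loss_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_run(run)
  payload <- list(
    summary = setNames(as.list(summ$value), summ$metric),
    loss_distribution = list(
      uncorrected = run$correction$uncorrected$distribution,
      corrected = run$correction$corrected$distribution))
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(summ, file.path(out_dir, "summary.tsv"), progress = FALSE)
  readr::write_tsv(run$found$per_genome, file.path(out_dir, "per_genome.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$absence_calls,
                   file.path(out_dir, "absence_calls.tsv"), progress = FALSE)
  write_matrix_tsv(run$correction$corrected_matrix,
                   file.path(out_dir, "corrected_matrix.tsv"))
  invisible(out_dir)
}
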