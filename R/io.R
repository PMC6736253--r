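#' Read a HMMER3 per-domain hits table (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout`. Lines starting with `#` are comments. Printed
#' coordinates are 1-based inclusive; they are converted to the package's
#' internal 0-based half-open convention at this boundary and nowhere else.
#'
#' @param path Path to a domtblout file.
#' @return A tibble with one row per domain hit: `target_id`, `target_len`,
#'   `domain_id`, `qlen`, `bitscore` (the per-domain score), and 0-based
#'   half-open `hmm_start`/`hmm_end`, `ali_start`/`ali_end`,
#'   `env_start`/`env_end`.
#' @export
read_domtblout <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      target_id = character(), target_len = integer(),
      domain_id = character(), qlen = integer(), bitscore = double(),
      hmm_start = integer(), hmm_end = integer(),
      ali_start = integer(), ali_end = integer(),
      env_start = integer(), env_end = integer()))
  }
  fields <- stringi::stri_split_regex(lines, "\\s+", omit_empty = TRUE)
  bad <- which(lengths(fields) < 22)
  if (length(bad)) {
    rlang::abort(sprintf("malformed domtblout row (fewer than 22 fields) at data line %d", bad[1]))
  }
  m <- t(vapply(fields, function(f) f[1:22], character(22)))
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x)) rlang::abort(sprintf("non-numeric %s in domtblout", what))
    x
  }
  tibble::tibble(
    target_id = m[, 1],
    target_len = as.integer(num(3, "target length")),
    domain_id = m[, 4],
    qlen = as.integer(num(6, "query length")),
    bitscore = num(14, "domain bitscore"),
    hmm_start = as.integer(num(16, "hmm from")) - 1L,
    hmm_end = as.integer(num(17, "hmm to")),
    ali_start = as.integer(num(18, "ali from")) - 1L,
    ali_end = as.integer(num(19, "ali to")),
    env_start = as.integer(num(20, "env from")) - 1L,
    env_end = as.integer(num(21, "env to")))
}

#' Presence/absence profile matrix
#'
#' Builds the binary domains-by-species profile used throughout the package:
#' an integer matrix with domain ids as row names and species ids as column
#' names, cells in \{0, 1\}.
#'
#' @param data Matrix-like of 0/1 values, or a long tibble with columns
#'   `domain_id`, `species_id`, `present`.
#' @param domain_ids,species_ids Row/column names when `data` is a bare matrix.
#' @return An integer matrix of class `matrix`.
#' @export
presence_matrix <- function(data, domain_ids = rownames(data),
                            species_ids = colnames(data)) {
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(data, id_cols = "domain_id",
                               names_from = "species_id",
                               values_from = "present", values_fill = 0L)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$domain_id
  } else {
    m <- as.matrix(data)
    rownames(m) <- domain_ids
    colnames(m) <- species_ids
  }
  storage.mode(m) <- "integer"
  validate_presence_matrix(m)
  m
}

validate_presence_matrix <- function(m) {
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "presence matrix needs domain row names and species column names")
  assert_that(!anyDuplicated(rownames(m)) && !anyDuplicated(colnames(m)),
              "duplicate domain or species ids in presence matrix")
  assert_that(all(m %in% c(0L, 1L)),
              "presence matrix cells must be 0 or 1")
  invisible(m)
}

#' Read / write a presence matrix as TSV
#'
#' The on-disk format is a TSV whose first column (`domain_id`) holds domain
#' ids and whose header row holds species ids; cells are 0/1. Reading and
#' writing are exact inverses on valid input.
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: an integer presence matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(names(df)[1] == "domain_id", "first column must be `domain_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$domain_id
  assert_that(all(m %in% c(0, 1)), "non-binary cell in presence matrix TSV")
  storage.mode(m) <- "integer"
  validate_presence_matrix(m)
  m
}

#' @param matrix An integer presence matrix.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(matrix, path) {
  validate_presence_matrix(matrix)
  df <- tibble::as_tibble(matrix, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(domain_id = rownames(matrix)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a per-domain score cutoff table
#'
#' TSV with columns `domain_id`, `score_cutoff` (bits) and optionally
#' `model_length` (match columns, amino acids) — the shape of a Pfam
#' gathering-cutoff export.
#'
#' @param path File path.
#' @return A tibble with one row per domain.
#' @export
read_cutoffs_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("domain_id", "score_cutoff") %in% names(df)),
              "cutoff table needs `domain_id` and `score_cutoff` columns")
  assert_that(!anyDuplicated(df$domain_id), "duplicate domain_id in cutoff table")
  assert_that(all(is.finite(df$score_cutoff)), "score cutoffs must be finite")
  tibble::as_tibble(df)
}

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline with its default, and
#' round-trips to a versioned YAML file.
#'
#' @param ... Overrides for the defaults listed below.
#' @return A named list of class `loss_config`.
#' @export
loss_config <- function(...) {
  cfg <- list(
    version = 1L,
    seed = 1L,
    min_supergroups = 3L,          # LECA: present in >= this many supergroups
    require_both_sides = TRUE,     # LECA: present left and right of the root
    leca_clade_mean_threshold = 0.15,  # HGT screen: mean supergroup fraction
    min_busco_absences = 5L,       # genomes with more absences than this enter BUSCO medians
    max_mismatches = 0L,           # toy detector tolerance
    p_loss_per_branch = 0.05,
    p_unpredicted = 0.10,
    p_pseudogene = 0.02,
    codon_table = "1")
  over <- list(...)
  assert_that(all(names(over) %in% names(cfg)),
              paste0("unknown config keys: ",
                     paste(setdiff(names(over), names(cfg)), collapse = ", ")))
  cfg[names(over)] <- over
  for (k in c("p_loss_per_branch", "p_unpredicted", "p_pseudogene",
              "leca_clade_mean_threshold")) assert_prob(cfg[[k]], k)
  structure(cfg, class = "loss_config")
}

#' @param path YAML file path.
#' @rdname loss_config
#' @export
read_config <- function(path) {
  do.call(loss_config, yaml::read_yaml(path))
}

#' @param config A `loss_config`.
#' @rdname loss_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings FASTA I/O returning plain named character
#' vectors, the representation used by the simulator and the six-frame
#' translator.
#'
#' @param path File path.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
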