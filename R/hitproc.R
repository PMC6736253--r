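# Validation, deduplication and pseudogene flagging of domain hits.
#
# Canonical hit table columns:
#   domain_id, species_id, target_id, target_kind ("proteome"/"sixframe"),
#   frame (NA for proteome hits), start, end (0-based half-open; genomic
#   forward-strand coordinates for sixframe hits, protein coordinates for
#   proteome hits), strand (NA for proteome), bitscore, aligned_seq.

#' Apply per-domain bitscore cutoffs
#'
#' Keeps hits whose domain bitscore reaches the domain's curated threshold
#' (gathering-cutoff semantics: the comparison is inclusive, `>=`). A hit
#' whose domain has no cutoff entry is an error, never silently kept.
#'
#' @param hits Hit tibble (see module header for columns).
#' @param cutoffs Tibble with `domain_id`, `score_cutoff`, e.g. from
#'   [read_cutoffs_tsv()] or [make_domain_models()].
#' @return The filtered hit tibble, input order preserved.
#' @export
apply_score_cutoffs <- function(hits, cutoffs) {
  missing <- setdiff(unique(hits$domain_id), cutoffs$domain_id)
  assert_that(length(missing) == 0,
              paste0("no score cutoff for domain(s): ",
                     paste(missing, collapse = ", ")))
  cut <- setNames(cutoffs$score_cutoff, cutoffs$domain_id)
  hits[hits$bitscore >= cut[hits$domain_id], , drop = FALSE]
}

#' Flag likely pseudogene hits
#'
#' A six-frame hit whose aligned target subsequence contains a stop symbol
#' (`*`) anywhere in the envelope is flagged as a likely pseudogene;
#' proteome hits are never flagged. Flagged hits are excluded from presence
#' calls and from "found absence" calls downstream, but are retained so that
#' pseudogene-only absences can be reported.
#'
#' @param hits Hit tibble.
#' @return The tibble with a logical `pseudogene` column added (replaced if
#'   present).
#' @export
flag_pseudogenes <- function(hits) {
  hits$pseudogene <- hits$target_kind == "sixframe" &
    stringi::stri_detect_fixed(hits$aligned_seq, "*")
  hits
}

#' Select best-scoring non-overlapping hits
#'
#' Greedy deduplication per domain family: hits are visited in order of
#' descending bitscore (ties: smaller start, then lexicographic target id)
#' and a hit is discarded when its interval overlaps (shares at least one
#' position with) an already-kept hit of the same domain on the same target
#' or contig — regardless of frame or strand, since two frames over one
#' locus are a single signal.
#'
#' @param hits Hit tibble for one or more species (grouping is by
#'   `species_id`, `domain_id`, `target_id`).
#' @return The kept hits, sorted by species, domain, target, start.
#' @export
select_best_nonoverlapping <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bitscore), .data$start,
                         .data$target_id)
  key <- paste(hits$species_id, hits$domain_id, hits$target_id, sep = "\r")
  kept <- rep(TRUE, nrow(hits))
  groups <- split(seq_along(key), key)
  for (rows in groups[lengths(groups) > 1]) {
    for (j in seq_along(rows)[-1]) {
      i <- rows[j]
      prior <- rows[seq_len(j - 1)]
      prior <- prior[kept[prior]]
      if (any(hits$start[prior] < hits$end[i] & hits$end[prior] > hits$start[i])) {
        kept[i] <- FALSE
      }
    }
  }
  dplyr::arrange(hits[kept, , drop = FALSE], .data$species_id,
                 .data$domain_id, .data$target_id, .data$start)
}

# --- toy detector -----------------------------------------------------------
#
# Matching model: a copy of a consensus peptide matches a target window when
# at most `max_mismatches` positions differ, where target positions holding
# '*' (in-frame stop) or 'X' (ambiguous codon) are alignment-compatible with
# anything and never count against the budget — a homology search aligns
# through stops, and it is the pseudogene filter, not the search, that
# decides the fate of a stop-containing hit.
#
# Search strategy is seed-and-verify: each pattern is cut into
# `max_mismatches + 2` contiguous seeds, seed occurrences are located
# exactly, and every anchored window is verified position-wise. Any copy
# with at most `max_mismatches` mismatches plus at most one '*'/'X' position
# is guaranteed to leave one seed intact and is therefore always found;
# windows more corrupted than that may be missed. The generator plants at
# most one stop per copy, so recall on planted data is 1 by construction.

# Mismatch count of pattern against the target window starting at 1-based
# `s`, ignoring '*'/'X' target positions.
window_mismatches <- function(target, s, pattern) {
  tch <- strsplit(stringi::stri_sub(target, s, length = nchar(pattern)), "")[[1]]
  pch <- strsplit(pattern, "")[[1]]
  sum(tch != pch & tch != "*" & tch != "X")
}

# Cut each pattern into n contiguous seeds. Returns a list with per-seed-rank
# character vectors `seed[[k]]` and 0-based offset vectors `offset[[k]]`
# (NA where a pattern is shorter than k).
pattern_seeds <- function(patterns, n) {
  plens <- nchar(patterns)
  seed <- vector("list", n)
  offset <- vector("list", n)
  for (k in seq_len(n)) {
    ni <- pmax(1L, pmin(n, plens))
    lo <- floor(plens * (k - 1) / ni)
    hi <- floor(plens * k / ni)
    use <- k <= ni
    s <- rep(NA_character_, length(patterns))
    s[use] <- stringi::stri_sub(patterns[use], lo[use] + 1, hi[use])
    seed[[k]] <- s
    offset[[k]] <- ifelse(use, lo, NA_integer_)
  }
  list(seed = seed, offset = offset, n = n)
}

# Locate all accepted matches of many patterns in one target string.
# `seeds` may be precomputed with pattern_seeds(patterns, max_mismatches + 2)
# when the same pattern set is scanned against many targets.
# Returns a list (per pattern) of 0-based match starts.
locate_patterns <- function(target, patterns, max_mismatches = 0,
                            seeds = NULL) {
  tlen <- nchar(target)
  if (is.null(seeds)) seeds <- pattern_seeds(patterns, max_mismatches + 2L)
  cand <- vector("list", length(patterns))
  for (k in seq_len(seeds$n)) {
    present <- which(!is.na(seeds$seed[[k]]))
    if (length(present) == 0) next
    loc <- stringi::stri_locate_all_fixed(target, seeds$seed[[k]][present])
    for (j in seq_along(present)) {
      pos <- loc[[j]][, 1]
      if (is.na(pos[1])) next
      p <- present[j]
      cand[[p]] <- c(cand[[p]], pos - 1L - seeds$offset[[k]][p])
    }
  }
  hit_idx <- which(lengths(cand) > 0)
  out <- rep(list(integer(0)), length(patterns))
  for (p in hit_idx) {
    starts <- sort(unique(cand[[p]]))
    starts <- starts[starts >= 0 & starts + nchar(patterns[p]) <= tlen]
    out[[p]] <- starts[vapply(starts + 1L, window_mismatches, numeric(1),
                              target = target,
                              pattern = patterns[p]) <= max_mismatches]
  }
  out
}

# Single-pattern convenience wrapper around locate_patterns().
find_matches <- function(target, pattern, max_mismatches = 0) {
  locate_patterns(target, pattern, max_mismatches)[[1]]
}

#' Toy motif detector (profile-search stand-in)
#'
#' Scans targets for near-exact occurrences of each domain's consensus
#' peptide, scoring `model_length - 2 * mismatches` bits. Stop (`*`) and
#' ambiguity (`X`) positions in the target are alignment-compatible and do
#' not count as mismatches, so pseudogene copies are still detected and then
#' handled by [flag_pseudogenes()]. This built-in detector lets the pipeline
#' run end-to-end on synthetic fixtures; real profile-HMM results enter via
#' [read_domtblout()] instead.
#'
#' @param targets For `toy_detect_sixframe()`: a translation tibble as
#'   returned by [translate_six_frames()], plus a `species_id` column. For
#'   `toy_detect_proteome()`: a tibble with `species_id`, `protein_id`,
#'   `seq`.
#' @param models Domain model tibble with `domain_id`, `consensus_peptide`.
#' @param max_mismatches Mismatch tolerance per hit.
#' @return A canonical hit tibble (see [flag_pseudogenes()] for the
#'   pseudogene column added downstream).
#' @export
toy_detect_sixframe <- function(targets, models, max_mismatches = 0) {
  need <- c("species_id", "contig_id", "frame", "peptide", "source_length")
  assert_that(all(need %in% names(targets)),
              "sixframe targets need species_id, contig_id, frame, peptide, source_length")
  pats <- models$consensus_peptide
  seeds <- pattern_seeds(pats, max_mismatches + 2L)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    pep <- targets$peptide[i]
    found <- locate_patterns(pep, pats, max_mismatches, seeds = seeds)
    hit_d <- which(lengths(found) > 0)
    if (length(hit_d) == 0) next
    d_idx <- rep(hit_d, lengths(found[hit_d]))
    starts <- unlist(found[hit_d], use.names = FALSE)
    plen <- nchar(pats[d_idx])
    mm <- vapply(seq_along(starts), function(j)
      window_mismatches(pep, starts[j] + 1L, pats[d_idx[j]]), numeric(1))
    g <- frame_to_genome(targets$source_length[i], targets$frame[i],
                         starts, starts + plen)
    out[[length(out) + 1L]] <- tibble::tibble(
      domain_id = models$domain_id[d_idx],
      species_id = targets$species_id[i],
      target_id = targets$contig_id[i],
      target_kind = "sixframe",
      frame = targets$frame[i],
      start = g$start, end = g$end, strand = g$strand,
      bitscore = plen - 2 * mm,
      aligned_seq = stringi::stri_sub(pep, starts + 1L, length = plen))
  }
  if (length(out) == 0) return(empty_hits())
  dplyr::bind_rows(out)
}

#' @rdname toy_detect_sixframe
#' @export
toy_detect_proteome <- function(targets, models, max_mismatches = 0) {
  need <- c("species_id", "protein_id", "seq")
  assert_that(all(need %in% names(targets)),
              "proteome targets need species_id, protein_id, seq")
  pats <- models$consensus_peptide
  seeds <- pattern_seeds(pats, max_mismatches + 2L)
  out <- list()
  for (sp in unique(targets$species_id)) {
    rows <- targets[targets$species_id == sp, ]
    # concatenate the proteome with a separator no alignment can cross
    concat <- paste(rows$seq, collapse = "#")
    offsets <- cumsum(c(0L, nchar(rows$seq) + 1L))[seq_len(nrow(rows))]
    found <- locate_patterns(concat, pats, max_mismatches, seeds = seeds)
    hit_d <- which(lengths(found) > 0)
    if (length(hit_d) == 0) next
    d_idx <- rep(hit_d, lengths(found[hit_d]))
    starts <- unlist(found[hit_d], use.names = FALSE)
    plen <- nchar(pats[d_idx])
    prot <- findInterval(starts, offsets)
    mm <- vapply(seq_along(starts), function(j)
      window_mismatches(concat, starts[j] + 1L, pats[d_idx[j]]), numeric(1))
    out[[length(out) + 1L]] <- tibble::tibble(
      domain_id = models$domain_id[d_idx],
      species_id = sp,
      target_id = rows$protein_id[prot],
      target_kind = "proteome",
      frame = NA_integer_,
      start = starts - offsets[prot],
      end = starts - offsets[prot] + plen,
      strand = NA_character_,
      bitscore = plen - 2 * mm,
      aligned_seq = stringi::stri_sub(concat, starts + 1L, length = plen))
  }
  if (length(out) == 0) return(empty_hits())
  dplyr::bind_rows(out)
}

empty_hits <- function() {
  tibble::tibble(
    domain_id = character(), species_id = character(), target_id = character(),
    target_kind = character(), frame = integer(), start = integer(),
    end = integer(), strand = character(), bitscore = double(),
    aligned_seq = character())
}

#' Collapse validated hits into a presence matrix
#'
#' A cell is 1 iff the species has at least one surviving, non-pseudogene
#' hit for the domain. Hits are expected to be cutoff-filtered and
#' deduplicated already.
#'
#' @param hits Hit tibble (a `pseudogene` column is honoured if present).
#' @param domain_ids,species_ids Row and column universe of the matrix; hits
#'   referencing ids outside it are an error.
#' @return An integer presence matrix.
#' @export
hits_to_matrix <- function(hits, domain_ids, species_ids) {
  assert_that(all(hits$domain_id %in% domain_ids),
              "hit references unknown domain")
  assert_that(all(hits$species_id %in% species_ids),
              "hit references unknown species")
  m <- matrix(0L, length(domain_ids), length(species_ids),
              dimnames = list(domain_ids, species_ids))
  live <- if ("pseudogene" %in% names(hits)) hits[!hits$pseudogene, ] else hits
  if (nrow(live) > 0) {
    m[cbind(live$domain_id, live$species_id)] <- 1L
  }
  m
}
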