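# Phylogenomic screen for horizontally transferred domains.
#
# The tree-analysis half of the HGT filter: gene trees (inferred externally)
# are scanned for monophyletic eukaryotic clades containing species from
# both sides of the eukaryotic root with broad supergroup coverage. Domains
# without such a clade are flagged as likely transfers and removed from the
# strict LECA set. Alignment, trimming and tree inference are inputs, not
# computation, of this module.

#' Cross-root bidirectional best hits
#'
#' ScrollSaw-like reduction of a eukaryotic sequence set: a pair of
#' sequences, one from each side of the eukaryotic root, is selected iff
#' each is the other's best-scoring partner on the opposite side (mutual
#' best hit). Ties are broken lexicographically by sequence id.
#'
#' @param scores Tibble with columns `seq_left`, `seq_right`, `score`
#'   (higher is better), covering cross-side sequence pairs.
#' @param left,right Character vectors of sequence ids on each side of the
#'   root; both must be non-empty.
#' @return A tibble of selected pairs (`seq_left`, `seq_right`, `score`);
#'   the reduced sequence set is the union of the two columns.
#' @export
cross_root_bbh <- function(scores, left, right) {
  assert_that(length(left) > 0 && length(right) > 0,
              "both sides of the root must have sequences")
  sc <- scores %>%
    dplyr::filter(.data$seq_left %in% left, .data$seq_right %in% right)
  best_r <- sc %>%  # best right partner of each left sequence
    dplyr::arrange(dplyr::desc(.data$score), .data$seq_right) %>%
    dplyr::distinct(.data$seq_left, .keep_all = TRUE)
  best_l <- sc %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$seq_left) %>%
    dplyr::distinct(.data$seq_right, .keep_all = TRUE)
  dplyr::inner_join(best_r, best_l,
                    by = c("seq_left", "seq_right", "score")) %>%
    dplyr::arrange(.data$seq_left, .data$seq_right)
}

#' Assign unsampled sequences to their best representative tree leaf
#'
#' Sequences dropped by the BBH reduction still carry species information;
#' each is assigned to its best-scoring leaf in the gene tree (ties broken
#' lexicographically by leaf id) so its species can be counted in clade
#' coverage percentages.
#'
#' @param scores Tibble with columns `seq_id`, `leaf`, `score`; every
#'   unsampled sequence must have at least one scored leaf.
#' @return A tibble `seq_id`, `leaf` with one row per sequence.
#' @export
assign_unsampled <- function(scores) {
  assert_that(nrow(scores) > 0, "no scores for unsampled sequences")
  scores %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$leaf) %>%
    dplyr::distinct(.data$seq_id, .keep_all = TRUE) %>%
    dplyr::select("seq_id", "leaf") %>%
    dplyr::arrange(.data$seq_id)
}

#' Annotate LECA clades in a gene tree and call the domain's LECA status
#'
#' Enumerates the maximal monophyletic eukaryote-only clades of a gene tree
#' (clades whose leaves are all eukaryotic and whose parent clade is not).
#' A clade is a LECA clade when (1) it holds species from both sides of the
#' eukaryotic root and (2) the mean of the per-supergroup species coverage
#' percentages reaches the threshold (comparison is `>=`, "at least"). The
#' domain is called ancestral (LECA) iff the tree has at least one LECA
#' clade; otherwise it is flagged as a likely HGT.
#'
#' @param gene_tree A `phylo`; leaf labels index into `leaf_meta`.
#' @param leaf_meta Tibble with columns `leaf`, `kind`
#'   (`"eukaryote"`/`"prokaryote"`), and for eukaryotic leaves `species_id`,
#'   `supergroup5`, `root_side`.
#' @param supergroup_totals Named integer vector: total species sampled per
#'   supergroup in the dataset (the percentage denominators; all must be
#'   positive). Conventionally the five deep groupings, e.g. Excavata,
#'   SAR+Haptista, Archaeplastida+Cryptista, Amoebozoa,
#'   Opisthokonta+Apusozoa.
#' @param threshold Minimum mean coverage fraction (default 0.15).
#' @param unsampled Optional tibble `seq_id`, `species_id`, `supergroup5`,
#'   `root_side`, `leaf` mapping unsampled sequences (leaf assignments from
#'   [assign_unsampled()]) into clades; their species augment clade
#'   coverage.
#' @param domain_id Optional domain label for the verdict row.
#' @return A list with `clades` (tibble: `clade`, `n_leaves`,
#'   `has_both_root_sides`, one `pct_*` column per supergroup,
#'   `mean_percentage`, `is_leca_clade`) and `verdict` (tibble: `domain_id`,
#'   `in_leca`, `hgt_flagged`, `n_leca_clades`).
#' @export
annotate_leca_clades <- function(gene_tree, leaf_meta, supergroup_totals,
                                 threshold = 0.15, unsampled = NULL,
                                 domain_id = NA_character_) {
  assert_that(all(supergroup_totals > 0),
              "supergroup totals must all be positive")
  phy <- label_internal_nodes(gene_tree)
  idx <- tree_index(phy)
  meta <- leaf_meta[match(phy$tip.label, leaf_meta$leaf), ]
  assert_that(!anyNA(meta$leaf), "gene tree leaf missing from leaf_meta")
  euk <- meta$kind == "eukaryote"
  assert_that(all(!euk | (!is.na(meta$supergroup5) & !is.na(meta$root_side))),
              "eukaryotic leaves need supergroup5 and root_side")

  # eukaryote-only status per node (postorder AND over children), then
  # maximality via the parent
  euk_only <- c(euk, rep(TRUE, phy$Nnode))
  for (i in seq_len(nrow(idx$postorder))) {
    e <- idx$postorder[i, ]
    euk_only[e[1]] <- euk_only[e[1]] && euk_only[e[2]]
  }
  parent_euk <- ifelse(is.na(idx$parent), FALSE, euk_only[idx$parent])
  nodes <- which(euk_only & !parent_euk)

  sg_names <- names(supergroup_totals)
  clades <- purrr::map(nodes, function(nd) {
    tips <- tips_under(phy, nd)
    sp <- meta$species_id[tips]
    sg <- meta$supergroup5[tips]
    side <- meta$root_side[tips]
    if (!is.null(unsampled)) {
      inclade <- unsampled[unsampled$leaf %in% phy$tip.label[tips], ]
      sp <- c(sp, inclade$species_id)
      sg <- c(sg, inclade$supergroup5)
      side <- c(side, inclade$root_side)
    }
    keep <- !duplicated(sp)
    sp <- sp[keep]; sg <- sg[keep]; side <- side[keep]
    pct <- vapply(sg_names, function(g)
      100 * sum(sg == g) / supergroup_totals[[g]], numeric(1))
    row <- tibble::tibble(
      clade = idx$labels[nd], n_leaves = length(tips),
      has_both_root_sides = all(c("left", "right") %in% side),
      mean_percentage = mean(pct))
    row$is_leca_clade <- row$has_both_root_sides &
      row$mean_percentage >= 100 * threshold
    for (g in sg_names) row[[paste0("pct_", g)]] <- pct[[g]]
    row
  }) %>% dplyr::bind_rows()

  n_leca <- if (nrow(clades)) sum(clades$is_leca_clade) else 0L
  list(clades = clades,
       verdict = tibble::tibble(domain_id = domain_id,
                                in_leca = n_leca > 0,
                                hgt_flagged = n_leca == 0,
                                n_leca_clades = as.integer(n_leca)))
}

#' Shared k-mer similarity (toy scorer for fixtures)
#'
#' Counts distinct shared k-mers between two peptide sequences — a cheap
#' stand-in for alignment scores when building BBH fixtures.
#'
#' @param a,b Peptide strings.
#' @param k K-mer size.
#' @return Integer count of shared distinct k-mers.
#' @export
kmer_similarity <- function(a, b, k = 3) {
  kmers <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(stringi::stri_sub(s, seq_len(nchar(s) - k + 1), length = k))
  }
  length(intersect(kmers(a), kmers(b)))
}
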