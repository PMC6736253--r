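# Dollo (single-gain) ancestral reconstruction of binary domain profiles.
#
# Under the Dollo model a domain is gained exactly once on the tree and may
# only be lost afterwards. For a binary presence profile over the leaves the
# minimum-loss single-gain history is unique and has a closed form: the gain
# sits at the MRCA of the present leaves, an internal node of the gain
# subtree is present iff at least one of its descendant leaves is present,
# and each maximal absent subtree contributes exactly one loss on the branch
# above its root.

node_labels <- function(phy) c(phy$tip.label, phy$node.label)

# Cached traversal orders and parent pointers for a phylo object.
tree_index <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  post <- ape::reorder.phylo(phy, "postorder")$edge
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  parent <- rep(NA_integer_, nn)
  parent[post[, 2]] <- post[, 1]
  list(ntip = ntip, n_nodes = nn, root = ntip + 1L,
       postorder = post, preorder = pre, parent = parent,
       labels = node_labels(phy))
}

#' Dollo parsimony reconstruction for one domain
#'
#' Reconstructs the minimum-loss single-gain history of a binary
#' presence/absence profile on a rooted binary species tree. The gain node is
#' the MRCA of the present leaves; losses are the branches on which the
#' domain switches from present (parent) to absent (child). Leaves outside
#' the gain subtree predate the gain (`pre_gain`) and are not absences.
#'
#' @param tree A [species_tree] or a rooted binary `phylo` object.
#' @param presence Binary vector (0/1 or logical) named by species id, one
#'   entry per leaf; at least one leaf must be present.
#' @param domain_id Optional domain label stored on the result.
#' @return An object of class `dollo_reconstruction`: a list with
#'   `domain_id`, `gain_node` (node label), `node_states` (named character
#'   vector over all node labels: `present`, `absent` or `pre_gain`),
#'   `loss_branches` (labels of the child nodes of loss branches) and
#'   `n_losses`.
#' @export
dollo_reconstruct <- function(tree, presence, domain_id = NA_character_,
                              .idx = NULL) {
  phy <- as_phylo(tree)
  idx <- if (is.null(.idx)) tree_index(phy) else .idx
  presence <- presence_as_logical(presence, phy)
  assert_that(any(presence), "all-absent profile: no gain node can be placed")

  po_p <- idx$postorder[, 1]
  po_c <- idx$postorder[, 2]
  any_present <- c(presence, rep(FALSE, idx$n_nodes - idx$ntip))
  n_present <- c(as.integer(presence), integer(idx$n_nodes - idx$ntip))
  size <- rep(1L, idx$n_nodes)
  for (i in seq_along(po_p)) {
    if (any_present[po_c[i]]) any_present[po_p[i]] <- TRUE
    n_present[po_p[i]] <- n_present[po_p[i]] + n_present[po_c[i]]
    size[po_p[i]] <- size[po_p[i]] + size[po_c[i]]
  }
  # gain = MRCA of present leaves: smallest clade containing all of them
  covering <- which(n_present == sum(presence))
  gain <- covering[which.min(size[covering])]

  in_subtree <- rep(FALSE, idx$n_nodes)
  in_subtree[gain] <- TRUE
  pre_p <- idx$preorder[, 1]
  pre_c <- idx$preorder[, 2]
  for (i in seq_along(pre_p)) {
    if (in_subtree[pre_p[i]]) in_subtree[pre_c[i]] <- TRUE
  }

  states <- ifelse(!in_subtree, "pre_gain",
                   ifelse(any_present, "present", "absent"))
  loss <- idx$postorder[, 2][
    in_subtree[idx$postorder[, 1]] &
      any_present[idx$postorder[, 1]] & !any_present[idx$postorder[, 2]]]
  structure(list(
    domain_id = domain_id,
    gain_node = idx$labels[gain],
    node_states = setNames(states, idx$labels),
    loss_branches = sort(idx$labels[loss]),
    n_losses = length(loss)),
    class = "dollo_reconstruction")
}

as_phylo <- function(tree) {
  if (inherits(tree, "species_tree")) return(tree$tree)
  assert_that(inherits(tree, "phylo"), "`tree` must be a species_tree or phylo")
  label_internal_nodes(tree)
}

presence_as_logical <- function(presence, phy) {
  assert_that(!is.null(names(presence)), "`presence` must be named by species id")
  assert_that(setequal(names(presence), phy$tip.label),
              "presence profile species do not match tree leaves")
  v <- as.logical(presence[phy$tip.label])
  assert_that(!anyNA(v), "presence profile must be binary")
  v
}

#' Reconstruct every domain of a presence matrix
#'
#' @param tree A [species_tree] or `phylo`.
#' @param matrix A presence matrix (domains x species, see
#'   [presence_matrix()]). Domains with no present species are rejected.
#' @return A named list of [dollo_reconstruct()] results, one per domain row.
#' @export
dollo_reconstruct_all <- function(tree, matrix) {
  phy <- as_phylo(tree)
  validate_presence_matrix(matrix)
  assert_that(setequal(colnames(matrix), phy$tip.label),
              "matrix species do not match tree leaves")
  assert_that(all(rowSums(matrix) > 0),
              "all-absent profile: no gain node can be placed")
  idx <- tree_index(phy)
  recs <- purrr::map(rownames(matrix), function(d) {
    dollo_reconstruct(phy, matrix[d, ], domain_id = d, .idx = idx)
  })
  setNames(recs, rownames(matrix))
}

#' Count Dollo losses
#'
#' Summarises loss counts across a set of reconstructions: per-domain counts,
#' the grand total, the median per domain, and the count distribution used
#' for loss histograms.
#'
#' @param reconstructions A list of `dollo_reconstruction` objects (e.g. from
#'   [dollo_reconstruct_all()]).
#' @return A list with `per_domain` (tibble: `domain_id`, `n_losses`),
#'   `total`, `median`, and `distribution` (tibble: `n_losses`, `n_domains`).
#' @export
count_losses <- function(reconstructions) {
  per <- tibble::tibble(
    domain_id = unname(purrr::map_chr(reconstructions, "domain_id")),
    n_losses = unname(purrr::map_int(reconstructions, "n_losses")))
  dist <- per %>% dplyr::count(.data$n_losses, name = "n_domains")
  list(per_domain = per, total = sum(per$n_losses),
       median = stats::median(per$n_losses), distribution = dist)
}

#' Classify absences as clade- or species-specific
#'
#' For every absent leaf inside the gain subtree: if its parent node is
#' reconstructed present the absence is a loss on the terminal branch
#' (`species_specific`, not corroborated by sister taxa); if the parent is
#' absent the absence is covered by an ancestral loss shared with neighbours
#' (`clade_specific`). Leaves outside the gain subtree yield no record.
#'
#' @param reconstruction A `dollo_reconstruction`.
#' @param tree The [species_tree] or `phylo` it was computed on.
#' @return A tibble with columns `domain_id`, `species_id`, `category`.
#' @export
classify_absences <- function(reconstruction, tree, .idx = NULL) {
  phy <- as_phylo(tree)
  idx <- if (is.null(.idx)) tree_index(phy) else .idx
  st <- reconstruction$node_states[idx$labels]
  tips <- seq_len(idx$ntip)
  absent_tips <- tips[st[tips] == "absent"]
  if (length(absent_tips) == 0) {
    return(tibble::tibble(domain_id = character(), species_id = character(),
                          category = character()))
  }
  parent_state <- st[idx$parent[absent_tips]]
  tibble::tibble(
    domain_id = reconstruction$domain_id,
    species_id = unname(idx$labels[absent_tips]),
    category = unname(ifelse(parent_state == "present",
                             "species_specific", "clade_specific")))
}

#' LECA membership filter
#'
#' Applies the ancestral-content criteria to each domain of a presence
#' matrix: a domain is a candidate LECA domain (non-strict) when it is
#' present in at least `min_supergroups` supergroups and on both sides of
#' the root; the strict set additionally removes domains flagged as likely
#' horizontal transfers by the phylogenomic screen (see
#' [annotate_leca_clades()]).
#'
#' @param tree A [species_tree] (supergroup and root-side annotations are
#'   taken from it).
#' @param matrix Presence matrix (domains x species).
#' @param min_supergroups Minimum number of supergroups with a presence.
#' @param require_both_sides Require presence left and right of the root.
#' @param hgt_flags Optional tibble (`domain_id`, `hgt_flagged`) or named
#'   logical vector; domains not listed are taken as not flagged.
#' @return A tibble with one row per domain: `domain_id`,
#'   `n_supergroups_present`, `both_sides_of_root`, `hgt_flagged`,
#'   `in_leca_nonstrict`, `in_leca_strict`.
#' @export
leca_filter <- function(tree, matrix, min_supergroups = 3,
                        require_both_sides = TRUE, hgt_flags = NULL) {
  assert_that(inherits(tree, "species_tree"),
              "`tree` must be a species_tree (supergroup annotations needed)")
  validate_presence_matrix(matrix)
  meta <- tree$meta[match(colnames(matrix), tree$meta$species_id), ]
  assert_that(!anyNA(meta$species_id), "matrix species missing from tree")

  pres <- matrix == 1L
  n_sg <- apply(pres, 1, function(r) dplyr::n_distinct(meta$supergroup[r]))
  left <- rowSums(pres[, meta$root_side == "left", drop = FALSE]) > 0
  right <- rowSums(pres[, meta$root_side == "right", drop = FALSE]) > 0
  both <- left & right

  flagged <- rep(FALSE, nrow(matrix))
  names(flagged) <- rownames(matrix)
  if (!is.null(hgt_flags)) {
    if (is.data.frame(hgt_flags)) {
      hgt_flags <- setNames(hgt_flags$hgt_flagged, hgt_flags$domain_id)
    }
    known <- intersect(names(hgt_flags), names(flagged))
    flagged[known] <- as.logical(hgt_flags[known])
  }

  nonstrict <- (n_sg >= min_supergroups) &
    (if (require_both_sides) both else TRUE)
  tibble::tibble(
    domain_id = rownames(matrix),
    n_supergroups_present = as.integer(n_sg),
    both_sides_of_root = both,
    hgt_flagged = unname(flagged),
    in_leca_nonstrict = unname(nonstrict),
    in_leca_strict = unname(nonstrict & !flagged))
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf("<dollo_reconstruction> domain %s: gain at %s, %d losses (%s)\n",
              x$domain_id, x$gain_node, x$n_losses,
              paste(x$loss_branches, collapse = ", ")))
  invisible(x)
}
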