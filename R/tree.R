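#' Annotated species tree
#'
#' A `species_tree` couples a rooted, strictly binary [ape::phylo] tree with a
#' per-species annotation table. The annotations carry the supergroup
#' membership used by the LECA filter, an optional phylum, and the side of the
#' root each species descends from ("left" = first root child, "right" =
#' second). Sides are always recomputed from the topology; a sidecar that
#' contradicts the tree is an error.
#'
#' @param phy A rooted binary `phylo` object. Internal nodes are given stable
#'   labels (`N1`, `N2`, ...) if they have none.
#' @param meta A data frame with columns `species_id` and `supergroup`
#'   (required), `phylum` and `root_side` (optional). `species_id` must match
#'   the tip labels of `phy` exactly (any order).
#' @return An object of class `species_tree`: a list with elements `tree`
#'   (the `phylo`) and `meta` (a tibble, ordered as the tip labels).
#' @export
species_tree <- function(phy, meta) {
  assert_that(inherits(phy, "phylo"), "`phy` must be a phylo object")
  assert_that(ape::is.rooted(phy), "species tree must be rooted")
  assert_that(is_strictly_binary(phy), "species tree has a non-binary node")
  meta <- tibble::as_tibble(meta)
  assert_that(all(c("species_id", "supergroup") %in% names(meta)),
              "annotation table needs `species_id` and `supergroup` columns")
  assert_that(!anyDuplicated(meta$species_id),
              "duplicate species_id in annotation table")
  assert_that(setequal(meta$species_id, phy$tip.label),
              "annotation species do not match tree tip labels")
  assert_that(!any(is.na(meta$supergroup) | meta$supergroup == ""),
              "every leaf needs a supergroup annotation")
  phy <- label_internal_nodes(phy)

  sides <- tree_root_sides(phy)
  if ("root_side" %in% names(meta) && !all(is.na(meta$root_side))) {
    declared <- setNames(meta$root_side, meta$species_id)[names(sides)]
    bad <- names(sides)[!is.na(declared) & declared != sides]
    assert_that(length(bad) == 0,
                paste0("root_side annotation contradicts tree topology for: ",
                       paste(bad, collapse = ", ")))
  }
  meta$root_side <- unname(sides[meta$species_id])
  if (!"phylum" %in% names(meta)) meta$phylum <- NA_character_
  meta <- meta[match(phy$tip.label, meta$species_id),
               c("species_id", "supergroup", "phylum", "root_side")]
  structure(list(tree = phy, meta = meta), class = "species_tree")
}

is_strictly_binary <- function(phy) {
  # every internal node (root included) has exactly two children
  tab <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  all(tab[seq_len(ape::Ntip(phy))] == 0) &&
    all(tab[ape::Ntip(phy) + seq_len(phy$Nnode)] == 2)
}

label_internal_nodes <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab) || any(is.na(lab)) || any(lab == "")) {
    fresh <- paste0("N", seq_len(phy$Nnode))
    if (is.null(lab)) {
      phy$node.label <- fresh
    } else {
      empty <- is.na(lab) | lab == ""
      lab[empty] <- fresh[empty]
      phy$node.label <- lab
    }
  }
  assert_that(!anyDuplicated(c(phy$tip.label, phy$node.label)),
              "node labels must be unique")
  phy
}

# Side of the root ("left"/"right") for every tip, named by tip label.
tree_root_sides <- function(phy) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  side <- character(ntip)
  for (i in seq_along(kids)) {
    tips <- tips_under(phy, kids[i])
    side[tips] <- c("left", "right")[i]
  }
  setNames(side, phy$tip.label)
}

# Tip indices in the clade rooted at `node` (node may itself be a tip).
tips_under <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[[1]]
    todo <- todo[-1]
    kids <- phy$edge[phy$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  tips
}

#' Read a species tree with its annotation sidecar
#'
#' Reads a rooted binary Newick tree plus a tab-separated sidecar with columns
#' `species_id`, `supergroup`, and optionally `phylum` and `root_side`.
#' Polytomies and unannotated leaves are rejected. Root sides are derived
#' from the topology and checked against the sidecar if present.
#'
#' @param path Path to a Newick file with named leaves.
#' @param sidecar Path to the annotation TSV, or a data frame.
#' @return A [species_tree].
#' @export
read_newick <- function(path, sidecar) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) rlang::abort(paste0("unreadable Newick file: ", path)))
  if (is.null(phy)) rlang::abort(paste0("unreadable Newick file: ", path))
  assert_that(ape::is.rooted(phy) && is_strictly_binary(phy),
              "non-binary node in species tree")
  meta <- if (is.data.frame(sidecar)) sidecar else
    readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
  species_tree(phy, meta)
}

#' Write a species tree and its annotation sidecar
#'
#' @param st A [species_tree].
#' @param path Output Newick path.
#' @param sidecar_path Optional output path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_newick <- function(st, path, sidecar_path = NULL) {
  ape::write.tree(st$tree, file = path)
  if (!is.null(sidecar_path)) {
    readr::write_tsv(st$meta, sidecar_path, progress = FALSE)
  }
  invisible(path)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d species, %d supergroups (%s)\n",
              ape::Ntip(x$tree), dplyr::n_distinct(x$meta$supergroup),
              paste(sort(unique(x$meta$supergroup)), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.species_tree <- function(x, ...) x$meta
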