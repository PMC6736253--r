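# Cross-root BBH reduction and LECA-clade annotation of gene trees.

# Gene-tree fixture: prokaryotic outgroup plus eukaryotic clades.
# Species e1..e10; supergroups A..E (2 species each); e1..e5 left of the
# eukaryotic root, e6..e10 right.
euk_meta <- function(leaves) {
  sp <- sub("\\|.*", "", leaves)
  n <- as.integer(sub("e", "", sp))
  tibble::tibble(
    leaf = leaves, kind = "eukaryote", species_id = sp,
    supergroup5 = LETTERS[1:5][ceiling(n / 2)],
    root_side = ifelse(n <= 5, "left", "right"))
}

prok_meta <- function(leaves) {
  tibble::tibble(leaf = leaves, kind = "prokaryote", species_id = NA,
                 supergroup5 = NA, root_side = NA)
}

totals5 <- c(A = 5, B = 5, C = 10, D = 10, E = 5)

test_that("cross-root BBH selects exactly the mutual best pairs", {
  one <- tibble::tibble(seq_left = "l1", seq_right = "r1", score = 3)
  expect_equal(nrow(cross_root_bbh(one, "l1", "r1")), 1)

  # l1's best is r1, but r1's best is l2: no pair for l1/r1
  asym <- tibble::tibble(
    seq_left = c("l1", "l2"), seq_right = c("r1", "r1"), score = c(5, 9))
  got <- cross_root_bbh(asym, c("l1", "l2"), "r1")
  expect_equal(got$seq_left, "l2")

  expect_error(cross_root_bbh(one, character(0), "r1"), "both sides")

  # random score matrices match the mutual-argmax oracle
  set.seed(31)
  for (i in 1:10) {
    nl <- sample(3:10, 1); nr <- sample(3:10, 1)
    sc <- expand.grid(seq_left = paste0("l", 1:nl),
                      seq_right = paste0("r", 1:nr),
                      stringsAsFactors = FALSE)
    sc$score <- sample(seq_len(nrow(sc)))
    got <- cross_root_bbh(tibble::as_tibble(sc),
                          paste0("l", 1:nl), paste0("r", 1:nr))
    want <- oracle_bbh(sc)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("unsampled sequences go to their best leaf, invariant to rescaling", {
  sc <- tibble::tibble(seq_id = c("u1", "u1", "u2"),
                       leaf = c("a", "b", "a"),
                       score = c(50, 40, 7))
  got <- assign_unsampled(sc)
  expect_equal(got$leaf[got$seq_id == "u1"], "a")
  sc2 <- dplyr::mutate(sc, score = score * 2)
  expect_equal(assign_unsampled(sc2), got)

  # ties break lexicographically by leaf id
  tie <- tibble::tibble(seq_id = "u", leaf = c("z", "b"), score = c(5, 5))
  expect_equal(assign_unsampled(tie)$leaf, "b")
})

test_that("the 15%-mean and both-sides rules decide LECA clades", {
  # one eukaryotic clade with one species of each supergroup:
  # percentages (20, 20, 10, 10, 20), mean 16 -> LECA
  tr <- ape::read.tree(text = "((p1,p2),((e1,e3),((e5,e7),e9)));")
  meta <- dplyr::bind_rows(prok_meta(c("p1", "p2")),
                           euk_meta(c("e1", "e3", "e5", "e7", "e9")))
  res <- annotate_leca_clades(tr, meta, totals5)
  expect_equal(nrow(res$clades), 1)
  expect_equal(res$clades$mean_percentage, 16)
  expect_true(res$clades$has_both_root_sides)
  expect_true(res$clades$is_leca_clade)
  expect_true(res$verdict$in_leca)
  expect_false(res$verdict$hgt_flagged)

  # mean below threshold: 2 species from C and D only -> (0,0,10,10,0) mean 4
  tr2 <- ape::read.tree(text = "((p1,p2),(e5,e7));")
  meta2 <- dplyr::bind_rows(prok_meta(c("p1", "p2")),
                            euk_meta(c("e5", "e7")))
  res2 <- annotate_leca_clades(tr2, meta2, totals5)
  expect_true(res2$clades$has_both_root_sides)
  expect_false(res2$clades$is_leca_clade)
  expect_true(res2$verdict$hgt_flagged)

  # high coverage from one root side only is never a LECA clade
  tr3 <- ape::read.tree(text = "((p1,p2),((e1,e2),(e3,e4)));")
  meta3 <- dplyr::bind_rows(prok_meta(c("p1", "p2")),
                            euk_meta(c("e1", "e2", "e3", "e4")))
  res3 <- annotate_leca_clades(tr3, meta3, totals5)
  expect_false(res3$clades$has_both_root_sides)
  expect_false(res3$clades$is_leca_clade)

  # boundary: mean exactly 15% qualifies ("at least 15%")
  res4 <- annotate_leca_clades(tr, meta, c(A = 4, B = 5, C = 10, D = 10, E = 5))
  expect_equal(res4$clades$mean_percentage, 17)
  res5 <- annotate_leca_clades(
    tr2, meta2, c(A = 10, B = 10, C = 2, D = 3, E = 10))
  # (0,0,50,100/3,0)/... -> compute directly instead
  expect_equal(res5$clades$mean_percentage,
               mean(c(0, 0, 100 * 1 / 2, 100 * 1 / 3, 0)))
  res_boundary <- annotate_leca_clades(
    tr2, meta2, c(A = 1, B = 1, C = 4, D = 4, E = 1))
  expect_equal(res_boundary$clades$mean_percentage, 10)
  res_hit <- annotate_leca_clades(
    tr2, meta2, c(A = 1, B = 1, C = 2, D = 4, E = 1))
  expect_equal(res_hit$clades$mean_percentage, 15)
  expect_true(res_hit$clades$is_leca_clade)
})

test_that("unsampled assignments extend clade coverage", {
  tr <- ape::read.tree(text = "((p1,p2),(e1,e7));")
  meta <- dplyr::bind_rows(prok_meta(c("p1", "p2")), euk_meta(c("e1", "e7")))
  base <- annotate_leca_clades(tr, meta, totals5)
  # (20, 0, 0, 10, 0): mean 6 -> not LECA
  expect_false(base$verdict$in_leca)

  extra <- euk_meta(c("e3|u", "e5|u", "e9|u"))
  uns <- tibble::tibble(seq_id = extra$leaf, species_id = extra$species_id,
                        supergroup5 = extra$supergroup5,
                        root_side = extra$root_side, leaf = "e1")
  res <- annotate_leca_clades(tr, meta, totals5, unsampled = uns)
  expect_equal(res$clades$mean_percentage, 16)
  expect_true(res$verdict$in_leca)
})

test_that("verdicts ignore leaf order and prokaryote-edge rerooting", {
  tr <- ape::read.tree(text = "((p1,p2),((e1,e3),((e5,e7),e9)));")
  meta <- dplyr::bind_rows(prok_meta(c("p1", "p2")),
                           euk_meta(c("e1", "e3", "e5", "e7", "e9")))
  base <- annotate_leca_clades(tr, meta, totals5)

  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  res_rot <- annotate_leca_clades(rot, meta, totals5)
  expect_equal(res_rot$verdict$in_leca, base$verdict$in_leca)
  expect_equal(sort(res_rot$clades$mean_percentage),
               sort(base$clades$mean_percentage))

  rerooted <- ape::root(tr, outgroup = "p1", resolve.root = TRUE)
  res_rr <- annotate_leca_clades(rerooted, meta, totals5)
  expect_equal(res_rr$verdict$in_leca, base$verdict$in_leca)

  # a fully sampled domain in one clade is LECA at any threshold <= 100%
  full <- ape::read.tree(text = paste0(
    "((p1,p2),", paste0(rep("(", 9), collapse = ""), "e1,e2),e3),e4),e5),",
    "e6),e7),e8),e9),e10));"))
  meta_full <- dplyr::bind_rows(
    prok_meta(c("p1", "p2")), euk_meta(paste0("e", 1:10)))
  res_full <- annotate_leca_clades(full, meta_full,
                                   c(A = 2, B = 2, C = 2, D = 2, E = 2),
                                   threshold = 1.0)
  expect_true(res_full$verdict$in_leca)
})

test_that("k-mer similarity counts shared distinct k-mers", {
  expect_equal(kmer_similarity("ABCDE", "ABCDE", 3), 3)
  expect_equal(kmer_similarity("ABCDE", "VWXYZ", 3), 0)
  expect_gt(kmer_similarity("MKLVANDE", "KLVA", 3), 0)
})
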