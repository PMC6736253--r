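# Absence verification against six-frame hits and the corrected loss recount.

test_that("planted failures drive the found/pseudogene calls exactly", {
  fx <- small_run()
  calls <- fx$run$absence_calls
  truth <- fx$sim$statuses
  joined <- dplyr::left_join(calls, truth, by = c("domain_id", "species_id"))

  # unpredicted cells are found, pseudogene cells are pseudogene-only,
  # true losses are neither
  expect_true(all(joined$found_in_genome[joined$status == "unpredicted"]))
  expect_true(all(joined$pseudogene_only[joined$status == "pseudogene"]))
  expect_false(any(joined$found_in_genome[joined$status == "lost"]))
  expect_false(any(joined$pseudogene_only[joined$status == "lost"]))
  # found and pseudogene-only are mutually exclusive
  expect_false(any(joined$found_in_genome & joined$pseudogene_only))

  sc <- score_against_truth(fx$run)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_true(sc$pseudogene_flags_exact)
})

test_that("hits on non-absent cells are ignored with a warning", {
  absences <- tibble::tibble(domain_id = "d1", species_id = "s1",
                             category = "species_specific")
  hits <- tibble::tibble(
    domain_id = c("d1", "d2"), species_id = "s1", target_id = "c",
    target_kind = "sixframe", frame = 1L, start = 0L, end = 30L,
    strand = "+", bitscore = 30, aligned_seq = "MKLVD")
  expect_warning(out <- find_absence_hits(absences, hits), "not marked absent")
  expect_true(out$found_in_genome)
  expect_equal(nrow(out), 1)
})

test_that("corrections shift losses exactly as the reconstruction dictates", {
  phy <- ape::read.tree(text = "((A,B),((C,D),E));")
  st <- species_tree(phy, tibble::tibble(
    species_id = LETTERS[1:5],
    supergroup = c("SG1", "SG1", "SG2", "SG2", "SG2")))
  m <- presence_matrix(
    matrix(c(1, 1, 1, 0, 1,   # d1: species-specific absence in D
             1, 1, 0, 0, 1),  # d2: clade-specific absences in C, D
           nrow = 2, byrow = TRUE),
    domain_ids = c("d1", "d2"), species_ids = LETTERS[1:5])

  # nothing found: corrected equals uncorrected
  none <- tibble::tibble(domain_id = "d1", species_id = "D",
                         category = "species_specific",
                         found_in_genome = FALSE, pseudogene_only = TRUE)
  same <- correct_and_recount(st, m, none, c("d1", "d2"))
  expect_equal(same$total_corrected, same$total_uncorrected)
  expect_identical(same$corrected_matrix, m)

  # rescuing one species-specific absence removes exactly one loss
  found_ss <- dplyr::mutate(none, found_in_genome = TRUE,
                            pseudogene_only = FALSE)
  fixed <- correct_and_recount(st, m, found_ss, c("d1", "d2"))
  expect_equal(
    fixed$per_domain$delta[fixed$per_domain$domain_id == "d1"], 1)
  expect_equal(fixed$total_corrected, fixed$total_uncorrected - 1)

  # rescuing one leaf of an absent cherry leaves the loss count unchanged
  found_cl <- tibble::tibble(domain_id = "d2", species_id = "C",
                             category = "clade_specific",
                             found_in_genome = TRUE, pseudogene_only = FALSE)
  cl <- correct_and_recount(st, m, found_cl, c("d1", "d2"))
  expect_equal(cl$per_domain$delta[cl$per_domain$domain_id == "d2"], 0)

  # a found flag for a present cell is rejected
  bad <- tibble::tibble(domain_id = "d1", species_id = "A",
                        category = "species_specific",
                        found_in_genome = TRUE, pseudogene_only = FALSE)
  expect_error(correct_and_recount(st, m, bad, "d1"), "not absent")
})

test_that("rescuing inside a larger absent clade can add a loss", {
  # ((A,B),(((C,D),E),F)): absent in C, D, E = one clade loss; rescuing D
  # splits the absent clade into C and E = two losses
  phy <- ape::read.tree(text = "((A,B),(((C,D),E),F));")
  meta <- tibble::tibble(species_id = LETTERS[1:6],
                         supergroup = c("SG1", "SG1", rep("SG2", 4)))
  st <- species_tree(phy, meta)
  m <- presence_matrix(matrix(c(1, 1, 0, 0, 0, 1), 1),
                       domain_ids = "d1", species_ids = LETTERS[1:6])
  found <- tibble::tibble(domain_id = "d1", species_id = "D",
                          category = "clade_specific",
                          found_in_genome = TRUE, pseudogene_only = FALSE)
  res <- correct_and_recount(st, m, found, "d1")
  expect_equal(res$total_uncorrected, 1)
  expect_equal(res$total_corrected, 2)
})

test_that("per-genome summaries compute percentages, filters and medians", {
  calls <- tibble::tibble(
    domain_id = sprintf("d%02d", 1:14),
    species_id = c(rep("g1", 10), rep("g2", 4)),
    category = c(rep("species_specific", 10), rep("species_specific", 4)),
    found_in_genome = c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 4)),
    pseudogene_only = FALSE)
  fs <- summarize_found(calls)
  g1 <- fs$per_genome[fs$per_genome$species_id == "g1" &
                        fs$per_genome$category == "total", ]
  expect_equal(g1$pct_found, 20)  # 2 of 10

  # BUSCO-style inclusion rule: genomes need more than `min_absences`
  fs5 <- summarize_found(calls, min_absences = 5)
  expect_false("g2" %in% fs5$per_genome$species_id)
  expect_true("g1" %in% fs5$per_genome$species_id)

  # genomes with no absences in a category are excluded from that median
  mixed <- dplyr::bind_rows(
    calls,
    tibble::tibble(domain_id = "d99", species_id = "g1",
                   category = "clade_specific", found_in_genome = FALSE,
                   pseudogene_only = FALSE))
  fsm <- summarize_found(mixed)
  med <- fsm$medians
  expect_equal(med$n_genomes[med$category == "clade_specific"], 1)
  expect_equal(med$n_genomes[med$category == "species_specific"], 2)
})

test_that("pseudogene-only absences never alter the corrected matrix", {
  fx <- small_run()
  run <- fx$run
  pg <- run$absence_calls[run$absence_calls$pseudogene_only, ]
  expect_gt(nrow(pg), 0)
  expect_true(all(run$correction$corrected_matrix[
    cbind(pg$domain_id, pg$species_id)] == 0L))
  # corrected matrix dominates the observed one elementwise
  expect_true(all(run$correction$corrected_matrix >= run$observed))
})
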