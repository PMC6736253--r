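# Synthetic data with planted ground truth.
#
# The generator emulates the statistical structure the analysis assumes: a
# rooted binary species tree partitioned into supergroup clades, domains
# gained once (at the root by default) and lost independently per branch,
# per-cell detection failures (unpredicted genes findable in the DNA,
# pseudogenes carrying an in-frame stop), and concrete genome/proteome
# sequences with the planted peptides embedded at known coordinates.

#' Generate a random annotated species tree
#'
#' Draws a rooted binary tree whose leaves are partitioned into
#' `n_supergroups` contiguous clades (each supergroup is monophyletic), with
#' supergroups on both sides of the root. Deterministic given `seed`.
#'
#' @param n_species Number of leaves (>= 4, and >= `n_supergroups`).
#' @param n_supergroups Number of supergroup clades (>= 2; the default 6
#'   mirrors the deep eukaryotic supergroup split).
#' @param seed Integer seed.
#' @return A [species_tree] with species `s001`, `s002`, ... and supergroups
#'   `SG1`, `SG2`, ...
#' @export
generate_species_tree <- function(n_species, n_supergroups = 6, seed = 1) {
  assert_that(n_species >= 4, "n_species must be >= 4")
  assert_that(n_supergroups >= 2 && n_supergroups <= n_species,
              "need 2 <= n_supergroups <= n_species")
  with_seed(seed, {
    sizes <- rep(n_species %/% n_supergroups, n_supergroups)
    extra <- n_species - sum(sizes)
    if (extra > 0) {
      idx <- sample.int(n_supergroups, extra)
      sizes[idx] <- sizes[idx] + 1L
    }
    species <- sprintf("s%03d", seq_len(n_species))
    groups <- split(species, rep(seq_len(n_supergroups), times = sizes))
    clades <- vapply(groups, random_binary_newick, character(1))
    backbone <- random_binary_newick(clades)
    phy <- ape::read.tree(text = paste0(backbone, ";"))
    meta <- tibble::tibble(
      species_id = unlist(groups, use.names = FALSE),
      supergroup = rep(paste0("SG", seq_len(n_supergroups)), times = sizes))
    meta$phylum <- paste0(meta$supergroup, "_p",
                          1 + (match(meta$species_id, species) %% 2))
    species_tree(phy, meta)
  })
}

# Random rooted binary newick over a set of already-formatted labels/clades.
random_binary_newick <- function(labels) {
  if (length(labels) == 1) return(labels)
  labels <- sample(labels)
  k <- if (length(labels) == 2) 1L else sample.int(length(labels) - 1L, 1L)
  paste0("(", random_binary_newick(labels[seq_len(k)]), ",",
         random_binary_newick(labels[-seq_len(k)]), ")")
}

#' Simulate single-gain domain evolution on a tree
#'
#' Realises the model the reconstruction assumes: every domain is gained
#' once (at the root by default, i.e. an ancestral domain), and on every
#' branch whose parent carries the domain it is lost independently with
#' probability `p_loss_per_branch`; once lost it is never regained on that
#' lineage.
#'
#' @param tree A [species_tree] or `phylo`.
#' @param n_domains Number of domains to simulate (ids `D0001`, ...).
#' @param p_loss_per_branch Per-branch loss probability.
#' @param seed Integer seed.
#' @param gain One of `"root"` (all domains ancestral) or `"random"` (gain
#'   node drawn uniformly over all nodes, to exercise pre-gain handling).
#' @return A list with `truth` (presence matrix, domains x species),
#'   `events` (tibble `domain_id`, `branch` = child-node label of each
#'   planted loss), `gains` (tibble `domain_id`, `gain_node`), and
#'   `pre_gain` (logical matrix, domains x species).
#' @export
simulate_dollo_evolution <- function(tree, n_domains, p_loss_per_branch,
                                     seed = 1, gain = c("root", "random")) {
  gain <- match.arg(gain)
  assert_prob(p_loss_per_branch, "p_loss_per_branch")
  phy <- as_phylo(tree)
  idx <- tree_index(phy)
  domains <- sprintf("D%04d", seq_len(n_domains))
  with_seed(seed, {
    gain_nodes <- if (gain == "root") rep(idx$root, n_domains) else
      sample.int(idx$n_nodes, n_domains, replace = TRUE)
    ne <- nrow(idx$preorder)
    draw <- matrix(runif(ne * n_domains) < p_loss_per_branch, nrow = ne)

    state <- matrix(FALSE, idx$n_nodes, n_domains)
    state[cbind(gain_nodes, seq_len(n_domains))] <- TRUE
    lost_on <- matrix(FALSE, ne, n_domains)
    for (i in seq_len(ne)) {
      p <- idx$preorder[i, 1]; ch <- idx$preorder[i, 2]
      is_gain_child <- gain_nodes == ch  # keep gain state regardless of parent
      loses <- state[p, ] & draw[i, ]
      lost_on[i, ] <- loses
      state[ch, ] <- (state[p, ] & !draw[i, ]) | state[ch, ] | is_gain_child
    }

    truth <- t(state[seq_len(idx$ntip), , drop = FALSE]) * 1L
    rownames(truth) <- domains
    colnames(truth) <- phy$tip.label

    ev <- which(lost_on, arr.ind = TRUE)
    events <- tibble::tibble(
      domain_id = domains[ev[, 2]],
      branch = idx$labels[idx$preorder[ev[, 1], 2]]) %>%
      dplyr::arrange(.data$domain_id, .data$branch)

    # leaves outside the gain subtree never had the domain
    pre_gain <- matrix(FALSE, n_domains, idx$ntip,
                       dimnames = list(domains, phy$tip.label))
    if (gain == "random") {
      for (d in seq_len(n_domains)) {
        under <- rep(FALSE, idx$n_nodes)
        under[gain_nodes[d]] <- TRUE
        for (i in seq_len(ne)) {
          e <- idx$preorder[i, ]
          if (under[e[1]]) under[e[2]] <- TRUE
        }
        pre_gain[d, ] <- !under[seq_len(idx$ntip)]
      }
    }
    list(truth = truth, events = events,
         gains = tibble::tibble(domain_id = domains,
                                gain_node = idx$labels[gain_nodes]),
         pre_gain = pre_gain)
  })
}

#' Inject detection failures into a true presence matrix
#'
#' Turns the true domain content into the content an imperfect annotation
#' pipeline would report. Each truly present (domain, species) cell is,
#' mutually exclusively, turned into a pseudogene with probability
#' `p_pseudogene` (still in the genome, carries an in-frame stop) or left
#' unpredicted with probability `p_unpredicted` (in the genome, missing from
#' the proteome); otherwise it stays predicted. Both marginal rates are exact.
#'
#' @param truth Presence matrix of true domain content.
#' @param p_unpredicted,p_pseudogene Failure probabilities
#'   (`p_unpredicted + p_pseudogene <= 1`). `p_unpredicted` may also be a
#'   per-domain vector named by domain id (e.g. a length-dependent miss
#'   probability: short proteins are dropped by annotation pipelines more
#'   often).
#' @param seed Integer seed.
#' @param pre_gain Optional logical matrix marking cells that predate the
#'   domain's gain (labelled `pre_gain` rather than `lost`).
#' @return A list with `observed` (the proteome presence matrix) and
#'   `statuses` (tibble `domain_id`, `species_id`, `status` in
#'   `predicted_present`, `unpredicted`, `pseudogene`, `lost`, `pre_gain`).
#' @export
inject_detection_failures <- function(truth, p_unpredicted, p_pseudogene,
                                      seed = 1, pre_gain = NULL) {
  validate_presence_matrix(truth)
  if (length(p_unpredicted) == 1) {
    assert_prob(p_unpredicted, "p_unpredicted")
    p_unp <- rep(p_unpredicted, nrow(truth))
  } else {
    assert_that(all(rownames(truth) %in% names(p_unpredicted)),
                "per-domain p_unpredicted must be named by domain id")
    p_unp <- unname(p_unpredicted[rownames(truth)])
    assert_that(all(p_unp >= 0 & p_unp <= 1),
                "p_unpredicted values must be probabilities")
  }
  assert_prob(p_pseudogene, "p_pseudogene")
  assert_that(all(p_unp + p_pseudogene <= 1),
              "p_unpredicted + p_pseudogene must not exceed 1")
  with_seed(seed, {
    u <- matrix(runif(length(truth)), nrow = nrow(truth))
    status <- matrix("lost", nrow(truth), ncol(truth),
                     dimnames = dimnames(truth))
    pres <- truth == 1L
    status[pres] <- "predicted_present"
    status[pres & u < p_pseudogene + p_unp] <- "unpredicted"
    status[pres & u < p_pseudogene] <- "pseudogene"
    if (!is.null(pre_gain)) status[!pres & pre_gain] <- "pre_gain"
    observed <- (status == "predicted_present") * 1L
    dimnames(observed) <- dimnames(truth)
    statuses <- tibble::tibble(
      domain_id = rep(rownames(truth), times = ncol(truth)),
      species_id = rep(colnames(truth), each = nrow(truth)),
      status = as.vector(status))
    list(observed = observed, statuses = statuses)
  })
}

#' Generate toy domain models
#'
#' One consensus peptide per domain (uniform over the 20 amino acids), with a
#' model length and a bitscore cutoff compatible with the toy detector's
#' score `length - 2 * mismatches`.
#'
#' @param n_domains Number of domains.
#' @param length_range Inclusive range of peptide lengths (amino acids).
#' @param seed Integer seed.
#' @param cutoff_slack The cutoff is `model_length - cutoff_slack` bits, i.e.
#'   up to `cutoff_slack / 2` mismatches still validate.
#' @return A tibble: `domain_id`, `model_length`, `score_cutoff`,
#'   `consensus_peptide`.
#' @export
make_domain_models <- function(n_domains, length_range = c(25, 45), seed = 1,
                               cutoff_slack = 4) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_domains, replace = TRUE)
    peps <- vapply(lens, function(l) paste(sample(aa, l, TRUE), collapse = ""),
                   character(1))
    tibble::tibble(
      domain_id = sprintf("D%04d", seq_len(n_domains)),
      model_length = as.integer(lens),
      score_cutoff = lens - cutoff_slack,
      consensus_peptide = peps)
  })
}

# Back-translate a peptide with uniformly random synonymous codons,
# never emitting a stop codon. `sampler` comes from codon_sampler().
back_translate <- function(peptide, sampler) {
  ai <- match(strsplit(peptide, "")[[1]], sampler$aa)
  assert_that(!anyNA(ai), "peptide has a residue the codon table cannot encode")
  j <- 1L + floor(runif(length(ai)) * sampler$n[ai])
  paste(sampler$mat[cbind(ai, j)], collapse = "")
}

codon_choices <- function(code) {
  split(names(code), unname(code))
}

# Indexable codon lookup for vectorised back-translation.
codon_sampler <- function(cmap) {
  n <- lengths(cmap)
  mat <- matrix(NA_character_, length(cmap), max(n))
  for (i in seq_along(cmap)) mat[i, seq_len(n[i])] <- cmap[[i]]
  list(aa = names(cmap), n = n, mat = mat)
}

#' Emit genome and proteome sequences for a planted ground truth
#'
#' Builds one genomic contig per species: uniform background nucleotides
#' with the back-translated consensus peptides of all genomically present
#' domains (`predicted_present`, `unpredicted`, `pseudogene`) embedded at
#' random non-overlapping positions, strands and frames. Pseudogene copies
#' get one strictly internal codon replaced by a stop codon of the active
#' table. Proteomes contain only the `predicted_present` peptides.
#'
#' @param statuses Ground-truth status tibble from
#'   [inject_detection_failures()].
#' @param models Domain model tibble from [make_domain_models()].
#' @param codon_table NCBI genetic code id (`"1"` or `"6"` supported).
#' @param seed Integer seed.
#' @param gap_range Inclusive range of background gap lengths (nt) between
#'   embedded segments.
#' @param genome_length Optional fixed contig length; an error is raised if
#'   the segments do not fit.
#' @return A list with `genomes` (named character vector, one contig per
#'   species, names `<species>_ctg`), `proteomes` (tibble `species_id`,
#'   `protein_id`, `seq`), and `manifest` (tibble `domain_id`, `species_id`,
#'   `contig_id`, `start`, `end` 0-based half-open forward-strand, `strand`,
#'   `frame`, `status`).
#' @export
emit_sequences <- function(statuses, models, codon_table = "1", seed = 1,
                           gap_range = c(20, 60), genome_length = NULL) {
  code <- genetic_code(codon_table)
  cmap <- codon_choices(code)
  stops <- cmap[["*"]]
  assert_that(length(stops) > 0, "codon table has no stop codon")
  cmap <- cmap[names(cmap) != "*"]
  sampler <- codon_sampler(cmap)
  with_seed(seed, {
    per_sp <- statuses %>%
      dplyr::filter(.data$status %in%
                      c("predicted_present", "unpredicted", "pseudogene")) %>%
      dplyr::left_join(models, by = "domain_id")
    assert_that(!anyNA(per_sp$consensus_peptide),
                "status table references a domain with no model")
    species <- unique(statuses$species_id)
    genomes <- character(0)
    manifest <- list()
    proteomes <- list()
    for (sp in species) {
      rows <- per_sp[per_sp$species_id == sp, ]
      rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
      contig <- paste0(sp, "_ctg")
      segs <- character(nrow(rows))
      strands <- character(nrow(rows))
      for (j in seq_len(nrow(rows))) {
        cds <- back_translate(rows$consensus_peptide[j], sampler)
        if (rows$status[j] == "pseudogene") {
          n_cod <- nchar(cds) %/% 3
          assert_that(n_cod >= 3, "peptide too short to plant an internal stop")
          internal <- 2:(n_cod - 1)  # strictly internal codon
          k <- internal[sample.int(length(internal), 1)]
          stringi::stri_sub(cds, 3 * (k - 1) + 1, 3 * k) <-
            stops[sample.int(length(stops), 1)]
        }
        strands[j] <- sample(c("+", "-"), 1)
        segs[j] <- if (strands[j] == "+") cds else revcomp(cds)
      }
      seg_len <- nchar(segs)
      n_gaps <- nrow(rows) + 1L
      gaps <- sample(gap_range[1]:gap_range[2], n_gaps, replace = TRUE)
      if (!is.null(genome_length)) {
        spare <- genome_length - sum(seg_len)
        assert_that(spare >= n_gaps,
                    sprintf("genome too short to place all segments for %s", sp))
        gaps <- 1L + tabulate(sample.int(n_gaps, spare - n_gaps, replace = TRUE),
                              nbins = n_gaps)
      }
      pieces <- character(2 * nrow(rows) + 1)
      pieces[seq(1, length(pieces), by = 2)] <-
        vapply(gaps, random_dna, character(1))
      if (nrow(rows) > 0) {
        pieces[seq(2, length(pieces) - 1, by = 2)] <- segs
      }
      genome <- paste(pieces, collapse = "")
      L <- nchar(genome)
      if (nrow(rows) > 0) {
        starts <- cumsum(c(0L, nchar(pieces)))[seq(2, length(pieces) - 1, by = 2)]
        fr <- genome_to_frame(L, starts, starts + seg_len, strands)
        manifest[[sp]] <- tibble::tibble(
          domain_id = rows$domain_id, species_id = sp, contig_id = contig,
          start = as.integer(starts), end = as.integer(starts + seg_len),
          strand = strands, frame = fr$frame, status = rows$status)
      }
      genomes[contig] <- genome
      pred <- rows[rows$status == "predicted_present", ]
      if (nrow(pred) > 0) {
        proteomes[[sp]] <- tibble::tibble(
          species_id = sp,
          protein_id = paste0(sp, "|", pred$domain_id),
          seq = pred$consensus_peptide)
      }
    }
    list(genomes = genomes,
         proteomes = dplyr::bind_rows(proteomes),
         manifest = dplyr::bind_rows(manifest))
  })
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a complete study dataset with ground truth
#'
#' Convenience wrapper chaining [generate_species_tree()],
#' [simulate_dollo_evolution()], [inject_detection_failures()],
#' [make_domain_models()] and [emit_sequences()] under one seed.
#'
#' @param n_species,n_supergroups,n_domains Dataset dimensions.
#' @param p_loss_per_branch,p_unpredicted,p_pseudogene Model rates.
#' @param peptide_length_range Domain consensus length range (aa).
#' @param codon_table NCBI genetic code id.
#' @param seed Integer master seed; step seeds are derived from it.
#' @param gain Gain placement, see [simulate_dollo_evolution()].
#' @param length_bias If TRUE, the unpredicted-miss probability is inversely
#'   proportional to the domain's model length (normalised so its mean over
#'   domains is `p_unpredicted`, capped at 0.95), mimicking the tendency of
#'   annotation pipelines to drop short proteins.
#' @return A list of class `loss_sim` with elements `tree`, `models`,
#'   `truth`, `observed`, `statuses`, `events`, `gains`, `genomes`,
#'   `proteomes`, `manifest`, `params`.
#' @export
simulate_loss_dataset <- function(n_species = 50, n_supergroups = 6,
                                  n_domains = 400, p_loss_per_branch = 0.05,
                                  p_unpredicted = 0.10, p_pseudogene = 0.02,
                                  peptide_length_range = c(25, 45),
                                  codon_table = "1", seed = 1,
                                  gain = "root", length_bias = FALSE) {
  seeds <- as.integer(seed) + 0:4 * 1009L
  st <- generate_species_tree(n_species, n_supergroups, seed = seeds[1])
  evo <- simulate_dollo_evolution(st, n_domains, p_loss_per_branch,
                                  seed = seeds[2], gain = gain)
  models <- make_domain_models(n_domains, peptide_length_range, seed = seeds[4])
  p_unp <- p_unpredicted
  if (length_bias) {
    w <- (1 / models$model_length) / mean(1 / models$model_length)
    p_unp <- setNames(pmin(0.95, p_unpredicted * w), models$domain_id)
  }
  inj <- inject_detection_failures(evo$truth, p_unp, p_pseudogene,
                                   seed = seeds[3], pre_gain = evo$pre_gain)
  seqs <- emit_sequences(inj$statuses, models, codon_table = codon_table,
                         seed = seeds[5])
  structure(list(
    tree = st, models = models, truth = evo$truth, observed = inj$observed,
    statuses = inj$statuses, events = evo$events, gains = evo$gains,
    genomes = seqs$genomes, proteomes = seqs$proteomes,
    manifest = seqs$manifest,
    params = list(n_species = n_species, n_supergroups = n_supergroups,
                  n_domains = n_domains, p_loss_per_branch = p_loss_per_branch,
                  p_unpredicted = p_unpredicted, p_pseudogene = p_pseudogene,
                  codon_table = codon_table, seed = seed, gain = gain)),
    class = "loss_sim")
}

#' @export
print.loss_sim <- function(x, ...) {
  cat(sprintf(
    "<loss_sim> %d species / %d domains; rates: loss %.3g, unpredicted %.3g, pseudogene %.3g (seed %d)\n",
    x$params$n_species, x$params$n_domains, x$params$p_loss_per_branch,
    x$params$p_unpredicted, x$params$p_pseudogene, x$params$seed))
  invisible(x)
}
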