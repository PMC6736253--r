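# Shared fixtures and independent oracles used across the suite.

# Four-leaf balanced tree ((A,B),(C,D)); with supergroup/side annotations.
quartet_tree <- function() {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  meta <- tibble::tibble(
    species_id = c("A", "B", "C", "D"),
    supergroup = c("SG1", "SG1", "SG2", "SG2"))
  species_tree(phy, meta)
}

# Random rooted binary tree with n leaves labelled t1..tn (plain phylo).
random_tree <- function(n) {
  phy <- ape::rtree(n, rooted = TRUE)
  phy$tip.label <- paste0("t", seq_len(n))
  phy$node.label <- paste0("N", seq_len(phy$Nnode))
  phy
}

# Brute-force Dollo oracle: minimum number of present->absent transitions
# over all node-state assignments with exactly one gain (an absent->present
# edge transition, or a present root). Leaves are fixed to the profile.
oracle_dollo_losses <- function(phy, presence) {
  ntip <- ape::Ntip(phy)
  n_nodes <- ntip + phy$Nnode
  edges <- phy$edge
  leaf_states <- as.integer(presence[phy$tip.label])
  internal <- (ntip + 1):n_nodes
  best <- Inf
  for (mask in 0:(2^length(internal) - 1)) {
    st <- integer(n_nodes)
    st[seq_len(ntip)] <- leaf_states
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    gains <- sum(st[edges[, 1]] == 0 & st[edges[, 2]] == 1) + st[ntip + 1]
    if (gains != 1) next
    losses <- sum(st[edges[, 1]] == 1 & st[edges[, 2]] == 0)
    best <- min(best, losses)
  }
  best
}

# O(n^2) greedy oracle for best-scoring non-overlapping interval selection
# within one (species, domain, target) group; mirrors the documented order
# (descending score, then start, then target id).
oracle_greedy_select <- function(df) {
  df <- df[order(-df$bitscore, df$start, df$target_id), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    same <- kept$species_id == df$species_id[i] &
      kept$domain_id == df$domain_id[i] & kept$target_id == df$target_id[i]
    overlap <- same & kept$start < df$end[i] & kept$end > df$start[i]
    if (!any(overlap)) kept <- rbind(kept, df[i, ])
  }
  kept
}

# Mutual-argmax oracle for cross-root bidirectional best hits.
oracle_bbh <- function(scores) {
  sel <- list()
  for (l in unique(scores$seq_left)) {
    sl <- scores[scores$seq_left == l, ]
    sl <- sl[order(-sl$score, sl$seq_right), ]
    r <- sl$seq_right[1]
    sr <- scores[scores$seq_right == r, ]
    sr <- sr[order(-sr$score, sr$seq_left), ]
    if (sr$seq_left[1] == l) {
      sel[[length(sel) + 1]] <- sl[1, c("seq_left", "seq_right", "score")]
    }
  }
  out <- do.call(rbind, sel)
  out[order(out$seq_left, out$seq_right), ]
}

# A small complete run shared by correction/pipeline tests (cached).
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_loss_dataset(n_species = 12, n_supergroups = 3,
                                   n_domains = 60, seed = 11)
      cache <<- list(sim = sim, run = run_loss_analysis(sim))
    }
    cache
  }
})
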