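---
title: "Quantifying falsely inferred gene absences with lossguard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying falsely inferred gene absences with lossguard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparative genomics routinely reads the absence of a gene (or protein
domain) from a predicted proteome as a *loss*. But an absence has several
possible causes: the gene may truly have been lost on that lineage; it may
sit in the genome but have been missed by the gene-prediction pipeline; or
it may survive only as a pseudogene. Treating every absence as a loss
inflates loss counts and can distort conclusions about genome evolution —
particularly for eukaryotes, where loss is thought to dominate over gain.

`lossguard` implements a pipeline to quantify this effect. Its core idea:
an absence that can still be found by homology search in the six-frame
translation of the species' genome (and is not explained by an in-frame
stop codon) is a *falsely inferred absence*, and loss estimates can be
corrected by adding those rescued presences back before recounting.

## The model

**Ancestral content by Dollo parsimony.** Presence/absence profiles of
domains across species are projected onto a rooted binary species tree
under the single-gain (Dollo) model: a domain is gained exactly once and
afterwards can only be lost. For a binary leaf profile the minimum-loss
single-gain history is unique and closed-form:

* the gain sits at the MRCA of the present leaves,
* an internal node of the gain subtree is *present* iff at least one of
  its descendant leaves is present,
* every maximal absent subtree contributes exactly one loss, attributed to
  the branch above its root (serialised by the child node's label).

`dollo_reconstruct()` implements this; the test suite checks it against a
brute-force minimisation over all single-gain state assignments on small
trees. Leaves outside the gain subtree are `pre_gain`, not absences. Note
the gain is always the MRCA: a profile confined to one side of the root is
reconstructed as a later gain, not as a root gain plus a side-wide loss.
In the full pipeline this distinction is moot, because only domains present
on both sides of the root are analysed (see the ancestral-content filter),
and for those the MRCA *is* the root.

**Ancestral (LECA-style) content filter.** A domain is a candidate
ancestral domain when it is present in at least `min_supergroups`
(default 3) supergroups and on both sides of the root (`leca_filter()`).
The *strict* set additionally removes domains flagged by the phylogenomic
horizontal-transfer screen. Both toggles are exposed because the two
criteria are logically independent.

**Horizontal-transfer screen.** Gene trees (inferred externally — tree
inference, alignment and trimming are inputs here, not computation) are
scanned for maximal monophyletic eukaryote-only clades. A clade is accepted
as ancestral when it holds species from both sides of the eukaryotic root
and the mean of the per-supergroup species-coverage percentages is at least
the threshold (default 15%; the comparison is inclusive). A domain with no
such clade in its tree is flagged as a likely transfer. Two helpers support
the screen: `cross_root_bbh()` (mutual-best-hit reduction of the eukaryotic
sequence set across the root) and `assign_unsampled()` (mapping sequences
dropped by that reduction back onto tree leaves so their species still
count toward clade coverage). Maximality of the clades avoids
double-counting nested sub-clades; percentages count distinct species, not
sequences.

**Absence classes.** Within a reconstruction, an absent leaf whose parent
node is absent shares an ancestral loss with its neighbours
(*clade-specific*); an absent leaf whose parent is present is a loss on the
terminal branch, uncorroborated by sister taxa (*species-specific*). The
hypothesis being tested is that species-specific absences — like absences
of near-universal single-copy (BUSCO-style) orthologs — are suspicious and
more often artefacts of gene prediction.

**Verification and correction.** Absences of ancestral-set domains are
looked up among validated six-frame hits. A hit only counts if it passed
the same chain as proteome hits: per-domain bitscore cutoff (inclusive,
gathering-cutoff semantics), best-scoring non-overlapping deduplication,
and the stop-codon filter. Hits whose aligned sequence contains `*` are
treated as pseudogenes: they never rescue an absence, but an absence whose
hits are *all* stop-containing is reported as `pseudogene_only`.
`correct_and_recount()` flips the found absences to present and re-runs the
reconstruction per domain with the ancestral set frozen from the
uncorrected analysis. A full re-run (rather than subtracting found
species-specific counts) is the principled choice: rescuing a
species-specific absence always removes exactly one loss, but rescuing
inside a larger absent clade can split the ancestral loss into several —
the recount handles both automatically, and the per-domain deltas are
reported.

## The synthetic-data generator

No public benchmark provides per-(domain, species) ground truth about *why*
a domain is absent, so the package ships a generator
(`simulate_loss_dataset()`) that emulates the statistical structure the
analysis assumes, with a planted ground truth:

* `generate_species_tree()` — a random rooted binary tree whose leaves are
  partitioned into contiguous supergroup clades on both sides of the root
  (default 6 supergroups, mirroring the deep eukaryotic supergroups);
* `simulate_dollo_evolution()` — domains gained at the root, lost
  independently on each branch with probability `p_loss_per_branch`
  (default 0.05), never regained;
* `inject_detection_failures()` — each truly present cell independently
  becomes a pseudogene (`p_pseudogene`, default 0.02) or goes unpredicted
  (`p_unpredicted`, default 0.10), mutually exclusively, with exact
  marginal rates; an optional length-biased mode makes short domains miss
  more often (annotation pipelines commonly drop short *in silico*-only
  proteins), with no particular functional form claimed — the inverse-length
  weighting is a convenience for sign checks only;
* `emit_sequences()` — one genomic contig per species: uniform background
  nucleotides with the back-translated consensus peptides of all
  genomically present domains embedded at random non-overlapping positions,
  strands and frames (synonymous codons drawn uniformly, never a stop);
  pseudogene copies get exactly one strictly internal codon replaced by a
  stop codon of the active table, so the stop-filter decision is
  unambiguous; unpredicted copies appear in the genome only; proteomes
  contain only the predicted peptides. A manifest records every embedding.

Default rates: a per-branch loss probability of 0.05 yields presence
profiles that keep most domains in the ancestral set while producing both
absence classes in quantity; 10% unpredicted and 2% pseudogene are of the
order suggested by per-genome annotation error rates in diverse eukaryotic
assemblies. The defaults are fixed study conditions, not tuning knobs.

What the generator does **not** emulate: sequence divergence along the tree
(detection is by planted motif, not remote homology), introns and split
genes, assembly gaps and coverage holes, and composition biases. Passing
tests therefore demonstrate that the *inference machinery* is correct under
the model's assumptions — they do not measure HMM sensitivity or assembly
quality effects on real data, which is exactly why the absolute found-%
values from synthetic runs differ from real-data values.

## Detection without an external search tool

The pipeline's production route consumes HMMER `--domtblout` tables
(`read_domtblout()`). So the whole analysis can also run self-contained,
`toy_detect_sixframe()`/`toy_detect_proteome()` provide a built-in
detector: a seed-and-verify scan for near-exact copies of each domain's
consensus peptide, scoring `model_length − 2·mismatches` bits. Two design
points matter:

* Target positions holding `*` (stop) or `X` (ambiguous codon) are
  alignment-compatible with anything and never count against the mismatch
  budget. A profile search aligns straight through a stop codon; it is the
  pseudogene *filter*, not the search, that must decide the fate of a
  stop-containing hit. Without this, every planted pseudogene would be
  invisible and the filter untestable.
* Each pattern is cut into `max_mismatches + 2` contiguous seeds located
  exactly; anchored windows are then verified position-wise. Any copy with
  at most `max_mismatches` mismatches plus at most one stop/ambiguity
  position is guaranteed to be found (one seed must be intact); the
  generator plants at most one stop per copy, so recall on planted data is
  1 by construction.

## Numerical and interface choices

* **Coordinates** are 0-based half-open everywhere internally; conversion
  to/from 1-based inclusive happens only in `read_domtblout()` (and
  display). Frames follow the transeq convention `+1..+3/−1..−3` with the
  offset on the reading strand's 5′ end; trailing bases are dropped, never
  padded. `frame_to_genome()`/`genome_to_frame()` are exact inverses.
* **Codon tables** come from the NCBI set via Biostrings; table 1
  (standard) and table 6 (ciliate, where `TAA`/`TAG` encode Gln) are the
  two the pipeline exercises.
* **Overlap** between hits is any shared genomic position of the same
  domain on the same contig, across frames and strands — two frames over
  one locus are one biological signal. Fractional-overlap rules were
  considered and rejected as an unforced parameter.
* **Ties** are broken deterministically everywhere: hit selection by
  (score desc, start asc, target id asc), best-hit assignment and BBH pairs
  lexicographically by id.
* **Cutoffs** are inclusive (`>=`), matching gathering-cutoff semantics;
  a missing cutoff is an error, never a silent keep.
* **Display percentages** round half-up to two decimals (`percent()`), so
  printed values agree with hand calculation from integer counts; all
  internal arithmetic is full precision.
* **Degenerate inputs**: all-absent profiles are rejected (they indicate an
  upstream filtering bug rather than a reconstructable history); a genome
  category with zero absences is excluded from that category's median; the
  rank-sum comparison of identical model lengths returns p = 1.
* **Tree annotations** travel in a sidecar TSV rather than Newick comments;
  comments are stripped by standard parsers and tie the file to one
  dialect. Root sides are always recomputed from the topology and checked
  against the sidecar.

## What the tests and the acceptance run compute

The test suite checks the reconstruction against exhaustive single-gain
enumeration on all small trees, the statistics against sign/label
enumeration oracles, the coordinate maps against round-trips, and the
pipeline end-to-end against the generator's manifest. The acceptance script
(`scripts/acceptance.R`) simulates the default study conditions — 50
species in 6 supergroups, 400 root-gained domains, per-branch loss 0.05,
unpredicted 0.10, pseudogene 0.02, exact-match detection — runs the full
analysis and reports precision/recall of found absences against the planted
unpredicted set, per-genome found-percentage medians by absence class, the
paired signed-rank contrast between species- and clade-specific classes,
and uncorrected vs corrected loss totals. Problem sizes were chosen so the
whole run completes in well under a minute while keeping per-genome
statistics stable (50 genomes, thousands of absences).

Two structural expectations worth noting, both verified by tests rather
than asserted: the per-genome found percentage is systematically higher
for species-specific than for clade-specific absences (a clade-specific
absence requires *correlated* detection failures in sister species, or a
false absence adjacent to a true ancestral loss); and the corrected loss
total can differ from "uncorrected minus found species-specific" only
through non-negative clade-splitting deltas.

## Known limitations

* Planted-motif detection makes recall exactly 1 by construction; real
  profile-HMM sensitivity (and its length dependence) is outside the model.
* The generator's sibling losses can be merged by Dollo minimisation (one
  parental loss explains two independent child losses), so planted and
  reconstructed loss branches coincide only for canonical patterns; the
  tests account for this.
* The HGT screen consumes externally inferred gene trees; it does not
  bootstrap-weight clades and does not infer transfer direction.
* Absences caused by assembly gaps or missing sequence cannot be rescued by
  DNA-level search and are out of scope.
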