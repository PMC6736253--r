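#' Six-frame translation
#'
#' Conceptually translates nucleotide sequences in all three offsets on both
#' strands. Frames follow the transeq convention: `+1..+3` read the forward
#' strand starting at offset 0..2, `-1..-3` read the reverse complement the
#' same way. Trailing nucleotides that do not fill a codon are dropped, never
#' padded. Codons containing `N` translate to `X`; stop codons are rendered
#' `*`.
#'
#' @param dna Named character vector of DNA sequences over `A,C,G,T,N`
#'   (names are contig ids), or a single unnamed string.
#' @param table_id NCBI genetic code id as a string; `"1"` (standard) and
#'   `"6"` (ciliate: `TAA`/`TAG` read as Gln) are the supported workhorses,
#'   any table known to [Biostrings::getGeneticCode()] is accepted.
#' @return A tibble with columns `contig_id`, `frame` (integer in
#'   `+1..+3, -1..-3`), `peptide`, `source_length` (nt). Exactly six rows per
#'   contig.
#' @export
translate_six_frames <- function(dna, table_id = "1") {
  if (is.null(names(dna))) {
    assert_that(length(dna) == 1, "unnamed `dna` must be a single sequence")
    names(dna) <- "contig"
  }
  assert_that(all(nzchar(dna)), "empty sequence")
  assert_that(!any(stringi::stri_detect_regex(dna, "[^ACGTN]")),
              "sequences must be over A,C,G,T,N")
  code <- genetic_code(table_id)
  out <- purrr::map(seq_along(dna), function(i) {
    seqs <- c(dna[[i]], revcomp(dna[[i]]))
    purrr::map(1:6, function(f) {
      strand_seq <- seqs[[if (f <= 3) 1 else 2]]
      off <- (f - 1L) %% 3L
      tibble::tibble(
        contig_id = names(dna)[i],
        frame = if (f <= 3) f else -(f - 3L),
        peptide = translate_frame(strand_seq, off, code),
        source_length = nchar(dna[[i]]))
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  out
}

genetic_code <- function(table_id) {
  tryCatch(Biostrings::getGeneticCode(as.character(table_id)),
           error = function(e) rlang::abort(sprintf("unsupported codon table '%s'", table_id)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate one reading frame of `seq` starting at 0-based `offset`,
# dropping the incomplete trailing codon.
translate_frame <- function(seq, offset, code) {
  n_cod <- (nchar(seq) - offset) %/% 3
  if (n_cod <= 0) return("")
  codons <- stringi::stri_sub(seq, offset + 1 + 3 * (seq_len(n_cod) - 1), length = 3)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Map peptide coordinates in a reading frame to genomic coordinates
#'
#' Converts a 0-based half-open amino-acid interval `[aa_start, aa_end)` in a
#' given frame into the 0-based half-open nucleotide interval it was read
#' from, always expressed on the forward strand. Forward frame `f` maps
#' `[p, q)` to `[(f-1) + 3p, (f-1) + 3q)`; reverse frames are computed on the
#' reverse complement and reflected. The mapping is inverted by
#' [genome_to_frame()].
#'
#' @param contig_length Contig length in nucleotides.
#' @param frame Frame in `+1..+3, -1..-3` (vectorised).
#' @param aa_start,aa_end 0-based half-open peptide interval (vectorised).
#' @return A tibble with columns `start`, `end` (0-based half-open, forward
#'   strand) and `strand` (`"+"`/`"-"`).
#' @export
frame_to_genome <- function(contig_length, frame, aa_start, aa_end) {
  assert_that(all(frame %in% c(1:3, -1:-3)), "frame must be in +1..+3, -1..-3")
  assert_that(all(aa_start >= 0 & aa_end >= aa_start), "invalid peptide interval")
  off <- abs(frame) - 1L
  fwd <- frame > 0
  start <- ifelse(fwd, off + 3 * aa_start, contig_length - (off + 3 * aa_end))
  end <- ifelse(fwd, off + 3 * aa_end, contig_length - (off + 3 * aa_start))
  assert_that(all(start >= 0 & end <= contig_length),
              "peptide interval out of contig range")
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 strand = ifelse(fwd, "+", "-"))
}

#' @param start,end 0-based half-open genomic interval (forward strand).
#' @param strand `"+"` or `"-"`.
#' @return `genome_to_frame()`: a tibble with `frame`, `aa_start`, `aa_end`.
#' @rdname frame_to_genome
#' @export
genome_to_frame <- function(contig_length, start, end, strand) {
  assert_that(all((end - start) %% 3 == 0),
              "interval length must be a multiple of 3")
  fwd <- strand == "+"
  s_local <- ifelse(fwd, start, contig_length - end)  # offset on the read strand
  off <- s_local %% 3L
  frame <- as.integer(ifelse(fwd, off + 1L, -(off + 1L)))
  aa_start <- as.integer(s_local %/% 3)
  aa_end <- aa_start + as.integer((end - start) %/% 3)
  tibble::tibble(frame = frame, aa_start = aa_start, aa_end = aa_end)
}
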