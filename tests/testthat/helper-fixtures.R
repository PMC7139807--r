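# shared fixtures and independent oracles used across the suite

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# i.i.d. substitutions, no indels
mutate_str <- function(s, divergence) {
  ch <- strsplit(s, "")[[1]]
  k <- round(divergence * length(ch))
  if (k > 0) {
    p <- sample(length(ch), k)
    ch[p] <- vapply(ch[p], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(ch, collapse = "")
}

# independent Smith-Waterman oracle (Biostrings), best local score over
# both strands under the sensitive scoring (match +2 mismatch -3,
# gap of length L costs 5 + 2L)
sw_best_score <- function(x, y, match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  plus <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y), type = "local",
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend))
  minus <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(x)),
    Biostrings::DNAString(y), type = "local",
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend))
  max(plus, minus)
}

# independent translation oracle
bs_translate <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# a random pair sharing one homologous segment (the aligner's operating
# regime); divergence drawn up to max_div
homologous_pair <- function(la, lb, max_div = 0.10, revcomp_frac = 0.3) {
  core_len <- sample(30:min(la, lb), 1)
  core <- random_dna_str(core_len)
  x <- random_dna_str(la); y <- random_dna_str(lb)
  pa <- sample(la - core_len + 1, 1); pb <- sample(lb - core_len + 1, 1)
  substr(x, pa, pa + core_len - 1) <- core
  core2 <- mutate_str(core, stats::runif(1, 0, max_div))
  if (stats::runif(1) < revcomp_frac) core2 <- organellr::revcomp(core2)
  substr(y, pb, pb + core_len - 1) <- core2
  list(x = x, y = y)
}

# canonical (maximally left-shifted) start of a planted deletion: the same
# normal form the detector reports, derived independently from the
# reference sequence
canonical_deletion_start <- function(cds, at, len) {
  ch <- strsplit(cds, "")[[1]]
  a <- at; b <- at + len - 1L
  while (a > 1L && ch[a - 1L] == ch[b]) { a <- a - 1L; b <- b - 1L }
  a
}
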