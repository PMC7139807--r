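#' Scoring scheme for seed-and-extend local alignment
#'
#' Bundles the match/mismatch rewards, affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), the seed word size and the
#' E-value cutoff, together with the Karlin-Altschul parameters `lambda`
#' and `K` calibrated for the match/mismatch pair at the given base
#' frequencies.  Two presets mirror the two search configurations used
#' throughout the package:
#'
#' * `"sensitive"` - word 7, match +2, mismatch -3, gap open 5, gap
#'   extend 2; the dispersed-repeat search.
#' * `"fast"` - word 28, match +2, mismatch -4, gap open 0, gap extend 5
#'   (the megablast-style +1/-2 with 2.5 gap extension, scaled by two to
#'   stay on integers); the shared-DNA search.
#'
#' `lambda` is the positive root of `sum_ij p_i p_j exp(lambda s_ij) = 1`
#' (solved by bisection to 1e-12); `K` is computed from the classical
#' series approximation for lattice score distributions.  Gapped hits
#' reuse the ungapped parameters, a documented approximation.
#'
#' @param preset `"sensitive"`, `"fast"`, or `NULL` for fully manual
#'   parameters.
#' @param match,mismatch,gap_open,gap_extend,word_size,evalue_cutoff
#'   Overrides for individual parameters.
#' @param xdrop Extension termination threshold (default `20 * match`).
#' @param base_freqs Background base frequencies (A, C, G, T).
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("sensitive")
#' @export
scoring_scheme <- function(preset = c("sensitive", "fast"),
                           match = NULL, mismatch = NULL,
                           gap_open = NULL, gap_extend = NULL,
                           word_size = NULL, evalue_cutoff = 1e-6,
                           xdrop = NULL,
                           base_freqs = c(0.25, 0.25, 0.25, 0.25)) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    def <- switch(preset,
      sensitive = list(match = 2L, mismatch = -3L, gap_open = 5L,
                       gap_extend = 2L, word_size = 7L),
      fast = list(match = 2L, mismatch = -4L, gap_open = 0L,
                  gap_extend = 5L, word_size = 28L))
  } else {
    def <- list(match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L,
                word_size = 11L)
  }
  match <- as.integer(match %||% def$match)
  mismatch <- as.integer(mismatch %||% def$mismatch)
  gap_open <- as.integer(gap_open %||% def$gap_open)
  gap_extend <- as.integer(gap_extend %||% def$gap_extend)
  word_size <- as.integer(word_size %||% def$word_size)
  if (match <= 0 || mismatch >= 0) {
    rlang::abort("degenerate scheme: need match > 0 > mismatch",
                 class = "organellr_scheme_error")
  }
  stopifnot(gap_open >= 0, gap_extend > 0, word_size >= 1,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-8)
  # expected score per aligned pair must be negative for local statistics
  p_match <- sum(base_freqs^2)
  exp_score <- p_match * match + (1 - p_match) * mismatch
  if (exp_score >= 0) {
    rlang::abort("degenerate scheme: expected score per pair is non-negative",
                 class = "organellr_scheme_error")
  }
  ka <- karlin_altschul(match, mismatch, base_freqs)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size,
                 evalue_cutoff = evalue_cutoff,
                 xdrop = as.integer(xdrop %||% (20L * match)),
                 lambda = ka$lambda, K = ka$K,
                 base_freqs = base_freqs,
                 preset = if (is.null(preset)) "custom" else preset),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> preset:", x$preset,
      sprintf("\n  match %+d mismatch %+d gap %d+%dL word %d",
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size),
      sprintf("\n  lambda %.4f K %.4f E-cutoff %g\n",
              x$lambda, x$K, x$evalue_cutoff))
  invisible(x)
}

# Karlin-Altschul parameters for a match/mismatch lattice score under
# i.i.d. base frequencies.  lambda solves sum p_i p_j exp(lambda s_ij) = 1;
# K follows the 1990 series: with S_k the k-step random walk of pair
# scores,
#   sigma = sum_k (1/k) [ E(e^{lambda S_k}; S_k < 0) + P(S_k >= 0) ]
#   K = d * lambda * e^{-2 sigma} / (H * (1 - e^{-lambda d}))
# where d is the score lattice span and H = lambda * E(S e^{lambda S}).
# Reproduces the published ungapped values (e.g. +1/-2: lambda 1.332,
# K 0.621) to three decimals.
karlin_altschul <- function(match, mismatch, base_freqs, niter = 200L) {
  p_match <- sum(base_freqs^2)
  s <- c(match, mismatch)
  p <- c(p_match, 1 - p_match)
  f <- function(l) sum(p * exp(l * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- stats::uniroot(f, c(1e-9, hi), tol = 1e-12)$root
  d <- gcd_int(abs(match), abs(mismatch))
  step <- tapply(p, s, sum)                       # names: score values
  cur <- step
  sigma <- 0
  for (k in seq_len(niter)) {
    sc <- as.integer(names(cur))
    pr <- as.numeric(cur)
    neg <- sc < 0
    term <- sum(pr[neg] * exp(lambda * sc[neg])) + sum(pr[!neg])
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
    # convolve with the single-step distribution
    M <- outer(pr, as.numeric(step))
    S <- outer(sc, as.integer(names(step)), "+")
    cur <- tapply(as.vector(M), as.vector(S), sum)
  }
  H <- lambda * sum(p * s * exp(lambda * s))
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `score`
#' between sequences of lengths `m` and `n`:
#' `E = K * m * n * exp(-lambda * score)`.  Monotone decreasing in the
#' score and linear in each sequence length.
#'
#' @param score Alignment score(s).
#' @param m,n Query and subject lengths.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, m, n, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (is.null(scheme$lambda) || is.null(scheme$K)) {
    rlang::abort("scheme is not calibrated", class = "organellr_scheme_error")
  }
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

# score threshold implied by the E-value cutoff (used to prune inside C++)
min_score_for_cutoff <- function(scheme, m, n) {
  if (!is.finite(scheme$evalue_cutoff)) return(scheme$word_size * scheme$match)
  s <- ceiling(log(scheme$K * as.numeric(m) * as.numeric(n) /
                     scheme$evalue_cutoff) / scheme$lambda)
  max(as.integer(s), scheme$word_size * scheme$match)
}

#' Pairwise local alignment by seed-and-extend
#'
#' Finds local alignments between every query and every subject record on
#' both strands: exact `word_size`-mers seed gapped x-drop extensions;
#' retained hits satisfy the scheme's E-value cutoff.  Hits are reported
#' in BLAST tabular convention: 1-based inclusive coordinates, minus-strand
#' hits carry `sstart > send` on the subject and `strand == "-"`.
#'
#' @param query,subject Genome tibbles (see [genome_record()]).
#' @param scheme A [scoring_scheme()].
#' @param circular_subject Double the subject to let hits wrap the origin
#'   of circular records (wrapped duplicates are removed).  Default FALSE.
#' @return A hit tibble sorted by score (columns `query_id`, `subject_id`,
#'   `identity_pct`, `length`, `mismatches`, `gapopens`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `score`, `strand`).  `identity_pct` is
#'   100 x identical columns / aligned columns including gap columns.
#' @examples
#' a <- genome_record("a", strrep("ACGTTGCA", 80), topology = "linear")
#' align_pair(a, a, scoring_scheme("fast"))
#' @export
align_pair <- function(query, subject, scheme = scoring_scheme("sensitive"),
                       circular_subject = FALSE) {
  stopifnot(is.data.frame(query), is.data.frame(subject),
            inherits(scheme, "scoring_scheme"))
  out <- vector("list", nrow(query) * nrow(subject))
  idx <- 1L
  for (qi in seq_len(nrow(query))) {
    for (si in seq_len(nrow(subject))) {
      out[[idx]] <- align_one(query[qi, ], subject[si, ], scheme,
                              circular_subject, self_mode = FALSE)
      idx <- idx + 1L
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$qstart, .data$sstart)
}

align_one <- function(qrec, srec, scheme, circular_subject, self_mode) {
  qseq <- qrec$sequence
  sseq <- srec$sequence
  n_sub <- srec$length
  doubled <- circular_subject && identical(srec$topology, "circular")
  if (doubled) sseq <- paste0(sseq, sseq)
  qcod <- encode_dna(qseq)
  scod <- encode_dna(sseq)
  ms <- min_score_for_cutoff(scheme, qrec$length, n_sub)

  run <- function(qc, strand) {
    # plus-strand self-comparison is confined to the strict upper triangle
    # (subject position > query position): the trivial self-identity
    # diagonal is excluded structurally and each repeat pair is mirrored
    # afterwards.  The minus strand has no identity diagonal.
    upper <- self_mode && strand == "+"
    sp <- if (upper && doubled) n_sub else 0L
    df <- cpp_seed_extend(qc, scod, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$word_size, scheme$xdrop, ms, sp, upper)
    df <- tibble::as_tibble(df)
    if (nrow(df) == 0L) return(df)
    if (strand == "-") {
      qs <- qrec$length - df$qend + 1L
      qe <- qrec$length - df$qstart + 1L
      df$qstart <- qs; df$qend <- qe
      tmp <- df$sstart
      df$sstart <- df$send; df$send <- tmp
    }
    df$strand <- strand
    if (upper) {
      mirror <- df
      mirror$qstart <- df$sstart; mirror$qend <- df$send
      mirror$sstart <- df$qstart; mirror$send <- df$qend
      df <- dplyr::bind_rows(df, mirror)
    }
    df
  }

  hits <- dplyr::bind_rows(run(qcod, "+"), run(encode_dna(revcomp(qseq)), "-"))
  if (nrow(hits) == 0L) return(empty_hits())
  if (doubled) {
    lo <- pmin(hits$sstart, hits$send)
    hi <- pmax(hits$sstart, hits$send)
    hits <- hits[lo <= n_sub, , drop = FALSE]      # drop pure second-copy copies
    hits$sstart <- wrap1(hits$sstart, n_sub)
    hits$send <- wrap1(hits$send, n_sub)
    hits <- dplyr::distinct(hits, .data$qstart, .data$qend, .data$sstart,
                            .data$send, .data$strand, .keep_all = TRUE)
    rm(lo, hi)
  }
  hits$evalue <- evalue(hits$score, qrec$length, n_sub, scheme)
  hits <- hits[hits$evalue <= scheme$evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits())
  tibble::tibble(query_id = qrec$id, subject_id = srec$id,
                 identity_pct = round(100 * hits$matches / hits$length, 1),
                 length = hits$length, mismatches = hits$mismatches,
                 gapopens = hits$gapopens,
                 qstart = hits$qstart, qend = hits$qend,
                 sstart = hits$sstart, send = hits$send,
                 evalue = hits$evalue, score = hits$score,
                 strand = hits$strand)
}

wrap1 <- function(x, n) ((x - 1L) %% n) + 1L

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 identity_pct = numeric(), length = integer(),
                 mismatches = integer(), gapopens = integer(),
                 qstart = integer(), qend = integer(),
                 sstart = integer(), send = integer(),
                 evalue = numeric(), score = integer(), strand = character())
}

#' Self-alignment for dispersed repeat discovery
#'
#' Aligns a genome against itself with the sensitive preset, excluding the
#' trivial full-length identity on the main diagonal, and keeps hits at
#' least `min_len` aligned columns long (default 31, i.e. repeats larger
#' than 30 bp).  Both orientations of each repeat pair are reported.
#'
#' @param genome One-row genome tibble.
#' @param scheme A [scoring_scheme()]; the sensitive preset by default.
#' @param min_len Minimum aligned length retained.
#' @param circular Respect circular topology via a doubled-sequence view.
#' @return A hit tibble, see [align_pair()].
#' @export
self_align <- function(genome, scheme = scoring_scheme("sensitive"),
                       min_len = 31L, circular = FALSE) {
  stopifnot(nrow(genome) == 1L)
  if (min_len < scheme$word_size) {
    rlang::abort("min_len must be at least the seed word size",
                 class = "organellr_scheme_error")
  }
  hits <- align_one(genome, genome, scheme, circular_subject = circular,
                    self_mode = TRUE)
  hits[hits$length >= min_len, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$score), .data$qstart, .data$sstart)
}

#' Write hits in 12-column tabular format
#'
#' The standard tabular alignment layout: query id, subject id, percent
#' identity, aligned length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, score.
#'
#' @param hits Hit tibble from [align_pair()] or [self_align()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits[, c("query_id", "subject_id", "identity_pct", "length",
                  "mismatches", "gapopens", "qstart", "qend",
                  "sstart", "send", "evalue", "score")]
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
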