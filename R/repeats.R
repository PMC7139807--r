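#' Find tandem repeat arrays
#'
#' A simplified tandem-array detector calibrated to the defaults of the
#' classical tandem repeat finder (match +2, mismatch 7, indel 7, minimum
#' alignment score 50, maximum period 500).  Candidate loci come from
#' positional self-comparison at every period up to `max_period`
#' (maximal-scoring segments of the shifted match profile); overlapping
#' candidates collapse to the smallest period, and each survivor is
#' refined by wraparound dynamic programming of the locus against its
#' period consensus, which supplies the reported score, boundaries and
#' fractional copy number.  Arrays need at least two copies
#' (`copy_number >= 1.9`).  The match/indel probability parameters of the
#' original tool's statistical model are accepted for interface
#' compatibility but the exact scanner does not use them.
#'
#' @param genome One-row genome tibble.
#' @param match,mismatch,indel Alignment weights (mismatch and indel are
#'   penalties, given positive).
#' @param min_score Minimum reported alignment score.
#' @param max_period Largest period considered; must be at most half the
#'   genome length.
#' @param match_prob,indel_prob Accepted, unused by the exact scanner.
#' @return Tibble of arrays: `seq_id`, `start`, `end`, `period`,
#'   `copy_number`, `score`, `consensus`.
#' @examples
#' g <- genome_record("t", paste0(strrep("GATC", 30), strrep("AACCGGTT", 10)),
#'                    topology = "linear")
#' find_tandem_repeats(g)
#' @export
find_tandem_repeats <- function(genome, match = 2L, mismatch = 7L,
                                indel = 7L, min_score = 50L,
                                max_period = 500L,
                                match_prob = 80, indel_prob = 10) {
  stopifnot(nrow(genome) == 1L)
  n <- genome$length
  if (max_period > n / 2) {
    rlang::abort("max_period exceeds half the genome length",
                 class = "organellr_coordinate_error")
  }
  codes <- encode_dna(genome$sequence)
  cand <- tibble::as_tibble(
    cpp_tandem_scan(codes, as.integer(max_period), as.integer(match),
                    as.integer(mismatch), as.integer(min_score)))
  if (nrow(cand) == 0L) return(empty_tandem())

  # collapse overlapping candidates to the smallest period (multiples of
  # the true period score equally well in positional comparison)
  cand <- cand |> dplyr::arrange(.data$period, .data$start)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    over <- which(keep & cand$start <= cand$end[i] & cand$end >= cand$start[i])
    over <- over[over != i & cand$period[over] > cand$period[i]]
    keep[over] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]

  out <- purrr::pmap(cand, function(start, end, period, score) {
    refine_tandem(genome$sequence, start, end, period,
                  match, mismatch, indel)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_tandem())
  res <- res[res$score >= min_score & res$copy_number >= 1.9, , drop = FALSE]
  if (nrow(res) == 0L) return(empty_tandem())
  res$seq_id <- genome$id
  res[, c("seq_id", "start", "end", "period", "copy_number", "score",
          "consensus")] |>
    dplyr::arrange(.data$start)
}

empty_tandem <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 period = integer(), copy_number = numeric(),
                 score = integer(), consensus = character())
}

# Refine one candidate: build a positional majority consensus of the
# copies, minimize its period (rotation/divisor test), then realign the
# padded locus against the cyclic consensus by wraparound DP.
refine_tandem <- function(seq, start, end, period, match, mismatch, indel) {
  n <- nchar(seq)
  cons <- tandem_consensus(substr(seq, start, end), period)
  period <- minimal_period(cons)
  cons <- substr(cons, 1L, period)
  pad <- max(period, 10L)
  rs <- max(1L, start - pad); re <- min(n, end + pad)
  region <- substr(seq, rs, re)
  al <- cpp_wraparound_align(encode_dna(region), encode_dna(cons),
                             as.integer(match), as.integer(mismatch),
                             as.integer(indel))
  tibble::tibble(start = rs + al$start - 1L, end = rs + al$end - 1L,
                 period = period,
                 copy_number = al$pattern_consumed / period,
                 score = al$score, consensus = cons)
}

# positional majority vote across the copies of a candidate array
tandem_consensus <- function(array_seq, period) {
  chars <- strsplit(array_seq, "", fixed = TRUE)[[1]]
  pos <- ((seq_along(chars) - 1L) %% period) + 1L
  cons <- vapply(seq_len(period), function(j) {
    tab <- table(chars[pos == j])
    names(tab)[which.max(tab)]
  }, character(1))
  paste(cons, collapse = "")
}

# smallest divisor period that exactly tiles the consensus
minimal_period <- function(cons) {
  d <- nchar(cons)
  for (p in seq_len(d - 1L)) {
    if (d %% p != 0L) next
    if (identical(strrep(substr(cons, 1L, p), d %/% p), cons)) return(p)
  }
  d
}

#' Non-redundant repeat percentage of a genome
#'
#' Combines tandem arrays and dispersed self-alignment hits into a single
#' non-redundant coverage: overlapping regions between hits are excluded
#' (counted once), and the repeat percentage is the covered fraction of
#' the genome.  Dispersed hits contribute their query-side intervals
#' (query and subject are the same genome, so subject intervals are mirror
#' images).
#'
#' @param genome One-row genome tibble.
#' @param tandem_arrays Tibble from [find_tandem_repeats()].
#' @param dispersed_hits Hit tibble from [self_align()].
#' @param dispersed_only Drop tandem coverage from the union (sensitivity
#'   analysis flag).
#' @return A `repeat_report` object; see [tidy.repeat_report()] and
#'   [glance.repeat_report()].
#' @export
repeat_percentage <- function(genome, tandem_arrays, dispersed_hits,
                              dispersed_only = FALSE) {
  stopifnot(nrow(genome) == 1L)
  tand <- if (nrow(tandem_arrays) > 0L) {
    stopifnot(all(tandem_arrays$seq_id == genome$id))
    tibble::tibble(seq_id = genome$id, start = tandem_arrays$start,
                   end = tandem_arrays$end)
  } else tibble::tibble(seq_id = character(), start = integer(),
                        end = integer())
  disp <- if (nrow(dispersed_hits) > 0L) {
    stopifnot(all(dispersed_hits$query_id == genome$id))
    tibble::tibble(seq_id = genome$id, start = dispersed_hits$qstart,
                   end = dispersed_hits$qend)
  } else tibble::tibble(seq_id = character(), start = integer(),
                        end = integer())
  lens <- stats::setNames(genome$length, genome$id)
  tand_m <- merge_intervals(tand, lens)
  disp_m <- merge_intervals(disp, lens)
  union_in <- if (dispersed_only) disp else dplyr::bind_rows(tand, disp)
  union_m <- merge_intervals(union_in, lens)
  union_bp <- interval_total(union_m)
  structure(list(genome_id = genome$id, genome_length = genome$length,
                 tandem_coverage = tand_m, dispersed_coverage = disp_m,
                 union_coverage = union_m,
                 tandem_bp = interval_total(tand_m),
                 dispersed_bp = interval_total(disp_m),
                 union_bp = union_bp,
                 repeat_pct = round(100 * union_bp / genome$length, 1),
                 dispersed_only = dispersed_only),
            class = "repeat_report")
}

#' Profile repeats in one genome
#'
#' Convenience wrapper running the tandem detector and the sensitive
#' dispersed self-search, then computing the non-redundant repeat
#' percentage.
#'
#' @param genome One-row genome tibble.
#' @param scheme Alignment scheme for the dispersed search.
#' @param min_len Minimum dispersed hit length (default 31 bp).
#' @param circular Respect circular topology in the self-search.
#' @param ... Passed to [find_tandem_repeats()].
#' @return A `repeat_report`.
#' @export
profile_repeats <- function(genome, scheme = scoring_scheme("sensitive"),
                            min_len = 31L, circular = FALSE, ...) {
  tand <- find_tandem_repeats(genome, ...)
  disp <- self_align(genome, scheme, min_len = min_len, circular = circular)
  repeat_percentage(genome, tand, disp)
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf("<repeat_report> %s (%s bp): %.1f%% repetitive\n",
              x$genome_id, format(x$genome_length, big.mark = ","),
              x$repeat_pct))
  cat(sprintf("  tandem %d bp, dispersed %d bp, union %d bp%s\n",
              x$tandem_bp, x$dispersed_bp, x$union_bp,
              if (x$dispersed_only) " (dispersed-only accounting)" else ""))
  invisible(x)
}

#' Tidy a repeat report into its coverage intervals
#'
#' @param x A `repeat_report`.
#' @param ... Unused.
#' @return Tibble of merged covered intervals labeled by component
#'   (`tandem`, `dispersed`, `union`).
#' @export
tidy.repeat_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$tandem_coverage, component = "tandem"),
    dplyr::mutate(x$dispersed_coverage, component = "dispersed"),
    dplyr::mutate(x$union_coverage, component = "union"))
}

#' One-row summary of a repeat report
#'
#' Mirrors a genome-size / repeat-percent / accession table row.
#'
#' @param x A `repeat_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.repeat_report <- function(x, ...) {
  tibble::tibble(genome_id = x$genome_id, size_bp = x$genome_length,
                 tandem_bp = x$tandem_bp, dispersed_bp = x$dispersed_bp,
                 union_bp = x$union_bp, repeat_pct = x$repeat_pct)
}
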