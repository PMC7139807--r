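#' Quantify DNA shared between genomic compartments
#'
#' Runs the fast (word-28) search of an organelle query against one or
#' more subject records, retains hits with identity strictly higher than
#' `min_identity` percent, and summarizes them: hit count, mean identity,
#' length statistics, the non-redundant total of query-side coverage
#' (overlapping regions between hits are excluded) and the GC content of
#' the covered query sequence.  For organelle-versus-nuclear comparisons
#' the organelle genome is the query; for the organelle-organelle
#' comparison the plastome is the query and the mitogenome the subject.
#' Multiple subject records (e.g. nuclear chromosomes) are searched
#' independently and pooled.
#'
#' @param query One-row genome tibble (the query compartment).
#' @param subject Genome tibble, one or more records.
#' @param scheme A [scoring_scheme()]; the fast preset by default.
#' @param min_identity Identity threshold in percent; strictly greater
#'   than (a hit at exactly the threshold is excluded).
#' @return A `shared_dna` object; `tidy()` returns the retained hits,
#'   `glance()` the summary row.
#' @export
shared_dna <- function(query, subject, scheme = scoring_scheme("fast"),
                       min_identity = 90) {
  stopifnot(nrow(query) == 1L)
  if (nrow(subject) == 0L) {
    rlang::abort("empty subject set", class = "organellr_input_error")
  }
  hits <- align_pair(query, subject, scheme)
  hits <- filter_hits_identity(hits, min_identity)
  build_shared_dna(query, subject, hits, min_identity)
}

# merged coverage of (start, end) vectors on one sequence
coverage_bp <- function(starts, ends) {
  interval_total(tibble::tibble(seq_id = "x", start = as.integer(starts),
                                end = as.integer(ends)))
}

filter_hits_identity <- function(hits, min_identity) {
  hits[hits$identity_pct > min_identity, , drop = FALSE]
}

build_shared_dna <- function(query, subject, hits, min_identity) {
  cov <- merge_intervals(
    tibble::tibble(seq_id = query$id,
                   start = pmin(hits$qstart, hits$qend),
                   end = pmax(hits$qstart, hits$qend)),
    stats::setNames(query$length, query$id))
  merged_bp <- interval_total(cov)
  shared_gc <- if (nrow(cov) > 0L) {
    covered_seq <- paste0(substring(query$sequence, cov$start, cov$end),
                          collapse = "")
    gc_content(covered_seq)
  } else NA_real_
  structure(list(query_id = query$id,
                 subject_id = paste(subject$id, collapse = ","),
                 hits = hits,
                 stats = hit_statistics(hits),
                 coverage = cov,
                 merged_total_bp = merged_bp,
                 merged_total_kb = round(merged_bp / 1000, 1),
                 shared_gc_pct = shared_gc,
                 min_identity = min_identity),
            class = "shared_dna")
}

#' Summary statistics over retained hits
#'
#' Length and identity summaries reported to one decimal; the median of
#' an even count is the midpoint average.  Zero hits yield a count-0 row
#' with the statistics flagged `NA`.
#'
#' @param hits Hit tibble.
#' @return One-row tibble: `n`, `mean_identity`, `min_len`, `max_len`,
#'   `mean_len`, `median_len`.
#' @examples
#' hit_statistics(tibble::tibble(identity_pct = 95, length = c(33, 93, 94, 3950)))
#' @export
hit_statistics <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(n = 0L, mean_identity = NA_real_,
                          min_len = NA_integer_, max_len = NA_integer_,
                          mean_len = NA_real_, median_len = NA_real_))
  }
  tibble::tibble(n = nrow(hits),
                 mean_identity = round(mean(hits$identity_pct), 1),
                 min_len = min(hits$length),
                 max_len = max(hits$length),
                 mean_len = round(mean(hits$length), 1),
                 median_len = stats::median(hits$length))
}

#' @export
print.shared_dna <- function(x, ...) {
  cat(sprintf("<shared_dna> %s vs %s (identity > %g%%)\n",
              x$query_id, x$subject_id, x$min_identity))
  cat(sprintf("  %d hits, %.1f kb non-redundant query coverage, GC %.1f%%\n",
              x$stats$n, x$merged_total_kb,
              if (is.na(x$shared_gc_pct)) NA else x$shared_gc_pct))
  invisible(x)
}

#' @export
tidy.shared_dna <- function(x, ...) x$hits

#' One-row summary of a shared-DNA comparison
#'
#' @param x A `shared_dna` object.
#' @param ... Unused.
#' @return One-row tibble mirroring a shared-DNA statistics table row.
#' @export
glance.shared_dna <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(query_id = x$query_id, subject_id = x$subject_id),
    x$stats,
    tibble::tibble(shared_gc_pct = x$shared_gc_pct,
                   merged_total_bp = x$merged_total_bp,
                   merged_total_kb = x$merged_total_kb))
}

#' Detect large contiguous organelle-derived blocks in nuclear sequence
#'
#' Clusters retained shared-DNA hits along each nuclear (subject)
#' sequence: consecutive hits at most `max_gap_bp` apart join one
#' cluster, and clusters spanning at least `min_span_kb` kilobases are
#' reported as putative large-scale transfer blocks with their span,
#' contained-hit count, GC content of the nuclear region, and the
#' fraction of the span covered by hits.  A block needs two or more hits,
#' or a single hit already spanning the minimum.
#'
#' @param organelle One-row genome tibble used as the query.
#' @param nuclear Genome tibble of nuclear sequences (subjects).
#' @param scheme,min_identity Passed to [shared_dna()].
#' @param min_span_kb Minimum nuclear span in kb (default 100).
#' @param max_gap_bp Maximum gap between clustered hits (default 10000;
#'   the chosen value is echoed in the output).
#' @param hits Optional precomputed hit tibble (skips the search).
#' @return Tibble of blocks sorted by span, with the clustering gap
#'   echoed in column `max_gap_bp`.
#' @export
find_igt_blocks <- function(organelle, nuclear,
                            scheme = scoring_scheme("fast"),
                            min_identity = 90,
                            min_span_kb = 100, max_gap_bp = 10000,
                            hits = NULL) {
  if (is.null(hits)) {
    hits <- tidy(shared_dna(organelle, nuclear, scheme, min_identity))
  }
  empty <- tibble::tibble(subject_id = character(), start = integer(),
                          end = integer(), span_kb = numeric(),
                          hits_contained = integer(),
                          block_gc_pct = numeric(),
                          organelle_coverage_fraction = numeric(),
                          max_gap_bp = numeric())
  if (nrow(hits) == 0L) return(empty)
  blocks <- hits |>
    dplyr::mutate(lo = as.numeric(pmin(.data$sstart, .data$send)),
                  hi = as.numeric(pmax(.data$sstart, .data$send))) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$lo, .by_group = TRUE) |>
    dplyr::mutate(new_cluster = .data$lo - dplyr::lag(cummax(.data$hi),
                                                      default = -Inf) >
                    max_gap_bp,
                  cluster = cumsum(.data$new_cluster)) |>
    dplyr::group_by(.data$subject_id, .data$cluster) |>
    dplyr::summarise(start = min(.data$lo), end = max(.data$hi),
                     hits_contained = dplyr::n(),
                     covered_bp = coverage_bp(.data$lo, .data$hi),
                     .groups = "drop") |>
    dplyr::mutate(span_kb = (.data$end - .data$start + 1) / 1000,
                  organelle_coverage_fraction =
                    .data$covered_bp / (.data$end - .data$start + 1)) |>
    dplyr::filter(.data$span_kb >= min_span_kb)
  if (nrow(blocks) == 0L) return(empty)
  blocks$block_gc_pct <- purrr::map2_dbl(
    blocks$subject_id, seq_len(nrow(blocks)),
    function(sid, k) {
      rec <- nuclear[nuclear$id == sid, , drop = FALSE]
      if (nrow(rec) != 1L) return(NA_real_)
      gc_content(rec, start = blocks$start[k], end = blocks$end[k])
    })
  blocks |>
    dplyr::mutate(span_kb = round(.data$span_kb, 1),
                  max_gap_bp = max_gap_bp) |>
    dplyr::select("subject_id", "start", "end", "span_kb", "hits_contained",
                  "block_gc_pct", "organelle_coverage_fraction",
                  "max_gap_bp") |>
    dplyr::arrange(dplyr::desc(.data$span_kb))
}
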