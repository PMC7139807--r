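#' Construct a genome record
#'
#' A genome record is one row of a genome tibble: an identifier, an
#' uppercase nucleotide sequence over `A`, `C`, `G`, `T`, `N`, the molecule
#' topology and the genomic compartment it belongs to.  All downstream
#' stages (alignment, repeat profiling, shared-DNA quantification) consume
#' and return these tibbles, so records chain naturally with the pipe.
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide sequence.  Lowercase is normalized to
#'   uppercase; characters outside `A/C/G/T/N` are mapped to `N` (a message
#'   reports how many).
#' @param topology `"circular"` or `"linear"`.  Organelle records default to
#'   circular, nuclear and unknown records to linear.
#' @param compartment One of `"mitochondrion"`, `"plastid"`, `"nucleus"`,
#'   `"unknown"`.
#' @return A one-row tibble with columns `id`, `sequence`, `length`,
#'   `topology`, `compartment`.
#' @examples
#' genome_record("toy", "acgtACGT", compartment = "mitochondrion")
#' @export
genome_record <- function(id, sequence,
                          topology = NULL,
                          compartment = c("unknown", "mitochondrion",
                                          "plastid", "nucleus")) {
  compartment <- match.arg(compartment)
  if (is.null(topology)) {
    topology <- if (compartment %in% c("mitochondrion", "plastid"))
      "circular" else "linear"
  }
  topology <- match.arg(topology, c("circular", "linear"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    rlang::abort("`id` must be a non-empty string.",
                 class = "organellr_format_error")
  }
  sequence <- clean_sequence(sequence, id)
  tibble::tibble(id = id, sequence = sequence,
                 length = nchar(sequence),
                 topology = topology, compartment = compartment)
}

clean_sequence <- function(sequence, id) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    rlang::abort("`sequence` must be a single string.",
                 class = "organellr_format_error")
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    rlang::abort(paste0("record '", id, "' has a zero-length sequence"),
                 class = "organellr_format_error")
  }
  bad <- stringr::str_count(sequence, "[^ACGTN]")
  if (bad > 0L) {
    message("record '", id, "': ", bad,
            " non-ACGTN character(s) mapped to N")
    sequence <- stringr::str_replace_all(sequence, "[^ACGTN]", "N")
  }
  sequence
}

#' Read genome sequences from FASTA
#'
#' Reads a (multi-record) FASTA file into a genome tibble.  Lowercase
#' bases are normalized to uppercase and any character outside `A/C/G/T/N`
#' is mapped to `N` with a message reporting the count per record.
#'
#' @param path Path to a FASTA file.
#' @param compartment,topology Passed to [genome_record()] for every record.
#' @return A genome tibble (one row per FASTA record).
#' @export
read_genome_fasta <- function(path,
                              compartment = c("unknown", "mitochondrion",
                                              "plastid", "nucleus"),
                              topology = NULL) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path),
                 class = "organellr_format_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) rlang::abort(
      paste0("malformed FASTA in ", path, ": ", conditionMessage(e)),
      class = "organellr_format_error"))
  if (length(set) == 0L) {
    rlang::abort(paste0("empty FASTA file: ", path),
                 class = "organellr_format_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    rlang::abort(paste0("malformed header (empty id) in ", path),
                 class = "organellr_format_error")
  }
  dplyr::bind_rows(purrr::map2(
    ids, as.character(set),
    function(i, s) genome_record(i, s, topology = topology,
                                 compartment = compartment)))
}

#' Write a genome tibble to FASTA
#'
#' Output is bit-stable given identical input: fixed 70-column wrapping,
#' records in row order.
#'
#' @param genomes Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  stopifnot(is.data.frame(genomes), all(c("id", "sequence") %in% names(genomes)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in seq_len(nrow(genomes))) {
    writeLines(paste0(">", genomes$id[k]), con, sep = "\n")
    s <- genomes$sequence[k]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con,
               sep = "\n")
  }
  invisible(path)
}

#' GC content of sequences or genome regions
#'
#' Percentage of G+C among unambiguous bases: `100 * (G + C) / (A + C + G +
#' T)`.  `N` is excluded from both numerator and denominator, so the value
#' reflects only resolved positions.  Reported to one decimal place.
#'
#' @param x A genome tibble (one value per row) or a character vector of
#'   sequences.
#' @param start,end Optional 1-based inclusive bounds restricting the
#'   computation to a region (only for a single sequence/record).
#' @return Numeric vector of percentages.
#' @examples
#' gc_content("GCGC")   # 100
#' gc_content("ATAT")   # 0
#' @export
gc_content <- function(x, start = NULL, end = NULL) {
  seqs <- if (is.data.frame(x)) x$sequence else x
  if (!is.null(start) || !is.null(end)) {
    stopifnot(length(seqs) == 1L)
    seqs <- substr(seqs, start %||% 1L, end %||% nchar(seqs))
  }
  gc <- stringr::str_count(seqs, "[GC]")
  at <- stringr::str_count(seqs, "[AT]")
  if (any(gc + at == 0L)) {
    rlang::abort("undefined composition: region contains no unambiguous bases",
                 class = "organellr_composition_error")
  }
  round(100 * gc / (gc + at), 1)
}

#' Reverse complement
#'
#' @param x Character vector of nucleotide sequences (IUPAC `N` allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Merge intervals into non-redundant coverage
#'
#' Collapses a set of (possibly overlapping, strand-collapsed) intervals
#' into the sorted disjoint union per sequence.  This union is the unit of
#' every "overlaps excluded" statistic in the package: adding an interval
#' that is already covered leaves the total unchanged.
#'
#' @param intervals Tibble with columns `seq_id`, `start`, `end` (1-based
#'   inclusive).  Extra columns are dropped.
#' @param seq_lengths Optional named vector of sequence lengths; intervals
#'   beyond the bounds raise a coordinate error.
#' @return Tibble of disjoint intervals sorted by `seq_id`, `start`.
#' @examples
#' merge_intervals(tibble::tibble(seq_id = "g", start = c(1, 50), end = c(100, 150)))
#' @export
merge_intervals <- function(intervals, seq_lengths = NULL) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer()))
  }
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) {
    rlang::abort("interval with start > end",
                 class = "organellr_coordinate_error")
  }
  if (any(intervals$start < 1L)) {
    rlang::abort("interval starts before position 1",
                 class = "organellr_coordinate_error")
  }
  if (!is.null(seq_lengths)) {
    lim <- seq_lengths[intervals$seq_id]
    if (any(is.na(lim)) || any(intervals$end > lim)) {
      rlang::abort("interval beyond sequence bounds",
                   class = "organellr_coordinate_error")
    }
  }
  intervals |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::reframe({
      r <- IRanges::reduce(IRanges::IRanges(start = .data$start,
                                            end = .data$end))
      tibble::tibble(start = IRanges::start(r),
                     end = IRanges::end(r))
    }) |>
    dplyr::arrange(.data$seq_id, .data$start)
}

#' Total covered length of an interval set
#'
#' @param intervals Tibble with `seq_id`, `start`, `end`; merged first, so
#'   overlapping input never double-counts.
#' @param seq_lengths Optional bounds check, see [merge_intervals()].
#' @return Total covered base pairs (scalar).
#' @export
interval_total <- function(intervals, seq_lengths = NULL) {
  m <- merge_intervals(intervals, seq_lengths)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start + 1L)
}

#' Extract a region from a genome record
#'
#' Coordinates are 1-based inclusive.  On circular records the region may
#' wrap the origin (`start > end`), in which case the returned sequence
#' spans `start..length` followed by `1..end`.  Minus-strand requests
#' return the reverse complement.
#'
#' @param genome One-row genome tibble (or a genome tibble plus `id`).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param id Row to use when `genome` has several records.
#' @return The region sequence (character scalar).
#' @examples
#' g <- genome_record("x", "ACGTACGT", topology = "linear")
#' extract_region(g, 3, 6)        # "GTAC"
#' extract_region(g, 3, 6, "-")   # reverse complement
#' @export
extract_region <- function(genome, start, end, strand = c("+", "-"),
                           id = NULL) {
  strand <- match.arg(strand)
  if (!is.null(id)) genome <- genome[genome$id == id, , drop = FALSE]
  stopifnot(nrow(genome) == 1L)
  n <- genome$length
  s <- genome$sequence
  circular <- identical(genome$topology, "circular")
  if (start < 1L || end < 1L || start > n || end > n) {
    rlang::abort("coordinates out of bounds",
                 class = "organellr_coordinate_error")
  }
  if (start <= end) {
    out <- substr(s, start, end)
  } else {
    if (!circular) {
      rlang::abort("start > end on a linear record",
                   class = "organellr_coordinate_error")
    }
    out <- paste0(substr(s, start, n), substr(s, 1L, end))
  }
  if (strand == "-") out <- revcomp(out)
  out
}

#' Read / write BED interval files
#'
#' On disk BED is 0-based half-open; in memory all coordinates in this
#' package are 1-based inclusive.  The conversion happens here, at the
#' boundary.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `seq_id`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("seq_id", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(raw) > 3L) {
    names(raw)[4:min(6L, ncol(raw))] <- extra[seq_len(min(3L, ncol(raw) - 3L))]
  }
  raw$start <- raw$start + 1L
  tibble::as_tibble(raw)
}

#' @rdname read_bed
#' @param intervals Tibble with `seq_id`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (1-based inclusive).
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  out <- data.frame(seq_id = intervals$seq_id,
                    start = intervals$start - 1L,
                    end = intervals$end)
  for (col in c("name", "score", "strand")) {
    if (col %in% names(intervals)) out[[col]] <- intervals[[col]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv_stable <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df <- df[, !list_cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer codes used by the C++ engines: A=0 C=1 G=2 T=3 N=4.
encode_dna <- function(s) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  v <- codes[strsplit(s, "", fixed = TRUE)[[1]]]
  unname(v)
}
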