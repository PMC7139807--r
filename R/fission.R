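#' Construct a reference gene model
#'
#' A gene model carries the reference coding sequence used for locating a
#' gene in a target genome and for classifying deletions, plus the
#' optional exon structure (for intron presence/loss calls) and conserved
#' domain intervals in CDS coordinates (for deciding whether a fission
#' leaves the product's domains intact).
#'
#' @param gene_id Gene name.
#' @param cds Reference coding sequence; length must be divisible by
#'   three and translate without internal stops.
#' @param exons Optional character vector of exon sequences in order
#'   (their concatenation must equal `cds`).
#' @param domains Optional tibble of `start`, `end` (1-based CDS
#'   coordinates) of conserved domains.
#' @return A one-row tibble with list-columns `exons` and `domains`.
#' @export
gene_model <- function(gene_id, cds, exons = NULL, domains = NULL) {
  cds <- clean_sequence(cds, gene_id)
  if (nchar(cds) %% 3 != 0) {
    rlang::abort(paste0("CDS of '", gene_id, "' is not divisible by 3"),
                 class = "organellr_gene_error")
  }
  aa <- translate_dna(cds)
  if (grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
    rlang::abort(paste0("CDS of '", gene_id, "' has internal stop codons"),
                 class = "organellr_gene_error")
  }
  if (!is.null(exons)) {
    exons <- toupper(exons)
    if (!identical(paste(exons, collapse = ""), cds)) {
      rlang::abort(paste0("exons of '", gene_id,
                          "' do not concatenate to the CDS"),
                   class = "organellr_gene_error")
    }
  }
  tibble::tibble(gene_id = gene_id, cds = cds, cds_length = nchar(cds),
                 exons = list(exons), domains = list(domains))
}

#' Translate a nucleotide sequence (standard code)
#'
#' Plant mitochondrial protein genes use the standard genetic code
#' (translation table 1).  Incomplete trailing codons are dropped; codons
#' containing `N` translate to `X`.
#'
#' @param seq Nucleotide sequence.
#' @return Amino acid string with `*` for stops.
#' @export
translate_dna <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3
  if (n == 0L) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- GENETIC_CODE_1[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

GENETIC_CODE_1 <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

#' Locate a gene in a target genome
#'
#' Searches the reference CDS against a target genome with the sensitive
#' preset, clusters hits into candidate loci (same strand, gaps up to
#' `cluster_gap` bp) and reports the best-scoring locus.  A gene is
#' called `absent` when less than `min_cds_fraction` of the CDS aligns
#' anywhere - the signature of a complete, precise deletion.  Loci tying
#' the best score are all returned and flagged.
#'
#' @param gene Gene model row from [gene_model()].
#' @param target Genome tibble (one record used per call).
#' @param min_cds_fraction Minimum aligned CDS fraction (default 0.3).
#' @param scheme Alignment scheme (sensitive preset by default).
#' @param cluster_gap Maximum within-locus gap between hits (bp).
#' @return Tibble of candidate loci with `status` (`found`/`absent`),
#'   `start`, `end`, `strand`, `frac_aligned`, `score`, `tied` flag.
#' @export
locate_gene <- function(gene, target, min_cds_fraction = 0.3,
                        scheme = scoring_scheme("sensitive"),
                        cluster_gap = 5000L) {
  stopifnot(nrow(gene) == 1L, nrow(target) == 1L)
  q <- genome_record(gene$gene_id, gene$cds, topology = "linear")
  hits <- align_pair(q, target, scheme)
  absent <- tibble::tibble(gene_id = gene$gene_id, target_id = target$id,
                           status = "absent", start = NA_integer_,
                           end = NA_integer_, strand = NA_character_,
                           frac_aligned = 0, score = 0L, tied = FALSE)
  if (nrow(hits) == 0L) return(absent)
  loci <- hits |>
    dplyr::mutate(lo = as.numeric(pmin(.data$sstart, .data$send)),
                  hi = as.numeric(pmax(.data$sstart, .data$send))) |>
    dplyr::group_by(.data$strand) |>
    dplyr::arrange(.data$lo, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      .data$lo - dplyr::lag(cummax(.data$hi), default = -Inf) > cluster_gap)) |>
    dplyr::group_by(.data$strand, .data$cluster) |>
    dplyr::summarise(start = min(.data$lo), end = max(.data$hi),
                     score = sum(.data$score),
                     frac_aligned = coverage_bp(.data$qstart, .data$qend) /
                       gene$cds_length,
                     .groups = "drop")
  best <- max(loci$score)
  loci <- loci[loci$score == best & loci$frac_aligned >= min_cds_fraction, ,
               drop = FALSE]
  if (nrow(loci) == 0L) return(absent)
  tibble::tibble(gene_id = gene$gene_id, target_id = target$id,
                 status = "found", start = loci$start, end = loci$end,
                 strand = loci$strand,
                 frac_aligned = round(loci$frac_aligned, 3),
                 score = loci$score, tied = nrow(loci) > 1L)
}

# Pairwise alignment of the reference CDS into a target locus, returning
# per-column mapping.  The CDS is aligned globally, the locus locally.
align_cds_to_locus <- function(cds, locus_seq) {
  al <- Biostrings::pairwiseAlignment(
    pattern = cds, subject = locus_seq, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  list(pattern = pat, subject = sub,
       subject_start = al@subject@range@start)
}

# Deletions (gap runs in the target) in reference CDS coordinates, with
# gap placement normalized by left-shifting: a deletion is slid left
# while the reference base preceding it equals its last base.
extract_deletions <- function(pat, sub, cds) {
  ref_pos <- cumsum(pat != "-")
  is_del <- sub == "-" & pat != "-"
  if (!any(is_del)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  r <- rle(is_del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  del <- tibble::tibble(start = ref_pos[starts[r$values]],
                        end = ref_pos[ends[r$values]])
  cds_chars <- strsplit(cds, "")[[1]]
  for (k in seq_len(nrow(del))) {
    a <- del$start[k]; b <- del$end[k]
    while (a > 1L && cds_chars[a - 1L] == cds_chars[b]) {
      a <- a - 1L; b <- b - 1L
    }
    del$start[k] <- a; del$end[k] <- b
  }
  del$length <- del$end - del$start + 1L
  del
}

#' Classify a target gene locus: intact, pseudogene or fission
#'
#' Aligns the reference CDS to the target locus and evaluates every
#' deletion.  In-frame deletions (length divisible by three) leave the
#' gene intact minus some codons.  A frameshifting deletion shifts the
#' downstream reading frame; the target is translated from the gene
#' start through the shifted frame to the first stop codon (the
#' premature stop).  A window downstream of the stop (default 200 bp) is
#' then scanned for the next start codon; if a second reading frame runs
#' from there to the reference C-terminus without stops, the event is a
#' fission into two ORFs - the deletion-driven gene fission pattern.
#' Otherwise the locus is called a pseudogene (as are loci whose
#' unshifted frame contains premature stops from point mutation, or with
#' frameshifting insertions).  Deletion coordinates are reported in
#' reference CDS space, gap placement left-shifted.
#'
#' @param gene Gene model row.
#' @param target_locus_sequence Target locus sequence (plus-strand
#'   orientation of the gene).
#' @param locus_offset Genome coordinate of the first locus base (used to
#'   report ORF intervals on the target genome; default 1).
#' @param start_codons Candidate start codons for the second ORF
#'   (default `"ATG"`; add `"GTG"` if desired).
#' @param scan_window Search window for the second start codon, bp
#'   downstream of the premature stop.
#' @param adjacency_bp Distance below which the two ORFs count as
#'   adjacent (same locus; default 5000).
#' @return One-row tibble with `status` (`intact`,
#'   `intact_with_deletion`, `fissioned`, `pseudogene`) and, for
#'   fissions, the deletion interval and length, `frame_shift`,
#'   `premature_stop_pos` (CDS coordinate in the target), ORF intervals,
#'   `orf2_start_codon_pos`, `adjacent` and `domains_intact`.
#' @export
detect_fission <- function(gene, target_locus_sequence, locus_offset = 1L,
                           start_codons = "ATG", scan_window = 200L,
                           adjacency_bp = 5000L) {
  stopifnot(nrow(gene) == 1L)
  locus <- toupper(target_locus_sequence)
  al <- align_cds_to_locus(gene$cds, locus)
  del <- extract_deletions(al$pattern, al$subject, gene$cds)
  ins_len <- sum(al$pattern == "-")
  fs_dels <- del[del$length %% 3L != 0L, , drop = FALSE]

  base <- tibble::tibble(gene_id = gene$gene_id, status = NA_character_,
                         deletion_start = NA_integer_,
                         deletion_end = NA_integer_,
                         deletion_length = NA_integer_,
                         frame_shift = NA_integer_,
                         premature_stop_pos = NA_integer_,
                         orf1_start = NA_integer_, orf1_end = NA_integer_,
                         orf2_start = NA_integer_, orf2_end = NA_integer_,
                         orf2_start_codon_pos = NA_integer_,
                         adjacent = NA, domains_intact = NA)

  # target CDS region: ungapped target sequence spanned by the alignment
  tstart <- al$subject_start
  target_cds <- paste(al$subject[al$subject != "-"], collapse = "")
  tend <- tstart + nchar(target_cds) - 1L

  if (nrow(fs_dels) == 0L && ins_len %% 3L == 0L) {
    aa <- translate_dna(target_cds)
    internal_stop <- regexpr("*", substr(aa, 1, nchar(aa) - 1),
                             fixed = TRUE)
    if (internal_stop > 0) {
      base$status <- "pseudogene"
      base$premature_stop_pos <- 3L * as.integer(internal_stop)
      return(base)
    }
    base$status <- if (nrow(del) > 0L) "intact_with_deletion" else "intact"
    if (nrow(del) > 0L) {
      base$deletion_start <- del$start[1]
      base$deletion_end <- del$end[1]
      base$deletion_length <- del$length[1]
      base$frame_shift <- 0L
    }
    return(base)
  }
  if (nrow(fs_dels) == 0L) {       # frameshifting insertion only
    base$status <- "pseudogene"
    return(base)
  }

  d <- fs_dels[1, ]
  base$deletion_start <- d$start
  base$deletion_end <- d$end
  base$deletion_length <- d$length
  base$frame_shift <- d$length %% 3L

  # translate the target CDS in the frame of the gene start; the shift
  # introduced by the deletion produces the premature stop downstream
  aa <- translate_dna(target_cds)
  stop_aa <- regexpr("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
  if (stop_aa < 0) {               # no stop before the C-terminus
    base$status <- "pseudogene"
    return(base)
  }
  stop_nt_end <- 3L * as.integer(stop_aa)          # target CDS coordinate
  base$premature_stop_pos <- stop_nt_end - 2L
  base$orf1_start <- locus_offset + tstart - 1L
  base$orf1_end <- locus_offset + tstart + stop_nt_end - 2L

  # scan downstream of the stop for the next start codon whose frame
  # reaches the reference C-terminus without stops
  found <- FALSE
  scan_from <- stop_nt_end + 1L
  scan_to <- min(nchar(target_cds) - 2L, stop_nt_end + scan_window)
  if (scan_from <= scan_to) {
    for (p in scan_from:scan_to) {
      codon <- substr(target_cds, p, p + 2L)
      if (!codon %in% start_codons) next
      tail_aa <- translate_dna(substr(target_cds, p, nchar(target_cds)))
      body <- substr(tail_aa, 1, nchar(tail_aa) - 1L)
      if (!grepl("*", body, fixed = TRUE)) {
        found <- TRUE
        base$orf2_start <- locus_offset + tstart + p - 2L
        base$orf2_end <- locus_offset + tend - 1L
        base$orf2_start_codon_pos <- p
        break
      }
    }
  }
  if (!found) {
    base$status <- "pseudogene"
    return(base)
  }
  base$status <- "fissioned"
  base$adjacent <- (base$orf2_start - base$orf1_end) <= adjacency_bp
  domains <- gene$domains[[1]]
  if (!is.null(domains) && nrow(domains) > 0L) {
    # disrupted reference region: the deletion plus the untranslated gap
    # between the premature stop and the second ORF start
    gap_ref_start <- d$start
    gap_ref_end <- d$end + (base$orf2_start_codon_pos - base$premature_stop_pos)
    base$domains_intact <- !any(domains$start <= gap_ref_end &
                                  domains$end >= gap_ref_start)
  } else {
    base$domains_intact <- NA
  }
  base
}

#' Frame consequences of single-nucleotide deletions
#'
#' Enumerates 1 bp deletions between a reference CDS and a variant locus
#' (a special case of [detect_fission()]): each is a frame shift of one
#' with its induced premature stop.  In-frame (multiple-of-three)
#' deletions are not reported here.
#'
#' @param reference_cds Reference coding sequence.
#' @param variant_locus Variant locus sequence.
#' @return Tibble of single-base deletions: `position` (reference CDS
#'   coordinate), `frame_shift` (always 1), `premature_stop_pos` (target
#'   CDS coordinate, `NA` if none before the C-terminus).
#' @export
single_nt_deletion_check <- function(reference_cds, variant_locus) {
  reference_cds <- toupper(reference_cds)
  al <- align_cds_to_locus(reference_cds, toupper(variant_locus))
  del <- extract_deletions(al$pattern, al$subject, reference_cds)
  del <- del[del$length == 1L, , drop = FALSE]
  if (nrow(del) == 0L) {
    return(tibble::tibble(position = integer(), frame_shift = integer(),
                          premature_stop_pos = integer()))
  }
  target_cds <- paste(al$subject[al$subject != "-"], collapse = "")
  aa <- translate_dna(target_cds)
  stop_aa <- regexpr("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
  stop_pos <- if (stop_aa > 0) 3L * as.integer(stop_aa) - 2L else NA_integer_
  tibble::tibble(position = del$start, frame_shift = 1L,
                 premature_stop_pos = stop_pos)
}

#' Intron presence or loss per intron of a gene
#'
#' Aligns the flanking exons of each intron to the target genome.  An
#' intron is `lost` when its exons are contiguous in the target (gap at
#' most `slack` bp, the signature of a cis-spliced intron loss) and
#' `present` otherwise; if a flanking exon cannot be aligned the status
#' is `unknown`.  Introns are named `geneName + "i" + CDS position of the
#' last reference base before the intron`.
#'
#' @param gene Gene model row with exon sequences.
#' @param target Genome tibble (one record).
#' @param slack Maximum target gap still counting as contiguous (bp).
#' @param scheme Alignment scheme.
#' @return Tibble with `intron`, `status` (`present`/`lost`/`unknown`)
#'   and the observed target gap.
#' @export
intron_status <- function(gene, target, slack = 10L,
                          scheme = scoring_scheme("sensitive")) {
  stopifnot(nrow(gene) == 1L, nrow(target) == 1L)
  exons <- gene$exons[[1]]
  if (is.null(exons) || length(exons) < 2L) {
    rlang::abort(paste0("gene '", gene$gene_id, "' has no intron structure"),
                 class = "organellr_gene_error")
  }
  cum <- cumsum(nchar(exons))
  out <- vector("list", length(exons) - 1L)
  locate_exon <- function(ex) {
    q <- genome_record("exon", ex, topology = "linear")
    h <- align_pair(q, target, scheme)
    if (nrow(h) == 0L) return(NULL)
    h[1, ]
  }
  hits <- lapply(exons, locate_exon)
  for (k in seq_len(length(exons) - 1L)) {
    name <- paste0(gene$gene_id, "i", cum[k])
    h1 <- hits[[k]]; h2 <- hits[[k + 1L]]
    if (is.null(h1) || is.null(h2) || h1$strand != h2$strand) {
      out[[k]] <- tibble::tibble(intron = name, status = "unknown",
                                 target_gap = NA_integer_)
      next
    }
    if (h1$strand == "+") {
      gap <- min(h2$sstart, h2$send) - max(h1$sstart, h1$send) - 1L
    } else {
      gap <- min(h1$sstart, h1$send) - max(h2$sstart, h2$send) - 1L
    }
    out[[k]] <- tibble::tibble(
      intron = name,
      status = if (!is.na(gap) && gap <= slack) "lost" else "present",
      target_gap = gap)
  }
  dplyr::bind_rows(out)
}

#' Gene and intron content matrix across taxa
#'
#' Applies [locate_gene()] and [detect_fission()] to every gene-taxon
#' pair, yielding one state per cell: `intact` (including in-frame
#' deletions), `pseudogene`, `fissioned` or `absent`.  Genes with exon
#' structure also contribute an intron presence/loss matrix.
#'
#' @param genes Gene model tibble (rows from [gene_model()]).
#' @param genomes Genome tibble, one row per taxon.
#' @param flank Locus flank included around located genes (bp).
#' @param ... Passed to [detect_fission()].
#' @return List with `genes` (long tibble `taxon`, `gene_id`, `state`),
#'   `gene_matrix` (wide), and `introns` (long tibble, possibly empty).
#' @export
gene_content_matrix <- function(genes, genomes, flank = 100L, ...) {
  if (nrow(genes) == 0L) {
    return(list(genes = tibble::tibble(taxon = character(),
                                       gene_id = character(),
                                       state = character()),
                gene_matrix = tibble::tibble(taxon = character()),
                introns = tibble::tibble(taxon = character(),
                                         intron = character(),
                                         status = character())))
  }
  cells <- tidyr::expand_grid(ti = seq_len(nrow(genomes)),
                              gi = seq_len(nrow(genes)))
  rows <- purrr::pmap(cells, function(ti, gi) {
    taxon <- genomes$id[ti]
    gene <- genes[gi, ]
    loc <- locate_gene(gene, genomes[ti, ])
    if (loc$status[1] == "absent") {
      return(tibble::tibble(taxon = taxon, gene_id = gene$gene_id,
                            state = "absent"))
    }
    lstart <- max(1L, loc$start[1] - flank)
    lend <- min(genomes$length[ti], loc$end[1] + flank)
    locus <- extract_region(genomes[ti, ], lstart, lend,
                            strand = loc$strand[1])
    call <- detect_fission(gene, locus, locus_offset = lstart, ...)
    state <- switch(call$status,
                    intact = "intact", intact_with_deletion = "intact",
                    fissioned = "fissioned", pseudogene = "pseudogene")
    tibble::tibble(taxon = taxon, gene_id = gene$gene_id, state = state)
  })
  long <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(long, names_from = "gene_id",
                             values_from = "state")
  with_introns <- which(vapply(genes$exons,
                               function(e) !is.null(e) && length(e) > 1L,
                               logical(1)))
  introns <- purrr::map_dfr(with_introns, function(gi) {
    purrr::map_dfr(seq_len(nrow(genomes)), function(ti) {
      st <- intron_status(genes[gi, ], genomes[ti, ])
      dplyr::mutate(st, taxon = genomes$id[ti], .before = 1)
    })
  })
  list(genes = long, gene_matrix = wide, introns = introns)
}

#' Read gene models from a genome FASTA and GFF3 annotation
#'
#' CDS features are grouped by their `Parent` (or `ID`) attribute,
#' ordered along the transcript (reverse order on the minus strand), and
#' extracted strand-aware from the genome, giving one gene model per
#' grouped CDS with the exon structure preserved.  Requires the
#' rtracklayer package for GFF3 parsing.
#'
#' @param genome A genome tibble (from [read_genome_fasta()]) or a FASTA
#'   path.
#' @param gff_path GFF3 file with CDS features.
#' @return A gene model tibble (rows as from [gene_model()]).
#' @export
read_gene_models <- function(genome, gff_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("read_gene_models requires the rtracklayer package",
                 class = "organellr_input_error")
  }
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  gr <- rtracklayer::import(gff_path)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) {
    rlang::abort(paste0("no CDS features in ", gff_path),
                 class = "organellr_format_error")
  }
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  if (length(parent) == 0L || all(is.na(parent)) || all(parent == "")) {
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  }
  parent[is.na(parent) | parent == ""] <- "unnamed"
  groups <- split(seq_along(cds), parent)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    sub <- cds[idx]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    ord <- order(BiocGenerics::start(sub),
                 decreasing = identical(strand, "-"))
    sub <- sub[ord]
    seqid <- as.character(GenomicRanges::seqnames(sub))[1]
    rec <- genome[genome$id == seqid, , drop = FALSE]
    if (nrow(rec) != 1L) {
      rlang::abort(paste0("GFF3 sequence '", seqid, "' not in the FASTA"),
                   class = "organellr_format_error")
    }
    exons <- vapply(seq_along(sub), function(k)
      extract_region(rec, BiocGenerics::start(sub)[k],
                     BiocGenerics::end(sub)[k],
                     strand = if (identical(strand, "-")) "-" else "+"),
      character(1))
    gene_model(g, paste(exons, collapse = ""),
               exons = if (length(exons) > 1L) exons else NULL)
  })
  dplyr::bind_rows(out)
}
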