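#' Build a genome simulation recipe
#'
#' A recipe fixes everything about a synthetic genome: the seed, the
#' background composition, and the planted features with their truth
#' coordinates to be.  Identical recipes yield byte-identical output.
#' Background GC defaults reflect the organelle/nuclear contrast of real
#' plant cells: 45% for organelle compartments, 33% for nuclear.
#' Divergence is applied as i.i.d. substitutions (no indels) unless an
#' indel rate is requested, keeping truth coordinates exact.
#'
#' @param genome_id Identifier for the simulated record.
#' @param length Genome length (bp).
#' @param compartment `"mitochondrion"`, `"plastid"`, `"nucleus"` or
#'   `"unknown"`.
#' @param gc Background GC fraction; default 0.45 for organelle
#'   compartments, 0.33 for nuclear/unknown.
#' @param seed Integer seed; each feature draws from its own
#'   deterministically derived substream, so adding a feature does not
#'   perturb the others.
#' @param dispersed_repeats Tibble with `length`, `copies`, `divergence`
#'   (one row per repeat family).
#' @param tandem_repeats Tibble with `period`, `copies`, `divergence`.
#' @param igt_tracts Tibble with `source_id`, `source_start`,
#'   `source_end`, `divergence` (requires `source` at simulation time).
#' @param indel_rate Per-base indel probability applied with the
#'   substitutions (default 0, coordinates stay exact).
#' @return A `simulation_recipe` object.
#' @export
simulation_recipe <- function(genome_id, length,
                              compartment = c("nucleus", "mitochondrion",
                                              "plastid", "unknown"),
                              gc = NULL, seed = 1L,
                              dispersed_repeats = NULL,
                              tandem_repeats = NULL,
                              igt_tracts = NULL,
                              indel_rate = 0) {
  compartment <- match.arg(compartment)
  if (is.null(gc)) {
    gc <- if (compartment %in% c("mitochondrion", "plastid")) 0.45 else 0.33
  }
  stopifnot(length >= 100, gc > 0, gc < 1, indel_rate >= 0)
  structure(list(genome_id = genome_id, length = as.integer(length),
                 compartment = compartment, gc = gc,
                 seed = as.integer(seed),
                 dispersed_repeats = dispersed_repeats,
                 tandem_repeats = tandem_repeats,
                 igt_tracts = igt_tracts,
                 indel_rate = indel_rate),
            class = "simulation_recipe")
}

substream_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# i.i.d. substitutions at the given per-base rate; returns the sequence
mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  k <- round(divergence * n)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(bases, b), 1L), character(1))
  paste(chars, collapse = "")
}

#' Simulate a genome with planted features and exact truth
#'
#' Generates a background sequence at the recipe's GC, then plants every
#' requested feature (dispersed repeat families, tandem arrays,
#' organelle-derived tracts) at non-overlapping positions.  Placement is
#' by seeded rejection sampling; if the features cannot be packed an
#' infeasible-packing error is raised.  The returned truth tibbles
#' enumerate every planted feature with its exact coordinates, so every
#' detector can be scored without re-deriving anything.
#'
#' @param recipe A [simulation_recipe()].
#' @param source Optional genome tibble supplying sequence for
#'   `igt_tracts` (matched by `source_id`).
#' @return List with `genome` (one-row genome tibble) and `truth` (list
#'   of tibbles: `dispersed`, `tandem`, `igt`).
#' @export
simulate_genome <- function(recipe, source = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  n <- recipe$length
  set.seed(substream_seed(recipe$seed, 0L))
  chars <- strsplit(random_dna(n, recipe$gc), "")[[1]]

  occupied <- tibble::tibble(seq_id = character(), start = integer(),
                             end = integer())
  margin <- 40L   # keep planted features from abutting (seeds can't bridge)

  place <- function(len) {
    for (try in 1:2000) {
      s <- sample.int(n - len + 1L, 1L)
      e <- s + len - 1L
      clash <- any(occupied$start <= e + margin & occupied$end >= s - margin)
      if (!clash) return(c(s, e))
    }
    rlang::abort("infeasible packing: feature does not fit",
                 class = "organellr_packing_error")
  }
  total_len <- 0
  add_occ <- function(s, e) {
    occupied <<- dplyr::bind_rows(occupied,
                                  tibble::tibble(seq_id = "g", start = s,
                                                 end = e))
  }

  truth_disp <- list(); truth_tand <- list(); truth_igt <- list()
  fidx <- 1L

  dr <- recipe$dispersed_repeats
  if (!is.null(dr) && nrow(dr) > 0L) {
    for (r in seq_len(nrow(dr))) {
      set.seed(substream_seed(recipe$seed, fidx)); fidx <- fidx + 1L
      if (sum(dr$length * dr$copies) + sum(occupied$end - occupied$start) >
            0.9 * n) {
        rlang::abort("infeasible packing: requested features exceed capacity",
                     class = "organellr_packing_error")
      }
      master <- random_dna(dr$length[r], recipe$gc)
      for (cp in seq_len(dr$copies[r])) {
        copy_seq <- mutate_sequence(master, dr$divergence[r])
        at <- place(dr$length[r])
        chars[at[1]:at[2]] <- strsplit(copy_seq, "")[[1]]
        add_occ(at[1], at[2])
        truth_disp[[length(truth_disp) + 1L]] <-
          tibble::tibble(family = r, copy = cp, start = at[1], end = at[2],
                         length = dr$length[r],
                         divergence = dr$divergence[r])
      }
    }
  }

  tr <- recipe$tandem_repeats
  if (!is.null(tr) && nrow(tr) > 0L) {
    for (r in seq_len(nrow(tr))) {
      set.seed(substream_seed(recipe$seed, 1000L + r))
      pat <- random_dna(tr$period[r], recipe$gc)
      div <- if ("divergence" %in% names(tr)) tr$divergence[r] else 0
      arr <- mutate_sequence(strrep(pat, tr$copies[r]), div)
      at <- place(nchar(arr))
      chars[at[1]:at[2]] <- strsplit(arr, "")[[1]]
      add_occ(at[1], at[2])
      truth_tand[[r]] <- tibble::tibble(start = at[1], end = at[2],
                                        period = tr$period[r],
                                        copies = tr$copies[r],
                                        pattern = pat)
    }
  }

  it <- recipe$igt_tracts
  if (!is.null(it) && nrow(it) > 0L) {
    if (is.null(source)) {
      rlang::abort("igt_tracts requested but no source genomes supplied",
                   class = "organellr_input_error")
    }
    for (r in seq_len(nrow(it))) {
      set.seed(substream_seed(recipe$seed, 2000L + r))
      src <- source[source$id == it$source_id[r], , drop = FALSE]
      stopifnot(nrow(src) == 1L)
      frag <- extract_region(src, it$source_start[r], it$source_end[r])
      frag <- mutate_sequence(frag, it$divergence[r])
      at <- place(nchar(frag))
      chars[at[1]:at[2]] <- strsplit(frag, "")[[1]]
      add_occ(at[1], at[2])
      truth_igt[[r]] <- tibble::tibble(source_id = it$source_id[r],
                                       source_start = it$source_start[r],
                                       source_end = it$source_end[r],
                                       start = at[1], end = at[2],
                                       length = nchar(frag),
                                       divergence = it$divergence[r])
    }
  }

  genome <- genome_record(recipe$genome_id, paste(chars, collapse = ""),
                          compartment = recipe$compartment)
  list(genome = genome,
       truth = list(dispersed = dplyr::bind_rows(truth_disp),
                    tandem = dplyr::bind_rows(truth_tand),
                    igt = dplyr::bind_rows(truth_igt)))
}

#' Write a simulated genome and its truth files
#'
#' Emits FASTA, BED truth per feature class (0-based half-open on disk)
#' and a JSON manifest echoing the recipe and seed.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param recipe The recipe used (echoed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, recipe = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  for (cls in names(sim$truth)) {
    tr <- sim$truth[[cls]]
    if (nrow(tr) == 0L) next
    bed <- tibble::tibble(seq_id = sim$genome$id, start = tr$start,
                          end = tr$end,
                          name = paste0(cls, "_", seq_len(nrow(tr))))
    write_bed(bed, file.path(dir, paste0("truth_", cls, ".bed")))
    write_tsv_stable(tr, file.path(dir, paste0("truth_", cls, ".tsv")))
  }
  if (!is.null(recipe)) {
    jsonlite::write_json(unclass(recipe),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Simulate a clean coding sequence
#'
#' Random CDS of `n_codons` codons: ATG start, TAA stop, internal codons
#' drawn uniformly from the 61 sense codons (no internal stops by
#' construction).
#'
#' @param n_codons Total codons including start and stop.
#' @param seed Seed.
#' @return CDS string of length `3 * n_codons`.
#' @export
simulate_cds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 3)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  sense <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Apply a clean deletion to a sequence
#'
#' @param seq Sequence.
#' @param start 1-based first deleted position.
#' @param len Deletion length.
#' @return Sequence with `len` bases removed.
#' @export
apply_deletion <- function(seq, start, len) {
  stopifnot(start >= 1, start + len - 1 <= nchar(seq))
  paste0(substr(seq, 1, start - 1), substr(seq, start + len, nchar(seq)))
}

#' Introduce a premature stop codon
#'
#' Replaces the codon at `codon_index` with TAA (a nonsense point
#' mutation), leaving the reading frame intact.
#'
#' @param cds Coding sequence.
#' @param codon_index Codon to replace (not the first or last).
#' @return Mutated CDS.
#' @export
apply_nonsense <- function(cds, codon_index) {
  n <- nchar(cds) %/% 3
  stopifnot(codon_index > 1, codon_index < n)
  paste0(substr(cds, 1, 3 * (codon_index - 1)), "TAA",
         substr(cds, 3 * codon_index + 1, nchar(cds)))
}

# --- transfer-scenario simulation ------------------------------------------

# nested-list tree node
tnode <- function(length, children = NULL, label = NULL) {
  list(label = label, length = length, children = children)
}

# The default species topology: two outgroups and a papilionoid ingroup
# with a nested clade of four genera.  Internal branches are short
# relative to terminal ones: the transfer points sit close to the root,
# so nearly the whole nuclear root-to-tip path evolves at the
# accelerated rate and the root-to-tip ratio approximates the
# post-transfer rate multiplier.
default_species_tree <- function() {
  trifolieae <- tnode(0.020, list(
    tnode(0.060, label = "Trigonella"),
    tnode(0.010, list(
      tnode(0.055, label = "Melilotus"),
      tnode(0.010, list(
        tnode(0.050, label = "Medicago"),
        tnode(0.050, label = "Trifolium")))))))
  ingroup <- tnode(0.015, list(
    tnode(0.070, label = "Lotus"),
    tnode(0.030, list(
      tnode(0.070, label = "Ononis"),
      trifolieae))))
  tnode(0, list(
    tnode(0.020, list(
      tnode(0.090, label = "Gmax"),
      tnode(0.090, label = "Mpinnata"))),
    ingroup))
}

tree_tips <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, tree_tips))
}

# relabel tips and scale branch lengths of a subtree (the nuclear copy)
scale_subtree <- function(node, mult, suffix) {
  node$length <- node$length * mult
  if (is.null(node$children)) {
    node$label <- paste0(node$label, suffix)
  } else {
    node$children <- lapply(node$children, scale_subtree, mult = mult,
                            suffix = suffix)
  }
  node
}

# attach a scaled nuclear copy at the parent of the clade whose tip set
# equals `taxa`; returns the modified tree or NULL if not found
attach_transfer <- function(node, taxa, mult) {
  if (is.null(node$children)) return(NULL)
  for (k in seq_along(node$children)) {
    child <- node$children[[k]]
    if (setequal(tree_tips(child), taxa)) {
      nuc <- scale_subtree(child, mult, "__nuc")
      node$children <- c(node$children, list(nuc))
      return(node)
    }
    sub <- attach_transfer(child, taxa, mult)
    if (!is.null(sub)) {
      node$children[[k]] <- sub
      return(node)
    }
  }
  NULL
}

to_newick <- function(node) {
  if (is.null(node$children)) {
    return(paste0(node$label, ":", sprintf("%.10g", node$length)))
  }
  inner <- paste(vapply(node$children, to_newick, character(1)),
                 collapse = ",")
  paste0("(", inner, "):", sprintf("%.10g", node$length))
}

# Jukes-Cantor sequence evolution along a phylo tree
evolve_jc <- function(tree, n_sites) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  bases <- c("A", "C", "G", "T")
  root <- ntip + 1L
  seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    t <- pre$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * t / 3))
    s <- seqs[[par]]
    hit <- stats::runif(n_sites) < p
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    seqs[[child]] <- s
  }
  stats::setNames(vapply(seqs[seq_len(ntip)], paste, character(1),
                         collapse = ""),
                  tree$tip.label)
}

#' Simulate a gene-transfer history and its copy alignment
#'
#' Evolves gene-copy sequences along a species tree carrying `k`
#' independent organelle-to-nucleus transfer events.  Each transfer
#' duplicates a clade: the nuclear copy evolves from the transfer point
#' with branch lengths scaled by `rate_multiplier` (the post-transfer
#' rate acceleration), while the mitochondrial copies continue at the
#' base rate.  Sites evolve under Jukes-Cantor.  The truth (which taxa
#' belong to which transfer event) is returned alongside the alignment.
#'
#' @param k Number of independent transfers (1-3 on the default tree:
#'   the Trifolieae clade, then Lotus, then Ononis).
#' @param rate_multiplier Nuclear branch-length scaling (default 5).
#' @param n_sites Alignment columns (default 1000).
#' @param seed Seed.
#' @param tree Optional species tree as a nested node list (advanced);
#'   default is the built-in legume topology with outgroups `Gmax` and
#'   `Mpinnata`.
#' @param transfer_clades Optional list of taxon vectors, each a clade of
#'   `tree`, overriding the default transfer points.
#' @return List with `aln` (copy alignment tibble), `truth` (list:
#'   `k`, `events` = taxa per event), `tree` (the combined `phylo`),
#'   and `outgroup`.
#' @export
simulate_transfer_scenario <- function(k = 1L, rate_multiplier = 5,
                                       n_sites = 1000L, seed = 1L,
                                       tree = NULL,
                                       transfer_clades = NULL) {
  stopifnot(k >= 1)
  if (is.null(tree)) tree <- default_species_tree()
  if (is.null(transfer_clades)) {
    transfer_clades <- list(
      c("Trigonella", "Melilotus", "Medicago", "Trifolium"),
      "Lotus",
      "Ononis")
  }
  if (k > length(transfer_clades)) {
    rlang::abort("k exceeds the available transfer lineages",
                 class = "organellr_input_error")
  }
  events <- transfer_clades[seq_len(k)]
  combined <- tree
  for (ev in events) {
    combined <- attach_transfer(combined, ev, rate_multiplier)
    if (is.null(combined)) {
      rlang::abort("transfer clade not found in the species tree",
                   class = "organellr_input_error")
    }
  }
  txt <- paste0(to_newick(combined), ";")
  phy <- ape::read.tree(text = txt)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tipseqs <- evolve_jc(phy, n_sites)

  labs <- names(tipseqs)
  nuclear <- grepl("__nuc$", labs)
  taxon <- sub("__nuc$", "", labs)
  aln <- copy_alignment(taxon = taxon,
                        compartment = ifelse(nuclear, "nuclear",
                                             "mitochondrial"),
                        sequence = unname(tipseqs))
  list(aln = aln,
       truth = list(k = k, events = events),
       tree = phy,
       outgroup = c("Gmax", "Mpinnata"))
}
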