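#' Build and validate a run configuration
#'
#' Collects every threshold of the full comparison in one validated
#' object.  Unknown arguments are rejected; every threshold is echoed
#' into the output manifest so a report is self-describing.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed governing every stochastic stage.
#' @param preset_repeat,preset_shared Aligner presets for the repeat and
#'   shared-DNA searches.
#' @param min_identity Identity threshold for shared DNA (percent,
#'   0-100, strict).
#' @param min_repeat_len Minimum dispersed repeat hit length (bp).
#' @param min_span_kb Minimum span of a reported transfer block (kb).
#' @param max_gap_bp Hit-clustering gap for blocks (bp).
#' @param adjacency_bp Distance for calling split ORFs adjacent (bp).
#' @param mito_fasta,plastid_fasta,nuclear_fasta Optional input FASTA
#'   paths; when absent a seeded synthetic demo cell is simulated.
#' @param demo_scale Length scale of the simulated demo genomes (bp).
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, seed = 1L,
                       preset_repeat = "sensitive",
                       preset_shared = "fast",
                       min_identity = 90, min_repeat_len = 31L,
                       min_span_kb = 100, max_gap_bp = 10000,
                       adjacency_bp = 5000,
                       mito_fasta = NULL, plastid_fasta = NULL,
                       nuclear_fasta = NULL,
                       demo_scale = 20000L) {
  if (!is.numeric(min_identity) || min_identity < 0 || min_identity > 100) {
    rlang::abort("min_identity must be between 0 and 100",
                 class = "organellr_config_error")
  }
  stopifnot(min_repeat_len >= 1, min_span_kb > 0, max_gap_bp >= 0,
            adjacency_bp >= 0, demo_scale >= 2000)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 preset_repeat = preset_repeat,
                 preset_shared = preset_shared,
                 min_identity = min_identity,
                 min_repeat_len = as.integer(min_repeat_len),
                 min_span_kb = min_span_kb, max_gap_bp = max_gap_bp,
                 adjacency_bp = adjacency_bp,
                 mito_fasta = mito_fasta, plastid_fasta = plastid_fasta,
                 nuclear_fasta = nuclear_fasta,
                 demo_scale = as.integer(demo_scale)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected at parse time.
#'
#' @param path JSON file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "organellr_config_error")
  }
  do.call(run_config, vals)
}

# simulated three-compartment demo cell
demo_cell <- function(config) {
  sc <- config$demo_scale
  mito <- simulate_genome(simulation_recipe(
    "demo_mito", sc, "mitochondrion", seed = substream_seed(config$seed, 11L),
    dispersed_repeats = tibble::tibble(length = 400L, copies = 3L,
                                       divergence = 0.02),
    tandem_repeats = tibble::tibble(period = 12L, copies = 30L)))
  plastid <- simulate_genome(simulation_recipe(
    "demo_plastid", as.integer(sc * 0.6), "plastid",
    seed = substream_seed(config$seed, 12L),
    dispersed_repeats = tibble::tibble(length = 300L, copies = 4L,
                                       divergence = 0.01)))
  nuc_len <- as.integer(sc * 3)
  nuclear <- simulate_genome(simulation_recipe(
    "demo_nuc1", nuc_len, "nucleus", seed = substream_seed(config$seed, 13L),
    igt_tracts = tibble::tibble(
      source_id = c("demo_mito", "demo_plastid"),
      source_start = c(1001L, 501L),
      source_end = c(1000L + as.integer(sc * 0.15), 500L + 2000L),
      divergence = c(0.02, 0.03))),
    source = dplyr::bind_rows(mito$genome, plastid$genome))
  list(mito = mito, plastid = plastid, nuclear = nuclear)
}

# three-taxon demo gene panel: one fission, one loss, rest intact
demo_gene_panel <- function(seed) {
  g1 <- gene_model("mtA", simulate_cds(120, seed = substream_seed(seed, 21L)))
  g2 <- gene_model("mtB", simulate_cds(150, seed = substream_seed(seed, 22L)))
  g3 <- gene_model("mtC", simulate_cds(100, seed = substream_seed(seed, 23L)))
  genes <- dplyr::bind_rows(g1, g2, g3)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  build_taxon <- function(id, cds_list, tseed) {
    set.seed(tseed)
    spacer <- function(n) random_dna(n, 0.45)
    seq <- paste0(spacer(400), paste0(vapply(cds_list, function(x)
      paste0(x, spacer(400)), character(1)), collapse = ""))
    genome_record(id, seq, compartment = "mitochondrion",
                  topology = "linear")
  }
  t1 <- build_taxon("taxon1", list(g1$cds, g2$cds, g3$cds),
                    substream_seed(seed, 31L))
  # taxon2: 59 bp deletion inside gene mtB -> fission
  g2_fiss <- apply_deletion(g2$cds, 100L, 59L)
  t2 <- build_taxon("taxon2", list(g1$cds, g2_fiss, g3$cds),
                    substream_seed(seed, 32L))
  # taxon3: gene mtC completely and precisely deleted
  t3 <- build_taxon("taxon3", list(g1$cds, g2$cds),
                    substream_seed(seed, 33L))
  list(genes = genes, genomes = dplyr::bind_rows(t1, t2, t3))
}

#' Run the full comparative analysis
#'
#' Orchestrates every stage into one report bundle: per-genome repeat
#' reports, the pairwise shared-DNA matrix with directional totals,
#' putative large transfer blocks, the gene/intron status matrix with
#' fission events, and the gene-copy phylogeny with its transfer-event
#' count.  Inputs come from the configured FASTA paths, or, when none
#' are given, from a seeded synthetic demonstration cell whose truth is
#' known.  All tables are written as TSV (intervals as BED, the tree as
#' Newick) into `config$out_dir` together with a JSON manifest echoing
#' every threshold, the seed and the package version.  Rerunning the
#' same configuration reproduces the outputs byte for byte.
#'
#' @param config A [run_config()].
#' @return The report bundle (class `organellr_run`), invisibly a list
#'   of tibbles.
#' @export
run_full_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "organellr_stage_error", parent = e)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  inputs <- stage("inputs", {
    if (is.null(config$mito_fasta)) {
      cell <- demo_cell(config)
      list(mito = cell$mito$genome, plastid = cell$plastid$genome,
           nuclear = cell$nuclear$genome, truth = cell)
    } else {
      list(mito = read_genome_fasta(config$mito_fasta, "mitochondrion"),
           plastid = if (!is.null(config$plastid_fasta))
             read_genome_fasta(config$plastid_fasta, "plastid") else NULL,
           nuclear = if (!is.null(config$nuclear_fasta))
             read_genome_fasta(config$nuclear_fasta, "nucleus") else NULL,
           truth = NULL)
    }
  })

  rep_scheme <- scoring_scheme(config$preset_repeat)
  sh_scheme <- scoring_scheme(config$preset_shared)

  repeats <- stage("repeats", {
    organelles <- dplyr::bind_rows(inputs$mito, inputs$plastid)
    reports <- purrr::map(seq_len(nrow(organelles)), function(k)
      profile_repeats(organelles[k, ], rep_scheme,
                      min_len = config$min_repeat_len))
    dplyr::bind_rows(purrr::map(reports, glance))
  })
  write_tsv_stable(repeats, file.path(config$out_dir, "repeats.tsv"))

  shared <- stage("shared_dna", {
    pairs <- list()
    if (!is.null(inputs$nuclear)) {
      pairs$mito_vs_nuclear <- shared_dna(inputs$mito, inputs$nuclear,
                                          sh_scheme, config$min_identity)
      if (!is.null(inputs$plastid)) {
        pairs$plastid_vs_nuclear <- shared_dna(inputs$plastid,
                                               inputs$nuclear, sh_scheme,
                                               config$min_identity)
      }
    }
    if (!is.null(inputs$plastid)) {
      pairs$plastid_vs_mito <- shared_dna(inputs$plastid, inputs$mito,
                                          sh_scheme, config$min_identity)
    }
    pairs
  })
  shared_tbl <- dplyr::bind_rows(purrr::map(shared, glance))
  write_tsv_stable(shared_tbl, file.path(config$out_dir, "shared_dna.tsv"))

  blocks <- stage("igt_blocks", {
    if (is.null(inputs$nuclear)) return(find_igt_blocks(
      inputs$mito, inputs$mito, hits = empty_hits(),
      min_span_kb = config$min_span_kb, max_gap_bp = config$max_gap_bp))
    find_igt_blocks(inputs$mito, inputs$nuclear,
                    hits = tidy(shared$mito_vs_nuclear),
                    min_span_kb = config$min_span_kb,
                    max_gap_bp = config$max_gap_bp)
  })
  write_tsv_stable(blocks, file.path(config$out_dir, "igt_blocks.tsv"))
  if (nrow(blocks) > 0L) {
    write_bed(blocks |>
                dplyr::transmute(seq_id = .data$subject_id, .data$start,
                                 .data$end,
                                 name = sprintf("block_%d",
                                                seq_len(nrow(blocks)))),
              file.path(config$out_dir, "igt_blocks.bed"))
  }

  gene_stage <- stage("gene_content", {
    panel <- demo_gene_panel(config$seed)
    mat <- gene_content_matrix(panel$genes, panel$genomes,
                               adjacency_bp = config$adjacency_bp)
    fission_rows <- purrr::map_dfr(seq_len(nrow(panel$genomes)), function(ti) {
      purrr::map_dfr(seq_len(nrow(panel$genes)), function(gi) {
        loc <- locate_gene(panel$genes[gi, ], panel$genomes[ti, ])
        if (loc$status[1] == "absent") return(NULL)
        locus <- extract_region(panel$genomes[ti, ],
                                max(1L, loc$start[1] - 100L),
                                min(panel$genomes$length[ti],
                                    loc$end[1] + 100L),
                                strand = loc$strand[1])
        ev <- detect_fission(panel$genes[gi, ], locus,
                             locus_offset = max(1L, loc$start[1] - 100L),
                             adjacency_bp = config$adjacency_bp)
        dplyr::mutate(ev, taxon = panel$genomes$id[ti], .before = 1)
      })
    })
    list(matrix = mat, fissions = fission_rows)
  })
  write_tsv_stable(gene_stage$matrix$gene_matrix,
                   file.path(config$out_dir, "gene_content.tsv"))
  write_tsv_stable(gene_stage$fissions,
                   file.path(config$out_dir, "fission_events.tsv"))

  tree_stage <- stage("copy_tree", {
    scen <- simulate_transfer_scenario(k = 2, rate_multiplier = 5,
                                       n_sites = 1000,
                                       seed = substream_seed(config$seed,
                                                             41L))
    fit <- copy_tree(scen$aln, outgroup = scen$outgroup, model = "k2p",
                     n_boot = 100, seed = substream_seed(config$seed, 42L))
    list(fit = fit, truth = scen$truth,
         events = count_transfer_events(fit),
         rates = rate_acceleration(fit, n_boot = 200,
                                   seed = substream_seed(config$seed, 43L)))
  })
  write_copy_tree(tree_stage$fit, file.path(config$out_dir, "copy_tree.nwk"))
  write_tsv_stable(tree_stage$rates,
                   file.path(config$out_dir, "rate_acceleration.tsv"))

  manifest <- c(unclass(config),
                list(package_version =
                       as.character(utils::packageVersion("organellr")),
                     transfer_events = tree_stage$events$k))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(repeats = repeats, shared = shared_tbl, blocks = blocks,
                 gene_matrix = gene_stage$matrix, fissions = gene_stage$fissions,
                 copy_tree = tree_stage$fit,
                 transfer_events = tree_stage$events,
                 rates = tree_stage$rates,
                 config = config),
            class = "organellr_run")
}

#' @export
print.organellr_run <- function(x, ...) {
  cat("<organellr_run>\n")
  cat("  repeat reports:", nrow(x$repeats), "genomes\n")
  cat("  shared-DNA comparisons:", nrow(x$shared), "\n")
  cat("  transfer blocks:", nrow(x$blocks), "\n")
  cat("  fission events:",
      sum(x$fissions$status == "fissioned", na.rm = TRUE), "\n")
  cat("  inferred transfer events:", x$transfer_events$k, "\n")
  invisible(x)
}
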