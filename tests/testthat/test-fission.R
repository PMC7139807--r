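test_that("in-repo translation agrees with an independent oracle", {
  set.seed(41)
  for (i in 1:20) {
    cds <- simulate_cds(sample(10:100, 1), seed = i)
    expect_identical(translate_dna(cds), bs_translate(cds))
  }
  expect_identical(translate_dna("ATGNNNTAA"), "MX*")
})

test_that("gene models enforce frame and clean translation", {
  cds <- simulate_cds(50, seed = 1)
  gm <- gene_model("g1", cds)
  expect_equal(gm$cds_length, 150L)
  expect_error(gene_model("bad", substr(cds, 1, 149)),
               class = "organellr_gene_error")
  expect_error(gene_model("bad", apply_nonsense(cds, 10)),
               class = "organellr_gene_error")
  expect_error(gene_model("bad", cds, exons = c("ATG", "CCC")),
               class = "organellr_gene_error")
})

test_that("a 59 bp deletion gives frame shift 2, a premature stop and a second ORF", {
  cds <- simulate_cds(120, seed = 11)             # 360 bp
  del_at <- 34L * 3L + 1L                         # start of codon 35
  mutant <- apply_deletion(cds, del_at, 59L)
  locus <- paste0(strrep("ACGTTACG", 30), mutant, strrep("TTGACGTA", 30))
  gm <- gene_model("ccmX", cds)
  ev <- detect_fission(gm, locus)
  expect_equal(ev$status, "fissioned")
  expect_equal(ev$frame_shift, 2L)                # 59 mod 3
  expect_equal(ev$deletion_length, 59L)
  expect_lte(abs(ev$deletion_start -
                 canonical_deletion_start(cds, del_at, 59L)), 1L)
  # premature stop position from an independent translation scan of the
  # target coding region
  aa <- bs_translate(substr(mutant, 1, 3 * (nchar(mutant) %/% 3)))
  stop_cod <- regexpr("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
  expect_equal(ev$premature_stop_pos, 3L * as.integer(stop_cod) - 2L)
  # ORF2 starts at an ATG downstream of the stop and runs to the
  # reference C-terminus without stops
  expect_false(is.na(ev$orf2_start))
  p <- ev$orf2_start_codon_pos
  expect_equal(substr(mutant, p, p + 2), "ATG")
  tail_aa <- translate_dna(substr(mutant, p, nchar(mutant)))
  expect_false(grepl("*", substr(tail_aa, 1, nchar(tail_aa) - 1),
                     fixed = TRUE))
  expect_true(ev$adjacent)
})

test_that("in-frame deletions stay intact; nonsense mutations are pseudogenes", {
  cds <- simulate_cds(120, seed = 12)
  gm <- gene_model("g", cds)
  ev60 <- detect_fission(gm, apply_deletion(cds, 100, 60))
  expect_equal(ev60$status, "intact_with_deletion")
  expect_equal(ev60$frame_shift, 0L)
  expect_equal(detect_fission(gm, cds)$status, "intact")
  expect_equal(detect_fission(gm, apply_nonsense(cds, 40))$status,
               "pseudogene")
})

test_that("frame shifts follow deletion length mod 3 over random genes", {
  set.seed(43)
  n_ok <- 0L
  for (i in 1:25) {
    cds <- simulate_cds(sample(80:150, 1), seed = 100 + i)
    L <- sample(c(1:5, 58:62), 1)
    at <- 3L * sample(20:40, 1) + 1L
    mutant <- apply_deletion(cds, at, L)
    gm <- gene_model(paste0("g", i), cds)
    ev <- detect_fission(gm, paste0(random_dna_str(50), mutant,
                                    random_dna_str(50)))
    if (L %% 3 == 0) {
      expect_equal(ev$status, "intact_with_deletion")
    } else {
      expect_equal(ev$frame_shift, L %% 3L)
      expect_lte(abs(ev$deletion_start - canonical_deletion_start(cds, at, L)), 1L)
      n_ok <- n_ok + 1L
    }
  }
  expect_gt(n_ok, 0L)
})

test_that("unmodified loci never trigger fission calls", {
  set.seed(44)
  for (i in 1:20) {
    cds <- simulate_cds(sample(60:140, 1), seed = 200 + i)
    gm <- gene_model(paste0("g", i), cds)
    locus <- paste0(random_dna_str(80), cds, random_dna_str(80))
    expect_equal(detect_fission(gm, locus)$status, "intact")
  }
})

test_that("single-nucleotide deletion check is the 1 bp special case", {
  cds <- simulate_cds(100, seed = 21)
  v1 <- apply_deletion(cds, 3L * 9L + 1L, 1L)     # remove a base of codon 10
  res <- single_nt_deletion_check(cds, v1)
  expect_equal(nrow(res), 1L)
  expect_equal(res$frame_shift, 1L)
  # premature stop agrees with direct translation of the shifted sequence
  aa <- translate_dna(substr(v1, 1, 3 * (nchar(v1) %/% 3)))
  stop_cod <- regexpr("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
  if (stop_cod > 0) {
    expect_equal(res$premature_stop_pos, 3L * as.integer(stop_cod) - 2L)
  }
  expect_equal(nrow(single_nt_deletion_check(cds, cds)), 0L)
  expect_equal(nrow(single_nt_deletion_check(cds,
                                             apply_deletion(cds, 30, 3))),
               0L)
})

test_that("locate_gene finds planted copies and calls clean deletions absent", {
  set.seed(45)
  cds <- simulate_cds(120, seed = 22)
  target <- paste0(random_dna_str(2000), cds, random_dna_str(2000))
  g <- genome_record("t1", target, compartment = "mitochondrion",
                     topology = "linear")
  gm <- gene_model("g", cds)
  loc <- locate_gene(gm, g)
  expect_equal(loc$status, "found")
  expect_lte(abs(loc$start - 2001L), 3L)
  expect_lte(abs(loc$end - (2000L + nchar(cds))), 3L)
  # complete precise deletion -> absent
  g2 <- genome_record("t2", paste0(random_dna_str(2000),
                                   random_dna_str(2000)),
                      compartment = "mitochondrion", topology = "linear")
  expect_equal(locate_gene(gm, g2)$status, "absent")
  # minus-strand copy is still found
  g3 <- genome_record("t3", paste0(random_dna_str(1000), revcomp(cds),
                                   random_dna_str(1000)),
                      compartment = "mitochondrion", topology = "linear")
  loc3 <- locate_gene(gm, g3)
  expect_equal(loc3$status, "found")
  expect_equal(loc3$strand, "-")
})

test_that("intron status distinguishes loss, presence and shortening", {
  set.seed(46)
  ex1 <- simulate_cds(40, seed = 31)          # 120 bp, used as exon blocks
  ex2 <- substr(simulate_cds(40, seed = 32), 4, 120)  # 117 bp, frame filler
  # build a two-exon gene whose concatenation is a valid CDS
  cds <- simulate_cds(80, seed = 33)          # 240 bp
  e1 <- substr(cds, 1, 120); e2 <- substr(cds, 121, 240)
  gm <- gene_model("gi", cds, exons = c(e1, e2))
  intron <- random_dna_str(300)
  with_intron <- paste0(random_dna_str(500), e1, intron, e2,
                        random_dna_str(500))
  no_intron <- paste0(random_dna_str(500), cds, random_dna_str(500))
  half_intron <- paste0(random_dna_str(500), e1, substr(intron, 1, 150),
                        e2, random_dna_str(500))
  tg <- function(s, id) genome_record(id, s, topology = "linear")
  st1 <- intron_status(gm, tg(with_intron, "a"))
  st2 <- intron_status(gm, tg(no_intron, "b"))
  st3 <- intron_status(gm, tg(half_intron, "c"))
  expect_equal(st1$status, "present")
  expect_equal(st2$status, "lost")
  expect_equal(st3$status, "present")
  # naming: gene + i + CDS position of the last base before the intron
  expect_equal(st1$intron, "gii120")
})

test_that("gene content matrix states one planted event per cell", {
  set.seed(47)
  g1 <- gene_model("gA", simulate_cds(100, seed = 51))
  g2 <- gene_model("gB", simulate_cds(110, seed = 52))
  genes <- dplyr::bind_rows(g1, g2)
  spacer <- function(n) random_dna_str(n)
  mk <- function(id, parts) genome_record(
    id, paste0(spacer(300), paste(vapply(parts, function(p)
      paste0(p, spacer(300)), character(1)), collapse = "")),
    compartment = "mitochondrion", topology = "linear")
  taxa <- dplyr::bind_rows(
    mk("t1", list(g1$cds, g2$cds)),
    mk("t2", list(g1$cds, apply_deletion(g2$cds, 100, 59))),  # fission
    mk("t3", list(g1$cds)),                                   # gB absent
    mk("t4", list(apply_nonsense(g1$cds, 20), g2$cds)))       # gA pseudo
  mat <- gene_content_matrix(genes, taxa)
  states <- tidyr::pivot_wider(mat$genes, names_from = "gene_id",
                               values_from = "state")
  expect_equal(states$gA, c("intact", "intact", "intact", "pseudogene"))
  expect_equal(states$gB, c("intact", "fissioned", "absent", "intact"))
  # empty gene list gives an empty matrix
  empty <- gene_content_matrix(genes[0, ], taxa)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("gene models round-trip through FASTA plus GFF3", {
  skip_if_not_installed("rtracklayer")
  set.seed(48)
  cds <- simulate_cds(60, seed = 61)             # 180 bp
  e1 <- substr(cds, 1, 90); e2 <- substr(cds, 91, 180)
  intron <- random_dna_str(120)
  gseq <- paste0(random_dna_str(200), e1, intron, e2, random_dna_str(200))
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(genome_record("chrT", gseq, topology = "linear"), fa)
  writeLines(c(
    "##gff-version 3",
    paste("chrT", "test", "CDS", 201, 290, ".", "+", "0",
          "ID=cds1;Parent=geneA", sep = "\t"),
    paste("chrT", "test", "CDS", 411, 500, ".", "+", "0",
          "ID=cds2;Parent=geneA", sep = "\t")), gff)
  gm <- read_gene_models(fa, gff)
  expect_equal(nrow(gm), 1L)
  expect_equal(gm$cds, cds)
  expect_equal(gm$exons[[1]], c(e1, e2))
  # minus-strand gene: exons in transcript order, reverse-complemented
  gseq2 <- paste0(random_dna_str(150), revcomp(cds), random_dna_str(150))
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(genome_record("chrU", gseq2, topology = "linear"), fa2)
  writeLines(c(
    "##gff-version 3",
    paste("chrU", "test", "CDS", 151, 150 + nchar(cds), ".", "-", "0",
          "ID=cdsB;Parent=geneB", sep = "\t")), gff2)
  gm2 <- read_gene_models(fa2, gff2)
  expect_equal(gm2$cds, cds)
})
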