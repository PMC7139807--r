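test_that("a planted organelle tract is recovered within 2 percent", {
  mito <- simulate_genome(simulation_recipe("mt", 30000, "mitochondrion",
                                            seed = 5))
  nuc <- simulate_genome(
    simulation_recipe("nuc", 60000, "nucleus", seed = 6,
                      igt_tracts = tibble::tibble(source_id = "mt",
                                                  source_start = 10001,
                                                  source_end = 15000,
                                                  divergence = 0.02)),
    source = mito$genome)
  sd <- shared_dna(mito$genome, nuc$genome)
  expect_lte(abs(sd$merged_total_bp - 5000) / 5000, 0.02)
  expect_gt(sd$stats$mean_identity, 95)
})

test_that("the identity threshold is strict (a hit at 89.9 is excluded)", {
  hits <- tibble::tibble(identity_pct = c(89.9, 90.0, 90.1, 95),
                         length = c(100L, 100L, 100L, 100L))
  kept <- organellr:::filter_hits_identity(hits, 90)
  expect_equal(kept$identity_pct, c(90.1, 95))
})

test_that("empty subject set is rejected", {
  g <- genome_record("mt", random_dna_str(500), compartment = "mitochondrion")
  expect_error(shared_dna(g, g[0, ]), class = "organellr_input_error")
})

test_that("hit statistics match hand values and an independent oracle", {
  one <- tibble::tibble(identity_pct = 95, length = 100L)
  st <- hit_statistics(one)
  expect_equal(unlist(st[c("min_len", "max_len", "mean_len", "median_len")],
                      use.names = FALSE), c(100, 100, 100, 100))
  expect_equal(st$mean_identity, 95.0)

  four <- tibble::tibble(identity_pct = 95,
                         length = c(33L, 93L, 94L, 3950L))
  expect_equal(hit_statistics(four)$median_len, 93.5)

  set.seed(31)
  lens <- round(rlnorm(1000, meanlog = 5, sdlog = 1))
  ids <- runif(1000, 90, 100)
  hits <- tibble::tibble(identity_pct = ids, length = lens)
  st2 <- hit_statistics(hits)
  expect_equal(st2$n, 1000L)
  expect_equal(st2$mean_len, round(sum(lens) / 1000, 1))
  srt <- sort(lens)
  expect_equal(st2$median_len, (srt[500] + srt[501]) / 2)
  expect_equal(st2$mean_identity, round(mean(ids), 1))

  none <- hit_statistics(hits[0, ])
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean_identity))
})

test_that("swapping query and subject preserves hit count but not coverage side", {
  set.seed(32)
  mito <- simulate_genome(simulation_recipe("mt", 20000, "mitochondrion",
                                            seed = 7))
  nuc <- simulate_genome(
    simulation_recipe("nuc", 30000, "nucleus", seed = 8,
                      igt_tracts = tibble::tibble(source_id = "mt",
                                                  source_start = 1001,
                                                  source_end = 4000,
                                                  divergence = 0.02)),
    source = mito$genome)
  ab <- shared_dna(mito$genome, nuc$genome)
  ba <- shared_dna(nuc$genome, mito$genome)
  expect_equal(ab$stats$n, ba$stats$n)
  # coverage is query-side: sides differ in genome length hence context
  expect_equal(ab$merged_total_bp, ba$merged_total_bp, tolerance = 0.05)
})

test_that("planted mitochondrial tracts carry organelle-like GC against nuclear background", {
  mito <- simulate_genome(simulation_recipe("mt", 30000, "mitochondrion",
                                            seed = 9))   # GC 45
  nuc <- simulate_genome(
    simulation_recipe("nuc", 60000, "nucleus", seed = 10,  # GC 33
                      igt_tracts = tibble::tibble(source_id = "mt",
                                                  source_start = 5001,
                                                  source_end = 11000,
                                                  divergence = 0.02)),
    source = mito$genome)
  sd <- shared_dna(mito$genome, nuc$genome)
  expect_gt(sd$shared_gc_pct, 40)
  expect_gt(sd$shared_gc_pct, gc_content(nuc$genome) + 5)
})

test_that("raising min_identity never adds hits or coverage", {
  mito <- simulate_genome(simulation_recipe("mt", 20000, "mitochondrion",
                                            seed = 11))
  nuc <- simulate_genome(
    simulation_recipe("nuc", 40000, "nucleus", seed = 12,
                      igt_tracts = tibble::tibble(
                        source_id = "mt",
                        source_start = c(1001, 8001),
                        source_end = c(3000, 10000),
                        divergence = c(0.02, 0.08))),
    source = mito$genome)
  lo <- shared_dna(mito$genome, nuc$genome, min_identity = 80)
  hi <- shared_dna(mito$genome, nuc$genome, min_identity = 95)
  expect_lte(hi$stats$n, lo$stats$n)
  expect_lte(hi$merged_total_bp, lo$merged_total_bp)
})

test_that("a 150 kb planted tract yields exactly one block above 100 kb", {
  mito <- simulate_genome(simulation_recipe("MT", 160000, "mitochondrion",
                                            seed = 13))
  nuc <- simulate_genome(
    simulation_recipe("chr1", 400000, "nucleus", seed = 14,
                      igt_tracts = tibble::tibble(source_id = "MT",
                                                  source_start = 2001,
                                                  source_end = 152000,
                                                  divergence = 0.03)),
    source = mito$genome)
  bl <- find_igt_blocks(mito$genome, nuc$genome)
  expect_equal(nrow(bl), 1L)
  expect_lte(abs(bl$span_kb - 150) / 150, 0.05)
  expect_equal(bl$max_gap_bp, 10000)
  expect_gt(bl$block_gc_pct, 40)     # organelle GC, not nuclear background
  expect_gt(bl$organelle_coverage_fraction, 0.9)
})

test_that("an isolated small hit does not form a block", {
  mito <- simulate_genome(simulation_recipe("mt", 20000, "mitochondrion",
                                            seed = 15))
  nuc <- simulate_genome(
    simulation_recipe("nuc", 50000, "nucleus", seed = 16,
                      igt_tracts = tibble::tibble(source_id = "mt",
                                                  source_start = 1001,
                                                  source_end = 3000,
                                                  divergence = 0.02)),
    source = mito$genome)
  bl <- find_igt_blocks(mito$genome, nuc$genome, min_span_kb = 100)
  expect_equal(nrow(bl), 0L)
})

test_that("glance/tidy expose the shared-DNA table row and hits", {
  mito <- simulate_genome(simulation_recipe("mt", 20000, "mitochondrion",
                                            seed = 17))
  nuc <- simulate_genome(
    simulation_recipe("nuc", 30000, "nucleus", seed = 18,
                      igt_tracts = tibble::tibble(source_id = "mt",
                                                  source_start = 1001,
                                                  source_end = 2500,
                                                  divergence = 0.02)),
    source = mito$genome)
  sd <- shared_dna(mito$genome, nuc$genome)
  gl <- glance(sd)
  expect_true(all(c("n", "mean_identity", "median_len", "merged_total_kb")
                  %in% names(gl)))
  expect_equal(gl$merged_total_kb, round(sd$merged_total_bp / 1000, 1))
  expect_s3_class(tidy(sd), "tbl_df")
})
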