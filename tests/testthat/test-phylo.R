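test_that("pairwise distances match the model formulas", {
  expect_equal(pairwise_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # p = 0.10 under Jukes-Cantor
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 90), rep("G", 10)), collapse = "")
  expect_equal(pairwise_distance(a, b, "jc"), -0.75 * log(1 - 0.4 / 3))
  # per-site counting oracle for K2P: 6 transitions, 4 transversions / 100
  x <- paste(c(rep("A", 90), rep("A", 10)), collapse = "")
  y <- paste(c(rep("A", 90), rep("G", 6), rep("C", 4)), collapse = "")
  P <- 0.06; Q <- 0.04
  expect_equal(pairwise_distance(x, y, "k2p"),
               0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q)))
  # saturation flagged as infinite
  z1 <- paste(rep("A", 10), collapse = "")
  z2 <- paste(rep("C", 10), collapse = "")
  expect_equal(pairwise_distance(z1, z2, "jc"), Inf)
  # all-gap overlap is an error
  expect_error(pairwise_distance("---A", "A---"),
               class = "organellr_alignment_error")
})

test_that("gap columns are pairwise-deleted", {
  d <- pairwise_distance("AC-TA", "ACGTA")
  expect_equal(d, 0)                     # gap column dropped, rest identical
  d2 <- pairwise_distance("AC-TT", "ACGTA")
  expect_equal(d2, pairwise_distance("ACTT", "ACTA"))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(61)
  for (t in 1:10) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- tr$edge.length + 0.1
    D <- stats::cophenetic(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    fit <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), fit), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(stats::cophenetic(fit)[rownames(D), colnames(D)] - D)),
              1e-8)
    # cross-check against an independent NJ implementation
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(ref, fit), 0, ignore_attr = TRUE)
  }
})

test_that("degenerate matrices are handled deterministically", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
  # three taxa resolve as the unique star
  D3 <- D[1:3, 1:3]
  tr3 <- neighbor_joining(D3)
  expect_equal(length(tr3$tip.label), 3L)
  expect_equal(tr3$Nnode, 1L)
  # invalid inputs
  Dbad <- D; Dbad[1, 2] <- Inf
  expect_error(neighbor_joining(Dbad), class = "organellr_alignment_error")
})

test_that("transfer events count maximal nuclear clades on the rooted tree", {
  # hand-built tree: nuclear copies monophyletic -> k = 1
  txt <- "((Gmax_m:1,Mpinnata_m:1):1,((A_m:1,B_m:1):1,(A_n:2,B_n:2):1):1);"
  tr <- ape::read.tree(text = txt)
  labels <- tibble::tibble(
    label = c("Gmax_m", "Mpinnata_m", "A_m", "B_m", "A_n", "B_n"),
    compartment = c("mitochondrial", "mitochondrial", "mitochondrial",
                    "mitochondrial", "nuclear", "nuclear"))
  rooted <- ape::root(tr, c("Gmax_m", "Mpinnata_m"), resolve.root = TRUE)
  ev <- count_transfer_events(rooted, labels)
  expect_equal(ev$k, 1L)
  expect_setequal(ev$clades[[1]], c("A_n", "B_n"))
  # two separate nuclear placements -> k = 2
  txt2 <- "((Gmax_m:1,Mpinnata_m:1):1,((L_n:2,(A_m:1,B_m:1):1):1,(A_n:2,B_n:2):1):1);"
  tr2 <- ape::read.tree(text = txt2)
  labels2 <- dplyr::bind_rows(labels,
                              tibble::tibble(label = "L_n",
                                             compartment = "nuclear"))
  rooted2 <- ape::root(tr2, c("Gmax_m", "Mpinnata_m"), resolve.root = TRUE)
  expect_equal(count_transfer_events(rooted2, labels2)$k, 2L)
})

test_that("transfer counting is invariant to leaf order permutation", {
  set.seed(63)
  sc <- simulate_transfer_scenario(k = 2, rate_multiplier = 5,
                                   n_sites = 800, seed = 17)
  base <- copy_tree(sc$aln, outgroup = sc$outgroup, model = "jc", n_boot = 0)
  k0 <- count_transfer_events(base)$k
  for (r in 1:3) {
    perm <- sc$aln[sample(nrow(sc$aln)), ]
    fit <- copy_tree(perm, outgroup = sc$outgroup, model = "jc", n_boot = 0)
    expect_equal(count_transfer_events(fit)$k, k0)
  }
})

test_that("simulated transfer histories are recovered end to end", {
  for (k in 1:2) {
    hits <- 0L
    for (s in 1:8) {
      sc <- simulate_transfer_scenario(k = k, rate_multiplier = 5,
                                       n_sites = 1000, seed = s)
      fit <- copy_tree(sc$aln, outgroup = sc$outgroup, model = "jc",
                       n_boot = 0)
      if (count_transfer_events(fit)$k == k) hits <- hits + 1L
    }
    expect_gte(hits, 7L)
  }
  expect_error(simulate_transfer_scenario(k = 9),
               class = "organellr_input_error")
})

test_that("rate acceleration tracks the simulated multiplier and the null", {
  sc <- simulate_transfer_scenario(k = 1, rate_multiplier = 5,
                                   n_sites = 1000, seed = 42)
  fit <- copy_tree(sc$aln, outgroup = sc$outgroup, model = "jc", n_boot = 0)
  ra <- rate_acceleration(fit, n_boot = 100, seed = 1)
  expect_gte(ra$ratio, 3)
  expect_lte(ra$ratio, 7)
  sc0 <- simulate_transfer_scenario(k = 1, rate_multiplier = 1,
                                    n_sites = 1000, seed = 42)
  fit0 <- copy_tree(sc0$aln, outgroup = sc0$outgroup, model = "jc",
                    n_boot = 0)
  ra0 <- rate_acceleration(fit0, n_boot = 100, seed = 1)
  # equal rates: ratio near one (nuclear tips sit slightly deeper in the
  # default topology, so the neutral expectation is just above 1)
  expect_gt(ra0$ratio, 0.75)
  expect_lt(ra0$ratio, 1.35)
  expect_lt(ra0$ci_lower, ra0$ratio)
  expect_gt(ra0$ci_upper, ra0$ratio)
})

test_that("bootstrap support is reproducible under a fixed seed", {
  sc <- simulate_transfer_scenario(k = 1, rate_multiplier = 5,
                                   n_sites = 500, seed = 3)
  f1 <- copy_tree(sc$aln, outgroup = sc$outgroup, model = "jc",
                  n_boot = 40, seed = 9)
  f2 <- copy_tree(sc$aln, outgroup = sc$outgroup, model = "jc",
                  n_boot = 40, seed = 9)
  expect_identical(f1$support, f2$support)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
})

test_that("outgroup must be present and alignments must be rectangular", {
  sc <- simulate_transfer_scenario(k = 1, n_sites = 200, seed = 4)
  expect_error(copy_tree(sc$aln, outgroup = "NotATaxon"),
               class = "organellr_outgroup_error")
  expect_error(copy_alignment(c("a", "b"),
                              c("nuclear", "mitochondrial"),
                              c("ACGT", "ACG")),
               class = "organellr_alignment_error")
})

test_that("copy alignments round-trip through FASTA with labeled headers", {
  sc <- simulate_transfer_scenario(k = 1, n_sites = 100, seed = 5)
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(paste0(">", sc$aln$label, "\n", sc$aln$sequence), f)
  back <- read_copy_alignment(f)
  expect_equal(back$taxon, sc$aln$taxon)
  expect_equal(back$compartment, sc$aln$compartment)
  expect_equal(back$sequence, sc$aln$sequence)
})

test_that("newick export carries bootstrap support values", {
  sc <- simulate_transfer_scenario(k = 1, n_sites = 300, seed = 6)
  fit <- copy_tree(sc$aln, outgroup = sc$outgroup, n_boot = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_copy_tree(fit, f)
  reread <- ape::read.tree(f)
  expect_false(is.null(reread$node.label))
  gl <- glance(fit)
  expect_equal(gl$n_copies, nrow(sc$aln))
  expect_s3_class(tidy(fit), "tbl_df")
})
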