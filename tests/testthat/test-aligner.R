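test_that("scoring schemes validate and presets carry the documented words", {
  s7 <- scoring_scheme("sensitive")
  expect_equal(s7$word_size, 7L)
  expect_equal(c(s7$match, s7$mismatch), c(2L, -3L))
  s28 <- scoring_scheme("fast")
  expect_equal(s28$word_size, 28L)
  expect_error(scoring_scheme(NULL, match = 1, mismatch = 1),
               class = "organellr_scheme_error")
  # expected score per pair must be negative: +3/-1 at uniform freqs is
  # degenerate (0.25*3 - 0.75*1 = 0)
  expect_error(scoring_scheme(NULL, match = 3, mismatch = -1),
               class = "organellr_scheme_error")
})

test_that("lambda solves the Karlin-Altschul equation (root-finder oracle)", {
  for (pm in list(c(1, -2), c(2, -3), c(1, -3))) {
    sch <- scoring_scheme(NULL, match = pm[1], mismatch = pm[2])
    p_match <- 0.25
    resid <- p_match * exp(sch$lambda * pm[1]) +
      (1 - p_match) * exp(sch$lambda * pm[2]) - 1
    expect_lt(abs(resid), 1e-9)
    expect_gt(sch$lambda, 0)
  }
  # independent bisection oracle for +1/-2
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lam <- uniroot(f, c(1e-9, 5), tol = 1e-12)$root
  expect_equal(scoring_scheme(NULL, match = 1, mismatch = -2)$lambda, lam,
               tolerance = 1e-9)
})

test_that("E-value is linear in lengths, monotone in score, K m n at score 0", {
  sch <- scoring_scheme("sensitive")
  expect_equal(evalue(50, 1000, 4000, sch), 2 * evalue(50, 1000, 2000, sch))
  expect_equal(evalue(50, 4000, 1000, sch), 2 * evalue(50, 2000, 1000, sch))
  expect_gt(evalue(40, 1000, 1000, sch), evalue(41, 1000, 1000, sch))
  expect_equal(evalue(0, 300, 700, sch), sch$K * 300 * 700)
})

test_that("engine equals the Smith-Waterman oracle on homologous pairs", {
  set.seed(101)
  sch <- scoring_scheme("sensitive", evalue_cutoff = Inf)
  for (t in 1:40) {
    p <- homologous_pair(sample(50:300, 1), sample(50:300, 1))
    gx <- genome_record("x", p$x, topology = "linear")
    gy <- genome_record("y", p$y, topology = "linear")
    h <- align_pair(gx, gy, sch)
    eng <- if (nrow(h) > 0) max(h$score) else 0
    expect_equal(eng, sw_best_score(p$x, p$y))
  }
})

test_that("identical sequences give one full-length perfect hit (fast preset)", {
  set.seed(5)
  s <- random_dna_str(500)
  g <- genome_record("a", s, topology = "linear")
  h <- align_pair(g, g, scoring_scheme("fast"))
  expect_equal(h$qstart[1], 1L)
  expect_equal(h$qend[1], 500L)
  expect_equal(h$sstart[1], 1L)
  expect_equal(h$send[1], 500L)
  expect_equal(h$identity_pct[1], 100)
})

test_that("one internal mismatch on 60 bp yields the hand-computed hit", {
  set.seed(9)
  x <- random_dna_str(60)
  y <- x
  substr(y, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                               substr(x, 30, 30))[1]
  sch <- scoring_scheme("sensitive", evalue_cutoff = Inf)
  h <- align_pair(genome_record("x", x, topology = "linear"),
                  genome_record("y", y, topology = "linear"), sch)
  top <- h[1, ]
  expect_equal(top$score, 59L * 2L - 3L)              # 115
  expect_equal(top$identity_pct, round(100 * 59 / 60, 1))  # 98.3
  expect_equal(top$length, 60L)
})

test_that("no shared word means no hits", {
  g1 <- genome_record("a", strrep("A", 60), topology = "linear")
  g2 <- genome_record("b", strrep("C", 60), topology = "linear")
  h <- align_pair(g1, g2, scoring_scheme("sensitive", evalue_cutoff = Inf))
  expect_equal(nrow(h), 0L)
})

test_that("align_pair is mirror-symmetric in query and subject", {
  set.seed(33)
  sch <- scoring_scheme("sensitive", evalue_cutoff = Inf)
  for (t in 1:8) {
    x <- random_dna_str(300)
    y <- mutate_str(x, 0.05)
    h1 <- align_pair(genome_record("x", x, topology = "linear"),
                     genome_record("y", y, topology = "linear"), sch)
    h2 <- align_pair(genome_record("y", y, topology = "linear"),
                     genome_record("x", x, topology = "linear"), sch)
    k1 <- paste(h1$qstart, h1$qend, h1$sstart, h1$send, h1$strand)
    # BLAST convention keeps qstart < qend; minus-strand hits transpose to
    # (send, sstart, qend, qstart)
    k2 <- ifelse(h2$strand == "+",
                 paste(h2$sstart, h2$send, h2$qstart, h2$qend, h2$strand),
                 paste(h2$send, h2$sstart, h2$qend, h2$qstart, h2$strand))
    expect_setequal(k1, k2)
  }
})

test_that("retained E-values respect the cutoff and tightening removes hits", {
  set.seed(55)
  x <- random_dna_str(2000)
  y <- paste0(random_dna_str(500), mutate_str(substr(x, 501, 1500), 0.08),
              random_dna_str(500))
  gx <- genome_record("x", x, topology = "linear")
  gy <- genome_record("y", y, topology = "linear")
  loose <- align_pair(gx, gy, scoring_scheme("sensitive", evalue_cutoff = 10))
  tight <- align_pair(gx, gy, scoring_scheme("sensitive",
                                             evalue_cutoff = 1e-10))
  expect_true(all(loose$evalue <= 10))
  expect_true(all(tight$evalue <= 1e-10))
  expect_lte(nrow(tight), nrow(loose))
  keys <- function(h) paste(h$qstart, h$qend, h$sstart, h$send, h$strand)
  expect_true(all(keys(tight) %in% keys(loose)))
})

test_that("self_align reports planted duplicates in both orientations", {
  set.seed(77)
  bg <- random_dna_str(10000)
  seg <- substr(bg, 2001, 2200)
  g <- genome_record("g", paste0(substr(bg, 1, 6000), seg,
                                 substr(bg, 6201, 10000)),
                     topology = "linear")
  hits <- self_align(g)
  expect_equal(nrow(hits), 2L)
  expect_setequal(paste(hits$qstart, hits$qend, hits$sstart, hits$send),
                  c("2001 2200 6001 6200", "6001 6200 2001 2200"))
  expect_true(all(hits$strand == "+"))
})

test_that("self_align of repeat-free sequence is empty and excludes the trivial diagonal", {
  set.seed(88)
  g <- genome_record("g", random_dna_str(5000), topology = "linear")
  hits <- self_align(g)
  expect_equal(nrow(hits), 0L)
  expect_error(self_align(g, min_len = 3L), class = "organellr_scheme_error")
})

test_that("a palindromic insert yields a single minus-strand self-hit", {
  set.seed(99)
  half <- random_dna_str(100)
  g <- genome_record("p", paste0(random_dna_str(2000), half, revcomp(half),
                                 random_dna_str(2000)),
                     topology = "linear")
  hits <- self_align(g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  # the hit covers the 200 bp palindrome (alignment end slack allowed)
  expect_lte(abs(hits$qstart - 2001L), 5L)
  expect_lte(abs(pmax(hits$sstart, hits$send) - 2200L), 5L)
})

test_that("hit TSV export has the 12 standard columns", {
  set.seed(12)
  s <- random_dna_str(400)
  g <- genome_record("a", s, topology = "linear")
  h <- align_pair(g, g, scoring_scheme("fast"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  raw <- read.table(f, sep = "\t")
  expect_equal(ncol(raw), 12L)
  expect_equal(raw$V1[1], "a")
})
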