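#' Build a labeled gene-copy alignment
#'
#' A copy alignment holds aligned sequences of the mitochondrial and
#' nuclear copies of a gene, each labeled with its taxon, compartment and
#' (optionally) chromosome.  Labels follow the
#' `taxon|compartment|chromosome` convention used in FASTA headers.
#'
#' @param taxon,compartment,sequence Character vectors of equal length;
#'   `compartment` values must be `"mitochondrial"` or `"nuclear"`.
#' @param chromosome Optional chromosome labels (multiple nuclear copies
#'   per genome stay distinct leaves).
#' @return Tibble with `label`, `taxon`, `compartment`, `chromosome`,
#'   `sequence` (aligned, equal lengths).
#' @export
copy_alignment <- function(taxon, compartment, sequence, chromosome = NA) {
  stopifnot(length(taxon) == length(compartment),
            length(taxon) == length(sequence))
  compartment <- match.arg(compartment, c("mitochondrial", "nuclear"),
                           several.ok = TRUE)
  widths <- nchar(sequence)
  if (length(unique(widths)) != 1L) {
    rlang::abort("aligned sequences must have equal lengths",
                 class = "organellr_alignment_error")
  }
  chromosome <- rep_len(as.character(chromosome), length(taxon))
  label <- ifelse(is.na(chromosome),
                  paste(taxon, compartment, sep = "|"),
                  paste(taxon, compartment, chromosome, sep = "|"))
  if (anyDuplicated(label)) {
    rlang::abort("duplicate copy labels", class = "organellr_alignment_error")
  }
  tibble::tibble(label = label, taxon = taxon, compartment = compartment,
                 chromosome = chromosome,
                 sequence = toupper(sequence))
}

#' Read a copy alignment from FASTA
#'
#' Headers are parsed as `taxon|compartment|chromosome` (chromosome
#' optional).
#'
#' @param path FASTA path (aligned sequences; `-` allowed).
#' @return A copy alignment tibble, see [copy_alignment()].
#' @export
read_copy_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- stringr::str_split_fixed(names(set), stringr::fixed("|"), 3)
  copy_alignment(taxon = parts[, 1],
                 compartment = parts[, 2],
                 sequence = unname(as.character(set)),
                 chromosome = ifelse(nzchar(parts[, 3]), parts[, 3], NA))
}

#' Pairwise evolutionary distance between two aligned sequences
#'
#' Gap columns are pairwise-deleted before counting differences.  Under
#' Jukes-Cantor, `d = -(3/4) log(1 - (4/3) p)` with `p` the proportion of
#' differing sites; under Kimura two-parameter, transitions and
#' transversions are corrected separately.  Saturated pairs (logarithm
#' argument at or below zero) are flagged with an infinite distance.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @param model `"jc"` or `"k2p"`.
#' @return Substitutions per site (possibly `Inf`).
#' @examples
#' pairwise_distance("ACGTACGTAC", "ACGTACGTAC")        # 0
#' @export
pairwise_distance <- function(seq_a, seq_b, model = c("jc", "k2p")) {
  model <- match.arg(model)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    rlang::abort("no comparable (gap-free, unambiguous) sites",
                 class = "organellr_alignment_error")
  }
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (model == "jc") {
    p <- mean(a != b)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(Inf)
    return(-0.75 * log(arg))
  }
  purine <- c("A", "G")
  transition <- (a != b) &
    ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(a != b) / n - P
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(Inf)
  0.5 * log(1 / a1) + 0.25 * log(1 / a2)
}

#' Distance matrix over a copy alignment
#'
#' Columns with more than `max_gap_frac` gaps are dropped first; the rest
#' go through [pairwise_distance()] with pairwise deletion.
#'
#' @param aln Copy alignment tibble.
#' @param model `"jc"` or `"k2p"`.
#' @param max_gap_frac Columns gappier than this are removed (default 0.5).
#' @return Symmetric labeled distance matrix.
#' @export
distance_matrix <- function(aln, model = c("jc", "k2p"),
                            max_gap_frac = 0.5) {
  model <- match.arg(model)
  seqs <- drop_gappy_columns(aln$sequence, max_gap_frac)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(aln$label, aln$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- pairwise_distance(seqs[i], seqs[j], model)
    }
  }
  D
}

drop_gappy_columns <- function(seqs, max_gap_frac) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  gapfrac <- colMeans(m == "-" | m == ".")
  keep <- gapfrac <= max_gap_frac
  apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration implemented in-repo with a
#' deterministic tie-break (the joinable pair with the lexicographically
#' smallest representative labels wins).  Negative branch lengths are
#' clamped to zero with the deficit moved to the sister edge.  On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D Symmetric distance matrix with zero diagonal and labeled
#'   dimnames; all entries finite.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (any(!is.finite(D))) {
    rlang::abort("non-finite distances (saturated pairs?)",
                 class = "organellr_alignment_error")
  }
  if (max(abs(D - t(D))) > 1e-9 || any(abs(diag(D)) > 1e-12)) {
    rlang::abort("distance matrix must be symmetric with zero diagonal",
                 class = "organellr_alignment_error")
  }
  labs <- rownames(D)
  n <- nrow(D)
  stopifnot(n >= 3)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  # active clusters: newick fragment + representative label
  nwk <- labs
  rep_lab <- labs
  act <- seq_len(n)
  Dw <- D
  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(Dw[act, act])
    Q <- (m - 2) * Dw[act, act] - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(rep_lab[act[cand[, 1]]], rep_lab[act[cand[, 2]]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    ai <- act[i]; aj <- act[j]
    dij <- Dw[ai, aj]
    li <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- paste0("(", nwk[ai], ":", fmt(li), ",",
                      nwk[aj], ":", fmt(lj), ")")
    # distances from the new node
    rest <- setdiff(act, c(ai, aj))
    dnew <- 0.5 * (Dw[ai, rest] + Dw[aj, rest] - dij)
    Dw[ai, rest] <- dnew; Dw[rest, ai] <- dnew
    nwk[ai] <- new_nwk
    rep_lab[ai] <- min(rep_lab[ai], rep_lab[aj])
    act <- setdiff(act, aj)
  }
  a <- act[1]; b <- act[2]; c <- act[3]
  la <- 0.5 * (Dw[a, b] + Dw[a, c] - Dw[b, c])
  lb <- 0.5 * (Dw[a, b] + Dw[b, c] - Dw[a, c])
  lc <- 0.5 * (Dw[a, c] + Dw[b, c] - Dw[a, b])
  txt <- paste0("(", nwk[a], ":", fmt(la), ",", nwk[b], ":", fmt(lb), ",",
                nwk[c], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

#' Fit a gene-copy phylogeny
#'
#' Distance-based inference over a labeled copy alignment: model-corrected
#' distances, in-repo neighbor joining, rooting on the outgroup taxa, and
#' bootstrap support by column resampling.  The resulting tree feeds
#' [count_transfer_events()] and [rate_acceleration()].
#'
#' @param aln Copy alignment tibble (at least 4 sequences).
#' @param outgroup Character vector of outgroup taxon names.
#' @param model Distance model, `"jc"` or `"k2p"`.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Seed for the bootstrap resampling.
#' @return A `copy_tree` object: rooted `phylo` tree with bootstrap node
#'   support, the alignment, and the leaf labeling.
#' @export
copy_tree <- function(aln, outgroup, model = c("jc", "k2p"),
                      n_boot = 100L, seed = 1L) {
  model <- match.arg(model)
  if (nrow(aln) < 4L) {
    rlang::abort("need at least 4 sequences for tree building",
                 class = "organellr_alignment_error")
  }
  og_labels <- aln$label[aln$taxon %in% outgroup]
  if (length(og_labels) == 0L) {
    rlang::abort("outgroup absent from alignment",
                 class = "organellr_outgroup_error")
  }
  tree <- neighbor_joining(distance_matrix(aln, model))
  rooted <- ape::root(tree, outgroup = og_labels, resolve.root = TRUE)
  boot <- NULL
  support <- NULL
  if (n_boot > 0L) {
    ncol_aln <- nchar(aln$sequence[1])
    boot_one <- function(cols) {
      b <- aln
      b$sequence <- vapply(strsplit(b$sequence, ""), function(ch)
        paste(ch[cols], collapse = ""), character(1))
      neighbor_joining(distance_matrix(b, model))
    }
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    boot <- lapply(seq_len(n_boot), function(i)
      boot_one(sample.int(ncol_aln, ncol_aln, replace = TRUE)))
    counts <- ape::prop.clades(rooted, boot, rooted = FALSE)
    support <- round(100 * counts / n_boot)
  }
  structure(list(tree = rooted, unrooted = tree, aln = aln,
                 outgroup = outgroup, model = model,
                 n_boot = n_boot, seed = seed, support = support),
            class = "copy_tree")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.copy_tree <- function(x, ...) {
  cat(sprintf("<copy_tree> %d copies (%d nuclear), model %s, %d bootstraps\n",
              nrow(x$aln), sum(x$aln$compartment == "nuclear"),
              x$model, x$n_boot))
  ev <- count_transfer_events(x)
  cat(sprintf("  inferred transfer events: %d\n", ev$k))
  invisible(x)
}

#' Count organelle-to-nucleus transfer events on a copy tree
#'
#' On the rooted tree, nuclear leaves descend from one or more maximal
#' nuclear-only clades; the number of such clades is the minimum number
#' of mitochondrial-to-nuclear transitions (Fitch-style) and hence the
#' minimum number of independent functional transfer events consistent
#' with the tree.  One clade = a single ancestral transfer; two or more =
#' repeated independent transfers.
#'
#' @param x A `copy_tree`, or a rooted `phylo` tree.
#' @param labels When `x` is a `phylo`: tibble with `label` and
#'   `compartment` columns.
#' @return List with `k` (event count) and `clades` (list of member
#'   labels per transfer clade).
#' @export
count_transfer_events <- function(x, labels = NULL) {
  if (inherits(x, "copy_tree")) {
    tree <- x$tree
    labels <- x$aln[, c("label", "compartment")]
  } else {
    tree <- x
    stopifnot(!is.null(labels))
  }
  comp <- stats::setNames(labels$compartment, labels$label)
  tips <- tree$tip.label
  is_nuc <- comp[tips] == "nuclear"
  ntip <- length(tips)
  if (!any(is_nuc)) return(list(k = 0L, clades = list()))
  # pure[v]: all descendant tips of v are nuclear (postorder accumulation)
  nnode <- tree$Nnode
  pure <- logical(ntip + nnode)
  pure[seq_len(ntip)] <- is_nuc
  po <- ape::reorder.phylo(tree, "postorder")
  agg <- rep(TRUE, ntip + nnode)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    val <- if (child <= ntip) pure[child] else agg[child]
    agg[par] <- agg[par] & val
  }
  pure[(ntip + 1):(ntip + nnode)] <- agg[(ntip + 1):(ntip + nnode)]
  # maximal pure vertices: pure, with non-pure parent (or the root)
  parent <- integer(ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  root <- ntip + 1L
  maximal <- which(pure & (seq_len(ntip + nnode) == root |
                             !pure[pmax(parent, 1L)] | parent == 0L))
  # collect member tips per maximal clade
  clades <- lapply(maximal, function(v) {
    if (v <= ntip) return(tips[v])
    desc <- ape::extract.clade(tree, v)$tip.label
    desc
  })
  list(k = length(clades), clades = clades)
}

#' Substitution-rate acceleration of nuclear copies
#'
#' Ratio of mean root-to-tip path length of nuclear leaves to that of
#' mitochondrial leaves on the rooted copy tree, with a bootstrap
#' percentile interval obtained by column resampling.  Outgroup leaves
#' are excluded from both classes by default.  A ratio near 1 means equal
#' rates; ratios well above 1 are the signature of accelerated nuclear
#' substitution after functional transfer.
#'
#' @param x A `copy_tree`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @param include_outgroup Keep outgroup leaves in the mitochondrial
#'   class.
#' @return One-row tibble: `ratio`, `ci_lower`, `ci_upper`, `n_nuclear`,
#'   `n_mitochondrial`, `flagged` (TRUE when either class has a single
#'   leaf).
#' @export
rate_acceleration <- function(x, n_boot = 1000L, seed = 1L,
                              include_outgroup = FALSE) {
  stopifnot(inherits(x, "copy_tree"))
  aln <- x$aln
  ratio_of <- function(tree) {
    depth <- ape::node.depth.edgelength(tree)
    tips <- tree$tip.label
    d <- depth[seq_along(tips)]
    keep <- rep(TRUE, length(tips))
    if (!include_outgroup) {
      og <- aln$label[aln$taxon %in% x$outgroup]
      keep <- !(tips %in% og)
    }
    comp <- stats::setNames(aln$compartment, aln$label)[tips]
    nuc <- keep & comp == "nuclear"
    mit <- keep & comp == "mitochondrial"
    if (!any(nuc) || !any(mit)) {
      rlang::abort("a compartment class has zero leaves",
                   class = "organellr_alignment_error")
    }
    mean(d[nuc]) / mean(d[mit])
  }
  est <- ratio_of(x$tree)
  og_labels <- aln$label[aln$taxon %in% x$outgroup]
  ncol_aln <- nchar(aln$sequence[1])
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    b <- aln
    b$sequence <- vapply(strsplit(b$sequence, ""), function(ch)
      paste(ch[cols], collapse = ""), character(1))
    tr <- tryCatch(
      ape::root(neighbor_joining(distance_matrix(b, x$model)),
                outgroup = og_labels, resolve.root = TRUE),
      error = function(e) NULL)
    if (is.null(tr)) return(NA_real_)
    tryCatch(ratio_of(tr), error = function(e) NA_real_)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  n_nuc <- sum(aln$compartment == "nuclear" & !(aln$label %in% og_labels))
  n_mit <- sum(aln$compartment == "mitochondrial" &
                 !(aln$label %in% og_labels))
  tibble::tibble(ratio = est, ci_lower = ci[1], ci_upper = ci[2],
                 n_nuclear = n_nuc, n_mitochondrial = n_mit,
                 flagged = n_nuc == 1L || n_mit == 1L)
}

#' Tidy the edges of a fitted copy tree
#'
#' @param x A `copy_tree`.
#' @param ... Unused.
#' @return Tibble of edges with branch lengths.
#' @export
tidy.copy_tree <- function(x, ...) {
  tr <- x$tree
  tibble::tibble(parent = tr$edge[, 1], child = tr$edge[, 2],
                 length = tr$edge.length,
                 child_label = ifelse(tr$edge[, 2] <= length(tr$tip.label),
                                      tr$tip.label[tr$edge[, 2]],
                                      NA_character_))
}

#' One-row summary of a fitted copy tree
#'
#' @param x A `copy_tree`.
#' @param ... Unused.
#' @return One-row tibble with copy counts, the inferred transfer-event
#'   count and the rate-acceleration point estimate.
#' @export
glance.copy_tree <- function(x, ...) {
  ev <- count_transfer_events(x)
  tibble::tibble(n_copies = nrow(x$aln),
                 n_nuclear = sum(x$aln$compartment == "nuclear"),
                 model = x$model,
                 k_transfers = ev$k,
                 n_boot = x$n_boot)
}

#' Write a copy tree to Newick
#'
#' Bootstrap support values (when present) are written as node labels.
#'
#' @param x A `copy_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_copy_tree <- function(x, path) {
  tr <- x$tree
  if (!is.null(x$support)) {
    tr$node.label <- as.character(x$support)
    tr$node.label[is.na(tr$node.label)] <- ""
  }
  ape::write.tree(tr, file = path)
  invisible(path)
}
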