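---
title: "Methods: repeats, intracellular gene transfer, gene fission and copy phylogenies"
author: "organellr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeats, intracellular gene transfer, gene fission and copy phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellr)
```

# Scope and model

Plant cells carry three genomes — nuclear, mitochondrial and plastid —
that exchange DNA throughout their history.  `organellr` implements the
comparative analyses that characterize that exchange and the fate of
mitochondrial genes: how repetitive each organelle genome is, how much
DNA the compartments share (intracellular gene transfer, IGT; nuclear
copies of organelle DNA are called NUMTs/NUPTs), whether a gene has
been lost, pseudogenized, or split into two open reading frames by a
frameshifting deletion (gene fission), and whether functional transfers
of a gene to the nucleus happened once or repeatedly, read off a
phylogeny of its mitochondrial and nuclear copies.

Every stage operates on tibbles and every stochastic stage is seeded, so
a full analysis is reproducible byte for byte.  A simulation module
generates genomes and gene-copy alignments with exact planted truth;
the test suite scores each detector against that truth.

# The local aligner

All sequence searches run on an in-package seed-and-extend local
aligner.  Exact words of length $k$ seed gapped extensions terminated by
an x-drop rule; a gap of length $L$ costs `gap_open + L * gap_extend`.
Two presets mirror the two search regimes used throughout:

| preset      | word | match/mismatch | gap open/extend | used for |
|-------------|------|----------------|-----------------|----------|
| `sensitive` | 7    | +2 / −3        | 5 / 2           | dispersed repeats, gene location |
| `fast`      | 28   | +2 / −4        | 0 / 5           | inter-compartment shared DNA |

The `fast` scores are the classical megablast +1/−2 with gap extension
2.5, doubled to stay on integers; doubling rescales $\lambda$ by one
half and leaves every decision unchanged.  Hits are filtered by the
Karlin–Altschul E-value $E = K m n e^{-\lambda S}$.  $\lambda$ solves
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ by bisection (tolerance
1e−12); $K$ comes from the classical series for lattice score
distributions, which reproduces the published ungapped constants (for
+1/−2 at uniform base composition: $\lambda = 1.332$, $K = 0.621$).
Gapped hits reuse the ungapped $\lambda, K$ — a standard, documented
approximation; no closed form exists for gapped statistics and the
cutoffs used here (1e−6) are orders of magnitude away from the decision
boundary for every planted feature.

Numerical choices worth knowing:

* **X-drop** defaults to `20 * match` (40 for both presets).  Extension
  ties are resolved toward the smaller coordinate, making hit sets
  deterministic and mirror-symmetric under query/subject exchange.
* **N** never matches anything and is excluded from GC computations.
* **Self-alignment** (dispersed-repeat search) confines the plus strand
  to the strict upper triangle of the dot plot — subject position
  strictly greater than query position — inside the dynamic program
  itself.  This excludes the trivial full-length self-identity hit
  *structurally*: chance near-diagonal seeds can otherwise gap-jump onto
  the main diagonal and resurrect it.  Each upper-triangle hit is then
  mirrored so both orientations of every repeat pair are reported.  The
  minus strand has no identity diagonal and is searched unrestricted.
* **Circular topology** is handled by a doubled-subject view with
  deduplication of wrapped hits.
* **Oracle equivalence.**  On pairs that share a homologous segment
  (up to ~10% divergence, the regime every analysis here operates in),
  the engine's best score equals the full Smith–Waterman optimum: the
  optimal alignment then contains an exact 7-mer and the x-drop
  extension through it is exhaustive.  On pairs of pure i.i.d. noise no
  word-based heuristic has that guarantee — roughly half of
  noise-optimal alignments contain no exact 7-mer run — which is why
  the equivalence checks in the test suite draw homologous pairs.

# Repeat quantification

The repeat content of a genome is the fraction covered by tandem plus
dispersed repeats with overlaps excluded: all coverage is projected
onto a non-redundant interval union before measuring, so a base counts
once no matter how many hits contain it.

*Dispersed* repeats come from a sensitive self-search keeping hits of at
least 31 aligned columns (repeats larger than 30 bp); no identity floor
is applied in repeat mode.  Hits contribute their query-side intervals;
because query and subject are the same genome and hits are mirrored,
both copies of each repeat are covered.

*Tandem* arrays come from a simplified reimplementation of the classical
tandem repeat finder, calibrated to its default weights (match +2,
mismatch 7, indel 7, minimum score 50, maximum period 500).  Candidate
loci are maximal-scoring segments of the positional self-comparison
`seq[i] == seq[i + d]` for every period `d`; overlapping candidates
collapse to the smallest period, and each survivor is refined by
wraparound dynamic programming against its positional-majority period
consensus (the wraparound transition from the last consensus column to
the first counts a new copy, giving the fractional copy number).  The
consensus period is minimized by a divisor test, so `ATAT…` is period 2,
never 4.  Arrays need `copy_number >= 1.9` and any array passing the
score threshold is counted regardless of length.  This is a calibrated
simplification, not a bug-for-bug clone: the match/indel probability
parameters of the original's statistical model are accepted but unused
by the exact scanner, and arrays interrupted by large insertions may be
reported as two loci (their coverage union is what matters here).

# Shared DNA and transfer blocks

Shared DNA between two compartments is measured with the fast preset:
hits with identity **strictly** greater than 90% are retained (a hit at
exactly 90.0 is excluded), summary statistics are computed over retained
hits (the median of an even count is the midpoint average), and the
total is the non-redundant union of query-side intervals.  The GC of
shared DNA is computed over the covered *query* (organelle) sequence;
computing it subject-side is the documented alternative, and on real
data the two differ only by post-transfer mutation.  For
organelle-versus-nuclear comparisons the organelle genome is the query;
for the organelle-organelle comparison the plastome is the query.
Nuclear chromosomes are searched independently and pooled.

Large contiguous organelle-derived blocks — candidate genomic-scale
transfers — are clusters of retained hits along a nuclear sequence with
inter-hit gaps of at most `max_gap_bp` (default 10,000 bp; tolerant of
post-transfer indels yet below gene-scale spacing; the chosen value is
echoed in every report) whose span reaches `min_span_kb` (default
100 kb).  Blocks report their span, contained hits, nuclear-region GC
and hit-coverage fraction; they are flagged putative only — an
assembly artifact produces the same signal, and distinguishing the two
needs data this package does not see.

# Gene fission, pseudogenes, introns

A reference gene model is a clean CDS (frame-checked at construction)
with optional exon structure and conserved-domain intervals in CDS
coordinates.  `locate_gene()` finds the best-scoring locus of the CDS
in a target genome (sensitive preset, hits clustered within 5 kb); a
gene whose CDS aligns over less than 30% of its length anywhere is
called **absent** — the signature of a complete, precise deletion.

`detect_fission()` aligns the reference CDS into the located locus
(pairwise, CDS global, locus local) and evaluates every deletion, with
gap placement normalized by maximal left-shifting so breakpoint
coordinates are canonical:

* deletion length ≡ 0 (mod 3): the frame is preserved — *intact with
  deletion* (or *pseudogene* if the junction codon happens to be a
  stop, or if point mutations put a stop in frame);
* otherwise the frame shifts by `L mod 3`.  The target is translated
  from the gene start through the shifted frame to the first stop (the
  premature stop), then a window (default 200 bp) downstream of the
  stop is scanned for the next start codon (`ATG` by default; `GTG`
  can be added).  If a second reading frame runs from there to the
  reference C-terminus without stops, the call is **fissioned** into
  ORF1/ORF2 — otherwise **pseudogene**.

Two ORFs within 5,000 bp on the same replicon are flagged *adjacent*
(the single-locus fission pattern, as opposed to families where the two
products sit at distant loci).  `domains_intact` records whether any
conserved-domain interval overlaps the deleted/untranslated gap — a
fission whose product domains survive is the pattern consistent with
continued function.  Translation uses the standard code (table 1, the
plant mitochondrial code), implemented in-package because the shifted
frame scanning needs it, and cross-checked against an independent
implementation in the tests.

Intron status: the flanking exons of each annotated intron are aligned
to the target; the intron is **lost** when the exons are contiguous
(gap ≤ 10 bp — a cis-spliced loss leaves exactly contiguous exons, and
the slack absorbs alignment jitter), **present** otherwise (a
half-length intron is still present), **unknown** when an exon cannot
be aligned.  Introns are named `gene + "i" + CDS position of the last
reference base before the intron` — a convention adopted here because
the field's usage (e.g. names like `ccmFci829`) implies but does not
define it.

# Copy phylogenies and transfer counting

Whether nuclear copies of a mitochondrial gene arose once or repeatedly
is a tree question: on the rooted copy tree, each maximal clade
consisting entirely of nuclear copies is one transfer event
(Fitch-style minimum count of mitochondrial→nuclear transitions).
`copy_tree()` fits the tree by neighbor joining on Jukes–Cantor or
Kimura two-parameter distances (gap columns pairwise-deleted; columns
with >50% gaps dropped first), roots it on the declared outgroups and
attaches bootstrap support from column resampling.  NJ is implemented
in-repo with a deterministic tie-break (lexicographically smallest
representative labels) and negative branch lengths clamped to zero with
the deficit moved to the sister edge; on additive matrices it recovers
the generating topology and branch lengths exactly, and the tests
cross-check it against an independent implementation.  Distance-based
inference replaces the heavier likelihood machinery deliberately: the
claims made from the tree are topology-level (monophyly and counting),
which are robust at these divergences, and the model is configurable.
Known limitation: like all distance methods, NJ is vulnerable to
long-branch attraction when highly accelerated lineages are separated
by very short internal branches; a warning regime (any branch exceeding
three times the median) is the practical guard on real data.

Rate acceleration after transfer is summarized as the ratio of mean
root-to-tip path length of nuclear versus mitochondrial leaves
(outgroups excluded by default), with a bootstrap percentile interval.

# What the simulator emulates — and what it does not

`simulation_recipe()`/`simulate_genome()` produce genomes with planted
dispersed repeat families (length, copy number, divergence), tandem
arrays (period, copies), and organelle-derived tracts copied from a
source genome with divergence; background GC defaults to the
organelle/nuclear contrast of real plant cells (45% vs 33%).
Divergence is i.i.d. substitution only — no indels unless requested —
so truth coordinates are exact.  Features are placed by seeded
rejection sampling with a 40 bp margin so planted features cannot
merge; each feature draws from a deterministically derived substream,
so adding one feature does not perturb the others.  The default
study-scale conditions used by the tests are: 20 kb genomes with two
dispersed families of 400–900 bp copies for repeat recovery (plant
mitogenome dispersed repeats are characteristically few and large);
5 kb tracts at 2% divergence and a 150 kb tract at 3% for transfer
recovery on a 400 kb chromosome; 50 random genes with planted
deletions of 1–90 bp for fission recovery.  These sizes keep a full
verification run to a few minutes while leaving each detector's
decision margins wide.

`simulate_transfer_scenario()` evolves gene copies along a fixed
species topology (two outgroups, an ingroup with a nested four-genus
clade) under Jukes–Cantor; each planted transfer duplicates a clade,
and the nuclear duplicate evolves with branch lengths scaled by the
rate multiplier from the transfer point on.  Transfer points sit close
to the root — as they do in the biological setting, where transfer
precedes the radiation of the descendant clade — so nearly the whole
nuclear root-to-tip path runs at the accelerated rate and the
root-to-tip ratio approximates the multiplier.  Internal branches are
long enough relative to the terminal ones that neighbor joining
resolves the two nuclear placements reliably at 1,000 sites; at much
higher divergences or shorter separating branches, long-branch
attraction would merge them (we verified exactly this failure mode at
roughly double the default terminal lengths).

What passing tests do **not** show about real data: the simulator plants
substitution-only divergence (real NUMTs decay with indels and
rearrangements, fragmenting hits more than the synthetic truth does),
uniform background composition (real genomes have local composition
structure that inflates chance tandem candidates), and assembly-perfect
sequence (real large NUMT calls can be assembly artifacts — the block
detector's output is labeled putative for that reason).

# Determinism

Every stochastic step — simulation, bootstrap, placement — takes an
explicit seed, restores the caller's RNG state afterwards, and all
writers emit fixed-format text, so rerunning `run_full_comparison()`
with the same configuration and seed reproduces every output file byte
for byte.  The configuration object rejects unknown keys and every
threshold is echoed into the run manifest.
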