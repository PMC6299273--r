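---
title: "Comparative mitogenomics with mitoarch: models and methods"
author: "mitoarch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitoarch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

# Scope

`mitoarch` implements the comparative analyses that a mitogenome study runs
after assembly and automated annotation: rule-based curation of gene
boundaries, genome geometry (intergenic spacers and overlaps), nucleotide
composition with AT/GC skew, relative synonymous codon usage (RSCU) with
per-family chi-square comparisons and sequential Bonferroni correction,
maximum-likelihood branch-model dN/dS inference with likelihood-ratio
tests, signed gene-order distances (breakpoints and common intervals), and
a root-to-tip branch-length test for lineage rate acceleration. A family
of seeded generators produces annotated genomes, codon alignments, gene
orders, and clock trees with known ground truth, so the whole pipeline is
testable without downloading anything.

The package ships, as plain-text data, the published annotation
coordinates and per-region composition percentages of the 15,676-bp
*Melarhaphe neritoides* (littorinid periwinkle) mitogenome; these support
all coordinate-based worked examples. The shipped `GenomeRecord` built
from them (`mneritoidesAnnotationRecord()`) carries a synthetic
placeholder sequence: composition or codon counting on it would be
meaningless, and that is stated on its help page.

# Data model

A `GenomeRecord` couples a `Biostrings::DNAString` with a feature table
(gene name, kind, strand, 1-based inclusive coordinates, start/stop
codons, optional quality score). Coordinates are 1-based inclusive
everywhere — the IRanges/GenBank convention — so there is no internal
coordinate conversion anywhere in the package; a feature with `end <
start` spans the origin of a circular genome. Minus-strand logic runs on
an *oriented* view of the genome (the reverse complement, with position
`p` mapping to `L - p + 1`), so both strands share one code path.

Translation uses NCBI table 5 (invertebrate mitochondrial) by default:
AGA/AGG encode serine, ATA methionine, TGA tryptophan, and only TAA/TAG
stop. Abbreviated stop codons (`T--`, `TA-`) — transcript ends cut at the
downstream tRNA and completed to TAA by polyadenylation — are stored as
annotation metadata; the completed codon is materialized only when a
sequence is translated or codons are counted.

# Annotation curation

Automated mitogenome annotators misplace protein-coding gene (PCG)
boundaries often enough that published comparative studies re-curate them
by hand. `curateRecord()` encodes that practice:

1. **Duplicates** (rule applied once, first): when a gene is annotated
   more than once, the candidate with the highest annotation quality is
   kept; ties keep the earliest and warn.
2. **Stop codons**: scanning in frame from the start, a PCG ends at the
   first full TAA/TAG. A full stop must *begin* before the downstream
   feature; it may end up to 2 nt inside a tRNA (such stop/tRNA overlaps
   of 1-2 nt occur in real littorinid annotations), and when the
   downstream feature is another PCG the scan continues up to 45 nt into
   it, where overlap is frame-legal. If no full stop occurs, the gene
   ends with an abbreviated `TA-`/`T--` flush against the downstream
   tRNA; otherwise the gene is flagged unresolved, never deleted.
3. **Start codons**: a PCG begins at the first eligible in-frame start
   codon nearest to the preceding gene without overlapping it. The
   eligible set defaults to `ATG, ATA, ATT, ATC, GTG` (non-ATG starts are
   real: atp6 starts with ATT in *M. neritoides*). Candidates may reach
   into a same-strand upstream PCG when the overlap is frame-legal —
   both mitochondrial strands are transcribed polycistronically, so two
   same-strand PCGs cannot overlap in the same reading frame, but
   different frames are possible, and conserved arrangements such as the
   7-nt nad4l/nad4 overlap must survive curation. Candidates are ranked
   by (overlap with the upstream gene, then 5' proximity to it); an
   annotated start that is itself a valid start codon is never evicted by
   the reference-length filter. When reference genomes are supplied,
   candidates whose protein length falls outside ±10% of the reference
   mean are passed over, and per-gene length deltas against the reference
   are reported but never auto-applied.
4. tRNA and rRNA boundaries are never touched: they come from the
   upstream structural predictor and re-deriving them from sequence alone
   would overfit.

**Pass ordering.** Start selection reads the upstream neighbour's
annotated end, so a record whose stops are also wrong can derail a
starts-first pass: a shrunken stop annotation exposes the upstream gene's
true tail as apparent intergenic sequence, and any in-frame start codon
there becomes a bogus "first eligible" candidate. Stop resolution, by
contrast, depends only on the gene's reading frame, which in-frame start
errors cannot change. Each curation pass therefore resolves stops before
starts, and passes iterate to a fixpoint (at most 3; clean records
converge immediately, and curation is idempotent by construction). This
was adopted after the starts-first order demonstrably failed to recover
ground truth on seeded corrupted genomes.

The default start-search window extends 90 nt into the annotated gene, a
figure chosen to comfortably cover observed start misplacements (a few
codons) without reaching deep into the gene body; it is a tunable
argument.

`computeGeneGeometry()` reports the signed gap between every pair of
consecutive features including the wrap-around junction, so the gaps and
feature lengths telescope exactly to the genome length — an identity the
tests enforce. On the shipped *M. neritoides* coordinates this reproduces
the published 23 intergenic spacers totalling 250 bp and 5 overlapping
pairs (deepest −36 nt).

# Composition and skew

Base percentages are computed over unambiguous A/C/G/T only (ambiguity
codes are excluded so percentages stay interpretable), and skews follow
the standard definitions AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C).
Rounding to the printed precision (1 decimal for percentages, 3 for
skews) happens only at report time, half away from zero; internal values
keep full precision. Per-gene rows are computed on the plus strand as
printed coordinates define the region, with a `codingStrand` switch for
the transcribed strand. Whether a published whole-genome GC skew was
computed before or after excluding ambiguous bases is generally not
recoverable from rounded percentages; recomputed skews can therefore
differ from printed ones in the third decimal for near-zero skews.

# Codon usage

Codon counting concatenates the PCGs' coding sequences, completes
abbreviated stops, drops terminal stops, and errors on internal ones.
The 62 sense codons of table 5 fall into 22 synonymous families (9
four-fold, 13 two-fold; leucine and serine each split into two families
named Leu1/Leu2 and Ser1/Ser2 after the decoding tRNAs). RSCU is the
Sharp–Li definition: a codon's count times family degeneracy over the
family total, so within-family RSCU sums equal the degeneracy.

Cross-species comparison runs one chi-square test per family: observed
counts are the focal species' codon counts; the expected count of a codon
is the focal family total times the pooled proportion of that codon
across both species (the count expected were the codon equally used in
the two species), with k−1 degrees of freedom. Families with any expected
count below 5 are flagged, not excluded; a family unused in both species
is reported untestable rather than silently dropped, and the number of
testable families is attached to the result. Note the statistic is *not*
invariant to rescaling one species' counts — expected counts depend on
pooled proportions, which shift with relative sample size — so comparing
species with very different coding capacity is a genuine modelling
choice, not a no-op. Multiple testing uses the sequential Bonferroni
(Holm step-down) procedure, implemented through `stats::p.adjust` and
verified against hand-stepped examples.

# Branch-model dN/dS

The selection machinery implements a Goldman–Yang-style codon
substitution model over the sense codons: substitutions changing more
than one codon position have rate zero; a single-position change has rate
proportional to the target codon's equilibrium frequency, multiplied by
κ for transitions and by ω = dN/dS for non-synonymous changes. The
generator is scaled to one expected substitution per codon per unit
branch length. Synonymous changes track mutation alone while
non-synonymous ones also feel selection, so ω measures the direction and
strength of selection: ω < 1 purifying, ω ≈ 1 neutral, ω > 1 positive.

Likelihoods are computed by Felsenstein pruning over aggregated site
patterns, with transition probabilities from the eigendecomposition of
the symmetrized reversible generator (the decomposition is cached per
(κ, ω) during optimization; per-node rescaling guards against underflow).
The model is reversible, so the likelihood is invariant to re-rooting —
checked numerically — and trees are treated as unrooted for fitting.

`fitBranchModel()` maximizes over κ, per-edge branch lengths, and either
one ω (`one_ratio`), a foreground/background pair (`two_ratios`), or one
ω per branch (`free_ratios`), using bounded quasi-Newton (`nlminb`) on
log-scale parameters with 3 seeded starts by default (the first from
neutral defaults, the rest jittered); ω is capped at 999 to accommodate
extreme estimates. Codon frequencies default to F3x4 (position-specific
nucleotide frequencies estimated from the alignment, with a half-count
prior so no sense codon gets zero mass); uniform and user-supplied modes
exist. Gap- or ambiguity-containing codon columns are removed
alignment-wide (complete deletion). Nested fits are compared by
`likelihoodRatioTest()`: 2Δℓ against a chi-square with the
parameter-count difference as degrees of freedom (the familiar 3.84
cutoff at df = 1 and 5%); statistics negative beyond tolerance raise a
warning advising a re-fit, tiny negatives are clamped to zero.

As an independent cross-check, `ng86()` implements Nei–Gojobori-style
counting (synonymous site fractions per codon, pathway-averaged
differences avoiding stop codons, Jukes–Cantor correction). It shares no
code with the likelihood machinery and is used in tests to confirm that
counting-based ω agrees in regime (purifying vs neutral) with the
generating values.

Reproducing published CODEML ω tables for real littorinid alignments
requires the external genome sequences and parity with CODEML's
frequency/optimizer choices (the exact frequency model used in such
studies is typically unstated); those values are conformance targets for
users with the data, not unit-test anchors. The tests instead verify
parameter recovery and test calibration on simulated data: median
relative error of ω̂ at most 25% over 21 seeded 4-taxon, 500-codon
replicates spanning ω ∈ {0.2, 1, 5}, and a type-I error near 5% at the
3.84 cutoff over 200 null simulations (150 codons, 3 taxa — sizes chosen
to keep the full calibration in the order of minutes on one CPU).

# Gene-order distances

Gene orders are signed circular permutations (sign = strand).
`canonicalizeOrder()` rotates the anchor gene (default cox1) to the
front, reflecting and negating if the anchor is on the minus strand.
Breakpoints are adjacency properties of the circle: the signed adjacency
(x, y) is matched in the other order by (x, y) or by its opposite-strand
reading (−y, −x); breakpoints = n − matches. Identical orders give 0, as
does a reverse-complemented copy (the same circular molecule read from
the other strand), and a single segment inversion introduces exactly 2 —
all property-tested.

Common intervals count gene subsets of size 2..n forming a contiguous
block in both orders, signs ignored. Circular orders are linearized at
the shared anchor after canonicalization, and the count is computed by
the O(n²) running min/max window scan, verified against an exhaustive
O(n³) set-comparison oracle on hundreds of random signed permutations.
Published interval counts from rearrangement tools may use a different
linearization or subset convention, so absolute counts are comparable
within this package's convention, not necessarily across tools; for
identical orders of n genes the count is n(n−1)/2.

# Branch length test

`branchLengthTest()` flags lineages whose substitution rate departs from
the tree-wide average: for each taxon the deviation δ = d − mean(d) of
its root-to-tip distance from the mean over taxa. The sign convention is
δ > 0 for faster-than-average lineages (a long branch has a positive
deviation); the mean is unweighted over leaves. With an alignment
supplied, SE(δ) comes from a nonparametric site bootstrap: columns are
resampled, model-corrected distances (TN93 by default) recomputed, branch
lengths re-fitted by ordinary least squares on the fixed topology
(negative solutions clamped to zero), and δ re-read. The two edges
incident to the root are not separately identifiable from distances, so
they are fitted as one and split back in the input tree's proportion —
which is also why δ is invariant to lengthening the root edge uniformly.
CP = 1 − p from the two-sided normal tail of δ/SE, flagged at CP ≥ 0.95
and ≥ 0.99. Without an alignment, user-supplied SEs are accepted;
otherwise CP is reported as unavailable rather than guessed. A default of
1000 bootstrap replicates is recommended; below 50 a warning is issued.

# Synthetic data: what it emulates, and what it does not

`makeAnnotatedGenome()` builds a circular genome whose true annotation
satisfies every curation rule. Its default layout mirrors the littorinid
mitogenome: 13 PCGs, 22 tRNAs, 2 rRNAs and a control region with the
published gene order, strands, lengths and intergenic gaps — including
the 7-nt nad4l/nad4 overlap (generated by joint rejection sampling of the
shared bytes so both reading frames stay valid) and the tRNA/rRNA
overlaps. Three bookkeeping constraints make curation exactly invertible
on generator output: intergenic spacers carry no in-frame start or stop
codons upstream of a PCG (a spacer start codon would pre-empt the true
one, and a spacer stop codon would truncate a start-shifted gene); the
90-nt start-search window of a gene whose
true start overlaps an upstream PCG carries no alternative in-frame
starts (extended by 9 nt to cover corrupted windows); and an abbreviated
stop is never completed by chance by the first tRNA bases. Corruption
switches shift PCG starts/stops by 1–3 codons (in frame, never across the
origin) and duplicate tRNAs at lower quality, returning the injected
changes as ground truth. What the generator does *not* emulate: sequence
similarity to real genes, realistic tRNA structure, frame-shifting
annotation errors, or assembly artefacts — so passing round-trip tests
demonstrates the curation logic, not performance on raw MITOS output.

`simulateCodonAlignment()` evolves root codons drawn from the equilibrium
frequencies down the tree with exact matrix-exponential transition
probabilities per branch (not Gillespie stepping), matching the
likelihood model being tested; branch-specific ω is supported via a named
vector. `scrambleGeneOrder()` applies counted inversions/transpositions
with an event log; `makeClockTree()` draws a coalescent topology, scales
it ultrametric to a given depth, and stretches named pendant edges so a
taxon's root-to-tip distance equals depth × factor, optionally simulating
a Jukes–Cantor alignment for bootstrap testing. Every generator is a pure
function of (arguments, seed): seeds are applied through an RNG-preserving
wrapper and identical seeds give identical output.

# Numerical choices and limitations

* Optimizer tolerance 1e-10 (relative) on the objective, 500 iterations;
  convergence is reported on the fit, and non-convergence is a flag, not
  an error.
* Matrix exponentials use the symmetric eigendecomposition of the
  reversible generator; tiny negative probabilities from round-off are
  clamped to zero.
* Rounding of reported percentages/skews is half away from zero, at
  report time only.
* The curation fixpoint is capped at 3 passes; records that still change
  would be pathological (none observed over hundreds of seeded genomes).
* The GenBank reader targets the flat-file subset that mitogenome
  records use (CDS/tRNA/rRNA/misc_feature, `complement`, origin-spanning
  `join`); it is not a general GenBank parser.
* Branch-model fits on large trees are feasible but slow in pure R; the
  intended scale is the few-taxon alignments of comparative mitogenomic
  studies.
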