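---
title: "Models and methods behind famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famevol packages the classical gene-family evolution workflow — domain
classification, duplication mapping, Ks dating, codon selection models,
functional divergence, expression and promoter characterization — as tested
R functions.  This vignette explains the models, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generators do
and do not emulate, and the design decisions taken where the underlying
methods are conventionally delegated to external services.

## Domain detection and family classification

A WRKY domain is recognised purely from sequence: the conserved heptapeptide
`WRKYGQK` followed, within a configurable gap (default 50 residues), by a
zinc finger matching either C–X4–5–C–X22–23–H–X–H (C2H2) or
C–X7–C–X23–H–X–C (C2HC).  Scanning enumerates all overlapping candidate
positions; overlapping finger candidates at the same start are resolved
left-most-first (smallest first spacer, then second), and each heptapeptide
is paired with the nearest unused downstream finger.  Classification follows
the standard scheme: two C2H2 domains → group I (domains labelled N and C by
position), one C2H2 → group II, one C2HC → group III, no hits → unassigned.
Proteins with two hits of mixed finger type are assigned group I — domain
count dominates in the scheme — and flagged for inspection.

The heptapeptide set is exact `WRKYGQK` by default.  Variants (e.g.
`WRKYGKK`) can be added through `domain_pattern()`, but are off by default
because the signature is stated as conserved in the family literature.

Group II subgroups (IIa–IIe) are conventionally drawn from a phylogeny plus
motifs outside the domain.  Neither is reproducible deterministically
without external motif discovery, so famevol replaces both with
nearest-labelled-reference classification: the query domain is globally
aligned (BLOSUM62, gap open 11 / extend 1) to every labelled reference and
takes the label of the closest under 1 − fractional identity, ties breaking
to the alphabetically smallest subgroup.  The shipped reference set
(`wrky_subgroup_refs_synthetic.tsv`) is *synthetic* — five well-separated
domain scaffolds (mean between-subgroup distance ≈ 0.69, within ≈ 0.09),
three replicates each — constructed so the classifier is exercised without
claiming any real subgroup membership.  Users with curated references
substitute their own table.  Proteins that fit no subgroup cleanly keep
their group with `subgroup = "none"`.

The similarity prescreen mirrors a BLASTP screen without the service
dependency: Smith–Waterman, BLOSUM62, affine gaps 11/1, score converted to
bits with the standard gapped Karlin–Altschul parameters (λ = 0.267,
K = 0.041).  The default cutoff of 50 bits admits every shipped reference
domain (self-scores ≳ 80 bits) while unrelated sequences score ≲ 30 bits.

## Duplication mapping

Tandem arrays follow the 10-intervening-genes rule: family genes on one
chromosome whose consecutive members are separated by at most
`max_intervening = 10` other genes form maximal clusters; singletons are not
arrays.  Segmental support for a candidate pair counts *anchors*: flanking
protein-coding genes within ±100 kb of the focal gene (measured between
gene midpoints) whose best non-self protein match falls within ±100 kb of
the partner.  Matches are directional by default — the flanking gene's best
hit must land in the partner window — with reciprocity available as a
toggle; the minimum anchor count defaults to 3, the smallest anchor number
in published soybean block tables.  Tandem and segmental flags are
independent: a gene can be both, and family summaries count each flag
separately, which is why flag counts can exceed the non-dispersed total.

## Ka/Ks estimation and clock dating

famevol implements NG86 because it is the simplest published standard that
supports the dating arithmetic exactly; the estimator sits behind one
function (`ng86_ka_ks()`) so an ML pairwise estimator could be substituted.
Per codon, the synonymous site count is the fraction of the nine
single-nucleotide changes that are synonymous, averaged over the two
sequences; changes that would create a stop codon count as nonsynonymous.
For codons differing at 2–3 positions, all substitution orderings are
averaged with equal weight, discarding orderings that pass through a stop
codon (if every ordering is blocked, all are kept with stop-creating steps
nonsynonymous — a totality fallback that essentially never fires on real
data).  Raw proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 raises a saturation error rather than
returning a number.  Codons with gaps or ambiguity in either row are
excluded pairwise.  Codon alignments are built by back-translating a
protein alignment, so each amino-acid column expands to one codon column.

Block dating filters anchors at Ks > 1.0 (saturation risk), averages the
rest, and applies T = Ks/(2λ) with λ = 6.1 × 10⁻⁹ /site/year (soybean) by
default.  Table ages round half-up to integer Myr; full precision is kept
internally.  The package reproduces all 86 rows of the shipped soybean
segment-pair table from their printed mean Ks — this is checked in the test
suite and recomputed by `scripts/acceptance.R`.

## The codon likelihood engine

Site and branch-site models share one GY94-style engine: 61 sense-codon
states, zero rate for multi-nucleotide changes, κ multiplying transitions,
ω multiplying nonsynonymous changes, target-codon frequency in every rate.
The generator is reversible, so transition matrices come from a symmetrized
spectral decomposition; Felsenstein pruning over compressed site patterns
runs in compiled code (RcppArmadillo), with per-class site likelihoods
returned to R where mixing, logs and posteriors happen.  Mixture models are
normalized by the weighted mean rate of the *background* class structure,
so branch lengths are expected substitutions per codon under the background
regime; the simulator uses the identical normalization, which is what makes
parameter-recovery tests fair.

Fitted models: M0 (one ω); M3 with K discrete classes (ω's parameterized as
ordered increments for identifiability); M7, a beta(p, q) distribution on
(0, 1) discretized into `ncat = 10` equal-probability categories
(median-of-bin representatives); M8 = M7 plus a free class with ωs ≥ 1; and
branch-site model A with classes 0, 1, 2a, 2b, proportions
p2a = (1−p0−p1)·p0/(p0+p1), p2b = (1−p0−p1)·p1/(p0+p1), ω1 = 1 fixed, and
ω2 ≥ 1 on the foreground (the null variant pins ω2 = 1).  Foreground
branches are named by their child node labels (a `#1` suffix is accepted).

Optimization is L-BFGS-B on log-transformed positive parameters and
logit-transformed proportions, with `n_starts = 3` by default (first start
from fixed moderate values, the rest jittered under a recorded seed) and
convergence tolerance `factr = 1e7`; non-convergence is flagged on the
returned object, never silent.  ω is capped at 999 and boundary hits are
flagged.  Branch lengths are held fixed at their supplied values by default;
`branch_lengths = "scale"` adds a single global multiplier.  Full per-branch
re-estimation is deliberately out of scope — the intended workflow supplies
a tree with branch lengths.

LRTs use χ² with df 4 (M0 vs M3, K = 3), 2 (M7 vs M8) and 1 (branch-site).
The branch-site null distribution is properly a 50:50 mixture of 0 and
χ²(1); using χ²(1) is the conservative standard choice, and the test suite
verifies empirically that the type-I error at α = 0.05 stays within
[0.01, 0.08].

Site posteriors: NEB plugs MLEs into Bayes' rule.  BEB (M8 and branch-site
A) integrates over a uniform 10-point grid per uncertain dimension — (p0,
ωs) for M8, (p0+p1, p0/(p0+p1), ω2) for branch-site A — holding the other
parameters at their MLEs.  This is a deliberately compact version of the
full BEB integration; NEB is the variant asserted in property tests, and
BEB is checked for the same rank ordering of selected versus neutral sites.
Site indices are alignment-relative.

## Functional divergence

Type-I divergence uses the two-state rate model: per cluster, per-site
substitution counts come from Fitch parsimony on the cluster subtree
(ambiguities and gaps are missing data).  With probability 1−θ a site draws
one rate from gamma(α, α) (mean 1) shared by both clusters, each cluster's
count being Poisson with intensity d·rate; with probability θ the clusters
draw independent rates.  The gamma integrals are evaluated in closed form
(negative-binomial likelihoods), so no rate discretization is needed — an
exact replacement for the usual 8-category discretization.  The intensity
scales d₁, d₂ are set by method of moments to the cluster mean counts
(E[count] = d because site rates average 1), a simpler calibration than
branch-length summation that the count likelihood makes self-consistent.  θ
and α are estimated jointly (two optimizer starts; the θ = 0 boundary is
part of the model, so the alternative never scores below the null), with
SEs from the numerical Hessian and an LRT against θ = 0 on 1 df.

Type-II divergence uses a count-category simplification, stated as such:
sites are cross-classified as conserved-identical, conserved with a
conservative difference, conserved with a *radical* difference (crossing
the shipped charge/polarity partition: nonpolar / polar / acidic / basic),
or variable in either cluster.  A Type-II divergent site (probability θ-II)
is conserved in both clusters but fixed for a radical difference; background
fixed differences are radical with probability ρ0, the fraction of radical
pairs among the 190 unordered amino-acid pairs.  The 2-parameter multinomial
likelihood is maximized over (θ, π); with a single property class ρ0 = 0
and θ-II = 0 by construction.  Per-site posteriors Qk are empirical-Bayes
in both types, and sites with Qk > 0.8 (configurable) are flagged as
candidate critical residues.

## Expression and promoters

Rows are Z-scored with the population standard deviation; constant rows map
to zeros by convention.  Clustering is average linkage on 1 − Pearson
correlation, with zero-variance genes excluded (with a warning) because
their correlation is undefined.  Breadth classes, in precedence order:
`not_detected` (all tissues below the expression floor, default 1.0 in the
matrix's RPKM-like units), `constitutive` (all at or above it),
`single_tissue_peak` (exactly one tissue with Z ≥ 1.5 that is also the row
maximum), else `intermediate`.  The floor and peak threshold are defaults,
not claims — the source analyses never define "expressed" or "marked peak"
numerically.

Promoter scanning counts overlapping IUPAC-pattern occurrences on both
strands by default (promoter elements are orientation-ambiguous), counting
distinct start positions so palindromic elements are not double-counted.
The shipped catalog holds best-effort literal patterns for the classical
plant elements (G-box `CACGTG`, Box 4 `ATTAAT`, ABRE, TCA-element, MBS,
HSE, TC-rich repeats, circadian, Skn-1, W-box, …); counts are always
relative to the catalog in use, and no equivalence with any database's
position-weight matrices is claimed.

## Synthetic data: what it does and does not emulate

The generators produce every input with known truth and are pure functions
of their arguments and a seed.  Codon alignments evolve by the same GY94
process the models fit, so recovery tests validate the estimation machinery,
not model robustness; real alignments violate the model (selection on
silent sites, CpG effects, indels), and passing tests therefore demonstrate
correctness of the implementation, not that the model is right for any
particular data set.  Genome layouts plant tandem arrays (members are
copies at Ks ≈ 0.1) and segmental blocks (focal gene plus flanking anchors
copied and evolved to a target Ks); gene spacing (~6–12 kb intergenic) is
chosen so the ±100-kb anchor window spans roughly ±10 genes, as in a real
compact plant genome, and extra family genes are placed at least 25
ordinals from other family genes so no unplanned arrays or blocks arise.
Realistic intron structure, transposable elements and indel evolution are
not emulated.  `evolve_pair_to_ks()` calibrates its branch length
numerically so that the *expected NG86 estimate* — not the raw synonymous
divergence — equals the target, because NG86 is the estimator used
downstream; the mutation process is synonymous-only (ω = 0), which the
returned object documents.  Expression atlases are log-normal with a planted
peak tissue per group (elevation in units of the log-sd); promoters are
i.i.d. background with planted verbatim element copies at recorded,
non-overlapping offsets.

## Problem sizes used in validation

The shipped tests validate at sizes chosen to exercise every code path at
desk scale: oracle equivalence of the likelihood engine on all trees with
≤ 4 taxa and ≤ 3 codons (100 random parameter draws, tolerance 1e-8); NG86
against brute-force path enumeration on 50 random 100-codon pairs
(tolerance 1e-12); M0 recovery at 8 taxa × 500 codons (10 replicates per
ω); branch-site type-I error over 200 null replicates at 6 taxa × 100
codons and power over 50 replicates at 8 taxa × 500 codons; θ-I recovery
over 20 replicates of 200 sites; duplication recovery on 90-gene genomes.
Genome-scale censuses (hundreds of family members over a full genome) run
with the same code but are not part of the test envelope.

## Known limitations

- Subgroup assignment is reference-relative; it does not reproduce any
  published subgroup membership, and ships synthetic references.
- NG86 underestimates Ks at high divergence relative to ML estimators; the
  Ks > 1 filter limits, but does not remove, this bias in block means.
- The branch-site χ²(1) reference is conservative; borderline p-values near
  0.05 should be interpreted accordingly.
- BEB uses a compact grid and fixes nuisance parameters at MLEs; posterior
  probabilities near the 0.95 threshold can differ from a full integration.
- The Type-II model is a category-count approximation, not the full
  covarion formulation; its θ is comparable across cluster pairs within an
  analysis, not across packages.
- Collinearity chaining (MCScanX-style) is out of scope; segmental support
  is anchor counting within a fixed window.
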