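---
title: "Comparative mitogenome analysis with mitochron: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome analysis with mitochron: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochron)
```

mitochron implements the full analysis chain used when a newly sequenced
mitochondrial genome is placed among its congeners: read quality filtering,
whole-genome alignment and variant classification, per-gene selection
summaries, model-based distances, neighbor-joining and maximum-likelihood
phylogenies with bootstrap support and BIC model choice, and relative-rate
divergence dating anchored at a single calibration point. This vignette
explains the models behind each stage, the defaults and their units, the
numerical choices, and what the bundled simulator does and does not emulate.

## Read filtering

A base is *low quality* when its Phred score is at most 7 (`threshold`
inclusive); a read is discarded when *more than* 10% of its bases are low
quality. Both boundaries are deliberate: a 100-bp read with exactly ten Q≤7
bases is kept. N bases are not treated as low quality — only the score
decides. Reads are filtered individually; mate-pair information, adapter
trimming and deduplication are out of scope. With i.i.d. base qualities the
kept fraction is the binomial tail `P(Binom(L, p) ≤ 0.1 L)`, which the test
suite verifies against simulated reads.

## Alignment of near-identical circular genomes

Mitogenomes from one genus are typically 95–100% identical, so a global
(Needleman–Wunsch) alignment with affine gaps is the appropriate, fully
reproducible tool; `align_pair()` scores match +1, mismatch −2, gap open −5,
gap extend −2 (a gap of length L costs 5 + 2L). The implementation delegates
the dynamic programming to Biostrings; the test suite checks its optimal
scores against an independent quadratic-space Gotoh implementation on
sub-kilobase inputs.

Because the molecules are circular and deposited sequences start at
arbitrary origins, `rotate_to_reference()` first rotates the query onto the
reference frame. Rotation anchors 200-bp seeds at eight positions around the
reference and accepts the first seed matching the doubled query within 20%
mismatches; multiple anchors matter because a single anchor can fall in the
hyper-variable control region. Annotation coordinates rotate with the
sequence; features pushed across the new origin are stored unrolled (end
beyond the sequence length) and normalized on access, the convention used
throughout for origin-spanning features.

`msa_center_star()` builds the multiple alignment by merging all pairwise
alignments against a center sequence under "once a gap, always a gap". For
sets of near-identical sequences this is essentially exact; it is not a
general-purpose progressive aligner and a warning is emitted beyond 30%
divergence from the center. *Complete deletion* — dropping every column with
a gap or ambiguous base in any row — defines the site set used by distances,
likelihoods and dating; *pairwise deletion* (per-pair masking) is available
for distance matrices.

## Variant classification

Every mismatching base column of a pairwise alignment is one directed
substitution (reference → query, so C→T and T→C are distinct), classified as
a transition (A↔G, C↔T) or transversion. Each maximal run of gap columns on
one side counts as a single indel *event* regardless of length, which is how
gap numbers are conventionally reported for mitogenome comparisons. Columns
containing N on either side are excluded from all counts and tallied
separately. Regional breakdowns assign each substitution to the reference
feature containing it and use the substitution count (indels excluded) as
the percentage denominator.

## Selection: the count-ratio dN/dS

For each protein-coding gene the reference and query codons are compared
under the vertebrate mitochondrial genetic code (NCBI table 2: ATA = Met,
TGA = Trp, AGA/AGG = stop). A codon pair translating identically is
synonymous; otherwise nonsynonymous with the replacement recorded as
`X-Y`. Codons hit at more than one position are evaluated once on the whole
codon, and the event is attributed to each differing position, so per-gene
counts sum exactly to the CDS total of the regional breakdown. Reverse-strand
genes (ND6 and several tRNAs in vertebrate mitogenomes) are handled through
the reverse complement as annotated.

dN/dS here is the *raw count ratio* `n_nonsynonymous / n_synonymous`,
the convention of comparative mitogenome tables (2/1 prints as 2, 1/4 as
0.25), not a site-normalized estimator; `dnds_site_normalized()` offers a
Nei–Gojobori-style per-site normalization for comparison but is not the
default. The ratio is reported only when both counts are positive (an em
dash otherwise), and the neutral category is decided by exact integer count
equality, never floating-point comparison. With the handful of substitutions
that separate conspecific mitogenomes these ratios are descriptive
summaries, not tests; codon-model ML estimation of ω is a non-goal.

## Distances

`count_site_pairs()` reduces a row pair to the proportions of
transition-differing sites (split into purine P1 and pyrimidine P2) and
transversion-differing sites Q over comparable columns. On these the package
computes the p-distance, the Kimura two-parameter distance
`d = −½ ln[(1 − 2P − Q)√(1 − 2Q)]`, and the Tamura–Nei (TN93) closed form
with empirical base frequencies. Saturation (a non-positive logarithm
argument) is flagged as an infinite distance and propagates as an error in
matrix construction, listing the offending pairs.

The default matrix model, `TN93-MCL`, is a composite variant of TN93:
base frequencies are pooled over the whole alignment, one global
transition/transversion rate structure (k1 for A↔G, k2 for C↔T, relative
to transversions) is estimated by maximum likelihood from the *pooled*
site-pair counts of all pairs, and each pairwise distance is then the 1-D
maximum-likelihood branch length under that shared structure (multinomial
likelihood over the four site-pair categories, solved by Brent search on
(10⁻⁹, 5)). Pooling parameters across pairs is the practical core of
composite-likelihood distance estimation; no attempt is made to replicate
the simultaneous optimization of any particular program, which is why
downstream quantities that depend on it (branch-length sums) carry a ~1%
tolerance in the acceptance checks. Rate heterogeneity across sites (gamma)
is not modeled.

## Trees

`nj_tree()` is the standard Saitou–Nei agglomeration. Two details are fixed
so runs are bit-reproducible: Q-matrix ties break toward the smallest
original index pair, and negative branch lengths are clamped to zero with
the deficit moved to the sibling (the count of clamped branches is kept as
an attribute). The suite verifies NJ against an exhaustive least-squares
topology oracle on additive matrices up to six taxa.

`tree_log_likelihood()` is Felsenstein pruning with site-pattern compression
and per-node rescaling; transition probabilities come from the eigen
decomposition of the TN93 rate matrix scaled to one expected substitution
per site. The models form the nested family JC ⊂ K2P ⊂ TN93. Reversibility
makes the value independent of root placement (checked to 1e-8), and the
implementation is cross-checked against an independent pruning code on
simulated data.

`optimize_ml_tree()` is a hill-climbing search: starting trees from NJ and
BioNJ on composite distances, per-branch Brent optimization (tolerance 1e-8,
branch lengths capped at 10 substitutions/site) swept to convergence,
nearest-neighbor interchanges accepted when they gain more than 1e-6 log
units, and the better of the two starts returned. Model parameters are
estimated from the data (frequencies empirically; rate ratios from the
pooled counts) before the search. This recovers the generating topology in
≥95% of simulated 11-taxon datasets at full genome length; SPR/TBR searches
and partitioned models are out of scope.

`select_model_bic()` scores each candidate on a fixed NJ topology with
branch lengths re-optimized per model and `BIC = −2 lnL + k ln(n_sites)`,
counting free branch lengths plus 0/1/5 model parameters for JC/K2P/TN93.
`bootstrap_support()` resamples columns, rebuilds the NJ tree per replicate
(closed-form distances with pooled frequencies — topologically equivalent to
the composite model at these divergences, and fast enough for thousands of
replicates), and reports bipartition frequencies as percentages; replicate
seeds derive deterministically from the root seed.

## Relative-rate dating

`reltime_relative()` implements relative-rate dating on a rooted tree. A
postorder pass computes each node's mean root-to-tip depth; at each node the
two child lineages receive relative rates proportional to their mean tip
depths, normalized by their geometric mean (so sister rates multiply to the
parent's squared rate), and the factors propagate root-ward. Branch
durations are lengths divided by lineage rates; node heights accumulate
tip-ward, averaging the two children's estimates, with the maximum taken in
the rare case the average would violate parent–child monotonicity. Three
exact properties anchor the implementation: a clock-like tree yields all
rates 1 and heights equal to node depths; ages are homogeneous of degree 1
in the calibration age; and the outgroup contrast at the root scales ingroup
rates only uniformly, so calibrated ages are invariant to outgroup branch
lengths. Zero-length sister pairs and single-tip lineages default to rate 1.

Outgroups root the tree (`root_with_outgroup()`) and are excluded from age
reporting (`node_ages()` drops pure-outgroup clades); the calibration node
may involve an outgroup taxon, as when the anchor is a split between the
study genus's relatives. `calibrate_timetree()` converts relative heights to
absolute ages by a single scale factor; confidence intervals come either
from the calibration interval alone or, via `timetree_ci()`, from a site
bootstrap (resampled columns → branch lengths re-optimized on the fixed
topology → dating rerun; percentile 2.5/97.5, compounded with the
calibration interval, with the point estimate kept inside its own
interval). The bootstrap default is 200 replicates; the analytic curvature
method of the original relative-rate framework is not implemented — the site
bootstrap is assumption-light and reproducible. Ages print at 2 decimals
(Ma) with rounding, not truncation.

## The simulator: what it emulates, and what it does not

`sim_config()` defines the study conditions: 11 taxa (7 ingroup + 4
outgroup, the shape of a genus panel with outgroups), a ~16.5-kb circular
genome tiled by a vertebrate mitogenome layout (control region, 13 CDS with
realistic lengths and strands, 22 tRNAs, 2 rRNAs), TN93 mutation with
primate-like base frequencies (A .321, C .259, G .116, T .304) and rate
ratios k1 = k2 = 20, which realize a transition:transversion count ratio
near 10 as observed between conspecific mitogenomes. Region multipliers
(control region 4×, rRNA 1×, CDS 0.8×, tRNA 0.3×) encode the canonical
ordering — control region fastest, tRNAs slowest. The mean rate 0.025
substitutions/site per unit time with ingroup root age 1 and total depth 3
produces ingroup divergences of a few percent and outgroup divergences near
15%, matching the ranges of real congeneric panels.

Trees are pure-birth, rejection-sampled until every internal branch exceeds
`min_split` (default 8%) of the subtree root age. This conditioning is part
of the study conditions: it emulates panels of clearly distinct lineages and
excludes splits so recent that no finite genome could resolve them — without
it, a sizable minority of pure-birth draws contain internal branches
expecting fewer than a handful of substitutions genome-wide, and topology
"failures" would measure the draw, not the method. Lineage-rate variation is
i.i.d. lognormal per branch (σ = 0.4 by default when enabled), with the
mean-one parameterization.

CDS sites evolve codon-aware by rejection: proposed codon changes creating
stops are always rejected, and nonsynonymous changes are accepted with a
per-gene probability calibrated from the root sequence (enumerating the nine
single-base mutations of every codon, weighted by their TN93 rates) so the
*realized* nonsynonymous:synonymous count ratio targets the configured
dN/dS (default 0.3, mildly purifying). This controls counts — which is what
the count-ratio statistic needs — rather than implementing a full codon rate
matrix. Optional short deletions (≤5 bp) are planted in noncoding regions
only, on random lineages, so reading frames stay intact; insertions are not
generated. Reads are exact substrings from uniform circular positions with
two-component qualities (low-quality probability configurable); instrument
error profiles, heteroplasmy and structural rearrangements are not
simulated. All randomness flows from the single configuration seed.

Because the simulator evolves sites independently given the region/codon
structure, passing recovery tests demonstrates correctness of the inference
chain under the stated model — not robustness to alignment error,
recombination, numts, or context-dependent mutation, none of which the
generator produces.

## Test and acceptance problem sizes

The test suite exercises most components on genomes scaled to 5–30% of full
length (the layout scales proportionally, CDS lengths staying multiples of
3), which keeps the default run to a few minutes; full-length (16.5-kb)
datasets are used where the claim depends on genome-scale resolution:
topology recovery across 100 seeds, the transition-bias and dN/dS targeting
checks, and the read-filter binomial comparison at ~10,000 reads. The
acceptance script reruns the recovery experiment at 30 seeds, one full
pipeline pass (NJ with 1,000 bootstrap replicates, ML, BIC, dating), the
TN93 bias measurement and the read filter, all from a single command-line
seed.

The checks that reproduce published comparative numbers need the 11
GenBank mitogenome accessions, which are not redistributed with the
package; `scripts/fetch_accessions.R` downloads and converts them once on a
networked machine, after which those checks and the panel section of the
acceptance script run automatically.

## Known limitations

Center-star alignment assumes low divergence from the center; the composite
distance model pools one rate structure across all pairs; the ML search is
NNI-only; dating uses a single hard calibration; the dN/dS is a descriptive
count ratio. These match the package's scope — placing a resequenced
mitogenome among close relatives — and are deliberately not generalized
beyond it.
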