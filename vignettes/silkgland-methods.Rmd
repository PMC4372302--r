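---
title: "Methods: models, parameters and design choices in silkgland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in silkgland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkgland)
```

silkgland packages the computations needed to compare the silk-gland
transcriptomes of six Saturniidae wild silkmoths (Antheraea pernyi,
A. yamamai, A. assama, Actias selene, Rhodinia newara, Samia cynthia)
against each other and against Bombyx mori. This vignette explains each
model, its assumptions, the tunable parameters, and the design choices
made where several defensible options existed. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The species tree and the cocoon-color groups

All comparative analyses hang off a fixed rooted seven-taxon species
tree, `make_species_tree()`: B. mori is the outgroup, the Antheraea
species form a clade with A. pernyi and A. yamamai as siblings, Ac.
selene is sister to Antheraea, then R. newara, and S. cynthia is the
deepest Saturniidae split. Branch lengths default to 1 and are
configurable; analyses that need real divergence (contrasts, codon
simulation) should supply them. `color_groups()` fixes the two cocoon
phenotype groups: stable coloration (A. yamamai, R. newara, A. assama)
versus unstable (A. pernyi, Ac. selene, S. cynthia).

## Silk protein features

**Isoelectric point.** `compute_pI()` solves for the pH at which the
Henderson–Hasselbalch net charge of the sequence (side chains C, D, E,
H, K, R, Y plus the two termini) crosses zero, by bisection on [0, 14]
to 1e-4 pH units. The pKa table is an electrophoresis-calibrated set
(`default_pka()`); it is an argument because published pI values for the
fibroin N terminus depend on the (usually unnamed) constants of the
calculator that produced them, and users comparing against another tool
should load that tool's table. `X` residues are ignored for charge.

**Hydropathy.** `hydropathy_profile()` is a sliding arithmetic mean of
the Kyte–Doolittle scale; window width defaults to 9 residues (odd by
construction) and hydrophilicity is reported as the negated scale when
requested. Pairwise comparisons of repeat regions are anchored on a
reference sequence via `align_to_reference()` — global alignment,
BLOSUM62, gap open 10 / extend 1 (all configurable) — and downstream
composition or hydropathy is restricted to columns where neither
sequence is gapped, so only genuinely alignable regions are compared.

**Repeat grammar.** Saturniid fibroin repeat regions alternate
poly-alanine runs with glycine-rich spacers. `decompose_repeats()` turns
maximal runs of `A` of length ≥ `min_run` (default 3 — long enough to
separate runs from incidental alanines) into `polyA` blocks; everything
between is spacer. `motif_inventory()` scans spacers left to right,
greedily trying GGGX, then GGX, then GX (X = any non-glycine residue);
longest-first matching avoids double counting, and residues matching no
motif are reported as an unparsed fraction, so every spacer residue is
accounted for. `detect_regions()` places the N-terminus/repeat boundary
at the first qualifying poly-A run after the conserved 14-residue head,
capped at `nterm_max` (default 120, comfortably above the 87–103-residue
N termini observed in these species). All coordinates are 0-based,
half-open.

## Codon-level molecular evolution

Two routes to dN/dS are provided deliberately, so that each can check
the other.

**NG86 counting.** `ng86_pair()` implements Nei–Gojobori (1986):
synonymous site counts per codon are the fraction of the three
single-nucleotide changes at each position that are synonymous
(mutations to stop codons count as nonsynonymous), averaged over the two
sequences; differences between codons are averaged over all minimal
mutational pathways, excluding pathways through stop codons whenever a
stop-free pathway exists; the Jukes–Cantor correction maps proportions
to distances. ω is undefined (NA) when dS = 0.

**Codon maximum likelihood.** `m0_loglik()` evaluates the one-ratio
(Goldman–Yang-style) codon model on the 61 sense codons: rates are zero
for multi-nucleotide changes and otherwise proportional to the target
codon frequency, times κ for transitions and ω for nonsynonymous
changes, scaled to one expected substitution per codon per unit branch
length. The likelihood uses Felsenstein pruning with transition matrices
from the spectral decomposition of the reversible rate matrix (the
matrix is symmetrized in the π^(1/2) inner product, so the eigen-solve
is numerically stable; negative round-off entries of P(t) are clamped
and rows renormalized). Codon frequencies default to F3x4 computed from
the alignment (positional nucleotide frequencies floored at 1e-4 so no
sense codon is impossible); a uniform-61 option keeps closed-form checks
simple. Gapped codon columns are removed by complete deletion —
the simplest reproducible rule.

`fit_one_ratio()` maximizes over (ω, κ, branch lengths) with L-BFGS-B on
log-transformed parameters, bounds ω ∈ [1e-4, 10], κ ∈ [1e-2, 50],
starting from ω = 0.4, κ = 2 and least-squares branch lengths on
Jukes–Cantor-corrected pairwise distances; everything is stated so the
fit is deterministic. `fit_free_ratio()` gives each branch its own ω,
started from the one-ratio solution; because the models are nested the
free-ratio log-likelihood is never reported below the one-ratio one.
`lrt()` compares nested fits with 2Δl against the chi-square upper tail;
for one-ratio versus free-ratio the degrees of freedom are the parameter
difference, (number of branches − 1).

## Trees, contrasts and reconciliation

`distance_matrix()` offers p-distances and Tajima–Nei (1984) distances
with complete pairwise gap deletion; saturated pairs (p ≥ b) are an
error naming the pair rather than a silent NaN. `nj_tree()` is canonical
neighbor joining on the Q criterion with two deterministic policies:
ties are broken by the lexicographic order of the smallest taxon label
in each cluster, and negative branch lengths are clamped to zero with
the deficit moved to the sibling branch so joined path lengths are
preserved.

`pic_contrasts()` is Felsenstein's recursion for phylogenetically
independent contrasts on a rooted, fully bifurcating tree; polytomies
are refused and `resolve_polytomies()` expands them deterministically
(zero-length branches, children ordered by smallest descendant label).
`pic_correlation()` correlates two traits' contrasts through the origin
and tests with a t distribution on (contrasts − 1) degrees of freedom.
The binary color-retention trait (1 stable, 0 unstable) is treated as a
continuous character, which is how a correlation of expression with a
0/1 label through contrasts has to be read; contrasts that vanish up to
rounding (constant traits) are flagged `zero_variance` with p = 1 rather
than producing a spurious correlation. The default sidedness of the
trait filter is two-sided, with `alternative = "greater"` available for
a strictly positive-association filter.

`reconcile()` embeds a rooted gene tree into the rooted species tree by
LCA mapping: an internal gene node is a duplication exactly when it maps
to the same species node as one of its children; losses along a gene
edge are the species-tree edges skipped minus one, plus one when the
parent is a duplication, and each lost lineage is attributed to the
species node rooting the lost subtree. This is parsimony reconciliation
without rearrangement — weakly supported gene-tree edges are taken at
face value.

## Family expression and differential families

RPKM is used at two levels: per transcript, and per family — total
member reads per kilobase of total member length per million mapped
reads — which makes the family measure invariant to how an assembler
split a gene into transcripts (an identity the tests exercise). A family
is group-specific when its RPKM clears `presence_min` (default 1, a
conventional detection floor) in every species of one group and stays
below it in every species of the other.

Differential families between the color groups use a negative-binomial
exact test with the three species of each group treated as replicates —
the only option open to a design with one silk gland per species, and a
documented caveat: the "dispersion" absorbs both biological noise and
genuine between-species differences. Counts are scaled to the geometric
mean of the library sizes before testing (a deliberately simple
normalization that keeps the test self-contained). The common dispersion
is estimated by conditional maximum likelihood (counts conditioned on
group totals, summed over families), maximized on a log grid refined by
golden-section search; the exact test conditions the group sums on the
grand total and doubles the smaller tail, reducing to the
binomial-conditioned Poisson test at φ = 0. Multiplicity is controlled
with Benjamini–Hochberg at FDR < 0.05.

## GO enrichment

`chisq_enrichment()` is a per-term 2×2 Pearson chi-square without
continuity correction, of annotation status against set membership. The
background must be disjoint from the target — inclusive backgrounds
double-count the target's annotations — and terms with any expected cell
below 5 are flagged rather than dropped. No multiple-testing correction
is applied by default, matching the chi-square-per-term convention of
the web tool this replaces, but `adjust = TRUE` adds BH-adjusted values.
GO-graph ancestor propagation is deliberately not performed; annotations
are taken as given.

## The synthetic-data generators

Every input the pipeline consumes can be generated with planted truth,
and every generator is a pure function of (parameters, seed) that leaves
the caller's RNG state untouched.

* `simulate_families()` evolves each family down the species tree:
  on each edge a lineage is lost with probability 1 − exp(−loss_rate)
  and otherwise duplicated a Poisson(dup_rate) number of times at the
  top of the edge. Events are recorded per edge, and
  `replay_family_events()` reproduces species membership from the event
  table alone — the consistency oracle the tests use. Families losing
  all lineages are emitted as extinct with empty membership.
* `simulate_counts()` plants fold-changes: transcript counts are
  negative binomial (variance μ + φμ²) around family-level RPKM-scale
  rates (log-normal, meanlog 2, sdlog 1), with lengths log-normal(6.5,
  0.5) truncated at 200 bp — the unigene length scale of moth silk-gland
  assemblies — drawn once per family because orthologous members
  conserve length; per-transcript independent lengths would make
  within-group means unequal and put a spurious floor under any
  dispersion estimate. Library sizes default to 2×10⁷ mapped reads per
  species, a realistic mapped fraction of a HiSeq lane. No dispersion or
  library-size figures are published for these libraries; these defaults
  are stated choices, not inferences.
* `simulate_codon_alignment()` draws root codons from the equilibrium
  frequencies and evolves them with the same one-ratio transition
  matrices the fitting code uses — so parameter recovery exercises the
  estimator, not a shared implementation shortcut, via the NG86 and
  closed-form cross-checks. Uniform sense-codon frequencies are the
  simulation default to keep expectations checkable.
* `generate_silk_proteins()` builds one ancestral fibroin-like protein —
  fixed 14-residue head, alanine-free N-terminal remainder of 87–103
  residues, then 12 repeat units alternating poly-A runs (8–14 residues)
  with spacers drawn from the GGGX/GGX/GX grammar — and then applies
  independent per-species substitutions (default 2%, an
  intra-genus-level divergence). Substitutions never introduce alanine
  into the N terminus and never touch the first three alanines of the
  repeat region, so the planted boundary remains exactly detectable;
  substitutions inside poly-A runs are allowed and are why recovery of
  planted poly-A residues is asserted at ≥ 95% rather than exactly.
* `generate_go_annotations()` annotates genes per term independently,
  multiplying the probability by the enrichment factor inside the target
  set (capped at 0.95).

What the generators do not emulate: sequencing reads and assembly
artifacts, indels in codon alignments, annotation noise structured by
the GO graph, or correlated expression between families. Passing tests
therefore demonstrate that the estimators recover the truth of this
generative model at these problem sizes, not that the model captures
every feature of real silk-gland data.

## Problem sizes and numerical choices

The validation suite and the acceptance script use: 300 codons × 7 taxa
× 20 seeds for ω recovery (band ±0.1 around truth 0.3); 500 families for
dispersion recovery (truth 0.2, band [0.1, 0.3]); 2000 replicates for
the type-I calibrations of the NB exact test, the contrast correlation
and the chi-square enrichment; and 1000 families with 50 planted 8-fold
changes for power (≥ 80% at FDR 0.05). These sizes were chosen so each
recovery is decisively inside or outside its band under the generative
model while the whole suite completes in minutes on a laptop.

Numerical details worth knowing: the pI bisection tolerance is 1e-4 pH;
the codon rate matrix is always rescaled to unit expected flux so branch
lengths are substitutions per codon; L-BFGS-B convergence uses factr =
1e8 (about 1e-8 relative); the free-ratio ω of a single-branch tree is
not identifiable separately from its branch length, which is why the
free fit starts at the one-ratio solution and never reports a worse
likelihood; contrasts below 1e-10 × (trait scale + 1) are treated as
exactly zero; and the degrees of freedom reported for the published
one-ratio/free-ratio comparison (16) are the branch count of the rooted
nine-taxon fibroin tree minus one parameter shared — the published test
statistic is reproduced only through its chi-square tail, since the
underlying alignment is not redistributable.

## Known limitations

Species-as-replicates is an assumption forced by the design, not a
statistical virtue; treat the DE family lists as ranking hypotheses.
The NB exact test here uses simple library scaling, not TMM, so strongly
asymmetric transcriptomes would shift logFCs slightly. The chi-square
enrichment inherits the weaknesses of 2×2 chi-square at small expected
counts (flagged, not fixed — use the flag). Reconciliation does not
rearrange weakly supported gene-tree edges, so bootstrap-fragile
topologies inflate duplication counts, and the published per-node
duplication/loss figures for sericins depend on the specific gene trees
used. Real fibroin N termini contain indels; the codon machinery
requires a pre-aligned, in-frame alignment and deletes gapped columns.
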