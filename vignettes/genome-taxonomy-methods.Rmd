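---
title: "Methods: genome-based taxonomy and nitrate-respiration physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-based taxonomy and nitrate-respiration physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`genotax` re-implements, as one tested pipeline, the comparative-genomics
computations used to place a bacterial isolate within a genus and species —
average nucleotide identity (ANI) with aligned fractions, reciprocal-best-hit
average amino-acid identity (AAI), pan/core gene-family accumulation,
concatenated-marker neighbor-joining phylogeny with bootstrap — together
with genome-organisation signatures (GC content and skew, dinucleotide
composition anomalies, hemE-anchored oriC prediction), the RpsL
streptomycin-resistance residue call, and growth-kinetics analysis of
anaerobic nitrate respiration. Every stage is exercisable on synthetic data
with planted ground truth, so the whole pipeline is testable offline.

# Alignment kernel and its conventions

All identity and coverage numbers derive from exact affine-gap dynamic
programming (Needleman–Wunsch with Gotoh's three-state recursion, compiled
in C++ under `src/`; Biostrings supplies sequence I/O and the BLOSUM/PAM
matrices, and a plain-R DP oracle in the test helpers independently
validates scores). A gap of length $L$ costs $g_\text{open} + L\,
g_\text{extend}$. Two conventions are fixed package-wide and stated rather
than inferred, because published identity thresholds rarely say which BLAST
convention they assume:

* **identity** = matches / alignment columns in which neither side is a
  terminal gap. Internal gap columns count against identity; terminal
  overhangs do not. This is the closest simple convention to BLAST percent
  identity.
* **coverage** (per side) = non-terminal-gap aligned span / full sequence
  length. The pan/core thresholds apply coverage to the *longer* protein of
  a pair.

Defaults: BLOSUM62 with gap open 11 / extend 1 for proteins (BLASTp
defaults); match +1 / mismatch −1, gap open 5 / extend 2 for DNA, with a
+2/−3 BLASTn-like preset. "Glocal" mode aligns the whole query against the
best-matching region of the subject with subject-terminal gaps free; it is
the fragment-mapping mode of the ANI machinery.

# ANI

`compute_ani()` is the classic fragment variant: the query is tiled into
1020 bp non-overlapping fragments; each fragment is mapped to the reference
by an exact-k-mer prefilter (k = 10, 24 seeds per fragment, both strands)
followed by glocal DP on the candidate window. A candidate diagonal must be
supported by at least **two** agreeing seed k-mers: a single chance k-mer
hit would otherwise align the fragment to an unrelated window, and such
windows occasionally pass the per-fragment acceptance filter (30 % identity
over ≥ 70 % of the fragment, mirroring the proteome thresholds) and bias the
identity mean downward by whole percentage points at high divergence.
Fragments failing the filter reduce the *aligned fraction* — which is
defined on the query genome and is therefore directional — but never the
identity mean.

Self-ANI is exactly 100 by construction. On substitution-only synthetic
genomes the recovered ANI tracks the planted $100(1-d)$ within 0.1 at
$d \le 0.15$. The species call uses the operational 95–96 % band: below →
different species, above → same, inside → borderline.

The MUMmer-based ANI variant used by popular web services is *not*
re-implemented; published ANI tables computed that way should be expected to
agree only approximately (±0.5) with the fragment variant.

# AAI, gene families, pan/core

All-vs-all global protein alignment with the 30 % identity / 70 %
longer-protein coverage thresholds yields the hit graph. AAI is the mean
identity over reciprocal best hits ("best" by alignment score, ties by
higher identity then lexicographic id; each protein in at most one pair).
Gene families are the **single-linkage** connected components of the passing
hit graph, including within-genome (paralog) edges; singletons are their own
families, so families partition the protein universe. Pan/core curves count
families touching any / all of the first $k$ genomes of an ordering; the
endpoints are order-invariant, which the tests verify over random orders.
Single linkage is the simplest consistent reading of the classical
comparative-microbial-genomics toolchain behaviour; it is stated here
because alternatives (e.g. MCL) would change family counts.

# Neighbor joining and bootstrap

`neighbor_joining()` is the standard Saitou–Nei agglomeration, written
in-package (the tree containers and Newick I/O come from `ape`). Negative
branch lengths are clamped to zero with the deficit moved to the sister
edge; Q-criterion ties break deterministically on the lexicographically
smallest pair of subtree representatives, so results are reproducible across
platforms. NJ is exact on additive matrices; the test battery checks exact
topology and path-length recovery (≤ 1e−9) on random additive matrices of
4–12 taxa.

Bootstrap resamples alignment columns with replacement under an explicit
integer seed, rebuilds the NJ tree per replicate, and reports the percentage
of replicates containing each internal bipartition of the full-data tree as
integer node labels. Distances default to the p-distance with
pairwise-deletion gap handling; a Jukes–Cantor correction is available by
flag, since the original analyses do not state their distance model and only
topology-level agreement is claimed.

A small center-star progressive aligner (`align_markers()`) is provided for
closely related marker sets; it is *not* a general MSA tool, and pre-aligned
input is preferred for anything divergent.

# Genome signatures and oriC

GC content excludes `N` from numerator and denominator; GC skew is
$(G-C)/(G+C)$ with empty windows reported as 0 and flagged. The composition
scan computes, per window and for the whole genome, the dinucleotide
relative abundance $\rho(xy) = f(xy)/(f(x)f(y))$ on both strands, and
$\delta^\* =$ mean over the 16 dinucleotides of $|\rho_w - \rho_g|$.
Windows with $\delta^\* > 0.05$ (a conventional signature-difference scale;
tunable) are flagged and merged. Two caveats are documented deliberately:

* the whole-genome reference signature includes any real island, so a large
  island (10 % of the genome) inflates background deltas toward the
  threshold; the *top* anomaly remains the island, but isolated marginal
  background flags can appear. On null (feature-free) genomes the per-window
  $\delta^\*$ tail reaches ≈ 0.03–0.046 at 10 kb windows — under the
  threshold, but close enough that across re-drawn random batteries an
  isolated marginal window ($\delta^\* \approx 0.05$) crosses it roughly
  once per several hundred windows. Larger windows or a higher threshold
  buy null stability at the cost of resolution; the defaults are documented,
  not optimised.
* $\delta^\*$ is blind to purely mononucleotide (GC-content) shifts, by
  construction of $\rho$.

oriC prediction anchors on *hemE*: the homolog is located by best protein
alignment against a supplied ORF table or a six-frame scan (six-frame ORFs
run stop-to-stop, so the anchor is refined to the aligned span of the query
within the ORF), then the 1 kb intergenic span upstream of the hemE start is
scanned on both strands for 9-mers within 1 mismatch of the DnaA-box
consensus (default the E. coli `TTATCCACA`, as a template), and the first
run of ≥ 50 bp with AT fraction ≥ 0.7 is reported as the duplex unwinding
element (DUE). Box positions are recovered exactly on planted fixtures. DUE
*boundaries* are intrinsically fuzzy: a sliding-threshold detector cannot
localise the edge of an AT-rich element more precisely than about one window
width, so planted-truth tests assert recovery to within 50 bp, and the
reported AT fraction of the merged run can sit marginally below the
per-window floor.

# RpsL resistance call

K42R or K87R in ribosomal protein S12 confer streptomycin resistance
(E. coli numbering). The query is globally aligned to a reference with
validated K42/K87 and the reference columns are mapped through the
alignment, so insertions shift the mapped query position correctly. Arginine
at either mapped site → resistant; a gap → indeterminate; any other residue
→ sensitive with a note (resistance is attributed specifically to
arginine). The packaged reference is a **synthetic stand-in** with validated
K42/K87 (the authentic E. coli sequence could not be bundled); any validated
real reference can be substituted per call.

# Growth kinetics

Doubling times are fitted by least squares on $\log_2(\mathrm{OD}_{600})$
versus time — the slope is directly doublings per hour — inside the longest
contiguous window with $R^2 \ge 0.99$ (ties to the earliest start). The
standard error on the doubling time follows from the slope standard error by
the delta method. Two estimator limitations are worth knowing: with a long
post-arrest plateau in the series, windows at $R^2 = 0.99$ can absorb a few
plateau points and bias the slope low by several percent (raise `r2_min` to
0.995+ or restrict sampling to the growth phase); and on Monod kinetics the
fitted rate estimates the *realised* rate, which is below $\mu_{max}$ when
substrate is near its half-saturation.

Stoichiometry regresses accumulated nitrite on consumed nitrate over points
with positive consumption; slope 1 means strict 1:1 nitrate→nitrite
conversion (no further reduction of nitrite). The yield ratio is
$\max(\mathrm{OD})$ treated / control.

# The simulators: what they state, and what they do not

**Genome sets.** A seeded random ancestor (GC 0.66, matching the high-GC
genus being emulated) carries: core and accessory gene families (families 1
and 2 are hemE and RpsL; genes are ATG + random-synonymous-codon coding
sequence + TAA — a fixed codon per amino acid would give genes an atypical
dinucleotide signature and turn them into artificial islands); three marker
genes (1200/900/1200 bp) extracted per genome from the mutated chromosome;
an oriC block (1000 bp intergenic region upstream of hemE containing a
63 bp DUE of `TAATTAC` repeats, AT = 6/7, and five consensus DnaA boxes
80 bp apart, with flanking sequence kept free of spurious near-consensus
9-mers by rejection sampling — by construction, not by test tuning);
and optional islands generated by a first-order Markov chain with
`P(next = current) = 0.4`. Each descendant receives exactly
`round(d * L)` substitutions at distinct positions outside the oriC
intergenic block, so ungapped identity to the ancestor is deterministically
$1-d$; accessory families absent from a genome are replaced in place by
unrelated same-length sequence (no indels, coordinates shared). An indel
mode exists for stress-testing alignment but is off in acceptance runs.

Descendant proteomes apply exact amino-acid substitution *counts*
(`round(p * len)`) to the ancestral family proteins, decoupled from genome
nucleotide substitutions. Translating the substituted ORFs instead would
make amino-acid divergence a stochastic function of nucleotide divergence
and destroy the deterministic AAI targets the tests rely on; the decoupling
is the deliberate design choice here. RpsL is exempt from divergence and
carries only its configured 42/87 residues.

What the generator does **not** emulate: indel evolution (by default), rate
heterogeneity, codon models, rearrangements, horizontal transfer other than
composition-shifted islands, or annotation noise. A green test therefore
establishes correctness of the *computations* on a stated world — not
robustness to assembly or annotation artifacts of real genomes.

**Growth.** Discrete-time Monod growth on nitrate with strict 1:1 nitrite
production and a hard toxicity threshold: rate
$= \mu_{max}\,\mathrm{NO_3}/(K + \mathrm{NO_3})$ while nitrite is below
20 mM, else 0; OD advances by an exact exponential step (a literal Euler
step biases the fitted log-slope by $\sim r\,\Delta t/2$, about 4 % at the
defaults, violating the package's own recovery targets); nitrate consumed =
ΔOD/yield, capped at the remaining nitrate; nitrite produced equals nitrate
consumed, so $\mathrm{NO_3}+\mathrm{NO_2}$ is conserved exactly pre-noise.
Defaults state the emulated experiment: $\mu_{max} = \ln 2/4.06\,h^{-1}$
(the rich-medium doubling time), initial OD 0.1, nitrate 20 mM (40 for the
high-nitrate scenario), nitrite 0 (6 for the toxicity scenario), yield
0.03 OD/mM, $K = 0.01$ mM — respiratory nitrate reductases have micromolar
half-saturation, so growth is substrate-saturated until exhaustion —
multiplicative OD noise sd 0.02 and additive chemistry noise sd 0.2 mM.

One known model-level discrepancy is documented rather than patched: with a
*hard* toxicity threshold and strict 1:1 conversion, the 6 mM-nitrite yield
ratio is bounded below by $(20-6)/20 = 0.7$ (plus the inoculum
contribution; observed ≈ 0.74–0.78), whereas the emulated experiment shows
roughly half yield. Reproducing "half" would need sub-threshold nitrite
inhibition of the growth rate, which the minimal mechanism deliberately
omits — adding it would trade away the clean $\mu_{max}$ recovery the
kinetics tests verify. The qualitative pattern (reduced yield, partial
nitrate consumption, earlier arrest) is reproduced.

# Numerical and interface choices

* Coordinates are 0-based half-open internally; BED output follows suit, and
  printed lengths are `end − start`, matching published genome-region table
  arithmetic. Percentages round half-up at 2 decimals; note that published
  tables occasionally truncate instead (a 0.01 discrepancy on one
  re-computed fraction is expected and documented).
* All randomized operations take an explicit integer seed and restore the
  caller's RNG state; there is no global random state.
* `N` bases are allowed in genomes, score as mismatches in alignment, and
  are excluded from GC statistics.
* The CLI (`exec/genotax`, or `genotax_cli()`) mirrors every flag in an
  optional JSON config file (`--config`); JSON is used because no YAML
  parser is available in the supported dependency set. Logs go to stderr,
  results to files.

# Known limitations

Fragment ANI is approximate relative to MUMmer-based services; the
composition scan's genome-wide reference is contaminated by large islands;
DUE boundaries carry ±50 bp uncertainty; the center-star aligner is for
small, closely related marker sets; the growth model is a stand-in mechanism
(no pH/temperature effects, no nitrite sub-threshold inhibition); and
published pan/core/exclusive counts for real genome sets depend on
annotation versions and are not reproducible offline.
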