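---
title: "Methods: models, estimators and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models and algorithmic choices
behind `mitocomp`, the conventions the package commits to where the
literature leaves room, and the design of the synthetic-cohort generator
used for end-to-end validation. It is a methods reference: every number
quoted here is a *parameter* of the package, not an empirical result.

## 1. Genome model and coordinates

A `mitogenome` is a circular molecule stored on a single deposited
strand. Internally every feature location is a set of 0-based,
half-open `[start, end)` segments on that strand, with a per-feature
strand flag. GenBank's 1-based inclusive coordinates are converted on
read and write. The origin is never moved implicitly: a feature that
spans the origin is represented as two segments, exactly as a GenBank
`join()` across the sequence end would record it. All downstream code
(extraction, partitioning, gene order) treats the two representations
of the same molecule — either strand of deposition, any rotation — as
equivalent where the statistic is strand- or rotation-invariant.

Translation uses NCBI genetic code 4 (mold mitochondrial; `TGA`
encodes tryptophan) with `ATG`, `GTG` and `TTG` accepted as start
codons. ORF scanning is codon-exact in all six frames and reports
stop-terminated runs only.

## 2. Composition and the region partition

GC content and the skews

$$\mathrm{GC\ skew} = \frac{G - C}{G + C}, \qquad
  \mathrm{AT\ skew} = \frac{A - T}{A + T}$$

are computed over unambiguous bases only; ambiguity codes are excluded
from both numerator and denominator.

`partition_regions()` assigns every position of the genome to exactly
one of five classes. Because annotations overlap (an accessory ORF
inside an intron, an intron inside a CDS), the partition applies a
fixed precedence:

1. core-PCG exon
2. RNA gene (rRNA, tRNA)
3. accessory ORF / non-core CDS
4. intron
5. intergenic

Higher classes win at overlapping positions. This is a modelling
commitment, not a discovery procedure: an intronic ORF is counted as
ORF, not intron, so class lengths always sum to the genome length and
cohort-wide fractions are comparable.

## 3. Codon usage

RSCU for codon $j$ in a synonymous family of size $k_i$ is
$x_{ij} / (\frac{1}{k_i}\sum_{j'} x_{ij'})$. Under code 4 the stop
family is $\{TAA, TAG\}$ (there is no `TGA` stop). A family with zero
total count yields `NA` rather than 0, so unused families do not
masquerade as biased ones. PCA of per-gene RSCU profiles is done on
centred (not rescaled) RSCU values; RSCU is already normalised within
family, so further scaling would up-weight rare families.

## 4. Distances and Ka/Ks

K2P distances use the closed form
$d = -\frac{1}{2}\ln(1-2P-Q) - \frac{1}{4}\ln(1-2Q)$ with pairwise
deletion of sites containing gaps or ambiguity. Saturated pairs (a log
argument $\le 0$) return `NA` rather than an arbitrary cap.

NG86 Ka/Ks follows Nei & Gojobori (1986) with these conventions made
explicit:

- Synonymous site counts $S$ per codon are the expected fraction of
  single-nucleotide changes that are synonymous, summed over the three
  positions; $S + N = 3$ per codon exactly.
- Between two codons differing at $m$ positions, all $m!$ substitution
  pathways are weighted equally; pathways passing through a stop codon
  are excluded. If every pathway is excluded the codon pair contributes
  nothing.
- A change that *creates* a stop codon as a terminal state is counted
  as nonsynonymous.
- Jukes–Cantor correction is applied to $p_s = S_d/S$ and
  $p_n = N_d/N$; $\omega = K_a/K_s$ is `NA` when $K_s$ is 0 or
  undefined.

The test suite checks these against an independent recursive
pathway-enumeration oracle, not only against fixtures.

## 5. Repeats

Dispersed repeats are found by exact $k$-mer seeding ($k = 16$) on both
strands, chaining seeds that share a diagonal, and verifying each chain
by banded realignment; identity is reported over the aligned span.
Self-comparison uses only $k$-mers that occur more than once, so the
trivial self-diagonal is never reported.

Tandem repeats use a period-restoring scan (periods up to 200) with a
majority consensus per period. Three thresholds define what counts as
an array: at least 2 copies, at least 80% position-wise agreement with
the consensus, and a minimum array length of 24 nt. The length floor
exists because below ~24 nt almost any sequence contains short
periodicity by chance; it is a detection definition, chosen a priori,
not a tuned value. Overlapping calls are resolved smallest-period-first
(a poly-A run is reported with period 1, not as its period-3 harmonic),
suppressing a candidate when at least half its length is already
covered.

**Limitation:** neither repeat detector is aware of the circular
origin; an array or repeat copy that spans the origin of the deposited
sequence is found only up to the origin. Rotating the deposition point
before scanning is the workaround.

## 6. cox1 intron position classes (Pcls)

Each cox1 intron insertion site is mapped from its host genome onto a
reference species' cox1 coding sequence by aligning the two coding
sequences and reading off the reference coordinate of the insertion
point. The Pcl name is `P<position>` with the position in reference
coding-sequence nucleotides. Two conventions matter:

- If the insertion point falls opposite a reference gap, the site is
  flagged and assigned to the end of the nearest upstream reference
  codon, so the reported position is always a codon-consistent
  reference coordinate.
- A Pcl is **common** when it occurs in at least
  $\lceil \theta \cdot n_{\text{species}} \rceil$ species (default
  $\theta = 0.2$), otherwise **rare**. The ceiling means small cohorts
  degenerate gracefully: with 4 species a single occurrence already
  meets the 20% threshold.

## 7. Gene order, breakpoints and synteny

Gene orders over 17 canonical markers (15 core PCGs + 2 rRNAs) are
extracted as signed circular sequences and canonicalised by rotating to
put cox1 first, reflecting (reversing and negating) when cox1 lies on
the minus strand. The breakpoint distance counts oriented adjacencies
of one order absent from the other; each adjacency $(a, b)$ is
canonicalised to $\min(a{\mid}b,\ -b{\mid}-a)$ so the distance is
symmetric and invariant under rotation and strand of deposition. A
single internal inversion therefore scores exactly 2. Duplicate
canonical markers are an error, not silently resolved.

Synteny blocks reuse the dispersed-repeat machinery across genomes:
seeded chains verified by realignment, reported with coordinates,
strand and identity.

## 8. Alignment and phylogeny

Pairwise and progressive alignment use an affine-gap (Gotoh)
Needleman–Wunsch kernel in C++. For coding genes alignment is
codon-aware: gaps are whole codons, so concatenated supermatrices keep
reading frame and `PCG12` (third positions removed) is well defined.

Supermatrix kinds: `PCG` (14 conserved PCGs; rps3 is excluded from
concatenation because its elevated rate and frequent absence make it a
poor concatenation partner), `PCG12`, `PCGR` / `PCG12R` (adding rnl and
rns), and `AA` (translations). Genes missing in a species are
gap-padded and flagged. Trees are neighbor-joining on K2P supermatrix
distances; bootstrap resamples columns with replacement and maps
bipartition frequencies onto the full-data tree. Fitch parsimony
scoring is provided for topology comparison and is cross-checked
against an independent implementation in the test suite.

Distance-based NJ was chosen over likelihood methods deliberately: it
is fast enough for resampling-heavy validation, fully deterministic
given a seed, and adequate for the within-order divergences the
package targets. For deep or heterogeneous datasets a dedicated ML
package is the right tool.

## 9. The synthetic cohort generator

`simulation_spec()` / `make_cohort()` generate fully annotated circular
genomes with a recorded ground truth (`$truth`) for every statistic the
package computes. The defaults describe the study system the package
is designed around — AT-rich polypore mitogenomes — and are fixed a
priori:

- **Substitution model:** K80 with $\kappa = 2$ on a 16-taxon tree
  whose internal branches are all $\ge 0.02$ substitutions/site, with
  stationary base frequencies $A = 0.36$, $C = 0.125$, $G = 0.14$,
  $T = 0.375$ (AT $\approx 73.5\%$, matching the AT richness and
  positive GC skew of the target genomes).
- **Rate heterogeneity:** per-gene rate multipliers (e.g. rps3 2.0,
  nad3 1.6, atp9 0.3, cox1 0.6) emulate the fast/slow gene spectrum of
  fungal mitochondria.
- **Architecture:** 15 PCGs (cox1 1596 nt; conserved-PCG total
  13008 nt), rnl/rns, 25 tRNAs, and intergenic spacers sized so genomes
  span roughly 49–68 kb.
- **Planted signal:** a cox1 intron plan (9 species; two positions
  shared by a three-species *Sanghuangporus*-like trio), a
  rearrangement plan (one transposition shared by four *Porodaedalea*
  species, two independent inversions), a 500-nt dispersed duplicate
  and an `(ACGTT)×8` tandem array per genome, and one GC-enriched
  110-codon accessory ORF inside the first cox1 intron.

What the generator deliberately does **not** emulate: recombination,
within-genome rate variation beyond the per-gene multipliers,
indel evolution inside genes (genes differ by substitution only, so
alignment is easy by construction), mobile-element turnover of
introns, and tRNA remolding. Validation results on the cohort
therefore certify the *analysis machinery*, not the difficulty of real
data.

Everything is driven by a single integer seed; the same spec and seed
reproduce the cohort byte-for-byte.

## 10. Validation strategy

Three layers, all in the test suite and `scripts/acceptance.R`:

1. **Closed-form fixtures** — K2P at $P=0.1, Q=0.05$; the
   single-pathway NG86 glycine fixture; RSCU family-sum identities.
2. **Estimator recovery** — seeded simulation replicates checking that
   mean K2P estimates are unbiased at true distance 0.1 and that NJ
   recovers the generating 16-taxon topology in (nearly) all
   replicates.
3. **Planted-truth recovery** — every planted feature of the default
   cohort (introns, orders, repeats, region lengths, clades) must be
   recovered from the annotated genomes alone, with independent
   hand-rolled oracles (adjacency counting, pathway enumeration,
   six-frame ORF brute force) guarding the main implementations.
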