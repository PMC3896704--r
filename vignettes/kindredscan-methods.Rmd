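---
title: "IBD-based variant prioritization in extended families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD-based variant prioritization in extended families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kindredscan` prioritizes rare, predicted-damaging variants shared identical
by descent (IBD) by all affected members of extended multiplex pedigrees.
This vignette documents the models, the tunable parameters, the synthetic
data the package validates itself against, and the numerical and design
choices a maintainer should know about.

## The inheritance-vector HMM

### Model

For a pedigree with $m$ meioses, the hidden state at each marker is the
inheritance vector $v \in \{0,1\}^m$: one bit per meiosis indicating which
parental haplotype (grandpaternal or grandmaternal) was transmitted. Under
the Haldane model (no crossover interference, identical male and female
maps), each bit flips independently between adjacent markers with
recombination fraction

$$\theta = \tfrac{1}{2}\left(1 - e^{-2d}\right),$$

where $d$ is the inter-marker map distance in Morgans. The prior over
vectors is uniform.

Given $v$, every individual's two allele slots map deterministically to
founder allele slots (founders have two each). The emission probability of
the observed unphased genotypes at a marker with panel alternate-allele
frequency $p$ sums over founder-allele assignments $b \in \{0,1\}^{2f}$ with
independent $\mathrm{Bernoulli}(p)$ priors:

$$P(G \mid v) = \sum_b \prod_{s} p^{b_s}(1-p)^{1-b_s}
  \prod_{i \in \text{typed}} P\!\left(g_i \mid b_{s_1(v,i)} + b_{s_2(v,i)}\right).$$

The sum factorizes over connected components of the founder-allele graph
induced by $v$ and the non-missing individuals, so each component is
enumerated separately rather than the full $2^{2f}$ space. An optional
per-genotype error rate $\varepsilon$ replaces the genotype indicator with
$P(g_i^{obs}\mid c) = 1-\varepsilon$ on match and $\varepsilon/2$ otherwise;
it is 0 in bare `compute_sharing()` and 0.01 in the pipeline composition
`segments_genomewide()`, where array genotyping error is expected.

Forward–backward posteriors are normalized per marker, and the reported
statistic is

$$s_t = \sum_v P(v \mid G_{1:M})\,
  \mathbf{1}\!\left[\exists\, \text{founder slot carried by every affected}\right],$$

the posterior probability that all affected members share at least one
founder allele IBD. This "at-least-one-shared-allele" event is the sharing
definition used throughout; it is the natural event for a dominant-acting
heterozygous variant inherited from one ancestor. A single affected member
shares with itself, so $s_t \equiv 1$; adding affected members can only
shrink the event.

### Founder symmetry

Swapping a founder's two haplotype labels toggles a fixed set of meiosis
bits (one per transmitting meiosis of that founder) and leaves emissions,
the uniform prior, and the sharing indicator invariant, because both
haplotypes carry the same frequency prior. Emissions are therefore computed
once per orbit of the XOR subgroup generated by these founder masks and
copied to the other orbit members — a $2^{f}$-fold reduction — while
transitions and posteriors remain on the full space. The reduction is exact;
the test suite verifies the full pipeline against brute-force enumeration
over all inheritance vectors (max absolute difference $\le 10^{-8}$ on
random pedigrees with up to 10 meioses).

### X chromosome

On the X, fathers transmit their single X to daughters deterministically and
nothing to sons, so only maternal meioses carry a bit (one per non-founder).
Males have one allele slot; their calls use the diploid hemizygous
convention (0/2), and a male heterozygous X call is treated as missing. The
X is analyzed only for families compatible with X-linked inheritance (a
single founder X allele could be carried by every affected member — no
male-to-male transmission on any connecting path).

### Capacity

The state space is $2^m$. The default cap is `max_meioses = 16`
(configurable): at $m = 16$ the stored forward/emission arrays for a
450-marker chromosome are ~250 MB, which we consider the practical ceiling
for interactive desk use; larger pedigrees should be split or trimmed.
Pedigrees with marriage loops (consanguinity) are rejected at validation —
the inheritance-vector space and the founder-allele factorization assume an
outbred structure.

### Error handling before the HMM

Two guards keep single genotyping errors from zeroing the chain likelihood:

- genotypes implicated in a duo-level Mendelian inconsistency are wiped
  (set missing) for that marker before sharing is computed;
- a marker whose genotypes are inconsistent with *every* inheritance vector
  is treated as missing (uniform emission) instead of aborting.

Both mirror the genotype-error handling conventions of classical multipoint
linkage software.

## Segment calling

A marker is IBD-flagged iff some window of `window_markers` (default 10)
consecutive retained markers containing it has sharing strictly greater
than `sharing_threshold` (default 0.5) at **every** marker; ties at the
threshold do not qualify. Maximal runs of flagged markers become segments
whose endpoints are the first and last flagged markers' physical positions
(1-based inclusive; BED export converts to 0-based half-open). Chromosomes
with fewer markers than the window require all markers to qualify. A
mean-over-window alternative rule was considered and rejected in favor of
the stricter every-marker reading.

### Resolution limits

Two properties of this rule matter when interpreting recall on synthetic
data. First, segment endpoints are quantized to marker positions, so a
variant between the outermost qualifying marker and the true recombination
breakpoint is missed. Second, and more importantly, the window imposes a
minimum segment span of `window_markers` × spacing. With biallelic markers,
sharing among cousins is only *resolvable* at markers where the shared
ancestor is heterozygous and both descendants' transmitted alleles can be
determined — roughly one marker in 2–4 even at allele frequency 0.5 — so the
posterior ramps approximately linearly across uninformative stretches
around each haplotype switch point, trimming a few resolvable markers from
each segment end. At 1 cM marker spacing the combined effect caps
end-to-end recall of a mid-segment causal variant at roughly 0.86–0.90 for
cousin pairs; on dense arrays (0.1–0.3 cM spacing, where a 10-marker window
spans ~1–3 cM) the same rule behaves as a noise smoother and these losses
essentially vanish. We verified the posterior itself is exact against
enumeration; the losses are properties of the window rule at coarse
spacing, not estimation error.

## LD pruning

`ld_prune()` implements greedy windowed pairwise pruning (window 50 markers,
step 5, $r^2 > 0.5$; genotype-dosage correlation). Within each window, while
any retained pair exceeds the threshold, the lower-MAF member of the pair is
removed (ties drop the later marker); the window then slides. Monomorphic
markers have undefined $r^2$ and are never removed for correlation. In the
pipeline, LD is measured on a reference-panel genotype table
(`prune_gt`) rather than on the family's own handful of samples: with 6–13
genotypes the sample $r^2$ exceeds 0.5 by chance for a large fraction of
independent marker pairs, which would discard ~40% of informative markers.

## Variant filter cascade

Per family, in order: call quality (VQSLOD strictly > 0; genotypes with
depth < 4 set missing — "minimum 4x" includes 4; records with no remaining
calls dropped), predicted-damaging effect (missense, nonsense, splice site;
splice sites are annotated within two nucleotides of an exon boundary),
rarity (minor allele frequency strictly < 5% in each of three external
panels, the external exome cohort, and the internal control chromosomes
`ac/an`; survivors tiered **novel** when absent from the external exome
catalog, the population-reference flag and dbSNP — internal-control absence
is *not* required for novelty), per-model segregation, and IBD restriction
(1-based inclusive interval membership).

Segregation conventions: `het` requires every affected, sequenced member to
be heterozygous (carrier homozygotes are not accepted); `hom` requires all
homozygous alternate; `xlinked` (X only) requires affected males hemizygous
and affected females heterozygous (homozygous females acceptable via
`xlinked_female_hom_ok`). A missing genotype in any affected member fails
the record — the conservative reading of "present in all affected".
Unaffected carriers are never penalized (incomplete-penetrance tolerance).
Records with unknown control frequency (`an = 0`) are kept and flagged.
Individuals with unknown affection status are excluded from every
affected-set computation, in both the IBD and the segregation stages.

Cross-family aggregation flags genes hit in at least two families
(`multi_family`) and families contributing two or more distinct candidate
variants in one gene (`cis_pair_families` — in this design two heterozygous
variants segregating together through the same ancestor are in cis; no
trans-phasing is attempted).

## Enrichment and QC

The enrichment statistic is the upper-tail hypergeometric probability
$P(X \ge k)$ of seeing $k$ candidate-list genes among the $n$ genes with
surviving variants, drawn from a universe of $N$ captured genes containing
$K$ list genes, with fold $(k/K)/(n/N)$. Terms are computed in log space
(`lchoose` + log-sum-exp). The observed count is included in the tail
(the standard enrichment convention; the upper tail is the only sensible
side for an enrichment claim). Gene symbols are uppercased and
whitespace-stripped; no alias resolution is attempted, so mixed-source gene
lists should be pre-normalized. `permutation_null()` draws random hit sets
of the observed size and provides a model-free cross-check. The universe is
supplied explicitly (genes captured by the design) rather than inferred.

Concordance QC matches sites across platforms by chromosome, position and
alleles after harmonization (swapped ref/alt flips the genotype, strand
complements are matched through complementation; unharmonizable sites are
excluded), compares only co-called genotypes, and averages per-sample
fractions unweighted. Call-rate QC passes a sample at ≥ 98% non-missing
calls (inclusive).

## The synthetic-data generator

The generator emulates the study design the pipeline targets: multiplex
families each containing at least one affected cousin pair.

- **Pedigree templates**: `cousin_pair` (8 members, exactly 2 affected),
  `avuncular_plus_cousin` (2–5 affected), `second_cousin` (2–3 affected).
  Affected members are ~90% male by default, reflecting the strong male
  bias of the target phenotype. All members are array-genotyped (such
  studies genotype substantially more relatives than they sequence);
  only affected members are exome-sequenced.
- **Marker map**: evenly spaced markers at 1 cM (default 4 autosomes × 450
  plus 200 X markers ≈ 2,000 positions), panel allele frequencies uniform
  on [0.2, 0.8] so markers are informative for sharing estimation.
- **Gene dropping**: founder haplotypes drawn allele-wise from panel
  frequencies; meioses transmit recombinant haplotypes under the Haldane
  model; founder-slot descent labels are tracked alongside alleles for
  truth bookkeeping. X transmission follows the hemizygous rules.
- **Causal injection** by rejection: the variant is assigned to founder
  haplotype(s) — a common-ancestor haplotype for `het`/`xlinked`, one
  haplotype of every founder lineage for `hom` — and the causal
  chromosome's drop is re-drawn until the configured pattern holds in all
  affected members, so marker data and causal variant share one coherent
  descent history (no post-hoc genotype editing). Impossible configurations
  (e.g. X-linked with an affected father–son pair) fail with a
  configuration error.
- **Array noise**: independent per-call missingness and single-allele-flip
  errors (defaults 1% and 0.5%).
- **Exome tables**: background variants with an effect-class mix
  (40% missense, 25% synonymous, 30% intronic, 3% splice site, 2%
  nonsense), a frequency mixture (10% novel, 45% rare < 4%, 45% common
  ≥ 5%), catalog membership flags correlated with frequency, binomial
  control counts over a 308-sample cohort with per-variant genotyping
  missingness uniform on [0, 2%] (yielding denominators around 604–616),
  per-sample depths (Poisson mean 55 with a 2% shallow fraction), a
  configurable VQSLOD failure fraction (default 8%), and genotypes from
  independent single-locus gene drops (hence Mendelian-consistent).
- **Reference panel**: unrelated Hardy–Weinberg genotypes at the map
  frequencies, used for LD pruning.

Default scale is desk-sized (6 families, ~2,000 markers, 5,000 exome
variants per family); the full study scale (40 families, ~90,000 variant
positions) is reachable by configuration. All outputs are bit-reproducible
from one root seed via deterministically derived per-stage seeds.

**What the simulator does not emulate**: linkage disequilibrium among
background markers (they are treated as pre-pruned; `ld_prune` is exercised
on engineered correlated data instead), sequencing read-level artifacts,
population stratification, indels, and locus heterogeneity within a family.
Passing tests on this synthetic data therefore demonstrate the correctness
of the inference machinery under the stated generative model, not
robustness to every property of real cohort data.

## Numerical and design notes

- All thresholds use the stated strict/inclusive conventions: VQSLOD
  strictly > 0, depth ≥ 4, MAF strictly < 0.05, sharing strictly > 0.5,
  call rate ≥ 0.98.
- `hypergeometric_tail` is exact to ~1e-14 relative against an
  integer-exact Pascal-triangle oracle over all configurations with
  N ≤ 60.
- Obligate-carrier inference returns the unsequenced individuals on the
  descent chains between the carriers and their most recent common
  transmitting ancestors; when the ancestors are an unresolvable couple
  directly above the carriers (affected sib pair), both are returned with
  status `candidate` rather than guessing.
- Meiosis order (sorted by child id, paternal before maternal) defines the
  inheritance-vector bit order; it is deterministic and invariant to input
  row order.
- Half-founders (exactly one recorded parent) are rejected at validation:
  the inheritance-vector space requires founders to have both parents
  absent. Pedigrees should be trimmed or completed before analysis.
- The `run_all()` orchestration writes deterministic text outputs (no
  timestamps), so identical configuration and seed reproduce every output
  byte for byte.

## Problem sizes used in the test and acceptance runs

Unit tests use pedigrees of 4–14 members with 1–300 markers; exhaustive
oracle comparisons run on pedigrees of up to 10 meioses and 20 markers. The
end-to-end recall experiment uses 100 cousin-pair replicates on 2 autosomes
× 150 markers at 1 cM with 5,000 exome variants per family; the desk-scale
study run uses the generator defaults above. These sizes were chosen so a
full validation cycle completes in minutes on a single core while keeping
every statistical check adequately powered.
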