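---
title: "Methods: models, thresholds and design choices in epiABA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in epiABA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiABA)
```

epiABA joins five analyses around one biological question: how an
RdDM-deficient maize mutant (*mop1-1*) re-wires its transcriptional and
epigenetic response to abscisic acid. This vignette is the package's own
account of the underlying models, the thresholds that matter, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open.

## Coordinates and gene anatomy

All genomic containers are `GRanges`: 1-based, closed intervals, the native
Bioconductor convention. GFF3 input therefore needs no coordinate shift, and
all interval arithmetic (promoters, flanks, tiling, overlap) goes through
`GenomicRanges`, which removes any ambiguity about half-open versus closed
ends. The TSS of a gene is its strand-aware 5′ end — the annotation start on
`+`, the annotation end on `-`. A promoter of length $L$ is the $L$ bases
immediately upstream of the TSS (`promoters(upstream = L, downstream = 0)`);
flanks mirror on strand reversal by construction. Promoters and flanks
running off a chromosome edge are truncated at base 1 (never dropped) and
flagged `truncated`, preserving gene counts; promoters are *not* clipped at
neighbouring genes, since the upstream extraction this emulates did not
document clipping either.

## DEG groups

Each of the four genotype×treatment pairwise comparisons contributes an
up/down group pair (wildtype ABA response I/II, loss-of-RdDM response
III/IV, mutant ABA response V/VI, mutant-vs-wildtype under ABA VII/VIII). A
gene joins the up group when log₂FC ≥ `lfcMin` and FDR ≤ `fdrMax`, the down
group when log₂FC ≤ −`lfcMin`. Both boundaries are **inclusive**
(defaults 0.95 and 0.05); the sources conflict on whether the FDR cutoff is
strict, and the inclusive reading of the stated "≤" wins here, with both
thresholds configurable. Within one comparison the up and down groups are
disjoint by construction.

Overlap accounting distinguishes genes from memberships: `total_memberships`
is the sum of group sizes, `shared_memberships` the memberships held by
multi-group genes, and `unique` the genes in exactly one group — so
`unique = total_memberships − shared_memberships` and
`total_genes = unique + shared` always hold. This bookkeeping is the only
reading under which published three-way totals of this kind are mutually
consistent, and it is what `overlapSummary()` reports. Contra-regulated
genes (an up membership and a down membership in different comparisons) are
necessarily shared.

The low-abundance filter retains a gene when CPM ≥ `cpmMin` (default 0.58,
inclusive) in at least $k$ libraries. The filter this emulates leaves $k$
unstated; we default $k$ to the smallest experimental group size (2 when no
grouping is given) and expose it. FDR is consumed, not recomputed; for
synthetic tables `recomputeFDR()` offers Benjamini–Hochberg from raw
p-values via `stats::p.adjust`.

## Methylation

The central statistic is **weighted methylation**: for the cytosines of one
context in a region, $m_C = \sum \#C / \sum(\#C + \#T)$ — a pooled ratio, not
a mean of per-site ratios, so aggregation over disjoint regions is exactly
count-additive (a tested identity). Evaluability filters are mode-specific:
genome-wide regions need mean coverage ≥ 5 and ≥ 2 sites; promoters relax
coverage to 2×. Separately from evaluability, context level minima (10% for
CG/CHG, 1% for CHH) gate whether an evaluable region *counts as methylated*
in summaries; the two gates are deliberately separate configuration knobs
because conflating them makes neither rule testable.

Differences come in two flavours with different units: relative,
$100(m_A - m_B)/m_B$ (percent of the reference, undefined at $m_B = 0$,
where the region is excluded with a warning) and absolute,
$100(m_A - m_B)$ (percentage points, exactly antisymmetric).
Differential-promoter calls use absolute differences: ≥ 40 points for
CG/CHG; for CHH, the lower sample must be ≤ 5% with a difference ≥ 15
points ("one sample" is read as the minimum of the two — the only reading
consistent with both clauses); a CG gain ≥ +10 points is additionally
flagged `CG_hypermethylated`, and a call satisfying both rules reports the
joined label.

Promoter tiling is TSS-anchored: tile 1 is the 100 bp adjacent to the TSS,
indices increasing upstream, so the biologically interesting −0.25 to
−0.75 kb window is addressable as tiles 3–7 regardless of strand. Tiles
with no covered site are non-evaluable and excluded from per-gene averages
and metagene means (never imputed as zero). Truncated promoters simply
contribute the tiles they retain.

Bisulfite **non-conversion** is estimated from the unmethylated
chloroplast-like contig as $nc = 1 - $ `conversionRate()`, and pooled levels
are corrected by inverting the observation model,
$p = (p_{obs} - nc)/(1 - nc)$, truncated at zero. This correction matters:
at the default 0.5% non-conversion, an uncorrected mutant CHH level of
~1.3% is inflated by a third, biasing the genotype relative difference by
roughly 7 points. Symmetric CG sites are pooled as independent calls;
destranding is a no-op for pooled ratios.

## Motifs and the regulatory cascade

The ABRE is matched as an exact degenerate string (`CACGYGKCS`, bracket
notation accepted) on both strands via `Biostrings::matchPattern(fixed =
"subject")`: pattern ambiguity codes are honoured, subject bases are
literal, so an `N` in the sequence never satisfies a constrained position.
Overlapping matches all count. A scored position-weight model with p-values
would add a scoring threshold with no published value to anchor it; exact
consensus matching is deterministic and fully testable against a naive
sliding-window oracle.

No coupling-element (CE) consensus is part of the core definition, so
strict mode scans ABRE only; a literature-derived CE1-like default
(`TGCCACCGG`) is available opt-in (`ceMotif =`), and is what the simulator
plants. It was chosen so that neither strand contains a `CACG` seed —
a planted CE can never fabricate an ABRE hit.

A DEG is a **primary** ABA target with ≥ 2 ABREs, or 1 ABRE plus a CE, in
its 2-kb promoter; a curated override list can force the call for
literature-documented direct targets (the override asserts direct
regulation, not differential expression — non-DEGs stay non-primary).
Primaries propagate **one step** through the GRN edge list: secondary
targets are the DEG-restricted targets of edges whose regulator is primary,
minus the primaries; self-loops are excluded by default and primaries
absent from the regulator column simply contribute nothing. Multi-step
closure exists behind `steps =` but is not part of any headline number.
The cascade summary is the explained fraction,
$100\,(n_{primary} + n_{secondary})/n_{DEG}$.

## 24-nt siRNA depletion

Losing RdDM removes a large 24-nt siRNA population, so total-count
normalization of mutant libraries inflates every surviving species. miRNAs
are biologically undisturbed between the genotypes and anchor the
correction: per miRNA, the mut/wt CPM ratio on replicate-pooled counts;
the factor is the **median** of those ratios (robust to the occasional
outlier miRNA; ratio-of-sums is implemented as the alternative, and
miRNAs with a zero count in either genotype are excluded and logged).
Promoter fold changes are then corrected as
`raw_lfc − log2(factor)`; zero-count sides get a 0.5 pseudocount.

A promoter is assessable at pooled CPM ≥ 1 in at least one genotype;
it is **depleted** when corrected log₂FC ≤ −1 *and* a two-sided binomial
test rejects at p ≤ 0.05. Under "no depletion beyond the compositional
shift", the mutant count among a promoter's pooled reads is binomial with
$p_0 = f\,L_{mut}/(f\,L_{mut} + L_{wt})$, where $f$ is the factor and $L$
the library sizes. Both halves of the rule are needed: the fold-change
floor keeps trivially significant small shifts out, and the test keeps
low-count noise out. Note a promoter with *equal* raw counts in both
genotypes is genuinely depleted relative to the compositional expectation —
the rule calls it so. Per-group summaries report gene counts, depleted
counts and the rate $100\,n_{dep}/n$ to two decimals; empty group subsets
are omitted with a warning rather than reported as zero.

## TE context

TEs intersecting a gene's 2-kb upstream or downstream flank are reported
per gene ("adjacent" is implemented as intersects-the-flank; a
nearest-only mode with ties kept exists behind a flag, and overlap is what
a closest-feature search reports at distance zero anyway). Superfamily
composition is a percentage vector over the closed 13-code set
(RLC/RLG/RLX, RIL/RIT, RST, DTA/DTC/DTH/DTM/DTT/DTX, DHH), deduplicated on
TE identity by default so a TE flanking several genes counts once in the
distribution; per-gene records remain available. The background is the
whole supplied TE annotation, and foreground-vs-background contrasts are
percentage-point deltas. No enrichment test is attached: the deliverable
is the composition itself.

## The synthetic-data generator

`simulateDataset()` emits, deterministically under one seed, everything the
pipeline reads. Defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `mutantChhScale` | 0.32 | genotype-wide CHH factor in the mutant (a 68% reduction) |
| `wtAbaChhGain` | 0.111 | relative CHH gain under ABA, wildtype promoters only |
| `mirnaGlobalFactor` | 2.2 | mut/wt miRNA CPM compositional factor |
| `baselineCG/CHG/CHH` | 0.80 / 0.65 / 0.04 | context methylation levels |
| `readDepth` | 10 | mean bisulfite coverage per cytosine (Poisson) |
| `nonConversion` | 0.005 | bisulfite non-conversion rate |
| `fracAbaResponsive` | 0.25 | genes ABA-responsive in wildtype |
| `fracMop1Dependent` | 0.20 | of those, responsive in wildtype only |
| `fracAmplifiedInMutant` | 0.30 | genes ABA-responsive only in the mutant |
| `effectLfcMean/Sd` | 2.0 / 0.6 | true log₂ effect distribution, random sign |
| `statNoiseSd` | 0.2 | Gaussian noise on observed log₂FC (0 = noiseless) |
| `mutantSirnaScale` | 0.25 | residual siRNA abundance at depleted promoters |
| `fracSirnaDepleted` | 0.25 | truly depleted promoters |

Genes sit on a regular grid (one per slot, alternating strands) so
promoters never overlap and motif planting is collision-free; the layout is
validated before any file is written. DE tables are generated directly —
true log₂FC plus Gaussian noise, z-based p-values, BH adjustment — because
count-level DE fitting is out of scope; with `statNoiseSd = 0`
classification recovers the truth table exactly, which the tests assert.
Promoter backgrounds are uniform-composition DNA; planted ABRE realizations
are drawn from the degenerate consensus and the finished genome is
**re-scanned**, so the truth table records observable motif content
(background hits included) rather than intended counts.

The methylome is site-annotation based: positions and contexts are labels,
not derived from the genome sequence (the sequence is used for motif work
only). Background sites are scattered uniformly; promoters carry a regular
grid of one CHH site per 10 bp (H = A/T/C makes real promoter CHH sites
denser still, so this is conservative) and one CG and CHG site per 200 bp.
The ABA CHH gain is applied *positionally* — any CHH site inside a promoter
region, including background sites that land there — so position-based
re-analysis recovers the configured effect without dilution. The
conversion control is a 100-kb chloroplast-like contig with 20,000 sites:
a sparse control would propagate its sampling error into every adjusted
level, amplified wherever CHH levels approach the non-conversion rate.

What the generator does **not** emulate: sequence-capture probe design and
its locus selection, read-level artifacts (M-bias, mapping bias,
duplicates), linked sites and regional methylation autocorrelation,
overlapping or nested gene models, realistic TE length/nesting structure,
and biological replicate variance beyond Poisson/binomial sampling. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated sampling model, not robustness to every artifact of real
bisulfite or small-RNA data.

## Problem sizes and numerical choices

The recovery analyses (acceptance script and the corresponding test) use
600 genes on two 2-Mb chromosomes, 20,000 background CHH sites plus ~200
CHH sites per promoter (~126,000–140,000 CHH sites per estimate) at 10×
depth — sizes at which the pre-computed binomial sampling error of the
pooled relative difference is ~0.35 points on the −68% effect and ~0.8
points on the +11.1% effect, comfortably inside the ±2-point recovery
band, while a full run stays under half a minute. The mutant effect is
pooled genome-wide; the wildtype ABA effect is pooled over the promoter
compartment that carries it, mirroring a promoter-anchored capture design.

Ties and degenerate inputs are handled explicitly throughout: boundary
values pass inclusive thresholds (CPM 0.58, log₂FC 0.95, FDR 0.05,
coverage 5.0); empty regions, empty gene lists and empty TE sets return
non-evaluable results, empty profiles or errors as documented rather than
NaN; zero reference methylation makes a relative difference undefined, not
infinite; equal-distance TEs in nearest-only mode are all kept.

## Known limitations

DE statistics and small-RNA counts are consumed as given — there is no
count-model inference, and the binomial depletion rule, while calibrated
and tested, is a deliberate simplification of a dispersion-aware
differential test. Exact-match motif scanning finds the consensus only;
degenerate sites diverging from it score zero. The GRN is used as a static
edge list: tissue filtering is supported but no edge weights or directions
of effect are modelled. These are scope boundaries, not accidents; each
sits behind a documented function surface so a richer model can be swapped
in without touching the rest of the pipeline.
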