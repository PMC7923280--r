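---
title: "Designing and validating a SNP microarray panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating a SNP microarray panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Medium-density genotyping arrays for livestock are built from a large
pool of sequencing-discovered SNPs, of which only a small fraction can
be placed on the array. The design goal is twofold: the retained SNPs
should be *reliable* (well genotyped, clearly flanked, manufacturable
as probes, informative in the target population) and *evenly spaced*
along the genome, so that downstream association and relationship
analyses see the whole genome at a roughly constant marker density.
`alpacapanel` implements the selection procedure used for the alpaca
(*Vicugna pacos*) 76K array — a genome assembled into tens of
thousands of scaffolds, most of them not assigned to chromosomes — and
the population-genetic checks used to validate the resulting panel.

# Staged quality filtering

Each candidate SNP carries five attributes: site Phred quality,
genotyping rate (GR, the fraction of samples with a call), minor
allele frequency (MAF), a vendor probe design score in $[0,1]$, and a
flank-clear flag (no other SNP within 35 or 40 bp, center-to-center;
another variant inside the probe flank destabilises hybridisation).
Selection proceeds through six rounds of decreasing stringency
(`default_round_schedule()`):

| round | GR | MAF | flank |
|---|---|---|---|
| 1 | ≥ 0.45 | 0.05–0.50 | 40 |
| 2 | ≥ 0.45 | 0.05–0.50 | 35 |
| 3 | ≥ 0.15 | 0.04–0.50 | 40 |
| 4 | ≥ 0.15 | 0.04–0.50 | 35 |
| 5 | ≥ 0.15 | 0.01–0.039 | 40 |
| 6 | ≥ 0.15 | 0.01–0.039 | 35 |

Phred quality (> 10, strict) and design score (≥ 0.60, inclusive)
never relax. The comparison operators follow the printed protocol
exactly: quality is strict, the rest inclusive. Duplicate records at
one locus are collapsed first, keeping the higher-quality copy.

# Location-score selection

Every scaffold is tiled into 40 kbp fragments (`partition_fragments()`;
the terminal fragment is clipped). Within a fragment spanning
$[S, E)$, a SNP at position $a$ scores

$$\mathrm{LS}(a) = (E - S) - 2\,\lvert a - \tfrac{S+E}{2}\rvert
               = 2 \min(a - S,\; E - a),$$

maximal at the fragment midpoint and approaching zero at the ends.
Taking the per-fragment maximum therefore keeps consecutive selected
SNPs near the 40 kbp spacing. Rounds are visited strictest-first: a
fragment filled in round $r$ is never revisited, so each entry records
the first round whose thresholds its SNP meets within that fragment.

A second, densifying set is then selected. Each fragment is divided
into five 8 kbp subfragments (numbered 1–5); if the first-set SNP sits
in subfragment $i$, the second SNP is sought in the target
subfragment $t = ((i - 1 + 2) \bmod 5) + 1$ — "two subfragments down,
clockwise", so 4 wraps to 1 and 5 to 2. Within the target the same
round schedule applies and the score is computed against the
*subfragment* midpoint: selecting "for subfragment $t$" is read as
centring within $t$, which keeps the second SNP well separated from
the first (they always sit two subfragments apart).

Finally, SNPs overlapping candidate-gene intervals (fibre-quality and
colour genes: the KRT/KRTAP clusters, ASIP, MC1R, TYRP1, KIT) are
added if manufacturable (design ≥ 0.6) and clearly flanked; they are
exempt from the one-per-fragment rule. `assemble_panel()` merges the
three sets, deduplicating by locus with the candidate label taking
priority.

Design choices where the procedure was genuinely open:

* **Ties** in location score break to higher MAF, then lower
  position — the MAF preference matches the design's stated bias
  toward informative SNPs, and the position rule makes selection
  deterministic.
* **Short terminal fragments** use their true midpoint and compress
  the five subfragments proportionally (width = length/5), so every
  scaffold remains eligible for both sets.
* **Coordinates** are 0-based half-open internally; VCF positions are
  1-based and converted on read. BED intervals are half-open as usual.
* **Round relaxation for the second set** is applied per target
  subfragment (not once per fragment), the natural reading when each
  subfragment is its own selection universe.

# Coverage accounting

A fragment is *covered* when it contains at least one panel SNP
(candidate SNPs count). Covered length is the sum of such fragments'
lengths, reported per chromosome and for the localized / unassigned /
total scaffold groups; percent coverage divides by the reference
length of the group, and SNP density divides SNP counts by reference
(not covered) megabases. Inter-SNP intervals are measured to the
previous panel SNP on the same scaffold, with the first SNP measured
from the scaffold start — under this construction the histogram bin
counts always sum to the panel size, matching how the published
spacing table totals equal the SNP counts. The published coverage
table also prints an "average interval" column whose construction is
not stated and is not covered-length/SNP-count; the package reports
its own definition above and does not attempt to reproduce that
column.

# Panel validation

Validation works on a samples × SNPs matrix coded 0/1/2 (ALT-allele
copies) with missing calls.

* **Genomic relationships** (`compute_grm()`): the VanRaden-type
  estimator
  $G_{jk} = \frac{1}{N}\sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
  {2 p_i (1 - p_i)}$ over polymorphic SNPs. $N$ is adjusted per pair
  to the SNPs non-missing in both samples (pairwise-complete), which
  avoids bias from missingness at the cost of slight non-positive-
  definiteness; with the near-complete matrices the simulator produces
  the two conventions agree closely.
* **Trio parentage** (`classify_trios()`): a parent–offspring pair is
  concordant when its $G$ lies in $[0.35, 0.65]$ (expected 0.5);
  half-sib pairs use $[0.15, 0.35]$ (expected 0.25). The windows are
  configurable defaults — the published analysis reports verdicts, not
  thresholds — and are wide enough to absorb the small downward bias
  that plug-in allele frequencies estimated from a sample containing
  relatives induce. Values *above* the window (a duplicated sample
  posing as its own parent) are flagged, not concordant.
* **Inbreeding** (`inbreeding_f3()`): the uniting-gametes estimator
  $\hat F_i = \frac{x_i^2 - (1 + 2p_i)x_i + 2p_i^2}{2p_i(1 - p_i)}$,
  averaged per sample over non-missing polymorphic SNPs; negative
  under heterozygote excess.
* **Concordance** (`genotype_concordance()`): two call sets are
  intersected on samples and SNPs; a call is comparable when
  non-missing in both and, where depths accompany the sequencing-based
  set, supported by ≥ 3 reads. The primary score is the mean of
  per-sample concordances, with the pooled ratio reported alongside
  (the aggregation is otherwise underdetermined).
* **FST** (`fst_pairwise()`): Weir–Cockerham, ratio-of-sums over SNPs,
  the field default when no estimator is printed; negative estimates
  are reported as computed.
* **LD pruning** (`ld_prune()`): sliding windows of 50 SNPs, step 5,
  $r^2 > 0.5$ drops the later member of the pair — common toolkit
  defaults, since only the outcome count of the original pruning run
  is known.
* **PCA** (`pca_structure()`): eigenvectors of $G$ scaled by root
  eigenvalues; the sign of each component is fixed by making its
  largest-magnitude loading positive, so runs are reproducible.

# The synthetic-data generator

The generator (`sim_config()` and friends) emulates the statistical
structure the analysis assumes, so the whole pipeline runs and is
tested with no external data:

* **Genome**: scaffold lengths uniform within a range; a configurable
  fraction (default 0.76, matching the share of the reference genome
  that is chromosome-assigned) carries chromosome labels.
* **Allele frequencies**: ancestral ALT frequencies are Beta(1, 3) by
  default. The discovery spectrum of the real callset is unpublished;
  this shape is the package's own calibration, chosen once because it
  yields a mean panel MAF of ≈ 0.22, in line with the array's reported
  0.215 ± 0.139.
* **Population structure**: founders split evenly over four
  subpopulations (the four-farm sampling design), whose frequencies
  diverge from the ancestral ones by a Balding–Nichols draw at an
  FST-like scalar (default 0.1) — the minimal standard model that
  produces nonzero FST. Optional within-subpopulation inbreeding makes
  a founder autozygous at a site with probability $f$.
* **Pedigree**: trios take distinct founders as sire and dam by
  default; an explicit sire assignment can reuse sires to create
  half-sib families. Progeny genotypes arise by Mendelian
  transmission, so error-free trios never show opposing homozygotes.
* **Sequencing calls**: per sample × site depth is Poisson at mean 6×
  (the reduced-representation sequencing depth of the study design);
  ALT read counts are binomial given the true dose and recorded in AD.
  A zero-depth site is missing. The *call* equals the true genotype
  and is then swapped to one of the other two codes with probability
  `genotype_error_rate`. We deliberately do not call genotypes from
  the sampled reads: at 6× depth a read-based caller miscalls
  heterozygotes at a rate set by the depth distribution rather than by
  the error dial, and the generator's purpose is an *interpretable*
  error channel whose rate downstream concordance statistics should
  recover exactly. Depth still matters — it drives missingness and
  the ≥ 3-read comparability rule.

What the generator does **not** emulate: restriction-site fragment
placement (sites are uniform along scaffolds), linkage disequilibrium
between nearby sites (sites are independent given the pedigree), base-
calling error profiles, and batch or plate effects. Passing tests
therefore show that the selection arithmetic and the estimators are
correct under the assumed statistical model, not that the pipeline is
robust to every artefact of real sequencing data.

# Problem sizes and numerical notes

The test suite and the acceptance script use simulation sizes chosen
so each estimator's sampling error is well inside its tolerance:
10,000 SNPs for relationship recovery (binomial SE of a
parent–offspring $G$ mean over 60 pairs ≈ 0.01), 20,000 SNPs × 100
samples for inbreeding recovery (±0.02 band), 145 samples × 5,000
SNPs for concordance (±0.01 band), and 5,000 SNPs × 2 × 50 samples
for FST (±0.02 band). Degenerate inputs are defined errors, not
silent results: all-missing SNPs for MAF, empty schedules, zero-length
references, pedigree ids absent from the genotype matrix, and sample
pairs sharing no genotyped SNP (NA with a warning).

# Reference tables

`alpaca76k_reference()` ships the published summary tables of the
alpaca 76K design (per-round selection counts, set sizes, the
fragment-length spacing histogram, the coverage table, candidate-gene
counts) as frozen inputs. They serve as arithmetic cross-checks —
percent-coverage recomputation and additivity of the printed counts —
and as the source of the default round schedule; the package does not
regenerate them.
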