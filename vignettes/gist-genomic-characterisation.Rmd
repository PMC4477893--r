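---
title: "Methods: purity-aware genomic characterisation of an impure tumour"
author: "gisttools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity-aware genomic characterisation of an impure tumour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gisttools)
```

`gisttools` collects the statistical machinery needed to characterise a
tumour genome sequenced together with a matched normal when the tumour
sample is *impure* — a substantial fraction of its cells are admixed
normal cells, as is typical for resected gastrointestinal stromal tumours
(GIST). The package was built around the analysis of a very low-risk
gastric GIST, but every stage is parameterised and works on any
tumour/normal allele-count data of the same shape. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions taken where more than one reading was defensible.

## 1. The binomial founder-mutation model

**Problem.** Among somatic mutations, we want the *founding* mutations:
those present in essentially all tumour cells, as a driver acquired at
tumour initiation must be. Read counts alone cannot be compared naively
against the KIT driver's allele fraction, because allele sampling in
sequencing is stochastic: a true founding mutation can easily be
under-represented in the reads at its site.

**Model.** Let $p$ be the tumour purity. At a heterozygous diploid site
covered by $n$ reads, each read carries the mutant allele independently
with probability $q = p/2$ (only tumour cells carry the mutation, on one
of two alleles), so the alt-read count of a founding mutation is
$X \sim \mathrm{Binomial}(n, p/2)$. The classifier accepts a mutation
with $a$ alt reads as founding iff $a \ge k(n)$ where

$$k(n) \;=\; \max\{\,k \ge 1 : P(X \ge k) \ge \gamma\,\},$$

with inclusion level $\gamma = 0.95$: by construction at least 95% of
true founding mutations pass, at any coverage. The tail is computed by
exact term-by-term summation of the binomial pmf, adding the smallest
terms first; around $n \approx 30$ consecutive thresholds differ by tail
masses of order $3\times10^{-3}$, so neither a normal approximation nor a
careless summation order is acceptable. When no $k \ge 1$ reaches the
required tail mass (tiny $n$), the threshold is floored at 1: a call
must always have at least one supporting read.

```{r thresholds}
build_threshold_table(12, 15)
founder_threshold(c(13, 14, 28, 33, 37))
```

**Parameters.**

* `purity` (default **0.6**, dimensionless fraction). Histology for the
  motivating tumour estimated 60–70% tumour cells; 0.6 is the unique
  value in that range consistent with the threshold being 1 up to
  coverage 13 and 2 from 14 (at 0.65 the threshold reaches 2 already at
  13). It is an explicit argument everywhere.
* `het_factor` (default **1/2**). The allele-dosage factor. Exposed so
  hemizygous sites (e.g. on an arm under monoallelic loss) can be
  classified with factor 1; the default model is strictly
  heterozygous-diploid.
* `inclusion` (default **0.95**). The designed sensitivity. Raising it
  lowers thresholds (more founders kept, more subclonal passengers
  admitted).

A wording subtlety: an equivalent-looking rule "largest $k$ with
$P(X > k) > 0.05$" does *not* reproduce the stated behaviour under any
parameter pair we examined; the implemented 95th-percentile criterion
above is the definition consistent with the designed 95% inclusion and
with the published threshold sequence, except for a single published
entry ("4 for n ≥ 19", where the exact computation gives 3, with 4 first
reached at n = 24) which we treat as a typo and exclude from validation.

**What the model is not.** There is no multi-sample clonal
deconvolution, no cancer-cell-fraction posterior and no copy-number
adjustment: the rule is a one-sample inclusion test, deliberately
minimal.

## 2. The somatic-variant filter cascade

Variants enter as tumour/normal records with per-strand tumour alt
counts. The cascade applies, in a fixed order, six independent
predicates: somatic (control alt reads ≤ `max_control_alt`, default 0),
strand support (alt reads on both strands), depth (both samples ≥
`min_depth`, default 10), transcribed region, non-silent effect, and
novelty (no known SNP id). The order is fixed only so that per-stage
attrition counts are well defined; the surviving set is order-invariant,
which the test suite checks by permutation, together with idempotence.

Two readings were open and are documented rather than guessed around:
"absent in the control" is implemented as a configurable tolerance with
default 0; and the depth rule is applied to *both* samples (the
conservative symmetric reading — a reliable allele-frequency estimate
needs depth on both sides). Effect and region classes are consumed as
input annotations; the package never predicts functional impact.

## 3. Arm-level LOH and purity from B-allele frequencies

At a germline-heterozygous SNP the control shows B-allele frequency
(BAF) near 0.5. If the tumour cells have lost one allele of the arm and
the sample has purity $t$, the average allele copies per cell are
$2 - t$, of which the retained allele contributes 1 and the lost allele
$1 - t$; the observed BAF concentrates at

$$\frac{1-t}{2-t} \quad\text{or}\quad \frac{1}{2-t},$$

depending on phase. We fold the BAF ($b = \min(f, 1-f)$), removing
phase, and summarise each arm by the median folded BAF of usable sites
(control BAF in `[0.4, 0.6]`, depth ≥ 10 in both samples). Inverting
the mixture gives the purity estimate $\hat t = (1-2b)/(1-b)$, computed
only on called arms with at least 20 usable sites.

```{r loh}
expected_baf_under_loh(0.65)
sim <- simulate_loh_genome(purity = 0.65, seed = 1)
summ <- arm_summaries(sim)
summ[summ$loh_call %in% TRUE, ]
```

**The LOH decision rule.** The analysis this package systematises called
arm-level LOH by inspection of the BAF bands; a reproducible rule must
be fixed. With known purity the cutoff is the midpoint between 0.5 and
the expected LOH BAF; with unknown purity (the default) a fixed folded-BAF
cutoff of 0.4 is used. The fixed cutoff is deliberately the default: the
*median folded* BAF of a truly diploid arm is biased below 0.5 by
roughly $0.8/\sqrt{\text{depth}}$ (folding maps the upper half of the
sampling distribution down), i.e. ≈ 0.45 at depth 45 and ≈ 0.44 at
depth 30, so a purity-aware midpoint cutoff computed at low purity can
collide with the diploid distribution at moderate depth, while 0.4
separates both sides with comfortable margins for purities ≥ 0.4 and
depths ≥ 30.

**Depth ratios.** Each sample's depths are divided by its genome-wide
median before the arm-level tumour/control ratio is taken, which removes
library-size differences. Under monoallelic loss the normalised ratio is
$(2-t)/2$ (0.675 at $t = 0.65$), not 0.5: an unnormalised "half the
control depth" can only arise when a genuine copy loss is conflated with
a global coverage difference between libraries. Both conventions can be
computed from the outputs; the package reports the normalised one.

Only whole-arm monoallelic loss is modelled — no segmentation, no
subclonal copy number, no uniparental disomy. That is exactly the
resolution of the claim the package reproduces.

## 4. Screening-panel enrichment against population frequencies

A prevalence screen reports, per variant site, in how many of $N$ panel
samples the variant was seen. Whether a site is *enriched* is tested
against its population minor allele frequency $m$: under the null the
panel's $2N$ alleles each carry the variant with probability $m$, and the
observed allele count is tested with a one-sided upper-tail exact
binomial test (`stats::binom.test`). Each carrier sample is counted as
**one** mutant allele — zygosity is not recorded in such screens, so this
is the conservative lower bound; a two-alleles-per-carrier mode is
provided. Sites with unknown MAF are reported untested rather than
guessed. No multiple-testing adjustment is applied by default (a
Bonferroni switch exists): the reproduced analysis made a single
unadjusted claim, and the package's default mirrors exactly that.

```{r screen}
sp <- screen_panel(znf407_screen_panel())
sp
```

On the packaged ZNF407 screen (52 samples, 117 observations at 20
sites, 15 with known MAF), exactly one site — rs75994611, 4 carriers
against 1.2 expected alleles, $p \approx 0.033$ — exceeds its population
expectation at $\alpha = 0.05$. Note the discreteness of the exact test
makes it conservative; the synthetic null suite bounds the realised
type-I error at 6%.

## 5. C2H2 zinc-finger scanning and substitution mapping

C2H2 zinc fingers coordinate a zinc ion with two cysteines and two
histidines; the residues between the second C and the first H form the
DNA-recognition helix, which extends through the two histidines. The
scanner matches the spacing pattern

```
C - x(1,5) - C - x(10,14) - H - x(3,5) - H
```

(a relaxation of the canonical `C-x(2)-C-x(12)-H-x(3)-H`; the bounds are
arguments, since finger counts in large proteins genuinely depend on
pattern stringency). Matching is greedy left-to-right and
non-overlapping; when several anchor placements start at the same
cysteine, the one closest to canonical spacing wins, ties going to the
shortest. This tie-break is not cosmetic: in the second packaged ZNF407
motif an internal histidine sits 4 residues after the second cysteine,
inside the recognition helix — the spacing window (10–14) keeps it from
being misread as a coordinating residue.

```{r zf}
zf <- znf407_zinc_fingers()
scan_c2h2(zf$motif_seq[3])
unlist(locate_substitution(scan_c2h2(zf$motif_seq[3]), 20))
```

Substitutions are mapped to roles (`zinc-coordinating`,
`recognition-helix`, `spacer`, with a `helix_adjacent` flag between the
histidines) plus the distance upstream of the terminal histidine — the
structurally loaded quantity for, e.g., an arginine-to-tryptophan change
two residues before the terminal H. No position-specific scoring matrix
is evaluated: in-pattern position is the computed output, profile
scores are out of scope.

The published finger spans (24 residues) disagree with the published
22-residue motif strings; the strings are treated as authoritative, and
the packaged offsets (`znf407_zinc_fingers()`) are offsets within the
strings.

## 6. Methylation normalisation and sample clustering

Array methylation probes have probe-specific dynamic ranges that are
stable across samples. Given reference intensities of the fully
unmethylated and fully methylated state per probe, read-outs are
linearly rescaled between the anchors and clipped to $[0,1]$ —
comparable to a beta value. This linear-anchor rescale is the minimal
model consistent with that intent; a conventional
$M/(M+U+\text{offset})$ beta transform is provided as an alternative
entry point. No probe-chemistry correction beyond the per-probe rescale
is attempted.

Probes are then filtered by across-sample variance (strictly greater
than `threshold`, default 0.1, with the $n-1$ denominator — the
conventional sample variance; the choice matters because the cutoff is
hard) and samples are clustered with distance $d = 1 - r$ (Pearson,
across probes) under complete linkage. $1 - r$ rather than $1 - |r|$:
anticorrelated methylomes are maximally distant. Agglomeration is
delegated to `stats::hclust`, which is deterministic given the input
order; with continuous data, exact ties have probability zero, and the
test suite confirms partition invariance under sample reordering.

A property worth knowing before trusting a dendrogram: a block of
probes that all shift in the *same* direction between groups is
invisible to correlation distance once background probes are removed —
every sample vector over such a block is flat up to noise, so all
correlations collapse toward 0. Separation under $d = 1 - r$ requires
probe-level variation *within* the profile: either retained background
probes (whose shared bimodal profile anchors the correlation) or a
contrast running in both directions (hyper- and hypomethylated probes),
which is what real group contrasts look like. The synthetic generator
exposes both regimes (`fraction_reversed`).

## 7. The synthetic world

`simulate_*` generators produce every input the pipeline reads, with
truth labels, under exactly the models the analysis assumes:

* **Variants** (`simulate_variant_table`): founder alt counts
  $\sim \mathrm{Binomial}(n, p/2)$; subclonal counts use
  $p\,c/2$ with clone fraction $c \sim U(0.05, 0.3)$ (not part of the
  original stated analysis; chosen to sit clearly below the founder band
  at desk scale); germline hets at 0.5 in both samples; strand split
  $\mathrm{Binomial}(\text{alt}, 1/2)$; control contamination 0 by
  default. Depth is Poisson with mean **45**, bracketing the motivating
  genome's tumour/control averages of 42 and 50; a negative-binomial
  option adds overdispersion.
* **LOH genome** (`simulate_loh_genome`): 44 synthetic 100 Mb autosome
  arms, 500 germline-het SNPs per arm, one arm (default `14q`) under
  monoallelic loss at purity 0.65 with tumour depth scaled by
  $(2-t)/2$ and BAF at the mixture bands.
* **Screen** (`simulate_screen_panel`): carriers per site are the number
  of 52 diploid samples with ≥ 1 mutant allele under
  $\mathrm{Binomial}(2, m)$; the default MAF vector is the 15 known
  frequencies of the packaged screen padded with five typical values;
  enriched sites inflate $m$ by ×8 (a desk-scale choice giving clear
  power separation).
* **Methylation** (`simulate_methylation`): 200 informative probes at
  group means 0.8 vs 0.2 (sd 0.05, 10 + 10 samples) over 2000
  background probes with $\mathrm{Beta}(0.5, 0.5)$ means (the
  characteristic bimodal methylome shape) and sd 0.01.
* **Protein** (`simulate_zf_protein`): C/H-free random background with
  canonical fingers planted at recorded coordinates, the two packaged
  ZNF407 motifs first, and one variant per finger two residues upstream
  of the terminal H.

Identical seeds give byte-identical outputs. **What a green test does
not establish:** the generators draw from the very models the estimators
invert, so recovery tests validate correctness of the implementation,
not robustness to real-data violations (mapping artefacts, GC waves,
subclonal copy number, batch effects in methylation, population
stratification in the screen). Those failure modes are outside the
package's claims.

## 8. Numerical choices and degenerate inputs

* Binomial tails: exact pmf summation, smallest terms first; oracle
  equivalence against the closed-form tail is tested for all
  $n \le 200$ and five purities.
* Thresholds floor at $k = 1$; coverage must be ≥ 1.
* `estimate_purity_from_baf` refuses fewer than 20 sites and clips to
  $[0,1]$; arms with no usable SNPs report `n_snps = 0` and no call.
* Zero-variance sample vectors make correlation undefined; clustering
  refuses them by name rather than propagating `NA` distances.
* Unknown MAFs are `NA` end to end and excluded only from testing,
  never from bookkeeping.
* The filter cascade validates enum fields and count invariants per
  record and names the first offending record in errors.

## 9. Known limitations

* The founder rule is heterozygous-diploid; on LOH arms it should be
  used with `het_factor = 1`, and this coupling is left to the user.
* Arm-level LOH only; focal events within an arm dilute the median
  folded BAF and can be missed.
* The screen test conditions on the printed MAF as exact; sampling error
  of the population frequency itself is ignored.
* The motif scanner is pattern-based; it neither scores against a
  profile nor models degenerate fingers with unusual spacings outside
  the configured bounds.
* Reference-anchor normalisation assumes the anchors bracket the
  observed intensities; values outside are clipped, not flagged.
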