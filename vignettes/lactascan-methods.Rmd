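---
title: "Methods: allele statistics, FST, the LSBL scan, and haplotype structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele statistics, FST, the LSBL scan, and haplotype structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactascan)
```

# The problem

Lactase persistence (LP) in humans is governed by a small set of enhancer
SNPs in intron 13 of *MCM6*, upstream of *LCT* on chromosome 2. Field
studies of LP genetics typically produce small per-population samples
(5–16 diploid individuals), several co-segregating LP alleles, and — when
combined with array data — a chromosome-scale SNP backdrop on which to
look for selection. `lactascan` implements that analysis layer: the
per-population allele-frequency and predicted-phenotype table, exact
Hardy–Weinberg checks, Weir–Cockerham F~ST~, a windowed locus-specific
branch length (LSBL) scan, and haplotype-structure summaries, together
with a synthetic-data generator that exercises every stage without any
external download.

# Data model and conventions

Genotypes are stored as derived-allele dosages in {0, 1, 2} with `NA` as
the missing marker. Two conventions matter throughout:

* **Derived-allele orientation.** Dosages count the *derived* allele,
  never the VCF ALT allele; at sites where REF is derived, input calls are
  flipped on read. Swapping REF/ALT labels in an input file therefore
  leaves every dosage unchanged (a tested invariant).
* **Missingness reduces denominators.** A missing genotype removes two
  chromosomes from the site's allele total for that population; it is
  never imputed and never counted as ancestral. This mirrors the
  per-individual dropouts expected from Sanger panels.

Coordinates are 1-based physical positions on the labeled reference build
and are authoritative for windowing; the familiar "-13910"-style
LCT-upstream labels are carried for presentation. All storage is
forward-strand: at -13910 the strands are complementary, so the variant
is stored as G>A with the upstream-reading label `C>T`. At -14010 the
segregating allele in the bundled fixture (A) is *not* the LP-associated
allele (C); the variant record carries both, and phenotype prediction and
the LP frequency layer count only the canonical LP allele.

# The allele-frequency layer

For a population of $N$ genotyped diploids with derived count $c$,
$\hat p = c / 2N$, and the binomial standard error is

$$\mathrm{SE} = \sqrt{\frac{p(1-p)}{2N}},$$

with the 95% interval $p \pm 1.96\,\mathrm{SE}$ clamped into $[0,1]$ — a
frequency interval extending below zero is truncated, as in the source
tables. The predicted LP phenotype of a population is the percentage of
individuals carrying at least one LP-associated derived allele; an
individual heterozygous at two LP loci counts once, and a missing call at
one locus does not disqualify a carrier at another.

The exact Hardy–Weinberg test conditions on the observed allele counts
and enumerates every heterozygote count of compatible parity; the
two-sided p-value sums the probabilities of configurations no more
probable than the observed one. With $n \le 16$ this enumeration is both
exact and instantaneous, which is why a conditional exact test (rather
than a chi-square approximation) is the only test offered. A monomorphic
site returns $p = 1$ by convention. The test is conservative
(super-uniform p-values under the null), which the suite verifies on
1,000 simulated tables at $n = 16$.

Rank correlations (e.g., an LP-allele frequency against per-population
admixture proportions supplied as a plain TSV) use Spearman's $\rho$ with
mid-rank ties. For $\le 10$ populations the permutation p-value is exact
— all $n!$ pairings are enumerated and compared two-sidedly on $|\rho|$ —
and for larger sets the $t$ approximation is used; both are always
reported because which convention a given publication used is usually
unknowable.

# Weir–Cockerham F~ST~

Per site, the two-population Weir & Cockerham (1984) estimator partitions
variance into components $a$ (among populations), $b$ (among individuals
within populations), and $c$ (within individuals), with
$\hat\theta = a/(a+b+c)$. Observed heterozygote counts feed $c$ directly
— no Hardy–Weinberg assumption enters the estimator. Three numerical
conventions:

* a site where both populations are monomorphic for the same allele has
  $a+b+c = 0$; the estimate is *undefined* and propagates as missing into
  LSBL and out of window SNP counts (a 0/0 variance ratio carries no
  information, and coding it as 0 would bias window means toward zero);
* $\hat\theta$ may be slightly negative for undifferentiated populations;
  negative estimates are retained by default, with `clamp = "zero"`
  provided as a control (the scan's outlier set is insensitive to the
  choice on the default synthetic scenario — a tested regression
  property);
* per-locus estimates feed the scan, matching the per-locus definition of
  LSBL; the multi-locus ratio-of-sums average is available separately for
  reporting.

The implementation is validated against an independently coded textbook
transcription of the estimator on 10,000 random small genotype tables to
1e-12, plus the exact boundary cases (fixation for opposite alleles gives
exactly 1).

# The LSBL scan

For a test population and two references (in the original design one
African and one non-African reference, to absorb admixture),

$$\mathrm{LSBL}_{pop} = \frac{F_{ST}(r_1, pop) + F_{ST}(r_2, pop) - F_{ST}(r_1, r_2)}{2}$$

is the branch length assigned to the test population on the
three-population star tree. Branch-length additivity
($\mathrm{LSBL}_x + \mathrm{LSBL}_y = F_{ST}(x,y)$ under role rotation)
is checked numerically. Reference panels larger than the field samples
are downsampled without replacement (default target 16 individuals,
seeded and reproducible) so that estimator noise is comparable across the
three pairs.

Windowing and calling:

* **Windows** are non-overlapping 500 kb tiles anchored at coordinate 0
  of the chromosome. The anchor is a deliberate choice: anchoring at the
  first SNP would make the tiling depend on the data, while a fixed
  origin is deterministic and build-stable.
* Windows with fewer than 50 defined-LSBL loci are dropped. The grand
  mean and SD behind the Z scores are computed over the *retained*
  windows only, avoiding noise from sparse windows.
* $z = (\bar{\mathrm{LSBL}}_w - \bar{\mathrm{LSBL}})/s$, two-sided
  normal $p = 2\Phi(-|z|)$ (at the 3-SD flag threshold,
  $p = 0.0027$), Benjamini–Hochberg $q$ across the windows of the
  scanned chromosome. The outlier flag uses the strict inequality
  $|z| > k$ with $k = 3$ by default. Both $p$ and $q$ are always
  reported, since published window p-values are often ambiguous about
  multiplicity correction.

## Power of window means against an isolated locus

The default synthetic scenario (below) injects a *single* strongly
differentiated locus. It is worth being explicit about what the scan can
and cannot do with that: a locus with per-site LSBL around 0.5 inside a
~200-SNP window raises the window mean by roughly 0.5/200 ≈ 0.0025,
while the between-window SD of window means under the island model is of
the same order (~0.005). A single unlinked locus therefore gives the
window a z-advantage well under one SD, and the injected window is the
top-ranked window only in a small fraction of replicates — the
acceptance run reports the measured rates rather than asserting high
power. The per-*site* signal is strong (the injected locus typically
lands in the top 1% of per-site F~ST~ values; a tested property). Real
selective sweeps elevate many linked SNPs across the window, which is
the regime the windowed statistic is designed for; the simulator draws
loci independently by design (see below), so it deliberately represents
the hard single-locus case. Null calibration, by contrast, is fully
testable and tested: with no injected locus, windows with $|z| > 3$
appear at well under 1%.

# Haplotype structure

From phased input, the haplotype matrix shows one row per chromosome over
all SNPs polymorphic in the selected populations within ±30 kb of the
core positions; rows are stably sorted so chromosomes carrying each
derived LP allele cluster together. The bifurcation tree roots at all
haplotypes carrying a chosen core allele (or, for the ancestral-core
tree, all haplotypes carrying none of the derived LP alleles) and splits
marker-by-marker outward in physical order, one SNP per step — no
genetic-map weighting, since the displays are per-SNP and no map is
assumed for a 30 kb flank. Counts are conserved at every depth (children
sum to their parent), construction stops at `max_steps`, marker
exhaustion, or full resolution into singletons, and haplotypes with a
missing allele anywhere on the traversed flank are dropped with a logged
count rather than imputed — imputation belongs to upstream phasing
software and is out of scope here.

# The synthetic-data generator

`simulate_island_genotypes()` implements the Balding–Nichols model: per
locus an ancestral frequency $p \sim U(0.05, 0.95)$, per population a
frequency drawn from $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, and per individual a
$\mathrm{Binomial}(2, p_{k\ell})$ dosage. This choice — rather than a
coalescent simulation — is deliberate: the scan tests need controlled
per-locus differentiation with a known true $F$, not linkage realism.
Consequences worth keeping in mind: loci are unlinked (no LD, hence no
multi-SNP sweep footprint), there is no mutation-model realism or allele
ascertainment, and sample sizes are exactly as configured. Passing tests
on this generator demonstrate estimator correctness and calibration, not
performance on real, LD-structured data.

The default scan scenario is sized for desk runtime: 3 populations × 16
diploids, 20,000 loci over 50 Mb, $F = 0.05$, one locus near the
chromosome midpoint with its ancestral frequency pinned at 0.2 and the
test population shifted by +0.6 (to ~0.8). Pinning the ancestral
frequency keeps the shift inside $[0,1]$ by construction and makes the
injected contrast interpretable (0.8 vs ~0.2). The test suite runs 100
replicates of this scenario plus 100 null replicates; the acceptance
script reports the same rates.

The phased-haplotype generator covers the bifurcation displays: neutral
mode draws each marker independently at $U(0.2, 0.8)$ frequencies; sweep
mode copies carriers of the derived core allele from a single founder
haplotype walking outward, with per-marker mutation probability 0.02 and
per-interval recombination (switch to a random neutral background)
probability 0.05. Default 60 haplotypes with core frequency 0.5 and 41
markers — values chosen once as representative of a phased field panel
(~30 carrier chromosomes) and a ±20-SNP display flank. Sweep trees are
systematically narrower than neutral trees deep into the flank; at depth
1 both trees usually split into exactly two branches, so the contrast is
asserted as "never wider at depths 1–10, strictly narrower at the
deepest compared depth".

# The reconstructed study fixture

The bundled fixture rebuilds a 203-individual × 9-SNP genotype matrix
from the published per-population summary layer. Derived-allele counts
per population are `round(p × 2n)`; LP-carrier counts are
`round(LP% × n / 100)`. Individual-level configurations are
under-determined by the summary layer, so a fixed, documented allocation
is used: within each population, the first $C$ individuals are the
carriers and LP-locus alleles are dealt to them round-robin in ascending
position order (two alleles landing on one individual at one locus form
a homozygote — the single Messiria carrier is thereby homozygous
-13915:G, reproducing its 12.5% phenotype from 2 alleles); non-LP
singleton alleles sit as heterozygotes in the highest-index individuals.
The allocation is deterministic, so the fixture is byte-identical across
runs, and running the full allele-statistics layer on it reproduces every
published frequency, SE, LP percentage, and derived-count cell.

Two printed cells are internally inconsistent with their own counts and
are reproduced at the count-implied values: a frequency of 2/24 prints as
0.084 in the source but equals 0.083 at three decimals (its printed SE
0.056 confirms $p = 0.0833$), and one SE of 0.0795 prints as 0.080 but
rounds to 0.079. Printed percentages round half away from zero
(1/16 → 6.3%), so the comparison layer uses half-up rounding rather than
R's default half-to-even.

# Numerical and degenerate-input choices

* HWE enumeration works in log-space with an $(1 + 10^{-12})$ slack on
  the "no more probable" comparison to make ties robust to rounding.
* `window_scan` with no surviving window warns and returns an empty
  result (a scan over a sparse region is an outcome, not an error);
  `call_outliers` errors on fewer than 2 windows or zero SD, where Z
  scores are undefined.
* Exact permutation p-values enumerate $n!$ pairings chunked by the
  first element, bounding memory at $9!$ rows per chunk; at $n = 10$
  this is ~3.6M statistics computed by a single matrix product.
* All result writers format floating point at 6 significant digits and
  write with fixed newlines, so identical inputs give byte-identical
  files; every stochastic stage takes an explicit seed and restores the
  session RNG state afterwards.

# Known limitations

* The simulator's lack of linkage means window-level power against
  realistic sweeps is *understated* by the single-locus scenario, and
  haplotype-based statistics (EHH/iHS, XP-CLR) are out of scope.
* The exact HWE test and the permutation correlation are small-sample
  tools; for thousands of individuals both have faster large-sample
  alternatives that are deliberately not implemented here.
* The fixture reproduces the published summary layer exactly, but
  individual-level het/hom configurations beyond those constraints are a
  documented convention, not data.
* Phasing and imputation are accepted as input, never performed; allelic
  dropout in whole-genome-amplified material can inflate apparent
  haplotype sharing, and the bifurcation module only reports counts — it
  applies no correction.
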