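---
title: "Mapping double-simplex SNPs in an autohexaploid S1 population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping double-simplex SNPs in an autohexaploid S1 population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexmap)
```

## The problem

An autohexaploid carries six copies of every chromosome, and any homolog
may pair with any other at meiosis. Genetic mapping in such a species is
hard for two reasons: genotypes are allele *dosages* (0–6 copies of the
alternative allele) that short-read data cannot call directly per
individual, and most marker configurations segregate in complicated
polysomic ratios. `hexmap` implements the strategy of working only with
**double-simplex** markers in a selfed (S1) population of a single
heterozygous parent: loci where exactly one of the six homologs carries
the alternative allele. Under random bivalent pairing such a locus
segregates 1:2:1 by dosage (0, 1, 2 copies), exactly like a selfed
heterozygous diploid, and a dominant-style dichotomy of its genotypes
segregates 1:3. Everything downstream — two-point linkage, grouping,
ordering, error correction — can then reuse well-understood diploid F2
machinery, at the price that each *homolog* produces its own linkage
group (LG): 6 × the basic chromosome number of LGs, which are finally
re-united into homologous groups (HGs) through a physical anchor, the
scaffolds of a diploid relative's assembly.

## From read depths to dosage classes

The observable is the per-genotype read-depth triple of a VarScan-style
VCF: `DP` (quality read depth), `RD` (reference-supporting reads) and
`AD` (variant-supporting reads, a scalar in this dialect). Two hard
filters come first: every data point needs `DP >= 10` (cells below are
set missing) and a locus is kept only if its missing proportion is
strictly below 0.25. The order matters — low-depth cells count as
missing in the second filter.

The ALT allele frequency of a locus pooled over the population,

$$\mathrm{AAF} = \frac{\sum \mathrm{AD}}{\sum(\mathrm{RD} + \mathrm{AD})},$$

has expectation $d/6$ for founder ALT dosage $d$, so pooled AAFs pile up
near 1/6, 2/6, …, 6/6 — a six-peak fingerprint of the dosage classes.
Two windows select the double-simplex candidates: $[0.0833, 0.2500)$
(simplex for the ALT allele, class `ds_ref`) and $[0.7500, 0.9167)$
(simplex for the REF allele, `ds_alt`). The windows are right-open and
placed midway to the neighbouring peaks. Loci at AAF exactly 1 are
monomorphic-ALT and cannot segregate, so they fall outside both windows
by construction.

Two AAF conventions coexist in practice: dividing by `DP` or by
`RD + AD`. They differ when `DP` counts reads supporting neither
reported allele. The package uses `RD + AD` (the convention under which
a worked population total of 17,391 REF and 5,236 ALT reads gives
0.231), and exposes `denominator = "dp"` as a switch. Likewise, whether
the selection windows apply to the pooled AAF or to a per-individual
summary is genuinely open; `hexmap` applies them to the pooled AAF,
which is the quantity the worked arithmetic above refers to, and uses
per-individual AAFs only for genotype calls.

Per-individual read counts cannot separate dosage 1 from dosage 2 at
realistic depths, so genotypes are *dichotomized*: at a `ds_ref` locus,
an individual with per-cell AAF exactly 0 is homozygous and anything
above 0 is "not homozygous" (mirror rule at AAF 1 for `ds_alt`). The
expected S1 ratio is then 1 homozygous : 3 not-homozygous, tested per
marker with a plain one-degree-of-freedom chi-square (no continuity
correction; n = 142 is large); markers are kept when $p \ge 0.01$. The
literal "AAF = 0" rule is fragile when the per-read error rate is
nonzero at very high depth, so `dichotomize()` takes a `tolerance`
(minority reads still counted as homozygous); the default 0 preserves
the strict rule.

## Two-point linkage of dominant dichotomized markers

A pair of double-simplex markers whose rare alleles sit on the same
homolog behaves exactly like a coupled diploid dominant-dominant F2
pair: per gamete, the rare alleles co-transmit with probability
$(1-r)/2$ each for the parental types and $r/2$ for recombinants, and
individuals are fusions of two independent gametes. With
$\theta = (1-r)^2$ (coupling) or $\theta = r^2$ (repulsion) the four
joint dichotomous classes have probabilities

$$P(1,1) = \tfrac{2+\theta}{4},\quad P(1,0) = P(0,1) =
\tfrac{1-\theta}{4},\quad P(0,0) = \tfrac{\theta}{4}.$$

The score equation in $\theta$ is a quadratic,
$n\theta^2 - (n_{11} - 2q - n_{00})\theta - 2n_{00} = 0$ with
$q = n_{10} + n_{01}$, whose positive root is the exact MLE — no
iteration, so millions of pairs are estimated by matrix cross-products
over the call matrix plus vectorized algebra. $\theta > 1/4$ means
coupling, $\theta < 1/4$ repulsion; the LOD compares the maximized
likelihood with independence ($\theta = 1/4$). Degenerate pairs (a
marker all one class among the shared individuals, or fewer than 20
shared non-missing individuals) are flagged uninformative rather than
estimated.

Why this diploid reduction is adequate: markers on *different* homologs
of one chromosome sit in generalized repulsion. Enumerating the 15
bivalent pairings shows two simplex alleles on different homologs
co-transmit with probability 1/5 — barely below the independence value
of 1/4 — which translates to an expected LOD of roughly 0.5 at n = 142.
Cross-homolog pairs therefore never reach a grouping threshold of LOD 7,
and each homolog cleanly becomes its own linkage group, which is what
the HG step expects.

Grouping is single-linkage: an edge joins any pair with LOD at or above
the threshold (default 7, sweep 3–10 reported by `lod_sweep()`), and
connected components are the groups. Groups below 20 markers are
reported separately, not dropped silently.

Markers with byte-identical call vectors (including the missing
pattern) are collapsed into co-segregation bins; one representative per
bin is ordered. Ordering is a deterministic rapid-chain-delineation
style greedy: seed with the highest-LOD pair, append the unplaced bin
with the strongest linkage to either chain end, then polish with a
window-4 ripple that accepts any permutation of four consecutive bins
strictly decreasing the sum of adjacent recombination fractions. Ties
break by higher LOD, then lower r, then lexicographic marker key, and a
final canonical orientation (lexicographically smaller end first) makes
output independent of input order. Adjacent fractions are mapped to cM
with the Kosambi function $d = 25\ln\frac{1+2r}{1-2r}$ (the conventional
default of plant mapping software; Haldane is a config switch since
nothing in the method depends on the choice), with r capped at 0.4999
before the transform.

## Map-based error correction and imputation

Genotyping errors in dense maps masquerade as double recombinants in
tiny intervals and inflate map length (a rule of thumb: each 1% marker
error adds roughly 2 cM). The clean-up pass works per linkage group on
the ordered bins, individual by individual:

* **Masking**: a call that disagrees with both immediate flanking bins'
  calls (which agree and are non-missing), and is the sole disagreement
  within a window of ±2 bins (`max_error = 1`), is set to missing. Group
  ends are left untouched. Calls are never flipped directly — every
  change is a mask followed by (possible) re-imputation, and every
  changed cell is logged with its provenance.
* **Imputation**: a missing cell whose nearest non-missing flanking
  calls within the window agree is set to that consensus; cells inside
  apparent crossover intervals stay missing.
* Bins with more than 33% missing data are passed through untouched.

The window rule set is a deterministic, auditable stand-in for
hidden-state smoothers; on two-class dominant calls it captures the
same signal (isolated double recombinants) without tuning. Applied
twice at a fixed order it is idempotent. After cleaning, the full
grouping/ordering pass is rerun on the corrected marker matrix
(`rerun_map()`), and the pass-1/pass-2 group counts and lengths are
compared — with injected errors the pass-2 map is reliably shorter.

## Homologous groups from shared scaffolds

Because all six homolog LGs of one chromosome align to the same region
of the diploid relative, the LG × scaffold incidence (counts of mapped
SNPs per LG and scaffold) links them physically. LGs become nodes of a
graph whose edge weights are shared-scaffold counts; edges below 2
shared scaffolds are discarded so that a single mis-joined scaffold
cannot bridge two HGs, and scaffolds claimed by more LGs than the
ploidy (> 6) are flagged chimeric and excluded from edge weighting
altogether. Connected components are the HGs. HGs and their member LGs
are numbered by decreasing map length (ties by marker count, then
original id), giving labels `HG01…`, `LG1…`.

## The simulator

Every stage above is testable against truth because the package ships a
generative model of the whole design:

* **Founder**: `n_chrom` chromosomes × 6 homologs; each homolog owns
  `loci_per_homolog` loci (evenly spaced with a per-homolog phase
  offset by default, so loci interleave along the chromosome), and a
  dosage-class mix decides how many extra homologs carry ALT. Physical
  coordinates are proportional to genetic ones (10 kb/cM by default);
  the physical axis is fragmented into scaffolds with exponential
  fragment sizes around a target mean, and a configurable fraction of
  scaffolds can be fused across chromosomes to emulate chimeric
  assemblies.
* **Meiosis**: random bivalent pairing — the six homologs form three
  disjoint pairs drawn uniformly from the 15 possible pairings at every
  meiosis; no multivalents, double reduction 0. The transmitted
  chromatid of each bivalent is a mosaic of its two partners, switching
  at Poisson(`length_cM`/100) points placed uniformly, so distances on
  the simulated axis are genetic distances in the Haldane sense. Each
  S1 individual fuses two independent gametes.
* **Depths**: per-cell `DP` is negative binomial (mean 40, size 5 by
  default — RAD-like overdispersion), ALT reads are binomial with
  success probability $(d/6)(1-\varepsilon) + (1-d/6)\varepsilon$, and
  whole cells drop out as missing at a fixed rate. Defaults
  $\varepsilon = 0.002$ and missing rate 0.022 put the simulated
  call-error and missingness burden at the few-percent level typical of
  filtered ddRAD data. The population size defaults to n = 142.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, PCR duplicates), locus dropout from restriction-site
polymorphism, multivalent pairing and double reduction, segregation
distortion from selection, and assembly errors beyond simple
two-chromosome chimeras. Passing tests on simulated data therefore
validate the *inference machinery* under the stated genetic model, not
robustness to every artifact of real libraries.

Two simulation behaviours deserve explicit mention because they mirror
real data:

* **Allele dropout.** At moderate depth a true dosage-1 cell can sample
  zero ALT reads ($P = (5/6)^{DP}$, ≈ 16% at DP = 10), so with the
  default depth model a percent-scale rate of dichotomization errors is
  *intrinsic* even at $\varepsilon = 0$ — this is exactly the error
  class the map-based correction exists for. Validation fixtures that
  need genuinely error-free calls use mean depth 100 with tight
  dispersion, where dropout is negligible.
* **Correlated segregation distortion.** All markers of one homolog
  share a single transmission draw (homozygous-class count ≈
  Binomial(142, 1/4) for the whole homolog), so the 1% chi-square
  filter tends to drop markers in homolog-sized blocks. With 90
  homologs, about one per simulated population is expected to sit
  beyond the rejection threshold; such a homolog's group then falls
  below the 20-marker reporting size. The idealized count of exactly 90
  reported LGs on a 15-chromosome design is therefore met only by
  populations in which no homolog drew a large skew — in practice the
  recovered count sits at 88–90 (the component structure itself, and
  the 15 recovered HGs, are stable). Real mapping studies show the same
  signature: slightly more groups than homologs, and some HGs with
  seven or eight LGs.

## Problem sizes and numerical choices

The test suite exercises the full design at 15 chromosomes × 6 homologs
× 30 loci (2,700 markers, n = 142) once per run — about 15 s for
all-pairs two-point estimation plus mapping — and smaller two- and
five-chromosome designs for the module-level properties; the
chi-square calibration uses ≥ 2,000 effectively unlinked simplex loci
(widely spaced on 50 chromosomes). Tolerances worth knowing: the
closed-form two-point MLE agrees with a $10^{-4}$ grid search to
$5\times10^{-4}$; log-likelihoods guard zero counts with a
$10^{-300}$ floor instead of special-casing; adjacent recombination
fractions are capped at 0.4999 before the (divergent) map-function
transform; all randomness derives from one master seed via a fixed
linear scheme, so every artifact of a run is reproducible from the seed
recorded in its manifest.

## Known limitations

Only double-simplex markers are mapped — duplex/triplex loci are
discarded rather than used as anchors, so linkage phase across homologs
is recovered physically (scaffolds), not genetically. The two-point
model assumes pure bivalent pairing; multivalents or double reduction
would bias r̂ downward or upward of truth in ways the package does not
model. Ordering is a greedy heuristic with local polish: global
inversions are possible in groups with weak internal linkage, and only
relative order (not orientation) is identifiable. The HG step needs
scaffolds long enough to carry SNPs of several LGs; an assembly much
more fragmented than the marker spacing leaves LGs unanchored as
singleton HGs.
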