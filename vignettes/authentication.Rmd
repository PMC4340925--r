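---
title: "Genotype-based authentication of human biosamples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based authentication of human biosamples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellauth)
```

## The problem

A cell line or DNA sample is authenticated by comparing its genotype
profile with a reference: the same line profiled earlier, a sibling
culture, or a public profile database. `cellauth` implements this
comparison for two marker systems that are routinely used together — a
96-marker SNP fingerprinting panel (90 autosomal SNPs for identity, 3
chromosome X and 3 chromosome Y SNPs for sex) and a 16-locus STR kit (13
CODIS core loci, Penta D, Penta E, amelogenin). The same scoring engine
serves both, because the identity score below is defined on allele *sets*
and does not care whether an allele is a base call or a repeat count.

## The identity score

For samples $1$ and $2$, let $L$ be the set of markers at which neither
sample is a no-call. At each $\ell \in L$ count the distinct alleles
$t_{1\ell}$, $t_{2\ell}$ observed in each sample and the distinct alleles
$s_\ell$ observed in both. Summing over $L$,

$$\mathrm{identity} \;=\; \frac{2\sum_\ell s_\ell}
  {\sum_\ell t_{1\ell} + \sum_\ell t_{2\ell}} \in [0, 1].$$

The score is exactly 1 iff the two profiles show the same allele set at
every co-called locus, and exactly 0 iff no allele is shared anywhere.
Distinct-allele counting means a homozygous `AA` contributes one allele —
multiplicity never matters — and the rule extends unchanged to loci with
three or more alleles, as seen in aneuploid lines on STR loci. Two
deliberate consequences:

* **No-calls are excluded, not penalised.** A marker missing in either
  sample contributes nothing; the score over the remaining loci is
  unchanged. A pair with *no* co-called locus has an undefined score —
  `tanabe_identity()` raises a classed error and `pairwise_identity()`
  emits an `NA`-scored flagged record. An undefined score is never
  coerced to 0, because 0 is a strong statement (proven unrelated).
* **Sex markers are excluded by default.** `autosomal_markers()` selects
  the 90 autosomal SNPs (or the 15 autosomal STR loci; amelogenin is the
  sex marker, not a fingerprint). Including allosome markers would make
  same-sex samples look systematically more related.

Internally each locus's allele set is encoded as a bitmask over the
locus's observed allele universe, and all $n(n-1)/2$ pairs are scored
with vectorised bit operations; loci with more than 30 distinct alleles
are rejected (far beyond any real STR locus). The engine is verified in
the test suite against an independent brute-force recount on thousands of
random small profiles.

## Relatedness statistics

Identity scores within one pair class — unrelated, same-patient
("synonymous"), replicate — are approximately Gaussian: each score is a
ratio of counts summed over ~90 roughly independent loci.
`fit_reference()` fits a class by its sample mean and $n-1$ SD after
iterative outlier trimming, and `relatedness_pvalue()` converts a score
into a tail probability: under the *unrelated* reference the upper tail
$1 - \Phi\!\left(\frac{s - \hat\mu}{\hat\sigma}\right)$ is the
probability that an unrelated pair scores at least $s$ — small values
are evidence of relatedness. A reference fitted to the *synonymous*
class uses the lower tail instead: small values flag a pair that is
annotated as related but scores suspiciously low. `classify_pairs()`
reports both p-values side by side and never merges them, together with
the hard decision `score >= threshold` (default 0.90) and a discordance
flag when the decision contradicts the annotation.

Design choices worth stating:

* **Outlier rule.** Reference sets are contaminated by exactly the thing
  the pipeline exists to find — misannotated pairs — so the fit must not
  let them in. Trimming uses a *robust* z-score,
  $|s - \mathrm{median}| / (1.4826\,\mathrm{MAD})$, thresholded at 4 and
  iterated to convergence, falling back to the SD when the MAD is zero.
  A plain SD-based z was rejected because a single gross outlier inflates
  the SD it is judged against and can mask itself (an 11-point class with
  one score at 0.44 among ten near 0.97 leaves the outlier at z ≈ 3).
  Excluded pairs are always recorded on the result (`tidy()`), never
  silently dropped.
* **$n-1$ SD** throughout: these are sample statistics on observed pairs.
* **Degenerate references** (all scores equal) yield a warned step
  function — 0/1 with 0.5 at exact equality — rather than an error, so a
  pipeline over a tiny perfect replicate set still runs.
* **No multiplicity correction** is applied across pairs; the p-values
  are reported per pair as descriptive evidence.
* The 0.90 threshold is the conventional operating point for this score;
  it is a parameter everywhere it appears.

One caveat the tests make explicit: all-pairs p-values are calibrated
only marginally. Pairs sharing a sample are dependent, so the test-suite
calibration check uses disjoint pairs (2N individuals paired off), for
which the binomial error bound is valid.

## Marker-subset power

`subset_power()` quantifies what is lost when fewer markers are used:
for each of `n_draws` (default 100) seeded draws it samples $k$ autosomal
markers without replacement and records the SD of unrelated-pair scores
over the subset. The mean score barely moves with $k$, but the SD grows
as the panel shrinks, widening the upper tail that crosses the 0.90
threshold by chance. Drawing many subsets rather than one is deliberate:
a single draw confounds subset choice with subset size, so the result
object keeps the per-draw spread and its seed.

## Sex typing

Three independent platforms, three deterministic rules:

* **Allosome SNPs** (`sex_from_snp_panel()`): chromosome Y assays yield
  no product in XX samples, so a Y call is presence evidence. Male
  requires ≥ 2 of 3 Y assays called; female requires 0 Y calls and ≥ 2 X
  calls; anything else (exactly one Y call, or too few valid assays) is
  `no_call`. The 2-of-3 vote is this package's declared rule — the
  triplicated design exists to tolerate one failed assay, and requiring
  two calls keeps a single spurious amplification from flipping a sex
  call. The vendor's own vote rule is unpublished.
* **STR amelogenin** (`sex_from_str()`): `{X}` female, `{X,Y}` male; a
  no-call or an implausible `{Y}` is `no_call`.
* **Array features** (`sex_from_array()`): male iff the chromosome X
  heterozygous fraction is ≤ 0.05 *and* the mean chromosome Y
  copy-number ratio is > 0.5 (ratio of 1 = genome average). The feature
  extraction itself is upstream of this package; the PCDH11X/Y
  ("PAR3") intervals that must be masked first are shipped as
  `par_exclusion_regions()` (hg19: chrY:2988462–5587151,
  chrX:88455396–92368901). The rule's known failure mode is a line in
  which only a minority of cells retain Y: the copy-number ratio sits
  between the zero- and one-copy expectations and the sample types
  female.

`sex_concordance()` cross-tabulates any platform's calls against
annotation, with no-calls shown but excluded from the row percentages.
The biological point the three-way comparison supports: when independent
platforms agree that an annotated-male line types female, the cause is
usually genomic — whole-chromosome Y loss — not an assay artifact. The
synthetic generator models exactly that mechanism (below), and the test
suite confirms the miscall fraction tracks the planted loss rate.

## Cross-contamination

`simulate_mixture()` builds the deterministic genotype of a DNA mixture.
At each marker, component $c$ contributes its alleles weighted by
(mixing fraction $f_c$) × (per-allele copy number); allele $a$'s relative
abundance is

$$\mathrm{ab}(a) = \frac{\sum_c f_c \cdot \mathrm{copies}_c(a)}
  {\sum_c f_c \cdot \mathrm{total}_c},$$

and the mixture's called allele set is every allele with
$\mathrm{ab}(a) \ge \tau$. Detection (`contamination_scan()`,
`sensitivity_curve()`) is then just authentication failure: the mixture's
identity to its expected reference drops below the same 0.90 threshold.

* **$\tau$ = 0.04 by default.** The genotyping chemistry's true allele
  sensitivity is not a published constant, so $\tau$ is an explicit knob.
  The default reproduces, on a fully informative diploid pair (host and
  contaminant homozygous for different alleles at every locus), the
  observed wet-lab behaviour: a 5% contaminant's alleles (abundance
  0.05) are called and drive identity far below 0.90, a 1% contaminant's
  (0.01) are not and identity stays at 1.0, identically in both
  reciprocal directions.
* **Detection sensitivity is profile-dependent**, and deliberately so:
  only loci where the contaminant carries an allele the host lacks are
  informative, and a heterozygous contaminant allele carries half the
  copies of a homozygous one (abundance $f/2$ vs $f$ in an equal-diploid
  mix). For a random pair of outbred profiles a large share of loci are
  uninformative, and the detectable fraction is correspondingly higher
  than for the fully informative pair. This mirrors the real assay,
  whose detection limit varies between sample pairs.
* **Reciprocal asymmetry is driven by copy number alone.** With equal
  copy-number profiles the detection threshold fraction is the same in
  both directions. Give the contaminant uniformly more copies per locus
  (say 4 vs the host's 2) and its alleles reach $\tau$ at a lower mixing
  fraction, while in the reciprocal direction the low-copy contaminant
  needs more — the mechanism proposed for why aneuploid lines are
  detected asymmetrically.
* The mapping from cell-count mixing fraction to allelic abundance is
  modeled as proportional; extraction and amplification biases between
  cell types are not modeled.
* A stochastic per-allele dropout mode was considered and left out: the
  deterministic rule is what the detection claims rest on, and noise is
  better injected through the replicate generator where it is
  characterised.

## The synthetic population generator

`generate_population()` emulates the statistical structure of a large
profiling campaign, so that every pipeline stage has a ground truth to be
scored against. Under a fixed seed the output is byte-identical.

| parameter | default | why |
|---|---|---|
| `n_individuals` | 200 | enough unrelated pairs (~20k) to fit stable references while keeping all-pairs scoring fast |
| panel | 46 + 44 + 3 + 3 | fingerprinting SNPs at allele frequency 0.5 (maximally informative), ancestry-informative SNPs at frequencies U(0.1, 0.9), triplicated X and Y assays |
| `no_call_rate` | 0.0066 | reproduces a ~99.34% autosomal call rate, the benchmark campaign's figure |
| `genotype_error_rate` | 0.005 | replicate re-assay discordance of a few loci per 90-marker profile; keeps replicate scores ≈ 0.99–1.0 |
| `loh_rate` | 0.1 | same-patient derivative drift; puts synonymous pairs between replicates and the 0.90 threshold |
| `chry_loss_rate` | 0.42 | fraction of male lines with whole-chromosome Y loss, the observed male→female miscall magnitude |
| `msi_slippage_rate` | 0.15 | free parameter; chosen to open a clear SNP ≫ STR identity gap for MSI derivatives, not to match any particular pair |
| `male_fraction` | 0.5 | unstructured population |
| `n_replicates`, `n_synonymous` | 8 + 8 | planted truth for class-separation and p-value checks |

Genotypes are Hardy–Weinberg draws, independent across markers and
individuals. What this *does not* emulate — and therefore what passing
tests do not demonstrate about real data: linkage disequilibrium between
markers (real panels are chosen to be unlinked-ish, but not perfectly),
population structure and relatedness in the collection, ancestry-specific
allele frequencies, batch effects in no-call placement, and partial or
mosaic chromosome Y loss (loss is all-or-none per sample, matching the
karyotype finding that miscalled lines usually lack Y entirely; a
partial-loss line would need per-marker modelling). STR generation draws
two alleles per locus from locus-specific integer repeat ranges; MSI
derivatives (`derive_msi()`) shift each allele ±1 full repeat at the
slippage rate, leaving amelogenin and all SNPs untouched — which is
exactly why an MSI line keeps perfect SNP identity to its parent while
its STR identity decays. Copy-number profiles (`generate_aneuploid_cn()`)
draw per-locus totals from 1–6 by default and split them across alleles,
with a point mass at 2 reproducing the diploid setting.

## Numerical and interface choices

* Genotypes are stored as `"/"-joined` sorted distinct-allele strings
  (`"A/B"`, `"9/9.3"`), `NA` = no-call; homozygous input tokens collapse
  on parsing (`AA` → `"A"`). STR microvariants are normalised
  (`9.30` → `9.3`) so nomenclature variants compare equal.
* The table reader accepts the no-call spellings `No Call`, `NC`,
  `NoCall`, empty cell and em dash, case-insensitively; the writer
  always emits `No Call`. Unparseable tokens are errors (strict mode,
  naming row and column) or recorded parse errors plus no-call (lenient
  mode) — never silent coercion. Write-then-read is the identity on
  valid tables, and row order never affects parsed content.
* Scores are stored at full precision; rounding to two decimals is left
  to reporting code.
* Allele abundance is compared against $\tau$ with a $10^{-12}$ slack so
  exact-boundary mixtures (e.g. abundance exactly 0.05 at $\tau = 0.05$)
  are included regardless of floating-point representation.
* Pair-class precedence when annotations overlap: replicate >
  synonymous > unrelated; pairs involving unannotated samples are
  `unannotated`, never guessed.
* All generator randomness is scoped with `withr::with_seed()`; nothing
  leaks into or out of the caller's RNG state.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic
data, at sizes chosen to make the statistical assertions sharp but keep a
full run in minutes on one core: 10,000 random small profiles for the
engine/oracle equivalence, a 200-individual population (≈ 23k pairs) for
class separation, reference fitting and subset power (100 draws at
k = 24 and 48), 1,000 disjoint pairs for type-I calibration, 800
individuals (~400 males) for the sex miscall rate, and 90-locus
deterministic pairs for the contamination arithmetic. The
supplementary-scale reproduction of a real 968-sample campaign is
supported by the same code paths (the reader parses the published wide
table layout directly) but requires that dataset as input; the bundled
checks verify the bookkeeping identities — calls + no-calls =
samples × markers, pairs = n(n−1)/2 — at the same dimensions.

## Known limitations

* No kinship or identity-by-descent coefficients, and no forensic
  likelihood ratios: the score is allele-sharing, not a population
  genetics model, and its p-values depend on the profiled collection
  through the fitted reference.
* No deconvolution of a detected mixture (who is the contaminant, at
  what fraction) — detection only.
* Ancestry inference from the panel's ancestry-informative SNPs is out
  of scope; those markers participate in identity scoring only.
* Array feature extraction (heterozygous fractions, copy-number ratios)
  happens upstream; this package only applies the published decision
  rule and ships the exclusion mask it requires.
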