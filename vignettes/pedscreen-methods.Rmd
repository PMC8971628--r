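---
title: "Methods: pedigree-based screening for rare driver variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based screening for rare driver variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
```

## The problem

A single multiplex family — here, a three-generation pedigree of 17 members
with 5 members affected by a depressive disorder — is exome-sequenced in the
hope of finding a rare germline variant of high penetrance that drives the
familial trait. Such a study has no cohort-scale statistics to lean on:
everything rests on how the variant tracks through the family, how rare it
is in reference populations, and how damaging it is predicted to be.
`pedscreen` implements that analysis as a reusable, testable pipeline:

1. genome-wide *differential mutation density* (DMD) landscapes and a
   consensus/differential copy-number screen, to rule out large-scale
   chromosomal differences between affected and healthy members;
2. *trait segregation model fitting* (sporadic vs. major-gene Mendelian
   models) by exact pedigree likelihood;
3. a four-stage *driver-variant prioritization cascade*; and
4. *endophenotype* comparison of brain-structure volumes between diagnostic
   or carrier groups by t- and label-randomization tests.

Because single-family data are essentially never public, the package ships a
first-class synthetic-data generator with known ground truth; every stage of
the pipeline is exercised end-to-end against it.

## Differential mutation density

Chromosomes are tiled in fixed windows of $w = 10^6$ bp. For a window
containing $n$ variants,

$$\mathrm{DMD} = \sum_{i=1}^{n}\left(\frac{O_{i,d}}{N_d} -
\frac{O_{i,h}}{N_h}\right),$$

where $O_{i,d}$ is the number of affected members carrying at least one
alternate allele of variant $i$, $N_d$ the number of affected members,
$O_{i,h}$ and $N_h$ the same for healthy members. Two reading choices were
open:

* **Denominators.** The source formulation describes both $N_d$ and $N_h$ as
  the number of *affected* members; we read the second as a typo and use
  $N_h$ = number of healthy members (12 in the 17-member design). The
  published hotspot scores support this: with $N_d = 5$, $N_h = 12$ every
  score must be an integer multiple of $1/\mathrm{lcm}(5,12) = 1/60$, and
  all three published hotspot values sit on that lattice to printed
  precision; the acceptance suite checks both facts.
* **Occurrence counts carriers, not alleles.** Counting members with
  genotype $\ge 1$ keeps $O \le N$ and matches the per-member phrasing;
  missing genotypes count as non-carrier.

Windows tile from position 1 with half-open arithmetic on 1-based
coordinates, so a variant at an exact multiple of $w$ belongs to the window
it terminates. Hotspots are windows with score strictly greater than the
threshold (default 20); adjacent qualifying windows merge. We deliberately
attach no significance statement to DMD peaks — none is defined for the
statistic.

The copy-number screen retains calls made concordantly by two callers
(same member, same copy state, reciprocal overlap $\ge$ 0.5, intersected
interval) and then reports merged regions whose carrier sets are exclusive
to one group. Running the CNV callers themselves is out of scope; the
package consumes their BED-like call sets.

## Segregation analysis

Affection statuses are modeled under four trait models:

| model | free parameters | k |
|---|---|---|
| sporadic | prevalence $p$ | 1 |
| sporadic + residual | $p$, family frailty prob. $\pi$, odds multiplier $\theta$ | 3 |
| Mendelian AD | allele freq. $q$, penetrances $f_1, f_0$ | 3 |
| Mendelian AR | $q$, $f_1, f_0$ | 3 |

Major-locus likelihoods are exact: founders carry Hardy–Weinberg genotype
priors at $q$, transmissions are Mendelian, and affection is Bernoulli with
penetrance $f_1$ for carriers (genotype $\ge 1$ under AD, $= 2$ under AR)
and phenocopy rate $f_0$ otherwise. The likelihood is computed by
Elston–Stewart-style peeling, implemented as variable elimination over the
latent genotypes with children eliminated before parents; for loop-free
pedigrees the intermediate factors stay small, and the result equals full
$3^n$ enumeration to floating-point accuracy (the test suite verifies
$<10^{-9}$ agreement in log-likelihood across randomized parameter draws on
all small pedigree shapes). Pedigrees with marriage or inbreeding loops are
rejected rather than approximated. Zero-probability data return
$-\infty$, not an error.

The "residual familial association" model is a simplification of regressive
models found in classic segregation software: a latent binary frailty shared
by the children of each nuclear family multiplies their affection odds. It
captures within-sibship clustering with two extra parameters and has a
closed-form likelihood.

**Fitting.** The sporadic MLE is closed-form. The 3-parameter models are
maximized by a deterministic coarse grid (96 points over $q$, $f_1$, $f_0$
or the frailty parameters) followed by Nelder–Mead refinement on a
logit/log scale — no random restarts, so fits are reproducible. A 0.01-step
grid in three dimensions (~$10^6$ likelihood evaluations per model) was
rejected on runtime grounds; grid-plus-refinement reaches the same optima on
every case we enumerate by hand.

**Model choice and its limits.** Models are compared by
$\mathrm{AIC} = -2\ln L + 2k$ with $k$ the number of parameters actually
estimated. One consequence deserves honesty: a single 17-member pedigree
carries limited information, and a dominant pattern transmitted through a
founder lineage costs roughly $\ln 2$ per informative meiosis, capping the
AD model's log-likelihood advantage over the 1-parameter sporadic model
near 1–1.6 for typical 4–5-affected patterns — *below* the AIC charge of 2
for its two extra parameters. The acceptance suite measures exactly this:
under fully penetrant AD simulation the AD model attains the lowest AIC in
roughly 70% of replicates, not the 95% the original study design would
suggest. The published analysis evidently charged its sporadic models more
parameters than its Mendelian ones (its deviances and AICs imply $k = 5$
for sporadic rows and a non-integer $k \approx 3.9$ for Mendelian rows, a
convention we could not reconstruct); under the standard identity used
here, the same preference is not reproducible at that rate. We keep the
standard identity and report the shortfall rather than emulate an
unrecoverable convention.

Distinct from the trait-level fit, the *variant-level* filters are pure
genotype-pattern tests: `mendelian_consistency()` (transmission
compatibility, marginalizing missing genotypes — computed as positivity of
the same peeling likelihood under genotype evidence) and
`cosegregation_filter()` (AD: every affected member an observed carrier, no
healthy comparator carrying; AR: the homozygous analogue).

## The prioritization cascade

Four stages, each a pure filter with logged survivor counts:

1. **Differential extraction.** Functionally relevant variants (exonic or
   splicing; nonsynonymous, stop-gain or frameshift) whose affected-carrier
   fraction exceeds the healthy-comparator fraction by at least 0.5
   (default). The lenient carrier-delta rule is deliberate: a strict
   all-affected/no-comparator rule here would leave the explicit
   co-segregation stage nothing to do.
2. **Segregation.** Mendelian consistency plus the AD-or-AR co-segregation
   pattern. Unaffected members of the youngest generation are *exempt*:
   they may be pre-symptomatic carriers, so their genotypes neither support
   nor veto a candidate. Dropping this exemption eliminates a
   fully-penetrant-in-adults driver at this stage — the regression suite
   pins that behavior.
3. **Rarity.** Every known reference-population frequency (ExAC-style
   subsets, 1000-Genomes-style) must be $\le$ 0.05; this mirrors the logic
   that a driver of a trait with a few-percent incidence cannot be a common
   polymorphism. Variants with no frequency evidence at all are kept and
   flagged rather than silently dropped. Case–control study frequencies are
   association evidence, not rarity evidence, and do not participate.
4. **Deleteriousness voting.** A panel of 13 predictor slots (12 named
   dbNSFP-style algorithms plus CADD as the configurable thirteenth — the
   upstream description names only 12 for "13 algorithms") votes; a variant
   needs at least one damaging call (default). Categorical calls take
   precedence; score-only conservation predictors use thresholds
   (GERP $\ge 2$, PhyloP $\ge 1.6$, CADD $\ge 20$), with the at-threshold
   score counting as damaging. InDels are scored by whatever predictors
   cover them and are never auto-excluded.

Survivors are ranked by damaging votes, then case–control odds ratio
(unknowns last), then genomic position — an invented but deterministic
tie-break. Odds ratios use allele frequencies directly,
$\mathrm{OR} = p_1(1-p_2)/(p_2(1-p_1))$, with boundary frequencies clamped
to $[\varepsilon, 1-\varepsilon]$ ($\varepsilon = 10^{-6}$) and flagged; no
confidence intervals are attached because no counts are available.

## Endophenotype comparison

Per-structure volumes (15 subcortical segments plus a cerebellum segment,
mm³, one hemisphere at a time — no left/right pooling) are compared between
groups by a two-sided two-sample t-test (Student by default; the upstream
analysis does not specify, so Welch is available) and by label
randomization. When the number of distinct relabelings is at most 200,000
the permutation distribution is enumerated exactly and
$p = \#\{|t^\ast| \ge |t|\}/N$ (the identity relabeling makes $p \ge 1/N$);
otherwise 10,000 relabelings are sampled with a seed and the add-one
estimator $(1 + \#\{|t^\ast| \ge |t|\})/(1+B)$ avoids $p = 0$. Calibration
under the null and agreement between the sampled and enumerated routes are
acceptance-tested. Multiple-testing correction across the 16 structures is
off by default (single-family practice); a Bonferroni flag exists.

## The synthetic world

`sim_config()` fixes the generator's stated world:

* **Pedigree template** (`paper_like_17`): 17 members over 3 generations —
  a founder couple, five G2 siblings (four affected), four marry-in
  spouses, six G3 children (one affected). Affection is fixed, not sampled.
  One G1 founder lacks exome data; 13 of 17 members have imaging. These
  availability flags are not cosmetic: the driver's carrier plan routes
  through the genotype-missing founder (an obligate transmitter), which is
  the only way the four affected siblings can carry a Mendelian-consistent
  heterozygous variant that no *observed* healthy comparator carries. The
  imaging subset yields the 5-vs-8 diagnosis comparison and the 9-vs-4
  carrier comparison the endophenotype tests expect.
* **Driver** : heterozygous in all affected members; the carrier count is
  `round(n_affected / penetrance)` (default penetrance 5/9 → 9 observed
  carriers), with the extra carriers drawn deterministically from
  unaffected youngest-generation children of carrier parents. Its
  annotation is rare everywhere (≤ 0.05), East-Asian-enriched
  (EAS > ALL, mirroring the enrichment pattern of the published
  candidates), and carries exactly `driver_damaging_count` (default 9 of
  13) damaging calls.
* **Background**: 2,000 variants by default, 30% common (AF > 0.05), the
  rest log-uniform down to $10^{-4}$; ~12% InDels (a typical germline
  SNV/InDel ratio); genotypes gene-dropped from founders at each record's
  AF (founders Hardy–Weinberg; each child receives one allele per parent
  with probability $g/2$). Predictor calls are independent per predictor
  with damaging probability 0.1 for nonsynonymous SNVs. No linkage
  disequilibrium between background variants is simulated.
* **Affection resimulation** (for segregation-recovery experiments): a
  latent locus at $q = 0.02$ (a rare driver allele, matching the ~0.1–2%
  frequencies of the published candidates), penetrance 0.9 (or 1 in the
  fully penetrant world), phenocopy 0.01, with multiplex ascertainment
  (redraw until ≥ 2 affected and ≥ 1 unaffected — families enter such
  studies because they visibly aggregate).
* **Volumes**: realistic mm³ baselines with multiplicative Gaussian noise
  (CV 0.07) and a standardized group effect (default $d = 1.5$ on the left
  amygdala for the affected group).
* **CNV calls**: a null world — every true region is carried in both
  groups; two emulated callers see it with jittered boundaries plus
  caller-private false positives, so the consensus filter has work and the
  differential screen correctly returns nothing.

A single integer seed governs everything through deterministic substreams;
identical configurations produce byte-identical fixture files.

**What a green test does and does not establish.** The generator produces
clean Mendelian genotypes with independent background variants, exact
predictor-vote counts and Gaussian volumes. Passing tests establish that
the pipeline's logic is correct on data obeying its assumptions; they say
nothing about genotyping error, LD structure, population stratification,
or the circularity risks of single-family candidate mining — all of which
affect real studies.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive internally (VCF convention); BED-style
  outputs convert at the IO boundary. Chromosome names are normalized to
  one style (default `"chr"`).
* Genotypes are alternate-allele counts; phase is ignored. Multiallelic
  VCF rows split into one record per alternate allele with per-allele
  recoding that conserves the site's total alternate-allele count.
* Members of unknown affection status join no analysis group and
  contribute no likelihood factor.
* Peeling works in linear probability space (minimum factor products for
  plausible pedigrees stay far above the double-precision floor) and logs
  only at the end; an exactly zero likelihood is reported as $-\infty$.
* Empty variant sets, empty cascade survivor sets and empty hotspot lists
  are valid outputs, not errors; monomorphic variants cannot define
  carrier groups and error explicitly.

## Known limitations

* Loop pedigrees and X-linked models are unsupported; liability classes
  and ascertainment-corrected likelihoods are not implemented (the
  AD-recovery shortfall above is partly a consequence — conditioning on
  ascertainment would favor the Mendelian models).
* The residual-association model is a two-parameter frailty simplification,
  not a reimplementation of classic regressive models.
* The DMD statistic has no null distribution; hotspot calling is a
  threshold rule.
* Upstream processing — read alignment, variant calling, annotation, CNV
  calling, MRI segmentation — is entirely out of scope; the package starts
  from VCF/TSV/PED/BED-like/volume tables.
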