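---
title: "Phylogenetic prey specificity of venom potency: models and methods"
author: "PreySpec maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic prey specificity of venom potency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PreySpec)
```

## The scientific problem

Median lethal dose (LD50, mg of lyophilized venom per kg of test subject)
is the most widely available measure of venom potency, but it is usually
measured on whatever model organism a laboratory had at hand — very often a
mouse — while most spiders eat arthropods.  A comparative analysis of venom
potency across species therefore confounds two things: how potent a venom
is, and how far the assay organism sits from the prey the venom evolved to
subdue.  PreySpec implements a comparative pipeline that makes this
confound explicit and models it:

1. **Diet scoring** converts heterogeneous literature diet reports
   (qualitative labels, partial quantitative proportions) into normalized
   diet profiles.
2. **Prey specificity** summarizes, for each LD50 record, the
   diet-weighted divergence time between the assay model organism and the
   predator's natural prey (the statistic `D`, in hundreds of millions of
   years, Hmya).
3. **Allometry** converts body length to mass by a power law and estimates
   scaling exponents on the log10–log10 scale.
4. **The phylogenetic mixed model** regresses log10 LD50 (or log10 venom
   yield) on `D`, mass, silk use, diet breadth and injection route, with a
   phylogenetic ("animal") random effect and a species repeat-measure
   effect, fitted by Gibbs sampling.
5. **Ancestral state estimation** asks whether a binary hunting trait
   (silk use in prey capture) is confined to one clade, by maximum
   likelihood under the Mk model.
6. **The synthetic-data generator** produces complete datasets with known
   ground truth so every stage above is testable without any external data.

## Diet scoring

Qualitative labels are scored `major` = 0.60, `common` = 0.20, `uncommon` =
0.05, `rare` = 0.01.  When one species carries both kinds of report, a prey
taxon with a quantitative proportion keeps it, and qualitative-only taxa
are *calibrated*: if some taxon carries both the label L and a quantitative
value, every qualitative-only taxon labelled L uses that value (the mean
when several taxa qualify).  The rationale is that a co-reported
quantitative study pins down what, e.g., "common" means for that species'
diet.  The calibration can be disabled (`calibrate = FALSE`), in which case
the default scores are always used.

The combined estimates generally sum to more than 1; dividing by their
total gives the diet profile.  Profiles are stored at full floating
precision and always sum to 1 to within 1e-9.

**Display convention.**  Three-decimal display of profile weights follows
the convention of published diet-composition tables in this literature:
weights of at least 0.01 are truncated toward zero (so 0.21/1.45 = 0.14483
displays as 0.144), and trace weights below 0.01 are rounded to nearest
(so 0.0069 displays as 0.007 rather than being biased down to 0.006).
Under this convention the displayed row of the classic seven-group worked
example totals 0.997 while the stored weights total exactly 1.  The
convention affects display only; every computation uses full precision.

```{r table1}
qual <- qualitativeDietReport(
  "Amaurobius similis",
  c(Coleoptera = "common", Dermaptera = "common", Diptera = "major",
    Hymenoptera = "uncommon", Araneae = "rare", Hemiptera = "common",
    Isopoda = "rare"))
quant <- quantitativeDietReport(
  "Amaurobius similis", c(Coleoptera = 0.21, Diptera = 0.75, Araneae = 0.01))
est <- combineReports(qual, quant)
est
sum(est)
displayedWeights(normalizeProfile(est, "Amaurobius similis"))
```

Diet class richness is the number of distinct prey classes (out of a
12-class universe: the arthropod classes Insecta, Arachnida, Malacostraca,
Diplopoda, Chilopoda, plus Gastropoda, Opisthopora, Osteichthyes, Amphibia,
Squamata, Aves, Mammalia) with positive weight in a profile.

## The prey-specificity statistic

For a diet profile with weights $w_i$ over prey taxa $p_i$ and an assay
model organism $m$,

$$D = \sum_i w_i \, \tau(m, p_i),$$

where $\tau$ is the divergence time in Hmya — the age of the most recent
common ancestor on a time-calibrated ultrametric reference tree, divided
by 100.  Weights are renormalized to sum exactly to 1 before weighting, so
the ±1% slack allowed in published profiles never propagates into `D`.

Two conventions deserve comment:

* **MRCA age, not patristic distance.**  Divergence time databases report
  the time since the common ancestor; the patristic (tip-to-tip) path on an
  ultrametric tree is exactly twice that.  `D` uses the MRCA age; a
  `type = "patristic"` switch exposes the doubled version for sensitivity
  checks.
* **Clade-rank prey.**  Diet data resolve prey to class or order, so prey
  taxa are named clades on the reference tree.  A model organism *inside*
  the prey clade (a housefly assayed against a diet of "Insecta") is
  assigned divergence 0: at class/order resolution, within-clade distances
  are unobservable, and 0 is the conservative reading of "the model is the
  kind of thing this spider eats".

The packaged reference tree (`preyReferenceTree()`) covers the 12 prey
classes and seven common model organisms.  It is *synthetic*: its depths
are loosely patterned on published metazoan timescales (root at 700 Myr,
insect–mammal divergence 7 Hmya), and it ships for simulation and worked
examples, not as an authoritative calibration.  Analyses of real data
should substitute a tree assembled from a divergence-time database.

## Allometry

`lengthToMass()` implements the power law Mass = Length^2.6 (mm to g, unit
coefficient) used when only body lengths are reported; both the exponent
and the coefficient are arguments, since the printed form of this
conversion omits its coefficient.  `fitLogLogSlope()` estimates a scaling
exponent by ordinary least squares of log10 y on log10 x with a
t-based 95% confidence interval.  OLS on logs is a deliberate
simplification of the generalized-linear-model fits sometimes used for
this conversion, whose family and link are rarely reported; for exponent
recovery on positive, roughly lognormal data the two agree closely.

## The phylogenetic mixed model

The central model is the Gaussian animal model with repeat measures:

$$y = X\beta + Z a + Z s + e, \qquad
a \sim \mathcal N(0, \sigma^2_a A), \quad
s \sim \mathcal N(0, \sigma^2_s I), \quad
e \sim \mathcal N(0, \sigma^2_e I),$$

where $y$ is log10 LD50 (or log10 yield), $X$ collects the fixed effects
(`D`, log10 mass, silk use, diet class richness, the `D` × richness
interaction, injection route — any subset), $Z$ maps assay records to
species, and $A$ is the phylogenetic correlation matrix: $A_{ij}$ is the
shared root-to-MRCA path length divided by tree depth, the expected trait
correlation under Brownian evolution.  The `animal` term $a$ absorbs
phylogenetic signal; the `species` term $s$ absorbs species-level
pseudoreplication from repeated LD50 measures.

**Priors.**  "Non-informative" is under-specified for variance components,
so the package uses the weakest conventional conjugate choice: an improper
flat prior on $\beta$ and inverse-gamma(0.001, 0.001) on each variance,
both configurable (`defaultPriors()`, `modelSpec(priors = ...)`).  With
these choices every full conditional is available in closed form and the
sampler is plain Gibbs, implemented in compiled code
(RcppArmadillo); all randomness is drawn from R's RNG, so a fixed seed
makes the entire draw stream bit-reproducible, and chain $k$ of a fit is
seeded `seed + k - 1`.

**Chain defaults.**  2 400 000 iterations, burn-in 40 000, thinning 100,
three chains — 23 600 retained draws per chain, comfortably above 1000
effective samples per parameter in practice.  These defaults suit a final
analysis; the test suite and the examples use scaled-down chains
(typically 20 000 iterations, burn-in 4 000, thinning 10) which already
give stable interval estimates for datasets of the study's size
(~150 records, 64 species).

**Inference.**  `summarizePMM()` reports posterior means, equal-tailed 95%
credibility intervals (the common default of animal-model software; highest
posterior density intervals are not used), a significance flag (interval
excludes zero), per-parameter Gelman–Rubin R-hat across chains and
effective sample sizes.  Phylogenetic heritability is computed per draw,

$$h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_s + \sigma^2_e},$$

and then summarized; since some analyses define $h^2$ without the species
term, `h2Denominator = "animal_resid"` restricts the denominator to
$\sigma^2_a + \sigma^2_e$.  $h^2 \in [0,1]$ holds draw-by-draw by
construction.

**Reference levels.**  Injection route contrasts are reported against IP
(intraperitoneal), and silk use against the non-silk-hunting state,
matching how such contrasts are conventionally reported.

**Convergence.**  `gelmanRubin()` implements the classic potential scale
reduction factor from between- and within-chain variances
($\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$, without the extra
sampling-variability correction some implementations add).

**Numerical notes.**  The per-iteration cost is dominated by a Cholesky
factorization of the q×q conditional precision of $a$ (q = number of
species); the fixed-effect design is checked for rank deficiency up front
and the offending columns named.  The animal and species variance
components are separated only by the off-diagonal structure of $A$, so
with few records per species their individual posteriors are wide even
when their sum is well identified — a generic feature of animal models
with repeat measures, worth remembering when interpreting $h^2$ from small
datasets.

## Ancestral state estimation

Silk use in prey capture is a binary trait; `estimateASR()` fits the
continuous-time Mk model by maximum likelihood.  Under equal rates (ER)
the probability of a state change over a branch of length $t$ is
$(1 - e^{-2qt})/2$; the all-rates-different (ARD) variant uses separate
gain and loss rates.  Likelihoods come from Felsenstein's pruning
algorithm; marginal state probabilities at every internal node come from
the re-rooting (inside–outside) pass, which is exact.  The root state is
weighted by the model's equilibrium frequencies (ER: ½, ½), configurable
to the observed tip frequencies.

The ER profile likelihood can have a finite mode and a high-rate plateau
(at infinite rate every reconstruction tends to ½), so the 1-D
optimization first scans a log-spaced grid and then refines around the
best point; the zero-rate boundary (monomorphic data) is checked
explicitly.  ER is the default — for a binary trait on a few dozen tips,
ARD's second rate is rarely identifiable.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the study's shape: 75 species, LD50 assays for 64 of them (1–5 assays per
species, mean 2.4, ≈153 records), 60 yield measures over 47 species.

* **Tree**: Yule (pure birth), rescaled to a 300 Myr root depth.
* **Diets**: per species, a random subset of the 12 prey classes — always
  including Insecta, since spider diets are insect-dominated — of size
  1 + Poisson(3) capped at 12 (median richness 4), with symmetric
  Dirichlet weights (concentration 1; the concentration → ∞ limit is
  uniform).
* **Traits**: body lengths lognormal around 12 mm; masses through
  `lengthToMass()`; silk use evolved on the tree under ER at 0.003
  transitions/Myr (a few expected origins/losses per tree, a labile but
  phylogenetically structured trait).
* **LD50**: generated from exactly the mixed model above, with defaults
  mirroring plausible magnitudes: prey-specificity slope
  `betaD = 0.4` per Hmya, route shifts +2.01 (thorax/cephalothorax) and
  +1.01 (abdomen) against IP, null mass and silk effects, variance
  components (0.2, 0.1, 0.2).  `D` is computed on the packaged reference
  tree, so the generative model and the fitted model agree.
* **Yields**: log10 yield = −0.8 + 0.75·log10 mass + noise (SD 0.3),
  i.e., the metabolic-theory scaling exponent of 0.75 with mg-scale
  yields for gram-scale bodies.

Component RNG streams are derived deterministically from one master seed,
so datasets are bit-reproducible and adding a component never perturbs the
others (`writeVenomData()` output is byte-identical under a fixed seed).

**What passing tests do and do not show.**  The generator draws routes and
model organisms independently of species, makes diets exactly Dirichlet,
and puts no error on the diet profiles or the tree.  Real data have
none of these luxuries: route choice correlates with spider lineage
(mammal models for medically significant species), diet reports carry
observation error, and the phylogeny is itself estimated.  Parameter
recovery on synthetic data therefore validates the implementation — the
estimator recovers the truth when the model is true — not the robustness
of the scientific conclusions to violations of those assumptions.

## Design choices where the design was open

* **Diet-label calibration** (the within-species rule above) reproduces
  published worked tables exactly; since the authoritative procedural
  description of such scoring lives in supplements that vary between
  studies, the rule is switchable.
* **Divergence convention**: MRCA age by default, patristic switchable.
* **h² denominator**: all three variance components by default,
  animal + residual switchable.
* **Equal-tailed intervals**, not HPD.
* **Diet inference from congeners** is an explicit copy
  (`inheritDiet()`), never automatic: which relative is a defensible
  donor is a literature judgement, not an algorithmic one.

## Known limitations

* Gaussian responses only; no multivariate models.
* The Mk machinery is binary-state only, without rate heterogeneity.
* Conditional likelihoods in the pruning pass are unscaled, which is
  ample for trees up to a few hundred tips but would underflow on very
  large trees.
* The packaged reference tree is illustrative; real analyses need real
  calibrations.
* Inverse-gamma(ε, ε) variance priors are proper but not uninformative
  near zero; exact invariance of h² to response rescaling holds only in
  the scale-free limit of these priors (empirically, posterior means move
  by < 0.05 under a sevenfold rescaling at the study's data size).
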