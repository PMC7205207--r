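---
title: "Charge-based viscosity engineering of antibody variable domains"
author: "AbViscosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based viscosity engineering of antibody variable domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbViscosity)
```

# The problem

Subcutaneous antibody dosing is limited to 1–2 ml per injection, which for
high-dose programs forces formulations above 150 mg/ml.  At such
concentrations many antibodies become too viscous to push through a thin
needle or to process through filtration trains; about 20 cP is the usual
syringeability ceiling.  Self-association driven by surface electrostatics —
in particular negative charge patches on the Fv interacting with the
net-positive remainder of the IgG — is a major driver.  This package
implements the computational workflow used to engineer such a molecule:
score variants from sequence, fit measured concentration–viscosity curves,
triage candidate mutations, and evaluate how well the predictors track the
measured endpoint.

Everything is exercised against the packaged study data: a parental
anti-PDGF-BB antibody (AB-001, 120-residue VH and 106-residue lambda VL)
plus 37 engineered variants over two design rounds, with their published
in-silico scores and fitted viscosity endpoints.

# The charge model

Side-chain charges follow the Henderson–Hasselbalch equation with the
textbook pKa set Asp 3.9, Glu 4.3, His 6.0, Lys 10.8, Arg 12.5.  An acid
carries $-1/(1+10^{pK_a-pH})$ and a base $+1/(1+10^{pH-pK_a})$; the other
fifteen residues carry zero.

Two deliberate conventions, both fixed by consistency with the packaged
panel rather than taste:

* **Side chains only.**  Terminal amine/carboxyl ionization is not modelled.
  Under this convention the recomputed parental Fv charge at the pH 5.5
  formulation condition is $-2.01$, exactly the published value; counting
  termini breaks the match.
* **Elementary-charge units throughout**, rounded only at presentation.

The Fv net charge is $q = q_{VH} + q_{VL}$ and the charge asymmetry is the
product $q_{sym} = q_{VH}\,q_{VL}$; a negative $q_{sym}$ flags oppositely
charged domains.

```{r}
p <- parentalChains()
fvCharge(p$VH, p$VL)
```

# The sequence viscosity score

The sequence-based viscosity predictor is

$$\eta_{pred} = 10^{\,0.15 \;+\; 1.26\,HI \;-\; 0.043\,q \;-\; 0.02\,q_{sym}}$$

with $q$, $q_{sym}$ at pH 5.5 and $HI$ the hydrophobicity index: the summed
Eisenberg scores of the hydrophobic residues divided by the magnitude of the
summed (negative) scores of the hydrophilic residues.  **HI is computed over
the full Fv** (VH and VL concatenated), not the CDRs: back-solving the score
equation for both the parental (78.17 cP) and the best round-1 clone
(58.99 cP) yields one consistent hydrophobic/hydrophilic sum pair only under
this reading, and direct summation confirms it:

```{r}
sharmaScore(p$VH, p$VL)
v <- buildVariant("R1-016")
sharmaScore(v$VH, v$VL)
```

# CDR charge at pH 7.4

A net-positive CDR charge at physiological pH is a known non-specificity
flag, so the package also reports the summed CDR charges at pH 7.4.  CDR
boundaries default to Kabat (heavy 31–35, 50–65, 95–102; light 24–34,
50–56, 89–97, insertion codes inherited).  A known limitation: for the
parental molecule a direct count over Kabat CDRs (8 Asp, 2 Lys, 1 Arg,
3 His) gives $-4.88$, whereas the published table prints $-3.7$ from an
external method whose exact CDR definition is not restated in the source.
The boundary set is therefore a configuration knob, and the packaged value
is kept as data; the constants were not tuned to force agreement.

# Kabat numbering as a packaged fixture

Numbering is shipped as explicit per-chain label maps rather than computed
by an alignment algorithm: every published mutation is given in Kabat
coordinates, and wild-type validation at application time
(`applyMutations()`) makes the fixture self-checking — the test suite
rebuilds all 38 panel rows and a single wild-type mismatch anywhere would
fail the build.  The load-bearing choices:

* **Heavy chain** (120 residues over labels 1–113): insertions 52a (giving
  the 17-residue CDR-H2), 82a–c, and 100a–c (giving the 11-residue CDR-H3).
  Validated by wild types D52a, Q100b, D101, K94 among others.
* **Lambda light chain** (106 residues): the canonical Kabat gap at
  position 10 (linear residue 10 is labelled 11).  This is the unique
  assignment under which every published light-chain mutation (E3V, T18R,
  D26N, S27K, H34K, Y49H/R, D50L, D51N, S52K, N53K, S65K, S67K, G68K,
  D96N/K) matches its stated wild type.
* The round-2 framework description uses **linear** coordinates for the FR1
  changes ("S13A, Q16K, S19R" are linear 13/16/19, i.e. Kabat 14/17/20
  after the gap); `swapFramework1()` therefore works on the linear FR1
  segment, and the panel's Kabat-coordinate mutation strings are left
  untouched.

Round-2 variants are built on R2-001, which the registry defines as the
R1-016 chains with the light-chain FR1 grafted from the lambda germline
IGLV3-21\*01 (four substitutions, removing an N-terminal clipping
liability).  The reconstruction is confirmed by the packaged Fv-charge
column: $0.93 \to 3.87$ with the FR1 changes alone.

# Rheology: the Ross–Minton model

Concentration–viscosity curves follow

$$\eta(c) = \eta_0\,
\exp\!\left(\frac{[\eta]\,c}{1-(k/\nu)[\eta]\,c}\right)$$

with the solvent viscosity fixed at $\eta_0 = 1.1$ cP and two free
parameters: the intrinsic viscosity $[\eta]$ (ml/mg) and the crowding/shape
ratio $k/\nu$ (only the ratio is identifiable).  Viscosity diverges at
$c_{sing} = 1/((k/\nu)[\eta])$.  The exact algebraic inverse is

$$c(\eta) = \frac{L}{[\eta]\,(1+(k/\nu)L)}, \qquad L=\ln(\eta/\eta_0),$$

which maps every finite $\eta > \eta_0$ to a concentration below
$c_{sing}$; inversion and prediction round-trip to $10^{-9}$ relative
error, a property the test suite asserts over random admissible parameter
draws.

## Numerical choices

* **Fitting scale.**  The default minimises residuals on the log-viscosity
  scale.  Cone-and-plate measurement error is multiplicative (it scales
  with the reading), so log-scale residuals are homoscedastic; an
  unweighted fit on raw cP is dominated by the highest readings, and its
  nominal parameter covariance — hence any delta-method interval built on
  it — is not trustworthy under multiplicative noise.  The test suite
  verifies that the default fit's 95% intervals achieve 90–99% empirical
  coverage of the true 20 cP crossing over 100 simulated curves.
  The raw-scale fit (the historical convention for this model) remains
  available via `scale = "linear"`, and a weighted raw-scale fit via
  `weights = 1/eta^2` is its near-equivalent.  $R^2$ is always reported on
  the untransformed cP scale, where well-behaved duplicate data at 2%
  relative noise stay above 0.99.
* **Initialisation.**  The model linearises exactly:
  $1/L = (1/[\eta])(1/c) - k/\nu$.  An ordinary regression of $1/L$ on
  $1/c$ gives deterministic starting values that are exact on noiseless
  data; Levenberg–Marquardt (with $[\eta]>0$, $k/\nu\ge 0$ bounds and a
  clamped denominator so excursions across the singularity yield large
  finite residuals rather than NaN) refines them.
* **Confidence intervals.**  The concentration at a viscosity threshold
  (20 cP by default) is the exact inverse at the fitted parameters; its
  standard error comes from first-order (delta-method) propagation of the
  NLS parameter covariance through the inverse, with a $t$ quantile on the
  residual degrees of freedom.  Replicate standard deviations are not used
  as weights by default (ordinary NLS), matching the original analysis.
* **Extrapolation flags.**  Reported viscosities at 100/150 mg/ml are
  flagged when the reporting concentration exceeds the measured range,
  mirroring the panel's asterisk convention.

```{r}
curve <- simulateViscosityCurve(seed = 7)
fit <- fitRossMinton(curve)
fit
concentrationAtThreshold(fit, 20)
```

# The design pipeline

The two-round mutation triage reproduces the published decision procedure
as pure, order-commuting predicates over an enumerated candidate set; every
rejected candidate keeps machine-readable reasons, and accepted + rejected
always equals enumerated.

1. **Enumeration**: every substitution with a strictly positive side-chain
   charge change at pH 5.5 (introduce K/R/H, or remove/neutralise D/E).
2. **Tolerance**: predicted change in stability *and* in binding affinity
   strictly below 1.0 kcal/mol (strict, as published; round-2 interface
   designs used a relaxed 2.0).  The structure-based predictor itself is
   out of scope — predictions are consumed from a table, and a seeded
   surrogate generator ships for tests.
3. **CDR rules**: in CDRs, E only to Q, D only to N, neutral residues only
   to R/K/H.  The round-2 "patch-extended" mode exempts flagged
   negative-patch sites, admitting the wider alphabet explored around the
   targeted patch (D to K/L/Y, Y to H/R, ...).
4. **Framework germline rule**: keep K/R introductions only where human
   repertoire frequency of K-or-R exceeds 10%, and D/E removals only where
   neutral-or-positive alternatives aggregate above 10% (aggregation, not
   maximum, across residues — the source is ambiguous and aggregation is
   the less restrictive reading).  Thresholds are strict inequalities.
5. **Score reduction**: at least one registered viscosity predictor must
   strictly decrease.  Heavy-chain candidates are scored *together with*
   the obligatory K94R (glycation-risk removal) because every emitted
   heavy-chain design carries it; scored in isolation, charge-adding heavy
   mutations can look worse through the asymmetry term than the designs
   they produce, and the published per-variant scores confirm the combined
   convention.
6. **Prioritise and combine**: negative-patch-proximal candidates first
   (patch flags are an input annotation — they came from electrostatic
   surface maps, which this package does not compute), then the heavy ×
   light combination.  How many top candidates enter the combination is
   not fixed by the source and is a configuration knob, including explicit
   selections.

```{r}
p <- parentalChains()
tabs <- simulateCandidateTables(p$VH, p$VL, seed = 1,
                                fraction_tolerated = 1,
                                fraction_permissive = 1)
report <- runDesignRound(p$VH, p$VL, ddg = tabs$ddg,
                         germline = tabs$germline)
report
```

# Evaluating predictors against measurements

`correlationSweep()` correlates each predictor column of the panel against
the measured concentration-at-20-cP endpoint, overall and per round.  The
parental molecule is grouped with round 1 (it anchors that round's panel).
Correlations run on the packaged printed columns; correlating *recomputed*
scores is a separate, explicitly chosen mode via `scoreVariantPanel()`.
Sign conventions: Fv charge correlates positively with the attainable
concentration and the viscosity scores negatively; published figures quote
the magnitudes panel-by-panel.

```{r}
correlationSweep(variantPanel(), c("fv_charge", "sharma_score"))
```

The overall correlations (~0.7) are dominated by the separation between
rounds; within either round all sequence-level predictors collapse toward
zero, which is the study's central observation: bulk charge descriptors
cannot resolve which of several similar charge changes actually hits the
viscosity-driving patch.

# What the synthetic generators do and do not emulate

`simulateViscosityCurve()` draws duplicate measurements at 8 concentrations
over 25–160 mg/ml (the serial-dilution design of the study) from a true
Ross–Minton curve with multiplicative log-normal noise (2% relative by
default, the scale of rheometer repeatability; multiplicative errors keep
viscosities positive and grow with the reading).  Default true parameters
$[\eta]=0.010$ ml/mg, $k/\nu = 0.45$ describe a moderately viscous
antibody whose 20 cP crossing sits near 126 mg/ml.  Under exactly these
conditions the test suite demonstrates median parameter recovery bias
below 1% and 90–99% empirical coverage of nominal 95% intervals over 100
simulated curves.

Not emulated: shear-rate and temperature dependence, inter-molecule
differences in $\eta_0$, concentration-measurement error, and any
systematic model misfit — so passing tests certify the estimator under the
model's own assumptions, not rheometer reality.  Similarly,
`simulateCandidateTables()` produces tables with the right *structure*
(controllable tolerated fractions, germline frequencies straddling the 10%
threshold, interface flags) but no biophysical content; real predictions
enter through the same CSV layout.

# Problem sizes and known limitations

The shipped tests rebuild all 38 panel variants, run 100-curve recovery and
coverage simulations, 200-draw inversion round-trips, and full design-round
replays (~900 candidates); the whole suite completes in well under a
minute.  Known limitations, all deliberate scope boundaries: no antibody
numbering algorithm (the fixture is validated, not computed), no
structure-based scores (their columns are data), no pKa shifting by local
environment, no alternative rheology models, and no significance testing
in the correlation sweep (none is reported for the reference analysis).
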