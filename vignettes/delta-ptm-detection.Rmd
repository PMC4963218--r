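---
title: "Detecting post-translational modifications from 13C shift deviations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting post-translational modifications from 13C shift deviations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The Delta statistic

A post-translational modification (PTM) perturbs the ¹³C chemical shift
of nuclei close to the modification site. **ptmdelta** works with the
deviation

$$\Delta_i \;=\; \delta_i \;-\; \overline{\delta}_{\mathrm{unmod}},$$

each conformation's shift minus the mean shift of the matched
*unmodified* ensemble. The construction that makes this informative is
pairing: every modified conformation is built on exactly the same
backbone and side-chain torsion angles as an unmodified twin, so the
conformational contribution to the shift is common to both sides and
cancels in $\Delta$. Two consequences are used as internal checks
throughout the test suite: the unmodified $\Delta$ distribution has mean
exactly zero, and $\Delta$ is invariant to any global referencing
constant (equivalently $\Delta_\delta = -\Delta_\sigma$ when working in
shielding rather than shift space).

The report nucleus is the closest informative carbon: Cε for Lys
(acetylation, mono/di/tri-methylation), Cζ for Arg (Nε/Nη mono- and
symmetric/asymmetric di-methylation), Cβ for Ser/Thr and Cγ for Asn
(O- and N-linked GalNAc/GlcNAc).

## Ensemble construction

Model systems are capped tripeptides Ace-Gly-Yyy-Gly-Nme built from
idealized internal coordinates (heavy atoms only) by natural-extension
(NeRF) chain growth; requested dihedrals are realized exactly, which the
suite verifies to 1e-3 degrees. Backbone and side-chain torsions of the
central residue are drawn from a packaged torsion library — a
four-basin Ramachandran Gaussian mixture (alpha-R, beta, polyproline-II,
alpha-L) with empirical chi-rotamer weights at -60/180/+60 degrees. The
library is a *surrogate* for a curated X-ray torsion database, which is
not redistributable; the analysis only requires a representative,
reproducible sample of accessible torsions, not the database itself.
Flanking residues are fixed extended glycine; neighbor-specific
restriction of glycosylated residues is therefore not emulated.

Added chemical groups introduce a new dihedral whose most frequent
positions are enumerated as discrete rotamers (each treated as equally
probable): 0/180 degrees for the acetyl amide plane, +60/-60/180 for
N-methyls on sp3 nitrogen. Glycans are rigid near-4C1-chair pyranose
templates attached via the linkage torsions, which are sampled at the
three staggered positions and carried in the torsion set itself. With
500 backbones per rotamer this yields the canonical bookkeeping of
5,000 Lys and 6,000 Arg conformations. For the Arg guanidinium the
published group totals (500 charged / 2,500 mono / 3,000 di) are honored
by enumerating site and in-plane orientation: mono-Nη = 2 sites x 2
orientations x 500; asymmetric di-methylation = 4 labels of 500, of
which geometry distinguishes only the Nη site — the orientation labels
exist to honor the conformer arithmetic and are documented as such.

Candidates are rejection-sampled: a backbone is accepted only if the
unmodified twin *and every rotamer* of every requested modified state
are free of atomic overlaps. The clash criterion — distance below 0.5 x
the sum of van der Waals radii, pairs within 3 bonds excluded — is a
deliberate design choice: the source analysis requires only "no atomic
overlaps" without quantifying the criterion, and this permissive form
flags genuine collisions while keeping acceptance rates near 0.6. The
detector is verified against a brute-force $O(n^2)$ oracle.

## The shielding surrogate

Desk-scale reproduction of quantum-chemical (GIAO DFT) shieldings for
thousands of conformations is not feasible, so a synthetic surrogate
emits shift records with the statistical structure the analysis
assumes:

$$\delta \;=\; \mathrm{base} \;+\; t(\phi,\psi,\chi_1)\;+\;
  o_{\mathrm{rot}} \;+\; E_{\mathrm{state}} \;+\; \varepsilon .$$

* $t$ is a smooth low-order periodic torsion response with amplitude
  1 ppm by default (chosen so the unmodified shift sd is about 1 ppm;
  no numeric dispersion is published, only that it is nonzero and
  identical across twins — which is what matters, since it cancels).
* $o_{\mathrm{rot}}$ are zero-sum per-rotamer offsets scaled to a mean
  absolute deviation of 1.3 ppm, the published average rotamer
  contribution; the state mean is therefore carried entirely by
  $E_{\mathrm{state}}$.
* $E_{\mathrm{state}}$ is the calibrated additive effect. The packaged
  table anchors the four modified Lys states to published mean
  $\Delta$ values (+1.5 / -10.1 / -19.1 / -25.8 ppm for
  acetyl/mono/di/tri-methyl Cε). Arg and glycan entries are published
  only as figures, so their defaults are flagged *illustrative* and are
  expected to be overridden — the package deliberately does not invent
  precise values for them, and the corresponding detection thresholds
  (e.g. the Arg di-methylation boundary) are exercised only on
  closed-form synthetic cases.
* $\varepsilon$ is i.i.d. Gaussian observation noise, 0.5 ppm by
  default — the simplest model consistent with treating the $\Delta$
  distributions as approximately Gaussian.

An adapter (`parse_shielding_log()`) ingests isotropic shieldings from
real quantum-chemistry text logs in place of the surrogate; the
locally dense basis input writer (`write_qc_input()`) emits the
corresponding jobs, assigning the large basis to the report nucleus and
its bonded shell and the small basis elsewhere. The functional string
defaults to "B98" but is free-form, since the level-of-theory label in
the source material is typographically ambiguous.

What passing tests show — and do not show. Calibration-recovery tests
demonstrate that the *pipeline arithmetic* (pairing, rotamer averaging,
$\Delta$, KDE) recovers the calibrated effects under realistic noise;
they cannot validate the quantum-chemical accuracy of those effects,
nor effects of solvent, neighboring residues or protonation changes,
none of which the surrogate models.

## Reference statistics

Experimental per-residue shift statistics anchor the classifier. The
pipeline order is fixed and tested: restrict to entries referenced to
DSS, TMS or TSP; re-reference to DSS (+0.12 ppm for TSP, -1.7 ppm for
TMS); remove Tukey-fence outliers (points outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, applied once,
closed fences, type-7 interpolated quartiles — stated explicitly because
hinge-based quartile variants change which points are outliers); then
the sample mean and sd. Fences are applied per (residue, nucleus) group,
the natural reading since the statistics are reported per residue.
Groups smaller than 4 pass through unfiltered with a warning, quartiles
being ill-defined there. Tests never download anything: a synthetic
repository-style table with planted outliers and mixed reference
standards emulates the input.

## Delta statistics

Because added methyl/acetyl groups make the molecule asymmetric, shifts
are computed per rotamer and averaged per backbone *before* $\Delta$ —
averaging shieldings, not densities. KDE summaries use a Gaussian
kernel, Silverman bandwidth by default, and a 512-point grid spanning
the samples plus/minus four bandwidths; the published analysis names KDE
without a bandwidth, so a deterministic default is required for
reproducibility and figure shapes are not treated as checkable
surfaces. The KDE mean (trapezoid first moment) equals the sample mean
up to grid truncation, the integral is 1 within 1e-3, and the mode is
the grid argmax with ties broken toward smaller $\Delta$.
Indistinguishable states (the two Arg mono-methylation sites, the two
symmetry classes of di-methylation, the two Ser glycoforms) are pooled
at the sample level and re-estimated.

## The Bayesian two-state model

Each state's $\Delta$ samples are modelled as Gaussian with unknown
$(\mu, \sigma)$, the two states fitted independently:

* $\mu \sim t(\mathrm{loc} = \bar{\Delta}_{\mathrm{state}},\;
  \mathrm{scale} = 0.35,\; \nu)$, with
  $\nu \sim \mathrm{Exponential}(\mathrm{mean}\,30)$. The 0.35 ppm
  scale encodes the established ~1 ppm agreement between computed and
  observed Lys shift changes; it is a fixed constant here, not a fitted
  quantity. The source wording leaves open whether the student-t is the
  likelihood or the prior on the mean; this package defaults to the
  prior-on-the-mean reading (with a Gaussian likelihood) and provides
  the student-t-likelihood alternative behind
  `build_model_spec(likelihood = "student_t")`.
* $\sigma \sim \mathrm{Gamma}$, moment-matched
  ($\mathrm{shape} = (m/s)^2$, $\mathrm{rate} = m/s^2$) to the
  experimental reference sd. The source states the Gamma moments come
  from the experimental values without printing them; the default takes
  prior mean = prior sd = reference sd (overridable), a weakly
  informative choice on the right scale.
* State prior probabilities default to 0.5/0.5 — exactly two states are
  assumed and no prior is published; multi-way discrimination is
  composed from pairwise profiles.

Sampling is JAGS (4 chains x 1,000 draws after 1,000 adaptation
iterations by default, explicitly seeded per chain, hence fully
reproducible); split-Rhat and effective sample size are recorded, with
Rhat > 1.05 a warning that strict mode escalates to an error. The
weakly identified $\nu$ mixes slowest and dominates the Rhat
diagnostics at small draw counts; $\mu$ and $\sigma$ mix well.

The probability profile evaluates, per posterior draw $k$,
$P_A(\Delta) = \pi_A f_A(\Delta \mid \theta_{A,k}) /
(\pi_A f_A + \pi_B f_B)$, computed in log-density space so the tails
where both densities underflow remain defined. The mean curve averages
all retained draws; the band is the 5th/95th percentile of draw curves.
Threshold queries return the maximal grid intervals on which the mean
curve reaches the requested level — possibly several, since unequal
posterior $\sigma$ values hand both far tails to the wider state.
Classification of an observed shift re-references it to DSS, forms
$\Delta$ against the experimental mean, and reads the profile by linear
interpolation; values outside the fitted grid are refused rather than
extrapolated.

## Numerical and reproducibility choices

Angles are degrees in (-180, 180] with IUPAC-signed dihedrals;
coordinates are Angstrom; shifts and shieldings ppm. Every stochastic
operation takes an explicit seed, and a run-level seed fans out
deterministically to sub-tasks (sub-seeds stay within 32-bit range).
Ensembles, shift tables, PDB output and MCMC draws are byte-reproducible
under a fixed configuration.

Problem sizes: the analysis drivers and the acceptance script use the
full published scale (500 backbones per rotamer; 5,000 Lys and 6,000 Arg
conformations; 500-sample $\Delta$ sets). Unit tests use 10-100
backbones and shorter chains, which the parameterized tolerances
account for.

## Known limitations

* The surrogate reproduces the assumed statistical structure of
  DFT shifts, not their physics; solvent, neighbor-residue and
  protonation effects are absent.
* Glycan geometry is a rigid template; ring flexibility and exocyclic
  rotamer preferences beyond the linkage torsions are not sampled.
* Arg and glycan calibration defaults are illustrative; quantitative
  thresholds for those states require user-supplied shielding data via
  the log adapter.
* The classifier is strictly pairwise two-state; modifications outside
  the candidate pair (phosphorylation, citrullination, ...) are not
  represented in the posterior.
* Observed-shift classification assumes the experimental reference mean
  of the unmodified residue transfers to the protein context; sequence-
  and structure-specific secondary-shift corrections are out of scope.
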