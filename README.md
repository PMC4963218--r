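# ptmdelta

Detection of protein post-translational modifications (PTMs) from ¹³C
chemical-shift deviations.

## The problem

Methylation, acetylation and glycosylation of protein residues shift the
¹³C resonances of nuclei near the modification site. If the shift of a
suitable report nucleus — ¹³Cε for Lys, ¹³Cζ for Arg, ¹³Cβ for Ser/Thr,
¹³Cγ for Asn — deviates far enough from the mean experimental value of
the *unmodified* residue, the deviation itself becomes a PTM probe that
works on intact, ¹³C-labelled proteins. The statistic is

Δ = δ(conformation) − mean δ(unmodified ensemble)

computed over an ensemble of *paired* conformations: each modified
conformation has an unmodified twin with identical backbone and
side-chain torsion angles, so the conformational contribution to the
shift cancels exactly and Δ isolates the modification effect. Unmodified
Δ distributions are centered at 0 ppm by construction, and Δ is invariant
to the shift-referencing constant.

Because the Δ distributions of neighboring states overlap, the decision
is probabilistic. Each state's Δ samples are modelled as Gaussian with
unknown mean μ and standard deviation σ:

- prior on μ: student-*t* centered at the state's empirical Δ mean, scale
  0.35 ppm, with degrees of freedom ν given an Exponential(mean 30)
  hyper-prior;
- prior on σ: Gamma, moment-matched to experimental per-residue shift
  statistics (DSS-re-referenced, Tukey-fence-filtered);
- the posterior predictive densities f_A, f_B of the two candidate
  states combine by Bayes' rule into a *probability profile*
  P(A | Δ) = π_A f_A / (π_A f_A + π_B f_B), one curve per posterior draw;
  the mean curve is the estimate and the draw curves its uncertainty.

This package implements the whole chain as testable components: torsion
sampling and tripeptide construction, clash-filtered paired-ensemble
generation, a synthetic shielding surrogate standing in for quantum-
chemical shift computation (with an adapter for real shielding logs),
reference-table preprocessing, Δ/KDE statistics, and the Bayesian
two-state classifier. It is aimed at NMR spectroscopists and method
developers who want to explore, calibrate or extend Δ-based PTM
detection without a quantum-chemistry pipeline.

## Worked example

```r
library(ptmdelta)

# paired ensembles: mono-methylated Lys vs its charged twin,
# 500 clash-free backbones, 3 methyl rotamers (+60/-60/180)
pair <- generate_paired_ensembles(ptm_state("LYS", "monomethyl"),
                                  n_backbones = 500, seed = 42)

# surrogate 13C-epsilon shifts, rotamer averaging, Delta, KDE
rec <- simulate_shift_records(pair, load_calibration(),
                              surrogate_params(noise_sd = 0.5, seed = 44))
avg <- average_over_rotamers(rec$modified, pair$scheme)
d   <- compute_delta(avg, rec$unmodified)
kde_density(d$modified, state = "monomethyl")
#> delta_distribution [monomethyl]: n=500, mean -10.105 ppm, sd 1.053 ppm,
#>   mode -10.978 ppm (bw 0.273)

# two-state classifier against the unmodified ensemble
ref  <- compute_reference_stats(simulate_bmrb_table(400, seed = 42), "LYS", "CE")
spec <- build_model_spec(d$modified$delta, d$unmodified$delta, ref, seed = 42)
prof <- probability_profile(fit_state_model(spec))
threshold_query(prof, 0.8, "A")
#>          lo        hi
#> 1 -22.43478 -5.436626

classify_observation(31.9, "DSS", ref, prof)$p_A
#> [1] 1
```

The mean Δ of −10.1 ppm is the calibrated ¹³Cε effect of Lys
mono-methylation; the threshold query says Δ values below about −5.4 ppm
imply >80% probability of mono-methylation relative to the charged form
(the lower end of the region reflects the span of the fitted grid). An
observed ¹³Cε shift of 31.9 ppm — Δ ≈ −10 ppm against the ~41.9 ppm
experimental mean — is classified as mono-methylated with probability
1.000. `classify_observation()` re-references the observed shift to DSS,
converts it to Δ against the experimental mean and reads the
probability (with uncertainty band) off the profile.

The numbered drivers under `analysis/` run the full study
(`01_build_ensembles.R` … `05_probability_profiles.R`), writing their
tables under `results/`. The first stage reports the conformer
bookkeeping — 5,000 Lys and 6,000 Arg conformations under the canonical
rotamer schemes — and the later stages the Δ summaries (≈ +1.5, −10.1,
−19.1, −25.8 ppm for acetyl/mono/di/tri-methyl Lys; rotamer contribution
≈ 1.3 ppm) and the 80% probability regions.

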