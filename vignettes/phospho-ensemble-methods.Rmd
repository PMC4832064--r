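---
title: "Methods: metadynamics ensembles of a phospho-regulated disordered loop"
author: "pepmetad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metadynamics ensembles of a phospho-regulated disordered loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmetad)
```

## The scientific problem

Cyclin-dependent kinase 1 phosphorylates the budding-yeast fimbrin Sac6 on
threonine 103, which sits in an intrinsically disordered loop connecting
the EF-hand domain to the first actin-binding domain. The mechanistic
question is conformational: does attaching a doubly charged phosphate to
T103 — in a segment that also carries three lysines — rigidify the loop?
The computational route to that answer is enhanced sampling of the loop
peptide (residues 99 onward, `APNSTPIVSTAATGLQHKGKGTQAKII`) in both
phospho states, followed by ensemble statistics: free-energy surfaces over
collective variables, reweighted cluster populations and their Boltzmann
free-energy gaps, contact-probability maps, and salt-bridge /
hydrogen-bond prevalences.

`pepmetad` implements that entire statistical pipeline, together with the
sequence-level operations around it (phospho annotation, formal charges,
Cdk1 S/T-P consensus scanning). What it deliberately does *not* implement
is all-atom explicit-solvent molecular dynamics: converged all-atom
metadynamics of a 27-mer requires cluster- or GPU-scale computing and a
specific force field. Published ensemble numbers obtained at that scale
(for instance a 93.64% phospho cluster population, or a ~10 kJ/mol gap
between the first two clusters) are therefore not targets for this
package's samplers; they are used only where they are pure arithmetic
inputs (the Boltzmann gap between two stated populations).

## What the synthetic-data stage emulates

Because the true free-energy surface of the real peptide is unknown, every
quantitative claim in the package is validated on systems where the answer
is known exactly:

* **Analytic landscapes.** Potentials defined directly in CV space —
  a quartic double well `U(x) = B((x/a)^2-1)^2`, Gaussian-mixture wells,
  and harmonic wells. For these, the free-energy surface *is* the
  potential (up to a constant), so metadynamics recovery, reweighting and
  Boltzmann sampling can be scored against closed forms.
* **A charged bead-chain surrogate** of the peptide: one bead per residue
  at C-alpha resolution, harmonic bonds (0.38 nm, 1000 kJ/mol/nm^2), soft
  excluded volume, and Debye–Hückel electrostatics (relative dielectric
  80, screening length 1.0 nm, roughly 100 mM ionic strength). Bead
  charges come from the sequence module's formal charge table: D/E −1,
  K/R +1, H 0, phospho group −2 (fully deprotonated at cytosolic pH;
  configurable). The phospho and unphospho chains differ in exactly one
  bead's charge, which isolates the electrostatic consequence of the
  modification.
* **Bias/CV record generators with ground truth.** `synthBiasRecords()`
  draws CV samples from the instantaneously biased Boltzmann distribution
  of an analytic landscape under a prescribed hill schedule and returns
  the exact importance weights that unbias them; `threeStateFixture()`
  draws labelled frames from three separated states at prescribed
  populations (default 68.6%/18.3%/13.1%).

The surrogate reproduces the *class* of behaviour (a chain whose
compaction responds to a localised charge change) but not the chemistry of
the real peptide: no backbone dihedral preferences, no hydrogen-bond
directionality, no solvent structure, no proline rigidity. Passing tests
therefore certify the statistical machinery — sampling, reweighting,
clustering, contact counting — not any claim about Sac6 itself.

## Sampling

The integrator is BAOAB Langevin splitting, a standard quasi-symplectic
scheme with excellent configurational accuracy at moderate time steps.
Units are kJ/mol, nm, ps, amu (so 1 kJ/mol = 1 amu nm^2 ps^-2 and no unit
constants enter the integrator), with k_B = 0.008314462618 kJ/mol/K and a
default temperature of 298 K. The default time step of 0.005 ps resolves
the stiffest default mode (bond frequency sqrt(1000/110) ≈ 3 ps^-1) by a
factor of more than a hundred; a divergence check aborts with a
diagnostic if the potential turns non-finite or coordinates blow up.
Chains start from the fully extended linear conformation; every run is
seeded explicitly and reproduces bit-identically from its seed.

## Collective variables

The two CVs mirror the standard choice for disordered-peptide compaction:

* mass-weighted **radius of gyration** over all beads (nm), and
* the **C-alpha contact number**: the sum over bead pairs with sequence
  separation |i−j| ≥ 3 of the rational switching function
  `s(r) = (1-(r/r0)^6)/(1-(r/r0)^12)` with r0 = 0.65 nm, evaluating the
  removable singularity at r = r0 by its limit n/m. Each unordered pair
  counts once.

The switching parameters, the exclusion and the selection are all exposed
because the published analysis does not state them; the defaults are the
typical C-alpha contact settings. Both CVs are invariant to rigid
rotations and translations, which the test suite checks to 1e-10 relative.

## Metadynamics and free-energy reconstruction

The bias is a sum of Gaussians deposited along the trajectory,
`V(s,t) = sum_{t_k <= t} w_k exp(-sum_d (s_d-c_{k,d})^2/(2 sigma_d^2))`.
Both standard (constant heights) and well-tempered deposition
(`w = w0 exp(-V/(k_B (gamma-1) T))`) are implemented; defaults are
well-tempered with gamma = 10, w0 = 1 kJ/mol, sigma = (0.05 nm, 0.5) for
(Rg, contact number), and a 500-step stride. During sampling the bias and
its gradient are accumulated on a grid (linear interpolation between
nodes, flat beyond the edges) so the per-step cost is independent of the
hill count; bias forces reach the beads through the analytic CV chain
rule.

The free-energy estimate is taken from the final bias, `F = -V` for
standard runs and `F = -gamma/(gamma-1) V` for well-tempered runs, with
the minimum shifted to exactly zero — the simplest defensible convention,
with `blockConvergence()` provided to judge whether the final-bias
estimate has stabilised (it rebuilds the FES from hill prefixes and
reports successive deviations over the low-free-energy region after mean
alignment). For barrier scoring on the double well, `barrierEstimate()`
averages the prefix estimates over the last 20% of depositions, which
suppresses the hill-sized sawtooth of standard metadynamics around the
converged profile; the suite requires the 10 kJ/mol barrier back within
1 k_B T at the default parameters.

## Reweighting

Unbiased averages are recovered with time-dependent-bias weights
`w_t ∝ exp(beta [V(s_t,t) - c(t)])`. The offset is evaluated on the FES
grid as

```
c(t) = -(1/beta) * ln [ ∫ exp(-beta (F(s) + V(s,t))) ds
                      / ∫ exp(-beta F(s)) ds ]
```

i.e. the log-ratio of the biased to unbiased partition functions implied
by the current bias — the importance-sampling offset of the
Tiwary–Parrinello scheme. The sign convention matters: with this form the
generator's exact ground-truth weights are reproduced to better than
1e-6 relative error for static biases and for multi-epoch time-dependent
schedules alike, and adding any constant to the bias leaves the weights
unchanged (a property the suite tests explicitly). With no hills the
weights are exactly uniform; a `static_bias` mode provides the
umbrella-unbiasing closed form `w ∝ exp(beta V(s))` used by the oracle
tests.

## Clustering and ensemble statistics

Conformations are clustered with the GROMOS/leader algorithm: repeatedly
take the frame with the most neighbours within the cutoff (ties broken
toward the lowest frame index, making outputs deterministic), form a
cluster, remove it, repeat. The default metric is pairwise RMSD after
optimal (Kabsch) superposition with a 0.2 nm cutoff appropriate to the
bead model; Euclidean clustering in CV space is offered because the
published analysis does not state its metric. Populations are summed
frame weights in percent; cluster free energies are
`F_i = -k_B T ln p_i` shifted so the top cluster sits at zero, which
makes the pairwise gap `-k_B T ln(p_j/p_i)` an identity. Applied to the
stated unphosphorylated populations 68.6% and 13.1% this arithmetic gives
4.10 kJ/mol, under the 5 kJ/mol bound quoted for easy conformational
switching.

Contact-probability maps count, per residue pair with |i−j| ≥ 2, the
weighted fraction of frames within 0.45 nm (bead-bead, a heavy-atom-like
criterion). Interaction detection is rule-based: salt bridges are
oppositely formally charged beads within 0.5 nm; the hydrogen-bond
surrogate is a phospho bead within 0.35 nm of any backbone-amide-bearing
residue (every residue except proline). The bead model has no angular
degrees of freedom, so the angle term of a true hydrogen-bond criterion
is documented but not applied; for all-atom input these cutoffs would be
applied to donor/acceptor heavy atoms with an angle check. The
two-condition display convention puts the phospho map in the upper
triangle and the unphospho map in the lower.

## Sequence-level conventions

* Phospho annotation uses the `{pX}` bracket dialect (`APNS{pT}PIV...`),
  chosen because it is unambiguous inside plain FASTA sequence lines and
  round-trips exactly.
* The numbering anchor is the *start* residue. Anchoring the printed
  27-mer at Ala99 places the S/T-P site on T103, consistent with the
  motif positions (103, 366, 589) of the full protein; note that A = 99
  implies the last printed residue is 125, although the segment is
  described as running to 126 — the package anchors at 99 and records the
  end-number discrepancy rather than resolving it.
* The minimal Cdk1 consensus is S/T followed by P; the full consensus
  `[S/T]-P-x-[K/R]` is available but the minimal form is the default,
  matching how the three Sac6 sites are defined.
* Termini are treated as uncharged by default because the simulated
  fragment is an internal loop; a flag adds the +1/−1 terminal charges.
* The bundled `sac6_synthetic.fasta` is a *synthetic* 642-residue
  stand-in for full-length Sac6 (built by `scripts/make_sac6_synthetic.R`):
  the 99–125 loop segment is genuine, minimal S/T-P sites are engineered
  at exactly 103, 366 and 589, and the background alphabet excludes
  S/T/P so no accidental motifs arise. It exercises the scanner at
  full-protein scale without claiming database identity.

## Numerical choices and degenerate inputs

* Bias grids: 201 nodes per CV for landscapes (domain-spanning), 161 for
  the chain CV box; FES reconstruction defaults to 100 bins per CV over
  the hill extent ± 5 sigma. Linear interpolation of grid-accumulated
  gradients is consistent to well below the hill widths used.
* Soft harmonic walls (1000 kJ/mol/nm^2) confine landscape sampling to
  the declared domain.
* `reconstructFES()` clamps the min-shift so the minimum is *exactly* 0;
  weight vectors are normalised to machine precision.
* Empty inputs fail loudly: empty sequences, empty hill lists for FES
  reconstruction, empty trajectories for clustering, HILLS files with a
  header but no rows.
* Zero-population clusters are excluded from free energies with a
  warning rather than returning infinities.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on a single CPU at
desk scale, sizes chosen so each statistical tolerance is comfortably
inside its Monte-Carlo error: 2e6-step metadynamics for the double-well
barrier (4000 hills), 4e5-step unbiased runs for Boltzmann histogram
checks, 1e5 frames for the three-state clustering recovery (multinomial
3-sigma ≈ 0.45% against a 1% tolerance), and 2e4-step surrogate runs per
condition for the end-to-end demonstration.

## Known limitations

* The bead chain is a surrogate: its cluster populations, contact maps
  and interaction prevalences characterise the surrogate, not the
  all-atom peptide; only the direction of charge-driven effects is
  expected to carry over.
* The hydrogen-bond criterion is distance-only at bead resolution.
* Standard metadynamics has a non-vanishing quasi-stationary error of
  order the hill height; the shipped defaults keep this below 1 k_B T
  for the double-well check but sharper surfaces would need smaller
  hills.
* The reweighting offset c(t) is computed on the *final* FES estimate;
  early in a run, before the bias has explored the relevant basins, the
  weights of those early frames are correspondingly less reliable.
* Leader clustering is O(n^2) per extraction round; at 1e5 frames the
  compacted kernel needs tens of seconds, and much larger ensembles
  should be subsampled or clustered in CV space.
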