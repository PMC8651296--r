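---
title: "Models and methods behind fretmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fretmod)
```

fretmod implements a complete single-molecule FRET (smFRET) analysis
chain and a FRET-restrained coarse-grained modeling stage for a dimeric
coiled-coil system: the STIM1 CC1 region clamped around the CAD (CC2-CC3)
dimer. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic ground truth does and does not
establish about real data.

## 1. The generative trace model

A molecule carries one donor and one acceptor dye. Its true FRET
efficiency follows a continuous-time Markov chain over `state_means`,
sampled exactly (exponential waiting times) and discretized by
frame-start occupancy at the camera interval (default 0.1 s). Frame-start
discretization, rather than within-frame averaging, keeps the ground
truth exact per frame; with 100 ms frames against ~0.8 s dwell times the
within-frame averaging error it ignores is small.

Ideal intensities invert the FRET ratio: before the acceptor bleach the
donor emits `total_intensity * (1 - E)` and the acceptor
`gamma_true * total_intensity * E`. Gamma is modeled as an acceptor-side
detection gain, so the donor rise at the acceptor bleach equals the
acceptor drop divided by gamma exactly in the noiseless limit -- a clean
oracle for the gamma estimator. After the acceptor bleach the donor
recovers to the full `total_intensity`; after the donor bleach both
channels are dark. Donor bleach clocks start at the acceptor bleach, so
clean molecules always bleach acceptor-first; the `donor_first` defect
reverses this.

Distortions are applied in the physical order: spectral leakage (7 % of
the donor signal added to the acceptor), background (level x aperture
area), Poisson shot noise, then Gaussian read noise. The correction
pipeline inverts them in the opposite order.

Default study conditions: 100 ms frames, 7 % leakage, lognormal gamma
(median 1, sdlog 0.25, essentially all mass in [0.5, 2.5]; the study
reported a mean of about 1.1), 400 detected photons/frame, and a
predominant high-FRET state (E = 0.85, 80 % occupancy) with brief
excursions to E = 0.45 lasting 0.8 s on average -- the fluctuation
pattern the recordings showed. Bleach rates (0.05 /s each) put typical
acceptor bleaches near mid-trace in a 40 s recording.

What the generator does **not** emulate: camera EM-gain statistics,
triplet blinking, spectral drift, stage drift, and dye photophysics
beyond single-step bleaching. Passing tests therefore demonstrate the
correctness of the analysis logic under idealized noise, not robustness
to every artifact of real recordings.

## 2. Movie rendering and processing

Movies place each molecule as a 2D Gaussian PSF (sigma 1.2 px by
default) in the donor half and at an affine-misaligned position in the
acceptor half, over a constant-plus-gradient background with pixel
noise. Registration is estimated from a bead image pair by
mutual-nearest-neighbor matching of detected maxima followed by a
least-squares affine fit, iterated once.

Spot detection follows the strict-maximum rule over the five-pixel-
diameter disk, with exact ties resolved to the lexicographically lowest
(row, col). Because a global threshold is meaningless on a tilted
background, a least-squares plane (with one robust reweighting pass) is
subtracted before thresholding. The summation aperture is a 5 x 5 square
(matching the detection neighborhood); the background estimate is the
per-frame median within a 35-px-diameter disk *excluding* the aperture
-- including the molecule's own pixels would bias the median upward.
Channel matching is mutual nearest neighbor with a 2 px gate. These
geometry choices (aperture, annulus, detection frame = average of the
first 10 frames, matching gate) are exposed as arguments.

## 3. Corrections, selection, and histograms

Per molecule, in order: leakage subtraction, bleach-step detection,
gamma estimation, FRET computation (`E = I_A / (I_A + gamma I_D)` on
pre-bleach frames), then the five selection criteria: SNR >= 5,
single-step acceptor-before-donor bleach, gamma in [0.5, 2.5], negative
donor/acceptor correlation, and a single-step donor bleach when one is
recorded. Each rejection carries the first failed criterion.

Numerical choices the criteria leave open:

* **SNR** is the mean detection-balanced total `I_A + gamma I_D` over
  pre-bleach frames divided by a robust noise SD from its first
  differences (`mad(diff)/sqrt(2)`). The balanced total is constant
  under FRET dynamics and first differences ignore slow fluctuations, so
  the estimate reflects noise, not kinetics.
* **Bleach steps** are classified on the running upper envelope (90th
  percentile, 25-frame window) of the acceptor: state excursions are
  brief dips that leave the envelope flat, whereas losing one of several
  acceptors halves it for a sustained period. Plateau models with 0, 1
  and 2 changepoints are compared by BIC; a multi-step call additionally
  requires a sustained intermediate plateau (>= 25 samples, between 15 %
  and 80 % of the initial level). The bleach frame is then refined on
  the raw trace as the first frame after which the acceptor stays at
  background. The distinction between a long-lived intermediate FRET
  state and a partial bleach is physically ambiguous; the sustained-
  plateau gates put that boundary at roughly 2.5 s.
* **Gamma** averages 10 frames on each side of the bleach (excluding the
  changepoint frame). Because the acceptor drop and donor rise both
  scale with the mean pre-bleach E, the ratio is insensitive to state
  mixing inside the window; 10 frames balances noise averaging against
  dwell contamination at ~0.8 s dwells.
* **Anticorrelation** uses Pearson correlation of the mean-subtracted
  pre-bleach channels with threshold -0.1 rather than 0, guarding
  against sign noise on short traces. A genuinely static molecule cannot
  demonstrate anticorrelation and is rejected -- as in the source
  protocol, which required observed fluctuations. Molecules lacking
  anticorrelation in the planted-defect suite co-fluctuate (common-mode,
  as scatterers and aggregates do); fluctuations that are exactly
  uncorrelated would sit at the statistical edge of this criterion at
  realistic trace lengths.

Histograms use 30 bins over [-0.25, 1.25]; per-trace histograms are
normalized to unit mass and the ensemble is their average. Out-of-range
E values are clipped into the end bins (the fixed range implies
inclusion, not discard), and mass is conserved.

## 4. Kinetics: HMM, clustering, dwells, transition plots

Each accepted trace's E series is fitted with Gaussian-emission HMMs of
1..5 states (EM with scaled forward-backward in compiled code; quantile
mean initialization; 5 restarts with jittered means; convergence at
1e-6 log-likelihood change; per-state variances). Model order minimizes
`BIC = -2 logL + p log T` with `p = n^2 + 2n - 1`; ties go to fewer
states; paths are Viterbi-decoded. State SDs are floored at 1e-6 so
noiseless inputs remain well-posed.

Ensemble FRET states are clustered by 1D k-means over all fitted state
means (k chosen per dataset from the histogram shape); clusters are
relabeled by increasing center. A cluster's representative level is the
center of the modal 0.05-wide bin of its decoded E points, and the
predominant cluster holds the most points. Dwells are consecutive
same-cluster runs; the first and last period of each trace are dropped
(their boundaries were not observed) and traces with fewer than two
transitions are excluded. Rates are exponential maximum-likelihood
estimates `1/mean(dwell)` with chi-square CIs. Frame discretization
shortens apparent dwells by roughly `1 - k dt/2` relative terms (about
9 % at 1 /s and 100 ms frames); no correction is applied, and the
recovery tests budget for this bias inside their 20 % band.

Transition density plots place one point per molecule per ordered
cluster pair (first occurrence; a "mean of occurrences" variant is
available) at the flanking fitted state means (cluster representative
levels are available as an option), binned on a 50 x 50 grid over
[-0.25, 1.25]^2 and convolved with a Gaussian kernel of 2 cells SD
truncated at 4 SD. Each stamp is renormalized after edge clipping so the
density integrates exactly to the point count.

## 5. Structures, dyes, and Forster distances

All internal coordinates are nm; PDB files are converted on read/write.
Distances derive from the Forster relation `R = R0 (1/E - 1)^(1/6)` with
R0 = 5.1 nm (Alexa 555/647 pair, isotropic re-orientation assumed).

Dye positions are modeled with a geometric accessible-volume sampler:
positions uniform in the ball of tether radius L around the attachment
C-alpha, rejecting positions within 0.3 nm of any protein atom or
0.2 nm of the C-alpha. Tether lengths (Cy3-like 1.35 nm, Cy5-like
1.50 nm) were chosen once so the unobstructed mean protrusion 3L/4 sits
near the reported mean dye-center protrusions (0.99 and 1.10 nm); this
sampler is the package's simplified substitute for an all-atom
simulated-annealing dye model and is the weakest correspondence to the
original method. Because labeling is stochastic, each site's Cy3 and
Cy5 mean centers are averaged into one effective pseudo-atom, and model
distances are measured center to center.

Constraint windows broaden the measured peak by +/-0.05 (the histogram
bin width) before conversion, then offset the lower bound by 1 nm
(CC1:CAD pairs; the CC1 dye may point away) or 2 nm (CC1:CC1 pairs; both
dyes may point away). Upper bounds start at the distance for
`E_peak - 0.05` and are only widened by explicit 1 nm relaxation.

The symmetric dimer is built by superposing chain A onto chain B over
the proximal CC2 (345-378) and CC3 (408-436) C-alphas (closed-form
Kabsch fit) and replacing B with the transformed copy; the returned
rigid transform mirrors nodes and dye centers thereafter. The C2
rotation is used rather than a literal mirror reflection, which would
invert chirality.

Apex optimization treats the distal CC2 helix (379-391) as a rigid body
pivoting about the G379 C-alpha, parameterized by the two angles that
redirect the helix axis (spin about the axis barely moves near-axis
sites and is omitted). The 392-407 linker follows with a displacement
tapering linearly to zero at 407 -- a connectivity-preserving stand-in
for torsion-space flexibility that needs no force field. The objective
penalizes squared distance-excess beyond each constraint's half-width,
plus a 1e-3-weighted quadratic pull toward the nominal distances that
breaks ties inside the windows (the hinge alone is flat there); a
5-degree polar x 15-degree azimuth grid seeds a Nelder-Mead refinement,
and orientations bringing moved atoms within 0.2 nm of fixed atoms are
rejected.

## 6. The chain-growth builder

CC1 (residues 344 down to 233) is modeled as one dimensionless node per
residue. Linker nodes step 0.38 nm in a uniformly random direction;
helical segments (CC1a1 246-271, CC1a2 275-305, CC1a3 310-337) are
placed as single rigid straight runs of 0.15 nm steps whose direction is
sampled once. "Random angles >= 90 degrees" is read as a bend-angle rule
at each junction: the chain may not turn by more than 90 degrees per
step, which is the only reading that constrains growth locally and
forbids sharp fold-backs. After each placement the partner node is
placed implicitly through the dimer's rigid C2 transform, and both are
checked against a 0.25 nm steric exclusion (scaffold atoms and all
non-adjacent nodes, both subunits) and against every distance constraint
whose sites are now both placed (node to effective dye center for
CC1:CAD, node to node for CC1:CC1). Distance checks run before steric
checks because they are cheaper and reject most candidates.

Failed placements are resampled in vectorized batches; trial budgets
persist while a unit stays on the search path, so repeated failures
above exhaust it and backtracking cascades deeper (depth-first search
with per-placement budgets: 256 trials per node, 4096 per helix, 400
backtracks per attempt -- engineering knobs, not physical parameters).
When attempts keep failing, the single constraint most often implicated
in rejections (ties toward the deeper residue) has its upper bound
relaxed in 1 nm increments until builds succeed; the relaxed set is then
frozen for the 50-solution ensemble. Every accepted solution is
re-validated by an independent validator sharing no code with the
builder, and classified as "stacked" when the CC1a2 axis packs
antiparallel (> 135 degrees) within 1.5 nm of the partner CC1a3' axis,
else "wedged"; the thresholds are configurable defaults motivated by the
antiparallel CC1a2:CC1a3' packing of the stacked class. Ensemble
averages are computed within one topology class (means across classes
are not meaningful structures), and averaged chains are flagged as such
since they need not obey the spacing invariants.

## 7. Synthetic structural ground truth

No crystal structure is bundled: `make_synthetic_cad()` builds a
C-alpha-only, exactly C2-symmetric V-shaped stand-in for the CAD dimer
(CC2 rising from a compact base, an apical linker, CC3 folding back),
and `make_planted_chain()` a resting-state CC1 chain with exact builder
spacings realizing the described topology -- closely apposed CC1a3
helices directed away from the core, CC1a2 stacked antiparallel against
the partner CC1a3', CC1a1 running along the partner CC3'. The bundled
36-pair constraint list mirrors the measurement sites highlighted for
the CC1-CAD clamp (inter-subunit pairs spanning all three helices,
intra-subunit pairs bracketing them, and CC1-to-core pairs); its peak
efficiencies are forward-simulated from the planted chain through the
same Forster relation, with +/-0.02 uniform jitter in E standing in for
measurement error. Ensemble results on this table (topology split,
relaxation counts) characterize the algorithm under a self-consistent
truth; with a self-consistent table, builds typically succeed without
any bound relaxation, unlike real measurements whose errors can exceed
the +/-0.05 band. They are not a re-measurement of the published
structural ensemble.

## 8. Problem sizes and determinism

The bundled checks use 200-molecule trace sets, 100 traces of 300
frames for model selection, 40-50 solution ensembles, and 100-sample
dye clouds -- sizes at which every stochastic recovery band in the test
suite is stable under reseeding. All randomness flows from explicit
integer seeds; seeded runs are bit-reproducible.

## 9. Known limitations

* The dye model is geometric; sites whose accessible volume is strongly
  anisotropic in reality will carry effective centers biased toward the
  backbone.
* Bleach-order and step classification assume background-corrected,
  leakage-corrected inputs; uncorrected offsets shift the sustained-zero
  refinement.
* The builder explores by random restart and backtracking; it is a
  feasibility sampler, not a Boltzmann sampler, so ensemble densities
  have no thermodynamic weight.
* Kinetic rates are not corrected for frame discretization or for the
  photobleaching-limited observation window.
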