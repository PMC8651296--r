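# fretmod

Single-molecule FRET (smFRET) trace analysis and FRET-constrained
coarse-grained structural modeling for dimeric coiled-coil systems, built
around the resting-state STIM1 CC1-CAD clamp.

smFRET reports the efficiency `E = I_A / (I_A + gamma * I_D)` of energy
transfer between a donor and an acceptor dye on a single molecule, and
through the Forster relation

```
R = R0 * (1/E - 1)^(1/6),        R0 = 5.1 nm (Alexa 555/647)
```

each measured efficiency peak becomes a distance restraint between two
labeled residues. fretmod covers the full chain from raw two-channel TIRF
movies to structural models:

* **Synthetic ground truth** — seeded generators for k-state Markov FRET
  dynamics at 100 ms frames, shot/read noise, per-molecule detection
  gain gamma, 7 % spectral leakage, single-step acceptor-then-donor
  photobleaching, side-by-side movie stacks with registration beads, and
  planted defect molecules (multi-step bleaches, donor-first bleaches,
  co-fluctuating channels, aggregates), plus a synthetic CAD-like dimer
  scaffold and a planted CC1 chain from which constraint tables are
  forward-simulated.
* **Movie processing** — bead-based affine channel registration, strict
  local-maximum spot detection in a five-pixel disk, mutual nearest-
  neighbor channel matching, aperture-sum trace extraction, and
  median-annulus background correction.
* **Trace analysis** — leakage subtraction, envelope-based bleach-step
  classification, per-molecule gamma from the acceptor bleach, the
  five-point selection filter (SNR, bleach order, gamma range,
  anticorrelation, donor step count), and normalized FRET histograms
  (30 bins over [-0.25, 1.25]).
* **Kinetics** — per-trace Gaussian-emission HMMs with BIC model-order
  selection, ensemble k-means clustering of FRET states, dwell-time rate
  estimates, and deduplicated transition density plots on a 50 x 50 grid.
* **Structural modeling** — accessible-volume dye centers, Forster
  distance windows with class-specific tether offsets, symmetric-dimer
  construction (Kabsch superposition), apex optimization about a pivot
  residue, and a constraint-satisfaction chain-growth sampler that grows
  node-per-residue CC1 chains (0.38 nm linker / 0.15 nm helix spacing,
  bend angles >= 90 degrees, 0.25 nm steric exclusion) with backtracking,
  1 nm bound relaxation, 50-solution ensembles, class-wise averaging, and
  stacked/wedged topology classification.

## Worked example

Simulate traces under the default study conditions, run the selection
filter, and fit kinetics:

```r
library(fretmod)

cfg   <- sim_config(n_molecules = 50, seed = 42)
sim   <- render_trace_set(simulate_state_paths(cfg))
sel   <- apply_selection(sim)
table(sel$summary$reason, useNA = "ifany")
#>
#> acceptor_multistep       bleach_order        correlation          too_short
#>                  1                  4                  3                  3
#>               <NA>
#>                 39

hist  <- build_histograms(sel)
fits  <- lapply(Filter(function(m) isTRUE(m$accepted), sel$molecules),
                function(m) fit_hmm_bic(m$E, seed = m$id))
table(vapply(fits, function(f) f$n_states, 1L))
#>
#>  1  2  3
#>  1 36  2
cm    <- cluster_states(fits, k = 2, seed = 1)
cm$representative
#> [1] 0.475 0.875
dwell_analysis(fits, cm, frame_interval = 0.1)$rates[, c("from", "to", "rate")]
#>   from to     rate
#> 1    2  1 0.346973
#> 2    1  2 1.091151
```

39 of 50 molecules pass the filter (`NA` reason = accepted); the others
carry the first criterion they failed. Most accepted traces decode as
the planted two-state system: the cluster representative levels (0.475,
0.875) sit one half-bin above the true efficiencies 0.45 and 0.85, and
the recovered exchange rates (1.09 /s out of, 0.35 /s into the brief
low-FRET state) match the simulated 1.25 /s and 0.31 /s up to frame
discretization and decoding losses.

Build a FRET-constrained CC1 ensemble around the synthetic scaffold:

```r
cad   <- effective_centers(make_synthetic_cad(), c(345, 363, 400, 417, 431),
                           dye_params("cy3", seed = 11),
                           dye_params("cy5", seed = 12))
truth <- make_planted_chain(cad)
cons  <- make_planted_constraints(truth, cad, epsilon = 0.02, seed = 5)
cfg_b <- builder_config(n_solutions = 50)
rb    <- relax_and_build(cad, cons, cfg_b, seed = 100)
ens   <- ensemble_build(cad, rb$constraints, cfg_b, seed = 200)
table(ens$topology)
#>
#> stacked  wedged
#>      34      16
write_chain_pdb(ens$solutions, "cc1_ensemble.pdb")
```

About two thirds of the accepted solutions pack CC1a2 antiparallel
against the partner CC1a3' ("stacked"); the rest splay ("wedged").

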