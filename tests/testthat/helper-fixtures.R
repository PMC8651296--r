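# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# CAD scaffold with effective dye centers at every site used by the
# bundled constraint list plus the apex sites.
fix_cad <- function() memo("cad", {
  sites <- default_constraint_sites()
  cad_sites <- sort(unique(c(sites$site_b_res[sites$pair_class == "cc1_cad"],
                             388, 389, 399, 400, 401)))
  effective_centers(make_synthetic_cad(), cad_sites,
                    dye_params("cy3", seed = 11), dye_params("cy5", seed = 12))
})

fix_planted_chain <- function() memo("chain", make_planted_chain(fix_cad()))

fix_constraints <- function() memo("constraints", {
  make_planted_constraints(fix_planted_chain(), fix_cad(),
                           epsilon = 0.02, seed = 5)
})

# Full relaxed 50-solution ensemble (used by several acceptance checks).
fix_ensemble <- function() memo("ensemble", {
  cfg <- builder_config(n_solutions = 50)
  rb <- relax_and_build(fix_cad(), fix_constraints(), cfg, seed = 100)
  ens <- ensemble_build(fix_cad(), rb$constraints, cfg, seed = 200)
  attr(ens, "relax_rounds") <- rb$rounds
  ens
})

# Default-condition trace simulation with planted defects, plus the
# selection result.
fix_defect_selection <- function() memo("defect_selection", {
  cfg <- sim_config(n_molecules = 200, seed = 7)
  sim <- plant_defects(render_trace_set(simulate_state_paths(cfg)),
                       c(multi_step_bleach = 0.2, donor_first = 0.2,
                         uncorrelated = 0.2, aggregate = 0.2))
  list(cfg = cfg, sim = sim, selection = apply_selection(sim))
})

# A defect's planted signature is only observable when its bleach events
# fall inside the recording with enough frames around them (the study
# likewise analyzed only molecules with recorded bleach events); the
# confusion matrix is evaluated on those molecules.
eligible_molecules <- function(sim, cfg) {
  vapply(sim$molecules, function(m) {
    ab <- m$acceptor_bleach_frame
    db <- m$donor_bleach_frame
    n <- cfg$n_frames
    if (m$defect == "donor_first") {
      return(is.finite(db) && db >= 60 && db <= n - 20)
    }
    if (m$defect == "multi_step_bleach") {
      return(is.finite(ab) && ab >= 100 && ab <= n - 20)
    }
    ok <- is.finite(ab) && ab >= 60 && ab <= n - 20 && (db - ab) >= 8
    if (m$defect == "clean") {
      ok <- ok && length(rle(m$states[seq_len(ab)])$lengths) > 2 &&
        m$gamma_true > 0.55 && m$gamma_true < 2.4
    }
    ok
  }, TRUE)
}

# Gaussian-noise two-state E series from an exact Markov path.
sim_two_state_E <- function(n_frames, means = c(0.4, 0.7), sd = 0.1,
                            rate = 1, seed = 1) {
  cfg <- sim_config(n_molecules = 1, n_frames = n_frames,
                    state_means = means,
                    rate_matrix = matrix(c(-rate, rate, rate, -rate), 2, 2,
                                         byrow = TRUE),
                    seed = seed)
  mol <- simulate_state_paths(cfg)$molecules[[1]]
  set.seed(seed + 1)
  list(E = mol$E_true + rnorm(n_frames, 0, sd), states = mol$states)
}

# 100 two-state traces (DE = 0.3, emission SD 0.1, 300 frames, symmetric
# 1/s exchange) fitted with BIC model selection.
fix_hmm_fits <- function() memo("fits_acceptance", {
  lapply(1:100, function(i) {
    x <- sim_two_state_E(300, means = c(0.4, 0.7), sd = 0.1, rate = 1,
                         seed = 5000 + i)
    fit_hmm_bic(x$E, max_states = 5, n_restarts = 3, seed = i)
  })
})

# Minimal hand-built hmm_fit object for kinetics tests.
fake_fit <- function(means, path, E = means[path], sds = rep(0.05,
                     length(means))) {
  structure(list(n_states = length(means), means = means, sds = sds,
                 transition = NULL, path = path, E = E,
                 loglik = 0, bic = 0, converged = TRUE),
            class = "hmm_fit")
}

# The 26 unit directions of the {-1,0,1}^3 lattice.
lattice_dirs <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g / sqrt(rowSums(g^2))
}
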