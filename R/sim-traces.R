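#' Simulation configuration for synthetic smFRET traces
#'
#' Defines the generative model for two-channel single-molecule traces:
#' a continuous-time Markov chain over true FRET states sampled at the
#' camera frame interval, ideal donor/acceptor intensities from the FRET
#' ratio, a per-molecule detection-gain factor gamma on the acceptor side,
#' donor-to-acceptor spectral leakage, single-step acceptor-then-donor
#' photobleaching, and shot plus read noise.
#'
#' Defaults mirror the study conditions the generator emulates: 100 ms
#' frames, 7 % leakage, lognormal per-molecule gamma with median 1 and a
#' spread placing essentially all molecules in [0.5, 2.5], and a
#' predominant high-FRET state with brief excursions to a lower state
#' (0.8 s mean excursion, 80 % high-state occupancy).
#'
#' @param n_molecules Number of molecules.
#' @param n_frames Frames per trace.
#' @param frame_interval Seconds per frame (default 0.1).
#' @param state_means True FRET efficiencies, strictly increasing, in [0, 1].
#' @param rate_matrix Square matrix of per-second transition rates;
#'   off-diagonals must be non-negative. A nonzero diagonal must make rows
#'   sum to zero (conservative generator); a zero diagonal is filled in.
#' @param total_intensity Mean detected photons per frame per molecule.
#' @param gamma_median,gamma_sdlog Lognormal law for per-molecule gamma.
#' @param leakage Fraction of donor signal leaking into the acceptor
#'   channel (default 0.07).
#' @param acceptor_bleach_rate,donor_bleach_rate Per-second bleach rates;
#'   the donor clock starts at the acceptor bleach, so clean molecules
#'   always bleach acceptor-first.
#' @param background_level Background counts per pixel (enters traces as
#'   level times aperture area; use 0 for background-corrected traces).
#' @param background_gradient Linear background slope, counts/pixel/pixel.
#' @param read_noise_sd Gaussian read noise per summed trace sample.
#' @param psf_sigma Gaussian PSF width in pixels (movie rendering).
#' @param aperture Side of the square summation aperture in pixels.
#' @param frame_size `c(height, width)` of one channel half in pixels.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_molecules = 100, n_frames = 400, frame_interval = 0.1,
                       state_means = c(0.45, 0.85),
                       rate_matrix = matrix(c(-1.25, 1.25, 0.3125, -0.3125),
                                            2, 2, byrow = TRUE),
                       total_intensity = 400,
                       gamma_median = 1.0, gamma_sdlog = 0.25,
                       leakage = 0.07,
                       acceptor_bleach_rate = 0.05, donor_bleach_rate = 0.05,
                       background_level = 0, background_gradient = 0,
                       read_noise_sd = 1.5,
                       psf_sigma = 1.2, aperture = 5, frame_size = c(64, 64),
                       seed = 1L) {
  k <- length(state_means)
  stopifnot(k >= 1, all(state_means >= 0 & state_means <= 1),
            n_molecules >= 1, n_frames >= 1, frame_interval > 0,
            total_intensity > 0, leakage >= 0, leakage < 1,
            acceptor_bleach_rate >= 0, donor_bleach_rate >= 0,
            read_noise_sd >= 0, aperture %% 2 == 1)
  if (k > 1 && any(diff(state_means) <= 0)) {
    stop("state_means must be strictly increasing")
  }
  rate_matrix <- as.matrix(rate_matrix)
  if (nrow(rate_matrix) != k || ncol(rate_matrix) != k) {
    stop("rate_matrix must be ", k, "x", k)
  }
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  if (any(diag(rate_matrix) != 0) &&
      any(abs(rowSums(rate_matrix)) > 1e-8 * (1 + max(abs(rate_matrix))))) {
    stop("rate_matrix is not conservative: rows must sum to zero")
  }
  diag(off) <- -rowSums(off)
  structure(list(
    n_molecules = as.integer(n_molecules), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, state_means = state_means,
    rate_matrix = off, total_intensity = total_intensity,
    gamma_median = gamma_median, gamma_sdlog = gamma_sdlog,
    leakage = leakage, acceptor_bleach_rate = acceptor_bleach_rate,
    donor_bleach_rate = donor_bleach_rate,
    background_level = background_level,
    background_gradient = background_gradient,
    read_noise_sd = read_noise_sd, psf_sigma = psf_sigma,
    aperture = as.integer(aperture), frame_size = as.integer(frame_size),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Stationary distribution of a conservative CTMC generator.
ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  if (k == 1) return(1)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- tryCatch(qr.solve(A, b), error = function(e) rep(1 / k, k))
  pi <- pmax(pi, 0)
  if (sum(pi) <= 0) pi <- rep(1, k)
  pi / sum(pi)
}

# Exact CTMC path over [0, t_end]; returns state index at each frame start.
sample_ctmc_frames <- function(Q, n_frames, dt, init) {
  k <- nrow(Q)
  t_end <- n_frames * dt
  times <- (seq_len(n_frames) - 1) * dt
  states <- integer(n_frames)
  s <- init
  t <- 0
  idx <- 1L
  repeat {
    rate <- -Q[s, s]
    t_next <- if (rate > 0) t + rexp(1, rate) else Inf
    while (idx <= n_frames && times[idx] < t_next) {
      states[idx] <- s
      idx <- idx + 1L
    }
    if (idx > n_frames || t_next >= t_end) break
    t <- t_next
    p <- Q[s, ]; p[s] <- 0
    s <- sample.int(k, 1, prob = p)
  }
  if (idx <= n_frames) states[idx:n_frames] <- s
  states
}

#' Simulate ground-truth state paths, gammas and bleach times
#'
#' Draws an exact continuous-time Markov path per molecule (exponential
#' waiting times) and discretizes it by frame-start occupancy. Acceptor
#' bleach frames are geometric at the per-frame bleach probability; the
#' donor bleach clock starts at the acceptor bleach, so clean molecules
#' always bleach acceptor-first. Spot positions are uniform within one
#' camera half with an aperture margin.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: list with `config` and
#'   `molecules`, each molecule carrying `id`, `states`, `E_true`,
#'   `gamma_true`, `acceptor_bleach_frame`, `donor_bleach_frame` (first
#'   dark frame, possibly beyond the trace), `pos` (x, y pixels) and
#'   `defect` ("clean").
#' @export
simulate_state_paths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Q <- config$rate_matrix
  pi0 <- ctmc_stationary(Q)
  dt <- config$frame_interval
  p_a <- 1 - exp(-config$acceptor_bleach_rate * dt)
  p_d <- 1 - exp(-config$donor_bleach_rate * dt)
  h <- config$frame_size[1]; w <- config$frame_size[2]
  m <- (config$aperture - 1) / 2 + 2
  mols <- lapply(seq_len(config$n_molecules), function(i) {
    init <- sample.int(length(pi0), 1, prob = pi0)
    states <- sample_ctmc_frames(Q, config$n_frames, dt, init)
    ab <- if (p_a > 0) rgeom_frames(p_a) else Inf
    db <- if (p_d > 0) ab + rgeom_frames(p_d) else Inf
    list(id = i, states = states, E_true = config$state_means[states],
         gamma_true = rlnorm(1, log(config$gamma_median), config$gamma_sdlog),
         acceptor_bleach_frame = ab, donor_bleach_frame = db,
         pos = c(x = runif(1, m + 1, w - m), y = runif(1, m + 1, h - m)),
         defect = "clean")
  })
  structure(list(config = config, molecules = mols), class = "sim_truth")
}

# First dark frame under a per-frame bleach probability (>= 2 so at least
# one active frame is observed; frame 1 active by construction).
rgeom_frames <- function(p) 2 + stats::rgeom(1, p)

# Ideal (noise-free, leakage-free, background-free) channels for one
# molecule. Gamma acts as acceptor-side detection gain, so the donor rise
# at acceptor bleach equals the acceptor drop divided by gamma exactly.
ideal_channels <- function(mol, config) {
  n <- config$n_frames
  f <- seq_len(n)
  Tt <- config$total_intensity
  E <- mol$E_true
  ab <- mol$acceptor_bleach_frame
  db <- mol$donor_bleach_frame
  if (db < ab) { # donor-first defect: FRET stops when the donor dies
    donor <- ifelse(f < db, Tt * (1 - E), 0)
    acceptor <- ifelse(f < db, mol$gamma_true * Tt * E, 0)
  } else {
    donor <- ifelse(f < ab, Tt * (1 - E), ifelse(f < db, Tt, 0))
    acceptor <- ifelse(f < ab, mol$gamma_true * Tt * E, 0)
  }
  if (identical(mol$defect, "multi_step_bleach") && is.finite(ab) && ab > 3) {
    m0 <- mol$multi_step_frame
    half <- f >= m0 & f < ab
    acceptor[half] <- acceptor[half] / 2
  }
  if (identical(mol$defect, "uncorrelated")) {
    donor <- donor * mol$telegraph_d
    acceptor <- acceptor * mol$telegraph_a
  }
  list(donor = donor, acceptor = acceptor)
}

#' Render noisy two-channel traces from ground truth
#'
#' Inverts the FRET formula as a generative model: before the acceptor
#' bleach the ideal donor is `total_intensity * (1 - E)` and the ideal
#' acceptor `gamma_true * total_intensity * E`; after the acceptor bleach
#' the donor recovers to `total_intensity` and the acceptor is dark; after
#' the donor bleach both are dark. Leakage, background, Poisson shot noise
#' and Gaussian read noise are then applied in that order (the physical
#' signal chain; the correction pipeline inverts it).
#'
#' @param truth A `sim_truth` from [simulate_state_paths()].
#' @param noise If `FALSE`, skip Poisson and read noise (ideal traces).
#' @return An object of class `sim_traces`: the truth plus per-molecule
#'   `donor` and `acceptor` count series.
#' @export
render_trace_set <- function(truth, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(config$seed + 1L)
  bg <- config$background_level * config$aperture^2
  truth$molecules <- lapply(truth$molecules, function(mol) {
    ch <- ideal_channels(mol, config)
    donor <- ch$donor
    acceptor <- ch$acceptor + config$leakage * donor
    donor <- donor + bg
    acceptor <- acceptor + bg
    if (noise) {
      donor <- rpois(length(donor), donor) +
        rnorm(length(donor), 0, config$read_noise_sd)
      acceptor <- rpois(length(acceptor), acceptor) +
        rnorm(length(acceptor), 0, config$read_noise_sd)
    }
    mol$donor <- donor
    mol$acceptor <- acceptor
    mol
  })
  class(truth) <- c("sim_traces", "sim_truth")
  truth
}

#' Plant labeled defect molecules into a simulated trace set
#'
#' Converts seeded, deterministic fractions of the molecules into defect
#' classes that the trace selection filter must reject:
#' \describe{
#'   \item{multi_step_bleach}{the acceptor loses half its signal at an
#'     intermediate frame before bleaching fully (two-step bleach).}
#'   \item{donor_first}{the donor bleaches before the acceptor; both
#'     channels go dark together.}
#'   \item{uncorrelated}{donor and acceptor carry independent slow
#'     telegraph fluctuations instead of shared FRET dynamics.}
#'   \item{aggregate}{gamma_true is redrawn outside [0.5, 2.5], the
#'     signature of multi-dye aggregates or photophysical anomalies.}
#' }
#' Exactly `round(fraction * n)` molecules get each label, assigned from a
#' seeded permutation, so counts are deterministic under a fixed seed.
#'
#' @param sim A `sim_traces` set (or `sim_truth`; traces are re-rendered).
#' @param fractions Named numeric vector with any of the names above;
#'   must sum to at most 1.
#' @param seed Integer seed for the assignment and re-rendering.
#' @return A `sim_traces` set with `defect` labels set and affected
#'   molecules re-rendered.
#' @export
plant_defects <- function(sim, fractions, seed = sim$config$seed + 2L) {
  stopifnot(inherits(sim, "sim_truth"))
  known <- c("multi_step_bleach", "donor_first", "uncorrelated", "aggregate")
  if (is.null(names(fractions)) || !all(names(fractions) %in% known)) {
    stop("fractions must be named with: ", paste(known, collapse = ", "))
  }
  if (sum(fractions) > 1 + 1e-12) stop("defect fractions sum to more than 1")
  config <- sim$config
  n <- length(sim$molecules)
  set.seed(seed)
  perm <- sample.int(n)
  counts <- round(fractions * n)
  at <- 0L
  for (lab in names(counts)) {
    idx <- perm[seq_len(counts[lab]) + at]
    at <- at + counts[lab]
    for (i in idx) {
      mol <- sim$molecules[[i]]
      mol$defect <- lab
      if (lab == "multi_step_bleach") {
        ab <- mol$acceptor_bleach_frame
        if (!is.finite(ab) || ab > config$n_frames) {
          ab <- mol$acceptor_bleach_frame <-
            max(4L, round(config$n_frames * 0.6))
          mol$donor_bleach_frame <- ab + rgeom_frames(
            1 - exp(-config$donor_bleach_rate * config$frame_interval))
        }
        mol$multi_step_frame <- max(2L, floor(ab / 2))
      } else if (lab == "donor_first") {
        ab <- mol$acceptor_bleach_frame
        d <- if (is.finite(ab)) max(2L, min(ab - 1L, config$n_frames - 5L))
             else max(2L, round(config$n_frames * 0.6))
        mol$donor_bleach_frame <- d
        mol$acceptor_bleach_frame <- max(d + 1L, ab, na.rm = TRUE)
      } else if (lab == "uncorrelated") {
        # channels co-fluctuate (common-mode, as for scatterers and
        # aggregates) instead of showing FRET anticorrelation
        p <- 1 - exp(-2 * config$frame_interval) # ~0.5 s dwell telegraph
        common <- telegraph(config$n_frames, p)
        mol$telegraph_d <- 1 + 0.12 * common +
          0.05 * telegraph(config$n_frames, p)
        mol$telegraph_a <- 1 + 0.12 * common +
          0.05 * telegraph(config$n_frames, p)
        mol$states <- rep(which.max(tabulate(mol$states)), config$n_frames)
        mol$E_true <- config$state_means[mol$states]
      } else if (lab == "aggregate") {
        # gamma just outside the acceptance band, probing the filter's
        # discrimination at the boundary
        lo <- runif(1) < 0.5
        mol$gamma_true <- if (lo) runif(1, 0.30, 0.45) else runif(1, 2.8, 4.0)
      }
      sim$molecules[[i]] <- mol
    }
  }
  render_trace_set(sim)
}

# +/-1 telegraph process with per-frame flip probability p.
telegraph <- function(n, p) {
  flips <- runif(n) < p
  s <- if (runif(1) < 0.5) 1 else -1
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (flips[i]) s <- -s
    out[i] <- s
  }
  out
}

#' Convert a simulated trace set to a long table
#'
#' @param sim A `sim_traces` set.
#' @return data.frame with columns `molecule_id`, `frame`, `donor`,
#'   `acceptor`.
#' @export
traces_to_table <- function(sim) {
  stopifnot(inherits(sim, "sim_traces"))
  do.call(rbind, lapply(sim$molecules, function(mol) {
    data.frame(molecule_id = mol$id, frame = seq_along(mol$donor),
               donor = mol$donor, acceptor = mol$acceptor)
  }))
}

#' Write / read the trace TSV dialect and ground-truth JSON sidecar
#'
#' Traces go to a TSV with columns `molecule_id`, `frame`, `donor`,
#' `acceptor`; ground truth to a JSON object keyed by molecule id.
#'
#' @param sim A `sim_traces` set.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @export
write_traces <- function(sim, path) {
  write.table(traces_to_table(sim), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- lapply(sim$molecules, function(mol) {
    list(gamma_true = mol$gamma_true,
         acceptor_bleach_frame = unbox_inf(mol$acceptor_bleach_frame),
         donor_bleach_frame = unbox_inf(mol$donor_bleach_frame),
         pos = unname(mol$pos), defect = mol$defect)
  })
  names(truth) <- vapply(sim$molecules, function(m) as.character(m$id), "")
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unbox_inf <- function(x) if (is.finite(x)) x else NULL

#' @rdname write_traces
#' @return `read_traces()` returns a list of per-molecule traces with
#'   `id`, `donor`, `acceptor`.
#' @export
read_traces <- function(path) {
  tab <- read.delim(path)
  lapply(split(tab, tab$molecule_id), function(d) {
    d <- d[order(d$frame), ]
    list(id = d$molecule_id[1], donor = d$donor, acceptor = d$acceptor)
  })
}
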