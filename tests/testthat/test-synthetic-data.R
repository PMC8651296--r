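test_that("state-path simulation honors the generator and is reproducible", {
  # single state: constant path
  cfg1 <- sim_config(n_molecules = 3, n_frames = 50, state_means = 0.7,
                     rate_matrix = matrix(0, 1, 1), seed = 1)
  tr <- simulate_state_paths(cfg1)
  expect_true(all(vapply(tr$molecules,
                         function(m) all(m$states == 1), TRUE)))
  # zero rates: never leaves the initial state
  cfg2 <- sim_config(n_molecules = 5, n_frames = 80,
                     state_means = c(0.3, 0.8),
                     rate_matrix = matrix(0, 2, 2), seed = 2)
  tr2 <- simulate_state_paths(cfg2)
  expect_true(all(vapply(tr2$molecules,
                         function(m) length(unique(m$states)) == 1, TRUE)))
  # symmetric 2-state chain: occupancy 0.50 +/- 0.02
  cfg3 <- sim_config(n_molecules = 2000, n_frames = 100,
                     state_means = c(0.3, 0.8),
                     rate_matrix = matrix(c(-1, 1, 1, -1), 2, 2,
                                          byrow = TRUE),
                     seed = 3)
  tr3 <- simulate_state_paths(cfg3)
  occ <- mean(unlist(lapply(tr3$molecules, function(m) m$states == 1)))
  expect_equal(occ, 0.5, tolerance = 0.02)
  # bit reproducibility
  a <- render_trace_set(simulate_state_paths(sim_config(n_molecules = 4,
                                                        seed = 9)))
  b <- render_trace_set(simulate_state_paths(sim_config(n_molecules = 4,
                                                        seed = 9)))
  expect_identical(a$molecules, b$molecules)
  expect_error(sim_config(rate_matrix = matrix(c(-2, 1, 1, -1), 2, 2)),
               "conservative")
  expect_error(sim_config(state_means = c(0.8, 0.3)), "increasing")
})

test_that("noise-free rendering inverts the FRET formula exactly", {
  cfg <- sim_config(n_molecules = 10, n_frames = 100, leakage = 0,
                    background_level = 0, seed = 4)
  sim <- render_trace_set(simulate_state_paths(cfg), noise = FALSE)
  for (m in sim$molecules) {
    pre <- seq_len(min(m$acceptor_bleach_frame - 1, cfg$n_frames))
    E <- m$acceptor[pre] / (m$acceptor[pre] + m$gamma_true * m$donor[pre])
    expect_equal(E, m$E_true[pre], tolerance = 1e-12)
    # gamma as acceptor-side gain: donor+acceptor/gamma conserved pre-bleach
    expect_equal(m$donor[pre] + m$acceptor[pre] / m$gamma_true,
                 rep(cfg$total_intensity, length(pre)), tolerance = 1e-9)
  }
  # E = 0.5, gamma 2 (noise-free): I_A / I_D = 2 and the formula inverts
  cfg5 <- sim_config(n_molecules = 1, n_frames = 20, state_means = 0.5,
                     rate_matrix = matrix(0, 1, 1), leakage = 0,
                     gamma_median = 2, gamma_sdlog = 0, seed = 5)
  m5 <- render_trace_set(simulate_state_paths(cfg5), noise = FALSE)$molecules[[1]]
  pre <- seq_len(min(m5$acceptor_bleach_frame - 1, 20))
  expect_equal(m5$acceptor[pre] / m5$donor[pre], rep(2, length(pre)))
  expect_equal(m5$acceptor[pre] / (m5$acceptor[pre] + 2 * m5$donor[pre]),
               rep(0.5, length(pre)))
})

test_that("leakage adds exactly the configured donor fraction", {
  cfg <- sim_config(n_molecules = 1, n_frames = 30, state_means = 1e-9,
                    rate_matrix = matrix(0, 1, 1), leakage = 0.07,
                    background_level = 0, seed = 6)
  m <- render_trace_set(simulate_state_paths(cfg), noise = FALSE)$molecules[[1]]
  pre <- seq_len(min(m$acceptor_bleach_frame - 1, 30))
  expect_equal(m$acceptor[pre], 0.07 * m$donor[pre], tolerance = 1e-6)
})

test_that("planted defects are deterministic, labeled and partition the set", {
  cfg <- sim_config(n_molecules = 200, seed = 7)
  sim0 <- render_trace_set(simulate_state_paths(cfg))
  # all-zero fractions leave the set unchanged
  same <- plant_defects(sim0, c(donor_first = 0))
  expect_equal(lapply(same$molecules, `[[`, "defect"),
               lapply(sim0$molecules, `[[`, "defect"))
  sim <- plant_defects(sim0, c(multi_step_bleach = 0.2, donor_first = 0.1),
                       seed = 21)
  labs <- vapply(sim$molecules, `[[`, "", "defect")
  expect_equal(sum(labs == "multi_step_bleach"), 40)  # exactly 20% of 200
  expect_equal(sum(labs == "donor_first"), 20)
  expect_equal(sum(labs == "clean"), 140)
  df <- Filter(function(m) m$defect == "donor_first", sim$molecules)
  expect_true(all(vapply(df, function(m) {
    m$donor_bleach_frame < m$acceptor_bleach_frame
  }, TRUE)))
  expect_error(plant_defects(sim0, c(donor_first = 0.7, aggregate = 0.6)),
               "sum")
})

test_that("planted chain obeys spacings, symmetry and the builder contract", {
  cad <- fix_cad()
  ch <- fix_planted_chain()
  cfg <- builder_config()
  labels <- ch$labels
  spac <- fretmod:::bond_spacings(ch$resno, labels)
  bonds <- sqrt(rowSums((ch$A[-1, ] - ch$A[-nrow(ch$A), ])^2))
  expect_equal(unname(bonds), spac[-length(spac)], tolerance = 1e-9)
  expect_equal(fretmod:::apply_rigid(ch$A, ch$transform),
               unname(ch$B), tolerance = 1e-12, ignore_attr = TRUE)
  v <- validate_chain(ch, cad, fix_constraints()[0, ], cfg)
  expect_true(v$ok)
})

test_that("planted constraints invert the Forster relation and validate", {
  cad <- fix_cad()
  ch <- fix_planted_chain()
  # distance exactly R0 gives E = 0.5 through the same code path
  expect_equal(distance_to_fret(5.1), 0.5)
  expect_equal(distance_to_fret(3.536, forster_config()), 0.9,
               tolerance = 1e-3)
  cons0 <- make_planted_constraints(ch, cad, epsilon = 0)
  expect_equal(nrow(cons0), 36)
  # with zero jitter the planted chain satisfies every constraint
  v <- validate_chain(ch, cad, cons0, builder_config())
  expect_true(v$ok)
  # jittered table still brackets the chain (uncertainty band covers it)
  v2 <- validate_chain(ch, cad, fix_constraints(), builder_config())
  expect_true(v2$ok)
  expect_error(
    make_planted_constraints(ch, cad,
                             sites = data.frame(site_a_res = 999,
                                                site_a_sub = "A",
                                                site_b_res = 999,
                                                site_b_sub = "B",
                                                pair_class = "cc1_cc1")),
    "not in chain")
})

test_that("trace tables and ground truth survive a disk round trip", {
  cfg <- sim_config(n_molecules = 5, n_frames = 40, seed = 11)
  sim <- render_trace_set(simulate_state_paths(cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(sim, path)
  back <- read_traces(path)
  expect_length(back, 5)
  expect_equal(back[[3]]$donor, sim$molecules[[3]]$donor, tolerance = 1e-9)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(truth[["2"]]$gamma_true, sim$molecules[[2]]$gamma_true,
               tolerance = 1e-9)
})
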