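toy_config <- function(n = 10, ...) {
  builder_config(start_residue = n, end_residue = 1, helix_ranges = list(),
                 ...)
}

empty_constraints <- function() fix_constraints()[0, ]

test_that("unconstrained growth yields exact spacings and legal bends", {
  cfg <- toy_config(10, seed = 1)
  for (s in 1:5) {
    ch <- build_chain_solution(NULL, empty_constraints(), cfg, seed = s,
                               anchor = c(1, 0.5, 0))
    expect_s3_class(ch, "node_chain")
    bonds <- ch$A[-1, ] - ch$A[-nrow(ch$A), ]
    expect_equal(unname(sqrt(rowSums(bonds^2))), rep(0.38, 9),
                 tolerance = 1e-9)
    # growth-order bond turns no sharper than 90 degrees
    bd <- -bonds[nrow(bonds):1, ]
    dots <- rowSums(bd[-1, ] * bd[-nrow(bd), ])
    expect_true(all(dots >= -1e-9))
    expect_equal(fretmod:::apply_rigid(ch$A, ch$transform), unname(ch$B),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a geometrically impossible bound produces a failure report", {
  cfg <- toy_config(6, max_backtracks = 30, seed = 2)
  cons <- random_lattice_instance(6, seed = 1)
  cons$lb <- 0
  cons$ub[1] <- 0.01   # unreachable: bonds are 0.38 nm long
  out <- build_chain_solution(NULL, cons, cfg, seed = 3,
                              anchor = c(1, 0.5, 0))
  expect_s3_class(out, "build_failure")
  expect_true(out$deepest_residue >= 1)
  expect_gt(sum(out$rejections), 0)
})

test_that("relaxation widens exactly the over-tight constraint", {
  # nodes 6..1 grown from the anchor can come no closer to the far-away
  # dye center than |far - anchor| - 6 bonds = 3.72 nm (hard floor); the
  # initial upper bound sits two relaxation increments below a
  # comfortably reachable distance
  anchor <- c(1, 0.5, 0)
  far <- anchor + c(6, 0, 0)
  cons <- data.frame(site_a_res = 1L, site_a_sub = "A", site_b_res = 1L,
                     site_b_sub = "A", pair_class = "cc1_cad",
                     E_peak = 0.5, E_uncertainty = 0.05,
                     D_FRET = 1.55, lb = 0, ub = 1.55,
                     n_relaxations = 0L)
  class(cons) <- c("constraint_table", "data.frame")
  cad <- fretmod:::new_atomic_model(data.frame(
    chain = c("A", "B"), resno = 1L, elety = "CA", element = "C",
    x = c(far[1], -far[1]), y = c(far[2], -far[2]), z = far[3]))
  cad$transform <- fretmod:::rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  cad$eff_centers <- data.frame(chain = c("A", "B"), resno = 1L,
                                x = c(far[1], -far[1]),
                                y = c(far[2], -far[2]), z = far[3])
  cfg <- toy_config(6, max_backtracks = 120, max_node_trials = 256,
                    relaxation_increment = 2, seed = 4)
  rb <- relax_and_build(cad, cons, cfg, seed = 5, attempts_per_round = 3,
                        anchor = anchor)
  expect_equal(rb$constraints$n_relaxations, 2L)
  expect_s3_class(rb$solution, "node_chain")
  # a feasible set needs no relaxation; an empty set succeeds immediately
  rb0 <- relax_and_build(NULL, empty_constraints(), cfg, seed = 6)
  expect_equal(rb0$rounds, 0L)
})

test_that("ensembles are reproducible, diverse and fully validated", {
  cfg <- toy_config(8, n_solutions = 4, seed = 7)
  e1 <- ensemble_build(NULL, empty_constraints(), cfg, seed = 11)
  e2 <- ensemble_build(NULL, empty_constraints(), cfg, seed = 11)
  expect_identical(lapply(e1$solutions, `[[`, "A"),
                   lapply(e2$solutions, `[[`, "A"))
  expect_length(e1$solutions, 4)
  # random growth is diverse
  rmsd <- sqrt(mean((e1$solutions[[1]]$A - e1$solutions[[2]]$A)^2))
  expect_gt(rmsd, 0)
  for (sol in e1$solutions) {
    v <- validate_chain(sol, NULL, empty_constraints(), cfg)
    expect_true(v$ok)
  }
})

test_that("sampler feasibility agrees with exhaustive lattice enumeration", {
  dirs <- lattice_dirs()
  agree <- 0
  n_inst <- 0
  for (seed in 1:20) {
    n_nodes <- if (seed %% 4 == 0) 5 else 4
    cons <- random_lattice_instance(n_nodes, seed = seed,
                                    tighten = seed %% 2 == 0)
    truth <- enumerate_feasible(c(1, 0.5, 0), n_nodes, cons)
    cfg <- builder_config(start_residue = n_nodes, end_residue = 1,
                          helix_ranges = list(), direction_set = dirs,
                          max_node_trials = 1500, max_backtracks = 600)
    found <- FALSE
    for (s in 1:3) {
      out <- build_chain_solution(NULL, cons, cfg, seed = 50 + s,
                                  anchor = c(1, 0.5, 0))
      if (inherits(out, "node_chain")) { found <- TRUE; break }
    }
    n_inst <- n_inst + 1
    agree <- agree + (found == truth)
  }
  expect_equal(agree, n_inst)
})

test_that("averaging preserves symmetry cases and propagates noise", {
  cfg <- toy_config(8, n_solutions = 3, seed = 8)
  ens <- ensemble_build(NULL, empty_constraints(), cfg, seed = 21)
  ens$topology <- rep("stacked", 3)
  # identical solutions average to themselves with zero spread
  same <- ens
  same$solutions <- rep(ens$solutions[1], 3)
  av0 <- average_model(same, class = "stacked")
  expect_equal(av0$chain$A, ens$solutions[[1]]$A, tolerance = 1e-12)
  expect_equal(max(av0$spread), 0)
  # planted isotropic noise: per-residue spread ~ sigma * sqrt(3)
  sigma <- 0.2
  set.seed(9)
  base <- ens$solutions[[1]]
  noisy <- lapply(1:200, function(i) {
    s <- base
    s$A <- base$A + matrix(rnorm(length(base$A), 0, sigma), nrow(base$A), 3)
    s
  })
  ens2 <- ens
  ens2$solutions <- noisy
  ens2$topology <- rep("stacked", length(noisy))
  av <- average_model(ens2, class = "stacked")
  expect_equal(mean(av$spread), sigma * sqrt(3), tolerance = 0.2 * sigma *
                 sqrt(3))
  # mixing topology classes errors unless forced
  ens3 <- ens
  ens3$topology <- c("stacked", "wedged", "wedged")
  expect_error(average_model(ens3, class = "stacked"), "fewer than 2")
  expect_silent(average_model(ens3, force = TRUE))
})

test_that("topology classification separates stacked from wedged packing", {
  cfg <- builder_config()
  tr <- fretmod:::rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  mk <- function(a2_start, a2_end) {
    resno <- 233:344
    A <- matrix(0, length(resno), 3)
    rownames(A) <- resno
    # cc1a3 on A: a vertical helix at x = 0.6 (so its B copy is at -0.6)
    A[as.character(310:337), ] <- cbind(0.6, 0.45,
                                        seq(-6, -2, length.out = 28))
    A[as.character(275:305), ] <- cbind(
      seq(a2_start[1], a2_end[1], length.out = 31),
      seq(a2_start[2], a2_end[2], length.out = 31),
      seq(a2_start[3], a2_end[3], length.out = 31))
    node_chain(A, resno, tr, kind = "average")
  }
  # antiparallel to the partner cc1a3' (which runs upward at (-0.6,-0.45))
  stacked <- mk(c(-1.3, -1.0, -2), c(-1.3, -1.0, -6))
  lab1 <- classify_topology(stacked, cfg)
  expect_equal(lab1$label, "stacked")
  expect_gt(lab1$angle, 135)
  expect_lt(lab1$distance, 1.5)
  # perpendicular and far: wedged
  wedged <- mk(c(-1.3, -1.0, -4), c(-4.3, -2.0, -4))
  expect_equal(classify_topology(wedged, cfg)$label, "wedged")
  # determinism
  expect_identical(lab1, classify_topology(stacked, cfg))
})

test_that("node-chain ensembles are written as multi-model PDB", {
  cfg <- toy_config(6, n_solutions = 2, seed = 10)
  ens <- ensemble_build(NULL, empty_constraints(), cfg, seed = 31)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ens$solutions, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  expect_equal(sum(grepl("^ATOM", lines)), 2 * 2 * 6)
  # coordinates are written in angstroms
  x1 <- as.numeric(substr(lines[grepl("^ATOM", lines)][1], 31, 38))
  expect_equal(x1 / 10, unname(ens$solutions[[1]]$A[1, 1]),
               tolerance = 1e-3)
})
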