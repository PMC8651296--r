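toy_dimer <- function(perturb_b = 0) {
  # two parallel 40-residue helices, chain B = chain A rotated by C2(z)
  z <- seq(0, 5.85, by = 0.15)
  a <- data.frame(chain = "A", resno = 345 + seq_along(z) - 1,
                  elety = "CA", element = "C",
                  x = 0.8, y = 0.4, z = z, stringsAsFactors = FALSE)
  b <- a
  b$chain <- "B"
  b$x <- -a$x + perturb_b * 0.05
  b$y <- -a$y
  b$z <- a$z + perturb_b * 0.02
  fretmod:::new_atomic_model(rbind(a, b))
}

test_that("rigid superposition recovers planted transforms exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  Q <- sweep(P %*% t(R), 2, c(1, -2, 0.5), "+")
  fit <- kabsch(P, Q)
  expect_lt(max(abs(fit$R - R)), 1e-9)
  expect_lt(max(abs(fit$t - c(1, -2, 0.5))), 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  # 3-point minimal case
  fit3 <- kabsch(P[1:3, ], Q[1:3, ])
  expect_lt(fit3$rmsd, 1e-9)
})

test_that("symmetrize_dimer yields an exactly symmetric model", {
  m0 <- toy_dimer(0)
  rng <- list(c(345, 360), c(365, 380))
  s0 <- symmetrize_dimer(m0, rng)
  # already-symmetric dimer: chain B unchanged
  expect_equal(fretmod:::coords(s0, "B"), fretmod:::coords(m0, "B"),
               tolerance = 1e-9)
  # perturbed chain B gets replaced by the transformed chain A copy
  m1 <- toy_dimer(1)
  s1 <- symmetrize_dimer(m1, rng)
  bb <- fretmod:::apply_rigid(fretmod:::coords(s1, "A"), s1$transform)
  expect_lt(max(abs(bb - fretmod:::coords(s1, "B"))), 1e-9)
  # missing residues are reported
  m2 <- toy_dimer(0)
  m2$atoms <- m2$atoms[m2$atoms$resno != 350 | m2$atoms$chain != "B", ]
  expect_error(symmetrize_dimer(m2, rng), "350")
})

test_that("accessible-volume dye sampling matches the uniform-ball law", {
  # isolated single-atom protein: mean protrusion ~ 3L/4
  lone <- fretmod:::new_atomic_model(data.frame(
    chain = "A", resno = 1, elety = "CA", element = "C",
    x = 0, y = 0, z = 0))
  s <- sample_dye_centers(lone, 1, "A", dye_params("cy3", L = 1.2,
                                                   n_samples = 4000,
                                                   seed = 2))
  expect_equal(s$protrusion, 0.9, tolerance = 0.02)
  # the mean position of an unobstructed cloud is near the attachment atom
  expect_lt(sqrt(sum(s$mean^2)), 0.05)
  # every sample obeys the hard exclusions
  expect_true(all(sqrt(rowSums(s$cloud^2)) >= 0.2))
  expect_true(all(sqrt(rowSums(s$cloud^2)) <= 1.2 + 1e-12))
  # a wall of atoms pushes the mean center away from it
  wall <- do.call(rbind, lapply(seq(-2, 2, by = 0.1), function(xx) {
    do.call(rbind, lapply(seq(-2, 2, by = 0.1), function(yy) {
      data.frame(chain = "A", resno = 5000 + round(1000 * (xx + 3) + yy * 10),
                 elety = "X", element = "C", x = xx, y = yy, z = -0.25)
    }))
  }))
  wall$resno <- seq_len(nrow(wall)) + 10
  walled <- fretmod:::new_atomic_model(rbind(lone$atoms, wall))
  sw <- sample_dye_centers(walled, 1, "A",
                           dye_params("cy3", L = 1.2, seed = 3))
  expect_gt(sw$mean[3], 0.1)          # displaced along +z, away from wall
  # fixed seed: bit-identical cloud
  sw2 <- sample_dye_centers(walled, 1, "A",
                            dye_params("cy3", L = 1.2, seed = 3))
  expect_identical(sw$cloud, sw2$cloud)
  # a buried site errors
  cage <- expand.grid(x = seq(-1.4, 1.4, 0.28), y = seq(-1.4, 1.4, 0.28),
                      z = seq(-1.4, 1.4, 0.28))
  cage <- cage[sqrt(rowSums(cage^2)) > 0.25, ]
  cage_atoms <- data.frame(chain = "A", resno = seq_len(nrow(cage)) + 10,
                           elety = "X", element = "C", cage)
  buried <- fretmod:::new_atomic_model(rbind(lone$atoms, cage_atoms))
  expect_error(sample_dye_centers(buried, 1, "A",
                                  dye_params("cy3", L = 1.2, seed = 4)),
               "buried")
})

test_that("effective centers are midpoints mirrored by the symmetry", {
  cad <- fix_cad()
  ec <- cad$eff_centers
  a431 <- fretmod:::eff_center(cad, 431, "A")
  b431 <- fretmod:::eff_center(cad, 431, "B")
  expect_equal(as.numeric(cad$transform$R %*% a431 + cad$transform$t),
               b431, tolerance = 1e-12)
  # midpoint arithmetic
  s3 <- sample_dye_centers(cad, 431, "A", dye_params("cy3", seed = 11))
  s5 <- sample_dye_centers(cad, 431, "A", dye_params("cy5", seed = 12))
  expect_equal((s3$mean + s5$mean) / 2, a431, tolerance = 1e-9)
  # effective center stays within the dye length of the backbone
  ca <- as.numeric(fretmod:::coords(cad, "A", 431))
  expect_lt(sqrt(sum((a431 - ca)^2)), 1.5)
})

test_that("PDB round trip preserves coordinates in nm", {
  m <- toy_dimer(0)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(fretmod:::coords(back, "A"), fretmod:::coords(m, "A"),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("apex optimization recovers planted rotations from constraints", {
  cad <- fix_cad()
  pivot <- as.numeric(fretmod:::coords(cad, "A", 379))
  tip <- as.numeric(fretmod:::coords(cad, "A", 391))
  d0 <- (tip - pivot); d0 <- d0 / sqrt(sum(d0^2))
  make_cons <- function(model) {
    get <- function(r, sub) fretmod:::eff_center(model, r, sub)
    pairs <- data.frame(a = c(388, 389, 399, 400, 401, 431),
                        b = c(388, 389, 399, 400, 401, 389),
                        sb = c("B", "B", "B", "B", "B", "A"),
                        cls = c(rep("cad_cad_inter", 5), "intra_subunit"))
    E <- vapply(seq_len(nrow(pairs)), function(i) {
      d <- sqrt(sum((get(pairs$a[i], "A") - get(pairs$b[i], pairs$sb[i]))^2))
      distance_to_fret(d)
    }, 1)
    constraint_table(pairs$a, "A", pairs$b, pairs$sb, pairs$cls,
                     pmin(pmax(E, 1e-3), 1 - 1e-3))
  }
  # constraints from the unrotated model itself: identity recovered
  res0 <- optimize_apex(cad, make_cons(cad))
  expect_lt(res0$rotation_angle, 3)
  expect_lt(res0$objective, 1e-6)
  # plant a 30-degree apex rotation and recover it
  e1 <- c(1, 0, 0); e1 <- e1 - sum(e1 * d0) * d0; e1 <- e1 / sqrt(sum(e1^2))
  dn <- cos(pi / 6) * d0 + sin(pi / 6) * e1
  R <- fretmod:::rotation_between(d0, dn)
  rot <- cad
  ec <- cad$eff_centers
  eca <- as.matrix(ec[ec$chain == "A", c("x", "y", "z")])
  resno <- ec$resno[ec$chain == "A"]
  w <- ifelse(resno >= 379 & resno <= 391, 1,
              ifelse(resno >= 392 & resno <= 407,
                     (407 - resno) / (407 - 391), 0))
  rr <- sweep(sweep(eca, 2, pivot) %*% t(R), 2, pivot, "+")
  moved <- eca + (rr - eca) * w
  rot$eff_centers[ec$chain == "A", c("x", "y", "z")] <- moved
  rot$eff_centers[ec$chain == "B", c("x", "y", "z")] <-
    fretmod:::apply_rigid(moved, cad$transform)
  res <- optimize_apex(cad, make_cons(rot))
  expect_lt(abs(res$rotation_angle - 30), 5)
  expect_lt(max(abs(res$residuals)), 0.05)
  expect_true(res$satisfied)
  # asymmetric input is rejected
  nosym <- cad
  nosym$transform <- NULL
  expect_error(optimize_apex(nosym, make_cons(cad)), "symmetrize_dimer")
})
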