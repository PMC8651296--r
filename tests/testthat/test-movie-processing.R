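test_that("spot detection applies the strict 5-px-diameter maximum rule", {
  img <- matrix(0, 40, 40)
  expect_equal(nrow(detect_spots(img, 1)), 0)        # flat image
  # one Gaussian spot at (10, 10) [x = col, y = row]
  for (dx in -3:3) for (dy in -3:3) {
    img[10 + dy, 10 + dx] <- 100 * exp(-(dx^2 + dy^2) / 2)
  }
  sp <- detect_spots(img, 5)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$x, sp$y), c(10, 10))
  # two spots 2 px apart: only the brighter survives the disk rule
  img2 <- matrix(0, 40, 40)
  img2[20, 20] <- 100
  img2[20, 22] <- 80
  sp2 <- detect_spots(img2, 5)
  expect_equal(nrow(sp2), 1)
  expect_equal(c(sp2$x, sp2$y), c(20, 20))
  # exact ties break to the lexicographically lowest (row, col)
  img3 <- matrix(0, 40, 40)
  img3[15, 15] <- 50
  img3[15, 16] <- 50
  sp3 <- detect_spots(img3, 5)
  expect_equal(nrow(sp3), 1)
  expect_equal(c(sp3$x, sp3$y), c(15, 15))
  # shift invariance: constant offset with shifted threshold
  expect_equal(detect_spots(img + 17, 5 + 17)[, c("x", "y")],
               sp[, c("x", "y")], ignore_attr = TRUE)
})

test_that("registration recovers planted transforms", {
  # identical images give the identity transform
  bp0 <- render_bead_pair(10, registration_map(), seed = 2)
  reg0 <- estimate_registration(bp0$donor, bp0$donor)
  expect_equal(reg0$A, diag(2), tolerance = 1e-6)
  expect_equal(reg0$t, c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(reg0$rms, 1e-6)
  # planted pure translation (2.0, -1.5) px
  mis <- registration_map(diag(2), c(2, -1.5))
  bp <- render_bead_pair(12, mis, seed = 3)
  reg <- estimate_registration(bp$donor, bp$acceptor)
  expect_lt(max(abs(reg$t - c(2, -1.5))), 0.1)
  # planted 1-degree rotation + translation
  th <- pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  mis2 <- registration_map(R, c(2, -1.5))
  bp2 <- render_bead_pair(12, mis2, seed = 4)
  reg2 <- estimate_registration(bp2$donor, bp2$acceptor)
  expect_lt(max(abs(reg2$A - R)), 1e-2)
  expect_lt(max(abs(reg2$t - c(2, -1.5))), 0.5)
  expect_error(estimate_registration(matrix(0, 32, 32), matrix(0, 32, 32)),
               "3 matched")
})

test_that("mutual nearest-neighbor matching discards unpaired donors", {
  reg <- registration_map()
  d <- data.frame(x = c(10, 20, 30), y = c(10, 20, 30), intensity = 1)
  a <- data.frame(x = c(10.3, 19.8), y = c(9.9, 20.2), intensity = 1)
  m <- match_spots(d, a, reg)
  expect_equal(nrow(m), 2)               # the donor at (30,30) is discarded
  expect_false(30 %in% m$xd)
  # two donors nearest to one acceptor: only the closer is matched
  d2 <- data.frame(x = c(10, 11.5), y = c(10, 10), intensity = 1)
  a2 <- data.frame(x = 10.2, y = 10, intensity = 1)
  m2 <- match_spots(d2, a2, reg)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$xd, 10)
  # beyond the gate nothing matches
  expect_equal(nrow(match_spots(d2, data.frame(x = 40, y = 40,
                                               intensity = 1), reg)), 0)
})

test_that("movie rendering conserves intensity and extraction inverts it", {
  cfg <- sim_config(n_molecules = 1, n_frames = 12, state_means = 0.5,
                    rate_matrix = matrix(0, 1, 1), background_level = 0,
                    psf_sigma = 0.7, acceptor_bleach_rate = 0,
                    donor_bleach_rate = 0, leakage = 0, seed = 8)
  truth <- simulate_state_paths(cfg)
  mv <- render_movie(truth, noise = FALSE)
  sim <- render_trace_set(truth, noise = FALSE)
  # frame sums in the donor half equal the trace within PSF truncation
  dsum <- apply(mv$frames[, 1:mv$w, ], 3, sum)
  expect_equal(dsum, sim$molecules[[1]]$donor, tolerance = 1e-3)
  # identity misalignment: coincident coordinates across halves
  pos <- truth$molecules[[1]]$pos
  tr <- extract_traces(mv, data.frame(xd = pos["x"], yd = pos["y"],
                                      xa = pos["x"], ya = pos["y"]),
                       aperture = 7)
  expect_equal(tr[[1]]$donor, sim$molecules[[1]]$donor, tolerance = 1e-3)
  # zero-intensity movie gives all-zero traces
  mv0 <- mv
  mv0$frames[] <- 0
  tr0 <- extract_traces(mv0, data.frame(xd = 20, yd = 20, xa = 20, ya = 20))
  expect_true(all(tr0[[1]]$donor == 0) && all(tr0[[1]]$acceptor == 0))
})

test_that("background correction removes constant and gradient fields", {
  cfg <- sim_config(n_molecules = 2, n_frames = 10, state_means = 0.5,
                    rate_matrix = matrix(0, 1, 1), background_level = 12,
                    background_gradient = 0.4, read_noise_sd = 0,
                    total_intensity = 1e-9, acceptor_bleach_rate = 0,
                    donor_bleach_rate = 0, leakage = 0, seed = 9)
  truth <- simulate_state_paths(cfg)
  mv <- render_movie(truth, noise = FALSE)   # zero-signal molecules
  pos <- truth$molecules[[1]]$pos
  pairs <- data.frame(xd = pos["x"], yd = pos["y"], xa = pos["x"],
                      ya = pos["y"])
  raw <- extract_traces(mv, pairs)
  cor_ <- correct_background(raw, mv)
  # raw aperture sum carries ~25 x local background; corrected ~ 0
  expect_gt(mean(raw[[1]]$donor), 25 * 10)
  expect_lt(max(abs(cor_[[1]]$donor)), 25 * 0.45)
  # with read noise, residual bias stays below the read noise SD
  cfg2 <- sim_config(n_molecules = 1, n_frames = 20, state_means = 0.5,
                     rate_matrix = matrix(0, 1, 1), background_level = 20,
                     background_gradient = 0.3, read_noise_sd = 1.5,
                     total_intensity = 1e-9, acceptor_bleach_rate = 0,
                     donor_bleach_rate = 0, leakage = 0, seed = 10)
  truth2 <- simulate_state_paths(cfg2)
  mv2 <- render_movie(truth2)
  pos2 <- truth2$molecules[[1]]$pos
  tr2 <- correct_background(extract_traces(mv2, data.frame(
    xd = pos2["x"], yd = pos2["y"], xa = pos2["x"], ya = pos2["y"])), mv2)
  expect_lt(abs(mean(tr2[[1]]$donor)) / 25, cfg2$read_noise_sd)
})

test_that("the end-to-end movie pipeline meets recall and accuracy targets", {
  mis <- registration_map(diag(2), c(1.4, -0.8))
  cfg <- sim_config(n_molecules = 15, n_frames = 40, total_intensity = 800,
                    background_level = 20, background_gradient = 0.1,
                    frame_size = c(96, 96), psf_sigma = 1.0, seed = 12)
  truth <- simulate_state_paths(cfg)
  mv <- render_movie(truth, mis)
  bp <- render_bead_pair(12, mis, frame_size = c(96, 96), seed = 13)
  reg <- estimate_registration(bp$donor, bp$acceptor)
  di <- flatten_background(detection_image(mv, "donor"))
  ai <- flatten_background(detection_image(mv, "acceptor"))
  sd_ <- detect_spots(di, 5 * mad(di))
  sa <- detect_spots(ai, 5 * mad(ai))
  pairs <- match_spots(sd_, sa, reg)
  truth_pos <- t(vapply(truth$molecules, function(m) m$pos, numeric(2)))
  # eligible molecules: neither dye bleached within the detection window
  elig <- vapply(truth$molecules, function(m) {
    m$acceptor_bleach_frame > 10
  }, TRUE)
  found <- vapply(which(elig), function(i) {
    any((pairs$xd - truth_pos[i, 1])^2 + (pairs$yd - truth_pos[i, 2])^2 < 4)
  }, TRUE)
  expect_gte(mean(found), 0.95)                     # recall
  false_pos <- sum(vapply(seq_len(nrow(pairs)), function(j) {
    min((pairs$xd[j] - truth_pos[, 1])^2 +
          (pairs$yd[j] - truth_pos[, 2])^2) > 4
  }, TRUE))
  expect_lte(false_pos / max(nrow(pairs), 1), 0.02) # false positives
})

test_that("movies survive a 16-bit TIFF round trip", {
  cfg <- sim_config(n_molecules = 3, n_frames = 5, background_level = 10,
                    seed = 14)
  mv <- render_movie(simulate_state_paths(cfg))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_equal(dim(back$frames), dim(mv$frames))
  expect_lt(max(abs(back$frames - pmax(pmin(mv$frames, 65535), 0))), 0.51)
})
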